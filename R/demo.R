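# Built-in example analytes used by the documentation, the demonstration
# studies and the test-suite: five synthetic substances with distinct
# Lorentzian fingerprints in the 1000-1400 cm^-1 region.

#' Built-in example substances
#'
#' Five synthetic analytes with one to three Lorentzian lines each in the
#' 1050--1360 cm^-1 fingerprint region, on the absorption-strength scale of
#' weak aqueous solutes (fractional magnitude depth `concentration *
#' strength` per line). They are used throughout the package documentation
#' and tests as a reproducible stand-in for a measured substance library.
#'
#' @return Named list of data frames, each with columns `center` (cm^-1),
#'   `fwhm` (cm^-1) and `strength` (fractional depth per concentration
#'   unit), suitable for [oscillator_model()].
#' @examples
#' names(demo_substances())
#' oscillator_model(demo_substances()$bravo, concentration = 100)
#' @export
demo_substances <- function() {
  list(
    alpha = data.frame(center = c(1080, 1210), fwhm = c(22, 28),
                       strength = c(2.0e-5, 1.5e-5)),
    bravo = data.frame(center = c(1139, 1308), fwhm = c(25, 30),
                       strength = c(2.0e-5, 1.6e-5)),
    charlie = data.frame(center = c(1060, 1185, 1330), fwhm = c(20, 26, 24),
                         strength = c(1.4e-5, 1.8e-5, 1.2e-5)),
    delta = data.frame(center = 1250, fwhm = 35, strength = 2.5e-5),
    echo = data.frame(center = c(1105, 1355), fwhm = c(24, 22),
                      strength = c(1.7e-5, 1.9e-5))
  )
}
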