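# S3 containers for traces, spectra and simulator specifications.

#' Uniformly sampled EOS time trace
#'
#' A real-valued electro-optic sampling signal on a uniform delay grid.
#'
#' @param t Numeric vector of delay times in femtoseconds; must be a uniform,
#'   strictly ascending grid (spacing constant to 1 part in 1e9).
#' @param values Numeric vector of real amplitudes (arbitrary units), same
#'   length as `t`, all finite.
#' @param meta Free-form named list of provenance (e.g. `role`, `day`,
#'   `seed`, `concentration`).
#' @return An object of class `"time_trace"` with fields `t`, `values`,
#'   `meta`.
#' @examples
#' tr <- time_trace(t = seq(0, 10, by = 2), values = rnorm(6))
#' trace_dt(tr)
#' @export
time_trace <- function(t, values, meta = list()) {
  t <- as.numeric(t)
  values <- as.numeric(values)
  if (length(t) < 2L) stop("time grid must have at least 2 samples")
  if (length(values) != length(t)) stop("t and values must have equal length")
  if (!all(is.finite(t))) stop("time grid contains non-finite values")
  if (!all(is.finite(values))) stop("trace values contain non-finite values")
  check_uniform(t, what = "time grid")
  structure(list(t = t, values = values, meta = meta), class = "time_trace")
}

#' @rdname time_trace
#' @param trace A `time_trace`.
#' @export
trace_dt <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  (trace$t[length(trace$t)] - trace$t[1L]) / (length(trace$t) - 1L)
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf(
    "<time_trace> %d samples, dt = %.6g fs, t in [%.6g, %.6g] fs\n",
    length(x$t), trace_dt(x), x$t[1L], x$t[length(x$t)]
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Complex spectrum on a uniform wavenumber grid
#'
#' @param nu Numeric vector of wavenumbers in cm^-1; uniform, strictly
#'   ascending.
#' @param values Complex (or numeric, for magnitude spectra) amplitudes, same
#'   length as `nu`, all finite.
#' @param meta Free-form named list (FFT bookkeeping, filter settings, ...).
#' @return Object of class `"complex_spectrum"` with fields `nu`, `values`,
#'   `meta`.
#' @export
complex_spectrum <- function(nu, values, meta = list()) {
  nu <- as.numeric(nu)
  if (length(nu) < 2L) stop("wavenumber grid must have at least 2 samples")
  if (length(values) != length(nu)) stop("nu and values must have equal length")
  if (!all(is.finite(nu))) stop("wavenumber grid contains non-finite values")
  if (anyNA(values) || !all(is.finite(Re(values)) & is.finite(Im(values)))) {
    stop("spectrum values contain non-finite values")
  }
  check_uniform(nu, what = "wavenumber grid")
  structure(list(nu = nu, values = values, meta = meta),
            class = "complex_spectrum")
}

#' @rdname complex_spectrum
#' @param spec A `complex_spectrum`.
#' @export
spectrum_dnu <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  (spec$nu[length(spec$nu)] - spec$nu[1L]) / (length(spec$nu) - 1L)
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat(sprintf(
    "<complex_spectrum> %d points, nu in [%.6g, %.6g] cm^-1 (d_nu = %.6g), %s\n",
    length(x$nu), x$nu[1L], x$nu[length(x$nu)], spectrum_dnu(x),
    if (is.complex(x$values)) "complex" else "real"
  ))
  invisible(x)
}

#' Referenced sample response H(w)
#'
#' The excitation-independent linear sample response obtained by referencing
#' a sample trace to a solvent trace, together with its region of interest
#' and the removed offset (baseline) component. Outside the tapered ROI the
#' stored spectrum equals the offset, so that subtracting the offset leaves a
#' compactly supported band.
#'
#' @param spectrum A [complex_spectrum()] holding H(w) on its full grid.
#' @param roi Numeric length-2, `c(nu_lo, nu_hi)` in cm^-1, inside the grid.
#' @param offset Complex scalar: the baseline component of H (close to 1 for
#'   weak responses in transmission geometry).
#' @return Object of class `"sample_response"`.
#' @export
sample_response <- function(spectrum, roi, offset) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  roi <- as.numeric(roi)
  if (length(roi) != 2L || roi[1L] >= roi[2L]) {
    stop("roi must be c(nu_lo, nu_hi) with nu_lo < nu_hi")
  }
  rng <- range(spectrum$nu)
  if (roi[1L] < rng[1L] - 1e-9 || roi[2L] > rng[2L] + 1e-9) {
    stop("roi must lie inside the spectrum's wavenumber grid")
  }
  if (length(offset) != 1L || !is.finite(Re(offset)) || !is.finite(Im(offset))) {
    stop("offset must be a finite scalar")
  }
  structure(list(spectrum = spectrum, roi = roi, offset = as.complex(offset)),
            class = "sample_response")
}

#' @export
print.sample_response <- function(x, ...) {
  cat(sprintf(
    "<sample_response> ROI [%.6g, %.6g] cm^-1, offset = %.4g%+.4gi, grid %d pts\n",
    x$roi[1L], x$roi[2L], Re(x$offset), Im(x$offset), length(x$spectrum$nu)
  ))
  invisible(x)
}

#' Excitation-pulse specification
#'
#' Describes a few-cycle mid-IR excitation pulse by its Gaussian magnitude
#' spectrum and polynomial spectral phase, plus the (optional) Gaussian
#' low-pass instrument response of the EOS detection.
#'
#' @param center_wavenumber Pulse centre, cm^-1 (> 0).
#' @param bandwidth_fwhm FWHM of the magnitude spectrum, cm^-1 (> 0).
#' @param gdd Group-delay dispersion, fs^2.
#' @param tod Third-order dispersion, fs^3.
#' @param amplitude Peak envelope amplitude, arbitrary units (> 0).
#' @param irf_bandwidth Half-transmission wavenumber of the Gaussian EOS
#'   low-pass, cm^-1, or `"flat"` (the default) for an ideal flat response.
#' @return Object of class `"pulse_spec"`.
#' @export
pulse_spec <- function(center_wavenumber, bandwidth_fwhm, gdd = 0, tod = 0,
                       amplitude = 1, irf_bandwidth = "flat") {
  if (center_wavenumber <= 0) stop("center_wavenumber must be > 0")
  if (bandwidth_fwhm <= 0) stop("bandwidth_fwhm must be > 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (!identical(irf_bandwidth, "flat")) {
    irf_bandwidth <- as.numeric(irf_bandwidth)
    if (!is.finite(irf_bandwidth) || irf_bandwidth <= 0) {
      stop("irf_bandwidth must be \"flat\" or a positive wavenumber")
    }
  }
  structure(list(center_wavenumber = center_wavenumber,
                 bandwidth_fwhm = bandwidth_fwhm,
                 gdd = gdd, tod = tod, amplitude = amplitude,
                 irf_bandwidth = irf_bandwidth),
            class = "pulse_spec")
}

#' Ground-truth analyte model
#'
#' A set of Lorentzian vibrational lines in the weak-response (linear
#' Beer-Lambert) regime, an overall concentration, and an optional
#' cuvette-window etalon echo (first reflection only).
#'
#' @param lines Data frame (or list coercible to one) with columns `center`
#'   (cm^-1), `fwhm` (cm^-1) and `strength` (fractional magnitude depth per
#'   unit concentration). May have zero rows.
#' @param concentration Scalar concentration (e.g. ug/mL); `strength *
#'   concentration` is the magnitude depth of each line.
#' @param echo Optional list `list(delay = <fs>, relative_amplitude = <r>)`
#'   with `|r| < 1`, or `NULL`.
#' @return Object of class `"oscillator_model"`.
#' @export
oscillator_model <- function(lines = NULL, concentration = 0, echo = NULL) {
  if (is.null(lines)) {
    lines <- data.frame(center = numeric(), fwhm = numeric(),
                        strength = numeric())
  }
  lines <- as.data.frame(lines)
  need <- c("center", "fwhm", "strength")
  if (!all(need %in% names(lines))) {
    stop("lines must have columns center, fwhm, strength")
  }
  if (nrow(lines) > 0 && (any(lines$center <= 0) || any(lines$fwhm <= 0))) {
    stop("all line centers and fwhm must be > 0")
  }
  if (concentration < 0) stop("concentration must be >= 0")
  if (!is.null(echo)) {
    if (!all(c("delay", "relative_amplitude") %in% names(echo))) {
      stop("echo must have fields delay and relative_amplitude")
    }
    if (abs(echo$relative_amplitude) >= 1) {
      stop("|echo relative_amplitude| must be < 1")
    }
  }
  structure(list(lines = lines[need], concentration = concentration,
                 echo = echo),
            class = "oscillator_model")
}

#' Noise specification for synthetic EOS traces
#'
#' Multiplicative noise scales with the analytic-signal envelope of the clean
#' trace and is band-limited; additive noise is a white detection floor.
#'
#' @param mult_rms Fractional RMS of the multiplicative noise process (>= 0).
#' @param mult_bandwidth Band limit of the multiplicative noise, cm^-1
#'   (Gaussian low-pass half-transmission point).
#' @param add_rms RMS of the additive floor, in trace amplitude units (>= 0).
#' @param seed Integer RNG seed; the same spec always produces the same
#'   noise.
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(mult_rms = 0, mult_bandwidth = 2000, add_rms = 0,
                       seed = 1L) {
  if (mult_rms < 0) stop("mult_rms must be >= 0")
  if (add_rms < 0) stop("add_rms must be >= 0")
  if (mult_bandwidth <= 0) stop("mult_bandwidth must be > 0")
  structure(list(mult_rms = mult_rms, mult_bandwidth = mult_bandwidth,
                 add_rms = add_rms, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Multi-day measurement-campaign specification
#'
#' Emulates a long measurement campaign in which the excitation pulse drifts
#' from day to day (instrument re-alignment, component swaps) while each
#' day's reference and sample traces share one pulse.
#'
#' @param n_days Number of measurement days (>= 1).
#' @param per_day_pulse_jitter Fractional 1-sigma day-to-day drift applied to
#'   the pulse amplitude, centre wavenumber and bandwidth (and, scaled by
#'   500 fs^2, to the GDD).
#' @param replicates_per_day Replicate sample measurements per day and
#'   concentration (>= 1).
#' @param concentrations Numeric vector of sample concentrations to measure
#'   each day; `0` yields pure-solvent sample traces (used for noise-level
#'   estimation).
#' @param base_seed Integer; all randomness is derived deterministically from
#'   it.
#' @return Object of class `"campaign_spec"`.
#' @export
campaign_spec <- function(n_days = 1L, per_day_pulse_jitter = 0.05,
                          replicates_per_day = 1L, concentrations = 0,
                          base_seed = 1L) {
  if (n_days < 1L) stop("n_days must be >= 1")
  if (per_day_pulse_jitter < 0) stop("per_day_pulse_jitter must be >= 0")
  if (replicates_per_day < 1L) stop("replicates_per_day must be >= 1")
  structure(list(n_days = as.integer(n_days),
                 per_day_pulse_jitter = per_day_pulse_jitter,
                 replicates_per_day = as.integer(replicates_per_day),
                 concentrations = as.numeric(concentrations),
                 base_seed = as.integer(base_seed)),
            class = "campaign_spec")
}

#' Named spectral library on a common wavenumber grid
#'
#' @param entries Named list of [complex_spectrum()] objects (real magnitude
#'   spectra) sharing one grid, or a named list of numeric vectors combined
#'   with `grid`.
#' @param grid Optional numeric wavenumber grid when `entries` are plain
#'   vectors.
#' @return Object of class `"spectral_library"` with fields `grid` and
#'   `entries` (named list of numeric vectors).
#' @export
spectral_library <- function(entries, grid = NULL) {
  if (length(entries) == 0L) stop("library must contain at least one entry")
  nm <- names(entries)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("library entries must have unique non-empty names")
  }
  if (inherits(entries[[1L]], "complex_spectrum")) {
    grid <- entries[[1L]]$nu
    vals <- lapply(entries, function(e) {
      if (!isTRUE(all.equal(e$nu, grid, tolerance = 1e-9))) {
        stop("all library entries must share one wavenumber grid")
      }
      as.numeric(Re(e$values))
    })
  } else {
    if (is.null(grid)) stop("grid must be given for plain-vector entries")
    vals <- lapply(entries, function(v) {
      if (length(v) != length(grid)) {
        stop("all library entries must share one wavenumber grid")
      }
      as.numeric(v)
    })
  }
  structure(list(grid = as.numeric(grid), entries = vals),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d entries on %d-point grid [%.5g, %.5g] cm^-1\n",
              length(x$entries), length(x$grid), min(x$grid), max(x$grid)))
  cat("  ", paste(names(x$entries), collapse = ", "), "\n")
  invisible(x)
}

# grid must be uniform to within 1 part in 1e9 of its mean spacing
check_uniform <- function(x, what = "grid") {
  d <- diff(x)
  if (any(d <= 0)) stop(sprintf("%s must be strictly ascending", what))
  dm <- mean(d)
  if (max(abs(d - dm)) > 1e-9 * abs(dm)) {
    stop(sprintf("%s is not uniform", what))
  }
  invisible(TRUE)
}
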