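# FFT conventions, used everywhere in the package:
#
#   forward:  X(nu_j) = dt * sum_k x(t_k) * exp(-2*pi*i * c * nu_j * t_k)
#   inverse:  x(t_k)  = c*d_nu * sum_j X(nu_j) * exp(+2*pi*i * c * nu_j * t_k)
#
# with t_k = t0 + k*dt (fs), nu_j = j*d_nu (cm^-1), d_nu = 1/(c*n*dt) and
# c = 2.99792458e-5 cm/fs. A real trace of n samples maps to a one-sided
# spectrum of floor(n/2)+1 points (DC..Nyquist); the negative-frequency half
# is the complex conjugate and is reconstructed on inversion. Under this sign
# convention a delay by +tau multiplies the spectrum by exp(-2*pi*i*c*nu*tau),
# and a causal response (support at t >= 0) has its poles in the upper
# half-plane of complex nu.

#' One-sided spectrum of a real EOS trace
#'
#' Computes the continuous-normalisation discrete Fourier transform of a
#' [time_trace()] and returns the non-negative-frequency half on the
#' conjugate wavenumber grid `nu_j = j / (c * n * dt)`.
#'
#' @param trace A [time_trace()].
#' @return A [complex_spectrum()]; `meta` carries the bookkeeping (`n`,
#'   `dt`, `t0`) required by [ifft_trace()] for a lossless round trip.
#' @seealso [ifft_trace()], [conjugate_grid()]
#' @examples
#' tr <- synth_pulse(pulse_spec(1200, 400), n = 1024, dt = 2)
#' sp <- fft_spectrum(tr)
#' sp$nu[which.max(Mod(sp$values))]  # ~1200 cm^-1
#' @export
fft_spectrum <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  n <- length(trace$t)
  dt <- trace_dt(trace)
  t0 <- trace$t[1L]
  dnu <- 1 / (C_CM_FS * n * dt)
  m <- n %/% 2L + 1L
  nu <- (seq_len(m) - 1L) * dnu
  # absolute-time phase reference: include the grid-origin phase factor
  vals <- dt * stats::fft(trace$values)[seq_len(m)] *
    exp(-2i * pi * C_CM_FS * nu * t0)
  complex_spectrum(nu, vals, meta = list(n = n, dt = dt, t0 = t0))
}

#' Inverse transform of a one-sided spectrum back to the time domain
#'
#' Inverts [fft_spectrum()]: the negative-frequency half is reconstructed by
#' Hermitian symmetry and the original time grid is restored from the
#' spectrum's metadata. The returned values are complex; for a spectrum that
#' came from a real trace the imaginary part is at rounding level.
#'
#' @param spec A [complex_spectrum()] produced by [fft_spectrum()] (its
#'   `meta` must contain `n`, `dt`, `t0`).
#' @return List with fields `t` (fs) and `values` (complex).
#' @export
ifft_trace <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  mt <- spec$meta
  if (is.null(mt$n) || is.null(mt$dt) || is.null(mt$t0)) {
    stop("spectrum lacks the time-grid metadata written by fft_spectrum()")
  }
  n <- mt$n; dt <- mt$dt; t0 <- mt$t0
  m <- length(spec$nu)
  if (m != n %/% 2L + 1L) stop("spectrum length inconsistent with meta$n")
  vals <- spec$values * exp(2i * pi * C_CM_FS * spec$nu * t0)
  full <- hermitian_full(vals, n)
  x <- stats::fft(full, inverse = TRUE) / (n * dt)
  list(t = t0 + (seq_len(n) - 1L) * dt, values = x)
}

#' Conjugate wavenumber grid of a time trace
#'
#' @param trace A [time_trace()].
#' @return Numeric vector: the one-sided wavenumber grid (cm^-1) on which
#'   [fft_spectrum()] of this trace is defined.
#' @export
conjugate_grid <- function(trace) {
  n <- length(trace$t)
  dnu <- 1 / (C_CM_FS * n * trace_dt(trace))
  (seq_len(n %/% 2L + 1L) - 1L) * dnu
}

#' Analytic-signal envelope of a trace
#'
#' Magnitude of the analytic signal (Hilbert-transform construction): the
#' negative-frequency half of the spectrum is zeroed, the positive half
#' doubled, and the modulus of the inverse transform taken.
#'
#' @param trace A [time_trace()] (or a plain numeric vector).
#' @return Numeric vector of envelope amplitudes, same length as the trace.
#' @export
envelope <- function(trace) {
  x <- if (inherits(trace, "time_trace")) trace$values else as.numeric(trace)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n %/% 2L + 1L] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Hermitian extension of a one-sided spectrum (length m = n %/% 2 + 1) to the
# full n-point DFT array. DC (and Nyquist, for even n) are forced real.
hermitian_full <- function(onesided, n) {
  m <- length(onesided)
  stopifnot(m == n %/% 2L + 1L)
  full <- complex(n)
  full[seq_len(m)] <- onesided
  full[1L] <- Re(full[1L]) + 0i
  if (n %% 2L == 0L) {
    full[m] <- Re(full[m]) + 0i
    if (m > 2L) full[n:(m + 1L)] <- Conj(onesided[2L:(m - 1L)])
  } else {
    full[n:(m + 1L)] <- Conj(onesided[2L:m])
  }
  full
}

# run code with a private, restored RNG state (deterministic given seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
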