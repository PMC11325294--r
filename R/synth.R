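# Synthetic FRS measurements: few-cycle excitation pulses, weak Lorentzian
# sample responses, envelope-following multiplicative noise + additive floor,
# and multi-day campaigns with pulse drift.

#' Synthesise a few-cycle excitation pulse trace
#'
#' Builds a waveform-stable real EOS trace whose magnitude spectrum is
#' Gaussian with the requested centre and FWHM and whose spectral phase is
#' the polynomial `gdd/2 * w^2 + tod/6 * w^3` (w = angular detuning from the
#' centre, rad/fs). If the pulse spec carries a finite `irf_bandwidth`, a
#' Gaussian low-pass (amplitude 1/2 at that wavenumber) models the EOS
#' instrument response. The grid is centred so that the peak of the
#' analytic-signal envelope sits exactly on the `t = 0` sample; all filter
#' cutoffs downstream are measured from this origin.
#'
#' @param spec A [pulse_spec()].
#' @param n Number of samples (>= 16; powers of two recommended).
#' @param dt Sample spacing in fs (> 0). The pulse spectrum must fit below
#'   the Nyquist wavenumber `1/(2*c*dt)`.
#' @return A [time_trace()] with `t = 0` at the envelope peak and peak
#'   envelope amplitude `spec$amplitude`.
#' @examples
#' tr <- synth_pulse(pulse_spec(1200, 400), n = 2048, dt = 2)
#' tr$t[which.max(envelope(tr))]  # 0
#' @export
synth_pulse <- function(spec, n, dt) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (n < 16L) stop("n must be >= 16")
  if (dt <= 0) stop("dt must be > 0")
  n <- as.integer(n)
  nyq <- 1 / (2 * C_CM_FS * dt)
  edge <- spec$center_wavenumber + 1.5 * spec$bandwidth_fwhm
  if (edge > nyq) {
    stop(sprintf(
      "pulse spectrum extends to %.1f cm^-1, beyond the Nyquist limit %.1f cm^-1",
      edge, nyq
    ))
  }
  m <- n %/% 2L + 1L
  dnu <- 1 / (C_CM_FS * n * dt)
  nu <- (seq_len(m) - 1L) * dnu
  amp <- exp(-4 * log(2) * ((nu - spec$center_wavenumber) / spec$bandwidth_fwhm)^2)
  if (!identical(spec$irf_bandwidth, "flat")) {
    amp <- amp * exp(-log(2) * (nu / spec$irf_bandwidth)^2)
  }
  w <- 2 * pi * C_CM_FS * (nu - spec$center_wavenumber)  # rad/fs
  phase <- spec$gdd / 2 * w^2 + spec$tod / 6 * w^3
  onesided <- amp * exp(1i * phase)
  x <- Re(stats::fft(hermitian_full(onesided, n), inverse = TRUE)) / n
  # centre the envelope peak on the t = 0 grid sample
  i0 <- n %/% 2L + 1L
  env <- envelope(x)
  ipk <- which.max(env)
  x <- roll(x, i0 - ipk)
  env <- roll(env, i0 - ipk)
  x <- x * (spec$amplitude / max(env))
  t <- (seq_len(n) - i0) * dt
  time_trace(t, x, meta = list(role = "pulse", pulse = unclass(spec)))
}

#' Referenced transfer function of an analyte model
#'
#' Evaluates the weak-response sample transfer function on a wavenumber
#' grid:
#' \deqn{H(\nu) = \left[1 - c \sum_k s_k L_k(\nu)\right]
#'               \left[1 + a\, e^{-2\pi i c \nu \tau}\right]}
#' where each `L_k` is a causal complex Lorentzian whose real (absorptive)
#' part peaks at 1 at the line centre with FWHM `fwhm_k`, so the magnitude
#' depth of line k is `concentration * strength_k` to first order — exactly
#' linear in concentration when no echo is present. The optional second
#' factor is a single cuvette-window etalon echo of relative amplitude `a`
#' delayed by `tau` (fs), producing spectral fringes of period
#' `1/(c*tau)` cm^-1.
#'
#' @param model An [oscillator_model()].
#' @param grid Uniform ascending wavenumber grid, cm^-1.
#' @return A [complex_spectrum()] holding H on `grid`; identically 1 for an
#'   empty model.
#' @export
transfer_function <- function(model, grid) {
  stopifnot(inherits(model, "oscillator_model"))
  grid <- as.numeric(grid)
  check_uniform(grid, what = "wavenumber grid")
  H <- rep(1 + 0i, length(grid))
  if (nrow(model$lines) > 0) {
    acc <- complex(length(grid))
    for (k in seq_len(nrow(model$lines))) {
      g2 <- model$lines$fwhm[k] / 2
      d <- model$lines$center[k] - grid
      acc <- acc + model$lines$strength[k] * (g2^2 + 1i * g2 * d) / (d^2 + g2^2)
    }
    H <- H - model$concentration * acc
  }
  if (!is.null(model$echo)) {
    H <- H * (1 + model$echo$relative_amplitude *
                exp(-2i * pi * C_CM_FS * grid * model$echo$delay))
  }
  complex_spectrum(grid, H, meta = list(concentration = model$concentration))
}

#' Apply a transfer function to a reference trace
#'
#' Produces the sample trace whose spectrum is the reference spectrum times
#' H: the transfer function is interpolated (linearly, in real and imaginary
#' part) onto the trace's conjugate wavenumber grid, points outside the given
#' grid default to the neutral value 1, and Hermitian symmetry of the product
#' is enforced so the output is exactly real.
#'
#' @param ref Reference [time_trace()].
#' @param h A [complex_spectrum()] holding H on any wavenumber grid covering
#'   (or partially covering) the trace's band.
#' @return A [time_trace()] on the same grid as `ref`.
#' @export
apply_response <- function(ref, h) {
  stopifnot(inherits(ref, "time_trace"), inherits(h, "complex_spectrum"))
  if (anyNA(h$values) || !all(is.finite(Re(h$values)) & is.finite(Im(h$values)))) {
    stop("transfer function contains non-finite values")
  }
  n <- length(ref$t)
  grid <- conjugate_grid(ref)
  hre <- stats::approx(h$nu, Re(h$values), xout = grid, rule = 1)$y
  him <- stats::approx(h$nu, Im(h$values), xout = grid, rule = 1)$y
  hre[is.na(hre)] <- 1
  him[is.na(him)] <- 0
  Hfull <- hermitian_full(complex(real = hre, imaginary = him), n)
  Y <- stats::fft(ref$values) * Hfull
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  meta <- ref$meta
  meta$role <- "sample"
  time_trace(ref$t, y, meta = meta)
}

#' Add the FRS noise structure to a clean trace
#'
#' Models a noisy EOS measurement as
#' `S0(t) + eps_m(t) * env(S0)(t) + eps_a(t)`: the multiplicative term is
#' zero-mean band-limited Gaussian noise (Gaussian low-pass at
#' `mult_bandwidth`) scaled to RMS `mult_rms` and multiplied by the
#' analytic-signal envelope of the clean trace, so the excess noise power
#' follows the excitation envelope and is temporally confined to the pulse;
#' the additive term is white Gaussian with RMS `add_rms`, the
#' delay-independent detection floor. Deterministic given `noise$seed`.
#'
#' @param trace Clean [time_trace()].
#' @param noise A [noise_spec()].
#' @return A [time_trace()]; identical to the input when both RMS values are
#'   zero.
#' @export
add_noise <- function(trace, noise) {
  stopifnot(inherits(trace, "time_trace"), inherits(noise, "noise_spec"))
  n <- length(trace$t)
  draws <- with_seed(noise$seed, list(em = stats::rnorm(n),
                                      ea = stats::rnorm(n)))
  x <- trace$values
  if (noise$mult_rms > 0) {
    dnu <- 1 / (C_CM_FS * n * trace_dt(trace))
    j <- seq_len(n) - 1L
    nu2 <- ifelse(j <= n %/% 2L, j, j - n) * dnu
    g <- exp(-log(2) * (nu2 / noise$mult_bandwidth)^2)
    em <- Re(stats::fft(stats::fft(draws$em) * g, inverse = TRUE)) / n
    em <- em - mean(em)
    em <- em * (noise$mult_rms / stats::sd(em))
    x <- x + em * envelope(trace)
  }
  if (noise$add_rms > 0) x <- x + noise$add_rms * draws$ea
  meta <- trace$meta
  meta$noise_seed <- noise$seed
  time_trace(trace$t, x, meta = meta)
}

#' Simulate a multi-day measurement campaign
#'
#' Generates reference/sample EOS trace pairs over `spec$n_days` simulated
#' measurement days. Each day draws a perturbed excitation pulse (fractional
#' Gaussian jitter `per_day_pulse_jitter` on amplitude, centre and bandwidth;
#' the same fraction of 500 fs^2 on the GDD) which is shared by all of that
#' day's traces, emulating instrument drift between — but not within —
#' days. Every replicate of every concentration receives independent noise
#' with a seed derived arithmetically from `base_seed`, so campaigns are
#' bit-reproducible.
#'
#' @param spec A [campaign_spec()].
#' @param model An [oscillator_model()] supplying lines and echo; its
#'   `concentration` field is overridden by `spec$concentrations` (a
#'   concentration of 0 yields pure-solvent sample traces).
#' @param noise A [noise_spec()]; its `seed` field is ignored in favour of
#'   derived per-trace seeds.
#' @param pulse Base [pulse_spec()] before jitter.
#' @param n,dt Trace length and sampling interval (fs).
#' @return Object of class `"frs_campaign"`: a list with `$pairs` (one
#'   record per measurement: `day`, `replicate`, `concentration`,
#'   `pulse_spec`, `reference`, `sample`) and the generating specifications.
#' @export
make_campaign <- function(spec, model, noise,
                          pulse = pulse_spec(1200, 400),
                          n = 4096L, dt = 2) {
  stopifnot(inherits(spec, "campaign_spec"),
            inherits(model, "oscillator_model"),
            inherits(noise, "noise_spec"),
            inherits(pulse, "pulse_spec"))
  pairs <- list()
  for (d in seq_len(spec$n_days)) {
    z <- with_seed(spec$base_seed + 7919L * d, stats::rnorm(4))
    j <- spec$per_day_pulse_jitter
    dspec <- pulse_spec(
      center_wavenumber = pulse$center_wavenumber * (1 + j * z[1L]),
      bandwidth_fwhm = pulse$bandwidth_fwhm * (1 + j * z[2L]),
      gdd = pulse$gdd + j * 500 * z[3L],
      tod = pulse$tod,
      amplitude = pulse$amplitude * (1 + j * z[4L]),
      irf_bandwidth = pulse$irf_bandwidth
    )
    clean_ref <- synth_pulse(dspec, n = n, dt = dt)
    grid <- conjugate_grid(clean_ref)
    k <- 0L
    for (cc in spec$concentrations) {
      h <- transfer_function(
        oscillator_model(model$lines, concentration = cc, echo = model$echo),
        grid
      )
      clean_sam <- apply_response(clean_ref, h)
      for (r in seq_len(spec$replicates_per_day)) {
        k <- k + 1L
        sref <- spec$base_seed + 1000000L * d + 2L * (1000L * k)
        ssam <- sref + 1L
        ref <- add_noise(clean_ref, noise_spec(noise$mult_rms,
                                               noise$mult_bandwidth,
                                               noise$add_rms, seed = sref))
        sam <- add_noise(clean_sam, noise_spec(noise$mult_rms,
                                               noise$mult_bandwidth,
                                               noise$add_rms, seed = ssam))
        ref$meta <- c(ref$meta, list(role = "reference", day = d,
                                     replicate = r, concentration = cc))
        sam$meta <- c(sam$meta, list(role = "sample", day = d,
                                     replicate = r, concentration = cc))
        pairs[[length(pairs) + 1L]] <- list(
          day = d, replicate = r, concentration = cc,
          pulse_spec = dspec, reference = ref, sample = sam
        )
      }
    }
  }
  structure(list(pairs = pairs, spec = spec, model = model, noise = noise,
                 pulse = pulse, n = n, dt = dt),
            class = "frs_campaign")
}

#' @export
print.frs_campaign <- function(x, ...) {
  cat(sprintf(
    "<frs_campaign> %d days x %d replicates x %d concentrations (%d pairs)\n",
    x$spec$n_days, x$spec$replicates_per_day,
    length(x$spec$concentrations), length(x$pairs)
  ))
  invisible(x)
}

# circular shift by k samples (positive k moves content to larger indices)
roll <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) x else c(x[(n - k + 1L):n], x[1L:(n - k)])
}
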