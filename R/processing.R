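# The three referencing procedures: frequency-domain ratio, time-domain
# difference, and time-domain filtering (TDF) of the referenced response.

#' Frequency-window specification (region of interest with smooth edges)
#'
#' @param roi Numeric length-2 `c(nu_lo, nu_hi)`, cm^-1, `nu_lo < nu_hi`.
#' @param transition_width Width of the raised-cosine taper on each ROI
#'   edge, cm^-1 (> 0).
#' @return Object of class `"freq_window_spec"`.
#' @export
freq_window_spec <- function(roi, transition_width = 50) {
  roi <- as.numeric(roi)
  if (length(roi) != 2L || roi[1L] >= roi[2L]) {
    stop("roi must be c(nu_lo, nu_hi) with nu_lo < nu_hi")
  }
  if (transition_width <= 0) stop("transition_width must be > 0")
  structure(list(roi = roi, transition_width = transition_width),
            class = "freq_window_spec")
}

#' Time-filter specification
#'
#' @param kind One of `"heaviside"` (hard high-pass in time: 0 before the
#'   cutoff, 1 after), `"butterworth"` (smooth high-pass
#'   `1/(1+(cutoff/t)^(2*order))` for `t > 0`, 0 at `t <= 0`) or `"none"`.
#' @param cutoff Cutoff delay in fs (>= 0).
#' @param order Butterworth order (>= 1); ignored for other kinds.
#' @return Object of class `"time_filter_spec"`.
#' @export
time_filter_spec <- function(kind = c("heaviside", "butterworth", "none"),
                             cutoff = 0, order = 4L) {
  kind <- match.arg(kind)
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (kind == "butterworth" && order < 1L) stop("order must be >= 1")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order)),
            class = "time_filter_spec")
}

#' Evaluate time-filter weights on a delay grid
#'
#' @param filt A [time_filter_spec()].
#' @param t_grid Numeric vector of delays, fs.
#' @return Numeric weights in `[0, 1]`, one per delay sample.
#' @export
time_filter_weights <- function(filt, t_grid) {
  stopifnot(inherits(filt, "time_filter_spec"))
  t_grid <- as.numeric(t_grid)
  switch(filt$kind,
    none = rep(1, length(t_grid)),
    heaviside = as.numeric(t_grid >= filt$cutoff),
    butterworth = ifelse(t_grid <= 0, 0,
                         1 / (1 + (filt$cutoff / t_grid)^(2 * filt$order)))
  )
}

#' Referenced sample response by spectral division (standard approach)
#'
#' Computes `H(nu) = S_sam(nu) / S_ref(nu)` from a sample/reference trace
#' pair. Both traces are zero-padded to the next power of two before the
#' transforms. The division is only evaluated where the reference has usable
#' spectral power (`|S_ref| >= floor_frac * max|S_ref|`); elsewhere the
#' response is masked to the offset rather than divided. The offset is the
#' complex mean of H over the valid part of the ROI; ROI edges are tapered
#' with raised cosines of width `window$transition_width`, applied to
#' `H - offset`, so the stored spectrum equals the offset exactly outside
#' the tapered region of interest.
#'
#' @param sam,ref Sample and reference [time_trace()]s on identical grids.
#' @param window A [freq_window_spec()].
#' @param floor_frac Spectral-support floor, as a fraction of the reference
#'   spectral peak (default 1e-3).
#' @return A [sample_response()].
#' @export
standard_response <- function(sam, ref, window, floor_frac = 1e-3) {
  stopifnot(inherits(sam, "time_trace"), inherits(ref, "time_trace"),
            inherits(window, "freq_window_spec"))
  if (length(sam$t) != length(ref$t) ||
      max(abs(sam$t - ref$t)) > 1e-9 * trace_dt(ref)) {
    stop("sample and reference traces must share one time grid")
  }
  n <- length(ref$t)
  dt <- trace_dt(ref)
  n2 <- 2^ceiling(log2(n))
  xs <- c(sam$values, numeric(n2 - n))
  xr <- c(ref$values, numeric(n2 - n))
  m <- n2 %/% 2L + 1L
  dnu <- 1 / (C_CM_FS * n2 * dt)
  nu <- (seq_len(m) - 1L) * dnu
  Xs <- stats::fft(xs)[seq_len(m)]
  Xr <- stats::fft(xr)[seq_len(m)]
  valid <- Mod(Xr) >= floor_frac * max(Mod(Xr))
  in_roi <- nu >= window$roi[1L] & nu <= window$roi[2L]
  if (!any(valid & in_roi)) {
    stop("reference has no usable spectral support in ROI")
  }
  H <- rep(0 + 0i, m)
  H[valid] <- Xs[valid] / Xr[valid]
  offset <- mean(H[valid & in_roi])
  H[!valid] <- offset
  w <- roi_taper(nu, window)
  Hwin <- offset + w * (H - offset)
  spec <- complex_spectrum(nu, Hwin, meta = list(
    n = n2, dt = dt, floor_frac = floor_frac,
    roi = window$roi, transition_width = window$transition_width
  ))
  sample_response(spec, window$roi, offset)
}

#' Time-domain difference of sample and reference traces
#'
#' Subtracts the reference from the sample trace — isolating the molecular
#' free-induction field in the weak-response limit — and applies a time
#' filter measured from the reference envelope peak. Unlike [tdf()], the
#' result still depends on the excitation pulse's amplitude and phase.
#'
#' @param sam,ref Sample and reference [time_trace()]s on identical grids.
#' @param filt A [time_filter_spec()]; `kind = "none"` returns the raw
#'   difference.
#' @return A [time_trace()] of the filtered difference.
#' @export
td_difference <- function(sam, ref, filt = time_filter_spec("none")) {
  stopifnot(inherits(sam, "time_trace"), inherits(ref, "time_trace"),
            inherits(filt, "time_filter_spec"))
  if (length(sam$t) != length(ref$t) ||
      max(abs(sam$t - ref$t)) > 1e-9 * trace_dt(ref)) {
    stop("sample and reference traces must share one time grid")
  }
  t0 <- ref$t[which.max(envelope(ref))]
  w <- time_filter_weights(filt, ref$t - t0)
  time_trace(ref$t, (sam$values - ref$values) * w,
             meta = list(role = "difference", filter = unclass(filt),
                         t0 = t0))
}

#' Time-domain filtering (TDF) of a referenced sample response
#'
#' The standardising filter at the core of the package: (1) the offset is
#' subtracted from H over its grid, (2) the result is inverse-transformed to
#' the time-domain response H(t), (3) the time filter is applied with t
#' measured from the transform's zero-delay origin (for the Heaviside and
#' Butterworth kinds all negative-time content — where only leakage and
#' excitation-localised noise live — is zeroed as well), (4) the filtered
#' H(t) is transformed forward again, and (5) the offset is re-added. For a
#' fixed filter and ROI the whole map is affine-linear in H, so filtered
#' spectra of mixtures remain linear combinations of filtered component
#' spectra and stay usable for linear concentration regression.
#'
#' The unambiguous time range is `T = 1/(c * d_nu)`; positive delays extend
#' to `T/2`. The cutoff is snapped to the nearest time-grid sample (reported
#' in the output's `meta$cutoff_fs`).
#'
#' @param resp A [sample_response()] (typically from [standard_response()]).
#' @param filt A [time_filter_spec()].
#' @param output `"complex"` (default) for the filtered complex response or
#'   `"magnitude"` for its modulus.
#' @return A [complex_spectrum()] on the same grid as `resp$spectrum`, with
#'   filter settings recorded in `meta`.
#' @export
tdf <- function(resp, filt, output = c("complex", "magnitude")) {
  stopifnot(inherits(resp, "sample_response"),
            inherits(filt, "time_filter_spec"))
  output <- match.arg(output)
  y <- resp$spectrum$values - resp$offset
  m <- length(y)
  dnu <- spectrum_dnu(resp$spectrum)
  t_range <- 1 / (C_CM_FS * dnu)     # full unambiguous window, fs
  dt_h <- t_range / m
  if (filt$kind != "none" && filt$cutoff > t_range) {
    stop("cutoff exceeds time window")
  }
  k <- seq_len(m) - 1L
  pos_half <- k <= m %/% 2L
  t_k <- k * dt_h                    # aliases above m/2 map to negative time
  if (filt$kind == "none") {
    w <- rep(1, m)
    cutoff_eff <- NA_real_
  } else {
    cutoff_eff <- round(filt$cutoff / dt_h) * dt_h
    w0 <- time_filter_weights(
      time_filter_spec(filt$kind, cutoff = cutoff_eff, order = filt$order),
      t_k
    )
    w <- ifelse(pos_half, w0, 0)
  }
  h <- stats::fft(y, inverse = TRUE) / m
  yf <- stats::fft(h * w)
  out <- resp$offset + yf
  if (output == "magnitude") out <- Mod(out)
  meta <- resp$spectrum$meta
  meta$filter_kind <- filt$kind
  meta$cutoff_fs <- cutoff_eff
  meta$output <- output
  meta$offset <- resp$offset
  complex_spectrum(resp$spectrum$nu, out, meta = meta)
}

#' Magnitude of a complex spectrum
#'
#' @param spec A [complex_spectrum()].
#' @return A [complex_spectrum()] with the pointwise modulus (real values)
#'   on the unchanged grid.
#' @export
magnitude_spectrum <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  complex_spectrum(spec$nu, Mod(spec$values), meta = spec$meta)
}

#' Spectral resolution of a scan window
#'
#' The wavenumber resolution corresponding to a measured delay window:
#' `1/(c*T)` in cm^-1 for a window of `T` picoseconds.
#'
#' @param time_window_ps Scan window length in ps (> 0).
#' @return Resolution in cm^-1.
#' @examples
#' spectral_resolution(8.3)  # ~4 cm^-1
#' @export
spectral_resolution <- function(time_window_ps) {
  if (any(time_window_ps <= 0)) stop("time window must be > 0")
  1 / (C_CM_FS * 1000 * time_window_ps)
}

#' Restrict a spectrum to a wavenumber band
#'
#' @param spec A [complex_spectrum()].
#' @param lo,hi Band edges, cm^-1.
#' @return A [complex_spectrum()] on the subgrid `lo <= nu <= hi`.
#' @export
crop_spectrum <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "complex_spectrum"))
  keep <- spec$nu >= lo & spec$nu <= hi
  if (sum(keep) < 2L) stop("band contains fewer than 2 grid points")
  complex_spectrum(spec$nu[keep], spec$values[keep], meta = spec$meta)
}

# raised-cosine ROI taper: 0 below roi[1]-tw, 1 inside the ROI, 0 above
# roi[2]+tw, with half-cosine flanks of width tw
roi_taper <- function(nu, window) {
  lo <- window$roi[1L]; hi <- window$roi[2L]; tw <- window$transition_width
  w <- numeric(length(nu))
  w[nu >= lo & nu <= hi] <- 1
  up <- nu > lo - tw & nu < lo
  w[up] <- 0.5 * (1 + cos(pi * (lo - nu[up]) / tw))
  dn <- nu > hi & nu < hi + tw
  w[dn] <- 0.5 * (1 + cos(pi * (nu[dn] - hi) / tw))
  w
}
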