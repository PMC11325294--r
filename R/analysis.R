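# Downstream evaluations: SNR-versus-cutoff optimisation, concentration
# retrieval, path-length calibration, and spectral-library identification.

#' Signal strength of a filtered magnitude spectrum
#'
#' Maximum absolute deviation from the baseline over the region of
#' interest — for transmission-like spectra the baseline is (the magnitude
#' of) the response offset, i.e. close to 1.
#'
#' @param filtered A [complex_spectrum()] with real (magnitude) values.
#' @param baseline Scalar baseline (default 1).
#' @param roi Optional `c(nu_lo, nu_hi)` restricting the evaluation.
#' @return Scalar signal strength.
#' @export
signal_strength <- function(filtered, baseline = 1, roi = NULL) {
  stopifnot(inherits(filtered, "complex_spectrum"))
  v <- Re(filtered$values)
  if (!is.null(roi)) {
    keep <- filtered$nu >= roi[1L] & filtered$nu <= roi[2L]
    if (!any(keep)) stop("ROI contains no grid points")
    v <- v[keep]
  }
  max(abs(v - baseline))
}

#' Noise level across replicate spectra
#'
#' Per-wavenumber standard deviation across replicate spectra, averaged over
#' a wavenumber band (default 1000-1400 cm^-1). Invariant under adding a
#' common (replicate-independent) baseline.
#'
#' @param replicate_spectra List of >= 2 [complex_spectrum()]s (real values)
#'   on one common grid covering the band.
#' @param band `c(nu_lo, nu_hi)`, cm^-1.
#' @return Scalar noise level.
#' @export
noise_level <- function(replicate_spectra, band = c(1000, 1400)) {
  if (length(replicate_spectra) < 2L) {
    stop("noise level needs at least 2 replicates")
  }
  grid <- replicate_spectra[[1L]]$nu
  mat <- vapply(replicate_spectra, function(s) {
    if (length(s$nu) != length(grid) ||
        max(abs(s$nu - grid)) > 1e-9 * max(abs(grid))) {
      stop("replicates must share one wavenumber grid")
    }
    Re(s$values)
  }, numeric(length(grid)))
  keep <- grid >= band[1L] & grid <= band[2L]
  if (!any(keep)) stop("band not covered by the replicate grid")
  mean(apply(mat[keep, , drop = FALSE], 1L, stats::sd))
}

#' Referenced responses for every pair of a campaign
#'
#' Convenience wrapper running [standard_response()] on each
#' reference/sample pair of a simulated campaign.
#'
#' @param campaign An `"frs_campaign"` from [make_campaign()].
#' @param window A [freq_window_spec()].
#' @param floor_frac Passed to [standard_response()].
#' @return List of records, each with `day`, `replicate`, `concentration`
#'   and `response` (a [sample_response()]).
#' @export
campaign_responses <- function(campaign, window, floor_frac = 1e-3) {
  stopifnot(inherits(campaign, "frs_campaign"))
  lapply(campaign$pairs, function(p) {
    list(day = p$day, replicate = p$replicate,
         concentration = p$concentration,
         response = standard_response(p$sample, p$reference, window,
                                      floor_frac = floor_frac))
  })
}

#' SNR versus time-filter cutoff
#'
#' For each candidate cutoff, every response is TDF-filtered (magnitude
#' output) and offset-corrected by subtracting its own mean over the noise
#' band — the usual step before comparing transmission-like spectra, which
#' removes the common-mode amplitude noise that the re-added offset carries
#' from measurement to measurement. The signal strength is then the maximum
#' absolute deviation of the mean analyte spectrum over the ROI, and the
#' noise level the band-averaged replicate standard deviation of the
#' pure-solvent spectra. The optimal cutoff is the argmax of
#' `signal/noise`, ties broken toward the smaller cutoff. Increasing a
#' Heaviside cutoff removes energy monotonically, so both signal and noise
#' decrease with cutoff; the SNR peaks where the envelope-localised
#' multiplicative noise has dropped to the additive detection floor.
#'
#' @param responses Output of [campaign_responses()] (records with
#'   `concentration` and `response`); records with `concentration > 0` are
#'   analytes, `concentration == 0` are solvent replicates. Both must be
#'   present.
#' @param cutoffs Numeric vector of cutoff delays, fs.
#' @param kind,order Time-filter kind (passed to [time_filter_spec()]).
#' @param band Noise-evaluation band, cm^-1.
#' @return Object of class `"snr_scan_result"`: list with `cutoffs`,
#'   `signal_strength`, `noise_level`, `snr`, `optimal_cutoff` and a
#'   `degenerate` flag (TRUE when the noise level vanished and the SNR is
#'   reported as `Inf`).
#' @export
snr_scan <- function(responses, cutoffs, kind = "heaviside", order = 4L,
                     band = c(1000, 1400)) {
  conc <- vapply(responses, function(r) r$concentration, numeric(1))
  analyte <- responses[conc > 0]
  solvent <- responses[conc == 0]
  if (length(analyte) == 0L) stop("no analyte responses in campaign")
  if (length(solvent) < 2L) stop("need >= 2 pure-solvent responses")
  roi <- analyte[[1L]]$response$roi
  # subtract each spectrum's own band mean (offset correction)
  decorrect <- function(s) {
    inb <- s$nu >= band[1L] & s$nu <= band[2L]
    complex_spectrum(s$nu, Re(s$values) - mean(Re(s$values)[inb]),
                     meta = s$meta)
  }
  sig <- noi <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    filt <- time_filter_spec(kind, cutoff = cutoffs[i], order = order)
    aspec <- lapply(analyte, function(r) {
      decorrect(tdf(r$response, filt, output = "magnitude"))
    })
    grid <- aspec[[1L]]$nu
    amean <- rowMeans(vapply(aspec, function(s) Re(s$values),
                             numeric(length(grid))))
    sig[i] <- signal_strength(complex_spectrum(grid, amean),
                              baseline = 0, roi = roi)
    noi[i] <- noise_level(lapply(solvent, function(r) {
      decorrect(tdf(r$response, filt, output = "magnitude"))
    }), band = band)
  }
  degenerate <- all(noi == 0)
  snr <- ifelse(noi > 0, sig / noi, Inf)
  best <- min(cutoffs[snr == max(snr)])   # ties toward the smaller cutoff
  structure(list(cutoffs = cutoffs, signal_strength = sig,
                 noise_level = noi, snr = snr,
                 optimal_cutoff = best,
                 degenerate = degenerate),
            class = "snr_scan_result")
}

#' @export
print.snr_scan_result <- function(x, ...) {
  cat(sprintf("<snr_scan_result> %d cutoffs in [%g, %g] fs; optimum at %g fs%s\n",
              length(x$cutoffs), min(x$cutoffs), max(x$cutoffs),
              x$optimal_cutoff,
              if (x$degenerate) " (degenerate: zero noise)" else ""))
  invisible(x)
}

#' Multiplicative/additive noise crossover time
#'
#' The delay after the excitation-envelope peak beyond which the
#' multiplicative noise amplitude `mult_rms * env(t)` stays at or below the
#' additive floor `add_rms` (the last exceedance, so ringing envelope tails
#' are covered) — the noise-analysis quantity that guides the choice of the
#' time-filter cutoff. Returns 0 when the multiplicative noise never exceeds
#' the floor, and `Inf` when there is no additive floor to cross.
#'
#' @param trace Clean reference [time_trace()] (noise-free excitation).
#' @param noise A [noise_spec()].
#' @return Crossover delay in fs, measured from the envelope peak.
#' @export
noise_crossover <- function(trace, noise) {
  stopifnot(inherits(trace, "time_trace"), inherits(noise, "noise_spec"))
  if (noise$add_rms <= 0) return(Inf)
  env <- envelope(trace)
  ipk <- which.max(env)
  if (noise$mult_rms * env[ipk] <= noise$add_rms) return(0)
  after <- seq(ipk, length(env))
  above <- after[noise$mult_rms * env[after] > noise$add_rms]
  last_above <- above[length(above)]
  if (last_above >= length(env)) return(Inf)
  trace$t[last_above + 1L] - trace$t[ipk]
}

#' Concentration retrieval by scalar-product projection
#'
#' Least-squares projection of a measured fingerprint onto a reference
#' fingerprint of known concentration:
#' `c_est = c_ref * <m, r> / <r, r>`, with the inner products taken over the
#' ROI after removing each spectrum's mean (offset removal). Both spectra
#' must have passed through identical processing (same filter settings).
#' The estimate is exactly linear in the measured spectrum.
#'
#' @param measured,reference [complex_spectrum()]s (real magnitude spectra)
#'   on one common grid.
#' @param c_ref Concentration of the reference fingerprint.
#' @param roi Optional `c(nu_lo, nu_hi)` restricting the inner products.
#' @return Estimated concentration (same units as `c_ref`).
#' @export
retrieve_concentration <- function(measured, reference, c_ref, roi = NULL) {
  stopifnot(inherits(measured, "complex_spectrum"),
            inherits(reference, "complex_spectrum"))
  if (length(measured$nu) != length(reference$nu) ||
      max(abs(measured$nu - reference$nu)) > 1e-9 * max(abs(reference$nu))) {
    stop("measured and reference spectra must share one grid")
  }
  m <- Re(measured$values); r <- Re(reference$values)
  if (!is.null(roi)) {
    keep <- measured$nu >= roi[1L] & measured$nu <= roi[2L]
    if (!any(keep)) stop("ROI contains no grid points")
    m <- m[keep]; r <- r[keep]
  }
  m <- m - mean(m); r <- r - mean(r)
  rr <- sum(r * r)
  if (rr == 0) stop("reference fingerprint is empty")
  c_ref * sum(m * r) / rr
}

#' Path-length calibration factor
#'
#' Projects the measurement of a known calibration liquid onto its expected
#' fingerprint: `s = <measured, expected> / <expected, expected>` (mean
#' removed from both). Spectra of the same measurement day are divided by
#' the returned factor to correct for cuvette path-length differences.
#'
#' @param measured_known,expected [complex_spectrum()]s on one grid with
#'   identical processing.
#' @param roi Optional band restriction.
#' @return Scalar calibration factor.
#' @export
path_calibration <- function(measured_known, expected, roi = NULL) {
  s <- retrieve_concentration(measured_known, expected, c_ref = 1, roi = roi)
  if (!is.finite(s)) stop("degenerate expected fingerprint")
  s
}

#' Identify a spectrum against a library by cosine similarity
#'
#' (1) The query is linearly interpolated onto the library grid, grid points
#' outside the query's range being dropped from all vectors; (2) an optional
#' preprocessing function (e.g. a TDF wrapper) is applied identically to the
#' query and every entry; (3) every spectrum is centred (mean subtracted);
#' (4) cosine similarity is computed against each entry and the entries
#' ranked descending. The top-ranked entry is the identification. The result
#' is invariant under positive rescaling of the query or of any entry.
#'
#' @param query A [complex_spectrum()] (real magnitude values).
#' @param lib A [spectral_library()].
#' @param preprocess Optional `function(complex_spectrum) -> complex_spectrum`
#'   applied to query and entries after interpolation (out-of-range query
#'   points are filled with the query mean for the call, then dropped).
#' @param query_name Label stored in the result.
#' @return Object of class `"identification_result"`: `query_name`,
#'   `ranking` (data frame `name`, `similarity`, sorted descending) and
#'   `top_hit`.
#' @export
cosine_identify <- function(query, lib, preprocess = NULL,
                            query_name = "query") {
  stopifnot(inherits(query, "complex_spectrum"),
            inherits(lib, "spectral_library"))
  grid <- lib$grid
  qi <- stats::approx(query$nu, Re(query$values), xout = grid, rule = 1)$y
  covered <- !is.na(qi)
  if (sum(covered) < 2L) stop("query does not overlap the library grid")
  qi[!covered] <- mean(qi[covered])
  entries <- lib$entries
  if (!is.null(preprocess)) {
    qi <- Re(preprocess(complex_spectrum(grid, qi))$values)
    entries <- lapply(entries, function(v) {
      Re(preprocess(complex_spectrum(grid, v))$values)
    })
  }
  q <- qi[covered]; q <- q - mean(q)
  qn <- sqrt(sum(q * q))
  if (qn == 0) stop("query carries no spectral contrast")
  sims <- vapply(entries, function(v) {
    e <- v[covered]; e <- e - mean(e)
    en <- sqrt(sum(e * e))
    if (en == 0) return(0)
    sum(q * e) / (qn * en)
  }, numeric(1))
  ord <- order(sims, decreasing = TRUE)
  ranking <- data.frame(name = names(entries)[ord], similarity = sims[ord],
                        row.names = NULL)
  structure(list(query_name = query_name, ranking = ranking,
                 top_hit = ranking$name[1L]),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> query '%s' -> top hit '%s' (cos = %.4f)\n",
              x$query_name, x$top_hit, x$ranking$similarity[1L]))
  invisible(x)
}
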