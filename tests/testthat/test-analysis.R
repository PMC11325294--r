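# SNR scan, noise crossover, concentration retrieval, path calibration and
# library identification.

test_that("signal_strength and noise_level behave as documented", {
  nu <- seq(1000, 1400, by = 10)
  sp <- complex_spectrum(nu, 1 - 0.05 * exp(-((nu - 1200) / 30)^2))
  expect_equal(signal_strength(sp), 0.05)
  expect_equal(signal_strength(sp, baseline = 0), 1)
  expect_error(signal_strength(sp, roi = c(4000, 4100)), "no grid points")

  set.seed(3)
  reps <- lapply(1:40, function(i) complex_spectrum(nu, rnorm(41, sd = 0.1)))
  expect_equal(noise_level(reps, band = c(1000, 1400)), 0.1,
               tolerance = 0.01)
  # invariant under a common baseline shift
  shifted <- lapply(reps, function(s)
    complex_spectrum(s$nu, Re(s$values) + 7))
  expect_equal(noise_level(shifted), noise_level(reps))
  expect_error(noise_level(reps[1]), "at least 2")
  expect_error(noise_level(reps, band = c(4000, 4100)), "band not covered")
})

make_tiny_campaign <- function(noise, base_seed = 11, conc = 2000) {
  cs <- campaign_spec(1, 0, 3, c(0, conc), base_seed = base_seed)
  make_campaign(cs, oscillator_model(demo_substances()$bravo), noise,
                pulse = study_pulse(), n = 2048, dt = 2)
}

test_that("snr_scan optimal cutoff equals the brute-force argmax and ties
           break toward the smaller cutoff", {
  camp <- make_tiny_campaign(noise_spec(0.02, 2000, 2e-4))
  rs <- campaign_responses(camp, study_window())
  cuts <- seq(0, 600, by = 100)
  sc <- snr_scan(rs, cuts)
  expect_s3_class(sc, "snr_scan_result")
  expect_equal(sc$snr, sc$signal_strength / sc$noise_level)
  # brute force: recompute each cutoff independently
  brute <- vapply(cuts, function(cf) {
    one <- snr_scan(rs, cf)
    one$snr
  }, numeric(1))
  expect_equal(sc$snr, brute, tolerance = 1e-12)
  expect_equal(sc$optimal_cutoff, min(cuts[brute == max(brute)]))
})

test_that("a zero-noise campaign is flagged degenerate with infinite SNR", {
  camp <- make_tiny_campaign(noise_spec(0, 2000, 0))
  rs <- campaign_responses(camp, study_window())
  sc <- snr_scan(rs, c(0, 200, 400))
  expect_true(sc$degenerate)
  expect_true(all(is.infinite(sc$snr)))
  expect_true(all(sc$noise_level < 1e-12))
  expect_equal(sc$optimal_cutoff, 0)    # tie broken toward smaller cutoff
})

test_that("snr_scan validates its inputs", {
  camp <- make_tiny_campaign(noise_spec(0.01, 2000, 1e-4))
  rs <- campaign_responses(camp, study_window())
  only_analyte <- Filter(function(r) r$concentration > 0, rs)
  only_solvent <- Filter(function(r) r$concentration == 0, rs)
  expect_error(snr_scan(only_analyte, c(0, 100)), "solvent")
  expect_error(snr_scan(only_solvent, c(0, 100)), "analyte")
})

test_that("noise_crossover implements the last-exceedance definition", {
  n <- 2048
  dt <- 2
  t <- (seq_len(n) - n / 2) * dt
  c0 <- frstdf:::C_CM_FS
  env <- exp(-(t / 200)^2)
  tr <- time_trace(t, env * cos(2 * pi * c0 * 1200 * t))
  # mult_rms * env crosses add_rms where env = add/mult
  xo <- noise_crossover(tr, noise_spec(0.02, 2000, 2e-4))
  expect_equal(xo, 200 * sqrt(log(100)), tolerance = 3 * dt)
  # no additive floor -> never crosses
  expect_equal(noise_crossover(tr, noise_spec(0.02, 2000, 0)), Inf)
  # floor above the multiplicative peak -> crossover at 0
  expect_equal(noise_crossover(tr, noise_spec(0.001, 2000, 0.5)), 0)
  # monotone in the floor level
  floors <- c(1e-4, 1e-3, 1e-2)
  xs <- vapply(floors, function(a)
    noise_crossover(tr, noise_spec(0.02, 2000, a)), numeric(1))
  expect_true(all(diff(xs) < 0))
})

test_that("retrieve_concentration is an exact linear projection", {
  nu <- seq(1000, 1400, by = 5)
  r <- complex_spectrum(nu, 1 - 0.02 * exp(-((nu - 1200) / 40)^2))
  expect_equal(retrieve_concentration(r, r, c_ref = 1000), 1000)
  tenth <- complex_spectrum(nu, 0.1 * Re(r$values))
  expect_equal(retrieve_concentration(tenth, r, c_ref = 1000), 100,
               tolerance = 1e-9)
  # exactly linear: retrieving a*m gives a*c_est
  set.seed(8)
  m <- complex_spectrum(nu, Re(r$values) + rnorm(length(nu), sd = 0.01))
  c1 <- retrieve_concentration(m, r, 1000)
  m3 <- complex_spectrum(nu, 3 * Re(m$values))
  expect_equal(retrieve_concentration(m3, r, 1000), 3 * c1,
               tolerance = 1e-9 * abs(c1))
  flat <- complex_spectrum(nu, rep(1, length(nu)))
  expect_error(retrieve_concentration(m, flat, 1000),
               "reference fingerprint is empty")
  expect_error(retrieve_concentration(m, crop_spectrum(r, 1100, 1300), 1000),
               "share one grid")
})

test_that("path_calibration returns the pure scale factor", {
  nu <- seq(1000, 1400, by = 5)
  expected <- complex_spectrum(nu, 1 - 0.05 * exp(-((nu - 1150) / 30)^2))
  measured <- complex_spectrum(nu, 0.8 * Re(expected$values))
  expect_equal(path_calibration(measured, expected), 0.8, tolerance = 1e-9)
})

test_that("cosine_identify ranks correctly and is scale invariant", {
  g <- seq(1000, 1400, by = 4)
  shapes <- list(
    a = exp(-((g - 1100) / 25)^2),
    b = exp(-((g - 1200) / 25)^2),
    c = exp(-((g - 1300) / 25)^2)
  )
  lib <- spectral_library(shapes, grid = g)
  q <- complex_spectrum(g, 5 * shapes$b + 0.01)
  res <- cosine_identify(q, lib, query_name = "probe")
  expect_s3_class(res, "identification_result")
  expect_equal(res$top_hit, "b")
  expect_equal(res$ranking$similarity[1], 1, tolerance = 1e-9)
  expect_true(all(diff(res$ranking$similarity) <= 0))
  expect_true(all(abs(res$ranking$similarity) <= 1 + 1e-12))
  # positive rescaling of the query leaves the ranking unchanged
  res2 <- cosine_identify(complex_spectrum(g, 0.037 * Re(q$values)), lib)
  expect_equal(res2$ranking, res$ranking, tolerance = 1e-12)
  # query on a different grid is interpolated; partial overlap drops points
  qfine <- complex_spectrum(seq(1050, 1350, by = 1),
                            exp(-((seq(1050, 1350, by = 1) - 1200) / 25)^2))
  expect_equal(cosine_identify(qfine, lib)$top_hit, "b")
  flat <- complex_spectrum(g, rep(2, length(g)))
  expect_error(cosine_identify(flat, lib), "no spectral contrast")
  far <- complex_spectrum(seq(4000, 4400, by = 4), rep(1, 101))
  expect_error(cosine_identify(far, lib), "overlap")
})

test_that("cosine_identify applies a preprocess hook identically to query
           and entries", {
  g <- seq(1000, 1400, by = 4)
  shapes <- list(a = exp(-((g - 1100) / 25)^2),
                 b = exp(-((g - 1250) / 25)^2))
  lib <- spectral_library(shapes, grid = g)
  flipped <- function(s) complex_spectrum(s$nu, -Re(s$values))
  q <- complex_spectrum(g, shapes$a)
  # an identical transform on both sides leaves similarities unchanged
  r0 <- cosine_identify(q, lib)
  r1 <- cosine_identify(q, lib, preprocess = flipped)
  expect_equal(r1$ranking, r0$ranking, tolerance = 1e-12)
})
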