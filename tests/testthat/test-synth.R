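# Pulse synthesis, transfer functions, response application, noise structure
# and campaign generation.

test_that("synth_pulse has the requested spectral centre and FWHM", {
  spec <- pulse_spec(1200, 400)
  tr <- synth_pulse(spec, n = 2048, dt = 2)
  sp <- fft_spectrum(tr)
  mag <- Mod(sp$values)
  expect_equal(sp$nu[which.max(mag)], 1200, tolerance = spectrum_dnu(sp))
  # FWHM from the dense magnitude spectrum, within 2%
  above <- sp$nu[mag >= max(mag) / 2]
  expect_equal(max(above) - min(above), 400, tolerance = 0.02 * 400)
})

test_that("synth_pulse centres the envelope peak on t = 0 with unit height", {
  for (gdd in c(0, 800)) {
    tr <- synth_pulse(pulse_spec(1200, 800, gdd = gdd), n = 4096, dt = 2)
    env <- envelope(tr)
    expect_equal(tr$t[which.max(env)], 0)
    expect_equal(max(env), 1, tolerance = 1e-9)
  }
  tr <- synth_pulse(pulse_spec(1200, 400, amplitude = 2.5), n = 1024, dt = 2)
  expect_equal(max(envelope(tr)), 2.5, tolerance = 1e-9)
})

test_that("synth_pulse applies the Gaussian EOS instrument response", {
  a <- synth_pulse(pulse_spec(1200, 400), n = 2048, dt = 2)
  b <- synth_pulse(pulse_spec(1200, 400, irf_bandwidth = 1200),
                   n = 2048, dt = 2)
  # the b/a magnitude ratio carries the Gaussian low-pass shape (up to the
  # overall peak renormalisation, which cancels between two wavenumbers)
  sa <- fft_spectrum(a)
  sb <- fft_spectrum(b)
  i1 <- which.min(abs(sa$nu - 1200))
  i2 <- which.min(abs(sa$nu - 800))
  rr <- Mod(sb$values) / Mod(sa$values)
  expect_equal(rr[i1] / rr[i2],
               exp(-log(2) * (1200^2 - 800^2) / 1200^2),
               tolerance = 0.02)
})

test_that("synth_pulse rejects spectra beyond the Nyquist limit", {
  expect_error(synth_pulse(pulse_spec(1200, 800), n = 1024, dt = 8),
               "Nyquist")
  expect_error(synth_pulse(pulse_spec(1200, 400), n = 8, dt = 2), ">= 16")
})

test_that("transfer_function magnitude depth is concentration * strength", {
  grid <- seq(900, 1600, by = 0.25)
  lines <- data.frame(center = 1200, fwhm = 30, strength = 2e-5)
  for (conc in c(10, 100, 1000)) {
    H <- transfer_function(oscillator_model(lines, concentration = conc),
                           grid)
    depth <- 1 - min(Mod(H$values))
    expect_equal(depth, conc * 2e-5, tolerance = 1e-6 + 1e-4 * depth)
    expect_equal(grid[which.min(Mod(H$values))], 1200, tolerance = 0.5)
  }
  # empty model is the identity
  H0 <- transfer_function(oscillator_model(), grid)
  expect_true(all(H0$values == 1 + 0i))
})

test_that("transfer_function lines are causal under the FFT convention", {
  # H - 1 back-transformed must live at t >= 0 only
  n <- 4096
  dt <- 2
  grid <- (seq_len(n %/% 2 + 1) - 1) / (frstdf:::C_CM_FS * n * dt)
  H <- transfer_function(
    oscillator_model(demo_substances()$bravo, concentration = 1000), grid
  )
  full <- frstdf:::hermitian_full(H$values - 1, n)
  h_t <- stats::fft(full, inverse = TRUE) / n
  # truncating the line shape's far tails at DC/Nyquist rings around t = 0
  # with a ~1/t envelope; past it (t < -200 fs) the acausal half must be
  # negligible, while the causal half carries the free-induction decay
  neg <- Mod(h_t[(n %/% 2 + 2):(n - 100)])  # t in (-T/2, -200 fs]
  pos <- Mod(h_t[2:(n %/% 2)])
  expect_lt(max(neg), 1e-2 * max(pos))
})

test_that("the etalon echo appears at +tau and makes the known fringes", {
  n <- 4096
  dt <- 2
  grid <- (seq_len(n %/% 2 + 1) - 1) / (frstdf:::C_CM_FS * n * dt)
  tau <- 280
  H <- transfer_function(
    oscillator_model(echo = list(delay = tau, relative_amplitude = 0.05)),
    grid
  )
  full <- frstdf:::hermitian_full(H$values - mean(H$values), n)
  h_t <- Mod(stats::fft(full, inverse = TRUE) / n)
  t_axis <- ifelse(seq_len(n) - 1 <= n %/% 2, seq_len(n) - 1,
                   seq_len(n) - 1 - n) * dt
  expect_equal(t_axis[which.max(h_t[-1]) + 1], tau)
  # fringe period 1/(c*tau) in the magnitude spectrum
  mag <- Mod(H$values)
  peaks <- which(diff(sign(diff(mag))) == -2) + 1
  expect_equal(mean(diff(grid[peaks])), 1 / (frstdf:::C_CM_FS * tau),
               tolerance = 0.01 / (frstdf:::C_CM_FS * tau))
})

test_that("apply_response is the identity for H = 1 and matches a direct
           circular convolution", {
  set.seed(21)
  tr <- synth_pulse(pulse_spec(1200, 600), n = 512, dt = 2)
  grid <- conjugate_grid(tr)
  H1 <- complex_spectrum(grid, rep(1 + 0i, length(grid)))
  expect_lt(max(abs(apply_response(tr, H1)$values - tr$values)), 1e-12)

  H <- transfer_function(
    oscillator_model(demo_substances()$delta, concentration = 2000), grid
  )
  out <- apply_response(tr, H)
  # oracle: direct circular convolution with the kernel IDFT(H)
  n <- length(tr$t)
  kern <- Re(dft_direct(frstdf:::hermitian_full(H$values, n),
                        inverse = TRUE)) / n
  expect_lt(max(abs(out$values - circ_conv_direct(tr$values, kern))), 1e-8)
})

test_that("apply_response defaults to H = 1 outside the supplied grid", {
  tr <- synth_pulse(pulse_spec(1200, 600), n = 512, dt = 2)
  sub <- seq(1100, 1300, by = 5)
  Hsub <- complex_spectrum(sub, rep(1 + 0i, length(sub)))
  expect_lt(max(abs(apply_response(tr, Hsub)$values - tr$values)), 1e-12)
})

test_that("add_noise is deterministic, seed-sensitive and has the stated
           RMS structure", {
  tr <- synth_pulse(pulse_spec(1200, 800, gdd = 800), n = 4096, dt = 2)
  ns <- noise_spec(0.02, 2000, 2e-4, seed = 123)
  a <- add_noise(tr, ns)
  b <- add_noise(tr, ns)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         add_noise(tr, noise_spec(0.02, 2000, 2e-4,
                                                  seed = 124))$values))
  # additive-only: residual is white with the requested RMS
  add_only <- add_noise(tr, noise_spec(0, 2000, 1e-3, seed = 5))
  expect_equal(sd(add_only$values - tr$values), 1e-3, tolerance = 0.05)
  # zero noise: unchanged
  expect_identical(add_noise(tr, noise_spec(0, 2000, 0))$values, tr$values)
})

test_that("multiplicative noise is confined to the excitation envelope", {
  tr <- synth_pulse(pulse_spec(1200, 800, gdd = 800), n = 4096, dt = 2)
  mult_only <- add_noise(tr, noise_spec(0.05, 2000, 0, seed = 9))
  res <- mult_only$values - tr$values
  inside <- abs(tr$t) < 150
  outside <- abs(tr$t) > 1000
  expect_gt(sd(res[inside]), 100 * sd(res[outside]))
})

test_that("make_campaign is reproducible and jitters the pulse by day", {
  lines <- demo_substances()$bravo
  cs <- campaign_spec(3, 0.05, 2, c(0, 100), base_seed = 42)
  ns <- noise_spec(0.01, 2000, 1e-4)
  a <- make_campaign(cs, oscillator_model(lines), ns,
                     pulse = pulse_spec(1200, 800, gdd = 800),
                     n = 1024, dt = 2)
  b <- make_campaign(cs, oscillator_model(lines), ns,
                     pulse = pulse_spec(1200, 800, gdd = 800),
                     n = 1024, dt = 2)
  expect_equal(length(a$pairs), 3 * 2 * 2)
  expect_identical(lapply(a$pairs, function(p) p$sample$values),
                   lapply(b$pairs, function(p) p$sample$values))
  # day pulses differ across days but are shared within a day
  amps <- vapply(a$pairs, function(p) p$pulse_spec$amplitude, numeric(1))
  days <- vapply(a$pairs, function(p) p$day, numeric(1))
  expect_length(unique(amps), 3)
  expect_true(all(tapply(amps, days, function(v) length(unique(v))) == 1))
  # all per-trace noise seeds are distinct
  seeds <- unlist(lapply(a$pairs, function(p)
    c(p$reference$meta$noise_seed, p$sample$meta$noise_seed)))
  expect_false(anyDuplicated(seeds) > 0)
  # concentration-0 samples are pure solvent (same clean trace as reference
  # up to noise): their mean over replicates approaches the reference pulse
  p0 <- a$pairs[[1]]
  expect_equal(p0$concentration, 0)
})
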