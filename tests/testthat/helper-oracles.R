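# Independent brute-force oracles and small shared fixtures. Everything here
# avoids stats::fft so the oracle tests cannot share a bug with the package
# transforms.

# direct O(n^2) DFT: X[k] = sum_j x[j] exp(-2i pi j k / n) (inverse: + sign,
# no 1/n normalisation — matching stats::fft conventions)
dft_direct <- function(x, inverse = FALSE) {
  n <- length(x)
  j <- seq_len(n) - 1L
  sgn <- if (inverse) 2i else -2i
  W <- exp(sgn * pi * outer(j, j) / n)
  as.vector(W %*% x)
}

# direct-sum oracle for tdf(): subtract the offset, inverse-DFT to delay
# domain, weight, forward-DFT, re-add the offset — each step written as an
# explicit sum
tdf_oracle <- function(resp, filt, output = "complex") {
  y <- resp$spectrum$values - resp$offset
  m <- length(y)
  dnu <- spectrum_dnu(resp$spectrum)
  t_range <- 1 / (frstdf:::C_CM_FS * dnu)
  dt_h <- t_range / m
  k <- seq_len(m) - 1L
  t_k <- k * dt_h
  pos_half <- k <= m %/% 2L
  if (filt$kind == "none") {
    w <- rep(1, m)
  } else {
    cutoff_eff <- round(filt$cutoff / dt_h) * dt_h
    w0 <- time_filter_weights(
      time_filter_spec(filt$kind, cutoff = cutoff_eff, order = filt$order),
      t_k
    )
    w <- ifelse(pos_half, w0, 0)
  }
  h <- dft_direct(y, inverse = TRUE) / m
  out <- resp$offset + dft_direct(h * w)
  if (output == "magnitude") out <- Mod(out)
  out
}

# direct circular convolution y[i] = sum_j x[j] kern[(i - j) mod n]
circ_conv_direct <- function(x, kern) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - seq_len(n)) %% n) + 1L
    y[i] <- sum(x * kern[idx])
  }
  y
}

# frozen demonstration study conditions shared by the acceptance tests and
# the worked examples (see the package vignette for the rationale)
study_pulse <- function() pulse_spec(1200, 800, gdd = 800, tod = 0)
study_window <- function() freq_window_spec(c(1000, 1400),
                                            transition_width = 250)
study_filter <- function() time_filter_spec("heaviside", cutoff = 200)

# random smooth complex spectrum on a small grid, for property tests
random_response <- function(m = 64, dnu = 5) {
  nu <- 900 + (seq_len(m) - 1L) * dnu
  vals <- complex(real = stats::rnorm(m, sd = 0.3),
                  imaginary = stats::rnorm(m, sd = 0.3))
  offset <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
  sample_response(complex_spectrum(nu, vals), roi = range(nu), offset = offset)
}
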