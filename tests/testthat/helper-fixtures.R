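# Shared fixtures: all data is generated in code, seeded.

# N-site AR(1) panel, cleaned (detrended + standardized).
make_ar1_sts <- function(n_sites = 5, n_months = 132, phi = 0.5, seed = 1) {
  withr::with_seed(seed, {
    v <- t(sapply(seq_len(n_sites), function(i) {
      if (phi == 0) stats::rnorm(n_months) else
        as.numeric(stats::arima.sim(list(ar = phi), n_months))
    }))
    clean_series(sts(v))
  })
}

# Sites sharing a sinusoid of given period (site-specific phase offsets),
# optionally lagged, plus white noise; cleaned.
make_seasonal_sts <- function(n_sites = 5, n_months = 132, period = 12,
                              lag = 0, noise = 0.3, site_phase = 0.2,
                              seed = 1) {
  withr::with_seed(seed, {
    tt <- seq_len(n_months)
    v <- t(sapply(seq_len(n_sites), function(i) {
      cos(2 * pi * (tt - lag) / period + i * site_phase) +
        noise * stats::rnorm(n_months)
    }))
    clean_series(sts(v))
  })
}

# clean -> transform -> across_locations normalization in one step
norm_fields <- function(x, grid = NULL, coi_factor = 1) {
  if (is.null(grid)) grid <- make_timescale_grid(ncol(x$values))
  normalize_transforms(wavelet_fieldset(x, grid, coi_factor),
                       "across_locations")
}

# Independent oracle: naive O(T^2) direct convolution with the analytic
# Morlet kernel, written as explicit loops (deliberately not sharing code
# with the package implementation).
naive_morlet_transform <- function(x, timescales) {
  T_len <- length(x)
  W <- matrix(0 + 0i, T_len, length(timescales))
  for (k in seq_along(timescales)) {
    s <- timescales[k]
    half <- floor(4 * s)
    norm <- 0
    for (v in (-half):half) norm <- norm + exp(-v^2 / (2 * s^2))
    for (t in seq_len(T_len)) {
      acc <- 0 + 0i
      for (u in seq_len(T_len)) {
        v <- u - t
        if (abs(v) <= half) {
          acc <- acc + x[u] * exp(-v^2 / (2 * s^2)) *
            exp(-2i * pi * v / s)
        }
      }
      W[t, k] <- acc / norm
    }
  }
  W
}

# Spectral oracle for expected wavelet-regression coefficient moduli:
# integrates known population spectra (AR(1) density, optional seasonal
# line) against the Morlet kernel's transfer function, independently of the
# package's transform code.
oracle_kernel_gain <- function(sigma, f) {
  half <- floor(4 * sigma)
  v <- (-half):half
  env <- exp(-v^2 / (2 * sigma^2))
  env <- env / sum(env)
  vapply(f, function(ff) abs(sum(env * exp(2i * pi * v * (ff - 1 / sigma)))),
         1.0)
}

oracle_beta_modulus <- function(sigma, a, phi_ar, noise_sd, seasonal_amp = 0,
                                M = 2048) {
  f <- (seq_len(M) - 1) / M
  G2 <- oracle_kernel_gain(sigma, f)^2
  S <- 1 / abs(1 - phi_ar * exp(-2i * pi * f))^2
  Px <- mean(S * G2) + seasonal_amp^2 / 4 * oracle_kernel_gain(sigma, 1 / 12)^2
  Pn <- noise_sd^2 * mean(G2)
  a * sqrt(Px / (a^2 * Px + Pn))
}
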