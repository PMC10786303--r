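# fields used across several blocks
wlm_fix <- local({
  g <- make_timescale_grid(132)
  x1 <- norm_fields(make_seasonal_sts(noise = 0.4, seed = 201), g)
  x2 <- norm_fields(make_ar1_sts(seed = 202), g)
  list(g = g, x1 = x1, x2 = x2, band = timescale_band(8, 16))
})

test_that("an exact linear field relation is recovered to precision", {
  y <- wlm_fix$x1
  y$coef <- (0.5 * exp(1i * pi / 4)) * y$coef
  fit <- fit_wlm(y, list(kelp = wlm_fix$x1), wlm_fix$band)
  expect_lt(max(abs(fit$coeffs - 0.5 * exp(1i * pi / 4))), 1e-8)
  se <- synchrony_explained(fit, y, list(kelp = wlm_fix$x1))
  expect_equal(se$sync_explained, 1, tolerance = 1e-10)
  pred <- predicted_mean_field(fit, list(kelp = wlm_fix$x1))
  wmf_y <- rowMeans(y$coef[, fit$band_idx, , drop = FALSE], dims = 2)
  expect_lt(max(abs(pred - wmf_y)), 1e-8)
})

test_that("single-predictor coefficients match the closed-form solution", {
  y <- wlm_fix$x2
  y$coef <- 0.8 * wlm_fix$x1$coef + 0.6 * wlm_fix$x2$coef
  fit <- fit_wlm(y, list(a = wlm_fix$x1), wlm_fix$band)
  for (j in seq_along(fit$band_idx)) {
    k <- fit$band_idx[j]
    m <- wlm_fix$x1$valid_mask[, k]
    closed <- mean(Conj(wlm_fix$x1$coef[m, k, ]) * y$coef[m, k, ]) /
      mean(abs(wlm_fix$x1$coef[m, k, ])^2)
    expect_lt(abs(fit$coeffs[1, j] - closed), 1e-10)
  }
})

test_that("orthogonal predictors separate cleanly", {
  fit <- fit_wlm(wlm_fix$x1, list(a = wlm_fix$x1, b = wlm_fix$x2),
                 wlm_fix$band)
  expect_lt(max(abs(fit$coeffs["a", ] - 1)), 1e-8)
  expect_lt(max(abs(fit$coeffs["b", ])), 1e-8)
})

test_that("the synchrony-attribution identity is exact on arbitrary data", {
  for (r in 1:4) {
    y <- norm_fields(make_ar1_sts(seed = 210 + r), wlm_fix$g)
    fit <- fit_wlm(y, list(a = wlm_fix$x1, b = wlm_fix$x2), wlm_fix$band)
    se <- synchrony_explained(fit, y, list(a = wlm_fix$x1, b = wlm_fix$x2))
    expect_lt(abs(se$S_mod - sum(se$contributions) - sum(se$crossterms)),
              1e-10)
    expect_true(all(se$contributions >= 0))
  }
})

test_that("attribution is invariant to predictor relabeling", {
  y <- norm_fields(make_ar1_sts(seed = 221), wlm_fix$g)
  se_ab <- synchrony_explained(
    fit_wlm(y, list(a = wlm_fix$x1, b = wlm_fix$x2), wlm_fix$band),
    y, list(a = wlm_fix$x1, b = wlm_fix$x2))
  se_ba <- synchrony_explained(
    fit_wlm(y, list(b = wlm_fix$x2, a = wlm_fix$x1), wlm_fix$band),
    y, list(b = wlm_fix$x2, a = wlm_fix$x1))
  expect_equal(se_ab$sync_explained, se_ba$sync_explained, tolerance = 1e-10)
  expect_equal(se_ab$contributions[c("a", "b")],
               se_ba$contributions[c("a", "b")], tolerance = 1e-10)
})

test_that("predictors confined to disjoint bands barely interact", {
  # periods 12 and 4 within one wide band: each component mean field lives
  # at its own timescales, so the interaction term is near zero
  for (r in 1:3) {
    x12s <- make_seasonal_sts(period = 12, noise = 0.05, seed = 2300 + r)
    x4s <- make_seasonal_sts(period = 4, noise = 0.05, seed = 2400 + r)
    fy <- norm_fields(clean_series(sts(x12s$values + x4s$values)), wlm_fix$g)
    f12 <- norm_fields(x12s, wlm_fix$g)
    f4 <- norm_fields(x4s, wlm_fix$g)
    fit <- fit_wlm(fy, list(slow = f12, fast = f4), timescale_band(2, 16))
    se <- suppressWarnings(
      synchrony_explained(fit, fy, list(slow = f12, fast = f4)))
    expect_lt(abs(se$crossterms), 0.05 * sum(se$contributions))
  }
})

test_that("model phases reproduce the lag and sign conventions", {
  base <- make_seasonal_sts(lag = 0, noise = 0.2, seed = 241)
  lag1 <- make_seasonal_sts(lag = 1, noise = 0.2, seed = 242)
  fb <- norm_fields(base); fl <- norm_fields(lag1)
  # response lags the 12-mo predictor by 1 month: phi ~ -1/6
  fit <- fit_wlm(fl, list(p = fb), wlm_fix$band)
  expect_lt(abs(model_band_phase(fit, "p", fl, list(p = fb)) - (-1 / 6)),
            0.03)
  # identical response: phi = 0
  fit0 <- fit_wlm(fb, list(p = fb), wlm_fix$band)
  expect_equal(model_band_phase(fit0, "p", fb, list(p = fb)), 0)
  # negated response: anti-phase maps to +1
  neg <- fb; neg$coef <- -neg$coef
  fitn <- fit_wlm(neg, list(p = fb), wlm_fix$band)
  expect_equal(model_band_phase(fitn, "p", neg, list(p = fb)), 1)
})

test_that("degenerate fits raise informative errors", {
  y <- norm_fields(make_ar1_sts(seed = 251), wlm_fix$g)
  expect_error(fit_wlm(y, list(a = wlm_fix$x1, b = wlm_fix$x1), wlm_fix$band),
               "collinear")
  zero_beta <- fit_wlm(wlm_fix$x1, list(p = wlm_fix$x2), wlm_fix$band)
  zero_beta$coeffs[] <- 0
  expect_error(model_band_phase(zero_beta, "p", wlm_fix$x1,
                                list(p = wlm_fix$x2)), "undefined")
})

test_that("diagnostics separate sound fits from misspecified ones", {
  # exact fit: residual power 0, unit R^2
  y <- wlm_fix$x1
  y$coef <- 2i * y$coef
  fit <- fit_wlm(y, list(p = wlm_fix$x1), wlm_fix$band)
  dg <- wlm_diagnostics(fit, y, list(p = wlm_fix$x1), seed = 5)
  expect_equal(unname(dg$r_squared), rep(1, length(fit$band_timescales)),
               tolerance = 1e-10)
  expect_equal(dg$resid_sync_frac, 0)
  # pure-noise response: R^2 near zero
  yn <- norm_fields(make_ar1_sts(seed = 261), wlm_fix$g)
  fitn <- fit_wlm(yn, list(p = wlm_fix$x2), wlm_fix$band)
  dgn <- wlm_diagnostics(fitn, yn, list(p = wlm_fix$x2), seed = 5)
  expect_lt(mean(dgn$r_squared), 0.2)
  # omitting a strong synchronized driver leaves residual coherence with it
  drv <- clean_series(generate_shared_field(5, 132, rho = 0.9, ar_coef = 0.6,
                                            seasonal_amp = 1, seed = 262))
  fd <- norm_fields(drv, wlm_fix$g)
  y2 <- norm_fields(make_ar1_sts(seed = 263), wlm_fix$g)
  y2$coef <- y2$coef + 2 * fd$coef
  fit2 <- fit_wlm(y2, list(p = wlm_fix$x2), wlm_fix$band)
  # probing the residuals with the omitted driver's series must reject
  dg2 <- wlm_diagnostics(fit2, y2, list(p = wlm_fix$x2),
                         x_series = list(p = drv),
                         n_surr = 99, seed = 5)
  expect_true(is.data.frame(dg2$resid_coherence))
  expect_lt(dg2$resid_coherence$p_value[1], 0.05)
  expect_gt(dg2$resid_sync_frac, 0.2)   # leftover synchrony is visible too
})

test_that("coefficient recovery converges toward the spectral truth", {
  err_at <- function(Tn, seed) {
    g <- make_timescale_grid(Tn)
    withr::with_seed(seed, {
      xv <- t(sapply(1:5, function(i) as.numeric(arima.sim(list(ar = 0.5), Tn))))
      yv <- 1.2 * xv + matrix(rnorm(5 * Tn, sd = 0.8), 5, Tn)
    })
    fx <- norm_fields(clean_series(sts(xv)), g)
    fy <- norm_fields(clean_series(sts(yv)), g)
    fit <- fit_wlm(fy, list(p = fx), timescale_band(8, 16))
    truth <- vapply(fit$band_timescales, oracle_beta_modulus, 1.0,
                    a = 1.2, phi_ar = 0.5, noise_sd = 0.8)
    abs(mean(abs(fit$coeffs)) - mean(truth))
  }
  e132 <- mean(vapply(1:5, function(r) err_at(132, 2700 + r), 1.0))
  e528 <- mean(vapply(1:5, function(r) err_at(528, 2800 + r), 1.0))
  expect_lt(e528, 0.05)            # consistent at the longer record
  expect_lt(e528, e132 + 0.01)     # and no worse than the short record
})
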