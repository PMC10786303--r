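test_that("self-coherence is exactly magnitude 1 at phase 0", {
  x <- make_ar1_sts(seed = 111)
  f <- norm_fields(x)
  co <- spatial_coherence(f, f, timescale_band(8, 16))
  per <- co$per_timescale[!is.na(co$per_timescale)]
  expect_equal(max(abs(per - 1)), 0, tolerance = 1e-10)
  expect_equal(co$magnitude, 1, tolerance = 1e-10)
  expect_equal(co$phi, 0)
})

test_that("a lagged response shows the quarter-cycle phase convention", {
  # y = x lagged 3 months at period 12: response lags driver, phi ~ -0.5
  x <- make_seasonal_sts(lag = 0, noise = 0.05, seed = 121)
  y <- make_seasonal_sts(lag = 3, noise = 0.05, seed = 122)
  fx <- norm_fields(x); fy <- norm_fields(y)
  co <- spatial_coherence(fx, fy, timescale_band(8, 16))
  expect_lt(abs(co$phi - (-0.5)), 0.02)
  expect_gt(co$magnitude, 0.9)
  # antisymmetry under swapping roles
  co_rev <- spatial_coherence(fy, fx, timescale_band(8, 16))
  expect_lt(abs(co$phi + co_rev$phi), 1e-10)
  # anti-phase maps to +1 under the (-1, 1] convention
  yneg <- x; yneg$values <- -yneg$values
  expect_equal(spatial_coherence(fx, norm_fields(yneg),
                                 timescale_band(8, 16))$phi, 1)
})

test_that("coherence magnitude is bounded and relabeling-invariant", {
  x <- make_ar1_sts(seed = 131); y <- make_ar1_sts(seed = 132)
  fx <- norm_fields(x); fy <- norm_fields(y)
  co <- spatial_coherence(fx, fy, timescale_band(2, 8))
  expect_true(all(Mod(co$per_timescale) <= 1 + 1e-12, na.rm = TRUE))
  # relabel sites consistently in both variables
  perm <- c(3, 1, 5, 2, 4)
  xp <- sts(x$values[perm, ], site_ids = x$site_ids[perm])
  yp <- sts(y$values[perm, ], site_ids = y$site_ids[perm])
  co_p <- spatial_coherence(norm_fields(xp), norm_fields(yp),
                            timescale_band(2, 8))
  expect_equal(co_p$magnitude, co$magnitude, tolerance = 1e-10)
})

test_that("independent variables show weak coherence that fades with T", {
  mags <- sapply(1:6, function(r) {
    c(short = spatial_coherence(
        norm_fields(make_ar1_sts(n_months = 132, seed = 1300 + r)),
        norm_fields(make_ar1_sts(n_months = 132, seed = 1400 + r)),
        timescale_band(8, 16))$magnitude,
      long = spatial_coherence(
        norm_fields(make_ar1_sts(n_months = 528, seed = 1500 + r)),
        norm_fields(make_ar1_sts(n_months = 528, seed = 1600 + r)),
        timescale_band(8, 16))$magnitude)
  })
  expect_lt(mean(mags["short", ]), 0.4)
  expect_lt(mean(mags["long", ]), mean(mags["short", ]))
})

test_that("the surrogate test handles the limiting cases", {
  x <- make_ar1_sts(seed = 141)
  b <- timescale_band(8, 16)
  ct <- coherence_test(x, x, b, n_surr = 99, seed = 4)
  expect_equal(ct$p_value, 1 / 100)            # smallest attainable
  expect_error(coherence_test(x, x, b, n_surr = 10), "19")
  expect_error(coherence_test(x, x, b, n_surr = 99, surr_type = "aaft",
                              method = "fast"), "slow")
})

test_that("a zero-phase surrogate reproduces the observed statistic", {
  x <- make_ar1_sts(seed = 151); y <- make_ar1_sts(seed = 152)
  b <- timescale_band(8, 16)
  prep <- wavesync:::coh_prepare(x, y, NULL, 1)
  obs <- spatial_coherence(prep$xn, prep$yn, b)
  idx <- wavesync:::band_indices(prep$grid, b)
  stat0 <- wavesync:::coh_surr_fast(x, prep, idx,
                                    matrix(0, ncol(x$values), 1))
  expect_equal(stat0, obs$magnitude, tolerance = 1e-12)
})

test_that("fast and slow schemes agree given shared seeds", {
  b <- timescale_band(8, 16)
  for (r in 1:3) {
    withr::with_seed(160 + r, {
      coup <- runif(1, 0.1, 0.5)
      xv <- t(sapply(1:5, function(i) as.numeric(arima.sim(list(ar = 0.5), 132))))
      yv <- coup * xv + matrix(rnorm(5 * 132), 5, 132)
    })
    x <- clean_series(sts(xv)); y <- clean_series(sts(yv))
    pf <- coherence_test(x, y, b, n_surr = 99, method = "fast", seed = 170 + r)
    ps <- coherence_test(x, y, b, n_surr = 99, method = "slow", seed = 170 + r)
    expect_equal(pf$p_value, ps$p_value)
    expect_equal(pf$magnitude, ps$magnitude)
  }
})

test_that("p-values rise as the driver-response link weakens", {
  b <- timescale_band(8, 16)
  mean_p <- vapply(c(0.8, 0.25, 0), function(coup) {
    mean(vapply(1:5, function(r) {
      withr::with_seed(1800 + 100 * coup + r, {
        xv <- t(sapply(1:5, function(i)
          as.numeric(arima.sim(list(ar = 0.5), 132))))
        yv <- coup * xv + matrix(rnorm(5 * 132), 5, 132)
      })
      coherence_test(clean_series(sts(xv)), clean_series(sts(yv)), b,
                     n_surr = 99, seed = 1900 + r)$p_value
    }, 1.0))
  }, 1.0)
  expect_true(all(diff(mean_p) > 0))
})

test_that("coherence tests are deterministic given their seed", {
  x <- make_ar1_sts(seed = 181); y <- make_ar1_sts(seed = 182)
  b <- timescale_band(2, 8)
  a1 <- coherence_test(x, y, b, n_surr = 49, seed = 6)
  a2 <- coherence_test(x, y, b, n_surr = 49, seed = 6)
  expect_identical(a1$p_value, a2$p_value)
})
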