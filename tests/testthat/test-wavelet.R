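test_that("a pure sinusoid peaks at the grid timescale nearest its period", {
  Tn <- 132
  x <- cos(2 * pi * seq_len(Tn) / 12)
  g <- make_timescale_grid(Tn)
  wt <- wavelet_transform(x, g)
  mean_mod <- vapply(seq_along(g$timescales), function(k) {
    m <- wt$valid_mask[, k]
    if (!any(m)) return(NA_real_)
    mean(abs(wt$W[m, k]))
  }, 1.0)
  expect_equal(which.max(mean_mod), which.min(abs(g$timescales - 12)))
})

test_that("phase advances by 2*pi per period at the matching timescale", {
  Tn <- 132
  x <- cos(2 * pi * seq_len(Tn) / 12)
  g <- make_timescale_grid(Tn)
  wt <- wavelet_transform(x, g)
  k <- which.min(abs(g$timescales - 12))
  for (t0 in c(40, 60, 80)) {
    dphi <- (Arg(wt$W[t0 + 3, k]) - Arg(wt$W[t0, k])) %% (2 * pi)
    expect_lt(abs(dphi - pi / 2), 1e-2)
  }
})

test_that("the transform is linear and annihilates the zero series", {
  withr::with_seed(11, {
    Tn <- 96
    x <- rnorm(Tn); y <- rnorm(Tn)
  })
  g <- make_timescale_grid(Tn)
  w_lin <- wavelet_transform(2.5 * x - 1.3 * y, g)$W
  w_sep <- 2.5 * wavelet_transform(x, g)$W - 1.3 * wavelet_transform(y, g)$W
  expect_lt(max(abs(w_lin - w_sep)), 1e-10)
  expect_equal(max(abs(wavelet_transform(rep(0, Tn), g)$W)), 0)
  expect_error(wavelet_transform(c(x[-1], NA), g), "finite")
})

test_that("circularly shifting an exact-period sinusoid rotates phases", {
  Tn <- 132  # 11 exact cycles of period 12
  tt <- seq_len(Tn)
  x <- cos(2 * pi * tt / 12)
  xs <- cos(2 * pi * (tt - 2) / 12)   # circular shift by 2 months
  g <- make_timescale_grid(Tn)
  k <- which.min(abs(g$timescales - 12))
  w0 <- wavelet_transform(x, g)$W[, k]
  w2 <- wavelet_transform(xs, g)$W[, k]
  interior <- 40:90
  rot <- Arg(w2[interior] / w0[interior])
  expect_lt(max(abs(rot - (-2 * pi * 2 / 12))), 1e-2)
})

test_that("the implementation matches a naive direct-convolution oracle", {
  withr::with_seed(21, x <- rnorm(64))
  g <- make_timescale_grid(64, s_min = 2, s_max = 24, ratio = 1.3)
  W <- wavelet_transform(x, g)$W
  W_oracle <- naive_morlet_transform(x, g$timescales)
  expect_lt(max(abs(W - W_oracle)), 1e-8)
})

test_that("the validity mask depends only on shape, never on data", {
  g <- make_timescale_grid(100, s_max = 50)
  m1 <- wavelet_transform(rnorm(100), g)$valid_mask
  m2 <- wavelet_transform(cos(seq_len(100)), g)$valid_mask
  expect_identical(m1, m2)
  # margin is coi_factor * sigma from either end
  k <- which.min(abs(g$timescales - 10))
  s <- g$timescales[k]
  expect_equal(which(m1[, k]), seq(ceiling(s) + 1, 100 - ceiling(s)))
  m3 <- wavelet_transform(rnorm(100), g, coi_factor = 2)$valid_mask
  expect_lt(sum(m3), sum(m1))
})

test_that("normalization scales powers as specified and is idempotent", {
  withr::with_seed(31, base <- rnorm(132))
  x <- sts(rbind(a = base, b = 3 * base))   # site B = 3 x site A
  g <- make_timescale_grid(132)
  wf <- wavelet_fieldset(x, g)
  across <- normalize_transforms(wf, "across_locations")
  perloc <- normalize_transforms(wf, "per_location")
  pw <- function(f, n) {
    vapply(seq_along(g$timescales), function(k) {
      m <- f$valid_mask[, k]
      if (!any(m)) return(NA_real_)
      mean(abs(f$coef[m, k, n])^2)
    }, 1.0)
  }
  # across_locations: B keeps 9x A's power; mean across sites is exactly 1
  # (timescales whose cone of influence is empty are NA and excluded)
  ok <- !is.na(pw(across, 1))
  expect_equal(pw(across, 2)[ok], 9 * pw(across, 1)[ok], tolerance = 1e-10)
  expect_equal((pw(across, 1)[ok] + pw(across, 2)[ok]) / 2,
               rep(1, sum(ok)), tolerance = 1e-10, ignore_attr = TRUE)
  # per_location: both sites at unit power
  expect_equal(pw(perloc, 1), pw(perloc, 2), tolerance = 1e-10)
  expect_equal(max(abs(pw(perloc, 1) - 1), na.rm = TRUE), 0, tolerance = 1e-10)
  # renormalizing changes nothing
  again <- normalize_transforms(across, "across_locations")
  expect_lt(max(abs(again$coef - across$coef)), 1e-10)
  # zero-power input names the offending pair
  z <- sts(rbind(base, 0 * base), site_ids = c("a", "zz"))
  expect_error(normalize_transforms(wavelet_fieldset(z, g)), "zz")
})
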