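test_that("fully shared forcing produces perfect phase synchrony", {
  f <- generate_shared_field(5, 132, rho = 1, ar_coef = 0.5,
                             seasonal_amp = 0, seed = 301)
  expect_true(all(apply(f$values, 2, function(col) max(abs(col - col[1]))) == 0))
  w <- wavelet_fieldset(clean_series(f), make_timescale_grid(132))
  expect_equal(min(wavelet_phasor_mean_field(w)[w$valid_mask]), 1,
               tolerance = 1e-12)
})

test_that("independent forcing leaves sites uncorrelated on average", {
  cors <- vapply(1:30, function(r) {
    f <- generate_shared_field(4, 132, rho = 0, ar_coef = 0.5,
                               seasonal_amp = 0, seed = 310 + r)
    cm <- stats::cor(t(f$values))
    mean(cm[lower.tri(cm)])
  }, 1.0)
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("pairwise correlation of the nonseasonal component matches rho", {
  cors <- vapply(1:4, function(r) {
    f <- generate_shared_field(5, 528, rho = 0.5, ar_coef = 0.6,
                               seasonal_amp = 0, seed = 320 + r)
    cm <- stats::cor(t(f$values))
    mean(cm[lower.tri(cm)])
  }, 1.0)
  expect_lt(abs(mean(cors) - 0.5), 0.05)
})

test_that("the cascade generator is seed-deterministic with exact truth", {
  sc <- cascade_scenario(seed = 331)
  g1 <- generate_cascade_scenario(sc)
  g2 <- generate_cascade_scenario(sc)
  expect_identical(g1$data$wrack$values, g2$data$wrack$values)
  expect_identical(g1$data$birds$values, g2$data$birds$values)
  expect_named(g1$data, c("kelp_local", "kelp_regional", "waves", "width",
                          "temp", "wrack", "birds"))
  expect_true(all(vapply(g1$data, function(d) ncol(d$values), 1L) == 132))
  # implied phases from the configured lags
  expect_equal(unname(g1$truth$implied_phase_12mo["birds_vs_wrack"]), -1 / 6)
  expect_equal(unname(g1$truth$implied_phase_12mo["wrack_vs_kelp_regional"]),
               -1 / 6)
  # nonnegative variables really are nonnegative, truncation rate recorded
  for (nm in c("kelp_local", "kelp_regional", "width", "wrack", "birds")) {
    expect_gte(min(g1$data[[nm]]$values), 0)
  }
  expect_true(all(g1$truth$truncation_rates < 0.05))
})

test_that("scenario parameters round-trip through the config file exactly", {
  sc <- cascade_scenario(seed = 341, a = 1 / 3, noise_sd_wrack = 0.123456789,
                         lag_bird = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_identical(unclass(sc), unclass(sc2))
})

test_that("zero coupling yields driver-response rejections at the null rate", {
  ps <- vapply(1:25, function(r) {
    g <- generate_cascade_scenario(
      cascade_scenario(seed = 350 + r, a = 0, b = 0, c = 0, d = 0))
    cl <- preprocess_variables(g$data)
    coherence_test(cl$kelp_regional, cl$wrack, timescale_band(8, 16),
                   n_surr = 99, seed = 400 + r)$p_value
  }, 1.0)
  # 95% binomial band around 0.05 for 25 tries: at most ~5 rejections
  expect_lte(sum(ps < 0.05), 5)
})

test_that("coupling raises explained synchrony over the uncoupled baseline", {
  sync_of <- function(seed, a) {
    g <- generate_cascade_scenario(
      cascade_scenario(seed = seed, a = a, b = 0, c = 0,
                       rho = c(kelp_regional = 0.8, kelp_local = 0.6,
                               waves = 0.8, width = 0.4, temp = 0.95)))
    cl <- preprocess_variables(g$data)
    grid <- make_timescale_grid(ncol(cl$wrack$values))
    fx <- norm_fields(cl$kelp_regional, grid)
    fy <- norm_fields(cl$wrack, grid)
    fit <- fit_wlm(fy, list(kelp = fx), timescale_band(8, 16))
    suppressWarnings(
      synchrony_explained(fit, fy, list(kelp = fx)))$sync_explained
  }
  wins <- vapply(1:10, function(r) {
    sync_of(500 + r, a = 1.5) > sync_of(600 + r, a = 0)
  }, TRUE)
  expect_gte(sum(wins), 9)
})

test_that("driver attribution grows with its coupling gain", {
  contrib_of <- function(bgain, seed) {
    g <- generate_cascade_scenario(cascade_scenario(seed = seed, b = bgain))
    cl <- preprocess_variables(g$data)
    grid <- make_timescale_grid(ncol(cl$wrack$values))
    fx <- list(dwaves = norm_fields(cl$dwaves, grid),
               kelp = norm_fields(cl$kelp_regional, grid))
    fy <- norm_fields(cl$wrack, grid)
    fit <- fit_wlm(fy, fx, timescale_band(2, 8))
    suppressWarnings(
      synchrony_explained(fit, fy, fx))$contributions[["dwaves"]]
  }
  gains <- c(0.3, 1.5, 4)
  cc <- vapply(gains, function(bg) {
    mean(vapply(1:3, function(r) contrib_of(bg, 700 + r), 1.0))
  }, 1.0)
  expect_true(all(diff(cc) > 0))
})
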