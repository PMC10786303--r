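#' Define a synthetic kelp-wrack-shorebird cascade scenario
#'
#' Parameters of the seeded generator that emulates the structure of the
#' monitoring data the analysis targets: 5 sites observed monthly for 11
#' years, strongly seasonal (~12 mo) components with a site-invariant
#' seasonal phase, interannual AR(1) variation split between a spatially
#' shared (Moran) component and site-independent noise, mechanistic wrack
#' formation from kelp, wave-change and beach-width forcing, and a lagged,
#' seasonally modulated consumer (shorebirds).
#'
#' Ground-truth structure: `wrack_n(t) = a * kelp_regional_n(t - lag_kelp) +
#' b * dwaves_n(t) + c * width_n(t) + noise`; `birds_n(t) = e_temp *
#' temp_n(t) + d * wrack_n(t - lag_bird) + noise`; the "local" kelp analog
#' is correlated with (but does not directly drive) wrack, with correlation
#' `local_regional_cor`, mirroring a local measurement of a regionally
#' transported resource.
#'
#' @param n_sites Number of sites (default 5).
#' @param n_months Number of monthly steps (default 132, i.e. 11 years).
#' @param seasonal_amp Named numeric: amplitude of the 12-mo seasonal cosine
#'   per driver variable.
#' @param rho Named numeric in `[0, 1]`: fraction of the nonseasonal AR(1)
#'   variance that is spatially shared, per driver variable.
#' @param seasonal_phase Named numeric: fixed seasonal phase offset (radians)
#'   per driver variable around one shared random base phase, emulating the
#'   calendar locking of annual cycles (kelp biomass and temperature peak in
#'   summer, waves in winter, beach width in late summer).
#' @param ar_coef Named numeric: AR(1) coefficient per driver variable.
#' @param seasonal_mod Strength of the regionally coherent interannual
#'   modulation of each driver's seasonal amplitude (log-scale standard
#'   deviation of the lognormal multiplicative envelope; 0 = a
#'   fixed-amplitude seasonal line).
#' @param env_shared Fraction (on the variance scale) of each variable's
#'   seasonal-modulation process that is one common climate mode shared by
#'   all drivers (the same mode strengthens storm seasons and kelp years),
#'   the remainder being variable-specific.
#' @param a,b,c,d Coupling gains kelp->wrack, dwaves->wrack, width->wrack and
#'   wrack->birds.
#' @param e_temp Gain of air temperature (seasonal forcing) on birds.
#' @param lag_kelp,lag_bird Integer lags in months (>= 0).
#' @param noise_sd_wrack,noise_sd_birds Innovation noise on the constructed
#'   variables.
#' @param local_regional_cor Correlation of the local kelp analog with
#'   regional kelp.
#' @param phase_jitter_sd Per-site jitter (radians) on the seasonal phase;
#'   0 = regionally coherent seasonality.
#' @param baseline_sds Positive shift, in within-site standard deviations,
#'   applied to naturally nonnegative variables before truncation at 0.
#' @param seed Integer seed driving all randomness.
#' @return Object of class `"cascade_scenario"` (a validated list).
#' @export
cascade_scenario <- function(n_sites = 5, n_months = 132,
                             seasonal_amp = c(kelp_regional = 1, kelp_local = 1,
                                              waves = 0.8, width = 0.5,
                                              temp = 1.2),
                             rho = c(kelp_regional = 0.9, kelp_local = 0.6,
                                     waves = 0.8, width = 0.4, temp = 0.95),
                             seasonal_phase = c(kelp_regional = 0,
                                                kelp_local = 0, waves = pi,
                                                width = 0.5, temp = 0.2),
                             ar_coef = c(kelp_regional = 0.7, kelp_local = 0.7,
                                         waves = 0.5, width = 0.6, temp = 0.5),
                             seasonal_mod = 0.8, env_shared = 0.7,
                             a = 1, b = 1.5, c = 0.5, d = 1, e_temp = 1,
                             lag_kelp = 1, lag_bird = 1,
                             noise_sd_wrack = 0.5, noise_sd_birds = 0.5,
                             local_regional_cor = 0.4,
                             phase_jitter_sd = 0, baseline_sds = 3,
                             seed = 1) {
  s <- list(n_sites = as.integer(n_sites), n_months = as.integer(n_months),
            seasonal_amp = seasonal_amp, rho = rho, ar_coef = ar_coef,
            seasonal_phase = seasonal_phase, seasonal_mod = seasonal_mod,
            env_shared = env_shared,
            a = a, b = b, c = c, d = d, e_temp = e_temp,
            lag_kelp = as.integer(lag_kelp), lag_bird = as.integer(lag_bird),
            noise_sd_wrack = noise_sd_wrack, noise_sd_birds = noise_sd_birds,
            local_regional_cor = local_regional_cor,
            phase_jitter_sd = phase_jitter_sd, baseline_sds = baseline_sds,
            seed = as.integer(seed))
  vars <- c("kelp_regional", "kelp_local", "waves", "width", "temp")
  stopifnot(s$n_sites >= 2, s$n_months >= 48,
            all(vars %in% names(s$seasonal_amp)),
            all(vars %in% names(s$rho)), all(vars %in% names(s$ar_coef)),
            all(vars %in% names(s$seasonal_phase)),
            all(s$rho >= 0 & s$rho <= 1), s$seasonal_mod >= 0,
            s$env_shared >= 0, s$env_shared <= 1,
            all(abs(s$ar_coef) < 1),
            s$lag_kelp >= 0, s$lag_bird >= 0,
            abs(s$local_regional_cor) <= 1)
  structure(s, class = "cascade_scenario")
}

# AR(1) with unit-variance innovations, stationary start.
ar1_series <- function(n, phi) {
  x0 <- stats::rnorm(1, 0, 1 / sqrt(1 - phi^2))
  as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive",
                           init = x0))
}

# standardized slow process (AR(1) at coefficient 0.9, unit stationary sd)
# used to modulate seasonal amplitudes between years; the high coefficient
# keeps the modulation sidebands close to the 12-mo line (inside the 8-16 mo
# band) rather than leaking into interannual timescales
mod_process <- function(n_months) ar1_series(n_months, 0.9) * sqrt(1 - 0.9^2)

shared_field_values <- function(n_sites, n_months, rho, ar_coef, seasonal_amp,
                                phase_jitter_sd = 0, phi0 = NULL,
                                seasonal_mod = 0, mod_z = NULL) {
  if (is.null(phi0)) phi0 <- stats::runif(1, 0, 2 * pi)
  jit <- if (phase_jitter_sd > 0) {
    stats::rnorm(n_sites, 0, phase_jitter_sd)
  } else rep(0, n_sites)
  common <- ar1_series(n_months, ar_coef)
  # regionally coherent year-to-year modulation of the seasonal amplitude:
  # lognormal (right-skewed, always positive) envelope with unit mean,
  # emulating strong vs weak storm seasons and good vs poor kelp years
  env <- if (seasonal_mod > 0) {
    if (is.null(mod_z)) mod_z <- mod_process(n_months)
    exp(seasonal_mod * mod_z - seasonal_mod^2 / 2)
  } else rep(1, n_months)
  tt <- seq_len(n_months)
  v <- matrix(NA_real_, n_sites, n_months)
  for (i in seq_len(n_sites)) {
    v[i, ] <- seasonal_amp * env * cos(2 * pi * tt / 12 + phi0 + jit[i]) +
      sqrt(rho) * common + sqrt(1 - rho) * ar1_series(n_months, ar_coef)
  }
  v
}

#' Generate one spatially shared (Moran-forced) driver field
#'
#' Per site: a 12-month seasonal cosine with a site-invariant phase, plus
#' `sqrt(rho)` times a spatially common AR(1) process and `sqrt(1 - rho)`
#' times a site-independent AR(1) process, both with unit-variance
#' innovations. The expected pairwise between-site correlation of the
#' nonseasonal component is `rho`.
#'
#' @param n_sites,n_months Field dimensions.
#' @param rho Shared fraction of the nonseasonal variance, in `[0, 1]`.
#' @param ar_coef AR(1) coefficient, `|ar_coef| < 1`.
#' @param seasonal_amp Seasonal amplitude.
#' @param seed Optional integer seed.
#' @param phase_jitter_sd Per-site seasonal phase jitter (radians).
#' @param t0 Calendar month of the first column.
#' @return An [sts()].
#' @export
generate_shared_field <- function(n_sites, n_months, rho, ar_coef,
                                  seasonal_amp, seed = NULL,
                                  phase_jitter_sd = 0, t0 = "2009-01") {
  stopifnot(rho >= 0, rho <= 1, abs(ar_coef) < 1, n_sites >= 1, n_months >= 2)
  gen <- function() shared_field_values(n_sites, n_months, rho, ar_coef,
                                        seasonal_amp, phase_jitter_sd)
  v <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  sts(v, site_ids = paste0("site", seq_len(n_sites)), t0 = t0)
}

# Shift a variable positive (baseline_sds within-site sds) and truncate at 0;
# returns values plus truncation rate.
shift_truncate <- function(v, baseline_sds) {
  for (i in seq_len(nrow(v))) v[i, ] <- v[i, ] + baseline_sds * stats::sd(v[i, ])
  rate <- mean(v < 0)
  v[v < 0] <- 0
  list(values = v, truncation_rate = rate)
}

#' Generate a full synthetic cascade dataset with known ground truth
#'
#' Draws the driver fields, builds wrack and shorebird abundances from the
#' scenario's mechanistic equations, shifts/truncates the naturally
#' nonnegative variables (wrack, birds, width, both kelp series) to be
#' nonnegative, and records the implied ground truth (gains, lags, and the
#' band phases implied by the lags at the 12-month timescale, e.g.
#' `lag_bird = 1` implies `phi = -2 * 1 / 12 = -1/6` in fractions of pi).
#'
#' @param s A [cascade_scenario()].
#' @return List with `data` (named list of [sts()]: `kelp_local`,
#'   `kelp_regional`, `waves`, `width`, `temp`, `wrack`, `birds`), `truth`
#'   (gains, lags, implied phases, truncation rates), and `scenario`.
#' @export
generate_cascade_scenario <- function(s) {
  stopifnot(inherits(s, "cascade_scenario"))
  withr::with_seed(s$seed, {
    lead <- max(s$lag_kelp, s$lag_bird) + 1L   # burn-in columns for lags/diff
    Tf <- s$n_months + lead
    N <- s$n_sites
    base_phase <- stats::runif(1, 0, 2 * pi)
    z_climate <- mod_process(Tf)     # common mode modulating all drivers
    fld <- function(v, Tlen = Tf) {
      z_v <- sqrt(s$env_shared) * z_climate +
        sqrt(1 - s$env_shared) * mod_process(Tlen)
      shared_field_values(N, Tlen, s$rho[[v]], s$ar_coef[[v]],
                          s$seasonal_amp[[v]], s$phase_jitter_sd,
                          phi0 = base_phase + s$seasonal_phase[[v]],
                          seasonal_mod = s$seasonal_mod, mod_z = z_v)
    }
    kelp_regional <- fld("kelp_regional")
    kelp_local <- s$local_regional_cor * kelp_regional +
      sqrt(1 - s$local_regional_cor^2) * fld("kelp_local")
    waves <- fld("waves")
    width <- fld("width")
    temp <- fld("temp")

    dwaves <- cbind(matrix(0, N, 1), waves[, -1] - waves[, -Tf])
    lagm <- function(v, lag) {
      if (lag == 0) v else cbind(matrix(0, N, lag), v[, 1:(Tf - lag)])
    }
    wrack <- s$a * lagm(kelp_regional, s$lag_kelp) + s$b * dwaves +
      s$c * width + s$noise_sd_wrack * matrix(stats::rnorm(N * Tf), N, Tf)
    birds <- s$e_temp * temp + s$d * lagm(wrack, s$lag_bird) +
      s$noise_sd_birds * matrix(stats::rnorm(N * Tf), N, Tf)

    keep <- (lead + 1):Tf
    trunc_rates <- c()
    out <- list()
    raw <- list(kelp_local = kelp_local, kelp_regional = kelp_regional,
                waves = waves, width = width, temp = temp,
                wrack = wrack, birds = birds)
    nonneg <- c("kelp_local", "kelp_regional", "width", "wrack", "birds")
    for (nm in names(raw)) {
      v <- raw[[nm]][, keep, drop = FALSE]
      if (nm %in% nonneg) {
        stv <- shift_truncate(v, s$baseline_sds)
        v <- stv$values
        trunc_rates[nm] <- stv$truncation_rate
      }
      out[[nm]] <- sts(v, site_ids = paste0("site", seq_len(N)))
    }
    truth <- list(
      gains = c(a = s$a, b = s$b, c = s$c, d = s$d, e_temp = s$e_temp),
      lags = c(kelp = s$lag_kelp, bird = s$lag_bird),
      implied_phase_12mo = c(
        wrack_vs_kelp_regional = wrap_phi(-2 * s$lag_kelp / 12),
        birds_vs_wrack = wrap_phi(-2 * s$lag_bird / 12),
        wrack_vs_dwaves = 0, wrack_vs_width = 0),
      truncation_rates = trunc_rates,
      seed = s$seed
    )
    list(data = out, truth = truth, scenario = s)
  })
}

# wrap a fractions-of-pi phase into (-1, 1]
wrap_phi <- function(phi) {
  out <- ((phi + 1) %% 2) - 1
  if (out == -1) 1 else out
}
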