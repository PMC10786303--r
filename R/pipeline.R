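# ---- raw-table aggregation ----------------------------------------------

# long (site, month, value) -> sts, aggregating replicate rows with `fun`;
# the site x month grid must be complete after aggregation.
long_to_sts <- function(df, fun, units = "") {
  stopifnot(all(c("site", "month", "value") %in% names(df)))
  sites <- unique(df$site)
  months <- sort(unique(month_num(unique(df$month))))
  if (!all(diff(months) == 1L)) {
    gap <- num_month(setdiff(seq(months[1], months[length(months)]), months)[1])
    stop("month index has a gap at ", gap)
  }
  agg <- stats::aggregate(value ~ site + month, data = df, FUN = fun)
  v <- matrix(NA_real_, length(sites), length(months),
              dimnames = list(sites, num_month(months)))
  v[cbind(match(agg$site, sites), match(month_num(agg$month), months))] <-
    agg$value
  if (anyNA(v)) {
    ij <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop(sprintf("no observation for site '%s' in month %s",
                 sites[ij[1]], num_month(months)[ij[2]]))
  }
  sts(v, site_ids = sites, t0 = num_month(months[1]), units = units)
}

#' Aggregate transect-level wrack surveys to site-month means
#'
#' Replicate cross-shore transect measurements within a site and survey month
#' are averaged to one value per site per month.
#'
#' @param df Data frame with columns `site`, `month` (`"YYYY-MM"`), `value`
#'   (and optionally `transect`, ignored).
#' @param units Units string for the result.
#' @return An [sts()].
#' @export
aggregate_transects <- function(df, units = "m per transect") {
  long_to_sts(df, mean, units)
}

#' Total species-level bird counts into aggregate shorebird abundance
#'
#' Counts of species in the configured shorebird list are summed per site and
#' month; records of species not in the list are excluded with a warning.
#'
#' @param df Data frame with columns `site`, `month`, `species`, `value`.
#' @param species Character vector of shorebird species to include.
#' @return An [sts()] of aggregate abundances.
#' @export
aggregate_species <- function(df, species) {
  stopifnot(all(c("site", "month", "species", "value") %in% names(df)))
  bad <- !(df$species %in% species)
  if (any(bad)) {
    warning("excluding species not in the shorebird list: ",
            paste(unique(df$species[bad]), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  long_to_sts(df[, c("site", "month", "value")], sum, "birds per transect")
}

#' Aggregate daily values to monthly means
#'
#' Used for wave data: daily maximum significant wave heights are averaged
#' within each month to one monthly value per site.
#'
#' @param df Data frame with columns `site`, `month` (`"YYYY-MM"`), `value`
#'   (one row per day).
#' @param units Units string.
#' @return An [sts()] of monthly means.
#' @export
aggregate_daily <- function(df, units = "m") {
  long_to_sts(df, mean, units)
}

#' Preprocess raw variables for the cascade analysis
#'
#' Applies the dataset-specific aggregation rules (transect means for wrack,
#' species totals for birds, monthly means of daily maxima for waves), takes
#' the first difference of wave intensity (the mechanistically relevant
#' quantity for wrack production), aligns every variable on the common
#' months 2..T imposed by differencing (the difference `x(t) - x(t-1)` is
#' indexed at the later month `t`), and cleans each series (detrend and
#' standardize by default).
#'
#' @param raw Named list. Recognized entries: [sts()] objects `kelp_local`,
#'   `kelp_regional`, `waves` (monthly), `width`, `temp`, `wrack`, `birds`;
#'   or raw tables `wrack_transects`, `birds_species`, `waves_daily` (see
#'   the aggregation helpers).
#' @param shorebird_species Species list for `birds_species`.
#' @param detrend,standardize,boxcox Passed to [clean_series()].
#' @return Named list of cleaned, aligned [sts()] objects; `waves` is
#'   replaced by its first difference `dwaves`.
#' @export
preprocess_variables <- function(raw, shorebird_species = NULL,
                                 detrend = TRUE, standardize = TRUE,
                                 boxcox = FALSE) {
  vars <- list()
  if (!is.null(raw$wrack_transects)) {
    vars$wrack <- aggregate_transects(raw$wrack_transects)
  } else vars$wrack <- raw$wrack
  if (!is.null(raw$birds_species)) {
    if (is.null(shorebird_species)) stop("birds_species needs shorebird_species")
    vars$birds <- aggregate_species(raw$birds_species, shorebird_species)
  } else vars$birds <- raw$birds
  waves <- if (!is.null(raw$waves_daily)) aggregate_daily(raw$waves_daily)
           else raw$waves
  for (nm in c("kelp_local", "kelp_regional", "width", "temp")) {
    vars[[nm]] <- raw[[nm]]
  }
  vars <- vars[!vapply(vars, is.null, TRUE)]
  if (!is.null(waves)) vars$dwaves <- first_difference(waves)
  # align on the intersection of months (differencing drops the first month)
  common <- Reduce(intersect, lapply(vars, function(v) v$months))
  if (length(common) < 24) stop("fewer than 24 common months across variables")
  vars <- lapply(vars, function(v) {
    sts_window(v, from = common[1], to = common[length(common)])
  })
  lapply(vars, clean_series, detrend = detrend, standardize = standardize,
         boxcox = boxcox)
}

# ---- driver screening ----------------------------------------------------

#' Screen candidate drivers for coherence with a response, per band
#'
#' Runs one surrogate coherence test per (driver, band) pair and selects, for
#' each band, the drivers coherent with the response at `P < alpha_screen`
#' (0.1 by default). When both the local and the regional kelp
#' analogs pass in the same band, only the one with the lower P-value is kept
#' for the multivariate model (ties at the attainable floor are broken by the
#' larger band coherence magnitude). Rejections at 0.05 are also counted to
#' support the multiple-testing accounting (n tests vs n significant).
#'
#' @param response Cleaned response [sts()] (kelp wrack in the motivating
#'   system).
#' @param candidates Named list of cleaned candidate driver [sts()] objects.
#' @param bands Named list of [timescale_band()]s (default [default_bands()]).
#' @param alpha_screen Screening level for model inclusion (default 0.1).
#' @param alpha_sig Level used for the significance count (default 0.05).
#' @param n_surr,surr_type,method,grid,coi_factor Passed to
#'   [coherence_test()].
#' @param seed Optional base seed; test `i` uses `seed + i`.
#' @param exclusive_pair Names of the two mutually exclusive candidates
#'   (default the local/regional kelp analogs); set `NULL` to disable.
#' @return Object of class `"screening"`: list with `table` (data frame:
#'   driver, band, p_value, phi, magnitude, selected, reason), `alpha_screen`,
#'   `alpha_sig`, `n_tests`, `n_reject_sig`, `n_surr`, `seed`.
#' @export
screen_drivers <- function(response, candidates, bands = default_bands(),
                           alpha_screen = 0.1, alpha_sig = 0.05,
                           n_surr = 1000, surr_type = "fourier",
                           method = "fast", seed = NULL, grid = NULL,
                           coi_factor = 1,
                           exclusive_pair = c("kelp_local", "kelp_regional")) {
  stopifnot(inherits(response, "sts"), length(candidates) >= 1)
  rows <- list()
  i <- 0L
  for (bn in names(bands)) {
    for (dn in names(candidates)) {
      i <- i + 1L
      ct <- coherence_test(candidates[[dn]], response, bands[[bn]],
                           n_surr = n_surr, surr_type = surr_type,
                           method = method,
                           seed = if (is.null(seed)) NULL else seed + i,
                           grid = grid, coi_factor = coi_factor)
      rows[[i]] <- data.frame(driver = dn, band = bn, p_value = ct$p_value,
                              phi = ct$phi, magnitude = ct$magnitude,
                              selected = ct$p_value < alpha_screen,
                              reason = "", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$reason <- ifelse(tab$selected, "coherent (P < alpha_screen)",
                       "not coherent (P >= alpha_screen)")
  if (!is.null(exclusive_pair) && all(exclusive_pair %in% tab$driver)) {
    for (bn in unique(tab$band)) {
      ii <- which(tab$band == bn & tab$driver %in% exclusive_pair &
                    tab$selected)
      if (length(ii) == 2L) {
        ord <- order(tab$p_value[ii], -tab$magnitude[ii])
        drop <- ii[ord[2]]
        tab$selected[drop] <- FALSE
        tab$reason[drop] <- sprintf(
          "excluded: '%s' coherent with lower P in this band",
          tab$driver[ii[ord[1]]])
      }
    }
  }
  structure(
    list(table = tab, alpha_screen = alpha_screen, alpha_sig = alpha_sig,
         n_tests = nrow(tab), n_reject_sig = sum(tab$p_value < alpha_sig),
         n_surr = n_surr, seed = seed),
    class = "screening"
  )
}

#' @export
print.screening <- function(x, ...) {
  cat(sprintf("driver screening: %d tests, %d significant at %g, %s\n",
              x$n_tests, x$n_reject_sig, x$alpha_sig,
              sprintf("%d selected at %g", sum(x$table$selected),
                      x$alpha_screen)))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Classify a band phase relationship
#'
#' Interprets a phase `phi` (fractions of pi) using the interval convention
#' of the subsidy-cascade analysis: approximately in-phase when
#' `-0.25 < phi < 0.25`, approximately anti-phase when `phi < -0.75` or
#' `phi > 0.75`; otherwise a negative phase means the response lags the
#' driver and a positive phase means response peaks precede the driver's.
#' Boundary values (`|phi|` exactly 0.25 or 0.75) fall in the lag/lead
#' categories, reading the in-/anti-phase intervals as strict.
#'
#' @param phi Numeric vector of phases in `(-1, 1]`, fractions of pi.
#' @param response_role,driver_role Names used only for labelling context.
#' @return Character vector with levels `"in-phase"`, `"anti-phase"`,
#'   `"response-lags-driver"`, `"response-leads-driver"`.
#' @export
classify_phase <- function(phi, response_role = "response",
                           driver_role = "driver") {
  stopifnot(all(phi > -1 - 1e-12 & phi <= 1 + 1e-12))
  out <- ifelse(phi > -0.25 & phi < 0.25, "in-phase",
         ifelse(phi < -0.75 | phi > 0.75, "anti-phase",
         ifelse(phi < 0, "response-lags-driver", "response-leads-driver")))
  out
}

# ---- end-to-end cascade --------------------------------------------------

#' Configuration for the cascade analysis
#'
#' @param bands Named list of [timescale_band()]s.
#' @param alpha_screen Driver-screening level (model inclusion).
#' @param alpha_sig Significance level for synchrony contours and the
#'   rejection counts.
#' @param n_surr Surrogates per coherence test.
#' @param n_rand Random-phasor draws for phasor-mean-field thresholds.
#' @param n_surr_diag Surrogates for model residual diagnostics (0 disables
#'   the residual coherence tests).
#' @param seed Integer base seed; every random stage derives its seed from it.
#' @param coi_factor Cone-of-influence margin.
#' @param method Coherence test scheme, `"fast"` or `"slow"`.
#' @param detrend,standardize,boxcox Cleaning options.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(bands = default_bands(), alpha_screen = 0.1,
                       alpha_sig = 0.05, n_surr = 1000, n_rand = 1000,
                       n_surr_diag = 200, seed = 1, coi_factor = 1,
                       method = "fast", detrend = TRUE, standardize = TRUE,
                       boxcox = FALSE) {
  stopifnot(is.numeric(seed), seed == round(seed), abs(seed) < 2^30)
  structure(
    list(bands = bands, alpha_screen = alpha_screen, alpha_sig = alpha_sig,
         n_surr = n_surr, n_rand = n_rand, n_surr_diag = n_surr_diag,
         seed = as.integer(seed), coi_factor = coi_factor, method = method,
         detrend = detrend, standardize = standardize, boxcox = boxcox),
    class = "run_config"
  )
}

# Fit one WLM stage (fields already normalized), returning the per-band model
# summary used by the report.
fit_band_model <- function(response_name, predictor_names, fields, series,
                           band, cfg, seed_offset, caution = FALSE) {
  y_f <- fields[[response_name]]
  x_f <- fields[predictor_names]
  fit <- fit_wlm(y_f, x_f, band)
  se <- withCallingHandlers(
    synchrony_explained(fit, y_f, x_f),
    warning = function(w) invokeRestart("muffleWarning"))
  phases <- vapply(predictor_names, function(nm) {
    model_band_phase(fit, nm, y_f, x_f)
  }, 1.0)
  diag <- wlm_diagnostics(
    fit, y_f, x_f,
    x_series = if (cfg$n_surr_diag > 0) series[predictor_names] else NULL,
    n_surr = max(cfg$n_surr_diag, 19), alpha = cfg$alpha_sig,
    n_rand = cfg$n_rand, seed = cfg$seed + seed_offset)
  list(response = response_name, predictors = predictor_names,
       band = c(lo = band$lo, hi = band$hi),
       sync_explained = se$sync_explained, S_obs = se$S_obs, S_mod = se$S_mod,
       contributions = as.list(se$contributions),
       crossterms = as.list(se$crossterms),
       phases = as.list(phases),
       phase_labels = as.list(classify_phase(phases)),
       mean_r_squared = mean(diag$r_squared),
       resid_sync_frac = diag$resid_sync_frac,
       resid_coherence = if (is.null(diag$resid_coherence)) NULL else
         lapply(seq_len(nrow(diag$resid_coherence)), function(i)
           as.list(diag$resid_coherence[i, ])),
       caution = caution,
       fit = fit)
}

#' Run the full subsidy-cascade synchrony analysis
#'
#' The end-to-end pipeline: preprocessing (wave first-differencing, common
#' alignment, cleaning), wrack mean fields with significance contours,
#' per-band driver screening, per-band multivariate wavelet linear models of
#' wrack with synchrony attribution and phases, shorebird mean fields,
#' bird--wrack coherence per band, bird models (wrack + air temperature as
#' predictors in every band, caution-flagged where bird--wrack coherence is
#' not significant), and a multiple-testing summary. Fully deterministic
#' given `config$seed`.
#'
#' @param data Named list of raw [sts()] objects: `kelp_local`,
#'   `kelp_regional`, `waves`, `width`, `temp`, `wrack`, `birds` (or the raw
#'   tables accepted by [preprocess_variables()]).
#' @param config A [run_config()].
#' @param shorebird_species Optional species list for raw bird tables.
#' @return Object of class `"cascade_report"`; serialize with
#'   [write_report()].
#' @export
run_cascade <- function(data, config = run_config(),
                        shorebird_species = NULL) {
  cfg <- config
  cleaned <- preprocess_variables(data, shorebird_species,
                                  detrend = cfg$detrend,
                                  standardize = cfg$standardize,
                                  boxcox = cfg$boxcox)
  need <- c("kelp_local", "kelp_regional", "dwaves", "width", "temp",
            "wrack", "birds")
  missing_v <- setdiff(need, names(cleaned))
  if (length(missing_v)) stop("missing variables: ",
                              paste(missing_v, collapse = ", "))
  T_len <- ncol(cleaned$wrack$values)
  grid <- make_timescale_grid(T_len)
  kernels <- morlet_kernels(T_len, grid)
  fields <- lapply(cleaned, function(v) {
    normalize_transforms(
      wavelet_fieldset(v, grid, cfg$coi_factor, kernels), "across_locations")
  })

  # (1) wrack synchrony + significance contours
  wrack_mf <- mean_field(fields$wrack, alpha = cfg$alpha_sig,
                         n_rand = cfg$n_rand, seed = cfg$seed + 1L)
  # (2) driver screening: 4 drivers x bands
  drivers <- c("kelp_local", "kelp_regional", "dwaves", "width")
  scr <- screen_drivers(cleaned$wrack, cleaned[drivers], bands = cfg$bands,
                        alpha_screen = cfg$alpha_screen,
                        alpha_sig = cfg$alpha_sig, n_surr = cfg$n_surr,
                        method = cfg$method, seed = cfg$seed + 1000L,
                        grid = grid, coi_factor = cfg$coi_factor)
  # (3) per-band wrack models from the selected drivers
  wrack_models <- list()
  for (bi in seq_along(cfg$bands)) {
    bn <- names(cfg$bands)[bi]
    sel <- scr$table$driver[scr$table$band == bn & scr$table$selected]
    wrack_models[bn] <- list(if (length(sel) == 0) NULL else
      fit_band_model("wrack", sel, fields, cleaned, cfg$bands[[bi]], cfg,
                     seed_offset = 2000L + 10L * bi))
  }
  # (4) bird synchrony
  bird_mf <- mean_field(fields$birds, alpha = cfg$alpha_sig,
                        n_rand = cfg$n_rand, seed = cfg$seed + 2L)
  # (5) bird-wrack coherence per band
  bird_coh <- list()
  for (bi in seq_along(cfg$bands)) {
    bn <- names(cfg$bands)[bi]
    ct <- coherence_test(cleaned$wrack, cleaned$birds, cfg$bands[[bi]],
                         n_surr = cfg$n_surr, method = cfg$method,
                         seed = cfg$seed + 3000L + bi, grid = grid,
                         coi_factor = cfg$coi_factor)
    bird_coh[[bn]] <- list(p_value = ct$p_value, phi = ct$phi,
                           magnitude = ct$magnitude,
                           phase_label = classify_phase(ct$phi))
  }
  # (6) bird models: wrack + air temperature, all bands, caution-flagged
  bird_models <- list()
  for (bi in seq_along(cfg$bands)) {
    bn <- names(cfg$bands)[bi]
    caution <- bird_coh[[bn]]$p_value >= cfg$alpha_sig
    bird_models[[bn]] <- fit_band_model("birds", c("wrack", "temp"), fields,
                                        cleaned, cfg$bands[[bi]], cfg,
                                        seed_offset = 4000L + 10L * bi,
                                        caution = caution)
  }
  # (7) multiple-testing summary
  sig_summary <- list(
    wrack_driver_tests = scr$n_tests,
    wrack_driver_reject_sig = scr$n_reject_sig,
    bird_wrack_tests = length(bird_coh),
    bird_wrack_reject_sig = sum(vapply(bird_coh, function(z)
      z$p_value < cfg$alpha_sig, TRUE)),
    alpha = cfg$alpha_sig)

  structure(
    list(schema_version = "1.0",
         config = list(
           bands = lapply(cfg$bands, function(b) c(lo = b$lo, hi = b$hi)),
           alpha_screen = cfg$alpha_screen, alpha_sig = cfg$alpha_sig,
           n_surr = cfg$n_surr, n_rand = cfg$n_rand,
           n_surr_diag = cfg$n_surr_diag, seed = cfg$seed,
           coi_factor = cfg$coi_factor, method = cfg$method),
         months = cleaned$wrack$months,
         wrack_meanfield = wrack_mf,
         wrack_screening = scr,
         wrack_models = wrack_models,
         bird_meanfield = bird_mf,
         bird_coherence = bird_coh,
         bird_models = bird_models,
         significance_summary = sig_summary),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade synchrony report\n")
  cat(sprintf("  months analyzed: %s .. %s (%d)\n", x$months[1],
              x$months[length(x$months)], length(x$months)))
  cat(sprintf("  wrack screening: %d tests, %d significant at %g\n",
              x$significance_summary$wrack_driver_tests,
              x$significance_summary$wrack_driver_reject_sig,
              x$significance_summary$alpha))
  for (bn in names(x$wrack_models)) {
    m <- x$wrack_models[[bn]]
    if (is.null(m)) {
      cat(sprintf("  wrack %s mo: no coherent drivers (model-free)\n", bn))
    } else {
      cat(sprintf("  wrack %s mo: predictors %s; synchrony explained %.2f\n",
                  bn, paste(m$predictors, collapse = "+"), m$sync_explained))
    }
  }
  for (bn in names(x$bird_models)) {
    m <- x$bird_models[[bn]]
    cat(sprintf("  birds %s mo: P(bird-wrack)=%.3g, %s %.2f%s\n", bn,
                x$bird_coherence[[bn]]$p_value, "synchrony explained",
                m$sync_explained, if (m$caution) " [caution]" else ""))
  }
  invisible(x)
}
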