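#' Fit a multivariate wavelet linear model
#'
#' At each grid timescale inside the band, regresses the response's
#' `across_locations`-normalized wavelet coefficients on the predictors'
#' coefficients by complex least squares, pooling observations over sites and
#' cone-valid times. No intercept is fitted: cleaned series and their wavelet
#' fields are zero-mean, so an intercept is not identifiable. The coefficients
#' are the unique normal-equations solution minimizing
#' `sum |w~y - sum_j beta_j w~x_j|^2`.
#'
#' @param y_fields Response `"wfs"`, normalized `across_locations`.
#' @param x_fields Named list of predictor `"wfs"` objects (same sites,
#'   months, grid and mask, all normalized `across_locations`).
#' @param band A [timescale_band()].
#' @param cond_limit Condition-number limit for the pooled predictor matrix
#'   at each timescale; beyond it the predictors are declared collinear.
#' @return Object of class `"wlm_fit"`: list with `response`, `predictors`,
#'   `band`, `band_timescales`, `band_idx`, `coeffs` (complex matrix,
#'   predictors x band timescales), `coef_phase` (arg(beta)/pi per
#'   timescale), `grid`, `months`, `valid_mask`.
#' @export
fit_wlm <- function(y_fields, x_fields, band, cond_limit = 1e8) {
  stopifnot(inherits(y_fields, "wfs"), inherits(band, "tsband"),
            is.list(x_fields), length(x_fields) >= 1)
  if (is.null(names(x_fields)) || any(!nzchar(names(x_fields)))) {
    names(x_fields) <- paste0("x", seq_along(x_fields))
  }
  for (xf in x_fields) {
    stopifnot(inherits(xf, "wfs"))
    check_compatible_wfs(y_fields, xf)
    if (xf$normalization != "across_locations") {
      stop("all predictor fields must be normalized across_locations")
    }
  }
  if (y_fields$normalization != "across_locations") {
    stop("response fields must be normalized across_locations")
  }
  idx <- band_indices(y_fields$grid, band)
  idx <- idx[colSums(y_fields$valid_mask[, idx, drop = FALSE]) > 0]
  if (length(idx) == 0L) stop("band contains no timescales with valid points")
  p <- length(x_fields)
  coeffs <- matrix(NA_complex_, p, length(idx),
                   dimnames = list(names(x_fields),
                                   signif(y_fields$grid$timescales[idx], 6)))
  for (j in seq_along(idx)) {
    k <- idx[j]
    m <- y_fields$valid_mask[, k]
    yv <- as.vector(y_fields$coef[m, k, ])
    X <- vapply(x_fields, function(xf) as.vector(xf$coef[m, k, ]),
                complex(length(yv)))
    dim(X) <- c(length(yv), p)
    sv <- svd(X)
    if (min(sv$d) <= 0 || max(sv$d) / min(sv$d) > cond_limit) {
      stop(sprintf("collinear predictors at timescale %.4g months",
                   y_fields$grid$timescales[k]))
    }
    # pseudo-inverse via the SVD: X = U diag(d) V^H
    coeffs[, j] <- sv$v %*% ((Conj(t(sv$u)) %*% yv) / sv$d)
  }
  structure(
    list(response = "y", predictors = names(x_fields), band = band,
         band_timescales = y_fields$grid$timescales[idx], band_idx = idx,
         coeffs = coeffs, coef_phase = Arg(coeffs) / pi,
         grid = y_fields$grid, months = y_fields$months,
         valid_mask = y_fields$valid_mask),
    class = "wlm_fit"
  )
}

#' @export
print.wlm_fit <- function(x, ...) {
  cat(sprintf("wavelet linear model, band [%g, %g] mo, %d timescales\n",
              x$band$lo, x$band$hi, length(x$band_timescales)))
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("  band-median |beta|:",
      paste(sprintf("%s=%.3f", x$predictors,
                    apply(abs(x$coeffs), 1, stats::median)), collapse = ", "),
      "\n")
  invisible(x)
}

# Per-predictor component mean fields M_j(t, k) = beta_j(k) * meanfield of
# predictor j's normalized coefficients (band timescales only).
component_mean_fields <- function(model, x_fields) {
  lapply(seq_along(model$predictors), function(jj) {
    xf <- x_fields[[model$predictors[jj]]]
    if (is.null(xf)) xf <- x_fields[[jj]]
    xmf <- rowMeans(xf$coef[, model$band_idx, , drop = FALSE], dims = 2)
    sweep(xmf, 2, model$coeffs[jj, ], "*")
  })
}

#' Model-predicted wavelet mean field
#'
#' The wavelet mean field of the fitted values `sum_j beta_j w~x_j,n`,
#' comparable cell-by-cell with the observed response mean field (e.g. to
#' track the ~12-month component of predicted vs observed synchrony through
#' time).
#'
#' @param model A fitted `"wlm_fit"`.
#' @param x_fields The predictor field list used in fitting.
#' @return Complex matrix, months x band timescales.
#' @export
predicted_mean_field <- function(model, x_fields) {
  stopifnot(inherits(model, "wlm_fit"))
  comp <- component_mean_fields(model, x_fields)
  Reduce(`+`, comp)
}

#' Fraction of synchrony explained, with per-driver attribution
#'
#' Implements the model-based decomposition of spatial synchrony: observed
#' band synchrony `S_obs` is the mean over band timescales and cone-valid
#' times of the squared response mean-field magnitude; model synchrony
#' `S_mod` is the same functional of the predicted mean field; and writing
#' `M_j` for the mean field of predictor j's fitted component,
#' `S_mod = sum_j mean|M_j|^2 + sum_(j<k) mean 2 Re(M_j conj(M_k))`
#' holds exactly. The first terms are the nonnegative per-driver
#' contributions; the signed cross terms are pairwise interaction effects
#' (positive = synergistic, negative = antagonistic).
#'
#' @param model A fitted `"wlm_fit"`.
#' @param y_fields Response fields used in fitting.
#' @param x_fields Predictor field list used in fitting.
#' @return List with `sync_explained` (= `S_mod / S_obs`; may exceed 1 in
#'   overfit cases and is then reported raw with a warning), `S_obs`,
#'   `S_mod`, `contributions` (named, nonnegative), `crossterms` (named
#'   `"a:b"`, signed).
#' @export
synchrony_explained <- function(model, y_fields, x_fields) {
  stopifnot(inherits(model, "wlm_fit"))
  m_band <- model$valid_mask[, model$band_idx, drop = FALSE]
  band_mean <- function(z) mean(z[m_band])
  wmf_y <- rowMeans(y_fields$coef[, model$band_idx, , drop = FALSE], dims = 2)
  S_obs <- band_mean(abs(wmf_y)^2)
  if (S_obs < 1e-12) stop("observed band synchrony is ~0; nothing to explain")
  comp <- component_mean_fields(model, x_fields)
  pred <- Reduce(`+`, comp)
  S_mod <- band_mean(abs(pred)^2)
  p <- length(comp)
  contributions <- vapply(comp, function(M) band_mean(abs(M)^2), 1.0)
  names(contributions) <- model$predictors
  crossterms <- numeric(0)
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    crossterms <- apply(pairs, 2, function(jk) {
      band_mean(2 * Re(comp[[jk[1]]] * Conj(comp[[jk[2]]])))
    })
    names(crossterms) <- apply(pairs, 2, function(jk) {
      paste(model$predictors[jk[1]], model$predictors[jk[2]], sep = ":")
    })
  }
  sync_explained <- S_mod / S_obs
  if (sync_explained > 1 + 1e-8) {
    warning(sprintf("sync_explained = %.3f exceeds 1 (possible overfit); %s",
                    sync_explained, "reported unclipped"))
  }
  list(sync_explained = sync_explained, S_obs = S_obs, S_mod = S_mod,
       contributions = contributions, crossterms = crossterms)
}

#' Band phase of a predictor in a fitted wavelet linear model
#'
#' The phase relationship between the response and one predictor, aggregated
#' over the band: the argument (in fractions of pi, mapped to `(-1, 1]`) of
#' the `|beta|`-weighted band average of the per-timescale cross-products
#' `mean(conj(w~x_j) * (w~y - sum_(k != j) beta_k w~x_k))` over sites and
#' valid times: the other predictors' fitted components are partialled out of
#' the response first, so that (for example) a seasonal covariate in the
#' model does not contaminate the phase read off for the predictor of
#' interest. Weighting by the fitted coefficient modulus concentrates the
#' phase estimate on the timescales where the model actually uses the
#' predictor, keeping it interpretable when the coefficient varies across a
#' multi-octave band.
#' The sign convention matches the coherence phase: negative (and not
#' in/anti-phase) means the response lags the predictor. Raw `arg(beta)` per
#' timescale is available in the fit as `coef_phase`.
#'
#' @param model A fitted `"wlm_fit"`.
#' @param predictor Predictor name.
#' @param y_fields,x_fields Fields used in fitting.
#' @return Scalar `phi` in `(-1, 1]`, fractions of pi.
#' @export
model_band_phase <- function(model, predictor, y_fields, x_fields) {
  stopifnot(inherits(model, "wlm_fit"))
  jj <- match(predictor, model$predictors)
  if (is.na(jj)) stop("unknown predictor: ", predictor)
  w <- abs(model$coeffs[jj, ])
  if (max(w) < 1e-12) {
    stop(sprintf("coefficient of '%s' is ~0 across the band; %s", predictor,
                 "phase undefined"))
  }
  xf <- x_fields[[predictor]]
  if (is.null(xf)) xf <- x_fields[[jj]]
  others <- setdiff(seq_along(model$predictors), jj)
  cross <- vapply(seq_along(model$band_idx), function(j) {
    k <- model$band_idx[j]
    m <- model$valid_mask[, k]
    part <- y_fields$coef[m, k, ]
    for (oo in others) {
      xo <- x_fields[[model$predictors[oo]]]
      if (is.null(xo)) xo <- x_fields[[oo]]
      part <- part - model$coeffs[oo, j] * xo$coef[m, k, ]
    }
    mean(Conj(xf$coef[m, k, ]) * part)
  }, complex(1))
  Arg(sum(w * cross) / sum(w)) / pi
}

#' Diagnostics for a fitted wavelet linear model
#'
#' Reports, per band timescale, the R-squared analogue
#' `1 - sum|resid|^2 / sum|w~y|^2`; the residual phasor mean field with its
#' random-phasor threshold (a sound model leaves no significant residual
#' synchrony); and, when the predictor time series are supplied, a surrogate
#' coherence test between the residual fields and each predictor (which
#' should be non-significant).
#'
#' @param model A fitted `"wlm_fit"`.
#' @param y_fields,x_fields Fields used in fitting.
#' @param x_series Optional named list of cleaned predictor [sts()] objects;
#'   enables the residual-coherence surrogate tests.
#' @param n_surr Surrogates for the residual coherence tests.
#' @param alpha Significance level for residual synchrony contours.
#' @param n_rand Random-phasor draws for the residual threshold.
#' @param seed Optional seed.
#' @return List with `r_squared` (per band timescale), `resid_sync_frac`
#'   (fraction of valid cells with residual phasor mean field above the
#'   threshold), `resid_threshold`, and `resid_coherence` (data frame of
#'   predictor, magnitude, p_value; `NULL` without `x_series`).
#' @export
wlm_diagnostics <- function(model, y_fields, x_fields, x_series = NULL,
                            n_surr = 200, alpha = 0.05, n_rand = 1000,
                            seed = NULL) {
  stopifnot(inherits(model, "wlm_fit"))
  idx <- model$band_idx
  fitted_fields <- y_fields
  fitted_fields$coef <- array(0 + 0i, dim(y_fields$coef))
  for (jj in seq_along(model$predictors)) {
    xf <- x_fields[[model$predictors[jj]]]
    if (is.null(xf)) xf <- x_fields[[jj]]
    for (j in seq_along(idx)) {
      k <- idx[j]
      fitted_fields$coef[, k, ] <- fitted_fields$coef[, k, ] +
        model$coeffs[jj, j] * xf$coef[, k, ]
    }
  }
  resid <- y_fields
  resid$coef <- y_fields$coef - fitted_fields$coef
  r2 <- vapply(seq_along(idx), function(j) {
    k <- idx[j]
    m <- model$valid_mask[, k]
    1 - sum(abs(resid$coef[m, k, ])^2) / sum(abs(y_fields$coef[m, k, ])^2)
  }, 1.0)
  names(r2) <- signif(model$band_timescales, 6)

  # residual phasor synchrony inside the band
  resid_band <- resid
  resid_band$coef <- resid$coef[, idx, , drop = FALSE]
  resid_band$valid_mask <- model$valid_mask[, idx, drop = FALSE]
  resid_band$grid$timescales <- model$band_timescales
  resid_power <- sum(abs(resid_band$coef)^2)
  if (resid_power > 1e-20) {
    wpmf <- wavelet_phasor_mean_field(resid_band)
    thr <- phasor_null_threshold(dim(y_fields$coef)[3], alpha, n_rand, seed)
    mv <- resid_band$valid_mask & !is.na(wpmf)
    resid_sync_frac <- if (any(mv)) mean(wpmf[mv] > thr) else NA_real_
  } else {
    thr <- NA_real_
    resid_sync_frac <- 0
  }

  resid_coh <- NULL
  if (!is.null(x_series) && resid_power > 1e-20) {
    resid_norm <- normalize_transforms(resid_band, "across_locations")
    resid_coh <- do.call(rbind, lapply(seq_along(model$predictors), function(jj) {
      nm <- model$predictors[jj]
      xs <- x_series[[nm]]
      if (is.null(xs)) return(NULL)
      grid_band <- model$grid
      grid_band$timescales <- model$band_timescales
      ct <- coherence_test(xs, resid_norm, model$band, n_surr = n_surr,
                           method = "fast",
                           seed = if (is.null(seed)) NULL else seed + jj,
                           grid = grid_band, coi_factor = y_fields$coi_factor)
      data.frame(predictor = nm, magnitude = ct$magnitude,
                 p_value = ct$p_value)
    }))
  }
  list(r_squared = r2, resid_sync_frac = resid_sync_frac,
       resid_threshold = thr, resid_coherence = resid_coh)
}
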