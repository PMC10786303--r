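#' @section Morlet convention:
#' The analyzing kernel at timescale `sigma` (months) is the analytic Morlet
#' wavelet parameterized so that timescale equals period:
#' `psi_sigma(v) = exp(2i*pi*v/sigma) * exp(-v^2/(2*sigma^2)) / norm(sigma)`,
#' truncated at `|v| <= 4*sigma` and L1-normalized so a unit-amplitude
#' sinusoid of period P yields `|W| ~ 1/2` at `sigma = P`. The transform is a
#' direct (non-circular) convolution; coefficients within `coi_factor*sigma`
#' of either series end are flagged invalid rather than hidden.
#' @keywords internal
#' @name wavelet-conventions
NULL

# Truncation half-width of the kernel, in units of sigma.
KERNEL_HALF_WIDTH <- 4

# Complex kernel matrix K (T x T) for one timescale: W(t) = sum_u K[t,u] x(u).
# K[t,u] = conj(psi_sigma(u - t)).
morlet_kernel <- function(T_len, sigma) {
  half <- floor(KERNEL_HALF_WIDTH * sigma)
  v <- (-half):half
  env <- exp(-v^2 / (2 * sigma^2))
  norm <- sum(env)
  d <- outer(seq_len(T_len), seq_len(T_len), function(t, u) u - t)
  K <- matrix(0 + 0i, T_len, T_len)
  keep <- abs(d) <= half
  dv <- d[keep]
  K[keep] <- exp(-dv^2 / (2 * sigma^2)) * exp(-2i * pi * dv / sigma) / norm
  K
}

# Kernel list over a grid (cached by callers that transform repeatedly).
morlet_kernels <- function(T_len, grid) {
  lapply(grid$timescales, function(s) morlet_kernel(T_len, s))
}

# Edge-validity mask: TRUE where the coefficient is at least coi_factor*sigma
# time steps (in months) from both series ends. Depends only on (T, grid,
# coi_factor), never on data.
coi_mask <- function(T_len, grid, coi_factor = 1) {
  tt <- seq_len(T_len)
  sapply(grid$timescales, function(s) {
    ((tt - 1) >= coi_factor * s / grid$dt) &
      ((T_len - tt) >= coi_factor * s / grid$dt)
  })
}

#' Continuous Morlet wavelet transform of a single series
#'
#' Transforms one cleaned (zero-mean) series over a timescale grid using the
#' period-parameterized analytic Morlet kernel (see package vignette). The
#' timescale of maximal time-averaged response to a pure sinusoid of period P
#' is the grid timescale nearest P, and the coefficient phase at that
#' timescale advances by `2*pi` per P months.
#'
#' @param x Numeric vector (a single site's cleaned series).
#' @param grid A [make_timescale_grid()] object.
#' @param coi_factor Cone-of-influence margin in units of timescale
#'   (default 1): coefficients closer than `coi_factor * sigma` to either
#'   series end are flagged invalid.
#' @param kernels Optional precomputed `morlet_kernels` list (internal reuse).
#'
#' @return List with `W` (complex `T x n_timescales` matrix), `valid_mask`
#'   (logical matrix of the same shape), and `grid`.
#' @export
wavelet_transform <- function(x, grid, coi_factor = 1, kernels = NULL) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("input series must be finite and numeric")
  }
  T_len <- length(x)
  if (max(grid$timescales) > T_len * grid$dt) {
    stop("grid extends beyond the series length")
  }
  if (is.null(kernels)) kernels <- morlet_kernels(T_len, grid)
  W <- vapply(kernels, function(K) as.vector(K %*% x),
              complex(T_len))
  dim(W) <- c(T_len, length(grid$timescales))
  list(W = W, valid_mask = coi_mask(T_len, grid, coi_factor), grid = grid)
}

#' Wavelet transforms of all sites of a spatio-temporal series
#'
#' @param x An [sts()] object (cleaned).
#' @param grid A [make_timescale_grid()]; defaults to the standard grid for
#'   the series length.
#' @param coi_factor Cone-of-influence margin (see [wavelet_transform()]).
#' @param kernels Optional precomputed kernel list.
#'
#' @return Object of class `"wfs"` (wavelet field set): list with `coef`
#'   (complex array `T x n_timescales x n_sites`), `grid`, `valid_mask`
#'   (shared by all sites), `normalization` tag, `site_ids`, `months`,
#'   `coi_factor`.
#' @export
wavelet_fieldset <- function(x, grid = NULL, coi_factor = 1, kernels = NULL) {
  stopifnot(inherits(x, "sts"))
  T_len <- ncol(x$values)
  if (is.null(grid)) grid <- make_timescale_grid(T_len, dt = x$dt)
  if (is.null(kernels)) kernels <- morlet_kernels(T_len, grid)
  K_n <- length(grid$timescales)
  N <- nrow(x$values)
  coef <- array(0 + 0i, c(T_len, K_n, N),
                dimnames = list(x$months, NULL, x$site_ids))
  Xt <- t(x$values)                      # T x N
  for (k in seq_len(K_n)) {
    coef[, k, ] <- kernels[[k]] %*% Xt
  }
  structure(
    list(coef = coef, grid = grid,
         valid_mask = coi_mask(T_len, grid, coi_factor),
         normalization = "none",
         site_ids = x$site_ids, months = x$months, coi_factor = coi_factor),
    class = "wfs"
  )
}

#' @export
print.wfs <- function(x, ...) {
  cat(sprintf("wfs: %d sites x %d months x %d timescales (normalization: %s)\n",
              dim(x$coef)[3], dim(x$coef)[1], dim(x$coef)[2], x$normalization))
  invisible(x)
}

# Per-site mean wavelet power over valid times: n_sites x n_timescales.
# Timescales with an empty valid mask fall back to all-times power (flagged
# via attribute "empty_mask").
site_powers <- function(wfs) {
  d <- dim(wfs$coef)
  K_n <- d[2]; N <- d[3]
  p <- matrix(NA_real_, N, K_n)
  empty <- logical(K_n)
  for (k in seq_len(K_n)) {
    m <- wfs$valid_mask[, k]
    if (!any(m)) { m <- rep(TRUE, d[1]); empty[k] <- TRUE }
    p[, k] <- colMeans(abs(wfs$coef[m, k, , drop = FALSE])^2)
  }
  attr(p, "empty_mask") <- empty
  p
}

#' Normalize a wavelet field set
#'
#' `per_location` divides each site's coefficients at each timescale by the
#' square root of that site's mean valid-time power at that timescale, giving
#' every site unit mean power. `across_locations` divides all sites by the
#' square root of the across-site mean of those per-site powers, preserving
#' between-site amplitude differences while making the across-site,
#' across-valid-time mean power exactly 1 at every timescale (the
#' normalization required by mean fields, coherence and wavelet linear
#' models). Renormalizing is idempotent.
#'
#' @param fields A `"wfs"` object.
#' @param method `"per_location"` or `"across_locations"`.
#' @return The normalized `"wfs"` with its `normalization` tag updated.
#' @export
normalize_transforms <- function(fields,
                                 method = c("across_locations", "per_location")) {
  stopifnot(inherits(fields, "wfs"))
  method <- match.arg(method)
  p <- site_powers(fields)
  if (any(p == 0)) {
    idx <- which(p == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero wavelet power at site '%s', timescale %.4g months",
                 fields$site_ids[idx[1]], fields$grid$timescales[idx[2]]))
  }
  d <- dim(fields$coef)
  out <- fields
  if (method == "per_location") {
    for (n in seq_len(d[3])) {
      out$coef[, , n] <- fields$coef[, , n] /
        rep(sqrt(p[n, ]), each = d[1])
    }
  } else {
    P <- colMeans(p)
    scal <- rep(sqrt(P), each = d[1])
    for (n in seq_len(d[3])) {
      out$coef[, , n] <- fields$coef[, , n] / scal
    }
  }
  out$normalization <- method
  out
}

# Shared-structure check used by coherence / wlm consumers.
check_compatible_wfs <- function(a, b) {
  if (!identical(a$site_ids, b$site_ids)) stop("field sets have different sites")
  if (!identical(a$months, b$months)) stop("field sets have different time indices")
  if (!isTRUE(all.equal(a$grid$timescales, b$grid$timescales))) {
    stop("field sets have different timescale grids")
  }
  if (!identical(a$valid_mask, b$valid_mask)) {
    stop("field sets have different validity masks")
  }
  invisible(TRUE)
}
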