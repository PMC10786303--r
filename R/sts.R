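#' Spatio-temporal series: site-by-month matrices with a common time index
#'
#' The universal input container of the package: an `N x T` numeric matrix of
#' one variable observed at `N` sites over `T` consecutive monthly time steps,
#' with site labels, the calendar month of the first column, the sampling
#' interval, and free-text units.
#'
#' @param values Numeric matrix, sites in rows, months in columns.
#' @param site_ids Character vector of site labels (defaults to rownames).
#' @param t0 Calendar month of the first column, `"YYYY-MM"`.
#' @param dt Sampling interval in months (1 for monthly data).
#' @param units Free-text units of the variable.
#'
#' @return An object of class `"sts"`: a list with elements `values`
#'   (labelled matrix), `site_ids`, `months` (column labels), `t0`, `dt`,
#'   `units`.
#' @export
#'
#' @examples
#' x <- sts(matrix(rnorm(10 * 24), 10, 24), site_ids = paste0("s", 1:10))
#' print(x)
sts <- function(values, site_ids = rownames(values), t0 = "2009-01", dt = 1,
                units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stop("an sts needs at least 2 time steps")
  if (nrow(values) < 1L) stop("an sts needs at least 1 site")
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(values)))
  site_ids <- as.character(site_ids)
  if (length(site_ids) != nrow(values)) {
    stop("length of site_ids must match number of rows")
  }
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  months <- month_seq(t0, ncol(values))
  dimnames(values) <- list(site_ids, months)
  structure(
    list(values = values, site_ids = site_ids, months = months,
         t0 = t0, dt = dt, units = units),
    class = "sts"
  )
}

#' @export
print.sts <- function(x, ...) {
  cat(sprintf("sts: %d sites x %d months (%s .. %s)%s\n",
              nrow(x$values), ncol(x$values), x$months[1],
              x$months[length(x$months)],
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
dim.sts <- function(x) dim(x$values)

# ---- month arithmetic ----------------------------------------------------

month_num <- function(ym) {
  m <- regmatches(ym, regexec("^([0-9]{4})-([0-9]{2})$", ym))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed month label(s): ", paste(ym[bad], collapse = ", "))
  vapply(m, function(g) as.integer(g[2]) * 12L + as.integer(g[3]) - 1L, 1L)
}

num_month <- function(n) sprintf("%04d-%02d", n %/% 12L, n %% 12L + 1L)

month_seq <- function(t0, len) num_month(month_num(t0) + seq_len(len) - 1L)

# ---- cleaning ------------------------------------------------------------

#' Clean site-level series for wavelet analysis
#'
#' Per-site preprocessing in a fixed order: optional Box-Cox transform
#' (profile-likelihood lambda; the series is shifted positive first if needed),
#' then least-squares linear detrend, then scaling to exactly zero mean and
#' unit sample variance. Missing values are a hard error -- interpolation is a
#' separate, deliberate step ([sts_interpolate()]).
#'
#' @param raw An [sts()] object.
#' @param detrend Remove a per-site least-squares linear trend (default TRUE).
#' @param standardize Scale each site to mean 0, sample variance 1 (default TRUE).
#' @param boxcox Apply an optimal Box-Cox transform first (default FALSE).
#'
#' @return A cleaned [sts()] object.
#' @export
clean_series <- function(raw, detrend = TRUE, standardize = TRUE,
                         boxcox = FALSE) {
  stopifnot(inherits(raw, "sts"))
  v <- raw$values
  tt <- seq_len(ncol(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    if (anyNA(x) || any(!is.finite(x))) {
      j <- which(!is.finite(x))[1]
      stop(sprintf("missing/non-finite value for site '%s' at month %s",
                   raw$site_ids[i], raw$months[j]))
    }
    scale0 <- stats::sd(x)
    if (boxcox) {
      if (min(x) <= 0) x <- x + 1 - min(x)
      bc <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
      lam <- bc$x[which.max(bc$y)]
      x <- if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
    }
    if (detrend) {
      fit <- stats::lm.fit(cbind(1, tt), x)
      x <- fit$residuals
    }
    if (standardize) {
      x <- x - mean(x)
      s <- stats::sd(x)
      if (s < 1e-10 * max(scale0, 1e-300)) {
        stop(sprintf("zero-variance series at site '%s' (cannot standardize)",
                     raw$site_ids[i]))
      }
      x <- x / s
      x <- x - mean(x)   # exact zero mean after rounding
    }
    v[i, ] <- x
  }
  out <- raw
  out$values <- v
  out
}

#' First-difference a spatio-temporal series
#'
#' Returns the month-to-month change per site, one time step shorter than the
#' input. The difference `x(t+1) - x(t)` is indexed at the later month, so
#' positive values correspond to periods where the variable is increasing into
#' the current month (the convention used for wave intensity when linking
#' waves to kelp wrack production).
#'
#' @param x An [sts()] object with T >= 2 months.
#' @return An [sts()] of length T - 1, starting one month later.
#' @export
first_difference <- function(x) {
  stopifnot(inherits(x, "sts"))
  Tn <- ncol(x$values)
  d <- x$values[, -1, drop = FALSE] - x$values[, -Tn, drop = FALSE]
  sts(d, site_ids = x$site_ids, t0 = x$months[2], dt = x$dt,
      units = if (nzchar(x$units)) paste0("delta ", x$units) else "")
}

#' Linearly interpolate missing values (explicit utility)
#'
#' Missing values are never filled silently by the analysis functions; call
#' this deliberately to fill internal gaps per site by linear interpolation
#' (boundary gaps are carried from the nearest observation).
#'
#' @param x An [sts()] possibly containing `NA`s.
#' @return An [sts()] with no missing values.
#' @export
sts_interpolate <- function(x) {
  stopifnot(inherits(x, "sts"))
  v <- x$values
  for (i in seq_len(nrow(v))) {
    if (anyNA(v[i, ])) {
      if (all(is.na(v[i, ]))) {
        stop(sprintf("site '%s' has no observed values to interpolate from",
                     x$site_ids[i]))
      }
      v[i, ] <- zoo::na.approx(v[i, ], na.rm = FALSE, rule = 2)
    }
  }
  out <- x
  out$values <- v
  out
}

#' Restrict an sts to a window of months
#'
#' @param x An [sts()].
#' @param from,to Month labels `"YYYY-MM"` (inclusive); `NULL` keeps the end.
#' @return The windowed [sts()].
#' @export
sts_window <- function(x, from = NULL, to = NULL) {
  stopifnot(inherits(x, "sts"))
  idx <- seq_along(x$months)
  if (!is.null(from)) idx <- idx[month_num(x$months[idx]) >= month_num(from)]
  if (!is.null(to))   idx <- idx[month_num(x$months[idx]) <= month_num(to)]
  if (length(idx) < 2L) stop("window retains fewer than 2 months")
  sts(x$values[, idx, drop = FALSE], site_ids = x$site_ids,
      t0 = x$months[idx[1]], dt = x$dt, units = x$units)
}
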