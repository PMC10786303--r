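#' Wavelet mean field
#'
#' Entrywise across-site average of `across_locations`-normalized wavelet
#' coefficients. Its squared magnitude measures spatial synchrony at each
#' time and timescale: near 1 when sites oscillate in phase with comparable
#' amplitude, near 0 when site phases cancel.
#'
#' @param fields A `"wfs"` normalized with `across_locations`.
#' @return Complex `T x n_timescales` matrix.
#' @export
wavelet_mean_field <- function(fields) {
  stopifnot(inherits(fields, "wfs"))
  if (fields$normalization != "across_locations") {
    stop("wavelet_mean_field requires across_locations normalization")
  }
  if (dim(fields$coef)[3] < 2L) stop("need at least 2 sites")
  rowMeans(fields$coef, dims = 2)
}

#' Wavelet phasor mean field
#'
#' Magnitude of the across-site average of unit-modulus wavelet phasors
#' `W/|W|`; lies in `[0, 1]` and measures phase synchrony irrespective of
#' amplitude (invariant to any per-site positive rescaling of the input).
#' Zero coefficients at valid points cannot contribute a phase; such points
#' are dropped from the across-site average with a warning.
#'
#' @param fields A `"wfs"` under any normalization.
#' @return Real `T x n_timescales` matrix in `[0, 1]`.
#' @export
wavelet_phasor_mean_field <- function(fields) {
  stopifnot(inherits(fields, "wfs"))
  d <- dim(fields$coef)
  if (d[3] < 2L) stop("need at least 2 sites")
  modulus <- abs(fields$coef)
  zero <- modulus == 0
  if (any(zero & as.vector(fields$valid_mask))) {
    warning("zero wavelet coefficients at valid points; ",
            "treated as missing phasors")
  }
  ph <- fields$coef / modulus
  ph[zero] <- 0 + 0i
  n_ok <- d[3] - rowSums(zero, dims = 2)
  out <- abs(rowSums(ph, dims = 2)) / pmax(n_ok, 1)
  out[n_ok == 0] <- NA_real_
  out
}

#' Random-phasor null threshold for the wavelet phasor mean field
#'
#' Under the null hypothesis of no synchrony beyond chance, site phases are
#' independent and uniform, so the phasor mean field magnitude at any cell is
#' distributed as the modulus of the mean of `n_sites` independent
#' unit-modulus phasors with uniform phases. This function returns the
#' `(1 - alpha)` empirical quantile of that modulus over `n_rand` random
#' draws (the "random phasor" null). A single global threshold applies to
#' every (time, timescale) cell because the null distribution is identical
#' across cells.
#'
#' @param n_sites Number of sites, >= 2.
#' @param alpha Significance level in (0, 1]; `alpha = 1` returns the sample
#'   minimum.
#' @param n_rand Number of random-phasor draws (default 1000).
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return Scalar threshold in `[0, 1]`.
#' @export
phasor_null_threshold <- function(n_sites, alpha = 0.05, n_rand = 1000,
                                  seed = NULL) {
  stopifnot(n_sites >= 2, alpha > 0, alpha <= 1, n_rand >= 1)
  draw <- function() {
    th <- matrix(stats::runif(n_rand * n_sites, 0, 2 * pi), n_rand, n_sites)
    Mod(rowMeans(exp(1i * th)))
  }
  mags <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  unname(stats::quantile(mags, 1 - alpha, type = 7))
}

#' Mean-field synchrony summary with significance contours
#'
#' Computes the wavelet mean field, the wavelet phasor mean field, the
#' random-phasor null threshold and the significance mask (cells where the
#' phasor mean field exceeds the threshold and lies inside the
#' cone-of-influence). Significance is pointwise; no field-wise
#' multiple-testing correction is applied.
#'
#' @param fields A `"wfs"`; will be normalized `across_locations` if not yet.
#' @param alpha Significance level for the null threshold.
#' @param n_rand Random-phasor draws.
#' @param seed Optional seed for the null draws.
#' @return Object of class `"meanfield"`: list with `wmf` (complex matrix),
#'   `wpmf_magnitude`, `threshold`, `sig_mask`, `valid_mask`, `n_sites`,
#'   `n_rand`, `alpha`, `grid`, `months`.
#' @export
mean_field <- function(fields, alpha = 0.05, n_rand = 1000, seed = NULL) {
  stopifnot(inherits(fields, "wfs"))
  if (fields$normalization == "none") {
    fields <- normalize_transforms(fields, "across_locations")
  }
  if (fields$normalization != "across_locations") {
    stop("mean_field requires across_locations (or raw) fields")
  }
  n_sites <- dim(fields$coef)[3]
  wmf <- wavelet_mean_field(fields)
  wpmf <- wavelet_phasor_mean_field(fields)
  thr <- phasor_null_threshold(n_sites, alpha, n_rand, seed)
  sig <- !is.na(wpmf) & wpmf > thr & fields$valid_mask
  structure(
    list(wmf = wmf, wpmf_magnitude = wpmf, threshold = thr, sig_mask = sig,
         valid_mask = fields$valid_mask, n_sites = n_sites, n_rand = n_rand,
         alpha = alpha, grid = fields$grid, months = fields$months),
    class = "meanfield"
  )
}

#' @export
print.meanfield <- function(x, ...) {
  cat(sprintf(paste0("meanfield: %d sites, %d months x %d timescales; ",
                     "wpmf threshold %.3f (alpha=%g, %d draws)\n"),
              x$n_sites, nrow(x$wmf), ncol(x$wmf), x$threshold, x$alpha,
              x$n_rand))
  cat(sprintf("  significant cells: %d of %d valid\n",
              sum(x$sig_mask), sum(x$valid_mask)))
  invisible(x)
}

#' Heatmap of a mean-field result
#'
#' Plots `|wmf|^2` (or the phasor mean field) against time and log timescale,
#' overlaying the significance contour from the random-phasor null and
#' shading the cone of influence.
#'
#' @param x A `"meanfield"` object.
#' @param what `"wmf2"` (squared mean-field magnitude, default), `"wmf"`
#'   (magnitude) or `"wpmf"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.meanfield <- function(x, what = c("wmf2", "wmf", "wpmf"), ...) {
  what <- match.arg(what)
  z <- switch(what, wmf2 = abs(x$wmf)^2, wmf = abs(x$wmf),
              wpmf = x$wpmf_magnitude)
  z[!x$valid_mask] <- NA
  tt <- seq_len(nrow(z))
  graphics::image(tt, log2(x$grid$timescales), z,
                  xlab = "month index", ylab = "log2 timescale (months)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = switch(what, wmf2 = "|wavelet mean field|^2",
                                wmf = "|wavelet mean field|",
                                wpmf = "wavelet phasor mean field"), ...)
  sig <- x$sig_mask * 1
  sig[!x$valid_mask] <- NA
  graphics::contour(tt, log2(x$grid$timescales), sig, levels = 0.5,
                    drawlabels = FALSE, add = TRUE, lwd = 2)
  invisible(x)
}
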