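#' Log-spaced timescale grid for the continuous wavelet transform
#'
#' Builds the multiplicatively spaced grid of analysis timescales (in months)
#' used by all wavelet operations. Defaults resolve the 2-month Nyquist limit
#' and extend a little beyond the longest reported band edge (60 mo) so band
#' statistics up to 60 mo are well covered on an 11-year monthly record.
#'
#' @param T_len Series length (number of time steps).
#' @param dt Sampling interval in months.
#' @param s_min Shortest timescale, months; must be at least `2 * dt`.
#' @param s_max Longest timescale, months; at most `T_len * dt`.
#' @param ratio Multiplicative spacing factor, > 1.
#'
#' @return Object of class `"tsgrid"`: list with `timescales` (strictly
#'   increasing, `timescales[k+1]/timescales[k] == ratio`), `s_min`, `s_max`,
#'   `ratio`, `dt`.
#' @export
#'
#' @examples
#' make_timescale_grid(132, s_min = 2, s_max = 64, ratio = 2)$timescales
make_timescale_grid <- function(T_len, dt = 1,
                                s_min = 2 * dt,
                                s_max = min(72 * dt, T_len * dt),
                                ratio = 1.05) {
  if (s_min < 2 * dt) stop("s_min must be >= 2*dt (Nyquist limit)")
  if (s_max > T_len * dt) stop("s_max must be <= T_len*dt")
  if (s_max < s_min) stop("s_max must be >= s_min")
  if (ratio <= 1) stop("ratio must be > 1")
  n <- floor(log(s_max / s_min) / log(ratio) + 1e-9)
  timescales <- s_min * ratio^(0:n)
  structure(
    list(timescales = timescales, s_min = s_min, s_max = s_max,
         ratio = ratio, dt = dt),
    class = "tsgrid"
  )
}

#' @export
print.tsgrid <- function(x, ...) {
  cat(sprintf("tsgrid: %d timescales, %.3g .. %.3g months (ratio %.4g)\n",
              length(x$timescales), min(x$timescales), max(x$timescales),
              x$ratio))
  invisible(x)
}

#' A contiguous timescale band
#'
#' Bands (2--8, 8--16, 16--60 months in the kelp-wrack analysis) are closed
#' intervals of timescale; membership is `lo <= sigma <= hi`.
#'
#' @param lo,hi Band limits in months, `0 < lo < hi`.
#' @return Object of class `"tsband"`.
#' @export
timescale_band <- function(lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo)) {
    stop("need 0 < lo < hi")
  }
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)), class = "tsband")
}

#' @export
print.tsband <- function(x, ...) {
  cat(sprintf("timescale band [%g, %g] months\n", x$lo, x$hi))
  invisible(x)
}

band_indices <- function(grid, band) {
  which(grid$timescales >= band$lo - 1e-9 & grid$timescales <= band$hi + 1e-9)
}

#' Standard analysis bands
#'
#' The three bands used throughout the subsidy-cascade analysis:
#' intra-annual (2--8 mo), annual (8--16 mo) and interannual (16--60 mo).
#'
#' @return Named list of [timescale_band()] objects.
#' @export
default_bands <- function() {
  list("2-8"   = timescale_band(2, 8),
       "8-16"  = timescale_band(8, 16),
       "16-60" = timescale_band(16, 60))
}
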