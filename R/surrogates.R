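# Random phase vector(s) for Fourier surrogates: a T x n_surr matrix of
# conjugate-symmetric phase perturbations (theta[1] = 0; theta at the Nyquist
# frequency = 0 for even T), shared across sites so the surrogated variable's
# own cross-site synchrony structure is preserved.
surrogate_phase_matrix <- function(T_len, n_surr) {
  half <- floor((T_len - 1) / 2)
  th <- matrix(0, T_len, n_surr)
  if (half >= 1) {
    ph <- matrix(stats::runif(half * n_surr, 0, 2 * pi), half, n_surr)
    th[2:(half + 1), ] <- ph
    th[T_len:(T_len - half + 1), ] <- -ph
  }
  th
}

# Fourier surrogates of a multi-site matrix (sites x T) for one shared phase
# column: preserves every site's periodogram exactly.
fourier_surrogate_once <- function(values, theta) {
  T_len <- ncol(values)
  out <- values
  rot <- exp(1i * theta)
  for (i in seq_len(nrow(values))) {
    X <- stats::fft(values[i, ])
    out[i, ] <- Re(stats::fft(X * rot, inverse = TRUE)) / T_len
  }
  out
}

# AAFT surrogate: gaussianize ranks per site, Fourier-surrogate the gaussian
# series with the shared phases, then remap ranks back onto each site's
# original value multiset (preserved exactly).
aaft_surrogate_once <- function(values, theta, gauss_ref) {
  T_len <- ncol(values)
  g <- matrix(NA_real_, nrow(values), T_len)
  for (i in seq_len(nrow(values))) {
    g[i, ] <- gauss_ref[rank(values[i, ], ties.method = "first")]
  }
  gs <- fourier_surrogate_once(g, theta)
  out <- values
  for (i in seq_len(nrow(values))) {
    out[i, ] <- sort(values[i, ])[rank(gs[i, ], ties.method = "first")]
  }
  out
}

#' Surrogate spatio-temporal series for significance testing
#'
#' Generates one randomized copy of a (cleaned) spatio-temporal series under
#' the null hypothesis of no cross-variable relationship, while preserving
#' the variable's own temporal spectrum and cross-site synchrony structure.
#'
#' `"fourier"` surrogates randomize the discrete-Fourier phases of every site
#' with one shared, conjugate-symmetric random phase sequence, preserving
#' each site's periodogram exactly and the between-site phase relationships
#' of the variable. `"aaft"` (amplitude-adjusted) surrogates additionally
#' preserve each site's marginal value distribution exactly by rank
#' remapping, at the cost of only approximately preserving the spectrum;
#' they are the robustness option for skewed variables.
#'
#' @param x A cleaned [sts()].
#' @param surr_type `"fourier"` (default) or `"aaft"`.
#' @param seed Optional integer seed (deterministic given it).
#' @return An [sts()] of the same shape.
#' @export
surrogate_series <- function(x, surr_type = c("fourier", "aaft"), seed = NULL) {
  stopifnot(inherits(x, "sts"))
  surr_type <- match.arg(surr_type)
  T_len <- ncol(x$values)
  gen <- function() {
    theta <- surrogate_phase_matrix(T_len, 1)[, 1]
    if (surr_type == "fourier") {
      fourier_surrogate_once(x$values, theta)
    } else {
      gauss_ref <- sort(stats::rnorm(T_len))
      aaft_surrogate_once(x$values, theta, gauss_ref)
    }
  }
  v <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- x
  out$values <- v
  out
}
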