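# Diagnostics: the expected-imputed-successes quadrature behind the choice of
# augmentation weight, and the likelihood-ratio check R on individual draws.

#' Expected number of imputed successes under an h-added-cells draw
#'
#' For a single group with `r` observed successes and `f` failures, adding a
#' pseudo-count `h` to both cells and drawing the log-odds from its normal
#' approximation \eqn{N(m, s^2)} with \eqn{m = \log\{(r+h)/(f+h)\}} and
#' \eqn{s^2 = 1/(r+h) + 1/(f+h)}, the mean number of imputed successes among
#' `n_missing` incomplete observations is
#' \eqn{n_{miss} \, E[\mathrm{expit}(m + Z s)]}, \eqn{Z \sim N(0,1)},
#' evaluated here by Gauss--Hermite quadrature.  The scale of `Z` is taken to
#' be the standard deviation \eqn{s = \sqrt{1/(r+h)+1/(f+h)}}, the usual
#' standard error of a log-odds with h-added cells.
#'
#' A value near 1 (for `r = 0`) is desirable: the imputation admits a success
#' as rare-but-possible without materially biasing the prevalence.  The value
#' is minimised near `h = 0.5` and rises as `h` moves away from it, which is
#' what motivates an augmentation weight totalling one pseudo-observation per
#' parameter.
#'
#' @param r,f Observed success and failure counts.
#' @param h Pseudo-count added to each cell (`r + h > 0`, `f + h > 0`).
#' @param n_missing Number of missing observations to be imputed.
#' @param n_nodes Number of Gauss--Hermite nodes (>= 20; default 40).
#' @return Expected number of imputed successes (scalar).
#' @examples
#' expected_imputed_successes(r = 0, f = 100, h = 0.5, n_missing = 100)
#' @export
expected_imputed_successes <- function(r, f, h, n_missing, n_nodes = 40L) {
  stopifnot(r + h > 0, f + h > 0, n_nodes >= 20L, n_missing >= 0)
  m <- log((r + h) / (f + h))
  s <- sqrt(1 / (r + h) + 1 / (f + h))
  gh <- pracma::gaussHermite(n_nodes)
  # E[g(Z)], Z ~ N(0,1) = (1/sqrt(pi)) * sum w_i g(sqrt(2) x_i)
  n_missing * sum(gh$w * stats::plogis(m + sqrt(2) * s * gh$x)) / sqrt(pi)
}

#' Expected-imputed-successes curve over a grid of pseudo-counts
#'
#' Tabulates [expected_imputed_successes()] over a grid of `h` for one or
#' more failure counts `f`, reporting both the expected count and the
#' per-missing-observation probability.
#'
#' @param f Vector of failure counts.
#' @param h Vector of pseudo-counts.
#' @param r Success count (default 0, the perfectly predicted case).
#' @param n_missing Number of missing observations (default 100).
#' @param n_nodes Gauss--Hermite node count.
#' @return A tibble with columns `f`, `h`, `expected_successes`,
#'   `expected_prob`.
#' @export
augmentation_tradeoff_curve <- function(f = c(10, 100, 1000),
                                        h = seq(0.05, 3, by = 0.05),
                                        r = 0, n_missing = 100, n_nodes = 40L) {
  grid <- tidyr::expand_grid(f = f, h = h)
  dplyr::mutate(grid,
    expected_successes = purrr::map2_dbl(
      f, h, ~ expected_imputed_successes(r, .x, .y, n_missing, n_nodes)),
    expected_prob = .data$expected_successes / n_missing
  )
}

#' Likelihood-ratio diagnostic for a parameter draw
#'
#' Compares the quadratic-approximation and exact likelihood ratios at a draw
#' \eqn{\theta^*}: on the likelihood scale,
#' \deqn{R = \exp\{-\tfrac12 d'\hat V^{-1} d - [\,l(\theta^*) - l(\hat\theta)\,]\},
#'       \qquad d = \theta^* - \hat\theta,}
#' the approximated likelihood ratio divided by the exact one.  R should be
#' close to 1; values outside (0.1, 10) flag a draw for which the normal
#' approximation to the posterior is a poor description of the likelihood.
#' Under mishandled perfect prediction R routinely exceeds 1000: the
#' approximation treats a sign-flipped draw as nearly as plausible as the
#' estimate, while the exact likelihood has collapsed there.
#'
#' @param fit A `"catreg"` fit.
#' @param theta_star A parameter vector (or a `"param_draw"`).
#' @return A one-row tibble with `R`, `log_R` and `flag`
#'   (`TRUE` if R falls outside (0.1, 10)).
#' @export
likelihood_ratio_R <- function(fit, theta_star) {
  stopifnot(inherits(fit, "catreg"))
  if (inherits(theta_star, "param_draw")) theta_star <- theta_star$theta_star
  stopifnot(length(theta_star) == length(fit$theta))
  d <- theta_star - fit$theta
  V <- fit$vcov
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(Vi)) {
    rlang::warn("Singular vcov in likelihood_ratio_R; using pseudo-inverse.",
                class = "sepmi_pseudoinverse_warning")
    Vi <- MASS::ginv(V)
  }
  quad <- -0.5 * drop(t(d) %*% Vi %*% d)
  log_R <- quad - (loglik_at(fit, theta_star) - fit$loglik)
  R <- exp(log_R)
  tibble::tibble(R = R, log_R = log_R,
                 flag = log_R < log(0.1) | log_R > log(10))
}
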