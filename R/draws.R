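# Parameter-draw strategies for proper imputation.
#
# Proper multiple imputation requires the imputation-model parameters to be
# drawn from (an approximation to) their posterior, not fixed at the MLE.
# The strategies here differ only in how that draw is produced, and hence in
# how they behave when the imputation model is perfectly predicted.

DRAW_METHODS <- c("mle", "normal_allow", "normal_augment", "normal_penalise",
                  "bootstrap", "bayes_beta")

sub_seed <- function(root_seed, counter) {
  as.integer((as.numeric(root_seed) * 1000003 + counter) %% 2147483647)
}

new_param_draw <- function(theta_star, method, extra = list()) {
  structure(c(list(theta_star = theta_star, method = method), extra),
            class = "param_draw")
}

#' @export
print.param_draw <- function(x, ...) {
  cat(sprintf("<param_draw> method = %s\n", x$method))
  if (!is.null(x$theta_star)) print(round(x$theta_star, 4))
  invisible(x)
}

#' Draw parameters from the normal approximation to the posterior
#'
#' Draws \eqn{\theta^* \sim N(\hat\theta, \hat V)} using a symmetric
#' eigenvalue square root, which tolerates a positive *semi*-definite
#' \eqn{\hat V} (as produced by a pseudo-inverse after a separated fit).
#' Negative eigenvalues beyond numerical tolerance are an error.
#'
#' @param fit A `"catreg"` fit.
#' @return A `"param_draw"` object.
#' @export
draw_normal <- function(fit) {
  stopifnot(inherits(fit, "catreg"))
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE)
  tol <- 1e-8 * max(1, max(abs(ev$values)))
  if (min(ev$values) < -tol) {
    rlang::abort("vcov has materially negative eigenvalues; cannot draw.",
                 class = "sepmi_vcov_error")
  }
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- stats::rnorm(length(fit$theta))
  theta_star <- fit$theta + drop(L %*% z)
  names(theta_star) <- names(fit$theta)
  new_param_draw(theta_star, "normal")
}

#' Draw parameters by bootstrap refitting
#'
#' Resamples the estimation sample with replacement (same size), refits the
#' model by unpenalised maximum likelihood (iteration cap applies) and takes
#' the refitted estimate as the draw.  A resample that loses an outcome level
#' entirely is redrawn, up to `retry_cap` times.
#'
#' Because a bootstrap resample can never contain outcome levels that were
#' unobserved in a covariate stratum, this strategy treats perfect prediction
#' as a logical impossibility: on perfectly predicted strata it always imputes
#' the observed level.
#'
#' @inheritParams fit_catreg
#' @param retry_cap Maximum redraws on degenerate resamples (default 10).
#' @return A list with the refitted `fit` and the `"param_draw"`.
#' @export
draw_bootstrap <- function(data, outcome, predictors = NULL,
                           kind = c("binary", "ordinal", "nominal"),
                           weights = NULL, maxit = 25L, levels = NULL,
                           retry_cap = 10L) {
  kind <- match.arg(kind)
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  obs_rows <- which(!is.na(data[[outcome]]))
  if (length(obs_rows) == 0L) {
    rlang::abort("Empty estimation sample.", class = "sepmi_empty_error")
  }
  lev <- outcome_levels(data[[outcome]], levels)
  w <- resolve_weights(data, weights)
  for (try in seq_len(retry_cap)) {
    idx <- sample(obs_rows, length(obs_rows), replace = TRUE)
    yb <- as.character(data[[outcome]][idx])
    if (!all(lev %in% yb)) next
    boot <- data[idx, , drop = FALSE]
    fit <- fit_catreg(boot, outcome, predictors, kind = kind,
                      penalty = "none", weights = w[idx],
                      maxit = maxit, levels = lev)
    return(list(fit = fit, draw = new_param_draw(fit$theta, "bootstrap")))
  }
  rlang::abort(sprintf("Bootstrap resample lost an outcome level %d times in a row.",
                       retry_cap),
               class = "sepmi_bootstrap_error")
}

#' Explicitly Bayesian beta draw for a stratified binary variable
#'
#' Draws \eqn{\pi^* \sim \mathrm{Beta}(r + a, f + b)} for a stratum with `r`
#' observed successes and `f` observed failures under a Beta(a, b) prior.
#'
#' @param r,f Observed success/failure counts (nonnegative).
#' @param prior_a,prior_b Beta prior parameters (default Beta(1, 1)).
#' @param n Number of draws (default 1).
#' @return Numeric vector of probability draws.
#' @export
draw_bayes_beta <- function(r, f, prior_a = 1, prior_b = 1, n = 1L) {
  stopifnot(prior_a > 0, prior_b > 0, r >= 0, f >= 0)
  stats::rbeta(n, r + prior_a, f + prior_b)
}

discrete_strata_or_abort <- function(data, predictors) {
  for (v in predictors) {
    col <- data[[v]]
    if (is.numeric(col) && length(unique(col[!is.na(col)])) > 10L) {
      rlang::abort(
        paste0("bayes_beta requires discrete predictors defining strata; '",
               v, "' looks quantitative."),
        class = "sepmi_config_error")
    }
  }
  interaction(lapply(data[predictors], as.character), drop = FALSE, sep = "\r")
}

#' Dispatch a parameter draw under a named strategy
#'
#' Fits the imputation model and produces one parameter draw under `method`:
#' \describe{
#'   \item{`mle`}{improper: \eqn{\theta^* = \hat\theta} from the unpenalised fit.}
#'   \item{`normal_allow`}{unpenalised fit, warts and all, then a normal draw.
#'     Under perfect prediction the reported variance is enormous and draws
#'     land at wildly positive or negative coefficients; this strategy exists
#'     to reproduce that pathology and is not recommended.}
#'   \item{`normal_penalise`}{Firth-penalised fit (binary only), normal draw.}
#'   \item{`normal_augment`}{fit on data augmented with the `2pk` weighted
#'     pseudo-records, normal draw.}
#'   \item{`bootstrap`}{refit on a bootstrap resample.}
#'   \item{`bayes_beta`}{per-stratum Beta posterior draws (binary outcome,
#'     discrete predictors only).}
#' }
#'
#' @inheritParams fit_catreg
#' @param method One of `"mle"`, `"normal_allow"`, `"normal_augment"`,
#'   `"normal_penalise"`, `"bootstrap"`, `"bayes_beta"`.
#' @param prior Beta prior (length-2) for `bayes_beta`.
#' @return A list with the underlying `fit` (`NULL` for `bayes_beta`) and the
#'   `"param_draw"`.
#' @examples
#' set.seed(1)
#' strategy_draw(make_table2(), "y", "x", kind = "binary",
#'               method = "normal_penalise")$draw
#' @export
strategy_draw <- function(data, outcome, predictors = NULL,
                          kind = c("binary", "ordinal", "nominal"),
                          method = DRAW_METHODS,
                          weights = NULL, maxit = 25L, levels = NULL,
                          prior = c(1, 1)) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  if (method == "normal_penalise" && kind != "binary") {
    rlang::abort("normal_penalise is only available for binary outcomes.",
                 class = "sepmi_config_error")
  }
  if (method == "bayes_beta") {
    if (kind != "binary") {
      rlang::abort("bayes_beta is only available for binary outcomes.",
                   class = "sepmi_config_error")
    }
    lev <- outcome_levels(data[[outcome]], levels)
    strat <- discrete_strata_or_abort(data, predictors)
    obs <- !is.na(data[[outcome]])
    tab <- table(strat[obs], factor(as.character(data[[outcome]][obs]), levels = lev))
    pi_star <- draw_bayes_beta(tab[, 2], tab[, 1], prior[1], prior[2],
                               n = nrow(tab))
    names(pi_star) <- rownames(tab)
    draw <- new_param_draw(NULL, "bayes_beta",
                           list(pi_star = pi_star, strata = strat,
                                levels = lev, prior = prior))
    return(list(fit = NULL, draw = draw))
  }
  if (method == "bootstrap") {
    return(draw_bootstrap(data, outcome, predictors, kind = kind,
                          weights = weights, maxit = maxit, levels = levels))
  }
  fit <- switch(method,
    mle = ,
    normal_allow = fit_catreg(data, outcome, predictors, kind = kind,
                              penalty = "none", weights = weights,
                              maxit = maxit, levels = levels),
    normal_penalise = fit_catreg(data, outcome, predictors, kind = kind,
                                 penalty = "firth", weights = weights,
                                 maxit = maxit, levels = levels),
    normal_augment = fit_augmented(data, outcome, predictors, kind = kind,
                                   weights = weights, maxit = maxit,
                                   levels = levels)
  )
  draw <- if (method == "mle") {
    new_param_draw(fit$theta, "mle")
  } else {
    d <- draw_normal(fit)
    d$method <- method
    d
  }
  list(fit = fit, draw = draw)
}
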