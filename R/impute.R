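# Imputation engines: univariate, monotone, and chained equations (MICE).

#' Specify the imputation model for one incomplete variable
#'
#' @param variable Column name of the incomplete variable.
#' @param predictors Character vector of predictor columns (taken verbatim; no
#'   automatic interactions).
#' @param kind Outcome family: `"binary"`, `"ordinal"` or `"nominal"`.
#' @param levels Optional explicit level set.
#' @return An `"imp_spec"` list.
#' @export
imp_spec <- function(variable, predictors, kind = c("binary", "ordinal", "nominal"),
                     levels = NULL) {
  kind <- match.arg(kind)
  structure(list(variable = variable, predictors = predictors,
                 kind = kind, levels = levels), class = "imp_spec")
}

#' Build an imputation configuration
#'
#' @param ... One [imp_spec()] per incomplete variable.
#' @param m Number of imputations (>= 1).
#' @param n_cycles Number of MICE cycles (>= 1; ignored by the monotone engine).
#' @param method Parameter-draw strategy (see [strategy_draw()]).
#' @param seed Root seed; all randomness is derived from it deterministically.
#' @param variable_order Optional explicit imputation order; defaults to
#'   increasing missingness.
#' @param prior Beta prior for `method = "bayes_beta"`.
#' @param maxit Iteration cap for unpenalised fits.
#' @return An `"imputation_config"` list.
#' @export
imputation_config <- function(..., m = 5L, n_cycles = 1L,
                              method = "normal_augment", seed = 1L,
                              variable_order = NULL, prior = c(1, 1),
                              maxit = 25L) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !inherits(specs[[1]], "imp_spec")) {
    specs <- specs[[1]]
  }
  stopifnot(length(specs) >= 1L, all(vapply(specs, inherits, TRUE, "imp_spec")))
  method <- match.arg(method, DRAW_METHODS)
  stopifnot(m >= 1L, n_cycles >= 1L)
  names(specs) <- vapply(specs, `[[`, "", "variable")
  structure(list(specs = specs, m = as.integer(m),
                 n_cycles = as.integer(n_cycles), method = method,
                 seed = as.integer(seed), variable_order = variable_order,
                 prior = prior, maxit = maxit),
            class = "imputation_config")
}

# restore the imputed codes to the original column type
restore_type <- function(template, lev, codes) {
  vals <- lev[codes]
  if (is.factor(template)) return(factor(vals, levels = base::levels(template)))
  if (is.numeric(template)) return(as.numeric(vals))
  if (is.logical(template)) return(as.logical(vals))
  vals
}

sample_levels <- function(P) {
  # one categorical draw per row of the probability matrix P
  u <- stats::runif(nrow(P))
  cp <- t(apply(P, 1, cumsum))
  codes <- rowSums(u > cp) + 1L
  pmin(codes, ncol(P))
}

# impute the missing cells of one variable in `current`, where the model is
# trained on rows with `train_mask` TRUE (observed outcome there)
impute_once <- function(current, spec, method, prior, maxit) {
  v <- spec$variable
  miss <- is.na(current[[v]])
  sd_ <- strategy_draw(current, v, spec$predictors, kind = spec$kind,
                       method = method, maxit = maxit, levels = spec$levels,
                       prior = prior)
  lev <- if (!is.null(sd_$fit)) sd_$fit$levels
         else outcome_levels(current[[v]], spec$levels)
  if (!any(miss)) {
    codes <- integer(0)
  } else if (method == "bayes_beta") {
    pi_star <- sd_$draw$pi_star
    strat <- as.character(sd_$draw$strata)
    p1 <- pi_star[strat[miss]]
    unseen <- is.na(p1)
    if (any(unseen)) {
      p1[unseen] <- stats::rbeta(sum(unseen), prior[1], prior[2])
    }
    codes <- 1L + (stats::runif(sum(miss)) < p1)
  } else {
    X <- build_design(current, spec$predictors)
    P <- predict_probs(sd_$fit, X[miss, , drop = FALSE], sd_$draw$theta_star)
    codes <- sample_levels(P)
  }
  R <- NA_real_
  if (!is.null(sd_$fit) && !is.null(sd_$draw$theta_star) &&
      method %in% c("normal_allow", "normal_augment", "normal_penalise")) {
    R <- likelihood_ratio_R(sd_$fit, sd_$draw$theta_star)$R
  }
  out <- current
  out[[v]][miss] <- restore_type(current[[v]], lev, codes)
  list(data = out,
       draw = sd_$draw,
       audit = tibble::tibble(
         variable = v, method = method,
         separated = if (is.null(sd_$fit)) NA else sd_$fit$separated,
         converged = if (is.null(sd_$fit)) NA else sd_$fit$converged,
         n_iter = if (is.null(sd_$fit)) NA_integer_ else sd_$fit$n_iter,
         R = R))
}

new_imputation_run <- function(completed, draws, audit, engine, config) {
  structure(list(completed = completed, draws = draws, audit = audit,
                 engine = engine, m = length(completed), config = config),
            class = "imputation_run")
}

#' Impute a single incomplete variable m times
#'
#' For each imputation, one parameter draw is taken under `method` and every
#' missing value is sampled from the fitted categorical distribution
#' \eqn{p(y \mid x; \theta^*)}.
#'
#' @inheritParams fit_catreg
#' @inheritParams imputation_config
#' @return An `"imputation_run"`: `completed` (list of m tibbles), `draws`,
#'   and an `audit` tibble with one row per imputation recording the draw
#'   method, separation flag and likelihood-ratio diagnostic R.
#' @examples
#' run <- impute_univariate(make_table2(), "y", "x", kind = "binary",
#'                          method = "normal_penalise", m = 3, seed = 1)
#' tidy(run)
#' @export
impute_univariate <- function(data, outcome, predictors = NULL,
                              kind = c("binary", "ordinal", "nominal"),
                              method = "normal_augment", m = 5L, seed = 1L,
                              prior = c(1, 1), maxit = 25L, levels = NULL) {
  kind <- match.arg(kind)
  method <- match.arg(method, DRAW_METHODS)
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  data <- tibble::as_tibble(data)
  spec <- imp_spec(outcome, predictors, kind = kind, levels = levels)
  completed <- vector("list", m)
  draws <- vector("list", m)
  audits <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(sub_seed(seed, i))
    res <- impute_once(data, spec, method, prior, maxit)
    completed[[i]] <- res$data
    draws[[i]] <- res$draw
    audits[[i]] <- dplyr::mutate(res$audit, imputation = i, .before = 1)
  }
  cfg <- imputation_config(spec, m = m, method = method, seed = seed,
                           prior = prior, maxit = maxit)
  new_imputation_run(completed, draws, dplyr::bind_rows(audits),
                     "univariate", cfg)
}

order_by_missingness <- function(data, vars) {
  miss <- vapply(vars, function(v) sum(is.na(data[[v]])), integer(1))
  vars[order(miss)]
}

validate_monotone <- function(data, vars) {
  # vars in imputation order (increasing missingness): a row missing an
  # earlier variable must be missing all later ones
  for (a in seq_along(vars)) {
    for (b in seq_along(vars)) {
      if (b <= a) next
      bad <- which(is.na(data[[vars[a]]]) & !is.na(data[[vars[b]]]))
      if (length(bad)) {
        rlang::abort(
          paste0("Missingness pattern is not monotone: rows ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else "",
                 " are missing '", vars[a], "' but observe '", vars[b], "'."),
          class = "sepmi_monotone_error")
      }
    }
  }
  invisible(TRUE)
}

#' Monotone (sequential-regression) multiple imputation
#'
#' Variables are imputed in increasing order of missingness; each model
#' conditions on the configured predictors, which by the time a variable is
#' reached are fully observed or already imputed.  One parameter draw is
#' taken per variable per imputation.
#'
#' @param data A data frame with a monotone missingness pattern among the
#'   configured variables (validated; non-monotone input is an error naming
#'   the offending cells).
#' @param config An [imputation_config()].
#' @return An `"imputation_run"`.
#' @export
impute_monotone <- function(data, config) {
  stopifnot(inherits(config, "imputation_config"))
  data <- tibble::as_tibble(data)
  vars <- config$variable_order %||% order_by_missingness(data, names(config$specs))
  validate_monotone(data, vars)
  completed <- vector("list", config$m)
  draws <- vector("list", config$m)
  audits <- list()
  for (i in seq_len(config$m)) {
    set.seed(sub_seed(config$seed, i))
    current <- data
    draws_i <- list()
    for (v in vars) {
      res <- impute_once(current, config$specs[[v]], config$method,
                         config$prior, config$maxit)
      current <- res$data
      draws_i[[v]] <- res$draw
      audits[[length(audits) + 1L]] <-
        dplyr::mutate(res$audit, imputation = i, .before = 1)
    }
    completed[[i]] <- current
    draws[[i]] <- draws_i
  }
  new_imputation_run(completed, draws, dplyr::bind_rows(audits),
                     "monotone", config)
}

#' Multiple imputation by chained equations (MICE / FCS)
#'
#' Missing values are first filled by sampling each variable's observed
#' values with replacement; then for `n_cycles` sweeps each incomplete
#' variable in turn is regressed (on its originally observed rows) on the
#' current values of its predictors, a parameter draw is taken, and its
#' missing cells are re-imputed.  The final sweep's values are returned.
#' With monotone data, a monotone visit order and `n_cycles = 1`, the result
#' coincides with monotone imputation apart from the initial fill, which only
#' affects variables imputed before their predictors are reached.
#'
#' @inheritParams impute_monotone
#' @return An `"imputation_run"`.
#' @export
impute_mice <- function(data, config) {
  stopifnot(inherits(config, "imputation_config"))
  data <- tibble::as_tibble(data)
  vars <- config$variable_order %||% order_by_missingness(data, names(config$specs))
  missing_any <- vapply(vars, function(v) anyNA(data[[v]]), logical(1))
  completed <- vector("list", config$m)
  draws <- vector("list", config$m)
  audits <- list()
  for (i in seq_len(config$m)) {
    set.seed(sub_seed(config$seed, i))
    current <- data
    # initial fill: draw from each variable's observed empirical distribution
    for (v in vars) {
      miss <- is.na(current[[v]])
      if (any(miss)) {
        pool_obs <- current[[v]][!miss]
        current[[v]][miss] <- sample(pool_obs, sum(miss), replace = TRUE)
      }
    }
    draws_i <- list()
    for (cycle in seq_len(config$n_cycles)) {
      for (v in vars) {
        if (!missing_any[[v]]) next
        work <- current
        work[[v]] <- data[[v]]  # re-blank originally missing cells
        res <- impute_once(work, config$specs[[v]], config$method,
                           config$prior, config$maxit)
        current <- res$data
        draws_i[[paste0(v, ".", cycle)]] <- res$draw
        audits[[length(audits) + 1L]] <-
          dplyr::mutate(res$audit, imputation = i, cycle = cycle, .before = 1)
      }
    }
    completed[[i]] <- current
    draws[[i]] <- draws_i
  }
  new_imputation_run(completed, draws, dplyr::bind_rows(audits), "mice", config)
}

#' @export
print.imputation_run <- function(x, ...) {
  cat(sprintf("<imputation_run> engine = %s, m = %d, method = %s\n",
              x$engine, x$m, x$config$method))
  nsep <- sum(x$audit$separated, na.rm = TRUE)
  cat(sprintf("  separation encountered in %d of %d model fits\n",
              nsep, nrow(x$audit)))
  invisible(x)
}

#' @rdname impute_univariate
#' @param x,object An `"imputation_run"`.
#' @param ... Unused.
#' @method tidy imputation_run
#' @export
tidy.imputation_run <- function(x, ...) x$audit

#' @rdname impute_univariate
#' @method glance imputation_run
#' @export
glance.imputation_run <- function(x, ...) {
  tibble::tibble(
    engine = x$engine, m = x$m, method = x$config$method,
    n_fits = nrow(x$audit),
    n_separated = sum(x$audit$separated, na.rm = TRUE),
    max_R = suppressWarnings(max(x$audit$R, na.rm = TRUE))
  )
}

#' Extract one completed dataset from an imputation run
#'
#' @param run An `"imputation_run"`.
#' @param i Imputation index in `1..m`.
#' @return A tibble with no missing cells in the imputed variables.
#' @export
completed_data <- function(run, i) {
  stopifnot(inherits(run, "imputation_run"), i >= 1, i <= run$m)
  run$completed[[i]]
}

#' Apply a complete-data analysis to every imputed dataset
#'
#' Maps `fn` over the m completed datasets and row-binds the results with an
#' `imputation` column, ready for [pool_rubin()].  `fn` must return a data
#' frame with columns `term`, `estimate` and `variance`.
#'
#' @param run An `"imputation_run"`.
#' @param fn A function of one completed tibble.
#' @return A tibble of per-imputation results.
#' @export
analyse_imputations <- function(run, fn) {
  stopifnot(inherits(run, "imputation_run"))
  purrr::map_dfr(seq_len(run$m), function(i) {
    dplyr::mutate(tibble::as_tibble(fn(run$completed[[i]])),
                  imputation = i, .before = 1)
  })
}
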