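# Reference datasets and experiment runners: the artificial perfect-prediction
# table, its three-level extension, the factorial simulation study, and a
# longitudinal generator with outcome-dependent dropout for exercising the
# monotone engine.

#' Artificial dataset illustrating perfect prediction
#'
#' A complete binary covariate `x` and an incomplete binary outcome `y`:
#' `x = 0` has 100 observed failures, no observed successes and 100 missing;
#' `x = 1` has 100 failures, 100 successes and 100 missing.  Fitting
#' `logit p(y = 1 | x)` to the 300 complete cases gives no finite MLE: `x`
#' perfectly predicts `y = 0` in the `x = 0` group.
#'
#' @return A 500-row tibble with numeric columns `x` and `y` (`y` has 200 NAs).
#' @examples
#' dplyr::count(make_table2(), x, y)
#' @export
make_table2 <- function() {
  tibble::tibble(
    x = c(rep(0, 200), rep(1, 300)),
    y = c(rep(0, 100), rep(NA_real_, 100),
          rep(0, 100), rep(1, 100), rep(NA_real_, 100))
  )
}

#' Three-level extension of the artificial dataset
#'
#' [make_table2()] plus 100 rows with `x = 0, y = 2` and 100 rows with
#' `x = 1, y = 2`.  Imputing `y` with a baseline-category multinomial model
#' still meets perfect prediction: level 1 is never observed when `x = 0`.
#'
#' @return A 700-row tibble; `y` takes levels 0, 1, 2 with 200 NAs.
#' @export
make_three_level <- function() {
  dplyr::bind_rows(
    make_table2(),
    tibble::tibble(x = c(rep(0, 100), rep(1, 100)), y = 2)
  )
}

#' Imputed-success counts on the artificial data, by draw strategy
#'
#' Runs [impute_univariate()] on [make_table2()] and counts, per imputation,
#' the imputed successes among the 100 originally missing outcomes in each
#' `x` group.  Under proper behaviour the `x = 1` count averages about 50 and
#' the `x = 0` count stays near 0; the `normal_allow` strategy instead
#' imputes the `x = 0` group as almost all failures or almost all successes.
#'
#' @param method Draw strategy (see [strategy_draw()]).
#' @param n_imputations Number of imputations (default 100).
#' @param seed Root seed.
#' @param prior Beta prior for `method = "bayes_beta"`.
#' @return A tibble with columns `imputation`, `successes_x0`, `successes_x1`.
#' @examples
#' tab <- table2_experiment("bootstrap", n_imputations = 10, seed = 1)
#' all(tab$successes_x0 == 0)
#' @export
table2_experiment <- function(method, n_imputations = 100L, seed = 1L,
                              prior = c(1, 1)) {
  d <- make_table2()
  run <- impute_univariate(d, "y", "x", kind = "binary", method = method,
                           m = n_imputations, seed = seed, prior = prior)
  miss <- is.na(d$y)
  purrr::map_dfr(seq_len(run$m), function(i) {
    comp <- run$completed[[i]]
    tibble::tibble(
      imputation = i,
      successes_x0 = sum(comp$y[miss & d$x == 0] == 1),
      successes_x1 = sum(comp$y[miss & d$x == 1] == 1)
    )
  })
}

#' Fraction of perfectly predicted rows imputed at the unobserved level
#'
#' Runs multinomial imputation on [make_three_level()] and records, per
#' imputation, the fraction of the 100 `x = 0` rows with missing `y` that
#' were imputed as level 1 -- the level never observed with `x = 0`.
#'
#' @inheritParams table2_experiment
#' @return A tibble with columns `imputation`, `n_level1`, `frac_level1`;
#'   the average percentage is `100 * mean(frac_level1)`.
#' @export
three_level_experiment <- function(method, n_imputations = 100L, seed = 1L) {
  d <- make_three_level()
  run <- impute_univariate(d, "y", "x", kind = "nominal", method = method,
                           m = n_imputations, seed = seed)
  sel <- is.na(d$y) & d$x == 0
  purrr::map_dfr(seq_len(run$m), function(i) {
    n1 <- sum(run$completed[[i]]$y[sel] == 1)
    tibble::tibble(imputation = i, n_level1 = n1,
                   frac_level1 = n1 / sum(sel))
  })
}

#' Configuration for the factorial simulation study
#'
#' Defaults reproduce the study design: n = 500 per replicate,
#' \eqn{\pi_1 = 0.1} (prevalence of the incomplete binary `x1`),
#' \eqn{\pi_2 = 0.8} with \eqn{p(x_2 = 1 \mid x_1 = 1) = 0} so that perfect
#' prediction always occurs, \eqn{\beta = (1, 1, 0.5)}, \eqn{\sigma = 2},
#' 30\% MCAR missingness in `x1`, m = 5 imputations, 1000 replicates.
#'
#' @param n Sample size per replicate.
#' @param n_reps Number of replicates.
#' @param pi1,pi2 Prevalence parameters.
#' @param beta1,beta2,beta3 Outcome-model coefficients.
#' @param sigma Outcome residual SD.
#' @param miss_prob MCAR missingness probability for `x1`.
#' @param m Imputations per replicate.
#' @param method Draw strategy.
#' @param seed Root seed.
#' @return A `"sim_study_config"` list.
#' @export
sim_study_config <- function(n = 500L, n_reps = 1000L, pi1 = 0.1, pi2 = 0.8,
                             beta1 = 1, beta2 = 1, beta3 = 0.5, sigma = 2,
                             miss_prob = 0.3, m = 5L,
                             method = "normal_allow", seed = 1L) {
  method <- match.arg(method, DRAW_METHODS)
  structure(list(n = as.integer(n), n_reps = as.integer(n_reps),
                 pi1 = pi1, pi2 = pi2, beta1 = beta1, beta2 = beta2,
                 beta3 = beta3, sigma = sigma, miss_prob = miss_prob,
                 m = as.integer(m), method = method, seed = as.integer(seed)),
            class = "sim_study_config")
}

#' Simulate one dataset from the study design
#'
#' `x1 ~ Bernoulli(pi1)`; `x2 ~ Bernoulli(pi2)` when `x1 = 0` and `x2 = 0`
#' whenever `x1 = 1` (so `x2 = 1` perfectly predicts `x1 = 0`);
#' `x3 ~ N(0, 1)`; `y ~ N(beta1 x1 + beta2 x2 + beta3 x3, sigma^2)`; `x1` is
#' then set missing completely at random with probability `miss_prob`.
#'
#' @param config A [sim_study_config()].
#' @return A tibble with columns `x1` (containing NAs), `x2`, `x3`, `y` and
#'   `x1_true` (the generated values, for checking only).
#' @export
simulate_study_dataset <- function(config) {
  n <- config$n
  x1 <- as.numeric(stats::runif(n) < config$pi1)
  x2 <- as.numeric(stats::runif(n) < ifelse(x1 == 1, 0, config$pi2))
  x3 <- stats::rnorm(n)
  y <- stats::rnorm(n, config$beta1 * x1 + config$beta2 * x2 + config$beta3 * x3,
                    config$sigma)
  x1_obs <- x1
  x1_obs[stats::runif(n) < config$miss_prob] <- NA_real_
  # x1_true is the pre-deletion vector; built first so the x1 column (which
  # contains NAs) cannot shadow the generator variable inside tibble()
  tibble::tibble(x1_true = x1, x1 = x1_obs, x2 = x2, x3 = x3,
                 y = y)[c("x1", "x2", "x3", "y", "x1_true")]
}

# OLS of y on (1, x1, x2, x3): coefficients and their variances, by hand for
# speed (the study fits 5 of these per replicate)
ols_fit <- function(d) {
  X <- cbind(1, d$x1, d$x2, d$x3)
  qr_ <- qr(X)
  coefs <- qr.coef(qr_, d$y)
  res <- d$y - X %*% coefs
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  XtXi <- chol2inv(qr.R(qr_))
  list(coef = coefs[2:4], var = s2 * diag(XtXi)[2:4])
}

#' Run the simulation study and tabulate frequentist properties
#'
#' For each replicate a dataset is generated, the missing `x1` is imputed m
#' times from a logistic regression on `x2`, `x3` and `y` under the
#' configured draw strategy, and two complete-data analyses are pooled by
#' Rubin's rules: the prevalence \eqn{\pi_1} (mean of completed `x1`, with
#' binomial variance \eqn{p(1-p)/n}) and the coefficients of the linear
#' regression of `y` on `x1, x2, x3`.  Across replicates the function
#' reports, per parameter: bias, empirical SE, the relative error of the
#' model SE (\eqn{100(\overline{SE}_{mod}/SE_{emp} - 1)}), coverage of the
#' nominal 95\% t-interval, power to reject 0, and Monte Carlo errors.
#'
#' Replicate-level failures are caught, counted and skipped.
#'
#' @param config A [sim_study_config()].
#' @param progress Print a dot every 100 replicates?
#' @return A tibble of class `"sim_metrics"`, one row per parameter, with
#'   attribute `"estimates"` holding the per-replicate pooled results and
#'   attribute `"n_failed"`.
#' @export
run_simulation_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_study_config"))
  truth <- c(pi1 = config$pi1, beta1 = config$beta1,
             beta2 = config$beta2, beta3 = config$beta3)
  rows <- vector("list", config$n_reps)
  n_failed <- 0L
  for (rep_i in seq_len(config$n_reps)) {
    res <- tryCatch(
      withCallingHandlers(
        sim_one_replicate(config, rep_i),
        warning = function(w) {
          if (inherits(w, "sepmi_pseudoinverse_warning")) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[rep_i]] <- res
    if (progress && rep_i %% 100L == 0L) cat(".")
  }
  est <- dplyr::bind_rows(rows)
  metrics <- est |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      true_value = truth[[unique(.data$parameter)]],
      n_reps = dplyr::n(),
      bias = mean(.data$estimate) - true_value,
      emp_se = stats::sd(.data$estimate),
      modse_relerr_pct = 100 * (mean(.data$std.error) / emp_se - 1),
      coverage_pct = 100 * mean(.data$conf.low <= true_value &
                                  true_value <= .data$conf.high),
      power_pct = 100 * mean(.data$conf.low > 0 | .data$conf.high < 0),
      mcse_bias = emp_se / sqrt(n_reps),
      mcse_emp_se = emp_se / sqrt(2 * (n_reps - 1)),
      mcse_coverage = 100 * sqrt(coverage_pct / 100 *
                                   (1 - coverage_pct / 100) / n_reps),
      mcse_power = 100 * sqrt(power_pct / 100 * (1 - power_pct / 100) / n_reps),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, names(truth)))
  out <- structure(metrics, class = c("sim_metrics", class(metrics)))
  attr(out, "estimates") <- est
  attr(out, "n_failed") <- n_failed
  attr(out, "config") <- config
  out
}

sim_one_replicate <- function(config, rep_i) {
  set.seed(sub_seed(config$seed, rep_i))
  d <- simulate_study_dataset(config)
  run <- impute_univariate(d[c("x1", "x2", "x3", "y")], "x1",
                           c("x2", "x3", "y"), kind = "binary",
                           method = config$method, m = config$m,
                           seed = sub_seed(config$seed, rep_i) + 1L)
  n <- config$n
  per_imp <- purrr::map_dfr(seq_len(config$m), function(i) {
    comp <- run$completed[[i]]
    p <- mean(comp$x1)
    ols <- ols_fit(comp)
    tibble::tibble(
      term = c("pi1", "beta1", "beta2", "beta3"),
      estimate = c(p, ols$coef),
      variance = c(p * (1 - p) / n, ols$var)
    )
  })
  pooled <- pool_rubin(per_imp)
  tibble::tibble(
    replicate = rep_i,
    parameter = pooled$term,
    estimate = pooled$estimate,
    std.error = pooled$std.error,
    conf.low = pooled$conf.low,
    conf.high = pooled$conf.high
  )
}

#' Configuration for the longitudinal dropout generator
#'
#' Describes a repeated binary outcome with strong state dependence and
#' monotone dropout driven by the previous outcome, in the mould of a
#' multi-arm pain-relief trial: occasions `1..first_dropout_occasion - 1` are
#' complete, and from then on a subject who showed no relief at the previous
#' occasion is much more likely to drop out.
#'
#' @param n_per_arm Subjects per arm.
#' @param n_arms Number of treatment arms.
#' @param n_occasions Number of measurement occasions.
#' @param alpha `n_arms x n_occasions` matrix (or scalar) of occasion
#'   intercepts on the logit scale.
#' @param beta `n_arms x n_occasions` matrix (or scalar) of coefficients on
#'   the previous outcome (state dependence).
#' @param first_dropout_occasion First occasion at which dropout can occur.
#' @param dropout_intercept,dropout_coef Logit-scale dropout model:
#'   `p(drop at j) = expit(dropout_intercept + dropout_coef * (1 - y[j-1]))`.
#' @return A `"longitudinal_config"` list.
#' @export
longitudinal_config <- function(n_per_arm = 50L, n_arms = 2L, n_occasions = 10L,
                                alpha = 0, beta = 2.5,
                                first_dropout_occasion = 6L,
                                dropout_intercept = -4, dropout_coef = 4) {
  expand_mat <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == n_arms, ncol(x) == n_occasions)
      x
    } else matrix(x, n_arms, n_occasions)
  }
  structure(list(n_per_arm = as.integer(n_per_arm), n_arms = as.integer(n_arms),
                 n_occasions = as.integer(n_occasions),
                 alpha = expand_mat(alpha), beta = expand_mat(beta),
                 first_dropout_occasion = as.integer(first_dropout_occasion),
                 dropout_intercept = dropout_intercept,
                 dropout_coef = dropout_coef),
            class = "longitudinal_config")
}

#' Generate monotone longitudinal binary data with outcome-dependent dropout
#'
#' Outcomes follow \eqn{\mathrm{logit}\, p(Y_{tij} = 1 \mid Y_{ti(j-1)}) =
#' \alpha_{tj} + \beta_{tj} Y_{ti(j-1)}} (first occasion: intercept only).
#' From `first_dropout_occasion` onwards a subject drops out with probability
#' `expit(dropout_intercept + dropout_coef * (1 - y_prev))`; once dropped,
#' all later outcomes are missing, so the pattern is monotone by
#' construction.
#'
#' @param config A [longitudinal_config()].
#' @return A wide tibble: `arm` (factor) and `y1..yJ` numeric columns with a
#'   monotone missingness pattern.
#' @export
make_longitudinal <- function(config) {
  stopifnot(inherits(config, "longitudinal_config"))
  J <- config$n_occasions
  rows <- vector("list", config$n_arms)
  for (t in seq_len(config$n_arms)) {
    n <- config$n_per_arm
    Y <- matrix(NA_real_, n, J)
    Y[, 1] <- as.numeric(stats::runif(n) < stats::plogis(config$alpha[t, 1]))
    dropped <- rep(FALSE, n)
    for (j in 2:J) {
      if (j >= config$first_dropout_occasion) {
        pdrop <- stats::plogis(config$dropout_intercept +
                                 config$dropout_coef * (1 - Y[, j - 1]))
        pdrop[dropped] <- 1
        dropped <- dropped | (stats::runif(n) < pdrop)
      }
      pj <- stats::plogis(config$alpha[t, j] + config$beta[t, j] * Y[, j - 1])
      yj <- as.numeric(stats::runif(n) < pj)
      yj[dropped] <- NA_real_
      Y[, j] <- ifelse(dropped, NA_real_, yj)
    }
    df <- tibble::as_tibble(as.data.frame(Y))
    names(df) <- paste0("y", seq_len(J))
    df$arm <- factor(t)
    rows[[t]] <- df[c("arm", paste0("y", seq_len(J)))]
  }
  dplyr::bind_rows(rows)
}
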