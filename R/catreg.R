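#' Fit a categorical regression model for imputation
#'
#' Fits a logistic (`kind = "binary"`), proportional-odds (`kind = "ordinal"`,
#' parameterised as \eqn{\log p(Y > y \mid x) = \alpha_y + \beta' x}) or
#' baseline-category multinomial (`kind = "nominal"`,
#' \eqn{\log p(Y = y \mid x) = \alpha_y + \beta_y' x} with the first level as
#' reference) regression by weighted maximum likelihood, or a Firth-penalised
#' logistic regression (`penalty = "firth"`).
#'
#' Unpenalised fits are deliberately *not* protected against perfect
#' prediction (separation): iteration stops at convergence or at `maxit`
#' Newton steps, whichever comes first, and the estimates and (pseudo-inverse
#' if necessary) covariance matrix are reported as-is, with the `separated`
#' flag set.  This mirrors what general-purpose GLM software hands to a
#' normal-approximation parameter draw, which is the failure mode the rest of
#' the package addresses.  The Firth fit augments every observation at each
#' iteration with one success and one failure of weight \eqn{h_i/2}, where
#' \eqn{h_i} is the i-th diagonal of the weighted hat matrix
#' \eqn{W^{1/2}X(X'WX)^{-1}X'W^{1/2}}; its estimates are always finite.
#'
#' @param data A data frame.  Rows with a missing outcome are excluded from
#'   fitting (they are the rows later imputed).
#' @param outcome Name of the outcome column (character scalar).
#' @param predictors Character vector of predictor column names; defaults to
#'   all other columns.  Factor/character predictors are dummy-coded.
#' @param kind One of `"binary"`, `"ordinal"`, `"nominal"`.
#' @param penalty `"none"` or `"firth"` (binary only).
#' @param weights Optional case weights: a numeric vector of length
#'   `nrow(data)` or the name of a column.  Fractional weights are allowed.
#' @param maxit Newton/IRLS iteration cap for unpenalised fits (default 25).
#' @param levels Optional explicit level set for the outcome (character);
#'   defaults to the sorted observed levels.
#'
#' @return An object of class `"catreg"` with components `theta` (named
#'   parameter vector on the logit scale), `vcov`, `loglik`, `n_iter`,
#'   `converged`, `separated`, `hat` (Firth hat diagonals), and bookkeeping
#'   needed for prediction.  Use [tidy()][generics::tidy],
#'   [glance()][generics::glance], `coef()`, `vcov()` and `logLik()`.
#' @examples
#' d <- make_table2()
#' f <- fit_catreg(d, "y", "x", kind = "binary")
#' glance(f)       # separated = TRUE: X = 0 has no observed successes
#' tidy(fit_catreg(d, "y", "x", kind = "binary", penalty = "firth"))
#' @export
fit_catreg <- function(data, outcome, predictors = NULL,
                       kind = c("binary", "ordinal", "nominal"),
                       penalty = c("none", "firth"),
                       weights = NULL, maxit = 25L, levels = NULL) {
  kind <- match.arg(kind)
  penalty <- match.arg(penalty)
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  if (!all(predictors %in% names(data))) {
    rlang::abort("Unknown predictor column(s).", class = "sepmi_config_error")
  }
  if (penalty == "firth" && kind != "binary") {
    rlang::abort("Firth penalisation is only available for binary outcomes.",
                 class = "sepmi_config_error")
  }
  w <- resolve_weights(data, weights)
  yraw <- data[[outcome]]
  if (all(is.na(yraw))) {
    rlang::abort("Empty estimation sample: no observed outcomes.",
                 class = "sepmi_empty_error")
  }
  lev <- outcome_levels(yraw, levels)
  k <- length(lev)
  if (k < 2) rlang::abort("Outcome has fewer than 2 levels.",
                          class = "sepmi_config_error")
  if (kind == "binary" && k != 2) {
    rlang::abort("kind = 'binary' requires exactly 2 outcome levels.",
                 class = "sepmi_config_error")
  }
  if (kind != "binary" && k == 2) {
    # one threshold: models (ordinal, nominal) coincide with the logistic
    kind_eng <- kind
  }
  ycode <- match(as.character(yraw), lev)  # NA where outcome missing
  X <- build_design(data, predictors)
  obs <- !is.na(ycode)
  if (!any(obs)) rlang::abort("Empty estimation sample: no observed outcomes.",
                              class = "sepmi_empty_error")
  if (anyNA(X[obs, , drop = FALSE])) {
    rlang::abort("Missing values in predictors among rows with observed outcome.",
                 class = "sepmi_config_error")
  }
  Xo <- X[obs, , drop = FALSE]
  yo <- ycode[obs]
  wo <- w[obs]
  eng <- switch(kind,
    binary = if (penalty == "firth") fit_binary_firth(Xo, yo, wo)
             else fit_binary_ml(Xo, yo, wo, maxit = maxit),
    ordinal = {
      if (k == 2) fit_binary_ml(Xo, yo, wo, maxit = maxit)
      else fit_ordinal_ml(Xo, yo, wo, k, maxit = maxit)
    },
    nominal = {
      if (k == 2) fit_binary_ml(Xo, yo, wo, maxit = maxit)
      else fit_multinom_ml(Xo, yo, wo, k, maxit = maxit)
    }
  )
  vc <- vcov_from_information(eng$information)
  fit <- structure(list(
    theta = eng$theta,
    vcov = vc,
    loglik = eng$loglik,
    n_iter = eng$n_iter,
    converged = eng$converged,
    hat = eng$hat,
    score = eng$score,
    kind = kind, penalty = penalty, k = k, levels = lev,
    outcome = outcome, predictors = predictors,
    design_names = colnames(X),
    n = sum(obs), maxit = maxit,
    X = Xo, y = yo, w = wo
  ), class = "catreg")
  sep <- if (penalty == "firth") list(separated = FALSE, columns = character())
         else separation_status(fit)
  fit$separated <- sep$separated
  fit$separation_columns <- sep$columns
  fit
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) return(rep(1, nrow(data)))
  if (is.character(weights) && length(weights) == 1L) {
    w <- data[[weights]]
  } else {
    w <- weights
  }
  stopifnot(length(w) == nrow(data), all(w >= 0))
  as.numeric(w)
}

outcome_levels <- function(y, levels = NULL) {
  if (!is.null(levels)) return(as.character(levels))
  if (is.factor(y)) return(base::levels(y))
  lev <- sort(unique(y[!is.na(y)]))
  as.character(lev)
}

# dummy-coded design matrix over ALL rows (NA rows preserved), no intercept
build_design <- function(data, predictors) {
  if (length(predictors) == 0L) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  df <- data[predictors]
  df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
  mf <- stats::model.frame(~., data = df, na.action = stats::na.pass)
  mm <- stats::model.matrix(~., data = mf)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

# which components of theta are slopes (not intercepts/thresholds)?
slope_index <- function(fit) {
  nm <- names(fit$theta)
  if (fit$kind == "binary" || fit$k == 2) return(which(nm != "(Intercept)"))
  if (fit$kind == "ordinal") return(which(!startsWith(nm, "alpha_")))
  which(!startsWith(nm, "(Intercept):"))
}

separation_status <- function(fit, beta_max = SEPARATION_BETA) {
  sl <- slope_index(fit)
  big <- sl[abs(fit$theta[sl]) > beta_max]
  capped <- !fit$converged && fit$n_iter >= fit$maxit &&
    max(abs(fit$score)) > 1e-6
  cols <- unique(strip_level_suffix(names(fit$theta)[big]))
  if (capped && length(cols) == 0L && length(sl) > 0L) {
    cols <- strip_level_suffix(names(fit$theta)[sl[which.max(abs(fit$theta[sl]))]])
  }
  list(separated = length(big) > 0L || capped, columns = cols)
}

strip_level_suffix <- function(x) sub(":[0-9]+$", "", x)

#' Detect separation (perfect prediction) in a fitted model
#'
#' A fit is flagged as separated when any slope coefficient exceeds 10 in
#' absolute value on the logit scale, or when the iteration cap was hit with
#' the score still materially nonzero.  Under separation the likelihood tends
#' to a limit as one or more coefficients go to plus or minus infinity, so a
#' capped fit reports huge finite estimates and an enormous variance.
#'
#' @param fit A `"catreg"` fit with `penalty = "none"`.
#' @return A list with `separated` (logical) and `columns` (design columns
#'   implicated).
#' @examples
#' detect_separation(fit_catreg(make_table2(), "y", "x", kind = "binary"))
#' @export
detect_separation <- function(fit) {
  stopifnot(inherits(fit, "catreg"))
  if (fit$penalty != "none") {
    rlang::abort("detect_separation() applies to penalty = 'none' fits.",
                 class = "sepmi_config_error")
  }
  separation_status(fit)
}

#' Exact log-likelihood at an arbitrary parameter value
#'
#' Evaluates the exact weighted log-likelihood of the fitted model family at
#' `theta`, over the estimation sample stored in the fit.  Used by the
#' likelihood-ratio diagnostic [likelihood_ratio_R()].
#'
#' @param fit A `"catreg"` fit.
#' @param theta Parameter vector matching `fit$theta` in length and layout.
#' @return A scalar log-likelihood.
#' @export
loglik_at <- function(fit, theta) {
  stopifnot(inherits(fit, "catreg"), length(theta) == length(fit$theta))
  X <- fit$X; y <- fit$y; w <- fit$w; k <- fit$k
  if (fit$kind == "binary" || k == 2) {
    loglik_binary(theta, cbind(1, X), as.numeric(y == 2L), w)
  } else if (fit$kind == "ordinal") {
    loglik_ordinal(theta, X, y, w, k)
  } else {
    loglik_multinom_eng(theta, cbind(1, X), y, w, k)
  }
}

# category probabilities for (possibly new) design rows at a given theta
predict_probs <- function(fit, X, theta = fit$theta) {
  k <- fit$k
  if (fit$kind == "binary" || k == 2) {
    p1 <- stats::plogis(drop(cbind(1, X) %*% theta))
    P <- cbind(1 - p1, p1)
  } else if (fit$kind == "ordinal") {
    P <- ordinal_probs(theta, X, k)
    P[P < 0] <- 0
    P <- P / rowSums(P)
  } else {
    P <- multinom_probs(theta, cbind(1, X), k)
  }
  colnames(P) <- fit$levels
  P
}

#' @export
print.catreg <- function(x, ...) {
  cat(sprintf("<catreg> %s regression (%s), k = %d, n = %d\n",
              x$kind, if (x$penalty == "firth") "Firth-penalised" else "ML",
              x$k, x$n))
  cat(sprintf("  loglik = %.4f after %d iteration(s); converged: %s; separated: %s\n",
              x$loglik, x$n_iter, x$converged, x$separated))
  if (x$separated && length(x$separation_columns)) {
    cat("  perfect prediction involves: ",
        paste(x$separation_columns, collapse = ", "), "\n", sep = "")
  }
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.catreg <- function(object, ...) object$theta

#' @export
vcov.catreg <- function(object, ...) object$vcov

#' @export
logLik.catreg <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @rdname fit_catreg
#' @param x,object A `"catreg"` fit.
#' @param ... Unused.
#' @method tidy catreg
#' @export
tidy.catreg <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = se,
    statistic = unname(x$theta) / ifelse(se > 0, se, NA_real_)
  )
}

#' @rdname fit_catreg
#' @method glance catreg
#' @export
glance.catreg <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, penalty = x$penalty, k = x$k, n = x$n,
    logLik = x$loglik, n_iter = x$n_iter,
    converged = x$converged, separated = x$separated
  )
}
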