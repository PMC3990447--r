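#' Build augmentation records that avert perfect prediction
#'
#' For each of the `p` design columns and each of the `k` outcome levels, two
#' pseudo-observations are added at the column mean plus/minus one standard
#' deviation (all other columns held at their means), giving `2pk` records in
#' total.  Each record carries the small weight \eqn{w = (p+1)/(2pk)}, so the
#' total added weight is exactly \eqn{W = p+1}, the number of parameters of a
#' binary imputation model.  The same construction is used whether a column is
#' quantitative or a dummy for a categorical predictor, so the method is not
#' exactly invariant to the choice of reference category.
#'
#' Means and SDs are computed over the estimation sample (rows with an
#' observed outcome), since those are the rows whose fit must be stabilised.
#'
#' @param data A data frame containing the outcome and predictors.
#' @inheritParams fit_catreg
#' @return A tibble with one row per augmentation record: the design columns,
#'   `.outcome` (level label) and `.weight`.  Attributes `p`, `k`, `w` and
#'   `total_weight` record the bookkeeping.
#' @examples
#' augmentation_records(make_table2(), "y", "x")  # p = 1, k = 2: 4 records
#' @export
augmentation_records <- function(data, outcome, predictors = NULL,
                                 levels = NULL, weights = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  lev <- outcome_levels(data[[outcome]], levels)
  k <- length(lev)
  if (k < 2) rlang::abort("Outcome must have at least 2 levels.",
                          class = "sepmi_config_error")
  X <- build_design(data, predictors)
  p <- ncol(X)
  if (p < 1) rlang::abort("Augmentation requires at least one predictor.",
                          class = "sepmi_config_error")
  obs <- !is.na(data[[outcome]])
  if (sum(obs) < 2) rlang::abort("Need at least 2 observed rows.",
                                 class = "sepmi_empty_error")
  Xo <- X[obs, , drop = FALSE]
  if (anyNA(Xo)) {
    rlang::abort("Missing values in predictors among rows with observed outcome.",
                 class = "sepmi_config_error")
  }
  mu <- colMeans(Xo)
  sd_ <- apply(Xo, 2, stats::sd)
  if (any(sd_ == 0)) {
    rlang::abort(paste0("Constant predictor column(s): ",
                        paste(colnames(X)[sd_ == 0], collapse = ", ")),
                 class = "sepmi_config_error")
  }
  w <- (p + 1) / (2 * p * k)
  rec <- vector("list", 2L * p * k)
  idx <- 0L
  # observed levels iterated in ascending code order
  for (l in seq_len(k)) {
    for (j in seq_len(p)) {
      for (s in c(-1, 1)) {
        idx <- idx + 1L
        x <- mu
        x[j] <- mu[j] + s * sd_[j]
        rec[[idx]] <- c(x, level = l)
      }
    }
  }
  M <- do.call(rbind, rec)
  out <- tibble::as_tibble(as.data.frame(M[, seq_len(p), drop = FALSE]))
  names(out) <- colnames(X)
  out$.outcome <- lev[M[, p + 1L]]
  out$.weight <- w
  attr(out, "p") <- p
  attr(out, "k") <- k
  attr(out, "w") <- w
  attr(out, "total_weight") <- w * 2 * p * k
  attr(out, "means") <- mu
  attr(out, "sds") <- sd_
  out
}

#' Maximum-likelihood fit on data augmented against perfect prediction
#'
#' Concatenates the original rows (weight 1, or the supplied case weights)
#' with the [augmentation_records()] pseudo-observations (weight
#' \eqn{(p+1)/(2pk)}) and fits the requested model with `penalty = "none"`.
#' The resulting fit has finite estimates even when the original data are
#' perfectly predicted; this is the model behind the "Normal/augment" draw
#' strategy.
#'
#' @inheritParams fit_catreg
#' @return A `"catreg"` fit.  The augmentation plan is attached as attribute
#'   `"augmentation"`.
#' @examples
#' f <- fit_catreg(make_table2(), "y", "x")            # separated
#' fa <- fit_augmented(make_table2(), "y", "x")        # finite, not separated
#' glance(fa)
#' @export
fit_augmented <- function(data, outcome, predictors = NULL,
                          kind = c("binary", "ordinal", "nominal"),
                          weights = NULL, maxit = 25L, levels = NULL) {
  kind <- match.arg(kind)
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  plan <- augmentation_records(data, outcome, predictors, levels = levels)
  X <- build_design(data, predictors)
  obs <- !is.na(data[[outcome]])
  lev <- outcome_levels(data[[outcome]], levels)
  w0 <- resolve_weights(data, weights)
  Xa <- rbind(X[obs, , drop = FALSE],
              as.matrix(plan[colnames(X)]))
  ya <- c(match(as.character(data[[outcome]][obs]), lev),
          match(plan$.outcome, lev))
  wa <- c(w0[obs], plan$.weight)
  syn <- make.names(colnames(X), unique = TRUE)
  aug_df <- as.data.frame(Xa)
  names(aug_df) <- syn
  aug_df$.y <- lev[ya]
  fit <- fit_catreg(aug_df, ".y", syn, kind = kind, penalty = "none",
                    weights = wa, maxit = maxit, levels = lev)
  fit$outcome <- outcome
  fit$predictors <- predictors
  attr(fit, "augmentation") <- plan
  fit
}
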