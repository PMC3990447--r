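#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines m complete-data estimates and their variances:
#' \deqn{\bar Q = \frac{1}{m}\sum_i \hat Q_i, \quad
#'       \bar U = \frac{1}{m}\sum_i U_i, \quad
#'       B = \frac{1}{m-1}\sum_i (\hat Q_i - \bar Q)^2, \quad
#'       T = \bar U + (1 + 1/m) B,}
#' with Rubin degrees of freedom
#' \eqn{\nu = (m-1)\{1 + \bar U / ((1+1/m)B)\}^2}, the df-adjusted fraction of
#' missing information \eqn{\mathrm{FMI} = (r + 2/(\nu+3))/(r+1)} where
#' \eqn{r = (1+1/m)B/\bar U}, the simple proportion
#' \eqn{\lambda = (1+1/m)B/T}, and a t-based confidence interval on \eqn{\nu}
#' degrees of freedom.
#'
#' Edge cases: with `B = 0` the pooled interval equals the single-imputation
#' Wald interval (`fmi = 0`, infinite df); with `U = 0` and `B > 0` all the
#' information is attributed to the missing data (`fmi = 1`, df = m - 1).
#'
#' @param data Optional data frame of per-imputation results with columns
#'   `estimate` and `variance`, and optionally `term` (pooled per term).
#' @param estimates,variances Alternatively, numeric vectors of length m.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per term: `estimate`, `u_bar`, `b`,
#'   `t` (total variance), `std.error`, `df`, `fmi`, `lambda`, `conf.low`,
#'   `conf.high`, `m`.
#' @examples
#' pool_rubin(estimates = c(0, 1), variances = c(1, 1))
#' @export
pool_rubin <- function(data = NULL, estimates = NULL, variances = NULL,
                       level = 0.95) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data),
              all(c("estimate", "variance") %in% names(data)))
    if ("term" %in% names(data)) {
      return(dplyr::group_modify(
        dplyr::group_by(tibble::as_tibble(data), .data$term),
        ~ rubin_one(.x$estimate, .x$variance, level)
      ) |> dplyr::ungroup())
    }
    return(rubin_one(data$estimate, data$variance, level))
  }
  stopifnot(!is.null(estimates), !is.null(variances))
  rubin_one(estimates, variances, level)
}

rubin_one <- function(q, u, level = 0.95) {
  stopifnot(length(q) == length(u), length(q) >= 1L, all(u >= 0))
  m <- length(q)
  qbar <- mean(q)
  ubar <- mean(u)
  b <- if (m > 1L) stats::var(q) else 0
  tt <- ubar + (1 + 1 / m) * b
  if (b <= 0 || m == 1L) {
    fmi <- 0
    lambda <- 0
    df <- Inf
  } else if (ubar == 0) {
    fmi <- 1
    lambda <- 1
    df <- m - 1
  } else {
    r <- (1 + 1 / m) * b / ubar
    df <- (m - 1) * (1 + 1 / r)^2
    fmi <- (r + 2 / (df + 3)) / (r + 1)
    lambda <- (1 + 1 / m) * b / tt
  }
  se <- sqrt(tt)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tibble::tibble(
    estimate = qbar, u_bar = ubar, b = b, t = tt, std.error = se,
    df = df, fmi = fmi, lambda = lambda,
    conf.low = qbar - tcrit * se, conf.high = qbar + tcrit * se, m = m
  )
}
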