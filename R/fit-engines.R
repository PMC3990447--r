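# Internal Newton/IRLS engines for categorical regression.
#
# All engines share a contract: design matrix X (no intercept column), outcome
# codes y in 1..k, nonnegative (possibly fractional) case weights w.  Fits with
# penalty = "none" are run to convergence or to `maxit` iterations and are then
# *reported as-is*: under separation this yields huge finite estimates and a
# near-singular information matrix, which is exactly the behaviour the
# normal-approximation draw strategies must be exposed to.

MAXIT_DEFAULT <- 25L
SCORE_TOL <- 1e-8
LOGLIK_RELTOL <- 1e-10
SEPARATION_BETA <- 10
PROB_FLOOR <- 1e-300

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# central-difference Jacobian of a vector-valued function (used for the
# ordinal observed information; dimensions are tiny)
num_jacobian <- function(fn, x, eps = 1e-6) {
  d <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), d)
  for (j in seq_len(d)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

solve_or_ginv <- function(A, b = NULL) {
  out <- tryCatch({
    if (is.null(b)) chol2inv(chol(A)) else solve(A, b)
  }, error = function(e) NULL)
  if (is.null(out)) {
    Ai <- MASS::ginv(A)
    out <- if (is.null(b)) Ai else drop(Ai %*% b)
    attr(out, "pseudo") <- TRUE
  }
  out
}

vcov_from_information <- function(I) {
  V <- tryCatch(chol2inv(chol(I)), error = function(e) NULL)
  pseudo <- FALSE
  if (is.null(V) || !all(is.finite(V))) {
    V <- MASS::ginv(I)
    pseudo <- TRUE
    rlang::warn(
      "Information matrix is numerically singular; using a Moore-Penrose pseudo-inverse for vcov.",
      class = "sepmi_pseudoinverse_warning"
    )
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(I)
  attr(V, "pseudo") <- pseudo
  V
}

check_rank <- function(Xt) {
  qrX <- qr(Xt)
  if (qrX$rank < ncol(Xt)) {
    bad <- colnames(Xt)[qrX$pivot[(qrX$rank + 1L):ncol(Xt)]]
    rlang::abort(
      paste0("Design matrix is rank deficient; offending columns: ",
             paste(bad, collapse = ", ")),
      class = "sepmi_rank_error"
    )
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------- binary ----

loglik_binary <- function(theta, Xt, y1, w) {
  eta <- drop(Xt %*% theta)
  sum(w * ifelse(y1 == 1, stats::plogis(eta, log.p = TRUE),
                 stats::plogis(-eta, log.p = TRUE)))
}

fit_binary_ml <- function(X, y, w, maxit = MAXIT_DEFAULT) {
  Xt <- cbind("(Intercept)" = 1, X)
  y1 <- as.numeric(y == 2L)  # level 2 of 2 is the "success"
  check_rank(Xt)
  pbar <- clamp_prob(sum(w * y1) / sum(w), 1e-6)
  theta <- c(stats::qlogis(pbar), rep(0, ncol(X)))
  ll <- loglik_binary(theta, Xt, y1, w)
  converged <- FALSE
  score <- rep(Inf, length(theta))
  iter <- 0L
  Ifin <- NULL
  while (iter < maxit) {
    iter <- iter + 1L
    p <- clamp_prob(stats::plogis(drop(Xt %*% theta)))
    W <- w * p * (1 - p)
    score <- drop(crossprod(Xt, w * (y1 - p)))
    Ifin <- crossprod(Xt, Xt * W)
    step <- solve_or_ginv(Ifin, score)
    ll_new <- loglik_binary(theta + step, Xt, y1, w)
    halved <- 0L
    while (!is.finite(ll_new) || (ll_new < ll && halved < 25L)) {
      step <- step / 2
      halved <- halved + 1L
      ll_new <- loglik_binary(theta + step, Xt, y1, w)
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) break  # no ascent possible
    theta <- theta + step
    if (max(abs(score)) < SCORE_TOL ||
        abs(ll_new - ll) < LOGLIK_RELTOL * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  p <- clamp_prob(stats::plogis(drop(Xt %*% theta)))
  Ifin <- crossprod(Xt, Xt * (w * p * (1 - p)))
  names(theta) <- colnames(Xt)
  dimnames(Ifin) <- list(colnames(Xt), colnames(Xt))
  list(theta = theta, information = Ifin, loglik = loglik_binary(theta, Xt, y1, w),
       n_iter = iter, converged = converged, score = score, hat = NULL)
}

# Firth penalised logistic fit: at every iteration each observation is
# augmented with one success and one failure, both of weight h_i/2, where h_i
# is the i-th diagonal of the weighted hat matrix.  The modified score is
# U*(theta) = X' { w(y - p) + h(1/2 - p) }, whose root is the Firth estimate.
fit_binary_firth <- function(X, y, w, maxit = 100L) {
  Xt <- cbind("(Intercept)" = 1, X)
  y1 <- as.numeric(y == 2L)
  check_rank(Xt)
  theta <- rep(0, ncol(Xt))
  penloglik <- function(th) {
    p <- clamp_prob(stats::plogis(drop(Xt %*% th)))
    XtWX <- crossprod(Xt, Xt * (w * p * (1 - p)))
    loglik_binary(th, Xt, y1, w) +
      0.5 * as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  }
  pll <- penloglik(theta)
  converged <- FALSE
  iter <- 0L
  h <- rep(0, nrow(Xt))
  Istar <- NULL
  while (iter < maxit) {
    iter <- iter + 1L
    p <- clamp_prob(stats::plogis(drop(Xt %*% theta)))
    W <- w * p * (1 - p)
    XtWX <- crossprod(Xt, Xt * W)
    M <- solve_or_ginv(XtWX)
    h <- W * rowSums((Xt %*% M) * Xt)
    score <- drop(crossprod(Xt, w * (y1 - p) + h * (0.5 - p)))
    Istar <- crossprod(Xt, Xt * (W + h * p * (1 - p)))
    step <- solve_or_ginv(Istar, score)
    pll_new <- penloglik(theta + step)
    halved <- 0L
    while (!is.finite(pll_new) || (pll_new < pll && halved < 25L)) {
      step <- step / 2
      halved <- halved + 1L
      pll_new <- penloglik(theta + step)
    }
    theta <- theta + step
    if (max(abs(score)) < SCORE_TOL) {
      converged <- TRUE
      break
    }
    pll <- pll_new
  }
  p <- clamp_prob(stats::plogis(drop(Xt %*% theta)))
  W <- w * p * (1 - p)
  XtWX <- crossprod(Xt, Xt * W)
  M <- solve_or_ginv(XtWX)
  h <- W * rowSums((Xt %*% M) * Xt)
  Istar <- crossprod(Xt, Xt * (W + h * p * (1 - p)))
  names(theta) <- colnames(Xt)
  dimnames(Istar) <- list(colnames(Xt), colnames(Xt))
  list(theta = theta, information = Istar,
       loglik = loglik_binary(theta, Xt, y1, w),
       n_iter = iter, converged = converged,
       score = drop(crossprod(Xt, w * (y1 - p) + h * (0.5 - p))), hat = h)
}

## --------------------------------------------------------------- ordinal ----

# theta = (alpha_1, ..., alpha_{k-1}, beta); log p(Y > y | x) = alpha_y + beta'x
# so cumulative "exceedance" probabilities gamma_y = expit(alpha_y + beta'x)
# and category probabilities p(Y = y) = gamma_{y-1} - gamma_y (gamma_0 = 1,
# gamma_k = 0).  Positive beta shifts mass towards higher levels.
ordinal_gamma <- function(theta, X, k) {
  a <- theta[seq_len(k - 1L)]
  b <- theta[-seq_len(k - 1L)]
  xb <- if (length(b)) drop(X %*% b) else rep(0, nrow(X))
  stats::plogis(outer(xb, a, `+`))  # n x (k-1)
}

ordinal_probs <- function(theta, X, k) {
  g <- ordinal_gamma(theta, X, k)
  gfull <- cbind(1, g, 0)
  gfull[, 1:k, drop = FALSE] - gfull[, 2:(k + 1L), drop = FALSE]
}

loglik_ordinal <- function(theta, X, y, w, k) {
  P <- ordinal_probs(theta, X, k)
  p <- P[cbind(seq_along(y), y)]
  if (any(p <= 0)) return(-Inf)
  sum(w * log(pmax(p, PROB_FLOOR)))
}

score_ordinal <- function(theta, X, y, w, k) {
  n <- nrow(X)
  g <- ordinal_gamma(theta, X, k)       # n x (k-1)
  dg <- g * (1 - g)
  gfull <- cbind(1, g, 0)
  p <- gfull[cbind(seq_len(n), y)] - gfull[cbind(seq_len(n), y + 1L)]
  p <- pmax(p, 1e-12)
  U <- numeric(length(theta))
  wp <- w / p
  # thresholds: d p_i / d alpha_j = dg_j (1[j = y-1] - 1[j = y])
  for (j in seq_len(k - 1L)) {
    U[j] <- sum(wp * dg[, j] * ((y == j + 1L) - (y == j)))
  }
  if (ncol(X) > 0) {
    # beta: d p_i / d beta = (dg_{y-1} 1[y>1] - dg_y 1[y<k]) x
    dprev <- ifelse(y > 1L, dg[cbind(seq_len(n), pmax(y - 1L, 1L))], 0)
    dcur <- ifelse(y < k, dg[cbind(seq_len(n), pmin(y, k - 1L))], 0)
    U[k:(k - 1L + ncol(X))] <- drop(crossprod(X, wp * (dprev - dcur)))
  }
  U
}

fit_ordinal_ml <- function(X, y, w, k, maxit = MAXIT_DEFAULT) {
  check_rank(cbind(1, X))
  cnt <- vapply(seq_len(k), function(l) sum(w[y == l]), numeric(1))
  if (any(cnt == 0)) {
    rlang::abort(
      paste0("Outcome level(s) with zero observed weight: ",
             paste(which(cnt == 0) - 1L, collapse = ", "),
             ". Collapse empty levels before fitting."),
      class = "sepmi_empty_level_error"
    )
  }
  exceed <- rev(cumsum(rev(cnt)))[-1] / sum(cnt)  # p(Y > y), y = 1..k-1
  theta <- c(stats::qlogis(clamp_prob(exceed, 1e-6)), rep(0, ncol(X)))
  nms <- c(paste0("alpha_", seq_len(k - 1L)), colnames(X))
  ll <- loglik_ordinal(theta, X, y, w, k)
  converged <- FALSE
  iter <- 0L
  score <- rep(Inf, length(theta))
  while (iter < maxit) {
    iter <- iter + 1L
    score <- score_ordinal(theta, X, y, w, k)
    J <- num_jacobian(function(th) score_ordinal(th, X, y, w, k), theta)
    I <- -(J + t(J)) / 2
    step <- solve_or_ginv(I, score)
    ll_new <- loglik_ordinal(theta + step, X, y, w, k)
    halved <- 0L
    while (!is.finite(ll_new) || (ll_new < ll && halved < 25L)) {
      step <- step / 2
      halved <- halved + 1L
      ll_new <- loglik_ordinal(theta + step, X, y, w, k)
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) break
    theta <- theta + step
    if (max(abs(score)) < SCORE_TOL ||
        abs(ll_new - ll) < LOGLIK_RELTOL * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  J <- num_jacobian(function(th) score_ordinal(th, X, y, w, k), theta)
  I <- -(J + t(J)) / 2
  names(theta) <- nms
  dimnames(I) <- list(nms, nms)
  list(theta = theta, information = I,
       loglik = loglik_ordinal(theta, X, y, w, k),
       n_iter = iter, converged = converged,
       score = score_ordinal(theta, X, y, w, k), hat = NULL)
}

## ----------------------------------------------------------- multinomial ----

# Baseline-category logit with level 1 as reference: for j = 2..k,
# log p(Y = j | x) - log p(Y = 1 | x) = alpha_j + beta_j'x.  theta is stored
# in per-level blocks (alpha_j, beta_j).
multinom_eta <- function(theta, Xt, k) {
  d <- ncol(Xt)
  eta <- matrix(0, nrow(Xt), k)
  for (j in 2:k) {
    eta[, j] <- Xt %*% theta[((j - 2L) * d + 1L):((j - 1L) * d)]
  }
  eta
}

multinom_probs <- function(theta, Xt, k) {
  eta <- multinom_eta(theta, Xt, k)
  emax <- apply(eta, 1, max)
  ee <- exp(eta - emax)
  ee / rowSums(ee)
}

loglik_multinom_eng <- function(theta, Xt, y, w, k) {
  eta <- multinom_eta(theta, Xt, k)
  emax <- apply(eta, 1, max)
  lse <- emax + log(rowSums(exp(eta - emax)))
  sum(w * (eta[cbind(seq_along(y), y)] - lse))
}

fit_multinom_ml <- function(X, y, w, k, maxit = MAXIT_DEFAULT) {
  Xt <- cbind("(Intercept)" = 1, X)
  check_rank(Xt)
  cnt <- vapply(seq_len(k), function(l) sum(w[y == l]), numeric(1))
  if (any(cnt == 0)) {
    rlang::abort(
      paste0("Outcome level(s) with zero observed weight: ",
             paste(which(cnt == 0) - 1L, collapse = ", "),
             ". Collapse empty levels before fitting."),
      class = "sepmi_empty_level_error"
    )
  }
  d <- ncol(Xt)
  theta <- unlist(lapply(2:k, function(j) c(log(cnt[j] / cnt[1]), rep(0, d - 1L))))
  nms <- unlist(lapply(2:k, function(j) paste0(colnames(Xt), ":", j)))
  ll <- loglik_multinom_eng(theta, Xt, y, w, k)
  converged <- FALSE
  iter <- 0L
  score <- rep(Inf, length(theta))
  info <- function(P) {
    I <- matrix(0, d * (k - 1L), d * (k - 1L))
    for (j in 2:k) {
      for (l in 2:k) {
        v <- w * P[, j] * ((j == l) - P[, l])
        I[((j - 2L) * d + 1L):((j - 1L) * d), ((l - 2L) * d + 1L):((l - 1L) * d)] <-
          crossprod(Xt, Xt * v)
      }
    }
    I
  }
  Ifin <- NULL
  while (iter < maxit) {
    iter <- iter + 1L
    P <- multinom_probs(theta, Xt, k)
    score <- unlist(lapply(2:k, function(j)
      drop(crossprod(Xt, w * ((y == j) - P[, j])))))
    Ifin <- info(P)
    step <- solve_or_ginv(Ifin, score)
    ll_new <- loglik_multinom_eng(theta + step, Xt, y, w, k)
    halved <- 0L
    while (!is.finite(ll_new) || (ll_new < ll && halved < 25L)) {
      step <- step / 2
      halved <- halved + 1L
      ll_new <- loglik_multinom_eng(theta + step, Xt, y, w, k)
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) break
    theta <- theta + step
    if (max(abs(score)) < SCORE_TOL ||
        abs(ll_new - ll) < LOGLIK_RELTOL * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  P <- multinom_probs(theta, Xt, k)
  Ifin <- info(P)
  names(theta) <- nms
  dimnames(Ifin) <- list(nms, nms)
  list(theta = theta, information = Ifin,
       loglik = loglik_multinom_eng(theta, Xt, y, w, k),
       n_iter = iter, converged = converged,
       score = unlist(lapply(2:k, function(j)
         drop(crossprod(Xt, w * ((y == j) - P[, j]))))),
       hat = NULL)
}
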