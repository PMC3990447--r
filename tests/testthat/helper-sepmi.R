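# Fixtures built in code, shared across test files.

# data frame for a 2x2 table of counts: cells (x, y) = (0,0)=a, (0,1)=b,
# (1,0)=c, (1,1)=d
table_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    x = rep(c(0, 0, 1, 1), times = c(a, b, c, d)),
    y = rep(c(0, 1, 0, 1), times = c(a, b, c, d))
  )
}

# independently maximise the unpenalised weighted logistic likelihood with
# optim (oracle for the Newton fitters)
optim_logistic <- function(x, y, w = rep(1, length(x)), start = c(0, 0)) {
  nll <- function(th) {
    eta <- th[1] + th[2] * x
    -sum(w * ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                    stats::plogis(-eta, log.p = TRUE)))
  }
  gr <- function(th) {
    p <- stats::plogis(th[1] + th[2] * x)
    -c(sum(w * (y - p)), sum(w * (y - p) * x))
  }
  stats::optim(start, nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

# a dataset with complete separation on a quantitative covariate
separated_quantitative <- function(n = 40) {
  x <- c(seq(-2, -0.1, length.out = n / 2), seq(0.1, 2, length.out = n / 2))
  tibble::tibble(x = x, y = as.numeric(x > 0))
}

# random small binary dataset guaranteed to be separated: one x level has a
# single observed outcome value
random_separated <- function(seed) {
  set.seed(seed)
  n0 <- sample(5:30, 1)
  n1 <- sample(5:30, 1)
  tibble::tibble(
    x = c(rep(0, n0), rep(1, n1)),
    y = c(rep(0, n0), rbinom(n1, 1, runif(1, 0.3, 0.7)))
  )
}

expect_tolerably_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
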