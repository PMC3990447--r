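test_that("augmentation bookkeeping is exact over a (p, k) grid", {
  set.seed(99)
  for (p in 1:6) {
    for (k in 2:4) {
      n <- 40
      d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p)))
      names(d) <- paste0("x", seq_len(p))
      d$y <- rep_len(seq_len(k) - 1L, n)
      plan <- augmentation_records(d, "y", paste0("x", seq_len(p)))
      expect_identical(nrow(plan), 2L * p * k)
      expect_true(all(plan$.weight == (p + 1) / (2 * p * k)))
      # exact arithmetic: total weight is p + 1
      expect_equal(sum(plan$.weight) - (p + 1), 0)
      # every outcome level appears in exactly 2p records
      expect_true(all(table(plan$.outcome) == 2 * p))
    }
  }
})

test_that("each record sits at the mean vector except one coordinate at mean +/- sd", {
  set.seed(7)
  d <- tibble::tibble(x1 = rnorm(50), x2 = runif(50), y = rbinom(50, 1, 0.5))
  plan <- augmentation_records(d, "y", c("x1", "x2"))
  mu <- attr(plan, "means"); s <- attr(plan, "sds")
  X <- as.matrix(plan[c("x1", "x2")])
  for (i in seq_len(nrow(X))) {
    off <- which(abs(X[i, ] - mu) > 1e-12)
    expect_length(off, 1)
    expect_equal(unname(abs(X[i, off] - mu[off])), unname(s[off]),
                 tolerance = 1e-12)
  }
})

test_that("means and SDs are computed over the estimation sample only", {
  d <- make_table2()  # 300 complete cases: 100 x=0, 200 x=1
  plan <- augmentation_records(d, "y", "x")
  obs_x <- d$x[!is.na(d$y)]
  expect_equal(unname(attr(plan, "means")), mean(obs_x), tolerance = 1e-12)
  expect_equal(unname(attr(plan, "sds")), sd(obs_x), tolerance = 1e-12)
  # brute force over the 300 rows
  expect_equal(unname(attr(plan, "means")), sum(obs_x) / 300, tolerance = 1e-12)
})

test_that("constant predictors and degenerate outcomes are rejected", {
  d <- tibble::tibble(x = rep(1, 20), y = rbinom(20, 1, 0.5))
  expect_error(augmentation_records(d, "y", "x"), class = "sepmi_config_error")
  d2 <- tibble::tibble(x = rnorm(20), y = rep(0, 20))
  expect_error(augmentation_records(d2, "y", "x"), class = "sepmi_config_error")
})

test_that("augmented fit of the artificial data is finite and not separated", {
  fa <- fit_augmented(make_table2(), "y", "x", kind = "binary")
  expect_false(fa$separated)
  expect_true(all(is.finite(fa$theta)))
  # the x = 0 success log-odds is strongly negative but bounded, while the
  # x = 1 group stays near 50:50
  p <- plogis(c(fa$theta[[1]], sum(fa$theta)))
  expect_lt(p[1], 0.05)
  expect_gt(p[1], 1e-4)
  expect_gt(p[2], 0.4)
  expect_lt(p[2], 0.6)
  # oracle: numerical maximisation of the augmented weighted likelihood
  plan <- attr(fa, "augmentation")
  d <- make_table2()
  obs <- !is.na(d$y)
  xall <- c(d$x[obs], plan$x)
  yall <- c(d$y[obs], as.numeric(plan$.outcome))
  wall <- c(rep(1, sum(obs)), plan$.weight)
  oracle <- optim_logistic(xall, yall, w = wall)
  expect_tolerably_equal(unname(fa$theta), oracle, 1e-4)
})

test_that("augmentation is a vanishing perturbation on well-behaved data", {
  d <- table_2x2(200, 100, 100, 200)
  f0 <- fit_catreg(d, "y", "x", kind = "binary")
  fa <- fit_augmented(d, "y", "x", kind = "binary")
  # total added weight is 2 against n = 600: effects of order W/n
  expect_tolerably_equal(unname(fa$theta), unname(f0$theta), 0.05)
})

test_that("single-group augmented fit reproduces the h-added-cells probability", {
  # intercept-plus-dummy analysis of one group with r successes, f failures:
  # adding total weight W split evenly across the two levels is the
  # h-added-cells fit with h = W / k, whose fitted p is (r + h)/(r + f + 2h)
  r <- 4; f <- 60
  h <- 0.5
  d0 <- tibble::tibble(y = rep(c(1, 0), times = c(r, f)))
  ll <- function(a) sum(rep(c(1, 0), times = c(r, f)) * plogis(a, log.p = TRUE) +
                          rep(c(0, 1), times = c(r, f)) * plogis(-a, log.p = TRUE))
  nll_aug <- function(a) {
    -( (r + h) * plogis(a, log.p = TRUE) + (f + h) * plogis(-a, log.p = TRUE) )
  }
  a_hat <- optimize(nll_aug, c(-10, 10), tol = 1e-10)$minimum
  expect_equal(plogis(a_hat), (r + h) / (r + f + 2 * h), tolerance = 1e-5)
})

test_that("recoding the reference level of a 3-level factor shifts estimates slightly", {
  set.seed(55)
  g <- factor(sample(c("a", "b", "c"), 300, replace = TRUE))
  y <- rbinom(300, 1, plogis(-0.5 + 0.6 * (g == "b") + 0.3 * (g == "c")))
  d1 <- tibble::tibble(g = g, y = y)
  d2 <- tibble::tibble(g = stats::relevel(g, "c"), y = y)
  f1 <- fit_augmented(d1, "y", "g", kind = "binary")
  f2 <- fit_augmented(d2, "y", "g", kind = "binary")
  # compare on a common scale: fitted probability for each original level
  p1 <- plogis(c(f1$theta[1], f1$theta[1] + f1$theta[2], f1$theta[1] + f1$theta[3]))
  p2 <- plogis(c(f2$theta[1] + f2$theta[2], f2$theta[1] + f2$theta[3], f2$theta[1]))
  gap <- max(abs(p1 - p2))
  expect_gt(gap, 0)      # not exactly invariant ...
  expect_lt(gap, 0.02)   # ... but of no practical importance
})
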