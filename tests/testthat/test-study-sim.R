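test_that("the artificial dataset has the published cell counts", {
  d <- make_table2()
  expect_equal(nrow(d), 500)
  expect_equal(sum(!is.na(d$y)), 300)
  counts <- dplyr::count(d, x, y)
  expect_equal(counts$n[counts$x == 0 & !is.na(counts$y) & counts$y == 0], 100)
  expect_equal(sum(d$x == 0 & !is.na(d$y) & d$y == 1), 0)  # no successes in x=0
  expect_equal(sum(is.na(d$y) & d$x == 0), 100)
  expect_equal(sum(is.na(d$y) & d$x == 1), 100)
  expect_identical(make_table2(), make_table2())  # deterministic
})

test_that("the three-level extension adds 200 level-2 rows and stays separated", {
  d <- make_three_level()
  expect_equal(nrow(d), 700)
  expect_equal(sum(!is.na(d$y) & d$y == 2), 200)
  expect_equal(sum(d$x == 0 & !is.na(d$y) & d$y == 1), 0)
  expect_identical(make_three_level(), make_three_level())
})

test_that("bootstrap imputes no successes in the perfectly predicted group", {
  tab <- table2_experiment("bootstrap", n_imputations = 30, seed = 2)
  expect_true(all(tab$successes_x0 == 0))
  expect_lt(abs(mean(tab$successes_x1) - 50), 6)
})

test_that("augmented imputation matches the quadrature oracle on the artificial data", {
  tab <- table2_experiment("normal_augment", n_imputations = 100, seed = 3)
  oracle <- expected_imputed_successes(r = 0, f = 100, h = 0.5, n_missing = 100)
  mc_se <- sd(tab$successes_x0) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$successes_x0) - oracle), 3 * mc_se)
})

test_that("the study-design generator has the specified joint distribution", {
  cfg <- sim_study_config(n = 1e6, seed = 1)
  set.seed(11)
  d <- simulate_study_dataset(cfg)
  expect_true(all(d$x2[d$x1_true == 1] == 0))  # x2 = 1 never with x1 = 1
  expect_lt(abs(mean(d$x1_true) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e6))
  expect_lt(abs(mean(is.na(d$x1)) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e6))
  expect_lt(abs(mean(d$x2[d$x1_true == 0]) - 0.8), 0.002)
  # y regression structure
  cf <- coef(lm(y ~ x1_true + x2 + x3, data = d))
  expect_lt(max(abs(cf[2:4] - c(1, 1, 0.5))), 0.02)
})

test_that("with no missing data all strategies leave the analysis unbiased", {
  cfg <- sim_study_config(n = 400, n_reps = 30, miss_prob = 0,
                          method = "normal_allow", seed = 5, m = 2)
  res <- run_simulation_study(cfg)
  expect_true(all(abs(res$bias) < 3 * res$mcse_bias + 1e-8))
  expect_equal(attr(res, "n_failed"), 0)
})

test_that("remediated strategies are nearly unbiased while normal_allow shows the sign pattern", {
  reps <- 120
  boot <- run_simulation_study(sim_study_config(n_reps = reps, method = "bootstrap",
                                                seed = 42))
  expect_true(all(abs(boot$bias) <= pmax(3 * boot$mcse_bias, 0.02)))
  allow <- run_simulation_study(sim_study_config(n_reps = reps,
                                                 method = "normal_allow", seed = 42))
  b <- setNames(allow$bias, allow$parameter)
  expect_gt(b[["pi1"]], 0.03)    # prevalence biased upwards
  expect_lt(b[["beta1"]], -0.1)  # associations attenuated
  expect_lt(b[["beta2"]], -0.05)
  expect_lt(abs(b[["beta3"]]), 0.05)  # x3 is independent of x1
})

test_that("the longitudinal generator respects its parameters and monotonicity", {
  set.seed(9)
  cfg <- longitudinal_config(n_per_arm = 400, n_arms = 2, beta = 0,
                             alpha = matrix(rep(c(-0.5, 0.5), each = 10),
                                            2, 10, byrow = TRUE),
                             dropout_intercept = -30, dropout_coef = 0)
  d <- make_longitudinal(cfg)
  expect_false(anyNA(d))  # dropout probability ~ 0 => complete data
  # beta = 0: occasion prevalences match expit(alpha)
  for (t in 1:2) {
    prev <- colMeans(d[d$arm == t, paste0("y", 1:10)])
    expect_lt(max(abs(prev - plogis(cfg$alpha[t, 1]))), 0.09)
  }
  # outcome-dependent dropout produces a monotone pattern
  set.seed(10)
  d2 <- make_longitudinal(longitudinal_config(n_per_arm = 100))
  ymat <- as.matrix(d2[paste0("y", 1:10)])
  bad_rows <- 0L
  for (i in seq_len(nrow(ymat))) {
    nas <- unname(which(is.na(ymat[i, ])))
    if (length(nas) && !identical(nas, seq(min(nas), 10L))) bad_rows <- bad_rows + 1L
  }
  expect_identical(bad_rows, 0L)
  expect_gt(sum(is.na(ymat)), 0)
})

test_that("strong state dependence provokes separation in occasion-wise fits", {
  set.seed(77)
  hits <- 0L
  for (i in 1:40) {
    cfg <- longitudinal_config(n_per_arm = 40, n_arms = 1, beta = 6, alpha = -2,
                               dropout_intercept = -3, dropout_coef = 2)
    d <- make_longitudinal(cfg)
    for (j in 6:10) {
      dd <- tibble::tibble(prev = d[[paste0("y", j - 1)]], y = d[[paste0("y", j)]])
      dd <- dd[!is.na(dd$prev), ]
      if (length(unique(dd$y[!is.na(dd$y)])) < 2) next
      f <- try(suppressWarnings(fit_catreg(dd, "y", "prev", kind = "binary")),
               silent = TRUE)
      if (!inherits(f, "try-error") && f$separated) hits <- hits + 1L
    }
    if (hits > 0) break
  }
  expect_gt(hits, 0)
})

test_that("monotone imputation runs on per-arm longitudinal models with state dependence", {
  set.seed(15)
  cfg_gen <- longitudinal_config(n_per_arm = 120, n_arms = 2, beta = 2.5,
                                 alpha = 0.3)
  d <- make_longitudinal(cfg_gen)
  arm1 <- dplyr::filter(d, arm == 1)
  specs <- lapply(6:10, function(j)
    imp_spec(paste0("y", j), paste0("y", j - 1), kind = "binary"))
  cfg <- imputation_config(specs, m = 3, method = "normal_augment", seed = 2)
  run <- impute_monotone(arm1, cfg)
  for (i in 1:3) {
    expect_false(anyNA(completed_data(run, i)[paste0("y", 6:10)]))
  }
  expect_equal(nrow(run$audit), 3 * 5)
})
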