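# Reductions, correlations, stepwise regression

test_that("of-means reductions reproduce the published arithmetic", {
  # spikelet fertility Control vs ROS
  r <- reduction_metrics(87.80, 54.48)
  expect_equal(r$absolute, 33.32)
  expect_equal(r$percent, 100 * 33.32 / 87.80, tolerance = 1e-12)
  # plant height Control vs TPE
  expect_equal(reduction_metrics(118.99, 80.99)$absolute, 38.00)
  # panicle length Control vs ROS: the trait means imply 0.62 (a printed
  # rounding of 0.60 exists elsewhere; we reproduce the arithmetic)
  expect_equal(reduction_metrics(23.92, 23.30)$absolute, 0.62)
  # identical distributions -> zero in both modes
  x <- c(4, 5, 6)
  expect_equal(reduction_metrics(x, x)$absolute, 0)
  expect_equal(reduction_metrics(x, x, mode = "mean-of-per-genotype")$percent,
               0)
  expect_error(reduction_metrics(c(-1, 1), c(0, 0)), "zero")
})

test_that("per-genotype mode pairs by name and averages the ratios", {
  ctl <- c(a = 10, b = 20, c = 40)
  str <- c(b = 10, c = 10, a = 5)
  r <- reduction_metrics(ctl, str, mode = "mean-of-per-genotype",
                         genotype = list(names(ctl), names(str)))
  # pairs: a 10->5 (50%), b 20->10 (50%), c 40->10 (75%)
  expect_equal(r$percent, mean(c(50, 50, 75)))
  expect_equal(r$absolute, mean(c(5, 10, 30)))
  expect_error(reduction_metrics(1:3, 1:2, mode = "mean-of-per-genotype"),
               "paired")
})

test_that("reduction_table emits both modes per trait x stress pair", {
  sim <- simulate_met(sim_config(n_test = 30, n_blocks = 3,
                                 traits = c("gy", "sf"), seed = 41))
  sta <- run_all_sta(sim$records)
  rt <- reduction_table(sta$blues)
  expect_equal(nrow(rt), 2 * 2 * 2)  # 2 traits x {ROS,TPE} x 2 modes
  expect_true(all(rt$absolute[rt$trait == "gy"] > 0))
})

test_that("trait correlations match the closed-form Pearson quantities", {
  m <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  cm <- trait_correlations(m)
  r_hand <- sum((m[, 1] - 3) * (m[, 2] - 3)) /
    sqrt(sum((m[, 1] - 3)^2) * sum((m[, 2] - 3)^2))
  expect_equal(cm$r["x", "y"], r_hand)
  expect_equal(diag(cm$r), c(x = 1, y = 1))
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(cm$p["x", "y"], 2 * pt(-abs(t_hand), 3))
  # exact anti-correlation and zero-variance handling
  m2 <- cbind(a = 1:4, b = -(1:4), c = rep(2, 4))
  cm2 <- trait_correlations(m2)
  expect_equal(cm2$r["a", "b"], -1)
  expect_true(is.na(cm2$r["a", "c"]))
  # symmetric PSD on complete random data
  set.seed(2)
  cm3 <- trait_correlations(matrix(rnorm(200), 40, 5))
  expect_equal(cm3$r, t(cm3$r))
  expect_gt(min(eigen(cm3$r, symmetric = TRUE)$values), -1e-10)
})

test_that("environment correlations reshape and correlate BLUEs", {
  b <- data.frame(environment = rep(c("A", "B"), each = 4),
                  genotype = rep(letters[1:4], 2),
                  blue = c(1, 2, 3, 4, 1, 2, 3, 4))
  cm <- env_correlations(b)
  expect_equal(cm$r["A", "B"], 1)
  expect_error(env_correlations(b[b$environment == "A", ]),
               ">= 2 environments")
})

test_that("environment correlation recovery from simulated trials", {
  cfg <- sim_config(n_test = 400, n_blocks = 5, traits = "hsw", seed = 55)
  # hsw: configured Control-TPE genetic correlation 0.89, high H2
  robs <- sapply(1:5, function(s) {
    sim <- simulate_met(cfg, seed = 550 + s)
    sta <- run_all_sta(sim$records)
    env_correlations(sta$blues)$r["Control", "TPE"]
  })
  expect_lt(abs(median(robs) - 0.89), 0.1)
  # independent environments: gy ROS-TPE configured at 0.00
  cfg0 <- sim_config(n_test = 400, n_blocks = 5, traits = "gy", seed = 56)
  robs0 <- sapply(1:5, function(s) {
    sim <- simulate_met(cfg0, seed = 560 + s)
    sta <- run_all_sta(sim$records)
    b <- sta$blues
    env_correlations(b[!b$is_check, ])$r["ROS", "TPE"]
  })
  expect_lt(abs(median(robs0)), 0.1)
})

test_that("stepwise selects a planted single predictor", {
  set.seed(61)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                            dimnames = list(NULL, paste0("t", 1:5))))
  y <- 2 + 5 * X$t3 + rnorm(n)
  res <- stepwise_regression(y, X)
  expect_identical(res$selected, "t3")
  expect_gt(res$r_squared, 0.9)
  expect_lte(res$adj_r_squared, res$r_squared)
})

test_that("stepwise agrees with exhaustive best-subset AIC", {
  set.seed(62)
  for (i in 1:6) {
    n <- 80
    X <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                              dimnames = list(NULL, paste0("t", 1:5))))
    beta <- c(1.2, 0, 0.8, 0, 0.4)
    y <- drop(as.matrix(X) %*% beta) + rnorm(n)
    res <- stepwise_regression(y, X, r_threshold = 0)
    orc <- oracle_best_subset(y, X)
    expect_identical(sort(res$selected), orc$selected)
    expect_equal(res$aic, orc$aic, tolerance = 1e-8)
  }
})

test_that("stepwise retains the intercept-only model under pure noise", {
  # AIC admits a noise predictor whenever its t^2 > ~2, i.e. with
  # P(chi2_1 > 2) ~ 0.157 per candidate, so null retention is only a
  # majority event for a small candidate set: with 2 candidates,
  # P(null) ~ 0.843^2 ~ 0.71
  picks <- sapply(1:20, function(s) {
    set.seed(700 + s)
    X <- as.data.frame(matrix(rnorm(200 * 2), 200, 2,
                              dimnames = list(NULL, paste0("t", 1:2))))
    length(stepwise_regression(rnorm(200), X)$selected)
  })
  expect_gte(sum(picks == 0), 11)  # majority keeps the null model
})

test_that("stepwise is invariant to candidate column order", {
  set.seed(63)
  X <- as.data.frame(matrix(rnorm(100 * 4), 100, 4,
                            dimnames = list(NULL, c("a", "b", "c", "d"))))
  y <- 1 + 2 * X$b - 1.5 * X$d + rnorm(100)
  r1 <- stepwise_regression(y, X)
  r2 <- stepwise_regression(y, X[, c("d", "c", "b", "a")])
  expect_identical(sort(r1$selected), sort(r2$selected))
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
})

test_that("collinear candidates are dropped with a warning", {
  set.seed(64)
  X <- data.frame(a = rnorm(50))
  X$b <- 2 * X$a
  X$c <- rnorm(50)
  y <- X$a + rnorm(50)
  expect_warning(res <- stepwise_regression(y, X), "collinear")
  expect_false(all(c("a", "b") %in% res$candidates))
})

test_that("the p-value criterion variant runs and matches on clear signal", {
  set.seed(65)
  X <- as.data.frame(matrix(rnorm(150 * 4), 150, 4,
                            dimnames = list(NULL, paste0("t", 1:4))))
  y <- 3 * X$t1 - 2 * X$t4 + rnorm(150)
  res <- stepwise_regression(y, X, criterion = "p")
  expect_setequal(res$selected, c("t1", "t4"))
})
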