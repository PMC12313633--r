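# REML engine against closed forms and dense oracles

test_that("balanced one-way REML equals the ANOVA estimators", {
  for (seed in c(2, 7, 19)) {
    set.seed(seed)
    q <- 10; r <- 4
    g <- rep(seq_len(q), each = r)
    y <- 5 + rnorm(q, 0, 1.5)[g] + rnorm(q * r, 0, 1)
    msb <- r * var(tapply(y, g, mean))
    msw <- sum((y - ave(y, g))^2) / (q * (r - 1))
    expect_gt(msb, msw)  # seeds chosen so the interior case applies
    vc <- reml_fit(model_spec(y, fixed = rep(1, q * r), random = g))
    expect_equal(vc$v_random, (msb - msw) / r, tolerance = 1e-5)
    expect_equal(vc$v_error, msw, tolerance = 1e-5)
    expect_true(vc$converged)
  }
})

test_that("reported REML log-likelihood matches the dense criterion", {
  set.seed(31)
  f <- sample(letters[1:3], 30, replace = TRUE)
  r <- sample(1:5, 30, replace = TRUE)
  y <- rnorm(30) + c(a = 0, b = 1, c = 2)[f] + rnorm(5, 0, 0.8)[r]
  sp <- model_spec(y, fixed = f, random = r)
  vc <- reml_fit(sp)
  ll_dense <- oracle_reml_loglik(y, f, r, vc$v_random, vc$v_error)
  expect_equal(vc$reml_loglik, as.numeric(ll_dense), tolerance = 1e-6)
  # and the optimum dominates a grid around it
  grid <- expand.grid(vu = vc$v_random * c(0.5, 0.8, 1.25, 2),
                      ve = vc$v_error * c(0.5, 0.8, 1.25, 2))
  lls <- mapply(function(vu, ve) oracle_reml_loglik(y, f, r, vu, ve),
                grid$vu, grid$ve)
  expect_true(all(vc$reml_loglik >= lls - 1e-6))
})

test_that("REML is invariant to adding a constant to the response", {
  set.seed(5)
  d <- make_augmented(seed = 5)
  sp1 <- model_spec(d$y, fixed = d$genotype, random = d$block)
  sp2 <- model_spec(d$y + 1000, fixed = d$genotype, random = d$block)
  ## shifted data lose mantissa bits, so exact equality is not attainable
  v1 <- reml_fit(sp1); v2 <- reml_fit(sp2)
  expect_equal(v1$v_random, v2$v_random, tolerance = 1e-4)
  expect_equal(v1$v_error, v2$v_error, tolerance = 1e-4)
})

test_that("zero within-level variance is flagged as degenerate", {
  g <- rep(1:4, each = 3)
  y <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4)
  vc <- reml_fit(model_spec(y, fixed = rep(1, 12), random = g))
  expect_false(vc$converged)
  expect_true(vc$boundary)
  expect_lt(vc$v_error, 1e-8)
})

test_that("empty fixed levels are dropped with a warning naming them", {
  f <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "ghost"))
  expect_warning(model_spec(rnorm(4), fixed = f, random = c(1, 2, 1, 2)),
                 "ghost")
})

test_that("solve_mme matches the balanced one-way shrinkage closed form", {
  set.seed(11)
  q <- 6; r <- 5
  g <- rep(seq_len(q), each = r)
  y <- 3 + rnorm(q, 0, 2)[g] + rnorm(q * r)
  sp <- model_spec(y, fixed = rep(1, q * r), random = g)
  vc <- list(v_random = 2.3, v_error = 0.9)
  eff <- solve_mme(sp, vc)
  shrink <- r * vc$v_random / (r * vc$v_random + vc$v_error)
  expected <- as.numeric(shrink * (tapply(y, g, mean) - mean(y)))
  expect_equal(eff$random$blup, expected, tolerance = 1e-10)
  # v_random -> Inf limit: predictions -> level means minus grand mean
  eff_inf <- solve_mme(sp, list(v_random = 1e8, v_error = 0.9))
  expect_equal(eff_inf$random$blup,
               as.numeric(tapply(y, g, mean) - mean(y)), tolerance = 1e-6)
})

test_that("BLUEs/BLUPs match the dense GLS oracle on random instances", {
  # augmented 12-obs toy plus a batch of random designs (<= 50 obs)
  d <- make_augmented(n_entries = 8, n_checks = 2, nb = 2, seed = 3)
  expect_equal(nrow(d), 12L)
  sp <- model_spec(d$y, fixed = d$genotype, random = d$block)
  vc <- list(v_random = 0.4, v_error = 0.3)
  eff <- solve_mme(sp, vc)
  orc <- oracle_mme(d$y, d$genotype, d$block, 0.4, 0.3)
  expect_equal(eff$fixed$estimate[match(orc$beta_names, eff$fixed$level)],
               orc$beta, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(eff$random$blup[match(orc$u_names, eff$random$level)],
               orc$u, tolerance = 1e-8, ignore_attr = TRUE)

  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    f <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    r <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    # ensure both factors keep >= 2 observed levels
    if (length(unique(f)) < 2 || length(unique(r)) < 2) next
    y <- rnorm(n, 0, 2)
    vu <- runif(1, 0.1, 3); ve <- runif(1, 0.1, 3)
    eff <- solve_mme(model_spec(y, fixed = f, random = r),
                     list(v_random = vu, v_error = ve))
    orc <- oracle_mme(y, f, r, vu, ve)
    expect_equal(eff$fixed$estimate[match(orc$beta_names, eff$fixed$level)],
                 orc$beta, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(eff$random$blup[match(orc$u_names, eff$random$level)],
                 orc$u, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("shrinkage is monotone in the residual variance", {
  set.seed(17)
  d <- make_augmented(n_entries = 10, n_checks = 3, nb = 3, seed = 17)
  sp <- model_spec(d$y, fixed = d$genotype, random = d$block)
  prev <- NULL
  for (ve in c(0.1, 0.5, 1, 5, 25)) {
    eff <- solve_mme(sp, list(v_random = 1, v_error = ve))
    cur <- abs(eff$random$blup)
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("weighted fits agree with the dense heteroscedastic oracle", {
  set.seed(23)
  n <- 30
  f <- sample(c("x", "y", "z"), n, replace = TRUE)
  r <- sample(1:4, n, replace = TRUE)
  y <- rnorm(n) + c(x = 0, y = 2, z = 4)[f]
  w <- runif(n, 0.5, 2)
  sp_w <- model_spec(y, fixed = f, random = r, weights = w)
  sp_1 <- model_spec(y, fixed = f, random = r, weights = rep(1, n))
  sp_0 <- model_spec(y, fixed = f, random = r)
  vc_w <- reml_fit(sp_w)
  expect_equal(reml_fit(sp_1)$reml_loglik, reml_fit(sp_0)$reml_loglik,
               tolerance = 1e-8)
  ll <- oracle_reml_loglik(y, f, r, vc_w$v_random, vc_w$v_error, w = w)
  expect_equal(vc_w$reml_loglik, as.numeric(ll), tolerance = 1e-6)
})

test_that("heritability follows vg/(vg+ve) with guarded edge cases", {
  expect_equal(heritability(list(v_random = 1, v_error = 1)), 0.5)
  expect_equal(heritability(list(v_random = 3, v_error = 1)), 0.75)
  expect_equal(heritability(list(v_random = 2, v_error = 0)), 1.0)
  expect_error(heritability(list(v_random = 0, v_error = 0)), "undefined")
  expect_error(heritability(list(v_random = -1, v_error = 1)),
               "non-negative")
})
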