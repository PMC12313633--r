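# Synthetic trial generator: published defaults, determinism, noise-free
# limits, correlation structure recovery

test_that("default configuration carries the published trial parameters", {
  cfg <- default_config()
  expect_equal(cfg$n_test, 500L)
  expect_equal(cfg$n_blocks, 10L)
  expect_equal(nrow(cfg$checks), 7L)
  expect_equal(sum(cfg$checks$role == "tolerant"), 4L)
  expect_equal(sum(cfg$checks$role == "susceptible"), 3L)
  expect_equal(cfg$mean["gy", "Control"], 4.57)
  expect_equal(cfg$mean["gy", "ROS"], 1.55)
  expect_equal(cfg$mean["gy", "TPE"], 1.37)
  expect_equal(cfg$mean["dff", "Control"], 85.26)
  expect_equal(cfg$h2["dff", "Control"], 0.98)
  expect_equal(cfg$h2["gy", "Control"], 0.88)
  # self-validation of the invariants (PSD correlation matrices etc.)
  expect_silent(validate_config(cfg))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_test = 25, n_blocks = 3, traits = c("gy", "sf"),
                    seed = 99)
  s1 <- simulate_met(cfg)
  s2 <- simulate_met(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_met(cfg, seed = 100)
  expect_false(identical(s1$records$value, s3$records$value))
  # byte-identical CSV round trip
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_phenotypes(s1$records, p1)
  write_phenotypes(s2$records, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  unlink(c(p1, p2))
})

test_that("noise-free limit returns environment mean plus genetic effect", {
  cfg <- sim_config(n_test = 15, n_blocks = 3, traits = c("gy", "sf"),
                    seed = 4)
  cfg$v_e[] <- 0
  cfg$v_block[] <- 0
  sim <- simulate_met(cfg)
  tr <- sim$truth$genetic
  key <- paste(tr$genotype, tr$environment, tr$trait)
  rec <- sim$records
  expected <- tr$true_value[match(paste(rec$genotype, rec$environment,
                                        rec$trait), key)]
  expect_equal(rec$value, expected, tolerance = 1e-12)
})

test_that("stress environments realize lower means than control", {
  # traits whose stress gap is many plot-SD standard errors wide (the
  # plant-height ROS gap of 3.17 cm is within sampling noise at this n)
  sim <- simulate_met(sim_config(n_test = 200, n_blocks = 5,
                                 traits = c("gy", "sf", "pw"), seed = 8))
  rs <- realized_summary(sim$records)
  for (tn in c("gy", "sf", "pw")) {
    m <- rs[rs$trait == tn, ]
    ctl <- m$mean[m$environment == "Control"]
    expect_true(all(m$mean[m$environment != "Control"] < ctl))
  }
})

test_that("realized summary computes mean/range/CV as documented", {
  rec <- data.frame(environment = "E", block = 1, genotype = "g",
                    is_check = FALSE,
                    trait = rep(c("a", "b"), each = 3),
                    value = c(2, 2, 2, 1, 2, 3))
  rs <- realized_summary(rec)
  a <- rs[rs$trait == "a", ]; b <- rs[rs$trait == "b", ]
  expect_equal(a$cv, 0)
  expect_equal(b$mean, 2)
  expect_equal(c(b$min, b$max), c(1, 3))
  expect_equal(b$cv, 100 * sd(c(1, 2, 3)) / 2)
  # zero mean -> CV reported missing
  rec0 <- data.frame(environment = "E", block = 1, genotype = "g",
                     is_check = FALSE, trait = "z", value = c(-1, 1))
  expect_true(is.na(realized_summary(rec0)$cv))
})

test_that("simulated grain yield mean tracks the configured 4.57 t/ha", {
  sim <- simulate_met(sim_config(traits = "gy", seed = 12))
  rs <- realized_summary(sim$records)
  m <- rs$mean[rs$environment == "Control"]
  # 570 plots, plot SD ~1.44 -> sampling SE ~0.06
  expect_lt(abs(m - 4.57), 0.25)
})

test_that("truth recovers the configured cross-environment correlations", {
  # median over 5 seeds of realized genetic correlation at n_test = 500
  cfg <- sim_config(traits = c("gy", "hsw"), seed = 1)
  obs <- sapply(1:5, function(s) {
    tr <- simulate_met(cfg, seed = s)$truth$genetic
    tr <- tr[!tr$genotype %in% cfg$checks$name, ]
    g <- function(tn, ev) tr$genetic_effect[tr$trait == tn &
                                              tr$environment == ev]
    c(gy_CR = cor(g("gy", "Control"), g("gy", "ROS")),
      gy_RT = cor(g("gy", "ROS"), g("gy", "TPE")),
      hsw_CT = cor(g("hsw", "Control"), g("hsw", "TPE")))
  })
  med <- apply(obs, 1, median)
  expect_lt(abs(med["gy_CR"] - 0.26), 0.05)
  expect_lt(abs(med["gy_RT"] - 0.00), 0.05)
  expect_lt(abs(med["hsw_CT"] - 0.89), 0.05)
})

test_that("between-trait correlation is realized within an environment", {
  cfg <- sim_config(traits = c("gy", "pw"), seed = 2)
  tr <- simulate_met(cfg)$truth$genetic
  tr <- tr[!tr$genotype %in% cfg$checks$name & tr$environment == "Control", ]
  r <- cor(tr$genetic_effect[tr$trait == "gy"],
           tr$genetic_effect[tr$trait == "pw"])
  expect_lt(abs(r - cfg$trait_corr["gy", "pw"]), 0.1)
})

test_that("layout: checks in every block, tests in exactly one block", {
  sim <- simulate_met(sim_config(n_test = 30, n_blocks = 4, traits = "gy",
                                 seed = 5))
  rec <- sim$records
  for (ev in unique(rec$environment)) {
    re <- rec[rec$environment == ev, ]
    chk <- table(re$genotype[re$is_check], re$block[re$is_check])
    expect_true(all(chk == 1))
    tst <- table(re$genotype[!re$is_check])
    expect_true(all(tst == 1))
  }
})

test_that("score traits land on the 1-9 integer scale", {
  sim <- simulate_met(sim_config(n_test = 50, n_blocks = 3,
                                 traits = c("pe", "lr", "ltd"), seed = 6))
  v <- sim$records$value
  expect_true(all(v == round(v) & v >= 1 & v <= 9))
  # availability: lr/ltd under ROS only, pe everywhere
  tab <- table(sim$records$trait, sim$records$environment)
  expect_equal(sum(tab["lr", c("Control", "TPE")]), 0)
  expect_equal(sum(tab["ltd", c("Control", "TPE")]), 0)
  expect_true(all(tab["pe", ] > 0))
})

test_that("plot dropout removes whole plots at the configured rate", {
  cfg <- sim_config(n_test = 200, n_blocks = 5, traits = c("gy", "sf"),
                    dropout = 0.2, seed = 9)
  sim <- simulate_met(cfg)
  full <- simulate_met(sim_config(n_test = 200, n_blocks = 5,
                                  traits = c("gy", "sf"), seed = 9))
  rate <- 1 - nrow(sim$records) / nrow(full$records)
  expect_lt(abs(rate - 0.2), 0.05)
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(sim_config(n_blocks = 1), "n_blocks")
  expect_error(sim_config(dropout = 1.5), "dropout")
  expect_error(sim_config(traits = "nope"), "unknown traits")
  cfg <- sim_config(traits = c("gy", "sf"))
  cfg$env_corr$gy["Control", "ROS"] <- 5   # not a correlation
  cfg$env_corr$gy["ROS", "Control"] <- 5
  expect_error(validate_config(cfg), "positive semi-definite")
})
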