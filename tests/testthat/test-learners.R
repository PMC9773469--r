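test_that("rmst integrates step survival curves exactly", {
  expect_equal(rmst(numeric(0), numeric(0), tau = 3), 3) # S identically 1
  expect_equal(rmst(1, 0.5, tau = 2), 1.5)
  expect_equal(rmst(c(2, 1), c(0.25, 0.5), tau = 3), 1 + 0.5 + 0.25)

  # fine discretization of exp(-t) converges to 1 - exp(-1)
  tgrid <- seq(1e-4, 1, by = 1e-4)
  expect_lt(abs(rmst(tgrid, exp(-tgrid), tau = 1) - (1 - exp(-1))), 2e-4)

  # monotone in the curve and bounded by tau
  set.seed(4)
  for (i in 1:10) {
    tms <- sort(runif(8, 0, 2))
    s_lo <- sort(runif(8), decreasing = TRUE)
    s_hi <- pmin(s_lo + runif(8, 0, 0.2), 1)
    s_hi <- cummin(s_hi)
    tau <- runif(1, 0.5, 3)
    expect_lte(rmst(tms, s_lo, tau), rmst(tms, s_hi, tau) + 1e-12)
    expect_lte(rmst(tms, s_lo, tau), tau)
  }

  expect_error(rmst(c(1, 2), c(0.4, 0.6), tau = 3), "nonincreasing")
})

test_that("all learners find the dominant arm under a uniform effect", {
  d <- toy_data(n = 150, seed = 9, effect = 1)
  set.seed(1)
  grid <- data.frame(x1 = runif(40), x2 = runif(40))

  expect_equal(unique(predict(fit_zom(d), grid)), 1L)
  expect_equal(unique(predict(fit_cox_learner(d), grid)), 1L)
  expect_equal(unique(predict(fit_rsf_learner(d, seed = 2, num_trees = 100),
                              grid)), 1L)
})

test_that("rules are deterministic and invariant to training row order", {
  d <- toy_data(n = 60, seed = 10, effect = 0.3)
  set.seed(2)
  grid <- data.frame(x1 = runif(30), x2 = runif(30))

  r1 <- fit_rsf_learner(d, seed = 5, num_trees = 50)
  expect_identical(predict(r1, grid), predict(r1, grid))
  r2 <- fit_rsf_learner(d, seed = 5, num_trees = 50)
  expect_identical(predict(r1, grid), predict(r2, grid))

  shuffled <- d[sample(nrow(d)), ]
  r3 <- fit_rsf_learner(shuffled, seed = 5, num_trees = 50)
  expect_identical(predict(r1, grid), predict(r3, grid))

  c1 <- fit_cox_learner(d)
  c2 <- fit_cox_learner(shuffled)
  expect_identical(predict(c1, grid), predict(c2, grid))
})

test_that("the zero-order model breaks exact ties toward arm 0", {
  times <- c(1, 2, 3, 4)
  df <- data.frame(time = rep(times, 2), status = 1L,
                   treatment = rep(c(0L, 1L), each = 4),
                   x1 = runif(8))
  d <- survival_data(df, tau = 5)
  expect_equal(predict(fit_zom(d), data.frame(x1 = c(.2, .8))), c(0L, 0L))
})

test_that("the zero-order model requires events in both arms", {
  df <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 0, 0),
                   treatment = c(0, 0, 1, 1), x1 = runif(4))
  expect_error(fit_zom(survival_data(df, tau = 10)), "no events")
})

test_that("decisions always land in {0,1} and degenerate arms error", {
  d <- simulate_scenario(1, 80, censoring = 0, seed = 15)
  grid <- d[1:20, dataset_covariates(d)]
  for (rule in list(fit_cox_learner(d), fit_zom(d),
                    fit_rsf_learner(d, seed = 1, num_trees = 30))) {
    expect_true(all(predict(rule, grid) %in% c(0L, 1L)))
  }
  d1 <- d
  d1$treatment <- 0L
  expect_error(fit_cox_learner(d1), "arms")
  expect_error(fit_rsf_learner(d1), "arms")
})

test_that("the forest outlearns the Cox rule under tree-structured effects", {
  # large sample, strongly non-linear effect structure: forest decisions agree
  # with the oracle rule more often than the interaction Cox model's
  d <- simulate_scenario(2, 800, censoring = 0, seed = 3)
  orc <- oracle_rule(2)
  set.seed(77)
  grid <- survjack:::draw_covariates(500, 5L)
  opt <- predict(orc, grid)
  acc_rsf <- mean(predict(fit_rsf_learner(d, seed = 1, num_trees = 150),
                          grid) == opt)
  acc_cox <- mean(predict(fit_cox_learner(d), grid) == opt)
  expect_gt(acc_rsf, acc_cox)
  expect_gt(acc_rsf, 0.8)
})

test_that("the Cox rule is at least as valuable as the forest at small n
          under a log-linear model", {
  vals <- vapply(1:6, function(b) {
    d <- simulate_scenario(1, 200, censoring = 0, seed = 100 + b)
    c(true_rule_value(1, fit_cox_learner(d), 2000, seed = 500 + b),
      true_rule_value(1, fit_rsf_learner(d, seed = 1, num_trees = 64), 2000,
                      seed = 500 + b))
  }, c(0, 0))
  expect_gte(mean(vals[1, ]), mean(vals[2, ]))
})
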