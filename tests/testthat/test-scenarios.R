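test_that("simulation is bit-reproducible and respects the data contract", {
  d1 <- simulate_scenario(2, 100, censoring = 0.2, seed = 11)
  d2 <- simulate_scenario(2, 100, censoring = 0.2, seed = 11)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_scenario(2, 100, censoring = 0.2, seed = 12)
  expect_false(identical(d1$time, d3$time))

  expect_true(all(d1$time <= dataset_tau(d1)))
  expect_true(all(d1$status %in% 0:1))
  expect_equal(dataset_covariates(d1), paste0("x", 1:5))
  # event indicator consistent with the latent times
  expect_equal(d1$status,
               as.integer(pmin(d1$true_T, dataset_tau(d1)) <= d1$true_C))
})

test_that("the scenario horizons and failure models match their definitions", {
  expect_equal(scenario_defaults()$tau, rep(c(1.8, 8, 2.5), each = 3))

  # proportional hazards inverse transform: Lambda0(t) = t^2, so with lp = 0
  # a uniform draw of exp(-1) maps to time exactly 1
  expect_equal(survjack:::ph_failure_time(exp(-1), 0), 1)

  # scenario 1 conditional median at x = (.5,...,.5), arm 0:
  # lp = -0.2 - 0.25 + 0.25 + 0.2 = 0, so the noise-free failure time is 1
  X <- as.data.frame(as.list(setNames(rep(0.5, 5), paste0("x", 1:5))))
  sp <- scenario_spec(1)
  expect_equal(sp$failure_lp(X, 0), 0)
  expect_equal(survjack:::conditional_value(sp, X, 0L, restricted = FALSE), 1)
})

test_that("reference censoring intercepts reproduce their target rates", {
  defaults <- scenario_defaults()
  for (i in seq_len(nrow(defaults))) {
    d <- simulate_scenario(defaults$scenario[i], 3e4,
                           alpha = defaults$alpha[i], seed = 40 + i)
    expect_lt(abs(censoring_rate(d) - defaults$censoring[i]), 0.015)
  }
  # no censoring: every latent failure before tau is observed
  d0 <- simulate_scenario(1, 1000, censoring = 0, seed = 2)
  expect_true(all(d0$status == 1L))
})

test_that("calibration recovers intercepts monotone in the target rate", {
  a10 <- calibrate_alpha(1, 0.10, n_cal = 2e4, seed = 3)
  a20 <- calibrate_alpha(1, 0.20, n_cal = 2e4, seed = 3)
  a40 <- calibrate_alpha(1, 0.40, n_cal = 2e4, seed = 3)
  expect_gt(a10, a20)
  expect_gt(a20, a40)
  # unreachably low target: the administrative floor P(T~ > tau) intervenes
  expect_error(calibrate_alpha(2, 0.005, n_cal = 2e4, seed = 3),
               "administrative floor")
})

test_that("closed-form rule values agree with brute-force simulation", {
  rule <- function(X) as.integer(X$x2 < 0.5)
  for (scen in c(1, 3)) {
    v_cf <- true_rule_value(scen, rule, 2e5, seed = 9)
    v_mc <- true_rule_value(scen, rule, 4e5, seed = 10, method = "simulation")
    expect_lt(abs(v_cf - v_mc), 0.01)
  }
})

test_that("the optimal rule attains the optimal value and dominates
          constant rules", {
  for (scen in 1:3) {
    orc <- oracle_rule(scen, restricted = TRUE)
    v_opt <- true_optimal_value(scen, 2e5, seed = 14, restricted = TRUE)
    v_orc <- true_rule_value(scen, orc, 2e5, seed = 14, restricted = TRUE)
    expect_lt(abs(v_orc - v_opt), 1e-10) # same draws, same inner means
    v0 <- true_rule_value(scen, 0, 2e5, seed = 14, restricted = TRUE)
    v1 <- true_rule_value(scen, 1, 2e5, seed = 14, restricted = TRUE)
    expect_lte(v0, v_opt)
    expect_lte(v1, v_opt)
  }
})

test_that("the known censoring evaluator matches the empirical censoring
          distribution", {
  alpha <- 0.22
  d <- simulate_scenario(1, 2e4, alpha = alpha, seed = 17)
  cm <- true_censoring_model(1, alpha)
  for (t0 in c(0.3, 0.8, 1.5)) {
    emp <- mean(d$true_C > t0)
    model <- mean(cm$evaluate(rep(t0, nrow(d)), d))
    expect_lt(abs(emp - model), 0.01)
  }
  cm0 <- true_censoring_model(1, Inf)
  expect_equal(cm0$evaluate(c(0.5, 1), d[1:2, ]), c(1, 1))
})

test_that("custom scenarios drive the same machinery", {
  null_scen <- custom_scenario(
    failure_lp = function(X, A) 0.1 * X$x1 + 0.5 * A, # arm 1 dominant
    cens_lp = function(X, A) 0.2 * X$x2,
    tau = 3, type = "aft", n_covariates = 2L)
  d <- simulate_scenario(null_scen, 200, censoring = 0, seed = 19)
  expect_equal(dataset_covariates(d), c("x1", "x2"))
  expect_equal(dataset_tau(d), 3)
  v1 <- true_rule_value(null_scen, 1, 5e4, seed = 20)
  v0 <- true_rule_value(null_scen, 0, 5e4, seed = 20)
  expect_gt(v1, v0)
  a <- calibrate_alpha(null_scen, 0.2, n_cal = 2e4, seed = 21)
  dc <- simulate_scenario(null_scen, 2e4, alpha = a, seed = 22)
  expect_lt(abs(censoring_rate(dc) - 0.2), 0.02)
})
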