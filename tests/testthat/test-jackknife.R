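test_that("value and variance match the hand-worked micro example", {
  U <- c(4, 0, 12)
  W <- c(2, 0, 2)
  expect_equal(jackknife_value(U, W), 4)
  vr <- jackknife_variance(U, W)
  # Ubar = 16/3, Wbar = 4/3: R = (3/4) U - 3 W = (-3, 0, 3)
  expect_equal(vr$residuals, c(-3, 0, 3))
  expect_equal(vr$variance, (9 + 0 + 9) / (3 * 2))
})

test_that("value is self-normalized and reduces to the sample mean", {
  tt <- c(1.5, 2, 0.7, 3)
  expect_equal(jackknife_value(tt, rep(1, 4)), mean(tt))
  expect_equal(jackknife_value(7 * tt, 7 * rep(1, 4)), mean(tt))
  expect_error(jackknife_value(c(0, 0), c(0, 0)), "No usable")
  expect_error(jackknife_variance(1, 1), "two subjects")
})

test_that("influence residuals average to zero and the variance is invariant
          to weight rescaling", {
  set.seed(6)
  for (i in 1:20) {
    m <- sample(5:60, 1)
    W <- rexp(m) * rbinom(m, 1, 0.8)
    if (sum(W) == 0) W[1] <- 1
    U <- runif(m, 0, 3) * W
    vr <- jackknife_variance(U, W)
    expect_lt(abs(mean(vr$residuals)), 1e-8 * (1 + max(abs(vr$residuals))))
    expect_gte(vr$variance, 0)
    vr2 <- jackknife_variance(5 * U, 5 * W)
    expect_equal(vr2$variance, vr$variance)
  }
  # perfectly constant outcome: U proportional to W
  vr0 <- jackknife_variance(3 * c(1, 2, 0.5), c(1, 2, 0.5))
  expect_equal(vr0$variance, 0)
})

test_that("with no censoring the IPCW estimator equals the uncensored one", {
  set.seed(7)
  for (i in 1:10) {
    n <- 40
    tt <- runif(n, 0, 2)
    match_ind <- rbinom(n, 1, 0.7)
    prop <- runif(n, 0.2, 0.8)
    # censored-data form with status = 1, S_c = 1
    W2 <- match_ind / prop * (1 / 1)
    U2 <- tt * W2
    # uncensored form
    W1 <- match_ind / prop
    U1 <- tt * W1
    expect_equal(jackknife_value(U2, W2), jackknife_value(U1, W1),
                 tolerance = 1e-12)
    expect_equal(jackknife_variance(U2, W2)$variance,
                 jackknife_variance(U1, W1)$variance, tolerance = 1e-12)
  }
})

test_that("leave-one-out decisions of a 1-nearest-neighbour stub are
          hand-checkable", {
  df <- data.frame(time = c(1, 2, 3), status = 1L,
                   treatment = c(0L, 1L, 1L), x1 = c(0, 0.1, 1))
  d <- survival_data(df, tau = 5)
  dec <- loo_decisions(d, nn1_learner)
  # nearest other point: 2 for subject 1, 1 for subject 2, 2 for subject 3
  expect_equal(dec, c(1L, 0L, 1L))
})

test_that("a fixed rule's leave-one-out decisions are its own decisions", {
  d <- toy_data(n = 20, seed = 3)
  rule <- fixed_rule(function(X) as.integer(X$x1 > 0.5))
  expect_equal(loo_decisions(d, rule), as.integer(d$x1 > 0.5))
  # constant-rule learner: all decisions equal the dominant arm
  expect_equal(unique(loo_decisions(d, itr_learner("zom"))), 1L)
})

test_that("value components implement the matched-IPCW products", {
  df <- data.frame(time = c(2, 4, 6), status = c(1, 0, 1),
                   treatment = c(1, 0, 1), x1 = c(.1, .2, .3))
  d <- survival_data(df, tau = 10)
  w <- tibble::tibble(id = d$id, propensity = rep(0.5, 3),
                      cens_survival = 1, ipcw = c(1, 0, 1))
  comp <- value_components(d, decisions = d$treatment, weights = w)
  expect_equal(comp$W, c(2, 0, 2))
  expect_equal(comp$U, c(4, 0, 12))
  # mismatched decisions zero out the components
  comp0 <- value_components(d, decisions = 1L - d$treatment, weights = w)
  expect_equal(comp0$U, c(0, 0, 0))
  expect_equal(comp0$W, c(0, 0, 0))
})

test_that("the estimate is reproducible, respects partial subsets, and stays
          within the observed time range", {
  d <- simulate_scenario(1, 35, censoring = 0.2, seed = 21)
  w <- known_weights(d, 1, 0.22)

  e1 <- jackknife_estimate(d, itr_learner("cox"), weights = w, seed = 5)
  e2 <- jackknife_estimate(d, itr_learner("cox"), weights = w, seed = 5)
  expect_equal(e1$value, e2$value)
  expect_identical(e1$components, e2$components)
  expect_equal(e1$m, 35L)

  # partial_r = n is the full jackknife
  ef <- jackknife_estimate(d, itr_learner("cox"), weights = w, partial_r = 35,
                           seed = 5)
  expect_equal(ef$value, e1$value)

  ep <- jackknife_estimate(d, itr_learner("cox"), weights = w, partial_r = 20,
                           seed = 5)
  expect_equal(ep$m, 20L)
  expect_equal(length(ep$subset), 20L)
  # variance denominator uses the subset size
  expect_equal(ep$variance,
               sum(ep$components$residual^2) / (20 * 19))

  used <- e1$components$W > 0
  expect_gte(e1$value, min(e1$components$time[used]))
  expect_lte(e1$value, max(e1$components$time[used]))
})

test_that("the estimate is invariant to subject ordering for a fixed rule", {
  d <- simulate_scenario(1, 60, censoring = 0.2, seed = 22)
  w <- known_weights(d, 1, 0.22)
  rule <- fixed_rule(function(X) as.integer(X$x2 < 0.5))
  e <- jackknife_estimate(d, rule, weights = w)

  set.seed(1)
  perm <- sample(60)
  dp <- d[perm, ]
  wp <- w[perm, ]
  e_perm <- jackknife_estimate(dp, rule, weights = wp)
  expect_equal(e_perm$value, e$value)
  expect_equal(e_perm$variance, e$variance)
})

test_that("tidy and glance expose the estimate's components", {
  d <- toy_data(n = 20, seed = 3)
  w <- estimate_weights(d, propensity_method = "known",
                        censoring_model = "none")
  e <- jackknife_estimate(d, itr_learner("zom"), weights = w)
  td <- tidy(e)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20)
  expect_true(all(c("U", "W", "residual", "decision") %in% names(td)))
  gl <- glance(e)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$value, e$value)
})
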