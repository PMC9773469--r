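# shared fixtures, all generated in code

# small fully observed two-arm dataset with one informative covariate
toy_data <- function(n = 30, seed = 42, tau = 10, effect = 1) {
  set.seed(seed)
  df <- data.frame(x1 = runif(n), x2 = runif(n),
                   treatment = rep_len(c(0L, 1L), n))
  df$time <- exp(0.2 + effect * df$treatment + rnorm(n, 0, 0.2))
  df$status <- 1L
  survival_data(df, tau = tau)
}

# known (true) nuisance weights for scenario-simulated data
known_weights <- function(data, scenario, alpha) {
  estimate_weights(data, propensity_method = "known", known = 0.5,
                   censoring_model = true_censoring_model(scenario, alpha),
                   winsorize_probs = FALSE)
}

# censoring model stub with user-supplied per-subject survival values
stub_censoring <- function(values) {
  survjack:::new_censoring_model("stub", evaluate = function(times, newdata) {
    values[seq_along(times)]
  })
}

# 1-nearest-neighbour learner on x1: recommends the arm of the closest
# training subject (hand-checkable leave-one-out behaviour)
nn1_learner <- function(train) {
  x_tr <- train$x1
  a_tr <- train$treatment
  fixed_rule(function(X) {
    vapply(X$x1, function(x) a_tr[which.min(abs(x_tr - x))], integer(1))
  }, name = "1nn")
}
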