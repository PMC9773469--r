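#' Built-in simulation scenarios
#'
#' Three data-generating mechanisms for a randomized two-arm survival study
#' with five independent U\[0, 1\] covariates and equal-probability treatment:
#'
#' * **Scenario 1** (accelerated failure time, `tau = 1.8`):
#'   `log(T~) = -0.2 - 0.5 x1 + 0.5 x2 + 0.4 x3 +
#'   (0.3 - 0.1 x1 - 0.6 x2 + 0.1 x3) A + eps`.
#' * **Scenario 2** (AFT with tree-structured effects, `tau = 8`):
#'   `log(T~) = x1 + I(x2 > .5) I(x3 > .5) + (0.3 - x1) A +
#'   2 I(x4 < .3) I(x5 < .3) A + eps`.
#' * **Scenario 3** (proportional hazards, baseline hazard `2t`, `tau = 2.5`):
#'   linear predictor `-0.2 + 0.75 x1^1.5 - 0.25 x2 +
#'   (1.6 - 1.4 sqrt(x1) - 2.4 x2^2) A`; failure times by inverse transform
#'   through the cumulative baseline hazard `t^2`.
#'
#' Failure-time errors `eps` are N(0, 0.2^2); censoring times are log-normal,
#' `log(C) = alpha + (scenario-specific linear predictor) + xi` with `xi`
#' N(0, 0.5^2). The intercept `alpha` controls the average censoring rate;
#' reference values for 10/20/40% censoring are stored per scenario.
#'
#' @param scenario Scenario id (1, 2, or 3) or a [custom_scenario()] object.
#' @return `scenario_spec()` returns the internal specification list;
#'   `scenario_defaults()` a tibble of the per-scenario horizon and the
#'   reference censoring intercepts.
#' @export
scenario_spec <- function(scenario) {
  if (inherits(scenario, "survjack_scenario")) return(scenario)
  stopifnot(length(scenario) == 1L, scenario %in% 1:3)
  specs <- list(
    `1` = custom_scenario(
      failure_lp = function(X, A) {
        -0.2 - 0.5 * X$x1 + 0.5 * X$x2 + 0.4 * X$x3 +
          (0.3 - 0.1 * X$x1 - 0.6 * X$x2 + 0.1 * X$x3) * A
      },
      cens_lp = function(X, A) {
        -0.1 * X$x1 + 0.2 * X$x2 + 0.2 * X$x3 +
          (0.5 - 0.1 * X$x1 - 0.6 * X$x2 + 0.3 * X$x3) * A
      },
      tau = 1.8, type = "aft", id = 1L,
      ref_alphas = c(`0.1` = 0.5, `0.2` = 0.22, `0.4` = -0.14)),
    `2` = custom_scenario(
      failure_lp = function(X, A) {
        X$x1 + (X$x2 > 0.5) * (X$x3 > 0.5) + (0.3 - X$x1) * A +
          2 * (X$x4 < 0.3) * (X$x5 < 0.3) * A
      },
      cens_lp = function(X, A) {
        -X$x1 + 2 * X$x2 + 2 * X$x3 +
          (5 - X$x1 - 6 * X$x2 + 3 * X$x3) * A
      },
      tau = 8, type = "aft", id = 2L,
      ref_alphas = c(`0.1` = 0.5, `0.2` = -0.25, `0.4` = -1.18)),
    `3` = custom_scenario(
      failure_lp = function(X, A) {
        -0.2 + 0.75 * X$x1^1.5 - 0.25 * X$x2 +
          (1.6 - 1.4 * sqrt(X$x1) - 2.4 * X$x2^2) * A
      },
      cens_lp = function(X, A) {
        0.5 * X$x1 + X$x2 + 0.3 * X$x3 + 0.1 * X$x4 +
          (0.1 + 0.5 * X$x1 - X$x2 + 0.3 * X$x3) * A
      },
      tau = 2.5, type = "ph", id = 3L,
      ref_alphas = c(`0.1` = -0.05, `0.2` = -0.40, `0.4` = -0.93))
  )
  specs[[as.character(scenario)]]
}

#' @rdname scenario_spec
#' @export
scenario_defaults <- function() {
  purrr::map_dfr(1:3, function(s) {
    sp <- scenario_spec(s)
    tibble::tibble(scenario = s, tau = sp$tau, type = sp$type,
                   censoring = as.numeric(names(sp$ref_alphas)),
                   alpha = unname(sp$ref_alphas))
  })
}

#' Define a custom data-generating scenario
#'
#' A hook for user-supplied coefficient structures (for example, null
#' constructions in which one arm dominates so two learners share one true
#' value). The failure model is either accelerated failure time
#' (`log(T~) = failure_lp + eps`) or proportional hazards with baseline hazard
#' `2t` (`T~ = sqrt(-log(U) / exp(failure_lp))`); the censoring model is
#' always log-normal, `log(C) = alpha + cens_lp + xi`.
#'
#' @param failure_lp,cens_lp Functions of a covariate data frame
#'   (columns `x1 ... xp`) and the 0/1 treatment vector, returning the linear
#'   predictor per subject.
#' @param tau Positive truncation horizon.
#' @param type `"aft"` or `"ph"`.
#' @param n_covariates Number of independent U\[0, 1\] covariates to draw.
#' @param sigma_eps,sigma_xi Standard deviations of the failure and censoring
#'   log-scale errors.
#' @param id Optional numeric tag.
#' @param ref_alphas Optional named vector of reference censoring intercepts
#'   (names are target censoring rates, e.g. `"0.2"`).
#' @return A `survjack_scenario` object accepted wherever a scenario id is.
#' @export
custom_scenario <- function(failure_lp, cens_lp, tau, type = c("aft", "ph"),
                            n_covariates = 5L, sigma_eps = 0.2,
                            sigma_xi = 0.5, id = NA_integer_,
                            ref_alphas = NULL) {
  type <- match.arg(type)
  stopifnot(is.function(failure_lp), is.function(cens_lp), tau > 0,
            sigma_eps > 0, sigma_xi > 0)
  structure(list(failure_lp = failure_lp, cens_lp = cens_lp, tau = tau,
                 type = type, p = as.integer(n_covariates),
                 sigma_eps = sigma_eps, sigma_xi = sigma_xi, id = id,
                 ref_alphas = ref_alphas),
            class = "survjack_scenario")
}

draw_covariates <- function(n, p) {
  X <- as.data.frame(matrix(runif(n * p), nrow = n))
  names(X) <- paste0("x", seq_len(p))
  X
}

# inverse-transform failure time under baseline hazard 2t (Lambda0(t) = t^2)
ph_failure_time <- function(u, lp) sqrt(-log(u) / exp(lp))

draw_failure_times <- function(spec, X, A, n) {
  lp <- spec$failure_lp(X, A)
  if (spec$type == "aft") {
    exp(lp + rnorm(n, 0, spec$sigma_eps))
  } else {
    ph_failure_time(runif(n), lp)
  }
}

#' Simulate a dataset from a scenario
#'
#' Draws covariates, randomized treatment, latent failure and censoring times
#' from the scenario's models, then applies the truncation convention: the
#' observed time is `min(T~, C, tau)` and the event indicator is
#' `I(min(T~, tau) <= C)` (a failure-free subject still uncensored at `tau`
#' is an administrative event at `tau`). The latent times are retained in
#' columns `true_T` and `true_C`.
#'
#' @inheritParams scenario_spec
#' @param n Sample size.
#' @param censoring Target average censoring rate. `0` disables censoring
#'   entirely; the reference rates (0.1, 0.2, 0.4) use the scenario's stored
#'   intercepts; any other rate is calibrated on the fly.
#' @param alpha Censoring intercept; overrides `censoring` when given
#'   (`Inf` disables censoring).
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#' @return A `survjack_data` tibble with `n` rows.
#' @export
simulate_scenario <- function(scenario, n, censoring = 0, alpha = NULL,
                              seed = NULL) {
  spec <- scenario_spec(scenario)
  stopifnot(n >= 2L)
  if (is.null(alpha)) {
    if (censoring == 0) {
      alpha <- Inf
    } else {
      key <- as.character(censoring)
      if (!is.null(spec$ref_alphas) && key %in% names(spec$ref_alphas)) {
        alpha <- unname(spec$ref_alphas[key])
      } else {
        alpha <- calibrate_alpha(spec, censoring,
                                 seed = if (is.null(seed)) NULL else seed + 1L)
      }
    }
  }
  if (!is.null(seed)) set.seed(seed)
  X <- draw_covariates(n, spec$p)
  A <- rbinom(n, 1L, 0.5)
  true_t <- draw_failure_times(spec, X, A, n)
  true_c <- if (is.infinite(alpha)) rep(Inf, n) else
    exp(alpha + spec$cens_lp(X, A) + rnorm(n, 0, spec$sigma_xi))

  df <- data.frame(
    time = pmin(true_t, true_c, spec$tau),
    status = as.integer(pmin(true_t, spec$tau) <= true_c),
    treatment = A, X, true_T = true_t, true_C = true_c)
  survival_data(df, tau = spec$tau, covariates = names(X))
}

# conditional value of arm `a` given covariates, in closed form
conditional_value <- function(spec, X, a, restricted = TRUE) {
  lp <- spec$failure_lp(X, a)
  tau <- spec$tau
  if (spec$type == "aft") {
    if (restricted) {
      s <- spec$sigma_eps
      # truncated log-normal mean E[min(exp(lp + s Z), tau)]
      exp(lp + s^2 / 2) * pnorm((log(tau) - lp - s^2) / s) +
        tau * (1 - pnorm((log(tau) - lp) / s))
    } else {
      exp(lp) # noise-free latent failure time
    }
  } else {
    rate <- exp(lp)
    if (restricted) {
      # int_0^tau exp(-t^2 rate) dt, Gaussian-integral closed form
      sqrt(pi / (4 * rate)) * (2 * pnorm(tau * sqrt(2 * rate)) - 1)
    } else {
      sqrt(pi / (4 * rate)) # untruncated mean survival time
    }
  }
}

resolve_rule <- function(rule) {
  if (inherits(rule, "itr_rule")) return(function(X) predict(rule, X))
  if (is.numeric(rule) && length(rule) == 1L) {
    arm <- as.integer(rule)
    return(function(X) rep(arm, nrow(X)))
  }
  if (is.function(rule)) return(function(X) as.integer(rule(X)))
  stop("`rule` must be an `itr_rule`, a constant arm, or a function of the ",
       "covariates.", call. = FALSE)
}

#' Population value of a treatment rule under a scenario
#'
#' Monte Carlo average over covariate draws of the closed-form conditional
#' value of the arm the rule assigns. With `restricted = TRUE` (default) this
#' is the tau-restricted value `E[min(T~, tau) | A = d(X)]` — the estimand the
#' jackknife estimator targets. With `restricted = FALSE` it is the value on
#' the latent failure-time scale (untruncated; for AFT scenarios with the
#' log-scale noise at zero), the convention under which the scenarios'
#' reference optimal values are quoted. `method = "simulation"` replaces the
#' closed-form conditional mean with brute-force simulation of the latent
#' failure times (a cross-check; restricted only).
#'
#' @inheritParams scenario_spec
#' @param rule An `itr_rule`, a constant arm (0 or 1), or a function of a
#'   covariate data frame returning 0/1 per row.
#' @param mc_draws Number of covariate draws.
#' @param seed Integer seed.
#' @param restricted Report the tau-restricted value? (See Details.)
#' @param method `"closed_form"` (default) or `"simulation"`.
#' @return Scalar value.
#' @export
true_rule_value <- function(scenario, rule, mc_draws = 1e5, seed = NULL,
                            restricted = TRUE,
                            method = c("closed_form", "simulation")) {
  spec <- scenario_spec(scenario)
  method <- match.arg(method)
  decide <- resolve_rule(rule)
  if (!is.null(seed)) set.seed(seed)
  X <- draw_covariates(mc_draws, spec$p)
  a <- decide(X)
  stopifnot(length(a) == mc_draws, all(a %in% c(0L, 1L)))
  if (method == "closed_form") {
    mean(conditional_value(spec, X, a, restricted = restricted))
  } else {
    if (!restricted) {
      stop("The simulation method computes the tau-restricted value only.",
           call. = FALSE)
    }
    tt <- draw_failure_times(spec, X, a, mc_draws)
    mean(pmin(tt, spec$tau))
  }
}

#' Population value of the optimal treatment rule
#'
#' Monte Carlo average of the per-draw best arm's conditional value,
#' `E_X[max_a E(T | X, A = a)]`. The default `restricted = FALSE` reports the
#' latent-scale convention under which the scenario reference values
#' (approximately 1.105, 3.590, and 1.144 for scenarios 1-3) are quoted; set
#' `restricted = TRUE` for the tau-restricted optimal value, the sharp upper
#' bound for jackknife value estimates.
#'
#' @inheritParams true_rule_value
#' @return Scalar optimal value.
#' @export
true_optimal_value <- function(scenario, mc_draws = 1e6, seed = NULL,
                               restricted = FALSE) {
  spec <- scenario_spec(scenario)
  if (!is.null(seed)) set.seed(seed)
  X <- draw_covariates(mc_draws, spec$p)
  m0 <- conditional_value(spec, X, 0L, restricted = restricted)
  m1 <- conditional_value(spec, X, 1L, restricted = restricted)
  mean(pmax(m0, m1))
}

#' Oracle optimal rule of a scenario
#'
#' The rule assigning each covariate vector the arm with the larger
#' conditional value (equivalently, the sign of the treatment effect on the
#' linear predictor). Useful as a fixed reference rule.
#'
#' @inheritParams true_rule_value
#' @return An `itr_rule`.
#' @export
oracle_rule <- function(scenario, restricted = TRUE) {
  spec <- scenario_spec(scenario)
  fixed_rule(function(X) {
    as.integer(conditional_value(spec, X, 1L, restricted) >
               conditional_value(spec, X, 0L, restricted))
  }, name = "oracle", tau = spec$tau)
}

#' Calibrate the censoring intercept to a target censoring rate
#'
#' Finds `alpha` so that the average censoring rate — the proportion of
#' subjects whose latent failure is not observed, `P(T~ > min(C, tau))` —
#' equals `target_rate`. Uses bisection on one fixed set of `n_cal` Monte
#' Carlo draws (common random numbers make the rate monotone nonincreasing
#' and piecewise constant in `alpha`).
#'
#' @inheritParams scenario_spec
#' @param target_rate Target censoring rate in (0, 1). Rates at or below the
#'   administrative floor `P(T~ > tau)` are unreachable (`alpha` would diverge)
#'   and raise an error.
#' @param n_cal Number of calibration draws per rate evaluation.
#' @param seed Integer seed.
#' @param tol Tolerance on the achieved rate (default 0.005).
#' @return The calibrated scalar `alpha`.
#' @export
calibrate_alpha <- function(scenario, target_rate, n_cal = 1e5, seed = NULL,
                            tol = 0.005) {
  spec <- scenario_spec(scenario)
  stopifnot(target_rate > 0, target_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  X <- draw_covariates(n_cal, spec$p)
  A <- rbinom(n_cal, 1L, 0.5)
  tt <- draw_failure_times(spec, X, A, n_cal)
  base <- spec$cens_lp(X, A) + rnorm(n_cal, 0, spec$sigma_xi)
  # censored = latent failure unobserved, whether by random censoring or by
  # reaching the administrative horizon
  rate <- function(alpha) mean(pmin(exp(alpha + base), spec$tau) < tt)

  lo <- -10; hi <- 10
  if (rate(lo) < target_rate) {
    stop("Target censoring rate is unreachable even with immediate ",
         "censoring; check the scenario.", call. = FALSE)
  }
  if (rate(hi) > target_rate) {
    stop("Target censoring rate ", target_rate, " is at or below the ",
         "administrative floor P(T~ > tau) = ", signif(rate(hi), 3),
         "; it cannot be reached by the random censoring mechanism.",
         call. = FALSE)
  }
  for (iter in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (rate(mid) > target_rate) lo <- mid else hi <- mid
    if (hi - lo < 1e-5) break
  }
  alpha <- (lo + hi) / 2
  if (abs(rate(alpha) - target_rate) > tol) {
    stop("Calibration did not reach the target rate within tolerance ",
         tol, "; increase `n_cal`.", call. = FALSE)
  }
  alpha
}

#' Known censoring-survival evaluator for a scenario
#'
#' The closed-form log-normal censoring survival
#' `S_c(t | X, A) = 1 - Phi((log t - alpha - cens_lp(X, A)) / sigma_xi)`,
#' packaged as a `censoring_model` so simulation studies can run with known
#' (rather than estimated) weights. `alpha = Inf` gives the no-censoring
#' evaluator (identically 1).
#'
#' @inheritParams scenario_spec
#' @param alpha Censoring intercept used to generate the data.
#' @return A `censoring_model`.
#' @export
true_censoring_model <- function(scenario, alpha) {
  spec <- scenario_spec(scenario)
  if (is.infinite(alpha)) {
    return(new_censoring_model("known", evaluate = function(times, newdata) {
      rep(1, length(times))
    }))
  }
  new_censoring_model("known", evaluate = function(times, newdata) {
    X <- as.data.frame(newdata)
    lp <- alpha + spec$cens_lp(X, X$treatment)
    1 - pnorm((log(pmax(times, .Machine$double.xmin)) - lp) / spec$sigma_xi)
  })
}
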