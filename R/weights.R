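#' Estimate per-subject propensity scores
#'
#' Returns the probability of each subject's *observed* arm,
#' `P(A_i = a_i | X_i)`: the fitted probability of treatment for treated
#' subjects and its complement for controls. The default is a main-effects
#' logistic regression of treatment on all covariates, as used in randomized
#' designs to reflect estimation variability even when the true propensity is
#' known. Fitted probabilities are clipped to `clip` to prevent weight
#' explosion in observational use.
#'
#' @param data A `survjack_data` object.
#' @param method `"logistic"` (main-effects logistic regression) or `"known"`
#'   (a fixed, known randomization probability).
#' @param known Known probability of treatment (`A = 1`) when
#'   `method = "known"`.
#' @param clip Two clipping bounds for fitted probabilities of each arm.
#'
#' @return Numeric vector of observed-arm propensities, strictly inside (0, 1).
#' @export
fit_propensity <- function(data, method = c("logistic", "known"), known = 0.5,
                           clip = c(0.01, 0.99)) {
  method <- match.arg(method)
  a <- data$treatment
  if (length(unique(a)) < 2L) {
    stop("Both treatment arms must be non-empty to fit a propensity model.",
         call. = FALSE)
  }
  if (method == "known") {
    stopifnot(known > 0, known < 1)
    p1 <- rep(known, nrow(data))
  } else {
    covs <- dataset_covariates(data)
    f <- as.formula(paste("treatment ~", paste(covs, collapse = " + ")))
    fit <- suppressWarnings(glm(f, family = binomial(), data = data))
    p1 <- as.numeric(fit$fitted.values)
    if (any(p1 < 1e-8 | p1 > 1 - 1e-8)) {
      stop("Propensity model is (quasi-)separated; use method = \"known\" ",
           "with the randomization probability instead.", call. = FALSE)
    }
  }
  p_obs <- ifelse(a == 1L, p1, 1 - p1)
  pmin(pmax(p_obs, clip[1]), clip[2])
}

#' Fit a model for the censoring distribution
#'
#' Fits a Cox proportional hazards model for the censoring time (event
#' indicator `1 - status`), by default with all covariates, treatment, and
#' treatment-by-covariate interactions. The result evaluates the censoring
#' survival probability `S_c(t | X, A)` as a right-continuous nonincreasing
#' step function in `t` with `S_c(0) = 1`. When the data contain no censored
#' observation (or `model = "none"`) the evaluator is identically 1, so the
#' IPCW estimator degrades gracefully to its uncensored form.
#'
#' @param data A `survjack_data` object.
#' @param model `"coxph_interactions"` (covariates, treatment, and their
#'   interactions), `"coxph_main"` (main effects only), or `"none"`
#'   (no censoring: evaluator identically 1).
#'
#' @return An object of class `censoring_model` with an `evaluate(times,
#'   newdata)` component returning `S_c(t_i | X_i, A_i)` for each row.
#' @export
fit_censoring_model <- function(data,
                                model = c("coxph_interactions", "coxph_main",
                                          "none")) {
  model <- match.arg(model)
  cens <- 1L - data$status
  if (model == "none" || sum(cens) == 0L) {
    return(new_censoring_model("none", evaluate = function(times, newdata) {
      rep(1, length(times))
    }))
  }
  covs <- dataset_covariates(data)
  rhs <- switch(model,
    coxph_interactions = paste0("(", paste(covs, collapse = " + "),
                                ") * treatment"),
    coxph_main = paste(c(covs, "treatment"), collapse = " + "))
  f <- as.formula(paste("survival::Surv(time, cens_event) ~", rhs))
  dd <- as.data.frame(data)
  dd$cens_event <- cens
  fit <- tryCatch(
    suppressWarnings(survival::coxph(f, data = dd, ties = "breslow")),
    error = function(e) {
      stop("Censoring model did not converge (", conditionMessage(e),
           "); consider the covariate-free `model = \"coxph_main\"` or a ",
           "known censoring distribution.", call. = FALSE)
    })
  bh <- suppressWarnings(survival::basehaz(fit, centered = FALSE))
  bh <- bh[is.finite(bh$hazard), , drop = FALSE] # degenerate fits can NaN out
  new_censoring_model(model, fit = fit, evaluate = function(times, newdata) {
    lp <- predict(fit, newdata = as.data.frame(newdata), type = "lp",
                  reference = "zero")
    # right-continuous: cumulative hazard at the latest jump <= t
    idx <- findInterval(times, bh$time)
    h0 <- c(0, bh$hazard)[idx + 1L]
    sc <- exp(-h0 * exp(lp))
    sc[h0 == 0] <- 1 # before the first jump, whatever the linear predictor
    unname(sc)
  })
}

new_censoring_model <- function(type, evaluate, fit = NULL) {
  structure(list(type = type, fit = fit, evaluate = evaluate),
            class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  cat("<censoring_model>", x$type, "\n")
  invisible(x)
}

#' Winsorize a numeric vector at empirical quantiles
#'
#' Clips the smallest and largest values to interior order statistics (the
#' default 5%/95% bounds are a 90% winsorization): with `n` observations, the
#' `floor(n * lower_pct)` smallest values are raised to the next order
#' statistic and the `floor(n * (1 - upper_pct))` largest are lowered to the
#' last retained one — the convention of the classical winsorized mean. The
#' operation preserves length and interior ranks and is exactly idempotent
#' (interpolation-based quantile definitions are not, because clipping shifts
#' the interpolated quantile inward on reapplication).
#'
#' @param x Nonempty numeric vector.
#' @param lower_pct,upper_pct Quantile bounds, `0 <= lower_pct < upper_pct <= 1`.
#' @return Numeric vector of the same length as `x`.
#' @export
winsorize <- function(x, lower_pct = 0.05, upper_pct = 0.95) {
  if (!length(x)) stop("`x` must be nonempty.", call. = FALSE)
  if (lower_pct >= upper_pct) {
    stop("`lower_pct` must be strictly below `upper_pct`.", call. = FALSE)
  }
  n <- length(x)
  xs <- sort(x)
  lo <- xs[floor(n * lower_pct) + 1L]
  hi <- xs[n - floor(n * (1 - upper_pct))]
  pmin(pmax(x, lo), hi)
}

#' Assemble inverse probability of censoring weights
#'
#' Evaluates the censoring survival at each subject's observed time and arm,
#' optionally winsorizes the resulting probabilities, and combines them with
#' the propensity into the per-subject nuisance weights used by the value
#' estimator: `ipcw_i = status_i / S_c(T_i | X_i, A_i)` (so censored subjects
#' get weight exactly 0).
#'
#' @param data A `survjack_data` object.
#' @param propensity Vector of observed-arm propensities, as returned by
#'   [fit_propensity()].
#' @param censoring A `censoring_model`, as returned by
#'   [fit_censoring_model()] or [true_censoring_model()].
#' @param winsorize_probs Winsorize the censoring survival probabilities
#'   before inverting? (90% winsorization by default, stabilizing extreme
#'   weights.)
#' @param winsor_limits Lower/upper quantile bounds for the winsorization.
#'
#' @return A tibble with columns `id`, `propensity`, `cens_survival`, `ipcw`.
#' @export
assemble_weights <- function(data, propensity, censoring,
                             winsorize_probs = TRUE,
                             winsor_limits = c(0.05, 0.95)) {
  stopifnot(length(propensity) == nrow(data))
  sc <- censoring$evaluate(data$time, data)
  stopifnot(length(sc) == nrow(data))
  if (winsorize_probs) {
    sc <- winsorize(sc, winsor_limits[1], winsor_limits[2])
  }
  if (any(sc <= 0 & data$status == 1L)) {
    stop("Censoring survival is 0 at an observed event time; the censoring ",
         "model has no support there.", call. = FALSE)
  }
  tibble::tibble(
    id = data$id,
    propensity = propensity,
    cens_survival = sc,
    ipcw = ifelse(data$status == 1L, data$status / sc, 0)
  )
}

#' One-call nuisance weight pipeline
#'
#' Convenience wrapper fitting the propensity and censoring models on the
#' complete sample (weights are estimated once, before any leave-one-out
#' loop, because singleton test sets cannot support their own nuisance fits)
#' and assembling the IPC weights.
#'
#' @inheritParams fit_propensity
#' @inheritParams fit_censoring_model
#' @inheritParams assemble_weights
#' @param propensity_method Passed to [fit_propensity()] as `method`.
#' @param censoring_model Passed to [fit_censoring_model()] as `model`, or a
#'   ready `censoring_model` object (e.g. a known one).
#' @return A tibble as from [assemble_weights()].
#' @export
estimate_weights <- function(data, propensity_method = "logistic",
                             known = 0.5,
                             censoring_model = "coxph_interactions",
                             winsorize_probs = TRUE,
                             winsor_limits = c(0.05, 0.95)) {
  prop <- fit_propensity(data, method = propensity_method, known = known)
  cm <- if (inherits(censoring_model, "censoring_model")) censoring_model
        else fit_censoring_model(data, model = censoring_model)
  assemble_weights(data, prop, cm, winsorize_probs = winsorize_probs,
                   winsor_limits = winsor_limits)
}
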