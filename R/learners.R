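#' Restricted mean survival time of a step survival curve
#'
#' Integrates a nonincreasing, right-continuous step survival curve from 0 to
#' `tau` exactly (sum of step width times step height). The curve is 1 before
#' its first jump; beyond its last jump it is carried forward flat.
#'
#' @param times Jump locations, nonnegative, in increasing order (unsorted
#'   input is sorted together with `surv`).
#' @param surv Survival values at (i.e. just after) each jump.
#' @param tau Positive horizon.
#' @return A scalar in (0, `tau`\].
#' @export
#' @examples
#' rmst(c(1), c(0.5), tau = 2) # 1 * 1 + 1 * 0.5 = 1.5
rmst <- function(times, surv, tau) {
  stopifnot(length(times) == length(surv), tau > 0)
  if (!length(times)) return(tau)
  if (is.unsorted(times)) {
    o <- order(times)
    times <- times[o]
    surv <- surv[o]
  }
  if (any(diff(surv) > 1e-10)) {
    stop("Survival curve must be nonincreasing.", call. = FALSE)
  }
  if (any(surv > 1 + 1e-10) || any(surv < -1e-10)) {
    stop("Survival values must lie in [0, 1].", call. = FALSE)
  }
  keep <- times < tau
  heights <- c(1, surv[keep])
  widths <- diff(c(0, times[keep], tau))
  sum(widths * heights)
}

# RMST for each row of a survival-probability matrix sharing one time grid
rmst_matrix <- function(times, survmat, tau) {
  keep <- times < tau
  heights <- cbind(1, survmat[, keep, drop = FALSE])
  widths <- diff(c(0, times[keep], tau))
  as.numeric(heights %*% widths)
}

new_itr_rule <- function(decide, learner_name, fitted_on, tau, fit = NULL) {
  structure(list(decide = decide, learner_name = learner_name,
                 fitted_on = fitted_on, tau = tau, fit = fit),
            class = "itr_rule")
}

#' @export
print.itr_rule <- function(x, ...) {
  cat("<itr_rule>", x$learner_name, "fitted on n =", x$fitted_on,
      "(tau =", format(x$tau), ")\n")
  invisible(x)
}

#' Apply a fitted treatment rule
#'
#' @param object An `itr_rule`.
#' @param newdata A data frame containing the rule's covariate columns (a
#'   `survjack_data` object works).
#' @param ... Unused.
#' @return Integer vector of recommended arms in \{0, 1\}.
#' @export
predict.itr_rule <- function(object, newdata, ...) {
  dec <- object$decide(as.data.frame(newdata))
  dec <- as.integer(dec)
  if (anyNA(dec) || !all(dec %in% c(0L, 1L))) {
    stop("Treatment rule returned values outside {0, 1}.", call. = FALSE)
  }
  dec
}

#' Wrap a fixed decision function as a treatment rule
#'
#' Useful for oracle rules and for fixed-rule simulation studies, where the
#' leave-one-out decisions coincide with the rule itself.
#'
#' @param decide Either a single arm (0 or 1, a constant rule) or a function
#'   taking a covariate data frame and returning 0/1 per row.
#' @param name Label for the rule.
#' @param tau Optional horizon tag.
#' @return An `itr_rule`.
#' @export
fixed_rule <- function(decide, name = "fixed", tau = NA_real_) {
  if (is.numeric(decide) && length(decide) == 1L) {
    arm <- as.integer(decide)
    stopifnot(arm %in% c(0L, 1L))
    decide_fun <- function(newdata) rep(arm, nrow(newdata))
  } else {
    stopifnot(is.function(decide))
    decide_fun <- function(newdata) decide(newdata)
  }
  new_itr_rule(decide_fun, learner_name = name, fitted_on = NA_integer_,
               tau = tau)
}

check_arms <- function(data) {
  if (length(unique(data$treatment)) < 2L) {
    stop("Both treatment arms must be non-empty in the training set.",
         call. = FALSE)
  }
}

# canonical row order so fitted rules are invariant to shuffling the
# training rows (the forest bootstrap depends on row order for a fixed seed)
canonical_order <- function(data, covs) {
  do.call(order, unname(as.list(as.data.frame(
    data[, c("time", "status", "treatment", covs)]))))
}

#' Random survival forest treatment-rule learner
#'
#' Fits a random survival forest (log-rank splitting) on the covariates plus
#' treatment as an ordinary feature. The rule predicts each subject's survival
#' curve with treatment forced to 0 and to 1 and recommends the arm with the
#' larger restricted mean survival time at the dataset horizon (ties go to
#' arm 0). Training rows are put in a canonical order before fitting so the
#' rule is invariant to row shuffling for a fixed seed.
#'
#' @param data A `survjack_data` training set.
#' @param seed Integer seed for the forest (required for determinism).
#' @param num_trees Number of trees (default 500).
#' @param min.node.size Minimal terminal node size (default 15, the customary
#'   survival-forest default).
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return An `itr_rule`.
#' @export
fit_rsf_learner <- function(data, seed = 1L, num_trees = 500L,
                            min.node.size = 15L, ...) {
  check_arms(data)
  covs <- dataset_covariates(data)
  tau <- dataset_tau(data)
  dd <- as.data.frame(data)[canonical_order(data, covs), ]
  x <- dd[, c(covs, "treatment"), drop = FALSE]
  y <- survival::Surv(dd$time, dd$status)
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees, seed = seed,
                        min.node.size = min.node.size,
                        num.threads = 1L, verbose = FALSE, ...)
  decide <- function(newdata) {
    nd <- newdata[, covs, drop = FALSE]
    nd0 <- cbind(nd, treatment = 0)
    nd1 <- cbind(nd, treatment = 1)
    pr <- predict(fit, data = rbind(nd0, nd1), num.threads = 1L,
                  verbose = FALSE)
    r <- rmst_matrix(pr$unique.death.times, pr$survival, tau)
    m <- nrow(nd)
    as.integer(r[m + seq_len(m)] > r[seq_len(m)])
  }
  new_itr_rule(decide, "rsf", nrow(data), tau, fit = fit)
}

#' Cox proportional hazards treatment-rule learner
#'
#' Fits a Cox model with main effects of the covariates and treatment plus all
#' first-order treatment-by-covariate interactions (a main-effects-only model
#' cannot tailor). The rule compares model-based restricted mean survival
#' times under each arm, with the baseline cumulative hazard from the Breslow
#' estimator; ties go to arm 0.
#'
#' @param data A `survjack_data` training set.
#' @param ... Further arguments passed to [survival::coxph()].
#' @return An `itr_rule`.
#' @export
fit_cox_learner <- function(data, ...) {
  check_arms(data)
  covs <- dataset_covariates(data)
  tau <- dataset_tau(data)
  f <- as.formula(paste0("survival::Surv(time, status) ~ (",
                         paste(covs, collapse = " + "), ") * treatment"))
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph(f, data = as.data.frame(data), ties = "breslow", ...)),
    error = function(e) {
      stop("Cox learner did not converge (", conditionMessage(e),
           "); consider a ridge penalty or fewer interactions.",
           call. = FALSE)
    })
  bh <- suppressWarnings(survival::basehaz(fit, centered = FALSE))
  bh <- bh[is.finite(bh$hazard), , drop = FALSE]
  decide <- function(newdata) {
    nd <- newdata[, covs, drop = FALSE]
    lp0 <- predict(fit, newdata = cbind(nd, treatment = 0), type = "lp",
                   reference = "zero")
    lp1 <- predict(fit, newdata = cbind(nd, treatment = 1), type = "lp",
                   reference = "zero")
    surv0 <- exp(-outer(exp(lp0), bh$hazard))
    surv1 <- exp(-outer(exp(lp1), bh$hazard))
    r0 <- rmst_matrix(bh$time, surv0, tau)
    r1 <- rmst_matrix(bh$time, surv1, tau)
    as.integer(r1 > r0)
  }
  new_itr_rule(decide, "cox", nrow(data), tau, fit = fit)
}

#' Zero-order model (one-size-fits-all) learner
#'
#' Estimates each arm's restricted mean survival time from its Kaplan-Meier
#' curve truncated at the dataset horizon and assigns every patient the arm
#' with the larger RMST (ties go to arm 0).
#'
#' @param data A `survjack_data` training set.
#' @return An `itr_rule` (a constant rule).
#' @export
fit_zom <- function(data) {
  check_arms(data)
  tau <- dataset_tau(data)
  arm_rmst <- function(arm) {
    sub <- data[data$treatment == arm, ]
    if (sum(sub$status) == 0L) {
      stop("Treatment arm ", arm, " has no events; the zero-order model is ",
           "undefined.", call. = FALSE)
    }
    km <- survival::survfit(survival::Surv(time, status) ~ 1,
                            data = as.data.frame(sub))
    rmst(km$time, km$surv, tau)
  }
  best <- as.integer(arm_rmst(1L) > arm_rmst(0L))
  rule <- fixed_rule(best, name = "zom", tau = tau)
  rule$fitted_on <- nrow(data)
  rule
}

#' Learner specification for the jackknife loop
#'
#' A lightweight registry entry naming one of the built-in learners together
#' with its hyperparameters, refitted on each leave-one-out training set by
#' [jackknife_estimate()].
#'
#' @param name `"rsf"`, `"cox"`, or `"zom"`.
#' @param ... Hyperparameters forwarded to the corresponding `fit_*` function
#'   (e.g. `num_trees` for `"rsf"`).
#' @return An `itr_learner` object.
#' @export
itr_learner <- function(name = c("rsf", "cox", "zom"), ...) {
  name <- match.arg(name)
  structure(list(name = name, args = list(...)), class = "itr_learner")
}

#' @export
print.itr_learner <- function(x, ...) {
  cat("<itr_learner>", x$name, "\n")
  invisible(x)
}

# Fit a learner spec (or call a user-supplied fitter) on a training set.
fit_learner <- function(learner, data, seed = NULL) {
  if (inherits(learner, "itr_learner")) {
    switch(learner$name,
      rsf = do.call(fit_rsf_learner,
                    c(list(data = data, seed = if (is.null(seed)) 1L else seed),
                      learner$args)),
      cox = do.call(fit_cox_learner, c(list(data = data), learner$args)),
      zom = do.call(fit_zom, list(data = data)))
  } else if (is.function(learner)) {
    rule <- learner(data)
    if (!inherits(rule, "itr_rule")) {
      stop("A learner function must return an `itr_rule`.", call. = FALSE)
    }
    rule
  } else {
    stop("`learner` must be an `itr_learner`, an `itr_rule`, or a function.",
         call. = FALSE)
  }
}
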