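#' Leave-one-out treatment decisions
#'
#' For each subject `i` in `subset`, fits the learner on all rows except `i`
#' and records the refitted rule's decision at that subject's covariates. A
#' fixed rule (an `itr_rule`) does not depend on the training set, so its
#' leave-one-out decision is simply its decision. Every refit reuses the same
#' seed, so forest randomness does not differ across left-out indices beyond
#' the change in training data.
#'
#' @param data A `survjack_data` object.
#' @param learner An `itr_learner` spec, a fitting function
#'   (`function(data) -> itr_rule`), or a fixed `itr_rule`.
#' @param subset Integer row indices to score (default: all rows).
#' @param seed Seed reused for every leave-one-out refit.
#' @return Integer vector of decisions, aligned with `subset`.
#' @export
loo_decisions <- function(data, learner, subset = NULL, seed = NULL) {
  n <- nrow(data)
  if (is.null(subset)) subset <- seq_len(n)
  stopifnot(all(subset >= 1L), all(subset <= n), !anyDuplicated(subset))
  if (inherits(learner, "itr_rule")) {
    return(predict(learner, data[subset, ]))
  }
  vapply(subset, function(i) {
    rule <- tryCatch(
      fit_learner(learner, data[-i, ], seed = seed),
      error = function(e) {
        stop("Leave-one-out fit failed with row ", i, " held out: ",
             conditionMessage(e), call. = FALSE)
      })
    predict(rule, data[i, ])
  }, integer(1))
}

#' Per-subject components of the IPCW value estimator
#'
#' Computes, for each subject in `subset`, the weight
#' `W_i = 1\{A_i = d^(-i)(X_i)\} / P(A_i | X_i) * status_i / S_c(T_i | X_i, A_i)`
#' and the numerator `U_i = T_i * W_i`. Censored subjects and subjects whose
#' observed arm disagrees with the leave-one-out decision contribute 0.
#'
#' @param data A `survjack_data` object.
#' @param decisions Integer decisions aligned with `subset`, as from
#'   [loo_decisions()].
#' @param weights Nuisance weights tibble from [assemble_weights()] /
#'   [estimate_weights()] (rows aligned with `data`).
#' @param subset Integer row indices used (default: all rows).
#' @return A tibble with columns `id`, `U`, `W`.
#' @export
value_components <- function(data, decisions, weights, subset = NULL) {
  n <- nrow(data)
  if (is.null(subset)) subset <- seq_len(n)
  stopifnot(length(decisions) == length(subset),
            nrow(weights) == n)
  rows <- data[subset, ]
  w <- weights[subset, ]
  match_ind <- as.numeric(rows$treatment == decisions)
  W <- match_ind / w$propensity * w$ipcw
  tibble::tibble(id = rows$id, U = rows$time * W, W = W)
}

#' Self-normalized jackknife value
#'
#' The ratio `sum(U) / sum(W)` of the per-subject components: a weighted
#' average of observed restricted survival times among subjects whose treatment
#' matched their leave-one-out recommendation, with IPCW correction. Invariant
#' to uniform rescaling of the weights.
#'
#' @param U,W Numeric component vectors from [value_components()].
#' @return Scalar value estimate.
#' @export
jackknife_value <- function(U, W) {
  stopifnot(length(U) == length(W))
  sw <- sum(W)
  if (!is.finite(sw) || sw <= 0) {
    stop("No usable observations: all subjects are censored or mismatched ",
         "with their leave-one-out recommendation.", call. = FALSE)
  }
  sum(U) / sw
}

#' Variance of the jackknife value via influence residuals
#'
#' Linearizes the ratio estimator: with `Ubar`, `Wbar` the component means
#' over the `m` subjects used, each subject's influence residual is
#' `R_i = U_i / Wbar - Ubar * W_i / Wbar^2`, and the variance estimate is
#' `sum(R_i^2) / (m * (m - 1))`. Residuals are computed over *all* subset
#' members, including zero-weight ones. Their mean is zero by construction.
#'
#' @param U,W Numeric component vectors (length at least 2).
#' @return A list with elements `variance` and `residuals`.
#' @export
jackknife_variance <- function(U, W) {
  m <- length(U)
  stopifnot(length(W) == m)
  if (m < 2L) stop("At least two subjects are required.", call. = FALSE)
  wbar <- mean(W)
  if (!is.finite(wbar) || wbar <= 0) {
    stop("Mean weight must be positive.", call. = FALSE)
  }
  ubar <- mean(U)
  residuals <- U / wbar - ubar * W / wbar^2
  list(variance = sum(residuals^2) / (m * (m - 1)), residuals = residuals)
}

#' Jackknife (leave-one-out) value estimate of a treatment rule
#'
#' Orchestrates the full estimator: draws the (optional) partial-jackknife
#' subset, computes leave-one-out decisions, assembles the IPCW value
#' components, and returns the value with its influence-residual variance.
#' Nuisance weights default to the standard pipeline (logistic propensity,
#' Cox censoring model with treatment interactions, 90% winsorization),
#' estimated once on the complete sample.
#'
#' @inheritParams loo_decisions
#' @param weights Optional nuisance weights tibble (rows aligned with `data`);
#'   computed by [estimate_weights()] when `NULL`.
#' @param partial_r Optional subset size `2 <= r <= n` for the partial
#'   jackknife: leave-one-out refits, value sums, and the variance denominator
#'   all use the `r` sampled subjects.
#' @param subset Optional explicit subset of row indices (overrides
#'   `partial_r`); used to share one subset draw across learners when
#'   comparing rules.
#' @param seed Seed for the subset draw and the leave-one-out refits.
#' @return An object of class `jackknife_estimate`: a list with `value`,
#'   `variance`, `se`, a per-subject `components` tibble (decisions, weights,
#'   `U`, `W`, residuals), the `subset` used, `m`, and the learner label.
#' @export
jackknife_estimate <- function(data, learner, weights = NULL,
                               partial_r = NULL, subset = NULL, seed = NULL) {
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(subset)) {
    if (!is.null(partial_r)) {
      stopifnot(partial_r >= 2L, partial_r <= n)
      subset <- sort(sample.int(n, partial_r))
    } else {
      subset <- seq_len(n)
    }
  } else {
    subset <- sort(as.integer(subset))
  }
  if (is.null(weights)) weights <- estimate_weights(data)
  decisions <- loo_decisions(data, learner, subset = subset, seed = seed)
  comp <- value_components(data, decisions, weights, subset = subset)
  value <- jackknife_value(comp$U, comp$W)
  vr <- jackknife_variance(comp$U, comp$W)

  rows <- data[subset, ]
  wsub <- weights[subset, ]
  components <- tibble::tibble(
    id = rows$id, time = rows$time, status = rows$status,
    treatment = rows$treatment, decision = decisions,
    propensity = wsub$propensity, cens_survival = wsub$cens_survival,
    ipcw = wsub$ipcw, U = comp$U, W = comp$W, residual = vr$residuals
  )
  learner_name <- if (inherits(learner, "itr_learner")) learner$name
    else if (inherits(learner, "itr_rule")) learner$learner_name
    else "custom"
  structure(
    list(value = value, variance = vr$variance, se = sqrt(vr$variance),
         components = components, subset = subset, m = length(subset),
         n = n, learner = learner_name, tau = dataset_tau(data)),
    class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat("Jackknife value estimate (", x$learner, ")\n", sep = "")
  cat("  value =", format(x$value, digits = 5),
      " se =", format(x$se, digits = 5), "\n")
  cat("  subjects used: m =", x$m, "of n =", x$n,
      if (x$m < x$n) "(partial jackknife)" else "", "\n")
  invisible(x)
}

#' @rdname jackknife_estimate
#' @param x A `jackknife_estimate`.
#' @param ... Unused.
#' @export
tidy.jackknife_estimate <- function(x, ...) {
  x$components
}

#' @rdname jackknife_estimate
#' @export
glance.jackknife_estimate <- function(x, ...) {
  tibble::tibble(learner = x$learner, value = x$value, se = x$se,
                 variance = x$variance, m = x$m, n = x$n, tau = x$tau)
}
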