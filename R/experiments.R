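#' Run a simulation grid of rule comparisons
#'
#' Batch driver for the simulation study: for every combination of scenario,
#' sample size, and censoring rate it simulates `B` replicate trials, runs the
#' full pipeline on each (nuisance weights on the complete sample, one shared
#' partial-jackknife subset, a jackknife estimate per learner, and the paired
#' Z-test per learner pair), and summarizes power alongside per-learner value
#' distributions.
#'
#' Replicate seeds are expanded from `seed` with a per-(cell, replicate)
#' counter, so any cell can be re-run independently and the whole grid is
#' reproducible byte for byte. A failed replicate (for instance a degenerate
#' arm at a small sample size) is redrawn with a recorded fallback seed.
#'
#' @param scenarios Integer vector of scenario ids (or a single
#'   [custom_scenario()]).
#' @param n Integer vector of sample sizes.
#' @param censoring Numeric vector of target censoring rates (0 = none).
#' @param B Replicates per cell.
#' @param learners Named list of learners ([itr_learner()] specs or fitting
#'   functions); only learners named in `pairs` are fitted.
#' @param pairs List of length-2 character vectors naming the comparisons.
#' @param partial_r Function of the sample size returning the
#'   partial-jackknife subset size, or `NA` for the full jackknife. The
#'   default uses a subset of 500 once `n` reaches 800.
#' @param seed Master integer seed.
#' @param winsorize_probs Winsorize censoring probabilities (90%)?
#' @param verbose Print one line per cell?
#' @return An object of class `survjack_grid`: a list with `summary` (one row
#'   per cell and pair: power, Monte Carlo error, mean statistic), `values`
#'   (one row per cell and learner: mean/SD of the value estimates), `tests`
#'   (per-replicate test records), `estimates` (per-replicate learner values),
#'   and the failure count.
#' @export
run_power_grid <- function(scenarios = 1L, n = 200L, censoring = 0,
                           B = 500L,
                           learners = list(rsf = itr_learner("rsf"),
                                           cox = itr_learner("cox"),
                                           zom = itr_learner("zom")),
                           pairs = list(c("rsf", "cox"), c("rsf", "zom")),
                           partial_r = function(n) if (n >= 800L) 500L else NA,
                           seed = 1L, winsorize_probs = TRUE,
                           verbose = FALSE) {
  needed <- unique(unlist(pairs))
  missing_learners <- setdiff(needed, names(learners))
  if (length(missing_learners)) {
    stop("No learner named: ", paste(missing_learners, collapse = ", "),
         call. = FALSE)
  }
  scen_list <- if (inherits(scenarios, "survjack_scenario")) list(scenarios)
               else as.list(scenarios)
  grid <- tidyr::expand_grid(si = seq_along(scen_list), n = as.integer(n),
                             censoring = censoring)
  tests <- list(); estimates <- list(); failures <- 0L

  for (ci in seq_len(nrow(grid))) {
    scen <- scen_list[[grid$si[ci]]]
    scen_id <- if (inherits(scen, "survjack_scenario")) {
      if (is.na(scen$id)) 0L else scen$id
    } else as.integer(scen)
    nn <- grid$n[ci]
    cens <- grid$censoring[ci]
    r <- partial_r(nn)
    if (verbose) {
      message("cell ", ci, "/", nrow(grid), ": scenario ", scen_id,
              ", n = ", nn, ", censoring = ", cens)
    }
    for (b in seq_len(B)) {
      rep_seed <- (seed + 1000003 * ci + b) %% 2147483647
      res <- NULL
      for (attempt in 0:3) {
        use_seed <- (rep_seed + attempt * 500000007) %% 2147483647
        res <- tryCatch(
          run_replicate(scen, nn, cens, learners, needed, pairs, r, use_seed,
                        winsorize_probs),
          error = function(e) NULL)
        if (!is.null(res)) break
        failures <- failures + 1L
      }
      if (is.null(res)) {
        stop("Replicate ", b, " of cell ", ci, " failed after 4 seeds.",
             call. = FALSE)
      }
      meta <- tibble::tibble(scenario = scen_id, n = nn, censoring = cens,
                             rep = b, seed = use_seed)
      tests[[length(tests) + 1L]] <- dplyr::bind_cols(meta[rep(1, nrow(res$tests)), ],
                                                      res$tests)
      estimates[[length(estimates) + 1L]] <-
        dplyr::bind_cols(meta[rep(1, nrow(res$values)), ], res$values)
    }
  }
  tests <- dplyr::bind_rows(tests)
  estimates <- dplyr::bind_rows(estimates)

  summary <- tests |>
    dplyr::group_by(.data$scenario, .data$n, .data$censoring, .data$pair) |>
    dplyr::summarise(
      power = mean(.data$p_value < 0.05),
      mc_se = sqrt(.data$power[1] * (1 - .data$power[1]) / dplyr::n()),
      mean_statistic = mean(.data$statistic),
      B = dplyr::n(), .groups = "drop")
  values <- estimates |>
    dplyr::group_by(.data$scenario, .data$n, .data$censoring, .data$learner) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     sd_value = sd(.data$value),
                     mean_se = mean(.data$se), .groups = "drop")

  structure(list(summary = summary, values = values, tests = tests,
                 estimates = estimates, failures = failures, seed = seed),
            class = "survjack_grid")
}

run_replicate <- function(scen, n, cens, learners, needed, pairs, partial_r,
                          rep_seed, winsorize_probs) {
  data <- simulate_scenario(scen, n, censoring = cens, seed = rep_seed)
  weights <- estimate_weights(
    data,
    censoring_model = if (cens == 0) "none" else "coxph_interactions",
    winsorize_probs = winsorize_probs)
  set.seed(rep_seed + 1L)
  subset <- if (!is.na(partial_r) && partial_r < n) {
    sort(sample.int(n, partial_r))
  } else {
    seq_len(n)
  }
  ests <- lapply(setNames(needed, needed), function(nm) {
    jackknife_estimate(data, learners[[nm]], weights = weights,
                       subset = subset, seed = rep_seed)
  })
  tests <- purrr::map_dfr(pairs, function(pr) {
    zt <- z_test(ests[[pr[1]]], ests[[pr[2]]])
    tibble::tibble(pair = paste(pr, collapse = "_vs_"),
                   value_1 = zt$value_1, value_2 = zt$value_2,
                   statistic = zt$statistic, p_value = zt$p_value,
                   se_diff = zt$se_diff, m = zt$m)
  })
  values <- purrr::map_dfr(needed, function(nm) {
    tibble::tibble(learner = nm, value = ests[[nm]]$value, se = ests[[nm]]$se)
  })
  list(tests = tests, values = values)
}

#' @export
print.survjack_grid <- function(x, ...) {
  cat("Simulation grid:", nrow(x$summary), "cell-pair summaries,",
      max(x$tests$rep), "replicates per cell,", x$failures,
      "redrawn replicates\n")
  print(x$summary)
  invisible(x)
}

#' Q-Q data for the jackknife test statistic
#'
#' Pairs the sorted statistics with standard normal quantiles and reports the
#' Kolmogorov-Smirnov distance to N(0, 1), the numerical core of a normality
#' Q-Q plot.
#'
#' @param z_stats Numeric vector of at least 20 test statistics.
#' @return An object of class `survjack_qq`: a list with `points` (a tibble
#'   of `theoretical` and `empirical` quantiles), `ks_distance`, `ks_p`, `n`.
#' @export
qq_data <- function(z_stats) {
  z_stats <- z_stats[is.finite(z_stats)]
  m <- length(z_stats)
  if (m < 20L) {
    stop("At least 20 finite statistics are required for Q-Q data.",
         call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(z_stats, "pnorm"))
  structure(
    list(points = tibble::tibble(theoretical = qnorm(ppoints(m)),
                                 empirical = sort(z_stats)),
         ks_distance = unname(ks$statistic), ks_p = ks$p.value, n = m),
    class = "survjack_qq")
}

#' @export
print.survjack_qq <- function(x, ...) {
  cat("Q-Q data for", x$n, "statistics: KS distance to N(0,1) =",
      format(x$ks_distance, digits = 4), "\n")
  invisible(x)
}
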