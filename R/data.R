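#' Construct a validated survival dataset
#'
#' Assembles and validates the per-subject data used throughout the package:
#' a follow-up time, an event indicator, a binary treatment, and numeric
#' covariates, together with a dataset-level truncation horizon `tau`.
#' Follow-up times are stored post-truncation: a recorded time beyond `tau`
#' becomes an administrative event at exactly `tau` (the subject is known to
#' have survived to the horizon, which is the outcome the restricted value
#' function rewards), so after construction `time <= tau` and the event
#' indicator is consistent with `T = min(T~, tau)`.
#'
#' @param data A data frame with one row per subject.
#' @param tau Positive truncation horizon, in the units of `time`.
#' @param time,status,treatment Names of the follow-up time, event indicator
#'   (1 = event, 0 = censored), and treatment (0/1) columns.
#' @param covariates Character vector of covariate column names. Defaults to
#'   every numeric column not otherwise used (the simulator's latent columns
#'   `true_T`, `true_C` are never defaulted in).
#' @param id Optional name of a subject identifier column; row numbers are
#'   used when absent.
#'
#' @return A tibble of class `survjack_data` with columns `id`, `time`,
#'   `status`, `treatment`, and the covariates, plus attributes `tau` and
#'   `covariates`. Any extra columns in `data` (for example latent times kept
#'   by the simulator) are carried along.
#' @export
#' @examples
#' df <- data.frame(time = c(1, 2, 3, 9), status = 1, treatment = c(0, 1, 0, 1),
#'                  x1 = runif(4))
#' survival_data(df, tau = 5)
survival_data <- function(data, tau, time = "time", status = "status",
                          treatment = "treatment", covariates = NULL,
                          id = NULL) {
  stopifnot(is.data.frame(data))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a positive finite scalar.", call. = FALSE)
  }
  for (col in c(time, status, treatment, id)) {
    if (!col %in% names(data)) {
      stop("Column `", col, "` not found in `data`.", call. = FALSE)
    }
  }
  used <- c(time, status, treatment, id, "true_T", "true_C") # latent columns
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          used)
  } else {
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov)) {
      stop("Covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
  }
  if (!length(covariates)) {
    stop("At least one numeric covariate column is required.", call. = FALSE)
  }

  out <- tibble::as_tibble(data)
  out <- dplyr::rename(out, time = !!time, status = !!status,
                       treatment = !!treatment)
  out$id <- if (is.null(id)) as.character(seq_len(nrow(out))) else
    as.character(out[[id]])
  if (!is.null(id) && id != "id") out[[id]] <- NULL
  extra <- setdiff(names(out), c("id", "time", "status", "treatment",
                                 covariates))
  out <- out[, c("id", "time", "status", "treatment", covariates, extra)]

  validate_survival_columns(out, covariates)

  # tau-truncation: anything recorded beyond tau is an event at tau
  over <- out$time > tau
  out$time[over] <- tau
  out$status[over] <- 1L
  out$status <- as.integer(out$status)
  out$treatment <- as.integer(out$treatment)

  new_survjack_data(out, tau = tau, covariates = covariates)
}

new_survjack_data <- function(x, tau, covariates) {
  structure(x, tau = tau, covariates = covariates,
            class = c("survjack_data", class(tibble::tibble())))
}

validate_survival_columns <- function(x, covariates) {
  bad_rows <- function(cond) paste(which(cond), collapse = ", ")
  for (col in c("time", "status", "treatment", covariates)) {
    if (anyNA(x[[col]])) {
      stop("Missing values in `", col, "` (rows ", bad_rows(is.na(x[[col]])),
           ").", call. = FALSE)
    }
  }
  if (any(x$time < 0)) {
    stop("Negative follow-up times (rows ", bad_rows(x$time < 0), ").",
         call. = FALSE)
  }
  for (col in c("status", "treatment")) {
    ok <- x[[col]] %in% c(0, 1)
    if (!all(ok)) {
      stop("`", col, "` must be 0/1; offending rows: ", bad_rows(!ok), ".",
           call. = FALSE)
    }
  }
  for (col in covariates) {
    if (!is.numeric(x[[col]]) || any(!is.finite(x[[col]]))) {
      stop("Covariate `", col, "` must be finite numeric.", call. = FALSE)
    }
  }
  if (nrow(x) < 2L) stop("At least two subjects are required.", call. = FALSE)
  if (length(unique(x$treatment[x$treatment %in% c(0, 1)])) < 2L) {
    stop("Both treatment arms must be non-empty.", call. = FALSE)
  }
  invisible(x)
}

#' @export
`[.survjack_data` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_survjack_data(out, tau = attr(x, "tau"),
                             covariates = attr(x, "covariates"))
  }
  out
}

#' Truncation horizon and covariate names of a dataset
#'
#' @param data A `survjack_data` object.
#' @return `dataset_tau()` returns the scalar horizon; `dataset_covariates()`
#'   the character vector of covariate column names.
#' @export
dataset_tau <- function(data) {
  tau <- attr(data, "tau")
  if (is.null(tau)) stop("Not a `survjack_data` object.", call. = FALSE)
  tau
}

#' @rdname dataset_tau
#' @export
dataset_covariates <- function(data) {
  covs <- attr(data, "covariates")
  if (is.null(covs)) stop("Not a `survjack_data` object.", call. = FALSE)
  covs
}

#' Read a survival dataset from a delimited text file
#'
#' Reads a comma-delimited file with a header and validates it with
#' [survival_data()], applying the tau-truncation convention.
#'
#' @param path Path to a CSV file.
#' @param tau Positive truncation horizon.
#' @param column_map Named character vector mapping the roles `time`,
#'   `status`, `treatment` (and optionally `id`) to column names in the file.
#'   Roles left out keep their default names.
#' @param covariates Optional character vector of covariate columns; defaults
#'   to all remaining numeric columns.
#'
#' @return A `survjack_data` tibble.
#' @export
read_survival_data <- function(path, tau, column_map = NULL,
                               covariates = NULL) {
  map <- c(time = "time", status = "status", treatment = "treatment")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), c("time", "status", "treatment", "id"))
    if (length(bad)) {
      stop("Unknown roles in `column_map`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  survival_data(raw, tau = tau, time = map[["time"]], status = map[["status"]],
                treatment = map[["treatment"]],
                id = if ("id" %in% names(map)) map[["id"]] else NULL,
                covariates = covariates)
}

#' Write a result table to a delimited text file
#'
#' Writes any rectangular result (an estimate summary, a power grid, raw
#' replicate records) as comma-delimited text with a header and a
#' deterministic column order, so that results round-trip through
#' [readr::read_csv()].
#'
#' @param table A data frame of results (possibly zero rows).
#' @param path Output file path.
#' @return Invisibly, `table`.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(table)
}

#' Censoring rate of a dataset
#'
#' The proportion of subjects whose latent failure is not observed before the
#' horizon: one minus the fraction of genuine (pre-`tau`) events. Subjects
#' carried to `tau` administratively count toward this rate even though their
#' event indicator is 1, matching how average censoring rates are tuned in the
#' simulation scenarios.
#'
#' @param data A `survjack_data` object.
#' @return A fraction in \[0, 1\].
#' @export
censoring_rate <- function(data) {
  tau <- dataset_tau(data)
  1 - mean(data$status == 1L & data$time < tau)
}
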