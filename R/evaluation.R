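# Evaluation harness: does the physician-prescribed dose fall inside the
# recommended interval? Matching is boundary-INCLUSIVE at both ends — doses
# exactly on an interval boundary count as matches — which is deliberately
# looser than the half-open partition used to encode doses for training.

#' Packaged 60-case test set
#'
#' Loads the packaged test table of 60 cases: the discretized patient state,
#' the physician-prescribed dose, the recommended dose interval (as an action
#' index) and the recorded match flag.
#'
#' @param path Optional path to an alternative test-case CSV with the same
#'   columns (`test_number`, `hba1c_level`, `bmi_level`, `activity_level`,
#'   `alcohol_level`, `actual_dose`, `action_index`, `printed_match`).
#' @return A tibble of test cases.
#' @export
test_cases <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table5_test_cases.csv",
                                package = "insulinrl", mustWork = TRUE)
  cases <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  required <- c("test_number", "hba1c_level", "bmi_level", "activity_level",
                "alcohol_level", "actual_dose", "action_index")
  missing_cols <- setdiff(required, names(cases))
  if (length(missing_cols) > 0) {
    stop("test-case file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cases
}

#' Boundary-inclusive interval membership
#'
#' `TRUE` iff `lower <= dose <= upper` for the action's dose interval. Both
#' boundaries are inclusive: a dose of 15 units matches the `[6,15)` interval
#' and a dose of 20 matches `[15,20)`. This is the matching rule of the
#' evaluation harness, distinct from the half-open partition that
#' [encode_action()] uses to assign logged doses to unique actions.
#'
#' @param dose Numeric vector of prescribed doses in units.
#' @param action Integer vector of recommended action indices in `1:6`
#'   (recycled against `dose`).
#' @return Logical vector.
#' @export
dose_in_interval <- function(dose, action) {
  check_action(action)
  if (!is.numeric(dose) || anyNA(dose)) {
    stop("`dose` must be numeric with no missing values.", call. = FALSE)
  }
  dose >= ACTION_LOWER[action] & dose <= ACTION_UPPER[action]
}

check_cases <- function(cases) {
  if (nrow(cases) == 0) stop("no test cases supplied.", call. = FALSE)
  invisible(TRUE)
}

#' Interval-match rate over test cases
#'
#' Recomputes boundary-inclusive membership of each prescribed dose in its
#' recommended interval. When the cases carry a `printed_match` column the
#' recomputed flags are cross-checked against it and any disagreement raises
#' a warning (a transcription or rule discrepancy).
#'
#' @param cases Tibble of test cases, e.g. from [test_cases()].
#' @return A one-row tibble: `n_match`, `n_cases`, `match_rate`,
#'   `n_flag_discrepancies`.
#' @examples
#' \dontrun{match_rate(test_cases())}
#' @export
match_rate <- function(cases) {
  check_cases(cases)
  match <- dose_in_interval(cases$actual_dose, cases$action_index)
  n_disc <- 0L
  if ("printed_match" %in% names(cases)) {
    recorded <- parse_match_flag(cases$printed_match)
    n_disc <- sum(match != recorded)
    if (n_disc > 0) {
      warning(n_disc, " case(s) where the recomputed match flag disagrees ",
              "with the recorded one.", call. = FALSE)
    }
  }
  tibble::tibble(
    n_match = sum(match),
    n_cases = nrow(cases),
    match_rate = sum(match) / nrow(cases),
    n_flag_discrepancies = n_disc
  )
}

parse_match_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("match", "true", "1", "yes")
}

#' Mean interval error over test cases
#'
#' The per-case error is 0 when the prescribed dose lies (boundary-inclusive)
#' inside the recommended interval, and otherwise the distance from the dose
#' to the nearest interval bound. Returns the mean over cases.
#'
#' @param cases Tibble of test cases.
#' @return Mean error in insulin units (a single number).
#' @export
mean_interval_error <- function(cases) {
  check_cases(cases)
  mean(case_errors(cases$actual_dose, cases$action_index))
}

case_errors <- function(dose, action) {
  ifelse(dose_in_interval(dose, action), 0,
         pmin(abs(dose - ACTION_LOWER[action]),
              abs(dose - ACTION_UPPER[action])))
}

#' Evaluate a dosing policy against test cases
#'
#' Looks up the policy's recommended action for each case's state and scores
#' the physician-prescribed dose against that recommendation
#' (boundary-inclusive match and nearest-bound error). Cases whose state was
#' never visited during training are scored but counted separately — their
#' recommendation is only the tie-break default.
#'
#' @param policy A policy tibble from [greedy_policy()] (columns `state`,
#'   `action`, `visited`).
#' @param cases Tibble of test cases.
#' @return An object of class `dose_eval`: a list with the per-case tibble
#'   (`cases`) and summary fields `n_cases`, `n_match`, `match_rate`,
#'   `mean_interval_error`, `n_unvisited`.
#' @export
evaluate_policy <- function(policy, cases) {
  check_cases(cases)
  stopifnot(all(c("state", "action") %in% names(policy)))
  if (!"visited" %in% names(policy)) policy$visited <- TRUE
  idx <- state_index(cases$hba1c_level, cases$bmi_level,
                     cases$activity_level, cases$alcohol_level)
  pos <- match(idx, policy$state)
  if (anyNA(pos)) {
    stop("policy does not cover all case states.", call. = FALSE)
  }
  per_case <- tibble::tibble(
    test_number = cases$test_number %||% seq_len(nrow(cases)),
    state = idx,
    actual_dose = cases$actual_dose,
    recommended_action = policy$action[pos],
    recommended_interval = interval_label(policy$action[pos]),
    visited = policy$visited[pos],
    match = dose_in_interval(cases$actual_dose, policy$action[pos]),
    error = case_errors(cases$actual_dose, policy$action[pos])
  )
  structure(
    list(cases = per_case,
         n_cases = nrow(per_case),
         n_match = sum(per_case$match),
         match_rate = sum(per_case$match) / nrow(per_case),
         mean_interval_error = mean(per_case$error),
         n_unvisited = sum(!per_case$visited)),
    class = "dose_eval"
  )
}

#' @export
print.dose_eval <- function(x, ...) {
  cat("<dose_eval> interval-match evaluation\n")
  cat(sprintf("  matches: %d / %d (%.1f%%)\n", x$n_match, x$n_cases,
              100 * x$match_rate))
  cat(sprintf("  mean interval error: %.3g units\n", x$mean_interval_error))
  if (x$n_unvisited > 0) {
    cat("  cases on states unvisited in training:", x$n_unvisited, "\n")
  }
  invisible(x)
}

#' @method tidy dose_eval
#' @export
tidy.dose_eval <- function(x, ...) {
  x$cases
}

#' @method glance dose_eval
#' @export
glance.dose_eval <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_cases, n_match = x$n_match, match_rate = x$match_rate,
    mean_interval_error = x$mean_interval_error, n_unvisited = x$n_unvisited
  )
}

#' Per-case plot of prescribed doses against recommended intervals
#'
#' @param object A `dose_eval` object.
#' @param ... Unused.
#' @return A ggplot with one row per test case: the recommended interval as a
#'   segment and the prescribed dose as a point, colored by match.
#' @method autoplot dose_eval
#' @export
autoplot.dose_eval <- function(object, ...) {
  df <- object$cases
  df$lower <- ACTION_LOWER[df$recommended_action]
  df$upper <- ACTION_UPPER[df$recommended_action]
  ggplot2::ggplot(df, ggplot2::aes(y = .data$test_number)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       yend = .data$test_number),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$actual_dose,
                                     color = .data$match)) +
    ggplot2::labs(x = "insulin dose (units)", y = "test case",
                  color = "dose in interval") +
    ggplot2::theme_minimal()
}
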