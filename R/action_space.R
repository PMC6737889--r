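# Action space: six glargine (Lantus) dose intervals, in insulin units.
# Encoding uses half-open partition semantics so every logged dose maps to a
# unique action; evaluation-time interval matching is boundary-inclusive (see
# dose_in_interval()).

N_ACTIONS <- 6L
ACTION_LOWER <- c(6, 15, 20, 30, 40, 50)
ACTION_UPPER <- c(15, 20, 30, 40, 50, 100)
DOSE_MIN <- 6
DOSE_MAX <- 100

#' The six canonical insulin dose intervals
#'
#' Doses are daily long-acting insulin in units. The first five intervals are
#' half-open `[lower, upper)`; the sixth, `[50, 100]`, is closed so the six
#' intervals partition `[6, 100]`.
#'
#' @return A 6-row tibble with columns `action`, `lower`, `upper`,
#'   `upper_inclusive`, `label`.
#' @examples
#' dose_intervals()
#' @export
dose_intervals <- function() {
  tibble::tibble(
    action = seq_len(N_ACTIONS),
    lower = ACTION_LOWER,
    upper = ACTION_UPPER,
    upper_inclusive = c(rep(FALSE, 5), TRUE),
    label = interval_label(seq_len(N_ACTIONS))
  )
}

#' Map a prescribed dose to its action index
#'
#' Uses partition semantics: each interval is closed below and open above,
#' except the last (`[50, 100]`), so every dose in `[6, 100]` maps to exactly
#' one action.
#'
#' @param dose Numeric vector of insulin doses in units, within `[6, 100]`.
#' @return Integer vector of action indices in `1:6`.
#' @examples
#' encode_action(c(14, 20, 100))
#' @export
encode_action <- function(dose) {
  if (!is.numeric(dose) || anyNA(dose)) {
    stop("`dose` must be numeric with no missing values.", call. = FALSE)
  }
  if (any(dose < DOSE_MIN | dose > DOSE_MAX)) {
    stop("dose outside the supported range [", DOSE_MIN, ", ", DOSE_MAX, "]: ",
         paste(utils::head(dose[dose < DOSE_MIN | dose > DOSE_MAX], 5),
               collapse = ", "),
         call. = FALSE)
  }
  k <- findInterval(dose, c(ACTION_LOWER, DOSE_MAX), rightmost.closed = TRUE)
  as.integer(pmin(k, N_ACTIONS))
}

#' Dose interval for an action index
#'
#' @param action Integer vector of action indices in `1:6`.
#' @return A tibble with one row per input action: `action`, `lower`, `upper`,
#'   `upper_inclusive`, `label`.
#' @examples
#' interval_of(3)
#' @export
interval_of <- function(action) {
  check_action(action)
  dose_intervals()[action, ]
}

#' Human-readable interval label for an action index
#'
#' @param action Integer vector of action indices in `1:6`.
#' @return Character vector such as `"[20,30)"` or `"[50,100]"`.
#' @export
interval_label <- function(action) {
  check_action(action)
  paste0("[", ACTION_LOWER[action], ",", ACTION_UPPER[action],
         ifelse(action == N_ACTIONS, "]", ")"))
}

check_action <- function(action) {
  if (!is.numeric(action) || anyNA(action) ||
      any(action != floor(action)) || any(action < 1 | action > N_ACTIONS)) {
    stop("`action` must contain integers in 1:", N_ACTIONS, call. = FALSE)
  }
  invisible(TRUE)
}
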