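# Discrete patient-state representation: HbA1c band x BMI bin x activity x
# alcohol usage. 3 * 17 * 2 * 3 = 306 states.

N_HBA1C_LEVELS <- 3L
N_BMI_LEVELS <- 17L
N_ACTIVITY_LEVELS <- 2L
N_ALCOHOL_LEVELS <- 3L
N_STATES <- N_HBA1C_LEVELS * N_BMI_LEVELS * N_ACTIVITY_LEVELS * N_ALCOHOL_LEVELS

# BMI bin edges: level 1 is [18.5, 19), levels 2..16 are the unit bins
# [19,20) ... [33,34), level 17 is [34, 35]. The top bin is closed at both
# ends so the 17 bins tile [18.5, 35] without a gap at 34.
BMI_BREAKS <- c(18.5, 19:35)
BMI_MIN <- 18.5
BMI_MAX <- 35

#' Discretize glycated hemoglobin into control bands
#'
#' HbA1c (%) is banded into three clinical control levels: 1 = well controlled
#' (\eqn{\le 7}), 2 = moderately controlled (7, 9], 3 = poorly controlled
#' (> 9).
#'
#' @param hba1c Numeric vector of HbA1c assay values in percent. Must be
#'   positive.
#' @return Integer vector of levels in `{1, 2, 3}`.
#' @examples
#' encode_hba1c(c(6.5, 8.1, 9.1))
#' @export
encode_hba1c <- function(hba1c) {
  if (!is.numeric(hba1c) || anyNA(hba1c) || any(hba1c <= 0)) {
    stop("`hba1c` must be a positive numeric vector with no missing values.",
         call. = FALSE)
  }
  ifelse(hba1c <= 7, 1L, ifelse(hba1c <= 9, 2L, 3L))
}

#' Discretize body mass index into 17 unit-width bins
#'
#' Bins cover 18.5 to 35 kg/m^2: level 1 is \[18.5, 19), levels 2 through 16
#' are the unit bins \[19, 20) up to \[33, 34), and level 17 is \[34, 35\]
#' (closed at the top so the bins tile the whole range).
#'
#' @param bmi Numeric vector of BMI values in kg/m^2. Must be positive.
#' @param policy How to treat BMI outside \[18.5, 35\]: `"clamp"` (default)
#'   assigns the nearest boundary level with a warning; `"strict"` errors.
#' @return Integer vector of levels in `1:17`.
#' @examples
#' encode_bmi(c(18.5, 21.4, 34))
#' @export
encode_bmi <- function(bmi, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  if (!is.numeric(bmi) || anyNA(bmi) || any(bmi <= 0)) {
    stop("`bmi` must be a positive numeric vector with no missing values.",
         call. = FALSE)
  }
  out_of_range <- bmi < BMI_MIN | bmi > BMI_MAX
  if (any(out_of_range)) {
    if (policy == "strict") {
      stop("BMI outside [", BMI_MIN, ", ", BMI_MAX, "]: ",
           paste(utils::head(bmi[out_of_range], 5), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(out_of_range), " BMI value(s) outside [", BMI_MIN, ", ",
            BMI_MAX, "] clamped to the boundary level.", call. = FALSE)
    bmi <- pmin(pmax(bmi, BMI_MIN), BMI_MAX)
  }
  lev <- findInterval(bmi, BMI_BREAKS, rightmost.closed = TRUE)
  as.integer(pmin(lev, N_BMI_LEVELS))
}

#' Discretize physical-activity frequency
#'
#' Level 1 ("active") is at least two sessions of physical activity per week;
#' level 2 ("nonactive") is fewer than two.
#'
#' @param sessions_per_week Nonnegative numeric vector of weekly activity
#'   sessions, or, with `coded = TRUE`, values already coded as levels
#'   `{1, 2}`.
#' @param coded Logical; is the input already level-coded?
#' @return Integer vector of levels in `{1, 2}`.
#' @export
encode_activity <- function(sessions_per_week, coded = FALSE) {
  x <- sessions_per_week
  if (!is.numeric(x) || anyNA(x)) {
    stop("activity input must be numeric with no missing values.", call. = FALSE)
  }
  if (coded) {
    if (!all(x %in% c(1, 2))) {
      stop("coded activity levels must be 1 or 2.", call. = FALSE)
    }
    return(as.integer(x))
  }
  if (any(x < 0)) stop("sessions per week must be nonnegative.", call. = FALSE)
  ifelse(x >= 2, 1L, 2L)
}

#' Discretize alcohol usage
#'
#' Level 1 is mild-to-no consumption (fewer than two drinking occasions per
#' week), level 2 moderate-to-high (two or more per week), level 3 heavy
#' (a few times a day, flagged via `daily`).
#'
#' @param times_per_week Nonnegative numeric vector of weekly drinking
#'   occasions, or, with `coded = TRUE`, values already coded as levels
#'   `{1, 2, 3}`.
#' @param daily Logical vector; `TRUE` flags heavy (multiple-times-a-day)
#'   consumption. Ignored when `coded = TRUE`.
#' @param coded Logical; is the input already level-coded?
#' @return Integer vector of levels in `{1, 2, 3}`.
#' @export
encode_alcohol <- function(times_per_week, daily = FALSE, coded = FALSE) {
  x <- times_per_week
  if (!is.numeric(x) || anyNA(x)) {
    stop("alcohol input must be numeric with no missing values.", call. = FALSE)
  }
  if (coded) {
    if (!all(x %in% c(1, 2, 3))) {
      stop("coded alcohol levels must be 1, 2 or 3.", call. = FALSE)
    }
    return(as.integer(x))
  }
  if (any(x < 0)) stop("times per week must be nonnegative.", call. = FALSE)
  daily <- rep_len(as.logical(daily), length(x))
  ifelse(daily, 3L, ifelse(x >= 2, 2L, 1L))
}

#' Encode visit observations into discrete state levels
#'
#' Takes a visit-level data frame (columns `hba1c`, `body_mass_index`,
#' `activity_level`, `alcohol_usage`) and appends the four discrete state
#' components plus the flat `state_index`. Activity and alcohol columns are
#' treated as already level-coded by default, matching the visit-record
#' schema; set the `coded_*` arguments to `FALSE` to map raw weekly
#' frequencies instead.
#'
#' @param visits Data frame of visit records; see [read_visits()].
#' @param coded_activity,coded_alcohol Logical; are the activity / alcohol
#'   columns already level-coded?
#' @param bmi_policy Out-of-range BMI policy passed to [encode_bmi()].
#' @return The input as a tibble with integer columns `hba1c_level`,
#'   `bmi_level`, `activity_lvl`, `alcohol_lvl` and `state_index` appended.
#' @examples
#' visits <- tibble::tibble(
#'   hba1c = c(8.1, 9.1, 8), body_mass_index = c(21.4, 24, 22),
#'   activity_level = 1, alcohol_usage = 1
#' )
#' encode_states(visits)
#' @export
encode_states <- function(visits, coded_activity = TRUE, coded_alcohol = TRUE,
                          bmi_policy = c("clamp", "strict")) {
  required <- c("hba1c", "body_mass_index", "activity_level", "alcohol_usage")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0) {
    stop("`visits` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(visits),
    hba1c_level = encode_hba1c(.data$hba1c),
    bmi_level = encode_bmi(.data$body_mass_index, policy = bmi_policy),
    activity_lvl = encode_activity(.data$activity_level, coded = coded_activity),
    alcohol_lvl = encode_alcohol(.data$alcohol_usage, coded = coded_alcohol)
  )
  dplyr::mutate(
    out,
    state_index = state_index(.data$hba1c_level, .data$bmi_level,
                              .data$activity_lvl, .data$alcohol_lvl)
  )
}

check_state_levels <- function(hba1c_level, bmi_level, activity_level,
                               alcohol_level) {
  ok <- hba1c_level %in% seq_len(N_HBA1C_LEVELS) &
    bmi_level %in% seq_len(N_BMI_LEVELS) &
    activity_level %in% seq_len(N_ACTIVITY_LEVELS) &
    alcohol_level %in% seq_len(N_ALCOHOL_LEVELS)
  if (!all(ok)) {
    stop("invalid state: levels must lie in 1:3 (HbA1c), 1:17 (BMI), ",
         "1:2 (activity), 1:3 (alcohol).", call. = FALSE)
  }
  invisible(TRUE)
}

#' Flat index of a discrete patient state
#'
#' Bijectively maps the 4-tuple (HbA1c level, BMI level, activity level,
#' alcohol level) onto `0:305` using a mixed-radix scheme with the HbA1c
#' level most significant. The ordering is a fixed serialization convention.
#'
#' @param hba1c_level,bmi_level,activity_level,alcohol_level Integer vectors
#'   of state components (recycled to a common length).
#' @return Integer vector of flat indices in `0:305`.
#' @seealso [decode_index()] for the inverse.
#' @examples
#' state_index(2, 4, 1, 1)
#' @export
state_index <- function(hba1c_level, bmi_level, activity_level, alcohol_level) {
  check_state_levels(hba1c_level, bmi_level, activity_level, alcohol_level)
  as.integer(
    (hba1c_level - 1L) * (N_BMI_LEVELS * N_ACTIVITY_LEVELS * N_ALCOHOL_LEVELS) +
      (bmi_level - 1L) * (N_ACTIVITY_LEVELS * N_ALCOHOL_LEVELS) +
      (activity_level - 1L) * N_ALCOHOL_LEVELS +
      (alcohol_level - 1L)
  )
}

#' Recover state levels from a flat index
#'
#' Inverse of [state_index()].
#'
#' @param index Integer vector of flat state indices in `0:305`.
#' @return A tibble with columns `state_index`, `hba1c_level`, `bmi_level`,
#'   `activity_level`, `alcohol_level`.
#' @export
decode_index <- function(index) {
  if (anyNA(index) || any(index != floor(index)) ||
      any(index < 0) || any(index >= N_STATES)) {
    stop("`index` must contain integers in 0:", N_STATES - 1L, call. = FALSE)
  }
  index <- as.integer(index)
  rad_b <- N_ACTIVITY_LEVELS * N_ALCOHOL_LEVELS
  rad_a <- N_BMI_LEVELS * rad_b
  tibble::tibble(
    state_index = index,
    hba1c_level = index %/% rad_a + 1L,
    bmi_level = (index %% rad_a) %/% rad_b + 1L,
    activity_level = (index %% rad_b) %/% N_ALCOHOL_LEVELS + 1L,
    alcohol_level = index %% N_ALCOHOL_LEVELS + 1L
  )
}

#' Enumerate the full discrete state space
#'
#' @return A 306-row tibble of all states in canonical `state_index` order.
#' @export
state_space <- function() {
  decode_index(seq_len(N_STATES) - 1L)
}

#' Read visit records from a delimited file
#'
#' Visit records are comma-separated with header columns `patient_id`,
#' `visit`, `hba1c`, `body_mass_index`, `activity_level`, `alcohol_usage`,
#' `lantus_dose`. Lines starting with `#` are treated as comments.
#'
#' @param path Path to the CSV file.
#' @return A tibble of visit records, ordered by patient and visit.
#' @export
read_visits <- function(path) {
  visits <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  required <- c("patient_id", "visit", "hba1c", "body_mass_index",
                "activity_level", "alcohol_usage", "lantus_dose")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0) {
    stop("visit file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(visits, .data$patient_id, .data$visit)
}

#' Write visit records to a delimited file
#'
#' @param visits Tibble of visit records.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`), e.g. the generating configuration.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, header = NULL) {
  write_commented_csv(visits, path, header)
}

write_commented_csv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
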