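# High-level pipeline entry points: simulate -> train -> recommend ->
# evaluate. Each works on files so a thin command-line wrapper (shipped in
# inst/cli/) can drive the whole workflow; every output file embeds the
# generating configuration, including the seed, as comment-header lines.

#' Simulate a cohort and write it as a visit-record file
#'
#' @param path Output CSV path.
#' @param params A [sim_params()] object.
#' @param quiet Suppress the cohort summary printed to stderr?
#' @return The visit tibble, invisibly.
#' @export
run_simulate <- function(path, params = sim_params(), quiet = FALSE) {
  visits <- generate_cohort(params)
  header <- paste0(names(unclass(params)), "=",
                   vapply(unclass(params), format, character(1)))
  write_visits(visits, path, header = header)
  if (!quiet) {
    s <- summarize_cohort(visits)
    message(sprintf("wrote %d visits for %d patients to %s",
                    nrow(visits), dplyr::n_distinct(visits$patient_id), path))
    message(paste(utils::capture.output(print(s$doses)), collapse = "\n"))
  }
  invisible(visits)
}

#' Train a Q-table from a visit-record file and write it out
#'
#' Offline mode (default) replays the logged transitions with experience
#' replay; online mode ignores the logged doses and trains epsilon-greedily
#' against the synthetic simulator instead.
#'
#' @param visits_file Input visit-record CSV (ignored when `online = TRUE`).
#' @param q_file Output path for the Q-table (a `_visits` companion file is
#'   written alongside).
#' @param config A [training_config()].
#' @param reward A [reward_params()] object.
#' @param online Train online against [make_simulator()] instead of replaying
#'   the logged visits?
#' @param sim_params_online A [sim_params()] for the online simulator.
#' @param n_episodes Episodes for online training.
#' @param quiet Suppress the training log on stderr?
#' @return The fitted `qlearn` object, invisibly.
#' @export
run_train <- function(visits_file, q_file, config = training_config(),
                      reward = reward_params(), online = FALSE,
                      sim_params_online = sim_params(), n_episodes = 2000L,
                      quiet = FALSE) {
  fit <- if (online) {
    fit_online(make_simulator(sim_params_online, reward), config, n_episodes)
  } else {
    visits <- read_visits(visits_file)
    transitions <- cohort_to_transitions(visits, reward)
    fit_offline(transitions, config)
  }
  write_q_table(fit, q_file)
  if (!quiet) {
    g <- glance(fit)
    message(sprintf(
      "trained on %d updates; %d of %d states visited; %d sweeps, final max |dQ| = %.3g",
      g$n_updates, g$n_states_visited, g$n_states, g$n_sweeps,
      g$final_max_delta))
  }
  invisible(fit)
}

#' Recommend a dose interval for one patient observation
#'
#' Encodes the raw observation, looks up the greedy action in a trained
#' Q-table and returns the recommended dose interval. If the state was never
#' visited during training the recommendation is only the tie-break default
#' and is flagged accordingly (with a warning).
#'
#' @param q_file Path to a Q-table written by [write_q_table()], or a
#'   `qlearn` object.
#' @param hba1c HbA1c in percent.
#' @param bmi BMI in kg/m^2.
#' @param activity_level,alcohol_usage Level-coded lifestyle factors.
#' @param bmi_policy Out-of-range BMI policy (see [encode_bmi()]).
#' @return A one-row tibble: the state levels, `state`, `action`, `label`,
#'   `q_value`, `visited`.
#' @export
run_recommend <- function(q_file, hba1c, bmi, activity_level = 1,
                          alcohol_usage = 1, bmi_policy = "clamp") {
  fit <- if (inherits(q_file, "qlearn")) q_file else read_q_table(q_file)
  idx <- state_index(encode_hba1c(hba1c), encode_bmi(bmi, policy = bmi_policy),
                     encode_activity(activity_level, coded = TRUE),
                     encode_alcohol(alcohol_usage, coded = TRUE))
  pol <- greedy_policy(fit)
  rec <- pol[pol$state == idx, ]
  if (!rec$visited) {
    warning("state ", idx, " was never visited during training; the ",
            "recommendation is the tie-break default.", call. = FALSE)
  }
  rec
}

#' Evaluate recommendations on a test-case table
#'
#' Without a Q-table, scores the recorded recommended intervals of the test
#' cases (boundary-inclusive match rate and mean nearest-bound error). With a
#' Q-table, extracts its greedy policy and scores that policy's
#' recommendations instead.
#'
#' @param cases_file Optional test-case CSV; defaults to the packaged 60-case
#'   table.
#' @param q_file Optional Q-table path or `qlearn` object.
#' @param out Optional path to write the per-case report CSV.
#' @param quiet Suppress the report summary on stderr?
#' @return A `dose_eval` object for policy evaluation, otherwise a one-row
#'   summary tibble from [match_rate()] with `mean_interval_error` appended.
#' @export
run_evaluate <- function(cases_file = NULL, q_file = NULL, out = NULL,
                         quiet = FALSE) {
  cases <- test_cases(cases_file)
  if (is.null(q_file)) {
    result <- match_rate(cases)
    result$mean_interval_error <- mean_interval_error(cases)
    per_case <- dplyr::mutate(
      cases,
      match = dose_in_interval(.data$actual_dose, .data$action_index),
      error = case_errors(.data$actual_dose, .data$action_index)
    )
    if (!quiet) {
      message(sprintf("matches: %d / %d (%.1f%%); mean interval error %.3g",
                      result$n_match, result$n_cases,
                      100 * result$match_rate, result$mean_interval_error))
    }
  } else {
    fit <- if (inherits(q_file, "qlearn")) q_file else read_q_table(q_file)
    result <- evaluate_policy(greedy_policy(fit), cases)
    per_case <- result$cases
    if (!quiet) message(paste(utils::capture.output(print(result)),
                              collapse = "\n"))
  }
  if (!is.null(out)) {
    write_commented_csv(per_case, out,
                        header = paste0("cases=", nrow(per_case)))
  }
  result
}
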