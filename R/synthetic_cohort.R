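# Seedable synthetic cohort with a known ground-truth dose requirement.
# This simulator is a testing stand-in for real clinic trajectories: its only
# contracts are (i) the visit-record schema, (ii) a dose requirement that is
# nondecreasing in every state component, and (iii) HbA1c that drifts down
# when the prescribed dose is close to the requirement and up otherwise.
# It deliberately models no glucose-insulin physiology.

# controlled HbA1c setpoint (%): a perfectly dosed patient equilibrates here
HBA1C_SETPOINT <- 6.5

#' Synthetic-cohort parameters
#'
#' @param n_patients Number of simulated patients. Default 87.
#' @param visits_per_patient Visits per trajectory. Default 40 (quarterly
#'   visits over ten years).
#' @param base_need Daily insulin requirement (units) of the reference state
#'   (controlled HbA1c, lowest BMI bin, active, little alcohol). Default 6.
#' @param bmi_slope Added units of requirement per BMI bin above the first.
#'   Default 1.5.
#' @param hba1c_slope Added units per HbA1c band above the first. Default 8.
#' @param inactive_increment Added units for the nonactive level. Default 5.
#' @param alcohol_slope Added units per alcohol level above the first.
#'   Default 3.
#' @param need_tolerance Relative dose error below which HbA1c is expected to
#'   improve. Default 0.2.
#' @param hba1c_noise_sd SD of the Gaussian visit-to-visit HbA1c noise, in
#'   percent HbA1c. Default 0.3.
#' @param misdose_slope Percent HbA1c added to the equilibrium per unit of
#'   relative dose error. Default 5: perfect dosing equilibrates at the 6.5%
#'   setpoint, dosing at the edge of the tolerance (relative error 0.2) at a
#'   borderline 7.5%, and grossly misdosed patients in the poorly controlled
#'   band.
#' @param reversion_rate Fraction of the gap between the current HbA1c and
#'   its dose-dependent equilibrium closed per visit. Default 0.5 (visits are
#'   about one HbA1c turnover apart).
#' @param bmi_walk_sd SD of the slow Gaussian random walk on BMI between
#'   visits. Default 0.1 kg/m^2.
#' @param prescriber_noise Half-width of the uniform relative error applied to
#'   logged doses around the true requirement, emulating imperfect clinical
#'   practice. Default 0.2.
#' @param lifestyle_switching Logical; if `TRUE`, activity and alcohol levels
#'   may occasionally switch within a trajectory (probability 0.02 per visit).
#'   Default `FALSE` (fixed per patient).
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   parameters and this seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 87L, visits_per_patient = 40L,
                       base_need = 6, bmi_slope = 1.5, hba1c_slope = 8,
                       inactive_increment = 5, alcohol_slope = 3,
                       need_tolerance = 0.2, hba1c_noise_sd = 0.3,
                       misdose_slope = 5, reversion_rate = 0.5,
                       bmi_walk_sd = 0.1,
                       prescriber_noise = 0.2, lifestyle_switching = FALSE,
                       seed = 1L) {
  stopifnot(
    n_patients >= 1, visits_per_patient >= 1,
    base_need > 0, bmi_slope >= 0, hba1c_slope >= 0,
    inactive_increment >= 0, alcohol_slope >= 0,
    need_tolerance > 0, need_tolerance < 1,
    hba1c_noise_sd >= 0, misdose_slope >= 0,
    reversion_rate > 0, reversion_rate <= 1, bmi_walk_sd >= 0,
    prescriber_noise >= 0, prescriber_noise < 1,
    is.logical(lifestyle_switching)
  )
  structure(
    list(n_patients = as.integer(n_patients),
         visits_per_patient = as.integer(visits_per_patient),
         base_need = base_need, bmi_slope = bmi_slope,
         hba1c_slope = hba1c_slope, inactive_increment = inactive_increment,
         alcohol_slope = alcohol_slope, need_tolerance = need_tolerance,
         hba1c_noise_sd = hba1c_noise_sd, misdose_slope = misdose_slope,
         reversion_rate = reversion_rate,
         bmi_walk_sd = bmi_walk_sd, prescriber_noise = prescriber_noise,
         lifestyle_switching = lifestyle_switching, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Ground-truth daily insulin requirement of a synthetic state
#'
#' A linear, additively separable requirement in the discrete state levels,
#' clamped to the supported dose range `[6, 100]` and nondecreasing in every
#' component: higher HbA1c band, higher BMI bin, inactivity and heavier
#' alcohol use all raise the requirement.
#'
#' @param hba1c_level,bmi_level,activity_level,alcohol_level Integer vectors
#'   of state components.
#' @param params A [sim_params()] object.
#' @return Numeric vector of dose requirements in insulin units.
#' @examples
#' true_dose_need(1, 1, 1, 1) # reference state: 6 units
#' @export
true_dose_need <- function(hba1c_level, bmi_level, activity_level,
                           alcohol_level, params = sim_params()) {
  check_state_levels(hba1c_level, bmi_level, activity_level, alcohol_level)
  need <- params$base_need +
    params$bmi_slope * (bmi_level - 1) +
    params$hba1c_slope * (hba1c_level - 1) +
    params$inactive_increment * (activity_level - 1) +
    params$alcohol_slope * (alcohol_level - 1)
  pmin(pmax(need, DOSE_MIN), DOSE_MAX)
}

#' Simulate one visit-to-visit transition
#'
#' HbA1c mean-reverts toward a dose-dependent equilibrium
#' `6.5 + misdose_slope * relative dose error`, closing `reversion_rate` of
#' the gap per visit, plus Gaussian noise. A dose within the relative
#' `need_tolerance` of the patient's requirement therefore pulls an elevated
#' HbA1c down toward the controlled band, while a badly misdosed patient
#' drifts up toward a poorly controlled equilibrium; the expected next HbA1c
#' is strictly increasing in the dosing error. BMI follows a slow random
#' walk; activity and alcohol stay fixed unless `lifestyle_switching` is
#' enabled. Uses the R random number generator; seed externally for
#' reproducibility.
#'
#' @param hba1c Current HbA1c in percent.
#' @param bmi Current BMI in kg/m^2.
#' @param activity_level,alcohol_usage Current lifestyle levels.
#' @param dose Prescribed dose in units, within `[6, 100]`.
#' @param params A [sim_params()] object.
#' @return A one-row tibble with columns `hba1c`, `body_mass_index`,
#'   `activity_level`, `alcohol_usage` describing the next visit.
#' @export
simulate_transition <- function(hba1c, bmi, activity_level, alcohol_usage,
                                dose, params = sim_params()) {
  if (any(dose < DOSE_MIN | dose > DOSE_MAX)) {
    stop("dose outside the supported range [", DOSE_MIN, ", ", DOSE_MAX, "].",
         call. = FALSE)
  }
  state <- list(
    a = encode_hba1c(hba1c),
    b = encode_bmi(bmi),
    c = encode_activity(activity_level, coded = TRUE),
    d = encode_alcohol(alcohol_usage, coded = TRUE)
  )
  need <- true_dose_need(state$a, state$b, state$c, state$d, params)
  rel_err <- abs(dose - need) / need
  equilibrium <- HBA1C_SETPOINT + params$misdose_slope * rel_err
  hba1c_next <- hba1c + params$reversion_rate * (equilibrium - hba1c) +
    stats::rnorm(length(hba1c), sd = params$hba1c_noise_sd)
  hba1c_next <- pmin(pmax(hba1c_next, 4.5), 14)
  bmi_next <- bmi + stats::rnorm(length(bmi), sd = params$bmi_walk_sd)
  bmi_next <- pmin(pmax(bmi_next, BMI_MIN), BMI_MAX)
  act_next <- state$c
  alc_next <- state$d
  if (params$lifestyle_switching) {
    if (stats::runif(1) < 0.02) act_next <- 3L - act_next
    if (stats::runif(1) < 0.02) alc_next <- sample.int(N_ALCOHOL_LEVELS, 1L)
  }
  tibble::tibble(
    hba1c = hba1c_next, body_mass_index = bmi_next,
    activity_level = act_next, alcohol_usage = alc_next
  )
}

draw_patient <- function() {
  list(
    hba1c = stats::runif(1, 5.5, 12.5),
    bmi = stats::runif(1, BMI_MIN, BMI_MAX),
    activity = sample.int(N_ACTIVITY_LEVELS, 1L),
    alcohol = sample(1:3, 1L, prob = c(0.55, 0.3, 0.15))
  )
}

#' Generate a synthetic visit-level cohort
#'
#' Simulates `n_patients` trajectories of `visits_per_patient` quarterly
#' visits. Logged doses are the patient's true requirement perturbed by
#' uniform prescriber noise (so logged data resemble imperfect clinical
#' practice while the optimal dose stays identifiable), and each next visit's
#' measurements follow [simulate_transition()]. Fully determined by
#' `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A tibble of visit records with columns `patient_id`, `visit`,
#'   `hba1c`, `body_mass_index`, `activity_level`, `alcohol_usage`,
#'   `lantus_dose`.
#' @export
generate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  rows <- vector("list", params$n_patients)
  for (p in seq_len(params$n_patients)) {
    pt <- draw_patient()
    hba1c <- numeric(params$visits_per_patient)
    bmi <- numeric(params$visits_per_patient)
    act <- integer(params$visits_per_patient)
    alc <- integer(params$visits_per_patient)
    dose <- numeric(params$visits_per_patient)
    h <- pt$hba1c; b <- pt$bmi; a_lvl <- pt$activity; d_lvl <- pt$alcohol
    for (v in seq_len(params$visits_per_patient)) {
      hba1c[v] <- round(h, 1)
      bmi[v] <- round(b, 1)
      act[v] <- a_lvl
      alc[v] <- d_lvl
      need <- true_dose_need(encode_hba1c(hba1c[v]), encode_bmi(bmi[v]),
                             a_lvl, d_lvl, params)
      d <- need * (1 + stats::runif(1, -params$prescriber_noise,
                                    params$prescriber_noise))
      dose[v] <- round(pmin(pmax(d, DOSE_MIN), DOSE_MAX))
      nxt <- simulate_transition(hba1c[v], bmi[v], a_lvl, d_lvl, dose[v],
                                 params)
      h <- nxt$hba1c; b <- nxt$body_mass_index
      a_lvl <- nxt$activity_level; d_lvl <- nxt$alcohol_usage
    }
    rows[[p]] <- tibble::tibble(
      patient_id = p, visit = seq_len(params$visits_per_patient),
      hba1c = hba1c, body_mass_index = bmi, activity_level = act,
      alcohol_usage = alc, lantus_dose = dose
    )
  }
  dplyr::bind_rows(rows)
}

#' Convert visit trajectories into Q-learning transitions
#'
#' Consecutive visits of each patient become experience tuples: the state is
#' the encoded visit, the action is the dose interval of the logged dose, the
#' reward follows the HbA1c band change into the next visit, and the final
#' pair of each trajectory is flagged terminal. Single-visit trajectories are
#' skipped with a warning.
#'
#' @param visits Tibble of visit records (see [generate_cohort()] /
#'   [read_visits()]).
#' @param reward A [reward_params()] object.
#' @param bmi_policy Out-of-range BMI policy passed to [encode_states()].
#' @return A tibble of transitions with columns `patient_id`, `state`,
#'   `action`, `reward`, `next_state`, `terminal`.
#' @export
cohort_to_transitions <- function(visits, reward = reward_params(),
                                  bmi_policy = "clamp") {
  if (nrow(visits) == 0) {
    return(tibble::tibble(patient_id = integer(), state = integer(),
                          action = integer(), reward = numeric(),
                          next_state = integer(), terminal = logical()))
  }
  if (!"patient_id" %in% names(visits)) visits$patient_id <- 1L
  if (!"visit" %in% names(visits)) {
    visits <- dplyr::mutate(visits, visit = dplyr::row_number(),
                            .by = "patient_id")
  }
  enc <- encode_states(visits, bmi_policy = bmi_policy)
  enc <- dplyr::arrange(enc, .data$patient_id, .data$visit)
  n_single <- sum(dplyr::count(enc, .data$patient_id)$n < 2)
  if (n_single > 0) {
    warning(n_single, " single-visit trajector",
            if (n_single == 1) "y" else "ies",
            " skipped (no transition can be formed).", call. = FALSE)
  }
  out <- dplyr::reframe(
    enc,
    state = .data$state_index[-dplyr::n()],
    action = encode_action(.data$lantus_dose[-dplyr::n()]),
    reward = compute_reward(.data$hba1c_level[-dplyr::n()],
                            .data$hba1c_level[-1], reward),
    next_state = .data$state_index[-1],
    terminal = seq_len(dplyr::n() - 1L) == dplyr::n() - 1L,
    .by = "patient_id"
  )
  tibble::as_tibble(out)
}

#' Interactive simulator for online training
#'
#' Wraps the synthetic cohort dynamics as an episodic environment for
#' [fit_online()]. `reset()` draws a fresh patient and returns the 0-based
#' state index; `step(action)` prescribes a dose within the chosen interval —
#' the physician is modeled as titrating to the patient's requirement within
#' the recommended range, at one-unit resolution — advances one visit, and
#' returns `list(state, reward, terminal)`. Episodes last
#' `params$visits_per_patient` steps. Uses the R random number generator;
#' [fit_online()] seeds it from its config.
#'
#' @param params A [sim_params()] object.
#' @param reward A [reward_params()] object.
#' @return A list with function elements `reset` and `step`.
#' @export
make_simulator <- function(params = sim_params(), reward = reward_params()) {
  intervals <- dose_intervals()
  # highest prescribable dose in each interval at one-unit resolution
  upper_eff <- ifelse(intervals$upper_inclusive, intervals$upper,
                      intervals$upper - 1)
  env <- new.env(parent = emptyenv())
  current_state <- function() {
    a <- if (env$hba1c <= 7) 1L else if (env$hba1c <= 9) 2L else 3L
    b <- min(findInterval(env$bmi, BMI_BREAKS, rightmost.closed = TRUE),
             N_BMI_LEVELS)
    (a - 1L) * 102L + (b - 1L) * 6L + (env$activity - 1L) * 3L +
      (env$alcohol - 1L)
  }
  reset <- function() {
    pt <- draw_patient()
    env$hba1c <- pt$hba1c
    env$bmi <- pt$bmi
    env$activity <- pt$activity
    env$alcohol <- pt$alcohol
    env$t <- 0L
    current_state()
  }
  # step() inlines the simulate_transition() arithmetic: it runs in the
  # innermost training loop, where per-step data-frame allocation would
  # dominate the runtime
  w_imp <- reward$improvement_weight
  w_bon <- reward$controlled_bonus
  w_pen <- reward$uncontrolled_penalty
  step <- function(action) {
    check_action(action)
    if (is.null(env$t)) stop("call reset() before step().", call. = FALSE)
    h <- env$hba1c
    a <- if (h <= 7) 1L else if (h <= 9) 2L else 3L
    b <- min(findInterval(env$bmi, BMI_BREAKS, rightmost.closed = TRUE),
             N_BMI_LEVELS)
    need <- min(max(params$base_need + params$bmi_slope * (b - 1) +
                      params$hba1c_slope * (a - 1) +
                      params$inactive_increment * (env$activity - 1) +
                      params$alcohol_slope * (env$alcohol - 1),
                    DOSE_MIN), DOSE_MAX)
    dose <- min(max(need, intervals$lower[action]), upper_eff[action])
    equilibrium <- HBA1C_SETPOINT + params$misdose_slope * abs(dose - need) / need
    h_next <- h + params$reversion_rate * (equilibrium - h) +
      stats::rnorm(1, sd = params$hba1c_noise_sd)
    env$hba1c <- min(max(h_next, 4.5), 14)
    env$bmi <- min(max(env$bmi + stats::rnorm(1, sd = params$bmi_walk_sd),
                       BMI_MIN), BMI_MAX)
    if (params$lifestyle_switching) {
      if (stats::runif(1) < 0.02) env$activity <- 3L - env$activity
      if (stats::runif(1) < 0.02) {
        env$alcohol <- sample.int(N_ALCOHOL_LEVELS, 1L)
      }
    }
    env$t <- env$t + 1L
    a_next <- if (env$hba1c <= 7) 1L else if (env$hba1c <= 9) 2L else 3L
    list(state = current_state(),
         reward = w_imp * (a - a_next) + w_bon * (a_next == 1L) -
           w_pen * (a_next == 3L),
         terminal = env$t >= params$visits_per_patient)
  }
  list(reset = reset, step = step)
}

#' Policy-recovery experiment on the synthetic cohort
#'
#' Trains a Q-learning agent online against the synthetic simulator and
#' checks, for every state visited at least `min_visits` times, whether the
#' greedy policy recovers the generator's optimal action — the dose interval
#' containing [true_dose_need()]. This is the package's parameter-recovery
#' validation: the generator's ground truth is known, so the fraction of
#' frequently visited states whose optimal action is recovered measures
#' whether training identifies the dose-response built into the data.
#'
#' The default training protocol favors estimator stability: a visit-count
#' step size (`1/n(s,a)`, under which Q-values converge to expected returns),
#' broad exploration (`epsilon = 0.5`, so every action is sampled often in
#' every visited state) and a moderate discount (`gamma = 0.5`). Under the
#' simulator's mean-reverting HbA1c dynamics the optimal action is the same
#' for any discount, so the choice of `gamma` trades bootstrap variance
#' (high `gamma`) against myopia in the poorly controlled band, where one
#' visit cannot distinguish adequate from nearly adequate dosing (low
#' `gamma`). States whose requirement sits within a few percent of an
#' interval boundary are near-ties by construction — the neighboring
#' interval's best dose is almost as good — and dominate whatever residual
#' error remains.
#'
#' @param params A [sim_params()] object (also supplies the seed).
#' @param config A [training_config()]; defaults to the recovery protocol
#'   above, seeded from `params$seed`.
#' @param n_episodes Training episodes. Default 30000 (about 1.2 million
#'   visits; roughly a minute of training).
#' @param min_visits Minimum state visit count for a state to be assessed.
#'   Default 30.
#' @param reward A [reward_params()] object.
#' @return A list of class `policy_recovery`: `summary` (one-row tibble with
#'   `n_assessed`, `n_recovered`, `recovery_rate`), `per_state` (per-state
#'   tibble with the target and learned actions), and `fit` (the `qlearn`
#'   object).
#' @export
policy_recovery <- function(params = sim_params(),
                            config = NULL,
                            n_episodes = 30000L, min_visits = 30L,
                            reward = reward_params()) {
  config <- config %||% training_config(gamma = 0.5, epsilon = 0.5,
                                        alpha_schedule = "visit_inverse",
                                        seed = params$seed)
  fit <- fit_online(make_simulator(params, reward), config, n_episodes)
  pol <- greedy_policy(fit)
  need <- true_dose_need(pol$hba1c_level, pol$bmi_level, pol$activity_level,
                         pol$alcohol_level, params)
  per_state <- dplyr::mutate(
    pol,
    true_need = need,
    target_action = encode_action(need),
    recovered = .data$action == .data$target_action,
    assessed = .data$visits >= min_visits
  )
  assessed <- per_state[per_state$assessed, ]
  structure(
    list(
      summary = tibble::tibble(
        n_assessed = nrow(assessed),
        n_recovered = sum(assessed$recovered),
        recovery_rate = mean(assessed$recovered)
      ),
      per_state = per_state,
      fit = fit
    ),
    class = "policy_recovery"
  )
}

#' @export
print.policy_recovery <- function(x, ...) {
  s <- x$summary
  cat("<policy_recovery> synthetic ground-truth recovery\n")
  cat(sprintf("  recovered optimal action in %d / %d frequently visited states (%.1f%%)\n",
              s$n_recovered, s$n_assessed, 100 * s$recovery_rate))
  invisible(x)
}

#' Summarize a visit-level cohort
#'
#' @param visits Tibble of visit records.
#' @return A list with elements `levels` (counts of visits per state
#'   component level) and `doses` (counts per dose interval).
#' @export
summarize_cohort <- function(visits) {
  enc <- encode_states(visits)
  levels <- dplyr::bind_rows(
    dplyr::count(enc, factor = "hba1c_level", level = .data$hba1c_level),
    dplyr::count(enc, factor = "bmi_level", level = .data$bmi_level),
    dplyr::count(enc, factor = "activity_level", level = .data$activity_lvl),
    dplyr::count(enc, factor = "alcohol_level", level = .data$alcohol_lvl)
  )
  doses <- dplyr::count(
    dplyr::mutate(enc, interval = interval_label(encode_action(.data$lantus_dose))),
    .data$interval
  )
  list(levels = tibble::as_tibble(levels), doses = tibble::as_tibble(doses))
}
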