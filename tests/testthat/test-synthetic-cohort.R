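test_that("the ground-truth dose requirement is linear and monotone", {
  expect_equal(true_dose_need(1, 1, 1, 1), 6)
  # 6 + 1.5*16 + 8*2 + 5*1 = 51, inside the [50,100] interval
  expect_equal(true_dose_need(3, 17, 2, 1), 51)
  expect_equal(encode_action(true_dose_need(3, 17, 2, 1)), 6L)
  space <- state_space()
  need <- true_dose_need(space$hba1c_level, space$bmi_level,
                         space$activity_level, space$alcohol_level)
  expect_true(all(need >= 6 & need <= 100))
  # nondecreasing in every component
  for (comp in c("hba1c_level", "bmi_level", "activity_level", "alcohol_level")) {
    bumped <- space
    top <- max(space[[comp]])
    keep <- bumped[[comp]] < top
    bumped[[comp]] <- pmin(bumped[[comp]] + 1L, top)
    expect_true(all(
      true_dose_need(bumped$hba1c_level, bumped$bmi_level,
                     bumped$activity_level, bumped$alcohol_level)[keep] >=
        need[keep]
    ))
  }
})

test_that("HbA1c drifts down under adequate dosing and up under gross misdosing", {
  p0 <- sim_params(hba1c_noise_sd = 0, bmi_walk_sd = 0)
  need <- true_dose_need(2, encode_bmi(25), 1, 1)
  nxt <- simulate_transition(8.5, 25, 1, 1, need, p0)
  expect_lt(nxt$hba1c, 8.5)
  # dose off by more than twice the tolerance
  bad_dose <- min(need * (1 + 2.5 * p0$need_tolerance), 100)
  nxt_bad <- simulate_transition(7.5, 25, 1, 1, bad_dose, p0)
  expect_gte(nxt_bad$hba1c, 7.5)
  # expected next HbA1c increases with the dosing error
  doses <- seq(need, min(need * 2, 100), length.out = 8)
  h_next <- vapply(doses,
                   function(d) simulate_transition(8, 25, 1, 1, d, p0)$hba1c,
                   numeric(1))
  expect_true(all(diff(h_next) >= 0))
  expect_error(simulate_transition(8, 25, 1, 1, 4, p0), "outside")
  # determinism under the same RNG state
  p <- sim_params()
  set.seed(11)
  a <- simulate_transition(8.5, 25, 1, 1, need, p)
  set.seed(11)
  b <- simulate_transition(8.5, 25, 1, 1, need, p)
  expect_identical(a, b)
})

test_that("generated cohorts have the configured shape and are reproducible", {
  p <- sim_params(seed = 123)
  cohort <- generate_cohort(p)
  expect_identical(dplyr::n_distinct(cohort$patient_id), 87L)
  expect_identical(nrow(cohort), 87L * 40L)
  expect_true(all(dplyr::count(cohort, patient_id)$n == 40L))
  expect_true(all(cohort$lantus_dose >= 6 & cohort$lantus_dose <= 100))
  expect_identical(generate_cohort(p), cohort)
  expect_false(identical(generate_cohort(sim_params(seed = 124)), cohort))
  # coverage: all three HbA1c bands and most BMI bins appear
  enc <- encode_states(cohort)
  expect_setequal(unique(enc$hba1c_level), 1:3)
  expect_gte(dplyr::n_distinct(enc$bmi_level), 10L)
  small <- generate_cohort(sim_params(n_patients = 2, visits_per_patient = 3,
                                      seed = 1))
  expect_identical(nrow(small), 6L)
})

test_that("trajectories convert to transitions pairwise with terminal tails", {
  tr <- cohort_to_transitions(worked_visits())
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$state, c(120L, 240L))
  expect_identical(tr$next_state, c(240L, 126L))
  expect_identical(tr$action, c(3L, 3L))
  expect_equal(tr$reward, c(compute_reward(2, 3), compute_reward(3, 2)))
  expect_identical(tr$terminal, c(FALSE, TRUE))
  # n visits yield n - 1 transitions, one terminal per patient
  p <- sim_params(n_patients = 5, visits_per_patient = 7, seed = 2)
  tr5 <- cohort_to_transitions(generate_cohort(p))
  expect_identical(nrow(tr5), 5L * 6L)
  expect_identical(sum(tr5$terminal), 5L)
  # single-visit trajectories are skipped with a warning
  lonely <- worked_visits()[1, ]
  lonely$patient_id <- 99L
  expect_warning(tr_mixed <- cohort_to_transitions(
    dplyr::bind_rows(worked_visits(), lonely)), "single-visit")
  expect_identical(nrow(tr_mixed), 2L)
  expect_identical(nrow(cohort_to_transitions(worked_visits()[0, ])), 0L)
})

test_that("the episodic simulator honors the reset/step contract", {
  p <- sim_params(visits_per_patient = 4)
  sim <- make_simulator(p)
  set.seed(6)
  s0 <- sim$reset()
  expect_true(s0 >= 0 && s0 <= 305)
  steps <- 0L
  repeat {
    out <- sim$step(3)
    steps <- steps + 1L
    expect_true(out$state >= 0 && out$state <= 305)
    expect_true(is.finite(out$reward))
    if (out$terminal) break
  }
  expect_identical(steps, 4L)
  expect_error(sim$step(7), "integers in 1:6")
})

test_that("cohort summaries count levels and dose intervals", {
  s <- summarize_cohort(generate_cohort(sim_params(n_patients = 10,
                                                   visits_per_patient = 5,
                                                   seed = 3)))
  expect_named(s, c("levels", "doses"))
  expect_equal(sum(s$doses$n), 50)
  expect_equal(sum(s$levels$n[s$levels$factor == "hba1c_level"]), 50)
})
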