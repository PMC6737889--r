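test_that("interval membership is inclusive at both boundaries", {
  expect_false(dose_in_interval(20, 1))
  expect_true(dose_in_interval(15, 1))   # upper boundary of [6,15)
  expect_true(dose_in_interval(20, 2))   # upper boundary of [15,20)
  expect_true(dose_in_interval(50, 6))
  expect_true(dose_in_interval(6, 1))
  expect_false(dose_in_interval(5.9, 1))
})

test_that("the packaged test set reproduces the recorded match column exactly", {
  cases <- test_cases()
  expect_identical(nrow(cases), 60L)
  recomputed <- dose_in_interval(cases$actual_dose, cases$action_index)
  recorded <- cases$printed_match == "match"
  expect_identical(recomputed, recorded)
  rate <- match_rate(cases)
  expect_identical(rate$n_match, 53L)
  expect_identical(rate$n_cases, 60L)
  expect_equal(rate$match_rate, 53 / 60)
  expect_identical(rate$n_flag_discrepancies, 0L)
  # the seven non-matching cases are the recorded ones
  expect_identical(cases$test_number[!recomputed],
                   c(4, 12, 17, 25, 37, 43, 54))
})

test_that("match-rate cross-check warns on a flag discrepancy", {
  cases <- test_cases()
  cases$printed_match[1] <- "not match"
  expect_warning(r <- match_rate(cases), "disagrees")
  expect_identical(r$n_flag_discrepancies, 1L)
  expect_identical(r$n_match, 53L)
  one <- cases[2, ]
  expect_equal(match_rate(one)$match_rate, 1)
  expect_error(match_rate(cases[0, ]), "no test cases")
})

test_that("mean interval error is the nearest-bound distance averaged over cases", {
  cases <- test_cases()
  expect_equal(mean_interval_error(cases), 0.8)
  # independent brute-force recomputation over all cases
  brute <- mapply(function(dose, k) {
    iv <- interval_of(k)
    if (dose >= iv$lower && dose <= iv$upper) 0
    else min(abs(dose - iv$lower), abs(dose - iv$upper))
  }, cases$actual_dose, cases$action_index)
  expect_equal(mean_interval_error(cases), mean(brute))
  # matching cases contribute zero
  expect_equal(mean_interval_error(cases[cases$printed_match == "match", ]), 0)
  single <- tibble::tibble(test_number = 1, actual_dose = 20, action_index = 1)
  expect_equal(mean_interval_error(single), 5)
  # order invariance
  expect_equal(mean_interval_error(cases[sample.int(60), ]),
               mean_interval_error(cases))
})

test_that("policy evaluation scores each case's state through the policy", {
  cases <- test_cases()
  idx <- state_index(cases$hba1c_level, cases$bmi_level,
                     cases$activity_level, cases$alcohol_level)
  # note: the recorded recommendations are not a function of the state alone
  # (e.g. tests 48 and 60 share a state but print different intervals), so a
  # state policy is built last-occurrence-wins and checked against an
  # independent per-case recomputation
  policy <- tibble::tibble(state = 0:305, action = 1L, visited = TRUE)
  policy$action[match(idx, policy$state)] <- as.integer(cases$action_index)
  ev <- evaluate_policy(policy, cases)
  expected_action <- policy$action[match(idx, policy$state)]
  expected_match <- mapply(function(dose, k) {
    iv <- interval_of(k)
    dose >= iv$lower && dose <= iv$upper
  }, cases$actual_dose, expected_action)
  expect_identical(ev$cases$recommended_action, expected_action)
  expect_identical(ev$n_match, as.integer(sum(expected_match)))
  expect_identical(ev$n_unvisited, 0L)
  # most printed recommendations survive the collapse into a state policy
  expect_gte(ev$n_match, 50L)
  # a constant lowest-interval policy is strictly worse on this test set
  lowest <- tibble::tibble(state = 0:305, action = 1L, visited = TRUE)
  ev_low <- evaluate_policy(lowest, cases)
  expect_lt(ev_low$n_match, ev$n_match)
  expect_error(evaluate_policy(policy, cases[0, ]), "no test cases")
})

test_that("unvisited case states are scored but flagged", {
  cases <- test_cases()[1:3, ]
  policy <- tibble::tibble(state = 0:305, action = 1L, visited = FALSE)
  ev <- evaluate_policy(policy, cases)
  expect_identical(ev$n_unvisited, 3L)
  gl <- glance(ev)
  expect_identical(gl$n_unvisited, 3L)
  td <- tidy(ev)
  expect_identical(nrow(td), 3L)
  expect_s3_class(autoplot(ev), "ggplot")
})
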