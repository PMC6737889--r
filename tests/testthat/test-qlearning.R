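toy_fit <- function(n_states = 4, n_actions = 2, config = training_config()) {
  new_qlearn(n_states, n_actions, config)
}

test_that("a single update follows the Bellman increment", {
  fit <- toy_fit(4, 3)
  # alpha 1, gamma 0: update collapses to the immediate reward
  f1 <- q_update(fit, state = 2, action = 1, reward = 1, next_state = 3,
                 alpha = 1, gamma = 0)
  expect_equal(f1$q[3, 1], 1)
  expect_equal(sum(f1$q != 0), 1)
  expect_equal(f1$visits[3, 1], 1L)
  # direct substitution: 0.5 + 0.1 * (1 + 0.9 * 2 - 0.5) = 0.73
  fit$q[1, 1] <- 0.5
  fit$q[2, 2] <- 2
  f2 <- q_update(fit, state = 0, action = 1, reward = 1, next_state = 1,
                 alpha = 0.1, gamma = 0.9)
  expect_equal(f2$q[1, 1], 0.73)
  # terminal transitions do not bootstrap
  f3 <- q_update(fit, state = 0, action = 1, reward = 1, next_state = 1,
                 terminal = TRUE, alpha = 1, gamma = 0.9)
  expect_equal(f3$q[1, 1], 1)
  expect_error(q_update(fit, 0, 1, Inf, 1), "finite")
  expect_error(q_update(fit, 9, 1, 0, 1), "out of range")
})

test_that("action selection is greedy with lowest-index ties, exploring with probability epsilon", {
  fit <- toy_fit(1, 6)
  fit$q[1, ] <- c(0, 1, 0, 0, 0, 0)
  set.seed(1)
  expect_identical(replicate(20, select_action(fit, 0, epsilon = 0)),
                   rep(2L, 20))
  fit$q[1, ] <- rep(0.5, 6)
  expect_identical(select_action(fit, 0, epsilon = 0), 1L)
  # epsilon = 1: all actions uniform within 3 binomial standard errors
  set.seed(42)
  n <- 60000
  draws <- replicate(n, select_action(fit, 0, epsilon = 1))
  freq <- tabulate(draws, 6) / n
  se <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})

test_that("offline replay converges to the value-iteration fixed point", {
  set.seed(7)
  mdp <- random_deterministic_mdp(n_states = 6, n_actions = 3)
  for (gamma in c(0.5, 0.9)) {
    q_star <- value_iteration_q(mdp, gamma)
    fit <- fit_offline(mdp_transitions(mdp),
                       training_config(alpha = 1, gamma = gamma,
                                       n_epochs = 500, tolerance = 1e-9,
                                       seed = 11),
                       n_states = mdp$n_states, n_actions = mdp$n_actions)
    expect_lt(max(abs(fit$q - q_star)), 1e-6)
    # greedy policy agrees with the oracle's argmax
    expect_identical(greedy_policy(fit)$action,
                     as.integer(apply(q_star, 1, which.max)))
  }
})

test_that("offline replay handles edge cases and is seed-deterministic", {
  tr <- tibble::tibble(state = 0, action = 2, reward = 3, next_state = 1,
                       terminal = FALSE)
  fit <- fit_offline(tr, training_config(alpha = 1, gamma = 0, n_epochs = 1),
                     n_states = 2, n_actions = 2)
  expect_equal(fit$q[1, 2], 3)
  expect_equal(sum(fit$q != 0), 1)
  expect_error(fit_offline(tr[0, ], training_config()), "empty")
  set.seed(3)
  mdp <- random_deterministic_mdp(5, 2)
  cfg <- training_config(n_epochs = 5, seed = 99)
  f1 <- fit_offline(mdp_transitions(mdp), cfg, mdp$n_states, mdp$n_actions)
  f2 <- fit_offline(mdp_transitions(mdp), cfg, mdp$n_states, mdp$n_actions)
  expect_identical(f1$q, f2$q)
  expect_identical(f1$convergence, f2$convergence)
})

test_that("with gamma 0 and 1/n steps, Q converges to the mean observed reward", {
  set.seed(5)
  rewards <- rnorm(200)
  tr <- tibble::tibble(state = 0, action = 1, reward = rewards,
                       next_state = 0, terminal = FALSE)
  fit <- fit_offline(tr, training_config(gamma = 0, n_epochs = 1,
                                         alpha_schedule = "visit_inverse"),
                     n_states = 1, n_actions = 1)
  expect_equal(fit$q[1, 1], mean(rewards))
})

test_that("positive reward rescaling leaves the greedy policy unchanged", {
  set.seed(13)
  mdp <- random_deterministic_mdp(8, 3)
  cfg <- training_config(alpha = 1, gamma = 0.9, n_epochs = 400,
                         tolerance = 1e-10, seed = 4)
  f1 <- fit_offline(mdp_transitions(mdp), cfg, mdp$n_states, mdp$n_actions)
  f2 <- fit_offline(mdp_transitions(mdp, reward = 7.3 * mdp$reward), cfg,
                    mdp$n_states, mdp$n_actions)
  expect_identical(greedy_policy(f1)$action, greedy_policy(f2)$action)
})

test_that("online training learns a single-state bandit and is reproducible", {
  # deterministic one-state environment rewarding only action 3
  bandit <- local({
    t <- 0L
    list(
      reset = function() {
        t <<- 0L
        0L
      },
      step = function(action) {
        t <<- t + 1L
        list(state = 0L, reward = as.numeric(action == 3), terminal = t >= 6L)
      }
    )
  })
  cfg <- training_config(alpha = 0.5, gamma = 0, epsilon = 1, seed = 8)
  fit <- fit_online(bandit, cfg, n_episodes = 30, n_states = 1, n_actions = 6)
  expect_identical(greedy_policy(fit)$action, 3L)
  sim <- make_simulator(sim_params(visits_per_patient = 5))
  cfg2 <- training_config(seed = 21)
  f1 <- fit_online(sim, cfg2, n_episodes = 10)
  f2 <- fit_online(make_simulator(sim_params(visits_per_patient = 5)), cfg2,
                   n_episodes = 10)
  expect_identical(f1$q, f2$q)
  # zero episodes: the initialization is returned untouched
  f0 <- fit_online(sim, training_config(q_init = 0.25), n_episodes = 0)
  expect_true(all(f0$q == 0.25))
  expect_true(all(f0$visits == 0))
})

test_that("greedy policy flags unvisited states and picks unique maxima", {
  fit <- toy_fit(306, 6)
  fit$q[10, ] <- c(0, 0, 5, 0, 0, 0)
  fit$visits[10, 3] <- 4L
  pol <- greedy_policy(fit)
  expect_identical(nrow(pol), 306L)
  expect_identical(pol$action[pol$state == 9], 3L)
  expect_identical(pol$label[pol$state == 9], "[20,30)")
  expect_true(pol$visited[pol$state == 9])
  # tie rows fall back to action 1 and are flagged unvisited
  expect_identical(unique(pol$action[pol$state != 9]), 1L)
  expect_false(any(pol$visited[pol$state != 9]))
})

test_that("q-table files round-trip and tidiers summarize the fit", {
  set.seed(2)
  mdp <- random_deterministic_mdp(4, 2)
  fit <- fit_offline(mdp_transitions(mdp), training_config(n_epochs = 3),
                     mdp$n_states, mdp$n_actions)
  path <- withr::local_tempfile(fileext = ".csv")
  write_q_table(fit, path)
  expect_match(readLines(path, n = 1), "^# alpha=")
  back <- read_q_table(path)
  expect_equal(back$q, fit$q)
  expect_equal(back$visits, fit$visits)
  td <- tidy(fit)
  expect_identical(nrow(td), 8L)
  expect_equal(td$q_value[td$state == 1 & td$action == 2], fit$q[2, 2])
  gl <- glance(fit)
  expect_identical(gl$n_states, 4L)
  expect_identical(gl$n_updates, sum(fit$visits))
  expect_s3_class(autoplot(fit), "ggplot")
})
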