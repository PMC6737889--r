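# Small deterministic MDPs with an independent value-iteration oracle, used
# to check that Q-learning converges to the Bellman fixed point.

# next_state: n_states x n_actions matrix of 0-based successor states
# reward:     n_states x n_actions matrix of immediate rewards
random_deterministic_mdp <- function(n_states, n_actions) {
  list(
    n_states = n_states,
    n_actions = n_actions,
    next_state = matrix(sample(0:(n_states - 1), n_states * n_actions,
                               replace = TRUE),
                        n_states, n_actions),
    reward = matrix(stats::rnorm(n_states * n_actions), n_states, n_actions)
  )
}

# independent oracle: synchronous value iteration on Q
value_iteration_q <- function(mdp, gamma, tol = 1e-12, max_iter = 10000L) {
  q <- matrix(0, mdp$n_states, mdp$n_actions)
  for (i in seq_len(max_iter)) {
    v <- apply(q, 1, max)
    q_new <- mdp$reward + gamma * matrix(v[mdp$next_state + 1L],
                                         mdp$n_states, mdp$n_actions)
    if (max(abs(q_new - q)) < tol) return(q_new)
    q <- q_new
  }
  q
}

# exhaustive experience: one transition per (state, action) pair
mdp_transitions <- function(mdp, reward = mdp$reward) {
  tibble::tibble(
    state = rep(0:(mdp$n_states - 1), times = mdp$n_actions),
    action = rep(seq_len(mdp$n_actions), each = mdp$n_states),
    reward = as.vector(reward),
    next_state = as.vector(mdp$next_state),
    terminal = FALSE
  )
}
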