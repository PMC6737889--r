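# Tabular Q-learning: the value function is a states x actions matrix updated
# from experience tuples (s, a, r, s'). Training is either offline
# (experience replay over logged visit transitions) or online (epsilon-greedy
# interaction with a simulator). The learned policy is the row-wise argmax.

#' Q-learning training configuration
#'
#' @param alpha Learning rate in (0, 1]. Default 0.1. Ignored when
#'   `alpha_schedule = "visit_inverse"`, which uses the Robbins-Monro step
#'   `1 / n(s, a)` (the per-pair visit count), under which Q-values converge
#'   to expected returns.
#' @param gamma Discount factor in \[0, 1\] weighting future against immediate
#'   reward. Default 0.9.
#' @param epsilon Exploration probability for epsilon-greedy action selection
#'   in \[0, 1\]. Default 0.1.
#' @param n_epochs Maximum number of full sweeps over the transition set in
#'   offline training. Default 50.
#' @param q_init Initial Q-value for every state-action pair. Default 0.
#' @param tolerance Offline training stops early once the largest absolute
#'   Q change over a sweep falls below this. Default 1e-6.
#' @param seed Integer seed controlling shuffling, exploration and any
#'   simulator randomness.
#' @param alpha_schedule `"constant"` (default) or `"visit_inverse"`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(alpha = 0.1, gamma = 0.9, epsilon = 0.1,
                            n_epochs = 50L, q_init = 0, tolerance = 1e-6,
                            seed = 1L,
                            alpha_schedule = c("constant", "visit_inverse")) {
  alpha_schedule <- match.arg(alpha_schedule)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1,
    is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1,
    is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0, epsilon <= 1,
    is.numeric(n_epochs), length(n_epochs) == 1, n_epochs >= 1,
    is.numeric(q_init), length(q_init) == 1, is.finite(q_init),
    is.numeric(tolerance), length(tolerance) == 1, tolerance > 0,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(alpha = alpha, gamma = gamma, epsilon = epsilon,
         n_epochs = as.integer(n_epochs), q_init = q_init,
         tolerance = tolerance, seed = as.integer(seed),
         alpha_schedule = alpha_schedule),
    class = "training_config"
  )
}

#' Construct an untrained Q-table
#'
#' Creates a `qlearn` object with every Q-value at `config$q_init` and zero
#' visit counts, ready for incremental updates with [q_update()]. Training
#' entry points ([fit_offline()], [fit_online()]) build this internally.
#'
#' @param n_states,n_actions Dimensions of the Q-table; default to the dosing
#'   problem's 306 states and 6 actions.
#' @param config A [training_config()].
#' @param convergence Optional convergence log (per-sweep tibble).
#' @return A `qlearn` object.
#' @export
new_qlearn <- function(n_states = N_STATES, n_actions = N_ACTIONS,
                       config = training_config(), convergence = NULL) {
  structure(
    list(
      q = matrix(config$q_init, nrow = n_states, ncol = n_actions),
      visits = matrix(0L, nrow = n_states, ncol = n_actions),
      n_states = as.integer(n_states),
      n_actions = as.integer(n_actions),
      config = config,
      convergence = convergence %||%
        tibble::tibble(sweep = integer(), max_delta = numeric())
    ),
    class = "qlearn"
  )
}

#' @export
print.qlearn <- function(x, ...) {
  visited <- sum(rowSums(x$visits) > 0)
  cat("<qlearn> tabular Q-learning fit\n")
  cat("  states:", x$n_states, " actions:", x$n_actions, "\n")
  cat("  updates:", sum(x$visits), " states visited:", visited, "of",
      x$n_states, "\n")
  if (nrow(x$convergence) > 0) {
    last <- x$convergence[nrow(x$convergence), ]
    cat("  sweeps:", last$sweep, " final max |dQ|:",
        format(last$max_delta, digits = 4), "\n")
  }
  invisible(x)
}

# shared single-entry update; states are 0-based indices
q_update_value <- function(q, state, action, reward, next_state, terminal,
                           alpha, gamma) {
  bootstrap <- if (terminal) 0 else max(q[next_state + 1L, ])
  q[state + 1L, action] +
    alpha * (reward + gamma * bootstrap - q[state + 1L, action])
}

#' Apply one Q-learning update
#'
#' `Q(s, a) <- Q(s, a) + alpha * (r + gamma * max_a' Q(s', a') - Q(s, a))`;
#' terminal transitions use a zero bootstrap. Only the `(s, a)` entry changes
#' and its visit count increments.
#'
#' @param fit A `qlearn` object (see [fit_offline()] / [fit_online()]), or a
#'   fresh one from training with `n_epochs = 0` is not needed — construct via
#'   [fit_offline()] or pass any existing fit.
#' @param state,next_state 0-based flat state indices.
#' @param action Action index in `1:n_actions`.
#' @param reward Finite numeric reward.
#' @param terminal Logical; terminal transitions do not bootstrap.
#' @param alpha,gamma Learning rate and discount; default to the fit's config.
#' @return The updated `qlearn` object.
#' @export
q_update <- function(fit, state, action, reward, next_state, terminal = FALSE,
                     alpha = fit$config$alpha, gamma = fit$config$gamma) {
  stopifnot(inherits(fit, "qlearn"), length(state) == 1, length(action) == 1)
  if (!is.finite(reward)) stop("`reward` must be finite.", call. = FALSE)
  if (state < 0 || state >= fit$n_states ||
      (!terminal && (next_state < 0 || next_state >= fit$n_states))) {
    stop("state index out of range.", call. = FALSE)
  }
  if (action < 1 || action > fit$n_actions) {
    stop("action index out of range.", call. = FALSE)
  }
  fit$visits[state + 1L, action] <- fit$visits[state + 1L, action] + 1L
  if (fit$config$alpha_schedule == "visit_inverse") {
    alpha <- 1 / fit$visits[state + 1L, action]
  }
  fit$q[state + 1L, action] <-
    q_update_value(fit$q, state, action, reward, next_state, terminal,
                   alpha, gamma)
  fit
}

#' Epsilon-greedy action selection
#'
#' Draws one uniform variate: with probability `epsilon` a uniformly random
#' action is returned, otherwise the greedy action `argmax_a Q(s, a)` with
#' ties broken by the lowest action index.
#'
#' @param fit A `qlearn` object.
#' @param state 0-based flat state index.
#' @param epsilon Exploration probability; defaults to the fit's config.
#' @return An action index in `1:n_actions`.
#' @export
select_action <- function(fit, state, epsilon = fit$config$epsilon) {
  stopifnot(inherits(fit, "qlearn"), length(state) == 1,
            epsilon >= 0, epsilon <= 1)
  u <- stats::runif(1)
  if (u < epsilon) {
    sample.int(fit$n_actions, 1L)
  } else {
    which.max(fit$q[state + 1L, ])
  }
}

check_transitions <- function(transitions, n_states, n_actions) {
  required <- c("state", "action", "reward", "next_state", "terminal")
  missing_cols <- setdiff(required, names(transitions))
  if (length(missing_cols) > 0) {
    stop("`transitions` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(transitions) == 0) {
    stop("`transitions` is empty: nothing to learn from.", call. = FALSE)
  }
  if (any(!is.finite(transitions$reward))) {
    stop("non-finite reward in transitions.", call. = FALSE)
  }
  if (any(transitions$state < 0 | transitions$state >= n_states) ||
      any(!transitions$terminal &
            (transitions$next_state < 0 | transitions$next_state >= n_states))) {
    stop("state index outside 0:", n_states - 1L, call. = FALSE)
  }
  if (any(transitions$action < 1 | transitions$action > n_actions)) {
    stop("action index outside 1:", n_actions, call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a Q-table by experience replay over logged transitions
#'
#' Initializes all Q-values to `q_init`, then repeatedly sweeps the
#' transition set (shuffled each sweep, reproducibly from `config$seed`),
#' applying the Q-learning update to every transition. Stops after
#' `n_epochs` sweeps or once the largest absolute Q change within a sweep
#' drops below `config$tolerance`.
#'
#' @param transitions Tibble with columns `state`, `action`, `reward`,
#'   `next_state`, `terminal` (0-based state indices, 1-based actions), e.g.
#'   from [cohort_to_transitions()].
#' @param config A [training_config()].
#' @param n_states,n_actions Dimensions of the Q-table. Defaults are the
#'   dosing problem's 306 states and 6 actions.
#' @return A `qlearn` object; its `convergence` element records per-sweep
#'   maximum absolute Q change.
#' @export
fit_offline <- function(transitions, config = training_config(),
                        n_states = N_STATES, n_actions = N_ACTIONS) {
  check_transitions(transitions, n_states, n_actions)
  set.seed(config$seed)
  q <- matrix(config$q_init, nrow = n_states, ncol = n_actions)
  visits <- matrix(0L, nrow = n_states, ncol = n_actions)
  s <- as.integer(transitions$state) + 1L
  a <- as.integer(transitions$action)
  r <- as.numeric(transitions$reward)
  sn <- as.integer(transitions$next_state) + 1L
  term <- as.logical(transitions$terminal)
  n <- length(s)
  sweeps <- integer(0)
  deltas <- numeric(0)
  for (sweep in seq_len(config$n_epochs)) {
    max_delta <- 0
    for (i in sample.int(n)) {
      visits[s[i], a[i]] <- visits[s[i], a[i]] + 1L
      alpha <- if (config$alpha_schedule == "visit_inverse") {
        1 / visits[s[i], a[i]]
      } else {
        config$alpha
      }
      bootstrap <- if (term[i]) 0 else max(q[sn[i], ])
      delta <- alpha * (r[i] + config$gamma * bootstrap - q[s[i], a[i]])
      q[s[i], a[i]] <- q[s[i], a[i]] + delta
      max_delta <- max(max_delta, abs(delta))
    }
    sweeps <- c(sweeps, sweep)
    deltas <- c(deltas, max_delta)
    if (max_delta < config$tolerance) break
  }
  fit <- new_qlearn(n_states, n_actions, config,
                    tibble::tibble(sweep = sweeps, max_delta = deltas))
  fit$q <- q
  fit$visits <- visits
  fit
}

#' Fit a Q-table by online epsilon-greedy interaction with a simulator
#'
#' Runs `n_episodes` episodes against a simulator exposing
#' `reset() -> state` and `step(action) -> list(state, reward, terminal)`
#' (0-based states). Actions are chosen epsilon-greedily and each step applies
#' one Q-learning update. Fully reproducible from `config$seed`.
#'
#' @param simulator A list with function elements `reset` and `step`, e.g.
#'   from [make_simulator()].
#' @param config A [training_config()].
#' @param n_episodes Number of episodes to run.
#' @param n_states,n_actions Dimensions of the Q-table.
#' @return A `qlearn` object; `convergence` records the per-episode maximum
#'   absolute Q change.
#' @export
fit_online <- function(simulator, config = training_config(),
                       n_episodes = 500L,
                       n_states = N_STATES, n_actions = N_ACTIONS) {
  if (!is.list(simulator) || !is.function(simulator$reset) ||
      !is.function(simulator$step)) {
    stop("`simulator` must provide reset() and step(action) functions.",
         call. = FALSE)
  }
  set.seed(config$seed)
  q <- matrix(config$q_init, nrow = n_states, ncol = n_actions)
  visits <- matrix(0L, nrow = n_states, ncol = n_actions)
  deltas <- numeric(0)
  for (ep in seq_len(n_episodes)) {
    state <- simulator$reset()
    terminal <- FALSE
    max_delta <- 0
    while (!terminal) {
      u <- stats::runif(1)
      action <- if (u < config$epsilon) {
        sample.int(n_actions, 1L)
      } else {
        which.max(q[state + 1L, ])
      }
      outcome <- simulator$step(action)
      if (!is.list(outcome) ||
          !all(c("state", "reward", "terminal") %in% names(outcome))) {
        stop("simulator step() must return list(state, reward, terminal).",
             call. = FALSE)
      }
      visits[state + 1L, action] <- visits[state + 1L, action] + 1L
      alpha <- if (config$alpha_schedule == "visit_inverse") {
        1 / visits[state + 1L, action]
      } else {
        config$alpha
      }
      bootstrap <- if (outcome$terminal) 0 else max(q[outcome$state + 1L, ])
      delta <- alpha * (outcome$reward + config$gamma * bootstrap -
                          q[state + 1L, action])
      q[state + 1L, action] <- q[state + 1L, action] + delta
      max_delta <- max(max_delta, abs(delta))
      state <- outcome$state
      terminal <- outcome$terminal
    }
    deltas <- c(deltas, max_delta)
  }
  fit <- new_qlearn(n_states, n_actions, config,
                    tibble::tibble(sweep = seq_len(n_episodes),
                                   max_delta = deltas))
  fit$q <- q
  fit$visits <- visits
  fit
}

#' Extract the greedy dosing policy from a fitted Q-table
#'
#' For every state, the recommended action is `argmax_a Q(s, a)` with ties
#' broken by the lowest action index. States never updated during training
#' are flagged `visited = FALSE`; for those the recommendation is the
#' tie-break default and should not be trusted.
#'
#' @param fit A `qlearn` object.
#' @return A tibble with one row per state: `state`, `action`, `q_value`,
#'   `visits`, `visited`, and — for the dosing problem's 306-state space —
#'   the decoded state levels and the recommended interval `label`.
#' @export
greedy_policy <- function(fit) {
  stopifnot(inherits(fit, "qlearn"))
  action <- apply(fit$q, 1, which.max)
  out <- tibble::tibble(
    state = seq_len(fit$n_states) - 1L,
    action = as.integer(action),
    q_value = fit$q[cbind(seq_len(fit$n_states), action)],
    visits = rowSums(fit$visits),
    visited = rowSums(fit$visits) > 0
  )
  if (fit$n_states == N_STATES && fit$n_actions == N_ACTIONS) {
    out <- dplyr::left_join(
      dplyr::rename(decode_index(out$state), state = "state_index"),
      out, by = "state"
    )
    out$label <- interval_label(out$action)
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Q-table into long form
#'
#' @param x A `qlearn` object.
#' @param ... Unused.
#' @return A tibble with one row per state-action pair: `state`, `action`,
#'   `q_value`, `visits`.
#' @method tidy qlearn
#' @export
tidy.qlearn <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$n_states) - 1L, times = x$n_actions),
    action = rep(seq_len(x$n_actions), each = x$n_states),
    q_value = as.vector(x$q),
    visits = as.integer(x$visits)
  )
}

#' One-row summary of a Q-learning fit
#'
#' @param x A `qlearn` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, total updates, states visited,
#'   sweeps run and final maximum absolute Q change.
#' @method glance qlearn
#' @export
glance.qlearn <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states,
    n_actions = x$n_actions,
    n_updates = sum(x$visits),
    n_states_visited = sum(rowSums(x$visits) > 0),
    n_sweeps = if (nrow(x$convergence) > 0) max(x$convergence$sweep) else 0L,
    final_max_delta = if (nrow(x$convergence) > 0) {
      x$convergence$max_delta[nrow(x$convergence)]
    } else {
      NA_real_
    }
  )
}

#' Heatmap of a fitted Q-table
#'
#' @param object A `qlearn` object.
#' @param ... Unused.
#' @return A ggplot: states on the y axis, actions on the x axis, fill is the
#'   Q-value; unvisited pairs are blanked.
#' @method autoplot qlearn
#' @export
autoplot.qlearn <- function(object, ...) {
  df <- tidy(object)
  df$q_value[df$visits == 0] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$action), y = .data$state,
                                   fill = .data$q_value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "action (dose interval)", y = "state index",
                  fill = "Q value") +
    ggplot2::theme_minimal()
}

#' Write a fitted Q-table to delimited text
#'
#' Writes two CSV files: `<path>` with columns `state_index`, `q1`..`q6` (or
#' as many actions as fitted) and `<path>` with suffix `_visits` holding the
#' parallel visit counts. The training configuration is embedded as `#`
#' comment lines.
#'
#' @param fit A `qlearn` object.
#' @param path Output CSV path for the Q-values.
#' @return `path`, invisibly.
#' @export
write_q_table <- function(fit, path) {
  stopifnot(inherits(fit, "qlearn"))
  cfg <- fit$config
  header <- paste0(
    c("alpha", "gamma", "epsilon", "n_epochs", "q_init", "tolerance", "seed",
      "alpha_schedule"),
    "=",
    c(cfg$alpha, cfg$gamma, cfg$epsilon, cfg$n_epochs, cfg$q_init,
      cfg$tolerance, cfg$seed, cfg$alpha_schedule)
  )
  qdf <- as.data.frame(fit$q)
  names(qdf) <- paste0("q", seq_len(fit$n_actions))
  qdf <- cbind(state_index = seq_len(fit$n_states) - 1L, qdf)
  write_commented_csv(qdf, path, header)
  vdf <- as.data.frame(fit$visits)
  names(vdf) <- paste0("n", seq_len(fit$n_actions))
  vdf <- cbind(state_index = seq_len(fit$n_states) - 1L, vdf)
  write_commented_csv(vdf, visits_path(path), header)
  invisible(path)
}

visits_path <- function(path) {
  sub("(\\.[^.]*)?$", "_visits\\1", path)
}

#' Read a fitted Q-table written by [write_q_table()]
#'
#' @param path Path to the Q-value CSV; the `_visits` companion file is read
#'   if present.
#' @return A `qlearn` object (with a default config; the original
#'   configuration is recorded in the file's comment header).
#' @export
read_q_table <- function(path) {
  qdf <- utils::read.csv(path, comment.char = "#")
  q <- as.matrix(qdf[, grep("^q[0-9]+$", names(qdf)), drop = FALSE])
  fit <- new_qlearn(nrow(q), ncol(q))
  fit$q <- unname(q)
  vp <- visits_path(path)
  if (file.exists(vp)) {
    vdf <- utils::read.csv(vp, comment.char = "#")
    fit$visits <- unname(as.matrix(
      vdf[, grep("^n[0-9]+$", names(vdf)), drop = FALSE]
    ))
  }
  fit
}
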