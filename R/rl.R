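#' Single-step MDP classification environment and DQN agent
#'
#' Window classification recast as reinforcement learning: the state is a
#' preprocessed EMG window (scaled to `[-1, 1]` by the converter full
#' scale), the discrete actions are the class labels, and each episode
#' terminates after one action with reward +1 (correct) or -1
#' (incorrect). Because episodes are single-step, the Q-learning target
#' reduces to the immediate reward; the discount factor gamma = 0.99 is
#' retained in the update for fidelity to the usual DQN formulation but
#' has no effect on a terminal transition.
#'
#' The agent is a small fully connected Q-network (one ReLU hidden layer
#' on the raw window) trained by stochastic gradient descent on
#' minibatches drawn from an experience replay buffer (capacity 2000,
#' batch 32, oldest-first eviction) under linearly annealed
#' epsilon-greedy exploration (1.0 to 0.01 over 1000 steps).
#'
#' @name rl
NULL

#' MDP configuration
#'
#' @param reward_correct Reward for a correct action (default +1).
#' @param reward_incorrect Reward for an incorrect action (default -1).
#' @param gamma Discount factor (default 0.99; inert for single-step
#'   episodes).
#' @param actions Label set (default binary `c(0, 1)`, rest/flex).
#' @return An object of class `mdp_config`.
#' @export
mdp_config <- function(reward_correct = 1.0, reward_incorrect = -1.0,
                       gamma = 0.99, actions = c(0L, 1L)) {
  structure(list(reward_correct = reward_correct,
                 reward_incorrect = reward_incorrect,
                 gamma = gamma, actions = actions),
            class = "mdp_config")
}

#' Agent configuration
#'
#' @param replay_capacity Replay buffer capacity (default 2000).
#' @param batch_size Minibatch size (default 32).
#' @param epsilon_start,epsilon_end Epsilon-greedy schedule endpoints
#'   (1.0 and 0.01).
#' @param epsilon_decay_steps Steps over which epsilon anneals linearly
#'   (default 1000).
#' @param episodes Training episodes (default 200, a reduced desk scale;
#'   500 matches the full schedule).
#' @param hidden_units Hidden-layer width of the Q-network (default 32).
#' @param learning_rate SGD learning rate (default 0.05).
#' @param seed Training seed.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(replay_capacity = 2000, batch_size = 32,
                         epsilon_start = 1.0, epsilon_end = 0.01,
                         epsilon_decay_steps = 1000, episodes = 200,
                         hidden_units = 32, learning_rate = 0.05,
                         seed = 1L) {
  if (epsilon_start < 0 || epsilon_start > 1 ||
      epsilon_end < 0 || epsilon_end > 1)
    stop("epsilon must stay in [0, 1]")
  structure(list(replay_capacity = replay_capacity, batch_size = batch_size,
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 epsilon_decay_steps = epsilon_decay_steps,
                 episodes = episodes, hidden_units = hidden_units,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "agent_config")
}

#' Build the single-step classification environment
#'
#' `reset()` draws the next window (in a seed-shuffled order, cycling)
#' and returns its normalized state vector; `step(action)` returns the
#' reward and terminates the episode. Calling `step()` twice without a
#' `reset()` is an error.
#'
#' @param windows Matrix of windows (rows) as produced by [segment()].
#' @param labels Integer labels aligned with the rows.
#' @param config An [mdp_config()].
#' @param full_scale_mv Normalization half-range (mV).
#' @param seed Shuffle seed for the presentation order.
#' @return An environment object of class `mdp_env` with functions
#'   `reset`, `step`, `n`, and fields `states`, `labels`.
#' @export
make_env <- function(windows, labels, config = mdp_config(),
                     full_scale_mv = 5.0, seed = 1L) {
  stopifnot(is.matrix(windows), nrow(windows) == length(labels))
  if (!all(labels %in% config$actions))
    stop("labels outside the configured action set")
  states <- pmin(pmax(windows / full_scale_mv, -1), 1)
  old <- .Random.seed_save()
  set.seed(seed)
  order_idx <- sample(nrow(states))
  .Random.seed_restore(old)
  pos <- 0L
  current <- NA_integer_
  in_episode <- FALSE
  env <- new.env()
  env$reset <- function() {
    pos <<- pos %% length(order_idx) + 1L
    current <<- order_idx[pos]
    in_episode <<- TRUE
    states[current, ]
  }
  env$step <- function(action) {
    if (!in_episode)
      stop("episode already terminated: call reset() before step()")
    if (!action %in% config$actions)
      stop("action outside the action set")
    in_episode <<- FALSE
    r <- if (action == labels[current]) config$reward_correct
         else config$reward_incorrect
    list(reward = r, terminal = TRUE, label = labels[current])
  }
  env$n <- function() nrow(states)
  env$states <- states
  env$labels <- labels
  env$config <- config
  class(env) <- c("mdp_env", "environment")
  env
}

#' Epsilon-greedy schedule
#'
#' Linear decay from `epsilon_start` to `epsilon_end` over
#' `epsilon_decay_steps`, constant afterwards.
#'
#' @param step_index 0-based step counter.
#' @param agent An [agent_config()].
#' @return Epsilon in `[epsilon_end, epsilon_start]`.
#' @export
epsilon <- function(step_index, agent = agent_config()) {
  if (any(step_index < 0)) stop("step_index must be >= 0")
  frac <- pmin(step_index / agent$epsilon_decay_steps, 1)
  agent$epsilon_start + frac * (agent$epsilon_end - agent$epsilon_start)
}

# Q-network: one ReLU hidden layer, linear output (one unit per action).
qnet_init <- function(n_in, n_hidden, n_actions) {
  list(W1 = matrix(stats::rnorm(n_in * n_hidden, 0, sqrt(2 / n_in)),
                   n_in, n_hidden),
       b1 = numeric(n_hidden),
       W2 = matrix(stats::rnorm(n_hidden * n_actions, 0,
                                sqrt(1 / n_hidden)),
                   n_hidden, n_actions),
       b2 = numeric(n_actions))
}

qnet_forward <- function(net, X) {
  H <- pmax(X %*% net$W1 + matrix(net$b1, nrow(X), length(net$b1),
                                  byrow = TRUE), 0)
  list(H = H,
       Q = H %*% net$W2 + matrix(net$b2, nrow(X), length(net$b2),
                                 byrow = TRUE))
}

# One SGD step on the squared TD error of the taken actions.
qnet_update <- function(net, X, actions, targets, lr) {
  fw <- qnet_forward(net, X)
  n <- nrow(X)
  dQ <- matrix(0, n, ncol(fw$Q))
  idx <- cbind(seq_len(n), actions)
  dQ[idx] <- 2 * (fw$Q[idx] - targets) / n
  dW2 <- t(fw$H) %*% dQ
  db2 <- colSums(dQ)
  dH <- dQ %*% t(net$W2)
  dH[fw$H <= 0] <- 0
  dW1 <- t(X) %*% dH
  db1 <- colSums(dH)
  net$W1 <- net$W1 - lr * dW1
  net$b1 <- net$b1 - lr * db1
  net$W2 <- net$W2 - lr * dW2
  net$b2 <- net$b2 - lr * db2
  net
}

#' Train a DQN agent on a single-step classification environment
#'
#' Standard DQN loop specialised to one-step episodes: act
#' epsilon-greedily, store `(state, action, reward)` in the replay buffer
#' (oldest-first eviction at capacity), and after each episode fit one
#' minibatch by SGD on the squared TD error. Terminal transitions make
#' the TD target equal the reward, so the discount factor never enters.
#' Updates begin once the buffer holds one full batch (warm-up).
#'
#' @param env A [make_env()] environment.
#' @param agent An [agent_config()].
#' @return An object of class `dqn_policy` with the trained network, the
#'   per-episode reward log, and the action set.
#' @export
train_dqn <- function(env, agent = agent_config()) {
  stopifnot(inherits(env, "mdp_env"))
  actions <- env$config$actions
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(agent$seed)
  net <- qnet_init(ncol(env$states), agent$hidden_units, length(actions))
  buf_s <- matrix(0, agent$replay_capacity, ncol(env$states))
  buf_a <- integer(agent$replay_capacity)
  buf_r <- numeric(agent$replay_capacity)
  buf_n <- 0L; buf_pos <- 0L
  rewards <- numeric(agent$episodes)
  for (ep in seq_len(agent$episodes)) {
    s <- env$reset()
    eps <- epsilon(ep - 1, agent)
    a_idx <- if (stats::runif(1) < eps) sample(length(actions), 1)
             else which.max(qnet_forward(net, matrix(s, 1))$Q)
    out <- env$step(actions[a_idx])
    rewards[ep] <- out$reward
    buf_pos <- buf_pos %% agent$replay_capacity + 1L  # oldest-first eviction
    buf_s[buf_pos, ] <- s
    buf_a[buf_pos] <- a_idx
    buf_r[buf_pos] <- out$reward
    buf_n <- min(buf_n + 1L, agent$replay_capacity)
    if (buf_n >= agent$batch_size) {
      pick <- sample(buf_n, agent$batch_size)
      net <- qnet_update(net, buf_s[pick, , drop = FALSE], buf_a[pick],
                         buf_r[pick], agent$learning_rate)
    }
  }
  structure(list(net = net, actions = actions, reward_log = rewards,
                 agent = agent),
            class = "dqn_policy")
}

#' @export
print.dqn_policy <- function(x, ...) {
  cat(sprintf("<dqn_policy> %d actions, %d episodes trained, final-50 mean reward %.2f\n",
              length(x$actions), length(x$reward_log),
              mean(utils::tail(x$reward_log, 50))))
  invisible(x)
}

#' Greedy-policy classification accuracy
#'
#' @param policy A `dqn_policy` (or any function mapping a state vector
#'   to an action).
#' @param windows Matrix of windows.
#' @param labels Integer labels.
#' @param full_scale_mv Normalization half-range (mV); must match
#'   training.
#' @param greedy When FALSE, actions are drawn uniformly at random
#'   (the pure-exploration control).
#' @param seed Seed for the random control.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
evaluate_policy <- function(policy, windows, labels, full_scale_mv = 5.0,
                            greedy = TRUE, seed = 1L) {
  if (is.function(policy)) {
    pred <- apply(windows, 1, policy)
    return(mean(pred == labels))
  }
  stopifnot(inherits(policy, "dqn_policy"))
  states <- pmin(pmax(windows / full_scale_mv, -1), 1)
  if (!greedy) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pred <- policy$actions[sample(length(policy$actions), nrow(states),
                                  replace = TRUE)]
    return(mean(pred == labels))
  }
  q <- qnet_forward(policy$net, states)$Q
  pred <- policy$actions[max.col(q, ties.method = "first")]
  mean(pred == labels)
}
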