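#' Asymmetric reward specification for imbalanced pixel classification
#'
#' The reward prioritizes the minority (lung) class: a minority-class pixel
#' earns +1 when classified correctly and -1 when misclassified, while a
#' majority-class pixel earns only +/- `lambda`, with `lambda` a positive
#' constant below one.
#'
#' @param lambda Majority-class reward magnitude, in (0, 1).
#' @param minority_labels,majority_labels Disjoint label sets.
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(lambda = 0.5, minority_labels = 1L,
                        majority_labels = 0L) {
  check_number(lambda, "lambda", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (length(intersect(minority_labels, majority_labels)) > 0)
    stopf("minority and majority label sets must be disjoint")
  structure(list(lambda = lambda, minority_labels = minority_labels,
                 majority_labels = majority_labels), class = "reward_spec")
}

#' Per-pixel asymmetric reward
#'
#' A pixel of the minority class earns +1 when classified correctly and -1
#' when misclassified; a majority-class pixel earns only +/- `lambda`. The
#' class that scales the reward is the pixel's true class, so minority-pixel
#' mistakes carry the full penalty and the minority class receives `1/lambda`
#' times the gradient weight of the majority class.
#'
#' @param action Predicted label(s).
#' @param truth True label(s), same length or length 1.
#' @param spec A [reward_spec()].
#' @return Numeric vector of rewards in `{+1, -1, +lambda, -lambda}`.
#' @export
reward <- function(action, truth, spec) {
  stopifnot(inherits(spec, "reward_spec"))
  known <- c(spec$minority_labels, spec$majority_labels)
  if (!all(action %in% known) || !all(truth %in% known))
    stopf("unknown label: actions and truths must lie in the declared label sets")
  if (length(truth) == 1L) truth <- rep(truth, length(action))
  minor <- truth %in% spec$minority_labels
  correct <- action == truth
  ifelse(minor, ifelse(correct, 1, -1),
         ifelse(correct, spec$lambda, -spec$lambda))
}

#' Interval clipping
#'
#' `clip(x, a, b) = max(a, min(b, x))`, elementwise in `x`.
#'
#' @param x Numeric vector.
#' @param a,b Lower and upper bounds, `a <= b` (vectorized).
#' @return Clipped values.
#' @export
clip <- function(x, a, b) {
  if (any(a > b)) stopf("lower bound exceeds upper bound")
  pmax(a, pmin(b, x))
}

#' Discounted return of a reward sequence
#'
#' `sum_t gamma^t r_t` with `t` starting at 0.
#'
#' @param rewards Non-empty numeric vector.
#' @param gamma Discount factor in `[0, 1]`.
#' @return A number.
#' @export
discounted_return <- function(rewards, gamma) {
  if (length(rewards) == 0) stopf("empty reward sequence")
  check_number(gamma, "gamma", lower = 0, upper = 1)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}

#' One-step advantage
#'
#' The per-pixel episode is a single decision with immediate reward, so the
#' advantage specializes to `r - V(s)` with `V` from a value head.
#'
#' @param r Reward(s).
#' @param v Value estimate(s).
#' @return `r - v`.
#' @export
advantage_onestep <- function(r, v) r - v

#' Per-pixel transition batch
#'
#' One record per classified pixel: sampled action, true label, reward,
#' advantage and the action's probability under the current, previous and
#' behavior policies. Probabilities are floored at `1e-8` before any ratio is
#' formed.
#'
#' @param action,label Integer vectors.
#' @param reward,advantage Numeric vectors.
#' @param prob_current,prob_old,prob_behavior Action probabilities in (0, 1].
#' @param state Optional state reference (kept as-is).
#' @return An object of class `transition_batch`.
#' @export
transition_batch <- function(action, label, reward, advantage,
                             prob_current, prob_old, prob_behavior,
                             state = NULL) {
  n <- length(action)
  lens <- c(length(label), length(reward), length(advantage),
            length(prob_current), length(prob_old), length(prob_behavior))
  if (any(lens != n)) stopf("all transition fields must have equal length")
  probs <- c(prob_current, prob_old, prob_behavior)
  if (any(probs <= 0) || any(probs > 1))
    stopf("probabilities must lie in (0, 1]")
  structure(list(action = action, label = label, reward = reward,
                 advantage = advantage,
                 prob_current = pmax(prob_current, 1e-8),
                 prob_old = pmax(prob_old, 1e-8),
                 prob_behavior = pmax(prob_behavior, 1e-8),
                 state = state), class = "transition_batch")
}

#' PPO configuration
#'
#' Defaults follow the tuned hyperparameters of the method: discount
#' `gamma = 0.68` (used only by [discounted_return()]; the per-pixel episode
#' is one-step), clip `epsilon`, KL bound `delta` used as a diagnostic, replay
#' capacity and the behavior-policy snapshot interval.
#'
#' @param epsilon Clip parameter in (0, 1).
#' @param gamma Discount factor in `[0, 1]`.
#' @param delta KL diagnostic bound (> 0).
#' @param buffer_capacity Replay buffer capacity (records).
#' @param snapshot_every Generator updates between behavior-policy snapshots.
#' @return An object of class `ppo_config`.
#' @export
ppo_config <- function(epsilon = 0.2, gamma = 0.68, delta = 0.01,
                       buffer_capacity = 64L, snapshot_every = 4L) {
  check_number(epsilon, "epsilon", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(gamma, "gamma", lower = 0, upper = 1)
  check_number(delta, "delta", lower = 0, strict_lower = TRUE)
  check_number(buffer_capacity, "buffer_capacity", lower = 1)
  check_number(snapshot_every, "snapshot_every", lower = 1)
  structure(list(epsilon = epsilon, gamma = gamma, delta = delta,
                 buffer_capacity = as.integer(buffer_capacity),
                 snapshot_every = as.integer(snapshot_every)),
            class = "ppo_config")
}

#' On-policy clipped surrogate objective
#'
#' Mean over records of `min(rho * A, clip(rho, 1 - eps, 1 + eps) * A)` with
#' `rho = pi / pi_old`.
#'
#' @param batch A [transition_batch()].
#' @param eps Clip parameter.
#' @return The surrogate value (to be maximized).
#' @export
surrogate_onpolicy <- function(batch, eps) {
  stopifnot(inherits(batch, "transition_batch"))
  rho <- batch$prob_current / batch$prob_old
  a <- batch$advantage
  mean(pmin(rho * a, clip(rho, 1 - eps, 1 + eps) * a))
}

#' Off-policy clipped surrogate objective
#'
#' Mean over records of
#' `min((pi/mu) A, clip(pi/mu, (pi_old/mu)(1 - eps), (pi_old/mu)(1 + eps)) A)`:
#' the on-policy clip bounds corrected by the factor `pi_old / mu`. When the
#' behavior policy equals the previous policy this reduces exactly to
#' [surrogate_onpolicy()].
#'
#' @inheritParams surrogate_onpolicy
#' @return The surrogate value (to be maximized).
#' @export
surrogate_offpolicy <- function(batch, eps) {
  stopifnot(inherits(batch, "transition_batch"))
  rho <- batch$prob_current / batch$prob_behavior
  corr <- batch$prob_old / batch$prob_behavior
  a <- batch$advantage
  mean(pmin(rho * a, clip(rho, corr * (1 - eps), corr * (1 + eps)) * a))
}

kl_discrete <- function(p, q) {
  keep <- p > 0
  sum(p[keep] * log(p[keep] / pmax(q[keep], 1e-12)))
}

#' KL divergence diagnostics for off-policy updates
#'
#' Computes, over a set of per-state discrete action distributions, the mean
#' KL from `pi_old` to `pi`, the mean square-root KL from `mu` to `pi_old`
#' and from `pi_old` to `pi`, and the trust-region style constraint value
#' `sqrtKL(mu, pi_old) * sqrtKL(pi_old, pi) + KL(pi_old, pi) <= delta`.
#' The constraint is reported, not enforced: the clipped surrogate is the
#' operative mechanism.
#'
#' @param p_mu,p_old,p_cur Matrices, one state per row, rows summing to 1.
#' @param delta Diagnostic bound.
#' @return List with `mean_kl_old_cur`, `mean_sqrt_kl_mu_old`,
#'   `mean_sqrt_kl_old_cur`, `constraint_lhs`, `within_delta`.
#' @export
kl_diagnostics <- function(p_mu, p_old, p_cur, delta) {
  p_mu <- rbind(p_mu); p_old <- rbind(p_old); p_cur <- rbind(p_cur)
  for (m in list(p_mu, p_old, p_cur))
    if (any(abs(rowSums(m) - 1) > 1e-6))
      stopf("distributions must be normalized per state")
  n <- nrow(p_mu)
  kl_oc <- vapply(seq_len(n), function(i) kl_discrete(p_old[i, ], p_cur[i, ]),
                  numeric(1))
  kl_mo <- vapply(seq_len(n), function(i) kl_discrete(p_mu[i, ], p_old[i, ]),
                  numeric(1))
  mean_kl_old_cur <- mean(kl_oc)
  mean_sqrt_kl_mu_old <- mean(sqrt(pmax(kl_mo, 0)))
  mean_sqrt_kl_old_cur <- mean(sqrt(pmax(kl_oc, 0)))
  lhs <- mean_sqrt_kl_mu_old * mean_sqrt_kl_old_cur + mean_kl_old_cur
  list(mean_kl_old_cur = mean_kl_old_cur,
       mean_sqrt_kl_mu_old = mean_sqrt_kl_mu_old,
       mean_sqrt_kl_old_cur = mean_sqrt_kl_old_cur,
       constraint_lhs = lhs, within_delta = lhs <= delta)
}

#' Bounded FIFO replay buffer
#'
#' Stores per-pixel transition records (state reference, action, behavior
#' probability, reward). When full, the oldest records are evicted first.
#' Sampling is seed-deterministic.
#'
#' @param capacity Maximum number of records.
#' @return An object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity) {
  check_number(capacity, "capacity", lower = 1)
  env <- new.env(parent = emptyenv())
  env$capacity <- as.integer(capacity)
  env$records <- list()
  class(env) <- "replay_buffer"
  env
}

#' @rdname replay_buffer
#' @param buffer A replay buffer.
#' @param record Arbitrary record (list) to store.
#' @export
buffer_push <- function(buffer, record) {
  stopifnot(inherits(buffer, "replay_buffer"))
  buffer$records[[length(buffer$records) + 1L]] <- record
  if (length(buffer$records) > buffer$capacity)
    buffer$records <- buffer$records[-seq_len(length(buffer$records) -
                                                buffer$capacity)]
  invisible(buffer)
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buffer) length(buffer$records)

#' @rdname replay_buffer
#' @param n Number of records to sample (without replacement, capped at size).
#' @param seed Sampling seed.
#' @export
buffer_sample <- function(buffer, n, seed) {
  stopifnot(inherits(buffer, "replay_buffer"))
  m <- length(buffer$records)
  if (m == 0) return(list())
  idx <- with_seed(seed, sample.int(m, min(n, m)))
  buffer$records[idx]
}
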