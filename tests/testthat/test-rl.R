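test_that("asymmetric reward follows the pixel-class truth table", {
  spec <- reward_spec(lambda = 0.3)
  # minority-class pixels carry the full +/-1 incentive
  expect_equal(reward(1L, 1L, spec), 1)
  expect_equal(reward(0L, 1L, spec), -1)
  # majority-class pixels earn only +/- lambda
  expect_equal(reward(0L, 0L, spec), 0.3)
  expect_equal(reward(1L, 0L, spec), -0.3)
  # reward image is exactly {+1, -1, +lambda, -lambda}
  acts <- c(0L, 0L, 1L, 1L); ys <- c(0L, 1L, 0L, 1L)
  expect_setequal(reward(acts, ys, spec), c(0.3, -1, -0.3, 1))
  expect_error(reward(2L, 1L, spec), "unknown label")
  expect_error(reward_spec(lambda = 1.5), "lambda")
  expect_error(reward_spec(minority_labels = 1, majority_labels = 1),
               "disjoint")
})

test_that("clip and discounted return are exact", {
  expect_equal(clip(5, 0, 1), 1)
  expect_equal(clip(-2, 0, 1), 0)
  expect_equal(clip(0.5, 0, 1), 0.5)
  expect_error(clip(0, 2, 1), "bound")
  expect_equal(discounted_return(c(3, 9, 9), 0), 3)
  expect_equal(discounted_return(c(1, 1, 1), 1), 3)
  expect_equal(discounted_return(c(1, 1, 1), 0.5), 1.75)
  expect_error(discounted_return(numeric(0), 0.5), "empty")
  expect_equal(advantage_onestep(1, 0), 1)
  expect_equal(advantage_onestep(0.3, 0.3), 0)
  expect_equal(advantage_onestep(-1, 0.25), -1.25)
})

single_batch <- function(p_cur, p_old, p_mu, a = 1) {
  transition_batch(action = 1L, label = 1L, reward = 1, advantage = a,
                   prob_current = p_cur, prob_old = p_old,
                   prob_behavior = p_mu)
}

test_that("clipped surrogates match hand evaluations", {
  # ratio 1 everywhere: clip inactive, surrogate is mean advantage
  b <- transition_batch(rep(1L, 4), rep(1L, 4), rep(1, 4), c(1, -2, 0.5, 3),
                        rep(0.5, 4), rep(0.5, 4), rep(0.5, 4))
  expect_equal(surrogate_onpolicy(b, 0.2), mean(c(1, -2, 0.5, 3)))
  expect_equal(surrogate_offpolicy(b, 0.2), mean(c(1, -2, 0.5, 3)))
  # single records, hand arithmetic
  expect_equal(surrogate_onpolicy(single_batch(0.8, 0.4, 0.4), 0.2), 1.2)
  expect_equal(surrogate_onpolicy(single_batch(0.3, 0.6, 0.6, a = -1), 0.2),
               -0.8)
  # off-policy: pi=0.6, pi_old=0.5, mu=0.25 -> ratio 2.4, bounds (1.6, 2.4)
  expect_equal(surrogate_offpolicy(single_batch(0.6, 0.5, 0.25), 0.2), 2.4)
  expect_error(transition_batch(1L, 1L, 1, 1, 0, 0.5, 0.5), "probabilities")
})

test_that("off-policy surrogate reduces to on-policy when mu == pi_old", {
  set.seed(5)
  for (k in 1:1000) {
    n <- sample(1:8, 1)
    p_old <- runif(n, 0.05, 0.95)
    b <- transition_batch(rep(1L, n), rep(1L, n), rep(1, n),
                          rnorm(n), runif(n, 0.05, 0.95), p_old, p_old)
    expect_equal(surrogate_offpolicy(b, 0.2), surrogate_onpolicy(b, 0.2))
  }
})

test_that("surrogates are order-invariant and linear in unclipped advantages", {
  set.seed(9)
  n <- 16
  b <- transition_batch(rep(1L, n), rep(1L, n), rep(1, n), rnorm(n),
                        runif(n, 0.3, 0.7), runif(n, 0.3, 0.7),
                        runif(n, 0.3, 0.7))
  perm <- sample(n)
  bp <- transition_batch(b$action[perm], b$label[perm], b$reward[perm],
                         b$advantage[perm], b$prob_current[perm],
                         b$prob_old[perm], b$prob_behavior[perm])
  expect_equal(surrogate_offpolicy(b, 0.2), surrogate_offpolicy(bp, 0.2))
  # ratios equal to 1: doubling A doubles the surrogate
  p <- runif(n, 0.2, 0.8)
  b1 <- transition_batch(rep(1L, n), rep(1L, n), rep(1, n), rnorm(n), p, p, p)
  b2 <- transition_batch(b1$action, b1$label, b1$reward, 2 * b1$advantage,
                         p, p, p)
  expect_equal(surrogate_offpolicy(b2, 0.2), 2 * surrogate_offpolicy(b1, 0.2))
})

test_that("KL diagnostics match hand computation and are non-negative", {
  p <- rbind(c(0.9, 0.1))
  q <- rbind(c(0.5, 0.5))
  out <- kl_diagnostics(p, p, q, delta = 1)
  hand <- 0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5)
  expect_equal(out$mean_kl_old_cur, hand)
  expect_equal(out$mean_sqrt_kl_mu_old, 0)
  expect_gte(out$constraint_lhs, 0)
  same <- kl_diagnostics(q, q, q, delta = 1e-9)
  expect_equal(same$constraint_lhs, 0)
  expect_true(same$within_delta)
  expect_error(kl_diagnostics(rbind(c(0.5, 0.4)), p, q, 1), "normalized")
})

test_that("replay buffer is bounded FIFO with deterministic sampling", {
  buf <- replay_buffer(3)
  for (i in 1:5) buffer_push(buf, list(id = i))
  expect_equal(buffer_size(buf), 3)
  expect_equal(vapply(buf$records, `[[`, numeric(1), "id"), c(3, 4, 5))
  s1 <- buffer_sample(buf, 2, seed = 42)
  s2 <- buffer_sample(buf, 2, seed = 42)
  expect_identical(s1, s2)
  expect_length(buffer_sample(buf, 10, seed = 1), 3)
})
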