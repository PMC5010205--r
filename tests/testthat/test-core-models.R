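test_that("rw_update follows the delta rule and tracks a stationary mean", {
  expect_equal(rw_update(0, 1, 0.1), 0.1)
  expect_equal(rw_update(2.5, 2.5, 0.3), 2.5)  # zero prediction error
  expect_error(rw_update(0, Inf, 0.1), "finite")
  expect_error(rw_update(0, 1, 1.5), "alpha")

  # long-run mean of the estimate matches the sample mean of the same
  # draws (the oracle); EWMA autocorrelation widens the band vs iid
  set.seed(11)
  r <- rnorm(10000, 2, 1)
  q <- 0
  qs <- numeric(length(r))
  for (t in seq_along(r)) qs[t] <- q <- rw_update(q, r[t], 0.1)
  tail_q <- qs[1001:10000]
  # effective SE of the EWMA mean: sd(q) * sqrt(2/alpha / n)
  se_eff <- sd(tail_q) * sqrt((2 / 0.1) / length(tail_q))
  expect_lt(abs(mean(tail_q) - mean(r)), 3 * se_eff)
})

test_that("au_update rectifies the prediction error and decays", {
  p <- learning_params(0.1, 0.05)
  w1 <- au_update(actor_weights(0, 0), r = 1, p)
  expect_equal(w1$G, 0.1)
  expect_equal(w1$N, 0)

  # zero prediction error: pure decay
  w <- actor_weights(0.8, 0.3)
  w2 <- au_update(w, r = 0.8 - 0.3, p)
  expect_equal(w2$G, 0.8 * (1 - 0.05))
  expect_equal(w2$N, 0.3 * (1 - 0.05))

  # asymmetry: positive delta leaves N on its decay path and vice versa
  w3 <- au_update(actor_weights(0.5, 0.5), r = 10, p)
  expect_equal(w3$N, 0.5 * (1 - 0.05))
  expect_gt(w3$G, 0.5)
  w4 <- au_update(actor_weights(0.5, 0.5), r = -10, p)
  expect_equal(w4$G, 0.5 * (1 - 0.05))
  expect_gt(w4$N, 0.5)

  expect_error(au_update(actor_weights(0, 0), 1,
                         learning_params(0.1, 0.1, 0.5)), "epsilon")
})

test_that("AU weights converge to sigma when beta = alpha / sqrt(2*pi)", {
  # with mu = 0 the fixed point gives G = N = S*/2 = sigma
  p <- learning_params(0.1, 0.1 / sqrt(2 * pi))
  task <- task_spec(list(gaussian_dist(0, 1)), n_trials = 300)
  ens <- run_ensemble("au", task, p, n_runs = 50, seed = 101, log = FALSE)
  G <- vapply(ens, `[[`, numeric(1), "G_final")
  N <- vapply(ens, `[[`, numeric(1), "N_final")
  expect_within_mc(G, 1)
  expect_within_mc(N, 1)
})

test_that("gen_au_update generalizes au_update and clamps at zero", {
  # epsilon = 0 reduces exactly to the AU rule
  set.seed(21)
  for (i in 1:20) {
    w <- actor_weights(runif(2, 0, 2), runif(2, 0, 2))
    r <- rnorm(1, 0, 3)
    p0 <- learning_params(0.1, 0.05, 0)
    expect_identical(gen_au_update(w, r, p0, action = 2L),
                     au_update(w, r, p0, action = 2L))
  }

  # direct substitution: delta = 0.9 - (0.2 - 0.3) = 1.0
  w <- gen_au_update(actor_weights(0.2, 0.3), r = 0.9,
                     learning_params(0.1, 0.1, 0.5))
  expect_equal(w$G, 0.28)
  expect_equal(w$N, 0.22)

  # a large negative error with a strong cross term clamps G at 0
  w <- gen_au_update(actor_weights(0, 0.5), r = -10,
                     learning_params(0.5, 0.1, 0.9))
  expect_equal(w$G, 0)
  expect_gt(w$N, 0.5)
})

test_that("acu_update uses the critic's prediction error", {
  w1 <- acu_update(actor_weights(0, 0), V = 0, r = 1, alpha = 0.1)
  expect_equal(w1$G, 0.1)
  expect_equal(w1$N, 0)

  # r = V: pure decay at rate alpha
  w2 <- acu_update(actor_weights(0.4, 0.2), V = 1, r = 1, alpha = 0.1)
  expect_equal(w2$G, 0.4 * 0.9)
  expect_equal(w2$N, 0.2 * 0.9)

  # single action, critic co-updated: S -> E|r - mu| = sigma*sqrt(2/pi)
  task <- task_spec(list(gaussian_dist(1, 2)), n_trials = 300)
  ens <- run_ensemble("acu", task, learning_params(0.1), n_runs = 50,
                      seed = 301, log = FALSE)
  expect_within_mc(final_S(ens), 2 * sqrt(2 / pi))
})

test_that("opal_update scales the error by the weight and fixes 0", {
  w1 <- opal_update(actor_weights(0.1, 0.1), V = 0, r = 1, alpha = 0.1)
  expect_equal(w1$G, 0.11)
  expect_equal(w1$N, 0.09)

  # all-zero weights are a fixed point for any prediction error
  for (r in c(-5, 0, 7)) {
    w <- opal_update(actor_weights(0, 0), V = 0, r = r, alpha = 0.1)
    expect_identical(c(w$G, w$N), c(0, 0))
  }

  # equal-mean actions: the higher-sigma action decays toward 0 faster
  task <- task_spec(list(gaussian_dist(1, 1), gaussian_dist(1, 2)),
                    n_trials = 300)
  ens <- run_ensemble("opal", task, learning_params(0.1), n_runs = 50,
                      seed = 401, log = FALSE)
  S1 <- final_S(ens, 1); S2 <- final_S(ens, 2)
  expect_lt(mean(S2), mean(S1))
})

test_that("actor_critic_update drifts while the critic converges", {
  expect_equal(actor_critic_update(0.3, V = 0.1, r = 1.1, alpha = 0.1),
               0.3 + 0.1 * 1.0)
  expect_equal(actor_critic_update(0.3, V = 2, r = 2, alpha = 0.1), 0.3)

  # decay-free actor integrates the error; critic tracks the sample mean
  set.seed(31)
  r <- rnorm(300, 1, 1)
  V <- 0; q <- 0
  for (t in seq_along(r)) {
    q <- actor_critic_update(q, V, r[t], 0.1)
    V <- critic_update(V, r[t], 0.1)
  }
  se_eff <- 1 * sqrt(0.1 / 2)  # sd of the EWMA around the mean
  expect_lt(abs(V - 1), 3 * se_eff)
})

test_that("weights stay nonnegative under every update rule", {
  set.seed(51)
  p <- learning_params(0.2, 0.1, 0.7)
  w_au <- w_acu <- w_op <- actor_weights(c(0.1, 0.1), c(0.1, 0.1))
  V <- 0.1
  for (t in 1:200) {
    r <- rnorm(1, 0, 4)
    i <- sample(2, 1)
    w_au <- gen_au_update(w_au, r, p, i)
    w_acu <- acu_update(w_acu, V, r, 0.2, i, epsilon = 0.7)
    w_op <- opal_update(w_op, V, r, 0.2, i)
    V <- critic_update(V, r, 0.2)
    for (w in list(w_au, w_acu, w_op)) {
      expect_true(all(w$G >= 0))
      expect_true(all(w$N >= 0))
    }
  }
})

test_that("removing the rectification asymmetry destroys spread coding", {
  # counterfactual symmetric rule (thresholds dropped, weights allowed
  # to go negative): S decays deterministically, independent of sigma
  sym_final_S <- function(sigma, n = 300, alpha = 0.1, beta = 0.1) {
    G <- N <- 0
    r <- rnorm(n, 0, sigma)
    for (t in seq_len(n)) {
      delta <- r[t] - (G - N)
      G2 <- G + alpha * delta - beta * G
      N2 <- N - alpha * delta - beta * N
      G <- G2; N <- N2
    }
    G + N
  }
  set.seed(61)
  s_lo <- replicate(20, sym_final_S(0.5))
  s_hi <- replicate(20, sym_final_S(4))
  expect_lt(abs(mean(s_hi) - mean(s_lo)), 1e-10)  # exactly 0 both

  # whereas the rectified rule separates the two spreads clearly
  p <- learning_params(0.1, 0.1)
  lo <- run_ensemble("au", task_spec(list(gaussian_dist(0, 0.5)), 300),
                     p, n_runs = 20, seed = 71, log = FALSE)
  hi <- run_ensemble("au", task_spec(list(gaussian_dist(0, 4)), 300),
                     p, n_runs = 20, seed = 91, log = FALSE)
  expect_gt(mean(final_S(hi)), 4 * mean(final_S(lo)))
})

test_that("converged S is monotone in sigma for AU, gen-AU and ACU", {
  sigmas <- c(0, 0.5, 1, 2, 4)
  cases <- list(list(model = "au", eps = 0), list(model = "au", eps = 0.5),
                list(model = "acu", eps = 0))
  for (cs in cases) {
    means <- vapply(seq_along(sigmas), function(i) {
      p <- learning_params(0.1, 0.1, cs$eps)
      ens <- run_ensemble(cs$model,
                          task_spec(list(gaussian_dist(1, sigmas[i])), 300),
                          p, n_runs = 20, seed = 500 + 40 * i, log = FALSE)
      mean(final_S(ens))
    }, numeric(1))
    expect_true(all(diff(means) > -0.05),
                info = paste(cs$model, "eps =", cs$eps))
  }
})
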