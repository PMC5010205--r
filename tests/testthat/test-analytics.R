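test_that("gaussian_mad and folded_normal_mean match quadrature", {
  expect_equal(gaussian_mad(0), 0)
  expect_equal(gaussian_mad(1), 0.797884560802865)  # frozen from quadrature
  expect_equal(gaussian_mad(c(1, 2, 3)), 3 * gaussian_mad(c(1, 2, 3) / 3))

  for (case in list(c(0, 1), c(1, 2), c(-2, 0.5), c(3, 1))) {
    expect_equal(folded_normal_mean(case[1], case[2]),
                 quad_abs_moment(case[1], case[2]), tolerance = 1e-8)
  }
  expect_equal(folded_normal_mean(-1.5, 0), 1.5)
  expect_equal(folded_normal_mean(0, 1), gaussian_mad(1))
})

test_that("expected_abs_dev is exact for both distribution families", {
  expect_equal(expected_abs_dev(gaussian_dist(1, 2), 0.5),
               quad_abs_moment(0.5, 2), tolerance = 1e-8)
  d <- discrete_dist(c(4, 0), c(0.25, 0.75))
  expect_equal(expected_abs_dev(d, 1), 0.25 * 3 + 0.75 * 1)
  expect_equal(expected_abs_dev(discrete_dist(2, 1), 2), 0)
})

test_that("au_fixed_points reproduces the closed forms", {
  # deterministic unit reward, alpha = beta: Q* = 0.5, S* = 0.5
  fp <- au_fixed_points(learning_params(0.1, 0.1), discrete_dist(1, 1))
  expect_equal(fp$q_star, 0.5)
  expect_equal(fp$s_star, 0.5)

  # zero-mean Gaussian: S* = (alpha/beta) * sigma * sqrt(2/pi)
  p <- learning_params(0.1, 0.02)
  for (sig in c(0.5, 1, 4)) {
    fp <- au_fixed_points(p, gaussian_dist(0, sig))
    expect_equal(fp$q_star, 0)
    expect_equal(fp$s_star, 5 * quad_abs_moment(0, sig), tolerance = 1e-8)
  }

  # generalized rule: direct substitution
  fp <- au_fixed_points(learning_params(0.1, 0.1, 0.5), gaussian_dist(1, 0))
  expect_equal(fp$q_star, 0.6)
  expect_equal(fp$s_star, 0.2)
})

test_that("the S* formula approaches proportionality as beta/alpha -> 0", {
  # relative bias of S* * beta / alpha vs the true deviation shrinks
  d <- gaussian_dist(1, 1)
  target <- expected_abs_dev(d, 1)  # E|r - mu|
  bias <- vapply(c(0.1, 0.05, 0.02, 0.005), function(b) {
    fp <- au_fixed_points(learning_params(0.1, b), d)
    abs(fp$s_star * b / 0.1 - target) / target
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("gen_au_clamp_prob flags where the closed form breaks down", {
  expect_equal(gen_au_clamp_prob(learning_params(0.1, 0.1),
                                 gaussian_dist(1, 2)), 0)
  # deterministic positive reward with a cross term: N* < 0, always invalid
  expect_equal(gen_au_clamp_prob(learning_params(0.1, 0.1, 0.5),
                                 gaussian_dist(1, 0)), 1)
  # known-frequent clamping: mean-dominated Gaussian with strong cross term
  expect_gt(gen_au_clamp_prob(learning_params(0.1, 0.1, 0.5),
                              gaussian_dist(1, 2)), 0.05)
  # symmetric zero-mean case: clamping is negligible
  expect_lt(gen_au_clamp_prob(learning_params(0.1, 0.1, 0.5),
                              gaussian_dist(0, 1)), 1e-3)
})

test_that("acu_fixed_points computes advantages and deviations", {
  # single action: V* = mu, Q* = 0, S* = sigma * sqrt(2/pi)
  fp <- acu_fixed_points(list(gaussian_dist(3, 2)))
  expect_equal(fp$v_star, 3)
  expect_equal(fp$q_star, 0)
  expect_equal(fp$s_star, gaussian_mad(2))

  # equal means, sigma ratio 2, even choice: S* ratio is 2
  fp2 <- acu_fixed_points(list(gaussian_dist(1, 1), gaussian_dist(1, 2)),
                          p_star = c(0.5, 0.5))
  expect_equal(fp2$s_star[2] / fp2$s_star[1], 2)

  # dominated action: V* tracks the chosen one
  fp3 <- acu_fixed_points(list(gaussian_dist(0, 1), gaussian_dist(1, 1)),
                          p_star = c(0, 1))
  expect_equal(fp3$v_star, 1)
  expect_equal(fp3$q_star, c(-1, 0))

  expect_error(acu_fixed_points(list(gaussian_dist(0, 1),
                                     gaussian_dist(1, 1)),
                                p_star = c(0.7, 0.7)), "sum to 1")
})

test_that("acu_solve_fixed_points is self-consistent and simulation-backed", {
  dists <- list(gaussian_dist(0.5, 1), gaussian_dist(1, 2))
  pol <- choice_policy(1, 1)
  fp <- acu_solve_fixed_points(dists, pol)
  w <- actor_weights(fp$g_star, fp$n_star)
  expect_equal(softmax_choice(w, pol)$P, fp$p_star, tolerance = 1e-8)
  expect_equal(fp$v_star, sum(fp$p_star * c(0.5, 1)))

  # long simulation hovers near the solved stationary choice rates;
  # exact equality is not expected (E[softmax(w)] != softmax(E[w]) for
  # fluctuating weights), so the band is absolute
  ens <- run_ensemble("acu", task_spec(dists, n_trials = 2000),
                      learning_params(0.1), pol, n_runs = 20, seed = 603)
  p2 <- vapply(ens, function(l) mean(l$action[1001:2000] == 2L), numeric(1))
  expect_lt(abs(mean(p2) - fp$p_star[2]), 0.06)
})

test_that("receptor occupancy follows the binding curve", {
  expect_equal(receptor_occupancy(10, 10), 0.5)     # half-maximal at EC50
  expect_equal(receptor_occupancy(60, 10), 6 / 7)   # D2 at baseline
  expect_equal(receptor_occupancy(60, 1000), 60 / 1060)  # D1 at baseline
  C <- c(1, 10, 60, 100, 1000, 1e5)
  occ <- receptor_occupancy(C, 1000)
  expect_true(all(diff(occ) > 0))
  expect_true(all(occ > 0 & occ < 1))
})
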