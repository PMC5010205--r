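# Shared oracles and fixtures, built in code at test time.

# E|X| for X ~ N(mu, sigma) by numerical quadrature, independent of the
# closed form in the package.
quad_abs_moment <- function(mu, sigma) {
  stats::integrate(function(x) abs(x) * stats::dnorm(x, mu, sigma),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# Exact stationary mean of S for the AU family, refining the fixed-point
# formula by accounting for the stationary fluctuation of Q (Q is an
# exactly linear AR(1), so its stationary law is Gaussian and E|r - Q|
# has a folded-normal closed form with inflated scale).  Valid only when
# the clamp at 0 is inactive.  Used to check the simulator itself.
stationary_s_mean <- function(alpha, beta, epsilon, mu, sigma) {
  a1 <- alpha * (1 + epsilon)
  q_star <- a1 / (a1 + beta) * mu
  var_q <- if (sigma == 0) 0 else
    a1^2 * sigma^2 / (1 - (1 - a1 - beta)^2)
  alpha * (1 - epsilon) / beta *
    folded_normal_mean(mu - q_star, sqrt(sigma^2 + var_q))
}

# run-mean +/- k * MC standard error band check
expect_within_mc <- function(values, target, k = 3, floor = 1e-8) {
  se <- stats::sd(values) / sqrt(length(values))
  expect_lt(abs(mean(values) - target), k * se + floor)
}

final_S <- function(ens, action = 1L)
  vapply(ens, function(l) l$G_final[action] + l$N_final[action], numeric(1))
final_Q <- function(ens, action = 1L)
  vapply(ens, function(l) l$G_final[action] - l$N_final[action], numeric(1))
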