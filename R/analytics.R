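#' Mean absolute deviation of a Gaussian
#'
#' For `r ~ N(mu, sigma)`, `E|r - mu| = sigma * sqrt(2/pi)`; the linear
#' relation that lets the summed weights `G + N`, which converge to a
#' scaled mean absolute deviation, serve as an estimate of the reward
#' standard deviation.
#'
#' @param sigma Standard deviation, `>= 0`.
#' @return `sigma * sqrt(2/pi)`.
#' @examples
#' gaussian_mad(1)  # 0.7978846
#' @export
gaussian_mad <- function(sigma) {
  stopifnot(is.numeric(sigma), all(sigma >= 0))
  sigma * sqrt(2 / pi)
}

#' Mean of the folded normal, E|X| for X ~ N(mu, sigma)
#'
#' Closed form
#' `sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2)) + mu * (2 pnorm(mu/sigma) - 1)`;
#' reduces to `|mu|` when `sigma = 0` and to [gaussian_mad()] when
#' `mu = 0`.
#'
#' @param mu Location.
#' @param sigma Scale, `>= 0`.
#' @return `E|X|`.
#' @export
folded_normal_mean <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), all(sigma >= 0))
  out <- ifelse(sigma == 0, abs(mu),
                sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
                  mu * (2 * stats::pnorm(mu / sigma) - 1))
  as.numeric(out)
}

#' Expected absolute deviation of a reward distribution from a center
#'
#' `E|r - center|`, evaluated noise-free: the folded-normal closed form
#' for Gaussian distributions and exact enumeration for discrete ones.
#' This is the expectation entering every fixed-point predictor of the
#' summed weights.
#'
#' @param dist A [gaussian_dist()] or [discrete_dist()].
#' @param center The reference point (e.g. a fixed-point `Q*` or `V*`).
#' @return `E|r - center|`.
#' @export
expected_abs_dev <- function(dist, center) {
  stopifnot(inherits(dist, "reward_dist"))
  check_scalar(center, "center")
  if (dist$type == "gaussian") {
    folded_normal_mean(dist$mu - center, dist$sigma)
  } else {
    sum(dist$probs * abs(dist$outcomes - center))
  }
}

#' Stochastic fixed points of the (generalized) AU model
#'
#' For a single action rewarded from `dist`, with learning rate `alpha`,
#' decay `beta` and cross term `epsilon`, the difference and sum of the
#' weights fluctuate around
#' `Q* = alpha (1 + epsilon) / (alpha (1 + epsilon) + beta) * E[r]` and
#' `S* = alpha (1 - epsilon) / beta * E|r - Q*|`.
#' With `epsilon = 0` these are the AU fixed points; `S*` is then
#' `alpha/beta` times the mean absolute deviation of the reward around
#' `Q*`, so when `Q*` is close to the mean reward (low `beta/alpha`, or
#' spread large relative to mean), `S*` is proportional to the reward
#' spread.
#'
#' The derivation ignores the clamp of negative weights at 0; it is exact
#' only where the clamp is inactive at stationarity.  Use
#' [gen_au_clamp_prob()] to check; [au_update()] (`epsilon = 0`) never
#' clamps.
#'
#' @param params [learning_params()].
#' @param dist A [gaussian_dist()] or [discrete_dist()].
#' @return A `fixed_point` list with `q_star`, `s_star`, and the implied
#'   `g_star = (s_star + q_star)/2`, `n_star = (s_star - q_star)/2`.
#' @examples
#' au_fixed_points(learning_params(0.1, 0.1), discrete_dist(1, 1))
#' # q_star = 0.5, s_star = 0.5
#' @export
au_fixed_points <- function(params, dist) {
  stopifnot(inherits(params, "learning_params"),
            inherits(dist, "reward_dist"))
  a1 <- params$alpha * (1 + params$epsilon)
  q_star <- a1 / (a1 + params$beta) * dist_mean(dist)
  s_star <- params$alpha * (1 - params$epsilon) / params$beta *
    expected_abs_dev(dist, q_star)
  structure(list(q_star = q_star, s_star = s_star,
                 g_star = (s_star + q_star) / 2,
                 n_star = (s_star - q_star) / 2,
                 v_star = NA_real_),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("fixed_point:\n")
  print(unclass(x)[!vapply(x, function(v) all(is.na(v)), logical(1))])
  invisible(x)
}

#' Probability that the generalized AU clamp is active at stationarity
#'
#' The fixed-point formulas of [au_fixed_points()] assume weights never
#' need clamping at 0.  This helper evaluates, at the nominal fixed point
#' `(G*, N*)`, the per-trial probability that the raw generalized update
#' would drive `G` or `N` negative.  When this probability is
#' non-negligible the clamp shifts the true stationary point away from
#' the closed form (the encoding becomes biased); when it is ~0 the
#' closed form is exact.  Always 0 for `epsilon = 0`.
#'
#' @inheritParams au_fixed_points
#' @return Per-trial clamp probability at the nominal fixed point.
#' @export
gen_au_clamp_prob <- function(params, dist) {
  fp <- au_fixed_points(params, dist)
  al <- params$alpha; be <- params$beta; ep <- params$epsilon
  if (ep == 0) return(0)
  # raw updates at (G*, N*): G' < 0 requires delta < -(1-be) G* / (al ep)
  #                          N' < 0 requires delta >  (1-be) N* / (al ep)
  if (fp$g_star < 0 || fp$n_star < 0) return(1)  # closed form self-inconsistent
  thr_g <- -(1 - be) * fp$g_star / (al * ep)
  thr_n <- (1 - be) * fp$n_star / (al * ep)
  p_delta <- function(x, strict) {  # P(r - Q* < x) or P(r - Q* <= x)
    if (dist$type == "gaussian") {
      if (dist$sigma == 0) {
        d <- dist$mu - fp$q_star
        as.numeric(if (strict) d < x else d <= x)
      } else stats::pnorm(x, dist$mu - fp$q_star, dist$sigma)
    } else {
      d <- dist$outcomes - fp$q_star
      sum(dist$probs[if (strict) d < x else d <= x])
    }
  }
  # G clamps when delta < thr_g (strictly); N clamps when delta > thr_n
  p_delta(thr_g, strict = TRUE) + (1 - p_delta(thr_n, strict = FALSE))
}

#' Stochastic fixed points of the ACU model
#'
#' Given per-action reward means `mu`, standard deviations `sigma` and
#' stationary choice probabilities `p_star`, the critic settles at the
#' choice-weighted average reward `V* = sum_i P*_i mu_i`, each action's
#' weight difference at its advantage `Q*_i = mu_i - V*`, and each
#' summed weight at `S*_i = E|r_i - V*|` (folded-normal closed form for
#' Gaussian rewards, exact enumeration for discrete).  With a single
#' action, `V* = mu` and `S* = sigma * sqrt(2/pi)`.
#'
#' @param dists List of `reward_dist` objects (or a [task_spec()]).
#' @param p_star Stationary choice probability vector; defaults to 1 for
#'   a single action, otherwise required (or use
#'   [acu_solve_fixed_points()] to solve for it self-consistently).
#' @return A `fixed_point` list with vectors `q_star`, `s_star`,
#'   `g_star`, `n_star` and scalar `v_star`.
#' @export
acu_fixed_points <- function(dists, p_star = NULL) {
  if (inherits(dists, "task_spec")) dists <- dists$actions
  stopifnot(is.list(dists),
            all(vapply(dists, inherits, logical(1), "reward_dist")))
  K <- length(dists)
  if (is.null(p_star)) {
    if (K != 1L) stop("`p_star` is required for more than one action")
    p_star <- 1
  }
  stopifnot(length(p_star) == K, all(p_star >= 0))
  if (abs(sum(p_star) - 1) > 1e-8) stop("`p_star` must sum to 1")
  mu <- vapply(dists, dist_mean, numeric(1))
  v_star <- sum(p_star * mu)
  q_star <- mu - v_star
  s_star <- vapply(dists, expected_abs_dev, numeric(1), center = v_star)
  structure(list(q_star = q_star, s_star = s_star,
                 g_star = (s_star + q_star) / 2,
                 n_star = (s_star - q_star) / 2,
                 v_star = v_star, p_star = p_star),
            class = "fixed_point")
}

#' Self-consistent ACU fixed point
#'
#' The stationary choice probabilities `P*` depend on the weights through
#' the softmax, while the weights' fixed points depend on `P*` through
#' `V*`.  This solver iterates the map `P -> (V*, Q*, S*) -> softmax ->
#' P'` with damping `P <- (1 - damping) P + damping P'` until the largest
#' change falls below `tol`.
#'
#' @inheritParams acu_fixed_points
#' @param policy [choice_policy()] generating the stationary choice
#'   probabilities.
#' @param damping Step fraction in (0, 1]; 0.5 by default.
#' @param tol Convergence tolerance on `max |P' - P|`.
#' @param max_iter Iteration cap; an error is raised if it is reached
#'   without convergence.
#' @return A `fixed_point` as in [acu_fixed_points()], with the solved
#'   `p_star` and the iteration count as attribute `iterations`.
#' @export
acu_solve_fixed_points <- function(dists, policy, damping = 0.5,
                                   tol = 1e-10, max_iter = 10000L) {
  if (inherits(dists, "task_spec")) dists <- dists$actions
  stopifnot(inherits(policy, "choice_policy"), damping > 0, damping <= 1)
  K <- length(dists)
  P <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    fp <- acu_fixed_points(dists, P)
    w <- actor_weights(pmax(fp$g_star, 0), pmax(fp$n_star, 0))
    P_new <- softmax_choice(w, policy)$P
    if (max(abs(P_new - P)) < tol) {
      out <- acu_fixed_points(dists, P_new)
      attr(out, "iterations") <- it
      return(out)
    }
    P <- (1 - damping) * P + damping * P_new
  }
  stop("ACU fixed-point iteration did not converge in ", max_iter,
       " iterations")
}

#' Dopamine receptor occupancy
#'
#' Fraction of receptors bound at dopamine concentration `C`:
#' `C / (EC50 + C)`, where `EC50` is the receptor affinity (the
#' concentration giving half-maximal occupancy).  Representative
#' affinities are ~1000 nM for the low-affinity D1 receptor and ~10 nM
#' for the high-affinity D2 receptor; at a ~60 nM baseline concentration
#' D2 receptors sit near saturation while D1 receptors are mostly
#' unbound, the asymmetry that motivates the rectified learning rules.
#'
#' @param concentration Dopamine concentration `C` (nM), `> 0`.
#' @param ec50 Receptor affinity (nM), `> 0`.
#' @return Occupancy in (0, 1), strictly increasing in `C`.
#' @examples
#' receptor_occupancy(60, 10)    # D2 at baseline: 6/7
#' receptor_occupancy(60, 1000)  # D1 at baseline: ~0.057
#' @export
receptor_occupancy <- function(concentration, ec50) {
  stopifnot(is.numeric(concentration), is.numeric(ec50),
            all(concentration > 0), all(ec50 > 0))
  concentration / (ec50 + concentration)
}
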