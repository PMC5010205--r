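#' Rescorla-Wagner update of a scalar reward estimate
#'
#' The delta rule `q' = q + alpha * (r - q)`: the estimate moves toward the
#' obtained reward by a fraction `alpha` of the prediction error.
#'
#' @param q Current estimate (reward units).
#' @param r Obtained reward.
#' @param alpha Learning rate in (0, 1).
#' @return Updated estimate.
#' @examples
#' rw_update(0, 1, 0.1)  # 0.1
#' @export
rw_update <- function(q, r, alpha) {
  check_scalar(q, "q"); check_scalar(r, "r"); check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  q + alpha * (r - q)
}

#' Critic update of the state value
#'
#' The critic tracks the average reward `V` of the current state with the
#' Rescorla-Wagner rule, applied on every trial regardless of which action
#' was selected.
#'
#' @param V Current state value.
#' @inheritParams rw_update
#' @return Updated state value.
#' @export
critic_update <- function(V, r, alpha) {
  rw_update(V, r, alpha)
}

#' Standard actor-critic update of an action tendency
#'
#' The baseline (decay-free) actor rule `Q' = Q + alpha * (r - V)`: the
#' tendency to choose the action moves in proportion to the critic-based
#' prediction error.
#'
#' @param q Current tendency for the chosen action.
#' @param V Critic's state value (pre-update, i.e. the value used to compute
#'   the prediction error on this trial).
#' @inheritParams rw_update
#' @return Updated tendency.
#' @export
actor_critic_update <- function(q, V, r, alpha) {
  check_scalar(q, "q"); check_scalar(V, "V"); check_scalar(r, "r")
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  q + alpha * (r - V)
}

# internal: shared machinery of the (generalized) asymmetric actor update.
# delta is computed from the PRE-update weights of the chosen action.
gen_au_step <- function(G, N, delta, alpha, beta, epsilon) {
  pos <- max(delta, 0)
  neg <- max(-delta, 0)
  G2 <- G + alpha * (pos - epsilon * neg) - beta * G
  N2 <- N + alpha * (neg - epsilon * pos) - beta * N
  # weights are synaptic strengths: clamp any negative result at 0
  c(G = max(G2, 0), N = max(N2, 0))
}

#' Asymmetric actor-only (AU) update
#'
#' Updates the chosen action's Go/NoGo weights from the actor-based
#' prediction error `delta = r - (G - N)` through rectified half-wave
#' channels plus decay:
#' `G' = G + alpha * max(delta, 0) - beta * G` and
#' `N' = N + alpha * max(-delta, 0) - beta * N`.
#' A positive prediction error strengthens only `G`, a negative one only
#' `N`; the decay keeps both weights bounded.  For `beta < 1` the results
#' are nonnegative by construction.  Consequently `G - N` follows a
#' Rescorla-Wagner-with-decay recursion toward (a scaled) mean reward,
#' while `G + N` integrates `|delta|` and converges near a scaled mean
#' absolute deviation of the reward.
#'
#' @param w [actor_weights()] (all actions).
#' @param r Obtained reward on this trial.
#' @param params [learning_params()]; `epsilon` must be 0 (use
#'   [gen_au_update()] for the generalized rule).
#' @param action Index of the chosen action; only its weights change.
#' @return Updated [actor_weights()].
#' @examples
#' w <- actor_weights(0, 0)
#' au_update(w, r = 1, learning_params(0.1, 0.05))  # G = 0.1, N = 0
#' @export
au_update <- function(w, r, params, action = 1L) {
  stopifnot(inherits(w, "actor_weights"), inherits(params, "learning_params"))
  if (params$epsilon != 0)
    stop("au_update() requires epsilon = 0; use gen_au_update()")
  gen_au_update(w, r, params, action)
}

#' Generalized asymmetric actor update
#'
#' Extends [au_update()] with a cross term scaled by `epsilon`: a positive
#' prediction error also weakens `N` (and a negative one weakens `G`),
#' `G' = G + alpha * (max(delta,0) - epsilon * max(-delta,0)) - beta * G`,
#' `N' = N + alpha * (max(-delta,0) - epsilon * max(delta,0)) - beta * N`.
#' Because the cross term can drive a weight below zero, any negative
#' result is set to 0 (synaptic weights cannot be negative).  With
#' `epsilon = 0` this is exactly the AU rule.
#'
#' @inheritParams au_update
#' @return Updated [actor_weights()].
#' @export
gen_au_update <- function(w, r, params, action = 1L) {
  stopifnot(inherits(w, "actor_weights"), inherits(params, "learning_params"))
  check_scalar(r, "r")
  action <- check_action(action, length(w$G))
  delta <- r - (w$G[action] - w$N[action])
  upd <- gen_au_step(w$G[action], w$N[action], delta,
                     params$alpha, params$beta, params$epsilon)
  w$G[action] <- upd[["G"]]
  w$N[action] <- upd[["N"]]
  w
}

#' Actor-critic (ACU) update of Go/NoGo weights
#'
#' Same rectified update as [au_update()] but with the prediction error
#' computed against the critic's state value, `delta = r - V`, and the
#' decay rate tied to the learning rate (`beta = alpha`):
#' `G' = G + alpha * max(delta, 0) - alpha * G`,
#' `N' = N + alpha * max(-delta, 0) - alpha * N`.
#' `G - N` then follows an advantage-learning recursion whose fixed point
#' is the action's mean reward relative to the state average, and `G + N`
#' converges to the mean absolute deviation of the action's reward around
#' the state value.  Pass `epsilon > 0` for the generalized variant (with
#' clamping at 0, as in [gen_au_update()]).
#'
#' @param w [actor_weights()].
#' @param V Critic's state value BEFORE this trial's critic update.
#' @param r Obtained reward.
#' @param alpha Learning rate in (0, 1); also used as the decay rate.
#' @param action Index of the chosen action.
#' @param epsilon Cross-term factor in `[0, 1)`, default 0.
#' @return Updated [actor_weights()].
#' @export
acu_update <- function(w, V, r, alpha, action = 1L, epsilon = 0) {
  stopifnot(inherits(w, "actor_weights"))
  check_scalar(V, "V"); check_scalar(r, "r"); check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (epsilon < 0 || epsilon >= 1) stop("`epsilon` must lie in [0, 1)")
  action <- check_action(action, length(w$G))
  delta <- r - V
  upd <- gen_au_step(w$G[action], w$N[action], delta, alpha, alpha, epsilon)
  w$G[action] <- upd[["G"]]
  w$N[action] <- upd[["N"]]
  w
}

#' Opponent actor learning (OpAL) update
#'
#' Comparator rule in which the critic-based prediction error is scaled
#' multiplicatively by the weight itself:
#' `G' = G + alpha * G * delta`, `N' = N - alpha * N * delta` with
#' `delta = r - V`.  The scaling keeps small weights near zero —
#' `G = N = 0` is a fixed point — and produces exponential growth early in
#' learning.  For large `alpha * |delta|` the literal update could cross
#' zero, so results are clamped at 0 to preserve that fixed point.
#'
#' @inheritParams acu_update
#' @return Updated [actor_weights()].
#' @export
opal_update <- function(w, V, r, alpha, action = 1L) {
  stopifnot(inherits(w, "actor_weights"))
  check_scalar(V, "V"); check_scalar(r, "r"); check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  action <- check_action(action, length(w$G))
  delta <- r - V
  w$G[action] <- max(w$G[action] * (1 + alpha * delta), 0)
  w$N[action] <- max(w$N[action] * (1 - alpha * delta), 0)
  w
}

# internal
check_action <- function(action, n_actions) {
  action <- as.integer(action)
  if (length(action) != 1L || is.na(action) || action < 1L ||
      action > n_actions)
    stop("`action` must index one of the ", n_actions, " action(s)")
  action
}
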