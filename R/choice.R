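#' Dopamine-modulated softmax over Go/NoGo weights
#'
#' Generalized softmax rule
#' `P_i = exp(a G_i - b N_i) / sum_k exp(a G_k - b N_k)`.
#' The exponents are shifted by their maximum before exponentiation; the
#' rule is exactly invariant under adding a constant to all exponents, so
#' this stabilization does not change the probabilities.
#'
#' The same probabilities can be written in terms of the mean code
#' `Q = G - N` and spread code `S = G + N` as `P_i \propto exp(U_i / 2)`
#' with the risk-sensitive utility `U_i = (a + b) Q_i - (b - a) S_i`
#' (see [utility()]): when `b > a` uncertain options are avoided, when
#' `a > b` they are sought.
#'
#' @param w [actor_weights()] over at least one action.
#' @param policy [choice_policy()] with gains `a`, `b`.
#' @return A `choice_distribution`: list with probability vector `P`
#'   (sums to 1) and utility vector `U`.
#' @examples
#' w <- actor_weights(G = c(1, 2), N = c(0.5, 1.5))
#' softmax_choice(w, choice_policy(2, 1))
#' @export
softmax_choice <- function(w, policy) {
  stopifnot(inherits(w, "actor_weights"), inherits(policy, "choice_policy"))
  if (length(w$G) < 1L) stop("at least one action is required")
  x <- policy$a * w$G - policy$b * w$N
  e <- exp(x - max(x))
  P <- e / sum(e)
  dec <- decompose_weights(w)
  structure(list(P = P, U = utility(dec$Q, dec$S, policy)),
            class = "choice_distribution")
}

#' @export
print.choice_distribution <- function(x, ...) {
  print(rbind(P = x$P, U = x$U))
  invisible(x)
}

#' Mean/spread decomposition of Go/NoGo weights
#'
#' `decompose_weights()` maps weights to the mean-reward code
#' `Q_i = G_i - N_i` and spread code `S_i = G_i + N_i`;
#' `compose_weights()` inverts the map, `G_i = (S_i + Q_i) / 2`,
#' `N_i = (S_i - Q_i) / 2`, and requires `S_i >= |Q_i|` so that both
#' weights are nonnegative.  The round trip is exact.
#'
#' @param w [actor_weights()].
#' @return For `decompose_weights`, a list with numeric vectors `Q` and
#'   `S`; for `compose_weights`, an [actor_weights()].
#' @examples
#' decompose_weights(actor_weights(1.5, 0.5))  # Q = 1, S = 2
#' compose_weights(Q = 0, S = 2)               # G = N = 1
#' @export
decompose_weights <- function(w) {
  stopifnot(inherits(w, "actor_weights"))
  list(Q = w$G - w$N, S = w$G + w$N)
}

#' @rdname decompose_weights
#' @param Q Numeric vector of mean codes.
#' @param S Numeric vector of spread codes, `S_i >= |Q_i|`.
#' @export
compose_weights <- function(Q, S) {
  stopifnot(is.numeric(Q), is.numeric(S), length(Q) == length(S))
  if (any(S < abs(Q)))
    stop("compose_weights() requires S_i >= |Q_i| (nonnegative weights)")
  actor_weights(G = (S + Q) / 2, N = (S - Q) / 2)
}

#' Risk-sensitive utility of the softmax choice rule
#'
#' `U_i = (a + b) Q_i - (b - a) S_i`, the exponent (times 2) of the choice
#' rule expressed in mean/spread coordinates.  The first term values mean
#' reward; the sign of `b - a` decides whether reward spread is penalized
#' (`b > a`, risk aversion) or rewarded (`a > b`, risk seeking).  With
#' `a = b` the spread term vanishes and choice depends on mean reward only.
#'
#' @param Q Numeric vector of mean codes (`G - N`).
#' @param S Numeric vector of spread codes (`G + N`).
#' @param policy [choice_policy()].
#' @return Numeric utility vector.
#' @export
utility <- function(Q, S, policy) {
  stopifnot(inherits(policy, "choice_policy"),
            is.numeric(Q), is.numeric(S), length(Q) == length(S))
  (policy$a + policy$b) * Q - (policy$b - policy$a) * S
}

#' Sample an action from a choice distribution
#'
#' Inverse-CDF sampling on the probability vector using the current R
#' random number stream (one uniform draw per call).
#'
#' @param P Probability vector (or a `choice_distribution`).
#' @return Integer action index.
#' @export
sample_action <- function(P) {
  if (inherits(P, "choice_distribution")) P <- P$P
  stopifnot(is.numeric(P), length(P) >= 1L, all(P >= 0))
  u <- stats::runif(1)
  cp <- cumsum(P) / sum(P)
  hit <- which(u <= cp)
  if (length(hit)) hit[1L] else length(P)
}
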