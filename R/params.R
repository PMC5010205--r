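#' Learning-rule parameters
#'
#' Bundles the constants that govern every per-trial weight update: the
#' learning rate `alpha` applied to the (rectified) reward prediction error,
#' the passive decay rate `beta` applied to each synaptic weight, and the
#' cross-term asymmetry `epsilon` of the generalized update rule.  With
#' `epsilon = 0` the generalized rule reduces to the basic asymmetric
#' (AU) rule in which a positive prediction error only strengthens Go
#' weights and a negative one only strengthens NoGo weights.
#'
#' @param alpha Learning rate, `0 < alpha < 1`.
#' @param beta Decay rate, `0 < beta < 1`.  Defaults to `alpha`, the setting
#'   used by the actor-critic (ACU) variant.
#' @param epsilon Cross-term factor, `0 <= epsilon < 1`.  When positive, a
#'   positive prediction error also weakens the NoGo weight (and vice
#'   versa), scaled by `epsilon`.
#'
#' @return An object of class `learning_params`.
#' @examples
#' learning_params(alpha = 0.1, beta = 0.05)
#' @export
learning_params <- function(alpha, beta = alpha, epsilon = 0) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
    is.numeric(beta), length(beta) == 1L, is.finite(beta),
    is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon)
  )
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (beta <= 0 || beta >= 1) stop("`beta` must lie in (0, 1)")
  if (epsilon < 0 || epsilon >= 1) stop("`epsilon` must lie in [0, 1)")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "learning_params")
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf("learning_params: alpha = %g, beta = %g, epsilon = %g\n",
              x$alpha, x$beta, x$epsilon))
  invisible(x)
}

#' Choice-gain parameters of the generalized softmax rule
#'
#' `a` and `b` weight the Go and NoGo pathways in the choice rule
#' `P_i = exp(a G_i - b N_i) / sum_k exp(a G_k - b N_k)` and act as the
#' model's proxy for tonic dopamine: dopamine excites D1 (Go) neurons and
#' inhibits D2 (NoGo) neurons, so a high dopamine level corresponds to high
#' `a` and low `b` (risk seeking) and a low level to the reverse (risk
#' aversion).  `a = b = 0` yields uniform random choice.
#'
#' @param a Go-pathway gain, `a >= 0`.
#' @param b NoGo-pathway gain, `b >= 0`.
#' @return An object of class `choice_policy`.
#' @examples
#' choice_policy(a = 2, b = 1)   # dopamine-elevated, risk seeking
#' @export
choice_policy <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a < 0 || b < 0) stop("choice gains `a` and `b` must be nonnegative")
  structure(list(a = a, b = b), class = "choice_policy")
}

#' @export
print.choice_policy <- function(x, ...) {
  cat(sprintf("choice_policy: a = %g, b = %g\n", x$a, x$b))
  invisible(x)
}

#' Go/NoGo synaptic weights
#'
#' Holds one nonnegative Go weight `G_i` and NoGo weight `N_i` per action.
#' The derived quantities `Q_i = G_i - N_i` (mean-reward code) and
#' `S_i = G_i + N_i` (reward-spread code) are available through
#' [decompose_weights()].
#'
#' @param G Numeric vector of Go weights, all `>= 0`.
#' @param N Numeric vector of NoGo weights, same length, all `>= 0`.
#' @return An object of class `actor_weights`.
#' @examples
#' actor_weights(G = c(1.5, 0.2), N = c(0.5, 0.2))
#' @export
actor_weights <- function(G, N) {
  stopifnot(is.numeric(G), is.numeric(N), length(G) == length(N),
            length(G) >= 1L)
  if (!all(is.finite(G)) || !all(is.finite(N)))
    stop("weights must be finite")
  if (any(G < 0) || any(N < 0))
    stop("synaptic weights cannot be negative")
  structure(list(G = as.numeric(G), N = as.numeric(N)),
            class = "actor_weights")
}

#' @export
print.actor_weights <- function(x, ...) {
  cat("actor_weights (", length(x$G), " action(s))\n", sep = "")
  print(rbind(G = x$G, N = x$N, Q = x$G - x$N, S = x$G + x$N))
  invisible(x)
}

# internal: single finite scalar check with a readable message
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
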