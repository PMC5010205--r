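#' Reward distributions for bandit actions
#'
#' Two families cover every task in the package: `gaussian_dist(mu, sigma)`
#' draws `r ~ N(mu, sigma)` (with `sigma = 0` a degenerate point mass at
#' `mu`), and `discrete_dist(outcomes, probs)` draws from a finite outcome
#' list.  Both use the current R random number stream, one standard-normal
#' or one uniform draw per reward respectively, so simulations are exactly
#' reproducible from a seed.
#'
#' @param mu Mean reward (reward units).
#' @param sigma Reward standard deviation, `>= 0`.
#' @return An object of class `reward_dist`.
#' @examples
#' gaussian_dist(1, 2)
#' discrete_dist(c(4, 0), c(0.25, 0.75))   # risky lever, 25% condition
#' @export
gaussian_dist <- function(mu, sigma) {
  check_scalar(mu, "mu"); check_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be nonnegative")
  structure(list(type = "gaussian", mu = mu, sigma = sigma),
            class = "reward_dist")
}

#' @rdname gaussian_dist
#' @param outcomes Numeric vector of possible rewards.
#' @param probs Probability of each outcome; must sum to 1.
#' @export
discrete_dist <- function(outcomes, probs) {
  stopifnot(is.numeric(outcomes), is.numeric(probs),
            length(outcomes) == length(probs), length(outcomes) >= 1L,
            all(is.finite(outcomes)), all(is.finite(probs)))
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must be nonnegative and sum to 1")
  structure(list(type = "discrete", outcomes = as.numeric(outcomes),
                 probs = as.numeric(probs) / sum(probs)),
            class = "reward_dist")
}

#' @export
print.reward_dist <- function(x, ...) {
  if (x$type == "gaussian") {
    cat(sprintf("reward_dist: Gaussian(mu = %g, sigma = %g)\n", x$mu, x$sigma))
  } else {
    cat("reward_dist: Discrete\n")
    print(rbind(outcome = x$outcomes, prob = x$probs))
  }
  invisible(x)
}

#' Draw one reward from a reward distribution
#'
#' Uses the current RNG stream: a Gaussian distribution consumes one
#' standard-normal draw (`mu + sigma * z`); a discrete one consumes one
#' uniform, mapped through the inverse CDF of the outcome list.
#'
#' @param dist A `reward_dist`.
#' @return A single reward.
#' @export
draw_reward <- function(dist) {
  stopifnot(inherits(dist, "reward_dist"))
  if (dist$type == "gaussian") {
    dist$mu + dist$sigma * stats::rnorm(1)
  } else {
    u <- stats::runif(1)
    cp <- cumsum(dist$probs)
    hit <- which(u <= cp)
    dist$outcomes[if (length(hit)) hit[1L] else length(cp)]
  }
}

#' Mean and standard deviation of a reward distribution
#' @param dist A `reward_dist`.
#' @return A single number.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "reward_dist"))
  if (dist$type == "gaussian") dist$mu else sum(dist$outcomes * dist$probs)
}

#' @rdname dist_mean
#' @export
dist_sd <- function(dist) {
  stopifnot(inherits(dist, "reward_dist"))
  if (dist$type == "gaussian") {
    dist$sigma
  } else {
    m <- dist_mean(dist)
    sqrt(sum(dist$probs * (dist$outcomes - m)^2))
  }
}

#' Specify a bandit task
#'
#' A task is a list of per-action reward distributions plus simulation
#' bookkeeping (trial count, run count, base seed).  Runs are seeded
#' deterministically as `seed + run - 1`, so the whole ensemble is
#' reproducible from `seed`.
#'
#' @param actions List of `reward_dist` objects, one per action.
#' @param n_trials Trials per run, `>= 1`.
#' @param n_runs Independent runs, `>= 1`.
#' @param seed Optional base seed (integer).
#' @return An object of class `task_spec`.
#' @examples
#' task_spec(list(gaussian_dist(1, 1), gaussian_dist(1, 2)), n_trials = 100)
#' @export
task_spec <- function(actions, n_trials, n_runs = 1L, seed = NULL) {
  stopifnot(is.list(actions), length(actions) >= 1L,
            all(vapply(actions, inherits, logical(1), "reward_dist")))
  n_trials <- as.integer(n_trials); n_runs <- as.integer(n_runs)
  if (is.na(n_trials) || n_trials < 1L) stop("`n_trials` must be >= 1")
  if (is.na(n_runs) || n_runs < 1L) stop("`n_runs` must be >= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(actions = actions, n_trials = n_trials, n_runs = n_runs,
                 seed = seed),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("task_spec: %d action(s), %d trial(s) x %d run(s)\n",
              length(x$actions), x$n_trials, x$n_runs))
  for (d in x$actions) print(d)
  invisible(x)
}

#' Safe-versus-risky lever task
#'
#' Two-alternative task modeled on rodent risky-choice experiments: the
#' safe lever always delivers 1 reward unit (one food pellet); the risky
#' lever delivers 4 units with probability `p_large` and nothing
#' otherwise.  The standard condition grid is
#' `p_large` in {1, 0.5, 0.25, 0.125}: the risky lever has the higher mean
#' reward in the 100% and 50% conditions, equal mean at 25%, and the lower
#' mean in the 12.5% condition.
#'
#' @param p_large Probability of the large (4-unit) reward on the risky
#'   lever.
#' @param n_trials Trials per run (default 10000, the trial count used
#'   when measuring stable choice fractions).
#' @param n_runs Independent runs.
#' @param seed Optional base seed.
#' @return A [task_spec()]; action 1 is the safe lever, action 2 the risky
#'   lever.
#' @examples
#' risky_lever_task(0.25)
#' @export
risky_lever_task <- function(p_large, n_trials = 10000L, n_runs = 1L,
                             seed = NULL) {
  check_scalar(p_large, "p_large")
  if (p_large < 0 || p_large > 1) stop("`p_large` must lie in [0, 1]")
  safe <- discrete_dist(1, 1)
  risky <- if (p_large == 1) discrete_dist(4, 1) else
    discrete_dist(c(4, 0), c(p_large, 1 - p_large))
  task_spec(list(safe = safe, risky = risky), n_trials, n_runs, seed)
}

#' Standard condition grid of the risky-lever task
#' @return The probabilities of the large reward across conditions.
#' @export
risky_lever_conditions <- function() c(1, 0.5, 0.25, 0.125)

#' Three-option probabilistic selection task
#'
#' Training presents three options A, B and C rewarded (`r = 1` for
#' "Correct" feedback, `r = 0` otherwise) with probabilities 0.8, 0.2 and
#' 0.5.  C has the maximal reward variance (Bernoulli SD 0.5).  The test
#' phase pairs A with C (accuracy of *choosing A* measures learning from
#' positive feedback) and B with C (accuracy of *avoiding B* measures
#' learning from negative feedback); the untrained pair A-B is not tested.
#' Test pairings are attached as the `test_pairs` attribute.
#'
#' @param n_trials Training trials per run (default 100).
#' @param n_runs Independent runs.
#' @param seed Optional base seed.
#' @return A [task_spec()] with actions A, B, C and attribute `test_pairs`.
#' @export
probabilistic_selection_task <- function(n_trials = 100L, n_runs = 1L,
                                         seed = NULL) {
  ps <- c(A = 0.8, B = 0.2, C = 0.5)
  actions <- lapply(ps, function(p) discrete_dist(c(1, 0), c(p, 1 - p)))
  spec <- task_spec(actions, n_trials, n_runs, seed)
  attr(spec, "test_pairs") <- list(AC = c(1L, 3L), BC = c(2L, 3L))
  spec
}

#' Serialize / restore a task specification as JSON
#'
#' Plain-text round trip for configuration files: distributions, trial and
#' run counts and the seed survive exactly.
#'
#' @param task A [task_spec()].
#' @param path File path.
#' @return `write_task_json` returns `path` invisibly; `read_task_json`
#'   returns a [task_spec()].
#' @export
write_task_json <- function(task, path) {
  stopifnot(inherits(task, "task_spec"))
  x <- list(
    actions = lapply(task$actions, unclass),
    n_trials = task$n_trials, n_runs = task$n_runs, seed = task$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_task_json
#' @export
read_task_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  actions <- lapply(seq_len(nrow_or_len(x$actions)), function(i) {
    a <- pick_action(x$actions, i)
    if (identical(a$type, "gaussian")) gaussian_dist(a$mu, a$sigma)
    else discrete_dist(unlist(a$outcomes), unlist(a$probs))
  })
  names(actions) <- action_names(x$actions)
  task_spec(actions, x$n_trials, x$n_runs %||% 1L, x$seed)
}

# internal helpers for the jsonlite simplification quirks
nrow_or_len <- function(a) if (is.data.frame(a)) nrow(a) else length(a)
pick_action <- function(a, i) if (is.data.frame(a)) as.list(a[i, ]) else a[[i]]
action_names <- function(a) if (is.data.frame(a)) rownames(a) else names(a)
`%||%` <- function(x, y) if (is.null(x)) y else x
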