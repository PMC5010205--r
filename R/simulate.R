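#' Simulate one learning run of a model on a bandit task
#'
#' Runs the per-trial loop: compute the softmax choice distribution from
#' the current weights, sample an action, draw its reward, update the
#' chosen action's actor weights from the pre-update prediction error,
#' then (for critic-bearing models) update the critic — also from the
#' pre-update state value.  Unchosen actions' weights are untouched,
#' including their decay terms, since the update rules apply after
#' selecting an action.
#'
#' Two engines are provided: the default compiled kernel, and a pure-R
#' reference loop built from the exported single-trial update functions
#' ([au_update()], [acu_update()], [opal_update()], [critic_update()]).
#' Both consume the RNG stream identically (one uniform for the choice,
#' then one normal or uniform for the reward), so with the same seed they
#' produce bit-identical trajectories; the test suite asserts this.
#'
#' @param model One of `"au"` (actor-only; `epsilon > 0` gives the
#'   generalized rule), `"acu"` (actor-critic, decay tied to `alpha`) or
#'   `"opal"` (opponent actor learning).
#' @param task A [task_spec()].
#' @param params [learning_params()].  For `"acu"` and `"opal"` only
#'   `alpha` (and `epsilon` for `"acu"`) are used.
#' @param policy [choice_policy()] used while learning.
#' @param init Optional list with starting `G`, `N` (vectors) and `V`
#'   (scalar).  Defaults: `G = N = 0`, `V = 0` for AU/ACU;
#'   `G = N = 0.1`, `V = 0.1` for OpAL, whose multiplicative rule cannot
#'   leave the all-zero fixed point.
#' @param seed Optional integer seed set before the run.
#' @param log Keep the full per-trial history (`TRUE`) or only the final
#'   state (`FALSE`, faster).
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @return A `trial_log`: list with `G_final`, `N_final`, `V_final` and,
#'   when `log = TRUE`, per-trial matrices `G`, `N` (trials x actions) and
#'   vectors `V`, `reward`, `action` reflecting post-update state.
#' @examples
#' task <- task_spec(list(gaussian_dist(0, 1)), n_trials = 50)
#' simulate_learning("au", task, learning_params(0.1, 0.05),
#'                   choice_policy(1, 1), seed = 1)
#' @export
simulate_learning <- function(model = c("au", "acu", "opal"), task, params,
                              policy = choice_policy(1, 1), init = NULL,
                              seed = NULL, log = TRUE,
                              engine = c("cpp", "r")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(inherits(task, "task_spec"), inherits(params, "learning_params"),
            inherits(policy, "choice_policy"))
  K <- length(task$actions)
  init <- default_init(model, K, init)
  if (!is.null(seed)) set.seed(as.integer(seed))

  res <- if (engine == "cpp") {
    code <- match(model, c("au", "acu", "opal")) - 1L
    cpp_simulate(code, lapply(task$actions, unclass), init$G, init$N,
                 init$V, params$alpha, params$beta, params$epsilon,
                 policy$a, policy$b, task$n_trials, log)
  } else {
    r_simulate(model, task, params, policy, init, log)
  }
  res$model <- model
  res$n_actions <- K
  class(res) <- "trial_log"
  res
}

default_init <- function(model, K, init) {
  d <- if (model == "opal") list(G = rep(0.1, K), N = rep(0.1, K), V = 0.1)
       else list(G = rep(0, K), N = rep(0, K), V = 0)
  if (is.null(init)) return(d)
  for (f in names(d)) if (!is.null(init[[f]])) d[[f]] <- init[[f]]
  stopifnot(length(d$G) == K, length(d$N) == K, length(d$V) == 1L)
  d
}

# pure-R reference engine; mirrors cpp_simulate draw for draw
r_simulate <- function(model, task, params, policy, init, log) {
  K <- length(task$actions)
  n <- task$n_trials
  w <- actor_weights(init$G, init$N)
  V <- init$V
  Glog <- Nlog <- if (log) matrix(NA_real_, n, K)
  Vlog <- rlog <- if (log) numeric(n)
  alog <- if (log) integer(n)
  for (t in seq_len(n)) {
    i <- sample_action(softmax_choice(w, policy))
    r <- draw_reward(task$actions[[i]])
    w <- switch(model,
      au = gen_au_update(w, r, params, i),
      acu = acu_update(w, V, r, params$alpha, i, params$epsilon),
      opal = opal_update(w, V, r, params$alpha, i))
    if (model %in% c("acu", "opal")) V <- critic_update(V, r, params$alpha)
    if (log) {
      Glog[t, ] <- w$G; Nlog[t, ] <- w$N
      Vlog[t] <- V; rlog[t] <- r; alog[t] <- i
    }
  }
  out <- list(G_final = w$G, N_final = w$N, V_final = V)
  if (log) out <- c(out, list(G = Glog, N = Nlog, V = Vlog,
                              reward = rlog, action = alog))
  out
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("trial_log: model %s, %d action(s)%s\n", x$model, x$n_actions,
              if (is.null(x$G)) " (final state only)" else
                sprintf(", %d logged trial(s)", nrow(x$G))))
  print(rbind(G_final = x$G_final, N_final = x$N_final))
  cat("V_final:", x$V_final, "\n")
  invisible(x)
}

#' Tidy data frame view of a trial log
#'
#' One row per trial with the chosen action, reward and the post-update
#' weight and value snapshots (`G.k`, `N.k` per action, `V`); suitable for
#' CSV export.
#'
#' @param x A `trial_log` simulated with `log = TRUE`.
#' @param run Value written into the `run` column (default 1).
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.trial_log <- function(x, run = 1L, ...) {
  if (is.null(x$G)) stop("trial_log was recorded with log = FALSE")
  K <- x$n_actions
  d <- data.frame(run = run, trial = seq_len(nrow(x$G)),
                  action = x$action, reward = x$reward)
  for (k in seq_len(K)) d[[paste0("G.", k)]] <- x$G[, k]
  for (k in seq_len(K)) d[[paste0("N.", k)]] <- x$N[, k]
  d$V <- x$V
  d
}

#' Write a trial log (or ensemble) to CSV
#' @param x A `trial_log` or the result of [run_ensemble()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_log_csv <- function(x, path) {
  d <- if (inherits(x, "trial_log")) as.data.frame(x)
       else do.call(rbind, lapply(seq_along(x), function(i)
         as.data.frame(x[[i]], run = i)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Simulate an ensemble of independent runs
#'
#' Repeats [simulate_learning()] `n_runs` times with run `j` seeded as
#' `seed + j - 1`, so the ensemble is reproducible and individual runs can
#' be regenerated in isolation.
#'
#' @inheritParams simulate_learning
#' @param n_runs Number of runs; defaults to `task$n_runs`.
#' @param seed Base seed; defaults to `task$seed`, else 1.
#' @return A list of `trial_log`s (class `trial_log_ensemble`).
#' @export
run_ensemble <- function(model, task, params, policy = choice_policy(1, 1),
                         n_runs = NULL, seed = NULL, init = NULL,
                         log = TRUE, engine = "cpp") {
  n_runs <- n_runs %||% task$n_runs
  seed <- seed %||% task$seed %||% 1L
  out <- lapply(seq_len(n_runs), function(j)
    simulate_learning(model, task, params, policy, init = init,
                      seed = seed + j - 1L, log = log, engine = engine))
  class(out) <- "trial_log_ensemble"
  out
}

#' Per-trial ensemble summary
#'
#' Run-mean and run-SD of every logged variable at each trial; the layout
#' of the learning-curve figures.
#'
#' @param ens A `trial_log_ensemble` with logged trials.
#' @return A `data.frame` with columns `trial`, `variable` (e.g. `"G.1"`),
#'   `mean`, `sd`, `se`.
#' @export
summarize_ensemble <- function(ens) {
  stopifnot(inherits(ens, "trial_log_ensemble"), !is.null(ens[[1]]$G))
  K <- ens[[1]]$n_actions
  n <- nrow(ens[[1]]$G)
  R <- length(ens)
  vars <- c(paste0("G.", seq_len(K)), paste0("N.", seq_len(K)), "V")
  get_var <- function(l, v) {
    if (v == "V") return(l$V)
    k <- as.integer(sub("^[GN]\\.", "", v))
    if (startsWith(v, "G")) l$G[, k] else l$N[, k]
  }
  out <- lapply(vars, function(v) {
    m <- vapply(ens, get_var, numeric(n), v = v)  # trials x runs
    data.frame(trial = seq_len(n), variable = v,
               mean = rowMeans(m),
               sd = apply(m, 1, stats::sd))
  })
  out <- do.call(rbind, out)
  out$se <- out$sd / sqrt(R)
  rownames(out) <- NULL
  out
}

#' Final-state summary of an ensemble
#'
#' Run-mean, SD and standard error of the final `G`, `N`, `Q = G - N`,
#' `S = G + N` per action and of `V`; the quantities compared against the
#' closed-form stochastic fixed points.
#'
#' @param ens A `trial_log_ensemble`.
#' @return A `data.frame` with one row per variable.
#' @export
final_state_summary <- function(ens) {
  stopifnot(inherits(ens, "trial_log_ensemble"))
  K <- ens[[1]]$n_actions
  R <- length(ens)
  G <- matrix(unlist(lapply(ens, `[[`, "G_final")), nrow = R, byrow = TRUE)
  N <- matrix(unlist(lapply(ens, `[[`, "N_final")), nrow = R, byrow = TRUE)
  V <- vapply(ens, `[[`, numeric(1), "V_final")
  cols <- cbind(G, N, G - N, G + N, V)
  colnames(cols) <- c(paste0("G.", 1:K), paste0("N.", 1:K),
                      paste0("Q.", 1:K), paste0("S.", 1:K), "V")
  data.frame(variable = colnames(cols),
             mean = colMeans(cols),
             sd = apply(cols, 2, stats::sd),
             se = apply(cols, 2, stats::sd) / sqrt(R),
             row.names = NULL)
}
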