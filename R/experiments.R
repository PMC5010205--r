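#' Ensemble learning curves for a model on a task
#'
#' Simulates `n_runs` independent runs and returns the per-trial run-mean
#' and run-SD of every weight and of the state value — the layout of the
#' weight-trajectory figures (e.g. 50 runs of 100 trials for the
#' actor-only sweeps, 50 runs of 300 trials for the OpAL comparison).
#'
#' @inheritParams run_ensemble
#' @return A list with `summary` (see [summarize_ensemble()]), `final`
#'   (see [final_state_summary()]) and the ensemble itself.
#' @export
run_learning_curves <- function(model, task, params,
                                policy = choice_policy(1, 1),
                                n_runs = NULL, seed = NULL, init = NULL) {
  ens <- run_ensemble(model, task, params, policy, n_runs = n_runs,
                      seed = seed, init = init, log = TRUE)
  list(summary = summarize_ensemble(ens), final = final_state_summary(ens),
       ensemble = ens)
}

#' Converged summed weights across a grid of reward spreads
#'
#' For each reward standard deviation in `sigma_grid` and each parameter
#' setting (`beta` values for the AU model, or `epsilon` values at fixed
#' `beta` for the generalized rule), simulates `n_reps` short runs and
#' records the final `S = G + N` of the single action — the scatter used
#' to show that `S` grows monotonically with reward spread, with a flat
#' region at small spreads whose width shrinks as `beta/alpha` drops.
#'
#' @param model `"au"` or `"acu"`.
#' @param sigma_grid Reward SDs to sweep.
#' @param mu Mean reward (default 1, so `sigma` is the coefficient of
#'   variation).
#' @param alpha Learning rate (default 0.1).
#' @param beta_grid Decay rates to sweep (AU; default `alpha`).
#' @param epsilon_grid Cross-term values to sweep (default 0).
#' @param n_reps Replicates per cell (default 10).
#' @param n_trials Trials per replicate (default 300).
#' @param seed Base seed.
#' @return A `data.frame` with columns `sigma`, `beta`, `epsilon`,
#'   `replicate`, `S_final`.
#' @export
run_sigma_sweep <- function(model = c("au", "acu"),
                            sigma_grid = c(0, 0.5, 1, 2, 4), mu = 1,
                            alpha = 0.1, beta_grid = alpha,
                            epsilon_grid = 0, n_reps = 10L,
                            n_trials = 300L, seed = 1L) {
  model <- match.arg(model)
  grid <- expand.grid(sigma = sigma_grid, beta = beta_grid,
                      epsilon = epsilon_grid, replicate = seq_len(n_reps))
  grid$S_final <- NA_real_
  for (i in seq_len(nrow(grid))) {
    task <- task_spec(list(gaussian_dist(mu, grid$sigma[i])),
                      n_trials = n_trials)
    params <- learning_params(alpha, grid$beta[i], grid$epsilon[i])
    log <- simulate_learning(model, task, params, choice_policy(1, 1),
                             seed = seed + i - 1L, log = FALSE)
    grid$S_final[i] <- log$G_final + log$N_final
  }
  grid[c("sigma", "beta", "epsilon", "replicate", "S_final")]
}

#' Probabilistic-selection (choose-A / avoid-B) experiment
#'
#' Trains a model on the three-option probabilistic selection task
#' (reward probabilities 0.8 / 0.2 / 0.5) with a training-phase policy,
#' then computes test-phase choice probabilities analytically from the
#' softmax over the frozen final weights — no test-phase learning — for
#' the two trained pairings: P(choose A | \{A, C\}) and
#' P(avoid B | \{B, C\}) = P(choose C | \{B, C\}).  Test policies model
#' the medication state during testing: on-medication `a = 4, b = 0`
#' (choice driven by Go weights), off-medication `a = 0, b = 4` (driven
#' by NoGo weights).
#'
#' @param model `"opal"`, `"au"` or `"acu"`.
#' @param n_sims Number of simulations (default 100).
#' @param n_trials Learning trials per simulation (default 100).
#' @param params [learning_params()] (default `alpha = beta = 0.1`).
#' @param train_policy Policy during learning (default `a = b = 2`).
#' @param test_policies Named list of test policies (default `on` =
#'   `choice_policy(4, 0)`, `off` = `choice_policy(0, 4)`).
#' @param init Initial state; default `G = N = 0.1`, `V = 0.1` for every
#'   model in this task.
#' @param seed Base seed.
#' @return A list with `per_sim` (one row per simulation and test state:
#'   `choose_A`, `avoid_B`) and `summary` (mean and SE per test state).
#' @export
run_probabilistic_selection <- function(model = c("opal", "au", "acu"),
                                        n_sims = 100L, n_trials = 100L,
                                        params = learning_params(0.1, 0.1),
                                        train_policy = choice_policy(2, 2),
                                        test_policies = list(
                                          on = choice_policy(4, 0),
                                          off = choice_policy(0, 4)),
                                        init = list(G = rep(0.1, 3),
                                                    N = rep(0.1, 3),
                                                    V = 0.1),
                                        seed = 1L) {
  model <- match.arg(model)
  task <- probabilistic_selection_task(n_trials = n_trials)
  pairs <- attr(task, "test_pairs")
  rows <- list()
  for (s in seq_len(n_sims)) {
    log <- simulate_learning(model, task, params, train_policy, init = init,
                             seed = seed + s - 1L, log = FALSE)
    w <- actor_weights(log$G_final, log$N_final)
    for (state in names(test_policies)) {
      pol <- test_policies[[state]]
      pick <- function(pair, target) {
        sub <- actor_weights(w$G[pair], w$N[pair])
        softmax_choice(sub, pol)$P[match(target, pair)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sim = s, state = state,
        choose_A = pick(pairs$AC, 1L),   # P(A | {A, C})
        avoid_B = pick(pairs$BC, 3L))    # P(C | {B, C})
    }
  }
  per_sim <- do.call(rbind, rows)
  agg <- function(v) {
    m <- tapply(per_sim[[v]], per_sim$state, mean)
    se <- tapply(per_sim[[v]], per_sim$state, stats::sd) /
      sqrt(tapply(per_sim[[v]], per_sim$state, length))
    data.frame(state = names(m), measure = v, mean = as.numeric(m),
               se = as.numeric(se))
  }
  list(model = model, per_sim = per_sim,
       summary = rbind(agg("choose_A"), agg("avoid_B")))
}

#' Fit and reproduce risky-choice fraction curves
#'
#' Orchestrates the drug-panel protocol on a user-supplied (or synthetic)
#' choice-fraction table: fits the choice gains with [fit_policy()], then
#' re-simulates the fraction of risky choices per condition under the
#' fitted control and drug policies for plotting against the observed
#' values.
#'
#' @inheritParams fit_policy
#' @return A list with `fit` (the [fit_policy()] result) and `curves`, a
#'   data.frame of observed and fitted fractions per condition and drug
#'   state.
#' @export
run_risky_lever_panels <- function(table, receptor = c("D1", "D2"),
                                   params = learning_params(0.1, 0.1),
                                   n_sim_choices = 10000L,
                                   n_restarts = 10L, init_range = c(0, 3),
                                   seed = 1L) {
  receptor <- match.arg(receptor)
  fit <- fit_policy(table, receptor, params, n_sim_choices, n_restarts,
                    init_range, seed)
  pol <- policies_from_par(unname(fit$par), receptor)
  conditions <- sort(unique(table$condition), decreasing = TRUE)
  sim_seed <- as.integer(seed) + 224737L
  sim <- rbind(
    data.frame(condition = conditions, drug_state = "control",
               fitted = as.numeric(simulate_choice_fractions(
                 pol$control, params, n_sim_choices, conditions,
                 seed = sim_seed))),
    data.frame(condition = conditions, drug_state = "drug",
               fitted = as.numeric(simulate_choice_fractions(
                 pol$drug, params, n_sim_choices, conditions,
                 seed = sim_seed + 1L))))
  curves <- merge(table, sim, by = c("condition", "drug_state"))
  list(fit = fit, curves = curves[order(curves$drug_state,
                                        -curves$condition), ])
}
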