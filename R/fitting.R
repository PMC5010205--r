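#' Simulated fraction of risky choices across probability conditions
#'
#' Runs the AU learner concurrently learning and choosing on the
#' safe-versus-risky lever task ([risky_lever_task()]) and returns the
#' fraction of risky-lever selections over all trials, one value per
#' probability condition.  With the standard `n_choices = 10000` the
#' standard error of each fraction is below 1%.
#'
#' @param policy [choice_policy()] in force during learning and choice.
#' @param params [learning_params()]; the behavioral-fitting default is
#'   `alpha = beta = 0.1`.
#' @param n_choices Trials per condition (default 10000).
#' @param conditions Probabilities of the large reward
#'   (default [risky_lever_conditions()]).
#' @param seed Optional seed set once before the condition loop, so a
#'   fixed seed makes the whole table deterministic (common random
#'   numbers for the fitting objective).
#' @return Named numeric vector of risky-choice fractions, one per
#'   condition.
#' @examples
#' simulate_choice_fractions(choice_policy(0, 0), n_choices = 1000,
#'                           seed = 1)  # ~0.5 everywhere
#' @export
simulate_choice_fractions <- function(policy,
                                      params = learning_params(0.1, 0.1),
                                      n_choices = 10000L,
                                      conditions = risky_lever_conditions(),
                                      seed = NULL) {
  stopifnot(inherits(policy, "choice_policy"),
            inherits(params, "learning_params"))
  n_choices <- as.integer(n_choices)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vapply(conditions, function(p)
    cpp_au_risky_fraction(p, params$alpha, params$beta, params$epsilon,
                          policy$a, policy$b, n_choices),
    numeric(1))
  names(out) <- paste0("p", conditions)
  out
}

#' Build / read / write an observed choice-fraction table
#'
#' The fitting input: one risky-choice fraction per (probability
#' condition, drug state) cell — 8 cells for the standard 4-condition
#' grid.  `choice_fraction_table()` assembles it from two vectors;
#' the CSV layout is `condition,drug_state,fraction` with `drug_state`
#' in `{control, drug}`.
#'
#' @param control,drug Numeric vectors of risky-choice fractions in
#'   `[0, 1]`, one per condition, control and drug state respectively.
#' @param conditions Probability conditions (default
#'   [risky_lever_conditions()]).
#' @return A `data.frame` with columns `condition`, `drug_state`,
#'   `fraction`.
#' @export
choice_fraction_table <- function(control, drug,
                                  conditions = risky_lever_conditions()) {
  stopifnot(length(control) == length(conditions),
            length(drug) == length(conditions),
            all(control >= 0 & control <= 1),
            all(drug >= 0 & drug <= 1))
  data.frame(
    condition = rep(conditions, 2L),
    drug_state = rep(c("control", "drug"), each = length(conditions)),
    fraction = c(control, drug)
  )
}

#' @rdname choice_fraction_table
#' @param path CSV file path.
#' @export
read_choice_fractions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "drug_state", "fraction")
  if (!all(need %in% names(d)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  if (!all(d$drug_state %in% c("control", "drug")))
    stop("`drug_state` must be 'control' or 'drug'")
  if (any(d$fraction < 0 | d$fraction > 1))
    stop("fractions must lie in [0, 1]")
  d[need]
}

#' @rdname choice_fraction_table
#' @param table A choice-fraction table.
#' @export
write_choice_fractions <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# internal: split a fitting parameter vector into control/drug policies
policies_from_par <- function(par, receptor) {
  if (receptor == "D1") {
    list(control = choice_policy(par[1], par[3]),
         drug = choice_policy(par[2], par[3]),
         names = c("a_control", "a_drug", "b"))
  } else {
    list(control = choice_policy(par[1], par[2]),
         drug = choice_policy(par[1], par[3]),
         names = c("a", "b_control", "b_drug"))
  }
}

#' Fit choice-gain parameters to observed risky-choice fractions
#'
#' Replicates the behavioral fitting protocol: learning parameters are
#' fixed (`alpha = beta = 0.1`) and only the choice gains are fit by
#' minimizing the sum of squared errors between observed and simulated
#' risky-choice fractions over the 8 (condition x drug state) cells.
#' For a D1-receptor manipulation the Go gain differs between drug
#' states while the NoGo gain is shared — parameters
#' `(a_control, a_drug, b)`; for D2, `(a, b_control, b_drug)`.
#' Minimization uses the Nelder-Mead simplex, restarted `n_restarts`
#' times from initial values drawn uniformly from `init_range`; the
#' minimum-SSE restart is reported.  Each objective evaluation simulates
#' with the same fixed seed (common random numbers), making the SSE
#' surface deterministic in the parameters — a requirement for simplex
#' stability.  The drug-state policy applies to both learning and choice
#' within its simulated condition.
#'
#' @param table Choice-fraction table (see [choice_fraction_table()]).
#' @param receptor `"D1"` or `"D2"`: which pathway's gain splits across
#'   drug states.
#' @param params Fixed [learning_params()] of the AU learner.
#' @param n_sim_choices Simulated trials per cell in the objective
#'   (default 10000).
#' @param n_restarts Number of random restarts (default 10).
#' @param init_range Range of the uniform initial parameter draws
#'   (default `c(0, 3)`).
#' @param seed Seed governing both the restart initializations and the
#'   common-random-number stream of the objective.
#' @return A `fit_result` list: `par` (named, 3 parameters), `sse`,
#'   `receptor`, `converged` (did any restart converge), and `restarts`,
#'   a data.frame tracing every restart's endpoint.
#' @export
fit_policy <- function(table, receptor = c("D1", "D2"),
                       params = learning_params(0.1, 0.1),
                       n_sim_choices = 10000L, n_restarts = 10L,
                       init_range = c(0, 3), seed = 1L) {
  receptor <- match.arg(receptor)
  stopifnot(is.data.frame(table),
            all(c("condition", "drug_state", "fraction") %in% names(table)),
            n_restarts >= 1L, length(init_range) == 2L)
  conditions <- sort(unique(table$condition), decreasing = TRUE)
  obs <- function(state) {
    d <- table[table$drug_state == state, ]
    d$fraction[match(conditions, d$condition)]
  }
  obs_control <- obs("control"); obs_drug <- obs("drug")
  if (anyNA(obs_control) || anyNA(obs_drug))
    stop("`table` must contain every condition in both drug states")

  sim_seed <- as.integer(seed) + 104729L  # objective CRN stream
  objective <- function(par) {
    if (any(par < 0)) return(1e6 + sum(pmax(-par, 0)))  # gains must be >= 0
    pol <- policies_from_par(par, receptor)
    sim_c <- simulate_choice_fractions(pol$control, params, n_sim_choices,
                                       conditions, seed = sim_seed)
    sim_d <- simulate_choice_fractions(pol$drug, params, n_sim_choices,
                                       conditions, seed = sim_seed + 1L)
    sum((sim_c - obs_control)^2) + sum((sim_d - obs_drug)^2)
  }

  set.seed(as.integer(seed))
  inits <- matrix(stats::runif(3L * n_restarts, init_range[1], init_range[2]),
                  ncol = 3L)
  fits <- lapply(seq_len(n_restarts), function(i)
    stats::optim(inits[i, ], objective, method = "Nelder-Mead"))

  par_names <- policies_from_par(c(1, 1, 1), receptor)$names
  restarts <- data.frame(
    restart = seq_len(n_restarts),
    sse = vapply(fits, `[[`, numeric(1), "value"),
    converged = vapply(fits, function(f) f$convergence == 0L, logical(1))
  )
  for (j in 1:3) restarts[[par_names[j]]] <-
    vapply(fits, function(f) f$par[j], numeric(1))
  best <- which.min(restarts$sse)
  if (!any(restarts$converged))
    warning("no Nelder-Mead restart reported convergence; ",
            "returning the best endpoint")
  par <- stats::setNames(fits[[best]]$par, par_names)
  structure(list(par = par, sse = restarts$sse[best], receptor = receptor,
                 converged = any(restarts$converged), restarts = restarts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s manipulation): SSE = %.5g%s\n", x$receptor,
              x$sse, if (x$converged) "" else " [no restart converged]"))
  print(round(x$par, 4))
  invisible(x)
}

#' Save a fit result as JSON
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(receptor = fit$receptor, par = as.list(fit$par), sse = fit$sse,
         converged = fit$converged, restarts = fit$restarts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
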