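# gonogo

Reinforcement-learning models of the basal ganglia that learn not just
how good an action is, but how *variable* its payoff is — and use tonic
dopamine to decide whether that variability is attractive.

## Who this is for, and the problem it addresses

Striatal projection neurons form two opponent pathways: D1 ("Go")
neurons that facilitate an action and D2 ("NoGo") neurons that suppress
it. If phasic dopamine broadcasts the reward prediction error
δ = r − expected, and positive errors strengthen Go synapses G while
negative errors strengthen NoGo synapses N, then

- the **difference** Q = G − N follows a Rescorla–Wagner recursion and
  codes the **mean** reward of the action, while
- the **sum** S = G + N integrates |δ| and codes the **spread** of the
  reward distribution.

`gonogo` is for computational neuroscientists and modelers who want to
simulate, analyze, and fit this family of models: the actor-only rule
(AU), its generalized form with a cross-term ε, the actor-critic form
(ACU, an advantage-learning rule), and the opponent actor learning
(OpAL) comparator in which errors are scaled by the weights themselves.

The core update (AU), applied to the chosen action with learning rate α
and decay β:

    G ← G + α·max(δ, 0) − β·G
    N ← N + α·max(−δ, 0) − β·N,      δ = r − (G − N)

with stochastic fixed points

    Q* = α(1+ε) / (α(1+ε) + β) · E[r]
    S* = α(1−ε)/β · E|r − Q*|        (σ·√(2/π) per unit α/β for Gaussians)

Choice is a dopamine-modulated softmax, P_i ∝ exp(a·G_i − b·N_i) —
equivalently exp(½[(a+b)Q_i − (b−a)S_i]) — so the D1/D2 gains a and b
price mean and spread separately: a > b seeks risk, b > a avoids it.

## Worked example

Learn a zero-mean, SD-2 Gaussian reward with β = α/√(2π), the setting
in which G and N each converge to σ:

```r
library(gonogo)
p    <- learning_params(alpha = 0.1, beta = 0.1 / sqrt(2 * pi))
task <- task_spec(list(gaussian_dist(0, 2)), n_trials = 300,
                  n_runs = 50, seed = 1)
res  <- run_learning_curves("au", task, p)
res$final
#>   variable   mean    sd     se
#> 1      G.1 2.0818 0.286 0.0405
#> 2      N.1 2.0445 0.316 0.0447
#> 3      Q.1 0.0374 0.414 0.0585
#> 4      S.1 4.1263 0.440 0.0622
#> 5        V 0.0000 0.000 0.0000
au_fixed_points(p, gaussian_dist(0, 2))[c("q_star", "s_star")]
#> $q_star 0       $s_star 4
```

Both weights sit at σ = 2 (run-mean ± SE: 2.08 ± 0.04 and 2.04 ± 0.04),
the mean code Q at 0, and the spread code S at its closed-form fixed
point 4 — the simulation and the analytics module agreeing within
Monte-Carlo error.

Risk attitude follows the gains. On the safe-vs-risky lever task (safe
lever: always 1 pellet; risky: 4 pellets with probability p), a
dopamine-high policy (a = 2, b = 0.5) seeks the risky lever while a
dopamine-low one (a = 0.5, b = 2) avoids it, most visibly where the
mean rewards tie (p = 0.25) or favor the safe lever (p = 0.125):

```r
simulate_choice_fractions(choice_policy(2, 0.5), n_choices = 1e4, seed = 1)
#>    p1   p0.5  p0.25 p0.125
#> 0.949  0.830  0.608  0.436
simulate_choice_fractions(choice_policy(0.5, 2), n_choices = 1e4, seed = 1)
#>    p1   p0.5  p0.25 p0.125
#> 0.679  0.367  0.367  0.388
```

`fit_policy()` inverts this mapping: given an 8-cell table of observed
risky-choice fractions (4 probability conditions × control/drug), it
fits (a_control, a_drug, b) — or (a, b_control, b_drug) for D2
manipulations — by simplex minimization of the squared error, 10
restarts, common random numbers. `run_probabilistic_selection()` runs
the three-option choose-A/avoid-B paradigm and
`run_sigma_sweep()`/`run_learning_curves()` the spread-coding sweeps.
A command-line front end ships in `inst/cli/bgu`
(`bgu fixed-point --model au --mu 1 --sigma 0`, `bgu run sigma-sweep`,
`bgu fit --table fractions.csv --receptor D1`).

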