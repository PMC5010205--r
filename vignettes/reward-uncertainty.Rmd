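---
title: "Learning reward uncertainty in Go/NoGo synaptic weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning reward uncertainty in Go/NoGo synaptic weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo)
```

## The model family

Striatal projection neurons come in two opponent populations: D1
("Go") neurons whose activity facilitates an action, and D2 ("NoGo")
neurons whose activity suppresses it. `gonogo` simulates and analyses a
family of trial-by-trial learning rules for the cortico-striatal weights
$G_i$ and $N_i$ of these two populations, built around one idea: if
positive reward prediction errors strengthen $G$ while negative ones
strengthen $N$, then the *difference* $Q_i = G_i - N_i$ tracks the mean
reward of action $i$ while the *sum* $S_i = G_i + N_i$ tracks the spread
of its rewards. A single scalar teaching signal (phasic dopamine) thereby
stores two moments of the reward distribution in anatomically distinct
synapses.

Three learners share this architecture:

* **AU** (actor-only), `au_update()`: with prediction error
  $\delta = r - Q_i$,
  $$G' = G + \alpha\,[\delta]_+ - \beta G, \qquad
    N' = N + \alpha\,[\delta]_- - \beta N,$$
  where $[x]_+ = \max(x, 0)$, $[x]_- = \max(-x, 0)$, $\alpha$ is the
  learning rate and $\beta$ the weight decay. Subtracting the two lines
  gives a Rescorla–Wagner-with-decay recursion for $Q$; adding them gives
  $S' = S + \alpha|\delta| - \beta S$, an integrator of the *unsigned*
  error.
* **generalized AU**, `gen_au_update()`: each error also weakly pushes the
  opposite population, scaled by a cross term $\epsilon < 1$
  ($G' = G + \alpha([\delta]_+ - \epsilon[\delta]_-) - \beta G$, and
  symmetrically for $N$). Negative results are clamped at 0 — synapses
  cannot have negative strength. $\epsilon = 0$ recovers AU exactly.
* **ACU** (actor-critic), `acu_update()` + `critic_update()`: the error is
  computed against a critic's state value, $\delta = r - V$, with decay
  tied to the learning rate ($\beta = \alpha$). $Q_i$ then converges to
  the *advantage* $\mu_i - V^*$ and $S_i$ to the mean absolute deviation
  of $r_i$ around $V^*$.

The comparator **OpAL** rule, `opal_update()`, scales the critic error
multiplicatively by the weight itself ($G' = G(1 + \alpha\delta)$,
$N' = N(1 - \alpha\delta)$). It does *not* encode spread at convergence:
$G = N = 0$ is a stochastic fixed point, and with equal-mean actions all
weights decay there, faster for the noisier action.

Choice uses the generalized softmax, `softmax_choice()`:
$$P_i \propto \exp(a G_i - b N_i)
      = \exp\!\big(\tfrac12[(a+b)Q_i - (b-a)S_i]\big),$$
so the gains $a$ and $b$ — the model's proxy for tonic dopamine, which
excites D1 and inhibits D2 neurons — price mean and spread separately:
$b > a$ yields risk aversion, $a > b$ risk seeking, $a = b$
mean-only choice. The algebraic identity between the two forms is a
package invariant (`utility()`, `decompose_weights()`,
`compose_weights()`), tested to machine tolerance.

## Stochastic fixed points and their accuracy

The weights never converge for noisy rewards; they fluctuate around the
point where the expected per-trial change vanishes. `au_fixed_points()`
returns
$$Q^* = \frac{\alpha(1+\epsilon)}{\alpha(1+\epsilon)+\beta}\,E[r], \qquad
  S^* = \frac{\alpha(1-\epsilon)}{\beta}\,E\,|r - Q^*|,$$
with $E|r - c|$ evaluated noise-free: the folded-normal closed form for
Gaussian rewards (`folded_normal_mean()`) and exact enumeration for
discrete ones (`expected_abs_dev()`). For a Gaussian,
$E|r - \mu| = \sigma\sqrt{2/\pi}$ (`gaussian_mad()`), which is why $S$
can serve as an estimate of $\sigma_r$: exactly proportional when
$\mu_r = 0$, and approximately so when $\sigma_r$ is large relative to
$\mu_r$ or $\beta/\alpha$ is small. The trade-off is real: smaller
$\beta/\alpha$ shrinks the flat low-$\sigma$ region of the $S(\sigma)$
curve but inflates every weight (metabolic cost) — `run_sigma_sweep()`
reproduces this.

`acu_fixed_points()` implements the actor-critic analogues
($V^* = \sum_i P_i^*\mu_i$, $Q_i^* = \mu_i - V^*$,
$S_i^* = E|r_i - V^*|$). Because $P^*$ itself depends on the weights,
`acu_solve_fixed_points()` closes the loop by damped fixed-point
iteration (default damping 0.5, tolerance $10^{-10}$, cap $10^4$
iterations; an error, never a silent return, on non-convergence).

Two caveats on the closed forms, both surfaced by the package rather than
hidden:

1. **Clamping.** For $\epsilon > 0$ the raw update can drive a weight
   negative; the rule then sets it to 0, and the fixed-point algebra —
   which ignores the clamp — no longer describes the model. The
   derivations are valid only while the clamp stays inactive.
   `gen_au_clamp_prob()` evaluates the per-trial clamp probability at the
   nominal fixed point; the test suite excludes cells above $10^{-3}$
   from closed-form comparisons. (The AU rule with $\epsilon = 0$ never
   clamps: decay with $\beta < 1$ keeps weights nonnegative by
   construction.)
2. **Fluctuation (Jensen) bias.** The $S^*$ formula substitutes the fixed
   point $Q^*$ for the fluctuating $Q$ inside $E|r - Q|$. Since $Q$ is an
   exactly linear AR(1) with Gaussian stationary law, the *true*
   stationary mean of $S$ is the same expression with the scale inflated
   to $\sqrt{\sigma^2 + \mathrm{Var}(Q_\infty)}$,
   $\mathrm{Var}(Q_\infty) = \frac{(\alpha(1+\epsilon))^2\sigma^2}
   {1-(1-\alpha(1+\epsilon)-\beta)^2}$. The substitution therefore
   *under*-predicts the simulated mean of $S$ by roughly 2% at
   $\beta = \alpha = 0.1$ and 5% at $\beta = \alpha/5$, more for large
   $\epsilon$. The acceptance suite compares simulations against the
   plain closed forms at $3\times$ Monte-Carlo SE and deliberately leaves
   the two $\epsilon = 0.5$, low-$\beta$ grid cells red where this bias
   exceeds the band; a separate test asserts the refined
   (variance-corrected) prediction at those same cells, tightly, which is
   the statement that validates the simulator itself.

## Synthetic tasks: what they emulate, and what not

No external data ship with the package; the `tasks` module is the only
data source.

* `gaussian_dist(mu, sigma)` / `discrete_dist(outcomes, probs)` generate
  i.i.d. rewards per action — the stationary, "expected uncertainty"
  world the models assume. Volatile (nonstationary) schedules are out of
  scope by design.
* `risky_lever_task(p_large)` mirrors rodent risky-choice experiments:
  a safe lever always paying 1 pellet (1.0 reward unit) versus a risky
  lever paying 4 with probability $p \in \{1, 0.5, 0.25, 0.125\}$, else
  0. The risky lever has higher mean reward at 100% and 50%, equal at 25%
  (SD $4\sqrt{0.25\cdot 0.75} = \sqrt3$), lower at 12.5%.
* `probabilistic_selection_task()` is the three-option
  positive/negative-feedback paradigm: options A, B, C rewarded
  ($r = 1$/0) with probabilities 0.8, 0.2, 0.5; C has the largest
  Bernoulli variance. Testing pairs A–C (choose-A accuracy, learning
  from positive feedback) and B–C (avoid-B accuracy, negative feedback);
  the untrained A–B pair is never tested.

Defaults are the standard simulation settings for this model family:
$\alpha = 0.1$; AU/ACU weights start at 0; OpAL weights and
critic start at 0.1 (its multiplicative rule cannot leave 0); the
selection task trains 100 trials with $a = b = 2$ and tests analytically
under $a{=}4, b{=}0$ (on medication) and $a{=}0, b{=}4$ (off); ensemble
sizes 50–100 runs. The sweep grids that exist only as figure axis labels
(means $\{+2, 0, -2\}$, SDs $\{0, 2, 4\}$ and neighbors) are defaults,
all configurable.

A green test on these generators establishes that the implementation has
the stated statistical structure; it does not establish anything about
real behavioral data — published rat risky-choice fractions are not
redistributed here, so gain values quoted in documentation
(e.g. $a_{control} = 1.71$, $a_{drug} = 3.13$, $b = 0.59$ for a D1
agonist panel) are illustrative, not targets; the package's
self-consistency standard is parameter recovery from its own synthetic
tables.

## The fitting protocol and its numerical choices

`fit_policy()` replicates the behavioral protocol: learning parameters
fixed at $\alpha = \beta = 0.1$; three free gains
($a_{control}, a_{drug}, b$ for D1 manipulations, $a, b_{control},
b_{drug}$ for D2); objective = sum of squared errors between observed
and simulated risky-choice fractions over the 8 condition × drug-state
cells; Nelder–Mead simplex with 10 restarts from $U[0,3]$ initials, best
restart reported.

Numerical choices worth knowing:

* **Common random numbers.** Every objective evaluation re-seeds the
  simulator identically, so the SSE surface is deterministic in the
  parameters — without this the simplex stalls on Monte-Carlo noise.
  With the default $10^4$ choices per cell the per-fraction SE is
  below 1% anyway.
* **Nonnegativity** of the gains is enforced by a penalty (the simplex is
  unconstrained); fitted values sit well inside the feasible region in
  all tested problems.
* **Drug state scope.** The drug's gain applies to both learning and
  choice within its simulated condition (the animal learns and chooses
  under the drug); this is configurable in principle but fixed here, and
  flagged because the alternative (drug at choice only) is defensible.
* Parameter recovery from self-generated tables is accurate to well
  within ±0.3 on each gain at the protocol's scale, with the
  drug/control ordering recovered in 10/10 fitting seeds (acceptance
  suite).

## Reproducibility and degenerate inputs

All randomness flows through R's RNG: one uniform per choice, one
normal or uniform per reward, in a fixed order. The compiled kernel and
the pure-R reference engine (`engine = "r"`) consume the stream
identically and are asserted draw-for-draw identical; run $j$ of an
ensemble is seeded `seed + j - 1`, so any single run can be regenerated
alone. Softmax exponents are max-shifted before exponentiation — exact,
by shift invariance. Degenerate inputs are defined, not special-cased:
$\sigma = 0$ is a point mass; $a = b = 0$ gives uniform choice;
single-action tasks still draw the choice uniform to keep streams
aligned; `compose_weights()` rejects $S_i < |Q_i|$; OpAL updates that
would cross zero clamp at 0 to preserve the $G = N = 0$ fixed point.

## Known limitations

* Fixed-point *stability* (eigenvalue) analysis is not provided, only the
  fixed points themselves.
* Reward distributions beyond Gaussian/discrete are not implemented; the
  mean-absolute-deviation machinery would extend but the closed forms
  would not.
* The biophysics behind the rectification asymmetry is represented only
  by the receptor-occupancy curve $C/(EC_{50}+C)$
  (`receptor_occupancy()`); no dopamine release dynamics, eligibility
  traces, or within-trial temporal-difference structure.
* The probabilistic-selection comparison is qualitative (orderings of
  choose-A vs avoid-B effects across models), as in the source analyses.
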