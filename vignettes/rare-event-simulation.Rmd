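---
title: "Weighted stochastic simulation and automatic importance-sampling parameter selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted stochastic simulation and automatic importance-sampling parameter selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raressa)
```

## The problem

A well-stirred mixture of $N$ molecular species reacts through $M$
mass-action channels.  The state $\mathbf{X}(t)$ is the vector of copy
numbers; channel $m$ has a state-change vector $\nu_m$ and a propensity
$a_m(\mathbf{x})$ such that $a_m(\mathbf{x})\,dt$ is the probability of
one firing in $[t, t+dt)$.  We want
$$
P(E_R) \;=\; \Pr\bigl(\exists\, t \le T:\; X_i(t) = \theta \mid
\mathbf{X}(0) = \mathbf{x}_0\bigr),
\qquad \theta = X_i(0) + \eta ,
$$
the probability that a target species first reaches a threshold within a
horizon.  For interesting thresholds this probability is $10^{-3}$ to
$10^{-7}$ or smaller, so the plain stochastic simulation algorithm (SSA)
needs prohibitively many runs: the relative standard error of the
hit-fraction estimator is $\approx 1/\sqrt{n p}$.

## Simulators

Four trajectory engines share one contract (start at $\mathbf{x}_0$,
stop on first entry into the event region or at $T$):

* **ssa** — Gillespie's direct method: $\tau \sim
  \mathrm{Exp}(a_0(\mathbf{x}))$, $\mu$ from the PMF
  $a_m/a_0$, two uniforms per step.
* **nrm** — the Gibson–Bruck next reaction method: per-channel putative
  absolute firing times in an indexed priority queue (binary min-heap,
  ties broken by the lowest channel index), a dependency graph so that
  only affected propensities are refreshed, and re-use of unexpired
  putative times by the rescaling $\tau_m' = (d_m/d_m')(\tau_m - t) + t$.
  One uniform per step.
* **wssa / wnrm** — the weighted (importance-sampling) variants.  The
  time law is never altered; only the channel-selection probabilities
  are changed to some $q_m(\mathbf{x})$, and each step multiplies the
  trajectory weight by the likelihood ratio
  $(a_\mu/a_0)/q_\mu$.  The wNRM achieves this by drawing putative times
  at rates $d_m = q_m a_0$, which preserves $\sum_m d_m = a_0$ and hence
  the exponential inter-event law.  Over $n$ runs the estimator
  accumulates $k_1 = \sum w$ and $k_2 = \sum w^2$ over successful runs;
  $\hat p = k_1/n$ is unbiased for any absolutely continuous scheme,
  with sample variance $\hat\sigma^2 = k_2/n - \hat p^2$ and a 68%
  uncertainty $\sqrt{\hat\sigma^2/n}$.

Weights accumulate in log space and are exponentiated once per
successful run, because products of hundreds of likelihood ratios
underflow double precision long before they matter statistically.

With the natural scheme ($q_m = a_m/a_0$) the weighted engines consume
the same random-number stream as the exact ones and reproduce their
trajectories bit for bit; the test suite asserts this degeneracy.

When a channel's putative rate drops to zero the wNRM stores
$\tau_m = \infty$; when a zero-rate channel becomes active again a fresh
exponential is drawn (rescaling from rate zero is undefined).  Ties on
putative times are resolved toward the lowest channel index — a
measure-zero event that matters only for deterministic replay in tests.

## Choosing the bias: the group heuristic

The selection procedure reasons about the number of reaction firings
rather than about full trajectories.  Let $K_T$ be the total number of
firings in $[0, T]$ under natural dynamics, with mean $\bar K_T$ and
standard deviation $\sigma_{K_T}$ (estimated from a pilot of unweighted
SSA runs that deliberately ignore the event region, so they measure the
natural flow).  Reactions are partitioned by their effect on the target
coordinate:

* $G_1$ — moves $X_i$ toward the threshold ($\nu_{im}\eta > 0$),
* $G_2$ — moves it away,
* $G_3$ — leaves it unchanged.

Reaching the threshold at exactly the $K_E$-th firing requires
$K_1 - K_2 = |\eta|$ toward/away firings.  The probability of that split
under constant group probabilities is a binomial (two groups) or
multinomial (three groups) expression, and the procedure maximizes its
dominant term:

1. **Event count.**  The conditional hit probability grows with the
   number of available steps, but the chance of seeing more firings than
   the natural mean falls off sharply (the pilot-measured $\sigma_{K_T}$
   is small relative to $\bar K_T$ for these systems).  $K_E$ is
   therefore placed at the top of its admissible band
   $[\,|\eta|,\ \bar K_T\,]$: $K_E = \lfloor \bar K_T \rfloor$, clamped
   below at $|\eta|$.  An event that needs more firings than naturally
   occur is reported as an infeasible horizon.
2. **Two groups.**  The binomial term is maximized in closed form at
   $Q_1^* = (K_E + |\eta|)/(2 K_E)$.
3. **Three groups.**  With natural group frequencies $\hat Q$ (pilot
   mean group counts over mean $K_T$), the dominant number of away-steps
   $\kappa$ is the argmax over $K_2$ of the multinomial term with
   exponents $(K_2 + |\eta|, K_2, K_E - 2K_2 - |\eta|)$; the search
   walks consecutive term ratios in the log domain, so no factorial is
   ever formed.  The simulation probabilities are then the exponent
   proportions $Q^* = (\kappa + |\eta|, \kappa, K_E - 2\kappa -
   |\eta|)/K_E$.
4. **Double steps.**  Channels that change the target by two molecules
   (dimerization products) get their own subgroups; within-group
   proportional allocation preserves the natural unit/double mix, so
   each coarse group acts with an effective step size
   $e_g = (\bar N_{g1} + 2\bar N_{g2})/(\bar N_{g1} + \bar N_{g2})$ and
   the count balance becomes $e_1 K_1 - e_2 K_2 = |\eta|$.  All closed
   forms reduce to the unit-step ones when no double steps exist; tests
   verify both the reduction and agreement with numeric maximization.

### From group targets to per-step probabilities

Two constructions turn the targets $Q^*$ into per-step probabilities:

* **Constant group totals** (the generic `group_scheme`): in every
  state each group receives exactly its target mass, split within the
  group in proportion to current propensities.  If a group is silent in
  some state (zero total propensity), its mass is redistributed over
  the live groups in proportion to their targets — this keeps
  $\sum q = 1$ and absolute continuity.
* **Scaled natural probabilities** (`scaled_scheme`): each directional
  channel keeps its natural state-conditional probability scaled by the
  constant $\lambda_g = Q_g^*/\hat Q_g$, and the neutral group absorbs
  the slack in proportion to its propensities.

The second construction exists because the first one is a poor fit for
systems in which directional channels are regularly silenced by binary
(0/1-valued) species, such as enzyme/complex cycles.  There the natural
probability of the committed catalytic step differs by an order of
magnitude between enzyme states; forcing a constant group total
over-biases it in some states and under-biases it in others, and we
measured estimator variances three to four orders of magnitude worse
than with the scaled construction on the futile-cycle benchmark.  The
scaled construction also keeps the per-step weight factor of every
directional firing constant at $1/\lambda_g$, which bounds the weight
spread.  `select_scheme()` picks the scaled construction automatically
whenever some directional reaction consumes a binary, non-frozen
species; the choice is recorded in the selection report.

### Partitioning with conserved pools

The sign rule $\nu_{im}\eta$ misclassifies systems in which a unit of
the target species is temporarily sequestered into a complex: the
binding and release shuttles would be labelled directional although they
do not move mass through the cycle.  The partition therefore works on a
lumped coordinate $Y = X_i + \sum(\text{complexes})$, where a complex is
a binary species produced one-for-one by a reaction that consumes the
target (binary species are detected from pairwise conservation laws
$X_a + X_b = \text{const}$ and frozen species).  For the enzymatic
futile cycle this sends all four shuttles to $G_3$ and leaves exactly
the two committed conversion steps as $G_1$ and $G_2$, from either of
the two equivalent event formulations ($X_5$ down or $X_2$ up).  In
systems with no pool structure, a directional reaction whose own firing
always silences it (a binary reactant it consumes) is demoted to $G_3$,
since consecutive firings are impossible and biasing it is fruitless.
Explicit user overrides take precedence over both rules.

### Fine-tuning the neutral group

$G_3$ reactions can still help or hinder by shifting the propensities of
the directional groups; `subpartition_g3()` classifies them by their
stoichiometric effect on the reactants of $G_1$/$G_2$ (helping $G_{31}$,
hindering $G_{32}$, neutral $G_{33}$), verified in tests against direct
perturbation.  With natural subgroup shares $s_{3i}$, the optional
fine-tuning reallocates the neutral mass as
$$
Q_{31} = Q_3^*\,(s_{31} + \alpha s_{33} + (1-\beta) s_{32}), \quad
Q_{32} = Q_3^*\,\beta s_{32}, \quad
Q_{33} = Q_3^*\,(1-\alpha) s_{33},
$$
with constants $\alpha \in (0,1)$, $\beta \in [0,1)$ (defaults 0.85 and
0.80).  The three parts sum to $Q_3^*$ identically; $Q_{31}$ always
exceeds and $Q_{32}$ always falls below their natural shares.  The
hindering subgroup keeps a fraction $\beta$ of its share, so the
perturbation is deliberately mild: aggressive reallocation makes the
neutral-group weight factors drift far from one and we observed it
destroy rather than improve the variance.  Fine-tuning silently passes
through (with a message) when there is no hindering flow to shift.  The
result is insensitive to the exact constants — the bundled tests compare
$(0.85, 0.80)$ against $(0.80, 0.75)$.

## The independent oracle

Every estimator is validated against a truncated continuous-time Markov
chain: `build_ctmc()` enumerates the states reachable from
$\mathbf{x}_0$ (breadth-first, bounded by conservation-implied or
user-given per-species bounds, with boundary flow collected in a "leak"
state), makes the event region absorbing, and `first_passage_prob()`
integrates the chain by uniformization — Poisson-weighted powers of the
uniformized transition matrix, with the dropped tail mass reported.  The
result is exact for the truncated chain up to the reported leak and tail
terms, both far below $10^{-10}$ on the bundled systems.  Tests assert
probability-mass conservation, monotonicity in $T$, the single-reaction
closed form $1 - e^{-cT}$, and agreement of transition rates with
independently evaluated propensities.

## Benchmark systems and what the tests show

Three bundled fixtures serve as study conditions (`fixture_system()`):
the production–degradation pair ($c = (1, 0.025)$, $x_0 = (1, 40)$,
$T = 100$, thresholds 65–80), the four-reaction convert/decay system
($c = (0.1, 0.1, 8, 0.1)$, $x_0 = (40, 40, 1)$, $T = 10$, thresholds
65/68), and the enzymatic futile cycle ($c_1 = c_2 = c_4 = c_5 = 1$,
$c_3 = c_6 = 0.1$, $x_0 = (1, 50, 0, 1, 50, 0)$, $T = 100$, thresholds
25/40).  Under the printed stoichiometry the futile cycle conserves
$X_1 + X_3$, $X_4 + X_6$ and $X_2 + X_3 + X_5 + X_6$ (the free pair sum
$X_2 + X_5$ dips by up to two while molecules sit in the complexes); the
tests assert the exact laws.

`random_system()` generates syntactically valid mass-action networks
(orders $\le 2$, positive rates) for property tests — dependency-graph
correctness, priority-queue agreement with a full scan, normalization of
biased probabilities, subgroup classification against perturbation.
These random networks exercise the machinery, not the biology: they need
not be ergodic, interesting, or even capable of reaching their event
threshold, and tests skip infeasible draws.  Passing them shows the
algorithms are implemented correctly, not that the selection heuristic
is effective on any particular real network; effectiveness is
demonstrated only on the three benchmark systems.

Problem sizes are chosen for desk-scale reproduction: pilots use $10^3$
runs, estimates $10^5$ weighted runs (the published tables used
$10^6$–$10^7$), try-and-test probes $10^5$ runs per candidate.  At
$10^5$ runs the selected schemes deliver relative standard errors of
0.3–1% on all ten benchmark quantities, so reproduction to a few percent
is expected and observed; the estimator-variance quantities themselves
are noisier (variance-of-variance), which the tests absorb with
proportionally wider bands.

## Numerical choices and degenerate inputs

* Dimerization propensity is $c\,x(x-1)/2$ (combinatorial pair count),
  so rate constants in configurations are unambiguous.
* $a_0 = 0$ is a no-reaction signal: the trajectory idles to $T$ and
  misses (unless it already sits in the event region, which counts as a
  hit at $t = 0$ with weight 1).
* A bias scheme that gives zero probability to a reaction with positive
  propensity raises an absolute-continuity error instead of silently
  biasing the estimator.
* With step size 2 the single-state event region can be jumped over; the
  default convention counts the first crossing
  ($\mathrm{sign}(\eta)(X_i - \theta) \ge 0$), which coincides with the
  exact hit for unit-step systems.  `convention = "hit"` restores the
  strict equality reading.
* $\kappa$ search ranges use $\lfloor (K_E - |\eta|)/2 \rfloor$; no
  parity forcing is applied to $K_E$.
* One seedable R random-number stream drives each run set, so
  `(method, scheme, seed, n)` fully determine an estimate; trajectories
  are consumed sequentially from the stream.

## Limitations

* Mass-action elementary kinetics only (orders 0–2); no Hill or
  Michaelis–Menten rate laws, no time-varying constants, no SBML.
* The event region is a single threshold on one species; no compound or
  time-dependent regions.
* Binary-species detection uses pairwise conservation laws; more exotic
  conservation structures (three-way cycles of complexes) would need
  partition overrides.
* The selection heuristic targets the dominant event-count term; it is
  near-optimal for the benchmark class but carries no optimality
  guarantee for arbitrary networks.  Unbiasedness, however, holds for
  every absolutely continuous scheme, optimal or not, and is tested
  with deliberately perturbed schemes.
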