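---
title: "Timing uncertainty in collective risk dilemmas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing uncertainty in collective risk dilemmas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crdtiming)
```

This vignette documents the modeling conventions, estimator choices and
parameter defaults behind `crdtiming`, in enough detail that every number
the package produces can be traced to a stated decision.

## The game and its timing model

A group of `N` players, each endowed with `E` monetary units, contributes
0, 2 or 4 units per round to a common pool. Reaching the collective
threshold `τ` secures everyone's remaining endowment; failing to reach it
by the end of the game destroys each remainder with probability `r`. The
defaults (`N = 6`, `E = 40`, `τ = 120`, `r = 0.9`) make the *fair share*
`F = E/2 = 20` the equal per-player total that exactly meets the
threshold.

**Termination convention.** Rounds `1..m0` are always played; after round
`m0`, and after every subsequent round, the game stops with probability
`w`. The ending round `M` is therefore `m0` plus a geometric random
variable: `P(M = m0 + k) = w (1 − w)^k`. This convention — the end check
*after* round `m0` rather than before it — is the one under which the
mean length `m0 + (1 − w)/w` equals 10 rounds for both uncertainty
presets (`m0 = 8, w = 1/3` and `m0 = 6, w = 1/5`) as well as for the
fixed-length game (`m0 = 10, w = 1`), which is how all three treatments
were presented to participants. If a variant protocol checks before
round `m0`, pass `m0 − 1` instead.

**Analytic tails instead of truncation.** Deterministic, memory-one
strategies make every trace eventually static: once the target is met all
strategies stop, and two consecutive all-zero rounds imply all-zero play
forever (the public state can never change again). `static_round()` finds
the exact round `M*` from which nothing changes, so expectations over the
ending round use explicit geometric masses for rounds `m0 .. M* − 1` plus
one aggregated tail mass `(1 − w)^(M* − m0)` at `M*`. No epsilon
truncation is involved; termination masses always sum to 1 to machine
precision.

**Payoffs in expectation.** When the group fails, the disaster is applied
in expectation: the payoff is `(1 − r)(E − C_i)` rather than a sampled
loss. The evolutionary model consumes expected payoffs, so sampling the
disaster would only add variance. The Monte-Carlo oracle used in the test
suite samples ending rounds (not disasters) for the same reason.

**Endowment clipping.** A rule requesting more than the remaining
endowment contributes the largest feasible action instead. With the
default parameters this never triggers mid-game (40 is divisible by every
action), but it keeps nonstandard configurations well defined.

## The five strategies

Three unconditional behaviors (`always0`, `always2`, `always4`) and two
conditional ones, both reacting to `x`, the total contributed by the
other `N − 1` group members in the previous round:

* `reciprocal`: contributes `high_action` when `x ≥ θ`, else
  `low_action`; opens with `first_action` in round 1.
* `compensator`: contributes `high_action` when `x < θ`, else
  `low_action`; round 1 counts as "no previous contribution".

All five return 0 once the pool has reached `τ`.

The conditional rules are described qualitatively in the experimental
literature ("contributes as long as the group contributes" / "contributes
when the group did not"); the package must fix numbers. Defaults, all
overridable per run:

* `θ = 2(N − 1) = 10`: the others averaging at least the low positive
  action counts as "the group contributed". This separates the observed
  regimes in conditional-response plots, where action 4 becomes frequent
  after high group contributions and action 0 after low ones.
* `high_action = 4`, `low_action = 0`: the conditional types move between
  the extremes; the middle action is the signature of the unconditional
  fair-share type.
* `first_action = 4` for the reciprocator: an optimistic opener. A
  homogeneous reciprocal group must be able to reach the target (it then
  replays the always-4 trace exactly), otherwise the strategy could never
  support group success in the evolutionary model.

These defaults are design decisions, not measured facts; conclusions that
depend on them should be checked against overrides (the `strategies`
section of the run config reaches every entry point).

## Evolutionary dynamics

A well-mixed population of `Z` individuals (default 50), each committed
to one strategy, plays in groups of `N` sampled without replacement.
The expected payoff of a focal player when the population holds `k`
copies of strategy A and `Z − k` of B weights each group composition by
its hypergeometric probability and scores it with the exact game
expectation above.

Strategy revision follows the pairwise-comparison (Fermi) rule with
selection strength `β` (default 0.004): a focal individual copies a
random model with probability `1/(1 + exp(−β Δπ))`. In the small-mutation
limit the population is monomorphic almost always, and the dynamics
reduce to a Markov chain over the five pure states whose transitions are
single-mutant fixation probabilities. Those are computed with the
standard birth–death closed form, with the products accumulated in log
space so large `Z·β` cannot overflow; the stationary distribution comes
from a null-space solve of the embedded chain. The test suite checks the
closed form against a numerical solve of the absorbing chain (to 1e−10)
and the stationary distribution against a direct simulation of the
rare-mutation imitation process (to Monte-Carlo error).

Model summary metrics:

* **Group achievement `η`** — success probability of a monomorphic group
  of each strategy, weighted by the stationary distribution. Monomorphic
  weighting is the consistent choice in the small-mutation limit, where
  polymorphic states are vanishingly rare.
* **Reciprocal prevalence** — stationary mass of `reciprocal` divided by
  the mass of the four contributing strategies (excluding `always0`).
* **Polarization** — `1 − P(|C − F| ≤ tol)` with `tol = 0` by default:
  the probability that a player's total contribution differs from the
  fair share, over groups sampled multinomially from the stationary
  mixture with geometric game lengths (default 10⁴ groups, seeded). A
  variance-based alternative (`Var(C)/F²`, capped at 1) is available via
  `polarization_index(method = "variance")` for sensitivity analysis.
  The band metric was chosen because the experimental observation it
  mirrors is a count of players away from `F`, not a spread statistic.

With the default strategy parameters at `Z = 50`, `β = 0.004`, the model
reproduces the qualitative pattern of interest — reciprocal prevalence
and polarization both increase from NU through LU to HU — while `η`
moves less, relative to its no-uncertainty baseline, than reciprocal
prevalence does. Selection at `β = 0.004` is weak, so stationary masses
stay well away from degeneracy; the sizes of these effects (though not
their directions) are sensitive to the conditional-strategy defaults
above.

## Analysis pipeline conventions

* **Per-round means** are means over groups of the group's round total,
  with a t-interval across groups (95% by default). Under uncertainty,
  later rounds are observed only for groups whose game lasted that long;
  the per-round group count is reported, and a single-group round yields
  an `NA` interval rather than a fabricated one.
* **Success** means the cumulative pool reached `τ` by the realized final
  round. The success fraction carries an exact Clopper–Pearson binomial
  interval.
* **Halves.** The first half is rounds `1 .. m0/2` (5, 4, 3 for the three
  presets); the second half runs from there to the realized end, so its
  length is random under uncertainty. Half-contributions are classified
  against `F/2`.
* **Conditional response.** For every decision from round 2 on, `x` is
  the others' previous-round total. Bin-level means are fit by weighted
  least squares with weights equal to bin observation counts; the slope
  sign is the reciprocity indicator. Raw bin counts are always exposed so
  other weighting or error-bar conventions can be applied downstream.
* **Profile classification** approximates a clustering of participants
  into behavioral types with a transparent rule: constant action →
  unconditional; otherwise the sign of the player's own action-on-`x`
  regression slope, with a default cutoff of 0.05 units per unit
  (config-exposed and reported with every output). Two classes of
  uninformative decisions are discarded first: rounds after the group met
  the target, and rounds where the player could no longer afford the
  smallest positive action — in both cases the observed zeros are forced,
  not chosen. Classification is identifiable only when a player's
  environment crossed `θ` in both directions; a reciprocator whose
  partners always contributed is observationally identical to `always4`
  and is reported as such.

## The synthetic generator

`generate_cohort()` emulates the *shape* of the experimental data: groups
of 6, actions on the {0, 2, 4} grid capped by the endowment, one realized
length per group drawn from the treatment's termination law, behaviors
drawn from a configurable mixture of the five strategies, and
trembling-hand noise (with probability `noise_eps` the intended action is
replaced by a uniform draw from the action set — replacement rather than
additive noise keeps actions on the grid). Noise applies only while the
target is unmet; reaching the target ends the dilemma, so post-target
decisions are forced zeros.

What it does *not* emulate: learning within or across games, memory
deeper than one round, framing or communication effects, demographic
heterogeneity, or any drift in strategy over rounds. Passing recovery
tests on generator output therefore shows that the pipeline's estimators
are correct and unbiased on data with planted structure — not that real
participants are well described by five deterministic rules.

## Numerical choices and degenerate inputs

* Termination masses are exact (explicit + analytic tail, sum 1 within
  1e−12); `w = 1` degenerates to a point mass at `m0`.
* Fixation sums run in log space; `β = 0` returns exactly `1/Z`.
* The stationary solve rejects solutions with negative mass beyond
  1e−12 (numerical guard) instead of silently clipping.
* Regression on fewer than two distinct bins, empty player selections,
  and single-group intervals raise or flag rather than guess.
* Problem sizes in the shipped tests and acceptance script — Z = 12 for
  oracle comparisons, 40k simulated embedded-chain transitions, 10⁴
  polarization groups, cohorts of 25–150 groups — were chosen so the
  Monte-Carlo standard errors are a few times smaller than the effects
  being checked.

## Known limitations

* The five-strategy space is minimal by design; richer conditional rules
  (longer memory, graded responses) would need new `decide()` kinds.
* The small-mutation-limit analysis cannot represent stable polymorphic
  mixtures; the full-chain process exists only as a simulation oracle.
* The polarization and η estimators are reasoned choices among several
  defensible ones (both are pluggable); comparisons across studies
  should state the estimator used.
* The deposit adapter ships as a validated schema template; column names
  should be confirmed against the downloaded file before use.
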