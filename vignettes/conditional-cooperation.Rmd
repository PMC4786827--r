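---
title: "Conditional cooperation under multilevel selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional cooperation under multilevel selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlspgg)
```

## The model

`mlspgg` simulates the evolution of conditional cooperation in a
group-structured population. A population of `g` groups of `n` individuals
plays a continuous-contribution public goods game within each group:
individual `i` in group `j` contributes `c_ij` of a unit endowment, the pooled
contributions are multiplied by the total return `r` (`1 < r < n`) and shared
equally, so

    w_ij = w0 + 1 - c_ij + (r/n) * sum_k c_kj.

The marginal per-capita return `r/n` is below 1, so contributing nothing is
the dominant action in one-shot play regardless of the others; `w0` is a
baseline payoff that dilutes payoff differences (large `w0` means weak
selection on the game).

Selection acts on two levels. Within groups, the next generation of a group
is drawn with replacement from its current members with probabilities equal
to payoff shares, which favors low contributors. Between groups, each group
enters a conflict pool with probability `k` per generation; pool members are
randomly paired, and a group with mean contribution `C_i` beats its opponent
`C_j` with probability `0.5 + 5 (C_i - C_j)` (clamped), so a contribution
advantage above 0.1 wins for sure. The winner's members repopulate the
loser's site. Mutation (probability `mu` per individual, uniform over the
strategy space) and migration (probability `m` per individual) complete the
generation.

## Strategies and within-group equilibrium

Strategies are piecewise linear response functions mapping the *others'*
mean contribution `xbar` to one's own contribution. A strategy is fixed by
its contribution at `xbar = 0, 0.5, 1`, each anchor in {0, 0.5, 1}, giving
27 strategies encoded as ternary strings (most significant digit first) and
decimal labels 0–26. Landmarks: Type 0 (000) is a free rider, Type 5 (012)
the perfectly conditional cooperator, Type 26 (222) an unconditional
cooperator, and Type 2 (002) contributes nothing until the others average
above 0.5, then rises linearly to full contribution — unexploitable, yet
able to sustain a fully cooperative group.

Realized contributions are the long-run outcome of repeated interaction.
Members start from an optimistic belief (everyone expects full
contribution), contribute according to their response function, and all
update beliefs simultaneously to the others' realized mean. The iteration
stops at a fixed point (max change below `tol = 1e-9`), or on an exact
recurrence of the contribution vector rounded to 12 decimals — a limit
cycle, whose per-member average over one period is the long-run average
contribution (a group of Type 18 "contrarians" alternates 0 and 1 and
realizes 0.5). Because anchors sit on a half-integer grid and the
interpolation is linear, most orbits live on a small rational set and exact
recurrence detection is effective. If neither occurs within `max_iter = 200`
rounds (slowly contracting mixtures can need more), the average over the
trailing 50 rounds is returned and flagged; this fallback is our choice of
equilibrium selection for non-convergent dynamics, and in baseline runs it
is rarely triggered.

Two consequences of this equilibrium concept are worth stating because they
shape everything downstream. First, a group of conditional cooperators
containing a single free rider has the all-zero profile as its unique
consistent fixed point, so the group collapses entirely; stabilized
populations are therefore near-binary at the group level (group means near 0
or 1). Second, in a collapsed group all payoffs are equal, so within-group
selection is inert there and the baseline payoff `w0` has little leverage on
the stabilized state (see "Known limitations").

Synchronous updating was chosen because it is deterministic and order-free;
an asynchronous scheme would need an update schedule that the model
description does not supply, and it would break the permutation symmetry
that the test suite asserts.

## Parameters

| Parameter | Meaning | Default | Swept range |
|---|---|---|---|
| `n` | group size | 20 | 5–30 |
| `g` | number of groups | 20 | `round(400/n)` when sweeping `n` |
| `k` | conflict probability per group | 0.20 | 0.05–0.30 |
| `m` | migration probability | 0.15 | 0.05–0.25 |
| `mu` | mutation probability | 0.01 | fixed |
| `w0` | baseline payoff | 0 (strong selection) | 0–5 |
| `r` | total return on cooperation | 2 | fixed |
| `generations` | horizon | 5000 | — |

`r` deserves a note: the conflict formulation treats equal differences in
group mean payoff and group mean contribution interchangeably, and since a
group's mean payoff is `w0 + 1 + (r - 1) C_j`, that equivalence pins
`r = 2` (marginal per-capita return 0.1 at `n = 20`). It remains a free
config field.

The conflict step reads "with probability `k`" as an independent Bernoulli
draw per group for entering the pool, making `k` a per-group per-generation
conflict rate; an odd pool member sits out. Migration is implemented as a
uniform random permutation of the vacated slots, which preserves both group
sizes and the population's strategy multiset exactly — unilateral relocation
would not.

## Observables

Per generation (recorded at the provision step, before reproduction):
population mean contribution, the 27 strategy frequencies, and two
selection-strength proxies — `Var(c_j)`, the variance across groups of
group-mean contributions (between-group selection), and `E[Var(c_ij)]`, the
mean within-group variance (within-group selection). All variances and
covariances are population (divide-by-N) moments; this is not cosmetic, as
the Price-equation identity and the law-of-total-variance decomposition
`Var(all c) = Var(c_j) + E[Var(c_ij)]` hold exactly only in that convention,
and both are asserted in the tests.

Cooperative epochs are maximal runs of generations with mean contribution
strictly above 0.6 (a generation exactly at the threshold ends an epoch);
their mean length summarizes the stability of cooperation. The qualitative
orderings reported by sweeps are insensitive to moving the threshold to
0.55 or 0.65.

The Price decomposition splits the expected change of a trait's frequency
into `Cov_q(w_j, p_j)` (between-group, selective migration) and
`E_q[Cov_j(w_ij, p_ij)]` (within-group, payoff-proportional reproduction),
scaled by mean payoff. For the public goods payoff these reduce to
`(r - 1) Var_q(p_j)` and `-E_q[Var_j(p_ij)]`, so a costly trait spreads iff
`(r - 1) Var_between > E[Var_within]` (`viability_condition()`). The
decomposition is verified against `price_oracle()`, a brute-force
computation of the expected next-generation frequency, on a thousand random
small instances to 1e-12.

## What the simulation shows

From random initial strategies (each of the 27 at roughly 1/27), mean
contribution starts near 0.5; within-group selection first strips out
exploitable strategies, collapsing cooperation below 0.1 within ~20
generations while unexploitable strategies (Types 0, 1, 2) rise; then
between-group selection takes over and Type 2 — unexploitable *and* capable
of full group contribution — spreads until it dominates, with cooperation
recovering to a high quasi-stationary level punctuated by occasional
collapses and recoveries (hence the epoch statistics; in a minority of runs
cooperation fails to recover within the horizon). The outcome is robust to
homogeneous initial conditions (all Type 0 or all Type 5), cooperation
increases with `k` and decreases with `n` and `m`, and restricting the
strategy space to the three unconditional strategies locks the population
at zero cooperation — all of which the test suite checks at reduced scale.

## Numerical and design choices

- Equilibrium iteration in compiled code (Rcpp): it runs for every group in
  every generation and is the only hot loop; everything else is vectorized R.
- Desk-scale defaults: experiments default to 5 replicates of 5000
  generations (a single baseline run takes a few seconds); the reference
  condition averages 50 replicates, available by setting `runs = 50`.
  Reduced-scale checks in the test suite use 1200–2000 generations, where
  the direction of sweep effects is already stable in the *stabilized* mean
  (whole-run means at short horizons are transient-dominated).
- "Stabilized" statistics average the final 20% of generations (the final
  1000 of 5000); whole-run means are used for sweep summaries.
- Replicate `i` of an experiment runs with seed `base_seed + i` (sweep cell
  `v` offsets by `1000 v`), so every run is individually reproducible.
- Degenerate inputs: empty groups and `max_iter < 2` are errors; a group
  with non-positive total payoff would fall back to uniform reproduction
  draws with a warning (unreachable for `w0 >= 0` since payoffs are then
  strictly positive, but guarded).

## Known limitations

- Under the literal iterate-to-equilibrium semantics, infected
  conditional-cooperator groups collapse to exactly zero, which makes
  stabilized group means near-binary, keeps the stabilized within-group
  proxy small (~0.006 in baseline runs), pushes the between-group proxy
  toward the binary bound `p(1-p)`, and largely removes the leverage of
  `w0` on stabilized cooperation. Reference accounts of this model report a
  larger stabilized within-group variance, a smaller between-group
  variance, and a strong positive `w0` effect, implying persistent
  within-group contribution heterogeneity; reproducing that would require a
  different (and, from the model description, unspecified) equilibrium
  concept. We verified that truncating the interaction to a small fixed
  number of rounds does not fix this — it instead destroys cooperation at
  strong selection entirely — and kept the literal semantics.
- At `w0 = 5` the dominant strategy in this implementation is Type 18
  (digits 200) rather than a third-digit-2 strategy: with within-group
  selection diluted everywhere and collapsed groups contributing nothing,
  groups anchored by contrarians (floor contribution ~0.5) win conflicts
  against collapse-prone conditional cooperators.
- The synthetic dynamics emulate idealized evolution: equal and fixed group
  sizes, global migration, uniform mutation, no spatial structure, no
  payoff noise, no perception error on `xbar`. Passing tests therefore
  validate the model's internal logic, not its fit to behavioral data.
- One Nash-consistency caveat: the trailing-window fallback for
  non-convergent, non-cyclic orbits is an averaging convention, not an
  equilibrium refinement.
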