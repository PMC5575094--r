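---
title: "Aspiration learning in the Dictator Game: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aspiration learning in the Dictator Game: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normsim)
```

## The model

`normsim` simulates a well-mixed population of `N` agents that repeatedly
play one-shot Dictator Games. The DG is degenerate as a game — the recipient
has no move — which makes it a clean probe of *expectations*: any positive
donation reflects something other than strategic best reply. The model's
premise is that donations are driven by aspirations (the donation an agent
expects to receive when it is the recipient) and that aspirations are updated
by reinforcement learning, a Bush–Mosteller-style rule, from the donations
actually received.

Each time step all agents are matched uniformly at random into `N/2` pairs,
roles are assigned by a fair coin within each pair, and every recipient
updates as follows (dictators never update — learning happens on the
receiving end and is used the next time the agent dictates):

* stimulus `s = (π − A)/(Φ − A)` (0 when `A = Φ`), clamped to `[−1, 1]`;
* aspiration `A′ = A + (Φ − A) l s` for `s ≥ 0`, `A′ = A + A l s` otherwise;
* donation `D′ = (1 − h) D + h π` (habituation/herding);
* aspiration bound `D′ ← max(0, min(D′, Φ − A′))` — a dictator never keeps
  less than she aspires to; note the bound uses the *updated* aspiration,
  which is what couples the two state variables;
* optionally, trembling-hand noise `D′ ← D′ (1 + ε)`, `ε ~ N(0, δ)`, clipped
  to `[0, Φ]`;
* optionally, an inequity-aversion cap `D′ ← min(D′, Φ/2)` for envious
  agents;
* a final clip to `[0, Φ]`.

Populations are initialized with `A ~ U[0, Φ]` i.i.d. and `D = Φ − A`.
Free-riders, when present, are frozen at a fixed donation (default 0) and
never update either variable; they do, however, play both roles, so their
fixed donation keeps entering other agents' updates.

### Parameters

| parameter | meaning | range | default |
|---|---|---|---|
| `endowment` (Φ) | pie per game, money units | > 0 | 1 |
| `learning_rate` (l) | weight of the stimulus in aspiration updates | [0, 1] | — |
| `habituation` (h) | weight of the received donation in one's own donation | [0, 1] | — |
| `noise_scale` (δ) | SD of the multiplicative trembling-hand term | ≥ 0 | 0 |
| `envy_probability` | chance an agent is inequity-averse (a fixed trait) | [0, 1] | 0 |
| `n_free_riders` | frozen agents | 0..N | 0 |
| `free_rider_donation` | their fixed donation | [0, Φ] | 0 |
| `n_agents` (N) | population size, even | ≥ 2 | 1000 |

The *general regime* is `l, h ∈ [0.2, 0.8]`: both learning and habituation
present but neither absent nor overwhelming. The predefined experiment suite
(`predefined_conditions()`) covers the grid `l, h ∈ {0.2, 0.4, 0.6, 0.8}`
under seven conditions: deterministic, weak (δ = 0.01) and moderate (δ = 0.1)
noise, inequity aversion (probability 0.05) with and without δ = 0.1, and one
frozen zero-donor with and without δ = 0.1. Envy probability 0.05 and a
*single* free-rider are deliberate: the point of the variants is that the
generous norm is robust to a few envious agents but fragile to even one
agent who refuses to learn.

### Stationarity and replication protocol

A run evolves through a transient (default 10000 steps), then through
1000-step windows; after each window an OLS line is fitted to the
population-mean donation against the step index within that window, and the
run stops when `|slope| < 10⁻⁴` (strict). The slope is computed on the raw
per-step means, unsmoothed — the simplest reading of the criterion. A
`max_steps` guard (default 10⁶) returns a flagged partial result instead of
looping forever; `slope_tol = 0` can never fire, which the tests use to
exercise the guard. Each condition is replicated (default 100×) and the
final-state donation vectors are pooled across replications and grid cells.

Seeding is hierarchical and documented: replication `i` of cell `c` (row-major
over the `(l, h)` grid) uses `set.seed(base_seed + (c−1)·n_reps + i − 1)`, so
any run of a sweep is reproducible in isolation.

## Summary statistics

Distributions are always reported on the fixed 0.1-wide binning: bin `n`
counts values with `n/10 ≤ D < (n+1)/10`, with `D = Φ` assigned to bin 10
(`donation_histogram()`). Three scalar summaries of the pooled final
donations are computed:

* `mean_donation()` — the pooled mean `⟨d⟩`;
* `histogram_gini()` — the Gini coefficient of the 11 bin frequencies, a
  **concentration** measure of the binned distribution. It is ≈ 10/11 when
  a single bin holds everyone (a strict social norm, "no deviant subjects")
  and 0 when all bins are equally occupied. This is the `G` statistic used
  to label conditions throughout the package;
* `equality_index()` — `1 − Gini(values)`, the value-based complement of the
  standard sample Gini (`gini_coefficient()`), with the Gini computed as the
  mean absolute pairwise difference over twice the mean.

The distinction matters: a population that uniformly donates *zero* is
perfectly concentrated (`histogram_gini` near its maximum — everyone follows
the same, selfish, norm) while its value-based Gini is dominated by the few
positive donors. We report the concentration index as the headline `G`
because it is the one that behaves consistently across all conditions,
including the free-rider collapse, and matches the interpretation "G close
to 1 ⇒ almost no deviant subjects"; both the equality index and the raw Gini
are nevertheless exposed in every summary and output file so users can pick
either convention.

## Numerical and design choices

* **Stimulus clamping.** The raw ratio `(π − A)/(Φ − A)` drops below −1
  whenever `A > Φ/2` and `π` is small, which would let the aspiration update
  produce negative aspirations. We clamp the stimulus to `[−1, 1]` after
  evaluation; this preserves the stated range of the stimulus and the
  invariant `A ∈ [0, Φ]`. We also checked the alternative (raw stimulus with
  the aspiration clipped to `[0, Φ]` afterwards): on the general-regime grid
  the pooled statistics agree to well within Monte-Carlo error, so nothing
  downstream hinges on this choice.
* **Update order.** Habituation → aspiration bound (against the updated
  aspiration) → noise → envy cap → final clip. Noise comes after the bound
  because the bound is only guaranteed in the absence of noise; the envy cap
  is an absolute ceiling, so it is applied last.
* **Noise clipping.** `(1 + ε)D` can leave `[0, Φ]` for large `|ε|`;
  donations are clipped to `[0, Φ]`, since donations outside the pie are
  meaningless. The clipping is asymmetric in effect (donations near 0 cannot
  fall further but can rise), which contributes to the downward drift of the
  mean under noise.
* **Matching semantics.** "Pairs are randomly chosen" is implemented as a
  full uniform random perfect matching each step, so every agent plays
  exactly one game per step. With one-pair-per-step matching, a 10⁴-step
  transient would give each agent only ~10 games — far too few for the
  convergence this protocol detects. Roles are independent fair coins per
  pair per step, not balanced or alternated.
* **Envy as a trait.** Inequity aversion is assigned once per agent at
  initialization (Bernoulli), not re-drawn per round: envious *individuals*,
  not envious moments.
* **Frozen agents.** Free-riders skip both updates entirely and draw no
  random numbers; their aspiration is initialized to their frozen donation
  but never enters the dynamics. Their placement in the state vectors is
  irrelevant because matching is uniform.
* **Engines.** The per-step loop exists twice: a pure-R reference
  (`dg_step`) and a compiled inner loop (Rcpp) used by default. Both consume
  R's global RNG stream in exactly the same order (an explicit Fisher–Yates
  shuffle, one uniform per pair for roles, one normal per non-frozen
  recipient), so the two implementations produce bitwise-identical
  trajectories from the same seed — this cross-check is part of the test
  suite, and makes the fast path verifiable against readable R code.
* **Degenerate inputs.** `A = Φ` gives stimulus 0 by definition; all-zero
  donation vectors make the Gini undefined and return, with a warning, 0
  (and equality index 1: no dispersion); `noise_scale = 0` bypasses the
  noise draw entirely rather than drawing and discarding.

## What the simulator does and does not emulate

The generator reproduces the study conditions: uniform initial aspirations,
complementary initial donations, well-mixed random matching, and the seven
predefined parameter conditions above. It does **not** emulate features of
real experimental data such as discrete donation grids (humans donate in
coins), session effects, framing, or heterogeneous individual learning rates
— passing tests therefore validate the dynamics of the model, not the
model's fit to any particular human dataset.

## Problem sizes used by the tests and acceptance script

The packaged checks run the sweeps at N = 200 agents, 10 replications per
cell and a 5000-step transient (about 30 s for all conditions on one CPU);
the predefined suite also carries the full scale (N = 1000, 100 replications,
10⁴-step transient) for users who want it. For the deterministic, weak-noise
and inequity-aversion conditions the pooled statistics at the two scales
agree to within Monte-Carlo error, and the test suite asserts the expected
stationary values (mean donation ≈ 0.37 deterministic, with ≥ 90% of pooled
donations in bins 3–4; lower and wider under δ = 0.1, with a visible selfish
fraction at `h = 0.8`).

## Known limitations

* **Scale sensitivity of the slow conditions.** The per-agent exposure rate
  to any single agent scales as 1/N, and the stationarity criterion is a
  slope threshold per *step*, not per interaction. Conditions whose
  stationary state is approached slowly — a single frozen free-rider, and to
  a lesser degree moderate noise — therefore end at systematically different
  points at N = 200 than at N = 1000 within the same protocol: the
  free-rider collapse is deeper (pooled mean near 0 instead of a small
  positive residual carried by the low-habituation cells), and the noisy
  mean donation is a few hundredths lower. The reduced-scale checks for
  these conditions should be read with that in mind; the qualitative claims
  (norm collapse for `h ≥ 0.4`, widening under noise) hold at both scales.
* A single stationarity criterion (windowed OLS slope of the mean) cannot
  distinguish a stationary distribution from a very slow drift; that is
  intrinsic to the protocol, not an implementation artifact.
* No spatial or network structure, no role persistence, no strategy-update
  rules other than reinforcement learning: all out of scope by design.

## Session info

```{r}
sessionInfo()
```
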