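# normsim

Agent-based simulation of how a *social norm of giving* emerges in the
Dictator Game (DG) from aspiration-based reinforcement learning.

In lab experiments, dictators — who can keep an endowment outright — donate
sizeable fractions of it, and people broadly *expect* such generosity. This
package implements a model in which that behaviour arises endogenously: agents
repeatedly play one-shot DGs against random partners, carry an **aspiration**
(the donation they expect to receive), learn from the mismatch between
received donations and aspirations, and donate according to those
expectations. The model is aimed at researchers in behavioural/evolutionary
game theory who want a tested, reproducible simulator of the dynamics and its
variants (decision noise, inequity aversion, obstinate free-riders).

## Model

A population of `N` agents shares an endowment `Φ` per game (default `Φ = 1`).
Every time step all agents are matched into `N/2` random pairs and one agent
per pair is randomly made dictator; the recipient gets a payoff `π` equal to
the dictator's current donation and is the only one to update:

1. **Stimulus** — `s = (π − A) / (Φ − A)` (0 if `A = Φ`), clamped to
   `[−1, 1]`: the signed, normalized surprise relative to the aspiration `A`.
2. **Aspiration learning** — `A′ = A + (Φ − A)·l·s` if `s ≥ 0`, else
   `A′ = A + A·l·s`, with learning rate `l ∈ [0, 1]`.
3. **Habituation** — `D′ = (1 − h)·D + h·π`: the agent's own donation `D`
   herds towards what it just received, with weight `h ∈ [0, 1]`.
4. **Aspiration bound** — `D′ ← max(0, min(D′, Φ − A′))`: a dictator never
   keeps less than her aspiration.
5. **Trembling hand** (optional) — `D′ ← D′·(1 + ε)`, `ε ~ N(0, δ)`,
   clipped to `[0, Φ]`: imperfect decision making.
6. **Inequity aversion** (optional) — envious agents (trait assigned with
   probability `envy_probability`) never donate more than `Φ/2`.
7. **Free-riders** (optional) — `n_free_riders` frozen agents donate a fixed
   amount (typically 0) and never update anything.

Runs start from `A ~ U[0, Φ]`, `D = Φ − A`, evolve through a transient
(default 10000 steps) and stop when the OLS slope of the population-mean
donation over a 1000-step window falls below `10⁻⁴` (the stationarity
criterion). Conditions are replicated and pooled over a grid of `(l, h)`
values; the pooled final-state donations are summarised by their mean `⟨d⟩`
and by a **concentration index G**: the Gini coefficient of the 11-bin
histogram frequencies (bin `n` covers `n/10 ≤ D < (n+1)/10`), which is near
its maximum when virtually everyone donates the same amount — a strict social
norm — and low for a spread-out distribution. The value-based equality index
`1 − Gini(donations)` and the raw sample Gini are also reported.

## Worked example

```r
library(normsim)
p <- dg_params(learning_rate = 0.5, habituation = 0.5, n_agents = 200)
runs <- simulate(p, nsim = 5, seed = 42, transient = 5000)
summary(runs[[1]])
#> mean donation 0.3660 | concentration G 0.9091 | 1-Gini 1.0000 | stationary at 6000
#> donation histogram (bins 0-10):
#>  0  1  2  3  4  5  6  7  8  9 10
#>  0  0  0  1  0  0  0  0  0  0  0

sw <- pool_sweep(list(list(l = 0.5, h = 0.5, runs = runs)))
sw
#> Dictator Game sweep: 1 cell(s) x 5 run(s) total, N = 200
#>   pooled mean donation <d>    : 0.3902
#>   pooled concentration G      : 0.8727 (histogram Gini)
#>   pooled equality index 1-Gini: 0.9799 (raw Gini 0.0201)
#>   stationary runs          : 5 / 5 (median 6000 steps)
```

Each deterministic replication settles on a sharp common donation — here the
first run's 200 agents all donate ≈ 0.37, every final donation falling in
histogram bin 3 (`0.3 ≤ D < 0.4`), so the binned concentration G is at its
maximum 10/11 ≈ 0.909 and the value-based equality index is ≈ 1. Pooling
several replications mixes slightly different per-run norms (pooled mean
0.39), which lowers the concentration to 0.87.

Full experiment conditions (sweep + files on disk):

```r
run_experiment("deterministic", out_dir = "out", scale = "small", seed = 1)
# writes out/histograms.csv, out/summary.json, out/convergence.csv
```

or from a shell via the bundled CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/normsim.R", package="normsim"))') \
    run --condition stochastic --scale small --seed 1 --out out
```

`predefined_conditions()` lists the seven study conditions (deterministic,
noise 0.01 and 0.1, inequity aversion with/without noise, one free-rider
with/without noise). `plot(sweep)` draws the per-cell donation/aspiration
histogram panels; `plot(run)` the mean-donation trajectory.

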