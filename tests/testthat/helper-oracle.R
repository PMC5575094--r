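# Independent oracles, deliberately written as plain straight-line scalar
# code with no reuse of package internals.

# One recipient update, basic deterministic model only (no noise, no envy):
# stimulus, aspiration learning, habituation, aspiration bound.
oracle_recipient_update <- function(a, d, pi, l, h, phi = 1) {
  if (phi == a) s <- 0 else s <- (pi - a) / (phi - a)
  if (s > 1) s <- 1
  if (s < -1) s <- -1
  if (s >= 0) a2 <- a + (phi - a) * l * s else a2 <- a + a * l * s
  d2 <- (1 - h) * d + h * pi
  if (d2 > phi - a2) d2 <- phi - a2
  if (d2 < 0) d2 <- 0
  c(aspiration = a2, donation = d2)
}

# Brute-force sample Gini: mean absolute difference over all ordered pairs
# (self-pairs included), divided by twice the mean.
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Small convenience: a scaled-down sweep over the general-regime grid.
small_sweep <- function(noise_scale = 0, envy_probability = 0,
                        n_free_riders = 0L, base_seed = 1000,
                        n_agents = 200L, n_reps = 10L, transient = 5000) {
  p <- dg_params(0.5, 0.5, n_agents = n_agents, noise_scale = noise_scale,
                 envy_probability = envy_probability,
                 n_free_riders = n_free_riders)
  run_sweep(p, c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.4, 0.6, 0.8),
            n_reps = n_reps, base_seed = base_seed, transient = transient)
}
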