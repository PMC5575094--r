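#' Initialize a population
#'
#' Aspirations are drawn i.i.d. uniform on `[0, endowment]` and each agent's
#' initial donation is the complement `endowment - aspiration`. The first
#' `n_free_riders` agents are frozen at `free_rider_donation` (their
#' aspiration is set to the same value; it never enters the dynamics since
#' frozen agents do not update). Envy flags are Bernoulli(`envy_probability`)
#' over the non-frozen agents. Matching is uniform over agents, so the
#' placement of frozen agents at the head of the vectors is immaterial.
#'
#' Draw order (fixed, so runs are reproducible given a seed): `n_agents`
#' uniforms for aspirations, then `n_agents` uniforms for envy flags.
#'
#' @param params a [dg_params()] object.
#' @return An object of class `dg_state`: list with numeric vectors
#'   `aspirations` and `donations`, logical vectors `envious` and `frozen`,
#'   and the step counter `t = 0`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "dg_params"))
  n <- params$n_agents
  phi <- params$endowment
  frozen <- rep(FALSE, n)
  if (params$n_free_riders > 0L) frozen[seq_len(params$n_free_riders)] <- TRUE

  aspirations <- runif(n, min = 0, max = phi)
  envious <- runif(n) < params$envy_probability
  envious[frozen] <- FALSE
  donations <- phi - aspirations
  aspirations[frozen] <- params$free_rider_donation
  donations[frozen] <- params$free_rider_donation

  structure(list(aspirations = aspirations, donations = donations,
                 envious = envious, frozen = frozen, t = 0L),
            class = "dg_state")
}

# Fisher-Yates shuffle driven by runif, one uniform per swap. Written out
# explicitly (rather than sample.int) so the compiled engine can consume the
# identical stream of deviates and produce bitwise-identical trajectories.
fy_shuffle <- function(n) {
  perm <- seq_len(n)
  u <- runif(n - 1L)
  for (i in n:2L) {
    j <- floor(u[n - i + 1L] * i) + 1L
    tmp <- perm[i]
    perm[i] <- perm[j]
    perm[j] <- tmp
  }
  perm
}

#' Advance the population by one time step (reference implementation)
#'
#' One step: a uniform random perfect matching splits the `n_agents` agents
#' into `n_agents / 2` pairs; within each pair one agent is chosen as
#' dictator with probability 1/2; every recipient receives a payoff equal to
#' its dictator's current donation and is updated by [recipient_update()].
#' Dictators are unchanged; every agent plays exactly one game per step.
#'
#' This is the pure-R reference engine. [run_steps()] dispatches to a
#' compiled equivalent that consumes the same random-number stream.
#'
#' @param state a `dg_state` from [init_population()].
#' @param params a [dg_params()] object.
#' @return The updated `dg_state` with `t` incremented.
#' @export
dg_step <- function(state, params) {
  n <- params$n_agents
  half <- n %/% 2L
  perm <- fy_shuffle(n)
  first <- perm[seq.int(1L, n, by = 2L)]
  second <- perm[seq.int(2L, n, by = 2L)]
  first_is_dictator <- runif(half) < 0.5
  dictators <- ifelse(first_is_dictator, first, second)
  recipients <- ifelse(first_is_dictator, second, first)

  payoffs <- state$donations[dictators]
  upd <- recipient_update(state$aspirations[recipients],
                          state$donations[recipients],
                          payoffs, params,
                          envious = state$envious[recipients],
                          frozen = state$frozen[recipients])
  state$aspirations[recipients] <- upd$aspiration
  state$donations[recipients] <- upd$donation
  state$t <- state$t + 1L
  state
}

#' Advance the population by many steps
#'
#' Runs `n_steps` time steps, optionally recording the population-mean
#' donation after each step. `engine = "compiled"` uses the C++ loop;
#' `engine = "reference"` loops over [dg_step()] in R. Both consume R's
#' global random-number stream in the same order, so they yield identical
#' trajectories from the same seed.
#'
#' @param state a `dg_state`.
#' @param params a [dg_params()] object.
#' @param n_steps number of steps to run.
#' @param engine `"compiled"` (default) or `"reference"`.
#' @param record record the mean-donation series? (default `TRUE`).
#' @return List with the updated `state` and the numeric vector
#'   `mean_donations` (length `n_steps`, or 0 if `record = FALSE`).
#' @export
run_steps <- function(state, params, n_steps,
                      engine = c("compiled", "reference"), record = TRUE) {
  engine <- match.arg(engine)
  n_steps <- as.integer(n_steps)
  if (engine == "compiled") {
    res <- run_steps_cpp(state$aspirations, state$donations,
                         state$envious, state$frozen, n_steps,
                         params$endowment, params$learning_rate,
                         params$habituation, params$noise_scale, record)
    state$aspirations <- res$aspirations
    state$donations <- res$donations
    state$t <- state$t + n_steps
    list(state = state, mean_donations = res$mean_donations)
  } else {
    means <- if (record) numeric(n_steps) else numeric(0)
    for (k in seq_len(n_steps)) {
      state <- dg_step(state, params)
      if (record) means[k] <- mean(state$donations)
    }
    list(state = state, mean_donations = means)
  }
}

# OLS slope of y against 1..length(y), in y-units per step.
ols_slope <- function(y) {
  x <- seq_along(y)
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc * xc)
}

#' Run one replication to stationarity
#'
#' Initializes a population, runs a transient, then keeps running windows of
#' fixed length; after each window an ordinary-least-squares line is fitted
#' to the population-mean donation against the step index over that window,
#' and the run stops when the absolute slope falls strictly below
#' `slope_tol` (in donation units per step). A `max_steps` guard returns a
#' partial, flagged result if stationarity is never detected.
#'
#' Defaults mirror the protocol the model was characterised with: transient
#' 10000 steps, window 1000 steps, slope threshold 1e-4.
#'
#' @param params a [dg_params()] object.
#' @param transient number of steps run before the first stationarity check.
#' @param window window length (steps) for the slope criterion.
#' @param slope_tol stationarity threshold on `|slope|` (strict).
#' @param max_steps guard on total steps; exceeded => non-convergence warning.
#' @param engine passed to [run_steps()].
#' @return An object of class `dg_run`: list with `params`,
#'   `mean_donation_series` (one value per step), `final_aspirations`,
#'   `final_donations`, `converged_at` (total steps run), `converged`
#'   (logical), and the criterion settings.
#' @export
run_to_stationarity <- function(params, transient = 10000, window = 1000,
                                slope_tol = 1e-4, max_steps = 1e6,
                                engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  state <- init_population(params)
  res <- run_steps(state, params, transient, engine = engine)
  state <- res$state
  series <- res$mean_donations
  converged <- FALSE
  repeat {
    res <- run_steps(state, params, window, engine = engine)
    state <- res$state
    series <- c(series, res$mean_donations)
    if (abs(ols_slope(res$mean_donations)) < slope_tol) {
      converged <- TRUE
      break
    }
    if (state$t >= max_steps) {
      warning(sprintf(
        "run did not reach stationarity within %d steps (|slope| >= %g)",
        state$t, slope_tol), call. = FALSE)
      break
    }
  }
  structure(
    list(params = params, mean_donation_series = series,
         final_aspirations = state$aspirations,
         final_donations = state$donations,
         converged_at = state$t, converged = converged,
         transient = transient, window = window, slope_tol = slope_tol),
    class = "dg_run"
  )
}

#' Run independent replications
#'
#' Runs `n_reps` independent replications of one condition. Replication `i`
#' is seeded with `set.seed(base_seed + i - 1)`, so any subset of the
#' replications is reproducible from `base_seed` alone.
#'
#' @param params a [dg_params()] object.
#' @param n_reps number of replications (>= 1).
#' @param base_seed integer seed for the first replication.
#' @param ... passed on to [run_to_stationarity()].
#' @return A list of `dg_run` objects, one per replication.
#' @export
run_replications <- function(params, n_reps, base_seed, ...) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(i) {
    set.seed(base_seed + i - 1L)
    run_to_stationarity(params, ...)
  })
}

#' Simulate replications from a parameter object
#'
#' `simulate()` method for [dg_params()]: runs `nsim` independent
#' replications to stationarity. Equivalent to
#' `run_replications(object, nsim, seed)`.
#'
#' @param object a [dg_params()] object.
#' @param nsim number of replications.
#' @param seed base seed (required, for reproducibility).
#' @param ... passed on to [run_to_stationarity()].
#' @return A list of `dg_run` objects.
#' @export
simulate.dg_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("'seed' is required", call. = FALSE)
  run_replications(object, n_reps = nsim, base_seed = seed, ...)
}

#' @export
print.dg_run <- function(x, ...) {
  cat("Dictator Game run\n")
  cat(sprintf("  l = %g, h = %g, delta = %g, N = %d\n",
              x$params$learning_rate, x$params$habituation,
              x$params$noise_scale, x$params$n_agents))
  cat(sprintf("  %s at step %d\n",
              if (x$converged) "stationary" else "NOT stationary",
              x$converged_at))
  cat(sprintf("  final mean donation: %.4f\n", mean(x$final_donations)))
  cat(sprintf("  final mean aspiration: %.4f\n", mean(x$final_aspirations)))
  invisible(x)
}

#' @export
summary.dg_run <- function(object, ...) {
  d <- object$final_donations
  out <- list(
    mean_donation = mean(d),
    mean_aspiration = mean(object$final_aspirations),
    histogram_gini = histogram_gini(d, object$params$endowment),
    equality_index = equality_index(d),
    gini = gini_coefficient(d),
    donation_histogram = donation_histogram(d, object$params$endowment),
    converged = object$converged,
    converged_at = object$converged_at
  )
  class(out) <- "summary.dg_run"
  out
}

#' @export
print.summary.dg_run <- function(x, ...) {
  cat(sprintf("mean donation %.4f | concentration G %.4f | 1-Gini %.4f | %s at %d\n",
              x$mean_donation, x$histogram_gini, x$equality_index,
              if (x$converged) "stationary" else "not stationary",
              x$converged_at))
  cat("donation histogram (bins 0-10):\n")
  print(round(x$donation_histogram, 3))
  invisible(x)
}

#' @export
plot.dg_run <- function(x, ...) {
  graphics::plot(seq_along(x$mean_donation_series), x$mean_donation_series,
                 type = "l", xlab = "time step",
                 ylab = "population mean donation",
                 ylim = c(0, x$params$endowment), ...)
  graphics::abline(v = x$transient, lty = 3)
  invisible(x)
}
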