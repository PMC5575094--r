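#' Run a (learning rate, habituation) parameter sweep
#'
#' Runs `n_reps` replications of [run_to_stationarity()] for every
#' combination of `l_values` and `h_values`, holding the other parameters of
#' `params` fixed, and pools the results with [pool_sweep()]. Cell `(i)` in
#' row-major order over `(l, h)` uses replication seeds
#' `base_seed + (i - 1) * n_reps + (0 : (n_reps - 1))`, so the whole sweep is
#' reproducible from `base_seed`.
#'
#' @param params a [dg_params()] template; its `learning_rate` and
#'   `habituation` are overridden cell by cell.
#' @param l_values,h_values numeric grids in `[0, 1]`.
#' @param n_reps replications per cell.
#' @param base_seed integer root seed.
#' @param ... passed to [run_to_stationarity()] (`transient`, `window`,
#'   `slope_tol`, `max_steps`, `engine`).
#' @return A `dg_sweep` object (see [pool_sweep()]) with an extra `cells`
#'   element keeping the per-cell `dg_run` lists.
#' @export
run_sweep <- function(params, l_values, h_values, n_reps, base_seed, ...) {
  stopifnot(inherits(params, "dg_params"),
            all(l_values >= 0 & l_values <= 1),
            all(h_values >= 0 & h_values <= 1),
            n_reps >= 1)
  grid <- expand.grid(h = h_values, l = l_values)[, c("l", "h")]
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$learning_rate <- grid$l[i]
    p$habituation <- grid$h[i]
    cells[[i]] <- list(
      l = grid$l[i], h = grid$h[i],
      runs = run_replications(p, n_reps,
                              base_seed + (i - 1L) * as.integer(n_reps), ...)
    )
  }
  out <- pool_sweep(cells)
  out$cells <- cells
  out
}

#' Define an experiment condition
#'
#' A named, validated bundle of everything one experiment needs: model
#' parameters, the `(l, h)` grid, replication count, stationarity settings
#' and a root seed. Conditions are plain lists so they round-trip through
#' YAML ([read_condition()]).
#'
#' @param name condition label used in output files.
#' @param l_values,h_values sweep grids in `[0, 1]`.
#' @param n_reps replications per grid cell.
#' @param endowment,noise_scale,envy_probability,n_free_riders,free_rider_donation,n_agents
#'   see [dg_params()].
#' @param transient,window,slope_tol,max_steps see [run_to_stationarity()].
#' @param seed default root seed for [run_experiment()].
#' @return An object of class `dg_condition`.
#' @export
dg_condition <- function(name,
                         l_values = c(0.2, 0.4, 0.6, 0.8),
                         h_values = c(0.2, 0.4, 0.6, 0.8),
                         n_reps = 100L, endowment = 1, noise_scale = 0,
                         envy_probability = 0, n_free_riders = 0L,
                         free_rider_donation = 0, n_agents = 1000L,
                         transient = 10000, window = 1000, slope_tol = 1e-4,
                         max_steps = 1e6, seed = 1L) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  if (any(l_values < 0 | l_values > 1) || any(h_values < 0 | h_values > 1))
    stop("grid values must lie in [0, 1]", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  # validates the scalar model parameters as a side effect
  dg_params(learning_rate = l_values[1], habituation = h_values[1],
            endowment = endowment, noise_scale = noise_scale,
            envy_probability = envy_probability,
            n_free_riders = n_free_riders,
            free_rider_donation = free_rider_donation, n_agents = n_agents)
  structure(
    list(name = name, l_values = as.numeric(l_values),
         h_values = as.numeric(h_values), n_reps = as.integer(n_reps),
         endowment = endowment, noise_scale = noise_scale,
         envy_probability = envy_probability,
         n_free_riders = as.integer(n_free_riders),
         free_rider_donation = free_rider_donation,
         n_agents = as.integer(n_agents), transient = transient,
         window = window, slope_tol = slope_tol, max_steps = max_steps,
         seed = as.integer(seed)),
    class = "dg_condition"
  )
}

#' @export
print.dg_condition <- function(x, ...) {
  cat(sprintf("Condition '%s': delta = %g, envy = %g, free-riders = %d\n",
              x$name, x$noise_scale, x$envy_probability, x$n_free_riders))
  cat(sprintf("  grid l in {%s}, h in {%s}; %d reps; N = %d; transient %g\n",
              paste(x$l_values, collapse = ","),
              paste(x$h_values, collapse = ","),
              x$n_reps, x$n_agents, x$transient))
  invisible(x)
}

#' The predefined experiment suite
#'
#' The seven study conditions: the deterministic model, the stochastic model
#' at noise scales 0.01 and 0.1, the inequity-aversion variant (envy
#' probability 0.05) with and without noise 0.1, and the single-free-rider
#' variant with and without noise 0.1. All use the general-regime grid
#' `l, h` in `{0.2, 0.4, 0.6, 0.8}`.
#'
#' `scale = "paper"` uses N = 1000 agents, 100 replications per cell and a
#' 10000-step transient. `scale = "small"` (N = 200, 10 replications,
#' 5000-step transient) gives the same stationary statistics to within
#' Monte-Carlo error in this well-mixed population and runs in minutes on one
#' CPU.
#'
#' @param scale `"paper"` or `"small"`.
#' @return Named list of [dg_condition()] objects.
#' @export
predefined_conditions <- function(scale = c("paper", "small")) {
  scale <- match.arg(scale)
  n_agents <- if (scale == "paper") 1000L else 200L
  n_reps <- if (scale == "paper") 100L else 10L
  transient <- if (scale == "paper") 10000 else 5000
  base <- function(name, ...) {
    dg_condition(name = name, n_agents = n_agents, n_reps = n_reps,
                 transient = transient, ...)
  }
  list(
    deterministic = base("deterministic"),
    small_noise = base("small_noise", noise_scale = 0.01),
    stochastic = base("stochastic", noise_scale = 0.1),
    envy = base("envy", envy_probability = 0.05),
    envy_noise = base("envy_noise", envy_probability = 0.05,
                      noise_scale = 0.1),
    free_rider = base("free_rider", n_free_riders = 1L),
    free_rider_noise = base("free_rider_noise", n_free_riders = 1L,
                            noise_scale = 0.1)
  )
}

#' Read an experiment condition from a YAML file
#'
#' The file holds a mapping whose keys are the [dg_condition()] argument
#' names (all optional except `name`).
#'
#' @param path path to a YAML file.
#' @return A `dg_condition` object.
#' @export
read_condition <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$name)) stop("condition file must set 'name'", call. = FALSE)
  allowed <- names(formals(dg_condition))
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown) > 0L)
    stop("unknown condition field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(dg_condition, spec)
}

#' Run an experiment condition and (optionally) write its outputs
#'
#' Executes the full sweep of a [dg_condition()] and, when `out_dir` is
#' given, writes three plain-text artifacts:
#' \describe{
#'   \item{`histograms.csv`}{columns `l`, `h`, `quantity`
#'     (donation/aspiration), `bin` (0-10), `freq_mean`, `freq_sd` -- the
#'     replication-averaged binned distributions per grid cell.}
#'   \item{`summary.json`}{condition label and parameters, pooled mean
#'     donation, equality index and raw Gini, run counts.}
#'   \item{`convergence.csv`}{per replication: `l`, `h`, `rep`, `seed`,
#'     `converged_at`, `converged`.}
#' }
#' Outputs are deterministic given `seed`.
#'
#' @param condition a `dg_condition` (or the name of a predefined one).
#' @param out_dir output directory, created if needed; `NULL` writes nothing.
#' @param seed root seed; defaults to the condition's own.
#' @param engine passed to [run_steps()].
#' @param scale scale of the predefined suite used when `condition` is given
#'   by name.
#' @return The `dg_sweep` result, invisibly when `out_dir` is given.
#' @export
run_experiment <- function(condition, out_dir = NULL, seed = NULL,
                           engine = c("compiled", "reference"),
                           scale = c("paper", "small")) {
  engine <- match.arg(engine)
  if (is.character(condition)) {
    suite <- predefined_conditions(match.arg(scale))
    if (!condition %in% names(suite))
      stop("unknown predefined condition '", condition, "'; see ",
           "predefined_conditions()", call. = FALSE)
    condition <- suite[[condition]]
  }
  stopifnot(inherits(condition, "dg_condition"))
  if (is.null(seed)) seed <- condition$seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }

  params <- dg_params(
    learning_rate = condition$l_values[1], habituation = condition$h_values[1],
    endowment = condition$endowment, noise_scale = condition$noise_scale,
    envy_probability = condition$envy_probability,
    n_free_riders = condition$n_free_riders,
    free_rider_donation = condition$free_rider_donation,
    n_agents = condition$n_agents
  )
  sweep <- run_sweep(params, condition$l_values, condition$h_values,
                     condition$n_reps, base_seed = seed,
                     transient = condition$transient,
                     window = condition$window,
                     slope_tol = condition$slope_tol,
                     max_steps = condition$max_steps, engine = engine)
  if (is.null(out_dir)) return(sweep)

  write.csv(sweep$cell_table, file.path(out_dir, "histograms.csv"),
            row.names = FALSE)

  conv <- do.call(rbind, lapply(seq_along(sweep$cells), function(i) {
    cell <- sweep$cells[[i]]
    n_reps <- length(cell$runs)
    data.frame(
      l = cell$l, h = cell$h, rep = seq_len(n_reps),
      seed = seed + (i - 1L) * n_reps + seq_len(n_reps) - 1L,
      converged_at = vapply(cell$runs, `[[`, numeric(1), "converged_at"),
      converged = vapply(cell$runs, `[[`, logical(1), "converged")
    )
  }))
  write.csv(conv, file.path(out_dir, "convergence.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(condition = condition$name,
         mean_donation = sweep$mean_donation,
         histogram_gini = sweep$histogram_gini,
         equality_index = sweep$equality_index,
         gini = sweep$gini,
         n_runs = sweep$n_runs,
         n_converged = sweep$n_converged,
         median_convergence_steps = stats::median(sweep$convergence_steps),
         seed = seed,
         params = unclass(condition)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(sweep)
}
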