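#' Parameters of one Dictator Game simulation condition
#'
#' Bundles and validates all scalar parameters of the aspiration-learning
#' model: the endowment to be split, the learning rate of the aspiration
#' update, the habituation weight of the donation update, the trembling-hand
#' noise scale, and the settings of the two behavioural variants
#' (inequity-averse "envious" agents and frozen free-riders).
#'
#' @param learning_rate weight `l` in `[0, 1]` of the current stimulus in the
#'   aspiration update; 0 means aspirations never move, 1 means they jump to
#'   the extreme the stimulus points at.
#' @param habituation weight `h` in `[0, 1]` of the just-received donation in
#'   the update of an agent's own donation (herding/conformity).
#' @param endowment size of the pie split in every game, in money units
#'   (default 1; all other money quantities are fractions of it).
#' @param noise_scale standard deviation `delta >= 0` of the multiplicative
#'   trembling-hand perturbation applied to updated donations; 0 gives the
#'   deterministic model.
#' @param envy_probability probability in `[0, 1]` that an agent is
#'   inequity-averse, i.e. never donates more than half the endowment. The
#'   trait is assigned once at initialization.
#' @param n_free_riders number of frozen agents whose donation is fixed and
#'   who never update aspirations or donations.
#' @param free_rider_donation the fixed donation of frozen agents, in
#'   `[0, endowment]` (0 = classic free-rider).
#' @param n_agents population size; must be even (agents are matched into
#'   pairs every step) and at least 2.
#'
#' @return An object of class `dg_params`: a validated named list.
#' @seealso [init_population()], [run_to_stationarity()], [run_sweep()]
#' @examples
#' p <- dg_params(learning_rate = 0.5, habituation = 0.5, n_agents = 100)
#' p
#' @export
dg_params <- function(learning_rate, habituation, endowment = 1,
                      noise_scale = 0, envy_probability = 0,
                      n_free_riders = 0L, free_rider_donation = 0,
                      n_agents = 1000L) {
  num_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite numeric scalar", nm), call. = FALSE)
    as.numeric(x)
  }
  learning_rate <- num_scalar(learning_rate, "learning_rate")
  habituation <- num_scalar(habituation, "habituation")
  endowment <- num_scalar(endowment, "endowment")
  noise_scale <- num_scalar(noise_scale, "noise_scale")
  envy_probability <- num_scalar(envy_probability, "envy_probability")
  n_free_riders <- as.integer(num_scalar(n_free_riders, "n_free_riders"))
  free_rider_donation <- num_scalar(free_rider_donation, "free_rider_donation")
  n_agents <- as.integer(num_scalar(n_agents, "n_agents"))

  if (learning_rate < 0 || learning_rate > 1)
    stop("'learning_rate' must lie in [0, 1]", call. = FALSE)
  if (habituation < 0 || habituation > 1)
    stop("'habituation' must lie in [0, 1]", call. = FALSE)
  if (endowment <= 0) stop("'endowment' must be positive", call. = FALSE)
  if (noise_scale < 0) stop("'noise_scale' must be >= 0", call. = FALSE)
  if (envy_probability < 0 || envy_probability > 1)
    stop("'envy_probability' must lie in [0, 1]", call. = FALSE)
  if (n_agents < 2L || n_agents %% 2L != 0L)
    stop("'n_agents' must be even and >= 2", call. = FALSE)
  if (n_free_riders < 0L || n_free_riders > n_agents)
    stop("'n_free_riders' must lie in [0, n_agents]", call. = FALSE)
  if (free_rider_donation < 0 || free_rider_donation > endowment)
    stop("'free_rider_donation' must lie in [0, endowment]", call. = FALSE)

  structure(
    list(learning_rate = learning_rate, habituation = habituation,
         endowment = endowment, noise_scale = noise_scale,
         envy_probability = envy_probability, n_free_riders = n_free_riders,
         free_rider_donation = free_rider_donation, n_agents = n_agents),
    class = "dg_params"
  )
}

#' @export
print.dg_params <- function(x, ...) {
  cat("Dictator Game model parameters\n")
  cat(sprintf("  endowment          : %g\n", x$endowment))
  cat(sprintf("  learning rate (l)  : %g\n", x$learning_rate))
  cat(sprintf("  habituation (h)    : %g\n", x$habituation))
  cat(sprintf("  noise scale (delta): %g%s\n", x$noise_scale,
              if (x$noise_scale == 0) " (deterministic)" else ""))
  if (x$envy_probability > 0)
    cat(sprintf("  envy probability   : %g\n", x$envy_probability))
  if (x$n_free_riders > 0)
    cat(sprintf("  free-riders        : %d frozen at donation %g\n",
                x$n_free_riders, x$free_rider_donation))
  cat(sprintf("  population size    : %d\n", x$n_agents))
  invisible(x)
}
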