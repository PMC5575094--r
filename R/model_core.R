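#' Stimulus felt by a recipient
#'
#' Signed, normalized mismatch between the donation a recipient just received
#' and her aspiration level:
#' `s = (payoff - aspiration) / (endowment - aspiration)`, defined as 0 when
#' the aspiration equals the endowment. The raw ratio can fall below -1 when
#' the aspiration exceeds half the endowment and the payoff is small; the
#' stimulus is clamped to `[-1, 1]` so that the aspiration update can never
#' leave `[0, endowment]`.
#'
#' @param payoff donation received, in `[0, endowment]`.
#' @param aspiration the recipient's aspiration level, in `[0, endowment]`.
#' @param endowment the pie size.
#' @return Stimulus value(s) in `[-1, 1]`; vectorized over `payoff` and
#'   `aspiration`.
#' @export
compute_stimulus <- function(payoff, aspiration, endowment = 1) {
  if (any(payoff < 0 | payoff > endowment))
    stop("'payoff' outside [0, endowment]", call. = FALSE)
  if (any(aspiration < 0 | aspiration > endowment))
    stop("'aspiration' outside [0, endowment]", call. = FALSE)
  n <- max(length(payoff), length(aspiration))
  payoff <- rep_len(payoff, n)
  aspiration <- rep_len(aspiration, n)
  s <- ifelse(aspiration == endowment, 0,
              (payoff - aspiration) / (endowment - aspiration))
  pmax(-1, pmin(1, s))
}

#' Aspiration update (reinforcement learning)
#'
#' Moves the aspiration towards the endowment after a positive stimulus and
#' towards zero after a negative one, at a speed set by the learning rate:
#' `A + (endowment - A) * l * s` for `s >= 0`, `A + A * l * s` for `s < 0`.
#' With a stimulus in `[-1, 1]` the result always stays in `[0, endowment]`.
#'
#' @param aspiration current aspiration(s), in `[0, endowment]`.
#' @param stimulus stimulus value(s) in `[-1, 1]`.
#' @param learning_rate learning rate `l` in `[0, 1]`.
#' @param endowment the pie size.
#' @return Updated aspiration(s).
#' @export
update_aspiration <- function(aspiration, stimulus, learning_rate,
                              endowment = 1) {
  ifelse(stimulus >= 0,
         aspiration + (endowment - aspiration) * learning_rate * stimulus,
         aspiration + aspiration * learning_rate * stimulus)
}

#' Donation update by habituation
#'
#' Convex combination of an agent's past donation and the donation it just
#' received: `(1 - h) * donation + h * payoff`. High habituation means the
#' agent herds towards what others give.
#'
#' @param donation the agent's current donation.
#' @param payoff the donation just received.
#' @param habituation weight `h` in `[0, 1]` of the received donation.
#' @return Updated donation(s), between `min(donation, payoff)` and
#'   `max(donation, payoff)`.
#' @export
update_donation_habituation <- function(donation, payoff, habituation) {
  (1 - habituation) * donation + habituation * payoff
}

#' Aspiration bound on donations
#'
#' A dictator never keeps less than her aspiration: donations are capped at
#' `endowment - aspiration` (and floored at 0). The bound is applied against
#' the aspiration *after* its update, coupling donations to aspirations.
#'
#' @param donation candidate donation(s); may transiently exceed the endowment.
#' @param aspiration the agent's (updated) aspiration.
#' @param endowment the pie size.
#' @return Bounded donation(s) in `[0, endowment - aspiration]`.
#' @export
apply_aspiration_bound <- function(donation, aspiration, endowment = 1) {
  pmax(0, pmin(donation, endowment - aspiration))
}

#' Trembling-hand perturbation of a donation
#'
#' Imperfect decision making: the updated donation is multiplied by
#' `(1 + eps)` with `eps ~ Normal(0, noise_scale)`, drawn fresh per value,
#' then clipped to `[0, endowment]`. With `noise_scale = 0` the donation is
#' returned unchanged (and no random numbers are consumed). The perturbed
#' donation may exceed the aspiration bound; the bound holds only in the
#' deterministic model.
#'
#' @param donation donation(s) in `[0, endowment]`.
#' @param noise_scale standard deviation `delta >= 0` of the perturbation.
#' @param endowment the pie size.
#' @return Perturbed donation(s) in `[0, endowment]`.
#' @export
apply_trembling_hand <- function(donation, noise_scale, endowment = 1) {
  if (noise_scale == 0) return(donation)
  eps <- rnorm(length(donation), mean = 0, sd = noise_scale)
  pmax(0, pmin(endowment, donation * (1 + eps)))
}

#' Inequity-aversion cap
#'
#' Envious (disadvantageous-inequity-averse) agents never donate more than
#' half the pie: `min(donation, endowment / 2)`.
#'
#' @param donation donation(s), non-negative.
#' @param endowment the pie size.
#' @return Capped donation(s).
#' @export
apply_envy_cap <- function(donation, endowment = 1) {
  pmin(donation, 0.5 * endowment)
}

#' Full recipient update
#'
#' Composition of the update rules applied to a recipient after one game, in
#' this order: stimulus, aspiration update, habituation of the donation,
#' aspiration bound against the *new* aspiration, trembling-hand noise (if
#' `noise_scale > 0`), envy cap (for envious agents), and a final clip to
#' `[0, endowment]`. Frozen agents are returned unchanged and consume no
#' random numbers. Dictators are never modified by the model; only recipients
#' learn.
#'
#' Vectorized over agents: all agent arguments are recycled to a common
#' length. When `noise_scale > 0`, exactly one normal deviate is drawn per
#' non-frozen agent, in input order (this draw discipline is what the engine
#' relies on for reproducibility across its two implementations).
#'
#' @param aspiration,donation the recipient's current values.
#' @param payoff the matched dictator's donation.
#' @param params a [dg_params()] object.
#' @param envious,frozen logical flags per agent.
#' @return A list with components `aspiration` and `donation`.
#' @export
recipient_update <- function(aspiration, donation, payoff, params,
                             envious = FALSE, frozen = FALSE) {
  n <- max(length(aspiration), length(donation), length(payoff))
  aspiration <- rep_len(aspiration, n)
  donation <- rep_len(donation, n)
  payoff <- rep_len(payoff, n)
  envious <- rep_len(envious, n)
  frozen <- rep_len(frozen, n)

  act <- !frozen
  if (any(act)) {
    phi <- params$endowment
    s <- compute_stimulus(payoff[act], aspiration[act], phi)
    a_new <- update_aspiration(aspiration[act], s, params$learning_rate, phi)
    d_new <- update_donation_habituation(donation[act], payoff[act],
                                         params$habituation)
    d_new <- apply_aspiration_bound(d_new, a_new, phi)
    if (params$noise_scale > 0)
      d_new <- apply_trembling_hand(d_new, params$noise_scale, phi)
    env <- envious[act]
    if (any(env)) d_new[env] <- apply_envy_cap(d_new[env], phi)
    aspiration[act] <- a_new
    donation[act] <- pmax(0, pmin(phi, d_new))
  }
  list(aspiration = aspiration, donation = donation)
}
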