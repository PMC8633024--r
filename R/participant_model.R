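#' Generative parameters of the synthetic participant's perception
#'
#' The synthetic human is a central-tendency observer with scalar
#' variability: a noisy percept `p ~ Normal(s, weber_fraction * s)` is
#' combined with a prior centered on the running mean of the percept history,
#' weighted by the relative reliabilities,
#' `estimate = lambda * prior_mean + (1 - lambda) * p + motor noise`, where
#' `lambda = sigma_s^2 / (sigma_s^2 + prior_sd^2)` and
#' `sigma_s = weber_fraction * s`. Because `sigma_s` grows with `s`, long
#' stimuli are pulled toward the prior more strongly than short ones, which
#' produces both a response slope below 1 (central tendency) and a session
#' mean below the 12 cm design mean (underestimation).
#'
#' Default values are the shipped calibration (see the package vignette):
#' they reproduce a cohort mean relative estimation error of about 0.20 and a
#' regression index of about 0.46 on the solo task.
#'
#' @param weber_fraction Scalar-noise coefficient in (0, 1).
#' @param prior_sd SD (cm) of the prior; smaller values mean stronger pull.
#' @param motor_sd SD (cm) of additive response noise.
#' @param prior_update_rate Exponential-moving-average rate in \[0, 1\] with
#'   which the prior mean tracks new percepts.
#' @param prior_mean Initial prior mean (cm); `NA` (default) initializes it
#'   at the first percept.
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(weber_fraction = 0.38,
                            prior_sd = 4.6,
                            motor_sd = 0.8,
                            prior_update_rate = 0.15,
                            prior_mean = NA_real_) {
  .check_number(weber_fraction, "weber_fraction", lower = 1e-9, upper = 1 - 1e-9)
  .check_number(prior_sd, "prior_sd", lower = 1e-9)
  .check_number(motor_sd, "motor_sd", lower = 0)
  .check_number(prior_update_rate, "prior_update_rate", lower = 0, upper = 1)
  structure(list(weber_fraction = weber_fraction,
                 prior_sd = prior_sd,
                 motor_sd = motor_sd,
                 prior_update_rate = prior_update_rate,
                 prior_mean = prior_mean),
            class = "observer_params")
}

#' One perceptual estimate of the synthetic participant
#'
#' Draws a percept, combines it with the prior (see [observer_params()]),
#' adds motor noise, clips the estimate to a positive on-screen range, and
#' updates the prior mean toward the percept. The function is pure in the
#' functional sense: the updated observer state is returned alongside the
#' estimate and must be threaded through successive trials by the caller.
#'
#' @param s True stimulus length (cm), > 0.
#' @param observer An [observer_params()] object (carrying the current prior).
#' @return List with `estimate` (cm), `percept` (cm) and `observer` (updated
#'   state).
#' @export
perceive_and_estimate <- function(s, observer) {
  .check_number(s, "s", lower = 1e-12)
  sigma_s <- observer$weber_fraction * s
  p <- rnorm(1, mean = s, sd = sigma_s)
  if (is.na(observer$prior_mean)) observer$prior_mean <- p
  lambda <- sigma_s^2 / (sigma_s^2 + observer$prior_sd^2)
  est <- lambda * observer$prior_mean + (1 - lambda) * p +
    rnorm(1, 0, observer$motor_sd)
  est <- min(max(est, 0.5), task_constants()$screen_width_cm - 6.6)
  observer$prior_mean <- observer$prior_mean +
    observer$prior_update_rate * (p - observer$prior_mean)
  list(estimate = est, percept = p, observer = observer)
}

#' Generative parameters of the synthetic participant's influence policy
#'
#' On decision turns the participant places a final decision between the two
#' estimates; the fraction moved toward the partner (the influence index) is
#' generated on the logit scale as
#' `logit(i) = baseline + distance_slope * normalized_distance +
#' condition_shift[condition] + is_final_block * final_block_shift + noise`,
#' then squashed to (0, 1). The logit-linear form keeps the realized
#' influence in range while making egocentric discounting (baseline below
#' logit(0.5)) and the decline of influence with inter-agent distance
#' (negative `distance_slope`) each a single interpretable parameter.
#'
#' One object describes one group's policy; [default_policy_params()] returns
#' the shipped calibrated policies (Computer mean influence about 0.26, Robot
#' about 0.35, both declining with distance).
#'
#' @param baseline_influence Logit-scale intercept.
#' @param distance_slope Logit change per unit of normalized response
#'   distance (negative under egocentric discounting).
#' @param condition_shift Named numeric: logit offsets for `SUSCEPTIBLE`,
#'   `UNSUSCEPTIBLE`, `TRANSITION` (baseline task implies 0).
#' @param final_block_shift Logit offset applied in the final block.
#' @param policy_noise_sd Logit-scale SD of trial-to-trial noise.
#' @return Object of class `influence_policy_params`.
#' @export
influence_policy_params <- function(baseline_influence = -0.7,
                                    distance_slope = -3.0,
                                    condition_shift = c(SUSCEPTIBLE = 0,
                                                        UNSUSCEPTIBLE = 0,
                                                        TRANSITION = 0),
                                    final_block_shift = 0,
                                    policy_noise_sd = 0.8) {
  .check_number(baseline_influence, "baseline_influence")
  .check_number(distance_slope, "distance_slope")
  .check_number(final_block_shift, "final_block_shift")
  .check_number(policy_noise_sd, "policy_noise_sd", lower = 0)
  shifts <- c(SUSCEPTIBLE = 0, UNSUSCEPTIBLE = 0, TRANSITION = 0)
  shifts[names(condition_shift)] <- condition_shift
  structure(list(baseline_influence = baseline_influence,
                 distance_slope = distance_slope,
                 condition_shift = shifts,
                 final_block_shift = final_block_shift,
                 policy_noise_sd = policy_noise_sd),
            class = "influence_policy_params")
}

#' Draw the participant's influence level for one decision turn
#'
#' @param normalized_distance `|own - other| / s`, >= 0.
#' @param condition Experimental condition of the trial (`"BASELINE"` for the
#'   first joint task).
#' @param is_final_block Logical; applies the final-block shift.
#' @param policy An [influence_policy_params()] object.
#' @return Influence in \[0, 1\].
#' @export
decide_influence <- function(normalized_distance, condition = "BASELINE",
                             is_final_block = FALSE,
                             policy = influence_policy_params()) {
  .check_number(normalized_distance, "normalized_distance", lower = 0)
  condition <- .match_label(condition, CONDITIONS, "condition")
  shift <- if (condition %in% names(policy$condition_shift)) {
    policy$condition_shift[[condition]]
  } else 0
  eta <- policy$baseline_influence +
    policy$distance_slope * normalized_distance +
    shift +
    (if (isTRUE(is_final_block)) policy$final_block_shift else 0) +
    rnorm(1, 0, policy$policy_noise_sd)
  plogis(eta)
}

#' The participant's final decision on a decision turn
#'
#' Mirror image of [agent_final_decision()]: the decision lies between the
#' participant's own estimate and the partner's, at fraction `i` of the way
#' toward the partner.
#'
#' @param own,other Estimates (cm).
#' @param i Influence in \[0, 1\].
#' @return Final decision (cm).
#' @export
participant_final_decision <- function(own, other, i) {
  if (any(!is.finite(i)) || any(i < 0 | i > 1)) {
    stop("influence i must lie in [0, 1]", call. = FALSE)
  }
  own + i * (other - own)
}

#' Rating-generation parameters
#'
#' Participants rate their own and the partner's estimation accuracy on a
#' 1-10 scale at scheduled pauses. Ratings are generated deterministically
#' from the partner's observed mean influence in the current condition: a
#' susceptible partner is judged less competent, so the other-rating drops by
#' `susceptibility_penalty` per unit of observed influence while the
#' self-rating is constant. Defaults keep self > other on average and give a
#' (self - other) slope of about 1.75 per unit of partner influence.
#'
#' @param self_rating_base,other_rating_base Baseline ratings on the 1-10
#'   scale.
#' @param susceptibility_penalty Drop of the other-rating per unit of
#'   observed partner influence.
#' @return Object of class `rating_model`.
#' @export
rating_model <- function(self_rating_base = 6.3,
                         other_rating_base = 6.1,
                         susceptibility_penalty = 1.75) {
  .check_number(self_rating_base, "self_rating_base", lower = 1, upper = 10)
  .check_number(other_rating_base, "other_rating_base", lower = 1, upper = 10)
  .check_number(susceptibility_penalty, "susceptibility_penalty")
  structure(list(self_rating_base = self_rating_base,
                 other_rating_base = other_rating_base,
                 susceptibility_penalty = susceptibility_penalty),
            class = "rating_model")
}

#' Emit a (self, other) performance-rating pair
#'
#' @param observed_partner_influence Mean influence observed from the partner
#'   in the current condition, in \[0, 1\] (use 0 when the partner has made no
#'   final decisions yet, e.g. in the first joint task).
#' @param model A [rating_model()] object.
#' @return Named numeric vector `c(self = ..., other = ...)`, clamped to
#'   \[1, 10\].
#' @export
emit_ratings <- function(observed_partner_influence, model = rating_model()) {
  .check_number(observed_partner_influence, "observed_partner_influence",
                lower = 0, upper = 1)
  clamp <- function(x) min(max(x, 1), 10)
  c(self = clamp(model$self_rating_base),
    other = clamp(model$other_rating_base -
                    model$susceptibility_penalty * observed_partner_influence))
}
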