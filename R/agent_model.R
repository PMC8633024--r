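#' Parameters of the algorithmic partner
#'
#' The partner (identical in both groups; only its framing differs) draws
#' perceptual estimates from a Gaussian centered on the true length with a
#' fixed SD of 1.52 cm, and on observation turns draws its influence level
#' from condition-specific mixtures of uniform distributions over quarters of
#' the [0, 1] range:
#'
#' * Susceptible: 0.45 on \[0.75, 1\], 0.35 on \[0.5, 0.75\],
#'   0.15 on \[0.25, 0.5\], 0.05 on \[0, 0.25\].
#' * Unsusceptible: 0.80 on \[0, 0.25\], 0.15 on \[0.25, 0.5\],
#'   0.05 on \[0.5, 0.75\].
#'
#' When a sampled estimate lands within `resample_threshold` (0.5 cm) of the
#' participant's current estimate, the agent redraws it with probability
#' `resample_prob` (0.5) until it is at least that far away; this keeps the
#' two responses distinguishable on screen without making near-agreement
#' impossible.
#'
#' @param estimate_sd SD (cm) of the Gaussian estimate sampler.
#' @param resample_threshold Distance (cm) below which a redraw may trigger.
#' @param resample_prob Probability that an offending draw is redrawn.
#' @param mixtures Named list of mixture tables (`prob`, `lo`, `hi`) for the
#'   `SUSCEPTIBLE` and `UNSUSCEPTIBLE` conditions.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(estimate_sd = 1.52,
                         resample_threshold = 0.5,
                         resample_prob = 0.5,
                         mixtures = default_mixtures()) {
  .check_number(estimate_sd, "estimate_sd", lower = 1e-12)
  .check_number(resample_threshold, "resample_threshold", lower = 0)
  .check_number(resample_prob, "resample_prob", lower = 0, upper = 1)
  for (cond in c("SUSCEPTIBLE", "UNSUSCEPTIBLE")) {
    m <- mixtures[[cond]]
    if (is.null(m) || !all(c("prob", "lo", "hi") %in% names(m))) {
      stop("mixtures must contain prob/lo/hi tables for SUSCEPTIBLE and UNSUSCEPTIBLE",
           call. = FALSE)
    }
    if (abs(sum(m$prob) - 1) > 1e-9) {
      stop(sprintf("%s mixture probabilities must sum to 1", cond), call. = FALSE)
    }
    if (any(m$lo < 0 | m$hi > 1 | m$lo >= m$hi)) {
      stop(sprintf("%s mixture intervals must be proper sub-intervals of [0, 1]", cond),
           call. = FALSE)
    }
    o <- order(m$lo)
    if (any(m$hi[o][-nrow(m)] > m$lo[o][-1] + 1e-12)) {
      stop(sprintf("%s mixture intervals must not overlap", cond), call. = FALSE)
    }
  }
  structure(list(estimate_sd = estimate_sd,
                 resample_threshold = resample_threshold,
                 resample_prob = resample_prob,
                 mixtures = mixtures),
            class = "agent_params")
}

#' @rdname agent_params
#' @export
default_mixtures <- function() {
  list(
    SUSCEPTIBLE = data.frame(
      prob = c(0.45, 0.35, 0.15, 0.05),
      lo   = c(0.75, 0.50, 0.25, 0.00),
      hi   = c(1.00, 0.75, 0.50, 0.25)
    ),
    UNSUSCEPTIBLE = data.frame(
      prob = c(0.80, 0.15, 0.05),
      lo   = c(0.00, 0.25, 0.50),
      hi   = c(0.25, 0.50, 0.75)
    )
  )
}

#' Sample the partner's perceptual estimate(s)
#'
#' Draws from Normal(`s`, `estimate_sd`). If a draw falls within
#' `resample_threshold` of `participant_estimate`, it is redrawn (with
#' probability `resample_prob`, independently per offending draw) until it is
#' at least that far away; the redraw loop is bounded at 1000 iterations per
#' draw, after which the last draw is returned with a warning. Draws are
#' clipped to the physical screen range with a warning in the (practically
#' negligible) case a draw falls outside it.
#'
#' @param s True stimulus length (cm), > 0.
#' @param participant_estimate The participant's current estimate (cm); `NA`
#'   disables the resampling rule (no referent).
#' @param params An [agent_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n` with a logical attribute
#'   `"resampled"` flagging draws whose returned value came from a redraw.
#' @export
agent_estimate <- function(s, participant_estimate = NA_real_,
                           params = agent_params(), n = 1L) {
  .check_number(s, "s", lower = 1e-12)
  x <- rnorm(n, mean = s, sd = params$estimate_sd)
  resampled <- logical(n)
  thr <- params$resample_threshold
  if (!is.na(participant_estimate) && thr > 0) {
    close_idx <- which(abs(x - participant_estimate) < thr)
    if (length(close_idx)) {
      do_resample <- runif(length(close_idx)) < params$resample_prob
      for (j in close_idx[do_resample]) {
        it <- 0L
        repeat {
          it <- it + 1L
          cand <- rnorm(1, mean = s, sd = params$estimate_sd)
          if (abs(cand - participant_estimate) >= thr) {
            x[j] <- cand
            resampled[j] <- TRUE
            break
          }
          if (it >= 1000L) {
            warning("agent_estimate: resampling loop hit 1000 iterations; ",
                    "returning last draw")
            x[j] <- cand
            resampled[j] <- TRUE
            break
          }
        }
      }
    }
  }
  w <- task_constants()$screen_width_cm
  if (any(x < 0 | x > w)) {
    warning("agent_estimate: draw outside screen range clipped")
    x <- pmin(pmax(x, 0), w)
  }
  attr(x, "resampled") <- resampled
  x
}

#' Sample the partner's influence level for observation turns
#'
#' Two-stage draw: an interval is picked according to the condition's mixture
#' probabilities, then the influence is uniform within that interval. The
#' final block reuses the mixture of the last main condition faced, passed via
#' `inherit`.
#'
#' @param condition `"SUSCEPTIBLE"`, `"UNSUSCEPTIBLE"`, or `"FINAL"`.
#'   `BASELINE` and `TRANSITION` are rejected: the baseline task has no agent
#'   final decisions and the transition block follows the deterministic
#'   interval ramp of [transition_schedule()].
#' @param params An [agent_params()] object.
#' @param n Number of draws.
#' @param inherit For `condition = "FINAL"`, the last main condition
#'   (`"SUSCEPTIBLE"` or `"UNSUSCEPTIBLE"`).
#' @return `data.frame` with columns `i` (influence in \[0, 1\]), `condition`,
#'   `interval_index` (1-based row of the mixture table), `lo`, `hi`.
#' @export
sample_influence <- function(condition, params = agent_params(), n = 1L,
                             inherit = NULL) {
  condition <- .match_label(condition, CONDITIONS, "condition")
  if (condition %in% c("BASELINE", "TRANSITION")) {
    stop("sample_influence applies only to SUSCEPTIBLE, UNSUSCEPTIBLE or FINAL ",
         "conditions; the transition block uses transition_schedule()",
         call. = FALSE)
  }
  eff <- condition
  if (condition == "FINAL") {
    if (is.null(inherit)) {
      stop("condition = FINAL requires `inherit` (the last main condition)",
           call. = FALSE)
    }
    eff <- .match_label(inherit, c("SUSCEPTIBLE", "UNSUSCEPTIBLE"), "inherit")
  }
  m <- params$mixtures[[eff]]
  k <- sample.int(nrow(m), n, replace = TRUE, prob = m$prob)
  i <- runif(n, m$lo[k], m$hi[k])
  data.frame(i = i, condition = condition, interval_index = k,
             lo = m$lo[k], hi = m$hi[k], stringsAsFactors = FALSE)
}

#' The deterministic influence ramp of the transition block
#'
#' Between the two main conditions the partner's influence interval ramps
#' across its 11 observation turns: from the Susceptible to the Unsusceptible
#' condition the interval is \[0.75, 1\] twice, \[0.5, 0.75\] twice,
#' \[0.25, 0.5\] three times and \[0, 0.25\] four times, in this exact order;
#' the opposite transition presents the same intervals in reverse order.
#' Within each listed interval the influence is drawn uniformly at
#' simulation time.
#'
#' @param direction `"S_TO_U"` or `"U_TO_S"`.
#' @return `data.frame` with 11 rows: `position` (1-based observation-turn
#'   index), `lo`, `hi`.
#' @export
transition_schedule <- function(direction) {
  direction <- .match_label(direction, c("S_TO_U", "U_TO_S"), "direction")
  lo <- rep(c(0.75, 0.50, 0.25, 0.00), times = c(2, 2, 3, 4))
  hi <- rep(c(1.00, 0.75, 0.50, 0.25), times = c(2, 2, 3, 4))
  if (direction == "U_TO_S") {
    lo <- rev(lo)
    hi <- rev(hi)
  }
  data.frame(position = 1:11, lo = lo, hi = hi)
}

#' The partner's final decision on an observation turn
#'
#' A final decision with influence `i` lies on the segment between the two
#' estimates: `i = 0` confirms the agent's own estimate, `i = 1` adopts the
#' participant's.
#'
#' @param agent_estimate,participant_estimate Estimates (cm).
#' @param i Influence level(s) in \[0, 1\].
#' @return Final decision position(s) in cm.
#' @export
#' @examples
#' agent_final_decision(10, 12, 0.25)  # 10.5
agent_final_decision <- function(agent_estimate, participant_estimate, i) {
  if (any(!is.finite(i)) || any(i < 0 | i > 1)) {
    stop("influence i must lie in [0, 1]", call. = FALSE)
  }
  agent_estimate + i * (participant_estimate - agent_estimate)
}
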