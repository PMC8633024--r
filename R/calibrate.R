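# Calibration of the synthetic participant's free parameters against the
# paradigm's reference group statistics. The agent's parameters are fully
# specified and never calibrated.

# light simulators used only inside the grid search -------------------------

# solo-task cohort: mean relative error and mean regression index
.sim_perceptual_stats <- function(weber_fraction, prior_sd, motor_sd,
                                  prior_update_rate, population, n_participants,
                                  seed) {
  errs <- numeric(n_participants)
  regs <- numeric(n_participants)
  for (k in seq_len(n_participants)) {
    set.seed(.subseed(seed, k))
    obs <- observer_params(
      weber_fraction = weber_fraction * exp(rnorm(1, 0, population$weber_log_sd)),
      prior_sd = prior_sd * exp(rnorm(1, 0, population$prior_sd_log_sd)),
      motor_sd = motor_sd, prior_update_rate = prior_update_rate)
    st <- generate_stimuli(66)
    est <- numeric(66)
    for (t in 1:66) {
      pe <- perceive_and_estimate(st$s[t], obs)
      obs <- pe$observer
      est[t] <- pe$estimate
    }
    errs[k] <- mean(estimation_error(est, st$s))
    regs[k] <- regression_index(st$s, est)
  }
  c(error = mean(errs), regression = mean(regs))
}

# baseline joint-task cohort: mean influence index for one group's policy
.sim_influence_stat <- function(observer, baseline_influence, policy_template,
                                agent, population, n_participants, seed) {
  means <- numeric(n_participants)
  for (k in seq_len(n_participants)) {
    set.seed(.subseed(seed, 10000L + k))
    obs <- observer_params(
      weber_fraction = observer$weber_fraction * exp(rnorm(1, 0, population$weber_log_sd)),
      prior_sd = observer$prior_sd * exp(rnorm(1, 0, population$prior_sd_log_sd)),
      motor_sd = observer$motor_sd,
      prior_update_rate = observer$prior_update_rate)
    pol <- policy_template
    pol$baseline_influence <- baseline_influence +
      rnorm(1, 0, population$baseline_logit_sd)
    # solo-task warm-up so the prior enters the joint task converged, as in
    # the full pipeline
    warm <- generate_stimuli(66)
    for (t in 1:66) obs <- perceive_and_estimate(warm$s[t], obs)$observer
    st <- generate_stimuli(66)
    ivals <- numeric(66)
    for (t in 1:66) {
      pe <- perceive_and_estimate(st$s[t], obs)
      obs <- pe$observer
      own <- pe$estimate
      other <- as.numeric(agent_estimate(st$s[t], own, agent))
      nd <- normalized_response_distance(own, other, st$s[t])
      ivals[t] <- decide_influence(nd, "BASELINE", FALSE, pol)
    }
    means[k] <- mean(ivals)
  }
  mean(means)
}

#' Calibrate generator defaults against reference group statistics
#'
#' Two-stage grid search. Stage 1 tunes the observer (Weber fraction and
#' prior SD on a grid) so that a synthetic Computer-group solo-task cohort
#' hits the target mean relative estimation error and mean regression index;
#' the loss is the sum of squared target distances standardized by each
#' target's tolerance. Stage 2, holding the observer fixed, tunes each
#' group's policy baseline (logit intercept, 1-D grid) to the target mean
#' influence of the baseline joint task.
#'
#' The search is deterministic given `seed`. The shipped package defaults
#' ([observer_params()], [default_policy_params()]) are a frozen output of
#' this routine.
#'
#' @param targets Named list of targets and tolerances; see default. Only
#'   the supported names are allowed.
#' @param grid Named list of candidate vectors: `weber_fraction`, `prior_sd`,
#'   `baseline` (logit).
#' @param n_participants Cohort size per evaluation.
#' @param seed Integer seed.
#' @param base_config Starting configuration whose non-calibrated fields are
#'   kept.
#' @return List: `config` (calibrated `run_config`), `achieved` (named
#'   statistics at the optimum), `loss` (stage-1 loss at the optimum).
#' @export
calibrate <- function(targets = list(error = c(0.20, 0.03),
                                     regression = c(0.46, 0.08),
                                     influence_computer = c(0.26, 0.04),
                                     influence_robot = c(0.35, 0.05)),
                      grid = list(weber_fraction = seq(0.14, 0.30, by = 0.02),
                                  prior_sd = seq(1.4, 3.4, by = 0.4),
                                  baseline = seq(-1.6, 0.4, by = 0.1)),
                      n_participants = 25,
                      seed = 1L,
                      base_config = default_config()) {
  supported <- c("error", "regression", "influence_computer", "influence_robot")
  bad <- setdiff(names(targets), supported)
  if (length(bad)) {
    stop("unsupported calibration targets: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  obs0 <- base_config$observer
  pop <- base_config$population

  best <- NULL
  for (wf in grid$weber_fraction) {
    for (ps in grid$prior_sd) {
      st <- .sim_perceptual_stats(wf, ps, obs0$motor_sd, obs0$prior_update_rate,
                                  pop, n_participants, seed)
      loss <- 0
      if (!is.null(targets$error)) {
        loss <- loss + ((st[["error"]] - targets$error[1]) / targets$error[2])^2
      }
      if (!is.null(targets$regression)) {
        loss <- loss + ((st[["regression"]] - targets$regression[1]) /
                          targets$regression[2])^2
      }
      if (is.null(best) || loss < best$loss) {
        best <- list(wf = wf, prior_sd = ps, loss = loss, stats = st)
      }
    }
  }

  observer <- observer_params(weber_fraction = best$wf, prior_sd = best$prior_sd,
                              motor_sd = obs0$motor_sd,
                              prior_update_rate = obs0$prior_update_rate)

  achieved <- c(best$stats)
  policy <- base_config$policy
  for (g in GROUPS) {
    tname <- paste0("influence_", tolower(g))
    if (is.null(targets[[tname]])) next
    tgt <- targets[[tname]][1]
    vals <- vapply(grid$baseline, function(b0) {
      .sim_influence_stat(observer, b0, policy[[g]], base_config$agent,
                          pop, n_participants, seed)
    }, numeric(1))
    kbest <- which.min(abs(vals - tgt))
    policy[[g]]$baseline_influence <- grid$baseline[kbest]
    achieved[tname] <- vals[kbest]
  }

  config <- base_config
  config$observer <- observer
  config$policy <- policy
  list(config = config, achieved = achieved, loss = best$loss)
}
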