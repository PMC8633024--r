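#' Default run configuration
#'
#' A run of the simulator is a pure function of its configuration. The
#' defaults are the shipped calibration: 25 participants per group, the
#' partner agent exactly as specified by the paradigm, and observer / policy
#' parameters calibrated (see [calibrate()] and the package vignette) so that
#' the synthetic Computer-group cohort reproduces the paradigm's headline
#' statistics (mean relative estimation error about 0.20, mean influence
#' about 0.26, regression index about 0.46; Robot group mean influence about
#' 0.35).
#'
#' Between-participant heterogeneity is log-normal on the Weber fraction and
#' prior SD and normal (logit scale) on the policy baseline; per-task
#' perceptual-learning effects are phenomenological multiplicative modifiers
#' on the Weber fraction per group and condition (the Computer group learns
#' from the partner's susceptibility feedback, the Robot group does not and
#' even deteriorates under the susceptible partner).
#'
#' @param n_per_group Even number of participants per group.
#' @param seed Master integer seed; every participant gets an independent
#'   substream derived from it.
#' @param agent [agent_params()] of the partner (shared by both groups).
#' @param observer [observer_params()] population-center of the synthetic
#'   participants.
#' @param policy Named list of [influence_policy_params()], one per group.
#' @param rating [rating_model()].
#' @param population Named list of heterogeneity SDs:
#'   `weber_log_sd`, `prior_sd_log_sd`, `baseline_logit_sd`,
#'   `rating_base_sd`.
#' @param learning_wf_multiplier Named list (per group) of named numeric
#'   multipliers on the Weber fraction per reciprocal-task condition.
#' @return Object of class `run_config`.
#' @export
default_config <- function(n_per_group = 25,
                           seed = 1L,
                           agent = agent_params(),
                           observer = observer_params(),
                           policy = default_policy_params(),
                           rating = rating_model(),
                           population = list(weber_log_sd = 0.18,
                                             prior_sd_log_sd = 0.15,
                                             baseline_logit_sd = 0.75,
                                             rating_base_sd = 0.8),
                           learning_wf_multiplier = default_learning_multipliers()) {
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 agent = agent, observer = observer, policy = policy,
                 rating = rating, population = population,
                 learning_wf_multiplier = learning_wf_multiplier),
            class = "run_config")
}

#' @rdname default_config
#' @export
default_policy_params <- function() {
  list(
    COMPUTER = influence_policy_params(
      baseline_influence = -0.65,
      distance_slope = -3.0,
      condition_shift = c(SUSCEPTIBLE = 0.16, UNSUSCEPTIBLE = 0.21,
                          TRANSITION = 0.10),
      final_block_shift = -0.08,
      policy_noise_sd = 0.8
    ),
    ROBOT = influence_policy_params(
      baseline_influence = -0.30,
      distance_slope = -2.0,
      condition_shift = c(SUSCEPTIBLE = -0.02, UNSUSCEPTIBLE = 0.06,
                          TRANSITION = 0.02),
      final_block_shift = -0.16,
      policy_noise_sd = 0.8
    )
  )
}

#' @rdname default_config
#' @export
default_learning_multipliers <- function() {
  list(
    COMPUTER = c(SUSCEPTIBLE = 0.90, UNSUSCEPTIBLE = 0.90, TRANSITION = 0.95),
    ROBOT = c(SUSCEPTIBLE = 1.10, UNSUSCEPTIBLE = 1.02, TRANSITION = 1.05)
  )
}

.validate_config <- function(config) {
  problems <- character()
  if (!inherits(config, "run_config")) problems <- c(problems, "not a run_config")
  if (!is.numeric(config$n_per_group) || config$n_per_group < 2 ||
      config$n_per_group %% 2 != 0) {
    problems <- c(problems, "n_per_group must be an even integer >= 2")
  }
  if (!inherits(config$agent, "agent_params")) {
    problems <- c(problems, "agent must be agent_params()")
  }
  if (!inherits(config$observer, "observer_params")) {
    problems <- c(problems, "observer must be observer_params()")
  }
  if (!all(GROUPS %in% names(config$policy))) {
    problems <- c(problems, "policy must name COMPUTER and ROBOT entries")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

# simulate one participant given their schedule and drawn parameters;
# returns list(trials = data.frame, ratings = data.frame)
.simulate_participant <- function(sched, config, observer, policy, rating_bases) {
  agent <- config$agent
  mult <- config$learning_wf_multiplier[[sched$group[1]]]
  wf0 <- observer$weber_fraction

  n <- nrow(sched)
  participant_estimate <- numeric(n)
  agent_est <- rep(NA_real_, n)
  infl <- rep(NA_real_, n)
  final <- rep(NA_real_, n)
  decider <- rep(NA_character_, n)
  resampled <- rep(NA, n)
  s_all <- numeric(n)
  off_all <- numeric(n)

  ratings <- list()

  # per-task stimulus sequences drawn from the participant's substream
  stim <- list()
  for (tk in TASKS) {
    stim[[tk]] <- generate_stimuli(sum(sched$task == tk))
  }

  # transition-ramp bookkeeping
  trans_dir <- if (sched$condition_order[1] == "SUSCEPTIBLE_FIRST") "S_TO_U" else "U_TO_S"
  ramp <- transition_schedule(trans_dir)
  trans_obs_seen <- 0L
  # agent influence draws observed in the current block (for ratings)
  block_agent_infl <- list()

  for (r in seq_len(n)) {
    row <- sched[r, ]
    st <- stim[[row$task]][row$trial_index + 1L, ]
    s <- st$s
    s_all[r] <- s
    off_all[r] <- st$first_disk_offset

    # phenomenological learning: condition-specific Weber-fraction modifier
    eff_wf <- wf0
    if (row$task == "RECIPROCAL") {
      key <- if (row$condition %in% c("TRANSITION")) "TRANSITION" else row$sampler_condition
      if (!is.null(mult) && key %in% names(mult)) eff_wf <- wf0 * mult[[key]]
    }
    observer$weber_fraction <- eff_wf

    pe <- perceive_and_estimate(s, observer)
    observer <- pe$observer
    own <- pe$estimate
    participant_estimate[r] <- own

    if (row$turn_kind == "SOLO") {
      # no partner in the solo task
    } else {
      ae <- agent_estimate(s, own, agent)
      agent_est[r] <- as.numeric(ae)
      resampled[r] <- attr(ae, "resampled")[1]

      if (row$turn_kind == "DECISION") {
        nd <- normalized_response_distance(own, agent_est[r], s)
        cond_for_policy <- if (row$task == "SOCIAL_INFLUENCE") "BASELINE"
          else if (row$condition == "TRANSITION") "TRANSITION"
          else row$sampler_condition
        i <- decide_influence(nd, condition = cond_for_policy,
                              is_final_block = identical(row$condition, "FINAL"),
                              policy = policy)
        infl[r] <- i
        final[r] <- participant_final_decision(own, agent_est[r], i)
        decider[r] <- "PARTICIPANT"
      } else {  # OBSERVATION: the partner decides
        if (row$condition == "TRANSITION") {
          trans_obs_seen <- trans_obs_seen + 1L
          i <- runif(1, ramp$lo[trans_obs_seen], ramp$hi[trans_obs_seen])
        } else if (row$condition == "FINAL") {
          i <- sample_influence("FINAL", agent, inherit = row$sampler_condition)$i
        } else {
          i <- sample_influence(row$condition, agent)$i
        }
        infl[r] <- i
        final[r] <- agent_final_decision(agent_est[r], own, i)
        decider[r] <- "AGENT"
        bk <- paste(row$task, row$block)
        block_agent_infl[[bk]] <- c(block_agent_infl[[bk]], i)
      }
    }

    if (row$rating_after) {
      observed <- if (row$task == "RECIPROCAL") {
        v <- block_agent_infl[[paste(row$task, row$block)]]
        if (is.null(v)) 0 else mean(v)
      } else 0
      rr <- emit_ratings(observed, config$rating)
      # per-participant anchor jitter plus 1..10 quantization
      self_r <- min(max(round(rr[["self"]] + rating_bases[["self"]]), 1), 10)
      other_r <- min(max(round(rr[["other"]] + rating_bases[["other"]]), 1), 10)
      ratings[[length(ratings) + 1L]] <- data.frame(
        participant_id = row$participant_id, group = row$group,
        task = row$task, block = row$block, condition = row$condition,
        trial_index = row$trial_index,
        partner_influence = observed,
        self = self_r, other = other_r, rating_diff = self_r - other_r,
        stringsAsFactors = FALSE
      )
    }
  }

  trials <- cbind(
    as.data.frame(sched),
    data.frame(s = s_all, first_disk_offset = off_all,
               participant_estimate = participant_estimate,
               agent_estimate = agent_est, decider = decider,
               influence = infl, final_decision = final,
               resampled = resampled)
  )
  list(trials = trials, ratings = do.call(rbind, ratings))
}

#' Simulate a full cohort
#'
#' Builds a counterbalanced cohort of schedules and plays every trial of the
#' three tasks for every participant: the synthetic observer produces the
#' perceptual estimates, the partner agent produces its estimates and (on
#' observation turns) its influence draws and final decisions, and the
#' participant's influence policy produces final decisions on decision
#' turns. Every participant runs on an independent random substream derived
#' from the master seed, so logs are reproducible and unaffected by cohort
#' size changes upstream of the participant.
#'
#' @param config A [default_config()]-shaped `run_config`.
#' @return Object of class `trial_log`: list with `trials` (one row per
#'   trial; observation turns carry the agent's final decision and
#'   `decider = "AGENT"`), `ratings` (one row per rating moment) and
#'   `config`.
#' @export
simulate_cohort <- function(config = default_config()) {
  .validate_config(config)
  logs <- lapply(GROUPS, function(g) simulate_group(g, config$n_per_group, config))
  out <- list(trials = do.call(rbind, lapply(logs, `[[`, "trials")),
              ratings = do.call(rbind, lapply(logs, `[[`, "ratings")),
              config = config)
  rownames(out$trials) <- NULL
  rownames(out$ratings) <- NULL
  class(out) <- "trial_log"
  out
}

#' Simulate one group of participants
#'
#' Lower-level entry point used by [simulate_cohort()]; unlike the cohort
#' builder it accepts odd `n` (condition orders then alternate with a
#' one-participant imbalance), which matches reanalyses that need exactly
#' the original group size of 25.
#'
#' @param group `"COMPUTER"` or `"ROBOT"`.
#' @param n Number of participants (>= 1).
#' @param config A `run_config`; its `n_per_group` is ignored here.
#' @param orders Optional explicit vector of condition orders (recycled to
#'   length `n`); default alternates the two orders starting from a
#'   seed-drawn leader, as in [build_cohort()].
#' @return Object of class `trial_log` for that group.
#' @export
simulate_group <- function(group, n, config = default_config(), orders = NULL) {
  group <- .match_label(group, GROUPS, "group")
  .check_number(n, "n", lower = 1)
  off <- .group_offset(group)
  if (is.null(orders)) {
    set.seed(.subseed(config$seed, off))
    orders <- rep(sample(ORDERS), length.out = n)
  } else {
    orders <- rep(orders, length.out = n)
  }
  prefix <- if (group == "COMPUTER") "C" else "R"
  pop <- config$population
  obs0 <- config$observer
  pol0 <- config$policy[[group]]
  all_trials <- vector("list", n)
  all_ratings <- vector("list", n)
  for (k in seq_len(n)) {
    pid <- sprintf("%s%02d", prefix, k)
    sched <- build_session(group, orders[k], pid)
    set.seed(.subseed(config$seed, off + k))
    observer <- observer_params(
      weber_fraction = obs0$weber_fraction * exp(rnorm(1, 0, pop$weber_log_sd)),
      prior_sd = obs0$prior_sd * exp(rnorm(1, 0, pop$prior_sd_log_sd)),
      motor_sd = obs0$motor_sd,
      prior_update_rate = obs0$prior_update_rate
    )
    policy <- pol0
    policy$baseline_influence <- pol0$baseline_influence +
      rnorm(1, 0, pop$baseline_logit_sd)
    rating_bases <- c(self = rnorm(1, 0, pop$rating_base_sd),
                      other = rnorm(1, 0, pop$rating_base_sd))
    sim <- .simulate_participant(sched, config, observer, policy, rating_bases)
    all_trials[[k]] <- sim$trials
    all_ratings[[k]] <- sim$ratings
  }
  out <- list(trials = do.call(rbind, all_trials),
              ratings = do.call(rbind, all_ratings),
              config = config)
  rownames(out$trials) <- NULL
  rownames(out$ratings) <- NULL
  class(out) <- "trial_log"
  out
}

#' Per-participant behavioral aggregates
#'
#' @param log A `trial_log` from [simulate_cohort()] (or read back with
#'   [read_trial_log()]).
#' @return `data.frame`, one row per participant: solo-task regression index,
#'   underestimation and mean estimation error; baseline-task mean error and
#'   influence; reciprocal-task mean error and influence per condition.
#' @export
participant_summary <- function(log) {
  tr <- log$trials
  by_part <- split(tr, tr$participant_id)
  rows <- lapply(by_part, function(df) {
    solo <- df[df$task == "PERCEPTUAL_INFERENCE", ]
    soc <- df[df$task == "SOCIAL_INFLUENCE", ]
    rec <- df[df$task == "RECIPROCAL", ]
    soc_ii <- influence_index(soc$participant_estimate, soc$agent_estimate,
                              soc$final_decision)
    cond_mean <- function(cond, what) {
      sel <- rec$sampler_condition == cond & rec$condition %in% c("SUSCEPTIBLE", "UNSUSCEPTIBLE")
      if (what == "error") {
        mean(estimation_error(rec$participant_estimate[sel], rec$s[sel]))
      } else {
        d <- rec[sel & rec$decider == "PARTICIPANT", ]
        ii <- influence_index(d$participant_estimate, d$agent_estimate,
                              d$final_decision)
        mean(ii$i[ii$valid])
      }
    }
    data.frame(
      participant_id = df$participant_id[1],
      group = df$group[1],
      condition_order = df$condition_order[1],
      regression_index = regression_index(solo$s, solo$participant_estimate),
      underestimation = underestimation(solo$participant_estimate),
      solo_error = mean(estimation_error(solo$participant_estimate, solo$s)),
      baseline_error = mean(estimation_error(soc$participant_estimate, soc$s)),
      baseline_influence = mean(soc_ii$i[soc_ii$valid]),
      agent_error = mean(estimation_error(
        df$agent_estimate[!is.na(df$agent_estimate)],
        df$s[!is.na(df$agent_estimate)])),
      susceptible_error = cond_mean("SUSCEPTIBLE", "error"),
      unsusceptible_error = cond_mean("UNSUSCEPTIBLE", "error"),
      susceptible_influence = cond_mean("SUSCEPTIBLE", "influence"),
      unsusceptible_influence = cond_mean("UNSUSCEPTIBLE", "influence"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# assemble trial-level analysis tables from a log
.analysis_tables <- function(log) {
  tr <- log$trials
  joint <- tr[tr$task != "PERCEPTUAL_INFERENCE", ]
  joint$norm_distance <- normalized_response_distance(
    joint$participant_estimate, joint$agent_estimate, joint$s)
  joint$estimation_error <- estimation_error(joint$participant_estimate, joint$s)
  dec <- joint[joint$decider == "PARTICIPANT", ]
  ii <- influence_index(dec$participant_estimate, dec$agent_estimate,
                        dec$final_decision)
  dec$influence_obs <- ii$i
  dec$valid <- ii$valid

  # condition label used by the models: baseline task plus the two main
  # reciprocal conditions (transition block excluded; final block only in
  # model 6)
  lab <- function(df) {
    ifelse(df$task == "SOCIAL_INFLUENCE", "BASELINE",
           ifelse(df$condition %in% c("SUSCEPTIBLE", "UNSUSCEPTIBLE"),
                  df$condition, NA_character_))
  }
  joint$cond_label <- lab(joint)
  dec$cond_label <- lab(dec)

  m1 <- dec[dec$task == "SOCIAL_INFLUENCE" & dec$valid, ]
  m1 <- data.frame(participant_id = m1$participant_id, group = m1$group,
                   influence = m1$influence_obs, distance = m1$norm_distance)

  rt <- log$ratings[log$ratings$task == "RECIPROCAL", ]
  m2 <- data.frame(participant_id = rt$participant_id, group = rt$group,
                   rating_diff = rt$rating_diff,
                   partner_influence = rt$partner_influence)

  m34 <- joint[!is.na(joint$cond_label), ]
  m34 <- data.frame(participant_id = m34$participant_id, group = m34$group,
                    condition = m34$cond_label,
                    estimation_error = m34$estimation_error,
                    norm_distance = m34$norm_distance)

  m5 <- dec[!is.na(dec$cond_label) & dec$valid, ]
  m5 <- data.frame(participant_id = m5$participant_id, group = m5$group,
                   condition = m5$cond_label, influence = m5$influence_obs)

  m6 <- dec[dec$task == "RECIPROCAL" & dec$block %in% c(3L, 4L) & dec$valid, ]
  m6 <- data.frame(participant_id = m6$participant_id, group = m6$group,
                   is_final = m6$block == 4L, influence = m6$influence_obs)

  list(m1 = m1, m2 = m2, m34 = m34, m5 = m5, m6 = m6, decision = dec)
}

#' Full analysis of a trial log
#'
#' Computes every behavioral index and statistical contrast of the paradigm
#' from a simulated (or re-loaded) trial log: per-participant aggregates,
#' group summaries, the nonparametric tests (influence vs indifference,
#' group contrasts, accuracy comparisons, influence-rating correlation), the
#' six random-intercept models, the Susceptible - Unsusceptible contrasts,
#' and the distance-binned standardized-influence table per group.
#'
#' @param log A `trial_log`.
#' @return Named list: `participants`, `group_summary`, `tests` (stacked
#'   one-row results), `correlations`, `models` (list of coefficient
#'   tables), `model_contrasts`, `influence_bins` (per group).
#' @export
analyze_cohort <- function(log) {
  need <- c("participant_id", "group", "task", "block", "condition",
            "sampler_condition", "turn_kind", "trial_index", "s",
            "participant_estimate", "agent_estimate", "decider",
            "final_decision")
  missing_cols <- setdiff(need, names(log$trials))
  if (length(missing_cols)) {
    stop("trial log is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ps <- participant_summary(log)
  gs <- do.call(rbind, lapply(split(ps, ps$group), function(df) {
    data.frame(group = df$group[1],
               n = nrow(df),
               mean_solo_error = mean(df$solo_error),
               sd_solo_error = sd(df$solo_error),
               mean_regression_index = mean(df$regression_index),
               mean_underestimation = mean(df$underestimation),
               mean_baseline_influence = mean(df$baseline_influence),
               sd_baseline_influence = sd(df$baseline_influence),
               mean_agent_error = mean(df$agent_error),
               stringsAsFactors = FALSE)
  }))
  rownames(gs) <- NULL

  comp <- ps[ps$group == "COMPUTER", ]
  rob <- ps[ps$group == "ROBOT", ]
  tests <- rbind(
    wilcoxon_rank_sum(rob$solo_error, comp$solo_error,
                      name = "solo_error_robot_vs_computer"),
    wilcoxon_signed_rank(comp$baseline_influence, mu = 0.5,
                         name = "influence_vs_0.5_computer"),
    wilcoxon_signed_rank(rob$baseline_influence, mu = 0.5,
                         name = "influence_vs_0.5_robot"),
    wilcoxon_rank_sum(rob$baseline_influence, comp$baseline_influence,
                      name = "influence_robot_vs_computer"),
    wilcoxon_signed_rank(comp$baseline_error, comp$solo_error,
                         name = "error_social_vs_solo_computer"),
    wilcoxon_signed_rank(rob$baseline_error, rob$solo_error,
                         name = "error_social_vs_solo_robot"),
    wilcoxon_rank_sum(comp$baseline_error, comp$agent_error,
                      name = "error_participant_vs_agent_computer"),
    wilcoxon_rank_sum(rob$baseline_error, rob$agent_error,
                      name = "error_participant_vs_agent_robot")
  )

  rt <- log$ratings
  soc_rt <- rt[rt$task == "SOCIAL_INFLUENCE", ]
  rd <- setNames(soc_rt$rating_diff, soc_rt$participant_id)
  correlations <- list(
    COMPUTER = spearman(comp$baseline_influence, rd[comp$participant_id],
                        name = "influence_vs_rating_diff_computer"),
    ROBOT = spearman(rob$baseline_influence, rd[rob$participant_id],
                     name = "influence_vs_rating_diff_robot")
  )

  tabs <- .analysis_tables(log)
  models <- list(
    "1" = fit_random_intercept_model(tabs$m1, 1L),
    "2" = fit_random_intercept_model(tabs$m2, 2L),
    "3" = fit_random_intercept_model(tabs$m34, 3L),
    "4" = fit_random_intercept_model(tabs$m34, 4L),
    "5" = fit_random_intercept_model(tabs$m5, 5L),
    "6" = fit_random_intercept_model(tabs$m6, 6L)
  )
  model_contrasts <- rbind(
    fixed_contrast(models[["5"]], "conditionSUSCEPTIBLE", "conditionUNSUSCEPTIBLE",
                   name = "m5_susceptible_minus_unsusceptible")
  )

  soc_dec <- tabs$decision[tabs$decision$task == "SOCIAL_INFLUENCE", ]
  bins <- lapply(split(soc_dec, soc_dec$group), function(df) {
    binned_standardized_influence(data.frame(
      participant_id = df$participant_id, s = df$s,
      participant_estimate = df$participant_estimate,
      agent_estimate = df$agent_estimate, influence = df$influence_obs))
  })

  list(participants = ps, group_summary = gs, tests = tests,
       correlations = correlations, models = models,
       model_contrasts = model_contrasts, influence_bins = bins)
}
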