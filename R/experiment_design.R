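#' Build the full trial schedule for one simulated participant
#'
#' A session always consists of three tasks in fixed order: a solo length
#' reproduction task (66 trials), a joint task in which the participant makes
#' every final decision (66 trials, the "Baseline" condition), and a
#' reciprocal joint task (176 trials) in which decision turns (participant
#' decides) strictly alternate with observation turns (partner decides).
#'
#' The reciprocal task comprises: a first main block of 66 trials under one
#' susceptibility condition, a 22-trial transition block in which the
#' partner's influence follows a fixed ramp, a second main block of 66 trials
#' under the other condition, and a final block of 22 trials (11 observation
#' turns in a row, then 11 decision turns in a row) in which the partner keeps
#' sampling from the distribution of the last main condition. Decision turns
#' lead each alternating pair; this choice is fixed across participants and
#' does not affect any trial count.
#'
#' Pauses occur every 22 trials; performance ratings are collected at the end
#' of the solo and joint tasks and at three pauses of the reciprocal task
#' (after 44 trials of each main condition and right after the transition
#' block). Both are recorded as schedule annotations, not interactive events.
#'
#' @param group `"COMPUTER"` or `"ROBOT"` (the framing of the partner).
#' @param condition_order `"SUSCEPTIBLE_FIRST"` or `"UNSUSCEPTIBLE_FIRST"`.
#' @param participant_id Identifier string (or coercible).
#' @return A `data.frame` of schedule slots with columns `participant_id`,
#'   `group`, `condition_order`, `task`, `block` (1-based within task),
#'   `condition`, `sampler_condition` (the mixture the partner samples from on
#'   observation turns; for the final block this is the inherited last main
#'   condition, for the transition block it is `NA` because the ramp schedule
#'   applies), `turn_kind`, `trial_index` (0-based within task), `pause_after`
#'   and `rating_after` (logical annotations).
#' @export
#' @examples
#' sched <- build_session("ROBOT", "SUSCEPTIBLE_FIRST", "P01")
#' table(sched$task)
build_session <- function(group, condition_order, participant_id) {
  group <- .match_label(group, GROUPS, "group")
  condition_order <- .match_label(condition_order, ORDERS, "condition_order")
  participant_id <- as.character(participant_id)

  first  <- if (condition_order == "SUSCEPTIBLE_FIRST") "SUSCEPTIBLE" else "UNSUSCEPTIBLE"
  second <- if (first == "SUSCEPTIBLE") "UNSUSCEPTIBLE" else "SUSCEPTIBLE"

  alt <- function(n_pairs) rep(c("DECISION", "OBSERVATION"), n_pairs)

  slot <- function(task, block, condition, sampler, turn_kind) {
    data.frame(task = task, block = block, condition = condition,
               sampler_condition = sampler, turn_kind = turn_kind,
               stringsAsFactors = FALSE)
  }

  parts <- rbind(
    slot("PERCEPTUAL_INFERENCE", 1L, NA_character_, NA_character_, rep("SOLO", 66)),
    slot("SOCIAL_INFLUENCE", rep(1:3, each = 22L), "BASELINE", NA_character_,
         rep("DECISION", 66)),
    slot("RECIPROCAL", 1L, first, first, alt(33)),
    slot("RECIPROCAL", 2L, "TRANSITION", NA_character_, alt(11)),
    slot("RECIPROCAL", 3L, second, second, alt(33)),
    slot("RECIPROCAL", 4L, "FINAL", second,
         c(rep("OBSERVATION", 11), rep("DECISION", 11)))
  )

  idx <- unlist(lapply(TASKS, function(tk) {
    seq_len(sum(parts$task == tk)) - 1L
  }))
  parts$trial_index <- idx

  parts$pause_after <- (parts$task != "PERCEPTUAL_INFERENCE") &
    ((parts$trial_index + 1L) %% 22L == 0L) &
    (parts$trial_index + 1L) < ifelse(parts$task == "RECIPROCAL", 176L, 66L)
  parts$rating_after <-
    (parts$task != "RECIPROCAL" & parts$trial_index == 65L) |
    (parts$task == "RECIPROCAL" & parts$trial_index %in% c(43L, 87L, 131L))

  out <- cbind(
    data.frame(participant_id = participant_id, group = group,
               condition_order = condition_order, stringsAsFactors = FALSE),
    parts
  )
  rownames(out) <- NULL
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' Build a counterbalanced cohort of session schedules
#'
#' Produces `n_per_group` schedules for each of the two groups, with exactly
#' half of each group receiving the Susceptible condition first. Orders
#' alternate along the participant index (which of the two orders leads the
#' alternation is drawn per group from `seed`), so growing the cohort never
#' changes the schedule of an already-existing participant.
#'
#' @param n_per_group Even integer >= 2, participants per group.
#' @param seed Integer seed controlling which condition order leads each
#'   group's alternation.
#' @return List of `session_schedule` data frames (Computer group first),
#'   with participant ids `C01..` and `R01..`.
#' @export
#' @examples
#' cohort <- build_cohort(4, seed = 1)
#' length(cohort)
build_cohort <- function(n_per_group, seed = 1L) {
  .check_number(n_per_group, "n_per_group", lower = 2)
  if (n_per_group %% 2 != 0) {
    stop("n_per_group must be even so that condition order can be exactly ",
         "counterbalanced within each group; use ", n_per_group - 1, " or ",
         n_per_group + 1, " participants per group instead", call. = FALSE)
  }
  sessions <- list()
  for (g in GROUPS) {
    set.seed(.subseed(seed, .group_offset(g)))
    orders <- rep(sample(ORDERS), length.out = n_per_group)
    prefix <- if (g == "COMPUTER") "C" else "R"
    for (k in seq_len(n_per_group)) {
      pid <- sprintf("%s%02d", prefix, k)
      sessions[[pid]] <- build_session(g, orders[k], pid)
    }
  }
  sessions
}

# fixed per-group offsets for substream derivation; keeps each participant's
# random stream invariant to the size of the other (or own) group
.group_offset <- function(group) {
  if (group == "COMPUTER") 0L else 100000L
}

#' Export a list of schedules as one tidy table
#'
#' @param sessions List of `session_schedule` objects (e.g. [build_cohort()]).
#' @param path Optional CSV path; if given the table is also written to disk.
#' @return The combined `data.frame`, invisibly if written to `path`.
#' @export
export_schedule <- function(sessions, path = NULL) {
  if (inherits(sessions, "session_schedule")) sessions <- list(sessions)
  tab <- do.call(rbind, lapply(sessions, as.data.frame))
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
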