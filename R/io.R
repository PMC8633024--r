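#' Write / read a trial log as plain-text CSV + JSON
#'
#' A trial log is persisted as `trials.csv`, `ratings.csv` and `config.json`
#' in a directory. Reading the directory back yields a `trial_log` whose
#' analysis output is identical to the in-memory original (full-precision
#' floats are preserved via 17 significant digits).
#'
#' @param log A `trial_log` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_trial_log`: the directory, invisibly. `read_trial_log`:
#'   the reconstructed `trial_log`.
#' @export
write_trial_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    df
  }
  write.csv(fmt(log$trials), file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(fmt(log$ratings), file.path(dir, "ratings.csv"), row.names = FALSE)
  write_config(log$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(dir) {
  trials <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  ratings <- read.csv(file.path(dir, "ratings.csv"), stringsAsFactors = FALSE)
  # columns that are entirely NA (e.g. sampler_condition in solo trials)
  # come back logical; restore types
  for (cc in c("condition", "sampler_condition", "decider")) {
    trials[[cc]] <- as.character(trials[[cc]])
  }
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) read_config(cfg_path) else NULL
  structure(list(trials = trials, ratings = ratings, config = config),
            class = "trial_log")
}

#' Serialize / deserialize a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `write_config`: `path`, invisibly. `read_config`: a `run_config`.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else if (is.atomic(x) && !is.null(names(x))) {
      x <- as.list(x)  # keep names: serialize as a JSON object
    }
    x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mix <- lapply(raw$agent$mixtures, as.data.frame)
  cfg <- default_config(
    n_per_group = raw$n_per_group,
    seed = raw$seed,
    agent = agent_params(estimate_sd = raw$agent$estimate_sd,
                         resample_threshold = raw$agent$resample_threshold,
                         resample_prob = raw$agent$resample_prob,
                         mixtures = mix),
    observer = do.call(observer_params,
                       raw$observer[setdiff(names(raw$observer), "prior_mean")]),
    policy = lapply(raw$policy, function(p) {
      influence_policy_params(
        baseline_influence = p$baseline_influence,
        distance_slope = p$distance_slope,
        condition_shift = unlist(p$condition_shift),
        final_block_shift = p$final_block_shift,
        policy_noise_sd = p$policy_noise_sd)
    }),
    rating = do.call(rating_model, raw$rating),
    population = raw$population,
    learning_wf_multiplier = lapply(raw$learning_wf_multiplier, unlist)
  )
  cfg
}

#' Export an analysis report
#'
#' Writes the tidy result tables of [analyze_cohort()] as CSV files plus a
#' machine-readable JSON summary of every statistic.
#'
#' @param analysis Result of [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(analysis$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write.csv(analysis$group_summary, file.path(dir, "group_summary.csv"),
            row.names = FALSE)
  write.csv(analysis$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  mod_tab <- do.call(rbind, analysis$models)
  write.csv(mod_tab, file.path(dir, "models.csv"), row.names = FALSE)
  write.csv(analysis$model_contrasts, file.path(dir, "model_contrasts.csv"),
            row.names = FALSE)
  for (g in names(analysis$influence_bins)) {
    write.csv(analysis$influence_bins[[g]],
              file.path(dir, sprintf("influence_bins_%s.csv", tolower(g))),
              row.names = FALSE)
  }
  summary <- list(
    group_summary = analysis$group_summary,
    tests = analysis$tests,
    correlations = analysis$correlations,
    models = lapply(analysis$models, function(m) m[setdiff(names(m), "fit")]),
    model_contrasts = analysis$model_contrasts
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
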