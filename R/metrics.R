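#' Influence index of a final decision
#'
#' The influence index `i` is the adjustment toward the partner, `a`, divided
#' by the distance between the two estimates, `d`. It is 0 when the decider
#' confirms its own estimate and 1 when it adopts the partner's. When the two
#' estimates (practically) coincide (`d` below `1e-6` cm), the index is
#' undefined and the record is flagged invalid; such trials are excluded from
#' influence analyses.
#'
#' @param own Decider's own estimate (cm); vectorized.
#' @param other Partner's estimate (cm).
#' @param final Final decision (cm); must lie between `own` and `other`
#'   (tolerance `1e-9`), otherwise a data-integrity error is raised.
#' @return `data.frame` with columns `a` (cm, signed toward the partner),
#'   `d` (cm), `i` (dimensionless, `NA` when invalid) and `valid`.
#' @export
#' @examples
#' influence_index(10, 14, 11)  # i = 0.25
influence_index <- function(own, other, final) {
  n <- max(length(own), length(other), length(final))
  own <- rep_len(own, n); other <- rep_len(other, n); final <- rep_len(final, n)
  lo <- pmin(own, other); hi <- pmax(own, other)
  bad <- final < lo - 1e-9 | final > hi + 1e-9
  if (any(bad, na.rm = TRUE)) {
    stop("final decision outside the segment between the two estimates ",
         "(first offending index: ", which(bad)[1], ")", call. = FALSE)
  }
  d <- abs(other - own)
  a <- (final - own) * sign(other - own)
  valid <- d >= 1e-6
  i <- ifelse(valid, a / d, NA_real_)
  i <- ifelse(valid, pmin(pmax(i, 0), 1), i)  # absorb the 1e-9 tolerance
  data.frame(a = a, d = d, i = i, valid = valid)
}

#' Relative estimation error
#'
#' Absolute difference between estimate and true length, divided by the true
#' length. Dimensionless and scale-invariant.
#'
#' @param estimate Estimate(s) in cm.
#' @param s True length(s) in cm, > 0.
#' @return `|estimate - s| / s`.
#' @export
#' @examples
#' estimation_error(10, 8)  # 0.25
estimation_error <- function(estimate, s) {
  if (any(s <= 0)) stop("s must be > 0", call. = FALSE)
  abs(estimate - s) / s
}

#' Regression index (strength of central tendency)
#'
#' One minus the OLS slope of responses on stimuli: 0 means veridical
#' reproduction, values near 1 mean complete regression to the mean of the
#' stimulus history. Invariant to adding a constant to all responses.
#'
#' @param stimuli Stimulus lengths (cm); at least 3 distinct values.
#' @param responses Reproduced lengths (cm), same length.
#' @return Dimensionless index.
#' @export
#' @examples
#' regression_index(1:10, 0.5 * (1:10) + 6)  # 0.5
regression_index <- function(stimuli, responses) {
  if (length(stimuli) != length(responses)) {
    stop("stimuli and responses must have equal length", call. = FALSE)
  }
  ok <- complete.cases(stimuli, responses)
  stimuli <- stimuli[ok]; responses <- responses[ok]
  if (length(unique(stimuli)) < 3) {
    stop("regression_index requires at least 3 distinct stimulus values",
         call. = FALSE)
  }
  1 - cov(stimuli, responses) / var(stimuli)
}

#' Mean underestimation relative to the 12 cm design mean
#'
#' Difference between the mean reproduced length and the mean of the stimulus
#' design distribution (exactly 12 cm under the balanced grid); negative
#' values indicate underestimation.
#'
#' @param responses Reproduced lengths (cm).
#' @return Mean response minus 12, in cm.
#' @export
underestimation <- function(responses) {
  if (length(responses) == 0) stop("responses must be non-empty", call. = FALSE)
  mean(responses) - 12
}

#' Response distance normalized by the stimulus length
#'
#' @param own,other The two estimates (cm).
#' @param s True stimulus length (cm), > 0.
#' @return `|own - other| / s` (symmetric in the two estimates).
#' @export
normalized_response_distance <- function(own, other, s) {
  if (any(s <= 0)) stop("s must be > 0", call. = FALSE)
  abs(own - other) / s
}

#' Within-subject standardized influence by response-distance bin
#'
#' Reproduces the distance-binning procedure used to visualize egocentric
#' discounting: per participant, the SD of the participant's own estimates is
#' computed for each stimulus length; each trial's inter-agent distance is
#' expressed in units of that per-stimulus SD and assigned to one of nine
#' half-open bins of width 0.05 SDs (`[0, 0.05)`, ..., with the ninth bin
#' absorbing everything at or above 0.40 SDs); influence is z-scored within
#' participant (a constant series z-scores to 0, with a warning); bin means
#' are taken within and then across participants. Bins never populated are
#' reported as `NA`, not 0.
#'
#' @param records `data.frame` with columns `participant_id`, `s`,
#'   `participant_estimate`, `agent_estimate` and `influence` (one row per
#'   decision trial). At least 2 trials per stimulus length per participant
#'   are required for the per-stimulus SDs.
#' @return `data.frame` with 9 rows: `bin`, `lo`, `hi` (SD units; the last
#'   `hi` is `Inf`), `mean_std_influence`, `n_participants`, `n_trials`.
#' @export
binned_standardized_influence <- function(records) {
  need <- c("participant_id", "s", "participant_estimate", "agent_estimate",
            "influence")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  edges <- seq(0, 0.45, by = 0.05)
  per_part <- lapply(split(records, records$participant_id), function(df) {
    cnt <- table(df$s)
    if (any(cnt < 2)) {
      stop("binned_standardized_influence needs >= 2 trials per stimulus ",
           "length per participant", call. = FALSE)
    }
    sd_by_s <- tapply(df$participant_estimate, df$s, sd)
    denom <- sd_by_s[as.character(df$s)]
    dist_sd <- abs(df$participant_estimate - df$agent_estimate) / denom
    bin <- pmin(findInterval(dist_sd, edges), 9L)
    s_infl <- sd(df$influence, na.rm = TRUE)
    if (is.na(s_infl) || s_infl == 0) {
      warning("constant influence series z-scored to 0 for participant ",
              df$participant_id[1])
      z <- rep(0, nrow(df))
    } else {
      z <- (df$influence - mean(df$influence, na.rm = TRUE)) / s_infl
    }
    out <- rep(NA_real_, 9)
    cnts <- integer(9)
    for (b in unique(bin[!is.na(df$influence)])) {
      sel <- bin == b & !is.na(df$influence)
      out[b] <- mean(z[sel])
      cnts[b] <- sum(sel)
    }
    list(means = out, counts = cnts)
  })
  mat <- do.call(rbind, lapply(per_part, `[[`, "means"))
  cnt <- Reduce(`+`, lapply(per_part, `[[`, "counts"))
  n_part <- colSums(!is.na(mat))
  msi <- colMeans(mat, na.rm = TRUE)
  msi[n_part == 0] <- NA_real_
  data.frame(
    bin = 1:9,
    lo = edges[1:9],
    hi = c(edges[2:9], Inf),
    mean_std_influence = msi,
    n_participants = n_part,
    n_trials = cnt
  )
}
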