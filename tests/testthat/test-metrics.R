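test_that("influence index implements a / d with degeneracy guard", {
  r <- influence_index(10, 14, 11)
  expect_equal(r$i, 0.25)
  expect_equal(r$a, 1)
  expect_equal(r$d, 4)
  expect_true(r$valid)
  # direction-agnostic: same index when the partner is below
  expect_equal(influence_index(14, 10, 13)$i, 0.25)
  expect_equal(influence_index(10, 14, 10)$i, 0)
  expect_equal(influence_index(10, 14, 14)$i, 1)
  deg <- influence_index(10, 10, 10)
  expect_false(deg$valid)
  expect_true(is.na(deg$i))
  expect_error(influence_index(10, 14, 15), "outside the segment")
  expect_error(influence_index(10, 14, 9.5), "outside the segment")
})

test_that("estimation error is relative and scale-invariant", {
  expect_equal(estimation_error(10, 8), 0.25)
  expect_equal(estimation_error(12, 12), 0)
  expect_equal(estimation_error(6, 12), 0.5)
  expect_equal(estimation_error(3 * 10, 3 * 8), estimation_error(10, 8))
  expect_error(estimation_error(10, 0), "s must be")
})

test_that("regression index has its closed forms and invariances", {
  s <- rep(stimulus_grid(), each = 3)
  expect_equal(regression_index(s, s), 0)
  expect_equal(regression_index(s, rep(12, length(s))), 1)
  expect_equal(regression_index(s, 0.5 * s + 6), 0.5)
  # shift invariance: adding a constant to all responses leaves it unchanged
  set.seed(31)
  resp <- 0.7 * s + rnorm(length(s))
  expect_equal(regression_index(s, resp), regression_index(s, resp + 3.7))
  expect_error(regression_index(rep(12, 5), rnorm(5)), "distinct")
  expect_error(regression_index(1:4, 1:3), "equal length")
})

test_that("underestimation is measured against the 12 cm design mean", {
  expect_equal(underestimation(rep(12, 10)), 0)
  expect_equal(underestimation(c(10, 10.96)), -1.52)
  expect_equal(underestimation(stimulus_grid()), 0)
  expect_error(underestimation(numeric(0)), "non-empty")
})

test_that("normalized response distance is symmetric and scale-invariant", {
  expect_equal(normalized_response_distance(10, 10, 12), 0)
  expect_equal(normalized_response_distance(10, 13, 12), 0.25)
  expect_equal(normalized_response_distance(13, 10, 12),
               normalized_response_distance(10, 13, 12))
  expect_equal(normalized_response_distance(20, 26, 24),
               normalized_response_distance(10, 13, 12))
})

test_that("distance binning standardizes influence within participants", {
  # participant with known per-stimulus SD: estimates at three lengths with
  # agent responses placed to land in chosen bins
  mk <- function(pid, est_jitter, agent_offset, infl) {
    s <- rep(c(8, 12, 16), each = 4)
    est <- s + est_jitter
    data.frame(participant_id = pid, s = s, participant_estimate = est,
               agent_estimate = est + agent_offset, influence = infl)
  }
  jit <- rep(c(-1, -0.5, 0.5, 1), times = 3)  # per-stimulus SD ~ 0.91
  df <- mk("P1", jit, agent_offset = 0.01, infl = runif(12))
  out <- binned_standardized_influence(df)
  expect_equal(nrow(out), 9)
  # all distances < 0.05 SD: only bin 1 populated
  expect_true(out$n_trials[1] == 12)
  expect_true(all(is.na(out$mean_std_influence[2:9])))
  expect_equal(out$n_participants[2:9], rep(0, 8))

  # constant influence z-scores to 0 with a warning
  df2 <- mk("P2", jit, agent_offset = 0.01, infl = rep(0.3, 12))
  expect_warning(out2 <- binned_standardized_influence(df2), "constant influence")
  expect_equal(out2$mean_std_influence[1], 0)

  # z-scored means average to ~0 over all of a participant's trials
  set.seed(32)
  df3 <- mk("P3", jit, agent_offset = runif(12, 0, 2), infl = runif(12))
  out3 <- binned_standardized_influence(df3)
  tot <- sum(out3$mean_std_influence * out3$n_trials, na.rm = TRUE)
  expect_lt(abs(tot), 1e-8)

  expect_error(binned_standardized_influence(df[, -2]), "missing columns")
  # fewer than 2 trials for some stimulus length is rejected
  df4 <- df[-c(1:3), ]
  expect_error(binned_standardized_influence(df4), ">= 2 trials")
})

test_that("bin means decline when the generative distance slope is negative", {
  # simulation oracle: steep negative slope, no policy noise, so influence is
  # a deterministic decreasing function of distance
  set.seed(33)
  pol <- influence_policy_params(baseline_influence = 0, distance_slope = -6,
                                 policy_noise_sd = 0)
  rows <- lapply(1:4, function(p) {
    s <- rep(stimulus_grid(), each = 6)
    est <- s + rnorm(length(s), 0, 0.12 * s)
    agent <- s + rnorm(length(s), 0, 1.52)
    infl <- vapply(seq_along(s), function(t) {
      decide_influence(abs(est[t] - agent[t]) / s[t], "BASELINE", FALSE, pol)
    }, numeric(1))
    data.frame(participant_id = sprintf("P%d", p), s = s,
               participant_estimate = est, agent_estimate = agent,
               influence = infl)
  })
  out <- binned_standardized_influence(do.call(rbind, rows))
  filled <- which(!is.na(out$mean_std_influence))
  expect_gt(length(filled), 3)
  fit <- coef(lm(out$mean_std_influence[filled] ~ filled))
  expect_lt(fit[2], 0)
})
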