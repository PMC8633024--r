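sim_session <- function(observer, n = 66, seed = 1) {
  set.seed(seed)
  st <- generate_stimuli(n)
  est <- numeric(n)
  for (t in seq_len(n)) {
    pe <- perceive_and_estimate(st$s[t], observer)
    observer <- pe$observer
    est[t] <- pe$estimate
  }
  list(s = st$s, est = est)
}

test_that("the observer is veridical in the noiseless limit", {
  obs <- observer_params(weber_fraction = 1e-8, motor_sd = 0)
  sim <- sim_session(obs)
  expect_equal(sim$est, sim$s, tolerance = 1e-5)
  expect_lt(abs(regression_index(sim$s, sim$est)), 1e-4)
})

test_that("central tendency grows with the Weber fraction", {
  # simulation oracle over a Weber-fraction grid: the fitted response slope
  # stays below 1 and decreases as sensory noise grows
  slopes <- vapply(c(0.1, 0.25, 0.4), function(wf) {
    obs <- observer_params(weber_fraction = wf)
    sims <- lapply(1:8, function(sd) sim_session(obs, seed = sd))
    mean(vapply(sims, function(x) 1 - regression_index(x$s, x$est), numeric(1)))
  }, numeric(1))
  expect_true(all(slopes < 1))
  expect_true(all(diff(slopes) < 0))
})

test_that("scalar variability: per-stimulus response SD grows with length", {
  obs <- observer_params()
  set.seed(21)
  s <- rep(stimulus_grid(), each = 60)
  est <- numeric(length(s))
  for (t in seq_along(s)) {
    pe <- perceive_and_estimate(s[t], obs)
    obs <- pe$observer
    est[t] <- pe$estimate
  }
  sd_by_s <- tapply(est, s, sd)
  fit <- coef(lm(sd_by_s ~ stimulus_grid()))
  expect_gt(fit[2], 0)
})

test_that("calibrated defaults underestimate on average", {
  # magnitude-dependent shrinkage pulls long stimuli toward the prior more
  # than short ones are pushed up; the expected session mean sits a few mm
  # below 12 cm, so average over enough sessions to resolve it
  means <- vapply(1:100, function(sd) {
    mean(sim_session(observer_params(), seed = sd)$est)
  }, numeric(1))
  expect_lt(mean(means), 12)
})

test_that("influence policy squashes a logit-linear predictor", {
  quiet <- influence_policy_params(baseline_influence = qlogis(0.5),
                                   distance_slope = 0, policy_noise_sd = 0)
  expect_equal(decide_influence(0.3, "BASELINE", FALSE, quiet), 0.5)
  expect_equal(decide_influence(0.3, "SUSCEPTIBLE", FALSE, quiet), 0.5)
  # negative slope: mean influence non-increasing across distances
  pol <- influence_policy_params(baseline_influence = 0, distance_slope = -3,
                                 policy_noise_sd = 0)
  iv <- vapply(seq(0, 1, by = 0.1), function(d) {
    decide_influence(d, "BASELINE", FALSE, pol)
  }, numeric(1))
  expect_true(all(diff(iv) < 0))
  # condition and final-block shifts act additively on the logit scale
  pol2 <- influence_policy_params(baseline_influence = 0, distance_slope = 0,
                                  condition_shift = c(SUSCEPTIBLE = 0.5),
                                  final_block_shift = -0.25,
                                  policy_noise_sd = 0)
  expect_equal(decide_influence(0, "SUSCEPTIBLE", FALSE, pol2), plogis(0.5))
  expect_equal(decide_influence(0, "SUSCEPTIBLE", TRUE, pol2), plogis(0.25))
})

test_that("participant final decisions interpolate and validate", {
  expect_equal(participant_final_decision(14, 10, 0), 14)
  expect_equal(participant_final_decision(14, 10, 1), 10)
  expect_equal(participant_final_decision(14, 10, 0.5), 12)
  expect_error(participant_final_decision(14, 10, 2), "\\[0, 1\\]")
})

test_that("influence index round-trips through the final decision", {
  # with zero policy noise and zero distance slope the influence recovered
  # from the logged decision equals the squashed baseline exactly
  pol <- influence_policy_params(baseline_influence = -0.4, distance_slope = 0,
                                 policy_noise_sd = 0)
  target <- plogis(-0.4)
  set.seed(22)
  for (k in 1:20) {
    own <- runif(1, 8, 16); other <- runif(1, 8, 16)
    i <- decide_influence(abs(own - other) / 12, "BASELINE", FALSE, pol)
    fin <- participant_final_decision(own, other, i)
    rec <- influence_index(own, other, fin)
    expect_equal(rec$i, target, tolerance = 1e-12)
  }
})

test_that("ratings reflect observed partner susceptibility", {
  flat <- rating_model(susceptibility_penalty = 0)
  expect_identical(emit_ratings(0.1, flat), emit_ratings(0.9, flat))
  m <- rating_model()
  lo <- emit_ratings(0.18, m)
  hi <- emit_ratings(0.64, m)
  expect_gt(hi[["self"]] - hi[["other"]], lo[["self"]] - lo[["other"]])
  # defaults: own accuracy rated above the partner's
  expect_gt(lo[["self"]], lo[["other"]])
  expect_true(all(c(lo, hi) >= 1 & c(lo, hi) <= 10))
  expect_error(emit_ratings(1.4, m), "observed_partner_influence")
})
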