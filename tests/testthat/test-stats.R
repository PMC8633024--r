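test_that("signed-rank test is symmetric-null calibrated", {
  # perfectly mirrored sample around the null (binary-exact offsets so the
  # mirroring survives floating point): no evidence at all
  res <- wilcoxon_signed_rank(c(0.25, 0.375, 0.4375, 0.5625, 0.625, 0.75),
                              mu = 0.5)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  expect_equal(res$r, 0)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), mu = 0), "at least 5")
})

test_that("small-sample signed-rank p equals brute-force enumeration", {
  set.seed(41)
  for (k in 1:6) {
    n <- sample(6:9, 1)
    x <- round(rnorm(n, 0.3, 1), 2)
    x <- x[x != 0]
    if (length(x) < 5) next
    res <- wilcoxon_signed_rank(x, mu = 0)
    expect_equal(res$p, oracle_signed_rank_p(x), tolerance = 1e-12)
    # cross-check against the independent base-R exact test when tieless
    if (!any(duplicated(abs(x)))) {
      expect_equal(res$p, wilcox.test(x, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("signed-rank effect sizes follow the z-based identities", {
  set.seed(42)
  x <- rnorm(25, 0.6, 0.15)
  res <- wilcoxon_signed_rank(x, mu = 0.5)
  expect_equal(res$r, res$z / sqrt(25))
  expect_equal(res$eta_sq, res$r^2)
  # the effect-size convention: z = 3.51 with N = 25 gives r = 0.702
  expect_equal(3.51 / sqrt(25), 0.702)
})

test_that("rank-sum test matches enumeration and is rank-invariant", {
  res0 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$z, 0)
  set.seed(43)
  for (k in 1:6) {
    x <- round(rnorm(sample(4:6, 1), 0, 1), 2)
    y <- round(rnorm(sample(4:6, 1), 0.8, 1), 2)
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$p, oracle_rank_sum_p(x, y), tolerance = 1e-12)
    if (!any(duplicated(c(x, y)))) {
      expect_equal(res$p, wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # invariance under a strictly monotone transform of the pooled data
    res_t <- wilcoxon_rank_sum(exp(x), exp(y))
    expect_equal(res$z, res_t$z)
    expect_equal(res$p, res_t$p)
    expect_equal(res$n, length(x) + length(y))
    expect_equal(res$r, res$z / sqrt(res$n))
  }
  # effect-size convention check: z = 1.00 with N = 50 gives r = 0.14
  expect_equal(round(1.00 / sqrt(50), 2), 0.14)
})

test_that("spearman hits its closed forms and enumeration oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -2 * x + 1)$rho, -1)
  set.seed(44)
  for (k in 1:4) {
    n <- sample(5:7, 1)
    a <- rnorm(n); b <- 0.5 * a + rnorm(n)
    res <- spearman(a, b)
    expect_equal(res$p, oracle_spearman_p(a, b), tolerance = 1e-12)
  }
  expect_warning(res <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman(1:3, 1:3), "n >= 4")
})

test_that("random-intercept model collapses to OLS without grouping variance", {
  set.seed(45)
  n <- 240
  d <- data.frame(
    participant_id = rep(sprintf("P%d", 1:12), each = n / 12),
    distance = runif(n, 0, 0.6)
  )
  d$influence <- 0.5 - 0.44 * d$distance + rnorm(n, 0, 0.05)
  spec <- list(model_id = 99L, response = "influence", fixed = "distance",
               formula = influence ~ distance + (1 | participant_id),
               required = c("influence", "distance", "participant_id"))
  res <- suppressWarnings(fit_random_intercept_model(d, spec = spec))
  ols <- coef(lm(influence ~ distance, data = d))
  expect_equal(res$estimate, unname(ols), tolerance = 1e-4)
  expect_equal(res$term, c("(Intercept)", "distance"))
  expect_equal(res$n, rep(n, 2))
  expect_equal(res$eta_sq, res$r^2)
})

test_that("the model recovers a known distance slope", {
  set.seed(46)
  n_part <- 20; n_trial <- 40
  d <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:n_part), each = n_trial),
    distance = runif(n_part * n_trial, 0, 0.6)
  )
  intercepts <- rnorm(n_part, 0.5, 0.1)
  d$influence <- intercepts[as.integer(factor(d$participant_id))] -
    0.44 * d$distance + rnorm(nrow(d), 0, 0.08)
  spec <- list(model_id = 98L, response = "influence", fixed = "distance",
               formula = influence ~ distance + (1 | participant_id),
               required = c("influence", "distance", "participant_id"))
  res <- fit_random_intercept_model(d, spec = spec)
  slope <- res[res$term == "distance", ]
  expect_lt(abs(slope$estimate + 0.44), 1.96 * slope$se)
})

test_that("model requirements are validated", {
  expect_error(fit_random_intercept_model(data.frame(x = 1), 1L),
               "missing columns")
  d <- data.frame(participant_id = "P1", influence = runif(10),
                  group = "COMPUTER", distance = runif(10))
  expect_error(fit_random_intercept_model(d, 1L), "at least 2 participants")
  expect_error(fit_random_intercept_model(d, 7L), "model_id")
})

test_that("model term names follow the frozen schema", {
  an <- suppressWarnings(analyze_cohort(small_log()))
  expect_equal(an$models[["1"]]$term,
               c("(Intercept)", "groupROBOT", "distance", "groupROBOT:distance"))
  expect_equal(an$models[["2"]]$term, c("(Intercept)", "partner_influence"))
  for (id in c("3", "4", "5")) {
    expect_equal(an$models[[id]]$term,
                 c("(Intercept)", "groupROBOT", "conditionSUSCEPTIBLE",
                   "conditionUNSUSCEPTIBLE", "groupROBOT:conditionSUSCEPTIBLE",
                   "groupROBOT:conditionUNSUSCEPTIBLE"))
  }
  expect_equal(an$models[["6"]]$term,
               c("(Intercept)", "groupROBOT", "is_finalTRUE",
                 "groupROBOT:is_finalTRUE"))
  expect_equal(an$model_contrasts$term[1], "m5_susceptible_minus_unsusceptible")
})

test_that("bonferroni thresholds are alpha / m", {
  out <- bonferroni(c(0.03, 0.01), m = 2)
  expect_equal(out$threshold, rep(0.025, 2))
  expect_equal(out$significant, c(FALSE, TRUE))
  expect_true(bonferroni(0.03, m = 1)$significant)
})
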