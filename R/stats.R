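# Nonparametric tests with rank-based effect sizes and random-intercept
# models. All tests are two-tailed. Effect sizes follow the z-based
# conventions r = z / sqrt(N) and eta^2 = z^2 / N with N the total number of
# observations entering the test.

.stat_result <- function(name, estimate, z, p, n) {
  data.frame(name = name, estimate = estimate, z = z, p = p,
             r = z / sqrt(n), eta_sq = z^2 / n, n = n,
             stringsAsFactors = FALSE)
}

# tie correction term sum(t^3 - t) over groups of tied values
.tie_term <- function(v) {
  t <- table(v)
  sum(t^3 - t)
}

#' Wilcoxon signed-rank test with z-based effect sizes
#'
#' One-sample (against `mu`) or paired test. The z statistic always comes
#' from the tie-corrected normal approximation of the signed-rank statistic
#' (so that `r = z / sqrt(N)` is well defined); the p value is exact -- by
#' full enumeration of all sign assignments -- when fewer than 10 non-zero
#' differences remain, and normal-based otherwise. Zero differences are
#' dropped from the ranking but still count toward `N` in the effect sizes.
#'
#' @param x Numeric sample.
#' @param y Optional paired sample.
#' @param mu Null value for the one-sample case (e.g. 0.5 for an influence
#'   index tested against indifference).
#' @param name Label carried into the result row.
#' @return One-row `data.frame`: `name`, `estimate` (median difference), `z`,
#'   `p`, `r`, `eta_sq`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0, name = "signed_rank") {
  d <- if (is.null(y)) x - mu else {
    if (length(x) != length(y)) stop("paired samples must have equal length",
                                     call. = FALSE)
    x - y
  }
  d <- d[!is.na(d)]
  N <- length(d)
  d_nz <- d[d != 0]
  n <- length(d_nz)
  if (n < 5) {
    stop("wilcoxon_signed_rank requires at least 5 non-zero differences",
         call. = FALSE)
  }
  r_abs <- rank(abs(d_nz))
  W <- sum(r_abs[d_nz > 0])
  mu_W <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - .tie_term(abs(d_nz)) / 48
  z <- (W - mu_W) / sqrt(sigma2)
  if (n < 10) {
    # exact two-sided p by enumeration of all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wdist <- as.vector(signs %*% r_abs)
    p <- mean(abs(Wdist - mu_W) >= abs(W - mu_W) - 1e-9)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  .stat_result(name, stats::median(d), z, min(p, 1), N)
}

#' Wilcoxon rank-sum test with z-based effect sizes
#'
#' Two-sample test on `x` vs `y`. The z statistic is the tie-corrected
#' normal approximation of the rank-sum of `x` (positive z: `x` tends to be
#' larger). The p value is exact -- full enumeration of all group
#' assignments -- when the pooled sample has at most 12 observations, and
#' normal-based otherwise.
#'
#' @param x,y Numeric samples.
#' @param name Label carried into the result row.
#' @return One-row `data.frame` as in [wilcoxon_signed_rank()]; `estimate` is
#'   the difference of sample medians, `n` is the pooled size.
#' @export
wilcoxon_rank_sum <- function(x, y, name = "rank_sum") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])
  mu_W <- n1 * (N + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - .tie_term(pooled) / (N * (N - 1)))
  z <- if (sigma2 > 0) (W - mu_W) / sqrt(sigma2) else 0
  if (N <= 12) {
    combos <- combn(N, n1)
    Wdist <- colSums(matrix(rk[combos], nrow = n1))
    p <- mean(abs(Wdist - mu_W) >= abs(W - mu_W) - 1e-9)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  .stat_result(name, stats::median(x) - stats::median(y), z, min(p, 1), N)
}

# all permutations of 1:n as an n! x n matrix (used for exact Spearman p)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Rank correlation with average ranks for ties. The two-tailed p value is
#' exact (full enumeration of the `n!` rank permutations) for `n <= 7` and
#' t-approximated otherwise. Constant input is flagged with a warning and an
#' `NA` correlation.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @param name Label for the result.
#' @return List with `name`, `rho`, `p`, `n`.
#' @export
spearman <- function(x, y, name = "spearman") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman requires n >= 4", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("spearman: constant input, correlation undefined")
    return(list(name = name, rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 7) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(name = name, rho = rho, p = min(p, 1), n = n)
}

#' Specifications of the six trial-level random-intercept models
#'
#' All models are linear mixed models with a participant-level random
#' intercept, fitted by maximum likelihood, with Wald z statistics and
#' normal-based two-tailed p values. Factors use treatment contrasts with
#' `COMPUTER` and `BASELINE` as reference levels, so a `conditionSUSCEPTIBLE`
#' coefficient reads "Susceptible - Baseline" in the Computer group and
#' interaction terms read "Robot - Computer" differences of those effects.
#'
#' 1. influence ~ group * distance (decision trials of the baseline joint
#'    task; distance is the normalized response distance)
#' 2. rating_diff ~ partner_influence (one row per rating moment in the
#'    reciprocal task; rating_diff = self - other)
#' 3. estimation_error ~ group * condition (all estimates in Baseline /
#'    Susceptible / Unsusceptible conditions)
#' 4. norm_distance ~ group * condition (same trials as model 3)
#' 5. influence ~ group * condition (decision trials)
#' 6. influence ~ group * is_final (decision trials of the final block vs the
#'    preceding main block)
#'
#' @return Named list of specs (`response`, `fixed`, `formula`, `required`).
#' @export
model_specs <- function() {
  mk <- function(id, response, fixed, required) {
    list(model_id = id, response = response, fixed = fixed,
         formula = as.formula(paste(response, "~", fixed, "+ (1 | participant_id)")),
         required = c(required, "participant_id"))
  }
  list(
    "1" = mk(1L, "influence", "group * distance", c("influence", "group", "distance")),
    "2" = mk(2L, "rating_diff", "partner_influence", c("rating_diff", "partner_influence")),
    "3" = mk(3L, "estimation_error", "group * condition",
             c("estimation_error", "group", "condition")),
    "4" = mk(4L, "norm_distance", "group * condition",
             c("norm_distance", "group", "condition")),
    "5" = mk(5L, "influence", "group * condition",
             c("influence", "group", "condition")),
    "6" = mk(6L, "influence", "group * is_final",
             c("influence", "group", "is_final"))
  )
}

#' Fit a trial-level random-intercept linear model
#'
#' Fits one of the six [model_specs()] (or a custom spec of the same shape)
#' with `lme4::lmer`, maximum likelihood (`REML = FALSE`), and returns a tidy
#' coefficient table with Wald z statistics, normal-based two-tailed p values
#' and z-based effect sizes. Singular fits are reported through a warning and
#' the `"singular"` attribute, never silently.
#'
#' @param data Trial-level `data.frame` containing the spec's required
#'   columns; `group` and `condition` are coerced to factors with `COMPUTER` /
#'   `BASELINE` reference levels.
#' @param model_id Integer 1-6 selecting a spec from [model_specs()].
#' @param spec Alternatively, a spec list (overrides `model_id`).
#' @return `data.frame` with one row per fixed-effect term: `model_id`,
#'   `term`, `estimate`, `se`, `z`, `p`, `r`, `eta_sq`, `n`. Attributes:
#'   `"fit"` (the `lmerMod` object) and `"singular"`.
#' @export
fit_random_intercept_model <- function(data, model_id = 1L, spec = NULL) {
  if (is.null(spec)) {
    spec <- model_specs()[[as.character(as.integer(model_id))]]
    if (is.null(spec)) stop("model_id must be 1..6", call. = FALSE)
  }
  missing_cols <- setdiff(spec$required, names(data))
  if (length(missing_cols)) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$participant_id)) < 2) {
    stop("random-intercept model requires at least 2 participants", call. = FALSE)
  }
  if ("group" %in% spec$required) {
    data$group <- factor(data$group, levels = intersect(GROUPS, unique(data$group)))
  }
  if ("condition" %in% spec$required) {
    lev <- intersect(c("BASELINE", "SUSCEPTIBLE", "UNSUSCEPTIBLE"),
                     unique(data$condition))
    data$condition <- factor(data$condition, levels = lev)
  }
  fit <- lme4::lmer(spec$formula, data = data, REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-intercept fit (between-participant variance ",
            "estimated at 0); Wald statistics remain valid but the random ",
            "effect is degenerate")
  }
  ct <- coef(summary(fit))
  N <- stats::nobs(fit)
  z <- ct[, "t value"]
  out <- data.frame(
    model_id = spec$model_id %||% NA_integer_,
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    se = ct[, "Std. Error"],
    z = z,
    p = 2 * pnorm(-abs(z)),
    r = z / sqrt(N),
    eta_sq = z^2 / N,
    n = N,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "singular") <- singular
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald contrast between two fixed-effect coefficients
#'
#' Computes `plus - minus` (e.g. "Susceptible - Unsusceptible" from two
#' condition coefficients of the same fit) with its Wald z and two-tailed p.
#'
#' @param model_table Result of [fit_random_intercept_model()] (must carry
#'   the `"fit"` attribute).
#' @param plus,minus Coefficient names as in the table's `term` column.
#' @param name Label for the contrast row.
#' @return One-row `data.frame` in the same shape as the model table.
#' @export
fixed_contrast <- function(model_table, plus, minus, name = paste(plus, "-", minus)) {
  fit <- attr(model_table, "fit")
  if (is.null(fit)) stop("model_table must carry a 'fit' attribute", call. = FALSE)
  b <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  if (!all(c(plus, minus) %in% names(b))) {
    stop("coefficients not found in fit: ", plus, ", ", minus, call. = FALSE)
  }
  est <- b[[plus]] - b[[minus]]
  se <- sqrt(V[plus, plus] + V[minus, minus] - 2 * V[plus, minus])
  z <- est / se
  N <- stats::nobs(fit)
  data.frame(model_id = model_table$model_id[1], term = name, estimate = est,
             se = se, z = z, p = 2 * pnorm(-abs(z)), r = z / sqrt(N),
             eta_sq = z^2 / N, n = N, stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance decisions
#'
#' @param p_values Numeric vector of p values.
#' @param m Number of comparisons in the family (default: the number of p
#'   values supplied).
#' @param alpha Family-wise error level.
#' @return `data.frame` with `p`, `threshold` (`alpha / m`) and `significant`.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  .check_number(m, "m", lower = 1)
  data.frame(p = p_values, threshold = alpha / m,
             significant = p_values < alpha / m)
}
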