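# Independent brute-force oracles used to pin down the statistics module.
# These deliberately recompute everything from first principles (no shared
# code with the package implementation beyond base R).

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    Wk <- sum(r[bits])
    total <- total + 1L
    if (abs(Wk - mu) >= abs(W - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  combos <- utils::combn(N, n1)
  Wd <- apply(combos, 2, function(idx) sum(rk[idx]))
  mean(abs(Wd - mu) >= abs(W - mu) - 1e-9)
}

# exact two-sided Spearman p by enumerating all n! permutations
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- all_perms(length(x))
  rhos <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
  mean(abs(rhos) >= abs(rho) - 1e-9)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# small cached cohort shared by pipeline-level tests (simulated once per run)
small_log <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(default_config(n_per_group = 6, seed = 404))
    }
    cache
  }
})
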