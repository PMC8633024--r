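#' The 11-length stimulus grid
#'
#' Target lengths are drawn from a fixed grid of 11 distances between 8 and
#' 16 cm in steps of 0.8 cm. The design mean of the grid is exactly 12 cm,
#' which is also the mean of the stimulus distribution seen by an observer
#' over any balanced session.
#'
#' @return Numeric vector of 11 ascending lengths (cm).
#' @export
#' @examples
#' stimulus_grid()
stimulus_grid <- function() {
  seq(8, 16, by = 0.8)
}

#' Generate the stimulus sequence for a task
#'
#' Lengths are balanced: each of the 11 grid lengths appears exactly
#' `n_trials / 11` times, in an order shuffled by the current random stream
#' (or by `seed` if given). Balancing, rather than i.i.d. sampling, keeps the
#' session mean at exactly 12 cm and guarantees the repeated observations per
#' length that per-stimulus variability estimates require. The first disk's
#' horizontal offset is sampled uniformly in [0.6, 6.6] cm.
#'
#' @param n_trials Number of trials; must be a positive multiple of 11.
#' @param seed Optional integer seed; `NULL` (default) uses the current RNG
#'   stream so the generator can be embedded in a larger seeded simulation.
#' @return `data.frame` with columns `trial_index` (0-based), `s` (target
#'   length, cm) and `first_disk_offset` (cm from the left screen border).
#' @export
#' @examples
#' st <- generate_stimuli(66, seed = 1)
#' table(st$s)   # six repetitions of each of the 11 lengths
generate_stimuli <- function(n_trials, seed = NULL) {
  .check_number(n_trials, "n_trials", lower = 11)
  if (n_trials %% 11 != 0) {
    stop("n_trials must be a multiple of 11 (balanced design over the 11-length grid)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- n_trials / 11
  s <- sample(rep(stimulus_grid(), each = reps))
  off <- runif(n_trials, 0.6, 6.6)
  data.frame(
    trial_index = seq_len(n_trials) - 1L,
    s = s,
    first_disk_offset = off
  )
}
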