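#' Single-trait Wright-Fisher reference simulation
#'
#' The standard neutral baseline the linked model is compared against: a
#' population of `N` individuals carrying one trait with `k` variants. Each
#' timestep the population is multinomially resampled from its own variant
#' frequencies (synchronous offspring generation) and every individual then
#' innovates with probability `mu`, switching to one of the other `k - 1`
#' variants uniformly.
#'
#' @param N Population size.
#' @param mu Innovation probability per timestep.
#' @param k Number of variants.
#' @param steps Number of timesteps.
#' @param counts Optional starting counts (default uniform multinomial).
#' @return Integer vector of final variant counts (sums to `N`).
#' @examples
#' set.seed(1)
#' wf_replicate(100, 0.01, 4, steps = 200)
#' @export
wf_replicate <- function(N, mu, k, steps, counts = NULL) {
  if (is.null(counts)) {
    counts <- as.integer(rmultinom(1, N, rep(1 / k, k))[, 1])
  }
  stopifnot(length(counts) == k, sum(counts) == N)
  for (t in seq_len(steps)) {
    counts <- as.integer(rmultinom(1, N, counts / N)[, 1])
    if (mu > 0) {
      leaving <- rbinom(k, counts, mu)
      counts <- counts - leaving
      for (j in which(leaving > 0)) {
        dest <- rmultinom(1, leaving[j], rep(1 / (k - 1), k - 1))[, 1]
        counts[-j] <- counts[-j] + dest
      }
    }
  }
  counts
}

#' Wright-Fisher pairwise-difference sample
#'
#' Distribution of the final pairwise difference over independent
#' Wright-Fisher replicates; the reference sample for the overlap
#' (equifinality) analysis.
#'
#' @inheritParams wf_replicate
#' @param replicates Number of replicates.
#' @param seed_base Integer seed for the whole sample.
#' @return A tibble with columns `replicate`, `pi`.
#' @export
wf_pi_sample <- function(N, mu, k, steps, replicates = 100, seed_base = 1L) {
  set.seed(seed_base)
  seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  pis <- vapply(seq_len(replicates), function(i) {
    set.seed(seeds[i])
    pairwise_difference(wf_replicate(N, mu, k, steps))
  }, numeric(1))
  tibble::tibble(replicate = seq_len(replicates), pi = pis)
}
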