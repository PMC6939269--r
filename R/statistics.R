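#' Pairwise difference (heterogeneity) of a trait
#'
#' The probability that two individuals sampled without replacement carry
#' different variants: `1 - sum_j n_j (n_j - 1) / (N (N - 1))` for variant
#' counts `n_j` summing to `N`. Zero for a monomorphic population, maximal
#' when counts are as even as possible; closely related to the Simpson
#' diversity index.
#'
#' @param counts Non-negative integer vector of variant counts (one trait).
#' @return Pairwise difference in `[0, 1]`.
#' @examples
#' pairwise_difference(c(2, 2, 0, 0))  # 2/3
#' @export
pairwise_difference <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  N <- sum(counts)
  if (N < 2) abort("`counts` must sum to at least 2.")
  1 - sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Pairwise-difference trajectory of a replicate
#'
#' @param x A `cl_trajectory` from [run_replicate()].
#' @param traits Traits to include (default all).
#' @return A tibble with columns `t`, `trait`, `pi`.
#' @export
pi_trajectory <- function(x, traits = NULL) {
  stopifnot(inherits(x, "cl_trajectory"))
  h <- dim(x$counts)[1]
  Tn <- dim(x$counts)[3]
  if (is.null(traits)) traits <- seq_len(h)
  purrr::map_dfr(traits, function(i) {
    tibble::tibble(
      t = seq_len(Tn),
      trait = i,
      pi = vapply(seq_len(Tn),
                  function(tt) pairwise_difference(x$counts[i, , tt]),
                  numeric(1))
    )
  })
}

#' Wright-Fisher expectation for the pairwise difference
#'
#' Closed-form equilibrium expectation for a single trait with `k` variants
#' under multi-allele Wright-Fisher drift with innovation rate `mu`:
#' `2 N mu (k - 1) / (k - 1 + 2 N mu k)`.
#'
#' @param N Population size.
#' @param mu Innovation probability per timestep.
#' @param k Number of variants.
#' @return Expected pairwise difference.
#' @examples
#' wf_expectation(1000, 0.01, 4)  # 60/83
#' @export
wf_expectation <- function(N, mu, k) {
  stopifnot(N >= 2, k >= 2, mu >= 0, mu <= 1)
  if (mu == 0) {
    warn("mu = 0: drift-only limit, expected pairwise difference is 0.")
    return(0)
  }
  2 * N * mu * (k - 1) / (k - 1 + 2 * N * mu * k)
}

#' Scaled Wright-Fisher expectation for the fixed-package control
#'
#' In the fixed-package control, `n` of the `h` traits are offered per step
#' and each is copied with probability `c`, so a trait is successfully
#' transmitted on average every `h / (n c)` timesteps while innovation keeps
#' its per-step rate. The single-trait Wright-Fisher expectation therefore
#' applies with the innovation rate scaled by `h / (n c)`.
#'
#' @inheritParams wf_expectation
#' @param h Number of traits.
#' @param n Fixed package size in `1:h`.
#' @param c Copy success probability in `(0, 1]`.
#' @return Expected pairwise difference.
#' @export
scaled_wf_expectation <- function(N, mu, k, h, n, c) {
  stopifnot(h >= 1, c > 0, c <= 1)
  if (n < 1 || n > h) {
    abort("`n` must lie in 1:h (n = 0 has no transmission and no finite scaling).")
  }
  wf_expectation(N, mu * h / (n * c), k)
}

#' Mean link frequency of a population
#'
#' Per individual, the number of realized links divided by the `h(h-1)/2`
#' possible links, averaged over individuals. Defined as 0 when `h = 1`.
#'
#' @param x A `cl_population` or a `cl_trajectory` (final state).
#' @return Value in `[0, 1]`.
#' @export
link_frequency <- function(x) {
  if (inherits(x, "cl_trajectory")) x <- x$final
  stopifnot(inherits(x, "cl_population"))
  h <- ncol(x$variants)
  if (h == 1) return(0)
  N <- nrow(x$variants)
  sum(x$links) / 2 / (h * (h - 1) / 2) / N
}

#' Package-size variance of a population
#'
#' For every individual and every trait, the size of the trait's connected
#' component (its package) is computed; the variance of these `N * h` sizes
#' is returned. Zero when all graphs are empty (all singletons) or all
#' complete (all packages of size `h`); highest at intermediate link
#' frequencies, where large packages confer a transmission advantage.
#'
#' @param x A `cl_population` or a `cl_trajectory` (final state).
#' @return Sample variance of the package sizes.
#' @export
package_size_variance <- function(x) {
  if (inherits(x, "cl_trajectory")) x <- x$final
  stopifnot(inherits(x, "cl_population"))
  N <- nrow(x$variants); h <- ncol(x$variants)
  sizes <- cpp_component_sizes(x$links, N, h)
  var(as.numeric(sizes))
}

#' Area of overlap between two pairwise-difference distributions
#'
#' Estimates the densities of two samples on the common support `[0, 1]` and
#' integrates the pointwise minimum. The default estimator is a shared
#' equal-width histogram (100 bins), which is deterministic given the
#' samples; a kernel-density alternative is available. The overlap is 1 for
#' identical distributions and 0 for disjoint supports, and is symmetric in
#' its arguments — the package's measure of equifinality between
#' transmission processes.
#'
#' @param x,y Numeric vectors of pairwise differences in `[0, 1]`, or data
#'   frames with a `pi` column (as returned by [pi_sample()]).
#' @param method `"histogram"` (default) or `"density"`.
#' @param bins Number of equal-width histogram bins on `[0, 1]`.
#' @param n_grid Grid size for the kernel-density estimator.
#' @return An object of class `cl_overlap` with elements `overlap`, `method`,
#'   `bins`/`n_grid`, and the sample sizes.
#' @examples
#' set.seed(1)
#' a <- runif(500, 0, 0.5)
#' b <- runif(500, 0.25, 0.75)
#' area_of_overlap(a, b)$overlap  # about 0.5
#' @export
area_of_overlap <- function(x, y, method = c("histogram", "density"),
                            bins = 100, n_grid = 512) {
  method <- match.arg(method)
  get_vals <- function(v, nm) {
    if (is.data.frame(v)) v <- v$pi
    v <- as.numeric(v)
    if (length(v) == 0) abort(sprintf("`%s` must be a non-empty sample.", nm))
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      abort(sprintf("`%s` must contain values in [0, 1].", nm))
    }
    v
  }
  x <- get_vals(x, "x")
  y <- get_vals(y, "y")
  if (method == "histogram") {
    breaks <- seq(0, 1, length.out = bins + 1)
    bin_of <- function(v) pmin(pmax(ceiling(v * bins), 1L), bins)
    px <- tabulate(bin_of(x), bins) / length(x)
    py <- tabulate(bin_of(y), bins) / length(y)
    ov <- sum(pmin(px, py))
  } else {
    grid <- seq(0, 1, length.out = n_grid)
    dx <- density(x, from = 0, to = 1, n = n_grid)$y
    dy <- density(y, from = 0, to = 1, n = n_grid)$y
    step <- grid[2] - grid[1]
    # renormalize on the truncated support
    dx <- dx / (sum(dx) * step)
    dy <- dy / (sum(dy) * step)
    ov <- min(1, sum(pmin(dx, dy)) * step)
  }
  structure(list(overlap = ov, method = method,
                 bins = if (method == "histogram") bins else NULL,
                 n_grid = if (method == "density") n_grid else NULL,
                 n_x = length(x), n_y = length(y),
                 x = x, y = y),
            class = "cl_overlap")
}

#' @export
print.cl_overlap <- function(x, ...) {
  cat(sprintf("<cl_overlap> area of overlap = %.3f (%s%s; n = %d, %d)\n",
              x$overlap, x$method,
              if (!is.null(x$bins)) sprintf(", %d bins", x$bins) else "",
              x$n_x, x$n_y))
  invisible(x)
}

#' Detect the end of a cultural sweep
#'
#' Given the post-adjustment frequency trajectory of the highest pay-off
#' variant of the swept trait (element 1 is the adjustment point, frequency
#' `1/N`), returns the earliest timestep at which the frequency does not
#' increase. If the frequency increases strictly through the final step, the
#' final timestep is returned with `censored = TRUE`.
#'
#' @param freq Numeric vector of frequencies on the post-burn-in clock
#'   (`freq[1]` is time 0).
#' @return A list with `sweep_end` (timestep index on the post-burn-in
#'   clock, >= 1) and `censored`.
#' @examples
#' detect_sweep_end(c(0.001, 0.3, 0.8, 0.8, 0.7))  # sweep_end = 3
#' @export
detect_sweep_end <- function(freq) {
  freq <- as.numeric(freq)
  if (length(freq) < 2) abort("`freq` needs at least two points.")
  flat <- which(diff(freq) <= 0)
  if (length(flat) == 0) {
    list(sweep_end = length(freq) - 1L, censored = TRUE)
  } else {
    list(sweep_end = as.integer(flat[1]), censored = FALSE)
  }
}

#' Hitchhiking metrics for the associated variant
#'
#' Evaluates whether the associated variant (the trait-2 variant relabeled
#' `k` at the sweep adjustment) hitchhiked: whether its frequency at the end
#' of the trait-1 sweep exceeds the absolute majority (strictly above 0.5),
#' and for how many consecutive timesteps after the sweep end it stays above
#' 0.5 (censored if the run ends while still above).
#'
#' @param freq Numeric vector: frequency of the associated variant on the
#'   post-burn-in clock (`freq[1]` is time 0, aligned with
#'   [detect_sweep_end()]).
#' @param sweep_end Sweep end timestep from [detect_sweep_end()].
#' @return One-row tibble with `sweep_end`, `assoc_freq_at_end`,
#'   `majority_reached`, `majority_duration` (NA unless majority was
#'   reached) and `duration_censored`.
#' @examples
#' hitchhike_metrics(c(0.1, 0.4, 0.7, 0.6, 0.55, 0.5, 0.3), sweep_end = 2)
#' @export
hitchhike_metrics <- function(freq, sweep_end) {
  freq <- as.numeric(freq)
  if (sweep_end < 1 || sweep_end + 1 > length(freq)) {
    abort("`sweep_end` must index into `freq`.")
  }
  assoc <- freq[sweep_end + 1]
  majority <- assoc > 0.5
  duration <- NA_integer_
  dur_censored <- FALSE
  if (majority) {
    after <- freq[-seq_len(sweep_end + 1)]
    below <- which(after <= 0.5)
    if (length(below) == 0) {
      duration <- length(after)
      dur_censored <- TRUE
    } else {
      duration <- below[1] - 1L
    }
  }
  tibble::tibble(sweep_end = as.integer(sweep_end),
                 assoc_freq_at_end = assoc,
                 majority_reached = majority,
                 majority_duration = as.integer(duration),
                 duration_censored = dur_censored)
}

#' Sweep and hitchhiking metrics of a replicate
#'
#' Applies [detect_sweep_end()] to the trait-1 variant-1 frequency and
#' [hitchhike_metrics()] to the associated (trait-2, variant `k`) frequency
#' of a hitchhike-scenario trajectory, both on the post-burn-in clock.
#'
#' @param x A `cl_trajectory` from a hitchhike scenario.
#' @return One-row tibble with `sweep_end`, `sweep_censored`,
#'   `assoc_freq_at_end`, `majority_reached`, `majority_duration`,
#'   `duration_censored`.
#' @export
sweep_metrics <- function(x) {
  stopifnot(inherits(x, "cl_trajectory"))
  if (!x$scenario$scenario %in% c("hitchhike_neutral",
                                  "hitchhike_functional")) {
    abort("sweep metrics apply to hitchhike scenarios.")
  }
  N <- x$params$N
  rows <- x$burn_in:dim(x$counts)[3]
  f1 <- x$counts[1, 1, rows] / N
  f2 <- x$counts[2, x$params$k, rows] / N
  sw <- detect_sweep_end(f1)
  hm <- hitchhike_metrics(f2, sw$sweep_end)
  dplyr::bind_cols(tibble::tibble(sweep_censored = sw$censored), hm)[
    , c("sweep_end", "sweep_censored", "assoc_freq_at_end",
        "majority_reached", "majority_duration", "duration_censored")]
}

#' Aggregate hitchhiking metrics across replicates
#'
#' Summarizes a set of per-replicate sweep metrics: the proportion of runs
#' in which the associated variant reached absolute majority, the mean
#' frequency of the associated variant at the sweep end, and, over runs that
#' reached majority, the mean time the majority persisted (censored
#' durations enter as observed lower bounds, with the censored fraction
#' reported). Following the reporting convention for sparse events, the mean
#' duration is returned as `NA` when fewer than 5% of runs hitchhiked.
#'
#' @param metrics A data frame with the columns of [sweep_metrics()], one
#'   row per replicate (e.g. a hitchhike [run_grid()] result).
#' @return One-row tibble with `n`, `prop_majority`, `mean_assoc_freq`,
#'   `mean_majority_duration`, `censored_fraction`.
#' @export
summarize_hitchhiking <- function(metrics) {
  n <- nrow(metrics)
  prop <- mean(metrics$majority_reached)
  reached <- metrics[metrics$majority_reached, , drop = FALSE]
  mean_dur <- if (prop > 0.05) mean(reached$majority_duration) else NA_real_
  cens <- if (nrow(reached) > 0) mean(reached$duration_censored) else NA_real_
  tibble::tibble(n = n, prop_majority = prop,
                 mean_assoc_freq = mean(metrics$assoc_freq_at_end),
                 mean_majority_duration = mean_dur,
                 censored_fraction = cens)
}
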