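#' Simulation parameters
#'
#' Bundles every model constant and scenario switch for one simulation run
#' and validates the joint constraints.
#'
#' @param N Population size (>= 2). Individuals are never added or removed.
#' @param h Number of cultural traits per individual (>= 1).
#' @param k Number of variants per trait (>= 2). Variant 1 carries the highest
#'   pay-off, variant `k` the lowest.
#' @param s Numeric vector of per-trait selection strengths, recycled to
#'   length `h`; `s[i]` in `[0, 1]` is the maximum pay-off difference between
#'   variants of trait `i` (0 = neutral trait).
#' @param a Link association probability: each currently unlinked trait pair
#'   within an individual gains a link with this probability per timestep.
#' @param b Link breakage probability: an in-package link that only the
#'   demonstrator holds is acquired with probability `1 - b`.
#' @param c Per-variant copy success probability.
#' @param mu Per-trait innovation probability per timestep; an innovating
#'   trait switches to one of the other `k - 1` variants uniformly (pairwise
#'   transition rate `mu / (k - 1)`).
#' @param s_kappa Conformity strength in `[0, 1]` used by conformist-biased
#'   partner choice (weight `1 - s_kappa * (1 - q)` for a candidate whose
#'   variant has population frequency `q`; 0 = unbiased).
#' @param transmission_mode One of `"unbiased"`, `"payoff"`, `"conformist"`.
#'   Conformist mode requires `h = 1`.
#' @param burn_in_steps Timesteps of unbiased burn-in (default 5000).
#' @param post_steps Timesteps after the burn-in (default 2000).
#' @param break_shared_links Sensitivity variant of the link-transmission
#'   table: when `TRUE`, an in-package link held by both individuals is also
#'   subject to breakage (kept with probability `1 - b`) instead of always
#'   being kept. Default `FALSE` (the link-outcome table).
#' @param n_fixed Optional fixed package size in `0:h` for the control mode
#'   in which each focal copies `n_fixed` randomly chosen traits and link
#'   dynamics are disabled; `NULL` (default) uses link-based packages.
#' @param seed Optional integer RNG seed; when set, [run_replicate()] seeds
#'   the R RNG so the run is bitwise reproducible.
#' @param replicate_id Integer label carried through to outputs.
#'
#' @return An object of class `cl_params` (a validated named list).
#' @examples
#' p <- sim_params(N = 100, h = 5, k = 4, mu = 0.01, a = 0.01, b = 0.1)
#' p$s
#' @export
sim_params <- function(N = 1000, h = 5, k = 4, s = 0, a = 0, b = 0.1,
                       c = 0.99, mu = 0.01, s_kappa = 0.03,
                       transmission_mode = c("unbiased", "payoff",
                                             "conformist"),
                       burn_in_steps = 5000, post_steps = 2000,
                       break_shared_links = FALSE,
                       n_fixed = NULL, seed = NULL, replicate_id = 1L) {
  transmission_mode <- match.arg(transmission_mode)
  N <- as.integer(N); h <- as.integer(h); k <- as.integer(k)
  if (N < 2) abort("`N` must be at least 2.")
  if (h < 1) abort("`h` must be at least 1.")
  if (k < 2) abort("`k` must be at least 2.")
  s <- rep_len(as.numeric(s), h)
  if (any(s < 0 | s > 1)) abort("every `s[i]` must lie in [0, 1].")
  for (nm in c("a", "b", "c", "mu")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) ||
        val < 0 || val > 1) {
      abort(sprintf("`%s` must be a single probability in [0, 1].", nm))
    }
  }
  if (!is.numeric(s_kappa) || s_kappa < 0 || s_kappa > 1) {
    abort("`s_kappa` must lie in [0, 1].")
  }
  if (transmission_mode == "conformist" && h != 1) {
    abort("conformist-biased transmission is modelled for a single trait: set `h = 1`.")
  }
  if (!is.null(n_fixed)) {
    n_fixed <- as.integer(n_fixed)
    if (n_fixed < 0 || n_fixed > h) {
      abort("`n_fixed` must lie in 0:h.")
    }
  }
  burn_in_steps <- as.integer(burn_in_steps)
  post_steps <- as.integer(post_steps)
  if (burn_in_steps < 0 || post_steps < 0) {
    abort("step counts must be non-negative.")
  }
  if (!is.logical(break_shared_links) || length(break_shared_links) != 1 ||
      is.na(break_shared_links)) {
    abort("`break_shared_links` must be TRUE or FALSE.")
  }
  structure(
    list(N = N, h = h, k = k, s = s, a = a, b = b, c = c, mu = mu,
         s_kappa = s_kappa, transmission_mode = transmission_mode,
         burn_in_steps = burn_in_steps, post_steps = post_steps,
         break_shared_links = break_shared_links,
         n_fixed = n_fixed, seed = seed,
         replicate_id = as.integer(replicate_id)),
    class = "cl_params"
  )
}

#' @export
print.cl_params <- function(x, ...) {
  cat("<cl_params>\n")
  cat(sprintf("  N = %d, h = %d, k = %d\n", x$N, x$h, x$k))
  cat(sprintf("  s = (%s)\n", paste(format(x$s), collapse = ", ")))
  cat(sprintf("  a = %g, b = %g, c = %g, mu = %g, s_kappa = %g\n",
              x$a, x$b, x$c, x$mu, x$s_kappa))
  cat(sprintf("  mode = %s, burn-in = %d, post = %d%s\n",
              x$transmission_mode, x$burn_in_steps, x$post_steps,
              if (!is.null(x$n_fixed))
                sprintf(", fixed package n = %d", x$n_fixed) else ""))
  invisible(x)
}

#' Update simulation parameters
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A [sim_params()] object.
#' @param ... Named fields to replace.
#' @return A new `cl_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cl_params"))
  new <- utils::modifyList(params, list(...), keep.null = FALSE)
  dots <- list(...)
  if ("n_fixed" %in% names(dots) && is.null(dots$n_fixed)) new$n_fixed <- NULL
  if ("seed" %in% names(dots) && is.null(dots$seed)) new$seed <- NULL
  do.call(sim_params, new[c("N", "h", "k", "s", "a", "b", "c", "mu",
                            "s_kappa", "transmission_mode", "burn_in_steps",
                            "post_steps", "break_shared_links", "n_fixed",
                            "seed", "replicate_id")])
}
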