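#' Tidy a simulation trajectory
#'
#' @param x A `cl_trajectory` from [run_replicate()].
#' @param ... Unused.
#' @return A tibble with one row per timestep, trait and variant: columns
#'   `t`, `trait`, `variant`, `count`, `freq`.
#' @export
tidy.cl_trajectory <- function(x, ...) {
  dims <- dim(x$counts)
  h <- dims[1]; k <- dims[2]; Tn <- dims[3]
  out <- tidyr::expand_grid(t = seq_len(Tn), variant = seq_len(k),
                            trait = seq_len(h))
  out$count <- as.integer(x$counts[cbind(out$trait, out$variant, out$t)])
  out$freq <- out$count / x$params$N
  dplyr::arrange(out[, c("t", "trait", "variant", "count", "freq")],
                 .data$t, .data$trait, .data$variant)
}

#' One-row summary of a simulation trajectory
#'
#' @param x A `cl_trajectory`.
#' @param ... Unused.
#' @return A tibble with the scenario, run length, final pairwise difference
#'   per trait (`pi_1` ...), final mean link frequency and package-size
#'   variance, and sweep metrics for hitchhike scenarios.
#' @export
glance.cl_trajectory <- function(x, ...) {
  pis <- final_pi(x)
  out <- dplyr::bind_cols(
    tibble::tibble(scenario = x$scenario$scenario,
                   n_steps = dim(x$counts)[3],
                   burn_in = x$burn_in),
    tibble::as_tibble(setNames(as.list(pis), paste0("pi_", seq_along(pis)))),
    tibble::tibble(link_freq = link_frequency(x$final),
                   pkg_var = package_size_variance(x$final))
  )
  if (x$scenario$scenario %in% c("hitchhike_neutral", "hitchhike_functional")) {
    out <- dplyr::bind_cols(out, sweep_metrics(x))
  }
  out
}

#' Tidy an overlap result
#'
#' @param x A `cl_overlap` from [area_of_overlap()].
#' @param ... Unused.
#' @return A one-row tibble with `overlap`, `method`, `bins`, `n_x`, `n_y`.
#' @export
tidy.cl_overlap <- function(x, ...) {
  tibble::tibble(overlap = x$overlap, method = x$method,
                 bins = if (is.null(x$bins)) NA_integer_ else x$bins,
                 n_x = x$n_x, n_y = x$n_y)
}

#' Per-combination summary of a grid result
#'
#' @param x A `cl_grid` from [run_grid()].
#' @param ... Unused.
#' @return The [summarize_grid()] tibble.
#' @export
glance.cl_grid <- function(x, ...) summarize_grid(x)
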