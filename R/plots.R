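#' Plot variant frequency trajectories
#'
#' Frequency of every variant over time, one panel per trait; a dashed
#' vertical line marks the end of the burn-in (and sweep adjustment, where
#' applicable).
#'
#' @param object A `cl_trajectory` from [run_replicate()].
#' @param traits Traits to display (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cl_trajectory <- function(object, traits = NULL, ...) {
  df <- tidy(object)
  if (!is.null(traits)) df <- dplyr::filter(df, .data$trait %in% traits)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$freq,
                                         colour = factor(.data$variant))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "timestep", y = "variant frequency",
                  colour = "variant") +
    ggplot2::theme_minimal()
  if (object$burn_in > 0) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$burn_in,
                                   linetype = "dashed", colour = "grey40")
  }
  gg
}

#' Plot two pairwise-difference distributions and their overlap
#'
#' Shared-bin histograms of both samples; the overlapping mass (the area of
#' overlap statistic) is the region where the two histograms coincide.
#'
#' @param object A `cl_overlap` from [area_of_overlap()].
#' @param labels Length-2 character vector naming the two samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cl_overlap <- function(object, labels = c("x", "y"), ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(sample = labels[1], pi = object$x),
    tibble::tibble(sample = labels[2], pi = object$y)
  )
  bins <- if (is.null(object$bins)) 100 else object$bins
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi, fill = .data$sample)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            breaks = seq(0, 1, length.out = bins + 1),
                            alpha = 0.5, position = "identity") +
    ggplot2::labs(
      x = "pairwise difference",
      y = "density",
      title = sprintf("area of overlap = %.2f", object$overlap)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean pairwise difference across a parameter grid
#'
#' Mean final pairwise difference of trait 1 (with 5-95% quantile ribbons)
#' against the first grid parameter, coloured by the second when present. A
#' horizontal reference line marks the Wright-Fisher expectation for the
#' base parameters.
#'
#' @param object A `cl_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cl_grid <- function(object, ...) {
  sm <- summarize_grid(object)
  grid_cols <- names(attr(object, "grid"))
  p <- attr(object, "params")
  xvar <- grid_cols[1]
  gg <- ggplot2::ggplot(sm, ggplot2::aes(x = .data[[xvar]],
                                         y = .data$mean_pi_1))
  if (length(grid_cols) >= 2) {
    gg <- gg + ggplot2::aes(colour = factor(.data[[grid_cols[2]]])) +
      ggplot2::labs(colour = grid_cols[2])
  }
  gg +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q05_pi_1,
                                          ymax = .data$q95_pi_1)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = wf_expectation(p$N, p$mu, p$k),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = xvar, y = "mean final pairwise difference (trait 1)") +
    ggplot2::theme_minimal()
}
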