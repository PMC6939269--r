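#' Scenario specification
#'
#' The study designs supported by [run_replicate()]:
#' * `"neutral"`: every trait neutral, unbiased transmission throughout.
#' * `"hitchhike_neutral"`: trait 1 functional (`s1 = 0.9`), trait 2 neutral
#'   (`s2 = 0`); unbiased burn-in, then the sweep adjustment and
#'   pay-off-biased transmission.
#' * `"hitchhike_functional"`: as above but trait 2 is also functional
#'   (`s2 > 0`, default 0.2), so the associated variant is detrimental.
#' * `"payoff"`: pay-off-biased equilibrium run (unbiased burn-in, then
#'   pay-off-biased transmission with `s1` on trait 1, no sweep adjustment).
#' * `"conformist"`: single-trait conformist-biased transmission for the
#'   whole run (no burn-in phase).
#' * `"fixed_package"`: unbiased transmission with the fixed-package-size
#'   control (`params$n_fixed` traits copied per step, link dynamics off).
#'
#' @param scenario Scenario name (see above).
#' @param s1,s2 Selection strengths applied to traits 1 and 2 (defaults per
#'   scenario).
#' @param post_mode Transmission mode after the burn-in; defaults to the
#'   scenario's canonical mode. The burn-in itself is always unbiased.
#' @return An object of class `cl_scenario`.
#' @export
scenario_spec <- function(scenario = c("neutral", "hitchhike_neutral",
                                       "hitchhike_functional", "payoff",
                                       "conformist", "fixed_package"),
                          s1 = NULL, s2 = NULL, post_mode = NULL) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    neutral = list(s1 = 0, s2 = 0, post_mode = "unbiased"),
    hitchhike_neutral = list(s1 = 0.9, s2 = 0, post_mode = "payoff"),
    hitchhike_functional = list(s1 = 0.9, s2 = 0.2, post_mode = "payoff"),
    payoff = list(s1 = 0.07, s2 = 0, post_mode = "payoff"),
    conformist = list(s1 = 0, s2 = 0, post_mode = "conformist"),
    fixed_package = list(s1 = 0, s2 = 0, post_mode = "unbiased"))
  s1 <- if (is.null(s1)) defaults$s1 else s1
  s2 <- if (is.null(s2)) defaults$s2 else s2
  post_mode <- if (is.null(post_mode)) defaults$post_mode else post_mode
  post_mode <- match.arg(post_mode, c("unbiased", "payoff", "conformist"))
  if (scenario == "neutral" && (s1 != 0 || s2 != 0)) {
    abort("the neutral scenario requires s1 = s2 = 0.")
  }
  if (scenario %in% c("hitchhike_neutral", "hitchhike_functional") &&
      post_mode != "payoff") {
    abort("hitchhike scenarios use pay-off-biased transmission after burn-in.")
  }
  structure(list(scenario = scenario, s1 = s1, s2 = s2,
                 post_mode = post_mode),
            class = "cl_scenario")
}

as_scenario <- function(scenario) {
  if (inherits(scenario, "cl_scenario")) return(scenario)
  scenario_spec(scenario)
}

#' Sweep adjustment at the end of the burn-in
#'
#' Sets up the hitchhiking experiment: at trait 1, one uniformly chosen
#' innovator receives the highest pay-off variant 1 while the remaining
#' `N - 1` individuals receive the lowest pay-off variant `k`. At trait 2,
#' the innovator is given the rarest variant in the population (ties broken
#' by lowest label) and trait-2 variant labels are then permuted so that this
#' "associated variant" becomes variant `k` (rarest and lowest pay-off); the
#' remaining labels `1:(k-1)` are assigned in decreasing order of frequency.
#' Link graphs are untouched. This is the most challenging (conservative)
#' starting condition for a hitchhiking trait.
#'
#' @param pop A `cl_population` with `h >= 2`.
#' @param params A [sim_params()] object.
#' @param scenario Optional scenario (name or [scenario_spec()]); supplying a
#'   non-hitchhike scenario is an error.
#' @return A list with elements `pop` (adjusted population), `innovator`
#'   (individual index) and `relabel` (the trait-2 label permutation,
#'   `relabel[old] = new`).
#' @export
apply_sweep_adjustment <- function(pop, params, scenario = NULL) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  if (!is.null(scenario)) {
    sc <- as_scenario(scenario)
    if (!sc$scenario %in% c("hitchhike_neutral", "hitchhike_functional")) {
      abort("the sweep adjustment applies only to hitchhike scenarios.")
    }
  }
  if (ncol(pop$variants) < 2) {
    abort("the sweep adjustment requires at least two traits.")
  }
  N <- nrow(pop$variants)
  k <- params$k
  innovator <- sample.int(N, 1)
  pop$variants[, 1] <- k
  pop$variants[innovator, 1] <- 1L

  # associated variant: rarest trait-2 variant, ties to the lowest label
  cnt <- tabulate(pop$variants[, 2], k)
  rarest <- which.min(cnt)
  pop$variants[innovator, 2] <- as.integer(rarest)
  cnt_post <- tabulate(pop$variants[, 2], k)
  others <- setdiff(seq_len(k), rarest)
  others <- others[order(-cnt_post[others], others)]
  relabel <- integer(k)
  relabel[rarest] <- k
  relabel[others] <- seq_len(k - 1)
  pop$variants[, 2] <- relabel[pop$variants[, 2]]
  validate_population(pop)
  list(pop = pop, innovator = innovator, relabel = relabel)
}

#' Run one complete replicate
#'
#' Initializes a population, runs the unbiased burn-in, applies any
#' scenario-specific adjustment, runs the post phase under the scenario's
#' transmission mode, and records per-timestep variant counts (and link
#' summaries). Trajectory rows are the states after steps `1:(burn_in +
#' post)`; in hitchhike scenarios the row at `t = burn_in` reflects the
#' post-adjustment state, which is also the time origin of the sweep clock.
#' The conformist scenario runs `burn_in_steps + post_steps` timesteps under
#' conformist bias with no burn-in phase.
#'
#' If `params$seed` is set the R RNG is seeded first, making the run bitwise
#' reproducible.
#'
#' @param params A [sim_params()] object.
#' @param scenario Scenario name or [scenario_spec()] object. The scenario's
#'   `s1`/`s2` override `params$s[1:2]`.
#' @param record_links Record the population mean link frequency each step?
#' @param record_pkg_var Record the package-size variance each step (adds
#'   noticeable cost)?
#' @return An object of class `cl_trajectory`: a list with the `h x k x T`
#'   count array `counts`, optional `link_freq` / `pkg_var` step series,
#'   `burn_in` (row index of the sweep clock origin), `innovator`, `relabel`,
#'   the final `cl_population`, and the `params`/`scenario` used.
#' @examples
#' p <- sim_params(N = 50, h = 2, k = 4, mu = 0.01, a = 0.05, b = 0.1,
#'                 burn_in_steps = 50, post_steps = 20, seed = 1)
#' tr <- run_replicate(p, "neutral")
#' dim(tr$counts)
#' @export
run_replicate <- function(params, scenario = "neutral", record_links = TRUE,
                          record_pkg_var = FALSE) {
  stopifnot(inherits(params, "cl_params"))
  sc <- as_scenario(scenario)
  if (sc$scenario == "conformist" && params$h != 1) {
    abort("the conformist scenario requires h = 1.")
  }
  if (sc$scenario == "fixed_package" && is.null(params$n_fixed)) {
    abort("the fixed_package scenario requires `params$n_fixed`.")
  }
  if (sc$scenario %in% c("hitchhike_neutral", "hitchhike_functional") &&
      params$burn_in_steps < 1) {
    abort("hitchhike scenarios need `burn_in_steps >= 1` so the adjusted state anchors the sweep clock.")
  }
  if (params$h >= 1) params$s[1] <- sc$s1
  if (params$h >= 2) params$s[2] <- sc$s2
  if (!is.null(params$seed)) set.seed(params$seed)

  pop <- initialize_population(params)
  n_fixed <- if (is.null(params$n_fixed)) -1L else params$n_fixed
  total <- params$burn_in_steps + params$post_steps
  innovator <- NA_integer_
  relabel <- NULL

  run_phase <- function(pop, steps, mode) {
    cpp_run(pop$variants, pop$links, steps, params$k, params$s, params$a,
            params$b, params$c, params$mu, params$s_kappa, .mode_code(mode),
            n_fixed, record_links, record_pkg_var,
            isTRUE(params$break_shared_links))
  }

  if (sc$scenario == "conformist") {
    res <- run_phase(pop, total, "conformist")
    counts <- res$counts
    link_freq <- if (record_links) res$link_freq else NULL
    pkg_var <- if (record_pkg_var) res$pkg_var else NULL
    burn_in <- 0L
    final <- new_population(res$variants, res$links, k = params$k, t = total)
  } else if (sc$scenario %in% c("hitchhike_neutral", "hitchhike_functional")) {
    res1 <- run_phase(pop, params$burn_in_steps, "unbiased")
    mid <- new_population(res1$variants, res1$links, k = params$k,
                          t = params$burn_in_steps)
    adj <- apply_sweep_adjustment(mid, params, sc)
    innovator <- adj$innovator
    relabel <- adj$relabel
    # the recorded state at t = burn_in is the post-adjustment state
    if (params$burn_in_steps > 0) {
      res1$counts[, , params$burn_in_steps] <-
        t(vapply(seq_len(params$h),
                 function(i) tabulate(adj$pop$variants[, i], params$k),
                 integer(params$k)))
    }
    res2 <- run_phase(adj$pop, params$post_steps, sc$post_mode)
    counts <- array(c(res1$counts, res2$counts),
                    dim = c(params$h, params$k, total))
    link_freq <- if (record_links) c(res1$link_freq, res2$link_freq) else NULL
    pkg_var <- if (record_pkg_var) c(res1$pkg_var, res2$pkg_var) else NULL
    burn_in <- params$burn_in_steps
    final <- new_population(res2$variants, res2$links, k = params$k, t = total)
  } else {
    # neutral / fixed_package: unbiased burn-in, then the scenario's post mode
    res1 <- run_phase(pop, params$burn_in_steps, "unbiased")
    mid <- new_population(res1$variants, res1$links, k = params$k,
                          t = params$burn_in_steps)
    res2 <- run_phase(mid, params$post_steps, sc$post_mode)
    counts <- array(c(res1$counts, res2$counts),
                    dim = c(params$h, params$k, total))
    link_freq <- if (record_links) c(res1$link_freq, res2$link_freq) else NULL
    pkg_var <- if (record_pkg_var) c(res1$pkg_var, res2$pkg_var) else NULL
    burn_in <- params$burn_in_steps
    final <- new_population(res2$variants, res2$links, k = params$k, t = total)
  }

  structure(list(counts = counts, link_freq = link_freq, pkg_var = pkg_var,
                 burn_in = burn_in, innovator = innovator, relabel = relabel,
                 final = final, params = params, scenario = sc),
            class = "cl_trajectory")
}

#' @export
print.cl_trajectory <- function(x, ...) {
  Tn <- dim(x$counts)[3]
  cat(sprintf("<cl_trajectory> scenario = %s, %d timesteps (burn-in %d)\n",
              x$scenario$scenario, Tn, x$burn_in))
  pis <- final_pi(x)
  cat("  final pairwise difference per trait:",
      paste(sprintf("%.3f", pis), collapse = ", "), "\n")
  invisible(x)
}

#' Final pairwise difference per trait of a trajectory
#'
#' @param x A `cl_trajectory`.
#' @return Numeric vector of length `h`.
#' @export
final_pi <- function(x) {
  stopifnot(inherits(x, "cl_trajectory"))
  Tn <- dim(x$counts)[3]
  apply(x$counts[, , Tn, drop = FALSE], 1, pairwise_difference)
}

#' Run a parameter grid of replicates
#'
#' Expands the Cartesian product of `grid` values, runs `replicates`
#' independently seeded replicates per combination, and returns one summary
#' row per run. Every run is reconstructible from its recorded seed (the
#' seeds are drawn once from `seed_base`).
#'
#' @param base_params A [sim_params()] object supplying all fixed values.
#' @param grid Named list of parameter values to cross, e.g.
#'   `list(a = c(0, 0.01), b = c(0.1, 0.4))`. Names must be `sim_params()`
#'   fields.
#' @param scenario Scenario name or [scenario_spec()].
#' @param replicates Number of replicates per combination.
#' @param seed_base Integer seed for the whole grid.
#' @param record_pkg_var Also record per-step package-size variance?
#' @return A tibble of class `cl_grid`: one row per run with the grid
#'   columns, `replicate`, `seed`, final pairwise difference per trait
#'   (`pi_1` ... `pi_h`), final `link_freq` and `pkg_var`, and sweep metrics
#'   (`sweep_end`, `assoc_freq_at_end`, `majority_reached`,
#'   `majority_duration`, `censored`) for hitchhike scenarios.
#' @examples
#' p <- sim_params(N = 30, h = 2, k = 4, mu = 0.02, burn_in_steps = 30,
#'                 post_steps = 10)
#' g <- run_grid(p, list(a = c(0, 0.1)), replicates = 2, seed_base = 1)
#' g
#' @export
run_grid <- function(base_params, grid, scenario = "neutral", replicates = 10,
                     seed_base = 1L, record_pkg_var = FALSE) {
  stopifnot(inherits(base_params, "cl_params"))
  sc <- as_scenario(scenario)
  if (length(grid) > 0) {
    nm <- names(grid)
    if (is.null(nm) || any(nm == "")) abort("`grid` must be a named list.")
    if (anyDuplicated(nm)) abort("duplicate grid keys.")
    bad <- setdiff(nm, setdiff(names(base_params), c("seed", "replicate_id")))
    if (length(bad)) {
      abort(paste0("unknown grid parameter(s): ", paste(bad, collapse = ", ")))
    }
    combos <- do.call(tidyr::expand_grid, grid)
  } else {
    combos <- tibble::tibble(.rows = 1)
  }
  # validate every combination before any run starts
  param_list <- if (ncol(combos) == 0) {
    list(base_params)
  } else {
    purrr::pmap(combos, function(...) update_params(base_params, ...))
  }

  n_runs <- nrow(combos) * replicates
  set.seed(seed_base)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  rows <- purrr::map(seq_len(n_runs), function(run) {
    ci <- (run - 1L) %/% replicates + 1L
    rep_j <- (run - 1L) %% replicates + 1L
    p <- param_list[[ci]]
    p$seed <- seeds[run]
    p$replicate_id <- rep_j
    # per-run summaries only need the final state, so skip per-step link
    # recording (link_frequency below reads the final population)
    tr <- run_replicate(p, sc, record_links = FALSE,
                        record_pkg_var = record_pkg_var)
    pis <- final_pi(tr)
    out <- dplyr::bind_cols(
      combos[ci, , drop = FALSE],
      tibble::tibble(replicate = rep_j, seed = seeds[run]),
      tibble::as_tibble(setNames(as.list(pis), paste0("pi_", seq_along(pis)))),
      tibble::tibble(link_freq = link_frequency(tr$final),
                     pkg_var = package_size_variance(tr$final))
    )
    if (sc$scenario %in% c("hitchhike_neutral", "hitchhike_functional")) {
      out <- dplyr::bind_cols(out, sweep_metrics(tr))
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "params") <- base_params
  attr(res, "scenario") <- sc
  attr(res, "grid") <- grid
  attr(res, "seed_base") <- seed_base
  class(res) <- c("cl_grid", class(res))
  res
}

#' Per-combination summary of a grid run
#'
#' Groups a [run_grid()] result by its grid columns and reports, per
#' combination, the mean and 5%/95% quantiles of the final pairwise
#' difference of trait 1, the mean link frequency and package-size variance,
#' and (for hitchhike scenarios) the proportion of runs in which the
#' associated variant reached absolute majority and the mean time that
#' majority persisted.
#'
#' @param x A `cl_grid` tibble.
#' @return A tibble with one row per parameter combination.
#' @export
summarize_grid <- function(x) {
  stopifnot(inherits(x, "cl_grid"))
  grid_cols <- names(attr(x, "grid"))
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grid_cols))) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_pi_1 = mean(.data$pi_1),
      q05_pi_1 = stats::quantile(.data$pi_1, 0.05),
      q95_pi_1 = stats::quantile(.data$pi_1, 0.95),
      mean_link_freq = mean(.data$link_freq),
      mean_pkg_var = mean(.data$pkg_var),
      .groups = "drop"
    )
  if ("majority_reached" %in% names(x)) {
    hh <- x |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grid_cols))) |>
      dplyr::summarize(
        prop_majority = mean(.data$majority_reached),
        mean_assoc_freq = mean(.data$assoc_freq_at_end),
        mean_majority_duration =
          mean(.data$majority_duration[.data$majority_reached]),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, hh, by = grid_cols)
  }
  out
}

#' Distribution of final pairwise differences across replicates
#'
#' Runs `replicates` independently seeded replicates and records, for one
#' trait, the pairwise difference either at the end of the run or at the end
#' of the cultural sweep (hitchhike scenarios). This is the ingredient of the
#' distribution-overlap (equifinality) analysis.
#'
#' @param params A [sim_params()] object.
#' @param scenario Scenario name or [scenario_spec()].
#' @param replicates Number of replicates.
#' @param trait Trait whose pairwise difference is recorded.
#' @param at `"end"` (final timestep) or `"sweep_end"` (the timestep at which
#'   the trait-1 sweep ends; hitchhike scenarios only).
#' @param seed_base Integer seed for the whole sample.
#' @return A tibble with columns `replicate`, `seed`, `pi` (and `sweep_end`,
#'   `censored` when `at = "sweep_end"`).
#' @export
pi_sample <- function(params, scenario = "neutral", replicates = 100,
                      trait = 1, at = c("end", "sweep_end"), seed_base = 1L) {
  stopifnot(inherits(params, "cl_params"))
  at <- match.arg(at)
  sc <- as_scenario(scenario)
  hitch <- sc$scenario %in% c("hitchhike_neutral", "hitchhike_functional")
  if (at == "sweep_end" && !hitch) {
    abort("`at = \"sweep_end\"` requires a hitchhike scenario.")
  }
  set.seed(seed_base)
  seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  rows <- purrr::map(seq_len(replicates), function(i) {
    p <- params
    p$seed <- seeds[i]
    p$replicate_id <- i
    tr <- run_replicate(p, sc, record_links = FALSE)
    if (at == "end") {
      Tn <- dim(tr$counts)[3]
      tibble::tibble(replicate = i, seed = seeds[i],
                     pi = pairwise_difference(tr$counts[trait, , Tn]))
    } else {
      sw <- sweep_metrics(tr)
      row <- tr$burn_in + sw$sweep_end
      tibble::tibble(replicate = i, seed = seeds[i],
                     pi = pairwise_difference(tr$counts[trait, , row]),
                     sweep_end = sw$sweep_end, censored = sw$sweep_censored)
    }
  })
  dplyr::bind_rows(rows)
}
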