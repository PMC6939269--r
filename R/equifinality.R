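#' Equifinality analysis: overlap of diversity distributions across processes
#'
#' Reproduces the package's headline equifinality comparison. Six pairs of
#' final pairwise-difference distributions are generated and their areas of
#' overlap computed:
#'
#' 1. linked unbiased (`a`, `b`) vs unlinked unbiased (`a = 0`);
#' 2. linked unbiased vs the single-trait Wright-Fisher model;
#' 3. linked unbiased vs unlinked pay-off-biased (`s1_weak`);
#' 4. linked unbiased vs conformist-biased (`s_kappa_weak`);
#' 5. the neutral associated trait at the end of a cultural sweep (linked
#'    pay-off scenario) vs unlinked pay-off-biased (`s1_strong`);
#' 6. the same sweep-end distribution vs conformist-biased
#'    (`s_kappa_strong`).
#'
#' High overlap means the two transmission processes are hard to distinguish
#' from trait-frequency data (equifinality); low overlap means links leave a
#' distinctive signature.
#'
#' @param replicates Replicates per condition (distribution sample size).
#' @param seed_base Integer seed; condition seeds are derived from it.
#' @param N,h,k,mu,c Shared model parameters.
#' @param a,b Link dynamics of the linked conditions.
#' @param s1_weak,s1_strong Pay-off strengths of the two unlinked
#'   pay-off-biased reference conditions.
#' @param s_kappa_weak,s_kappa_strong Conformity strengths of the two
#'   conformist reference conditions.
#' @param burn_in_steps,post_steps Run lengths (equilibrium horizon is their
#'   sum); `sweep_post_steps` is the post-adjustment horizon of the sweep
#'   condition (the sweep itself ends after a few dozen timesteps).
#' @param sweep_post_steps Post-burn-in steps of the hitchhike condition.
#' @param method,bins Density estimator passed to [area_of_overlap()]. The
#'   default kernel estimator is preferred here because a few hundred
#'   replicates spread over 100 histogram bins underestimate the overlap.
#' @param progress Print per-condition progress to `stderr()`?
#' @param keep_samples Attach the per-condition pairwise-difference samples
#'   as an attribute `samples`?
#' @return A tibble with one row per comparison: `comparison`, `overlap`,
#'   `n` (replicates per sample), plus the two sample means.
#' @export
equifinality_overlaps <- function(replicates = 200, seed_base = 1L,
                                  N = 1000, h = 5, k = 4, mu = 0.01,
                                  c = 0.99, a = 0.01, b = 0.1,
                                  s1_weak = 0.07, s1_strong = 0.24,
                                  s_kappa_weak = 0.03,
                                  s_kappa_strong = 0.048,
                                  burn_in_steps = 5000, post_steps = 2000,
                                  sweep_post_steps = 300,
                                  method = c("density", "histogram"),
                                  bins = 100, progress = FALSE,
                                  keep_samples = FALSE) {
  method <- match.arg(method)
  base <- sim_params(N = N, h = h, k = k, mu = mu, c = c, b = b,
                     burn_in_steps = burn_in_steps, post_steps = post_steps)
  note <- function(msg) if (progress) message(msg)
  seeds <- seed_base + 1000L * (1:8)

  note("linked unbiased ...")
  linked <- pi_sample(update_params(base, a = a), "neutral",
                      replicates, seed_base = seeds[1])$pi
  note("unlinked unbiased ...")
  unlinked <- pi_sample(update_params(base, a = 0), "neutral",
                        replicates, seed_base = seeds[2])$pi
  note("Wright-Fisher ...")
  wf <- wf_pi_sample(N, mu, k, burn_in_steps + post_steps,
                     replicates, seed_base = seeds[3])$pi
  note("pay-off-biased (weak) ...")
  pay_weak <- pi_sample(update_params(base, a = 0),
                        scenario_spec("payoff", s1 = s1_weak),
                        replicates, seed_base = seeds[4])$pi
  note("pay-off-biased (strong) ...")
  pay_strong <- pi_sample(update_params(base, a = 0),
                          scenario_spec("payoff", s1 = s1_strong),
                          replicates, seed_base = seeds[5])$pi
  conf_base <- sim_params(N = N, h = 1, k = k, mu = mu, c = c,
                          transmission_mode = "conformist",
                          burn_in_steps = burn_in_steps,
                          post_steps = post_steps)
  note("conformist (weak) ...")
  conf_weak <- pi_sample(update_params(conf_base, s_kappa = s_kappa_weak),
                         "conformist", replicates, seed_base = seeds[6])$pi
  note("conformist (strong) ...")
  conf_strong <- pi_sample(update_params(conf_base,
                                         s_kappa = s_kappa_strong),
                           "conformist", replicates, seed_base = seeds[7])$pi
  note("hitchhike sweep-end ...")
  sweep <- pi_sample(update_params(base, a = a,
                                   post_steps = sweep_post_steps),
                     "hitchhike_neutral", replicates, trait = 2,
                     at = "sweep_end", seed_base = seeds[8])$pi

  pair <- function(comparison, x, y) {
    tibble::tibble(comparison = comparison,
                   overlap = area_of_overlap(x, y, method = method,
                                             bins = bins)$overlap,
                   n = replicates, mean_x = mean(x), mean_y = mean(y))
  }
  out <- dplyr::bind_rows(
    pair("linked_vs_unlinked", linked, unlinked),
    pair("linked_vs_wright_fisher", linked, wf),
    pair("linked_vs_payoff", linked, pay_weak),
    pair("linked_vs_conformist", linked, conf_weak),
    pair("sweep_assoc_vs_payoff", sweep, pay_strong),
    pair("sweep_assoc_vs_conformist", sweep, conf_strong)
  )
  if (keep_samples) {
    attr(out, "samples") <- list(
      linked = linked, unlinked = unlinked, wright_fisher = wf,
      payoff_weak = pay_weak, payoff_strong = pay_strong,
      conformist_weak = conf_weak, conformist_strong = conf_strong,
      sweep_assoc = sweep)
  }
  out
}
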