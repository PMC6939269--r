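#' Package of a trait under a link graph
#'
#' The package transmitted with a chosen trait is the connected component of
#' that trait in the demonstrator's link graph; an unlinked trait forms a
#' singleton package.
#'
#' @param trait Trait index in `1:h`.
#' @param links Symmetric `h x h` logical adjacency matrix (one individual's
#'   link graph).
#' @return Sorted integer vector of trait indices, always containing `trait`.
#' @examples
#' L <- matrix(FALSE, 3, 3)
#' L[1, 2] <- L[2, 1] <- L[2, 3] <- L[3, 2] <- TRUE
#' package_of(1, L)
#' @export
package_of <- function(trait, links) {
  links <- as.matrix(links)
  h <- nrow(links)
  if (length(trait) != 1 || trait < 1 || trait > h) {
    abort("`trait` must be a single index in 1:h.")
  }
  if (!isTRUE(all(links == t(links)))) {
    abort("`links` must be symmetric.")
  }
  as.integer(cpp_package_of(as.integer(trait), links))
}

#' Copy package variants from a demonstrator
#'
#' For each trait in `package` independently, the focal individual adopts the
#' partner's variant with probability `c` and otherwise keeps its own; traits
#' outside the package are untouched. Copying is blind to pay-offs.
#'
#' @param focal,partner Integer vectors of length `h` (variant assignments).
#' @param package Integer vector of trait indices (the transmitted package).
#' @param c Per-variant copy success probability.
#' @return Updated focal variant vector.
#' @export
transmit_variants <- function(focal, partner, package, c) {
  stopifnot(length(focal) == length(partner))
  as.integer(cpp_transmit_variants(as.integer(focal), as.integer(partner),
                                   as.integer(package), c))
}

#' Transmit, break and prune links during package copying
#'
#' Applies the link outcome table for one transmission event. For a trait
#' pair with both endpoints inside the package: a link both individuals hold
#' is kept; a link only the partner holds is acquired with probability
#' `1 - b`; a link only the focal holds is broken. Every focal link joining a
#' package trait to a non-package trait is lost. Links entirely outside the
#' package are untouched. The result is symmetric.
#'
#' @param focal_links,partner_links Symmetric `h x h` logical matrices.
#' @param package Integer vector of trait indices (from the partner's graph).
#' @param b Link breakage probability.
#' @param break_shared Apply breakage to links both individuals hold
#'   (sensitivity variant; default `FALSE`, the table above).
#' @return Updated focal adjacency matrix.
#' @export
transmit_links <- function(focal_links, partner_links, package, b,
                           break_shared = FALSE) {
  focal_links <- as.matrix(focal_links)
  partner_links <- as.matrix(partner_links)
  stopifnot(identical(dim(focal_links), dim(partner_links)))
  out <- cpp_transmit_links(focal_links, partner_links,
                            as.integer(package), b, break_shared)
  dimnames(out) <- dimnames(focal_links)
  out
}

#' Random link formation
#'
#' After transmission, every currently unlinked trait pair of every
#' individual independently gains a link with probability `a` (the rate of
#' association).
#'
#' @param pop A `cl_population`.
#' @param params A [sim_params()] object (uses `a`).
#' @return The population with newly formed links.
#' @export
form_links <- function(pop, params) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  N <- nrow(pop$variants); h <- ncol(pop$variants)
  pop$links <- cpp_form_links(pop$links, N, h, params$a)
  pop
}

#' Random innovation
#'
#' Each individual-trait cell independently innovates with probability `mu`;
#' an innovating trait switches to one of the other `k - 1` variants chosen
#' uniformly (it never retains its current variant), giving a pairwise
#' transition rate of `mu / (k - 1)`. Links are unaffected.
#'
#' @param pop A `cl_population`.
#' @param params A [sim_params()] object (uses `mu`, `k`).
#' @return The population with innovated variants.
#' @export
innovate <- function(pop, params) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  pop$variants <- cpp_innovate(pop$variants, params$k, params$mu)
  pop
}

#' Advance the population one timestep
#'
#' Executes one synchronous timestep: (1) all individuals choose an
#' interaction partner from the start-of-step state; (2) each focal picks one
#' of its `h` traits uniformly at random, builds the package from the
#' partner's start-of-step link graph, copies package variants (probability
#' `c` each) and updates its links per the transmission table; (3) new links
#' form at rate `a`; (4) innovation at rate `mu`. All reads use the
#' start-of-step snapshot, so an individual's influence on others within the
#' step depends only on its state when the step began.
#'
#' When `params$n_fixed` is set, stages (1)-(2) are replaced by the
#' fixed-package-size control (each focal copies `n_fixed` randomly chosen
#' distinct traits) and the link stages are skipped.
#'
#' @param pop A `cl_population`.
#' @param params A [sim_params()] object.
#' @return The next population state (`t` incremented).
#' @examples
#' p <- sim_params(N = 10, h = 3, k = 4, a = 0.2, mu = 0.01)
#' pop <- initialize_population(p)
#' set.seed(1)
#' pop2 <- step_population(pop, p)
#' pop2$t
#' @export
step_population <- function(pop, params) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  mode <- params$transmission_mode
  if (mode == "conformist" && ncol(pop$variants) != 1) {
    abort("conformist-biased transmission requires h = 1.")
  }
  n_fixed <- if (is.null(params$n_fixed)) -1L else params$n_fixed
  out <- cpp_step(pop$variants, pop$links, params$k, params$s, params$a,
                  params$b, params$c, params$mu, params$s_kappa,
                  .mode_code(mode), n_fixed,
                  isTRUE(params$break_shared_links))
  if (isTRUE(out$degenerate)) {
    warn("all candidate weights were zero in at least one step; partners drawn unbiased.")
  }
  new_population(out$variants, out$links, k = params$k, t = pop$t + 1L)
}

#' @describeIn step_population Fixed-package-size control step: requires
#'   `params$n_fixed` to be set; equivalent to `step_population` in that mode.
#' @export
fixed_package_step <- function(pop, params) {
  if (is.null(params$n_fixed)) {
    abort("`params$n_fixed` must be set for the fixed-package control mode.")
  }
  step_population(pop, params)
}
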