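#' Construct a population state
#'
#' A population state holds the `N x h` matrix of variant assignments
#' (integers in `1:k`) and, per individual, a symmetric irreflexive adjacency
#' matrix over trait pairs (stored as an `h x h x N` logical array).
#'
#' @param variants Integer matrix `N x h` with entries in `1:k`.
#' @param links Logical array `h x h x N`; defaults to no links.
#' @param k Number of variants per trait (used for validation).
#' @param t Current timestep counter.
#' @return An object of class `cl_population`.
#' @export
new_population <- function(variants, links = NULL, k = max(variants), t = 0L) {
  variants <- as.matrix(variants)
  storage.mode(variants) <- "integer"
  N <- nrow(variants); h <- ncol(variants)
  if (is.null(links)) {
    links <- array(FALSE, dim = c(h, h, N))
  }
  if (!is.array(links) || !identical(dim(links), c(h, h, N))) {
    abort("`links` must be a logical array with dim c(h, h, N).")
  }
  storage.mode(links) <- "logical"
  pop <- structure(list(variants = variants, links = links, t = as.integer(t),
                        k = as.integer(k)),
                   class = "cl_population")
  validate_population(pop)
  pop
}

#' @rdname new_population
#' @param pop A `cl_population` object.
#' @export
validate_population <- function(pop) {
  v <- pop$variants
  if (any(v < 1L) || any(v > pop$k)) {
    abort("all variant entries must lie in 1:k.")
  }
  h <- ncol(v)
  for (r in seq_len(dim(pop$links)[3])) {
    L <- pop$links[, , r]
    if (h == 1) next
    if (any(diag(L))) abort("link graphs must have no self-links.")
    if (!isTRUE(all(L == t(L)))) abort("link graphs must be symmetric.")
  }
  invisible(pop)
}

#' @export
print.cl_population <- function(x, ...) {
  cat(sprintf("<cl_population> N = %d, h = %d, k = %d, t = %d\n",
              nrow(x$variants), ncol(x$variants), x$k, x$t))
  cat(sprintf("  mean link frequency: %.4f\n", link_frequency(x)))
  invisible(x)
}

#' Initialize a population
#'
#' Each individual receives an independent uniform variant at every trait and
#' carries no links; the timestep counter starts at zero.
#'
#' @param params A [sim_params()] object.
#' @return A `cl_population`.
#' @examples
#' p <- sim_params(N = 20, h = 3, k = 4)
#' pop <- initialize_population(p)
#' table(pop$variants[, 1])
#' @export
initialize_population <- function(params) {
  stopifnot(inherits(params, "cl_params"))
  v <- matrix(sample.int(params$k, params$N * params$h, replace = TRUE),
              nrow = params$N, ncol = params$h)
  new_population(v, k = params$k, t = 0L)
}

#' Variant pay-off
#'
#' Pay-off of variant `j` at trait `i`: `1 - ((j - 1) / (k - 1)) * s_i`.
#' Variant 1 always has pay-off 1; variant `k` has pay-off `1 - s_i`; a
#' neutral trait (`s_i = 0`) gives every variant pay-off 1.
#'
#' @param params A [sim_params()] object.
#' @param trait Trait index in `1:h`.
#' @param variant Variant index (vectorized) in `1:k`.
#' @return Numeric vector of pay-offs in `(0, 1]`.
#' @examples
#' p <- sim_params(N = 10, h = 1, k = 4, s = 0.9)
#' variant_payoff(p, 1, 1:4)
#' @export
variant_payoff <- function(params, trait, variant) {
  stopifnot(inherits(params, "cl_params"))
  if (length(trait) != 1 || trait < 1 || trait > params$h) {
    abort("`trait` must be a single index in 1:h.")
  }
  if (any(variant < 1 | variant > params$k)) {
    abort("`variant` must lie in 1:k.")
  }
  1 - ((variant - 1) / (params$k - 1)) * params$s[trait]
}

#' Individual pay-off
#'
#' The pay-off of an individual is the product over traits of the pay-offs of
#' the variants it carries.
#'
#' @param pop A `cl_population`.
#' @param params A [sim_params()] object.
#' @param individuals Optional integer vector of individuals (default all).
#' @return Numeric vector of pay-offs.
#' @export
individual_payoff <- function(pop, params, individuals = NULL) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  v <- pop$variants
  if (is.null(individuals)) individuals <- seq_len(nrow(v))
  if (any(individuals < 1 | individuals > nrow(v))) {
    abort("`individuals` out of range.")
  }
  f <- rep(1, length(individuals))
  for (i in seq_len(ncol(v))) {
    if (params$s[i] != 0) {
      f <- f * (1 - ((v[individuals, i] - 1) / (params$k - 1)) * params$s[i])
    }
  }
  f
}

#' Partner-choice probabilities
#'
#' Row `r` gives focal individual `r`'s probability of choosing each candidate
#' as interaction partner (self excluded, each row sums to 1):
#' * unbiased: `1 / (N - 1)` for every non-self candidate;
#' * payoff: proportional to the candidate's total pay-off;
#' * conformist: proportional to `1 - s_kappa * (1 - q)` where `q` is the
#'   population frequency of the candidate's variant (single-trait model);
#'   `s_kappa = 0` recovers unbiased choice and the weight rises with the
#'   variant's frequency, disproportionately favouring common variants.
#'
#' If every candidate weight is zero (degenerate conformist or pay-off edge
#' case) the row falls back to unbiased weights with a warning.
#'
#' @param pop A `cl_population`.
#' @param params A [sim_params()] object; `transmission_mode` selects the bias.
#' @return An `N x N` row-stochastic matrix with a zero diagonal.
#' @examples
#' p <- sim_params(N = 4, h = 1, k = 2, transmission_mode = "conformist",
#'                 s_kappa = 0.03)
#' pop <- new_population(matrix(c(1L, 1L, 1L, 2L), ncol = 1), k = 2)
#' partner_probabilities(pop, p)
#' @export
partner_probabilities <- function(pop, params) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  N <- nrow(pop$variants)
  mode <- params$transmission_mode
  if (mode == "conformist" && ncol(pop$variants) != 1) {
    abort("conformist-biased transmission requires h = 1.")
  }
  w <- switch(mode,
    unbiased = rep(1, N),
    payoff = individual_payoff(pop, params),
    conformist = {
      q <- tabulate(pop$variants[, 1], params$k)[pop$variants[, 1]] / N
      1 - params$s_kappa * (1 - q)
    })
  if (!all(is.finite(w)) || sum(w) <= 0) {
    warn("all candidate weights are zero or non-finite; falling back to unbiased weights.")
    w <- rep(1, N)
  }
  P <- matrix(rep(w, each = N), nrow = N)
  diag(P) <- 0
  P / rowSums(P)
}

#' Choose interaction partners
#'
#' All individuals simultaneously draw an interaction partner (never
#' themselves) from their [partner_probabilities()] distribution; several
#' focal individuals may choose the same partner. Uses the current R RNG
#' stream.
#'
#' @inheritParams partner_probabilities
#' @return Integer vector of length `N`; entry `r` is individual `r`'s partner.
#' @export
choose_partners <- function(pop, params) {
  stopifnot(inherits(pop, "cl_population"), inherits(params, "cl_params"))
  mode <- params$transmission_mode
  if (mode == "conformist" && ncol(pop$variants) != 1) {
    abort("conformist-biased transmission requires h = 1.")
  }
  out <- cpp_choose_partners(pop$variants, params$k, params$s,
                             params$s_kappa, .mode_code(mode))
  if (isTRUE(attr(out, "degenerate"))) {
    warn("all candidate weights were zero; partners drawn unbiased.")
  }
  as.integer(out)
}
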