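#' Deterministic two-individual transmission fixture
#'
#' A fully specified focal/partner configuration that exercises every row of
#' the link transmission outcome table in a single call to
#' [transmit_links()]: the chosen trait (1) belongs to the partner's
#' three-trait package `{1, 2, 3}`; link (1,2) is shared (kept), link (2,3)
#' is partner-only (acquired with probability `1 - b`), link (1,3) is
#' focal-only (broken), link (3,4) crosses the package boundary (removed)
#' and link (4,5) lies fully outside (untouched).
#'
#' @return A list with `focal_variants`, `focal_links`, `partner_variants`,
#'   `partner_links`, `chosen_trait`, the expected `package`, and a matching
#'   [sim_params()] object.
#' @examples
#' fx <- fig_fixture()
#' package_of(fx$chosen_trait, fx$partner_links)
#' @export
fig_fixture <- function() {
  h <- 5
  mk <- function(pairs) {
    L <- matrix(FALSE, h, h)
    for (p in pairs) L[p[1], p[2]] <- L[p[2], p[1]] <- TRUE
    L
  }
  list(
    focal_variants = c(1L, 1L, 1L, 1L, 1L),
    focal_links = mk(list(c(1, 2), c(1, 3), c(3, 4), c(4, 5))),
    partner_variants = c(2L, 3L, 4L, 1L, 2L),
    partner_links = mk(list(c(1, 2), c(2, 3))),
    chosen_trait = 1L,
    package = c(1L, 2L, 3L),
    params = sim_params(N = 2, h = h, k = 4, mu = 0, a = 0, b = 0.1)
  )
}

#' Brute-force pairwise difference
#'
#' Independent oracle for [pairwise_difference()]: enumerates all unordered
#' pairs of individuals and returns the fraction that differ at the trait.
#'
#' @param x A `cl_population`, or an integer vector of per-individual
#'   variants.
#' @param trait Trait index (when `x` is a population).
#' @return Fraction of differing pairs, in `[0, 1]`.
#' @export
brute_force_pairwise <- function(x, trait = 1) {
  v <- if (inherits(x, "cl_population")) x$variants[, trait] else as.integer(x)
  N <- length(v)
  stopifnot(N >= 2)
  diff_mat <- outer(v, v, "!=")
  sum(diff_mat[upper.tri(diff_mat)]) / choose(N, 2)
}

#' Exact Markov oracle for the two-individual chain
#'
#' For `N = 2`, `h <= 2`, `k = 2` the full state space of the model is small
#' enough to enumerate, and one timestep's transition probabilities can be
#' computed exactly by summing over every possible RNG outcome (partner
#' choice is forced, then trait choice, per-trait copy successes,
#' link-acquisition draws, link formation and innovation). The returned
#' transition matrix is the exact distribution that [step_population()]
#' samples from.
#'
#' @param params A [sim_params()] object with `N = 2`, `h <= 2`, `k = 2`.
#' @return A list with:
#' * `states`: tibble of all states (`v11`, ..., plus `l1`, `l2` when
#'   `h = 2`);
#' * `P`: the exact one-step transition matrix (rows = from-state);
#' * `encode(pop)`: state index of a `cl_population`;
#' * `decode(idx)`: the corresponding `cl_population`;
#' * `distribution_after(n, init)`: exact distribution after `n` steps from
#'   an initial distribution or state index.
#' @examples
#' p <- sim_params(N = 2, h = 1, k = 2, c = 1, mu = 0, burn_in_steps = 0)
#' orc <- two_individual_markov_oracle(p)
#' dim(orc$P)
#' @export
two_individual_markov_oracle <- function(params) {
  stopifnot(inherits(params, "cl_params"))
  if (params$N != 2 || params$h > 2 || params$k != 2) {
    abort("the exact oracle requires N = 2, h <= 2, k = 2.")
  }
  h <- params$h
  cc <- params$c; b <- params$b; a <- params$a; mu <- params$mu
  b_shared <- isTRUE(params$break_shared_links)
  nbits <- 2 * h + if (h == 2) 2 else 0
  S <- 2^nbits

  bits_of <- function(idx) as.integer(intToBits(idx - 1))[seq_len(nbits)]
  idx_of <- function(bits) as.integer(sum(bits * 2^(seq_along(bits) - 1))) + 1L

  # bit layout: variants v[r, i] - 1 at position (r - 1) * h + i; links l[r]
  # (h = 2 only) at positions 2 * h + r
  decode <- function(idx) {
    bt <- bits_of(idx)
    v <- matrix(bt[seq_len(2 * h)] + 1L, nrow = 2, ncol = h, byrow = TRUE)
    links <- array(FALSE, dim = c(h, h, 2))
    if (h == 2) {
      for (r in 1:2) {
        if (bt[2 * h + r] == 1) links[1, 2, r] <- links[2, 1, r] <- TRUE
      }
    }
    new_population(v, links, k = 2L, t = 0L)
  }
  encode <- function(pop) {
    v <- pop$variants
    bt <- integer(nbits)
    for (r in 1:2) for (i in seq_len(h)) bt[(r - 1) * h + i] <- v[r, i] - 1L
    if (h == 2) for (r in 1:2) bt[2 * h + r] <- as.integer(pop$links[1, 2, r])
    idx_of(bt)
  }

  # outcome distribution of one focal's transmission stage, given snapshots
  focal_dist <- function(fv, fl, pv, pl) {
    out <- list()
    for (t in seq_len(h)) {
      pkg <- if (h == 2 && pl == 1) 1:2 else t
      copy_masks <- expand.grid(rep(list(c(TRUE, FALSE)), length(pkg)))
      for (m in seq_len(nrow(copy_masks))) {
        mask <- as.logical(copy_masks[m, ])
        pm <- prod(ifelse(mask, cc, 1 - cc)) / h
        if (pm == 0) next
        v_new <- fv
        v_new[pkg[mask]] <- pv[pkg[mask]]
        if (h == 2 && length(pkg) == 2 && pl == 1 &&
            (fl == 0 || (b_shared && fl == 1))) {
          if (1 - b > 0) {
            out[[length(out) + 1]] <- list(v = v_new, l = 1L,
                                           p = pm * (1 - b))
          }
          if (b > 0) {
            out[[length(out) + 1]] <- list(v = v_new, l = 0L, p = pm * b)
          }
        } else {
          # shared link kept; singleton package breaks a boundary link;
          # otherwise no link to hold
          l_new <- if (h == 2 && length(pkg) == 2 && pl == 1 && fl == 1)
            1L else 0L
          out[[length(out) + 1]] <- list(v = v_new, l = l_new, p = pm)
        }
      }
    }
    out
  }

  bern <- function(p1, v1 = 1L, v0 = 0L) {
    out <- list()
    if (p1 > 0) out[[length(out) + 1]] <- list(val = v1, p = p1)
    if (p1 < 1) out[[length(out) + 1]] <- list(val = v0, p = 1 - p1)
    out
  }

  step_dist <- function(idx) {
    bt <- bits_of(idx)
    v <- matrix(bt[seq_len(2 * h)] + 1L, nrow = 2, ncol = h, byrow = TRUE)
    l <- if (h == 2) bt[2 * h + 1:2] else c(0L, 0L)
    outA <- focal_dist(v[1, ], l[1], v[2, ], l[2])
    outB <- focal_dist(v[2, ], l[2], v[1, ], l[1])
    dist <- numeric(S)
    for (oa in outA) for (ob in outB) {
      p0 <- oa$p * ob$p
      # link formation per individual on currently unlinked pairs
      formA <- if (h == 2 && oa$l == 0) bern(a) else list(list(val = oa$l, p = 1))
      formB <- if (h == 2 && ob$l == 0) bern(a) else list(list(val = ob$l, p = 1))
      for (fa in formA) for (fb in formB) {
        p1 <- p0 * fa$p * fb$p
        # innovation: each of the 2h variant cells flips w.p. mu (k = 2)
        flip_masks <- expand.grid(rep(list(c(TRUE, FALSE)), 2 * h))
        for (fm in seq_len(nrow(flip_masks))) {
          mask <- as.logical(flip_masks[fm, ])
          p2 <- p1 * prod(ifelse(mask, mu, 1 - mu))
          if (p2 == 0) next
          vA <- oa$v; vB <- ob$v
          cells <- c(vA, vB)  # order: A traits 1..h, B traits 1..h
          cells[mask] <- 3L - cells[mask]
          btn <- integer(nbits)
          for (i in seq_len(h)) btn[i] <- cells[i] - 1L
          for (i in seq_len(h)) btn[h + i] <- cells[h + i] - 1L
          if (h == 2) {
            btn[2 * h + 1] <- fa$val
            btn[2 * h + 2] <- fb$val
          }
          j <- idx_of(btn)
          dist[j] <- dist[j] + p2
        }
      }
    }
    dist
  }

  P <- t(vapply(seq_len(S), step_dist, numeric(S)))
  states <- purrr::map_dfr(seq_len(S), function(i) {
    pop <- decode(i)
    row <- setNames(as.list(as.vector(t(pop$variants))),
                    paste0("v", rep(1:2, each = h), rep(seq_len(h), 2)))
    if (h == 2) {
      row$l1 <- as.integer(pop$links[1, 2, 1])
      row$l2 <- as.integer(pop$links[1, 2, 2])
    }
    tibble::as_tibble(row)
  })
  distribution_after <- function(n, init) {
    d <- if (length(init) == 1) {
      z <- numeric(S); z[init] <- 1; z
    } else init
    for (i in seq_len(n)) d <- as.numeric(d %*% P)
    d
  }
  list(states = states, P = P, encode = encode, decode = decode,
       distribution_after = distribution_after)
}
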