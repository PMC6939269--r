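# small deterministic populations and statistical test helpers

make_pop <- function(variants, link_pairs = NULL, k = max(variants)) {
  variants <- as.matrix(variants)
  h <- ncol(variants)
  N <- nrow(variants)
  links <- array(FALSE, dim = c(h, h, N))
  for (p in link_pairs %||% list()) {
    links[p[2], p[3], p[1]] <- links[p[3], p[2], p[1]] <- TRUE
  }
  new_population(variants, links, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_linked_pop <- function(N, h, k, p_link) {
  v <- matrix(sample.int(k, N * h, replace = TRUE), N, h)
  links <- array(FALSE, dim = c(h, h, N))
  for (r in seq_len(N)) {
    for (x in seq_len(h - 1)) {
      for (y in seq(x + 1, h)) {
        if (runif(1) < p_link) links[x, y, r] <- links[y, x, r] <- TRUE
      }
    }
  }
  new_population(v, links, k = k)
}

# chi-square goodness of fit of observed category indices against exact
# probabilities, pooling low-expectation categories
expect_gof <- function(obs_idx, probs, p_min = 1e-6) {
  n <- length(obs_idx)
  counts <- tabulate(obs_idx, length(probs))
  expected <- probs * n
  keep <- expected >= 5
  o <- c(counts[keep], sum(counts[!keep]))
  e <- c(expected[keep], sum(expected[!keep]))
  use <- e > 0
  stat <- sum((o[use] - e[use])^2 / e[use])
  df <- max(1L, sum(use) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  expect_gt(p, p_min)
}
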