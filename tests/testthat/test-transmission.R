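test_that("a package is the connected component of the chosen trait", {
  L0 <- matrix(FALSE, 3, 3)
  expect_identical(package_of(2, L0), 2L)

  L <- matrix(FALSE, 3, 3)
  L[1, 2] <- L[2, 1] <- L[2, 3] <- L[3, 2] <- TRUE
  expect_identical(package_of(1, L), c(1L, 2L, 3L))

  L5 <- matrix(FALSE, 5, 5)
  L5[1, 2] <- L5[2, 1] <- L5[4, 5] <- L5[5, 4] <- TRUE
  expect_identical(package_of(4, L5), c(4L, 5L))
  expect_identical(package_of(3, L5), 3L)

  expect_error(package_of(0, L5), "trait")
  L5[1, 3] <- TRUE  # asymmetric
  expect_error(package_of(1, L5), "symmetric")
})

test_that("packages agree with igraph connected components", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (i in 1:20) {
    h <- sample(4:8, 1)
    L <- matrix(FALSE, h, h)
    for (x in seq_len(h - 1)) {
      for (y in seq(x + 1, h)) {
        if (runif(1) < 0.3) L[x, y] <- L[y, x] <- TRUE
      }
    }
    g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected")
    comp <- igraph::components(g)$membership
    t0 <- sample.int(h, 1)
    expect_identical(package_of(t0, L),
                     as.integer(which(comp == comp[t0])))
  }
})

test_that("variant copying is certain at c = 1, absent at c = 0, Bernoulli(c) otherwise", {
  focal <- c(1L, 1L, 1L, 1L, 1L)
  partner <- c(2L, 3L, 4L, 1L, 2L)
  set.seed(3)
  expect_identical(transmit_variants(focal, partner, 1:3, c = 1),
                   c(2L, 3L, 4L, 1L, 1L))
  expect_identical(transmit_variants(focal, partner, 1:5, c = 0), focal)

  n <- 5000
  adopted <- replicate(n, transmit_variants(1L, 2L, 1L, c = 0.7) == 2L)
  phat <- mean(adopted)
  expect_lt(abs(phat - 0.7), 4 * sqrt(0.7 * 0.3 / n))
})

test_that("the link outcome table is honoured row by row", {
  fx <- fig_fixture()
  expect_identical(package_of(fx$chosen_trait, fx$partner_links), fx$package)

  # b = 0: in-package links equal the partner's; boundary link gone;
  # outside link untouched
  out0 <- transmit_links(fx$focal_links, fx$partner_links, fx$package, b = 0)
  expect_identical(out0[1:3, 1:3], fx$partner_links[1:3, 1:3])
  expect_false(out0[3, 4])
  expect_true(out0[4, 5])
  expect_identical(out0, t(out0))

  # b = 1: shared link kept, focal-only broken, partner-only not acquired
  set.seed(5)
  out1 <- transmit_links(fx$focal_links, fx$partner_links, fx$package, b = 1)
  expect_true(out1[1, 2])    # shared within package
  expect_false(out1[1, 3])   # focal-only within package
  expect_false(out1[2, 3])   # partner-only, acquisition prob 1 - b = 0
  expect_false(out1[3, 4])   # boundary-crossing
  expect_true(out1[4, 5])    # fully outside

  # shared in-package link survives any b
  for (b in c(0, 0.3, 0.7, 1)) {
    expect_true(transmit_links(fx$focal_links, fx$partner_links,
                               fx$package, b = b)[1, 2])
  }

  # acquisition frequency of the partner-only link is 1 - b
  n <- 4000
  acq <- replicate(n, transmit_links(fx$focal_links, fx$partner_links,
                                     fx$package, b = 0.3)[2, 3])
  expect_lt(abs(mean(acq) - 0.7), 4 * sqrt(0.7 * 0.3 / n))
})

test_that("the shared-link breakage sensitivity variant breaks shared links at rate b", {
  fx <- fig_fixture()
  # default: shared in-package link immune to b
  expect_true(transmit_links(fx$focal_links, fx$partner_links,
                             fx$package, b = 1)[1, 2])
  # variant: shared link subject to the same breakage probability
  expect_false(transmit_links(fx$focal_links, fx$partner_links,
                              fx$package, b = 1, break_shared = TRUE)[1, 2])
  expect_true(transmit_links(fx$focal_links, fx$partner_links,
                             fx$package, b = 0, break_shared = TRUE)[1, 2])
  set.seed(17)
  n <- 3000
  kept <- replicate(n, transmit_links(fx$focal_links, fx$partner_links,
                                      fx$package, b = 0.3,
                                      break_shared = TRUE)[1, 2])
  expect_lt(abs(mean(kept) - 0.7), 4 * sqrt(0.7 * 0.3 / n))

  # the exact two-individual chain under the variant still matches simulation
  pm <- sim_params(N = 2, h = 2, k = 2, c = 0.8, mu = 0.05, a = 0.2, b = 0.4,
                   break_shared_links = TRUE)
  orc <- two_individual_markov_oracle(pm)
  pop0 <- make_pop(rbind(c(1L, 2L), c(2L, 1L)), list(c(1, 1, 2), c(2, 1, 2)),
                   k = 2)
  exact <- orc$P[orc$encode(pop0), ]
  set.seed(18)
  idx <- vapply(seq_len(2000), function(i) {
    orc$encode(step_population(pop0, pm))
  }, integer(1))
  expect_gof(idx, exact)
})

test_that("package-boundary, subset and symmetry laws hold on random graphs", {
  set.seed(11)
  h <- 6
  rand_links <- function(p) {
    L <- matrix(FALSE, h, h)
    for (x in seq_len(h - 1)) {
      for (y in seq(x + 1, h)) {
        if (runif(1) < p) L[x, y] <- L[y, x] <- TRUE
      }
    }
    L
  }
  for (i in 1:40) {
    fl <- rand_links(0.4)
    pl <- rand_links(0.4)
    pkg <- package_of(sample.int(h, 1), pl)
    b <- sample(c(0, 0.5), 1)
    out <- transmit_links(fl, pl, pkg, b = b)
    expect_identical(out, t(out))
    expect_false(any(diag(out)))
    inpkg <- seq_len(h) %in% pkg
    expect_false(any(out[inpkg, !inpkg]))  # boundary law
    if (b == 0) {
      expect_identical(out[inpkg, inpkg], pl[inpkg, inpkg])  # subset law
    }
  }
})

test_that("link formation is Bernoulli(a) per unlinked pair", {
  p0 <- sim_params(N = 20, h = 5, k = 2, a = 0)
  pop <- make_pop(matrix(1L, 20, 5), list(c(1, 1, 2)), k = 2)
  set.seed(2)
  expect_identical(form_links(pop, p0)$links, pop$links)

  p1 <- sim_params(N = 20, h = 5, k = 2, a = 1)
  full <- form_links(pop, p1)
  expect_true(all(vapply(1:20, function(r) {
    L <- full$links[, , r]
    all(L[upper.tri(L)])
  }, logical(1))))

  # mean new links per individual ~ 10 * a
  pa <- sim_params(N = 2000, h = 5, k = 2, a = 0.05)
  pop2 <- make_pop(matrix(1L, 2000, 5), k = 2)
  set.seed(8)
  grown <- form_links(pop2, pa)
  n_new <- sum(grown$links) / 2
  expect_lt(abs(n_new / 2000 - 0.5),
            4 * sqrt(20000 * 0.05 * 0.95) / 2000)
})

test_that("innovation switches uniformly among the other variants", {
  p0 <- sim_params(N = 50, h = 2, k = 4, mu = 0)
  pop <- make_pop(matrix(2L, 50, 2), k = 4)
  set.seed(4)
  expect_identical(innovate(pop, p0)$variants, pop$variants)

  pflip <- sim_params(N = 50, h = 2, k = 2, mu = 1)
  pop2 <- make_pop(matrix(rep(c(1L, 2L), 50), 50, 2), k = 2)
  expect_identical(innovate(pop2, pflip)$variants, 3L - pop2$variants)

  # per-pair transition rate mu / (k - 1); never retains the current variant
  pmu <- sim_params(N = 3000, h = 4, k = 4, mu = 0.3)
  pop3 <- make_pop(matrix(2L, 3000, 4), k = 4)
  set.seed(6)
  out <- innovate(pop3, pmu)$variants
  n_cells <- 3000 * 4
  for (target in c(1L, 3L, 4L)) {
    phat <- mean(out == target)
    expect_lt(abs(phat - 0.1), 4 * sqrt(0.1 * 0.9 / n_cells))
  }
  expect_lt(abs(mean(out == 2L) - 0.7), 4 * sqrt(0.7 * 0.3 / n_cells))
})

test_that("stepping preserves the state invariants", {
  set.seed(12)
  p <- sim_params(N = 40, h = 4, k = 3, a = 0.1, b = 0.2, c = 0.9, mu = 0.05)
  pop <- initialize_population(p)
  for (i in 1:5) {
    pop <- step_population(pop, p)
    expect_silent(validate_population(pop))  # symmetry, domain closure
    expect_identical(pop$t, i)
  }

  # without link formation a linkless population stays linkless
  p0 <- sim_params(N = 40, h = 4, k = 3, a = 0, b = 0.2, c = 0.9, mu = 0.05)
  pop0 <- initialize_population(p0)
  for (i in 1:10) pop0 <- step_population(pop0, p0)
  expect_equal(sum(pop0$links), 0)
})

test_that("a fixed seed reproduces a step and a run bitwise", {
  p <- sim_params(N = 30, h = 3, k = 4, a = 0.1, b = 0.2, c = 0.9, mu = 0.02)
  pop <- {
    set.seed(9)
    initialize_population(p)
  }
  set.seed(10)
  s1 <- step_population(pop, p)
  set.seed(10)
  s2 <- step_population(pop, p)
  expect_identical(s1, s2)
})

test_that("fixed-package control copies exactly n random traits", {
  # n = 0: no transmission; with mu = 0 the state is frozen
  p0 <- sim_params(N = 20, h = 5, k = 4, mu = 0, n_fixed = 0)
  pop <- make_pop(matrix(sample.int(4, 100, TRUE), 20, 5), k = 4)
  set.seed(13)
  expect_identical(fixed_package_step(pop, p0)$variants, pop$variants)

  # n = h, c = 1: every focal becomes a copy of its partner's snapshot
  ph <- sim_params(N = 2, h = 5, k = 4, mu = 0, c = 1, n_fixed = 5)
  pop2 <- make_pop(rbind(c(1, 2, 3, 4, 1), c(4, 3, 2, 1, 4)), k = 4)
  nxt <- fixed_package_step(pop2, ph)
  expect_identical(nxt$variants[1, ], pop2$variants[2, ])
  expect_identical(nxt$variants[2, ], pop2$variants[1, ])

  expect_error(fixed_package_step(pop2, sim_params(N = 2, h = 5, k = 4)),
               "n_fixed")
})

test_that("n_fixed = 1 matches the linkless model in distribution", {
  set.seed(14)
  p1 <- sim_params(N = 60, h = 3, k = 3, mu = 0.02, c = 0.9, a = 0,
                   burn_in_steps = 150, post_steps = 0)
  pfix <- update_params(p1, n_fixed = 1)
  pis_a0 <- pi_sample(p1, "neutral", replicates = 50, seed_base = 31)$pi
  pis_n1 <- pi_sample(pfix, "fixed_package", replicates = 50,
                      seed_base = 32)$pi
  se <- sqrt(var(pis_a0) / 50 + var(pis_n1) / 50)
  expect_lt(abs(mean(pis_a0) - mean(pis_n1)), 4 * se)
})
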