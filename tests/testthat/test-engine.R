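test_that("initialization is uniform, linkless and reproducible", {
  p <- sim_params(N = 4000, h = 2, k = 4)
  set.seed(20)
  pop <- initialize_population(p)
  expect_equal(sum(pop$links), 0)
  expect_identical(pop$t, 0L)
  expect_gof(pop$variants[, 1], rep(1 / 4, 4))

  set.seed(21)
  a <- initialize_population(p)
  set.seed(21)
  b <- initialize_population(p)
  expect_identical(a, b)
})

test_that("the sweep adjustment installs the innovator configuration", {
  set.seed(22)
  p <- sim_params(N = 300, h = 5, k = 4, s = c(0.9, 0, 0, 0, 0))
  pop <- make_pop(matrix(sample.int(4, 1500, TRUE, prob = c(.4, .3, .2, .1)),
                         300, 5), k = 4)
  links_before <- pop$links
  adj <- apply_sweep_adjustment(pop, p)
  v <- adj$pop$variants

  expect_equal(tabulate(v[, 1], 4), c(1L, 0L, 0L, 299L))
  expect_identical(v[adj$innovator, 1], 1L)
  expect_identical(v[adj$innovator, 2], 4L)

  cnt2 <- tabulate(v[, 2], 4)
  expect_true(cnt2[4] <= min(cnt2[1:3]))
  # relabeling is a bijection on variant labels: the count multiset after the
  # innovator's move is preserved, and counts still sum to N
  cnt_before <- tabulate(pop$variants[, 2], 4)
  rarest <- which.min(cnt_before)
  cnt_moved <- cnt_before
  old <- pop$variants[adj$innovator, 2]
  cnt_moved[old] <- cnt_moved[old] - 1L
  cnt_moved[rarest] <- cnt_moved[rarest] + 1L
  expect_equal(sort(cnt2), sort(cnt_moved))
  expect_identical(sort(adj$relabel), 1:4)
  expect_identical(adj$pop$links, links_before)

  expect_error(apply_sweep_adjustment(pop, p, scenario = "neutral"),
               "hitchhike")
  pop1 <- make_pop(matrix(1L, 10, 1), k = 4)
  expect_error(apply_sweep_adjustment(pop1, sim_params(N = 10, h = 1, k = 4)),
               "two traits")
})

test_that("replicates record the right phases and are seed-reproducible", {
  p <- sim_params(N = 40, h = 2, k = 4, mu = 0.02, a = 0.05, b = 0.1,
                  burn_in_steps = 30, post_steps = 0, seed = 101)
  tr <- run_replicate(p, "neutral")
  expect_identical(dim(tr$counts), c(2L, 4L, 30L))

  p2 <- update_params(p, post_steps = 12)
  tr2 <- run_replicate(p2, "neutral")
  expect_identical(dim(tr2$counts), c(2L, 4L, 42L))
  # per-trait counts sum to N at every recorded timestep
  expect_true(all(apply(tr2$counts, c(1, 3), sum) == 40L))

  tr3 <- run_replicate(p2, "neutral")
  expect_identical(tr2$counts, tr3$counts)
  expect_identical(tr2$final, tr3$final)
})

test_that("hitchhike replicates adjust the state at the end of the burn-in", {
  p <- sim_params(N = 50, h = 3, k = 4, mu = 0.02, a = 0.05, b = 0.1,
                  burn_in_steps = 25, post_steps = 15, seed = 55)
  tr <- run_replicate(p, "hitchhike_neutral")
  expect_identical(tr$counts[1, , p$burn_in_steps], c(1L, 0L, 0L, 49L))
  expect_true(all(apply(tr$counts, c(1, 3), sum) == 50L))
  expect_false(is.na(tr$innovator))

  # the burn-in itself is unbiased: identical to the neutral run's burn-in
  trn <- run_replicate(p, "neutral")
  pre <- seq_len(p$burn_in_steps - 1)
  expect_identical(tr$counts[, , pre], trn$counts[, , pre])

  sw <- sweep_metrics(tr)
  expect_gte(sw$sweep_end, 1L)
  expect_error(sweep_metrics(trn), "hitchhike")
})

test_that("the conformist scenario runs single-trait with no burn-in phase", {
  p <- sim_params(N = 30, h = 1, k = 4, mu = 0.02, s_kappa = 0.3,
                  transmission_mode = "conformist",
                  burn_in_steps = 20, post_steps = 10, seed = 7)
  tr <- run_replicate(p, "conformist")
  expect_identical(tr$burn_in, 0L)
  expect_identical(dim(tr$counts), c(1L, 4L, 30L))
  expect_error(run_replicate(sim_params(N = 30, h = 2, k = 4, seed = 1),
                             "conformist"), "h = 1")
})

test_that("grid runs validate inputs up front and are reconstructible", {
  base <- sim_params(N = 25, h = 2, k = 4, mu = 0.02, b = 0.1,
                     burn_in_steps = 20, post_steps = 5)
  expect_error(run_grid(base, list(a = 0.1, a = 0.2), replicates = 1),
               "duplicate")
  expect_error(run_grid(base, list(zz = 1), replicates = 1), "unknown")
  expect_error(run_grid(base, list(a = c(0, 2)), replicates = 1),
               "probability")

  g <- run_grid(base, list(a = c(0, 0.1)), replicates = 3, seed_base = 9)
  expect_s3_class(g, "cl_grid")
  expect_identical(nrow(g), 6L)
  g2 <- run_grid(base, list(a = c(0, 0.1)), replicates = 3, seed_base = 9)
  expect_identical(as.data.frame(g), as.data.frame(g2))

  # each row reconstructs from its recorded seed
  row <- g[4, ]
  p <- update_params(base, a = row$a)
  p$seed <- row$seed
  tr <- run_replicate(p, "neutral")
  expect_equal(unname(final_pi(tr)[1]), row$pi_1)

  sm <- summarize_grid(g)
  expect_identical(nrow(sm), 2L)
  expect_equal(sm$n, c(3L, 3L))
  g1 <- run_grid(base, list(a = 0.1), replicates = 1, seed_base = 3)
  expect_equal(summarize_grid(g1)$mean_pi_1, g1$pi_1)

  # an empty grid runs replicates of the base parameters alone
  g0 <- run_grid(base, list(), replicates = 2, seed_base = 5)
  expect_identical(nrow(g0), 2L)
  expect_true(all(c("pi_1", "link_freq") %in% names(g0)))
})

test_that("tidiers expose trajectories and summaries as tibbles", {
  p <- sim_params(N = 20, h = 2, k = 3, mu = 0.05, a = 0.1,
                  burn_in_steps = 10, post_steps = 5, seed = 77)
  tr <- run_replicate(p, "neutral")
  td <- tidy(tr)
  expect_identical(nrow(td), 15L * 2L * 3L)
  expect_equal(sum(td$count[td$t == 3 & td$trait == 1]), 20)

  gl <- glance(tr)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$pi_1, unname(final_pi(tr)[1]))

  pt <- pi_trajectory(tr, traits = 1)
  expect_identical(nrow(pt), 15L)
  expect_equal(pt$pi[15], unname(final_pi(tr)[1]))
})
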