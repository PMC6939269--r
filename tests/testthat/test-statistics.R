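test_that("pairwise difference matches hand values and brute-force enumeration", {
  expect_equal(pairwise_difference(c(4, 0, 0, 0)), 0)
  expect_equal(pairwise_difference(c(2, 2, 0, 0)), 2 / 3)
  expect_equal(pairwise_difference(c(1, 1, 1, 1)), 1)
  expect_error(pairwise_difference(c(1.5, 2)), "integer")
  expect_error(pairwise_difference(c(1, 0)), "at least 2")

  set.seed(30)
  for (i in 1:25) {
    N <- sample(2:50, 1)
    k <- sample(2:5, 1)
    v <- sample.int(k, N, replace = TRUE)
    expect_equal(pairwise_difference(tabulate(v, k)),
                 brute_force_pairwise(v), tolerance = 1e-12)
  }
  pop <- make_pop(matrix(c(1L, 1L, 2L, 3L), ncol = 1), k = 3)
  expect_equal(brute_force_pairwise(pop, 1), 5 / 6)
})

test_that("the Wright-Fisher expectation evaluates the closed form", {
  expect_equal(wf_expectation(1000, 0.01, 4), 60 / 83)
  expect_equal(wf_expectation(1000, 0.01, 2), 20 / 41)
  expect_warning(z <- wf_expectation(1000, 0, 4), "drift")
  expect_equal(z, 0)
  # saturates towards (k - 1) / k as innovation dominates
  expect_lt(abs(wf_expectation(1000, 1, 4) - 0.75), 0.01)
  expect_true(all(diff(vapply(c(.001, .01, .1, 1),
                              function(m) wf_expectation(1000, m, 4),
                              numeric(1))) > 0))
})

test_that("the scaled expectation applies the h/(nc) innovation rescaling", {
  expect_equal(scaled_wf_expectation(500, 0.01, 4, 5, 5, 1),
               wf_expectation(500, 0.01, 4))
  # independent evaluation: mu_eff = 0.01 * 5 / (1 * 0.99)
  mu_eff <- 0.01 * 5 / 0.99
  expect_equal(scaled_wf_expectation(1000, 0.01, 4, 5, 1, 0.99),
               2 * 1000 * mu_eff * 3 / (3 + 2 * 1000 * mu_eff * 4))
  expect_error(scaled_wf_expectation(1000, 0.01, 4, 5, 0, 0.99), "1:h")
  # the effective innovation rate falls with n, so the expectation falls too
  vals <- vapply(1:5, function(n)
    scaled_wf_expectation(1000, 0.01, 4, 5, n, 0.99), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("link frequency averages per-individual link density", {
  pop <- make_pop(rbind(c(1, 1, 1), c(1, 1, 1)),
                  list(c(1, 1, 2), c(2, 1, 2), c(2, 1, 3), c(2, 2, 3)),
                  k = 2)
  expect_equal(link_frequency(pop), mean(c(1 / 3, 1)))

  linkless <- make_pop(matrix(1L, 4, 3), k = 2)
  expect_equal(link_frequency(linkless), 0)
  single <- make_pop(matrix(1L, 4, 1), k = 2)
  expect_equal(link_frequency(single), 0)
})

test_that("package-size variance is the variance of component sizes", {
  linkless <- make_pop(matrix(1L, 6, 5), k = 2)
  expect_equal(package_size_variance(linkless), 0)

  complete <- new_population(matrix(1L, 3, 4),
                             array(rep(!diag(4), 3), dim = c(4, 4, 3)),
                             k = 2)
  expect_equal(package_size_variance(complete), 0)

  # one individual, components {1,2}, {3}, {4}, {5}: sizes (2,2,1,1,1)
  one <- make_pop(matrix(1L, 1, 5), list(c(1, 1, 2)), k = 2)
  expect_equal(package_size_variance(one), var(c(2, 2, 1, 1, 1)))
})

test_that("area of overlap behaves like a bounded symmetric overlap measure", {
  set.seed(31)
  x <- runif(400, 0, 1)
  self <- area_of_overlap(x, x)
  expect_equal(self$overlap, 1)

  lo <- runif(300, 0, 0.39)
  hi <- runif(300, 0.61, 1)
  expect_equal(area_of_overlap(lo, hi)$overlap, 0)

  y <- runif(400, 0.3, 0.9)
  expect_equal(area_of_overlap(x, y)$overlap, area_of_overlap(y, x)$overlap)

  # analytic: U(0, .5) vs U(.25, .75) overlap exactly 1/2
  a <- runif(5000, 0, 0.5)
  b <- runif(5000, 0.25, 0.75)
  expect_lt(abs(area_of_overlap(a, b)$overlap - 0.5), 0.05)
  expect_lt(abs(area_of_overlap(a, b, method = "density")$overlap - 0.5),
            0.08)

  expect_error(area_of_overlap(numeric(0), x), "non-empty")
  expect_error(area_of_overlap(c(0.2, 1.4), x), "\\[0, 1\\]")
  # tibble input as produced by pi_sample
  expect_equal(area_of_overlap(tibble::tibble(pi = a),
                               tibble::tibble(pi = b))$overlap,
               area_of_overlap(a, b)$overlap)
})

test_that("sweep end is the first non-increase of the swept variant", {
  r <- detect_sweep_end(c(0.001, 0.3, 0.8, 0.8, 0.7))
  expect_identical(r$sweep_end, 3L)
  expect_false(r$censored)

  r2 <- detect_sweep_end(c(0.2, 0.2, 0.3))
  expect_identical(r2$sweep_end, 1L)

  r3 <- detect_sweep_end(c(0.1, 0.2, 0.5, 0.9))
  expect_identical(r3$sweep_end, 3L)
  expect_true(r3$censored)

  expect_error(detect_sweep_end(0.5), "two points")
})

test_that("hitchhiking metrics count the strict-majority episode", {
  m <- hitchhike_metrics(c(0.1, 0.4), sweep_end = 1)
  expect_false(m$majority_reached)
  expect_true(is.na(m$majority_duration))

  m2 <- hitchhike_metrics(c(0.1, 0.7, 0.7, 0.6, 0.55, 0.5, 0.3),
                          sweep_end = 1)
  expect_true(m2$majority_reached)
  expect_identical(m2$majority_duration, 3L)
  expect_false(m2$duration_censored)

  m3 <- hitchhike_metrics(c(0.1, 0.8, 1, 1, 1), sweep_end = 1)
  expect_identical(m3$majority_duration, 3L)
  expect_true(m3$duration_censored)

  expect_error(hitchhike_metrics(c(0.1, 0.4), sweep_end = 5), "index")
})

test_that("hitchhiking aggregation applies the 5% reporting rule", {
  few <- tibble::tibble(majority_reached = c(TRUE, rep(FALSE, 39)),
                        assoc_freq_at_end = runif(40, 0, 0.4),
                        majority_duration = c(10L, rep(NA_integer_, 39)),
                        duration_censored = rep(FALSE, 40))
  s <- summarize_hitchhiking(few)
  expect_equal(s$prop_majority, 1 / 40)
  expect_true(is.na(s$mean_majority_duration))

  many <- tibble::tibble(majority_reached = rep(c(TRUE, FALSE), c(30, 10)),
                         assoc_freq_at_end = runif(40),
                         majority_duration = c(rep(4L, 30),
                                               rep(NA_integer_, 10)),
                         duration_censored = rep(FALSE, 40))
  s2 <- summarize_hitchhiking(many)
  expect_equal(s2$mean_majority_duration, 4)
  expect_equal(s2$censored_fraction, 0)
})
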