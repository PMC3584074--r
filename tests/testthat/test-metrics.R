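test_that("paired overlap counts shared resources of the narrower diet", {
  expect_equal(paired_overlap(1:4, 2:3), 1)          # subset
  expect_equal(paired_overlap(1:3, 4:6), 0)          # disjoint
  expect_equal(paired_overlap(1:4, 3:5), 2 / 3)      # partial
  expect_true(is.na(paired_overlap(1:3, integer(0))))
  expect_error(paired_overlap(1:2, 1:3), "at least as large")
})

test_that("strictly nested matrices score NODF 100 and flat ones are undefined", {
  tri <- generate_nested_matrix(10)
  res <- nodf_consumers(tri)
  expect_identical(res$score, 100)
  expect_equal(res$n_pairs_used, choose(10, 2))
  # all-equal degrees: every pair excluded under the modified rule
  eye <- bipartite_network(diag(1, 4))
  expect_true(is.na(nodf_consumers(eye)$score))
  # ... but scores 0 under the original convention
  expect_equal(nodf_consumers(eye, original = TRUE)$score, 0)
  expect_error(nodf_consumers(bipartite_network(matrix(1, 3, 1))),
               "two consumers")
})

test_that("NODF matches a brute-force oracle on random matrices", {
  set.seed(31)
  for (rep in 1:100) {
    a <- random_binary_matrix(6, 6, p = runif(1, 0.2, 0.8))
    got <- nodf_consumers(bipartite_network(a))$score
    want <- oracle_nodf_consumers(a)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want,
                                                               tolerance = 1e-12)
    # and under the original equal-degree convention
    expect_equal(nodf_consumers(bipartite_network(a), original = TRUE)$score,
                 oracle_nodf_consumers(a, original = TRUE), tolerance = 1e-12)
  }
})

test_that("NODF is invariant to row/column permutations", {
  set.seed(13)
  for (rep in 1:25) {
    a <- random_binary_matrix(5, 7)
    base <- nodf_consumers(bipartite_network(a))$score
    p <- a[sample(nrow(a)), sample(ncol(a))]
    got <- nodf_consumers(bipartite_network(p))$score
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("niche intervals use the half-width convention without clipping", {
  expect_equal(r_interval(0.5, 0.2), c(0.4, 0.6))
  expect_equal(diff(r_interval(0.3, 0.77)), 0.77)
  expect_equal(r_interval(0.05, 0.2), c(-0.05, 0.15))  # extends past the axis
  expect_error(r_interval(0.5, 0), "positive")
  # quantile convention: cutoffs where the kernel drops to 2.5% of peak
  q <- r_interval(0.5, 0.2, g = 2, convention = "quantile")
  expect_equal(diff(q), 0.2 * sqrt(-log(0.025)))
})

test_that("continuous overlap scores nested, disjoint and partial intervals", {
  # concentric intervals, strictly decreasing widths -> perfect overlap
  conc <- bpnm_params(n = runif(3), centers = rep(0.5, 10),
                      widths = seq(0.05, 0.5, by = 0.05))
  res <- continuous_overlap(conc)
  expect_identical(res$score, 100)
  expect_equal(res$n_pairs_used, choose(10, 2))
  # pairwise disjoint intervals -> 0
  disj <- bpnm_params(n = runif(3), centers = c(0.1, 0.5, 0.9),
                      widths = c(0.1, 0.08, 0.06))
  expect_equal(continuous_overlap(disj)$score, 0)
  # wider [0, 0.4], narrower [0.3, 0.5] -> 100 * 0.1 / 0.2 = 50
  two <- bpnm_params(n = 0.5, centers = c(0.2, 0.4), widths = c(0.4, 0.2))
  expect_equal(continuous_overlap(two)$score, 50)
  # equal widths are excluded; all-equal -> undefined
  eq <- bpnm_params(n = 0.5, centers = c(0.2, 0.8), widths = c(0.3, 0.3))
  expect_true(is.na(continuous_overlap(eq)$score))
})

test_that("f_L is the expected fraction of observed links realized", {
  a <- matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  net <- bipartite_network(a)
  P <- matrix(c(0.9, 0.1, 0.1, 0.7), 2, 2, byrow = TRUE)
  expect_equal(suppressWarnings(fraction_links_predicted(net, P)),
               (0.9 + 0.7) / 2)
  # constant matrix p -> f_L = p
  net4 <- bipartite_network(random_binary_matrix(4, 4))
  pc <- n_links(net4) / 16
  Pc <- matrix(pc, 4, 4)
  expect_equal(fraction_links_predicted(net4, Pc), pc)
  # perfect model: P = clamped adjacency
  Pa <- pmin(pmax(net4$adjacency, 1e-10), 1 - 1e-10)
  expect_warning(f <- fraction_links_predicted(net4, Pa), NA)
  expect_equal(f, 1 - 1e-10)
  # warning when expected links drift from observed
  expect_warning(fraction_links_predicted(net, matrix(0.9, 2, 2)),
                 "expected link count")
  # threshold variant counts links above the cutoff
  expect_equal(suppressWarnings(
    fraction_links_predicted(net, P, threshold = 0.8)), 0.5)
})

test_that("probability connectance averages the matrix", {
  expect_equal(connectance_from_probabilities(matrix(0.37, 5, 8)), 0.37)
  net <- bipartite_network(random_binary_matrix(5, 5))
  Pa <- pmin(pmax(net$adjacency, 1e-10), 1 - 1e-10)
  expect_equal(connectance_from_probabilities(Pa),
               connectance_empirical(net), tolerance = 1e-8)
})

test_that("degree/width rank correlation handles ties like the oracle", {
  a <- matrix(0L, 5, 4)
  a[1:3, 1] <- 1L; a[1:2, 2] <- 1L; a[1, 3] <- 1L; a[1:2, 4] <- 1L
  net <- bipartite_network(a)
  par_up <- bpnm_params(n = runif(5), centers = runif(4),
                        widths = c(0.8, 0.5, 0.1, 0.5))
  expect_equal(degree_r_rank_correlation(net, par_up),
               oracle_spearman(colSums(a), par_up$r))
  # strictly aligned and reversed orderings
  b <- matrix(0L, 4, 3); b[1, 1] <- 1L; b[1:2, 2] <- 1L; b[1:3, 3] <- 1L
  netb <- bipartite_network(b)
  expect_equal(degree_r_rank_correlation(
    netb, bpnm_params(n = runif(4), centers = runif(3),
                      widths = c(0.1, 0.2, 0.3))), 1)
  expect_equal(degree_r_rank_correlation(
    netb, bpnm_params(n = runif(4), centers = runif(3),
                      widths = c(0.3, 0.2, 0.1))), -1)
  # zero variance -> undefined
  expect_true(is.na(degree_r_rank_correlation(
    netb, bpnm_params(n = runif(4), centers = runif(3),
                      widths = rep(0.2, 3)))))
})

test_that("niche-center dispersion is the sample standard deviation", {
  expect_equal(c_dispersion(bpnm_params(n = 0.5, centers = rep(0.3, 5),
                                        widths = rep(0.2, 5))), 0)
  expect_equal(c_dispersion(bpnm_params(n = 0.5, centers = c(0, 1),
                                        widths = c(0.2, 0.2))), sqrt(0.5))
  set.seed(3)
  cc <- runif(8)
  par <- bpnm_params(n = 0.5, centers = cc, widths = rep(0.2, 8))
  ref <- bpnm_params(n = 0.5, centers = 1 - cc, widths = rep(0.2, 8))
  expect_equal(c_dispersion(par), c_dispersion(ref))
})
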