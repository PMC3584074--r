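test_that("niche kernel has the right peak, shoulder and tail", {
  # resource exactly at the niche optimum -> p_max
  expect_equal(bpnm_probability(0.5, 0.5, 0.3, 2, 0.9), 0.9)
  # one half-width from the center with g = 2 -> p_max / e
  expect_equal(bpnm_probability(0.5 + 0.15, 0.5, 0.3, 2, 0.9),
               0.9 * exp(-1))
  # far tail is held at the clamp floor
  far <- bpnm_probability(0.99, 0.01, 0.098, 2, 0.9)
  expect_lte(far, 1e-10 * (1 + 1e-9))
  expect_error(bpnm_probability(0.5, 0.5, 0, 2, 0.9), "positive")
})

test_that("probability matrix matches the scalar kernel elementwise", {
  par <- bpnm_params(n = c(0.2, 0.8), centers = c(0.3, 0.6),
                     widths = c(0.4, 0.25), g = 3, p_max = 0.85)
  P <- probability_matrix(par)
  for (j in 1:2) for (i in 1:2) {
    expect_equal(P[j, i],
                 bpnm_probability(par$n[j], par$c[i], par$r[i], 3, 0.85))
  }
  # identical consumers give identical columns
  par2 <- bpnm_params(n = runif(4), centers = rep(0.4, 3),
                      widths = rep(0.3, 3))
  P2 <- probability_matrix(par2)
  expect_equal(P2[, 1], P2[, 2])
  expect_equal(P2[, 1], P2[, 3])
})

test_that("niche model is invariant under axis reflection", {
  set.seed(11)
  for (rep in 1:10) {
    par <- bpnm_params(n = runif(6), centers = runif(4),
                       widths = runif(4, 0.1, 1.5),
                       g = runif(1, 1, 5), p_max = runif(1, 0.3, 1))
    ref <- bpnm_params(1 - par$n, 1 - par$c, par$r, par$g, par$p_max)
    expect_equal(probability_matrix(par), probability_matrix(ref),
                 tolerance = 1e-12)
    a <- random_binary_matrix(6, 4)
    net <- bipartite_network(a)
    expect_equal(log_likelihood(net, probability_matrix(par)),
                 log_likelihood(net, probability_matrix(ref)),
                 tolerance = 1e-12)
  }
})

test_that("cascade matrix calibrates expected links to the observed count", {
  # 2x2 with one forbidden pair: phi/psi chosen so psi_2 >= phi_1 only
  par <- cascade_params(phi = c(0.5, 0.9), psi = c(0.1, 0.6))
  # allowed: (r1,c1), (r1,c2), (r2,c2) -> L_p = 3
  P <- probability_matrix(par, L_observed = 2)
  expect_equal(P[1, 1], 2 / 3)
  expect_equal(P[1, 2], 2 / 3)
  expect_equal(P[2, 2], 2 / 3)
  expect_equal(P[2, 1], 1e-10)  # forbidden pair at the clamp floor
  # limiting case: everything allowed reduces to the random model
  par_all <- cascade_params(phi = rep(1, 3), psi = rep(0.2, 4))
  P_all <- probability_matrix(par_all, L_observed = 6)
  expect_true(all(abs(P_all - 6 / 12) < 1e-12))
  expect_error(probability_matrix(cascade_params(phi = 0.1, psi = 0.9),
                                  L_observed = 1), "L_p = 0")
})

test_that("cascade likelihood depends only on the induced allowed set", {
  set.seed(5)
  a <- random_binary_matrix(4, 4)
  net <- bipartite_network(a)
  # same order structure, different numeric values
  p1 <- cascade_params(phi = c(0.9, 0.5, 0.7, 0.2), psi = c(0.1, 0.6, 0.3, 0.8))
  p2 <- cascade_params(phi = c(0.95, 0.45, 0.75, 0.15),
                       psi = c(0.05, 0.6, 0.35, 0.85))
  stopifnot(identical(outer(p1$psi, p1$phi, "<"), outer(p2$psi, p2$phi, "<")))
  L <- n_links(net)
  expect_equal(log_likelihood(net, probability_matrix(p1, L_observed = L)),
               log_likelihood(net, probability_matrix(p2, L_observed = L)))
})

test_that("random model is constant and its MLE is the connectance", {
  P <- probability_matrix(random_params(0.5), S_C = 2, S_R = 2)
  expect_true(all(P == 0.5))
  expect_equal(sum(P), 0.5 * 4)
  set.seed(9)
  for (rep in 1:5) {
    a <- random_binary_matrix(5, 6)
    net <- bipartite_network(a)
    phat <- n_links(net) / 30
    # 1-D grid oracle for the Bernoulli MLE
    grid <- seq(0.01, 0.99, by = 0.0001)
    ll <- sapply(grid, function(p) {
      sum(a) * log(p) + (30 - sum(a)) * log(1 - p)
    })
    expect_lt(abs(grid[which.max(ll)] - phat), 1e-4 + 1e-12)
  }
})

test_that("log-likelihood is a finite cellwise Bernoulli sum", {
  one <- bipartite_network(matrix(1L, 1, 1))
  expect_equal(log_likelihood(one, matrix(0.5, 1, 1)), log(0.5))
  # hand-summed 2x2 case
  a <- matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  P <- matrix(c(0.9, 0.2, 0.3, 0.8), 2, 2, byrow = TRUE)
  expect_equal(log_likelihood(bipartite_network(a), P),
               log(0.9) + log(0.8) + log(0.8) + log(0.7))
  # perfect prediction: P equals the clamped adjacency
  net <- bipartite_network(random_binary_matrix(4, 5))
  Pa <- pmin(pmax(net$adjacency, 1e-10), 1 - 1e-10)
  expect_lt(abs(log_likelihood(net, Pa)), 20 * abs(log(1 - 1e-10)) * 2)
  expect_error(log_likelihood(net, matrix(0.5, 2, 2)), "dimensions")
})

test_that("parameter counts follow the model structure", {
  expect_equal(parameter_count("bpnm", 10, 10), 32)
  expect_equal(parameter_count("cascade", 5, 5), 10)
  expect_equal(parameter_count("random", 50, 70), 1)
})

test_that("AICc formula, monotonicity and large-sample limit", {
  expect_equal(aicc(-10, 1, 100), 22 + 4 / 98)
  expect_gt(aicc(-10, 5, 100), aicc(-10, 2, 100))
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 2 * 3, tolerance = 1e-6)
  expect_warning(v <- aicc(-10, 10, 11), "undefined")
  expect_true(is.na(v))
})

test_that("parameter files round-trip exactly", {
  par <- bpnm_params(n = runif(5), centers = runif(3),
                     widths = runif(3, 0.1, 1), g = 2.5, p_max = 0.77)
  f <- tempfile(fileext = ".json")
  write_params(par, f)
  back <- read_params(f)
  expect_equal(back, par)
  casc <- cascade_params(runif(3), runif(5))
  write_params(casc, f)
  expect_equal(read_params(f), casc)
  write_params(random_params(0.123456789012345), f)
  expect_equal(read_params(f)$p, 0.123456789012345)
})
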