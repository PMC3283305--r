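# Frozen expected values below were computed from the closed forms and
# cross-checked against truncated series in this suite's property tests.

test_that("bdi1 closed forms match frozen values and limits", {
  p <- bdi1_params(0.5)
  expect_equal(bdi1_qn(p, 1:3), c(0.7213475, 0.1803369, 0.0601123),
               tolerance = 1e-6)
  expect_equal(bdi1_mean(0.5), 1 / log(2), tolerance = 1e-12)
  expect_equal(bdi1_mean(0.9), 3.90865, tolerance = 1e-5)
  # r -> 0+: all singletons, mean -> 1
  expect_gt(bdi1_qn(bdi1_params(1e-8), 1), 1 - 1e-7)
  expect_equal(bdi1_mean(1e-8), 1, tolerance = 1e-7)
  expect_error(bdi1_params(1.2), "0, 1")
  expect_error(bdi1_params(0), "0, 1")
})

test_that("bdi1 expected counts obey detailed balance and innovation balance", {
  p <- bdi1_params(0.5, u_over_delta = 1)
  expect_equal(bdi1_fn(p, 1:3), c(1, 0.25, 1 / 12), tolerance = 1e-12)
  expect_equal(bdi1_fn(p, 1), p$u_over_delta)  # u = delta * f(1)
  expect_equal(bdi1_ftot(p), log(2) / 0.5, tolerance = 1e-12)
  # f(n) * n * delta = f(n-1) * (n-1) * lambda with lambda/delta = r
  for (r in c(0.1, 0.5, 0.9)) {
    pr <- bdi1_params(r, u_over_delta = 2.5)
    n <- 2:50
    expect_equal(bdi1_fn(pr, n) * n, bdi1_fn(pr, n - 1) * (n - 1) * r,
                 tolerance = 1e-12)
  }
})

test_that("closed forms agree with brute-force truncated series", {
  for (r in c(0.05, 0.3, 0.5, 0.8, 0.95)) {
    n <- seq_len(1e6)
    series_phi <- sum(r^(n - 1) / n)
    expect_equal(bdi_phi(r), series_phi, tolerance = 1e-9)
    q <- bdi1_qn(bdi1_params(r), n)
    expect_equal(sum(q), 1, tolerance = 1e-9)
    expect_equal(bdi1_mean(r), sum(n * q), tolerance = 1e-9)
    expect_equal(calibrate_scale(r, 1000), 1000 / series_phi,
                 tolerance = 1e-9)
  }
  expect_equal(calibrate_scale(0.5, 1000), 721.3475, tolerance = 1e-4)
  expect_equal(calibrate_scale(0.5, bdi_phi(0.5)), 1, tolerance = 1e-12)
  expect_equal(calibrate_scale(1e-8, 100), 100, tolerance = 1e-6)
})

test_that("bdik mixtures evaluate, normalize, and reduce to bdi1", {
  p <- bdik_params(c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(bdik_qn(p, 1), 0.696676, tolerance = 1e-6)
  n <- seq_len(1e5)
  expect_equal(sum(bdik_qn(p, n)), 1, tolerance = 1e-9)
  # K = 1 is exactly BDI1
  p1 <- bdik_params(1, 0.63)
  expect_equal(bdik_qn(p1, 1:200), bdi1_qn(bdi1_params(0.63), 1:200),
               tolerance = 1e-12)
  # constraint violations
  expect_error(bdik_params(c(0.6, 0.6), c(0.2, 0.8)), "sum to 1")
  expect_error(bdik_params(c(0.5, 0.5), c(0.8, 0.2)), "increasing")
  expect_error(bdik_params(c(0.5, 0.5), c(0.2, 1.2)), "strictly in")
})

test_that("gbdi ratios, normalization and limits behave", {
  g <- gbdi_params(0.8, 1, 2)
  q <- gbdi_qn(g, 1:2)
  expect_equal(q[2] / q[1], 0.8 * (1 + 1) / (2 + 2), tolerance = 1e-12)
  # a = b: q2/q1 = r (1 + a) / (2 + a)
  ga <- gbdi_params(0.5, 1.5, 1.5)
  qa <- gbdi_qn(ga, 1:2)
  expect_equal(qa[2] / qa[1], 0.5 * 2.5 / 3.5, tolerance = 1e-12)
  # a, b -> 0 approaches the BDI1 shape: ratios r (m-1)/m
  g0 <- gbdi_params(0.6, 1e-9, 1e-9)
  q0 <- gbdi_qn(g0, 1:20)
  m <- 2:20
  expect_equal(q0[m] / q0[m - 1], 0.6 * (m - 1) / m, tolerance = 1e-6)
  # r = 1, b > a: power-law tail with slope -(1 + b - a)
  g1 <- gbdi_params(1, 0.5, 1.5)
  n <- 100:1000
  slope <- unname(coef(lm(log(gbdi_qn(g1, n)) ~ log(n)))[2])
  expect_equal(slope, -2, tolerance = 0.05)
  # domain errors
  expect_error(gbdi_params(1.1, 1, 2), "0, 1")
  expect_error(gbdi_params(0.5, -1, 2), "positive")
  expect_error(gbdi_params(1, 2, 1), "b > a")
})

test_that("gbdi normalizer is stable under deeper truncation", {
  for (p in list(gbdi_params(0.8, 1, 2), gbdi_params(0.99, 0.3, 0.1),
                 gbdi_params(1, 0.5, 1.5), gbdi_params(1, 0.2, 2.5))) {
    q1_default <- gbdi_qn(p, 1)
    q1_deep <- gbdi_qn(p, 1, n_max_support = 1e6)
    expect_equal(q1_default, q1_deep, tolerance = 1e-7)
  }
})

test_that("power law uses zeta normalization", {
  p <- powerlaw_params(2)
  expect_equal(powerlaw_qn(p, 1), 6 / pi^2, tolerance = 1e-12)
  expect_equal(powerlaw_qn(p, 2), powerlaw_qn(p, 1) / 4, tolerance = 1e-12)
  # exact zeta values
  expect_equal(riemann_zeta(2), pi^2 / 6, tolerance = 1e-12)
  expect_equal(riemann_zeta(4), pi^4 / 90, tolerance = 1e-12)
  # truncation oracle for fast-converging exponents
  expect_equal(riemann_zeta(3), sum(seq_len(1e6)^-3), tolerance = 1e-9)
  # Euler-Maclaurin depth does not matter
  expect_equal(riemann_zeta(1.2, N = 500), riemann_zeta(1.2, N = 5e4),
               tolerance = 1e-11)
  expect_error(powerlaw_params(1), "exceed 1")
})

test_that("normalization holds across a parameter grid for every model", {
  n <- seq_len(2e4)
  for (r in seq(0.05, 0.95, by = 0.1)) {
    q <- bdi1_qn(bdi1_params(r), n)
    tail_bound <- r^(2e4 + 1) / ((2e4 + 1) * (1 - r) * (-log1p(-r)))
    expect_lt(abs(sum(q) + tail_bound - 1), 1e-9)
  }
  set.seed(42)
  for (i in 1:20) {
    K <- sample(1:4, 1)
    r <- sort(runif(K, 0.02, 0.95))
    while (any(diff(r) <= 0)) r <- sort(runif(K, 0.02, 0.95))
    xi <- rexp(K) + 0.1; xi <- xi / sum(xi)
    q <- bdik_qn(bdik_params(xi, r), n)
    expect_lt(abs(sum(q) - 1), 1e-9)
  }
  for (gamma in c(1.1, 1.5, 2, 3, 4)) {
    N <- 1e6
    q <- powerlaw_qn(powerlaw_params(gamma), seq_len(N))
    tail <- (N^(1 - gamma) / (gamma - 1) - N^(-gamma) / 2) /
      riemann_zeta(gamma)
    expect_lt(abs(sum(q) + tail - 1), 1e-9)
  }
})

test_that("bdi1_mean is strictly increasing in r", {
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(bdi1_mean(grid)) > 0))
})

test_that("log_likelihood sums count-weighted log probabilities", {
  f <- family_size_distribution(1L, 2)
  expect_equal(log_likelihood(bdi1_params(0.5), f), 2 * log(0.7213475),
               tolerance = 1e-6)
  f2 <- family_size_distribution(c(1L, 2L), c(1, 1))
  expect_equal(log_likelihood(powerlaw_params(2), f2),
               log(6 / pi^2) + log(6 / pi^2 / 4), tolerance = 1e-9)
  expect_equal(-2.3810, log(6 / pi^2) + log(6 / pi^2 / 4), tolerance = 1e-3)
  # empty distribution
  empty <- family_size_distribution(integer(), numeric())
  expect_equal(log_likelihood(bdi1_params(0.5), empty), 0)
  # underflow sentinel: tiny r cannot generate a huge family
  big <- family_size_distribution(c(1L, 50000L), c(10, 1))
  expect_equal(log_likelihood(bdi1_params(0.01), big), -Inf)
  # real-valued (mean) counts are legal weights
  mf <- family_size_distribution(c(1L, 2L), c(2.5, 0.5), mean = TRUE)
  expect_equal(log_likelihood(bdi1_params(0.5), mf),
               2.5 * log(bdi1_qn(bdi1_params(0.5), 1)) +
                 0.5 * log(bdi1_qn(bdi1_params(0.5), 2)))
})

test_that("out-of-band r is clamped with a message", {
  expect_message(p <- bdi1_params(1 - 1e-12), "clamped")
  expect_equal(p$r, 1 - 1e-9)
})
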