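test_that("K2P matrices are stochastic, symmetric and satisfy Chapman-Kolmogorov", {
  set.seed(3)
  for (i in 1:8) {
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2); kap <- runif(1, 0.3, 12)
    P1 <- k2p_transition_matrix(t1, kap)
    P2 <- k2p_transition_matrix(t2, kap)
    P12 <- k2p_transition_matrix(t1 + t2, kap)
    expect_equal(P1 %*% P2, P12, tolerance = 1e-10)
    expect_equal(rowSums(P1), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
    # detailed balance with uniform frequencies: symmetry
    expect_equal(P1, t(P1), tolerance = 1e-12)
    expect_true(all(P1 >= 0))
  }
})

test_that("K2P limits: t = 0 identity, kappa = 1 Jukes-Cantor, large t stationarity", {
  expect_equal(k2p_transition_matrix(0, 4), diag(4), ignore_attr = TRUE)
  # JC closed form P(same) = 1/4 + 3/4 exp(-4t/3)
  for (t in c(0.05, 0.1, 0.7)) {
    P <- k2p_transition_matrix(t, 1)
    expect_equal(diag(P), rep(1 / 4 + 3 / 4 * exp(-4 * t / 3), 4),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(length(unique(round(P[upper.tri(P)], 14))), 1)
  }
  expect_equal(k2p_transition_matrix(100, 7), matrix(0.25, 4, 4),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(k2p_transition_matrix(-0.1, 2), "nonnegative")
  expect_error(k2p_transition_matrix(0.1, 0), "positive")
})

test_that("ts/tv conventions convert as kappa = 2R", {
  expect_equal(tstv_to_kappa(2), 4)
  expect_equal(kappa_to_tstv(4), 2)
  expect_equal(kappa_to_tstv(tstv_to_kappa(3.7)), 3.7)
  # under kappa = 2R the instantaneous transition:transversion flux is R
  kap <- tstv_to_kappa(2)
  beta <- 1 / (kap + 2)
  expect_equal((kap * beta) / (2 * beta), 2)
})

test_that("discrete-Gamma rates are normalized, ordered, and match quadrature", {
  for (alpha in c(0.1, 0.5, 1, 5)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  # shape -> infinity: rates concentrate at 1
  expect_equal(discrete_gamma_rates(1e6, 4), rep(1, 4), tolerance = 1e-2)
  # alpha = 1 is a unit exponential: category means by direct quadrature
  q <- qgamma(seq(0, 1, 0.25), 1, 1)
  want <- vapply(1:4, function(i)
    4 * integrate(function(x) x * dexp(x), q[i], q[i + 1])$value, numeric(1))
  expect_equal(discrete_gamma_rates(1, 4), want / mean(want), tolerance = 1e-8)
  # medians option
  rm <- discrete_gamma_rates(0.5, 4, type = "median")
  qm <- qgamma((1:4 - 0.5) / 4, 0.5, 0.5)
  expect_equal(rm, qm / mean(qm), tolerance = 1e-12)
  # the smallest rate decreases as heterogeneity grows
  expect_lt(discrete_gamma_rates(0.1, 4)[1], discrete_gamma_rates(1, 4)[1])
  expect_error(discrete_gamma_rates(0, 4), "positive")
  expect_error(discrete_gamma_rates(-1, 4), "positive")
})

test_that("rate mixtures satisfy the weight and mean-rate constraints", {
  for (alpha in c(0.1, 0.5, 1)) {
    for (p in c(0, 0.25, 0.5, 0.9)) {
      mix <- rate_mixture(alpha, p, 4)
      expect_equal(mix$rates[1], 0)
      expect_equal(mix$weights[1], p)
      expect_equal(mix$weights[-1], rep((1 - p) / 4, 4))
      expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
      expect_equal(sum(mix$weights * mix$rates), 1, tolerance = 1e-12)
      expect_true(all(diff(mix$rates[-1]) > 0))
    }
  }
  # continuity at p_inv -> 0: the variable rates approach the plain
  # discrete-Gamma rates
  expect_equal(rate_mixture(0.5, 1e-9)$rates[-1],
               discrete_gamma_rates(0.5, 4), tolerance = 1e-6)
  expect_error(rate_mixture(0.5, 1), "\\[0, 1\\)")
  expect_error(rate_mixture(0.5, -0.1), "\\[0, 1\\)")
})
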