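test_that("the reference hebbian configuration is admissible up to p = 1/3", {
  p <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 100,
                   sigma = 0.05)
  rep <- check_assumption(p, 1)  # u_m = 1
  expect_true(rep$assumption_ok)
  expect_true(rep$stability_ok)
  lo <- rep$admissible_p_set[1, 1]
  hi <- rep$admissible_p_set[1, 2]
  expect_lt(lo, 1 / 3)
  expect_gt(hi, 1 / 3)
  # p -> 0+ always fails when u_m > 0: the admissible set is bounded away
  # from zero
  expect_gt(lo, 0)
  expect_gt(plastav:::admissibility_gap(lo / 10, p, 1), 0)
})

test_that("overwhelming noise empties the admissible set", {
  p <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 100,
                   sigma = 1e4)
  rep <- check_assumption(p, 1)
  expect_false(rep$assumption_ok)
  expect_false(rep$stability_ok)
  expect_null(rep$admissible_p_set)
})

test_that("stdp admissibility follows its own inequality", {
  p <- make_params(rule = "stdp", n = 3, l = 10, kappa = 100, gamma = 3,
                   a_plus = 1, a_minus = 1, sigma = 0.001)
  rep <- check_assumption(p, 1)
  expect_true(rep$stability_ok)
  # direct evaluation of the inequality at p = 1/3
  gap <- plastav:::admissibility_gap(1 / 3, p, 1)
  amp <- 2
  lhs <- amp / (1 / 3 * 2 / 3) *
    (p$s2 * 3 / (2 * (1 + 3 / 10 - 1 / 3)) + 1 / (2 / 3))
  expect_equal(gap, lhs - 100 * 1000, tolerance = 1e-10)
})

test_that("invariant set membership is checked with strict margins", {
  p <- make_params(rule = "hebbian", n = 3, l = 2, kappa = 1, sigma = 0.1)
  expect_true(invariant_set_check(matrix(0, 3, 3), 0.5, p)$inside)
  # boundary point: strict inequality puts it outside
  Wb <- diag(0.5 * 2, 3)
  expect_false(invariant_set_check(Wb, 0.5, p)$inside)
  # asymmetric matrices are outside for symmetric rules
  Wa <- matrix(c(0, 0.1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_false(invariant_set_check(Wa, 0.5, p)$inside)
  expect_error(invariant_set_check(Wb, 1.5, p), "p")
})

test_that("the contraction certificate matches its inequality", {
  p <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 100,
                   sigma = 0.05)
  expect_true(contraction_condition(p, 1 / 3, 1))
  pk <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 1e-9,
                    sigma = 0.05)
  expect_false(contraction_condition(pk, 1 / 3, 1))
  # equality is reported false (strict inequality)
  # choose u_m so that the two sides match exactly at p = 1/2
  l <- 2; kap <- 1; pval <- 0.5
  um2 <- (kap * l^3) * (1 - pval)^3 / 2
  pe <- make_params(rule = "hebbian", n = 1, l = l, kappa = kap, sigma = 0)
  expect_false(contraction_condition(pe, pval, sqrt(um2)))
})

test_that("scalar truncation equilibria solve the averaged scalar field", {
  l <- 1.5; kap <- 2; sig <- 0.4
  eq <- scalar_truncation_equilibria(l, kap, sig)
  expect_lt(eq$eta, 1)
  G <- function(w) -kap * w + sig^2 / (2 * (l - w))
  expect_equal(G(eq$w_minus), 0, tolerance = 1e-12)
  expect_equal(G(eq$w_plus), 0, tolerance = 1e-12)
  expect_true(eq$w_minus > 0 && eq$w_plus < l)

  # eta = 1: double root at l/2;  sigma = 0: roots 0 and l
  sig1 <- sqrt(kap * l^2 / 2)
  eq1 <- scalar_truncation_equilibria(l, kap, sig1)
  expect_equal(eq1$w_minus, l / 2, tolerance = 1e-12)
  expect_equal(eq1$w_plus, l / 2, tolerance = 1e-12)
  eq0 <- scalar_truncation_equilibria(l, kap, 0)
  expect_equal(c(eq0$w_minus, eq0$w_plus), c(0, l))
  # eta >= 1: no equilibria
  expect_true(is.na(scalar_truncation_equilibria(1, 1, 10)$w_minus))
})

test_that("admissible parameters keep averaged trajectories inside E_p", {
  p <- make_params(rule = "hebbian", n = 2, l = 2, kappa = 3, sigma = 0.2)
  u <- make_sinusoid_input(2, tau = 1.5, amplitudes = c(0.8, 0.3))
  rep <- check_assumption(p, u)
  expect_true(rep$assumption_ok)
  pmid <- mean(rep$admissible_p_set[1, ])
  f <- averaged_field(p, u, mode = "direct")
  traj <- integrate_averaged(f, T = 2, dt = 0.01)
  for (i in seq(1, dim(traj$W)[3], by = 20)) {
    expect_true(invariant_set_check(traj$W[, , i], pmid, p)$inside)
  }
})

test_that("energy decays monotonically towards the equilibrium", {
  p <- make_params(rule = "hebbian", n = 2, l = 2, kappa = 3, sigma = 0.2)
  u <- make_sinusoid_input(2, tau = 1.5, amplitudes = c(0.8, 0.3))
  f <- averaged_field(p, u, mode = "direct")
  Wstar <- solve_equilibrium(f)
  traj <- integrate_averaged(f, T = 2, dt = 0.01)
  en <- apply(traj$W, 3, function(m) sum((m - Wstar)^2))
  expect_true(all(diff(en) <= 1e-12 * max(en)))
})

test_that("the scalar stochastic system respects asymptotic well-posedness", {
  # eta < 1: w stays below the unstable root for several slow units
  l <- 1; kap <- 1; sig <- 0.3
  eq <- scalar_truncation_equilibria(l, kap, sig)
  p <- make_params(rule = "hebbian", n = 1, l = l, kappa = kap, sigma = sig,
                   eps1 = 1e-3)
  tr <- simulate_network(p, zero_input(1), T_fast = 5e3, dt = 0.01, seed = 4)
  expect_lt(max(tr$W), eq$w_plus)
})
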