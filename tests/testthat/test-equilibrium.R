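test_that("weak connectivity index evaluates the printed formulas", {
  p <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 100,
                   sigma = 0.05)
  set.seed(1)
  a <- rnorm(3); a <- a / sqrt(sum(a^2))
  u <- make_sinusoid_input(3, tau = 1, amplitudes = a)  # u_m = 1
  idx <- weak_connectivity_index(p, u)
  expect_equal(idx$p_tilde, 1 / (100 * 12^3) + 0.05^2 / (2 * 100 * 12^2),
               tolerance = 1e-10)
  expect_equal(idx$lam, 0.05^2 * 12 / 2, tolerance = 1e-10)

  # sigma = 0: lambda = 0, p_tilde = u_m^2 / (kappa l^3)
  p0 <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 100, sigma = 0)
  idx0 <- weak_connectivity_index(p0, u)
  expect_equal(idx0$lam, 0)
  expect_equal(idx0$p_tilde, 1 / (100 * 12^3), tolerance = 1e-10)

  # stdp limit a- = 0, gamma -> infinity: (a+ / kappa l^3)(s^2/2l + u_m^2)
  ps <- make_params(rule = "stdp", n = 3, l = 2, kappa = 5, gamma = 1e9,
                    a_plus = 1.5, a_minus = 0, sigma = 0.3)
  idxs <- weak_connectivity_index(ps, u)
  expect_equal(idxs$p_tilde, 1.5 / (5 * 8) * (0.09 / 4 + 1),
               tolerance = 1e-6)
  expect_error(weak_connectivity_index(p, zero_input(3)), "u_m")
})

test_that("the noise-only scalar equilibrium is the stable truncation root", {
  p <- make_params(rule = "hebbian", n = 1, l = 1, kappa = 1, sigma = 0.3)
  f <- averaged_field(p, zero_input(1), mode = "direct")
  Wstar <- solve_equilibrium(f)
  eq <- scalar_truncation_equilibria(1, 1, 0.3)
  expect_equal(Wstar[1, 1], eq$w_minus, tolerance = 1e-10)
})

test_that("the equilibrium is independent of the admissible starting point", {
  p <- make_params(rule = "hebbian", n = 3, l = 2, kappa = 3, sigma = 0.2,
                   mu = 1)
  u <- two_pattern_input(3, seed = 2, M = 1024, amp = 0.8)
  f <- averaged_field(p, u, mode = "direct")
  tol <- 1e-12
  ref <- solve_equilibrium(f, tol = tol)
  for (s in 1:4) {
    W0 <- rand_admissible_W(3, 2, frac = 0.2, seed = s)
    Ws <- solve_equilibrium(f, tol = tol, W0 = W0)
    expect_lt(frob(Ws - ref), 10 * tol * max(1, frob(ref)) + 1e-11)
  }
})

test_that("hebbian expansion orders match their printed assembly", {
  n <- 3
  p <- make_params(rule = "hebbian", n = n, l = 2, kappa = 2, sigma = 0.4,
                   mu = 1)
  u <- two_pattern_input(n, seed = 11, M = 1024, amp = 0.8)
  fam <- correlation_family(p, u, K = 1)
  ex <- equilibrium_expansion(p, u, family = fam, order = 2, solve = FALSE)
  C00 <- fam$mats[[1, 1]]; C10 <- fam$mats[[2, 1]]; C01 <- fam$mats[[1, 2]]
  pt <- ex$p_tilde; lam <- ex$lam; l <- p$l
  o1 <- pt * l / (1 + lam) * (lam * diag(1, n) + C00)
  o2 <- pt^2 * l / (1 + lam)^2 *
    (lam^2 * diag(1, n) + lam * (C00 + C10 + C01) +
       C00 %*% C10 + C01 %*% C00)
  expect_equal(ex$order1, o1, tolerance = 1e-12)
  expect_equal(ex$order2, o2, tolerance = 1e-12)
  expect_lt(max(abs(ex$order1 - t(ex$order1))), 1e-12)
  expect_lt(max(abs(ex$order2 - t(ex$order2))), 1e-12)
})

test_that("expansion error shrinks at the expected order in p_tilde", {
  n <- 3
  u0 <- two_pattern_input(n, seed = 11, M = 1024)
  e1 <- e2 <- pts <- c()
  for (f in c(1, 0.25)) {
    u <- periodic_input(u0$samples * 0.8 * sqrt(f), u0$tau)
    p <- make_params(rule = "hebbian", n = n, l = 2, kappa = 2,
                     sigma = 0.4 * sqrt(f), mu = 1)
    ex <- equilibrium_expansion(p, u, order = 2, solve = TRUE)
    pts <- c(pts, ex$p_tilde)
    e1 <- c(e1, frob(ex$W_numeric - ex$order1))
    e2 <- c(e2, frob(ex$W_numeric - ex$order1 - ex$order2))
  }
  # scaling p_tilde by 1/4 shrinks the order-1 error ~16x, order-2 ~64x
  expect_equal(log(e1[1] / e1[2]) / log(pts[1] / pts[2]), 2,
               tolerance = 0.15)
  expect_equal(log(e2[1] / e2[2]) / log(pts[1] / pts[2]), 3,
               tolerance = 0.15)
})

test_that("trace expansion reduces to the hebbian one for fast filters", {
  n <- 4
  u <- two_pattern_input(n, seed = 6, M = 1024, amp = 0.6)
  ph <- make_params(rule = "hebbian", n = n, l = 2, kappa = 2, sigma = 0.3)
  ptr <- make_params(rule = "trace", n = n, l = 2, kappa = 2, sigma = 0.3,
                     beta = 1e5)
  exh <- equilibrium_expansion(ph, u, order = 2, solve = FALSE)
  extr <- equilibrium_expansion(ptr, u, order = 2, solve = FALSE)
  expect_lt(max(abs(exh$order1 - extr$order1)), 1e-6)
  expect_lt(max(abs(exh$order2 - extr$order2)), 1e-8)
})

test_that("trace expansion is accurate on the oscillatory branch", {
  n <- 4
  u <- two_pattern_input(n, seed = 6, M = 1024, amp = 0.6)
  p <- make_params(rule = "trace", n = n, l = 2, kappa = 4, sigma = 0.2,
                   beta = 1, mu = 1)
  ex <- equilibrium_expansion(p, u, order = 2, solve = TRUE)
  e1 <- frob(ex$W_numeric - ex$order1)
  e2 <- frob(ex$W_numeric - ex$order1 - ex$order2)
  rho <- ex$p_tilde * plastav:::v_l1_closed(p)
  expect_lt(e1, 5 * rho * frob(ex$order1))
  expect_lt(e2, 5 * rho * e1)
})

test_that("neurons without input decouple at first order", {
  # spatially uncorrelated noise: a silent neuron's order-1 row/column is
  # the lambda-diagonal only
  n <- 4
  u0 <- two_pattern_input(n - 1, seed = 8, M = 1024, amp = 0.8)
  samples <- rbind(u0$samples, 0)
  u <- periodic_input(samples, u0$tau)
  p <- make_params(rule = "hebbian", n = n, l = 2, kappa = 2, sigma = 0.3)
  ex <- equilibrium_expansion(p, u, order = 1, solve = FALSE)
  off <- ex$order1[n, -n]
  expect_equal(max(abs(off)), 0, tolerance = 1e-14)
  expect_equal(ex$order1[n, n],
               ex$p_tilde * p$l * ex$lam / (1 + ex$lam), tolerance = 1e-12)
})

test_that("STDP S/A decomposition has the claimed structure", {
  u <- make_pattern_input(3, 2, durations = c(0.7, 1.3), seed = 3,
                          orthogonalize = TRUE)
  base <- list(n = 3, l = 2, kappa = 5, gamma = 1.5, sigma = 0.2, mu = 0.8)
  mk <- function(ap, am) make_params(c(base, list(rule = "stdp",
                                                  a_plus = ap,
                                                  a_minus = am)))
  # a+ = a-: S vanishes; a+ = -a-: A vanishes
  sa1 <- stdp_sym_antisym(mk(1, 1), u)
  expect_equal(max(abs(sa1$S)), 0)
  sa2 <- stdp_sym_antisym(mk(1, -1), u)
  expect_equal(max(abs(sa2$A)), 0)
  # symmetry types and reconstruction of D00
  p <- mk(1, 0.4)
  sa <- stdp_sym_antisym(p, u)
  expect_lt(max(abs(sa$S - t(sa$S))), 1e-12)
  expect_lt(max(abs(sa$A + t(sa$A))), 1e-12)
  fam <- correlation_family(p, u, K = 0)
  rec <- (sa$S + sa$A) / (u$u_m^2 * u$tau * 1.4)
  expect_lt(max(abs(rec - fam$mats[[1, 1]])), 1e-8)
})

test_that("antisymmetric STDP learning yields an antisymmetric equilibrium", {
  p <- make_params(rule = "stdp", n = 3, l = 10, kappa = 100, gamma = 3,
                   a_plus = 1, a_minus = 1, sigma = 0.001, mu = 1)
  u <- make_pattern_input(3, diag(3), durations = rep(1, 3))
  ex <- equilibrium_expansion(p, u, order = 2, solve = TRUE)
  W <- ex$W_numeric
  expect_lt(max(abs(W + t(W))), 1e-8)
  # first-order noise contribution vanishes (alpha+ = alpha-)
  expect_equal(ex$alpha_plus, ex$alpha_minus)
  fam <- correlation_family(p, u, K = 0)
  o1_corr_only <- ex$p_tilde * p$l / (1 + ex$lam) * fam$mats[[1, 1]]
  expect_equal(ex$order1, o1_corr_only, tolerance = 1e-14)
  expect_error(equilibrium_expansion(p, u, order = 3), "order")
})
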