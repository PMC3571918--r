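test_that("exponential kernels match their closed-form calculus", {
  k <- exp_kernel(3, dt = 1e-4)
  expect_equal(k$integral, 1, tolerance = 1e-6)
  expect_equal(k$values[1], 3)
  expect_equal(k$freq_response(0), 1 + 0i)
  expect_error(exp_kernel(3, horizon = 1), "truncation")

  # iterated: k = 0 identical to the plain kernel; unit L1 for all k;
  # mode at k / rate
  k0 <- iterated_exp_kernel(2, 0, dt = 1e-3, horizon = 20)
  e0 <- exp_kernel(2, dt = 1e-3, horizon = 20)
  expect_equal(k0$values, e0$values, tolerance = 1e-12)
  for (kk in c(1, 3, 7)) {
    ik <- iterated_exp_kernel(1.5, kk, dt = 1e-3, horizon = 60)
    expect_equal(kernel_l1_norm(ik), 1, tolerance = 1e-5)
    expect_equal(ik$t[which.max(ik$values)], kk / 1.5, tolerance = 1e-2)
  }
  expect_error(iterated_exp_kernel(1, 100), "64")
})

test_that("temporal profiles are even for k = q and lag-shifted for k > q", {
  even <- temporal_profile(1, 2, 2, dt = 0.01, horizon = 50)
  expect_lt(max(abs(even$values - rev(even$values))), 1e-12)
  expect_equal(even$integral, 1, tolerance = 1e-4)

  skew <- temporal_profile(1, 3, 0, dt = 0.01, horizon = 50)
  expect_gt(skew$t[which.max(skew$values)], 0)
  expect_equal(skew$integral, 1, tolerance = 1e-4)
})

test_that("damped kernels v and w integrate to one on both branches", {
  # overdamped: 4l <= beta, real Delta; kernels are nonnegative
  dk <- damped_kernels(0.5, 4, 1, dt = 1e-3, horizon = 80)
  expect_equal(dk$v$integral, 1, tolerance = 1e-5)
  expect_equal(dk$w$integral, 1, tolerance = 1e-5)
  expect_true(all(dk$v$values >= 0))
  expect_equal(kernel_l1_norm(dk$v), 1, tolerance = 1e-5)

  # oscillatory: 4l > beta; v changes sign, L1 norm is coth(pi / 2|Delta|)
  dko <- damped_kernels(1, 1, 1, dt = 5e-4)
  expect_equal(dko$v$integral, 1, tolerance = 1e-5)
  expect_equal(dko$w$integral, 1, tolerance = 1e-5)
  expect_true(any(dko$v$values < 0))
  expect_equal(kernel_l1_norm(dko$v), 1 / tanh(pi / (2 * sqrt(3))),
               tolerance = 1e-5)

  # confluent branch Delta = 0 agrees with the limit of nearby branches
  dcc <- damped_kernels(1, 4, 1, dt = 1e-3, horizon = 40)
  dcn <- damped_kernels(1, 4 + 1e-7, 1, dt = 1e-3, horizon = 40)
  expect_lt(max(abs(dcc$v$values - dcn$v$values)), 1e-6)
  expect_lt(max(abs(dcc$w$values - dcn$w$values)), 1e-6)
  expect_equal(dcc$v$integral, 1, tolerance = 1e-5)
})

test_that("transfer functions of v and w have unit DC gain", {
  for (cfg in list(c(1, 1), c(0.5, 4), c(1, 4))) {
    dk <- damped_kernels(cfg[1], cfg[2], 1.3)
    expect_equal(dk$v$freq_response(0), 1 + 0i, tolerance = 1e-12)
    expect_equal(dk$w$freq_response(0), 1 + 0i, tolerance = 1e-12)
  }
})

test_that("Bessel closed form of iterated damped kernels matches convolution", {
  for (cfg in list(c(1, 1), c(0.5, 4))) {
    l <- cfg[1]; beta <- cfg[2]
    dt <- 5e-4
    v1 <- damped_kernels(l, beta, 1, dt = dt, horizon = 60)$v
    v2 <- iterated_damped_kernel(l, beta, 1, 2, dt = dt, horizon = 60)
    conv <- plastav:::conv_trapz(v1$values, v1$values, dt)[seq_along(v1$t)]
    expect_lt(max(abs(v2$values - conv)), 1e-6 * max(abs(conv)))
  }
  # k = 1 is v itself
  v1 <- damped_kernels(1, 1, 2, dt = 1e-3, horizon = 60)$v
  vk1 <- iterated_damped_kernel(1, 1, 2, 1, dt = 1e-3, horizon = 60)
  expect_lt(max(abs(v1$values - vk1$values)), 1e-10)
})

test_that("the filter identity w * v_k * g_{beta/mu} = v_{k+1} holds", {
  l <- 1; beta <- 1; mu <- 1.3
  dt <- 1e-3; hor <- 60
  dk <- damped_kernels(l, beta, mu, dt = dt, horizon = hor)
  g <- exp_kernel(beta / mu, dt = dt, horizon = hor)
  nt <- length(dk$v$t)
  v2 <- iterated_damped_kernel(l, beta, mu, 2, dt = dt, horizon = hor)
  lhs <- plastav:::conv_trapz(dk$w$values, dk$v$values, dt)[1:nt]
  lhs <- plastav:::conv_trapz(lhs, g$values[1:nt], dt)[1:nt]
  expect_lt(max(abs(lhs - v2$values)), 1e-6 * max(abs(v2$values)))
})

test_that("exponential correlation identity (two-sided kernel) holds", {
  # (g_gamma + g_gamma') / 2 viewed as a two-sided kernel equals the
  # correlation g_gamma star g_gamma = gamma/2 e^{-gamma |t|}
  gam <- 1.7
  dt <- 1e-4
  g <- exp_kernel(gam, dt = dt)
  z <- plastav:::corr_trapz(g$values, g$values, dt)
  tt <- seq(-max(g$t), max(g$t), by = dt)
  expect_lt(max(abs(z - gam / 2 * exp(-gam * abs(tt)))), 1e-8)
})

test_that("reversal-difference identity holds in the frequency domain", {
  # g' - g = (1/gamma) d/dt (g' + g): checked at 100 frequencies via
  # numerically integrated Fourier transforms of the sampled kernel
  gam <- 2.3
  g <- exp_kernel(gam, dt = 1e-4)
  xi <- seq(-5, 5, length.out = 100)
  num_ft <- vapply(xi, function(x) {
    v <- g$values * exp(-2i * pi * x * g$t)
    plastav:::trapz_signed(Re(v), g$dt) + 1i * plastav:::trapz_signed(Im(v), g$dt)
  }, complex(1))
  lhs <- Conj(num_ft) - num_ft
  rhs <- (2i * pi * xi / gam) * (Conj(num_ft) + num_ft)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("periodic filtering is exact in the Fourier domain", {
  # constant signal through any unit-integral kernel is unchanged
  uc <- periodic_input(matrix(2.5, 1, 64), tau = 1)
  expect_equal(apply_filter_periodic(uc, exp_kernel(4))$samples,
               uc$samples, tolerance = 1e-12)

  # sinusoid through g_gamma: amplitude gain and phase lag match closed form
  u <- make_sinusoid_input(1, tau = 2)
  g <- exp_kernel(3)
  uf <- apply_filter_periodic(u, g)
  om <- 2 * pi / 2
  expect_equal(max(abs(uf$samples)), 3 / sqrt(9 + om^2), tolerance = 1e-9)
  closed <- 3 / sqrt(9 + om^2) * sin(om * u$grid - atan(om / 3))
  expect_equal(uf$samples[1, ], closed, tolerance = 1e-9)

  # zero in, zero out
  expect_equal(max(abs(apply_filter_periodic(zero_input(2), g)$samples)), 0)
})

test_that("fast exponential filters converge to the identity", {
  u <- make_sinusoid_input(2, tau = 2, amplitudes = c(1, 0.5))
  uf <- apply_filter_periodic(u, exp_kernel(1000))
  rel <- sqrt(sum((uf$samples - u$samples)^2) / sum(u$samples^2))
  expect_lt(rel, 0.01)
})

test_that("Young bound: L1 norm of self-convolutions is submultiplicative", {
  v <- damped_kernels(1, 1, 1, dt = 1e-3, horizon = 80)$v
  l1v <- kernel_l1_norm(v)
  for (k in 2:4) {
    vk <- iterated_damped_kernel(1, 1, 1, k, dt = 1e-3, horizon = 80)
    expect_lte(kernel_l1_norm(vk), l1v^k + 1e-6)
  }
})
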