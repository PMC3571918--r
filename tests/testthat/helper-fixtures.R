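# Shared fixtures: all inputs and matrices are generated in code under fixed
# seeds; nothing is read from disk.

# symmetric PSD matrix with spectral norm frac * l (admissible for the
# hebbian / trace averaged dynamics)
rand_admissible_W <- function(n, l, frac = 0.3, seed = 1) {
  set.seed(seed)
  S <- matrix(rnorm(n * n), n, n)
  S <- S %*% t(S)
  S / max(eigen(S, symmetric = TRUE, only.values = TRUE)$values) * frac * l
}

# generic (possibly asymmetric) matrix with spectral norm frac * l
rand_general_W <- function(n, l, frac = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  A / sqrt(max(Re(eigen(A %*% t(A), only.values = TRUE)$values))) * frac * l
}

frob <- function(M) sqrt(sum(M^2))

zero_input <- function(n, M = 64L, tau = 1) {
  periodic_input(matrix(0, n, M), tau)
}

two_pattern_input <- function(n, seed = 5, M = 2048L, tau = 2, amp = 1) {
  u <- make_pattern_input(n, 2, durations = rep(tau / 2, 2), M = M,
                          seed = seed, orthogonalize = TRUE)
  if (amp != 1) u <- periodic_input(u$samples * amp, u$tau) else u
}

params_for_rule <- function(rule, n = 4, l = 2, kappa = 3, sigma = 0.3,
                            mu = 0.7) {
  switch(rule,
    hebbian = make_params(rule = "hebbian", n = n, l = l, kappa = kappa,
                          sigma = sigma, mu = mu),
    trace = make_params(rule = "trace", n = n, l = l, kappa = kappa,
                        sigma = sigma, mu = mu, beta = 1.5),
    stdp = make_params(rule = "stdp", n = n, l = l, kappa = kappa,
                       sigma = sigma, mu = mu, gamma = 2,
                       a_plus = 1, a_minus = 0.5))
}
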