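# Periodic attractor of the frozen fast dynamics and the direct
# (attractor-based) evaluation of the correlation term.

# angular frequencies of the harmonics on the fast time-scale
fast_omegas <- function(input, mu) {
  2 * pi * mu * fourier_harmonics(input$M) / input$tau
}

# transfer of the exponential filter at angular frequency omega
gexp_angular <- function(rate, omega) rate / (rate + 1i * omega)

# Fourier coefficients of the attractor; optionally post-filtered by the
# rule's activity filter.  Returns an n x M complex matrix.
attractor_fourier <- function(W, params, input) {
  n <- params$n
  A <- W - diag(params$l, n)
  omega <- fast_omegas(input, params$mu)
  if (params$rule == "trace") {
    aug <- rbind(cbind(matrix(0, n, n), A),
                 cbind(diag(params$beta, n), diag(-params$beta, n)))
    if (max(Re(eigen(aug, only.values = TRUE)$values)) >= 0) {
      stop("frozen fast system unstable: filtered dynamics not contracting")
    }
    gb <- gexp_angular(params$beta, omega)
  } else {
    if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0) {
      stop("frozen fast system unstable: spectral abscissa of W - L is >= 0")
    }
    gb <- rep(1 + 0i, input$M)
  }
  ev <- eigen(A)
  V <- ev$vectors
  Ct <- solve(V, input$fourier)            # n x M
  denom <- outer(ev$values, gb, function(lam, g) -lam * g) +
    matrix(1i * omega, n, input$M, byrow = TRUE)
  if (min(abs(denom)) < 1e-12) {
    stop("singular resolvent at a harmonic: frozen fast system unstable")
  }
  V %*% (Ct / denom)
}

#' Periodic attractor of the frozen fast system
#'
#' For a frozen connectivity W, the fast activity settles onto the unique
#' \eqn{\tau/\mu}-periodic attractor of \eqn{d\bar v/dt = (W - L)\bar v +
#' u(\mu t)} (Hebbian/STDP) or \eqn{d\bar v/dt = (W - L)(\bar v \ast g_\beta)
#' + u(\mu t)} (trace).  The solve is done per harmonic:
#' \eqn{\hat v_k = (i\omega_k I - (W - L)\hat g(\omega_k))^{-1}\hat u_k} with
#' \eqn{\omega_k = 2\pi k \mu/\tau}.
#'
#' @param W frozen `n x n` connectivity (spectral abscissa of `W - L` must be
#'   negative).
#' @param params a [make_params] object.
#' @param input a [periodic_input] (period tau on the input time-scale).
#' @return a [periodic_input] of period `tau / mu` holding the attractor.
#' @examples
#' p <- make_params(rule = "hebbian", n = 1, l = 1, kappa = 1, sigma = 0)
#' u <- make_sinusoid_input(1, tau = 2 * pi)
#' vb <- periodic_attractor(matrix(0, 1, 1), p, u)
#' # closed form: (sin(mu t) - mu cos(mu t)) / (1 + mu^2), here mu = 1
#' @export
periodic_attractor <- function(W, params, input) {
  vf <- attractor_fourier(W, params, input)
  periodic_input_from_fourier(force_real_nyquist(vf),
                              input$tau / params$mu)
}

# activity post-filter entering the learning rule, per harmonic
rule_postfilter <- function(params, omega) {
  switch(params$rule,
         hebbian = rep(1 + 0i, length(omega)),
         trace = gexp_angular(params$beta, omega),
         stdp = rep(1 + 0i, length(omega)))
}

#' Correlation term of the averaged field (direct evaluation)
#'
#' The period-average of the learning rule's activity outer product along the
#' frozen-W periodic attractor, computed from the attractor's Fourier
#' coefficients (Parseval):
#' \itemize{
#'   \item hebbian: \eqn{\frac{\mu}{\tau}\int \bar v \bar v' }
#'   \item trace:   \eqn{\frac{\mu}{\tau}\int (\bar v \ast g_\beta)(\bar v
#'     \ast g_\beta)'}
#'   \item stdp:    \eqn{\frac{\mu}{\tau}\int a_+ \bar v (\bar v \ast
#'     g_\gamma)' - a_- (\bar v \ast g_\gamma) \bar v'}
#' }
#' Hebbian and trace results are symmetric positive semidefinite Gramians.
#'
#' @inheritParams periodic_attractor
#' @return an `n x n` matrix.
#' @export
correlation_term_direct <- function(W, params, input) {
  vf <- attractor_fourier(W, params, input)
  omega <- fast_omegas(input, params$mu)
  if (params$rule == "stdp") {
    gg <- gexp_angular(params$gamma, omega)
    s <- params$a_plus * Conj(gg) - params$a_minus * gg
    return(Re(sweep(vf, 2, s, "*") %*% Conj(t(vf))))
  }
  pf <- rule_postfilter(params, omega)
  x <- sweep(vf, 2, pf, "*")
  Re(x %*% Conj(t(x)))
}
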