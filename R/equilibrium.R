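# Equilibrium connectivity: fixed-point solver, weak connectivity index,
# weakly connected expansions (orders 1-2), STDP symmetric/antisymmetric
# decomposition.

#' Weak connectivity index and noise/input ratio
#'
#' The small parameter controlling the weakly connected expansion of the
#' equilibrium connectivity, and the ratio of its noise and input parts:
#' \describe{
#'   \item{hebbian / trace}{\eqn{\tilde p = \frac{u_m^2}{\kappa l^3} +
#'     \frac{\sigma^2}{2\kappa l^2}},\; \eqn{\lambda =
#'     \frac{\sigma^2 l}{2 u_m^2}}}
#'   \item{stdp}{\eqn{\tilde p = \frac{|a_+|+|a_-|}{\kappa l^3}
#'     \left(\frac{s^2}{2}(\frac1l + \frac1\gamma) + u_m^2\right)},\;
#'     \eqn{\lambda = \frac{s^2}{2 u_m^2}(\frac1l + \frac1\gamma)}}
#' }
#'
#' @param params a [make_params] object.
#' @param input a [periodic_input] with `u_m > 0`.
#' @return a list with `p_tilde` and `lam`.
#' @export
weak_connectivity_index <- function(params, input) {
  u_m <- input$u_m
  if (u_m <= 0) stop("u_m = 0: weak connectivity index undefined")
  p <- params
  if (p$rule == "stdp") {
    amp <- abs(p$a_plus) + abs(p$a_minus)
    p_tilde <- amp / (p$kappa * p$l^3) *
      (p$s2 / 2 * (1 / p$l + 1 / p$gamma) + u_m^2)
    lam <- p$s2 / (2 * u_m^2) * (1 / p$l + 1 / p$gamma)
  } else {
    sig2 <- p$s2
    p_tilde <- u_m^2 / (p$kappa * p$l^3) + sig2 / (2 * p$kappa * p$l^2)
    lam <- sig2 * p$l / (2 * u_m^2)
  }
  list(p_tilde = p_tilde, lam = lam)
}

#' Equilibrium of the averaged connectivity dynamics
#'
#' Solves \eqn{\bar G(W^*) = 0} by damped Picard iteration on the fixed-point
#' form \eqn{W = F(W)/\kappa} (F = correlation + noise), which the
#' contraction certificate ([contraction_condition]) guarantees to converge
#' from any admissible start.
#'
#' @param field an [averaged_field].
#' @param tol convergence tolerance: stop when \eqn{\|\bar G(W)\|_F <
#'   \mathrm{tol}\,\kappa\,\max(\|W\|_F, 10^{-9} l)}.
#' @param max_iter iteration cap.
#' @param W0 starting matrix (default 0).
#' @param damping relaxation weight on the new iterate (default 0.8).
#' @return the equilibrium `n x n` matrix, with the final residual attached
#'   as attribute `"residual"`.
#' @export
solve_equilibrium <- function(field, tol = 1e-12, max_iter = 500L, W0 = NULL,
                              damping = 0.8) {
  p <- field$params
  n <- p$n
  W <- if (is.null(W0)) matrix(0, n, n) else W0
  res <- Inf
  for (it in seq_len(max_iter)) {
    parts <- averaged_rhs(W, field)
    res <- sqrt(sum(parts$total^2))
    if (res < tol * p$kappa * max(sqrt(sum(W^2)), 1e-9 * p$l)) {
      attr(W, "residual") <- res
      attr(W, "iterations") <- it
      return(W)
    }
    Fw <- parts$correlation + parts$noise
    W <- (1 - damping) * W + damping * Fw / p$kappa
  }
  stop("no convergence in ", max_iter, " iterations; last residual ",
       format(res))
}

#' Weakly connected expansion of the equilibrium connectivity
#'
#' Assembles the order-1 and order-2 terms of the expansion of \eqn{W^*} in
#' the weak connectivity index \eqn{\tilde p}:
#' \describe{
#'   \item{hebbian}{\eqn{W^* = \frac{\tilde p\,l}{1+\lambda}(\lambda I +
#'     C_{0,0}) + \frac{\tilde p^2 l}{(1+\lambda)^2}(\lambda^2 I +
#'     \lambda(C_{0,0} + C_{1,0} + C_{0,1}) + C_{0,0}C_{1,0} +
#'     C_{0,1}C_{0,0}) + O(\tilde p^3)}}
#'   \item{trace}{the same structure with \eqn{\tilde C_{k,q}} and explicit
#'     \eqn{\|v\|_1} powers (the expansion runs in orders of
#'     \eqn{\tilde p\|v\|_1})}
#'   \item{stdp}{\eqn{W^* = \frac{\tilde p\,l}{1+\lambda}
#'     (\lambda(\alpha_+-\alpha_-)\frac{\Sigma\Sigma'}{s^2} + D_{0,0}) +
#'     \tilde p^2 l\,\Omega_1 + O(\tilde p^3)} with \eqn{\Omega_1}
#'     assembled from the first-order correlation and noise corrections
#'     (see the methods vignette); the noise normalisation d is taken to be
#'     \eqn{s^2 = \|\Sigma\Sigma'\|}.}
#' }
#' For stdp the first order is additionally split into symmetric and
#' antisymmetric parts S and A (see [stdp_sym_antisym]).
#'
#' @param params a [make_params] object (its `rule` selects the expansion).
#' @param input a [periodic_input].
#' @param family optionally a precomputed [correlation_family] with
#'   `K >= 1`; built on the fly otherwise.
#' @param order 1 or 2.
#' @param solve if `TRUE` (default), also compute the numerical fixed point
#'   `W_numeric` from the direct-mode field for comparison.
#' @return an object of class `expansion_result` with fields `p_tilde`,
#'   `lam`, `order1`, `order2`, `W_expansion`, `W_numeric`, `rule`, and for
#'   stdp `S`, `A`, `alpha_plus`, `alpha_minus`.
#' @export
equilibrium_expansion <- function(params, input, family = NULL, order = 2L,
                                  solve = TRUE) {
  if (order > 2) stop("expansion orders above 2 are not supported")
  if (is.null(family)) family <- correlation_family(params, input, K = max(1L, order - 1L))
  if (family$K < order - 1L) stop("family truncation K too small for this order")
  idx <- weak_connectivity_index(params, input)
  pt <- idx$p_tilde
  lam <- idx$lam
  if (pt >= 0.2) {
    warning("weak connectivity index p_tilde = ", format(pt),
            " is not small; the expansion may be inaccurate")
  }
  l <- params$l
  n <- params$n
  Id <- diag(1, n)
  C00 <- family$mats[[1, 1]]
  rule <- params$rule
  S <- A <- NULL
  alpha_p <- alpha_m <- NULL
  if (rule == "hebbian") {
    Omega0 <- (lam * Id + C00) / (1 + lam)
    order1 <- pt * l * Omega0
    order2 <- NULL
    if (order >= 2) {
      C10 <- family$mats[[2, 1]]
      C01 <- family$mats[[1, 2]]
      Omega1 <- (lam * Omega0 + Omega0 %*% C10 + C01 %*% Omega0) / (1 + lam)
      order2 <- pt^2 * l * Omega1
    }
  } else if (rule == "trace") {
    nv <- family$v_l1
    Omega0 <- (lam * Id + nv^2 * C00) / (1 + lam)
    order1 <- pt * l * Omega0
    order2 <- NULL
    if (order >= 2) {
      C10 <- family$mats[[2, 1]]
      C01 <- family$mats[[1, 2]]
      Omega1 <- (lam * Omega0 + nv^3 * (Omega0 %*% C10 + C01 %*% Omega0)) /
        (1 + lam)
      order2 <- pt^2 * l * Omega1
    }
  } else { # stdp
    amp <- abs(params$a_plus) + abs(params$a_minus)
    alpha_p <- params$a_plus / amp
    alpha_m <- params$a_minus / amp
    Mn <- params$Sigma %*% t(params$Sigma) / params$s2
    D00 <- C00
    Omega0 <- (lam * (alpha_p - alpha_m) * Mn + D00) / (1 + lam)
    order1 <- pt * l * Omega0
    order2 <- NULL
    if (order >= 2) {
      D10 <- family$mats[[2, 1]]
      D01 <- family$mats[[1, 2]]
      gl <- 1 + params$gamma / params$l
      F1 <- Omega0 %*% D10 + D01 %*% t(Omega0)
      Q1 <- (alpha_p - alpha_m) / 2 * (Omega0 %*% Mn + Mn %*% t(Omega0)) +
        (alpha_p * Omega0 %*% Mn - alpha_m * Mn %*% t(Omega0)) / gl
      Omega1 <- (F1 + lam * Q1) / (1 + lam)
      order2 <- pt^2 * l * Omega1
    }
    sa <- stdp_sym_antisym(params, input)
    S <- sa$S
    A <- sa$A
  }
  W_exp <- order1 + if (is.null(order2)) 0 else order2
  W_num <- NULL
  if (solve) {
    W_num <- solve_equilibrium(averaged_field(params, input, mode = "direct"))
  }
  structure(list(rule = rule, p_tilde = pt, lam = lam,
                 order1 = order1, order2 = order2, W_expansion = W_exp,
                 W_numeric = W_num, S = S, A = A,
                 alpha_plus = alpha_p, alpha_minus = alpha_m),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("<expansion_result>", x$rule, " p_tilde =", format(x$p_tilde),
      " lambda =", format(x$lam), "\n")
  if (!is.null(x$W_numeric)) {
    err <- sqrt(sum((x$W_numeric - x$W_expansion)^2)) /
      max(sqrt(sum(x$W_numeric^2)), .Machine$double.eps)
    cat("  relative Frobenius error vs numerical fixed point:",
        format(err), "\n")
  }
  invisible(x)
}

#' Symmetric / antisymmetric decomposition of the STDP equilibrium
#'
#' The first-order STDP equilibrium splits into a symmetric Hebbian-like
#' part and an antisymmetric causal part,
#' \deqn{S = (a_+ - a_-)\,(u \ast g_{l/\mu} \ast g_{\gamma/\mu})\cdot(u \ast
#'   g_{l/\mu} \ast g_{\gamma/\mu})'}
#' \deqn{A = \frac{(a_+ + a_-)\mu}{\gamma}\,(\dot u \ast g_{l/\mu} \ast
#'   g_{\gamma/\mu})\cdot(u \ast g_{l/\mu} \ast g_{\gamma/\mu})',}
#' the cross-correlation of the filtered input with itself (S) and with its
#' time derivative (A).  They reconstruct the first correlation matrix as
#' \eqn{S + A = u_m^2\tau(|a_+|+|a_-|) D_{0,0}}.
#'
#' @param params an stdp [make_params] object.
#' @param input a [periodic_input] (differentiated spectrally).
#' @return a list with the symmetric matrix `S` and antisymmetric matrix `A`.
#' @export
stdp_sym_antisym <- function(params, input) {
  if (params$rule != "stdp") stop("'params' must use the stdp rule")
  xi <- fourier_harmonics(input$M) / input$tau
  rl <- params$l / params$mu
  rg <- params$gamma / params$mu
  g2 <- (rl / (rl + 2i * pi * xi)) * (rg / (rg + 2i * pi * xi))
  U <- sweep(input$fourier, 2, g2, "*")
  Ud <- sweep(U, 2, 2i * pi * xi, "*")   # derivative in the Fourier domain
  tau <- input$tau
  S <- (params$a_plus - params$a_minus) * tau * Re(U %*% Conj(t(U)))
  A <- (params$a_plus + params$a_minus) * params$mu / params$gamma * tau *
    Re(Ud %*% Conj(t(U)))
  list(S = S, A = A)
}
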