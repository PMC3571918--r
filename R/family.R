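# Filtered input-correlation families C_{k,q} (hebbian), C~_{k,q} (trace),
# D_{k,q} (stdp), built in the Fourier domain.

#' Filtered input-correlation family
#'
#' Builds the normalised lagged input-correlation matrices entering the
#' series form of the averaged correlation term:
#' \describe{
#'   \item{hebbian}{\eqn{C_{k,q} = \frac{1}{u_m^2\tau}(u \ast
#'     g_{l/\mu}^{(k+1)})\cdot(u \ast g_{l/\mu}^{(q+1)})'}}
#'   \item{trace}{\eqn{\tilde C_{k,q} = \frac{1}{u_m^2\tau\|v\|_1^{k+q+2}}
#'     (u \ast v^{(k+1)})\cdot(u \ast v^{(q+1)})'} with the damped kernel v}
#'   \item{stdp}{\eqn{D_{k,q} = \frac{1}{u_m^2\tau(|a_+|+|a_-|)}(u \ast
#'     g_{l/\mu}^{(k+1)} \ast (a_+ g_{\gamma/\mu}' - a_- g_{\gamma/\mu}))
#'     \cdot(u \ast g_{l/\mu}^{(q+1)})'}}
#' }
#' All products are evaluated exactly per harmonic (Parseval).  Young's
#' inequality guarantees every matrix has (entrywise L2, hence also spectral)
#' norm at most 1; this bound is asserted at build time.
#'
#' @param params a [make_params] object.
#' @param input a [periodic_input] with `u_m > 0`.
#' @param K truncation order: matrices are built for all `0 <= k, q <= K`.
#' @return an object of class `correlation_family` with fields `rule`, `K`,
#'   `mats` (a `(K+1) x (K+1)` list-matrix of `n x n` matrices), `u_m`,
#'   `tau`, `v_l1`, `norms`.
#' @export
correlation_family <- function(params, input, K = 4L) {
  if (K < 0 || K != round(K)) stop("'K' must be a non-negative integer")
  if (input$u_m <= 0) stop("input is identically zero: normalisation by u_m undefined")
  n <- params$n
  M <- input$M
  xi <- fourier_harmonics(M) / input$tau
  v_l1 <- 1
  if (params$rule == "trace") {
    base <- damped_freq_response(params$l, params$beta, params$mu, "v")(xi)
    v_l1 <- v_l1_closed(params)
  } else {
    rate <- params$l / params$mu
    base <- rate / (rate + 2i * pi * xi)
  }
  # A_k = u-hat filtered by base^(k+1), k = 0..K
  Ak <- vector("list", K + 1L)
  filt <- rep(1 + 0i, M)
  for (k in 0:K) {
    filt <- filt * base
    Ak[[k + 1L]] <- sweep(input$fourier, 2, filt, "*")
  }
  left_extra <- NULL
  norm_c <- input$u_m^2
  if (params$rule == "stdp") {
    rate_g <- params$gamma / params$mu
    gg <- rate_g / (rate_g + 2i * pi * xi)
    left_extra <- params$a_plus * Conj(gg) - params$a_minus * gg
    norm_c <- norm_c * (abs(params$a_plus) + abs(params$a_minus))
  }
  mats <- vector("list", (K + 1L)^2)
  dim(mats) <- c(K + 1L, K + 1L)
  norms <- matrix(0, K + 1L, K + 1L)
  for (k in 0:K) {
    left <- Ak[[k + 1L]]
    if (!is.null(left_extra)) left <- sweep(left, 2, left_extra, "*")
    for (q in 0:K) {
      Cm <- Re(left %*% Conj(t(Ak[[q + 1L]]))) / (norm_c * v_l1^(k + q + 2))
      mats[[k + 1L, q + 1L]] <- Cm
      norms[k + 1L, q + 1L] <- sqrt(sum(Cm^2))
    }
  }
  if (max(norms) > 1 + 1e-8) {
    stop("internal error: correlation matrix norm exceeds the Young bound")
  }
  structure(list(rule = params$rule, K = as.integer(K), mats = mats,
                 u_m = input$u_m, tau = input$tau, v_l1 = v_l1,
                 norms = norms, n = n),
            class = "correlation_family")
}

#' @export
print.correlation_family <- function(x, ...) {
  cat("<correlation_family>", x$rule, " K =", x$K, " n =", x$n,
      " max norm =", format(max(x$norms)), "\n")
  invisible(x)
}

#' Correlation term of the averaged field (series evaluation)
#'
#' Evaluates the weakly connected series
#' \eqn{\frac{u_m^2}{l^2}\sum_{k,q} \frac{W^k}{l^k} C_{k,q}
#' \frac{W'^q}{l^q}} (hebbian; trace and stdp analogues carry
#' \eqn{\|v\|_1} and \eqn{|a_+|+|a_-|} factors) truncated at the family's
#' order K.  Requires the spectral norm of W below \eqn{l} (hebbian/stdp) or
#' \eqn{l/\|v\|_1} (trace) for convergence; a geometric tail estimate is
#' attached as attribute `"tail_bound"`.
#'
#' @param W connectivity matrix.
#' @param family a [correlation_family].
#' @param params the matching [make_params] object.
#' @return an `n x n` matrix with attribute `tail_bound`.
#' @export
correlation_term_series <- function(W, family, params) {
  l <- params$l
  scale <- family$v_l1 / l   # W enters as (W ||v||_1 / l)^k; ||v||_1 = 1 otherwise
  rho <- sqrt(max(0, max(Re(eigen(W %*% t(W), only.values = TRUE)$values)))) * scale
  if (rho >= 1) {
    stop("series precondition violated: spectral norm of W too large (",
         format(rho), " >= 1 after scaling)")
  }
  K <- family$K
  n <- family$n
  Wp <- vector("list", K + 1L)
  Wp[[1L]] <- diag(1, n)
  for (k in seq_len(K)) Wp[[k + 1L]] <- Wp[[k]] %*% (W * scale)
  acc <- matrix(0, n, n)
  for (k in 0:K) {
    for (q in 0:K) {
      acc <- acc + Wp[[k + 1L]] %*% family$mats[[k + 1L, q + 1L]] %*% t(Wp[[q + 1L]])
    }
  }
  pref <- family$u_m^2 * family$v_l1^2 / l^2
  if (family$rule == "stdp") {
    pref <- family$u_m^2 * (abs(params$a_plus) + abs(params$a_minus)) / l^2
  }
  out <- pref * acc
  # geometric tail: sum over (k,q) with max(k,q) > K of rho^(k+q)
  tail <- if (rho > 0) {
    pref * (2 * rho^(K + 1) / ((1 - rho)^2) )
  } else 0
  attr(out, "tail_bound") <- tail
  out
}
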