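# Lyapunov equation solvers: a dense direct backend (Kronecker
# vectorisation) and the geometric-series backend valid for the
# leak-minus-connectivity structure A = L - W.

#' Solve the continuous Lyapunov equation A Q + Q A' + D = 0
#'
#' The stationary covariance of a linear diffusion \eqn{dc = -A c\,dt +
#' \Sigma dB} solves \eqn{A Q + Q A' = \Sigma\Sigma'}; this function solves
#' the equivalent homogeneous form \eqn{A Q + Q A' + D = 0} for any A with
#' no pair of eigenvalues summing to zero.
#'
#' Two backends are available: a dense direct solve of the Kronecker
#' vectorised system, and (for \eqn{A = L - W} with scalar leak matrix
#' \eqn{L = l\,\mathrm{Id}}) the geometric series
#' \eqn{Q = -\sum_{k\ge0} W^k D (2L - W')^{-(k+1)}}, convergent when
#' \eqn{\|W\|\,\|(2L - W)^{-1}\| < 1}.
#'
#' @param A an `n x n` matrix.
#' @param D an `n x n` matrix (typically a noise covariance).
#' @param method `"direct"` (default) or `"series"`.
#' @param l the scalar leak rate; required by the series backend, which
#'   interprets `A` as `l * I - W`.
#' @param tol residual tolerance for the returned solution (relative to
#'   `norm(D)`).
#' @return the `n x n` solution Q; an error is thrown if the residual
#'   `||A Q + Q A' + D||` exceeds `tol * ||D||`.
#' @examples
#' Q <- solve_lyapunov(diag(2, 3), -diag(0.1, 3))  # Q = 0.1/(2*2) * I
#' @export
solve_lyapunov <- function(A, D, method = c("direct", "series"), l = NULL,
                           tol = 1e-10) {
  method <- match.arg(method)
  n <- nrow(A)
  if (method == "direct") {
    ev <- eigen(A, only.values = TRUE)$values
    if (min(abs(outer(ev, ev, "+"))) < 1e-12 * max(1, max(abs(ev)))) {
      stop("Lyapunov equation degenerate: an eigenvalue pair of A sums to zero")
    }
    K <- kronecker(diag(1, n), A) + kronecker(A, diag(1, n))
    Q <- matrix(solve(K, -as.vector(D)), n, n)
  } else {
    if (is.null(l)) stop("series backend requires the leak rate 'l'")
    W <- diag(l, n) - A
    B <- solve(diag(2 * l, n) - t(W))
    nW <- sqrt(max(Re(eigen(W %*% t(W), only.values = TRUE)$values)))
    nB <- sqrt(max(Re(eigen(B %*% t(B), only.values = TRUE)$values)))
    if (nW * nB >= 1) {
      stop("series backend divergent: ||W|| ||(2L - W)^-1|| >= 1")
    }
    Q <- matrix(0, n, n)
    term <- -D %*% B
    k <- 0
    repeat {
      Q <- Q + term
      k <- k + 1
      term <- W %*% term %*% B
      if (max(abs(term)) < 1e-16 * max(1, max(abs(Q))) || k > 1000) break
    }
  }
  res <- A %*% Q + Q %*% t(A) + D
  nD <- sqrt(sum(D^2))
  if (sqrt(sum(res^2)) > tol * max(nD, .Machine$double.eps)) {
    stop("Lyapunov residual ", format(sqrt(sum(res^2))),
         " exceeds tolerance")
  }
  Q
}

#' Noise term of the averaged field
#'
#' The stationary-covariance contribution of the fast noise to the averaged
#' connectivity drift:
#' \itemize{
#'   \item hebbian / trace: \eqn{Q = \frac{\sigma^2}{2}(L - W)^{-1}}
#'     (requires symmetric W with spectral norm below l);
#'   \item stdp: solve \eqn{(W-L) Q_{11} + Q_{11}(W'-L) + \Sigma\Sigma' = 0},
#'     set \eqn{Q_{12} = \gamma Q_{11}(L + \gamma - W')^{-1}} and return
#'     \eqn{a_+ Q_{12}' - a_- Q_{12}}.
#' }
#'
#' @param W connectivity matrix (admissible for the rule).
#' @param params a [make_params] object.
#' @return an `n x n` matrix.
#' @export
noise_term <- function(W, params) {
  n <- params$n
  L <- diag(params$l, n)
  nW <- sqrt(max(0, max(Re(eigen(W %*% t(W), only.values = TRUE)$values))))
  if (nW >= params$l) {
    stop("inadmissible W: spectral norm ", format(nW), " >= l")
  }
  if (params$rule %in% c("hebbian", "trace")) {
    if (max(abs(W - t(W))) > 1e-8 * max(1, nW)) {
      stop("inadmissible W: hebbian/trace noise term requires symmetric W")
    }
    sig2 <- if (is.na(params$sigma)) {
      # scalar noise is the assumption of these rules; fall back to s2
      params$s2
    } else params$sigma^2
    return(sig2 / 2 * solve(L - W))
  }
  SS <- params$Sigma %*% t(params$Sigma)
  Q11 <- solve_lyapunov(L - W, -SS)
  Q12 <- params$gamma * Q11 %*% solve(L + diag(params$gamma, n) - t(W))
  params$a_plus * t(Q12) - params$a_minus * Q12
}
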