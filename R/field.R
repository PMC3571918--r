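# Assembly and integration of the averaged deterministic connectivity ODE
#   dW/dt = -kappa W + correlation(W) + noise(W).

#' Averaged connectivity vector field
#'
#' Bundles parameters, input and (for series mode) a precomputed
#' [correlation_family] into the averaged deterministic field
#' \deqn{\bar G(W) = -\kappa W + \mathrm{correlation}(W) +
#'   \mathrm{noise}(W),}
#' the decay / input-correlation / noise decomposition of the averaged slow
#' dynamics.  `mode = "direct"` evaluates the correlation term from the
#' periodic attractor of the frozen fast system (exact); `mode = "series"`
#' uses the truncated weakly connected series (order `K`).
#'
#' @param params a [make_params] object.
#' @param input a [periodic_input].
#' @param mode `"direct"` (default) or `"series"`.
#' @param K series truncation order (default 4), used when
#'   `mode = "series"` (the family is built lazily otherwise).
#' @return an object of class `averaged_field`.
#' @export
averaged_field <- function(params, input, mode = c("direct", "series"),
                           K = 4L) {
  mode <- match.arg(mode)
  family <- if (mode == "series") correlation_family(params, input, K) else NULL
  structure(list(params = params, input = input, mode = mode, K = K,
                 family = family),
            class = "averaged_field")
}

#' @export
print.averaged_field <- function(x, ...) {
  cat("<averaged_field>", x$params$rule, " mode =", x$mode,
      if (x$mode == "series") paste(" K =", x$K) else "", "\n")
  invisible(x)
}

#' Evaluate the averaged field at a connectivity
#'
#' Returns the three labelled components of the averaged drift (decay,
#' correlation, noise) and their sum.
#'
#' @param W connectivity matrix.
#' @param field an [averaged_field].
#' @return a list with components `decay`, `correlation`, `noise`, `total`
#'   (all `n x n` matrices) and, in series mode, `tail_bound`.
#' @export
averaged_rhs <- function(W, field) {
  p <- field$params
  decay <- -p$kappa * W
  if (field$mode == "direct") {
    corr <- correlation_term_direct(W, p, field$input)
    tail <- 0
  } else {
    corr <- correlation_term_series(W, field$family, p)
    tail <- attr(corr, "tail_bound")
    attr(corr, "tail_bound") <- NULL
  }
  noise <- noise_term(W, p)
  list(decay = decay, correlation = corr, noise = noise,
       total = decay + corr + noise, tail_bound = tail)
}

#' Integrate the averaged connectivity ODE
#'
#' Deterministic integration of \eqn{dW/dt = \bar G(W)} from `W0` (default:
#' the zero matrix, the conventional initial connectivity) with deSolve's
#' adaptive "lsoda" solver, sampled on a uniform grid.
#'
#' @param field an [averaged_field].
#' @param W0 initial connectivity (default 0).
#' @param T integration horizon in slow-time units.
#' @param dt output sampling step.
#' @param ... passed to [deSolve::ode].
#' @return a `trajectory` object (see [simulate_network]) with `W` an
#'   `n x n x nt` array.
#' @export
integrate_averaged <- function(field, W0 = NULL, T, dt, ...) {
  p <- field$params
  n <- p$n
  if (is.null(W0)) W0 <- matrix(0, n, n)
  rhs <- function(t, y, parms) {
    W <- matrix(y, n, n)
    nW <- sqrt(max(0, max(Re(eigen(W %*% t(W), only.values = TRUE)$values))))
    if (nW >= p$l) {
      stop("trajectory left the invariant set (spectral norm >= l); ",
           "check the admissibility certificate (check_assumption)")
    }
    list(as.vector(averaged_rhs(W, field)$total))
  }
  times <- seq(0, T, by = dt)
  sol <- deSolve::ode(y = as.vector(W0), times = times, func = rhs,
                      parms = NULL, ...)
  nt <- nrow(sol)
  Warr <- array(t(sol[, -1, drop = FALSE]), dim = c(n, n, nt))
  new_trajectory(times = sol[, 1], W = Warr,
                 meta = list(kind = "averaged", rule = p$rule,
                             mode = field$mode, dt = dt))
}
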