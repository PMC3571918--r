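#' Network and learning-rule parameters
#'
#' Assembles and validates the full scalar parameter set of a slow-fast
#' plasticity model: a recurrent network of `n` linear rate neurons with leak
#' rate `l`, driven by a periodic input and additive noise, whose connectivity
#' decays at rate `kappa` and is updated by one of three learning rules.
#'
#' The rules are
#' \describe{
#'   \item{`hebbian`}{instantaneous outer-product update \eqn{-\kappa W + v
#'     \otimes v}.}
#'   \item{`trace`}{the same update applied to exponentially low-pass filtered
#'     activity (filter rate `beta`); the activity itself is a damped
#'     oscillator when \eqn{4 l > \beta}.}
#'   \item{`stdp`}{temporally asymmetric update \eqn{-\kappa W + a_+\, v
#'     \otimes (v \ast g_\gamma) - a_-\, (v \ast g_\gamma) \otimes v} with an
#'     exponential window of rate `gamma` and amplitudes `a_plus`, `a_minus`.}
#' }
#'
#' Derived quantities are stored alongside: the discriminant
#' \eqn{\Delta = \sqrt{1 - 4l/\beta}} (with a branch flag: "overdamped" for
#' real \eqn{\Delta}, "oscillatory" for pure imaginary \eqn{\Delta}, i.e.
#' \eqn{4l > \beta}, and "critical" at the confluent point), and
#' \eqn{s^2 = \|\Sigma\Sigma'\|}, the largest eigenvalue of the noise
#' covariance.
#'
#' @param ... named parameter values, or a single named list.  Recognised
#'   names: `rule` (one of "hebbian", "trace", "stdp"), `n`, `l`, `kappa`,
#'   `mu` (time-scale ratio, default 1), `sigma` (scalar noise amplitude) or
#'   `Sigma` (an `n x n` noise matrix), `eps1`, `eps2` (time-scale separation,
#'   only used by the stochastic simulator; default `1e-3`), `beta` (trace
#'   rule), `gamma`, `a_plus`, `a_minus` (stdp rule).
#'
#' @return An object of class `model_params`.
#' @examples
#' p <- make_params(rule = "hebbian", n = 3, l = 12, kappa = 100,
#'                  sigma = 0.05, mu = 1)
#' p$s2            # 0.05^2
#' pt <- make_params(rule = "trace", n = 2, l = 1, kappa = 1, sigma = 0.1,
#'                   beta = 1)
#' pt$branch       # "oscillatory", |Delta| = sqrt(3)
#' @export
make_params <- function(...) {
  raw <- list(...)
  if (length(raw) == 1L && is.null(names(raw)) && is.list(raw[[1L]])) {
    raw <- raw[[1L]]
  }
  get_num <- function(name, default = NULL) {
    x <- raw[[name]]
    if (is.null(x)) return(default)
    if (!is.numeric(x)) stop("parameter '", name, "' must be numeric", call. = FALSE)
    x
  }
  need_pos <- function(x, name, strict = TRUE) {
    if (is.null(x)) stop("missing required parameter '", name, "'", call. = FALSE)
    if (length(x) != 1L || !is.finite(x)) {
      stop("parameter '", name, "' must be a finite scalar", call. = FALSE)
    }
    if (strict && x <= 0) stop("parameter '", name, "' must be > 0", call. = FALSE)
    if (!strict && x < 0) stop("parameter '", name, "' must be >= 0", call. = FALSE)
    x
  }

  rule <- raw$rule
  if (is.null(rule) || !rule %in% c("hebbian", "trace", "stdp")) {
    stop("'rule' must be one of \"hebbian\", \"trace\", \"stdp\"", call. = FALSE)
  }
  n <- get_num("n")
  if (is.null(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("parameter 'n' must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  l     <- need_pos(get_num("l"), "l")
  kappa <- need_pos(get_num("kappa"), "kappa")
  mu    <- need_pos(get_num("mu", 1), "mu")
  eps1  <- need_pos(get_num("eps1", 1e-3), "eps1")
  eps2  <- need_pos(get_num("eps2", eps1 / mu), "eps2")

  Sigma <- raw$Sigma
  sigma <- get_num("sigma")
  if (is.null(Sigma)) {
    if (is.null(sigma)) sigma <- 0
    sigma <- need_pos(sigma, "sigma", strict = FALSE)
    Sigma <- diag(sigma, n)
    s2 <- sigma^2
  } else {
    Sigma <- as.matrix(Sigma)
    if (!all(dim(Sigma) == n)) stop("'Sigma' must be an n x n matrix", call. = FALSE)
    s2 <- max(eigen(Sigma %*% t(Sigma), symmetric = TRUE,
                    only.values = TRUE)$values)
    sigma <- NA_real_
  }

  beta <- gamma <- a_plus <- a_minus <- NULL
  if (rule == "hebbian") {
    beta <- Inf
  } else if (rule == "trace") {
    beta <- need_pos(get_num("beta"), "beta")
  } else { # stdp
    gamma   <- need_pos(get_num("gamma"), "gamma")
    a_plus  <- get_num("a_plus")
    a_minus <- get_num("a_minus")
    if (is.null(a_plus) || is.null(a_minus)) {
      stop("stdp rule requires 'a_plus' and 'a_minus'", call. = FALSE)
    }
  }

  # discriminant of the damped-oscillator activity (trace rule)
  if (is.null(beta) || !is.finite(beta)) {
    disc <- 1
  } else {
    disc <- 1 - 4 * l / beta
  }
  branch <- if (abs(disc) < 1e-16) "critical" else if (disc < 0) "oscillatory" else "overdamped"
  delta_abs <- sqrt(abs(disc))
  delta_c <- sqrt(as.complex(disc))

  structure(list(
    rule = rule, n = n, l = l, kappa = kappa, mu = mu,
    eps1 = eps1, eps2 = eps2,
    sigma = sigma, Sigma = Sigma, s2 = s2,
    beta = beta, gamma = gamma, a_plus = a_plus, a_minus = a_minus,
    delta_abs = delta_abs, delta_c = delta_c, branch = branch
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> rule =", x$rule, "| n =", x$n, "\n")
  cat("  l =", x$l, " kappa =", x$kappa, " mu =", x$mu,
      " s2 =", format(x$s2), "\n")
  if (x$rule == "trace") {
    cat("  beta =", x$beta, " branch =", x$branch,
        " |Delta| =", format(x$delta_abs), "\n")
  }
  if (x$rule == "stdp") {
    cat("  gamma =", x$gamma, " a+ =", x$a_plus, " a- =", x$a_minus, "\n")
  }
  invisible(x)
}

# L1 norm of the damped kernel v, closed form (1 on the real/critical branch,
# coth(pi / (2|Delta|)) on the oscillatory branch).
v_l1_closed <- function(params) {
  if (params$branch == "oscillatory") {
    1 / tanh(pi / (2 * params$delta_abs))
  } else {
    1
  }
}
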