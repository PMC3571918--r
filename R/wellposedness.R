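# Admissibility and stability certificates: the invariant set E_p, the
# rule-specific admissibility inequalities, the contraction bound, and the
# scalar truncation example.

# left-hand side minus right-hand side of the admissibility inequality,
# negative where the assumption holds
admissibility_gap <- function(p, params, u_m) {
  l <- params$l
  kap <- params$kappa
  if (params$rule == "stdp") {
    amp <- abs(params$a_plus) + abs(params$a_minus)
    lhs <- amp / (p * (1 - p)) *
      (params$s2 * params$gamma / (2 * (1 + params$gamma / l - p)) +
         u_m^2 / (1 - p))
  } else {
    sig2 <- params$s2
    lhs <- sig2 * l / (2 * p * (1 - p)) + u_m^2 / (p * (1 - p)^2)
  }
  lhs - kap * l^3
}

#' Admissibility certificate for the averaged dynamics
#'
#' Determines for which \eqn{p \in (0,1)} the rule's admissibility
#' inequality holds, i.e. for which radii the set
#' \eqn{E_p = \{W \ \mathrm{symmetric},\ W \ge 0,\ \|W\| < p\,l\}} is
#' invariant under the averaged flow:
#' \itemize{
#'   \item hebbian / trace: \eqn{\frac{\sigma^2 l}{2 p(1-p)} +
#'     \frac{u_m^2}{p(1-p)^2} < \kappa l^3};
#'   \item stdp: \eqn{\frac{|a_+|+|a_-|}{p(1-p)}\Big(
#'     \frac{s^2\gamma}{2(1+\gamma/l-p)} + \frac{u_m^2}{1-p}\Big) <
#'     \kappa l^3}.
#' }
#' The admissible set is found by a dense scan over (0,1) with bisection
#' refinement of the boundaries.  Global stability (a unique, globally
#' attracting equilibrium) is certified when the assumption holds at the
#' rule-specific threshold: \eqn{p \le 1/3} (hebbian, stdp) or
#' \eqn{p \le 1/(2\|v\|_1^3 + 1)} (trace).
#'
#' @param params a [make_params] object.
#' @param input a [periodic_input], or a scalar taken directly as `u_m`.
#' @param n_scan scan resolution (default 1e4).
#' @return an object of class `wellposedness_report` with fields `rule`,
#'   `admissible_p_set` (two-column matrix of intervals), `assumption_ok`,
#'   `stability_ok`, `stability_threshold`, `P_coefficients` (the cubic
#'   boundary polynomial, hebbian/trace), and for the scalar truncation
#'   example `eta`, `w_minus`, `w_plus` (hebbian, n = 1, no input).
#' @export
check_assumption <- function(params, input, n_scan = 1e4) {
  u_m <- if (inherits(input, "periodic_input")) input$u_m else as.numeric(input)
  ps <- seq(1 / n_scan, 1 - 1 / n_scan, length.out = n_scan)
  gap <- vapply(ps, admissibility_gap, numeric(1), params = params, u_m = u_m)
  ok <- gap < 0
  # refine boundaries of admissible runs by bisection
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  intervals <- NULL
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    lo <- ps[starts[i]]
    hi <- ps[ends[i]]
    f <- function(p) admissibility_gap(p, params, u_m)
    if (starts[i] > 1) {
      lo <- stats::uniroot(f, c(ps[starts[i] - 1], ps[starts[i]]),
                           tol = 1e-12)$root
    } else if (f(1e-12) > 0) {
      lo <- stats::uniroot(f, c(1e-12, ps[1]), tol = 1e-12)$root
    }
    if (ends[i] < length(ps)) {
      hi <- stats::uniroot(f, c(ps[ends[i]], ps[ends[i] + 1]),
                           tol = 1e-12)$root
    } else if (f(1 - 1e-12) > 0) {
      hi <- stats::uniroot(f, c(ps[length(ps)], 1 - 1e-12), tol = 1e-12)$root
    }
    intervals <- rbind(intervals, c(lo, hi))
  }
  assumption_ok <- any(ok)
  thr <- if (params$rule == "trace") {
    1 / (2 * v_l1_closed(params)^3 + 1)
  } else 1 / 3
  stability_ok <- assumption_ok &&
    any(vapply(seq_len(NROW(intervals)), function(i) {
      intervals[i, 1] <= thr
    }, logical(1)))
  # boundary polynomial P(alpha) of the hebbian derivation
  P_coef <- if (params$rule != "stdp") {
    sig2 <- params$s2
    c(u_m^2 + params$l * sig2 / 2,
      -(params$kappa * params$l^2 + sig2 / 2),
      2 * params$kappa * params$l,
      -params$kappa)
  } else NULL
  scalar <- if (params$rule == "hebbian" && u_m == 0) {
    scalar_truncation_equilibria(params$l, params$kappa, sqrt(params$s2))
  } else NULL
  structure(list(rule = params$rule, u_m = u_m,
                 admissible_p_set = intervals,
                 assumption_ok = assumption_ok,
                 stability_ok = stability_ok,
                 stability_threshold = thr,
                 P_coefficients = P_coef,
                 scalar = scalar),
            class = "wellposedness_report")
}

#' @export
print.wellposedness_report <- function(x, ...) {
  cat("<wellposedness_report>", x$rule, "\n")
  if (is.null(x$admissible_p_set)) {
    cat("  admissible p set: empty\n")
  } else {
    for (i in seq_len(nrow(x$admissible_p_set))) {
      cat("  admissible p in (", format(x$admissible_p_set[i, 1]), ",",
          format(x$admissible_p_set[i, 2]), ")\n")
    }
  }
  cat("  assumption_ok:", x$assumption_ok,
      " stability_ok:", x$stability_ok,
      " (threshold p <=", format(x$stability_threshold), ")\n")
  invisible(x)
}

#' Membership in the invariant set E_p
#'
#' Checks (with margins) that W is symmetric (hebbian/trace only), positive
#' semidefinite, and has spectral norm strictly below `p * l`.
#'
#' @param W connectivity matrix.
#' @param p radius parameter in (0, 1).
#' @param params a [make_params] object.
#' @return a list with `inside` (logical) and per-criterion diagnostics
#'   `symmetry_defect`, `min_eigenvalue`, `spectral_margin`.
#' @export
invariant_set_check <- function(W, p, params) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  need_sym <- params$rule %in% c("hebbian", "trace")
  sym_defect <- max(abs(W - t(W)))
  Ws <- (W + t(W)) / 2
  ev <- eigen(Ws, symmetric = TRUE, only.values = TRUE)$values
  nW <- sqrt(max(0, max(Re(eigen(W %*% t(W), only.values = TRUE)$values))))
  margin <- p * params$l - nW
  tol <- 1e-9 * params$l
  inside <- (!need_sym || sym_defect <= tol) &&
    min(ev) >= -tol && margin > tol
  list(inside = inside, symmetry_defect = sym_defect,
       min_eigenvalue = min(ev), spectral_margin = margin)
}

#' Contraction certificate for uniqueness and global stability
#'
#' Evaluates the Lipschitz bound guaranteeing that \eqn{F/\kappa} is a
#' contraction on \eqn{E_p}:
#' \deqn{\frac{2 u_m^2}{(1-p)^3} + \frac{l\sigma^2}{2(1-p)^2} < \kappa l^3.}
#'
#' @param params a [make_params] object.
#' @param p radius parameter in (0, 1).
#' @param input a [periodic_input] or scalar `u_m`.
#' @return `TRUE` if the strict inequality holds.
#' @export
contraction_condition <- function(params, p, input) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  u_m <- if (inherits(input, "periodic_input")) input$u_m else as.numeric(input)
  lhs <- 2 * u_m^2 / (1 - p)^3 + params$l * params$s2 / (2 * (1 - p)^2)
  lhs < params$kappa * params$l^3
}

#' Equilibria of the scalar noise-only averaged system
#'
#' For the scalar system \eqn{\dot w = -\kappa w + \sigma^2/(2(l-w))}
#' (a single self-connected neuron driven by noise alone), the equilibria
#' are governed by \eqn{\eta = 2\sigma^2/(\kappa l^2)}: two roots
#' \eqn{w_\pm = \frac{l}{2}(1 \pm \sqrt{1-\eta}) \in (0, l)} exist iff
#' \eqn{\eta < 1}, with \eqn{w_-} stable and \eqn{w_+} unstable.
#'
#' @param l,kappa positive rates.
#' @param sigma noise amplitude.
#' @return a list with `eta`, `w_minus`, `w_plus` (the roots are `NA` when
#'   `eta >= 1`, and coincide at `l/2` when `eta == 1`).
#' @export
scalar_truncation_equilibria <- function(l, kappa, sigma) {
  if (l <= 0 || kappa <= 0) stop("'l' and 'kappa' must be > 0")
  eta <- 2 * sigma^2 / (kappa * l^2)
  if (eta > 1) {
    return(list(eta = eta, w_minus = NA_real_, w_plus = NA_real_))
  }
  disc <- sqrt(1 - eta)
  list(eta = eta, w_minus = l / 2 * (1 - disc), w_plus = l / 2 * (1 + disc))
}
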