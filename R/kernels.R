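#' Causal convolution kernels
#'
#' The averaged plasticity equations are built from a small family of causal
#' scalar filters: the normalised exponential \eqn{g_\gamma(t) = \gamma
#' e^{-\gamma t} H(t)}, its (k+1)-fold self-convolutions (gamma densities),
#' and the damped-oscillator kernels v and w arising from trace learning with
#' activity discriminant \eqn{\Delta = \sqrt{1 - 4l/\beta}}.  Each kernel
#' object carries sampled values on a grid (for plotting, L1 norms and
#' numerical cross-checks) and its exact transfer function, used for all
#' periodic filtering.
#'
#' @name kernels
NULL

new_kernel <- function(kind, params, t, values, freq_response,
                       closed_l1 = NA_real_, two_sided = FALSE) {
  dt <- t[2] - t[1]
  structure(list(kind = kind, params = params, dt = dt, t = t,
                 values = values, freq_response = freq_response,
                 closed_l1 = closed_l1, two_sided = two_sided,
                 l1 = trapz_abs(values, dt),
                 integral = trapz_signed(values, dt)),
            class = "conv_kernel")
}

trapz_signed <- function(v, dt) {
  n <- length(v)
  dt * (sum(v) - (v[1] + v[n]) / 2)
}

trapz_abs <- function(v, dt) trapz_signed(abs(v), dt)

#' @export
print.conv_kernel <- function(x, ...) {
  cat("<conv_kernel>", x$kind, " dt =", format(x$dt),
      " horizon =", format(max(abs(x$t))),
      " L1 =", format(x$l1), "\n")
  invisible(x)
}

#' Exponential kernel
#'
#' \eqn{g_\gamma(t) = \gamma e^{-\gamma t} H(t)}, transfer function
#' \eqn{\hat g_\gamma(\xi) = \gamma / (\gamma + 2 i \pi \xi)}; unit signed
#' integral and unit L1 norm.
#'
#' @param rate decay rate gamma (> 0).
#' @param dt grid step; defaults to `horizon / 4096`.
#' @param horizon grid extent; default `40 / rate`.  Must be at least
#'   `5 / rate` or the sampled tail is considered too aggressively truncated.
#' @return a `conv_kernel`.
#' @export
exp_kernel <- function(rate, dt = NULL, horizon = NULL) {
  if (rate <= 0) stop("'rate' must be > 0")
  if (is.null(horizon)) horizon <- 40 / rate
  if (horizon < 5 / rate) {
    stop("horizon shorter than 5/rate: truncation too aggressive")
  }
  if (is.null(dt)) dt <- horizon / 4096
  t <- seq(0, horizon, by = dt)
  new_kernel("exp", list(rate = rate), t, rate * exp(-rate * t),
             freq_response = function(xi) rate / (rate + 2i * pi * xi),
             closed_l1 = 1)
}

#' Iterated exponential kernel
#'
#' The (k+1)-fold self-convolution
#' \eqn{g^{(k+1)}(t) = \gamma^{k+1} t^k e^{-\gamma t} H(t)/k!} (a gamma
#' density), with unit L1 norm for every k and mode at `k / rate`.
#'
#' @inheritParams exp_kernel
#' @param k iteration order (integer >= 0; `k = 0` is [exp_kernel]); capped
#'   at 64.
#' @return a `conv_kernel`.
#' @export
iterated_exp_kernel <- function(rate, k, dt = NULL, horizon = NULL) {
  if (rate <= 0) stop("'rate' must be > 0")
  if (k < 0 || k != round(k)) stop("'k' must be a non-negative integer")
  if (k > 64) stop("'k' too large (capped at 64)")
  if (is.null(horizon)) horizon <- (40 + 2 * k) / rate
  if (is.null(dt)) dt <- horizon / 4096
  t <- seq(0, horizon, by = dt)
  new_kernel("exp_iter", list(rate = rate, k = k), t,
             stats::dgamma(t, shape = k + 1, rate = rate),
             freq_response = function(xi) (rate / (rate + 2i * pi * xi))^(k + 1),
             closed_l1 = 1)
}

# open (linear) convolution of two sampled kernels on matching dt
conv_open <- function(x, y, dt) {
  stats::convolve(x, rev(y), type = "open") * dt
}

# trapezoid-corrected convolution of two causal sampled kernels (halving the
# t = 0 sample of each factor turns the rectangle sum into the trapezoid
# rule, error O(dt^2) instead of O(dt))
conv_trapz <- function(x, y, dt) {
  x[1] <- x[1] / 2
  y[1] <- y[1] / 2
  stats::convolve(x, rev(y), type = "open") * dt
}

# trapezoid-corrected correlation (x star y)(tau) = int x(s) y(s - tau) ds of
# two causal sampled kernels; output on lags seq(-T, T, by = dt)
corr_trapz <- function(x, y, dt) {
  N <- length(x)
  stopifnot(length(y) == N)
  x[1] <- x[1] / 2
  y[1] <- y[1] / 2
  z <- stats::convolve(x, y, type = "open") * dt
  z[N] <- z[N] + x[1] * y[1] * dt  # both halved endpoints coincide at lag 0
  z
}

#' Two-sided temporal correlation profile
#'
#' The (k,q)-temporal profile \eqn{g^{(k+1)} \ast g'^{(q+1)}} (prime denoting
#' time reversal): the effective lag window through which the averaged
#' Hebbian dynamics correlates the input with itself.  Even about 0 when
#' `k == q`; its maximum moves to positive lags as `k - q` grows.
#'
#' @inheritParams iterated_exp_kernel
#' @param k,q iteration orders (>= 0).
#' @return a two-sided `conv_kernel` on `[-horizon, horizon]`.
#' @export
temporal_profile <- function(rate, k, q, dt = NULL, horizon = NULL) {
  if (k < 0 || q < 0) stop("'k' and 'q' must be >= 0")
  if (is.null(horizon)) horizon <- (40 + 2 * max(k, q)) / rate
  if (is.null(dt)) dt <- horizon / 4096
  t <- seq(0, horizon, by = dt)
  a <- stats::dgamma(t, shape = k + 1, rate = rate)
  b <- stats::dgamma(t, shape = q + 1, rate = rate)
  # correlate: (g^(k+1) * rev(g^(q+1)))(s), support [-horizon, horizon]
  vals <- corr_trapz(a, b, dt)
  tt <- seq(-horizon, horizon, by = dt)
  new_kernel("profile", list(rate = rate, k = k, q = q), tt, vals,
             freq_response = function(xi) {
               g <- rate / (rate + 2i * pi * xi)
               g^(k + 1) * Conj(g)^(q + 1)
             },
             closed_l1 = NA_real_, two_sided = TRUE)
}

damped_branch_values <- function(l, beta, mu, t, which = c("v", "w")) {
  which <- match.arg(which)
  disc <- 1 - 4 * l / beta
  if (abs(disc) < 1e-16) {
    c0 <- beta / (2 * mu)
    if (which == "v") return(l * beta / mu^2 * t * exp(-c0 * t))
    return(l / mu * exp(-c0 * t) * (1 + c0 * t))
  }
  if (disc > 0) {
    D <- sqrt(disc)
    a <- beta * (1 - D) / (2 * mu)
    b <- beta * (1 + D) / (2 * mu)
    if (which == "v") return(l / (mu * D) * (exp(-a * t) - exp(-b * t)))
    return(l / (2 * mu * D) * ((1 + D) * exp(-a * t) - (1 - D) * exp(-b * t)))
  }
  D <- sqrt(-disc)
  z <- beta * D * t / (2 * mu)
  e <- exp(-beta * t / (2 * mu))
  if (which == "v") return(2 * l / (mu * D) * e * sin(z))
  l / (mu * D) * e * (sin(z) + D * cos(z))
}

damped_freq_response <- function(l, beta, mu, which = c("v", "w")) {
  which <- match.arg(which)
  Dc <- sqrt(as.complex(1 - 4 * l / beta))
  if (which == "v") {
    function(xi) {
      4 * l * beta /
        ((beta * (1 + Dc) + 4i * pi * mu * xi) *
           (beta * (1 - Dc) + 4i * pi * mu * xi))
    }
  } else {
    function(xi) {
      4 * l * (beta + 2i * pi * mu * xi) /
        ((beta * (1 + Dc) + 4i * pi * mu * xi) *
           (beta * (1 - Dc) + 4i * pi * mu * xi))
    }
  }
}

damped_horizon <- function(l, beta, mu) {
  disc <- 1 - 4 * l / beta
  slow <- if (disc > 1e-16) beta * (1 - sqrt(disc)) / (2 * mu) else beta / (2 * mu)
  40 / slow
}

#' Damped-oscillator kernels v and w
#'
#' The impulse responses of the trace-learning activity dynamics:
#' \eqn{v(t) = \frac{l}{\mu\Delta}(e^{-\beta(1-\Delta)t/2\mu} -
#' e^{-\beta(1+\Delta)t/2\mu}) H(t)} and the companion kernel w, in their
#' hyperbolic (real \eqn{\Delta}, i.e. \eqn{4l \le \beta}), trigonometric
#' (pure imaginary \eqn{\Delta}) or confluent (\eqn{\Delta = 0}) branches.
#' Both have unit signed integral; v additionally has
#' \eqn{\|v\|_1 = \coth(\pi/2|\Delta|)} on the oscillatory branch and 1
#' otherwise.
#'
#' @param l activity leak rate.
#' @param beta filter/adaptation rate.
#' @param mu time-scale ratio (rescales time by 1/mu).
#' @param dt,horizon sampling grid (defaults: horizon `40 / slowest rate`,
#'   dt `horizon / 8192`).
#' @return a list with components `v` and `w`, both `conv_kernel`s.
#' @export
damped_kernels <- function(l, beta, mu = 1, dt = NULL, horizon = NULL) {
  if (l <= 0 || beta <= 0 || mu <= 0) stop("'l', 'beta', 'mu' must be > 0")
  if (is.null(horizon)) horizon <- damped_horizon(l, beta, mu)
  if (is.null(dt)) dt <- horizon / 8192
  t <- seq(0, horizon, by = dt)
  disc <- 1 - 4 * l / beta
  l1_v <- if (disc < -1e-16) 1 / tanh(pi / (2 * sqrt(-disc))) else 1
  pars <- list(l = l, beta = beta, mu = mu)
  v <- new_kernel("damped_v", pars, t, damped_branch_values(l, beta, mu, t, "v"),
                  damped_freq_response(l, beta, mu, "v"), closed_l1 = l1_v)
  w <- new_kernel("damped_w", pars, t, damped_branch_values(l, beta, mu, t, "w"),
                  damped_freq_response(l, beta, mu, "w"), closed_l1 = NA_real_)
  list(v = v, w = w)
}

#' Iterated damped kernel (Bessel closed form)
#'
#' The k-fold self-convolution of the damped kernel v admits the closed form
#' \deqn{v_k(t) = \frac{(l\beta/\mu^2)^k}{(k-1)!}\sqrt{\pi}\,
#'   e^{-\beta t/2\mu}\Big(\frac{\mu t}{\beta|\Delta|}\Big)^{k-1/2}
#'   J_{k-1/2}\Big(\frac{\beta|\Delta|}{2\mu}t\Big) H(t)}
#' on the oscillatory branch (Bessel J of the first kind), with J replaced by
#' the modified Bessel I on the overdamped branch; the confluent limit is a
#' gamma-type kernel.  Satisfies the filter identity
#' \eqn{w \ast v_k \ast g_{\beta/\mu} = v_{k+1}}.
#'
#' @inheritParams damped_kernels
#' @param k convolution order (integer >= 1; `k = 1` is v itself).
#' @return a `conv_kernel`.
#' @export
iterated_damped_kernel <- function(l, beta, mu = 1, k, dt = NULL,
                                   horizon = NULL) {
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (is.null(horizon)) horizon <- damped_horizon(l, beta, mu) * (1 + 0.2 * (k - 1))
  if (is.null(dt)) dt <- horizon / 8192
  t <- seq(0, horizon, by = dt)
  disc <- 1 - 4 * l / beta
  nu <- k - 1 / 2
  pref <- (l * beta / mu^2)^k / factorial(k - 1) * sqrt(pi)
  vals <- tryCatch({
    if (abs(disc) < 1e-16) {
      (l * beta / mu^2)^k * t^(2 * k - 1) *
        exp(-beta * t / (2 * mu)) / factorial(2 * k - 1)
    } else if (disc < 0) {
      D <- sqrt(-disc)
      z <- beta * D * t / (2 * mu)
      out <- pref * exp(-beta * t / (2 * mu)) *
        (mu * t / (beta * D))^nu * besselJ(z, nu)
      out[t == 0] <- 0
      out
    } else {
      D <- sqrt(disc)
      z <- beta * D * t / (2 * mu)
      # scaled Bessel I avoids overflow: I_nu(z) = besselI(z, nu, TRUE) * e^z
      out <- pref * exp(-beta * (1 - D) * t / (2 * mu)) *
        (mu * t / (beta * D))^nu * besselI(z, nu, expon.scaled = TRUE)
      out[t == 0] <- 0
      out
    }
  }, error = function(e) NULL)
  if (is.null(vals) || anyNA(vals)) {
    message("Bessel evaluation failed; falling back to FFT self-convolution")
    base <- damped_branch_values(l, beta, mu, t, "v")
    vals <- base
    for (i in seq_len(k - 1)) vals <- conv_open(vals, base, dt)[seq_along(t)]
  }
  fr_v <- damped_freq_response(l, beta, mu, "v")
  new_kernel("damped_v_iter", list(l = l, beta = beta, mu = mu, k = k),
             t, vals, freq_response = function(xi) fr_v(xi)^k,
             closed_l1 = NA_real_)
}

#' Numerical L1 norm of a kernel
#'
#' Trapezoidal integral of |values| over the sampling grid.  For the
#' exponential family this is 1; for the damped kernel v it is 1 on the
#' overdamped branch and \eqn{\coth(\pi/2|\Delta|)} on the oscillatory one.
#'
#' @param kernel a `conv_kernel`.
#' @return a scalar.
#' @export
kernel_l1_norm <- function(kernel) {
  trapz_abs(kernel$values, kernel$dt)
}

#' @export
as.data.frame.conv_kernel <- function(x, ...) {
  data.frame(t = x$t, value = x$values)
}

#' Filter a periodic signal through a kernel
#'
#' Multiplies each Fourier coefficient by the kernel's transfer function
#' at the harmonic's frequency \eqn{\xi_k = k\,\texttt{mu\_rescale}/\tau}.
#' This is exact for periodic signals (the kernel's infinite tail is fully
#' accounted for) and preserves the period.
#'
#' @param input a [periodic_input].
#' @param kernel a `conv_kernel`.
#' @param mu_rescale optional factor applied to the evaluation frequency,
#'   used to apply a fast-time kernel to a signal on the input time-scale.
#' @return a filtered [periodic_input].
#' @export
apply_filter_periodic <- function(input, kernel, mu_rescale = 1) {
  if (is.null(kernel$freq_response)) stop("kernel has no frequency response")
  xi <- fourier_harmonics(input$M) * mu_rescale / input$tau
  H <- kernel$freq_response(xi)
  out <- sweep(input$fourier, 2, H, "*")
  periodic_input_from_fourier(force_real_nyquist(out), input$tau)
}
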