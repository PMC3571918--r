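#' Periodic input signals
#'
#' A `periodic_input` stores one period of a tau-periodic vector signal
#' u(t) in R^n on a uniform grid of M samples, together with its complex
#' Fourier coefficients and the sup-norm \eqn{u_m = \sup_t \|u(t)\|_2}.
#' All filtering and averaging in the package operates on the Fourier
#' coefficients, so the grid exists mainly for construction, plotting and
#' export.
#'
#' Coefficients follow the convention \eqn{u_i(t) = \sum_k c_{i,k}
#' e^{2\pi i k t/\tau}} with the usual FFT ordering of harmonics
#' (`fourier_harmonics()`).
#'
#' @param samples an `n x M` real matrix, column `j` holding u at time
#'   `(j-1) * tau / M`.
#' @param tau the period (> 0).
#' @return An object of class `periodic_input` with fields `tau`, `grid`,
#'   `samples`, `fourier`, `u_m`, `n`, `M`.
#' @export
periodic_input <- function(samples, tau) {
  samples <- rbind(samples)
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (tau <= 0) stop("'tau' must be > 0")
  n <- nrow(samples)
  M <- ncol(samples)
  grid <- (seq_len(M) - 1) * tau / M
  fourier <- t(stats::mvfft(t(samples))) / M
  dim(fourier) <- c(n, M)
  u_m <- sqrt(max(colSums(samples^2)))
  structure(list(tau = tau, grid = grid, samples = samples,
                 fourier = fourier, u_m = u_m, n = n, M = M),
            class = "periodic_input")
}

#' Integer harmonic numbers in FFT order
#'
#' @param M number of samples per period.
#' @return integer vector of length `M`: `0, 1, ..., M/2, -(M/2-1), ..., -1`.
#' @export
fourier_harmonics <- function(M) {
  j <- 0:(M - 1)
  ifelse(j <= M / 2, j, j - M)
}

# rebuild the sample matrix from coefficients (used after filtering)
samples_from_fourier <- function(fourier, warn_tol = 1e-8) {
  M <- ncol(fourier)
  x <- t(stats::mvfft(t(fourier), inverse = TRUE))
  mx <- max(abs(x))
  if (mx > 0 && max(abs(Im(x))) > warn_tol * mx) {
    warning("discarding non-negligible imaginary part in reconstruction")
  }
  matrix(Re(x), nrow(fourier), M)
}

periodic_input_from_fourier <- function(fourier, tau) {
  periodic_input(samples_from_fourier(fourier), tau)
}

# The unpaired Nyquist harmonic (k = M/2, even M) of a real signal is real;
# after multiplication by a complex gain it must be projected back so the
# reconstructed signal stays real.
force_real_nyquist <- function(fourier) {
  M <- ncol(fourier)
  if (M %% 2 == 0) {
    j <- M / 2 + 1
    fourier[, j] <- Re(fourier[, j])
  }
  fourier
}

#' Sinusoidal periodic input
#'
#' Component i is `amplitudes[i] * sin(2*pi*t/tau + phases[i])`.
#'
#' @param n number of components.
#' @param tau period (> 0).
#' @param amplitudes,phases numeric vectors recycled to length `n`; phases
#'   default to 0.
#' @param M samples per period (>= 8; default 4096).
#' @return A [periodic_input].
#' @examples
#' u <- make_sinusoid_input(1, tau = 2 * pi)
#' u$u_m  # 1
#' @export
make_sinusoid_input <- function(n, tau, amplitudes = 1, phases = 0, M = 4096L) {
  if (M < 8) stop("'M' must be at least 8 to resolve a sinusoid")
  if (tau <= 0) stop("'tau' must be > 0")
  amplitudes <- rep_len(amplitudes, n)
  phases <- rep_len(phases, n)
  t <- (seq_len(M) - 1) * tau / M
  samples <- vapply(t, function(tt) amplitudes * sin(2 * pi * tt / tau + phases),
                    numeric(n))
  periodic_input(matrix(samples, n, M), tau)
}

#' Piecewise pattern presentation input
#'
#' Cycles through a set of spatial patterns, holding pattern p for
#' `durations[p]` time units; the period is `sum(durations)`.  This is the
#' kind of stimulus used to probe what correlation structure the plasticity
#' rules store: alternating orthogonal random patterns, or a circular
#' sequence of one-hot patterns where each neuron is excited in turn.
#'
#' @param n number of components.
#' @param patterns either an `n x P` matrix (columns are patterns), a list of
#'   n-vectors, or a single integer P meaning "P random Gaussian patterns"
#'   (drawn with `seed`, normalised to unit norm).
#' @param durations positive vector of presentation times, one per pattern.
#' @param M samples per period (default 4096).
#' @param smooth_frac fraction of each segment over which the switch is
#'   cross-faded with a raised cosine; 0 (default) keeps hard switches.
#' @param seed RNG seed for random patterns (default 1).
#' @param orthogonalize replace the patterns by an orthonormal set spanning
#'   the same space (requires P <= n).
#' @return A [periodic_input].
#' @examples
#' u <- make_pattern_input(3, diag(3), durations = rep(1, 3))  # one-hot cycle
#' range(colSums(u$samples != 0))  # exactly one active neuron at any time
#' @export
make_pattern_input <- function(n, patterns, durations, M = 4096L,
                               smooth_frac = 0, seed = 1L,
                               orthogonalize = FALSE) {
  if (any(durations <= 0)) stop("'durations' must be positive")
  if (is.list(patterns) && !is.matrix(patterns)) {
    patterns <- do.call(cbind, patterns)
  }
  if (length(patterns) == 1L && is.numeric(patterns)) {
    P <- as.integer(patterns)
    set.seed(seed)
    patterns <- matrix(stats::rnorm(n * P), n, P)
    patterns <- sweep(patterns, 2, sqrt(colSums(patterns^2)), "/")
  }
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != n) stop("patterns must have n rows")
  P <- ncol(patterns)
  if (length(durations) != P) stop("one duration per pattern required")
  if (orthogonalize) {
    if (P > n) stop("cannot orthogonalize more patterns than dimensions (P > n)")
    qrd <- qr(patterns)
    Q <- qr.Q(qrd)
    # fix signs for determinism
    s <- sign(diag(qr.R(qrd)))
    s[s == 0] <- 1
    patterns <- Q %*% diag(s, P)
  }
  tau <- sum(durations)
  t <- (seq_len(M) - 1) * tau / M
  bounds <- cumsum(c(0, durations))
  idx <- findInterval(t, bounds, rightmost.closed = TRUE)
  idx[idx > P] <- P
  weights <- matrix(0, P, M)
  weights[cbind(idx, seq_len(M))] <- 1
  if (smooth_frac > 0) {
    width <- max(3L, round(smooth_frac * min(durations) / (tau / M)))
    win <- 0.5 * (1 - cos(2 * pi * seq_len(width) / (width + 1)))
    win <- win / sum(win)
    Wf <- stats::fft(c(win, rep(0, M - width)))
    for (p in seq_len(P)) {
      weights[p, ] <- Re(stats::fft(stats::fft(weights[p, ]) * Wf,
                                    inverse = TRUE)) / M
    }
    weights <- sweep(weights, 2, colSums(weights), "/")
  }
  periodic_input(patterns %*% weights, tau)
}

#' @export
as.data.frame.periodic_input <- function(x, ...) {
  d <- data.frame(time = x$grid, t(x$samples))
  names(d) <- c("time", paste0("u", seq_len(x$n)))
  d
}

#' @export
print.periodic_input <- function(x, ...) {
  cat("<periodic_input> n =", x$n, " tau =", format(x$tau),
      " M =", x$M, " u_m =", format(x$u_m), "\n")
  invisible(x)
}

#' Plot a periodic input
#'
#' One line per component over one period (requires ggplot2).
#' @param x a [periodic_input].
#' @return a ggplot object.
#' @export
plot_input <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- as.data.frame(x)
  long <- stats::reshape(d, direction = "long",
                         varying = names(d)[-1], v.names = "value",
                         timevar = "component", times = names(d)[-1])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (input scale)", y = "u(t)")
}
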