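# Euler-Maruyama simulation of the coupled slow-fast stochastic systems.

new_trajectory <- function(times, W, v = NULL, z = NULL, meta = list()) {
  structure(list(times = times, W = W, v = v, z = z, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$W)
  cat("<trajectory>", if (!is.null(x$meta$kind)) x$meta$kind else "",
      " n =", d[1], " samples =", d[3],
      " t in [", format(min(x$times)), ",", format(max(x$times)), "]\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  d <- dim(x$W)
  n <- d[1]
  # row-major Wij columns: W11, W12, ..., W1n, W21, ...
  flat <- t(apply(x$W, 3, function(m) as.vector(t(m))))
  if (d[3] == 1L) flat <- matrix(flat, 1)
  nm <- as.vector(t(outer(seq_len(n), seq_len(n),
                          function(i, j) paste0("W", i, j))))
  out <- data.frame(time = x$times, flat)
  names(out) <- c("time", nm)
  out
}

#' Plot connectivity weights along a trajectory
#'
#' One line per connectivity entry (requires ggplot2).
#' @param x a `trajectory`.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- as.data.frame(x)
  long <- stats::reshape(d, direction = "long", varying = names(d)[-1],
                         v.names = "weight", timevar = "entry",
                         times = names(d)[-1])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$weight,
                                     colour = .data$entry)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (slow scale)", y = "W entries")
}

#' Simulate the coupled slow-fast stochastic learning system
#'
#' Euler-Maruyama integration on the fast time-scale s of
#' \deqn{dv = ((W - L)\phi(v) + u(\mu s))\,ds + \Sigma\,dB_s, \qquad
#'       dW = \epsilon_1(-\kappa W + \mathrm{rule}(v))\,ds,}
#' where \eqn{\phi} is the identity (hebbian, stdp) or the exponential trace
#' (trace rule; implemented by the auxiliary variable z with
#' \eqn{dz = \beta(v - z)ds}, the memoryless reformulation with the
#' auxiliary noise set to zero), and rule(v) is the outer-product update of
#' the chosen rule.  The initial connectivity is the zero matrix.  Stored
#' times are in slow units \eqn{t = \epsilon_1 s}.
#'
#' @param params a [make_params] object (uses `eps1`, `mu`, `Sigma`).
#' @param input a [periodic_input]; it is evaluated at phase `mu * s` by
#'   linear interpolation of its sampled period.
#' @param T_fast horizon in fast-time units.
#' @param dt fast-time step (default 0.01).
#' @param seed RNG seed (reproducible: same seed and dt give bit-identical
#'   paths).
#' @param thinning store every `thinning`-th step (default 10).
#' @param feedback if `FALSE`, the connectivity is decoupled from the
#'   activity drift (`W v` term dropped); this reproduces the classical
#'   scalar worked examples where the slow variable does not feed back.
#' @return a `trajectory` with fields `times` (slow units), `W`
#'   (`n x n x nt`), `v` (`n x nt`), optionally `z`, and `meta`.
#' @export
simulate_network <- function(params, input, T_fast, dt = 0.01, seed = 1L,
                             thinning = 10L, feedback = TRUE) {
  p <- params
  n <- p$n
  nsteps <- floor(T_fast / dt)
  if (nsteps < 1) stop("'T_fast' shorter than one step")
  if (dt * p$l >= 1) stop("unstable step: dt * l >= 1")
  set.seed(seed)
  has_z <- p$rule %in% c("trace", "stdp")
  zrate <- if (p$rule == "trace") p$beta else p$gamma
  sqdt <- sqrt(dt)
  Sig <- p$Sigma
  dvals <- diag(Sig)
  scalar_noise <- all(Sig[row(Sig) != col(Sig)] == 0) &&
    all(dvals == dvals[1])
  sig <- if (scalar_noise) Sig[1, 1] else NA_real_

  # precompute the input at every step by linear interpolation on its grid
  phase <- (p$mu * (0:(nsteps - 1)) * dt) %% input$tau
  pos <- phase / input$tau * input$M
  i0 <- floor(pos)
  frac <- pos - i0
  i1 <- (i0 %% input$M) + 1L
  i2 <- (i1 %% input$M) + 1L

  v <- numeric(n)
  z <- numeric(n)
  W <- matrix(0, n, n)
  keep <- seq(0, nsteps, by = thinning)
  nt <- length(keep)
  Wout <- array(NA_real_, c(n, n, nt))
  vout <- matrix(NA_real_, n, nt)
  zout <- if (has_z) matrix(NA_real_, n, nt) else NULL
  Wout[, , 1] <- W
  vout[, 1] <- v
  if (has_z) zout[, 1] <- z
  ki <- 2L

  chunk <- 50000L
  s0 <- 1L
  while (s0 <= nsteps) {
    s1 <- min(s0 + chunk - 1L, nsteps)
    m <- s1 - s0 + 1L
    noise <- matrix(stats::rnorm(n * m), n, m)
    if (scalar_noise) {
      noise <- sig * sqdt * noise
    } else {
      noise <- sqdt * (Sig %*% noise)
    }
    uu <- input$samples[, i1[s0:s1], drop = FALSE] * (1 - rep(frac[s0:s1], each = n)) +
      input$samples[, i2[s0:s1], drop = FALSE] * rep(frac[s0:s1], each = n)
    for (j in seq_len(m)) {
      act <- if (p$rule == "trace") z else v
      drift <- -p$l * act + uu[, j]
      if (feedback) drift <- drift + W %*% act
      if (p$rule == "hebbian") {
        G <- -p$kappa * W + tcrossprod(v)
      } else if (p$rule == "trace") {
        G <- -p$kappa * W + tcrossprod(z)
      } else {
        G <- -p$kappa * W + p$a_plus * tcrossprod(v, z) -
          p$a_minus * tcrossprod(z, v)
      }
      if (has_z) z <- z + dt * zrate * (v - z)
      v <- v + dt * drift + noise[, j]
      W <- W + p$eps1 * dt * G
      step <- s0 + j - 1L
      if (ki <= nt && step == keep[ki]) {
        Wout[, , ki] <- W
        vout[, ki] <- v
        if (has_z) zout[, ki] <- z
        ki <- ki + 1L
      }
    }
    mx <- max(abs(W), abs(v))
    if (is.na(mx) || mx > 1e8) {
      stop("numerical blow-up at fast step ", s1,
           ": check the admissibility assumption (check_assumption)")
    }
    s0 <- s1 + 1L
  }
  new_trajectory(times = keep * dt * p$eps1, W = Wout, v = vout, z = zout,
                 meta = list(kind = "stochastic", rule = p$rule, seed = seed,
                             dt = dt, thinning = thinning, eps1 = p$eps1,
                             feedback = feedback))
}

#' Sup deviation between two connectivity trajectories
#'
#' The supremum over the shared time range of the squared Frobenius distance
#' between the two connectivity matrices, after linear interpolation of each
#' entry onto the common sampling times.  This is the empirical precision
#' measure of the averaging approximation.
#'
#' @param traj_a,traj_b `trajectory` objects with overlapping time ranges.
#' @return a non-negative scalar.
#' @export
sup_deviation <- function(traj_a, traj_b) {
  lo <- max(min(traj_a$times), min(traj_b$times))
  hi <- min(max(traj_a$times), max(traj_b$times))
  if (lo >= hi) stop("trajectories have disjoint time ranges")
  ta <- traj_a$times[traj_a$times >= lo & traj_a$times <= hi]
  tb <- traj_b$times[traj_b$times >= lo & traj_b$times <= hi]
  tt <- if (length(ta) >= length(tb)) ta else tb
  n <- dim(traj_a$W)[1]
  interp <- function(traj) {
    apply_entries <- matrix(NA_real_, length(tt), n * n)
    flat <- matrix(traj$W, n * n, dim(traj$W)[3])
    for (e in seq_len(n * n)) {
      apply_entries[, e] <- stats::approx(traj$times, flat[e, ], xout = tt,
                                          rule = 2)$y
    }
    apply_entries
  }
  da <- interp(traj_a)
  db <- interp(traj_b)
  max(rowSums((da - db)^2))
}
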