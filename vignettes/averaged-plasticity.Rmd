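---
title: "Averaged dynamics of slow-fast stochastic plasticity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Averaged dynamics of slow-fast stochastic plasticity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastav)
```

## The model

`plastav` studies recurrent networks of $n$ linear rate neurons whose
connectivity matrix $W$ changes slowly under an unsupervised plasticity rule
while the activity $v$ is fast, noisy and periodically driven:

$$
dv = \tfrac{1}{\epsilon_1}\big[(W - L)\,\phi(v) + u(t/\epsilon_2)\big]dt
     + \tfrac{\sigma}{\sqrt{\epsilon_1}}\, dB_t, \qquad
dW = \big[-\kappa W + \mathrm{rule}(v)\big]\,dt,
$$

with leak matrix $L = l\,\mathrm{Id}$, a $\tau$-periodic input $u$, and three
learning rules:

* **Hebbian** — $\mathrm{rule}(v) = v \otimes v$;
* **trace** — the same outer product applied to the exponentially filtered
  activity $v \ast g_\beta$ (and filtered synaptic transmission), which makes
  single neurons damped oscillators when $4l > \beta$;
* **STDP** — the temporally asymmetric window
  $a_+\, v \otimes (v \ast g_\gamma) - a_-\, (v \ast g_\gamma) \otimes v$,
  an additive caricature of spike-timing-dependent plasticity.

Two small parameters control the time-scale structure: $\epsilon_1$ (activity
vs. learning) and $\epsilon_2$ (input vs. learning).  Their asymptotic ratio
$\mu = \epsilon_1/\epsilon_2$ survives in the limit and measures how fast the
input is relative to the intrinsic activity time-scale: $\mu \to 0$ means
quasi-static inputs, $\mu \to \infty$ inputs too fast to track.

## The averaged equation

In the double limit $\epsilon_1, \epsilon_2 \to 0$ at fixed $\mu$, $W$ is
approximated (uniformly on finite slow-time intervals, in probability) by the
deterministic flow

$$
\frac{dW}{dt} \;=\; \underbrace{-\kappa W}_{\text{decay}}
\;+\; \underbrace{\tfrac{\mu}{\tau}\textstyle\int_0^{\tau/\mu}
  \mathrm{rule}(\bar v)\,dt}_{\text{correlation}}
\;+\; \underbrace{Q(W)}_{\text{noise}},
$$

where $\bar v$ is the $\tau/\mu$-periodic attractor of the frozen fast
dynamics and $Q$ is the stationary covariance contribution of the noise,
obtained from a Lyapunov equation.  Because the frozen fast equation is
linear, its periodic law is a Gaussian of constant covariance translated
along $\bar v$, and input and noise enter the averaged drift *additively*
(the package verifies this by Monte-Carlo in its test suite).

`averaged_field()` assembles this drift; `averaged_rhs()` exposes the three
labelled components; `integrate_averaged()` follows the flow with deSolve.

### Exact periodic computation

All periodic quantities are computed in the Fourier domain:

* the attractor solves per harmonic
  $\hat v_k = (i\omega_k I - (W-L)\hat g(\omega_k))^{-1}\hat u_k$ with
  $\omega_k = 2\pi k \mu/\tau$ (with $\hat g \equiv 1$ except for the trace
  rule), via one eigendecomposition of $W - L$ per evaluation;
* period averages of products are Parseval sums of coefficient outer
  products.

This avoids time quadrature entirely: there is no truncation tail and no
transient contamination, and filtering by a causal kernel is exact however
long its memory.  Sampled kernels exist alongside (`exp_kernel()`,
`damped_kernels()`, ...) for plotting, $L^1$ norms and the numerical
cross-checks; their grids default to a horizon of 40 times the slowest decay
time.

### The kernel family

The series form of the correlation term rests on a small calculus of causal
filters: the exponential $g_\gamma(t)=\gamma e^{-\gamma t}H(t)$, its
$(k{+}1)$-fold self-convolutions (gamma densities, unit $L^1$ norm), and for
the trace rule the damped kernels $v, w$ with discriminant
$\Delta = \sqrt{1-4l/\beta}$.  On the oscillatory branch ($4l > \beta$,
$\Delta$ pure imaginary) the iterated kernels have closed forms in Bessel
functions of the first kind and $\|v\|_1 = \coth(\pi/2|\Delta|)$; on the
overdamped branch modified Bessel functions appear and $\|v\|_1 = 1$.  The
confluent point $\Delta = 0$ is served by the analytic limit kernels (a band
of $|\Delta|^2 < 10^{-16}$ routes there).  The transfer functions of $v$ and
$w$ are normalised to unit DC gain — the normalisation consistent with their
unit signed integrals — and with that choice the filter identity
$w \ast v_k \ast g_{\beta/\mu} = v_{k+1}$ holds exactly; the identity is
checked on the sampling grid in the tests.

### Correlation families and the series form

Expanding the attractor in powers of $W/l$ yields

$$
\tfrac{\mu}{\tau}\,\bar v \cdot \bar v' \;=\;
\frac{u_m^2}{l^2}\sum_{k,q\ge 0} \frac{W^k}{l^k}\, C_{k,q}\,
\frac{W'^q}{l^q},
\qquad
C_{k,q} = \frac{(u \ast g_{l/\mu}^{(k+1)})\cdot(u \ast
  g_{l/\mu}^{(q+1)})'}{u_m^2\,\tau},
$$

with trace ($\tilde C_{k,q}$, damped kernels, $\|v\|_1$ scaling) and STDP
($D_{k,q}$, with the window filter $a_+ g' - a_- g$) analogues.  Young's
inequality bounds every family matrix by $1$ in the entrywise $L^2$
(Frobenius) norm, which also dominates the spectral norm; the bound is
asserted at build time.  One convention deserves note: the STDP window
$g_\gamma$ acts on the fast time-scale, so on the input time-scale (where
the $C$-families live) it must be rescaled to $g_{\gamma/\mu}$.  At
$\mu = 1$ — the value used in all our reference configurations — the two
conventions coincide; the package uses the rescaled form, which is the one
that makes the series agree with the attractor-based evaluation for every
$\mu$ (a property the tests enforce to $10^{-6}$ relative).

`correlation_family()` builds the matrices; `correlation_term_series()`
evaluates the truncated double sum and reports a geometric tail bound.  The
default truncation $K = 4$ follows the reference numerics of the
antisymmetric-STDP configuration; integration uses the direct (attractor)
mode by default, which is exact in $W$.

## Well-posedness and stability

The averaged flow is confined to
$E_p = \{W\ \text{symmetric},\ W \ge 0,\ \|W\| < p\,l\}$ whenever the
rule-specific admissibility inequality holds for some $p\in(0,1)$ —
essentially, input power $u_m^2$ and noise power $\sigma^2$ must be small
against the decay budget $\kappa l^3$.  `check_assumption()` locates the
admissible $p$ by a $10^4$-point scan with bisection refinement (one code
path for all three rules, rather than rule-specific cubic root formulas).
Inside $p \le 1/3$ (hebbian, STDP) or $p \le 1/(2\|v\|_1^3+1)$ (trace), the
fixed-point map $F/\kappa$ is a contraction: the equilibrium is unique and
globally attracting, and $\|W(t)-W^*\|_F^2$ decays monotonically.
`solve_equilibrium()` exploits this with damped Picard iteration
($\omega = 0.8$; plain iteration is already guaranteed, damping merely
widens the practical basin).

The scalar noise-only system is kept as a worked example: with
$\eta = 2\sigma^2/(\kappa l^2) < 1$ the field
$-\kappa w + \sigma^2/(2(l-w))$ has the two roots
$w_\pm = \tfrac{l}{2}(1\pm\sqrt{1-\eta})$, the lower stable, the upper
unstable (`scalar_truncation_equilibria()`).

## The weakly connected expansion

The equilibrium admits an expansion in the *weak connectivity index*
$\tilde p$ ($= u_m^2/\kappa l^3 + \sigma^2/2\kappa l^2$ for hebbian/trace),
with the noise/input balance $\lambda$:

$$
W^* = \frac{\tilde p\, l}{1+\lambda}\big(\lambda\,\mathrm{Id} + C_{0,0}\big)
+ \frac{\tilde p^2 l}{(1+\lambda)^2}\big(\lambda^2 \mathrm{Id}
  + \lambda(C_{0,0}+C_{1,0}+C_{0,1})
  + C_{0,0}C_{1,0} + C_{0,1}C_{0,0}\big) + O(\tilde p^3).
$$

At first order the learned connectivity *is* the filtered input correlation
(plus a noise diagonal): the network stores what its inputs covary like,
through a temporal window whose width and lag are set by $\mu$.  Orders
$\ge 3$ exist recursively but are not implemented.  The second-order terms
are assembled directly from the order-by-order matching of the underlying
series (the form that reduces to the Hebbian expansion as
$\beta \to \infty$ and is consistent with the first order): the trace
$\lambda^2$ term carries no $\|v\|_1$ factor, the STDP corrections use the
normalised amplitudes $\alpha_\pm = a_\pm/(|a_+|+|a_-|)$, and the STDP noise
normalisation is $s^2 = \|\Sigma\Sigma'\|$ — the unique choice under which
the zeroth-order noise term of the series reproduces
$\lambda(\alpha_+-\alpha_-)\Sigma\Sigma'/s^2$.

For STDP the first order splits into a symmetric part
$S \propto (a_+ - a_-)$ — correlation of the doubly filtered input with
itself, in effect trace learning — and an antisymmetric part
$A \propto (a_+ + a_-)\,(\dot u \ast \cdots)\cdot(u \ast \cdots)'$, the
cross-correlation of the input with its derivative: a causality detector.
With $a_+ = a_-$ the equilibrium is purely antisymmetric, and with
spatially uncorrelated (diagonal) noise the first-order noise contribution
cancels exactly: only the Hebbian (symmetric) component writes noise into
the connectivity.

## The stochastic simulator and what the tests show

`simulate_network()` integrates the coupled system by Euler–Maruyama on the
fast time-scale (the noise is additive, so the scheme is strong order 1.0).
The trace and STDP filters are realised by the memoryless augmented variable
$z$ with its auxiliary noise set to zero — the auxiliary noise exists only
to make the limit theory non-degenerate and drops out of the averaged
equations.  $\epsilon$ enters only the $W$-update ($\epsilon_1 = \epsilon_2$
by default, with $\mu$ applied as an input-period rescaling); the initial
connectivity is always $0$.

Choices that matter and their defaults:

* `dt = 0.01` fast-time step (the reference antisymmetric-STDP run);
  configurations with $l \ge 10$ use the stability headroom $l\,dt \le 0.12$,
  and the averaging-precision experiment lowers `dt` to $0.002$ so that the
  $O(l\,dt)$ Euler bias sits well below the $O(\sqrt\epsilon)$ averaging
  error it measures.
* `M = 4096` input samples per period — resolves the sharpest kernels used
  at desk scale; pattern inputs switch hard (`smooth_frac = 0`) as in the
  reference pattern-presentation protocols.
* Pattern amplitudes are unit-norm (orthonormal after orthogonalisation);
  nothing in the reference configurations pins the input scale, and $u_m$
  propagates explicitly through $\tilde p$ and $\lambda$, so this is a pure
  normalisation choice.
* The averaging-precision experiment (`fig2_convergence`) runs $n = 3$,
  $l = 12$, $\kappa = 100$, $\sigma = 0.05$, slow horizon $0.06$, five
  seeds, $\epsilon \in \{0.01, 0.001\}$; the expansion experiment
  (`fig3_expansion`) runs $n = 8$ with $\mu \in \{0.1, 1, 10\}$ spanning
  the slow/matching/fast regimes.  These sizes keep every experiment within
  seconds on one core while leaving the measured effects orders of
  magnitude above solver tolerances.

The synthetic inputs emulate the study conditions — sinusoidal drives,
alternating orthogonal random patterns, circular one-hot sequences — not
real spike trains: activities are linear and Gaussian, neurons identical,
inputs exactly periodic.  Passing tests therefore certify the reduction
machinery (averaging, series, expansions, certificates) under those
conditions; they say nothing about nonlinear, heterogeneous or aperiodic
networks, which are outside the model class.

## Numerical edges

* Degenerate Lyapunov problems (an eigenvalue pair of $A$ summing to zero)
  are rejected rather than regularised; the returned solution must pass a
  residual check at $10^{-10}\|D\|$.
* The geometric-series Lyapunov backend requires
  $\|W\| \|(2L-W)^{-1}\| < 1$ and is used as an independent oracle against
  the dense solve.
* Fixed-point convergence is declared at
  $\|\bar G(W)\|_F < \mathrm{tol}\,\kappa \max(\|W\|_F, 10^{-9} l)$ — the
  absolute floor guards the $W^* \approx 0$ regime.
* The unpaired Nyquist harmonic of an even-length sample grid is projected
  back to the real axis after complex-gain filtering, so reconstructed
  signals are exactly real.
* Discrete convolutions used in kernel cross-checks carry trapezoid
  endpoint corrections (halved $t=0$ samples, with a lag-zero fix-up for
  correlations); this is what lets grid identities hold to $10^{-6}$ at
  millisecond-scale steps.

## Known limitations

Expansion orders stop at 2; inputs must be periodic (no ergodic extension);
activities are linear (no spiking or sigmoidal saturation); the trace rule
assumes a single shared filter rate $\beta$ for neurons, synapses and
learning window; `simulate_network()` is plain Euler–Maruyama, adequate for
additive noise but first-order in the drift.  The L1 norm of the damped
kernel $w$ on the oscillatory branch has no known closed form and is only
computed numerically.
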