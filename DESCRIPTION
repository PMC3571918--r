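Package: plastav
Title: Averaged Dynamics of Slow-Fast Stochastic Plasticity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recurrent linear rate networks whose connectivity
    evolves slowly under Hebbian, trace or spike-timing-dependent (STDP)
    plasticity while the neuronal activity is a fast periodically forced
    Ornstein-Uhlenbeck process.  Implements Euler-Maruyama simulation of the
    coupled slow-fast stochastic systems, the rigorously averaged
    deterministic connectivity equation (periodic attractor of the frozen
    fast dynamics, filtered input-correlation series with exponential and
    damped-oscillator Bessel kernels, Lyapunov noise terms), admissibility
    and contraction certificates for the invariant set of the averaged flow,
    the unique equilibrium connectivity, and its weakly connected expansions
    up to second order, including the symmetric/antisymmetric decomposition
    of the STDP equilibrium.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    yaml
Config/testthat/edition: 3
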