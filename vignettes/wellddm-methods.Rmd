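---
title: "Modelling arousal in 2AFC decisions with a two-square-well quantum potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arousal in 2AFC decisions with a two-square-well quantum potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellddm)
```

## The model

`wellddm` treats a two-alternative forced-choice (2AFC) decision — say,
judging the direction of a random-dot-motion stimulus — as the behaviour of
a one-dimensional quantum particle in a piecewise-constant potential with
two square wells. Each well is one response option. The well's depth below
the barrier energy encodes the signal strength of that option (for dot
motion, coherence: the fraction of coherently moving dots), and its width
the conceptual generality of the option. The landscape is geometrically
symmetric — equal well widths `w` and edge widths `e` — because "left" and
"right" are equally general concepts; only the well bottom energies `EwL`
and `EwR` may differ. Throughout, the barrier energy is the bound-state
cutoff, and the fitting layer fixes it to `Eb = 1` to pin the energy scale.
A note on conventions: `EwR` is the *bottom energy* of the right well, so a
deeper (stronger-signal) well has a *smaller* `EwR`; where we speak of
depth we mean `Eb - EwR`.

The dynamics are generated by the discretized Hamiltonian

    H = alpha * K + diag(V),

where `K` is the Matrix Numerov discretization of `-(1/2) d^2/dx^2`
(`hbar = m = 1`; fourth-order accurate, built from the tridiagonal pair
`A = dx^-2 tridiag(1, -2, 1)`, `B = tridiag(1, 10, 1)/12` as
`K = -(1/2) B^-1 A`) and `alpha >= 0` scales the kinetic energy. All
quantities are dimensionless except times, which we read in seconds.

The decision-relevant quantity is the *mean integration efficiency* (MIE):
the probability mass of the wavefunction inside each well,

    P_C = sum_{i in correct well} |psi_i|^2,
    P_W = sum_{i in incorrect well} |psi_i|^2.

These do not sum to one (mass can sit between and beside the wells) and
are not themselves choice probabilities. They drive a standard
drift-diffusion model (DDM) through the drift mapping

    A = lam * (P_C - P_W),

after which the usual Wiener first-passage machinery — absorbing
boundaries at `+z` and `-z`, diffusion variance `d2`, start `x0`,
response time `RT = T0 + DT` — yields choice probabilities and RT
distributions. The quantum layer supplies only the drift `A`; `d2` and
`z` remain free DDM-layer parameters with defaults `d2 = 1`, `z = 1`, and
the start is unbiased (`x0 = 0`) because nothing in the task motivates a
bias.

## Two mechanisms for arousal

**Eigenstate sampling (total-energy arousal).** The decision state is a
*bound eigenstate* of `H` (energy below `Eb`). Arousal is a criterion
energy `E*` drawn from a classical distribution `p(E)` on `(0, Emax]`; the
model forms the window `[E*, E* + delta]`, with `delta` the maximum gap
between adjacent bound energies, and selects an eigenstate uniformly from
the window. Because `delta` is the maximal gap, every `E*` inside
`[E0, Ef]` is guaranteed a nonempty window. An empty window below the
ground energy is hypoarousal; `E*` above the top bound energy is
hyperarousal; in both, the decision layer is undefined and performance is
scored exactly zero. The resulting performance-versus-`E*` curve is an
inverted U with sharp cliffs at `E0` and `Ef`.

**Kinetic scaling (time-evolution arousal).** The decision state is the
unitary evolution of the neutral uniform superposition
`psi_0 = (1/sqrt(n), ..., 1/sqrt(n))` for the duration of the non-decision
time: `psi(T0) = exp(-i H T0) psi_0`. Arousal is the kinetic scale
`alpha`. At `alpha = 0` the Hamiltonian is diagonal and only phases move,
so the drift is identically zero; at very large `alpha` the kinetic term
dwarfs the potential and the evolution is effectively free, so the
asymmetry between the wells again fades. In between there is an optimal
`alpha`, producing a smooth inverted-U performance curve — the
Yerkes-Dodson pattern — without the eigenstate method's cliffs.

## Design choices in detail

Several points are underdetermined by the conceptual model; the package
resolves them as follows.

*Edge energy.* The regions between the outer walls and the wells have no
prescribed energy; `E_edge` defaults to the middle-region energy `Em` and
is configurable.

*Wall placement and grids.* A `spatial_grid(x_min, x_max, n)` includes
both endpoints and treats all `n` points as dynamical; the Dirichlet walls
implied by the Numerov stencil sit one spacing outside the grid. The
discrete system is therefore exactly a hard box of length
`(x_max - x_min) + 2 dx`, which is the length analytic comparisons should
use. An optional `pad` adds barrier-energy points beyond the box as a
sensitivity check on the hard-wall truncation.

*Region membership.* Points left of the box center are assigned by
half-open `[l, r)` intervals, points right of it by the mirrored rule
`(l, r]`. A point exactly on a well's inner boundary thus belongs to the
middle region, and the final grid point belongs to the right edge. The
mirrored rule matters: with a single global half-open convention, two
equal-width wells can capture point counts differing by one (a pure
phase effect of the grid), which would leave a spurious drift of order
`lam/n` on perfectly symmetric landscapes. With mirrored membership,
reflecting the landscape reflects the potential vector exactly and the
symmetric-landscape drift vanishes to machine precision — a null the test
suite asserts at 1e-10.

*Propagation.* `propagate()` uses the full spectral decomposition of `H` —
exact for the discretized operator, unconditionally norm-preserving, and
reusable across evolution times and `alpha` scans. Eigenvector signs are
fixed (first significant component positive) so decompositions are
deterministic.

*Sampling distribution.* `p(E)` defaults to uniform on `(0, Emax]` with
`Emax = 2 Eb`: the least informative choice on a scale where `Eb = 1`.
A truncated normal is available when a unimodal arousal distribution is
wanted. The hypoarousal rule is operational: an empty selection window
with `E*` below the ground energy. (A literal "negative energy" condition
would be unreachable under a sampler supported on positive energies.) An
empty bound spectrum is classified as hyperarousal: any demanded energy
exceeds the highest supported perceptual state, there being none.

*Method A performance.* Within the engaged band the curve reports, by
default, the *expected* DDM accuracy under the uniform within-window
selection — deterministic and smooth where the stochastic single-draw
protocol would be noisy; the raw drift is available via
`measure = "drift"`, and single stochastic draws via
`sample_arousal_state()`.

*Averaging window.* Empirical non-decision times jitter across trials, so
arousal scans average the drift over `k_times = 11` evolution times in
`[T0 - 0.05 T0, T0 + 0.05 T0]`. The *fitting objective*, by contrast,
evaluates the drift at the single fitted `T0`: the window is a
presentation-stage average around an already-fitted time, and keeping it
out of the objective makes the forward model cheap and the fit
well-defined.

## The parameter-sharing fit

Fitting a `P x C` table of mean drift rates (participants by coherence
levels) uses `6 + C + P` free parameters instead of `P * C`:

* fixed: `Eb = 1` (scale), middle width `m_gap` (default 0.6), `xbL = 0`;
* shared: `EwL`, `Em`, `w`, `e`, `T0`, `lam` (6);
* per coherence: the correct-well bottom `EwR[c]` — the stimulus defines
  the landscape, identically for everyone;
* per participant: the kinetic scale `alpha[p]` — individual differences
  are arousal differences.

For 17 participants and 5 coherence levels this is 28 parameters for 85
cells. The objective is the summed squared error; landscapes that violate
the geometry invariants during search receive a large finite penalty
(1e6) so swarm trajectories stay inside the search dynamics rather than
dying on exceptions. Default bounds: energies in `[0, Eb)`, widths in
`(0, 5]` (edge width may reach 0), `T0` in the conventional 0.2-0.5 s
band, `lam` in `(0, 10]`, `alpha` in `(0, 200]` (the scan interval).

The optimizer is a seeded global-best particle swarm (60 particles,
up to 300 iterations, 3 restarts by default) with the stopping semantics
common to particle-swarm implementations: stall-based termination (20
iterations without relative improvement above 1e-6), an optional
objective limit that also short-circuits remaining restarts, and a
bounded quasi-Newton polish (`L-BFGS-B`) from the best swarm point.
Because no installed R package provides a particle swarm, the optimizer
is implemented in the package (`R/pso.R`); it is deliberately compact and
fully seeded.

Search runs on a 256-point grid for speed. The hot loop — one full
symmetric eigendecomposition per (participant, coherence) cell per
objective evaluation — is a small RcppArmadillo kernel; a unit test pins
the kernel to the R-level `uniform_initial_state -> propagate -> mie ->
drift_from_mie` pipeline at 1e-9 absolute, so the compiled path is an
implementation detail, not a second model.

## What the synthetic generator does and does not emulate

`generate_synthetic_table()` produces drift tables from known parameters
plus independent Gaussian noise — the stand-in for an empirically fitted
participant-by-coherence drift-rate table. The packaged recovery scenario
(`recovery_scenario()`) uses 3 participants x 2 coherence levels (8% and
32%) with shared landscape `EwL = 0.45`, `Em = 0.85`, `w = 1.1`,
`e = 0.3`, `m_gap = 0.6`, `T0 = 0.3 s`, `lam = 5`, well bottoms
`EwR = 0.38, 0.12` and kinetic scales `alpha = 3, 6, 12`. These values
were chosen once as a physically sensible family — several bound states
below the barrier at eigenstate-regime kinetic scales, clear asymmetric
localization, an interior optimum on the `[0, 200]` arousal scan — and
are the same family shipped as the five coherence-graded configs under
`inst/extdata` (`EwR = 0.43, 0.38, 0.31, 0.20, 0.05` for coherence
0/4/8/16/32%; the 0% member is nearly symmetric, so its drift is nearly
zero, as fitted drifts at zero coherence are).

What passing recovery tests show is that the pipeline — generator,
forward model, objective, optimizer — is internally consistent and that
the coherence ordering of well depths is recoverable. They do not show
identifiability of individual parameters: with `6 + C + P` parameters
against `P * C` cells the small scenario is deliberately
over-parameterized, and even at scale several parameters trade off
against each other (notably `T0` against the energy scale, and `lam`
against overall depth). Gaussian cell noise is also an idealization of
the sampling error of empirically estimated drift rates, which is
heteroscedastic and correlated within participants.

## Numerical notes

* Problem sizes: unit and property tests run on 48-128 point grids, where
  the physics (symmetry nulls, parity, unitarity) is exact or
  grid-independent; spectral-accuracy checks use 500-2000 points;
  fitting and scan checks use the fitting default of 256.
* The box-spectrum check at `n = 2000` agrees with the analytic ladder to
  ~1e-9 relative once the effective box length is used; the remaining
  error is genuine fourth-order discretization error, `O((k pi / n)^4)`.
* First-passage densities use the classical small-time/large-time series
  pair with the switch at normalized time `t d2 / (2z)^2 = 0.25`; the two
  representations agree to better than 1e-10 across `[0.15, 0.35]`, and
  each defective density integrates to its boundary's absorption
  probability to 1e-6.
* The Euler-Maruyama oracle applies the diffusion-bridge crossing
  correction each step; without it, first-passage simulation at
  `dt = 1e-3` carries an `O(sqrt(dt))` bias several Monte-Carlo standard
  errors wide at 2e5 paths, which would falsely indict the closed forms.
* Degenerate cases: `m_gap = 0` merges the wells (the shared center point
  goes to the zero-width middle region); `e = 0` collapses the edges;
  `alpha = 0` gives a diagonal Hamiltonian whose evolution only rotates
  phases, so every well mass is frozen at its initial value and the drift
  is exactly zero — asserted as an identity, not a tolerance.

## Known limitations

* Closed-system unitary dynamics only; no dissipative (density-matrix)
  variant, which would square the state-space dimension.
* One spatial dimension and exactly two wells; the machinery generalizes
  but nothing here exercises more than 2AFC.
* The DDM layer covers choice probabilities, mean times and first-passage
  densities for symmetric boundaries; it does not fit empirical RT
  distributions (the fitting pipeline targets drift rates only).
* Performance at the hypo/hyper-arousal boundaries is scored exactly
  zero by construction; whether real performance falls off that sharply
  is an open empirical question the model deliberately leaves open.
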