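# wellddm

Quantum square-well models of arousal in two-alternative forced-choice
(2AFC) perceptual decision-making.

## The problem

Drift–diffusion models (DDMs) describe 2AFC decisions — e.g. judging the
direction of a random-dot-motion stimulus — as noisy evidence accumulation
`dx = A dt + sqrt(d2) dW` between absorbing boundaries at `+z` and `-z`,
with response time `RT = T0 + DT`. They fit choices and response times
remarkably well, but say nothing about *arousal*: the Yerkes–Dodson law's
inverted-U relation between alertness and performance has no mechanistic
slot in a standard DDM.

`wellddm` supplies that mechanism. The decision is modelled as a quantum
particle in a one-dimensional potential with two square wells — one per
response option. Well depth encodes signal strength (motion coherence),
well width conceptual generality. The probability mass the wavefunction
accumulates inside each well (its *mean integration efficiency*, MIE)
drives the DDM through the drift mapping

    A = lam * (P_C - P_W),

where `P_C` and `P_W` are the masses in the correct and incorrect wells.
The Hamiltonian is `H = alpha * K + V`, with `K` the Matrix Numerov
discretization of the kinetic operator and `alpha` a kinetic scale.
Arousal enters in one of two ways:

* **Eigenstate sampling** — a sampled criterion energy `E*` selects among
  the bound eigenstates through the spectral window `[E*, E* + delta]`;
  energies outside the bound spectrum mean hypo-/hyper-arousal and zero
  performance (an inverted U with sharp cliffs).
* **Kinetic scaling** — the neutral uniform state evolves unitarily for
  the non-decision time `T0` under kinetic scale `alpha`; the drift is
  zero at `alpha = 0`, fades again as kinetic energy swamps the landscape,
  and peaks at an interior `alpha` (a smooth inverted U).

A parameter-sharing pipeline fits participant-by-coherence drift-rate
tables with `6 + C + P` parameters (barrier fixed at `Eb = 1`; landscape
shared; per-coherence correct-well depth; per-participant `alpha`) — 28
parameters for a classic 17-participant, 5-coherence dataset of 85 drift
rates — using a seeded particle swarm with quasi-Newton polish.

## Worked example

```r
library(wellddm)

# a landscape whose right (correct) well is deeper: barrier Eb = 1,
# well bottoms 0.45 / 0.12, middle region at 0.85
spec <- well_spec(EwL = 0.45, EwR = 0.12, Em = 0.85,
                  w = 1.1, e = 0.3, m_gap = 0.6)

# kinetic-scaling arousal: evolve the neutral state for T0 = 0.3 s
A <- method_b_drift(spec, alpha = 6, T0 = 0.3, lam = 5, k_times = 1)
A
#> [1] 0.1657384

# feed the drift into the DDM layer
pred <- ddm_predict(ddm_spec(A = A, d2 = 1, z = 1, T0 = 0.3))
pred
#> <ddm_prediction> p(correct) = 0.5821, mean DT = 0.9909 s, mean RT = 1.2909 s

# arousal scan: inverted-U performance curve over alpha in [0, 200]
curve <- yerkes_dodson_scan(spec, seq(0, 200, length.out = 50),
                            T0 = 0.3, lam = 5, n = 256)
curve$arousal[which.max(curve$performance)]
#> [1] 4.081633
```

The drift is zero for `alpha = 0` (a diagonal Hamiltonian only rotates
phases) and for any left-right symmetric landscape; it peaks at an
interior kinetic scale — the Yerkes–Dodson pattern. `p(correct)` and the
RT densities come from the closed-form Wiener first-passage expressions,
cross-checked in the test suite against a bias-corrected Euler–Maruyama
simulator (`simulate_paths()`).

Fitting and recovery:

```r
scen <- recovery_scenario()          # P = 3 x C = 2 known generator
tab <- generate_synthetic_table(scen$theta, scen$scheme, noise_sd = 0,
                                grid_n = 256)
fit <- fit_drift_table(tab, scen$scheme, seed = 1, objective_limit = 1e-8)
fit$sse                              # ~0: the generator is recovered
```

Command line:

```sh
Rscript inst/cli/wellddm yd-scan --config inst/extdata/coherence_16.yaml --out curve.csv
Rscript inst/cli/wellddm recover --seed 7 --out recovery.json
```

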