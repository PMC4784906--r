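---
title: "Noise-induced oscillations from promoter architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-induced oscillations from promoter architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promosc)
```

## The circuit

A single gene encodes its own repressor. The promoter carries `N` identical
binding sites; synthesis proceeds at rate `a` only while *no* repressor is
bound, and free repressor is degraded at rate `g`. The promoter therefore
moves on a ladder of occupancy states `0, 1, ..., N` with binding constants

    kon[s] = eps^(s-1) * (N + 1 - s) * p     (transition s-1 -> s)
    koff[s] = s * q                          (transition s -> s-1)

combinatorial site counting times a cooperative enhancement `eps` per
repressor already bound (`eps = 1` means independent sites). The network has
`N + 2` species (ladder states plus repressor) and `2N + 2` reactions;
binding consumes a free repressor molecule and unbinding releases it.

There is no explicit delay and no post-transcriptional step. The interest of
the circuit is that the *ladder itself* buffers time: once repressor is
abundant the promoter tends to fill completely, and expression only resumes
after a cascade of unbinding events. In a cell-sized volume this produces
degrade-and-fire excursions — sustained, noisy oscillations — even though the
deterministic rate equations converge to a stable fixed point for every
parameter set we have examined.

## Units: why the analysis runs in molecule counts

The package works with the repressor in *molecule counts* and the promoter in
occupancy fractions. Binding constants act per repressor molecule (`kon * n`,
with `p` numerically as published in concentration units), while the
synthesis flux is specified in µM min⁻¹ and converted through the volume
factor `Phi = N_A * omega * 1e-6` (`counts_per_micromolar()`; ≈ 602.2
molecules per µM at 1 fL).

This convention is a deliberate reconstruction choice. Read strictly in
concentration units, the reference parameter set (`p = 1.7e-3`, `q = 0.75`,
`eps = 9`, `a0 = 0.075`, `g0 = 0.3`, `omega = 1e-15` L) produces an almost
unrepressed promoter (`phi0* = 0.998`) with a purely real Jacobian spectrum —
no damped oscillation and no spectral peak, contradicting every reported
behaviour of the circuit. Under the count convention the same numbers give a
stable focus with eigenfrequency 0.3727 rad min⁻¹ (damped period ≈ 17 min),
bursty stochastic trajectories spanning hundreds of molecules, and spectral
peaks where the study reports them. No uniform rescaling of units can map one
reading onto the other (diagonal changes of variables leave spectral shapes
invariant), so the count reading is the only one consistent with the reported
phenomenology. One consequence worth noting: the volume `omega` is a physical
dial here, not a pure noise scale — changing it changes the circuit.

## Deterministic level

`integrate_circuit()` integrates the full `N + 2` system with `deSolve::lsoda`
(relative tolerance 1e-8). The state keeps all ladder fractions (no
conservation elimination) so that the Jacobian and diffusion matrices retain
the shape the fluctuation formula expects; the structural zero eigenvalue
along the conservation direction is discounted during stability
classification with a scale-free tolerance (`1e-9` of the spectral radius).

`find_fixed_point()` exploits detailed balance on the ladder: conditional on
the repressor level `c`, `phi_i(c) ∝ prod_{j<=i} kon[j] c / koff[j]`, and the
binding/unbinding terms cancel in the repressor balance, leaving the scalar
root problem `a * phi_0(c) = g * c`, bracketed on `(0, a/g]`. The left end is
positive and the right end negative for every monotone ladder, so the
bracketed root always exists; the residual of the full system at the solution
is below 1e-10 for all tested parameter sets, and the same point is recovered
by a full-dimensional Newton solve and by the long-time limit of the
integrator. The default initial condition (empty promoter, no repressor) is
the experimentally natural induction start; the fixed point is unique and
attracting in every regime we probed, so the choice only affects transients.

## Fluctuation spectra: the two noise conventions

About a stable fixed point the stationary fluctuation spectrum of species `i`
is

    S_i(w) = (Phi / pi) * [ (-J + iwI)^-1 D (-J' - iwI)^-1 ]_ii

with `J` the Jacobian and `D` the diffusion matrix. `diffusion_matrix()`
implements the textbook form `D = S diag(f) S'` with all `2N + 2` reaction
propensities. `lna_spectrum()` evaluates the formula by complex linear solves
on a configurable grid (default 0.001–5 rad min⁻¹, step 0.001, which covers
every peak the circuit produces and makes peak/Q90 readings grid-converged to
better than 0.5%).

The `noise` argument selects which reactions drive the linearized
fluctuations:

* `noise = "full"` keeps the complete `D`. This is the orthodox linear noise
  approximation — and for this circuit it is known to be qualitatively wrong,
  because the promoter is a *single-copy, binary* variable whose noise is as
  large as its range. Linearizing it inflates the low-frequency power fed
  through the synthesis gain: at the reference point the resulting repressor
  spectrum peaks at 0.256 rad min⁻¹ with a floor above 90% of the peak, so
  the quality factor is undefined even in the strongly oscillatory regime.
  (We validated this evaluation independently by simulating the linear
  stochastic differential equation and estimating its spectrum; the two
  agree, so this behaviour is a property of the approximation, not a bug.)
* `noise = "expression"` (default) keeps only the repressor
  synthesis/degradation shot noise (`D` restricted to the repressor
  coordinate) and treats the promoter deterministically inside the noise
  term. This hybrid gives a clean resonance at the damped eigenfrequency:
  at the reference point a single interior peak at 0.414 rad min⁻¹ with
  Q90 = 2.17, undefined quality at `eps = 2`, quality maximal near
  `lambda = 2` and undefined for slow synthesis/degradation, and markedly
  higher quality for `N = 5` — the full phenomenology this mechanism study
  reports. It is the convention used for all reported spectra and phase
  diagrams in this package.

Both conventions coincide for a plain birth-death process, where the spectrum
is the Lorentzian `(Phi/pi) * 2a / (g^2 + w^2)`; the test suite pins the
evaluator to that closed form at 1e-8 relative accuracy.

The exact stochastic spectrum remains the gold standard, and neither
linearization tracks it everywhere: at the reference point the simulated
spectrum peaks at ≈ 0.36 rad min⁻¹ (between the two conventions, much closer
in shape to the expression-noise curve), while at large `lambda` the
simulated peak stays near 0.38 rad min⁻¹ even though the expression-noise
spectrum climbs to ≈ 1.6 rad min⁻¹. Spectral claims at `lambda ≳ 4` should
therefore be read as statements about the linearized model, and checked by
simulation before being interpreted physically.

## Exact stochastic simulation

`simulate_circuit()` is a direct-method Gillespie sampler (two uniforms per
event) over the `2N + 2` reactions, written in C++ for throughput; with
`2N + 2 ≤ 12` reactions there is nothing to gain from dependency graphs or
tau-leaping. The promoter is a single categorical state, the repressor an
integer count. Default burn-in is 200 min — several multiples of the slowest
relaxation time across the swept regimes — and the default initial state
(promoter empty, `n = round(c*)`) shortens the transient further.
Reproducibility comes from R's RNG stream, so `seed` gives bit-identical
trajectories.

`simulate_batch()` records only the repressor count on a uniform grid by
zero-order hold (the value at a grid point is the state after the most recent
event), the input needed for spectral estimation; `resample()` applies the
same hold to event-resolved trajectories. The default grid — 4096 samples at
0.2 min, 819.2 min per realization — is the power-of-two grid closest to the
820-min realization length used for the reference spectra.

## Periodogram and the Q90 statistic

`periodogram()` is the plain, unwindowed periodogram of the mean-subtracted
series: power `|X_k|^2 dt / (pi M)` on angular frequencies
`w_k = 2 pi k / (M dt)`. The convention makes the power a one-sided density
per rad min⁻¹: summing `P_k dw` over bins (half weight at Nyquist) recovers
the series variance exactly, and the white-noise expectation is
`variance * dt / pi`. `average_periodograms()` takes the bin-wise mean over
realizations and normalizes the trapezoid integral to one; whether one
normalizes by a bin sum or an integral is immaterial for every reported
statistic, since peak location and Q90 are invariant under positive scaling.

`find_peak()` returns the global maximum among *strict interior* local
maxima, excluding the DC-adjacent bin — this is what distinguishes a genuine
spectral peak from a Lorentzian noise floor, which is monotone and therefore
peakless. Ties break toward the lower frequency. `q90()` finds the two
frequencies where power crosses 90% of the peak, by linear interpolation
between adjacent bins (grid-resolution independent), and reports
`Q90 = omega_hat / delta_omega`. When a peak exists but the floor never drops
below the 90% level, the width — and hence Q90 — is reported as undefined
(`NA`) while the peak frequency stands; `NA` is an explicit outcome
("no clear oscillation"), never coded as zero. When several small maxima
exist, only the global one is used.

The suite cross-checks the geometry on a triangular spectrum (where the
interpolation gives `delta_omega = 0.2 w` exactly) and pins Parseval, the
white-noise level, and the `1/R` variance shrinkage of averaged bins.

## Quasi-steady-state reduction

With the ladder equilibrated at fixed `c`, `occupancy_distribution()` gives
the stationary ladder distribution and `F(c) = pi_0(c)` is the effective
regulatory function (`regulatory_function()`): `F(0) = 1`, strictly
decreasing, with `Kd_eff` from a bracketed root of `F = 1/2`. The effective
Hill coefficient uses the logit-slope convention,
`nH_eff = -d log(F/(1-F)) / d log c` at `Kd_eff` (central differences, step
1e-4 in log c), which is exact on Hill functions: a single non-cooperative
site returns `nH_eff = 1` to 1e-3. Steepness grows with both `eps` and `N`,
and only the ratio `p/q` enters, both verified by scan. The reduced flow
`dc/dt = a F(c) - g c` is one-dimensional, hence cannot oscillate — it
relaxes monotonically to the same fixed point as the full system
(`reduced_integrate()`). This is the cleanest statement of why the
*deterministic* circuit cannot be the oscillator: the oscillation needs
either the ladder's phase lag (damped spirals) or, for sustained rhythms,
the noise.

## Phase-diagram sweeps

`run_sweep()` maps `find_fixed_point() -> lna_spectrum() -> q90()` over an
`(eps, lambda)` grid, where `a = lambda * a0`, `g = lambda * g0`. Scaling
synthesis and degradation together leaves `F(c)` and the fixed point exactly
invariant (asserted to 1e-10 in the tests), so `lambda` isolates the
*time-scale competition* between the ladder and expression turnover. The
default grids — `eps` in {1, 1.5, 2, 3, 5, 7, 9} and `lambda` in {0.5, 0.75,
1, 1.25, 1.5, 2, 3, 4, 8, 16} — bracket all the landmark behaviours: quality
undefined for `lambda < 2`, best quality around `lambda = 2`, fastest peaks
at the largest `lambda`. Failed cells are recorded with their error message
and the sweep continues; undefined quality is `NA`, never 0. Sweeps use the
linearized spectra because exact spectral estimation over 70 cells is orders
of magnitude more expensive; `ssa_spectrum()` exists precisely to spot-check
individual cells.

## What the simulator does and does not emulate

The stochastic simulator *is* the data generator for this package: it
produces exact samples of the jump process the model defines, under the study
conditions (reference rates above, 1 fL volume, single promoter copy,
realizations of ~819 min after a 200-min burn-in; 500 realizations by
default for spectra, against 8000 in the full protocol — the peak location
stabilizes long before the floor does). It does not emulate features of real
gene expression outside the model: no separate transcription/translation
steps, no cell growth, division or dilution, no extrinsic noise, one gene
copy, identical binding sites. Passing tests therefore demonstrate agreement
with the model's own mathematics — ladder distributions, death-process decay,
adiabatic limits — not fidelity to any particular organism's promoter.

## Numerical choices and degenerate inputs

* Root finding: `uniroot` at tolerance 1e-14 on a bracket that provably
  contains the root; `a0 = 0` is accepted and short-circuits to `c* = 0`
  (used by the pure-death oracle).
* Focus/node boundary: eigenvalues are complex "enough" when the imaginary
  part exceeds 1e-9 of the spectral radius; the conservation zero mode is
  excluded before classification.
* `lna_spectrum()` refuses unstable fixed points rather than returning a
  meaningless stationary spectrum.
* Spectral grids exclude zero frequency; `(-J + iwI)` is nonsingular for all
  real `w > 0` at a stable `J` even with the structural zero mode, because
  that mode carries no noise (its left null vector annihilates `D`).
* Degenerate spectra: constant series give identically zero periodograms;
  series shorter than 16 samples are rejected; non-uniform sampling is
  rejected with a pointer to `resample()`.

## Known limitations

* Both linear-noise conventions are approximations; the expression-noise
  default reproduces the reported phenomenology but overestimates the peak
  frequency by ~15% at the reference point relative to exact simulation, and
  increasingly so at large `lambda` (see above). The full-`D` convention is
  included for completeness and for systems with extensive species where it
  is the right object.
* The quality statistic Q90 depends mildly on binning and interpolation
  conventions near broad peaks; on noisy averaged periodograms the raw peak
  location itself has substantial sampling variability unless many hundreds
  of realizations are averaged.
* No bifurcation continuation or limit-cycle machinery is included: the
  deterministic system has none within the explored parameter ranges, and
  the package asserts rather than searches.
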