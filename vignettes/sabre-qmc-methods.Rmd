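---
title: "Quantum Monte Carlo simulation of SABRE hyperpolarization: model and methods"
author: "sabreqmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum Monte Carlo simulation of SABRE hyperpolarization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical problem

Signal Amplification By Reversible Exchange (SABRE) hyperpolarizes nuclear
spins by reversibly binding parahydrogen (H~2~ in its nuclear singlet state)
and a target ligand — typically ^15^N-pyridine or ^15^N-benzonitrile — to an
Ir(IMes) polarization transfer catalyst (PTC). While both are bound, scalar
couplings let the hydride singlet order flow into target-ligand
magnetization, either through level anti-crossings at microtesla fields
(SHEATH-type experiments) or through weak rf irradiation in the rotating
frame at high field (DARTH/LIGHT-type experiments). The catalyst then
dissociates, carrying the polarized ligand into the detected free pool, and
rebinds a fresh, unpolarized one.

The difficulty is that the couplings driving transfer (tens of Hz), the
width set by the PTC lifetime (20–50 ms), and the field/rf matching
conditions are all comparable, so the dynamics are neither fully coherent
nor describable by ensemble-averaged (relaxation-superoperator) equations of
motion: individual dissociation events produce excursions from the mean
density matrix that such methods cannot represent. `sabreqmc` therefore
simulates *individual stochastic trajectories* — exact density-matrix
evolution punctuated by discrete exchange events — and averages an ensemble
of them (a "quantum Monte Carlo" treatment of chemical exchange).

## The model

### Coherent part

A bound complex is a small spin system (3–8 spins here; up to 10 spin-1/2
equivalents supported). Between exchange events the density matrix obeys the
Liouville–von Neumann equation
$$\partial_t \hat\rho = -i[\hat H, \hat\rho],$$
solved segment-by-segment with matrix exponentials from Hermitian
eigendecompositions. Two Hamiltonians are implemented:

* **Low field** (strong-coupling limit, used by SHEATH sequences):
  Zeeman terms $2\pi\gamma_i B_0 \hat I_{z,i}$ for every spin with *signed*
  gyromagnetic ratios, plus the full scalar coupling
  $2\pi J_{ij}\,\hat{\mathbf I}_i\cdot\hat{\mathbf I}_j$ for every pair.
* **High field rotating frame** (DARTH sequences): species offsets
  $\Omega_i \hat S_{z,i}$, full homonuclear couplings, *secular* (z–z
  truncated) heteronuclear couplings, and an rf term
  $\omega_1(t)(\cos\phi\,\hat S_x + \sin\phi\,\hat S_y)$ on the addressed
  species. With the secular approximation switched off and offsets set to
  $\gamma_i B_0$ the two forms coincide, which the test suite uses as a
  consistency check.

Linearly ramped rf amplitudes are propagated with first-order Magnus steps
(midpoint-averaged Hamiltonian) of at most 0.1 ms; at the default ramp rate
of 42 Hz/s the nutation frequency changes by < 0.005 Hz per step, far below
every coupling, and a step-halving test confirms convergence.

### Stochastic part

Chemical exchange is a set of independent dissociation channels — one per
target-ligand group, one for hydride/H~2~ exchange — with mean bound
lifetimes (defaults: 20 ms per ligand for the DARTH tris-pyridine complex,
50 ms for the SHEATH benzonitrile complex, 547 ms for the hydrides). Event
times are sampled per trajectory either

* `uniform_count` (default): exactly `round(T/τ)` i.i.d. uniform times on
  `[0, T]` — the literal Monte Carlo recipe this engine reproduces — or
* `exponential`: a Poisson process, provided for sensitivity checks.

At a target-ligand event the departing spins are removed by **partial trace**
(tensor contraction in the spin product basis) and a fresh ligand state is
tensored back into the same slots. The reduced state of the remaining spins
is *exactly* unchanged — coherences on the PTC survive every event, which is
the property that distinguishes this engine from reduced-equation
approaches. At a hydride event the pair is replaced by fresh hydrogen whose
singlet content is `para_enrichment`, with weight `replenish_fraction` f
(deterministic mixture by default; a Bernoulli-f variant is provided). The
departing ligand's reduced density matrix is accumulated across the
ensemble: that running average is the experimentally detected free pool, and
it seeds the pulse-acquire spectrum synthesis.

### Isotopic dilution

When the target enrichment ζ < 1 most catalysts carry no polarizable ligand.
The mean hyperpolarization-inactive period is $T_\mathrm{inactive} =
(k_d\,\zeta)^{-1}$. Dilute trajectories start at a uniformly random
activation time in $[0, T_\mathrm{inactive} + T_\mathrm{sim}]$ and are
frozen once their single active ligand dissociates (the replacement is
almost surely unpolarizable and, being far off resonance, does not evolve
under the pulse). In the quasi-CW regime ($T_\mathrm{inactive} \gg$
hydride lifetime) this reproduces the single-binding picture in which each
active complex sees at most one pulse.

An auxiliary quadrupolar ^14^N (spin-1) can be included; its reduced state
is damped toward maximal mixing with time constant $T_Q$ (2.2 ms by
default), interleaved with coherent steps of $T_Q/20$ by first-order
splitting (error second order in the step). Uniform damping of populations
and coherences is assumed — the minimal phenomenological model when only
$T_Q$ is known; this is a documented simplification, not a mechanism.

## Pulse sequences

* `sheath_sequence()`: n × [τ~p~ at the evolution field (default 0.6 µT,
  near the hydride–^15^N anti-crossing), τ~d~ at the storage field (default
  55 µT, ~100-fold higher)]. From fresh singlet order the storage field
  transfers about four orders of magnitude less than the evolution field
  over the respective default durations — that ratio, not the phase wobble
  of an already-created coherence, is how the suite tests the "storage"
  contract: after a transfer pulse the state carries coherences whose
  bounded oscillation at 55 µT (mixing coefficient J/Δν ≈ 1–2%) is
  physically unavoidable and does not constitute transfer.
* `darth_sequence()`: n × [ramped rf pulse on ^15^N (ω₁ starting at 32 Hz,
  ramping at 42 Hz/s, restarting each pulse), optional ideal 90°~x~ ^1^H
  refocusing pulse, free-evolution delay]. The rotating-frame offset is a
  free knob defaulting to 0 in the builder; **the presets set it to
  +20 Hz**. This is a deliberate design decision: exactly on resonance the
  effective field is purely transverse and, by symmetry, the target
  z-magnetization is identically zero for all time — transfer goes entirely
  to the spin-lock axis. The experiment is described as "slightly off
  resonance", and a tilt of the order of the dominant ²J~NH~ (≈ 23 Hz)
  projects the transferred order onto z. The +20 Hz value was fixed from
  this argument before any acceptance quantity was measured.
* `darth_exsy_sequence()`: one single-pulse sequence per delay; the
  EXSY observable is the hyperpolarized hydride magnetization carried into
  the free pool during the delay, fitted by
  `fit_exsy_lifetime()` with the model $A_0 e^{-\tau/\tau_{ex}}
  e^{-\tau/T_1}$ and $T_1$ held fixed (888.4 ms by default usage). Reading
  "weighted with T₁" as a multiplicative fixed-T₁ factor in the forward
  model is one of two possible interpretations; it is the one implemented.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| J~HH'~ | −7 | Hz | hydride–hydride coupling; sets singlet protection and matching |
| ²J~NH~ trans / cis | −23 / −1 | Hz | transfer-driving couplings; **approximate** (figure-only in the source), overridable |
| ligand lifetime | 0.020 / 0.050 | s | DARTH / SHEATH PTC lifetimes from the fitted experiments |
| hydride lifetime | 0.547 | s | slow H₂ exchange; limits singlet replenishment |
| B evolution / storage | 0.6 / 55 | µT | SHEATH anti-crossing and storage fields |
| ω₁ init / ramp | 32 / 42 | Hz, Hz/s | DARTH adiabatic ramp |
| DARTH offset | +20 (presets) | Hz | see above; 0 in the raw builder |
| f (replenish) | 1 | — | unprinted in the source; depletion is carried by the 547 ms hydride lifetime |
| ζ, T_Q | 0.14, 2.2 ms | —, s | dilute fixture enrichment and ^14^N quadrupolar time |

## What the synthetic world does and does not establish

The built-in fixtures are *stated worlds*, not fits: J values are standard
literature magnitudes for Ir-IMes SABRE complexes because the source
reports them only graphically. A green test establishes that the engine
reproduces the structural claims — coherence-preserving exchange, ~1% Monte
Carlo error at 1600 iterations, 1/√N error scaling, singlet-order
consumption, the pulsed-beats-static direction at equal experiment length —
on systems of the right topology and timescales. It does **not** establish
the experimental enhancement values (ε = 1350, 2.5× over baseline, 4.5%
^15^N polarization, factor-47 per-pulse variation): those depend on
unprinted couplings and conditions and are out of scope by design.

Two observable recording modes exist because they answer different
questions: the *bound-complex* expectation (mode a) shows the coherent
dynamics and is reset toward zero by every ligand exchange; the *detected
pool* (mode b, `pool_z` = cumulative dissociated-ligand polarization plus
the bound residue) is what an experiment measures and is the quantity used
for ensemble-convergence checks — the bound expectation alone has a
near-zero mean with an ill-defined relative error.

## Numerical choices

* Hamiltonians are built in rad/s; all interfaces speak Hz, µT, s.
* Constant-segment propagators come from one cached Hermitian
  eigendecomposition per distinct segment; caches are shared across an
  entire ensemble (this, plus precomputed index tables for the exchange
  contraction, is what makes 10⁵-trajectory references feasible in R).
* Exchange events use precomputed linear-index contractions over the
  contiguous ligand block; they are bit-identical to the generic
  `ptrace()`/`embed_state()` path (tested).
* Ensemble reproducibility: one master seed generates per-trajectory
  substreams (`sample.int` of 2³¹−2); identical seeds give bit-identical
  results regardless of how trajectories are batched.
* Degenerate inputs: zero-duration segments are dropped; `mean_lifetime =
  Inf` disables a channel; a storage field at or below the evolution field
  warns rather than errors (the physics is well defined, merely useless).
* The trailing-window exchange baseline defaults to the last 20% of the
  grid.
* Positivity is monitored (eigenvalue floor −10⁻⁸) rather than enforced;
  unitary evolution plus convex event maps cannot violate it beyond
  round-off.

## Known limitations

* No T₁/T₂ relaxation of spin-1/2 nuclei during evolution — the hydride T₁
  enters only as the fixed weight in the EXSY fit, per the measurement's
  design.
* Exchange is first-order by construction; the second-order kinetics of H₂
  exchange are represented only through the effective hydride lifetime.
* Ideal, instantaneous field switching and hard pulses; shaped pulses
  beyond linear rf ramps are out of scope.
* One rf channel at a time.
* The spin-ordering convention (hydrides first, groups contiguous) is a
  hard layout requirement, enforced at build time.
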