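# sabreqmc

Quantum Monte Carlo simulation of SABRE hyperpolarization dynamics in R.

## What problem this solves, and for whom

SABRE (Signal Amplification By Reversible Exchange) hyperpolarizes
spin-1/2 nuclei — most importantly ¹⁵N — by reversibly binding parahydrogen
and a target ligand to an iridium polarization transfer catalyst (PTC).
While bound, scalar couplings convert hydride singlet order into target
magnetization, at microtesla fields (SABRE-SHEATH and its pulsed, coherent
variant) or in the rotating frame at high field (DARTH-SABRE). The catch for
anyone modelling these experiments: the couplings (tens of Hz) and the
exchange rates (PTC lifetimes of 20–50 ms) live on the same timescale, so
neither a fully coherent treatment nor ensemble-averaged equations of motion
describe the dynamics. This package is for magnetic-resonance
methodologists who need a faithful simulator of that regime.

The engine simulates **individual stochastic trajectories**: exact
Liouville–von Neumann propagation of the bound complex's density matrix

$$\partial_t\hat\rho = -i[\hat H,\hat\rho],\qquad
\hat H_{\rm low} = \sum_i 2\pi\gamma_i B_0\hat I_{z,i}
 + 2\pi\sum_{i<j}J_{ij}\,\hat{\mathbf I}_i\cdot\hat{\mathbf I}_j,$$

interrupted by discrete dissociation events sampled from the exchange model.
A dissociating ligand is removed by partial trace and a fresh, unpolarized
one is tensored back in — coherences among the spins still on the catalyst
are *exactly* preserved — and the hydride singlet is fractionally
replenished on H₂ exchange. Averaging 10²–10⁵ such trajectories (with
per-trajectory RNG substreams off one master seed) gives ensemble means,
standard errors, and the accumulated density matrix of the dissociated
ligand pool, which is what the experiment detects and what seeds the
pulse-acquire spectrum synthesis.

Included: the four canonical model systems (3-spin AA'X, 4-spin AA'XX',
4-spin AA'XQ with a quadrupolar ¹⁴N auxiliary, 8-spin AA'(XB₂)(X'B'₂));
pulsed-SHEATH, DARTH (adiabatically ramped rf), quasi-CW and DARTH-EXSY
sequences; isotopic-dilution inactive periods; ¹⁴N quadrupolar damping;
EXSY lifetime fitting; a JSON-config CLI.

## Worked example

Pulsed coherent SHEATH on the AA'X (¹⁵N-benzonitrile) system: 50 ms
evolution periods at 0.6 µT interleaved with 350 ms storage periods at
55 µT, ligand lifetime 50 ms, hydride lifetime 547 ms:

```r
library(sabreqmc)

fx  <- generate_fixture("aax_sheath")
ens <- run_ensemble(fx$system, fx$sequence, fx$model, 1600, master_seed = 7,
                    grid = seq(0, fx$sequence$duration, length.out = 25))
ens
#> <ensemble_result: 1600 iterations, 25 time points, seed 7>
#>   observables: target_z, target_pool_z, hydride_singlet
#>   mean dissociation events per trajectory: 52.00
#>   terminal means:  target_z = 6.0813e-07, target_pool_z = -0.24426, hydride_singlet = 0.45479

exchange_baseline(ens, observable = "target_z")$value
#> -0.002326 (bound-complex 15N z-magnetization the dynamics converge to)

200 * ens$mean[25, "target_pool_z"]
#> -48.9  (% of maximum polarization in the detected 15N pool)
```

Reading the numbers: the *bound* ¹⁵N expectation (`target_z`) is tiny
because every ~50 ms exchange event replaces the polarized ligand with a
fresh one — the polarization has not vanished, it has moved into the
detected free pool (`target_pool_z`), which accumulates to −0.244 in
⟨I_z⟩ units, i.e. ≈ 49% of maximum polarization (negative sign: ¹⁵N's
negative gyromagnetic ratio makes the transferred magnetization point
"down" at this matching). `hydride_singlet` shows the singlet-order fuel
partially consumed and partially replenished by the slow (547 ms) H₂
exchange.

Other entry points: `run_trajectory()` (one stochastic realization),
`darth_sequence()` / `sheath_sequence()` / `darth_exsy_sequence()`
(sequence builders), `simulate_spectrum()` (pulse-acquire spectrum from the
accumulated dissociated-ligand state), `fit_exsy_lifetime()` (hydride
lifetime from delayed-detection signals), `load_config()` /
`generate_fixture()` (configuration).

Command line (after install):

```sh
Rscript -e 'sabreqmc::run_cli()' ensemble --fixture aax_sheath \
    --iterations 1600 --seed 7 --out results/
# or: inst/cli/sabreqmc ensemble --fixture aax_sheath ...
```

## Caveats

J-couplings of the built-in systems are approximate literature magnitudes
(the source reports them only graphically) and are config-overridable;
experimental enhancement factors are deliberately out of scope. See the
methods vignette (`vignettes/sabre-qmc-methods.Rmd`) for the model,
assumptions, and design decisions.
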