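# mfdyn

Model-free analysis of protein backbone ¹⁵N relaxation and NMR-ensemble
plasticity, built around the workflow used to characterize the dynamics
of three-finger (Ly-6/uPAR) proteins: small disulfide-stabilized domains
whose rigid β-structural "head" and three mobile loops move on separate
timescales.

For an NMR spectroscopist or structural bioinformatician, the package
answers: given per-residue R1, R2 and heteronuclear NOE (at one or two
fields) and a multi-model structure ensemble, *which residues move, how
fast, and what does that cost in binding free energy?*

## What it computes

**Forward model.** Lipari–Szabo spectral densities for the standard
model set 1–5,

J(ω) = (2/5)·[S²·τ_R/(1+(ωτ_R)²) + (1−S²)·τ′/(1+(ωτ′)²)],
  1/τ′ = 1/τ_R + 1/τ_e,

for isotropic or axially symmetric tumbling, and the dipolar + CSA
¹⁵N relaxation equations with a field-squared exchange term added to R2
(`spectral_density()`, `predict_relaxation()`, `rex_at_field()`).

**Inverse problem.** Monoexponential intensity-decay fitting with
duplicate-plane uncertainties (`fit_exponential_decay()`), global
rotational-diffusion fitting on a trimmed rigid subset
(`estimate_tauR_initial()`, `fit_diffusion()`), and per-residue model
selection (stepwise χ²/F-test, Mandel-style) with Monte-Carlo parameter
errors (`fit_residue_models()`).

**Classification.** The threshold rules of the field: S² < 0.8 marks
high-amplitude ps–ns motion; R_ex > 3.0 s⁻¹ at 800 MHz (2.3 at 700,
1.7 at 600 — quadratic field scaling) marks µs–ms exchange; doubled
resonances mark ms–s two-state exchange; the R1·R2 product serves as an
independent exchange indicator (`classify_residue()`,
`rex_threshold()`, `r1r2_indicator()`).

**Region aggregation & ensemble geometry.** Cys-anchored region schemes
(loops I–III, C-tail, head), mean S² per region, iterative-mean Kabsch
superposition of 20-model NMR ensembles on the stable regions, and
per-residue displacement / per-region RMSD disorder profiles
(`region_scheme()`, `region_mean()`, `superpose_ensemble()`,
`disorder_profile()`).

**Thermodynamics.** Backbone conformational entropy from order
parameters via the bond-vector cone relation
S_conf/k_B = ln[π(3 − √(1+8S))], the −TΔS penalty of rigidification,
and the Boltzmann affinity fold-change of a ΔG difference
(`residue_entropy()`, `entropy_penalty()`, `affinity_ratio()`).

**Synthetic data.** A seeded generator for ground-truth parameter
profiles, forward-simulated two-field datasets (with raw intensity
decays at the standard delay schedules), and structure ensembles with
region-scaled disorder (`dynamics_profile_spec()`, `make_profile()`,
`simulate_dataset()`, `simulate_ensemble()`), so the whole pipeline is
benchmarked end to end without downloads.

Sequence/shift utilities (amide temperature coefficients, H/D
half-exchange times, the methanol-d4 thermometer, Kyte–Doolittle and
charge census) and IO for TSV, FASTA, multi-model PDB and NMR-STAR
relaxation saveframes round out the toolkit.

## Worked example

Simulate the packaged 100-residue benchmark (τ_R = 4.3 ns, full triple
at 800 MHz plus R2 at 600 MHz, 3% noise), then recover everything:

```r
library(mfdyn)

spec    <- dynamics_profile_spec(seed = 1)   # the benchmark preset
profile <- make_profile(spec)                # ground truth
dataset <- simulate_dataset(profile, spec)

tensor <- fit_diffusion(dataset, kind = "isotropic")
tensor
#> Rotational diffusion tensor (isotropic): tau_R = 4.28 ns

fit <- fit_residue_models(dataset, tensor, mc_reps = 100, seed = 3)
fit[fit$residue_id == 60, c("model", "s2", "s2_err", "tau_e_ps")]
#>    model      s2     s2_err tau_e_ps
#> 60     2 0.61892 0.01140692 73.87694
```

The recovered τ_R is within 0.6% of the generating 4.3 ns, and residue
60 (a loop III site simulated with model 2) comes back with its order
parameter to ±0.011.  Classify and aggregate:

```r
cl <- classify_dynamics(fit, dataset)
table(cl$labels)
#>                 broadened                fast_ps_ns fast_ps_ns,us_ms_exchange
#>                         2                        33                         2
#>       ms_s_two_conformers                   no_data                   ordered
#>                         2                         3                        52
#>            us_ms_exchange
#>                         6

region_mean(setNames(fit$s2[fit$status == "ok"],
                     fit$residue_id[fit$status == "ok"]), spec$scheme)
#>     region      mean n_available n_total
#> 1   loop_i 0.8593627           9      11
#> 2  loop_ii 0.7950978          16      20
#> 3 loop_iii 0.6536317          14      16
#> 4   c_tail 0.7723917          15      15
#> 5     head 0.8797840          35      37
```

All eight simulated exchange sites are labelled `us_ms_exchange`, and
the region means reproduce the three-finger signature — rigid head
(S² ≈ 0.88), mobile loop III (S² ≈ 0.65) — to within 0.01 of the
ground truth.  Finally, the entropic price of rigidifying 15 such
residues from S² = 0.7 to 0.85 on binding:

```r
entropy_penalty(0.7, 0.85, n_residues = 15, temperature_k = 303.15)
#> Conformational entropy change (cone_bv): S2 0.70 -> 0.85, n = 15, T = 303.15 K
#>   dS    = -11.39 kB (-22.63 cal/mol/K)
#>   -T*dS = +6.86 kcal/mol (+11.39 kB*T)

affinity_ratio(5.7)$fold_change
#> [1] 298.8674
```

A ΔG of 5.7 k_BT corresponds to a ~299-fold (more than two orders of
magnitude) difference in dissociation constant.  Note the recorded
`cone_bv` formula id: the cone relation is sometimes applied with a 1/2
prefactor (`formula = "cone_bv_half"` gives exactly half), and entropy
estimates are only comparable under a stated convention.

`run_pipeline(pipeline_config(seed = 1))` chains all of the above and
`write_report()` emits a deterministic TSV bundle stamped with the seed
and config hash.

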