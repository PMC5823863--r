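# micropk

Micro-pharmacokinetics: quantifying the ligand concentration a membrane
receptor actually sees.

## The problem

Binding affinities are calculated assuming the ligand concentration at the
receptor equals the bulk concentration added to the assay. Lipophilic ligands
of membrane receptors — the fluorescent β₂-adrenoceptor antagonist
BY-propranolol is the motivating case — partition into and interact with the
plasma membrane, and dissociated molecules can rebind neighbouring receptors
before escaping, so the local concentration just above the membrane can be
tens of nanomolar when only 1.8 nM was added. An apparent K_d measured
against the bulk concentration then overstates the true affinity by the same
factor.

Fluorescence correlation spectroscopy (FCS) measures concentration inside a
~0.25 fL focal volume that can be stepped 2–200 µm above a single cell. This
package implements the complete quantification chain for that experiment,
for researchers who want to analyse such data or test the estimators against
simulated ground truth:

* **Simulation** — Brownian-dynamics photon traces from 3D-diffusing
  fluorophores (plus membrane-confined 2D diffusers) sampled by a 3D
  Gaussian detection volume; seeded gradient tables and TR-FRET binding
  plates.
* **Correlation** — brute-force and multi-tau estimators of
  G(τ) = ⟨δI(t)δI(t+τ)⟩/⟨I⟩², symmetric normalization, per-lag errors.
* **Model fitting** — G(τ) = G∞ + (1/N) Σᵢ φᵢ gᵢ(τ) with
  g₃D = (1+τ/τ_D)⁻¹(1+τ/(S²τ_D))^(−1/2) and g₂D = (1+τ/τ_D)⁻¹;
  one free 3D component for solution reads, 3D (dwell time fixed) + one or
  two 2D components for membrane reads, selected by AICc.
* **Quantification** — detection-volume calibration from a reference dye
  (w₀ = √(4Dτ_D), V_eff = π^{3/2} w₀² z₀), C = N/(N_A V_eff),
  D = w₀²/4τ_D, molecular brightness, the closed-form two-species
  brightness correction, and the membrane-phase estimate
  C_mem = N₂D/(N_A π w₀² h) with h = 5 nm.
* **Binding kinetics** — TR-FRET ratios, saturation K_d/B_max, global
  association fits sharing k_on and k_off across concentrations
  (K_d = k_off/k_on, t½ = ln2/k_off).
* **Statistics & correction** — distance/time profiles (mean ± SEM over
  cells), one-sample t-tests against the added concentration, Type-II
  two-way ANOVA with Tukey/Dunnett post-hoc tests, and the true-affinity
  correction K_d^true = K_d^app × L_micro/L_bulk.

## Worked example

The `analysis/` directory is a numbered workflow (simulate → correlate/fit →
gradients/statistics → binding → correction). Running it end-to-end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fcs_pipeline.R
Rscript analysis/03_gradients.R
Rscript analysis/04_binding.R
Rscript analysis/05_true_affinity.R
```

prints, for one seeded realization:

```
<fcs_calibration> w0 = 0.2 um, z0 = 1 um, S = 5, V_eff = 0.2228 fL (gaussian)
solution: N = 0.274, tau_D = 125 us -> 2.04 nM, D = 8.02e-11 m2/s
...
receptor-high 2 um: 43.1 +/- 2.6 nM (n = 13); bulk 200 um: 1.44 nM
16 of 16 near-membrane t-tests reject 1.8 nM at alpha 0.05
...
<saturation_fit> Kd = 1.965 nM (SE 0.174), Bmax = 406
<kinetic_fit> kon = 2.171e+07 M^-1 min^-1, koff = 0.04545 min^-1, Kd = 2.094 nM, t1/2 = 15.25 min
...
<micropk_result> Kd(apparent) = 1.965 nM, L_micro/L_bulk = 23.9-fold -> Kd(true) = 46.99 nM
```

Reading: a 20-s trace simulated at the added 1.8 nM is autocorrelated and
fitted, and the calibrated volume converts the fitted particle number
(N = 0.274) back to ~2 nM; the simulated receptor-expressing cells show
~43 nM two micrometres above the membrane falling to ~1.4 nM in bulk; the
TR-FRET plates return K_d ≈ 2 nM and k_off ≈ 0.045 min⁻¹; and substituting
the near-membrane concentration for the bulk one shifts the apparent
affinity ~24-fold, to ~47 nM. Each value sits within the sampling spread of
its generating truth (1.8 nM, 45.7 nM, 1.8 nM, 0.04 min⁻¹, 25-fold).

Smaller pieces work standalone:

```r
library(micropk)
tr  <- simulate_solution_trace(solution_sim_config(1.8, duration = 20, seed = 11))
fit <- fit_acf(multitau_autocorrelate(tr), "3D", fixed = list(S = 5))
cal <- calibrate_volume(list(tau_d = 31.65e-6, S = 5), dye_D = 3.16e-10)
concentration_from_N(fit$model$total_n, cal)   # ~1.8 nM
true_affinity(1.8, l_bulk = 1.8, l_micro = 45.7)
#> <micropk_result> Kd(apparent) = 1.8 nM, L_micro/L_bulk = 25.4-fold -> Kd(true) = 45.7 nM
```

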