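---
title: "Quantifying local ligand concentrations at cell membranes by FCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local ligand concentrations at cell membranes by FCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Equilibrium and kinetic binding calculations assume the ligand concentration
at the receptor equals the concentration added to the bulk medium. Lipophilic
ligands of membrane receptors violate this assumption: they partition into
and interact with the plasma membrane, and dissociated molecules can rebind
neighbouring receptors before escaping to the bulk, so the concentration in
the receptor's microenvironment can be many-fold higher than the nominal one.
An affinity estimated against the bulk concentration then overstates how
tightly the ligand binds.

Fluorescence correlation spectroscopy (FCS) can measure concentration in a
sub-femtolitre focal volume positioned micrometres above a single cell's
membrane, which makes the local-concentration gradient directly observable.
This package implements the full quantification chain for that experiment —
physically simulated photon traces, multi-tau autocorrelation, diffusion-model
fitting, detection-volume calibration, concentration conversion with a
brightness correction for membrane-bound ligand, TR-FRET binding kinetics,
gradient statistics, and the final "true affinity" correction — so that every
step can be tested against known ground truth.

## The measurement model

An FCS read is a photon-count trace $I(t)$ binned at width $\Delta$. Its
normalized autocorrelation
$$G(\tau) = \frac{\langle \delta I(t)\, \delta I(t+\tau)\rangle}{\langle I \rangle^2}$$
has amplitude $G(0) = 1/N$, with $N$ the mean number of fluorescent molecules
in the effective detection volume, and decays on the diffusional dwell time
$\tau_D = w_0^2 / 4D$ through the focal waist $w_0$. For a 3D Gaussian
detection profile $W = \exp(-2(x^2+y^2)/w_0^2 - 2z^2/z_0^2)$,

* free 3D diffusion: $g_{3D}(\tau) = (1+\tau/\tau_D)^{-1}\,(1+\tau/(S^2\tau_D))^{-1/2}$,
  with structure parameter $S = z_0/w_0$;
* membrane-confined 2D diffusion: $g_{2D}(\tau) = (1+\tau/\tau_D)^{-1}$;
* mixtures: $G(\tau) = G_\infty + \tfrac{1}{N}\sum_i \phi_i\, g_i(\tau)$ with
  fractions $\phi_i$ and a fitted long-time offset $G_\infty$ guarding
  against drift.

Solution reads are fitted with one free 3D component. Membrane-positioned
reads are fitted with one 3D component — its dwell time *fixed* to the
same-session solution value (about 140 µs for the BODIPY-labelled
propranolol this emulates) — plus one or two 2D components; the choice
between one and two is made by corrected AIC, preferring the simpler model
when the AICc difference is under 2.

The detection volume is calibrated from a reference dye of known diffusion
coefficient (Cy5, $D = 3.16 \times 10^{-10}\,\mathrm{m^2/s}$):
$w_0 = \sqrt{4 D \tau_D}$, $z_0 = S w_0$, and
$V_\mathrm{eff} = \pi^{3/2} w_0^2 z_0$ (the standard Gaussian convention,
0.223 fL at $w_0 = 0.2$ µm, $S = 5$). A `cylinder` convention
($\pi w_0^2 \cdot 2 z_0 \approx 0.25$ fL) is also provided because focal
volumes are often quoted that way; every calibration result records which
convention produced it. Concentration follows as
$C = N / (N_A V_\mathrm{eff})$.

### Membrane-bound ligand and the brightness correction

BODIPY-labelled ligands are several-fold brighter in the membrane than in
water (a measured ratio of about 9.1). An autocorrelation fit assumes equal
brightness across components, so the bright membrane species grabs more than
its share of the amplitude. The package keeps the fit and the correction
separate, exactly as the vendor-software workflow does: `fit_acf()` reports
apparent numbers, and `correct_two_species_numbers()` inverts the
brightness-weighted amplitude system
$$A_i = \frac{N_i \eta_i^2}{(\sum_j N_j \eta_j)^2}, \qquad
  T = \frac{1}{A_1 + A_2/r}, \quad N_1 = A_1 T^2, \quad N_2 = A_2 T^2/r^2,$$
in closed form. One subtlety matters here: $\eta$ is the *apparent*
per-particle brightness, which includes a detection-geometry shape factor —
$\varepsilon\,2^{-3/2}$ for a 3D species averaged over the full Gaussian but
$\varepsilon/2$ for a planar species seen only by the lateral Gaussian. A
molecular brightness ratio of 9.1 therefore enters the correction as
$\sqrt{2} \times 9.1$; equivalently, the ratio of uncorrected
counts-per-particle measured in situ (`brightness_cpm()` with
`geometry = "none"`) can be used directly. `brightness_cpm()` applies the
shape factors by default so that it reports molecular brightness and
recovers the simulation's configured ratio.

The corrected membrane particle number is referred to a cylinder with the
area of the focal waist and the height of the lipid bilayer (5 nm), giving a
membrane-phase concentration $C_\mathrm{mem} = N_{2D}/(N_A\,\pi w_0^2 h)$ —
0.278 corrected particles correspond to about 735 nM. Only $w_0$ and $h$
enter; the axial extent of the detection volume is irrelevant for a planar
species.

## The synthetic-data generators

No raw experimental data are distributed with this package, so every input
is generated, seeded and configurable.

**Photon traces** (`simulate_solution_trace()`, `simulate_membrane_trace()`)
are produced by Brownian dynamics: point emitters step with per-axis SD
$\sqrt{2D\Delta}$ in a periodic box, are weighted by the 3D Gaussian profile,
and the summed rate is Poisson-sampled per bin. Design choices, made once:

* **Default conditions.** 20-s reads (matching 30-s-scale experimental
  reads at tractable cost), 40-µs bins ($\tau_D/3.5$; fine enough for
  amplitude work — fits that target the dwell time itself benefit from
  10–20-µs bins, at proportional cost), $w_0 = 0.2$ µm, $z_0 = 1$ µm,
  brightness 50 kHz/molecule, zero background unless configured.
* **Box.** Periodic in all axes, half-widths `box_scale` (default 4, the
  contract minimum) times $w_0$ laterally and $z_0$ axially. For slow 2D
  diffusers ($\tau_{D,2D} \sim 20$ ms) the default lateral box supports only
  a handful of diffusive modes and fattens the ACF tail; membrane analyses
  here use `box_scale = 8`, which restores the continuum decay.
* **Open-system statistics.** The particle count in the box is drawn
  Poisson($C N_A V_\mathrm{box}$) per trace, so the expected amplitude is
  exactly $1/(C N_A V_\mathrm{eff})$; a fixed count would bias $G(0)$ by
  $-1/M$ (about 1% here).
* **Photon model.** Per-bin Poisson on the summed rate; no dead time,
  afterpulsing, triplet blinking or bleaching — deliberately matching the
  assumptions of the analysis model, so recovery tests probe the estimators,
  not photophysics mismatch.

**Gradient tables** (`generate_gradient_dataset()`) emulate the structure of
distance- and time-resolved single-cell measurements: a monotone exponential
decay from a near-membrane concentration at the 2-µm reference distance to
the bulk value, with a 15-µm default decay length. The experiment showed a
decline but no functional form; the exponential is the simplest monotone
choice and is a knob, not an inference. Near-membrane defaults per condition
are the printed values (5.1 / 19.2 / 45.7 / 27.1 nM for no-cell,
receptor-none, receptor-high and receptor-high + antagonist), with bulk
0.8–1.5 nM and n = 8/10/13/7 cells. The time build-up is constant for
no-cell (observed flat), linear for receptor-absent membranes, and a
saturating exponential (45-min half-time, normalized to reach the final
value at 2 h) for receptor-present conditions. Noise is mean-one log-normal
with CV 0.25 per cell-position, approximating the printed SEM-to-mean ratio
near the membrane; negative floors are clipped at 0.01 nM with a warning.
Per-cell sub-seeds are pre-drawn from the root seed so enlarging `n_cells`
never reshuffles earlier cells.

**Binding plates** (`generate_saturation_dataset()`,
`generate_association_timecourses()`) emulate TR-FRET reads in ratio units
(665/620 × 10 000): specific binding $B_\mathrm{max} L/(L+K_d)$ with
$K_d = 1.8$ nM, $k_\mathrm{off} = 0.04\ \mathrm{min^{-1}}$ and
$k_\mathrm{on} = k_\mathrm{off}/K_d \approx 2.2\times 10^7\
\mathrm{M^{-1}min^{-1}}$ by construction, over a linear non-specific
component; association sampled every 30 s for 1 h at four rising
concentrations, saturation over 12 log-spaced points from 0.001 to 300 nM.
Default noise is 2% of the plateau.

What passing tests on these generators do **not** show: robustness to
detector artifacts, photobleaching, triplet dynamics, cell movement, optical
aberrations of the real point-spread function, or non-exponential gradient
shapes. They show that the estimators are correct under the stated model.

## Estimators and numerical choices

* **Correlator.** The brute-force estimator evaluates, at every lag $k$,
  the symmetrically normalized
  $G(k\Delta) = \frac{\sum_i I_i I_{i+k}/(n-k)}{\bar I_\mathrm{head} \bar I_\mathrm{tail}} - 1$;
  separate head/tail means reduce drift bias. The multi-tau estimator uses
  $m = 16$ lags per level and pairwise coarsening, extending to about a
  tenth of the trace duration; its level-0 values are bit-identical to the
  brute-force estimator. Coarsening triangularly averages the true
  correlation; with evaluated lags always at least $m/2$ coarse bins the
  relative bias is bounded by roughly $(2/m)^2$ and is left uncorrected.
  Lag zero (pure shot noise) is excluded everywhere. Per-lag SDs, when
  requested, come from splitting the trace into 10 segments.
* **Fitting.** Levenberg–Marquardt with box bounds
  ($\tau_D \in [1\ \mu s, 10\ s]$, $S \in [2, 10]$ when free,
  $G_\infty \in [-0.5, 0.5]$) and at least five log-spaced dwell-time
  starts; best residual sum of squares wins. Internally the model is
  parameterized by per-component amplitudes $a_i = \phi_i/N$, which keeps
  fractions in $[0,1]$ without constraints. Standard errors come from the
  local curvature, with the delta method for $N$ and $\phi_i$;
  non-convergence and bound-hitting are flagged, never silent. Two 2D
  components are reported in increasing dwell-time order.
* **Kinetics.** Association curves are fitted globally — shared
  $k_\mathrm{on}$, $k_\mathrm{off}$ (on log scale), one free plateau per
  concentration — to specific (total − NSB) signals; a total-signal mode
  with a shared linear NSB term exists. Free plateaus are robust to
  depletion and plateau miscalibration; the constrained alternative is a
  single flag away in the generator truth. Starting values come from
  per-curve brute-force $k_\mathrm{ob}$ scans regressed on $L$. A single
  concentration is refused: with a free plateau, $k_\mathrm{off}$ is not
  identifiable from one curve. Saturation fits flag
  $\mathrm{SE}(K_d)/K_d > 1$ as poorly constrained.
* **Statistics.** Cell-level values are the replicates (one cell, one n).
  The two-way ANOVA reports Type-II F tests with both factors categorical;
  post-hoc comparisons use estimated marginal means with Tukey adjustment
  (all pairwise, optionally per stratum) or a Dunnett-style adjustment
  versus a reference level. The one-sample t-test accepts raw values or a
  printed (mean, SEM, n) summary; the routes coincide exactly. Two-sided
  throughout, $\alpha = 0.05$. A zero-SEM input yields the degenerate
  $p = 0$ with an explicit flag rather than an error.
* **True affinity.** `true_affinity()` is the exact algebra
  $K_d^\mathrm{true} = K_d^\mathrm{app} \cdot L_\mathrm{micro}/L_\mathrm{bulk}$:
  with the defaults (1.8 nM apparent, 1.8 nM bulk, 45.7 nM local) a
  25.4-fold shift to 45.7 nM.

## Problem sizes in the test suite

Recovery suites use 20-s traces: 50 seeds per concentration (1.8, 20 and
45.7 nM) for end-to-end concentration recovery, 9 seeds for the membrane
fraction/dwell suite, 7 for the brightness ratio, 100 replicate plates for
kinetic rate recovery, and 150 simulated null datasets for the ANOVA
calibration, with thresholds set by binomial simulation error. These sizes
give medians stable well inside the asserted bands.

## Known limitations

* The Gaussian detection profile is an idealization; real confocal volumes
  deviate at the few-percent level in calibration.
* The gradient generator's spatial and temporal forms are emulation knobs;
  nothing in the package infers gradient shape from data.
* The brightness correction treats all 2D components with a single ratio,
  and three-species corrections reuse the two-species closed form with both
  2D species pooled.
* At high brightness contrast (ratio ~9) the dim 3D component carries under
  1% of a membrane read's amplitude, so its corrected number is effectively
  unconstrained — a property of the physics, not the estimator.
* Multiplicative noise makes raw concentrations heteroscedastic across
  distances; the ANOVA's nominal type-I rate holds in homoscedastic strata
  (e.g. condition × time at one distance) and inflates moderately when
  variances differ several-fold across cells.
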