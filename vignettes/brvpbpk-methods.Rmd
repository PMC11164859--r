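---
title: "Methods: a whole-body PBPK model of brivaracetam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model of brivaracetam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brvpbpk simulates the pharmacokinetics of brivaracetam — an antiepileptic
cleared mainly by hepatic CYP2C19 with a small renal component — in
healthy adults and in adults with Child-Pugh liver cirrhosis or chronic
kidney disease (CKD). This vignette documents the model, its parameters
and defaults, the numerical choices, and what the synthetic data and
tests do and do not establish.

## Model structure

The body is represented by fourteen compartments: eleven perfused organs
(adipose, bone, brain, gut, heart, kidney, liver, muscle, skin, spleen,
and a `rest` compartment that closes the mass and flow balances), the
lung in series with cardiac output, and arterial and venous blood pools.
Every tissue is perfusion-limited:

$$V_i \frac{dC_i}{dt} = Q_i \left( C_{art} - \frac{C_i \cdot B\!:\!P}{K_{p,i}} \right)$$

with amounts in µmol, flows in L/h of whole blood, and $K_{p,i}$ the
tissue:plasma partition coefficient. The liver receives the hepatic
artery plus the portal outflow of gut and spleen and clears drug by
Michaelis–Menten kinetics on the unbound liver concentration
($V_{max} = k_{cat} \times \mathrm{CYP2C19\ amount} \times
\mathrm{enzyme\ scale}$, $K_m$ = 71.20 µM). The kidney clears unbound
plasma at $CL_{renal} = 0.06\ \mathrm{ml/min/kg} \times \mathrm{weight}
\times \mathrm{GFR}/\mathrm{GFR}_{healthy}$, so renal clearance scales
exactly with GFR.

Oral doses enter a stomach compartment that empties with first-order
half-time equal to the gastric emptying time (default 15 min), into a
chain of three small-intestine segments with total mean transit equal to
the small-intestinal transit time (default 190 min). Each segment
absorbs into gut tissue at a first-order rate
$k_a = P_{eff} \times (S/V)_{eff}$; drug leaving the last segment is
counted as fecal loss. These two transit parameters are exactly the
levers the CKD physiology moves. Dissolution is not modeled: at a
solubility of 850 mg/ml even the 1400 mg dose dissolves in a few ml of
fluid, so it cannot be rate-limiting.

## Drug parameters and partitioning

The shipped `brivaracetam.json` mirrors the published parameter table:
MW 212.29 g/mol, pKa 7.07 (treated as a monoprotic weak base — a single
pKa is reported), logP 1.04, solubility 850 mg/ml, intestinal
permeability 3.36 × 10⁻⁶ (printed without units; interpreted as cm/min,
the convention of the source simulator, and exposed in the config),
CYP2C19 $K_m$ 71.20 µM and $k_{cat}$ 0.81 (interpreted as min⁻¹), renal
clearance 0.06 ml/min/kg. The fraction unbound defaults to 0.61 — the
value the reference model actually integrated — while the literature
range 0.79–0.83 is kept in the config for documentation.

Partition coefficients use the Rodgers–Rowland weak-base equations:
Henderson–Hasselbalch ionization at plasma pH 7.4 and intracellular pH
7.0, partitioning of the neutral species into tissue water, neutral
lipid and neutral phospholipid, and association of the cation with
acidic phospholipids. Tissue composition constants are packaged from the
standard published composition tables of the partitioning literature
(`tissue_composition()`); the adipose lipid term uses the olive-oil
conversion $\log D_{vo} = 1.115 \log P - 1.35$, as is standard for that
tissue.

Two related constants deserve emphasis:

* **Blood:plasma ratio.** Not printed for brivaracetam; derived as
  $B\!:\!P = 1 - hct + hct \cdot f_u \cdot k_{ery}$ with
  $k_{ery} = 1$ by default, overridable in the config.
* **Acidic-phospholipid association ($K_{a,AP}$).** The textbook method
  back-calculates $K_{a,AP}$ from *measured* erythrocyte partitioning.
  Brivaracetam has no measured value here — $k_{ery} = 1$ is itself a
  stand-in — and propagating an assumed constant through that
  back-calculation manufactures tissue binding from a convention: it
  yields a steady-state volume near 1.2 L/kg and a terminal half-life
  near 19 h, where brivaracetam is known to distribute essentially into
  body water (≈0.5–0.6 L/kg) with a half-life of about 9 h. The package
  therefore exposes `ka_ap` as an explicit drug parameter (`NULL`
  retains the back-calculation, which remains implemented and tested)
  and ships `ka_ap = 0` for brivaracetam. With that choice the model's
  simulated half-life is 9.0 h. This is a model-development decision
  made on the drug's established distribution characteristics.

Disease albumin scaling adjusts binding through linear binding-protein
mass action, $f_u' = 1/(1 + s\,(1-f_u)/f_u)$ with $s$ the albumin scale
factor, applied before partitioning and B:P at simulation time.

## Absorption calibration

The printed permeability is a simulator-specific quantity whose
normalization is proprietary. The package folds the geometric and
mucosal-amplification factors into one effective surface-area-to-volume
ratio, default $1.5 \times 10^4$ cm⁻¹, chosen once so that the shipped
permeability reproduces brivaracetam's rapid and essentially complete
oral absorption (absorbed fraction > 95%, $t_{max}$ ≈ 1–1.5 h). It is a
documented constant, not a fitted quantity, and is exposed as the
`sa_v` argument of `simulate_pbpk()`.

## Reference physiology and disease scaling

Reference healthy physiology is a packaged constant table for a 73-kg
adult in the ICRP style: cardiac output 390 L/h, hematocrit 0.45, GFR
110 ml/min/1.73 m², liver inflow = hepatic artery (25.35 L/h) + gut
(58.5) + spleen (11.7). Volumes and flows scale linearly with body
weight relative to 73 kg — the simplest defensible choice for the
40–150 kg range the constructor accepts. Structural invariants (flow
balance to cardiac output, portal composition, positivity) are enforced
by a validator on every construction and transformation.

Child-Pugh cirrhosis scaling is a packaged per-class table (albumin
scale 0.90/0.75/0.60, hematocrit 0.41/0.37/0.34, GFR scale
0.90/0.70/0.45, hepatic perfusion scale 0.85/0.65/0.50, liver volume
scale 0.90/0.80/0.65, CYP2C19 abundance scale 0.60/0.35/0.25 for
A/B/C), compiled from the standard cirrhosis-physiology literature.
Every entry is overridable through `disease_spec(overrides = )`. The
published evaluation lists a quintet of cirrhosis values (0.92, 0.4205,
14.56, 24.01, 1.734) without units or class assignment; the two
unambiguous entries are exposed verbatim as the preset
`cirrhosis_reported_overrides()`, the other three are carried
uninterpreted. Hepatic perfusion reduction is rerouted through the
`rest` compartment so cardiac output — and with it the flow-balance
invariant — is preserved.

CKD scaling sets absolute GFR (45 moderate, 20 severe ml/min/1.73 m²)
and adjusts hematocrit (0.37/0.33), albumin scale (0.90/0.80), gastric
emptying (×1.3/×1.6) and small-intestinal transit (×1.2/×1.4). The GFR
values are the published ones; the remaining magnitudes are packaged,
overridable defaults — the mechanism (which parameters change) is the
specified part, their size is configuration.

## Calibration of hepatic activity

The absolute hepatic CYP2C19 amount is not published. Following the
reference model's implicit procedure, `calibrate_hepatic_activity()`
finds by deterministic bisection the enzyme amount at which the NCA
clearance of a simulated single 100 mg IV bolus equals the literature
plasma clearance of 3.4 L/h (convergence tolerance 0.2% relative,
comfortably inside the 1% acceptance band). In the linear regime the
result agrees with the closed-form well-stirred liver algebra to
within 2%, which the test suite checks independently.

## Non-compartmental analysis and evaluation statistics

NCA uses the linear-up/log-down trapezoid (log segment only for
strictly decreasing positive pairs), $C_{max}/t_{max}$ taken exactly
from the samples, and a terminal slope chosen by best adjusted $R^2$
over candidate tails of the last 3–8 positive samples strictly after
$t_{max}$; a non-negative slope flags the fit as failed and leaves the
extrapolated quantities unset. $AUC_{0-\infty} = AUC_{0-t} +
C_{last}/\lambda_z$ and $CL = \mathrm{dose}/AUC_{0-\infty}$ (apparent
CL/F for oral dosing), reported in both L/h and ml/min/kg.

Model evaluation follows the published statistics: the
observed/predicted ratio $R = \mathrm{obs}/\mathrm{pre}$, the average
fold error $AFE = 10^{\sum \log_{10}(\mathrm{fold\ error})/N}$ (the
geometric mean; fold error is taken as the observed/predicted ratio,
the direction consistent with $R$), and a closed two-fold window
$[0.5, 2]$. The shipped `clinical_pk_reference.csv` carries the
published observed and reference-predicted values; two printed cells
required interpretation (documented in the file's tests): one composite
cell decodes uniquely as obs 31.42 / pre 19.524 / R 1.6, and the
clearance columns are on the L/h scale (obs oral CL 3.05 = 100 mg /
32.75 µg·h/ml) despite their ml/min/kg heading.

## Virtual populations, VPC, synthetic observations

`sample_population()` draws weight uniformly over the specified range,
scales physiology allometrically, and applies independent
median-preserving lognormal perturbations (default CVs: flows 0.10,
volumes 0.10, CYP2C19 abundance 0.35, GFR 0.10) — the published
evaluation states only the demographic ranges and the population size
of five hundred, so the varied parameter set is configuration, not a
claim. Cardiac output is recomputed as the sum of sampled flows, so the
balance invariants hold by construction. `vpc_summary()` reports the
pointwise arithmetic mean, empirical 5th/95th percentiles (type-7
linear interpolation between order statistics, frozen by a golden
test), minimum and maximum.

The synthetic-observation generator stands in for digitized clinical
profiles: per-subject simulation at sampled physiology, multiplicative
lognormal residual noise (default CV 20% — digitization plus assay
error are relative), and censoring below 0.01 µg/ml to mimic a
quantification limit. It emulates smooth relative noise around the
model's own predictions; it does not emulate digitization bias,
axis-reading error, or real between-study heterogeneity, so tests built
on it establish internal consistency of the pipeline (for example, the
generate → NCA → evaluate loop closing at AFE = 1 on noise-free data),
not agreement with any particular clinical dataset. Agreement with the
clinical record is tested separately against the shipped published
values.

## Numerical choices

* Integrator: `deSolve::lsoda`, relative tolerance 10⁻⁸, absolute
  10⁻¹⁰ µmol, reporting grid 0.1 h by default. Halving tolerances moves
  $C_{max}$ and AUC by far less than 0.1%.
* Multiple doses are solver event restarts (venous increment for IV,
  stomach increment for oral), avoiding discontinuity artifacts. The
  solver output row at a dose time precedes the event; the mass-balance
  bookkeeping counts doses strictly before each reporting time.
* Mass balance (compartments + eliminated + unabsorbed vs administered)
  holds to ~10⁻¹⁴ relative in practice; the suite enforces 10⁻³.
* Degenerate inputs: zero dose yields an identically zero profile;
  all-zero profiles, non-monotone time grids and rising terminal phases
  are rejected or flagged in NCA rather than silently extrapolated.
* Seeds: every stochastic step (population sampling, residual noise)
  derives from an explicit integer seed; equal seeds give bitwise-equal
  output.

## Problem sizes in the shipped tests

The test suite exercises the model at sizes chosen to probe each
property sharply: population determinism and VPC ordering at n = 25–40
individuals on a 0.5 h grid, distributional recovery of the enzyme CV
at n = 500 sampled physiologies (sampling only), residual-CV recovery
at n = 100 subjects on a three-point schedule, and single-profile
checks on the default 0.1 h grid. The full evaluation chain
(`reproduce_evaluation()`) runs eight scenarios at clinical sampling
schedules.

## Known limitations

* Tissues are perfusion-limited; no permeability-limited organs, no
  enterohepatic recirculation, no transporters, no target-site (SV2A)
  binding.
* CYP2C19 genotype strata (EM/IM/PM) are not modeled — no per-genotype
  kinetic constants are published in the source material.
* The cirrhosis and CKD tables are literature-style defaults, not
  fitted quantities; their magnitudes are deliberately configuration.
* Linear body-weight scaling is crude outside roughly 50–110 kg.
* The single calibrated enzyme amount absorbs any error in liver
  composition, B:P and unbound referencing; it is not an abundance
  measurement.
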