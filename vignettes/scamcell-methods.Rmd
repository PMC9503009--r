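---
title: "Models and methods behind scamcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scamcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scamcell)
```

scamcell simulates and analyses cell-based substituted-cysteine
accessibility (SCAM) assays that read transporter conformation out of
fluorescent-substrate signal in single cells. This vignette is the package's
account of its science: the generative model and its assumptions, the
parameters that matter, the numerical choices in the fitting code, and what
the synthetic data do and do not establish about real experiments.

## The assay, as the package models it

One assay condition is a row of a tidy table (`conditions()`): a transporter
construct, a fluorescent substrate at a concentration, optionally an MTS
reagent at a molar concentration for a fixed exposure, a modification-phase
ligand, one of five 150 mM ion media, a digitonin dose, and an experiment
index. `signal_model()` maps a condition to the expected noise-free
fluorescence of a cell, split into an interior (cytosolic accumulation) and
a membrane-surface component:

* **Specific uptake** is Michaelis–Menten initial-rate transport,
  $V_{max} S/(K_m+S)$, accumulated linearly over the 5-min incubation. The
  wild-type SERT constants for these substrates are the defaults: $K_m$
  2.63 µM (APP⁺) and 8.52 µM (ASP⁺), $V_{max}$ 30.5 and 75.8 AFU. Accumulation is single-timepoint;
  progress curves are out of scope.
* **Ionic requirement.** Specific uptake needs Na⁺ and Cl⁻ together. The
  gate applies to the medium of the *uptake* step. When a condition includes
  an MTS exposure, the listed medium is the modification-phase medium — the
  protocol always washes cells into NaCl buffer before the substrate
  readout — so the gate is open regardless of that medium. Conditions
  without an MTS phase interpret the medium as the uptake medium. This
  distinction is why the ion-panel presets place their untreated reference
  rows in NaCl.
* **Membrane binding (ASP⁺ only)** is saturable, $B_{max} S/(K_d+S)$, with
  defaults $K_d$ 5 µM (micromolar affinity) and $B_{max}$ 40 AFU.
* **Nonspecific signal** is the fluoxetine-insensitive remainder: a
  substrate-independent cellular autofluorescence (1 AFU) plus a component
  linear in substrate concentration. The linear slope is calibrated so that
  exactly 95% of APP⁺ and 84% of ASP⁺ accumulation at the top of the default
  concentration ladder is blockable by 10 µM fluoxetine. The
  autofluorescence term keeps cells detectable in conditions with little
  specific signal (fully blocked or fully modified); because it is part of
  the blocked series, nonspecific subtraction removes it exactly.
* **MTS modification** is pseudo-first-order with a single rate constant per
  cysteine and condition: the unmodified fraction after exposure to
  concentration $c$ for time $t$ is
  $f + (1-f)\,e^{-k_{\mathrm{eff}} c t}$ with an optional unmodifiable floor
  $f$ (default 0). $k_{\mathrm{eff}}$ is a baseline constant per
  (mutant, reagent) times a multiplicative ligand factor and a
  multiplicative ion factor — the model deliberately encodes *fold-changes*,
  not mechanism. Baselines: 70 M⁻¹s⁻¹ (Y107C/C109A·MTSET),
  308 M⁻¹s⁻¹ (S404C/C109A·MTSET), 11.97 (S277C/X5C·MTSEA), 0.05
  (X5C·MTSEA), and 0 for constructs without a reactive cysteine or for
  MTSET against the cytoplasmic pathway.
* **Digitonin permeabilization** (µg/mL) acts three ways: specific uptake
  falls with a Hill curve (IC50 5, slope 2, so under 4% remains at
  25 µg/mL); specific membrane binding is retained at a fraction
  $0.65^{d/25}$ (65% at the working dose of 25); and the modifiable fraction
  of cytoplasmic cysteines by MTSEA follows a piecewise-linear access
  completeness through (10, 0.40), (15, 0.50), (25, 1.0) — the doses at
  which maximal inhibition of binding reaches 40%, 50% and completeness.
* **Exposure times** default to the protocol values: 900 s for MTSET on
  intact cells, 300 s for MTSEA on permeabilized cells; substrate
  accumulation 300 s.

Ligand factors (at 10 µM, on $k_{\mathrm{eff}}$): extracellular pathway —
fluoxetine 2.0, paroxetine 2.2, citalopram 1.7, imipramine 1.9 (the
antidepressant enhancement band), 5-HT 0.5 (substrate protection), 5-HTP and
tryptophan 1.0, vilazodone 1.8; cytoplasmic pathway — fluoxetine 0.5,
citalopram 0.33, 5-HT 2.0, vilazodone 0.5. Ion factors are normalized so
NaCl (the buffer in which baseline constants are defined) is 1: relative to
it, Na⁺-free media sit at 0.8 (extracellular) and 1.25 (cytoplasmic), and
Na⁺ without Cl⁻ at 1.28 and 0.75. "NaCl + 5-HT" composes the NaCl factor
with the 5-HT ligand factor. These place NaCl strictly between
Na-isethionate and NaCl+5-HT on both pathways — the chloride signature the
comparison stage tests for.

## From model to images

`build_scene()` places non-overlapping ellipses (semi-axes 4–8 µm at
0.5 µm/px, default 320 × 320 px fields) by rejection sampling, fully inside
the frame, and partitions each cell into a 3-px membrane ring and an
interior by disc erosion. `render_stack()` writes interior pixels at the
cytosolic value and ring pixels at cytosol + surface value (the 2-D
projection of a labelled membrane over cytosol), scales per-cell specific
components by a lognormal expression factor (CV 0.2 — the single-cell
variability that motivates per-cell quantification), then applies Poisson
shot noise at 4 photons/AFU, Gaussian read noise of 1.5 AFU, a Gaussian PSF
of 1 px, and 16-bit quantization at 100 counts/AFU. The same seed yields
byte-identical TIFFs. `simulate_cells()` is the fast path: the same
mechanism and per-cell variability, emitting the per-cell measurement table
directly with a 1 AFU Gaussian stand-in for residual area-averaged pixel
noise.

None of the geometry or noise defaults are reported by the assay protocols;
they were chosen once as plausible for HeLa fields on a confocal with a
20–60× objective and are stated here rather than inferred.

## Quantification

`quantify_cells()` implements per-cell "counted and normalized to the cell
area" quantification: per-pixel background subtraction (median of non-cell
pixels), `mean_fluor = total/area` floored at zero, and the membrane
decomposition used for ASP⁺: the intracellular component is assumed uniform
across the cell, its contribution under the ring is extrapolated from the
interior mean and subtracted from the total, and the remainder per ring
pixel is the surface signal. This makes
`total = interior + surface_mean × ring_area` an identity, and on noise-free
renders quantification reproduces the generator's truth exactly (the
generator and the quantifier share one erosion definition for the ring, on
purpose). Edge-touching cells are excluded by default — their areas are
truncated — and cells whose interior erodes to nothing are flagged
`too_small`, keeping `mean_fluor` but no decomposition.

`segment_cells()` detects cells by smoothing (σ 1 px), global Otsu
threshold, morphological opening (speckle removal), hole filling and
labelling, with an optional watershed split. Detected cells whose level
stands more than 4 MADs above background are then refined to their
half-maximum boundary: a blurred step edge crosses half its height at the
true edge, so the refinement undoes the halo that a single global threshold
puts around bright cells (which otherwise costs exactly the small, bright
cells their mask accuracy). Low-contrast cells keep the Otsu boundary —
growing them toward a half-maximum that sits inside the noise would invent
area. The area filter is applied permissively at detection (half of
`min_area`, so refinement can rescue weakly expressing cells) and strictly
(150–20 000 px) on the final mask.

## Fitting

**Transport kinetics.** `subtract_nonspecific()` subtracts the
fluoxetine-present series concentration-by-concentration (matched grids
only — no interpolation; negatives floored at zero with a warning), then
`fit_mm()` fits $v = V_{max}S/(K_m+S)$ by unweighted nonlinear least squares
per experiment, reporting curvature-based standard errors, and aggregates
experiments as mean-of-fits ± SEM, not a pooled fit. A $K_m$ beyond the
tested range flags the fit unreliable rather than extrapolating.

**Inhibition curves.** `fit_inhibition()` offers two models. The default
*exponential* model fits the first-order scheme directly for $k$; its
half-maximal concentration is $\ln 2/(kt)$ identically, including with a
floor, because the midpoint between $A_0$ and the floor always sits at
$e^{-kct}=1/2$. The *logistic* model fits an empirical sigmoid
$A_0/(1+(c/c_{50})^h)$ and converts the midpoint through
`rate_constant_from_c50()`; on clean first-order data the two routes agree
to a few percent, which the test suite checks across random $(k, t)$ pairs.
The floor is fixed at zero unless the high-concentration plateau exceeds 5%
of $A_0$: the activity readout is uncorrected accumulation, which carries a
~7% nonspecific plateau under the generator defaults, and leaving that
plateau unmodeled biases $k$ low by about 12% (a 20-replicate check drops
the bias to ~1% with the 5% trigger). When maximal observed inhibition is
under 20%, no rate is fitted; the result is *below detection* with the
bound $\ln 2/(t\,c_{max})$ — the honest rendering of "no measurable
inhibition" entries, instead of a pseudo-value beyond the tested range.

**Fixed-concentration protocols.** With the reagent applied once near its
half-inhibiting concentration, `fixed_concentration_protection()`
back-calculates the rate fold under the first-order model,
$k_{lig}/k_{ctrl} = \log(A_{lig}/A_0)/\log(A_{ctrl}/A_0)$, warning when the
control sits outside 0.3–0.7 of untreated (where the back-calculation loses
precision), calling full protection at $A_{lig} \ge A_0$ and capping at
zero activity. The pipeline generalizes this to per-experiment rate
constants $k = -\log(A/A_0)/(ct)$ so ladder-based and fixed-concentration
designs feed the same comparison machinery.

## Comparison and classification

`compare_conditions()` pairs per-experiment rate constants by experiment,
tests them with Student's paired t-test (two-sided; a perfectly consistent
nonzero difference short-circuits to p = 0, identical values to p = 1), and
summarizes the effect as the *geometric* mean of per-experiment ratios —
chosen over the arithmetic mean so that swapping condition and control
inverts the fold exactly while the t-test's two-sided p is unchanged
(antisymmetry). A direction is called only when p < α (0.05, per-contrast,
no multiplicity correction by default — matching per-panel asterisk
conventions) *and* the fold clears a minimal magnitude (1.2). Pairing is by
experiment, matching "mean ± SEM of three experiments" reporting.

`call_conformation()` maps the two pathway directions to a call:
extracellular up + cytoplasmic down is *outward-open stabilized*; the
reverse is *inward-open shifted* when both folds pass the full-shift
thresholds (≤ 0.6 extracellular, ≥ 1.67 cytoplasmic) and
*partial/intermediate* otherwise — the pattern expected of Cl⁻ alone; both
unchanged is *no change*; anything else *discordant*.
`ion_panel_analysis()` runs the ordered contrasts (each medium vs
NMDG-gluconate, NaCl vs Na-isethionate, NaCl+5-HT vs NaCl) and flags the
chloride signature as a point-estimate pattern: the NaCl shift lies in the
same direction as the substrate-driven shift but does not exceed it. The
flag is deliberately qualitative; the per-contrast p-values sit alongside it
in the comparisons table, because with three paired experiments the small
Cl⁻ effect is near the edge of the design's power and its asterisk can
legitimately come and go between replications.

## Problem sizes in tests and the acceptance script

The standard simulated designs are the assay layouts: 8-point concentration
ladders plus the zero anchor, 30 cells per condition, three experiments.
Parameter-recovery and direction-pattern checks run on the generator's
table-level path (100 ladder replicates for rate-constant recovery; the
ligand, ion and vilazodone panels end-to-end), while rendering, segmentation
and the decomposition identity are exercised on full images over 20
independent fields of 15–30 cells. Table-level and image-level paths share
the mechanism and cell-variability model, so the split is a matter of where
the computation is spent, not of what is tested; the image path is validated
against ground-truth masks separately.

## Limitations

The generator emulates the statistical structure of the assays, not their
biology or optics: no z-dimension or optics-accurate PSF, no photobleaching,
cell motion, or time-resolved two-phase ASP⁺ traces (only the endpoint
membrane/interior decomposition); cells are non-touching ellipses, so the
watershed split is available but not stressed; experiments are independent
draws with no shared day effects, which means the paired design is honored
but pairing gains no power here, unlike in real data where it cancels
batch variation; and ligand/ion effects are multiplicative fold-factors on a
single rate constant — adequate for direction-and-magnitude questions, silent
on mechanism. Passing tests therefore establish that the analysis recovers
the truth of *this* generative model at realistic noise, not that the model
captures everything a microscope produces.
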