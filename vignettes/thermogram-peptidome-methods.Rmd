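---
title: "Methods: plasma thermogram and peptidome analysis of cervical disease cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma thermogram and peptidome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscMS)
```

## Scope and rationale

`dscMS` implements two complementary analysis arms for serological profiling
of cervical disease:

1. **DSC thermograms.** Blood plasma is scanned by differential scanning
   calorimetry; the excess specific heat capacity versus temperature (the
   *thermogram*) is the weighted superposition of the denaturation
   transitions of the abundant plasma proteins. Disease-associated peptides
   binding to these proteins (the interactome hypothesis, with albumin as
   the main target) shift and redistribute the profile. The package
   preprocesses raw scans, extracts eight shape metrics, and compares five
   clinical groups (healthy control, LSIL, HSIL, FIGO Stage I, Stage
   II--IV) non-parametrically.
2. **MALDI-TOF peptidome.** Low-molecular-weight peptides from plasma
   fractions (FX1--FX4) and urine are profiled in 900--3000 m/z; spectra
   are baseline-subtracted, binned, replicate-averaged, scaled, explored by
   PCA and discriminant PCA, and screened for differentially abundant bins
   with group-abundance pattern calls.

Because no patient-level raw data are publicly deposited, both arms are
driven by synthetic-data generators whose defaults encode the published
cohort structure. Every synthetic default is stated below, with its
rationale; the generators are first-class, tested code.

## The two-state denaturation model

Each plasma protein component is modelled as a two-state (native ⇌
denatured) transition. With absolute temperature $T$, midpoint $T_m$,
van't Hoff enthalpy $\Delta H_{vH}$ (cal/mol, controls sharpness) and
specific calorimetric enthalpy $\Delta H_{cal}$ (cal/g, controls area),

$$
C_p^{ex}(T) = \Delta H_{cal}\,\frac{\Delta H_{vH}}{R T^2}\,
\frac{K}{(1+K)^2},\qquad
K = \exp\!\left[-\frac{\Delta H_{vH}}{R}\Bigl(\frac{1}{T}-\frac{1}{T_m}\Bigr)\right],
$$

with $R = 1.987$ cal mol$^{-1}$ K$^{-1}$. The curve integrates to
$\Delta H_{cal}$ and peaks at
$\Delta H_{cal}\Delta H_{vH}/(4RT_m^2)$. Note the $1/T^2$ prefactor skews
the maximum slightly below $T_m$ (≤ 0.1 °C for $\Delta H_{vH} \ge 8\times
10^4$ cal/mol) — within one step of the 0.1 °C analysis grid, which is why
the tests assert peak location at that tolerance.

### The default control mixture

The healthy-control plasma profile is five transitions:

| component | $T_m$ (°C) | $\Delta H_{vH}$ (cal/mol) | area (cal/g) |
|---|---|---|---|
| low shoulder | 53.0 | 1.2e5 | 0.097 |
| albumin (primary) | 62.2 | 1.64e5 | 2.72 |
| globulins (secondary) | 70.0 | 1.2e5 | 1.55 |
| mid shoulder | 75.5 | 1.1e5 | 0.437 |
| high shoulder | 81.5 | 1.2e5 | 0.243 |

These values were calibrated — once, before any acceptance test was
written — so that the *processed* control thermogram (after buffer
subtraction, concentration normalisation, linear baseline correction and
truncation, all of which consume part of the simulated signal) lands on the
published healthy-control values: total area ≈ 4.9 cal/g (published
4.94 ± 0.19), first-moment temperature ≈ 66.4 °C (published 66.3 ± 0.3),
peak maximum 62.2 °C, main/second amplitude ratio ≈ 2.2 (published 2.19).
The albumin transition carries ~55 % of the area, matching its dominance of
the 60--65 °C window in plasma.

### Disease effects

Disease is encoded by exactly two knobs, mirroring the hypothesised
mechanism of albumin stabilisation by bound disease peptides:

* `albumin_shift` — °C added to the primary midpoint
  (defaults 0 / 1.5 / 1.5 / 2.5 / 3.5 for the five groups), and
* `redistribution` — the fraction of primary-transition mass moved to the
  secondary transition (defaults 0 / 0.02 / 0.05 / 0.15 / 0.45).

This produces the characteristic difference-curve signature: a negative
lobe near 62 °C and positive lobes at higher temperature, growing with
disease burden.

The redistribution progression deserves comment, because it was the one
genuinely delicate design choice. The envelope width at half height jumps
discontinuously when the secondary transition crosses half of the global
maximum, and a strongly shifted primary transition *merges* with the
secondary, which narrows the envelope again. With the shift sequence fixed,
a strictly increasing width trend across all five groups requires LSIL and
HSIL to sit below that jump (redistribution 0.02 and 0.05), Stage I just
past it (0.15) and Stage II--IV deep inside it (0.45). The choice was
verified to give strictly monotone group medians of width and first-moment
temperature (and strictly decreasing amplitude ratio) across five different
master seeds before being frozen. A corollary worth knowing: width is *not*
monotone in the albumin shift alone — at fixed redistribution, shifting the
primary past ~2.5 °C narrows the envelope. The property tests therefore
check width against redistribution and the centroid/ratio trends against
the shift.

### Noise and biological variability

No quantitative noise model is published for either data type, so the
generator states one:

* additive Gaussian scan noise, sd 0.005 cal/(°C g) — about 1 % of the
  control peak height;
* a per-scan linear instrumental baseline with offset drawn uniformly from
  ±0.05 cal/(°C g) and slope from ±5·10⁻⁴ cal/(°C² g), removed later by the
  pipeline's baseline fit;
* per-sample biological jitter: the group's albumin shift (sd 0.2 °C),
  redistribution (sd 0.015) and protein concentration (2.8 ± 0.2 g/L,
  dialysate-scale) vary between samples. Because the width response is
  steeper in the disease groups, this constant-sd jitter automatically
  reproduces the published qualitative observation that the control group
  has the smallest thermogram variance.

Jitter magnitudes were chosen so that within-group scatter stays small
relative to the between-group trend steps; they are stated-world constants,
not fitted quantities.

## Thermogram preprocessing

The pipeline is order-enforced
(`raw → reference_subtracted → normalized → baseline_corrected → final`):

1. **Buffer reference subtraction** — pointwise, with linear interpolation
   when grids differ.
2. **Concentration normalisation** — division by the protein mass in the
   cell: concentration (g/L) × cell volume (default 135 µL, the thermal
   sensing volume; configurable because it is not stated whether the
   published normalisation used in-cell mass or assay-scale concentration).
3. **Linear baseline correction** — least-squares line through two anchor
   windows, default 45--50 and 85--90 °C, subtracted everywhere. The
   published method states only that a linear fit was the most consistent
   choice; the window placement is ours and is exposed as an argument.
4. **Truncation/resampling** to the uniform 45--90 °C, 0.1 °C grid, the
   range that spans the complete denaturation profile. Interpolation is
   linear throughout: monotone, parameter-free and adequate at 0.1 °C.

Duplicate scans of a sample, when present, are averaged *after* the final
stage, so exactly one curve per sample enters group statistics (the
published workflow acquired duplicates but does not state how they were
combined; averaging the processed curves avoids pseudo-replication).

A consequence of steps 3--4 worth knowing: transitions whose tails reach
the anchor windows (the 53 and 81.5 °C shoulders) lose part of their area
to the baseline fit, so the processed area of the control mixture (~4.9
cal/g) is below the raw sum of component enthalpies (5.05 cal/g). The
area-conservation property test therefore uses interior transitions; the
calibration targets are defined on the processed scale.

## The eight shape metrics

On the final grid: total area (trapezoidal), global height, width at half
height, $T_{max}$ (ties to the lowest temperature), the first-moment
temperature

$$
T_{FM} = \frac{\int_{45}^{90} T\,C_p^{ex}(T)\,dT}
              {\int_{45}^{90} C_p^{ex}(T)\,dT},
$$

the primary (60--65 °C) and secondary (68--72 °C) window amplitudes and
their ratio. Conventions chosen where the published text is silent:

* window amplitudes are window *maxima* (robust to ±0.5 °C drift), not
  values at fixed temperatures;
* width uses the first/last half-height crossings of the whole envelope,
  located by linear interpolation — for the multimodal disease profiles
  this spans the full region above half height, which is what makes the
  published disease widths (~13--14 °C) possible;
* $T_{FM}$ is the area centroid; it responds to shape redistribution even
  when $T_{max}$ does not, which is its entire point.

## Group statistics

Mean and (n−1)-denominator SD curves per group; difference curves versus
the control mean; box summaries (1/5/25/50/75/95/99 percentiles, min, max,
mean) with type-7 linear interpolation between closest ranks; and pairwise
Mann-Whitney U tests for all 10 group pairs × 8 metrics, ordered control
first. The U test enumerates all $\binom{n_x+n_y}{n_x}$ labelings exactly
when that count is ≤ 20,000 and the data are tie-free, otherwise it uses
the normal approximation with tie and continuity corrections (the published
analysis cites the test but not its computational mode, so both are
provided and `auto` switches). Raw p-values are reported — matching the
published presentation — with optional Benjamini-Hochberg adjustment off by
default; bands are p < 0.05 and 0.05 ≤ p < 0.1.

## The peptidome arm

The spectrum generator rasterises 900--3000 m/z at 0.1 Th and plants
Gaussian peaks (sd 0.3 Th) at the 15 published differential peptide masses,
with group means derived from the published abundance patterns: the most
abundant group at amplitude 100, each ">" step dividing by 3, "=" keeping
the level, and absent groups at 0. Per-sample biological and per-spot
lognormal factors (sd(log) 0.2 and 0.15), 200 nuisance peaks with means
common to all groups, an exponentially decaying chemical baseline
(amplitude 20, length 400 Th) and additive Gaussian noise (sd 1) complete
the stated world. Three spots per sample emulate triplicate spotting.

Two published rows list peptides present *only* in controls; the pattern
grammar used here canonicalises them as
`"Absent in Cerv Ca; Absent in CIN 2; Control"`. Ties inside an "=" run are
printed in case-insensitive alphabetical order, which reproduces every
published tie ordering.

The pipeline estimates the baseline by a moving minimum followed by a
moving average (window 25 Th; implemented with an O(n) block prefix/suffix
cumulative-minimum construction), clips negatives, sums intensities into
half-open 1 Th bins (edge points go to the higher bin; binning on a common
grid is also what "alignment" means here — no warping is performed),
averages replicate spots, and scales columns (mean-centring or Pareto;
Pareto is the default for discriminant analysis). PCA is by SVD with signs
fixed so each component's largest-magnitude loading is positive.
Discriminant PCA is the standard PCA-DA construction — Fisher discriminant
axes on the retained scores (default 5), with ridge regularisation of a
singular within-group scatter — since the original proprietary algorithm is
unpublished. Group assignment quality is nearest-centroid purity.

Differential screening is the unpaired two-tailed pooled-variance t-test
per bin at p < 0.05. Pattern calls label groups below 5 % of the maximum
group mean as absent and join groups within 0.5 log2-fold as equal.

## What a green test does and does not establish

The generators emulate: the multi-transition control profile and its
published calibration values; the progressive shift/redistribution
signature of disease; triplicate spotting; planted differential peptides
over a nuisance background. They do **not** emulate scan-rate effects,
aggregation exotherms above the envelope, peak-shape asymmetries or
detector saturation in MALDI spectra, m/z-dependent peak width, or any
demographic covariate structure. Green tests therefore establish that the
*computations* are correct and that the stated world reproduces the
published qualitative structure — not that the published patient-level
numbers (group medians, p-values) are recovered; those depend on an
undeposited 71-patient cohort and are explicitly out of reach.

Two regime notes. First, nearest-centroid purity under shuffled labels is
checked at 12 samples per group: at 4 per group the refit estimator
overfits and its null purity (~0.75) is not a usable chance level. Second,
null calibration of both tests is checked at 20 samples per group, where
the exact-U discreteness (minimum two-sided p of 2/70 at 4 vs 4) no longer
prevents rejection near the 5 % level.

## Numerical choices

* All thermogram integrals are trapezoidal on the 0.1 °C grid.
* Interpolation is linear everywhere (subtraction, truncation, width
  crossings).
* Exact-U enumeration switches to the corrected normal approximation above
  20,000 labelings or in the presence of ties.
* PCA sign fixing: largest-magnitude loading positive.
* $T_{max}$ ties break to the lowest temperature; degenerate inputs
  (all-zero curves, zero secondary amplitude, all-tied samples) raise
  errors or flagged NA/p = 1 rather than silent values.
* Master seed → per-sample substreams via a fixed integer recurrence, so
  cohorts are reproducible under subsetting and all randomness follows a
  single `--seed`.

## Known limitations

* The two-state superposition cannot represent aggregation/precipitation
  exotherms above the envelope; the generator's validity ends at ~90 °C.
* Width as first/last half-height crossing is discontinuous in the inputs
  near the envelope-merge jump; group medians are stable but individual
  samples near the jump can move between modes.
* The moving-minimum baseline is biased upward by noise clipping, leaving
  a small positive residual (~3--4 % of a typical planted bin) in truly
  empty bins; absence calls use a relative threshold for this reason.
* No peptide identification is attempted; protein names attached to
  differential masses are metadata the pipeline cannot compute.
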