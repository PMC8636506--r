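---
title: "Methods: imaging markers of early brain injury and cognitive outcome after SAH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging markers of early brain injury and cognitive outcome after SAH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebisah)
library(dplyr)
```

## The scientific problem

Patients who present in good clinical condition after aneurysmal
subarachnoid haemorrhage (WFNS grade 1–2) often still develop cognitive
impairment months later, despite being clinically indistinguishable at
admission from patients who recover fully. The working hypothesis is that
early brain injury — cytotoxic oedema in the first ~72 h after rupture —
leaves measurable traces on MRI: an apparent *increase* in grey-matter (GM)
volume and a *decrease* in the apparent diffusion coefficient (ADC), with a
residual posterior-cerebellar abnormality in the patients who go on to poor
cognitive outcome. `ebisah` implements the complete analysis chain for this
question:

1. **Global volumetry** — SIENAX-style normalised tissue volumes from
   segmented fraction maps, and group comparisons of those volumes.
2. **Voxel-based morphometry (VBM)** — voxelwise two-sample inference on
   aligned, modulated GM maps with TFCE enhancement and permutation-based
   family-wise-error (FWE) correction.
3. **Diffusion summaries** — mean GM ADC within a mask.
4. **Cognition** — the codified impairment rule: a domain is a deficit at
   or below the normative 5th percentile (z ≤ −1.65), and a subject is
   impaired with two or more deficits across five domains.
5. **Prediction** — the headline procedure: weighted ROI averages of
   acute-phase GM maps over the supra-threshold cluster, an
   accuracy-maximising threshold classifier evaluated by leave-one-out
   cross-validation (LOOCV), ROC/AUC, and Cohen's d.
6. **Synthetic data** — generators that emulate the statistical structure
   of the cohort so that every stage is testable without patient data.

Patient-level MRI data are not available, so the package is organised
around two kinds of evidence: *analytic* checks (closed forms, exhaustive
enumeration, parameter recovery) and a *calibrated synthetic fixture* whose
prediction metrics reproduce the published ones exactly.

## Global volumetry

`compute_global_volumes()` integrates GM, WM and ventricular-CSF fraction
maps: each volume is (sum of fractions) × voxel volume × scaling factor,
where the scaling factor is the dimensionless skull-based normalisation
produced upstream (estimating it is preprocessing and out of scope). Total
brain volume is GM + WM; ventricular CSF is reported separately, mirroring
the SIENAX convention.

Group tables report volumes in the units the cohort table carries. The
reference cohort quantities (`sah_reference_measures()`) are per-group
means ± sd of five measures at three assessments (A1 < 72 h, A2 5–10 days,
A3 3 months). Values near 1500 for whole-brain volume are treated as
"mL-equivalent" at face value — the physiologically natural reading of
numbers of that magnitude.

**Choice of test.** The published group comparisons do not name their test,
and although controls were age/sex paired to patients, the pairing keys are
not part of any summary table. `compare_groups()` therefore uses Welch's
unequal-variance t computed *from summary statistics*
(`welch_from_summary()`), documented as an approximation. Under this
reading the acute-phase table cells reproduce to two decimals (e.g.
ventricular CSF 45 ± 20 vs 37 ± 8, n = 27 per arm, gives p = 0.06; total
brain volume 1521 ± 66 vs 1461 ± 90 gives p = 0.007 → 0.01). Later
timepoints are not guaranteed to reproduce and are not asserted. A
Mann–Whitney test with midrank ties (`mann_whitney_test()`) is provided for
rank-scale scores; it enumerates all label assignments exactly for combined
n ≤ 12 and uses the tie-corrected normal approximation above that.

## Voxelwise inference

`fit_voxelwise_glm()` computes a pooled-variance two-sample t per voxel
(sign convention: first group higher = positive). Covariates, when
supplied, are residualised out of the voxel data (with intercept) before
the statistic is formed; permutations are then applied to the residualised
data, a standard simplification of covariate-respecting permutation
schemes. Paired designs take within-pair differences and use the
one-sample t. Voxels with exactly zero residual variance (possible in
noiseless phantoms) are degenerate for a t statistic; they are set to 0 and
counted, with a warning, rather than propagated as ±∞.

### TFCE

`tfce_enhance()` implements threshold-free cluster enhancement: each
voxel's enhanced value is

$$\mathrm{TFCE}(v)\;=\;\sum_{0 < h \le t(v)} e(h)^{E}\, h^{H}\, \Delta h,$$

where $e(h)$ is the size (voxel count) of the connected component
containing $v$ in the supra-threshold set at height $h$. Defaults are the
standard published ones — $E = 0.5$, $H = 2$, 6-connectivity — with the
integration step $\Delta h$ set adaptively to (max statistic)/100 and the
sum evaluated at midpoint heights $(k - \tfrac12)\Delta h$. Extents are
measured in voxels; `extent_scale` converts to physical units if wanted.
Negative statistics are enhanced separately on the negated map. The
implementation is a single pass over descending heights with an
incremental union-find (compiled code), which makes dense permutation
loops affordable; a per-height flood-fill oracle in the test suite checks
it exactly on small grids, and the single-voxel closed form
$\int_0^1 h^2\,dh = 1/3$ is recovered by the midpoint rule as 0.333325 at
$\Delta h = 0.01$.

### Permutation FWE correction

`permutation_maxstat_test()` permutes group labels (two-sample) or flips
difference signs (paired), recomputes the enhanced map each time, and
corrects every voxel against the permutation distribution of the
image-wide maximum enhanced statistic. When the number of distinct
relabelings is at most `n_perm` the full enumeration is used (identity
included) and p-values are exact fractions; otherwise random relabelings
are drawn — without replacement from the enumerated set when that set is
small enough — and the add-one estimator
$p = (1 + \#\{\max_{\text{null}} \ge \text{obs}\})/(1 + n_\text{perm})$
keeps p-values off zero. The adaptive $\Delta h$ is fixed from the
*observed* map and reused across permutations so that null and observed
values are on a common scale. Two-sided tests take the maximum of the
absolute enhanced map; one-sided alternatives are available since the
published contrasts are directional.

`threshold_and_extract_roi()` collects all voxels with corrected p below
α into a `cluster_roi`. α defaults to 0.05; the published 3-month map used
0.016 (≈ 0.05/3, a Bonferroni split over three timepoints), which is a
per-run flag here, never hard-coded. The published "weighted average" in
the cluster is not defined precisely, so two weighting schemes are
provided and recorded in the object: `"uniform"` (default) and
`"statistic"` (weights ∝ absolute enhanced statistic). An empty ROI is an
explicit, non-error outcome.

## Diffusion

`mean_gm_adc()` is the unweighted mean of an ADC map over voxels whose GM
fraction is at or above a threshold (default 0.5 — the published analysis
states no value, and 0.5 is the conventional majority-tissue cut).
Diffusion comparisons at the acute assessment involve the 14 patients with
diffusion data against 27 controls; later-timepoint diffusion group sizes
are not knowable from the summaries and are not asserted anywhere.

## The impairment rule

`domain_z_scores()` converts raw domain scores to z-scores against
normative means/sds, flipping sign for lower-is-better domains so that
negative is always worse. `classify_impairment()` applies the codified
rule: deficit ⇔ z ≤ −1.65 (inclusive), impaired ⇔ at least two deficits.
The −1.65 cut is the standard-normal 5th percentile quoted at two
decimals (z₀.₀₅ = 1.645). Missing domains are left unavailable rather than
imputed; deficits are counted over available domains, the ≥ 2 requirement
stays absolute (a conservative reading), and subjects with fewer than two
available domains are unclassifiable (`NA`). Which tests aggregate into
which domain is configuration, not code: the package consumes one score
per domain.

Under null scores with five independent domains the impairment rate is the
binomial tail $P(\mathrm{Bin}(5, 0.05) \ge 2) \approx 0.0226$ — a property
the test suite verifies by simulation against the generator.

## The prediction procedure

Given one weighted-ROI GM value per patient (`roi_values_table()` /
`weighted_roi_mean()`) and the 3-month impairment label:

- `full_sample_threshold()` scans every cut point; a subject is classified
  impaired when the value is **at or above** the threshold (impaired
  patients carry the *higher* cerebellar GM values). Candidates are the
  midpoints of open intervals between adjacent distinct sorted values plus
  the two unbounded cuts; among equal-accuracy intervals the **lowest**
  interval's midpoint is returned. The tie-break makes fold-level results
  deterministic and reproducible.
- `loocv_classify()` repeats that scan on each leave-one-out training set
  and classifies the held-out subject; the confusion matrix, sensitivity,
  specificity, accuracy and balanced accuracy come from held-out
  predictions only, while the *reported* operating threshold is the
  full-sample one. Selection uses raw accuracy by default (balanced
  accuracy is an option).
- `roc_auc()` computes AUC as the Mann–Whitney pair fraction with
  half-credit ties — identical to the normalised U statistic, which the
  tests exploit as a cross-module identity. A stratified-bootstrap CI is
  available for exploration but is deliberately not a reproduction target:
  the CI method behind the published interval is unstated.
- `cohens_d()` is the pooled-sd standardised mean difference, positive
  when impaired subjects score higher.

### The calibrated reference fixture

The per-patient ROI values behind the published metrics were never
released. `sah_roi_fixture()` ships a synthetic 25-value set (14
non-impaired, 11 impaired) constructed so that the full pipeline
reproduces every published prediction metric simultaneously: unique
accuracy-maximising interval (0.172, 0.1864) with midpoint **0.1792** and
accuracy 21/25 = **84%**; LOOCV confusion TP 9 / FN 2 / FP 2 / TN 12,
i.e. sensitivity **82%**, specificity **86%**, balanced accuracy **84%**;
AUC 124/154 = **0.805**. These properties were re-verified with an
independent brute-force oracle (exhaustive threshold scan and per-fold
enumeration) before the values were frozen into the package. One caveat is
intentional: the fixture's Cohen's d (≈ 1.4) does *not* match the
published 3-month effect size of 0.72, which was computed on a different
quantity (the 3-month ROI values, not the acute ones); the d = 0.72 check
in this package is a parameter-recovery test on synthetic draws instead.

## What the synthetic generators emulate — and what they do not

- `generate_cohort_table()` draws each global measure independently from
  per-group normals at each timepoint (means ± sds are the only
  distributional information available), with 27 patients and 27 controls
  by default; ages are Normal(55, 11) rounded and truncated to 31–77, and
  controls copy their paired patient's age ± ≤ 2 years and sex (11:16
  M:F), emulating the recruitment pairing. Cross-measure and
  cross-timepoint correlations are *not* emulated — real volumes are
  strongly autocorrelated across visits — so longitudinal power estimates
  from these tables would be meaningless, and nothing in the package uses
  them that way.
- `generate_phantom_cohort()` builds 32³-voxel, 2 mm phantoms (defaults):
  uniform background 0.5 plus Gaussian noise (sd 0.05), with a spherical
  blob of configurable amplitude added in group B and values clipped at
  zero. The blob stands in for the localized posterior-cerebellar
  difference. There is no anatomy, no registration error, no spatial noise
  correlation; passing tests demonstrate the *statistical* correctness of
  the inference chain (FWE calibration, detection of a planted effect),
  not robustness to realistic imaging artefacts.
- `generate_cognitive_scores()` gives every subject normative
  Wechsler-scaled scores (mean 100, sd 15) in five domains; designated
  impaired subjects have 2 domains shifted down by 2.5 sd by default —
  far past the deficit cut, emulating unambiguous impairment. Domains are
  independent, which real cognitive batteries are not; the binomial-tail
  null-rate check depends on that independence and is a check of the
  generator-plus-rule pair, not a claim about real batteries.

All generators are deterministic given their spec's seed.

## Numerical choices and degenerate inputs

- TFCE integration uses midpoint heights; `dh` fixed from the observed map
  within a permutation run. One-voxel components and all-zero maps are
  handled exactly.
- Exhaustive permutation p-values are plain enumeration fractions
  (identity included, so p ≥ 1/N automatically); sampled p-values use the
  add-one estimator.
- Thresholds are never placed on data values: candidates are interval
  midpoints, so the ≥ decision boundary cannot collide with an observed
  value; ties in accuracy are broken toward the lowest interval.
- Zero-variance voxels → t = 0 with a warning; empty ROIs and empty
  post-threshold masks are explicit signalled outcomes; classification
  refuses single-class inputs.
- Problem sizes in the test suite are chosen for desk-scale runs: the FWE
  calibration uses 200 repetitions of a 16³-voxel, 8-vs-8 null design at
  99 permutations each (corrected-p granularity 1/100, so the expected
  family-wise rate at α = 0.05 is exactly 0.05 under a continuous null);
  moment-recovery runs use 10⁵ draws; Cohen's d recovery uses 5 × 10⁵ per
  group (sampling se ≈ 0.002).

## Known limitations

- No image preprocessing: brain extraction, bias correction, registration,
  segmentation and the SIENAX scaling factor are all inputs, not outputs.
- The Welch-from-summary reading of the group tables is one defensible
  choice among several (paired tests, rank tests); only the acute-phase
  rows are expected to reproduce.
- The LOOCV tie-break (lowest interval) is a convention; other
  implementations may report a different but equally accurate threshold on
  tied data.
- Bootstrap AUC intervals are percentile intervals from stratified
  resampling and are not comparable to published intervals of unknown
  provenance.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
# phantom cohort with a planted group difference
spec <- phantom_spec(amplitude = 0.12, noise_sd = 0.05, seed = 42)
stack <- generate_phantom_cohort(spec, n_a = 14, n_b = 11)

# voxelwise inference with TFCE + permutation FWE correction
perm <- permutation_maxstat_test(stack, n_perm = 999, seed = 42)
roi  <- threshold_and_extract_roi(perm, alpha = 0.05)

# ROI summarisation and outcome prediction
outcomes <- tibble::tibble(subject_id = stack$subject_id,
                           impaired = stack$group == "B")
vals <- roi_values_table(stack, roi, outcomes)
glance(loocv_classify(vals))
glance(roc_auc(vals))
```

```{r fixture}
# the calibrated reference values reproduce the published metrics
fx <- sah_roi_fixture()
full_sample_threshold(fx)
glance(loocv_classify(fx))
glance(roc_auc(fx))
```
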