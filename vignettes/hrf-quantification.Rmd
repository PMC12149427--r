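---
title: "Quantifying hyperreflective foci in OCT volumes and analysing their longitudinal course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyperreflective foci in OCT volumes and analysing their longitudinal course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrfoct)
```

## The problem

Hyperreflective foci (HRF) are small bright dots visible on spectral-domain
OCT B-scans of eyes with diabetic macular edema (DME), with reflectivity
similar to the retinal pigment epithelium (RPE). They are thought to mark
inflammatory activity and lipid extravasation, and their longitudinal
behaviour under anti-VEGF or dual Ang-2/VEGF-A therapy is of interest as an
imaging biomarker of disease control. `hrfoct` provides the complete
computational chain for studying them:

1. **Quantification** of HRF from a binary hyperreflective-material
   segmentation mask: per-B-scan connected components, equivalent-ellipse
   sizing, a 20--50 µm long-axis inclusion window, localisation to ETDRS
   rings and retinal compartments, and per-eye count/volume summaries.
2. **Longitudinal analysis** of per-eye endpoints in a three-arm trial
   setting: MMRM adjusted means, a stratified Wilcoxon sensitivity test,
   time-to-absence survival analysis, and a cube-root-scale correlation of
   HRF and intraretinal-fluid (IRF) volume changes.
3. **Synthetic data generation** for both stages, with known ground truth,
   so every estimator can be validated by parameter recovery.

The upstream segmentation itself (in practice a trained neural network) is
out of scope; the package consumes its binary masks, and offers a
transparent intensity-threshold detector (`detect_candidates()`) for
synthetic volumes and exploration.

## Quantification model

**Objects are 2-D, per B-scan.** Components are never merged across
B-scans: counting is defined at the B-scan level, and typical volume scans
are far from isotropic (a B-scan spacing of ~62 µm against an in-plane
pitch of a few µm), so 3-D linking would be poorly determined. The default
pixel connectivity is 8; 4-connectivity is available in `quant_config()`.

**Equivalent ellipse.** Each component is sized by the ellipse having the
same second central moments, computed in physical units on the anisotropic
grid (`lateral_px_um` × `axial_px_um`). The axis diameters are
$4\sqrt{\lambda_{1,2}}$ of the 2×2 moment matrix, which recovers the true
diameters exactly for a continuous ellipse (a disc of radius $r$ has second
moment $r^2/4$). A per-pixel self-moment of $a^2/12$ per axis — the
variance of a uniform density over one pixel side — gives single pixels
finite extent: one 11.5 µm × 3.87 µm pixel measures
$4\sqrt{11.5^2/12} \approx 13.3$ µm along its long axis. Moments were
chosen over boundary-fitting because they are deterministic,
rotation-covariant and have an exact analytic oracle, which the test suite
exercises against a brute-force double-loop implementation at relative
tolerance 1e-9.

**Size window.** An object is an HRF iff its long axis lies in
[`min_diameter_um`, `max_diameter_um`] = [20, 50] µm, inclusive at both
ends: an object measuring exactly 50 µm is an HRF, anything above is
discarded as oversized. The lower limit reflects the resolution limit of
SD-OCT; objects below it are excluded but tallied in the QC report rather
than silently dropped, since a segmentation model's behaviour below the
resolution limit is not well defined.

**Regions and compartments.** Region membership uses the en-face Euclidean
distance of the object *centroid* from the fovea: R1 (central 1-mm
subfield) for $d \le 0.5$ mm, the 3-mm disc for $d \le 1.5$ mm, boundaries
inclusive. Centroid assignment avoids fractional objects in counts; a
sub-50 µm object is small against the ring scale, so the alternative
(pixel-majority splitting) could differ only for a thin shell of straddling
objects. By default the 3-mm figures are **cumulative discs** (R1 ⊆ R3),
which matches "1-mm diameter"/"3-mm diameter" phrasing; an annulus mode
(`ring_mode = "annulus"`) reports the 1--3 mm ring instead, and the two are
reconciled by `R3_disc = R3_annulus + R1`, which the tests assert. The 6-mm
ring is not analysed: variable scan areas mean it is not reliably covered.

The inner retina runs from the internal limiting membrane (ILM) to, *and
including*, the outer plexiform layer--Henle fiber layer boundary
(OPL-HFL); the outer retina from there to the RPE; the total retina is
inner + outer exactly. A centroid exactly on the OPL-HFL is inner.
Centroids above the ILM or below the RPE are excluded and QC-counted.

**Volumes.** A per-B-scan object of area $A$ µm² contributes
$A \times \Delta_B$ µm³, where $\Delta_B$ is the B-scan spacing (the
distance between the centers of adjacent B-scans), reported in picoliters
(1 pL = 1000 µm³).

## The phantom generator

`generate_phantom()` builds volumes in which the truth is known by
construction: analytic layer surfaces (flat RPE, foveal pit on the ILM),
planted ellipses rasterised by the pixel-center-in-ellipse rule (which
makes area and moment oracles computable), an intensity rendering in which
planted objects take RPE-band reflectivity over a layered background, and
optional hyporeflective cysts plus Gaussian noise. Each planted object
lives on a single B-scan, mirroring the per-B-scan object definition.

Random placement enforces margins that make the planted truth unambiguous
under discretisation: centers are snapped to pixel centers; long axes are
drawn with a buffer away from the 20/50 µm classification cuts (HRF in
[25, 45] µm, oversized distractors in [65, 100] µm, undersized in
[8, 14] µm), because moment estimates on an 11.5 µm grid carry up to about
one pixel of discretisation error; centroids keep two axial pixels clear
of the OPL-HFL and 0.02 mm clear of the ring radii. Under these margins
the quantification stage must recover planted counts per (region,
compartment) *exactly* and per-object long axes within one pixel pitch —
the acceptance suite checks 20 seeded phantoms with oversized and
undersized distractors.

`degrade_with_turbidity()` removes mask voxels inside defined cysts with a
stated probability, emulating the masking of HRF by turbid intraretinal
fluid. It is never applied silently; it exists to reproduce the
early-trajectory artifact (below) mechanically when desired.

What the phantoms do **not** emulate: speckle statistics, vendor-specific
appearance, segmentation-model error modes beyond turbidity masking, real
layer-surface topology under severe edema. Passing recovery tests
therefore validates the measurement chain, not any segmentation model.

## The trial generator

`generate_trial()` draws three arms (faricimab Q8W, faricimab
treat-and-extend, aflibercept Q8W) on a 4-weekly visit grid to week 48,
matching Q4W monitoring. Arm-mean volume trajectories are piecewise linear
through four anchors: baseline, an early inner-retina peak at week 8, a
common week-12 level, and arm-specific week-48 end levels; arms share the
path through week 12 and separate from week 16 onward (the end of a
head-to-head dosing period). Defaults:

* **Early rise**: amplitude 0.25 (i.e. +25% over baseline at week 8) in
  the inner retina, inside the empirically reported 13%--36% band; 0 in
  the outer retina. The literature offers no quantitative mechanism for
  this artifact (turbid-fluid masking at baseline is the leading
  explanation), so it is a free parameter of the generator, not a model.
* **Baselines and week-48 levels**: baseline means (250 / 90 / 1400 / 700
  pL for inner-1mm / outer-1mm / inner-3mm / outer-3mm) are plausible
  choices for a DME population — baseline adjusted means are not published
  for these endpoints — while the week-48 per-arm end levels are set to
  published adjusted means for the corresponding endpoints
  (104.1/110.1/180.3 pL in the inner 1-mm, etc.), so that analyses of
  generated data land in a realistic range.
* **Noise**: multiplicative log-normal by default (mean-preserving,
  positively skewed like observed volume distributions), with an
  exchangeable within-patient correlation (ρ = 0.6) on the latent scale;
  AR(1) and unstructured options exist. An additive-normal option is used
  by the estimator-recovery simulations, where exact planted means and
  covariance matter more than skewness.
* **Zero attainment**: an absorbing per-patient "HRF-free" state with
  geometric waiting time on the visit grid; per-visit probabilities are
  derived from a reference probability (0.03 for aflibercept, placing the reference 25th-percentile time near week 44, safely inside the 48-week horizon) and
  planted hazard ratios (1.48, 1.23) through the complementary-log link,
  so the grouped-proportional-hazards HR is exact. Counts are
  `max(Poisson, 1)` before absorption: zeros occur only through the
  absorbing state, keeping the planted hazard clean; the robustness of the
  event definition to transient zeros is tested on crafted sequences
  instead. Under this geometric model the planted HRs and the published
  25th-percentile times (36 vs 44 weeks) cannot both hold exactly; the
  HRs were kept.
* **IRF correlation**: after the HRF volumes are drawn, the IRF cube-root
  change is constructed as a linear blend with the standardised HRF
  cube-root change so that the planted correlation (default ρ = 0.42)
  is recovered at large n.
* 2% of patients are HRF-free already at baseline (exercising the
  exclusion rule) and a 1% per-visit dropout hazard produces censoring.

## Statistical analyses

**MMRM.** `fit_mmrm()` fits, to post-baseline visits, fixed effects of
baseline endpoint value, arm, visit (categorical), visit×arm, baseline
BCVA, and the randomization-stratification factors (BCVA <64/≥64 letters,
prior anti-VEGF, region), with REML and an unstructured within-patient
covariance by default — implemented as `nlme::gls()` with `corSymm` plus
per-visit `varIdent` weights. All available rows are used (MAR, no
imputation). Details the analysis plan leaves open were resolved as
follows and are configuration-exposed: covariance fallback order
unstructured → exchangeable (reported prominently when triggered, with a
final ordinary-least-squares fallback flagged as non-converged); adjusted
means from `emmeans` with factor margins weighted proportionally to the
observed data (`emm_weights = "equal"` gives the equal-weight
convention); contrasts of each faricimab arm versus aflibercept from the
same fit with *nominal* p-values — no multiplicity adjustment anywhere.
Endpoints may be analysed in µm³ or pL; the model is equivariant, and the
tests assert the exact 1/1000 scaling. If an endpoint has zero residual
variance the model degenerates to OLS cell means, which makes the
noiseless recovery case exact rather than a numerical accident.

**Stratified Wilcoxon (van Elteren).** Within-stratum Mann-Whitney
statistics on mid-ranks are combined with weights $1/(N_s+1)$ and referred
to the normal distribution with tie-corrected variance and no continuity
correction; a single stratum reduces exactly (to 1e-10) to
`wilcox.test(exact = FALSE, correct = FALSE)`. No installed package
provides this test, so it is implemented here directly.

**Time to absence of HRF.** The event is the *first* visit of the
earliest pair of consecutive visits with HRF count 0; patients with such a
pair at or before baseline are excluded; everyone else is censored at
their last observed week. The implementation is validated against
exhaustive enumeration of all 0/1 count patterns up to length 6.
Kaplan-Meier curves use `survival::survfit`; the reported percentile is
the earliest time with cumulative incidence ≥ p, "not reached" otherwise.
Hazard ratios come from pairwise Cox models (one model per comparison)
stratified by the three randomization factors, with Efron tie handling —
the planned-visit grid produces heavy ties, for which Efron is the
accepted default — and the log-rank test is stratified identically.

**Correlation.** The cube root is applied to each visit's volume *before*
differencing ($\Delta = v_{48}^{1/3} - v_0^{1/3}$), then Pearson's r with
a t-based two-sided p; a test fixture distinguishes this order from the
transform-after-difference alternative.

## Validation problem sizes

The packaged validation suite runs at sizes chosen to give tight Monte
Carlo error while staying desk-scale: 1000 random components for the
moment oracle; 20 phantoms of 8 + 2 + 2 planted objects on a 25 × 120 ×
160 grid; 200 replicates of n = 500/arm for Cox HR recovery (planted
HR 1.5, mean within ±0.1, CI coverage in [0.92, 0.98]); 200 replicates of
n = 500/arm for MMRM contrast recovery (planted week-48 difference −70 pL,
mean within ±5) and 1000 replicates of n = 100/arm for its type-I error
(5% ± 1.5%), both on a reduced 16-weekly visit grid with exchangeable
covariance so the simulations stay fast; 1000 replicates for the van
Elteren null; n = 1500 for correlation recovery (planted ρ = 0.42, within
±0.05). The acceptance script analyses a full 4-weekly-grid trial of
n = 150/arm with the unstructured covariance of the primary analysis.

## Known limitations

* Masks are consumed as given; no segmentation accuracy is modelled, so
  recovery results certify the measurement chain only.
* Region assignment is centroid-based; objects straddling a ring boundary
  are not split (a deliberate convention, see above).
* The trial generator's trajectories are piecewise linear means with a
  single absorbing zero state; real count processes show transient zeros
  and remission-relapse patterns it does not attempt to model.
* `fit_mmrm()` relies on `nlme::gls`; with many visits and an unstructured
  covariance, fits are minutes, not seconds, at four-figure patient
  counts.
* Proprietary container formats (Heidelberg E2E/VOL, DICOM OPT) are not
  parsed; use TIFF/NIfTI exports.
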