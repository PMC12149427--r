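# hrfoct

Quantification and longitudinal analysis of **hyperreflective foci (HRF)**
in retinal spectral-domain OCT volume scans, for imaging scientists and
trial statisticians studying diabetic macular edema (DME).

HRF are small bright dots on OCT B-scans, with reflectivity similar to the
retinal pigment epithelium, that behave as an imaging biomarker of
inflammatory activity in DME. `hrfoct` implements the complete measurement
and analysis chain downstream of a hyperreflective-material segmentation:

* **Quantification** — per-B-scan connected components of a binary mask;
  equivalent-ellipse sizing from second central moments in physical units
  (axis diameters 4·√λ of the moment matrix, with a per-pixel self-moment
  a²/12 so single pixels have finite extent); inclusion window
  20 µm ≤ long axis ≤ 50 µm; localisation to the ETDRS 1-mm and 3-mm rings
  by centroid distance from the fovea and to the inner (ILM to, and
  including, OPL-HFL) or outer (OPL-HFL to RPE) retina; per-eye counts and
  volumes, where an object of area *A* contributes *A* × Δ_B (the B-scan
  spacing) reported in picoliters (1 pL = 1000 µm³).
* **Longitudinal analysis** — mixed-model repeated measures (REML,
  unstructured within-patient covariance, baseline value + arm + visit +
  arm×visit + baseline BCVA + randomization strata) with adjusted means and
  nominal contrasts; van Elteren stratified Wilcoxon sensitivity test;
  time to absence of HRF (first visit of the earliest pair of consecutive
  zero-count visits, baseline-zero patients excluded, censoring at last
  observation) with Kaplan–Meier percentiles and pairwise stratified Cox
  hazard ratios (Efron ties); Pearson correlation of cube-root-transformed
  HRF and intraretinal-fluid volume changes.
* **Synthetic data** — OCT-like phantoms with planted objects of known
  size, region and compartment, and three-arm trial datasets with planted
  treatment effects (early inner-retina rise peaking at week 8, arm
  separation from week 16, planted hazard ratios and cube-root-scale
  correlation), so that every estimator is validated by parameter recovery.

Volumes are read/written as multi-page TIFF or NIfTI, layer surfaces and
trial tables as CSV. See the vignette in `vignettes/hrf-quantification.Rmd`
for the full model description and design rationale.

## Worked example

```r
library(hrfoct)

# -- quantify a phantom with known truth ------------------------------------
g  <- scan_geometry(n_bscans = 25, depth_px = 120, n_ascans = 160,
                    axial_px_um = 3.87, bscan_spacing_um = 62)
ph <- generate_phantom(phantom_spec(g, n_hrf = 8, n_oversized = 2,
                                    n_undersized = 2, seed = 7))
q  <- quantify_volume(ph$mask, ph$surfaces, ph$geometry, eye = "phantom01")
q$summary
#>        eye visit_week region compartment hrf_count hrf_volume_pl
#>  phantom01          0     R1       inner         0        0.0000
#>  phantom01          0     R3       inner         5      306.2834
#>  phantom01          0     R1       outer         0        0.0000
#>  phantom01          0     R3       outer         3      135.2062
#>  phantom01          0     R1       total         0        0.0000
#>  phantom01          0     R3       total         8      441.4896
```

All 8 planted HRF are recovered in their true ring/compartment cells (this
seed placed none inside the central 1-mm subfield); the 2 oversized and 2
undersized distractors are excluded and tallied in `q$qc`.

```r
# -- analyse a synthetic three-arm trial ------------------------------------
tr  <- generate_trial(trajectory_spec(), n_per_arm = 150, seed = 3)
fit <- fit_mmrm(tr, "vol_inner_r1_pl", covariance = "exchangeable")
fit
#> MMRM fit for endpoint 'vol_inner_r1_pl'
#>   447 patients; covariance: exchangeable
#>   adjusted means at week 48:
#>     faricimab_q8w       104.0 (SE 8.85)
#>     faricimab_te        107.4 (SE 8.85)
#>     aflibercept_q8w     179.1 (SE 9.04)
#>   faricimab_q8w - aflibercept_q8w @ wk 48: -75.2 [-100.0, -50.4], p = 3.03e-09
#>   faricimab_te - aflibercept_q8w @ wk 48: -71.8 [-96.6, -47.0], p = 1.51e-08

ev <- absence_events(tr, "count_inner_r1")
stratified_cox(ev)
#> Stratified Cox regression, time to absence of HRF
#>   strata: bcva_stratum, prior_anti_vegf, region_stratum
#>   faricimab_q8w vs aflibercept_q8w: HR 1.38 (95% CI 0.92, 2.07); Wald p = 0.115; log-rank p = 0.111
#>   faricimab_te vs aflibercept_q8w: HR 1.18 (95% CI 0.78, 1.81); Wald p = 0.433; log-rank p = 0.436
```

The adjusted means sit at the generator's planted week-48 levels
(104.1/110.1/180.3 pL), and the hazard ratios scatter around the planted
1.48/1.23 at this sample size. `run_pipeline(config)` chains
simulate → quantify → analyse from a single YAML config and writes
summaries, results and a reproducibility manifest.

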