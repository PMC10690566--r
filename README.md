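# specktools

Quantitative analysis of inflammasome **ASC speck** assembly from
single-molecule localization microscopy (SMLM) data.

Upon NLRP3 inflammasome activation, the adaptor protein ASC condenses from
a diffuse cytosolic pool into a single ~1 µm perinuclear assembly — the ASC
speck — with filaments protruding from a dense core. dSTORM and DNA-PAINT
record this not as images but as *localization tables*: one row per
fluorophore blink, with nanometre coordinates and finite precision σ_xy.
`specktools` is for microscopists and image analysts who need to turn such
tables (plus cell/speck segmentations) into quantitative statements about
speck assembly, and to validate every step against simulated ground truth.

## What it computes

* **Cytoplasmic cluster statistics** — DBSCAN with the field's convention
  (a cluster = 10–300 localizations within a 70 nm search radius;
  `dbscan_clusters()`), and Ripley's
  `L(r) − r = √(K(r)/π) − r` with a same-density randomization control
  (`ripley_l()`, `ripley_randomization()`).
* **Speck morphometrics** — radius of gyration
  `Rg = √(Var(x) + Var(y))`, eccentricity `√(λ_max/λ_min)` of the
  coordinate covariance, localization count and density; summaries as
  mean / median / histogram mode / unscaled MAD (`speck_metrics()`,
  `summarize_values()`).
* **Filament diameters** — Gaussian fits of transverse localization
  density profiles along user-traced backbones; diameter =
  `FWHM = 2√(2 ln 2)·σ`, corrected for label size by
  `FWHM − 2ε` (`filament_profile()`, `filament_summary()`).
* **Pseudo-time** — per-cell assembly progression as the in-speck fraction
  of localizations, with day-to-day slope calibration
  (`day_calibrate()`), cell-area normalization
  (`normalize_by_cell_area()`), and center-of-mass aligned, pseudo-time
  binned sum projections with 9-pixel-band cross-sections
  (`align_and_sum()`).
* **Plumbing** — localization/ROI I/O (CSV/TSV + JSON polygons), affine
  two-channel registration from fiducial beads (`estimate_affine()`),
  super-resolution rendering (10.6 nm pixels, 1 px Gaussian blur;
  `render()`), background-corrected widefield intensities.
* **Synthetic ground truth** — `simulate_scene()` generates cells with a
  dense-core + filament speck, cytosolic oligomers, two labeling probes
  (bulky antibody complex sterically excluded from the dense core vs
  small low-affinity nanobody washed from sparse regions), blinking,
  localization noise and multiplicative day effects; this is what makes
  the analysis testable without microscope data.

## Worked example

Simulate a 12-cell stimulated scene and run the per-cell pipeline:

```r
library(specktools)

scene <- simulate_scene(scene_params(n_cells = 12), seed = 42)
scene
#> <smlm_scene> 12 cells, 229680 localizations (AF647 + DL755), seed 42

rec <- cell_records(scene$locs, scene$regions,
                    wf = scene$truth$cells[, c("cell_id", "wf_intensity")])
rec <- day_calibrate(rec)
rec[1:5, c("cell_id", "cell_area_um2", "pseudo_time",
           "speck_rg_nm", "speck_eccentricity", "clusters_per_um2")]
#>   cell_id cell_area_um2 pseudo_time speck_rg_nm speck_eccentricity clusters_per_um2
#> 1       1      198.9580   0.5480722    399.0057           1.117805        1.5708652
#> 2       2      138.2375   0.9388906    290.1112           1.359666        0.2040747
#> 3       3      180.5514   0.2576127    376.6172           1.199315        1.2070907
#> 4       4      179.7117   0.3321637    386.0949           1.592593        1.9773321
#> 5       5      181.3933   0.2237115    412.6658           1.705856        1.8598442
```

Each row is one cell: `pseudo_time` is the fraction of its AF647
localizations inside the speck segment (assembly progression),
`speck_rg_nm` the speck's radius of gyration, `clusters_per_um2` the
DBSCAN cluster density of the remaining cytoplasmic ASC — note how the
nearly fully recruited cell 2 has an almost empty cytoplasm.

```r
correlate(rec$speck_density_per_um2, rec$pseudo_time)            # 0.94
norm_rg <- normalize_by_cell_area(rec$speck_rg_nm, rec$cell_area_um2)
summarize_values(rec$speck_rg_nm)
#> <summary_stats> n = 12: mean 360.7, median 381.1, mode 375 (fd bins), MAD 29.18
```

Speck *density* rises strongly with pseudo-time while the area-normalized
speck *size* does not (at 50 cells the size correlation is ≈ 0): the speck
densifies rather than grows as ASC is recruited.

Filament diameter from a phantom with the antibody label chain
(true diameter 15 nm, label ε = 11 nm, precision σ = 10 nm):

```r
ph <- simulate_filament_phantom(true_diameter_nm = 15, length_nm = 500,
                                label_size_nm = 11, sigma_nm = 10,
                                n_labels = 1e4, seed = 1)
filament_summary(filament_profile(ph, attr(ph, "backbone")), label_size_nm = 11)
#> <filament_summary> 1 filaments, 11 sections: median FWHM 32.8 nm ->
#>   corrected thickness 10.8 nm (linear, label 11 nm; quadrature 24.3 nm)
```

The measured FWHM is the true diameter broadened by the label on both
sides and by localization precision; the linear label correction
`FWHM − 2ε` is the headline value, and the quadrature alternative is
reported alongside because how precision enters the correction is a
modeling choice.

See `vignettes/speck-analysis.Rmd` for the full account of the methods,
the generator's model, defaults and their rationale.

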