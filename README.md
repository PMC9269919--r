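# atriaquant

Quantification of left atrial (LA) myocardial fibrosis from 3D late
gadolinium enhanced (LGE) cardiac MR, for imaging scientists studying
atrial fibrillation and fibrotic remodelling in serial (baseline vs
post-pacing) animal or clinical studies.

Fibrotic myocardium retains gadolinium and appears bright on LGE images,
but raw intensities are not comparable across scans. The package
implements the image intensity ratio (IIR) pipeline:

- every LA voxel is normalized by the mean blood-pool intensity,
  `NI(x) = I(x) / mu_BP`;
- the fibrosis threshold is `T_fib = mu_NI + 2 sigma_NI`, the mean plus
  two standard deviations of NI over the LA wall (the multiplier is
  configurable);
- a wall voxel is fibrotic iff `NI > T_fib`; volumetric `%MF` is the
  fibrotic share of the wall volume, and slice-wise `%MF` is the fibrotic
  share of the wall area in the axial slice with the most fibrotic
  pixels;
- longitudinal change is the signed difference
  `D_abs = V_post - V_baseline` in percentage points.

The LA wall itself is derived from a manually segmented blood-pool mask
by a 4-pixel in-plane (axial) disk dilation followed by Boolean removal
of the chamber, with an optional exclusion mask standing in for manual
corrections. Around this core the package provides: exact small-sample
Wilcoxon signed-rank and Mann-Whitney tests (full enumeration of the
conditional null distribution); closed-form landmark rigid registration
(SVD Procrustes); NEMA-4 SNR with Rayleigh correction; observer
variability metrics (Dice, boundary F1, relative volume error, ICC,
inter-rater R); Masson's-trichrome histology quantification by hue
classification; NRRD / NIfTI / landmark-CSV I/O; and a synthetic phantom
generator with exact ground truth that makes every stage testable.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study.
`analysis/01_simulate_cohort.R` writes 9 paced + 3 control phantom
animals (wall fibrosis fraction 0.05 at baseline, +0.02 after pacing in
the paced group) to `scratch/cohort/`; `analysis/02_run_study.R` then
runs segmentation, quantification and statistics:

```
$ Rscript analysis/01_simulate_cohort.R
Simulated 12 animals (seed 42 ) into scratch/cohort
Experimental true %MF: baseline 5.04 +/- 0.21, post 6.91 +/- 0.26
Control true %MF:      baseline 4.87, post 4.95

$ Rscript analysis/02_run_study.R
...
Experimental mean D_abs: 1.87 points; control: 0.07 points
Paired signed-rank p: experimental 0.003906, control 0.75
Between-group Mann-Whitney at post (volumetric): p = 0.009091
```

The paced group's measured mean change tracks the injected 2-point
increment (up to biological jitter built into the simulation), the paired
exact test flags the paced group only, and the 9-vs-3 between-group test
under complete separation attains its minimal two-sided exact p-value of
2/220 = 0.009. `analysis/03_histology.R` reproduces the per-animal and
group summaries of the published slice-wise trichrome table (paced-group
mean 19.42 +/- 4.80%) and validates hue-based quantification on synthetic
slides; `analysis/04_variability.R` and `analysis/05_registration.R`
exercise the observer-variability and registration modules.

The same operations are available directly:

```r
library(atriaquant)
ph  <- generate_la_phantom(phantom_spec(fibrosis_fraction = 0.1, seed = 3))
seg <- extract_wall(ph$truth$blood_pool_mask, radius = 4)
quantify_fibrosis(ph$image, ph$truth$blood_pool_mask, seg$wall,
                  timepoint = "baseline")
#> <fibrosis_measurement> baseline: T_fib=1.162, %MF vol=9.99%, slice 16=19.03%
```

## Layout

- `R/` - package code (I/O, phantom generator, wall segmentation, IIR
  quantification, registration, metrics, exact tests, histology,
  pipeline).
- `analysis/` - numbered narrative drivers writing tables to `results/`.
- `tests/testthat/` - unit, property and acceptance tests with
  brute-force oracles.
- `vignettes/fibrosis-quantification.Rmd` - methods notes: model,
  assumptions, parameter choices, numerical conventions, limitations.
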