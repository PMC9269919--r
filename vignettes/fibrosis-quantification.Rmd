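---
title: "Quantifying left atrial fibrosis with the image intensity ratio: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left atrial fibrosis with the image intensity ratio: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriaquant)
```

## The measurement problem

Late gadolinium enhancement makes fibrotic myocardium bright, but the raw
signal depends on contrast dose, timing, coil placement and physiology, so
intensities cannot be compared across scans or animals. The image intensity
ratio (IIR) approach removes the per-scan scale by dividing every left
atrial (LA) voxel by the mean blood-pool intensity of the *same* scan:

$$NI(x) = \frac{I(x)}{\mu_{BP}}.$$

Fibrosis is then declared where the normalized intensity exceeds a
data-driven threshold

$$T_{fib} = \mu_{NI} + k\,\sigma_{NI}, \qquad k = 2 \text{ by default},$$

with $\mu_{NI}, \sigma_{NI}$ the mean and standard deviation of $NI$ over
the segmented LA wall. Because the statistic is a pure quotient, any global
rescaling of the image cancels exactly; the test suite asserts this
invariance, and also asserts by counterexample that *additive* offsets do
not cancel — IIR assumes a signal that scales multiplicatively.

Two fibrosis fractions are reported. Volumetric `%MF` is the fibrotic share
of all wall voxels times 100. Slice-wise `%MF` restricts to the single
axial slice containing the most fibrotic pixels, which mimics what a
histology section can see; ties between slices are broken toward the
lowest slice index and flagged. Absence of any supra-threshold voxel is an
error for the slice-wise measure (there is no "slice of greatest
enhancement") while it is a legitimate 0% for the volumetric one.
Longitudinal change is the signed difference
$D_{abs} = V_{post} - V_{baseline}$ in percentage points; the sign is
informative (fibrosis should not regress) and is never collapsed to a
magnitude.

Post-mortem (in-situ) scans are refused by `quantify_fibrosis()`: without
circulation, gadolinium pools and stagnates in the chamber, so blood-pool
normalization is meaningless there. Such scans may still serve
segmentation or registration.

## Wall extraction

The LA wall mask is derived from a blood-pool chamber mask by a 4-pixel
dilation applied *independently within each axial slice*, followed by
Boolean removal of the chamber. "4-pixel dilation" is read as a single
dilation by a Euclidean disk of radius 4 in pixel units — the lattice
points with $i^2 + j^2 \le 16$, 49 pixels — rather than 4 iterations of a
3×3 element. The interactive tool this emulates does not document its
element, so the iterated-3×3 alternative is available via
`axial_dilate(..., element = "iterated3x3")`; the disk is the default
because it is the most literal reading of a fixed-size named dilation.
In-plane pixel units are used as stated, so anisotropy between in-plane
and through-plane spacing does not affect the element.

Manual corrections (removal of valves, septal regions, appendage
decisions) are replaced by an explicit exclusion mask applied after
subtraction, with the excluded voxel count recorded — this keeps the whole
pipeline scriptable and reproducible without a GUI.

## Exact nonparametric inference

At study sizes of 9 and 3 animals, normal approximations to rank tests are
not defensible; both tests here are exact. The signed-rank test computes
the full conditional distribution of $W^+$ over all $2^n$ sign
assignments, and the Mann-Whitney test the distribution of the rank sum
over all $\binom{n_1+n_2}{n_1}$ group assignments. The distributions are
built by a generating-function recursion over (doubled) midranks, which is
algebraically the same enumeration without materializing it; brute-force
enumeration oracles in the test suite confirm equality for every
$n \le 12$ case tried, and `stats::wilcox.test(exact = TRUE)` agrees on
tie-free inputs.

Conventions: zero differences are dropped (and counted); tied magnitudes
receive midranks and set a tie flag; the two-sided p-value is
$\min(1,\, 2\min(P_{lower}, P_{upper}))$ on the discrete support. This
doubling convention reproduces the canonical small-sample values: complete
separation at 9 vs 3 gives $2/220 = 0.009$; 9 pairs with the two negatives
at absolute ranks 1–2 give $10/512 = 0.0195$; 3 pairs with the negative at
rank 1 give $0.50$. Note that at $n = 3$ the smallest achievable two-sided
p is $0.25$, so a 3-animal control group can never reach significance —
exact tests at these sizes are conservative by construction.

## Registration

Landmark correspondence is by label (13 anatomical fiducials), never by
file order. The least-squares rigid transform has the standard closed
form: align centroids, then take the rotation from the SVD of the
cross-covariance with a determinant correction that excludes reflections.
Noiseless correspondences are recovered to machine precision; with jitter,
the fitted SSD never exceeds the identity SSD (asserted as a property).
Collinear configurations and label mismatches are rejected. Volumes are
resampled with trilinear interpolation (nearest-neighbour for label maps)
onto the fixed grid. The coordinate frame of landmark tables is treated as
an abstract consistent frame — both sets must simply live in the same one.
No cross-timepoint voxel-overlap metrics are offered anywhere in the
reporting layer: anatomy genuinely moves and deforms between surgical
timepoints, so such overlaps would be misleading.

## Quality and variability metrics

NEMA-4 SNR uses one blood-pool ROI and exactly four disjoint background
ROIs: `snr = 0.66 * mean(signal) / mean(SD_1..SD_4)`. The 0.66 factor
converts the SD of a magnitude-image background — Rayleigh distributed,
$SD = \sigma\sqrt{2-\pi/2} \approx 0.655\,\sigma$ — into Gaussian-equivalent
noise.

Dice is reported on a 0–100 scale (100 for two empty masks, 0 when exactly
one is empty); repeated segmentations are summarized as the mean ± SD over
all unordered attempt pairs. Boundary precision/recall/F1 use boundary
voxels defined by 6-connectivity (a mask voxel with any non-mask
6-neighbour, array edges counting as outside), Euclidean distance in voxel
units, and a default tolerance of 2 voxels; both-empty boundaries score
100, one-empty 0. Distances are computed by chunked brute force, which is
exact and fast at study-scale masks.

Repeatability uses the reliability form $(1 + \sigma^2_w / (k\sigma^2_b))^{-1}$
($k = 1$ gives the ICC). The combining formula fixes neither estimator, so
the package declares them: $\sigma^2_w$ is the mean within-cell sample
variance over repeats, $\sigma^2_b$ the sample variance of condition
means. This estimator slightly inflates $\sigma^2_b$ (by
$\sigma^2_w/m$ for $m$ repeats), biasing ICC upward by well under the
Monte-Carlo noise at the simulated settings used in the tests
(200 conditions × 3 repeats recovering ICC ≈ 0.8). Because the grouping
axis for $\sigma^2_b$ in the multi-operator case is ambiguous in common
usage, `inter_rater_r()` exposes it (`"condition"` pools operators within
condition; `"cell"` treats each condition × operator cell separately).

## Histology

Trichrome slides are classified in HSV space: background is excluded by
low saturation (< 0.15) or high value (> 0.95), and remaining tissue
pixels are labelled collagen (fibrosis) when the hue lies in [90°, 270°)
and myocyte/red otherwise. Published workflows tune stain thresholds per
slide; that optimization rule is not published, so this package uses fixed,
fully configurable cutoffs whose defaults are pinned by synthetic slides
with known collagen fraction (recovery within ±1 point across fractions
0–0.9). Classification depends only on hue ordering, so it is invariant to
gamut-preserving brightness scaling. Per-animal histology summaries are
means over available slices; group summaries reuse `group_summary()`.

## The phantom generator

The generator is the package's ground-truth instrument, not a cardiac
simulator. It emulates exactly the features the pipeline is sensitive to:

- a bright ellipsoidal blood pool (default intensity 600) enclosed by a
  thin wall whose healthy and enhancing voxels sit at 360 and 840, i.e.
  noise-free NI of 0.6 and 1.4 — bracketing the 0.90–1.3 range of
  thresholds seen in practice;
- fibrotic voxels grown as contiguous surface patches (seeded 6-connected
  region growing to the achievable count nearest $f\,|wall|$), not
  salt-and-pepper noise;
- Rician magnitude noise $|(S + g_1) + i g_2|$, $g \sim N(0, \sigma)$
  (default $\sigma = 20$, i.e. blood-pool SNR ≈ 30), whose zero-signal
  background obeys the Rayleigh mean/SD relations (asserted within 3
  standard errors in the tests);
- 13 uniquely labelled landmarks, and paired studies whose post-timepoint
  landmarks move by a recorded rigid transform;
- two-class trichrome slides with an exact blue-pixel count.

One deliberate geometric choice: the phantom wall is the *in-plane
annulus* (each chamber cross-section dilated by the wall thickness, minus
the chamber) rather than a full 3D shell. This leaves the chamber poles
unwalled — anatomically a simplification — but makes the morphological
pipeline exactly self-consistent: a matched-radius wall extraction
recovers the ground-truth wall voxel-for-voxel, so end-to-end %MF and
$D_{abs}$ recovery can be asserted up to voxel quantization instead of up
to an arbitrary cap mismatch. The default wall thickness is 4 voxels,
matching the 4-pixel dilation radius and the 2–4 mm wall at sub-millimetre
resolution.

Determinism: every generator takes one integer seed; the stream order is
fixed (patch seeds, then noise draws, then landmark placement), and
identical seeds give bit-identical outputs. The cohort simulator draws
per-animal sub-seeds and per-timepoint biological jitter (SD 0.002 of the
wall fraction, i.e. 0.2 %MF points) from the cohort seed; the jitter makes
control paired differences nonzero, as in any real repeated measurement.
Default study conditions mirror the target design: 9 experimental + 3
control animals, baseline fraction 0.05, pacing increment 0.02.

What passing phantom tests do **not** show: robustness to partial-volume
contamination at the wall boundary, motion artifact, surface-coil
inhomogeneity, mis-segmentation of the chamber, or realistic atrial
anatomy. Those effects dominate error in real data (they are the reason
observer variability is reported at all) and are out of scope for the
generator.

## Numerical conventions and degenerate inputs

- $\sigma_{NI}$ and all summary SDs use the $n-1$ denominator; fewer than
  2 wall voxels is an error for thresholding.
- Fibrosis classification is strict (`NI > T_fib`); voxels exactly at the
  threshold are non-fibrotic.
- IQR is Q3 − Q1 with linear-interpolation quantiles (R type 7). Reported
  medians ± IQR elsewhere may use other hinge rules; this one is declared
  and used consistently.
- A single value summarizes to mean = median = value with SD and IQR `NA`.
- Thresholding degrades by design at high burden: on a noise-free
  two-class wall with fractions $f$ of enhancement, $T_{fib} < NI_{fib}$
  iff $f < 0.2$, so measured %MF equals $100f$ exactly below 0.2 and
  collapses to 0 above — the mean + 2 SD statistic presumes fibrosis is
  the minority class. The tests assert both regimes.
- Empty chamber, empty blood pool, all-zero paired differences, fewer
  than 4 noise ROIs, zero between-condition variance, and non-axis-aligned
  volume orientations are all explicit errors, not silent results.
- Volume headers without spacing fall back to 0.625 × 0.625 × 0.975 mm
  (the acquisition geometry this pipeline was designed around) with a
  warning.

## Problem sizes

The test suite and analysis scripts run phantoms of 28×28×20 to 36×36×30
voxels (walls of roughly 3,000–5,600 voxels), cohorts of 12 animals, 20
seeded end-to-end replicates, Monte-Carlo reliability checks at 200
conditions × 3 repeats, a 1.5–2 × 10^5-voxel Gaussian null, and 256–512 px
trichrome slides. These sizes were chosen so every statistical assertion
has adequate resolution (e.g. voxel quantization of 0.02–0.03 %MF points;
3-SE Monte-Carlo bands) while the whole suite stays interactive.

## Known limitations

- Only axis-aligned volume geometry is supported; oblique direction
  matrices are rejected rather than resampled.
- The package quantifies; it does not segment the chamber. Segmentation
  quality is the dominant error source in practice.
- The in-plane-annulus phantom wall and landmark-only pose changes mean
  registration resampling is exercised synthetically, not against real
  deformation.
- Histology thresholds are fixed per run, not per-slide optimized.
- Exact tests enumerate conditional distributions; at the intended study
  sizes this is instantaneous, but the signed-rank support grows as
  $n^2$ and the Mann-Whitney DP as $n_1 n_2 (n_1 + n_2)$ — comfortably
  fast to a few hundred observations, far beyond the design range.
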