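---
title: "Correlating amyloid plaque morphology with peptide chemistry: methods and design"
author: "plaquemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plaquemap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemap)
```

## The problem

Amyloid-beta (A&beta;) deposits in Alzheimer's disease are morphologically
heterogeneous: loose diffuse plaques (DP), dense-core/cored plaques (CP)
with a bright compact core and a fibrillar corona, large multi-cored
coarse-grained plaques (CGP) without a corona, cotton-wool plaques (CWP) of
familial AD, and vascular amyloid (CAA). Correlative imaging studies pair
amyloid-probe (LCO) fluorescence microscopy of a tissue section with MALDI
mass-spectrometry imaging (MSI) of the same section, so that every
morphologically classified plaque can be interrogated for its A&beta;
peptide composition — full-length A&beta;1-40/1-42 and the N-terminally
truncated and pyroglutamated species (e.g. A&beta;3pE-42, A&beta;11pE-42,
A&beta;4-40) that discriminate plaque populations.

`plaquemap` implements the complete analysis side of such a study:

1. a **synthetic-cohort generator** with known ground truth, standing in
   for post-mortem tissue;
2. **microscopy image analysis**: background subtraction, Li-threshold
   segmentation of LCO-positive plaques, per-ROI fluorescence density;
3. a **CNN morphotype classifier** trained by three-fold cross-validated
   ensembling;
4. the **ROI spectral chain** producing an ROI-by-peptide area table;
5. **bisecting k-means** spatial segmentation of MSI datacubes;
6. **landmark registration** of microscopy onto the MSI grid and
   plaque-load summaries;
7. the **statistics layer**: OPLS-DA with VIP scores, Ward clustering,
   Kruskal-Wallis with Dunn post-hoc tests, Mann-Whitney / Wilcoxon with
   Benjamini-Hochberg adjustment, correlation and CV summaries;
8. **pipeline orchestration** with evaluation against the simulator's
   ground truth.

## The synthetic cohort: what it emulates

No raw imaging data are available to ship, so every claim the package
tests is made against simulated data whose generating process mirrors the
study conditions.

**Peptide panel.** `build_abeta_panel()` derives average (not
monoisotopic) masses from the canonical A&beta;1-42 sequence; linear-mode
TOF at a resolving power of m/&Delta;m = 1000 does not resolve isotopes,
so the average-mass [M+H]+ convention matches the observed centroids
(A&beta;1-42 at m/z 4515.1). Pyroglutamate formation subtracts one water
(E) or one ammonia (Q).

**Geometry.** Plaque diameters are drawn uniformly from the histological
ranges: CP 30-50 um, CGP 50-100 um, DP and CWP at 50 um and above, with
CGP carrying 3-8 dense cores and no corona, and CAA rendered as an
annular wall along a curved vessel path (wall 10-20 um). Microscopy
pixels default to 0.5 um (tests mostly use 1 um for speed); the MSI
raster is fixed at the acquisition pitch of 10 um.

**Abundance profiles.** Each morphotype template carries a relative
abundance profile over the nine-peptide panel. Profile ratios *are* the
planted effects: CP vs DP plants threefold elevations of A&beta;1-40,
A&beta;3pE-42 and A&beta;11pE-42 (plus twofold elevations of the
N-truncated x-40 forms, mirroring the higher truncation levels of cored
plaques) while A&beta;1-42, A&beta;2-42, A&beta;4-42 and A&beta;5-42 are
planted equal and serve as the null set;
CGP vs CP elevates the x-40 species (A&beta;4-40, A&beta;3pE-40,
A&beta;1-40) and lowers the x-42 species; CAA exceeds CGP in
A&beta;1-40/3pE-40 and falls below it in x-42 content. A non-panel
"filler" component (at m/z 5500, i.e. at a peak width comparable to the
panel) pads every profile to the same total ion content, so TIC
normalization cannot convert composition differences into spurious shifts
of null peptides (the closure artifact).

**Noise model.** Three multiplicative log-normal layers with unit mean
parameterized by their CV (sigma_log = sqrt(log(1 + CV^2))): technical
replicates at 10%, plaque-to-plaque within a patient at 16%, and
patient-level at 18% — the replicate structure the statistics module
summarizes. Spectra add a decaying-exponential chemical baseline
b(m) = b0 exp(-(m - 1500)/1200) (a smooth, SNIP-removable surrogate for
matrix-cluster decay) and an additive Gaussian detector floor. Peaks are
Gaussian with FWHM = m/z / 1000.

**Cohort structure.** Default group sizes are CUAP 5, sAD 12, fAD 6.
Per-patient plaque counts are Poisson draws around group-specific means
chosen to reproduce the qualitative load ordering (DP prominent in CUAP
and sAD but low in fAD; CP increasing CUAP < sAD < fAD; CGP and CAA
absent from CUAP by construction and more abundant in fAD than sAD; CWP
confined to fAD). Absolute counts per section are not published, so the
means are simulator parameters fixed once at values that give 5-15
plaques per subtype per patient.

What the simulator deliberately does **not** model: photorealistic
texture, isotope fine structure, m/z calibration drift across sections,
spatial chemical gradients within the corona, and tau/neuritic chemistry
beyond a co-localized PHF-1-like intensity channel. Passing tests
therefore demonstrate the correctness and power of the *analysis* under
the stated noise model, not performance on real tissue.

## Microscopy quantification

Background is estimated by grayscale morphological opening with a disc
(rolling-ball equivalent; default radius 50 um) and subtracted with
clipping at zero; large radii are computed on a conservatively
downsampled copy since the background is smooth by construction. The Li
minimum-cross-entropy threshold is found by Li & Tam's fixed-point
iteration; segmentation keeps 8-connected components of at least
100 um^2 (well below the smallest 30-um CP archetype, which covers about
700 um^2). Fluorescence density is summed ROI intensity divided by ROI
area in um^2; with the per-um^2 convention a uniform image of value v at
0.5 um pixels yields 4v. Batch connected-component capture replaces the
interactive per-object "wand" selection of desktop tools — a documented
substitution that makes segmentation reproducible.

## The morphotype classifier

Patches are resized bilinearly to 120 x 120, converted to grayscale, and
contrast-stretched by mapping the 1st/99th intensity percentiles onto
[0, 1] (constant crops map to zero). Augmentation applies random
rotations (+-20 degrees), independent horizontal/vertical flips, and
isotropic rescaling (0.9-1.1), resampled bilinearly with zero padding —
label-preserving by construction.

Training follows the published protocol: a held-out stratified test set
(20% per class, `round` per class, so 385 images yield a test set of 77
or 78 depending on class counts — the implementation reports the achieved
size rather than forcing one), three mutually exclusive stratified folds,
one network per fold trained on the other two folds, Adam at learning
rate 0.001 decayed by 0.96 every 10 epochs, categorical cross-entropy,
mini-batches of 32, and final prediction by averaging the three softmax
outputs (ties broken by the fixed class order CGP < CP < DP).

The network itself is authored in the package (no deep-learning framework
is required): blocks of 3x3 convolution, batch normalization, ReLU and
2x2 max-pooling, then a dense layer, dropout 0.5 and a softmax head. The
default stack downscales the input by 2x average pooling (120 to 60) and
uses 4/8/16 filters with a 32-unit dense layer: the smallest stack that
cleanly separates the synthetic morphotypes on a single CPU in about a
minute. Filter counts, dense width and the downscale factor are
configurable through `train_config()` for harder data. Default epoch
budget is 30 with early stopping (patience 5) on validation loss; the
synthetic experiments converge in well under 10.

`reconstruct_confusion()` addresses a bookkeeping gap: published
evaluation tables often print accuracy, per-class precision, recall and
F1 without the underlying confusion matrix. An integer search over all
3 x 3 matrices with the stated total and correct counts returns every
matrix consistent with the printed values after two-decimal rounding (for
the default inputs there are exactly two, differing only in the CP/DP
diagonal split).

## The ROI spectral chain

Per ROI, member-pixel spectra are averaged and processed in a fixed,
logged order: square-root transform, Savitzky-Golay smoothing
(half-window 10 bins, cubic, reflection edges), SNIP baseline estimation
(100 iterations, decreasing window, LLS transform
log(log(sqrt(v+1)+1)+1)), baseline subtraction, back-transform to the
intensity scale, TIC normalization, MAD noise, SNR gating, and
trapezoidal peak areas.

Numerical choices worth stating:

* **Half-window in bins, not Da** — the processing operates on index
  windows; with 1-Da bins a window of 21 bins spans several peak widths
  at the top of the mass range and well under one at the bottom.
* **Back-transform before integration.** The square root is variance
  stabilization for the smoothing and baseline stages. Areas are reported
  on the squared (intensity) scale: on the square-root scale a planted
  abundance ratio f would surface as sqrt(f), and fold changes would no
  longer be comparable to the planted effects or to each other. Signal
  and baseline are back-transformed separately and subtracted on the
  intensity scale.
* **Noise before TIC, on the stabilized scale.** The MAD noise level is
  taken from the baseline-subtracted square-root spectrum, where detector
  noise is approximately Gaussian. Because the clipped baseline rides
  below the noise band, the residual has a positive median; apexes are
  therefore gated as (apex - median)/MAD > 2. Peptides failing the gate
  are recorded as zero with a below-noise flag, and
  `consistent_peptides()` restricts tables to the panel detected in every
  ROI before group statistics.
* **Integration half-width of one FWHM** (m/z / 1000) around each panel
  mass — not stated in desktop tools; configurable.
* **ROI spectrum = mean (not sum) of pixel spectra**, making areas
  independent of ROI pixel count.

On noise-free synthetic input the chain recovers planted fold changes to
within a few percent for abundant species; very low-abundance peptides
(template abundance near the baseline amplitude) are compressed by up to
roughly 15%, which matters for effect-size interpretation but not for
detection or ranking.

## Spatial segmentation

`bisecting_kmeans()` TIC-normalizes pixel spectra (optionally after
coarse binning), then repeatedly bisects the leaf with the largest
within-cluster sum of squares using seeded 2-means with 10 restarts; ties
break to the lower node id. Cuts replay splits in order, so the cut at n
clusters always refines the cut at n-1. "Medium" spatial smoothing maps
to an isotropic Gaussian of sigma = 1 pixel (none/weak/strong = 0/0.5/2),
applied per m/z bin with symmetric (edge-duplicating) reflection — the
padding variant under which a symmetric kernel conserves total intensity
exactly. The number of clusters is exposed as a parameter rather than
fixed, mirroring interactive dendrogram cutting.

## Registration and plaque loads

Both modalities image the same physical section, so a similarity
transform (scale, rotation, translation — no shear) suffices; it is
fitted in closed form (orthogonal Procrustes with scale) from landmark
pairs, which in synthetic work come from the generator's true transform
and in real use from a fiducial table. Microscopy ROIs are rasterized
onto the 10-um MSI grid with a 50% area-coverage rule estimated by 5x5
subpixel sampling (odd grids avoid tie degeneracies on symmetric
alignments). Plaque load is the ROI area fraction of analyzed tissue (%)
and the count density per mm^2.

## Statistics

* `autoscale()` centers and unit-scales columns (n-1 denominator),
  dropping constants with a warning.
* `oplsda_fit()` estimates one predictive PLS component after removing
  `n_orth` y-orthogonal components (default 1, the usual choice for
  two-class problems); R2X/R2Y are reconstruction fractions and Q2 comes
  from stratified 7-fold cross-validation. VIP scores use the normalized
  predictive weights, so sum(VIP^2) equals the number of variables.
* `kruskal_dunn()` uses the tie-corrected H (cross-checked against
  `stats::kruskal.test`) and Dunn z statistics on mean ranks with the
  tie-corrected variance; two-sided p values are multiplied by the number
  of pairwise comparisons (capped at 1).
* `pairwise_bh()` runs exact Mann-Whitney tests for small tie-free
  samples (both n <= 8) and the continuity-corrected normal approximation
  otherwise, Wilcoxon signed-rank for paired designs, with
  Benjamini-Hochberg adjustment across the supplied batch via the
  explicit step-up arithmetic in `bh_adjust()`.
* Plaques are treated as independent observations despite nesting within
  patients — deliberately mirroring the published analysis; the pipeline
  tags outputs with patient ids so a mixed-model reanalysis remains
  possible downstream.

## Problem sizes used by the test-suite experiments

Simulation sizes are chosen so the full suite runs comfortably on one
CPU: classifier experiments use 120 patches per class; parameter-recovery
experiments run 50 seeded cohorts of 13 patients (CUAP 3 / sAD 6 / fAD 4)
with one technical replicate and the m/z window restricted to
3000-5600 Da (which contains the full panel plus the filler); end-to-end
pipeline runs use two to four patients on 450-600 um fields. Statistical
power at these sizes is ample for the planted threefold effects, and all
generator noise parameters stay at the study values (10/16/18% CVs).

## Known limitations

* The CNN is a compact, CPU-sized stack; transfer to real micrographs
  would require retraining and likely a larger network.
* The spectral chain's fold-change compression near the noise floor is
  documented above; absolute quantification is out of scope.
* No m/z recalibration across sections, no isotope deconvolution, no
  deformable registration, no mixed-effects modeling of the
  plaque-within-patient hierarchy.
* imzML support covers continuous mode fully and processed mode with a
  shared axis length; compression and nonstandard binary types are not
  handled.
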