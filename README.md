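# plaquemap

Correlative imaging analysis of amyloid-beta (Aβ) plaque polymorphism in R.

Alzheimer's disease amyloid pathology is morphologically diverse — diffuse
plaques (DP), cored plaques (CP), coarse-grained plaques (CGP), cotton-wool
plaques (CWP) and vascular amyloid (CAA) — and each morphotype carries a
distinct Aβ peptide signature (full-length Aβ1-40/Aβ1-42 plus N-terminally
truncated and pyroglutamated species such as Aβ3pE-42, Aβ11pE-42 and
Aβ4-40). Correlative studies image the same tissue section with
amyloid-probe (LCO) fluorescence microscopy and MALDI mass-spectrometry
imaging (MSI), classify plaques morphologically, and test which peptides
discriminate the morphotypes.

`plaquemap` implements that entire analysis as tested, reusable R code, for
researchers who want to run, audit or extend the workflow:

* **Synthetic cohorts with ground truth** (`make_microscopy_scene()`,
  `make_msi_dataset()`, `make_cohort()`): morphotype-specific geometries,
  planted peptide abundance profiles, Gaussian peaks at instrument
  resolution (FWHM = m/z / 1000 over 1500–6000 Da, 10 µm raster), baseline
  plus noise at 10% technical / 16% intra-patient / 18% inter-patient CV,
  and the CUAP / sporadic-AD / familial-AD cohort structure (coarse-grained
  and vascular deposits absent from the cognitively unimpaired group).
* **Microscopy quantification** (`subtract_background()`, `li_threshold()`,
  `segment_plaques()`, `quantify_roi_fluorescence()`): rolling-ball-style
  background removal, Li minimum cross-entropy thresholding, 8-connected
  components, per-ROI intensity/µm².
* **CNN morphotype classifier** (`train_crossval()`, `predict_ensemble()`,
  `classification_metrics()`, `reconstruct_confusion()`): 120×120 patch
  preprocessing, rotation/flip/scale augmentation, three-fold
  cross-validated training (Adam, learning rate 0.001 decayed 0.96 every
  10 epochs, batches of 32) with softmax averaging — the network is
  implemented in the package on plain BLAS matrix operations.
* **ROI spectral chain** (`preprocess_roi_spectra()`): sqrt transform →
  Savitzky-Golay (half-window 10) → SNIP baseline (100 iterations) → TIC
  normalization → MAD noise → SNR > 2 gate → trapezoidal peak areas.
* **Spatial segmentation** (`bisecting_kmeans()`, `cut_tree()`,
  `single_ion_image()`, `spatial_smooth()`).
* **Registration and loads** (`fit_similarity()`, `transfer_rois()`,
  `plaque_load()`).
* **Statistics** (`oplsda_fit()`, `vip_scores()`, `hca_ward()`,
  `kruskal_dunn()`, `pairwise_bh()`, `corr_and_cv()`, `autoscale()`).
* **Orchestration** (`run_pipeline()`, `evaluate_truth()`) with one root
  seed and full provenance.

## Worked example

Simulate a small field, quantify it, and test the cored-vs-diffuse
contrast:

```r
library(plaquemap)

panel <- default_abeta_panel()
panel[panel$name == "Abeta1-42", c("name", "mz_obs")]
#>        name   mz_obs
#> 2 Abeta1-42 4515.103

# scene with 3 cored, 2 diffuse, 2 coarse-grained plaques
sc <- make_microscopy_scene(c(CP = 3, DP = 2, CGP = 2),
                            field_um = c(500, 500), px_um = 1, seed = 17)
ms <- make_msi_dataset(sc$truth, panel, noise_cv = 0.10, seed = 4,
                       mz_range = c(3000, 5600))

# segment the LCO channel and extract the ROI peak table
img  <- channel_image(sc$scene$channels$LCO, 1, "LCO")
rois <- segment_plaques(subtract_background(img))
nrow(rois$morphometrics)
#> [1] 7

pt <- preprocess_roi_spectra(ms$msi, truth_msi_rois(ms$msi, ms$truth), panel)
round(pt[["Abeta1-40"]][1:3], 4)
#> [1] 0.0487 0.0494 0.0512

# morphotype contrast on a simulated 13-patient cohort
co   <- make_cohort(cohort_spec(groups = c(CUAP = 3, sAD = 6, fAD = 4),
                                seed = 1001, n_tech_replicates = 1),
                    mz_range = c(3000, 5600))
ptab <- cohort_peak_table(co)
keep <- ptab$tags$type %in% c("CP", "DP", "CGP")
scan <- contrast_scan(ptab$table[keep, ], ptab$tags$type[keep], c("CP", "DP"))
scan[scan$p_adj < 0.05, c("peptide", "z", "p_adj")]
#>        peptide        z        p_adj
#> 1    Abeta1-40 11.06171 5.772128e-28
#> 4  Abeta3pE-40 10.72622 2.300115e-26
#> 5  Abeta3pE-42 14.80653 3.988052e-49
#> 6    Abeta4-40 10.40864 6.792656e-25
#> 9 Abeta11pE-42 14.46668 5.902215e-47
```

The significant peptides are exactly the species the simulator plants as
elevated in cored over diffuse plaques — the threefold discriminators
Aβ1-40, Aβ3pE-42 and Aβ11pE-42 plus the twofold-elevated N-truncated x-40
forms — while the four peptides planted at equal abundance (Aβ1-42,
Aβ2-42, Aβ4-42, Aβ5-42) stay non-significant.

## Further reading

The methods vignette (`vignettes/plaquemap-methods.Rmd`) documents the
model behind the simulator, every numerical choice in the spectral chain,
the classifier architecture, the registration conventions, and the known
limitations.
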