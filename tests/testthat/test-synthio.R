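test_that("empty scenes are blank and carry no truth entries", {
  sc <- make_microscopy_scene(c(CP = 0), field_um = c(200, 200), seed = 1)
  expect_equal(nrow(sc$truth$roi_labels), 0)
  expect_true(all(sc$scene$channels$LCO == sc$scene$channels$LCO[1, 1]))
  expect_true(all(sc$truth$pixel_class_map == 0))
})

test_that("generated diameters respect the morphotype geometry intervals", {
  sc <- make_microscopy_scene(c(CGP = 20), field_um = c(1500, 1500),
                              px_um = 1, seed = 5)
  expect_equal(nrow(sc$truth$roi_labels), 20)
  expect_true(all(sc$truth$roi_labels$diameter_um >= 50 &
                    sc$truth$roi_labels$diameter_um <= 100))
  sc2 <- make_microscopy_scene(c(CP = 15, DP = 10), field_um = c(1500, 1500),
                               px_um = 1, seed = 6)
  d <- sc2$truth$roi_labels
  expect_true(all(d$diameter_um[d$class == "CP"] >= 30 &
                    d$diameter_um[d$class == "CP"] <= 50))
  expect_true(all(d$diameter_um[d$class == "DP"] >= 50))
})

test_that("scene generation is a pure function of its seed", {
  a <- make_microscopy_scene(c(CP = 3, DP = 2), field_um = c(400, 400), seed = 9)
  b <- make_microscopy_scene(c(CP = 3, DP = 2), field_um = c(400, 400), seed = 9)
  expect_identical(a$scene, b$scene)
  expect_identical(a$truth$roi_labels, b$truth$roi_labels)
})

test_that("infeasible packing reports the achieved count", {
  expect_error(
    make_microscopy_scene(c(CGP = 30), field_um = c(250, 250), seed = 1,
                          max_tries = 20),
    "placed"
  )
})

test_that("noise-free pixel spectra equal the analytic Gaussian sum", {
  sc <- make_microscopy_scene(c(CP = 1), field_um = c(150, 150), px_um = 1,
                              seed = 3)
  panel <- tiny_panel()
  ms <- make_msi_dataset(sc$truth, panel, noise_cv = 0, seed = 1,
                        mz_range = c(3000, 5600), baseline_b0 = 0,
                        detector_sd = 0)
  idx <- which(rowSums(ms$truth$amplitudes) > 0)
  expect_gt(length(idx), 0)
  for (i in idx[1:3]) {
    amps <- ms$truth$amplitudes[i, ]
    # filler sits off-panel; add its planted contribution to the oracle
    tpl <- plaque_templates()$CP
    oracle <- oracle_gaussian_sum(ms$msi$mz,
                                  c(panel$mz_obs, plaquemap::FILLER_MZ),
                                  c(amps, tpl$filler))
    expect_equal(ms$msi$intensities[i, ], oracle, tolerance = 1e-10)
  }
})

test_that("simulated peak width matches the instrument resolving power", {
  panel <- build_abeta_panel("Abeta1-42")
  mz <- seq(4400, 4700, 0.2)
  s <- simulate_roi_spectrum(c(`Abeta1-42` = 100), panel, mz,
                             baseline_b0 = 0, detector_sd = 0)
  apex <- which.max(s$intensity)
  half <- s$intensity[apex] / 2
  cross <- function(i0, i1) {
    # linear interpolation of the half-maximum crossing
    s$mz[i0] + (half - s$intensity[i0]) /
      (s$intensity[i1] - s$intensity[i0]) * (s$mz[i1] - s$mz[i0])
  }
  lo <- max(which(s$intensity[1:apex] < half))
  hi <- apex - 1 + min(which(s$intensity[apex:length(s$mz)] < half))
  fwhm <- cross(hi - 1, hi) - cross(lo, lo + 1)
  expect_lt(abs(fwhm - panel$mz_obs / 1000), 0.2)
})

test_that("noise-free ROI AUC ratios recover planted fold changes", {
  # SNIP baseline + trapezoid areas on noise-free, baseline-free spectra
  panel <- default_abeta_panel()
  mz <- seq(3000, 5600, 1)
  tpl <- plaque_templates()
  auc_for <- function(type) {
    s <- simulate_roi_spectrum(tpl[[type]]$profile, panel, mz,
                               filler = tpl[[type]]$filler,
                               baseline_b0 = 0, detector_sd = 0)
    s <- subtract_baseline(s, snip_baseline(s, 100))
    vapply(seq_len(nrow(panel)), function(k) {
      peak_auc(s, panel$mz_obs[k], panel$mz_obs[k] / 1000)
    }, 0)
  }
  ratio <- auc_for("CP") / auc_for("DP")
  planted <- unname(planted_fold_changes(tpl, "CP", "DP")[panel$name])
  expect_equal(ratio, planted, tolerance = 0.01)
})

test_that("planted CP:DP fold change of 3 is recovered under technical noise", {
  panel <- default_abeta_panel()
  mz <- seq(3000, 5600, 1)
  tpl <- plaque_templates()
  set.seed(41)
  sdlog <- sqrt(log(1 + 0.10^2))
  mk <- function(type) {
    t <- tpl[[type]]
    amp <- t$profile * rlnorm(length(t$profile), -sdlog^2 / 2, sdlog)
    simulate_roi_spectrum(amp, panel, mz, filler = t$filler)
  }
  spectra <- c(lapply(1:15, function(i) mk("CP")),
               lapply(1:15, function(i) mk("DP")))
  names(spectra) <- sprintf("r%02d", 1:30)
  pt <- preprocess_roi_spectra(panel = panel, spectra = spectra)
  ratio <- stats::median(pt[["Abeta1-40"]][1:15]) /
    stats::median(pt[["Abeta1-40"]][16:30])
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 3.8)
})

test_that("cohorts honour group sizes and structural zeros", {
  spec <- cohort_spec(seed = 7)
  co <- make_cohort(spec, mz_range = c(3300, 4600))
  tags <- co$amplitude_tags
  expect_equal(length(unique(tags$patient)), 23)
  expect_equal(length(unique(tags$patient[tags$group == "CUAP"])), 5)
  expect_equal(length(unique(tags$patient[tags$group == "sAD"])), 12)
  expect_equal(length(unique(tags$patient[tags$group == "fAD"])), 6)
  expect_equal(sum(tags$type %in% c("CGP", "CAA") & tags$group == "CUAP"), 0)
  # DP load CUAP ~ sAD > fAD; CP load CUAP < sAD < fAD; CGP fAD > sAD
  mean_count <- function(g, ty) {
    n <- table(tags$patient[tags$group == g & tags$type == ty])
    sum(tags$group == g & tags$type == ty) /
      length(unique(tags$patient[tags$group == g]))
  }
  expect_gt(mean_count("CUAP", "DP"), mean_count("fAD", "DP"))
  expect_lt(mean_count("CUAP", "CP"), mean_count("fAD", "CP"))
  expect_gt(mean_count("fAD", "CGP"), mean_count("sAD", "CGP"))
})

test_that("cohort generation is deterministic in the spec seed", {
  spec <- cohort_spec(groups = c(CUAP = 1, sAD = 2, fAD = 1), seed = 13)
  a <- make_cohort(spec, mz_range = c(3300, 4600))
  b <- make_cohort(spec, mz_range = c(3300, 4600))
  expect_identical(a$amplitudes, b$amplitudes)
  expect_identical(lapply(a$spectra, `[[`, "intensity"),
                   lapply(b$spectra, `[[`, "intensity"))
})

test_that("CUAP spec rejects nonzero coarse-grained means", {
  mc <- rbind(CUAP = c(DP = 5, CP = 3, CGP = 1, CWP = 0, CAA = 0),
              sAD = c(DP = 5, CP = 3, CGP = 1, CWP = 0, CAA = 0),
              fAD = c(DP = 5, CP = 3, CGP = 1, CWP = 0, CAA = 0))
  expect_error(cohort_spec(mean_counts = mc), "CUAP")
  expect_error(cohort_spec(technical_cv = 1.2), "coefficients of variation")
})
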