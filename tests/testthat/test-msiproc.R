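test_that("Savitzky-Golay reproduces polynomials and the textbook kernel", {
  mz <- seq(2000, 2200, 1)
  x <- seq_along(mz)
  cubic <- 5 + 0.3 * x + 0.02 * x^2 + 1e-4 * x^3
  s <- smooth_savgol(spectrum(mz, cubic), half_window = 10, poly_order = 3)
  interior <- 12:(length(mz) - 11)
  expect_equal(s$intensity[interior], cubic[interior], tolerance = 1e-9)

  # impulse response reads off the kernel: window 5, order 2
  imp <- numeric(101); imp[51] <- 1
  si <- smooth_savgol(spectrum(seq_len(101), imp), half_window = 2,
                      poly_order = 2)
  expect_equal(si$intensity[49:53], c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-10)
  expect_equal(si$intensity[49:53], oracle_sg_kernel(2, 2),
               tolerance = 1e-10)

  const <- spectrum(mz, rep(4, length(mz)))
  expect_equal(smooth_savgol(const)$intensity, const$intensity,
               tolerance = 1e-10)
  expect_error(smooth_savgol(spectrum(1:5, rep(1, 5)), half_window = 10),
               "shorter")
})

test_that("SNIP matches an independent reference and respects the envelope", {
  mz <- seq_len(500)
  expect_equal(snip_baseline(spectrum(mz, numeric(500)))$intensity,
               numeric(500))
  c0 <- 2
  peak <- 50 * c0 * exp(-0.5 * ((mz - 250) / (5 / 2.3548))^2)
  v <- c0 + peak
  b <- snip_baseline(spectrum(mz, v), 100)
  expect_equal(b$intensity, oracle_snip(v, 100), tolerance = 1e-9)
  under <- abs(mz - 250) < 5
  expect_lt(max(abs(b$intensity[under] - c0)) / c0, 0.05)
  expect_true(all(b$intensity <= v + 1e-9))
  # apex stays positive after subtraction
  expect_gt((v - b$intensity)[250], 0)
})

test_that("the SNIP baseline under a peak never grows with more iterations", {
  mz <- seq_len(400)
  v <- 3 + 100 * exp(-0.5 * ((mz - 200) / 4)^2)
  under <- abs(mz - 200) < 8
  b25 <- snip_baseline(spectrum(mz, v), 25)$intensity[under]
  b50 <- snip_baseline(spectrum(mz, v), 50)$intensity[under]
  b100 <- snip_baseline(spectrum(mz, v), 100)$intensity[under]
  expect_true(all(b50 <= b25 + 1e-9))
  expect_true(all(b100 <= b50 + 1e-9))
})

test_that("MAD noise estimation is sigma-consistent", {
  expect_equal(estimate_noise_mad(spectrum(1:10, rep(3, 10))), 0)
  alt <- spectrum(1:100, rep(c(0, 2), 50))  # +-1 around the median
  expect_equal(estimate_noise_mad(alt), 1.4826)
  set.seed(17)
  g <- spectrum(seq_len(1e5), abs(rnorm(1e5, 50, 2)))
  expect_lt(abs(estimate_noise_mad(g) - 2) / 2, 0.02)
})

test_that("TIC normalization is exact and scale-invariant", {
  s <- spectrum(1:50, runif(50) + 0.1)
  n1 <- tic_normalize(s)
  n5 <- tic_normalize(spectrum(s$mz, s$intensity * 5))
  expect_equal(sum(n1$intensity), 1)
  expect_equal(n1$intensity, n5$intensity, tolerance = 1e-12)
  expect_error(tic_normalize(spectrum(1:5, numeric(5))), "zero spectrum")
})

test_that("peak detection applies the SNR gate and FWHM merging", {
  mz <- seq(3000, 3200, 0.5)
  noise <- 1
  g1 <- 10 * exp(-0.5 * ((mz - 3100) / 1.3)^2)
  s1 <- spectrum(mz, g1)
  pk <- detect_peaks(s1, snr_threshold = 2, noise = noise)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mz, 3100, tolerance = 0.5)

  weak <- spectrum(mz, 1.5 * exp(-0.5 * ((mz - 3100) / 1.3)^2))
  expect_equal(nrow(detect_peaks(weak, 2, noise = noise)), 0)

  sep <- 3 * 3.1  # three FWHM at m/z ~3100
  two <- spectrum(mz, g1 + 8 * exp(-0.5 * ((mz - 3100 - sep) / 1.3)^2))
  pk2 <- detect_peaks(two, 2, noise = noise)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$mz[1] - 3100), 0.51)
  expect_lt(abs(pk2$mz[2] - (3100 + sep)), 0.51)

  # detection count is monotone nonincreasing in the threshold
  set.seed(5)
  noisy <- spectrum(mz, pmax(g1 + rnorm(length(mz), 0, 1), 0))
  counts <- vapply(c(1, 2, 4, 8), function(tau) {
    nrow(detect_peaks(noisy, tau, noise = 1))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("trapezoidal areas match closed forms", {
  mz <- seq(1000, 1100, 1)
  s <- spectrum(mz, rep(3, length(mz)))
  expect_equal(peak_auc(s, 1050, 10), 3 * 20)
  tri <- pmax(1 - abs(mz - 1050) / 10, 0) * 6
  expect_lt(abs(peak_auc(spectrum(mz, tri), 1050, 10) - 6 * 20 / 2), 6)
  expect_error(peak_auc(s, 5000, 0.4), "fewer than two bins")
})

test_that("the ROI chain flags sub-noise peptides and ignores pixel order", {
  panel <- default_abeta_panel()
  sc <- make_microscopy_scene(c(CP = 1), field_um = c(150, 150), px_um = 1,
                              seed = 31)
  ms <- make_msi_dataset(sc$truth, panel, noise_cv = 0, seed = 2,
                        mz_range = c(3000, 5600), baseline_b0 = 2,
                        detector_sd = 0)
  rois <- truth_msi_rois(ms$msi, ms$truth)
  pt <- preprocess_roi_spectra(ms$msi, rois, panel)
  expect_true(all(as.matrix(pt) > 0))
  expect_false(any(attr(pt, "below_noise")))
  expect_equal(attr(pt, "stages")[1:5],
               c("average_pixels", "sqrt", "savitzky_golay",
                 "snip_subtract", "square_back_transform"))

  shuffled <- lapply(rois, rev)
  pt2 <- preprocess_roi_spectra(ms$msi, shuffled, panel)
  expect_equal(as.matrix(pt), as.matrix(pt2), tolerance = 1e-12)

  expect_error(preprocess_roi_spectra(ms$msi, list(bad = integer()), panel),
               "bad")
})

test_that("an absent peptide is recorded as zero with a below-noise flag", {
  panel <- default_abeta_panel()
  mz <- seq(3000, 5600, 1)
  amps <- plaque_templates()$DP$profile
  amps["Abeta3pE-40"] <- 0  # plant a truly absent species
  set.seed(9)
  s <- simulate_roi_spectrum(amps, panel, mz, filler = 40,
                             baseline_b0 = 2, detector_sd = 0.05)
  pt <- preprocess_roi_spectra(panel = panel, spectra = list(x = s))
  expect_true(attr(pt, "below_noise")[1, "Abeta3pE-40"])
  expect_equal(pt[["Abeta3pE-40"]], 0)
})
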