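test_that("background subtraction removes constant images and keeps output nonnegative", {
  img <- channel_image(matrix(7, 80, 80), 1)
  out <- subtract_background(img, 10)
  expect_true(all(out$pixels == 0))
  set.seed(3)
  rnd <- channel_image(matrix(runif(6400), 80, 80), 1)
  expect_true(all(subtract_background(rnd, 10)$pixels >= 0))
  expect_error(subtract_background(img, 0.3), "smaller than one pixel")
})

test_that("a small bright disk survives subtraction with a large radius", {
  m <- matrix(0, 100, 100)
  ctr <- 50
  for (i in 1:100) for (j in 1:100) {
    if ((i - ctr)^2 + (j - ctr)^2 < 36) m[i, j] <- 1
  }
  out <- subtract_background(channel_image(m, 1), 30)
  expect_gt(sum(out$pixels), 0.99 * sum(m))
})

test_that("Li threshold minimizes the cross-entropy criterion", {
  v <- c(rep(10, 50), rep(100, 50))
  img <- channel_image(matrix(v, 10, 10), 1)
  t_impl <- li_threshold(img)
  expect_gt(t_impl, 10)
  expect_lt(t_impl, 100)
  # brute-force oracle: minimize Li & Lee cross-entropy over candidates
  li_criterion <- function(vals, t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (length(lo) == 0 || length(hi) == 0) return(Inf)
    -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
  }
  cands <- seq(min(v) + 0.5, max(v) - 0.5, by = 0.5)
  best <- min(vapply(cands, li_criterion, 0, vals = v))
  expect_equal(li_criterion(v, t_impl), best, tolerance = 1e-9)
})

test_that("Li threshold is scale-equivariant and rejects constant images", {
  set.seed(8)
  v <- c(rgamma(300, 2, 1), rgamma(80, 2, 1) + 8)
  t1 <- li_threshold(matrix(v, 20, 19))
  t3 <- li_threshold(matrix(3 * v, 20, 19))
  expect_equal(t3 / t1, 3, tolerance = 1e-6)
  expect_error(li_threshold(matrix(5, 4, 4)), "constant")
})

test_that("plaque segmentation separates disks and applies 8-connectivity", {
  px_um <- 1
  blank <- channel_image(matrix(0, 50, 50), px_um)
  expect_equal(nrow(segment_plaques(blank)$morphometrics), 0)

  m <- matrix(0, 200, 200)
  for (i in 1:200) for (j in 1:200) {
    if ((i - 60)^2 + (j - 60)^2 < 100) m[i, j] <- 1
    if ((i - 60)^2 + (j - 120)^2 < 100) m[i, j] <- 1
  }
  rois <- segment_plaques(channel_image(m, px_um), min_area_um2 = 50)
  expect_equal(nrow(rois$morphometrics), 2)
  for (a in rois$morphometrics$area_um2) {
    expect_lt(abs(a - pi * 100) / (pi * 100), 0.05)
  }

  # diagonal-only touching components merge under 8-connectivity
  d <- matrix(0, 40, 40)
  d[10:15, 10:15] <- 1
  d[16:21, 16:21] <- 1  # touches only at the corner pixel diagonal
  rois8 <- segment_plaques(channel_image(d, 2), min_area_um2 = 10)
  expect_equal(nrow(rois8$morphometrics), 1)
})

test_that("fluorescence density is intensity per square micrometre", {
  mask <- matrix(FALSE, 20, 20); mask[5:10, 5:10] <- TRUE
  ch <- channel_image(matrix(3, 20, 20), 0.5)
  expect_equal(quantify_roi_fluorescence(mask, ch), 12)  # 3 / 0.25
  ch2 <- channel_image(matrix(6, 20, 20), 0.5)
  expect_equal(quantify_roi_fluorescence(mask, ch2),
               2 * quantify_roi_fluorescence(mask, ch))
  expect_error(quantify_roi_fluorescence(matrix(FALSE, 20, 20), ch), "empty")
})

test_that("planted neuritic (PHF-1) contrast is recovered: CGP above CP", {
  sc <- make_microscopy_scene(c(CGP = 5, CP = 5), field_um = c(900, 900),
                              px_um = 1, seed = 21)
  lco <- channel_image(sc$scene$channels$LCO, 1, "LCO")
  phf <- channel_image(sc$scene$channels$PHF1, 1, "PHF1")
  rois <- segment_plaques(subtract_background(lco), 100)
  truth_cls <- vapply(seq_len(nrow(rois$morphometrics)), function(i) {
    d <- sqrt((sc$truth$roi_labels$center_x_um -
                 rois$morphometrics$centroid_x_um[i])^2 +
                (sc$truth$roi_labels$center_y_um -
                   rois$morphometrics$centroid_y_um[i])^2)
    sc$truth$roi_labels$class[which.min(d)]
  }, "")
  dens <- vapply(rois$morphometrics$roi_id, function(id) {
    quantify_roi_fluorescence(rois, phf, id)
  }, 0)
  expect_gt(mean(dens[truth_cls == "CGP"]), mean(dens[truth_cls == "CP"]))
})

test_that("segmentation recalls planted plaques and ignores offsets the background removes", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    sc <- make_microscopy_scene(c(CP = 3, DP = 3, CGP = 2),
                                field_um = c(700, 700), px_um = 1,
                                seed = seed)
    img <- channel_image(sc$scene$channels$LCO, 1, "LCO")
    rois <- segment_plaques(subtract_background(img), 100)
    total <- total + nrow(sc$truth$roi_labels)
    for (i in seq_len(nrow(sc$truth$roi_labels))) {
      d <- sqrt((rois$morphometrics$centroid_x_um -
                   sc$truth$roi_labels$center_x_um[i])^2 +
                  (rois$morphometrics$centroid_y_um -
                     sc$truth$roi_labels$center_y_um[i])^2)
      if (length(d) > 0 &&
          min(d) < sc$truth$roi_labels$diameter_um[i] / 2 + 10) {
        hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)

  # constant offsets vanish in background subtraction
  sc <- make_microscopy_scene(c(CP = 2, DP = 2), field_um = c(500, 500),
                              px_um = 1, seed = 4)
  base <- sc$scene$channels$LCO
  n0 <- nrow(segment_plaques(subtract_background(
    channel_image(base, 1)))$morphometrics)
  n1 <- nrow(segment_plaques(subtract_background(
    channel_image(base + 0.3, 1)))$morphometrics)
  expect_equal(n0, n1)
})
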