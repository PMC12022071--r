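test_that("autoscaling centers, scales and drops constant columns", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  Z <- autoscale(X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-12)
  expect_warning(Zc <- autoscale(cbind(a = 1:4, b = rep(2, 4))), "constant")
  expect_equal(colnames(Zc), "a")
  expect_error(autoscale(matrix(1, 1, 3)), "two rows")
})

test_that("OPLS-DA matches a hand-rolled PLS1 when no orthogonal variation is removed", {
  set.seed(21)
  X <- matrix(rnorm(200), 20, 10)
  y <- rep(c("A", "B"), each = 10)
  Xa <- autoscale(X)
  m0 <- oplsda_fit(Xa, y, n_orth = 0, cv_folds = 5, seed = 2)
  # independent PLS1 oracle
  yv <- ifelse(y == "B", 1, -1); yc <- yv - mean(yv)
  w <- t(Xa) %*% yc; w <- w / sqrt(sum(w^2))
  t_ <- Xa %*% w
  expect_equal(as.numeric(m0$w), as.numeric(w), tolerance = 1e-10)
  expect_equal(as.numeric(m0$t), as.numeric(t_), tolerance = 1e-10)
})

test_that("a single discriminating variable dominates weights, VIP and Q2", {
  set.seed(5)
  n <- 100
  y <- rep(c("low", "high"), each = n / 2)
  X <- matrix(rnorm(n * 9, 0, 0.05), n, 9)
  X[, 1] <- ifelse(y == "high", 1, -1) + rnorm(n, 0, 0.05)
  colnames(X) <- paste0("v", 1:9)
  m <- oplsda_fit(autoscale(X), y, n_orth = 1, seed = 7)
  expect_gt(abs(m$w[1]), 0.9)
  expect_gt(m$Q2, 0.9)
  expect_true(m$R2X >= 0 && m$R2X <= 1)
  expect_true(m$R2Y >= 0 && m$R2Y <= 1)
  v <- vip_scores(m)
  expect_equal(sum(v^2), 9, tolerance = 1e-9)
  expect_gt(v[1], 2.5)
  expect_lt(max(v[-1]), 1)
  # predictive score orthogonal to every orthogonal component
  expect_lt(abs(sum(m$t * m$T_o[, 1])), 1e-10)
})

test_that("no class structure yields non-positive Q2 and flat VIP edge cases", {
  set.seed(9)
  X <- autoscale(matrix(rnorm(40 * 6), 40, 6))
  m <- oplsda_fit(X, rep(c("A", "B"), each = 20), seed = 3)
  expect_lte(m$Q2, 0.05)
  X1 <- autoscale(matrix(rnorm(30), 30, 1))
  m1 <- oplsda_fit(X1, rep(c("A", "B"), 15), n_orth = 0, seed = 1)
  expect_equal(unname(vip_scores(m1)), 1)
  expect_error(oplsda_fit(X, rep("A", 40), seed = 1), "two classes")
})

test_that("Ward clustering merges the obvious pair first", {
  X <- matrix(c(0, 1, 10), 3, 1)
  h <- hca_ward(X)
  expect_equal(sort(h$merge[1, ]), c(-2, -1))
  expect_true(all(diff(h$height) >= -1e-12))
  X2 <- rbind(c(1, 2), c(1, 2), c(5, 8))
  h2 <- hca_ward(X2)
  expect_equal(h2$height[1], 0)
  expect_error(hca_ward(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("Kruskal-Wallis and Dunn reproduce the rank arithmetic", {
  kd <- kruskal_dunn(1:9, rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(kd$H, 7.2, tolerance = 1e-9)
  expect_equal(kd$df, 2)
  z13 <- kd$pairwise$z[kd$pairwise$group_a == "g1" &
                         kd$pairwise$group_b == "g3"]
  expect_equal(z13, -6 / sqrt(5), tolerance = 1e-9)
  p13 <- kd$pairwise$p_adj[kd$pairwise$group_a == "g1" &
                             kd$pairwise$group_b == "g3"]
  expect_equal(p13, 2 * pnorm(-6 / sqrt(5)) * 3, tolerance = 1e-9)

  same <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  # relabelling permutes results consistently
  set.seed(2)
  vals <- rnorm(15)
  g <- rep(c("x", "y", "z"), 5)
  kd1 <- kruskal_dunn(vals, g)
  relab <- c(x = "z", y = "x", z = "y")[g]
  kd2 <- kruskal_dunn(vals, relab)
  for (i in seq_len(nrow(kd1$pairwise))) {
    a <- c(x = "z", y = "x", z = "y")[[kd1$pairwise$group_a[i]]]
    b <- c(x = "z", y = "x", z = "y")[[kd1$pairwise$group_b[i]]]
    j <- which((kd2$pairwise$group_a == a & kd2$pairwise$group_b == b) |
                 (kd2$pairwise$group_a == b & kd2$pairwise$group_b == a))
    expect_equal(abs(kd2$pairwise$z[j]), abs(kd1$pairwise$z[i]),
                 tolerance = 1e-12)
  }
  expect_error(kruskal_dunn(1:3, c("a", "a", "b")), "at least two values")
})

test_that("BH step-up arithmetic matches both the closed form and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(20)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("two-group tests give exact small-sample and degenerate results", {
  out <- pairwise_bh(list(sep = list(a = c(1, 2, 3), b = c(10, 11, 12))))
  expect_equal(out$p_raw, 0.1)
  expect_equal(out$method, "mann_whitney_u")
  idn <- suppressWarnings(
    pairwise_bh(list(same = list(a = c(1, 2, 3), b = c(1, 2, 3))))
  )
  expect_gt(idn$p_raw, 0.99)
  pair <- pairwise_bh(list(p1 = list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))),
                      paired = TRUE)
  expect_equal(pair$method, "wilcoxon_signed_rank")
  expect_error(pairwise_bh(list(x = list(a = 1:3, b = 1:4)), paired = TRUE),
               "unequal")
})

test_that("correlations and CV summaries follow their definitions", {
  X <- cbind(p1 = c(90, 100, 110, 100, 95, 105),
             p2 = -c(90, 100, 110, 100, 95, 105))
  out <- corr_and_cv(X, group = rep("pat1", 6))
  expect_equal(out$correlation["p1", "p1"], 1)
  expect_equal(out$correlation["p1", "p2"], -1)
  cvout <- corr_and_cv(cbind(p = c(90, 100, 110)), group = rep("r", 3))
  expect_equal(cvout$cv$cv_pct, 10)
  expect_equal(cvout$cumulative_cv_pct, 10)
})

test_that("simulated cohorts reproduce the printed replicate CV structure", {
  # technical replicates of one plaque profile at 10% CV recover ~10%
  spec <- cohort_spec(groups = c(CUAP = 1, sAD = 2, fAD = 1), seed = 3,
                      n_tech_replicates = 25)
  co <- make_cohort(spec, mz_range = c(3300, 3400))
  one <- co$tags$roi_id == co$tags$roi_id[1]
  # spectra amplitudes per replicate at the Abeta11pE-42 apex
  apexes <- vapply(co$spectra[one], function(s) max(s$intensity), 0)
  cv <- 100 * sd(apexes) / mean(apexes)
  expect_gt(cv, 5)
  expect_lt(cv, 16)
})
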