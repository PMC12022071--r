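test_that("patch preprocessing standardizes size, scale and contrast", {
  expect_identical(preprocess_patch(matrix(5, 120, 120)),
                   matrix(0, 120, 120))
  ramp <- outer(seq(0, 1, length.out = 240), seq(0, 1, length.out = 240))
  out <- preprocess_patch(ramp)
  expect_equal(dim(out), c(120, 120))
  # contrast stretch maps the 1%..99% band onto [0, 1]; compare against the
  # stretched original
  stretch <- function(m) {
    q <- quantile(m, c(0.01, 0.99), names = FALSE)
    pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
  }
  expect_lt(abs(mean(out) - mean(stretch(ramp))) / mean(stretch(ramp)), 0.02)
  expect_true(all(out >= 0 & out <= 1))
  # multichannel input collapses to the channel mean
  arr <- array(runif(120 * 120 * 3), c(120, 120, 3))
  expect_equal(dim(preprocess_patch(arr)), c(120, 120))
  expect_error(preprocess_patch(matrix(numeric(0), 0, 0)), "empty input|zero-sized")
})

test_that("augmentation hooks behave as exact index permutations", {
  set.seed(2)
  p <- matrix(runif(120 * 120), 120, 120)
  expect_identical(augment_patch(p, 0, FALSE, FALSE, 1), p)
  flipped_twice <- augment_patch(augment_patch(p, 0, TRUE, FALSE, 1),
                                 0, TRUE, FALSE, 1)
  expect_equal(flipped_twice, p, tolerance = 1e-12)
  r90 <- augment_patch(p, 90, FALSE, FALSE, 1)
  oracle <- t(p)[rev(seq_len(nrow(p))), ]
  expect_equal(r90, oracle, tolerance = 1e-9)
})

test_that("stratified split matches per-class rounding and partitions the data", {
  labels <- rep(c("CGP", "CP", "DP"), times = c(42, 208, 135))
  sp <- split_train_test(labels, 0.2, seed = 11)
  # round(0.2 * 42) + round(0.2 * 208) + round(0.2 * 135) = 8 + 42 + 27
  expect_equal(attr(sp, "test_size"), 77)
  expect_true(attr(sp, "test_size") %in% c(77, 78))
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- split_train_test(labels, 0.2, seed = 11)
  expect_identical(sp, sp2)
})

test_that("stratified folds deal every sample into exactly one fold", {
  labels <- rep(c("CGP", "CP", "DP"), times = c(40, 160, 107))  # n = 307
  set.seed(5)
  fold <- plaquemap:::.fold_assign(labels, 3)
  expect_equal(as.integer(sort(table(fold), decreasing = TRUE)),
               c(103L, 102L, 102L))
  expect_true(all(fold %in% 1:3))
  for (cl in unique(labels)) {
    per <- table(fold[labels == cl])
    expect_lte(diff(range(per)), 1)
  }
})

test_that("ensemble averaging keeps the simplex and breaks ties by class order", {
  p1 <- matrix(c(1, 0, 0), 1, 3); p2 <- matrix(c(0, 1, 0), 1, 3)
  p3 <- matrix(c(0, 0, 1), 1, 3)
  avg <- plaquemap:::.average_probs(list(p1, p2, p3), CLASSIFIER_CLASSES)
  expect_equal(as.numeric(avg), rep(1 / 3, 3))
  expect_equal(attr(avg, "predicted"), "CGP")
  same <- plaquemap:::.average_probs(list(p1, p1), CLASSIFIER_CLASSES)
  expect_equal(as.numeric(same), c(1, 0, 0))
  set.seed(3)
  rnd <- lapply(1:3, function(i) {
    m <- matrix(runif(15), 5, 3); m / rowSums(m)
  })
  avg2 <- plaquemap:::.average_probs(rnd, CLASSIFIER_CLASSES)
  expect_equal(rowSums(avg2), rep(1, 5))
  expect_true(all(avg2 >= 0))
})

test_that("confusion-matrix metrics reproduce the printed evaluation numbers", {
  M <- matrix(c(9, 1, 0,
                2, 41, 0,
                0, 3, 22), 3, 3, byrow = TRUE)
  r <- classification_metrics(M)
  expect_equal(round(r$accuracy, 3), 0.923)
  expect_equal(r$n_misclassified, 6)
  expect_equal(round(r$recall, 2), c(0.90, 0.95, 0.88))
  expect_equal(round(r$precision, 2), c(0.82, 0.91, 1.00))
  expect_equal(round(r$f1, 2), c(0.86, 0.93, 0.94))

  D <- diag(c(5, 7, 9))
  rd <- classification_metrics(D)
  expect_equal(rd$accuracy, 1)
  expect_equal(unname(rd$f1), rep(1, 3))

  Z <- matrix(c(0, 5, 0, 0, 5, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  expect_warning(rz <- classification_metrics(Z), "never predicted")
  expect_equal(unname(rz$recall[1]), 0)
  expect_error(classification_metrics(matrix(1, 2, 3)), "square")
})

test_that("gradients of the network agree with finite differences", {
  set.seed(7)
  net <- plaquemap:::.cnn_init(input_dim = c(8L, 8L), filters = c(2L),
                               dense_units = 4L, n_classes = 3L)
  X <- matrix(rnorm(8 * 8 * 2), ncol = 1)
  Y <- plaquemap:::.one_hot(c("a", "b"), c("a", "b", "c"))
  loss_at <- function(net) {
    fw <- plaquemap:::.cnn_forward(net, X, 2, train = TRUE, dropout = 0)
    -mean(log(pmax(fw$probs[cbind(1:2, max.col(Y))], 1e-12)))
  }
  set.seed(1)
  fw <- plaquemap:::.cnn_forward(net, X, 2, train = TRUE, dropout = 0)
  grads <- plaquemap:::.cnn_backward(net, fw, Y)
  eps <- 1e-6
  for (probe in list(c("W1", 3), c("W2", 2), c("b2", 1))) {
    nm <- probe[[1]]; k <- as.integer(probe[[2]])
    np <- net; np[[nm]][k] <- np[[nm]][k] + eps
    nm2 <- net; nm2[[nm]][k] <- nm2[[nm]][k] - eps
    fd <- (loss_at(np) - loss_at(nm2)) / (2 * eps)
    expect_equal(unname(grads[[nm]][k]), fd, tolerance = 1e-4)
  }
  # conv kernel gradient
  np <- net; np$layers[[1]]$W_[5] <- np$layers[[1]]$W_[5] + eps
  nm2 <- net; nm2$layers[[1]]$W_[5] <- nm2$layers[[1]]$W_[5] - eps
  fd <- (loss_at(np) - loss_at(nm2)) / (2 * eps)
  expect_equal(unname(grads$layers[[1]]$W_[5]), fd, tolerance = 1e-4)
})

test_that("a linearly separable toy problem trains to perfect accuracy", {
  set.seed(12)
  classes <- c("CGP", "CP", "DP")
  mk <- function(v) matrix(v + rnorm(400, 0, 0.02), 20, 20)
  patches <- c(lapply(1:8, function(i) mk(0.1)),
               lapply(1:8, function(i) mk(0.5)),
               lapply(1:8, function(i) mk(0.9)))
  labels <- rep(classes, each = 8)
  cfg <- train_config(epochs = 15, learning_rate = 0.01, batch_size = 4,
                      augment = FALSE, patience = 0, filters = c(4),
                      dense_units = 8, seed = 9)
  ens <- train_crossval(patches, labels, cfg)
  pr <- predict_ensemble(ens, patches)
  expect_equal(mean(attr(pr, "predicted") == labels), 1)
  # ensemble at least matches its worst member on the pooled training data
  member_acc <- vapply(ens$members, function(m) {
    p <- plaquemap:::.cnn_predict(m, patches)
    mean(ens$classes[max.col(p)] == labels)
  }, 0)
  expect_gte(mean(attr(pr, "predicted") == labels), min(member_acc) - 0.02)
  expect_error(train_crossval(patches[c(1:8, 9)], labels[c(1:8, 9)], cfg),
               "fewer than")
})

test_that("augmentation never changes the label structure of a patch", {
  # the augmented patch stays close in gross intensity, so class identity
  # (encoded here as mean level) is preserved
  set.seed(4)
  for (lv in c(0.2, 0.5, 0.8)) {
    p <- matrix(lv, 30, 30) + rnorm(900, 0, 0.01)
    a <- augment_patch(p, theta_deg = 10, flip_h = TRUE, flip_v = FALSE,
                       scale = 1.05)
    expect_lt(abs(mean(a[8:23, 8:23]) - lv), 0.05)
  }
})
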