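#' Training configuration for the plaque-morphotype classifier
#'
#' Defaults follow the training protocol: Adam with learning rate 0.001
#' decayed by 0.96 every 10 epochs, categorical cross-entropy, mini-batch
#' size 32, three-fold cross-validation with ensemble averaging, and
#' rotation/flip/scale augmentation.
#'
#' @param k_folds number of cross-validation folds (>= 2).
#' @param learning_rate Adam learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decay steps.
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (0 disables).
#' @param filters convolution filter counts per block.
#' @param dense_units hidden dense-layer width.
#' @param dropout dropout probability before the softmax head.
#' @param input_downscale average-pooling factor applied to patches before
#'   the convolution stack (2 halves each side of the 120 x 120 input).
#' @param augment apply random augmentation during training.
#' @param rotation_range,scale_range augmentation ranges (degrees;
#'   isotropic scale factors).
#' @param seed integer seed controlling fold assignment, initialization,
#'   shuffling, dropout and augmentation.
#' @return list of hyperparameters.
#' @export
train_config <- function(k_folds = 3, learning_rate = 0.001, lr_decay = 0.96,
                         decay_every = 10, batch_size = 32, epochs = 30,
                         patience = 5, filters = c(4, 8, 16),
                         dense_units = 32, dropout = 0.5, augment = TRUE,
                         input_downscale = 2,
                         rotation_range = c(-20, 20),
                         scale_range = c(0.9, 1.1), seed = 1L) {
  stopifnot(k_folds >= 2, learning_rate > 0, lr_decay > 0, batch_size >= 1,
            epochs >= 1, all(filters >= 1), dense_units >= 1,
            dropout >= 0, dropout < 1)
  list(k_folds = k_folds, learning_rate = learning_rate, lr_decay = lr_decay,
       decay_every = decay_every, batch_size = batch_size, epochs = epochs,
       patience = patience, filters = as.integer(filters),
       dense_units = as.integer(dense_units), dropout = dropout,
       input_downscale = as.integer(input_downscale),
       augment = augment, rotation_range = rotation_range,
       scale_range = scale_range, seed = as.integer(seed))
}

#' Class order of the morphotype classifier
#'
#' Fixed class order used for probability vectors and tie breaking.
#' @export
CLASSIFIER_CLASSES <- c("CGP", "CP", "DP")

#' Preprocess a raw image crop into a classifier patch
#'
#' Grayscale conversion (channel mean for multichannel input), bilinear
#' resize to `size` x `size`, and a contrast stretch mapping the 1st/99th
#' intensity percentiles onto \[0, 1\]. Constant crops map to all-zero
#' patches.
#'
#' @param raw numeric matrix or 3D array (H x W x C).
#' @param size output side length (120).
#' @return `size` x `size` numeric matrix with values in \[0, 1\].
#' @export
preprocess_patch <- function(raw, size = 120L) {
  if (length(raw) == 0) stop("empty input image")
  if (length(dim(raw)) == 3) raw <- apply(raw, c(1, 2), mean)
  if (!is.matrix(raw)) stop("input must be a matrix or H x W x C array")
  if (any(dim(raw) == 0)) stop("zero-sized input image")
  m <- if (all(dim(raw) == c(size, size))) raw else
    EBImage::resize(raw, w = size, h = size)
  q <- stats::quantile(m, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] <= 0) return(matrix(0, size, size))
  pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
}

# bilinear resampling of `patch` under an inverse affine map of the output
# grid; coordinates are relative to the patch centre, outside pixels are 0
.warp_patch <- function(patch, theta = 0, scale = 1, flip_h = FALSE,
                        flip_v = FALSE) {
  H <- nrow(patch); W <- ncol(patch)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gi <- rep(seq_len(H), W) - cy
  gj <- rep(seq_len(W), each = H) - cx
  if (flip_h) gj <- -gj
  if (flip_v) gi <- -gi
  # inverse map: rotate by -theta, scale by 1/scale
  ct <- cos(-theta); st <- sin(-theta)
  si <- (gi * ct - gj * st) / scale + cy
  sj <- (gi * st + gj * ct) / scale + cx
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- numeric(length(ii))
    v[ok] <- patch[cbind(ii[ok], jj[ok])]
    v
  }
  v <- (1 - fi) * (1 - fj) * val(i0, j0) +
    fi * (1 - fj) * val(i0 + 1, j0) +
    (1 - fi) * fj * val(i0, j0 + 1) +
    fi * fj * val(i0 + 1, j0 + 1)
  matrix(v, H, W)
}

#' Randomly augment a classifier patch
#'
#' Applies a random rotation, horizontal/vertical flips (probability 0.5
#' each) and an isotropic rescale, re-sampled bilinearly onto the original
#' 120 x 120 grid (zero padding outside). Passing explicit values fixes
#' the corresponding component (test hook).
#'
#' @param patch square numeric matrix.
#' @param theta_deg rotation in degrees (`NULL`: draw from `rotation`).
#' @param flip_h,flip_v flips (`NULL`: Bernoulli(0.5)).
#' @param scale isotropic scale (`NULL`: draw from `scaling`).
#' @param rotation,scaling sampling ranges for the random components.
#' @return augmented patch, same dimensions.
#' @export
augment_patch <- function(patch, theta_deg = NULL, flip_h = NULL,
                          flip_v = NULL, scale = NULL,
                          rotation = c(-20, 20), scaling = c(0.9, 1.1)) {
  if (is.null(theta_deg)) theta_deg <- stats::runif(1, rotation[1], rotation[2])
  if (is.null(flip_h)) flip_h <- stats::runif(1) < 0.5
  if (is.null(flip_v)) flip_v <- stats::runif(1) < 0.5
  if (is.null(scale)) scale <- stats::runif(1, scaling[1], scaling[2])
  if (theta_deg == 0 && !flip_h && !flip_v && scale == 1) return(patch)
  .warp_patch(patch, theta = theta_deg * pi / 180, scale = scale,
              flip_h = flip_h, flip_v = flip_v)
}

#' Stratified train/test split
#'
#' Randomly sets aside `round(test_fraction * n_c)` samples of every class
#' `c` as an unseen test set; the achieved test size is reported as an
#' attribute (per-class rounding can make it differ by one from
#' `round(test_fraction * n)`).
#'
#' @param labels class label per sample.
#' @param test_fraction fraction per class set aside for testing.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`; attribute
#'   `test_size`.
#' @export
split_train_test <- function(labels, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- round(test_fraction * length(idx))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  out <- list(train = setdiff(seq_along(labels), test), test = test)
  attr(out, "test_size") <- length(test)
  out
}

# stratified fold assignment: within each class, fold sizes differ by at
# most one, and per-class remainders go to the globally smallest folds so
# total fold sizes also differ by at most one
.fold_assign <- function(labels, k) {
  fold <- integer(length(labels))
  totals <- integer(k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    sizes <- rep(n %/% k, k)
    rem <- n - sum(sizes)
    if (rem > 0) {
      ord <- order(totals, seq_len(k))
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
    totals <- totals + sizes
  }
  fold
}

#' Train the morphotype classifier by k-fold cross-validated ensembling
#'
#' Splits the training set into `k_folds` mutually exclusive stratified
#' folds; member `f` is trained (with augmentation) on all folds except
#' `f` and validated on fold `f`, so every sample validates exactly once.
#' The returned ensemble predicts by averaging member softmax outputs.
#'
#' @param patches list of preprocessed 120 x 120 patches
#'   (see [preprocess_patch()]).
#' @param labels character class labels.
#' @param cfg a [train_config()].
#' @param classes class order.
#' @return object of class `cnn_ensemble`: `members`, `fold` assignment,
#'   `val_metrics` (per-fold validation accuracy/loss), `classes`, `cfg`.
#' @export
train_crossval <- function(patches, labels, cfg = train_config(),
                           classes = CLASSIFIER_CLASSES) {
  stopifnot(length(patches) == length(labels))
  classes <- intersect(classes, unique(labels))
  if (length(classes) < 2) stop("need at least two classes present")
  small <- table(labels)[table(labels) < cfg$k_folds + 1]
  if (length(small) > 0) {
    stop("class(es) with fewer than k_folds + 1 members: ",
         paste(names(small), collapse = ", "))
  }
  set.seed(cfg$seed)
  fold <- .fold_assign(labels, cfg$k_folds)
  members <- list()
  val_metrics <- data.frame()
  for (f in seq_len(cfg$k_folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    fit <- .cnn_train(patches[tr], labels[tr], classes, cfg,
                      val_patches = patches[va], val_labels = labels[va])
    members[[f]] <- fit$net
    hb <- fit$history[which.min(fit$history$val_loss), ]
    val_metrics <- rbind(val_metrics,
                         data.frame(fold = f, val_loss = hb$val_loss,
                                    val_acc = hb$val_acc,
                                    epochs_run = max(fit$history$epoch)))
  }
  structure(list(members = members, fold = fold, val_metrics = val_metrics,
                 classes = classes, cfg = cfg),
            class = "cnn_ensemble")
}

#' @export
print.cnn_ensemble <- function(x, ...) {
  cat(sprintf("CNN morphotype classifier: %d members, classes %s\n",
              length(x$members), paste(x$classes, collapse = " < ")))
  print(x$val_metrics, row.names = FALSE)
  invisible(x)
}

#' Ensemble class-probability prediction
#'
#' Arithmetic mean of the member softmax outputs; rows sum to one. The
#' predicted class is the argmax, ties broken by the fixed class order.
#'
#' @param ens a `cnn_ensemble`.
#' @param patches a single patch or list of preprocessed patches.
#' @return matrix (n x classes) of probabilities with attribute
#'   `predicted` (character vector).
#' @export
predict_ensemble <- function(ens, patches) {
  if (is.matrix(patches)) patches <- list(patches)
  d <- dim(patches[[1]])
  if (!all(vapply(patches, function(p) all(dim(p) == d), TRUE))) {
    stop("all patches must share the ensemble input dimensions")
  }
  .average_probs(lapply(ens$members, .cnn_predict, patches = patches),
                 ens$classes)
}

# arithmetic mean of member probability matrices; argmax with ties broken
# by the fixed class order (first maximum wins)
.average_probs <- function(prob_list, classes) {
  probs <- Reduce(`+`, prob_list) / length(prob_list)
  colnames(probs) <- classes
  pred <- classes[apply(probs, 1, function(p) which(p >= max(p) - 1e-12)[1])]
  attr(probs, "predicted") <- pred
  probs
}

#' @export
predict.cnn_ensemble <- function(object, newdata, ...) {
  predict_ensemble(object, newdata)
}

#' Classification metrics from a confusion matrix
#'
#' @param M square confusion matrix of counts, rows = true class,
#'   columns = predicted class.
#' @return object of class `eval_report`: `confusion`, `accuracy`,
#'   `n_correct`, `n_misclassified`, and per-class `precision`, `recall`,
#'   `f1` (a class never predicted yields `NA` precision with a warning).
#' @export
classification_metrics <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("confusion matrix must be square")
  if (any(M < 0) || any(M != round(M))) stop("confusion matrix must hold nonnegative counts")
  total <- sum(M)
  if (total == 0) stop("empty confusion matrix")
  diagm <- diag(M)
  recall <- ifelse(rowSums(M) > 0, diagm / rowSums(M), 0)
  precision <- diagm / colSums(M)
  if (any(colSums(M) == 0)) {
    warning("class(es) never predicted: precision undefined")
    precision[colSums(M) == 0] <- NA_real_
  }
  f1 <- ifelse(!is.na(precision) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  structure(list(confusion = M, accuracy = sum(diagm) / total,
                 n_correct = sum(diagm), n_misclassified = total - sum(diagm),
                 precision = precision, recall = recall, f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f (%d/%d correct)\n", x$accuracy, x$n_correct,
              sum(x$confusion)))
  print(data.frame(precision = round(x$precision, 3),
                   recall = round(x$recall, 3), f1 = round(x$f1, 3)))
  invisible(x)
}

#' Reconstruct confusion matrices consistent with printed metrics
#'
#' Integer search over all 3 x 3 confusion matrices with the given total
#' and correct counts whose accuracy, per-class precision, recall and F1
#' all round (to `digits` decimals) to the target values. Used to recover
#' the unprinted confusion matrix behind a published metrics table.
#'
#' @param n_total,n_correct total and correctly classified instances.
#' @param recall,precision,f1 target per-class values (class order CGP,
#'   CP, DP).
#' @param digits rounding precision of the printed values.
#' @param max_solutions stop after this many consistent matrices.
#' @return list of consistent confusion matrices (possibly empty).
#' @export
reconstruct_confusion <- function(n_total = 78, n_correct = 72,
                                  recall = c(0.90, 0.95, 0.88),
                                  precision = c(0.82, 0.91, 1.00),
                                  f1 = c(0.86, 0.93, 0.94),
                                  digits = 2, max_solutions = 10) {
  n_err <- n_total - n_correct
  # enumerate off-diagonal compositions (6 cells summing to n_err)
  offs <- .compositions(n_err, 6)
  sols <- list()
  rd <- function(x) round(x + 1e-9, digits)
  # diagonal candidates per class, keyed by row error count: the recall
  # constraint round(d / (d + e)) == recall[i] prunes the diagonal search
  diag_cand <- lapply(1:3, function(i) {
    lapply(0:n_err, function(e) {
      d <- 0:n_correct
      d[rd(d / pmax(d + e, 1)) == recall[i] & (d + e) > 0]
    })
  })
  for (r in seq_len(nrow(offs))) {
    e1 <- offs[r, 3] + offs[r, 5]; e2 <- offs[r, 1] + offs[r, 6]
    e3 <- offs[r, 2] + offs[r, 4]
    # off-diagonals are stored column-major per row below
    M0 <- matrix(c(0, offs[r, 1], offs[r, 2],
                   offs[r, 3], 0, offs[r, 4],
                   offs[r, 5], offs[r, 6], 0), 3, 3, byrow = TRUE)
    er <- rowSums(M0)
    for (d1 in diag_cand[[1]][[er[1] + 1]])
      for (d2 in diag_cand[[2]][[er[2] + 1]]) {
        d3 <- n_correct - d1 - d2
        if (d3 < 0 || !(d3 %in% diag_cand[[3]][[er[3] + 1]])) next
        M <- M0; diag(M) <- c(d1, d2, d3)
        cs <- colSums(M)
        if (any(cs == 0)) next
        pre <- diag(M) / cs
        if (!all(rd(pre) == precision)) next
        rec <- diag(M) / rowSums(M)
        fv <- 2 * pre * rec / (pre + rec)
        if (!all(rd(fv) == f1)) next
        sols[[length(sols) + 1]] <- M
        if (length(sols) >= max_solutions) return(sols)
      }
  }
  sols
}

.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    rest <- .compositions(n - i, k - 1)
    out[[i + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}
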