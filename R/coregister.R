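#' Similarity transform (scale + rotation + translation)
#'
#' Maps source coordinates (micrometres, microscopy frame) to destination
#' coordinates (MSI frame): `dst = s * R(theta) %*% src + t`.
#'
#' @param s positive scale factor.
#' @param theta rotation in radians.
#' @param t translation, length-2 numeric (micrometres).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(s = 1, theta = 0, t = c(0, 0)) {
  stopifnot(s > 0, length(t) == 2)
  structure(list(s = s, theta = theta, t = as.numeric(t)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.6g, rotation %.4g rad, translation (%.4g, %.4g)\n",
              x$s, x$theta, x$t[1], x$t[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#' @param tf a [similarity_transform()].
#' @param xy n x 2 matrix of coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(tf, xy) {
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2)
  R <- matrix(c(cos(tf$theta), sin(tf$theta),
                -sin(tf$theta), cos(tf$theta)), 2, 2)
  sweep(tf$s * (xy %*% t(R)), 2, tf$t, `+`)
}

#' Invert a similarity transform
#' @param tf a [similarity_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(tf) {
  similarity_transform(
    s = 1 / tf$s, theta = -tf$theta,
    t = -transform_points(similarity_transform(1 / tf$s, -tf$theta, c(0, 0)),
                          matrix(tf$t, 1, 2))[1, ]
  )
}

#' Fit a similarity transform from landmark pairs
#'
#' Closed-form least-squares (orthogonal Procrustes with isotropic scale,
#' Umeyama's solution) mapping `src` landmarks onto `dst`.
#'
#' @param src,dst n x 2 matrices of matched landmark coordinates (n >= 2).
#' @return a [similarity_transform()] with attribute `rms` (root-mean-square
#'   residual of the fitted mapping).
#' @export
fit_similarity <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  if (nrow(src) < 2 || nrow(src) != nrow(dst)) {
    stop("need at least two matched landmark pairs")
  }
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  Xc <- sweep(src, 2, mu_s); Yc <- sweep(dst, 2, mu_d)
  var_s <- sum(Xc^2) / nrow(src)
  if (var_s < 1e-12) stop("degenerate landmark configuration: source points coincide")
  S <- crossprod(Yc, Xc) / nrow(src)
  sv <- svd(S)
  D <- diag(2)
  if (det(sv$u) * det(sv$v) < 0) D[2, 2] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(diag(D %*% diag(sv$d))) / var_s
  t <- mu_d - s * as.numeric(R %*% mu_s)
  theta <- atan2(R[2, 1], R[1, 1])
  tf <- similarity_transform(s = s, theta = theta, t = t)
  res <- transform_points(tf, src) - dst
  attr(tf, "rms") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Transfer microscopy ROIs onto the MSI pixel grid
#'
#' Maps each microscopy ROI through a similarity transform and rasterizes it
#' onto the MSI grid. An MSI pixel is included when at least half of its
#' area (estimated by `supersample` x `supersample` subpixel sampling) falls
#' inside the transformed ROI.
#'
#' @param rois a `micro_roi_set` from [segment_plaques()], or a list of
#'   logical mask matrices with attribute `px_um`.
#' @param tf [similarity_transform()] from microscopy micrometre coordinates
#'   to MSI micrometre coordinates.
#' @param msi an `msi_dataset` (defines the target grid), or a list with
#'   `nx`, `ny`, `pitch_um`.
#' @param coverage minimum covered-area fraction for pixel inclusion.
#' @param supersample subpixel sampling density per axis (odd values
#'   avoid tie degeneracies on symmetric alignments).
#' @return named list (by ROI id) of integer vectors of MSI pixel indices
#'   (row-major into the `ny` x `nx` grid, matching `msi$coords`). ROIs that
#'   map entirely off-grid are dropped with a warning.
#' @export
transfer_rois <- function(rois, tf, msi, coverage = 0.5, supersample = 5) {
  grid <- .msi_grid(msi)
  px_um <- attr(rois, "px_um")
  masks <- if (inherits(rois, "micro_roi_set")) rois$masks else rois
  if (is.null(px_um)) px_um <- rois$px_um
  if (is.null(px_um)) stop("rois must carry a px_um attribute")
  inv <- invert_transform(tf)
  out <- list()
  off <- seq_len(supersample) / supersample - 1 / (2 * supersample)
  for (id in names(masks)) {
    mask <- masks[[id]]
    idx <- which(mask, arr.ind = TRUE)  # (row=y, col=x) microscopy pixels
    if (nrow(idx) == 0) next
    # bounding box of the ROI in MSI frame
    corners_um <- cbind((range(idx[, 2]) - c(1, 0)) * px_um,
                        (range(idx[, 1]) - c(1, 0)) * px_um)
    box <- transform_points(tf, expand.grid(corners_um[, 1], corners_um[, 2]))
    j0 <- max(1L, floor(min(box[, 1]) / grid$pitch_um))
    j1 <- min(grid$nx, ceiling(max(box[, 1]) / grid$pitch_um) + 1L)
    i0 <- max(1L, floor(min(box[, 2]) / grid$pitch_um))
    i1 <- min(grid$ny, ceiling(max(box[, 2]) / grid$pitch_um) + 1L)
    if (j1 < j0 || i1 < i0) {
      warning("ROI ", id, " maps outside the MSI grid; dropped")
      next
    }
    sel <- integer()
    for (i in i0:i1) for (j in j0:j1) {
      # subpixel centres of MSI pixel (i, j) in MSI um coordinates
      sx <- (j - 1 + rep(off, each = supersample)) * grid$pitch_um
      sy <- (i - 1 + rep(off, times = supersample)) * grid$pitch_um
      src <- transform_points(inv, cbind(sx, sy))
      jj <- ceiling(src[, 1] / px_um); ii <- ceiling(src[, 2] / px_um)
      ok <- ii >= 1 & ii <= nrow(mask) & jj >= 1 & jj <= ncol(mask)
      frac <- sum(mask[cbind(ii[ok], jj[ok])]) / length(sx)
      if (frac >= coverage) sel <- c(sel, (j - 1L) * grid$ny + i)
    }
    if (length(sel) == 0) {
      warning("ROI ", id, " covers no MSI pixel at ", coverage,
              " coverage; dropped")
      next
    }
    out[[id]] <- sel
  }
  if (length(out) == 0) stop("no ROI overlaps the MSI grid")
  out
}

.msi_grid <- function(msi) {
  if (inherits(msi, "msi_dataset")) {
    list(nx = msi$nx, ny = msi$ny, pitch_um = msi$pitch_um)
  } else {
    stopifnot(all(c("nx", "ny", "pitch_um") %in% names(msi)))
    msi
  }
}

#' Plaque loads per morphotype
#'
#' Area fraction (%) and count density (per mm^2) of each plaque type
#' relative to the analyzed tissue area.
#'
#' @param rois_by_type named list (morphotype -> list of logical mask
#'   matrices, or a single labelled mask per type).
#' @param tissue_mask logical matrix of analyzed tissue pixels (same grid).
#' @param px_um pixel size in micrometres.
#' @return data frame with `type`, `n_plaques`, `area_fraction_pct`,
#'   `count_per_mm2`.
#' @export
plaque_load <- function(rois_by_type, tissue_mask, px_um) {
  if (sum(tissue_mask) == 0) stop("empty tissue mask")
  tissue_um2 <- sum(tissue_mask) * px_um^2
  rows <- lapply(names(rois_by_type), function(ty) {
    masks <- rois_by_type[[ty]]
    if (is.matrix(masks)) masks <- list(masks)
    n <- length(masks)
    area <- sum(vapply(masks, function(m) sum(m) * px_um^2, 0))
    data.frame(type = ty, n_plaques = n,
               area_fraction_pct = 100 * area / tissue_um2,
               count_per_mm2 = n / (tissue_um2 / 1e6),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
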