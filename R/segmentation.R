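#' Spatial smoothing of an MSI datacube
#'
#' Per-m/z-bin 2D Gaussian smoothing on the pixel grid with reflected
#' boundaries, so the total intensity of every bin is conserved. The named
#' strengths map to kernel widths sigma = 0 / 0.5 / 1 / 2 pixels.
#'
#' @param msi an `msi_dataset`.
#' @param strength one of `"none"`, `"weak"`, `"medium"`, `"strong"`.
#' @return smoothed `msi_dataset`.
#' @export
spatial_smooth <- function(msi, strength = c("medium", "none", "weak", "strong")) {
  strength <- match.arg(strength)
  sigma <- c(none = 0, weak = 0.5, medium = 1, strong = 2)[[strength]]
  if (sigma == 0) return(msi)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  ny <- msi$ny; nx <- msi$nx
  out <- msi$intensities
  for (b in seq_along(msi$mz)) {
    img <- matrix(msi$intensities[, b], ny, nx)  # pixel index = (x-1)*ny + y
    out[, b] <- as.numeric(.gauss_blur(img, k, r))
  }
  msi$intensities <- out
  msi$meta$spatial_smooth <- strength
  msi
}

# separable convolution with symmetric (edge-duplicating) reflection,
# which conserves total mass for symmetric kernels
.gauss_blur <- function(img, k, r) {
  pad_idx <- function(n) c(rev(seq_len(min(r, n))), seq_len(n),
                           n + 1 - seq_len(min(r, n)))
  ri <- pad_idx(nrow(img)); ci <- pad_idx(ncol(img))
  p <- img[ri, , drop = FALSE]
  tmp <- matrix(0, nrow(img), ncol(img))
  for (o in seq_along(k)) {
    tmp <- tmp + k[o] * p[(o - 1) + seq_len(nrow(img)), , drop = FALSE]
  }
  p2 <- tmp[, ci, drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (o in seq_along(k)) {
    out <- out + k[o] * p2[, (o - 1) + seq_len(ncol(img)), drop = FALSE]
  }
  out
}

#' Bisecting k-means segmentation of an MSI datacube
#'
#' TIC-normalizes the pixel spectra (optionally after binning to a coarser
#' m/z resolution), then iteratively bisects the leaf cluster with the
#' largest within-cluster sum of squares using 2-means (multiple seeded
#' restarts) until `max_leaves` leaves exist.
#'
#' @param msi an `msi_dataset`.
#' @param max_leaves target number of leaves (>= 2).
#' @param seed integer seed (2-means restarts are seeded).
#' @param bin_da optional coarse binning width in Da before clustering
#'   (`NULL` clusters the native profile).
#' @param nstart 2-means restarts per split.
#' @param tic_normalize normalize each pixel spectrum to unit TIC first
#'   (zero-TIC pixels are left as all-zero rows).
#' @return object of class `segmentation_tree`: `nodes` (list with member
#'   pixel ids, centroid, WCSS, children), `splits` (node ids in split
#'   order), `n_pixels`, grid dimensions.
#' @export
bisecting_kmeans <- function(msi, max_leaves, seed = 1L, bin_da = NULL,
                             nstart = 10, tic_normalize = TRUE) {
  stopifnot(max_leaves >= 2)
  X <- msi$intensities
  if (!is.null(bin_da) && bin_da > diff(msi$mz[1:2])) {
    groups <- floor((msi$mz - msi$mz[1]) / bin_da)
    X <- t(rowsum(t(X), groups))
  }
  if (tic_normalize) {
    tic <- rowSums(X)
    pos <- tic > 0
    X[pos, ] <- X[pos, ] / tic[pos]
  }
  set.seed(seed)
  wcss <- function(idx) {
    if (length(idx) < 2) return(0)
    xc <- sweep(X[idx, , drop = FALSE], 2, colMeans(X[idx, , drop = FALSE]))
    sum(xc^2)
  }
  nodes <- list(list(id = 1L, members = seq_len(nrow(X)),
                     centroid = colMeans(X), wcss = wcss(seq_len(nrow(X))),
                     children = NULL, parent = NA_integer_))
  splits <- integer()
  leaves <- 1L
  while (length(leaves) < max_leaves) {
    lw <- vapply(leaves, function(i) nodes[[i]]$wcss, 0)
    cand <- leaves[lw > 0 &
                     vapply(leaves, function(i) {
                       nrow(unique(X[nodes[[i]]$members, , drop = FALSE])) >= 2
                     }, TRUE)]
    if (length(cand) == 0) {
      warning("fewer distinct pixel spectra than requested leaves; ",
              "stopping at ", length(leaves), " leaves")
      break
    }
    # split the candidate with largest WCSS; ties -> lowest node id
    lw <- vapply(cand, function(i) nodes[[i]]$wcss, 0)
    node_id <- cand[order(-lw, cand)][1]
    idx <- nodes[[node_id]]$members
    km <- stats::kmeans(X[idx, , drop = FALSE], centers = 2, nstart = nstart)
    for (cl in 1:2) {
      ci <- idx[km$cluster == cl]
      nodes[[length(nodes) + 1L]] <- list(
        id = length(nodes) + 1L, members = ci,
        centroid = km$centers[cl, ], wcss = wcss(ci),
        children = NULL, parent = node_id
      )
    }
    nodes[[node_id]]$children <- c(length(nodes) - 1L, length(nodes))
    splits <- c(splits, node_id)
    leaves <- setdiff(c(leaves, length(nodes) - 1L, length(nodes)), node_id)
  }
  structure(list(nodes = nodes, splits = splits, n_pixels = nrow(X),
                 nx = msi$nx, ny = msi$ny),
            class = "segmentation_tree")
}

#' @export
print.segmentation_tree <- function(x, ...) {
  cat(sprintf("bisecting k-means tree: %d pixels, %d splits (%d leaves)\n",
              x$n_pixels, length(x$splits), length(x$splits) + 1L))
  invisible(x)
}

#' Cut a segmentation tree into n clusters
#'
#' Replays the first `n_clusters - 1` splits, so the cut at `n` is always a
#' refinement of the cut at `n - 1`.
#'
#' @param tree a `segmentation_tree`.
#' @param n_clusters number of clusters (1 to leaves).
#' @return integer label matrix (`ny` x `nx`), labels 1..n_clusters in
#'   split order.
#' @export
cut_tree <- function(tree, n_clusters) {
  if (n_clusters < 1 || n_clusters > length(tree$splits) + 1) {
    stop("n_clusters must be between 1 and ", length(tree$splits) + 1)
  }
  active <- list(tree$nodes[[1]]$members)
  node_of <- 1L
  active_ids <- 1L
  for (s in seq_len(n_clusters - 1)) {
    nid <- tree$splits[s]
    pos <- match(nid, active_ids)
    ch <- tree$nodes[[nid]]$children
    active[[pos]] <- tree$nodes[[ch[1]]]$members
    active_ids[pos] <- ch[1]
    active[[length(active) + 1L]] <- tree$nodes[[ch[2]]]$members
    active_ids <- c(active_ids, ch[2])
  }
  lab <- integer(tree$n_pixels)
  for (i in seq_along(active)) lab[active[[i]]] <- i
  matrix(lab, tree$ny, tree$nx)[seq_len(tree$ny), , drop = FALSE]
}

#' Single-ion image
#'
#' Per-pixel trapezoidal area over an m/z window, arranged on the pixel
#' grid.
#'
#' @param msi an `msi_dataset`.
#' @param center window centre (Da).
#' @param half_width window half-width (Da); defaults to one FWHM at the
#'   instrument resolving power.
#' @return numeric `ny` x `nx` intensity matrix.
#' @export
single_ion_image <- function(msi, center, half_width = center / 1000) {
  sel <- which(msi$mz >= center - half_width & msi$mz <= center + half_width)
  if (length(sel) < 2) stop("empty or single-bin m/z window")
  mzw <- msi$mz[sel]
  w <- diff(mzw)
  V <- msi$intensities[, sel, drop = FALSE]
  auc <- as.numeric((V[, -1, drop = FALSE] + V[, -length(sel), drop = FALSE]) %*% w) / 2
  matrix(auc, msi$ny, msi$nx)
}
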