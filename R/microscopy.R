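#' Single-channel microscopy image
#'
#' @param pixels 2D nonnegative intensity matrix (rows = y, cols = x).
#' @param px_um pixel size in micrometres.
#' @param channel_tag one of `"LCO"`, `"PHF1"`, `"RTN3"`, `"other"`.
#' @return object of class `channel_image`.
#' @export
channel_image <- function(pixels, px_um, channel_tag = "other") {
  stopifnot(is.matrix(pixels), px_um > 0)
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and nonnegative")
  }
  channel_tag <- match.arg(channel_tag, c("LCO", "PHF1", "RTN3", "other"))
  structure(list(pixels = pixels, px_um = px_um, channel_tag = channel_tag),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("channel image [%s]: %d x %d px at %g um/px\n", x$channel_tag,
              nrow(x$pixels), ncol(x$pixels), x$px_um))
  invisible(x)
}

#' Morphological background subtraction
#'
#' Estimates the background as the grayscale morphological opening with a
#' disc of the given radius (the rolling-ball equivalent) and subtracts it,
#' clipping at zero. For radii much larger than a bright feature, the
#' feature survives subtraction intact; a constant image maps to zero.
#' Large radii are computed on a downsampled copy of the image (background
#' is smooth by construction) and upsampled back.
#'
#' @param img a [channel_image()].
#' @param radius_um structuring-element radius in micrometres (default
#'   50 um).
#' @return background-subtracted [channel_image()].
#' @export
subtract_background <- function(img, radius_um = 50) {
  stopifnot(inherits(img, "channel_image"), radius_um > 0)
  r_px <- radius_um / img$px_um
  if (r_px < 1) stop("background radius is smaller than one pixel")
  m <- img$pixels
  ds <- max(1L, floor(r_px / 12))
  if (ds > 1) {
    small <- .block_reduce(m, ds)
    bg_s <- .gray_open(small, max(1, round(r_px / ds)))
    bg <- .upsample(bg_s, dim(m), ds)
  } else {
    bg <- .gray_open(m, round(r_px))
  }
  out <- pmax(m - pmin(bg, m), 0)
  channel_image(out, img$px_um, img$channel_tag)
}

.gray_open <- function(m, r_px) {
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  mmax <- max(m)
  if (mmax > 1) return(.gray_open(m / mmax, r_px) * mmax)
  brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  pad <- r_px + 1
  # replicate-pad so image borders behave like an extended tissue field
  rr <- c(rep(1, pad), seq_len(nrow(m)), rep(nrow(m), pad))
  cc <- c(rep(1, pad), seq_len(ncol(m)), rep(ncol(m), pad))
  mp <- m[rr, cc]
  op <- EBImage::opening(mp, brush)
  op[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}

.block_reduce <- function(m, f) {
  nr <- floor(nrow(m) / f) * f; nc <- floor(ncol(m) / f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # block minimum: a conservative background sample
  res <- m[seq(1, nr, f), , drop = FALSE]
  for (off in seq_len(f - 1)) {
    res <- pmin(res, m[seq(1 + off, nr, f), , drop = FALSE])
  }
  out <- res[, seq(1, nc, f), drop = FALSE]
  for (off in seq_len(f - 1)) {
    out <- pmin(out, res[, seq(1 + off, nc, f), drop = FALSE])
  }
  out
}

.upsample <- function(m, target_dim, f) {
  big <- m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
           drop = FALSE]
  out <- matrix(big[nrow(big)], target_dim[1], target_dim[2])
  rr <- seq_len(min(nrow(big), target_dim[1]))
  cc <- seq_len(min(ncol(big), target_dim[2]))
  out[rr, cc] <- big[rr, cc]
  # pad any remaining margin with the nearest computed value
  if (max(rr) < target_dim[1]) out[(max(rr) + 1):target_dim[1], ] <-
    out[rep(max(rr), target_dim[1] - max(rr)), ]
  if (max(cc) < target_dim[2]) out[, (max(cc) + 1):target_dim[2]] <-
    out[, rep(max(cc), target_dim[2] - max(cc))]
  out
}

#' Li minimum cross-entropy threshold
#'
#' Iterative minimum cross-entropy thresholding (Li & Lee's criterion,
#' Li & Tam's fast iterative solution): starting from the image mean, the
#' threshold is repeatedly updated from the foreground/background means
#' until it converges to the cross-entropy minimizer.
#'
#' @param img a [channel_image()] or numeric matrix/vector with at least
#'   two distinct values.
#' @param tol convergence tolerance on the threshold.
#' @return scalar threshold, strictly between the minimum and maximum
#'   intensity.
#' @export
li_threshold <- function(img, tol = 1e-7) {
  v <- if (inherits(img, "channel_image")) as.numeric(img$pixels) else as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  # iterate on a positive copy (criterion uses logarithms of class means)
  shift <- if (rng[1] <= 0) -rng[1] + diff(rng) * 1e-3 else 0
  w <- v + shift
  t_cur <- mean(w)
  for (it in 1:200) {
    m1 <- mean(w[w <= t_cur]); m2 <- mean(w[w > t_cur])
    if (!is.finite(m2) || !is.finite(m1)) break
    t_new <- (m1 - m2) / (log(m1) - log(m2))
    if (abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_out <- t_cur - shift
  max(min(t_out, rng[2] - .Machine$double.eps * abs(rng[2])), rng[1])
}

#' Segment LCO-positive plaques
#'
#' Binarizes the (background-subtracted) LCO channel at the Li threshold,
#' labels 8-connected components, and keeps components of at least
#' `min_area_um2`.
#'
#' @param img a [channel_image()] (LCO channel after
#'   [subtract_background()]).
#' @param min_area_um2 minimum ROI area in square micrometres (default
#'   100 um^2, below the smallest plaque archetype).
#' @return object of class `micro_roi_set`: list with `masks` (named list
#'   of logical matrices), `morphometrics` (data frame: roi_id, area_um2,
#'   equiv_diameter_um, centroid_x_um, centroid_y_um) and `px_um`.
#'   Empty set when nothing is detected.
#' @export
segment_plaques <- function(img, min_area_um2 = 100) {
  stopifnot(inherits(img, "channel_image"))
  v <- img$pixels
  empty <- function() {
    structure(list(masks = stats::setNames(list(), character()),
                   morphometrics = data.frame(
                     roi_id = character(), area_um2 = numeric(),
                     equiv_diameter_um = numeric(), centroid_x_um = numeric(),
                     centroid_y_um = numeric(), stringsAsFactors = FALSE),
                   px_um = img$px_um),
              class = "micro_roi_set")
  }
  if (diff(range(v)) == 0) return(empty())
  thr <- li_threshold(img)
  mask <- v > thr
  lab <- .label8(mask)
  n <- max(lab)
  if (n == 0) return(empty())
  masks <- list(); rows <- list()
  k <- 0L
  for (i in seq_len(n)) {
    sel <- lab == i
    area <- sum(sel) * img$px_um^2
    if (area < min_area_um2) next
    k <- k + 1L
    id <- sprintf("roi%03d", k)
    masks[[id]] <- sel
    idx <- which(sel, arr.ind = TRUE)
    rows[[k]] <- data.frame(
      roi_id = id, area_um2 = area,
      equiv_diameter_um = 2 * sqrt(area / pi),
      centroid_x_um = (mean(idx[, 2]) - 0.5) * img$px_um,
      centroid_y_um = (mean(idx[, 1]) - 0.5) * img$px_um,
      stringsAsFactors = FALSE
    )
  }
  if (k == 0) return(empty())
  out <- structure(list(masks = masks, morphometrics = do.call(rbind, rows),
                        px_um = img$px_um),
                   class = "micro_roi_set")
  attr(out, "px_um") <- img$px_um
  attr(out, "threshold") <- thr
  out
}

# 8-connected labelling: 4-connected EBImage labelling plus a union pass
# that merges labels touching diagonally.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nr - 1), if (dd[2] == 1) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr,       if (dd[2] == 1) 2:nc       else 1:(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (t in touch) union(a[t], b[t])
  }
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Per-ROI fluorescence density
#'
#' Summed channel intensity over the ROI pixel set divided by the ROI area
#' in square micrometres (intensity per um^2).
#'
#' @param roi a logical mask matrix, or a `micro_roi_set` with `roi_id`.
#' @param channel a [channel_image()] sharing the mask geometry.
#' @param roi_id ROI identifier when `roi` is a `micro_roi_set`.
#' @return scalar intensity / um^2.
#' @export
quantify_roi_fluorescence <- function(roi, channel, roi_id = NULL) {
  stopifnot(inherits(channel, "channel_image"))
  mask <- if (inherits(roi, "micro_roi_set")) {
    if (is.null(roi_id)) stop("roi_id required for a micro_roi_set")
    roi$masks[[roi_id]]
  } else roi
  if (is.null(mask) || sum(mask) == 0) stop("empty ROI")
  if (!all(dim(mask) == dim(channel$pixels))) {
    stop("ROI and channel dimensions differ")
  }
  sum(channel$pixels[mask]) / (sum(mask) * channel$px_um^2)
}
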