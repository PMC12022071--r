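#' Write a microscopy scene as a multi-page TIFF
#'
#' One 32-bit float page per channel, in channel order.
#'
#' @param scene a `micro_scene`.
#' @param path output TIFF path.
#' @return invisibly, the path.
#' @export
write_scene_tiff <- function(scene, path) {
  pages <- lapply(scene$channels, function(m) {
    m <- m / max(max(m), 1)  # writeTIFF expects [0, 1]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a list of channel matrices
#'
#' @param path TIFF path.
#' @param px_um pixel size to attach.
#' @param channel_tags optional channel names in page order.
#' @return named list of [channel_image()] objects.
#' @export
read_scene_tiff <- function(path, px_um, channel_tags = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(channel_tags)) {
    channel_tags <- rep("other", length(pages))
    if (length(pages) >= 1) channel_tags[1] <- "LCO"
    if (length(pages) >= 2) channel_tags[2] <- "PHF1"
  }
  out <- Map(function(p, tag) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    channel_image(p, px_um, tag)
  }, pages, channel_tags)
  names(out) <- channel_tags
  out
}

#' Write a ground-truth ROI table as CSV
#'
#' Columns: roi_id, class, center_x_um, center_y_um, diameter_um.
#'
#' @param truth a `synthetic_truth`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth$roi_labels, path, row.names = FALSE)
  invisible(path)
}

#' Write a peak table (plus tags) as CSV
#'
#' Wide format: one row per ROI, one column per peptide, preceded by any
#' tag columns supplied.
#'
#' @param pt a `peak_table`.
#' @param path output CSV path.
#' @param tags optional data frame of per-ROI annotation columns.
#' @return invisibly, the path.
#' @export
write_peak_table <- function(pt, path, tags = NULL) {
  df <- as.data.frame(pt)
  df <- cbind(roi_id = rownames(df), df)
  if (!is.null(tags)) df <- cbind(tags[match(df$roi_id, tags$roi_id),
                                       setdiff(names(tags), "roi_id"),
                                       drop = FALSE], df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save a similarity transform as JSON
#' @param tf a [similarity_transform()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(list(scale = tf$s, theta_rad = tf$theta,
                            tx_um = tf$t[1], ty_um = tf$t[2]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a similarity transform from JSON
#' @param path JSON path written by [write_transform_json()].
#' @return a [similarity_transform()].
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path)
  similarity_transform(j$scale, j$theta_rad, c(j$tx_um, j$ty_um))
}
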