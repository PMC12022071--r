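#' Build an ROI x peptide peak table from MSI data
#'
#' Runs the ROI spectral-processing chain for each region of interest, in
#' this fixed order: average member-pixel spectra, square-root intensity
#' transform, Savitzky-Golay smoothing, SNIP baseline subtraction,
#' back-transform (squaring, returning to the intensity scale so that
#' fold changes are reported on the abundance scale), TIC normalization,
#' MAD noise estimation, and trapezoidal peak area at each panel peptide's
#' m/z window. Peptides whose apex falls at or below the SNR gate are
#' recorded as 0 and flagged below-noise.
#'
#' @param msi an `msi_dataset`, or `NULL` when `spectra` is given.
#' @param roi_masks named list (roi_id -> integer MSI pixel indices), e.g.
#'   from [transfer_rois()] or [truth_msi_rois()]; ignored when `spectra`
#'   is given.
#' @param panel peptide panel from [build_abeta_panel()].
#' @param params chain parameters from [preprocess_params()].
#' @param spectra optional named list of per-ROI [spectrum()] objects
#'   (already averaged), bypassing the pixel-averaging stage.
#' @return object of class `peak_table`: a data frame (rows = ROIs,
#'   columns = panel peptides, values = normalized trapezoidal AUC) with
#'   attributes `below_noise` (logical matrix of flags), `noise` (per-ROI
#'   MAD noise), and `stages` (the logged processing order).
#' @export
preprocess_roi_spectra <- function(msi = NULL, roi_masks = NULL, panel,
                                   params = preprocess_params(),
                                   spectra = NULL) {
  if (is.null(spectra)) {
    stopifnot(inherits(msi, "msi_dataset"), length(roi_masks) > 0)
    empty <- names(roi_masks)[vapply(roi_masks, length, 0L) == 0]
    if (length(empty) > 0) {
      stop("ROI(s) with no MSI pixels: ", paste(empty, collapse = ", "))
    }
    spectra <- lapply(roi_masks, function(idx) {
      spectrum(msi$mz, colMeans(msi$intensities[idx, , drop = FALSE]))
    })
  }
  ids <- names(spectra)
  if (is.null(ids)) ids <- sprintf("roi%03d", seq_along(spectra))
  auc <- matrix(0, length(spectra), nrow(panel),
                dimnames = list(ids, panel$name))
  below <- matrix(FALSE, length(spectra), nrow(panel),
                  dimnames = list(ids, panel$name))
  noise_out <- stats::setNames(numeric(length(spectra)), ids)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    s <- spectrum(s$mz, sqrt(s$intensity), s$meta)
    s <- smooth_savgol(s, params$sg_half_window, params$sg_poly_order)
    # least-squares smoothing can undershoot zero; clamp before clipping
    s <- spectrum(s$mz, pmax(s$intensity, 0), s$meta)
    b <- snip_baseline(s, params$snip_iterations)
    sub_sqrt <- spectrum(s$mz, pmax(s$intensity - b$intensity, 0), s$meta)
    # noise is estimated on the variance-stabilized (sqrt) scale, where
    # detector noise is approximately Gaussian; the clipped baseline sits
    # below the noise band, so apexes are gated against the residual
    # median in MAD units
    noise <- estimate_noise_mad(sub_sqrt)
    resid_med <- stats::median(sub_sqrt$intensity)
    noise_out[i] <- noise
    # back-transform signal and baseline, subtract on the intensity scale
    s <- spectrum(s$mz, pmax(s$intensity^2 - b$intensity^2, 0), s$meta)
    s <- tic_normalize(s, params$tic_target)
    for (k in seq_len(nrow(panel))) {
      ctr <- panel$mz_obs[k]
      fwhm <- ctr / params$resolving_power
      sel <- which(s$mz >= ctr - fwhm & s$mz <= ctr + fwhm)
      apex <- if (length(sel) > 0) max(sub_sqrt$intensity[sel]) else 0
      if (noise > 0 && (apex - resid_med) / noise <= params$snr_threshold) {
        below[i, k] <- TRUE
        auc[i, k] <- 0
      } else {
        auc[i, k] <- peak_auc(s, ctr, params$auc_halfwidth_fwhm * fwhm)
      }
    }
  }
  out <- as.data.frame(auc)
  attr(out, "below_noise") <- below
  attr(out, "noise") <- noise_out
  attr(out, "stages") <- c("average_pixels", "sqrt", "savitzky_golay",
                           "snip_subtract", "square_back_transform",
                           "tic_normalize", "mad_noise", "snr_gate",
                           "trapezoid_auc")
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Restrict a peak table to consistently detected peptides
#'
#' Keeps only panel peptides detected (above noise) in every ROI — the
#' "consistent peptide set" filter applied before group statistics.
#'
#' @param pt a `peak_table`.
#' @return filtered `peak_table` with attribute `dropped` naming removed
#'   columns.
#' @export
consistent_peptides <- function(pt) {
  below <- attr(pt, "below_noise")
  keep <- colSums(below) == 0
  out <- pt[, keep, drop = FALSE]
  attr(out, "below_noise") <- below[, keep, drop = FALSE]
  attr(out, "noise") <- attr(pt, "noise")
  attr(out, "stages") <- attr(pt, "stages")
  attr(out, "dropped") <- names(keep)[!keep]
  class(out) <- class(pt)
  out
}

#' Build the ROI-average spectra of a cohort and its peak table
#'
#' Convenience wrapper: averages technical-replicate spectra per ROI and
#' runs [preprocess_roi_spectra()].
#'
#' @param cohort a `plaque_cohort` (roi mode).
#' @param params chain parameters.
#' @return list with `table` (a `peak_table`) and `tags` (one row per ROI:
#'   roi_id, patient, group, type).
#' @export
cohort_peak_table <- function(cohort, params = preprocess_params()) {
  stopifnot(inherits(cohort, "plaque_cohort"))
  ids <- unique(cohort$tags$roi_id)
  spectra <- lapply(ids, function(id) {
    sel <- which(cohort$tags$roi_id == id)
    ints <- vapply(cohort$spectra[sel], `[[`, cohort$spectra[[sel[1]]]$intensity,
                   "intensity")
    spectrum(cohort$spectra[[sel[1]]]$mz, rowMeans(as.matrix(ints)))
  })
  names(spectra) <- ids
  pt <- preprocess_roi_spectra(panel = cohort$panel, params = params,
                               spectra = spectra)
  tags <- cohort$amplitude_tags[match(ids, cohort$amplitude_tags$roi_id), ]
  list(table = pt, tags = tags)
}
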