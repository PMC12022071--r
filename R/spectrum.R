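#' Mass spectrum container
#'
#' @param mz strictly increasing m/z vector (Da).
#' @param intensity nonnegative intensity vector of the same length
#'   (intermediate processing stages such as least-squares smoothing may
#'   carry small negative excursions; set `allow_negative`).
#' @param meta free-form metadata (pixel coordinate or ROI id).
#' @param allow_negative skip the nonnegativity check.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, meta = list(), allow_negative = FALSE) {
  stopifnot(length(mz) == length(intensity))
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (!allow_negative && any(intensity < 0)) {
    stop("intensities must be nonnegative")
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 meta = meta), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d bins, m/z %.1f-%.1f, TIC %.4g\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' ROI spectral preprocessing parameters
#'
#' Defaults follow the processing chain used throughout: Savitzky-Golay
#' half-window 10 bins (full window 21, cubic), 100 SNIP iterations,
#' MAD noise estimation, TIC normalization, SNR > 2 peak gate, and
#' integration half-width of one FWHM (m/z / 1000) per peptide.
#'
#' @param sg_half_window Savitzky-Golay half window (bins).
#' @param sg_poly_order Savitzky-Golay polynomial order.
#' @param snip_iterations SNIP clipping iterations.
#' @param snr_threshold signal-to-noise gate for peak acceptance.
#' @param tic_target TIC normalization target.
#' @param auc_halfwidth_fwhm integration half-width in units of the local
#'   peak FWHM (m/z / resolving power).
#' @param resolving_power instrument resolving power (FWHM definition).
#' @return list of parameters.
#' @export
preprocess_params <- function(sg_half_window = 10, sg_poly_order = 3,
                              snip_iterations = 100, snr_threshold = 2,
                              tic_target = 1, auc_halfwidth_fwhm = 1,
                              resolving_power = 1000) {
  stopifnot(sg_half_window >= 1, snip_iterations >= 1, snr_threshold > 0,
            auc_halfwidth_fwhm > 0)
  list(sg_half_window = sg_half_window, sg_poly_order = sg_poly_order,
       snip_iterations = snip_iterations, snr_threshold = snr_threshold,
       tic_target = tic_target, auc_halfwidth_fwhm = auc_halfwidth_fwhm,
       resolving_power = resolving_power)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with window `2w + 1` bins; edges are
#' handled by reflecting the spectrum, so an exact polynomial of degree
#' `poly_order` or lower passes through unchanged in the interior.
#'
#' @param s a [spectrum()].
#' @param half_window half window size w in bins.
#' @param poly_order polynomial order (must be < 2w + 1).
#' @return smoothed [spectrum()] on the same m/z grid.
#' @export
smooth_savgol <- function(s, half_window = 10, poly_order = 3) {
  n <- length(s$intensity)
  win <- 2 * half_window + 1
  if (win > n) stop("spectrum shorter than the smoothing window")
  if (poly_order >= win) stop("polynomial order must be below the window size")
  fl <- signal::sgolay(p = poly_order, n = win)
  kern <- fl[half_window + 1, ]  # central least-squares kernel
  padded <- c(rev(s$intensity[2:(half_window + 1)]), s$intensity,
              rev(s$intensity[(n - half_window):(n - 1)]))
  sm <- stats::filter(padded, rev(kern), sides = 2)
  out <- as.numeric(sm[(half_window + 1):(half_window + n)])
  spectrum(s$mz, out, s$meta, allow_negative = TRUE)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive nonlinear iterative peak clipping with the
#' decreasing-window variant: intensities are mapped through the LLS
#' operator log(log(sqrt(v + 1) + 1) + 1), clipped iteratively with window
#' half-widths shrinking from `iterations` down to 1, and mapped back.
#'
#' @param s a [spectrum()] (nonnegative intensities).
#' @param iterations number of clipping iterations (also the starting
#'   half-window in bins).
#' @return baseline as a [spectrum()] on the same grid.
#' @export
snip_baseline <- function(s, iterations = 100) {
  v <- s$intensity
  if (any(v < 0)) stop("SNIP requires nonnegative intensities")
  n <- length(v)
  y <- log(log(sqrt(v + 1) + 1) + 1)
  for (w in seq(min(iterations, n - 1), 1)) {
    # edge bins clip against the clamped boundary value
    left <- c(rep(y[1], w), y[1:(n - w)])
    right <- c(y[(w + 1):n], rep(y[n], w))
    y <- pmin(y, (left + right) / 2)
  }
  b <- (exp(exp(y) - 1) - 1)^2 - 1
  spectrum(s$mz, pmax(b, 0), s$meta)
}

#' Subtract an estimated baseline from a spectrum
#' @param s a [spectrum()].
#' @param baseline a baseline [spectrum()] on the same grid.
#' @return baseline-subtracted [spectrum()] (clipped at zero).
#' @export
subtract_baseline <- function(s, baseline) {
  stopifnot(length(s$mz) == length(baseline$mz))
  spectrum(s$mz, pmax(s$intensity - baseline$intensity, 0), s$meta)
}

#' MAD noise estimate
#'
#' Scaled median absolute deviation, `1.4826 * median(|v - median(v)|)`,
#' consistent for the standard deviation of Gaussian noise.
#'
#' @param s a [spectrum()] (typically baseline-subtracted).
#' @return scalar noise level.
#' @export
estimate_noise_mad <- function(s) {
  stopifnot(length(s$intensity) >= 2)
  stats::mad(s$intensity, constant = 1.4826)
}

#' Total-ion-count normalization
#'
#' @param s a [spectrum()].
#' @param target normalized TIC (default 1).
#' @return rescaled [spectrum()].
#' @export
tic_normalize <- function(s, target = 1) {
  tic <- sum(s$intensity)
  if (tic <= 0) {
    stop("cannot TIC-normalize a zero spectrum",
         if (length(s$meta) > 0) paste0(" (", toString(unlist(s$meta)), ")") else "")
  }
  spectrum(s$mz, s$intensity * (target / tic), s$meta)
}

#' SNR-gated peak detection
#'
#' Finds local maxima of a baseline-subtracted, smoothed spectrum whose
#' signal-to-noise ratio exceeds `snr_threshold`; neighbouring maxima closer
#' than one local FWHM are merged to the higher apex.
#'
#' @param s a [spectrum()].
#' @param snr_threshold SNR gate (peaks require intensity/noise >
#'   `snr_threshold`).
#' @param noise noise level; estimated with [estimate_noise_mad()] if `NULL`.
#' @param resolving_power FWHM definition for merging.
#' @return data frame with `mz`, `intensity`, `snr` (possibly empty).
#' @export
detect_peaks <- function(s, snr_threshold = 2, noise = NULL,
                         resolving_power = 1000) {
  v <- s$intensity
  n <- length(v)
  if (is.null(noise)) noise <- estimate_noise_mad(s)
  if (noise <= 0) noise <- .Machine$double.eps
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  idx <- which(is_max & v / noise > snr_threshold)
  if (length(idx) == 0) {
    return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  }
  # merge apexes closer than one local FWHM, keeping the higher
  idx <- idx[order(-v[idx])]
  kept <- integer()
  for (i in idx) {
    fwhm <- s$mz[i] / resolving_power
    if (all(abs(s$mz[kept] - s$mz[i]) >= fwhm)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(mz = s$mz[kept], intensity = v[kept], snr = v[kept] / noise)
}

#' Trapezoidal peak area
#'
#' Trapezoidal integral of a (baseline-subtracted) spectrum over
#' `[center - half_width, center + half_width]`; negative bins are clipped
#' at zero before integration.
#'
#' @param s a [spectrum()].
#' @param center window centre (Da).
#' @param half_width window half-width (Da).
#' @return nonnegative area.
#' @export
peak_auc <- function(s, center, half_width) {
  stopifnot(half_width > 0)
  sel <- which(s$mz >= center - half_width & s$mz <= center + half_width)
  if (length(sel) < 2) {
    stop("integration window around m/z ", center,
         " overlaps fewer than two bins")
  }
  pracma::trapz(s$mz[sel], pmax(s$intensity[sel], 0))
}
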