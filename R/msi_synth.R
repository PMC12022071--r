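#' MSI dataset container
#'
#' @param mz strictly increasing m/z grid (Da).
#' @param intensities numeric matrix, one row per pixel (row-major grid
#'   order: pixel index = (x-1)*ny + y), one column per m/z bin.
#' @param nx,ny grid dimensions (10 um pitch pixels).
#' @param pitch_um pixel pitch in micrometres.
#' @param meta free-form metadata list.
#' @return object of class `msi_dataset`.
#' @export
msi_dataset <- function(mz, intensities, nx, ny, pitch_um = 10, meta = list()) {
  stopifnot(length(mz) == ncol(intensities), nrow(intensities) == nx * ny,
            all(diff(mz) > 0))
  coords <- data.frame(
    x = rep(seq_len(nx), each = ny),
    y = rep(seq_len(ny), times = nx)
  )
  coords$x_um <- (coords$x - 0.5) * pitch_um
  coords$y_um <- (coords$y - 0.5) * pitch_um
  structure(list(mz = mz, intensities = intensities, coords = coords,
                 nx = nx, ny = ny, pitch_um = pitch_um, meta = meta),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("MSI dataset: %d x %d pixels at %g um pitch, %d m/z bins (%.1f-%.1f Da)\n",
              x$nx, x$ny, x$pitch_um, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

# Gaussian peak basis: one column per peptide, FWHM = mz/resolving_power
.peak_basis <- function(mz, mz_obs, resolving_power = 1000) {
  B <- matrix(0, length(mz), length(mz_obs))
  for (k in seq_along(mz_obs)) {
    fwhm <- mz_obs[k] / resolving_power
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    B[, k] <- exp(-(mz - mz_obs[k])^2 / (2 * sigma^2))
  }
  B
}

.baseline_profile <- function(mz, b0, lambda) b0 * exp(-(mz - 1500) / lambda)

#' Simulate an MSI datacube over a synthetic scene
#'
#' Builds a 10-um-pitch pixel grid covering the microscopy field of a
#' [make_microscopy_scene()] ground truth, and synthesizes one spectrum per
#' pixel: a sum of Gaussian peptide peaks at the instrument resolving power
#' (FWHM = m/z / 1000) whose amplitudes follow the plaque-template profiles
#' (with core enrichment inside dense cores), plus a decaying-exponential
#' chemical baseline, multiplicative log-normal amplitude noise with
#' coefficient of variation `noise_cv`, and an additive Gaussian detector
#' floor.
#'
#' @param truth `synthetic_truth` from [make_microscopy_scene()].
#' @param panel peptide panel from [build_abeta_panel()].
#' @param templates template list with abundance profiles.
#' @param noise_cv multiplicative amplitude CV (0 = noise-free).
#' @param seed integer seed.
#' @param mz_range acquisition window (Da).
#' @param bin_da m/z bin width (Da).
#' @param pitch_um MSI pixel pitch (10 um, the acquisition raster).
#' @param baseline_b0 baseline amplitude at 1500 Da (0 disables baseline).
#' @param baseline_lambda baseline decay constant (Da).
#' @param detector_sd additive detector noise standard deviation.
#' @param transform optional true microscopy-to-MSI [similarity_transform()]
#'   (defaults to identity); recorded in the returned truth.
#' @return list with `msi` (an `msi_dataset`) and `truth` (input truth
#'   augmented with `transform_true`, per-MSI-pixel `pixel_class_map_msi`
#'   and the noise-free `amplitudes` matrix, pixels x peptides).
#' @export
make_msi_dataset <- function(truth, panel, templates = plaque_templates(),
                             noise_cv = 0.10, seed = 1L,
                             mz_range = c(1500, 6000), bin_da = 1,
                             pitch_um = 10, baseline_b0 = 2,
                             baseline_lambda = 1200, detector_sd = 0.05,
                             transform = NULL) {
  stopifnot(nrow(panel) >= 1, noise_cv >= 0)
  set.seed(seed)
  if (is.null(transform)) transform <- similarity_transform(1, 0, c(0, 0))
  nx <- ceiling(truth$field_um[1] / pitch_um)
  ny <- ceiling(truth$field_um[2] / pitch_um)
  if (nx * ny == 0) stop("scene yields no MSI pixels")
  mz <- seq(mz_range[1], mz_range[2], by = bin_da)

  # MSI pixel centres in MSI frame, mapped back into the microscopy frame
  xs <- (rep(seq_len(nx), each = ny) - 0.5) * pitch_um
  ys <- (rep(seq_len(ny), times = nx) - 0.5) * pitch_um
  src <- transform_points(invert_transform(transform), cbind(xs, ys))

  A <- matrix(0, nx * ny, nrow(panel))
  colnames(A) <- panel$name
  fillerA <- numeric(nx * ny)
  class_map <- matrix(0L, ny, nx)
  for (g in truth$geoms) {
    tpl <- templates[[g$class]]
    ev <- .geom_eval(g, src[, 1], src[, 2])
    hit <- ev$w > 0
    if (!any(hit)) next
    prof <- tpl$profile[panel$name]
    contrib <- outer(ev$w[hit], prof)
    if (any(ev$core[hit])) {
      enr <- tpl$core_enrichment[panel$name]
      contrib[ev$core[hit], ] <- sweep(contrib[ev$core[hit], , drop = FALSE],
                                       2, enr, `*`)
    }
    A[hit, ] <- A[hit, ] + contrib
    fillerA[hit] <- fillerA[hit] + ev$w[hit] * tpl$filler
    class_map[cbind(((which(hit) - 1L) %% ny) + 1L,
                    ((which(hit) - 1L) %/% ny) + 1L)] <-
      match(g$class, MORPHOTYPE_LEVELS)
  }

  Anoisy <- A
  if (noise_cv > 0) {
    Anoisy <- A * matrix(.lnorm_factor(length(A), noise_cv), nrow(A), ncol(A))
    fillerA <- fillerA * .lnorm_factor(length(fillerA), noise_cv)
  }
  B <- .peak_basis(mz, panel$mz_obs)
  S <- Anoisy %*% t(B) +
    fillerA %*% t(.peak_basis(mz, FILLER_MZ))
  if (baseline_b0 > 0) {
    S <- sweep(S, 2, .baseline_profile(mz, baseline_b0, baseline_lambda), `+`)
  }
  if (detector_sd > 0) {
    S <- pmax(S + matrix(stats::rnorm(length(S), 0, detector_sd),
                         nrow(S), ncol(S)), 0)
  }
  msi <- msi_dataset(mz, S, nx, ny, pitch_um,
                     meta = list(noise_cv = noise_cv, baseline_b0 = baseline_b0,
                                 baseline_lambda = baseline_lambda,
                                 detector_sd = detector_sd, seed = seed))
  truth$transform_true <- transform
  truth$pixel_class_map_msi <- class_map
  truth$amplitudes <- A
  list(msi = msi, truth = truth)
}

#' Ground-truth MSI ROI masks from scene geometry
#'
#' Computes, analytically from the planted geometry, which MSI pixels belong
#' to each plaque (in the MSI frame of the recorded true transform).
#'
#' @param msi an `msi_dataset`.
#' @param truth the matching augmented `synthetic_truth`.
#' @return named list (roi_id -> integer pixel indices into `msi$coords`).
#' @export
truth_msi_rois <- function(msi, truth) {
  src <- transform_points(invert_transform(truth$transform_true),
                          cbind(msi$coords$x_um, msi$coords$y_um))
  out <- list()
  for (i in seq_along(truth$geoms)) {
    g <- truth$geoms[[i]]
    ev <- .geom_eval(g, src[, 1], src[, 2])
    idx <- which(ev$w > 0)
    if (length(idx) > 0) out[[truth$roi_labels$roi_id[i]]] <- idx
  }
  out
}

#' Simulate one ROI-average spectrum from a peptide amplitude vector
#'
#' The fast path used for cohort-scale experiments: instead of building a
#' full datacube and averaging member pixels, the ROI-average spectrum is
#' synthesized directly from the (already noise-jittered) peptide
#' amplitudes.
#'
#' @param amplitude named numeric vector of peptide amplitudes.
#' @param panel peptide panel (provides `mz_obs`).
#' @param mz m/z grid.
#' @param filler amplitude of the non-panel filler component at `FILLER_MZ`.
#' @param baseline_b0,baseline_lambda,detector_sd see [make_msi_dataset()].
#' @return a [spectrum()] object.
#' @export
simulate_roi_spectrum <- function(amplitude, panel, mz, filler = 0,
                                  baseline_b0 = 2, baseline_lambda = 1200,
                                  detector_sd = 0.05) {
  B <- .peak_basis(mz, panel$mz_obs)
  v <- as.numeric(B %*% amplitude[panel$name])
  if (filler > 0) v <- v + filler * as.numeric(.peak_basis(mz, FILLER_MZ))
  if (baseline_b0 > 0) v <- v + .baseline_profile(mz, baseline_b0, baseline_lambda)
  if (detector_sd > 0) v <- pmax(v + stats::rnorm(length(v), 0, detector_sd), 0)
  spectrum(mz, v)
}

#' Generate a synthetic multi-patient cohort
#'
#' Draws per-patient plaque counts from the group-specific means of the
#' [cohort_spec()] (coarse-grained and vascular deposits structurally absent
#' from CUAP), then plants the template abundance profiles with three levels
#' of log-normal variability: patient level (inter-patient CV), plaque level
#' (intra-patient CV) and replicate-section level (technical CV).
#'
#' Two modes: `"roi"` (default) generates one ROI-average spectrum per
#' plaque and technical replicate, the input expected by
#' [preprocess_roi_spectra()]; `"full"` additionally renders a microscopy
#' scene and MSI datacube per patient (use small `field_um`/narrow
#' `mz_range` to keep this tractable).
#'
#' @param spec a [cohort_spec()].
#' @param templates,panel generator templates and peptide panel.
#' @param mode `"roi"` or `"full"`.
#' @param mz_range,bin_da spectral axis settings.
#' @param baseline_b0,detector_sd nuisance-signal settings.
#' @param field_um (full mode) per-patient field size.
#' @param msi_noise_cv (full mode) pixel amplitude CV.
#' @return object of class `plaque_cohort`: `spec`, `panel`, `mode`,
#'   `tags` (one row per ROI spectrum: roi_id, patient, group, type,
#'   replicate), `spectra` (parallel list), `amplitudes` (planted noise-free
#'   patient x plaque amplitudes, rows matching unique ROIs), and in full
#'   mode `patients` (list of per-patient scene/msi/truth bundles).
#' @export
make_cohort <- function(spec = cohort_spec(), templates = plaque_templates(),
                        panel = default_abeta_panel(),
                        mode = c("roi", "full"),
                        mz_range = c(1500, 6000), bin_da = 1,
                        baseline_b0 = 2, detector_sd = 0.05,
                        field_um = c(400, 400), msi_noise_cv = 0.10) {
  mode <- match.arg(mode)
  set.seed(spec$seed)
  mz <- seq(mz_range[1], mz_range[2], by = bin_da)
  tags <- list(); spectra <- list(); amps <- list(); patients <- list()
  amp_tags <- list()
  pid <- 0L
  for (g in names(spec$groups)) {
    for (i in seq_len(spec$groups[[g]])) {
      pid <- pid + 1L
      patient <- sprintf("%s_%02d", g, i)
      means <- spec$mean_counts[g, ]
      counts <- stats::setNames(integer(length(means)), names(means))
      for (ty in names(means)) {
        counts[ty] <- if (means[ty] == 0) 0L else
          max(stats::rpois(1, means[ty]), if (means[ty] >= 3) 3L else 0L)
      }
      # patient-level peptide abundance factor (inter-patient CV)
      pf <- .lnorm_factor(nrow(panel), spec$inter_patient_cv)
      names(pf) <- panel$name
      roi_n <- 0L
      for (ty in names(counts)) {
        if (counts[ty] == 0) next
        tpl <- templates[[ty]]
        for (p in seq_len(counts[ty])) {
          roi_n <- roi_n + 1L
          roi_id <- sprintf("%s_%s%02d", patient, ty, p)
          plaque_f <- .lnorm_factor(nrow(panel), spec$intra_patient_cv)
          base_amp <- tpl$profile[panel$name] * pf * plaque_f
          base_filler <- tpl$filler *
            .lnorm_factor(1, spec$intra_patient_cv)
          amps[[length(amps) + 1L]] <- base_amp
          amp_tags[[length(amp_tags) + 1L]] <-
            data.frame(roi_id = roi_id, patient = patient, group = g,
                       type = ty, stringsAsFactors = FALSE)
          for (r in seq_len(spec$n_tech_replicates)) {
            amp <- base_amp * .lnorm_factor(nrow(panel), spec$technical_cv)
            spectra[[length(spectra) + 1L]] <-
              simulate_roi_spectrum(amp, panel, mz,
                                    filler = base_filler *
                                      .lnorm_factor(1, spec$technical_cv),
                                    baseline_b0 = baseline_b0,
                                    detector_sd = detector_sd)
            tags[[length(tags) + 1L]] <-
              data.frame(roi_id = roi_id, patient = patient, group = g,
                         type = ty, replicate = r, stringsAsFactors = FALSE)
          }
        }
      }
      if (mode == "full") {
        cnt <- counts[counts > 0]
        sc <- make_microscopy_scene(cnt, templates, field_um = field_um,
                                    seed = (spec$seed * 131 + pid * 7919) %% 2147483629)
        ms <- make_msi_dataset(sc$truth, panel, templates,
                               noise_cv = msi_noise_cv,
                               seed = (spec$seed * 137 + pid * 104729) %% 2147483629,
                               mz_range = mz_range, bin_da = bin_da,
                               baseline_b0 = baseline_b0,
                               detector_sd = detector_sd)
        patients[[patient]] <- list(id = patient, group = g, counts = counts,
                                    scene = sc$scene, msi = ms$msi,
                                    truth = ms$truth)
      }
    }
  }
  amplitudes <- do.call(rbind, amps)
  rownames(amplitudes) <- vapply(amp_tags, `[[`, "", "roi_id")
  structure(list(
    spec = spec, panel = panel, mode = mode,
    tags = do.call(rbind, tags), spectra = spectra,
    amplitudes = amplitudes, amplitude_tags = do.call(rbind, amp_tags),
    patients = patients
  ), class = "plaque_cohort")
}

#' @export
print.plaque_cohort <- function(x, ...) {
  cat(sprintf("Synthetic plaque cohort (%s mode): %d patients, %d ROI spectra\n",
              x$mode, sum(x$spec$groups), length(x$spectra)))
  print(table(x$amplitude_tags$group, x$amplitude_tags$type))
  invisible(x)
}
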