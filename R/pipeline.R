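#' Pipeline configuration
#'
#' Bundles per-stage parameter blocks for [run_pipeline()] and computes a
#' deterministic configuration hash for provenance. Defaults give a small
#' synthetic end-to-end run.
#'
#' @param seed root seed; every stochastic stage derives its stream from it.
#' @param cohort list: `groups`, optional `mean_counts`, CV overrides.
#' @param scene list: `field_um`, `px_um`.
#' @param msi list: `mz_range`, `bin_da`, `noise_cv`, `baseline_b0`,
#'   `detector_sd`.
#' @param classifier list: `mode` (`"train"` or `"truth"`), plus
#'   [train_config()] overrides when training.
#' @param segmentation list: `leaves`, `smoothing`.
#' @param extraction [preprocess_params()] overrides.
#' @param stats list: `contrasts` (list of length-2 character vectors).
#' @param out_dir optional output directory for artifact files.
#' @return object of class `pipeline_config` with attribute `hash`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = list(
                              groups = c(CUAP = 1, sAD = 2, fAD = 1),
                              mean_counts = rbind(
                                CUAP = c(DP = 4, CP = 3, CGP = 0, CWP = 0, CAA = 0),
                                sAD  = c(DP = 3, CP = 3, CGP = 2, CWP = 0, CAA = 0),
                                fAD  = c(DP = 2, CP = 3, CGP = 2, CWP = 0, CAA = 0))),
                            scene = list(field_um = c(600, 600), px_um = 1),
                            msi = list(mz_range = c(3000, 5600), bin_da = 1,
                                       noise_cv = 0.10, baseline_b0 = 2,
                                       detector_sd = 0.02),
                            classifier = list(mode = "truth"),
                            segmentation = list(leaves = 2,
                                                smoothing = "medium"),
                            extraction = list(),
                            stats = list(contrasts = list(c("CP", "DP"))),
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), cohort = cohort, scene = scene,
              msi = msi, classifier = classifier,
              segmentation = segmentation, extraction = extraction,
              stats = stats, out_dir = out_dir)
  known <- c("seed", "cohort", "scene", "msi", "classifier", "segmentation",
             "extraction", "stats", "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config", hash = .config_hash(cfg))
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")], tmp,
                       auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] blocks.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in intersect(names(y), c("seed", "cohort", "scene", "msi",
                                   "classifier", "segmentation",
                                   "extraction", "stats", "out_dir"))) {
    args[[nm]] <- y[[nm]]
  }
  if (!is.null(args$cohort$groups)) args$cohort$groups <- unlist(args$cohort$groups)
  do.call(pipeline_config, args)
}

.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 1009 + stage * 999331) %% 2147483629
}

#' Run the end-to-end synthetic pipeline
#'
#' Fixed stage order: simulate cohort, segment microscopy, classify
#' morphotypes, register microscopy to MSI, extract ROI peak tables,
#' spatial MSI segmentation, group statistics. All randomness flows from
#' the root seed (one derived stream per stage); any stage failure aborts
#' with a stage-labelled error.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `pipeline_result`: `config`, `hash`, `cohort`
#'   (per-patient bundles), `rois` (detected microscopy ROIs per patient),
#'   `classified` (per-ROI predicted types), `peak_table` + `tags`,
#'   `seg_trees` (per patient), `stats` (per-contrast scans; `NA` rows for
#'   contrasts whose types are absent), `ensemble` (when trained).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  templates <- plaque_templates()
  panel <- default_abeta_panel()

  # stage 1: simulate
  bundle <- stage("simulate", {
    spec_args <- cfg$cohort
    spec_args$seed <- .stage_seed(cfg$seed, 1)
    spec <- do.call(cohort_spec, spec_args)
    patients <- list()
    pid <- 0L
    for (g in names(spec$groups)) for (i in seq_len(spec$groups[[g]])) {
      pid <- pid + 1L
      patient <- sprintf("%s_%02d", g, i)
      set.seed(.stage_seed(cfg$seed, 100 + pid))
      means <- spec$mean_counts[g, ]
      counts <- vapply(names(means), function(ty) {
        if (means[ty] == 0) 0L else max(stats::rpois(1, means[ty]),
                                        if (means[ty] >= 3) 3L else 0L)
      }, 0L)
      sc <- make_microscopy_scene(counts[counts > 0], templates,
                                  field_um = cfg$scene$field_um,
                                  px_um = cfg$scene$px_um,
                                  seed = .stage_seed(cfg$seed, 200 + pid))
      ms <- make_msi_dataset(sc$truth, panel, templates,
                             noise_cv = cfg$msi$noise_cv,
                             seed = .stage_seed(cfg$seed, 300 + pid),
                             mz_range = cfg$msi$mz_range,
                             bin_da = cfg$msi$bin_da,
                             baseline_b0 = cfg$msi$baseline_b0,
                             detector_sd = cfg$msi$detector_sd)
      patients[[patient]] <- list(id = patient, group = g, counts = counts,
                                  scene = sc$scene, msi = ms$msi,
                                  truth = ms$truth)
    }
    list(spec = spec, patients = patients)
  })

  # stage 2: microscopy segmentation
  rois <- stage("microscopy", {
    lapply(bundle$patients, function(p) {
      img <- channel_image(p$scene$channels$LCO, p$scene$px_um, "LCO")
      segment_plaques(subtract_background(img), min_area_um2 = 100)
    })
  })

  # stage 3: classification
  cls_out <- stage("classify", {
    ensemble <- NULL
    if (identical(cfg$classifier$mode, "train")) {
      tc_args <- cfg$classifier[setdiff(names(cfg$classifier),
                                        c("mode", "n_per_class"))]
      tc_args$seed <- .stage_seed(cfg$seed, 3)
      tc <- do.call(train_config, tc_args)
      train <- make_patch_set(n_per_class = cfg$classifier$n_per_class %||% 60,
                              seed = .stage_seed(cfg$seed, 4))
      pp <- lapply(train$patches, preprocess_patch)
      set.seed(.stage_seed(cfg$seed, 5))
      ensemble <- train_crossval(pp, train$labels, tc)
    }
    classified <- lapply(names(bundle$patients), function(nm) {
      p <- bundle$patients[[nm]]
      rs <- rois[[nm]]
      if (nrow(rs$morphometrics) == 0) return(NULL)
      truth_lab <- .match_truth(rs$morphometrics, p$truth)
      if (!is.null(ensemble)) {
        crops <- .roi_crops(p$scene, rs)
        pr <- predict_ensemble(ensemble, lapply(crops, preprocess_patch))
        pred <- attr(pr, "predicted")
        # non-classifier morphotypes keep their truth annotation
        pred[!truth_lab %in% ensemble$classes] <-
          truth_lab[!truth_lab %in% ensemble$classes]
      } else {
        pred <- truth_lab
      }
      data.frame(patient = nm, group = p$group,
                 roi_id = paste0(nm, ".", rs$morphometrics$roi_id),
                 local_roi = rs$morphometrics$roi_id,
                 predicted = pred, truth = truth_lab,
                 stringsAsFactors = FALSE)
    })
    list(classified = do.call(rbind, classified), ensemble = ensemble)
  })
  classified <- cls_out$classified
  ensemble <- cls_out$ensemble

  # stage 4 + 5: registration and extraction
  extraction <- stage("extract", {
    params <- do.call(preprocess_params, cfg$extraction)
    tabs <- list(); tags <- list()
    for (nm in names(bundle$patients)) {
      p <- bundle$patients[[nm]]
      rs <- rois[[nm]]
      if (nrow(rs$morphometrics) == 0) next
      # landmarks: truth plaque centres seen in both frames
      src <- as.matrix(p$truth$roi_labels[, c("center_x_um", "center_y_um")])
      if (nrow(src) < 2) next
      dst <- transform_points(p$truth$transform_true, src)
      tf <- fit_similarity(src, dst)
      masks <- transfer_rois(rs, tf, p$msi)
      if (length(masks) == 0) next
      pt <- preprocess_roi_spectra(p$msi, masks, panel, params)
      ids <- paste0(nm, ".", rownames(pt))
      rownames(pt) <- ids
      tabs[[nm]] <- pt
      tags[[nm]] <- data.frame(roi_id = ids, stringsAsFactors = FALSE)
    }
    pt_all <- do.call(rbind, unname(lapply(tabs, as.data.frame)))
    below <- do.call(rbind, unname(lapply(tabs, attr, "below_noise")))
    tags_all <- do.call(rbind, unname(tags))
    tags_all <- merge(tags_all, classified, by = "roi_id", all.x = TRUE,
                      sort = FALSE)
    list(table = pt_all, below = below, tags = tags_all)
  })

  # stage 6: MSI spatial segmentation
  seg_trees <- stage("segment_msi", {
    out <- list()
    for (nm in names(bundle$patients)) {
      sm <- spatial_smooth(bundle$patients[[nm]]$msi,
                           cfg$segmentation$smoothing)
      out[[nm]] <- bisecting_kmeans(sm, max_leaves = cfg$segmentation$leaves,
                                    seed = .stage_seed(cfg$seed, 6))
    }
    out
  })

  # stage 7: statistics
  stats_out <- stage("stats", {
    tg <- extraction$tags
    res <- list()
    for (ct in cfg$stats$contrasts) {
      key <- paste(ct, collapse = "_vs_")
      n_of <- vapply(ct, function(ty) sum(tg$predicted == ty, na.rm = TRUE),
                     0)
      if (any(n_of < 2)) {
        res[[key]] <- data.frame(peptide = NA_character_, note = paste(
          "not applicable: type(s)", paste(ct[n_of < 2], collapse = ", "),
          "absent or singleton in this cohort"))
        next
      }
      ok <- !is.na(tg$predicted)
      res[[key]] <- contrast_scan(extraction$table[tg$roi_id[ok], ,
                                                   drop = FALSE],
                                  tg$predicted[ok], ct)
    }
    res
  })

  out <- structure(list(config = cfg, hash = attr(cfg, "hash"),
                        cohort = bundle, rois = rois,
                        classified = classified,
                        peak_table = extraction$table,
                        tags = extraction$tags,
                        seg_trees = seg_trees, stats = stats_out,
                        ensemble = ensemble),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) .write_bundle(out, cfg$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# crop detected ROIs from the scene for classification
.roi_crops <- function(scene, rois, margin = 1.4) {
  img <- scene$channels$LCO
  lapply(rois$masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    half <- max(diff(range(idx[, 1])), diff(range(idx[, 2]))) * margin / 2
    ci <- mean(range(idx[, 1])); cj <- mean(range(idx[, 2]))
    i0 <- max(1, round(ci - half)); i1 <- min(nrow(img), round(ci + half))
    j0 <- max(1, round(cj - half)); j1 <- min(ncol(img), round(cj + half))
    img[i0:i1, j0:j1, drop = FALSE]
  })
}

# assign each detected ROI the class of the nearest truth plaque (within
# its radius plus a tolerance); unmatched ROIs get NA
.match_truth <- function(morpho, truth, slack_um = 15) {
  lab <- character(nrow(morpho))
  for (i in seq_len(nrow(morpho))) {
    dx <- truth$roi_labels$center_x_um - morpho$centroid_x_um[i]
    dy <- truth$roi_labels$center_y_um - morpho$centroid_y_um[i]
    d <- sqrt(dx^2 + dy^2)
    j <- which.min(d)
    lab[i] <- if (length(j) == 1 &&
                  d[j] <= truth$roi_labels$diameter_um[j] / 2 + slack_um) {
      truth$roi_labels$class[j]
    } else NA_character_
  }
  lab
}

.write_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_table(structure(res$peak_table, class = c("peak_table",
                                                       "data.frame")),
                   file.path(dir, "peak_table.csv"), tags = res$tags)
  utils::write.csv(res$classified, file.path(dir, "classified_rois.csv"),
                   row.names = FALSE)
  summary <- list(hash = res$hash, seed = res$config$seed,
                  n_patients = length(res$cohort$patients),
                  n_rois = nrow(res$peak_table))
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Evaluate a pipeline result against the synthetic ground truth
#'
#' @param result a `pipeline_result` from a synthetic run.
#' @return object of class `truth_evaluation`: `classifier` (confusion
#'   matrix and accuracy of predicted vs planted morphotypes),
#'   `segmentation_ari` (per patient: adjusted Rand index of the
#'   plaque-vs-background cut against the planted pixel map), and
#'   `effect_recovery` (per contrast: planted fold change, detected flag).
#' @export
evaluate_truth <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  cl <- result$classified[!is.na(result$classified$truth), ]
  conf <- table(truth = cl$truth, predicted = cl$predicted)
  acc <- sum(cl$truth == cl$predicted) / nrow(cl)

  ari <- vapply(names(result$cohort$patients), function(nm) {
    p <- result$cohort$patients[[nm]]
    lab <- cut_tree(result$seg_trees[[nm]], 2)
    truth_bin <- as.integer(p$truth$pixel_class_map_msi > 0)
    mclust::adjustedRandIndex(as.integer(lab), truth_bin)
  }, 0)

  templates <- plaque_templates()
  rec <- list()
  for (key in names(result$stats)) {
    sc <- result$stats[[key]]
    if (!"p_adj" %in% names(sc)) next
    ct <- strsplit(key, "_vs_")[[1]]
    planted <- planted_fold_changes(templates, ct[1], ct[2])
    rec[[key]] <- data.frame(
      contrast = key, peptide = sc$peptide,
      planted_fold = unname(planted[sc$peptide]),
      p_adj = sc$p_adj,
      planted_effect = abs(log2(planted[sc$peptide])) > 0.1,
      detected = sc$p_adj < 0.05,
      stringsAsFactors = FALSE
    )
  }
  structure(list(classifier = list(confusion = conf, accuracy = acc),
                 segmentation_ari = ari,
                 effect_recovery = do.call(rbind, rec)),
            class = "truth_evaluation")
}

#' @export
print.truth_evaluation <- function(x, ...) {
  cat(sprintf("classifier accuracy vs truth: %.3f\n", x$classifier$accuracy))
  cat("segmentation ARI (plaque vs background):",
      paste(sprintf("%.2f", x$segmentation_ari), collapse = ", "), "\n")
  if (!is.null(x$effect_recovery)) {
    agg <- stats::aggregate(detected ~ contrast + planted_effect,
                            data = x$effect_recovery, FUN = mean)
    print(agg)
  }
  invisible(x)
}
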