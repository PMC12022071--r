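#' Default plaque morphotype templates
#'
#' One template per morphotype, bundling the geometry the histology
#' literature attributes to each deposit class with a planted relative
#' A\eqn{\beta} abundance profile whose pairwise ratios encode the group
#' contrasts the analysis is meant to recover:
#'
#' * `DP` (diffuse): large (>= 50 um), low-contrast, x-42 dominated, no
#'   appreciable x-40 content.
#' * `CP` (cored): 30-50 um, bright compact core plus corona; elevated
#'   Abeta1-40, Abeta3pE-42 and Abeta11pE-42 relative to DP (planted fold 3),
#'   with Abeta1-40 core-enriched.
#' * `CGP` (coarse-grained): 50-100 um, multiple dense cores, no corona;
#'   x-40 species (Abeta4-40, Abeta3pE-40, Abeta1-40) elevated over CP and
#'   x-42 species reduced.
#' * `CWP` (cotton wool): large amorphous familial-AD deposit; pE-x-42 /
#'   Abeta1-42 ratios above CP.
#' * `CAA` (vascular amyloid): annular deposit along a vessel path;
#'   Abeta1-40/Abeta3pE-40 above CGP, x-42 species below CGP.
#'
#' @return Named list of templates. Each template has `morphotype`,
#'   `diameter_range_um`, `n_cores_range`, `has_corona`, `profile` (named
#'   numeric, relative abundance per panel peptide), `core_enrichment`
#'   (named numeric core/halo intensity ratios) and `phf1` (relative
#'   tau/PHF-1 co-staining intensity used by the neuritic-content channel).
#' @export
plaque_templates <- function() {
  peps <- c("Abeta1-40", "Abeta1-42", "Abeta2-42", "Abeta3pE-40",
            "Abeta3pE-42", "Abeta4-40", "Abeta4-42", "Abeta5-42",
            "Abeta11pE-42")
  prof <- function(...) {
    v <- c(...)
    stopifnot(length(v) == length(peps), all(v >= 0))
    names(v) <- peps
    v
  }
  enr <- function(...) {
    v <- rep(1, length(peps)); names(v) <- peps
    ov <- c(...)
    v[names(ov)] <- ov
    v
  }
  tpl <- list(
    DP = list(
      morphotype = "DP", diameter_range_um = c(50, 90),
      n_cores_range = c(0, 0), has_corona = FALSE,
      #         1-40 1-42 2-42 3pE40 3pE42 4-40 4-42 5-42 11pE42
      profile = prof(5,  60,  20,   1,    8,   1,  15,  10,  5),
      core_enrichment = enr(), phf1 = 0
    ),
    CP = list(
      morphotype = "CP", diameter_range_um = c(30, 50),
      n_cores_range = c(1, 1), has_corona = TRUE,
      profile = prof(15, 60,  20,   2,   24,   2,  15,  10, 15),
      core_enrichment = enr(`Abeta1-40` = 3), phf1 = 0.3
    ),
    CGP = list(
      morphotype = "CGP", diameter_range_um = c(50, 100),
      n_cores_range = c(3, 8), has_corona = FALSE,
      profile = prof(45, 30,  12,  10,   10,  10,   8,   4,  6),
      core_enrichment = enr(), phf1 = 0.8
    ),
    CWP = list(
      morphotype = "CWP", diameter_range_um = c(60, 110),
      n_cores_range = c(0, 0), has_corona = FALSE,
      profile = prof(8,  50,  25,   1,   30,   1,  22,  16, 20),
      core_enrichment = enr(), phf1 = 0
    ),
    CAA = list(
      morphotype = "CAA", diameter_range_um = c(60, 120),
      n_cores_range = c(0, 0), has_corona = FALSE,
      profile = prof(80, 15,   4,  20,    5,  12,   3,   2,  3),
      core_enrichment = enr(), phf1 = 0
    )
  )
  # Non-panel filler component (other plaque constituents) sized so every
  # morphotype carries the same total planted ion content; keeps TIC
  # normalization neutral with respect to between-class contrasts.
  total <- 180
  for (nm in names(tpl)) tpl[[nm]]$filler <- total - sum(tpl[[nm]]$profile)
  tpl
}

#' m/z of the simulator's non-panel filler component
#'
#' The filler is synthesized outside the peptide panel but at a comparable
#' peak width, so smoothing losses match the panel peaks and TIC
#' normalization stays contrast-neutral.
#' @export
FILLER_MZ <- 5500

#' Planted fold changes between morphotype profiles
#'
#' Ratio of template abundances for a given contrast, the generator's ground
#' truth against which detected effects are scored.
#'
#' @param templates template list from [plaque_templates()].
#' @param num,den morphotype codes for numerator and denominator.
#' @return Named numeric vector of fold changes (numerator / denominator).
#' @export
planted_fold_changes <- function(templates = plaque_templates(),
                                 num = "CP", den = "DP") {
  stopifnot(num %in% names(templates), den %in% names(templates))
  templates[[num]]$profile / templates[[den]]$profile
}

#' Cohort specification
#'
#' Parameters of the synthetic multi-patient cohort. Defaults follow the
#' study conditions: group sizes CUAP 5 / sAD 12 / fAD 6; technical CV 10%
#' (three technical replicates), intra-patient CV 16%, inter-patient CV 18%;
#' coarse-grained and vascular deposits absent from CUAP; diffuse-plaque
#' load high in CUAP and sAD but low in fAD; cored-plaque load increasing
#' CUAP < sAD < fAD; coarse-grained load fAD > sAD > CUAP = 0.
#'
#' @param groups named integer vector of patients per group.
#' @param mean_counts matrix (group x morphotype) of mean plaque counts per
#'   patient section; CUAP rows must be zero for CGP and CAA.
#' @param technical_cv,intra_patient_cv,inter_patient_cv fractional
#'   coefficients of variation (in (0,1)).
#' @param n_tech_replicates technical replicate sections per patient.
#' @param seed integer seed; cohort generation is a pure function of
#'   (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c(CUAP = 5, sAD = 12, fAD = 6),
                        mean_counts = NULL,
                        technical_cv = 0.10,
                        intra_patient_cv = 0.16,
                        inter_patient_cv = 0.18,
                        n_tech_replicates = 3,
                        seed = 1L) {
  if (is.null(mean_counts)) {
    mean_counts <- rbind(
      CUAP = c(DP = 12, CP = 4,  CGP = 0, CWP = 0, CAA = 0),
      sAD  = c(DP = 12, CP = 8,  CGP = 4, CWP = 0, CAA = 2),
      fAD  = c(DP = 5,  CP = 12, CGP = 7, CWP = 1, CAA = 3)
    )
  }
  mean_counts <- mean_counts[names(groups), , drop = FALSE]
  if (any(mean_counts[rownames(mean_counts) == "CUAP", c("CGP", "CAA")] != 0)) {
    stop("CUAP patients must carry zero CGP and zero CAA deposits")
  }
  for (cv in c(technical_cv, intra_patient_cv, inter_patient_cv)) {
    if (!(cv > 0 && cv < 1)) stop("coefficients of variation must lie in (0, 1)")
  }
  if (any(groups < 1)) stop("every group needs at least one patient")
  structure(list(
    groups = groups, mean_counts = mean_counts,
    technical_cv = technical_cv, intra_patient_cv = intra_patient_cv,
    inter_patient_cv = inter_patient_cv,
    n_tech_replicates = n_tech_replicates, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  groups:", paste(names(x$groups), x$groups, sep = "=", collapse = ", "), "\n")
  cat("  CVs: technical", x$technical_cv, "| intra-patient", x$intra_patient_cv,
      "| inter-patient", x$inter_patient_cv, "\n")
  cat("  mean plaque counts per patient:\n")
  print(x$mean_counts)
  invisible(x)
}

# lognormal multiplier with unit mean and coefficient of variation cv
.lnorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
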