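#' Morphotype class codes used in label images
#' @export
MORPHOTYPE_LEVELS <- c("DP", "CP", "CGP", "CWP", "CAA")

# Per-plaque geometry record. All coordinates in micrometres in the
# microscopy frame (x right, y down, origin at the field corner).
.new_geom <- function(class, cx, cy, r_um, cores = NULL, harmonics = NULL,
                      path = NULL, lumen_um = NA, wall_um = NA) {
  list(class = class, cx = cx, cy = cy, r_um = r_um, cores = cores,
       harmonics = harmonics, path = path, lumen_um = lumen_um,
       wall_um = wall_um)
}

# Signed membership/intensity of one plaque evaluated at micrometre
# coordinates (x, y). Returns list(w = fill weight in [0,1], core = logical).
.geom_eval <- function(g, x, y) {
  if (g$class == "CAA") {
    # distance to the polyline vessel path; deposit is the vessel wall band
    d <- .dist_to_path(x, y, g$path)
    w <- as.numeric(d >= g$lumen_um & d <= g$lumen_um + g$wall_um)
    return(list(w = w, core = rep(FALSE, length(x))))
  }
  dx <- x - g$cx; dy <- y - g$cy
  d <- sqrt(dx^2 + dy^2)
  r <- g$r_um / 2
  if (!is.null(g$harmonics)) {
    th <- atan2(dy, dx)
    mod <- rep(1, length(x))
    for (k in seq_len(nrow(g$harmonics))) {
      mod <- mod + g$harmonics[k, "amp"] *
        cos(g$harmonics[k, "k"] * th + g$harmonics[k, "phase"])
    }
    r <- r * pmax(mod, 0.5)
  }
  inside <- d < r
  core <- rep(FALSE, length(x))
  if (g$class == "CP") core <- d < 0.3 * (g$r_um / 2)
  if (g$class == "CGP" && !is.null(g$cores)) {
    for (k in seq_len(nrow(g$cores))) {
      core <- core | (sqrt((x - g$cores$cx[k])^2 + (y - g$cores$cy[k])^2) <
                        g$cores$r[k])
    }
    core <- core & inside
  }
  list(w = as.numeric(inside), core = core)
}

.dist_to_path <- function(x, y, path) {
  # path: matrix of densely sampled (x, y) vertices
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(path))) {
    d <- pmin(d, sqrt((x - path[k, 1])^2 + (y - path[k, 2])^2))
  }
  d
}

.bezier_path <- function(p0, p1, p2, n = 80) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# Draw geometry for one plaque of a template at centre (cx, cy)
.draw_geom <- function(tpl, cx, cy) {
  r_um <- stats::runif(1, tpl$diameter_range_um[1], tpl$diameter_range_um[2])
  cls <- tpl$morphotype
  if (cls == "DP") {
    h <- cbind(k = 2:4, amp = stats::runif(3, 0.03, 0.10),
               phase = stats::runif(3, 0, 2 * pi))
    return(.new_geom(cls, cx, cy, r_um, harmonics = h))
  }
  if (cls == "CGP") {
    n_cores <- sample(seq(tpl$n_cores_range[1], tpl$n_cores_range[2]), 1)
    ang <- stats::runif(n_cores, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_cores)) * 0.70 * r_um / 2
    cores <- data.frame(cx = cx + rad * cos(ang), cy = cy + rad * sin(ang),
                        r = stats::runif(n_cores, 3, 6))
    return(.new_geom(cls, cx, cy, r_um, cores = cores))
  }
  if (cls == "CAA") {
    half <- r_um * 0.75
    th <- stats::runif(1, 0, 2 * pi)
    p0 <- c(cx - half * cos(th), cy - half * sin(th))
    p2 <- c(cx + half * cos(th), cy + half * sin(th))
    bend <- stats::runif(1, -0.4, 0.4) * half
    p1 <- c(cx - bend * sin(th), cy + bend * cos(th))
    wall <- stats::runif(1, 10, 20)
    return(.new_geom(cls, cx, cy, r_um, path = .bezier_path(p0, p1, p2),
                     lumen_um = 5, wall_um = wall))
  }
  .new_geom(cls, cx, cy, r_um)
}

# Per-class fluorescence intensity profile on the LCO channel
.render_intensity <- function(g, x, y) {
  ev <- .geom_eval(g, x, y)
  r <- g$r_um / 2
  d <- sqrt((x - g$cx)^2 + (y - g$cy)^2)
  v <- switch(g$class,
    DP  = 0.25 * ev$w * pmax(1 - (d / r)^2 * 0.6, 0.2),
    CP  = ev$w * (0.35 * pmax(1 - (d - 0.3 * r) / (0.7 * r), 0)) +
          as.numeric(ev$core) * 0.65,
    CGP = ev$w * 0.45 + as.numeric(ev$core) * 0.50,
    CWP = 0.5 * ev$w,
    CAA = 0.8 * ev$w
  )
  pmin(v, 1)
}

#' Generate a synthetic fluorescence microscopy scene
#'
#' Places non-overlapping plaques of the requested morphotypes in a field
#' and renders an LCO (amyloid) channel together with a co-localized
#' PHF-1-like (neuritic tau) channel. Morphologies follow the histological
#' archetypes: compact bright core plus weaker corona (CP), low-contrast
#' irregular diffuse blob (DP), multiple dense cores without corona inside
#' a large disk (CGP), large uniform moderately bright deposit (CWP), and
#' an annular deposit along a curved vessel path (CAA).
#'
#' @param counts named integer vector of plaques per morphotype
#'   (names among `r toString(MORPHOTYPE_LEVELS)`).
#' @param templates template list, see [plaque_templates()].
#' @param field_um field size in micrometres, `c(width, height)`.
#' @param px_um microscopy pixel size (default 0.5 um/px, 20x widefield).
#' @param seed integer seed; the scene is a pure function of its arguments.
#' @param background constant tissue autofluorescence level.
#' @param noise_sd additive Gaussian pixel noise (0 = noise-free).
#' @param max_tries placement attempts per plaque before giving up.
#' @return A list with `scene` (class `micro_scene`: channel matrices `LCO`
#'   and `PHF1`, `px_um`, `field_um`) and `truth` (class `synthetic_truth`:
#'   `roi_labels` data frame, `pixel_class_map`, per-plaque `geoms`,
#'   identity `transform_true`).
#' @export
make_microscopy_scene <- function(counts, templates = plaque_templates(),
                                  field_um = c(600, 600), px_um = 0.5,
                                  seed = 1L, background = 0.02,
                                  noise_sd = 0, max_tries = 500) {
  stopifnot(px_um > 0, all(field_um > 0))
  counts <- counts[counts > 0]
  if (length(counts) > 0 && !all(names(counts) %in% names(templates))) {
    stop("counts names must match template morphotypes")
  }
  set.seed(seed)
  nx <- round(field_um[1] / px_um); ny <- round(field_um[2] / px_um)

  # place plaques with rejection sampling, largest first
  order_req <- rep(names(counts), counts)
  geoms <- list(); placed <- data.frame(cx = numeric(), cy = numeric(), r = numeric())
  for (cls in order_req) {
    tpl <- templates[[cls]]
    rmax <- tpl$diameter_range_um[2] / 2
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, rmax + 5, field_um[1] - rmax - 5)
      cy <- stats::runif(1, rmax + 5, field_um[2] - rmax - 5)
      g <- .draw_geom(tpl, cx, cy)
      reach <- if (cls == "CAA") g$r_um * 0.75 + g$lumen_um + g$wall_um else g$r_um / 2
      if (nrow(placed) == 0 ||
          all(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) >
                placed$r + reach + 10)) {
        geoms[[length(geoms) + 1]] <- g
        placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = reach))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place all requested plaques without overlap: placed ",
           length(geoms), " of ", length(order_req),
           " (enlarge the field or reduce counts)")
    }
  }

  lco <- matrix(background, ny, nx)
  phf <- matrix(0, ny, nx)
  class_map <- matrix(0L, ny, nx)
  if (length(geoms) > 0) {
    for (i in seq_along(geoms)) {
      g <- geoms[[i]]
      reach <- if (g$class == "CAA") g$r_um * 0.75 + g$lumen_um + g$wall_um + 5 else
        g$r_um / 2 * 1.4
      j0 <- max(1L, floor((g$cx - reach) / px_um)); j1 <- min(nx, ceiling((g$cx + reach) / px_um))
      i0 <- max(1L, floor((g$cy - reach) / px_um)); i1 <- min(ny, ceiling((g$cy + reach) / px_um))
      jj <- j0:j1; ii <- i0:i1
      xg <- (rep(jj, each = length(ii)) - 0.5) * px_um
      yg <- (rep(ii, times = length(jj)) - 0.5) * px_um
      v <- .render_intensity(g, xg, yg)
      vm <- matrix(v, length(ii), length(jj))
      lco[ii, jj] <- pmax(lco[ii, jj], background + vm)
      tphf <- templates[[g$class]]$phf1
      if (tphf > 0) phf[ii, jj] <- pmax(phf[ii, jj], tphf * (vm > 0) * pmin(vm * 2, 1))
      cm <- class_map[ii, jj]
      cm[vm > 0] <- match(g$class, MORPHOTYPE_LEVELS)
      class_map[ii, jj] <- cm
    }
  }
  if (noise_sd > 0) {
    lco <- pmax(lco + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx), 0)
    phf <- pmax(phf + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx), 0)
  }

  roi_labels <- if (length(geoms) == 0) {
    data.frame(roi_id = character(), class = character(),
               center_x_um = numeric(), center_y_um = numeric(),
               diameter_um = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      roi_id = sprintf("roi%03d", seq_along(geoms)),
      class = vapply(geoms, `[[`, "", "class"),
      center_x_um = vapply(geoms, `[[`, 0, "cx"),
      center_y_um = vapply(geoms, `[[`, 0, "cy"),
      diameter_um = vapply(geoms, `[[`, 0, "r_um"),
      stringsAsFactors = FALSE
    )
  }
  scene <- structure(list(channels = list(LCO = lco, PHF1 = phf),
                          px_um = px_um, field_um = field_um),
                     class = "micro_scene")
  truth <- structure(list(roi_labels = roi_labels, pixel_class_map = class_map,
                          geoms = geoms, px_um = px_um, field_um = field_um,
                          transform_true = similarity_transform(1, 0, c(0, 0))),
                     class = "synthetic_truth")
  list(scene = scene, truth = truth)
}

#' Extract raw image patches around each plaque of a scene
#'
#' Crops a square window of side `margin` times the plaque diameter around
#' each ground-truth plaque centre from the LCO channel. Crops are raw
#' (unscaled); feed them through [preprocess_patch()] for the classifier.
#'
#' @param scene,truth output of [make_microscopy_scene()].
#' @param classes morphotypes to keep.
#' @param margin window side as a multiple of the plaque diameter.
#' @return list with `patches` (list of matrices) and `labels` (character).
#' @export
plaque_patches <- function(scene, truth, classes = c("CGP", "CP", "DP"),
                           margin = 1.4) {
  keep <- truth$roi_labels$class %in% classes
  labs <- truth$roi_labels$class[keep]
  rows <- which(keep)
  px <- scene$px_um
  img <- scene$channels$LCO
  patches <- lapply(rows, function(i) {
    r <- truth$roi_labels[i, ]
    half <- margin * r$diameter_um / 2
    j0 <- max(1L, round((r$center_x_um - half) / px))
    j1 <- min(ncol(img), round((r$center_x_um + half) / px))
    i0 <- max(1L, round((r$center_y_um - half) / px))
    i1 <- min(nrow(img), round((r$center_y_um + half) / px))
    img[i0:i1, j0:j1, drop = FALSE]
  })
  list(patches = patches, labels = labs)
}

#' Generate a labelled synthetic patch set for classifier training
#'
#' Renders one single-plaque mini-scene per patch (fast path used for
#' training experiments), returning raw crops plus labels.
#'
#' @param n_per_class patches per morphotype.
#' @param classes morphotypes to generate.
#' @param seed integer seed.
#' @param noise_sd additive pixel noise of each mini-scene.
#' @return list with `patches` and `labels`.
#' @export
make_patch_set <- function(n_per_class = 100, classes = c("CGP", "CP", "DP"),
                           seed = 1L, noise_sd = 0.01) {
  templates <- plaque_templates()
  patches <- list(); labels <- character()
  k <- 0L
  for (cls in classes) {
    fld <- max(plaque_templates()[[cls]]$diameter_range_um[2] * 1.8, 150)
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      cnt <- stats::setNames(1L, cls)
      sc <- make_microscopy_scene(cnt, templates, field_um = c(fld, fld),
                                  px_um = 1,
                                  seed = (as.numeric(seed) * 97 + k * 7919) %% 2147483629,
                                  noise_sd = noise_sd)
      pp <- plaque_patches(sc$scene, sc$truth, classes = cls)
      patches[[k]] <- pp$patches[[1]]
      labels[k] <- cls
    }
  }
  list(patches = patches, labels = labels)
}
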