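# Synthetic tray scenes with known geometry: the validation backbone.
# Fish are capsule polygons (rectangle with semicircular caps) laid out on
# the metric tray plane with known lengths; a sampled plane-to-plane
# projective camera maps everything to pixels; the emitted annotations are
# exactly what a labeller (and a detector) would produce, plus a truth
# channel no real dataset has.

#' Synthetic scene configuration
#'
#' Defaults emulate a hand-held camera photographing rectangular market
#' trays from a roughly constant distance and incidence angle: per-scene
#' pixel scale 9-13 px/cm, tilt up to 10 degrees, small in-plane rotation
#' and principal-point offset. Species lengths are log-normal per species
#' (medians spanning 7-32 cm across the 13 default species, sdlog 0.25),
#' clipped to the 5-83 cm range of realistic market catches; the resulting
#' mean length is about 17 cm. All noise channels default to zero so the
#' default scene is an exact oracle; switch them on to study degradation.
#'
#' @param tray A [tray_geometry()].
#' @param catalog A [species_catalog()].
#' @param length_median_cm Per-species log-normal medians (recycled to the
#'   catalog size).
#' @param length_sdlog Log-scale standard deviation.
#' @param length_clip_cm Two-element clip range for sampled lengths (cm).
#' @param aspect Fish width as a fraction of length.
#' @param species_weights Sampling weights over the catalog (default
#'   uniform).
#' @param fish_per_tray Integer range (min, max) of fish per scene.
#' @param image_px Image (width, height) in pixels.
#' @param scale_px_per_cm,tilt_deg,rotation_deg,offset_px Camera ranges:
#'   centre pixel scale, plane tilt, in-plane rotation, principal-point
#'   offset per axis.
#' @param view_distance_cm Camera distance entering the perspective term.
#' @param corner_jitter_px,polyline_jitter_px Gaussian label noise (sd).
#' @param dropout_prob,misclass_prob Detection degradation probabilities.
#' @param confidence_shape Beta(a, b) parameters for detection confidences.
#' @return A `scene_config` list.
#' @export
scene_config <- function(tray = tray_geometry(60, 40),
                         catalog = default_species_catalog(),
                         length_median_cm = c(7, 8, 9, 10, 11, 12, 14, 16,
                                              18, 20, 23, 27, 32),
                         length_sdlog = 0.25,
                         length_clip_cm = c(5, 83),
                         aspect = 0.22,
                         species_weights = NULL,
                         fish_per_tray = c(3, 10),
                         image_px = c(1024, 768),
                         scale_px_per_cm = c(9, 13),
                         tilt_deg = c(0, 10),
                         rotation_deg = c(-5, 5),
                         offset_px = c(-40, 40),
                         view_distance_cm = 100,
                         corner_jitter_px = 0,
                         polyline_jitter_px = 0,
                         dropout_prob = 0,
                         misclass_prob = 0,
                         confidence_shape = c(8, 2)) {
  n_sp <- nrow(catalog)
  med <- rep_len(length_median_cm, n_sp)
  if (is.null(species_weights)) species_weights <- rep(1, n_sp)
  stopifnot(length_clip_cm[1] > 0, length_clip_cm[2] > length_clip_cm[1],
            aspect > 0, aspect < 1,
            dropout_prob >= 0, dropout_prob <= 1,
            misclass_prob >= 0, misclass_prob <= 1)
  structure(list(
    tray = tray, catalog = catalog, length_median_cm = med,
    length_sdlog = length_sdlog, length_clip_cm = length_clip_cm,
    aspect = aspect, species_weights = species_weights / sum(species_weights),
    fish_per_tray = fish_per_tray, image_px = image_px,
    scale_px_per_cm = scale_px_per_cm, tilt_deg = tilt_deg,
    rotation_deg = rotation_deg, offset_px = offset_px,
    view_distance_cm = view_distance_cm,
    corner_jitter_px = corner_jitter_px,
    polyline_jitter_px = polyline_jitter_px,
    dropout_prob = dropout_prob, misclass_prob = misclass_prob,
    confidence_shape = confidence_shape), class = "scene_config")
}

runif1 <- function(range) runif(1, range[1], range[2])

# cm -> px projective camera: centre the tray, tilt the plane about the
# horizontal axis, project at distance D with focal length scale * D, then
# rotate in-plane and shift to the (offset) principal point.
sample_camera <- function(config) {
  W <- config$tray$width_cm; H <- config$tray$height_cm
  s <- runif1(config$scale_px_per_cm)
  th <- runif1(config$tilt_deg) * pi / 180
  phi <- runif1(config$rotation_deg) * pi / 180
  off <- c(runif1(config$offset_px), runif1(config$offset_px))
  D <- config$view_distance_cm
  f <- s * D
  Tc <- rbind(c(1, 0, -W / 2), c(0, 1, -H / 2), c(0, 0, 1))
  P <- rbind(c(f, 0, 0), c(0, f * cos(th), 0), c(0, -sin(th), D))
  ctr <- config$image_px / 2 + off
  A <- rbind(c(cos(phi), -sin(phi), ctr[1]),
             c(sin(phi), cos(phi), ctr[2]),
             c(0, 0, 1))
  Hm <- A %*% P %*% Tc
  structure(Hm / Hm[3, 3], class = "homography")
}

# Convex capsule ring of total length len, width wid, centred at the
# origin with its axis along x; n_cap vertices per semicircular cap.
capsule_ring <- function(len, wid, n_cap = 8) {
  r <- wid / 2
  hb <- len / 2 - r
  t_right <- seq(-pi / 2, pi / 2, length.out = n_cap + 1)
  t_left <- seq(pi / 2, 3 * pi / 2, length.out = n_cap + 1)[-1]
  rbind(cbind(hb + r * cos(t_right), r * sin(t_right)),
        cbind(-hb + r * cos(t_left), r * sin(t_left)))
}

# Sample an orientation, compute the exact feasible centre region for it,
# and place uniformly inside. Returns NULL when no tried orientation fits
# (fish longer than any tray chord at the tried angles).
place_fish <- function(config, len, max_tries = 60) {
  W <- config$tray$width_cm; H <- config$tray$height_cm
  wid <- config$aspect * len
  ring0 <- capsule_ring(len, wid)
  for (try in seq_len(max_tries)) {
    psi <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(psi), -sin(psi)), c(sin(psi), cos(psi)))
    ring <- ring0 %*% t(R)
    rx <- range(ring[, 1]); ry <- range(ring[, 2])
    if (diff(rx) > W || diff(ry) > H) next
    ctr <- c(runif(1, -rx[1], W - rx[2]), runif(1, -ry[1], H - ry[2]))
    axis_pts <- cbind(seq(-len / 2, len / 2, length.out = 4), 0)
    return(list(ring = sweep(ring, 2, -ctr),
                polyline = sweep(axis_pts %*% t(R), 2, -ctr)))
  }
  NULL
}

#' Generate one synthetic tray scene
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   `(config, seed)`.
#' @param image_id Image id for the emitted record.
#' @return List with `record` (a [tray_image_record()] with jittered corner
#'   labels and projected annotations), `truth` (data frame `instance_id`,
#'   `species_id`, `length_cm`, `area_cm2`: exact tray-plane values),
#'   `detections` (ground-truth copies degraded by dropout and
#'   misclassification, with sampled confidences) and `homography_cm_to_px`
#'   (the true camera map).
#' @export
generate_scene <- function(config, seed = 1, image_id = 1L) {
  set.seed(seed)
  W <- config$tray$width_cm; H <- config$tray$height_cm
  cam <- sample_camera(config)
  n_fish <- if (config$fish_per_tray[1] == config$fish_per_tray[2]) {
    config$fish_per_tray[1]
  } else {
    sample(config$fish_per_tray[1]:config$fish_per_tray[2], 1)
  }

  corners_cm <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  corners_px <- map_points(cam, corners_cm)
  if (config$corner_jitter_px > 0) {
    corners_px <- corners_px +
      matrix(stats::rnorm(8, 0, config$corner_jitter_px), 4, 2)
  }

  anns <- list(); truth <- list()
  for (i in seq_len(n_fish)) {
    sp <- sample(config$catalog$species_id, 1,
                 prob = config$species_weights)
    med <- config$length_median_cm[sp + 1]
    # lengths are drawn from the species law truncated to fish that can lie
    # flat inside the tray: redraw on an infeasible draw, error only when
    # even redrawn lengths never fit (degenerate tray/length configuration)
    placed <- NULL
    for (redraw in 1:40) {
      len <- rlnorm(1, log(med), config$length_sdlog)
      len <- min(max(len, config$length_clip_cm[1]), config$length_clip_cm[2])
      placed <- place_fish(config, len)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) {
      stop_traymetry("traymetry_placement_error",
                     sprintf("could not place fish %d of %d (length %.1f cm)",
                             i, n_fish, len))
    }
    mask_px <- map_points(cam, placed$ring)
    poly_px <- map_points(cam, placed$polyline)
    if (config$polyline_jitter_px > 0) {
      poly_px <- poly_px + matrix(stats::rnorm(length(poly_px), 0,
                                               config$polyline_jitter_px),
                                  nrow(poly_px), 2)
    }
    anns[[i]] <- fish_annotation(i, sp, list(mask_px),
                                 size_polyline = poly_px)
    truth[[i]] <- data.frame(instance_id = i, species_id = sp,
                             length_cm = len,
                             area_cm2 = abs(ring_area_signed(placed$ring)))
  }
  record <- tray_image_record(image_id, config$image_px[1],
                              config$image_px[2],
                              corner_quad(corners_px), anns)

  detections <- list()
  for (i in seq_len(n_fish)) {
    dropped <- runif(1) < config$dropout_prob
    sp <- anns[[i]]$species_id
    mis <- runif(1) < config$misclass_prob
    conf <- rbeta(1, config$confidence_shape[1], config$confidence_shape[2])
    if (dropped) next
    if (mis && nrow(config$catalog) > 1) {
      sp <- sample(setdiff(config$catalog$species_id, sp), 1)
    }
    detections[[length(detections) + 1]] <-
      detection_instance(sp, anns[[i]]$mask, anns[[i]]$bbox, conf,
                         instance_id = i)
  }

  list(record = record,
       truth = if (n_fish > 0) do.call(rbind, truth) else
         data.frame(instance_id = integer(0), species_id = integer(0),
                    length_cm = numeric(0), area_cm2 = numeric(0)),
       detections = detections,
       homography_cm_to_px = cam)
}

#' Generate a synthetic tray dataset
#'
#' Per-tray seeds are derived as `seed + index - 1`, so any tray of a
#' dataset can be regenerated in isolation.
#'
#' @inheritParams generate_scene
#' @param n_trays Number of scenes.
#' @return List: `records`, `truth` (row-bound truth table with
#'   `image_id`), `detections` (named list by image id),
#'   `homographies` (true cm->px maps).
#' @export
generate_dataset <- function(config, n_trays, seed = 1) {
  records <- vector("list", n_trays)
  truths <- vector("list", n_trays)
  detections <- list()
  homs <- vector("list", n_trays)
  for (i in seq_len(n_trays)) {
    sc <- generate_scene(config, seed = seed + i - 1, image_id = i)
    records[[i]] <- sc$record
    truths[[i]] <- if (nrow(sc$truth) > 0) cbind(image_id = i, sc$truth) else
      NULL
    detections[[as.character(i)]] <- sc$detections
    homs[[i]] <- sc$homography_cm_to_px
  }
  truth <- do.call(rbind, truths) %||%
    data.frame(image_id = integer(0), instance_id = integer(0),
               species_id = integer(0), length_cm = numeric(0),
               area_cm2 = numeric(0))
  list(records = records, truth = truth, detections = detections,
       homographies = homs)
}
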