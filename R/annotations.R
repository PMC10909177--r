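# Domain records: tray geometry, corner quads, fish annotations, detections,
# tray image records. All coordinates are continuous pixels, origin at the
# top-left, x rightward, y downward (COCO convention); boxes are
# (x_min, y_min, width, height).

#' Tray geometry in centimetres
#'
#' The real-world rectangle that the labelled tray-handle corners describe.
#' Canonicalized so that `width_cm >= height_cm`.
#'
#' @param width_cm,height_cm Positive tray side lengths in cm.
#' @return A `tray_geometry` list with `width_cm` and `height_cm`.
#' @export
tray_geometry <- function(width_cm = 60, height_cm = 40) {
  if (!is.finite(width_cm) || !is.finite(height_cm) ||
      width_cm <= 0 || height_cm <= 0) {
    stop_traymetry("traymetry_validation_error",
                   "tray dimensions must be strictly positive")
  }
  if (width_cm < height_cm) {
    tmp <- width_cm; width_cm <- height_cm; height_cm <- tmp
  }
  structure(list(width_cm = width_cm, height_cm = height_cm),
            class = "tray_geometry")
}

#' Corner quadrilateral of the tray rectangle
#'
#' Four labelled pixel points marking the tray-handle rectangle as seen in
#' the image, stored in canonical order: starting at the top-left (smallest
#' y, then x) and proceeding top-right, bottom-right, bottom-left. Use
#' [canonicalize_corners()] to build one from unordered clicks.
#'
#' @param points 4 x 2 numeric matrix (or length-8 vector, row-wise) of
#'   pixel coordinates, already in ring order.
#' @return A `corner_quad` (4 x 2 matrix).
#' @export
corner_quad <- function(points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 2, byrow = TRUE)
  if (nrow(pts) != 4 || ncol(pts) != 2 || anyNA(pts) || !all(is.finite(pts))) {
    stop_traymetry("traymetry_validation_error",
                   "a corner quad needs exactly 4 finite (x, y) points")
  }
  storage.mode(pts) <- "double"
  pts <- unname(pts)
  assert_nondegenerate_quad(pts)
  # convexity of the ring as stored: all cross products share a sign
  d <- rbind(pts[c(2, 3, 4, 1), ] - pts)
  cr <- vapply(1:4, function(i) {
    j <- if (i == 4) 1 else i + 1
    cross2(d[i, ], d[j, ])
  }, numeric(1))
  if (!(all(cr > 0) || all(cr < 0))) {
    stop_traymetry("traymetry_degenerate_quad",
                   "corner points do not form a convex quadrilateral in ring order")
  }
  structure(pts, class = "corner_quad")
}

assert_nondegenerate_quad <- function(pts, tol = 1e-9) {
  combs <- utils::combn(4, 3)
  areas <- apply(combs, 2, function(idx) {
    p <- pts[idx, , drop = FALSE]
    abs(cross2(p[2, ] - p[1, ], p[3, ] - p[1, ])) / 2
  })
  scale2 <- max(1, max(abs(pts))^2)
  if (any(areas <= tol * scale2)) {
    stop_traymetry("traymetry_degenerate_quad",
                   "three of the four corner points are (near-)collinear")
  }
  invisible(TRUE)
}

#' Canonicalize four corner points
#'
#' Sorts four pixel points into the canonical tray-corner order: the ring
#' around their centroid starting from the point with the smallest y (ties
#' broken by x), i.e. top-left, top-right, bottom-right, bottom-left for an
#' upright tray. The result is independent of the input permutation and the
#' operation is idempotent.
#'
#' @param points 4 x 2 matrix (or length-8 vector) of pixel points in any
#'   order; no three may be collinear.
#' @return A [corner_quad()].
#' @examples
#' canonicalize_corners(rbind(c(100, 50), c(0, 0), c(0, 50), c(100, 0)))
#' @export
canonicalize_corners <- function(points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 2, byrow = TRUE)
  if (nrow(pts) != 4 || ncol(pts) != 2) {
    stop_traymetry("traymetry_validation_error", "need exactly 4 points")
  }
  if (anyDuplicated(round(pts, 12)) > 0) {
    stop_traymetry("traymetry_degenerate_quad", "corner points must be distinct")
  }
  assert_nondegenerate_quad(unname(pts))
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  ord <- order(ang)
  pts <- pts[ord, , drop = FALSE]
  start <- order(pts[, 2], pts[, 1])[1]  # lexicographic (y, then x)
  pts <- pts[c(start:4, seq_len(start - 1))[1:4], , drop = FALSE]
  corner_quad(pts)
}

#' A single labelled fish instance
#'
#' Ground-truth annotation for one fish: an instance id, a species id, a
#' polygon mask (one or more rings, pixel coordinates), a COCO-style
#' bounding box, and optionally the mouth-to-tail size polyline.
#'
#' @param instance_id Integer id, unique within its image record.
#' @param species_id Integer species id (0-based, from the catalog).
#' @param mask List of rings (n x 2 matrices) or a single ring; pixel coords.
#' @param bbox Length-4 numeric `(x_min, y_min, width, height)`; if `NULL`,
#'   computed as the hull of the mask.
#' @param size_polyline m x 2 matrix (m >= 2) of pixel vertices from the
#'   mouth to the base of the tail, or `NULL` when not labelled.
#' @return A `fish_annotation`.
#' @export
fish_annotation <- function(instance_id, species_id, mask, bbox = NULL,
                            size_polyline = NULL) {
  mask <- as_mask(mask)
  if (is.null(bbox)) bbox <- mask_bbox(mask)
  bbox <- as.numeric(bbox)
  out <- structure(
    list(instance_id = as.integer(instance_id),
         species_id = as.integer(species_id),
         mask = mask, bbox = bbox,
         size_polyline = if (is.null(size_polyline)) NULL else
           as_polyline(size_polyline)),
    class = "fish_annotation")
  validate_instance_geometry(out)
  out
}

as_polyline <- function(p) {
  m <- if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 2, byrow = TRUE)
  if (nrow(m) < 2 || anyNA(m)) {
    stop_traymetry("traymetry_invalid_polyline",
                   "a size polyline needs >= 2 finite vertices")
  }
  storage.mode(m) <- "double"
  unname(m)
}

validate_instance_geometry <- function(inst, tol = 1e-6) {
  bbox <- inst$bbox
  if (length(bbox) != 4 || anyNA(bbox) || bbox[3] <= 0 || bbox[4] <= 0) {
    stop_traymetry("traymetry_validation_error",
                   sprintf("instance %d: bbox width/height must be > 0",
                           inst$instance_id))
  }
  hull <- mask_bbox(inst$mask)
  pad <- tol * max(1, bbox[3], bbox[4])
  if (hull[1] < bbox[1] - pad || hull[2] < bbox[2] - pad ||
      hull[1] + hull[3] > bbox[1] + bbox[3] + pad ||
      hull[2] + hull[4] > bbox[2] + bbox[4] + pad) {
    stop_traymetry("traymetry_validation_error",
                   sprintf("instance %d: bbox does not enclose the mask",
                           inst$instance_id))
  }
  for (ring in inst$mask) {
    if (ring_self_intersects(ring)) {
      stop_traymetry("traymetry_validation_error",
                     sprintf("instance %d: mask ring self-intersects",
                             inst$instance_id))
    }
  }
  invisible(TRUE)
}

#' A predicted fish instance
#'
#' Output of an external instance-segmentation model: mask, box, species
#' label and confidence score.
#'
#' @inheritParams fish_annotation
#' @param confidence Numeric confidence in `[0, 1]`.
#' @return A `detection_instance`.
#' @export
detection_instance <- function(species_id, mask, bbox = NULL, confidence = 1,
                               instance_id = NA_integer_) {
  if (!is.finite(confidence) || confidence < 0 || confidence > 1) {
    stop_traymetry("traymetry_validation_error",
                   "confidence must lie in [0, 1]")
  }
  mask <- as_mask(mask)
  if (is.null(bbox)) bbox <- mask_bbox(mask)
  out <- structure(
    list(instance_id = as.integer(instance_id),
         species_id = as.integer(species_id),
         mask = mask, bbox = as.numeric(bbox),
         confidence = as.numeric(confidence)),
    class = "detection_instance")
  validate_instance_geometry(out)
  out
}

#' One tray image with its annotations
#'
#' @param image_id Integer image id.
#' @param width_px,height_px Image dimensions in pixels.
#' @param corners A [corner_quad()] or `NULL` when the tray corners were not
#'   labelled for this image.
#' @param annotations List of [fish_annotation()] objects.
#' @return A `tray_image_record`.
#' @export
tray_image_record <- function(image_id, width_px, height_px, corners = NULL,
                              annotations = list()) {
  if (width_px <= 0 || height_px <= 0) {
    stop_traymetry("traymetry_validation_error",
                   "image dimensions must be positive")
  }
  if (!is.null(corners) && !inherits(corners, "corner_quad")) {
    corners <- corner_quad(corners)
  }
  ids <- vapply(annotations, function(a) a$instance_id, integer(1))
  if (anyDuplicated(ids)) {
    stop_traymetry("traymetry_validation_error",
                   sprintf("image %s: duplicate instance ids", image_id))
  }
  structure(list(image_id = as.integer(image_id),
                 width_px = as.numeric(width_px),
                 height_px = as.numeric(height_px),
                 corners = corners,
                 annotations = annotations),
            class = "tray_image_record")
}

#' @export
print.tray_image_record <- function(x, ...) {
  cat(sprintf("<tray_image_record> image %d (%g x %g px), %d fish, corners %s\n",
              x$image_id, x$width_px, x$height_px, length(x$annotations),
              if (is.null(x$corners)) "absent" else "present"))
  invisible(x)
}

#' @export
print.species_catalog <- function(x, ...) {
  cat(sprintf("<species_catalog> %d species\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.tray_geometry <- function(x, ...) {
  cat(sprintf("<tray_geometry> %g x %g cm\n", x$width_cm, x$height_cm))
  invisible(x)
}
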