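# Planar metrology: image pixels -> tray plane (cm) via a homography
# estimated from the four labelled tray-handle corners.

#' Estimate the image-to-tray-plane homography
#'
#' Solves the exact 4-point (8 degree-of-freedom) projective map sending the
#' labelled corner quad onto the tray rectangle, via the normalized direct
#' linear transform: both point sets are translated to their centroid and
#' isotropically scaled to RMS distance sqrt(2) before the linear solve,
#' which keeps the system well conditioned for slanted quads. Corner
#' correspondence is fixed by the canonical order: top-left -> (0, 0),
#' top-right -> (width_cm, 0), bottom-right -> (width_cm, height_cm),
#' bottom-left -> (0, height_cm).
#'
#' @param corners A [corner_quad()] in canonical order.
#' @param tray A [tray_geometry()].
#' @return A `homography`: 3 x 3 matrix (bottom-right entry normalized to 1)
#'   with attribute `ill_conditioned` (logical). A condition estimate above
#'   1e8 triggers a warning, not an error, because human-labelled corners
#'   are approximate by nature.
#' @examples
#' h <- estimate_homography(corner_quad(rbind(c(0, 0), c(600, 0),
#'                                            c(600, 400), c(0, 400))),
#'                          tray_geometry(60, 40))
#' map_points(h, c(300, 200))  # tray centre, in cm
#' @export
estimate_homography <- function(corners, tray) {
  if (!inherits(corners, "corner_quad")) corners <- corner_quad(corners)
  if (!inherits(tray, "tray_geometry")) {
    stop_traymetry("traymetry_validation_error", "tray must be a tray_geometry")
  }
  src <- unclass(corners)
  dst <- rbind(c(0, 0),
               c(tray$width_cm, 0),
               c(tray$width_cm, tray$height_cm),
               c(0, tray$height_cm))

  Ts <- normalizing_transform(src)
  Td <- normalizing_transform(dst)
  s <- apply_affine3(Ts, src)
  d <- apply_affine3(Td, dst)

  A <- matrix(0, 8, 9)
  for (i in 1:4) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]

  if (abs(det(H)) < 1e-12) {
    stop_traymetry("traymetry_degenerate_configuration",
                   "corner configuration yields a singular homography")
  }
  cond <- sv$d[1] / max(sv$d[8], .Machine$double.xmin)
  ill <- cond > 1e8
  if (ill) {
    warning("homography system is ill-conditioned (condition estimate ",
            format(cond, digits = 3), "); corner labels may be near-degenerate")
  }
  h <- structure(H, class = "homography", ill_conditioned = ill)

  resid <- max(sqrt(rowSums((map_points(h, src) - dst)^2)))
  if (resid >= 1e-6) {
    stop_traymetry("traymetry_degenerate_configuration",
                   sprintf("corner residual %.3g cm exceeds 1e-6", resid))
  }
  h
}

normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  rms <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  s <- if (rms > 0) sqrt(2) / rms else 1
  rbind(c(s, 0, -s * ctr[1]),
        c(0, s, -s * ctr[2]),
        c(0, 0, 1))
}

apply_affine3 <- function(Tm, pts) {
  out <- cbind(pts, 1) %*% t(Tm)
  out[, 1:2, drop = FALSE]
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> px -> cm",
      if (isTRUE(attr(x, "ill_conditioned"))) " (ill-conditioned)" else "",
      "\n", sep = "")
  print(unclass(x)[1:3, 1:3])
  invisible(x)
}

#' Apply a homography to points
#'
#' Standard projective action: `(x, y, 1)` is multiplied by the matrix and
#' divided by the resulting homogeneous coordinate.
#'
#' @param h A `homography`.
#' @param points n x 2 matrix (or length-2 vector) of pixel points.
#' @param tol Homogeneous coordinates with `|w|` below this are rejected
#'   (the point maps to the horizon).
#' @return n x 2 matrix of cm points.
#' @export
map_points <- function(h, points, tol = 1e-12) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 2, byrow = TRUE)
  hom <- cbind(pts, 1) %*% t(unclass(h))
  w <- hom[, 3]
  bad <- which(abs(w) <= tol)
  if (length(bad) > 0) {
    p <- pts[bad[1], ]
    stop_traymetry("traymetry_horizon_point",
                   sprintf("point (%g, %g) maps to the horizon", p[1], p[2]))
  }
  cbind(hom[, 1] / w, hom[, 2] / w)
}

#' Rectified arc length of a pixel polyline
#'
#' Maps each vertex through the homography and sums the Euclidean lengths of
#' consecutive segments. This is the fish "size": the mouth-to-tail polyline
#' measured in cm on the tray plane. Bent fish are traced by more vertices,
#' so the arc length (not the endpoint chord) is the measurement.
#'
#' @inheritParams map_points
#' @param polyline m x 2 matrix (m >= 2) of pixel vertices.
#' @return Length in cm.
#' @export
polyline_length_cm <- function(h, polyline) {
  p <- as_polyline(polyline)
  q <- map_points(h, p)
  sum(sqrt(rowSums(diff(q)^2)))
}

#' Rectify one annotation into centimetres
#'
#' Produces the ground-truth size entry for one fish: the polyline length,
#' the shoelace area of the mapped mask (holes subtracted), and the
#' axis-aligned hull of the mapped mask in cm. Mask vertices are mapped
#' individually; segments between them are treated as straight in cm space,
#' which is exact for the map restricted to lines through adjacent vertices
#' and accurate for the vertex densities of practical labels.
#'
#' @inheritParams map_points
#' @param ann A [fish_annotation()] with a size polyline.
#' @return One-row data frame: `instance_id`, `species_id`, `length_cm`,
#'   `area_cm2`, `bbox_x`, `bbox_y`, `bbox_w`, `bbox_h` (cm).
#' @export
rectify_annotation <- function(h, ann) {
  if (is.null(ann$size_polyline)) {
    stop_traymetry("traymetry_invalid_polyline",
                   sprintf("instance %d has no size polyline", ann$instance_id))
  }
  len <- polyline_length_cm(h, ann$size_polyline)
  signs <- ring_signs(ann$mask)
  mapped <- lapply(ann$mask, function(r) map_points(h, r))
  area <- sum(signs * abs(vapply(mapped, ring_area_signed, numeric(1))))
  bb <- mask_bbox(mapped)
  data.frame(instance_id = ann$instance_id, species_id = ann$species_id,
             length_cm = len, area_cm2 = area,
             bbox_x = bb[1], bbox_y = bb[2], bbox_w = bb[3], bbox_h = bb[4])
}

#' Ground-truth sizes for a whole record
#'
#' Estimates the record's homography from its tray corners and rectifies
#' every annotation, yielding the cm sizes used as the regression target.
#'
#' @param record A [tray_image_record()] with labelled corners.
#' @param tray A [tray_geometry()].
#' @return Data frame with one row per annotation (order preserved), columns
#'   as in [rectify_annotation()] plus `image_id`.
#' @export
ground_truth_sizes <- function(record, tray) {
  if (is.null(record$corners)) {
    stop_traymetry("traymetry_missing_calibration",
                   sprintf("image %d has no labelled tray corners",
                           record$image_id))
  }
  h <- estimate_homography(record$corners, tray)
  if (length(record$annotations) == 0) {
    return(data.frame(image_id = integer(0), instance_id = integer(0),
                      species_id = integer(0), length_cm = numeric(0),
                      area_cm2 = numeric(0), bbox_x = numeric(0),
                      bbox_y = numeric(0), bbox_w = numeric(0),
                      bbox_h = numeric(0)))
  }
  rows <- lapply(record$annotations, function(a) rectify_annotation(h, a))
  out <- do.call(rbind, rows)
  cbind(image_id = record$image_id, out)
}
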