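# Planar polygon primitives shared by metrology, evaluation and augmentation.
#
# A "mask" is a list of rings, each ring an n x 2 numeric matrix of vertices
# (pixel or cm coordinates, implicitly closed). Rings nested inside an odd
# number of other rings are holes (even-odd rule, as COCO polygon sets are
# interpreted). Boolean operations are delegated to polyclip (Vatti clipper).

as_ring <- function(v) {
  if (is.matrix(v)) {
    m <- v
  } else {
    m <- matrix(as.numeric(v), ncol = 2, byrow = TRUE)
  }
  if (ncol(m) != 2 || nrow(m) < 3 || anyNA(m)) {
    stop_traymetry("traymetry_validation_error",
                   "a polygon ring needs >= 3 finite (x, y) vertices")
  }
  storage.mode(m) <- "double"
  unname(m)
}

as_mask <- function(mask) {
  if (is.matrix(mask) || (is.numeric(mask) && !is.list(mask))) mask <- list(mask)
  lapply(mask, as_ring)
}

# Signed shoelace area; sign depends on vertex order (y grows downward in
# image coordinates, so visually clockwise rings come out positive).
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Even-odd point-in-ring (crossing number), vectorized over query points.
points_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    k <- j[i]
    crosses <- ((y[i] > py) != (y[k] > py))
    if (any(crosses)) {
      xi <- x[i] + (py[crosses] - y[i]) * (x[k] - x[i]) / (y[k] - y[i])
      inside[crosses] <- xor(inside[crosses], xi > px[crosses])
    }
  }
  inside
}

# +1 for outer rings, -1 for holes (even-odd nesting depth).
ring_signs <- function(mask) {
  n <- length(mask)
  if (n == 1L) return(1)
  vapply(seq_len(n), function(i) {
    p <- mask[[i]][1, ]
    depth <- sum(vapply(seq_len(n)[-i], function(j) {
      points_in_ring(p[1], p[2], mask[[j]])
    }, logical(1)))
    if (depth %% 2 == 0) 1 else -1
  }, numeric(1))
}

# Area of the region a ring set encloses, holes subtracted.
mask_area <- function(mask) {
  mask <- as_mask(mask)
  signs <- ring_signs(mask)
  sum(signs * abs(vapply(mask, ring_area_signed, numeric(1))))
}

mask_bbox <- function(mask) {
  mask <- as_mask(mask)
  xs <- unlist(lapply(mask, function(r) r[, 1]))
  ys <- unlist(lapply(mask, function(r) r[, 2]))
  c(min(xs), min(ys), max(xs) - min(xs), max(ys) - min(ys))
}

mask_to_pc <- function(mask) {
  lapply(as_mask(mask), function(r) list(x = r[, 1], y = r[, 2]))
}

pc_area <- function(rings) {
  if (length(rings) == 0) return(0)
  # Vatti output orients holes opposite to outers: the signed sum nets out.
  abs(sum(vapply(rings, function(r) {
    ring_area_signed(cbind(r$x, r$y))
  }, numeric(1))))
}

# Area of the intersection of two even-odd polygon regions.
mask_intersection_area <- function(a, b) {
  out <- polyclip::polyclip(mask_to_pc(a), mask_to_pc(b), op = "intersection",
                            fillA = "evenodd", fillB = "evenodd")
  pc_area(out)
}

bbox_overlaps <- function(a, b, tol = 0) {
  !(a[1] + a[3] < b[1] - tol || b[1] + b[3] < a[1] - tol ||
    a[2] + a[4] < b[2] - tol || b[2] + b[4] < a[2] - tol)
}

# Quick self-intersection scan for a single ring: O(n^2) over non-adjacent
# edge pairs. Sufficient for labelling-scale polygons.
ring_self_intersects <- function(ring, tol = 1e-12) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  p <- ring
  q <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_cross(p[i, ], q[i, ], p[j, ], q[j, ], tol)) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a1, a2, b1, b2, tol = 1e-12) {
  d1 <- cross2(b2 - b1, a1 - b1)
  d2 <- cross2(b2 - b1, a2 - b1)
  d3 <- cross2(a2 - a1, b1 - a1)
  d4 <- cross2(a2 - a1, b2 - a1)
  (d1 * d2 < -tol) && (d3 * d4 < -tol)
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]
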