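# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry/matching code paths: point-in-polygon rasterization
# for areas and IoU, direct formula evaluation for homographies, explicit
# rank-by-rank PR construction for AP, exhaustive enumeration for plans.

# Even-odd point-in-region test (crossing parity over all rings).
oracle_points_in_mask <- function(px, py, rings) {
  crossings <- rep(0L, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      cond <- (y[i] > py) != (y[j] > py)
      if (any(cond)) {
        xint <- x[i] + (py[cond] - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
        hit <- cond
        hit[cond] <- xint > px[cond]
        crossings[hit] <- crossings[hit] + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

# Grid-counting area of a polygon region (cell centres, even-odd).
oracle_raster_area <- function(rings, cell = 0.1) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  gx <- seq(min(xs) + cell / 2, max(xs), by = cell)
  gy <- seq(min(ys) + cell / 2, max(ys), by = cell)
  grid <- expand.grid(x = gx, y = gy)
  sum(oracle_points_in_mask(grid$x, grid$y, rings)) * cell^2
}

# Grid-counting IoU of two regions over their joint bounding box.
oracle_raster_iou <- function(a, b, cell = 0.05) {
  xs <- unlist(lapply(c(a, b), function(r) r[, 1]))
  ys <- unlist(lapply(c(a, b), function(r) r[, 2]))
  gx <- seq(min(xs) + cell / 2, max(xs), by = cell)
  gy <- seq(min(ys) + cell / 2, max(ys), by = cell)
  grid <- expand.grid(x = gx, y = gy)
  ina <- oracle_points_in_mask(grid$x, grid$y, a)
  inb <- oracle_points_in_mask(grid$x, grid$y, b)
  sum(ina & inb) / sum(ina | inb)
}

# Direct homogeneous multiply-and-divide, scalar per point.
oracle_apply_homography <- function(H, pts) {
  t(apply(pts, 1, function(p) {
    v <- H %*% c(p, 1)
    c(v[1] / v[3], v[2] / v[3])
  }))
}

# A random mild projective map cm -> px (invertible, convexity-preserving
# over the tray for these parameter ranges).
oracle_random_projective <- function(pmax = 5e-4) {
  s <- runif(1, 5, 20)
  th <- runif(1, -pi / 6, pi / 6)
  shear <- runif(1, -0.2, 0.2)
  tx <- runif(1, 50, 400); ty <- runif(1, 50, 400)
  p1 <- runif(1, -pmax, pmax); p2 <- runif(1, -pmax, pmax)
  A <- rbind(c(s * cos(th), -s * sin(th) + shear, tx),
             c(s * sin(th), s * cos(th), ty),
             c(p1, p2, 1))
  A
}

# Reference AP: explicit precision/recall table, then 101-point grid with a
# plain loop over ranks (no envelope trick).
oracle_ap <- function(conf, is_tp, n_gt) {
  ord <- order(-conf, seq_along(conf))
  tp <- is_tp[ord]
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_gt
  vals <- sapply(seq(0, 1, by = 0.01), function(r) {
    ok <- which(rec >= r)
    if (length(ok) == 0) return(0)
    max(prec[min(ok):length(prec)])
  })
  mean(vals)
}

# Reference matching: literal restatement of the rule with scalar loops.
oracle_match <- function(conf, species_pred, species_gt, iou, threshold,
                         class_agnostic) {
  taken <- rep(FALSE, length(species_gt))
  pairs <- NULL
  for (i in order(-conf, seq_along(conf))) {
    best_j <- 0; best_iou <- -1
    for (j in seq_along(species_gt)) {
      if (taken[j]) next
      if (!class_agnostic && species_pred[i] != species_gt[j]) next
      if (iou[i, j] < threshold) next
      if (iou[i, j] > best_iou) { best_iou <- iou[i, j]; best_j <- j }
    }
    if (best_j > 0) {
      taken[best_j] <- TRUE
      pairs <- rbind(pairs, c(i, best_j))
    }
  }
  pairs
}

# Exhaustive augmentation-plan search on tiny datasets: the minimal number
# of per-image copies reaching the target ratio (within budgets), tie-broken
# by the smallest achieved ratio.
oracle_best_plan <- function(base, img_counts, target, max_per_image,
                             total_budget) {
  ratio <- function(cnt) {
    pos <- cnt[cnt > 0]
    if (length(pos) == 0) NA_real_ else max(pos) / min(pos)
  }
  n <- length(img_counts)
  best <- list(ops = Inf, ratio = ratio(base))
  grid <- expand.grid(rep(list(0:max_per_image), n))
  for (r in seq_len(nrow(grid))) {
    mult <- as.numeric(grid[r, ])
    if (sum(mult) > total_budget) next
    cnt <- base
    for (i in seq_len(n)) cnt <- cnt + mult[i] * img_counts[[i]]
    rt <- ratio(cnt)
    if (rt <= target) {
      if (sum(mult) < best$ops ||
          (sum(mult) == best$ops && rt < best$ratio)) {
        best <- list(ops = sum(mult), ratio = rt, mult = mult)
      }
    }
  }
  best
}
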