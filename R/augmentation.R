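# Annotation-level augmentation: rotations about the image centre plus
# translations, and a greedy planner that chooses per-image augmentation
# multiplicities so that per-species instance counts end up as close as the
# tray composition permits (species co-occur within trays, so exact balance
# is generally impossible).

#' Augmentation operation configuration
#'
#' The allowed operation space: a discrete rotation set and a translation
#' magnitude range (pixels per axis).
#'
#' @param rotations_deg Allowed rotation angles (degrees).
#' @param translation_px Two-element range of allowed `|dx|`, `|dy|`.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(rotations_deg = c(15, 45, 90, 135, 180,
                                                  225, 270, 315),
                                translation_px = c(5, 50)) {
  structure(list(rotations_deg = rotations_deg,
                 translation_px = sort(translation_px)),
            class = "augmentation_config")
}

#' A single augmentation operation
#'
#' @param rotation_deg Rotation angle (degrees, about the image centre).
#' @param dx,dy Translation in pixels (applied after the rotation).
#' @param config An [augmentation_config()]; the op must lie in its ranges.
#'   `rotation_deg = 0, dx = dy = 0` (the identity) is always allowed.
#' @return An `augmentation_op`.
#' @export
augmentation_op <- function(rotation_deg, dx = 0, dy = 0,
                            config = augmentation_config()) {
  identity_op <- rotation_deg == 0 && dx == 0 && dy == 0
  if (!identity_op) {
    rot_ok <- rotation_deg == 0 || rotation_deg %in% config$rotations_deg
    tr <- config$translation_px
    t_ok <- function(v) v == 0 || (abs(v) >= tr[1] && abs(v) <= tr[2])
    if (!rot_ok || !t_ok(dx) || !t_ok(dy)) {
      stop_traymetry("traymetry_invalid_op",
                     sprintf("op (rot %g, dx %g, dy %g) outside configured ranges",
                             rotation_deg, dx, dy))
    }
  }
  structure(list(rotation_deg = rotation_deg, dx = dx, dy = dy),
            class = "augmentation_op")
}

op_affine <- function(op, width_px, height_px) {
  th <- op$rotation_deg * pi / 180
  c0 <- c(width_px / 2, height_px / 2)
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c0 - R %*% c0 + c(op$dx, op$dy)
  list(R = R, t = as.numeric(shift))
}

apply_affine_pts <- function(aff, pts) {
  sweep(pts %*% t(aff$R), 2, -aff$t)
}

#' Apply an augmentation operation to a record
#'
#' Rotates all geometry (masks, polylines, boxes, corners) about the image
#' centre, then translates. Boxes are recomputed as the hull of the
#' transformed mask. Instances whose in-canvas mask area falls below
#' `visibility` times their full area are dropped; retained instances keep
#' their full geometry (renderers clip at the canvas). The image size is
#' unchanged.
#'
#' @param record A [tray_image_record()].
#' @param op An [augmentation_op()].
#' @param visibility Minimum retained in-canvas area fraction (default 0.5).
#' @return The transformed `tray_image_record`.
#' @export
apply_op <- function(record, op, visibility = 0.5) {
  if (!inherits(op, "augmentation_op")) {
    stop_traymetry("traymetry_invalid_op", "op must be an augmentation_op")
  }
  aff <- op_affine(op, record$width_px, record$height_px)
  canvas <- list(list(x = c(0, record$width_px, record$width_px, 0),
                      y = c(0, 0, record$height_px, record$height_px)))
  anns <- list()
  for (a in record$annotations) {
    mask <- lapply(a$mask, function(r) apply_affine_pts(aff, r))
    full <- mask_area(mask)
    vis <- pc_area(polyclip::polyclip(mask_to_pc(mask), canvas,
                                      op = "intersection",
                                      fillA = "evenodd", fillB = "evenodd"))
    if (full <= 0 || vis / full < visibility) next
    b <- a
    b$mask <- mask
    b$bbox <- mask_bbox(mask)
    if (!is.null(b$size_polyline)) {
      b$size_polyline <- apply_affine_pts(aff, b$size_polyline)
    }
    anns[[length(anns) + 1]] <- b
  }
  corners <- record$corners
  if (!is.null(corners)) {
    pts <- apply_affine_pts(aff, unclass(corners))
    # keep the transformed ring order (round-trips compose exactly);
    # re-canonicalize explicitly if the metric orientation is needed
    corners <- structure(pts, class = "corner_quad")
  }
  out <- record
  out$corners <- corners
  out$annotations <- anns
  out
}

#' Invert an augmentation operation
#'
#' The inverse of "rotate by theta about the centre, then translate by d" is
#' "rotate by -theta about the centre, then translate by -R(-theta) d" — the
#' same parametric family, so [apply_op()] applies it directly. The inverse
#' translation is exempt from the configured magnitude ranges.
#'
#' @param op An [augmentation_op()].
#' @return The inverse `augmentation_op`.
#' @export
invert_op <- function(op) {
  th <- -op$rotation_deg * pi / 180
  Rinv <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  d <- -as.numeric(Rinv %*% c(op$dx, op$dy))
  structure(list(rotation_deg = -op$rotation_deg, dx = d[1], dy = d[2]),
            class = "augmentation_op")
}

#' Per-species instance counts
#' @param records List of [tray_image_record()]s.
#' @param catalog A [species_catalog()].
#' @return Named integer vector, catalog order.
#' @export
species_counts <- function(records, catalog) {
  counts <- setNames(integer(nrow(catalog)), catalog$name)
  for (rec in records) {
    for (a in rec$annotations) {
      counts[a$species_id + 1] <- counts[a$species_id + 1] + 1L
    }
  }
  counts
}

balance_ratio <- function(counts) {
  pos <- counts[counts > 0]
  if (length(pos) == 0) return(NA_real_)
  max(pos) / min(pos)
}

#' Plan class-balancing augmentation
#'
#' Greedy planner: while the balance ratio (max over min per-species count,
#' over species present in the data) exceeds `target_ratio` and budget
#' remains, augment once the image whose extra copy most reduces the ratio
#' (ties broken by lowest image index). The loop also stops when no single
#' augmentation strictly reduces the ratio, so the achieved ratio never
#' exceeds the initial one. Rotation angles are drawn round-robin from the
#' configured set; translations are sampled uniformly from the configured
#' magnitude range with the given seed.
#'
#' @param records List of [tray_image_record()]s.
#' @param catalog A [species_catalog()].
#' @param config An [augmentation_config()] (the op space).
#' @param target_ratio Stop once max/min count <= this.
#' @param max_per_image Per-image cap on planned ops.
#' @param total_budget Total cap on planned ops.
#' @param seed Seed for translation sampling.
#' @return An `augmentation_plan`: `ops` (data frame `image_index`,
#'   `rotation_deg`, `dx`, `dy`), `base_counts`, `achieved_counts`,
#'   `initial_ratio`, `achieved_ratio`, `unbalanceable` (species names with
#'   zero instances anywhere, which no augmentation can balance).
#' @export
plan_balanced_augmentation <- function(records, catalog,
                                       config = augmentation_config(),
                                       target_ratio = 2, max_per_image = 20,
                                       total_budget = 200, seed = 1) {
  if (length(records) == 0) {
    stop_traymetry("traymetry_validation_error", "no records to balance")
  }
  base <- species_counts(records, catalog)
  if (sum(base) == 0) {
    stop_traymetry("traymetry_validation_error", "dataset has no instances")
  }
  unbalanceable <- names(base)[base == 0]
  if (length(unbalanceable) > 0) {
    warning("species present in zero images cannot be balanced: ",
            paste(unbalanceable, collapse = ", "))
  }
  img_counts <- lapply(records, function(r) species_counts(list(r), catalog))
  counts <- base
  per_image <- integer(length(records))
  ineligible <- rep(FALSE, length(records))
  rot_set <- config$rotations_deg
  tr <- config$translation_px
  set.seed(seed)
  op_rows <- list()
  n_drawn <- 0L
  # mean of the 3 smallest present-species counts: the secondary objective
  # that lets the planner make progress when several distinct rare species
  # pin the max/min ratio in place
  bottom <- function(cnt) {
    pos <- sort(cnt[cnt > 0])
    mean(pos[seq_len(min(3, length(pos)))])
  }
  while (length(op_rows) < total_budget &&
         isTRUE(balance_ratio(counts) > target_ratio)) {
    cand <- which(per_image < max_per_image & !ineligible)
    if (length(cand) == 0) break
    # rank candidates by the ratio their full instance set would give,
    # then by how much they lift the rarest species
    ratios <- vapply(cand, function(i)
      balance_ratio(counts + img_counts[[i]]), numeric(1))
    bottoms <- vapply(cand, function(i)
      bottom(counts + img_counts[[i]]), numeric(1))
    best <- cand[order(ratios, -bottoms, cand)][1]
    k <- match(best, cand)
    cur_ratio <- balance_ratio(counts)
    if (!(ratios[k] < cur_ratio ||
          (ratios[k] <= cur_ratio && bottoms[k] > bottom(counts)))) break
    # draw the concrete op, apply it, and book the surviving instances —
    # a fish clipped off the canvas must not be counted
    n_drawn <- n_drawn + 1L
    op <- augmentation_op(
      rot_set[(n_drawn - 1L) %% length(rot_set) + 1L],
      sample(c(-1, 1), 1) * runif(1, tr[1], tr[2]),
      sample(c(-1, 1), 1) * runif(1, tr[1], tr[2]), config)
    add <- species_counts(list(apply_op(records[[best]], op)), catalog)
    new_ratio <- balance_ratio(counts + add)
    if (new_ratio < cur_ratio ||
        (new_ratio <= cur_ratio && bottom(counts + add) > bottom(counts))) {
      per_image[best] <- per_image[best] + 1L
      counts <- counts + add
      op_rows[[length(op_rows) + 1]] <- data.frame(
        image_index = best, rotation_deg = op$rotation_deg,
        dx = op$dx, dy = op$dy)
    } else {
      ineligible[best] <- TRUE
    }
  }
  ops <- if (length(op_rows) > 0) do.call(rbind, op_rows) else
    data.frame(image_index = integer(0), rotation_deg = numeric(0),
               dx = numeric(0), dy = numeric(0))
  structure(list(ops = ops, base_counts = base, achieved_counts = counts,
                 initial_ratio = balance_ratio(base),
                 achieved_ratio = balance_ratio(counts),
                 target_ratio = target_ratio,
                 unbalanceable = unbalanceable, config = config, seed = seed),
            class = "augmentation_plan")
}

#' Replay an augmentation plan
#'
#' Applies every planned op to its image, returning the augmented records
#' (originals followed by augmented copies with fresh image ids).
#'
#' @param plan An `augmentation_plan`.
#' @param records The records the plan was computed for.
#' @param visibility Passed to [apply_op()].
#' @return List of `tray_image_record`s.
#' @export
apply_plan <- function(plan, records, visibility = 0.5) {
  out <- records
  next_id <- max(vapply(records, function(r) r$image_id, integer(1))) + 1L
  cfg <- plan$config
  for (i in seq_len(nrow(plan$ops))) {
    row <- plan$ops[i, ]
    op <- augmentation_op(row$rotation_deg, row$dx, row$dy, cfg)
    rec <- apply_op(records[[row$image_index]], op, visibility)
    rec$image_id <- next_id
    next_id <- next_id + 1L
    out[[length(out) + 1]] <- rec
  }
  out
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat(sprintf(
    "<augmentation_plan> %d ops; ratio %.3g -> %.3g (target %.3g)\n",
    nrow(x$ops), x$initial_ratio, x$achieved_ratio, x$target_ratio))
  invisible(x)
}
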