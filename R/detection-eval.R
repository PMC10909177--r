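# Mask-level detection evaluation: polygon IoU, confidence-greedy one-to-one
# matching, 101-point interpolated AP / mAP over IoU thresholds, confusion
# matrices with an explicit Missed (FN) column, per-class F1.

#' Mask intersection-over-union
#'
#' IoU of two polygon regions, computed on the polygon geometry itself
#' (resolution-independent), holes handled even-odd.
#'
#' @param a,b Masks: lists of rings (n x 2 matrices) or single rings.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  aa <- mask_area(a); ab <- mask_area(b)
  if (aa <= 0 || ab <= 0) {
    stop_traymetry("traymetry_empty_mask", "mask with zero area")
  }
  if (!bbox_overlaps(mask_bbox(a), mask_bbox(b))) return(0)
  inter <- mask_intersection_area(a, b)
  uni <- aa + ab - inter
  if (uni <= 0) return(0)
  min(1, inter / uni)
}

# IoU matrix between predictions and ground truths of one image, with a
# bounding-box pre-filter (disjoint boxes -> IoU 0 without clipping).
iou_matrix <- function(preds, gts) {
  m <- matrix(0, length(preds), length(gts))
  if (length(preds) == 0 || length(gts) == 0) return(m)
  pb <- lapply(preds, function(p) mask_bbox(p$mask))
  gb <- lapply(gts, function(g) mask_bbox(g$mask))
  for (i in seq_along(preds)) {
    for (j in seq_along(gts)) {
      if (bbox_overlaps(pb[[i]], gb[[j]])) {
        m[i, j] <- mask_iou(preds[[i]]$mask, gts[[j]]$mask)
      }
    }
  }
  m
}

#' Match predicted instances to ground truth
#'
#' Greedy one-to-one matching in descending confidence order: each
#' prediction claims its highest-IoU still-unmatched ground truth with
#' IoU >= `iou_threshold` (restricted to its own class unless
#' `class_agnostic`). Deterministic tie-breaks: equal confidences by lower
#' prediction index, equal IoUs by lower ground-truth index.
#'
#' @param preds List of [detection_instance()]s (one image).
#' @param gts List of [fish_annotation()]s (same image).
#' @param iou_threshold Acceptance threshold in (0, 1).
#' @param class_agnostic Ignore class labels when matching (used for the
#'   confusion matrix, so misclassified-but-detected fish stay visible).
#' @param iou_mat Optional precomputed [iou_matrix()].
#' @return A `match_result`: data frame `pairs` (`pred`, `gt`, `iou`),
#'   integer vectors `unmatched_gt` (false negatives) and `unmatched_pred`
#'   (false positives), and the threshold.
#' @export
match_instances <- function(preds, gts, iou_threshold = 0.5,
                            class_agnostic = FALSE, iou_mat = NULL) {
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop_traymetry("traymetry_validation_error",
                   "iou_threshold must lie in (0, 1)")
  }
  if (is.null(iou_mat)) iou_mat <- iou_matrix(preds, gts)
  conf <- vapply(preds, function(p) p$confidence, numeric(1))
  ord <- order(-conf, seq_along(preds))
  gt_free <- rep(TRUE, length(gts))
  pairs <- list()
  for (i in ord) {
    elig <- which(gt_free & iou_mat[i, ] >= iou_threshold)
    if (!class_agnostic && length(elig) > 0) {
      same <- vapply(elig, function(j)
        gts[[j]]$species_id == preds[[i]]$species_id, logical(1))
      elig <- elig[same]
    }
    if (length(elig) == 0) next
    best <- elig[order(-iou_mat[i, elig], elig)][1]
    gt_free[best] <- FALSE
    pairs[[length(pairs) + 1]] <- data.frame(pred = i, gt = best,
                                             iou = iou_mat[i, best])
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  structure(list(pairs = pairs,
                 unmatched_gt = which(gt_free),
                 unmatched_pred = setdiff(seq_along(preds), pairs$pred),
                 iou_threshold = iou_threshold,
                 class_agnostic = class_agnostic),
            class = "match_result")
}

# Pool class-wise TP/FP flags over images, in global descending-confidence
# order (standard detection-AP bookkeeping).
class_tp_fp <- function(detections, records, species_id, iou_threshold,
                        iou_mats = NULL) {
  rows <- list()
  n_gt <- 0
  for (r in seq_along(records)) {
    rec <- records[[r]]
    dets <- detections[[as.character(rec$image_id)]] %||% list()
    keep <- which(vapply(dets, function(d) d$species_id, integer(1)) ==
                    species_id)
    gt_keep <- which(vapply(rec$annotations, function(a) a$species_id,
                            integer(1)) == species_id)
    n_gt <- n_gt + length(gt_keep)
    if (length(keep) == 0) next
    sub_preds <- dets[keep]
    sub_gts <- rec$annotations[gt_keep]
    sub_iou <- if (!is.null(iou_mats)) {
      iou_mats[[r]][keep, gt_keep, drop = FALSE]
    } else {
      iou_matrix(sub_preds, sub_gts)
    }
    mr <- match_instances(sub_preds, sub_gts, iou_threshold,
                          class_agnostic = TRUE, iou_mat = sub_iou)
    tp <- seq_along(sub_preds) %in% mr$pairs$pred
    rows[[length(rows) + 1]] <- data.frame(
      conf = vapply(sub_preds, function(d) d$confidence, numeric(1)),
      tp = tp)
  }
  flags <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(conf = numeric(0), tp = logical(0))
  flags <- flags[order(-flags$conf), , drop = FALSE]
  list(flags = flags, n_gt = n_gt)
}

#' Average precision for one species
#'
#' Predictions of the class are pooled over all images and sorted by
#' confidence; TP/FP flags come from per-image one-to-one matching at the
#' IoU threshold; AP is the 101-point interpolated mean of best precision
#' at recalls 0, 0.01, ..., 1 (the dominant mask-AP convention).
#'
#' @param detections Named list (by image id) of [detection_instance()]
#'   lists.
#' @param records List of [tray_image_record()]s (ground truth).
#' @param species_id Class to evaluate; must have at least one ground-truth
#'   instance.
#' @param iou_threshold Acceptance IoU in (0, 1).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(detections, records, species_id,
                              iou_threshold = 0.5) {
  pooled <- class_tp_fp(detections, records, species_id, iou_threshold)
  if (pooled$n_gt == 0) {
    stop_traymetry("traymetry_undefined_ap",
                   sprintf("no ground-truth instances of species %d",
                           species_id))
  }
  ap_from_flags(pooled$flags$tp, pooled$n_gt)
}

ap_from_flags <- function(tp, n_gt) {
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_gt
  # best precision at recall >= r, for r on the 101-point grid
  rgrid <- seq(0, 1, by = 0.01)
  # precision envelope from the right
  prec_env <- rev(cummax(rev(precision)))
  ap_vals <- vapply(rgrid, function(r) {
    idx <- which(recall >= r)
    if (length(idx) == 0) 0 else prec_env[idx[1]]
  }, numeric(1))
  mean(ap_vals)
}

#' mAP across a sweep of IoU thresholds
#'
#' Mean over classes (with at least one ground-truth instance) of per-class
#' AP, evaluated at each threshold. Classes with zero ground truth are
#' skipped and recorded.
#'
#' @inheritParams average_precision
#' @param catalog A [species_catalog()].
#' @param thresholds Strictly increasing IoU thresholds in (0, 1).
#' @return Data frame `iou_threshold`, `map` plus attributes
#'   `per_class` (matrix class x threshold) and `skipped_species`.
#' @export
map_curve <- function(detections, records, catalog,
                      thresholds = c(0.5, 0.6, 0.7)) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1)) {
    stop_traymetry("traymetry_validation_error",
                   "thresholds must be strictly increasing in (0, 1)")
  }
  # one IoU matrix per image, shared across thresholds and classes
  iou_mats <- lapply(records, function(rec) {
    iou_matrix(detections[[as.character(rec$image_id)]] %||% list(),
               rec$annotations)
  })
  gt_species <- unlist(lapply(records, function(rec)
    vapply(rec$annotations, function(a) a$species_id, integer(1))))
  present <- intersect(catalog$species_id, gt_species)
  skipped <- setdiff(catalog$species_id, present)
  per_class <- matrix(NA_real_, length(present), length(thresholds),
                      dimnames = list(as.character(present),
                                      as.character(thresholds)))
  for (sp in present) {
    for (t in seq_along(thresholds)) {
      pooled <- class_tp_fp(detections, records, sp, thresholds[t], iou_mats)
      per_class[as.character(sp), t] <- ap_from_flags(pooled$flags$tp,
                                                      pooled$n_gt)
    }
  }
  out <- data.frame(iou_threshold = thresholds,
                    map = colMeans(per_class))
  attr(out, "per_class") <- per_class
  attr(out, "skipped_species") <- skipped
  out
}

#' Confusion matrix with a Missed (FN) column
#'
#' Rows are ground-truth species, columns are predicted species plus a final
#' `"Missed (FN)"` column. Matching is class-agnostic (at `iou_threshold`),
#' so a detected-but-misclassified fish lands off-diagonal rather than
#' vanishing; an unmatched ground truth lands in the FN column. Rows are
#' normalized to percentages; rows with zero ground-truth instances are
#' all-zero and listed in the `empty_rows` attribute.
#'
#' @inheritParams map_curve
#' @param iou_threshold IoU acceptance for the class-agnostic matching.
#' @return A `|catalog| x (|catalog| + 1)` matrix of row percentages with
#'   attributes `counts` (raw integer matrix) and `empty_rows`.
#' @export
confusion_with_fn <- function(detections, records, catalog,
                              iou_threshold = 0.5) {
  ncls <- nrow(catalog)
  counts <- matrix(0L, ncls, ncls + 1,
                   dimnames = list(catalog$name,
                                   c(catalog$name, "Missed (FN)")))
  for (rec in records) {
    dets <- detections[[as.character(rec$image_id)]] %||% list()
    mr <- match_instances(dets, rec$annotations, iou_threshold,
                          class_agnostic = TRUE)
    for (p in seq_len(nrow(mr$pairs))) {
      g_sp <- rec$annotations[[mr$pairs$gt[p]]]$species_id
      p_sp <- dets[[mr$pairs$pred[p]]]$species_id
      counts[g_sp + 1, p_sp + 1] <- counts[g_sp + 1, p_sp + 1] + 1L
    }
    for (g in mr$unmatched_gt) {
      g_sp <- rec$annotations[[g]]$species_id
      counts[g_sp + 1, ncls + 1] <- counts[g_sp + 1, ncls + 1] + 1L
    }
  }
  totals <- rowSums(counts)
  pct <- counts * 0
  nz <- totals > 0
  pct[nz, ] <- 100 * counts[nz, , drop = FALSE] / totals[nz]
  structure(pct, counts = counts, empty_rows = rownames(counts)[!nz],
            class = c("confusion_with_fn", "matrix"))
}

#' Per-class F1 score
#'
#' TP / FP / FN per class under class-aware matching at the threshold;
#' `F1 = 2 TP / (2 TP + FP + FN)`. A class with no ground truth and no
#' predictions has undefined F1 (`NA`).
#'
#' @inheritParams confusion_with_fn
#' @return Data frame `species_id`, `name`, `tp`, `fp`, `fn`, `f1`.
#' @export
per_class_f1 <- function(detections, records, catalog, iou_threshold = 0.5) {
  ncls <- nrow(catalog)
  tp <- fp <- fn <- integer(ncls)
  for (rec in records) {
    dets <- detections[[as.character(rec$image_id)]] %||% list()
    mr <- match_instances(dets, rec$annotations, iou_threshold,
                          class_agnostic = FALSE)
    for (p in seq_len(nrow(mr$pairs))) {
      sp <- dets[[mr$pairs$pred[p]]]$species_id
      tp[sp + 1] <- tp[sp + 1] + 1L
    }
    for (i in mr$unmatched_pred) {
      sp <- dets[[i]]$species_id
      fp[sp + 1] <- fp[sp + 1] + 1L
    }
    for (g in mr$unmatched_gt) {
      sp <- rec$annotations[[g]]$species_id
      fn[sp + 1] <- fn[sp + 1] + 1L
    }
  }
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom > 0, 2 * tp / denom, NA_real_)
  data.frame(species_id = catalog$species_id, name = catalog$name,
             tp = tp, fp = fp, fn = fn, f1 = f1)
}
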