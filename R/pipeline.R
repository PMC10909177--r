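# End-to-end dataflow. Training: labelled records -> homography ground-truth
# sizes -> pixel features -> cross-validated report + final regressor.
# Inference: external detections -> pixel features -> sizes (-> weights).
# Inference never touches tray corners: the calibration lives entirely in
# the training targets.

#' Train the size-regression pipeline
#'
#' Chains [ground_truth_sizes()] over all records, [dataset_features()],
#' [kfold_evaluate()] and a final [train_size_regressor()] on the full
#' dataset. Stage-level progress (record and instance counts, seed) is
#' logged via `message()`.
#'
#' @param records List of [tray_image_record()]s with corners and size
#'   polylines.
#' @param tray A [tray_geometry()].
#' @param catalog A [species_catalog()].
#' @param model,scheme,k,repeats,base_seed,params Passed to
#'   [kfold_evaluate()] / [train_size_regressor()].
#' @param include_corners Train the calibrated variant (corner coordinates
#'   as extra features).
#' @param evaluate Run the repeated k-fold evaluation (set `FALSE` to train
#'   only).
#' @return List: `model` (a `size_model`), `report` (a
#'   `regression_report` or `NULL`), `sizes` (the ground-truth size table),
#'   `features`.
#' @export
run_training <- function(records, tray, catalog, model = "gbt",
                         scheme = "minmax_input", k = 10, repeats = 10,
                         base_seed = 1, include_corners = FALSE,
                         evaluate = TRUE, params = list()) {
  sizes <- lapply(records, function(rec) {
    tryCatch(ground_truth_sizes(rec, tray), traymetry_error = function(e) {
      stop_traymetry(class(e)[1],
                     sprintf("[stage gt-sizes, image %d] %s", rec$image_id,
                             conditionMessage(e)))
    })
  })
  sizes <- do.call(rbind, sizes)
  message(sprintf("[gt-sizes] %d records -> %d ground-truth sizes",
                  length(records), nrow(sizes)))

  feats <- dataset_features(records, catalog, include_corners)
  stopifnot(nrow(feats$features) == nrow(sizes))
  message(sprintf("[features] %d x %d feature matrix (%s)",
                  nrow(feats$features), ncol(feats$features),
                  if (include_corners) "calibrated" else "uncalibrated"))

  report <- NULL
  if (evaluate) {
    report <- kfold_evaluate(feats$features, sizes$length_cm, model, scheme,
                             k = k, repeats = repeats, base_seed = base_seed,
                             params = params)
    message(sprintf("[eval] %dx%d-fold %s: MAE %.4f cm", repeats, k, model,
                    report$mae_cm))
  }
  fitted <- train_size_regressor(feats$features, sizes$length_cm, model,
                                 scheme, seed = base_seed, params = params)
  message(sprintf("[train] final %s model on %d instances (seed %d)",
                  model, nrow(feats$features), base_seed))
  list(model = fitted, report = report, sizes = sizes,
       features = feats$features)
}

#' Run size inference on detections
#'
#' Builds the uncalibrated feature vector for every detection, predicts its
#' length with the trained model, and (when coefficients cover the species)
#' appends the allometric weight. Detections pass through unchanged — the
#' output has exactly one row per detection.
#'
#' @param model A `size_model` (uncalibrated layout).
#' @param detections Named list (by image id) of [detection_instance()]
#'   lists, as produced by [read_detections()] or [generate_dataset()].
#' @param catalog A [species_catalog()].
#' @param coefficients Optional allometric coefficient table
#'   (`species_id`, `a`, `b`); species it does not cover get `NA` weight.
#' @return Data frame: `image_id`, `instance_id`, `species_id`, `bbox_*`,
#'   `confidence`, `length_cm`, `weight_g`.
#' @export
run_inference <- function(model, detections, catalog, coefficients = NULL) {
  rows <- list(); feats <- list()
  for (key in names(detections)) {
    for (d in detections[[key]]) {
      feats[[length(feats) + 1]] <-
        extract_features(d, catalog, include_corners = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        image_id = as.integer(key), instance_id = d$instance_id,
        species_id = d$species_id,
        bbox_x = d$bbox[1], bbox_y = d$bbox[2],
        bbox_w = d$bbox[3], bbox_h = d$bbox[4],
        confidence = d$confidence)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = integer(0), instance_id = integer(0),
               species_id = integer(0), bbox_x = numeric(0),
               bbox_y = numeric(0), bbox_w = numeric(0), bbox_h = numeric(0),
               confidence = numeric(0))
  if (nrow(out) == 0) {
    out$length_cm <- numeric(0)
    out$weight_g <- numeric(0)
    return(out)
  }
  X <- do.call(rbind, feats)
  out$length_cm <- predict_sizes(model, X)
  out$weight_g <- NA_real_
  if (!is.null(coefficients)) {
    cov <- has_coefficients(out$species_id, coefficients)
    if (any(cov)) {
      out$weight_g[cov] <- allometric_weight(out$length_cm[cov],
                                             out$species_id[cov],
                                             coefficients)
    }
  }
  out
}
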