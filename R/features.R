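# Regressor input features: pixel-level quantities an instance-segmentation
# model emits (box, mask area, species), optionally augmented with the
# labelled tray-corner coordinates (the "calibrated" variant, available only
# during training).

feature_names <- function(catalog, include_corners) {
  nm <- c("bbox_x", "bbox_y", "bbox_w", "bbox_h", "mask_area_px",
          paste0("sp_", catalog$species_id))
  if (include_corners) {
    nm <- c(nm, paste0("corner_", rep(1:4, each = 2), c("x", "y")))
  }
  nm
}

#' Extract the regressor feature vector for one instance
#'
#' Deterministic layout `[bbox(4) | mask_area(1) | one-hot species |
#' corners(8, optional)]`. The full box (position and size) is encoded, not
#' just width/height: position is what lets an uncalibrated regressor learn
#' perspective implicitly. Species enters one-hot so no artificial order is
#' imposed. Mask area is the shoelace area of the pixel mask (holes
#' subtracted).
#'
#' @param instance A [fish_annotation()] or [detection_instance()].
#' @param catalog A [species_catalog()].
#' @param corners A [corner_quad()] (required when `include_corners`).
#' @param include_corners Append the 8 corner coordinates (calibrated
#'   variant).
#' @return Named numeric vector of length `5 + n_species (+ 8)`.
#' @export
extract_features <- function(instance, catalog, corners = NULL,
                             include_corners = FALSE) {
  assert_species_in_catalog(instance$species_id, catalog)
  onehot <- as.numeric(catalog$species_id == instance$species_id)
  v <- c(instance$bbox, mask_area(instance$mask), onehot)
  if (include_corners) {
    if (is.null(corners)) {
      stop_traymetry("traymetry_missing_calibration",
                     "include_corners = TRUE but no corner quad supplied")
    }
    v <- c(v, as.numeric(t(unclass(corners))))
  }
  setNames(v, feature_names(catalog, include_corners))
}

#' Feature matrix for a dataset of records
#'
#' Applies [extract_features()] to every annotation of every record, in
#' order.
#'
#' @param records List of [tray_image_record()]s.
#' @inheritParams extract_features
#' @return List: `features` (n x p matrix), `meta` (data frame with
#'   `image_id`, `instance_id`, `species_id`).
#' @export
dataset_features <- function(records, catalog, include_corners = FALSE) {
  rows <- list(); meta <- list()
  for (rec in records) {
    for (a in rec$annotations) {
      rows[[length(rows) + 1]] <-
        extract_features(a, catalog, rec$corners, include_corners)
      meta[[length(meta) + 1]] <-
        data.frame(image_id = rec$image_id, instance_id = a$instance_id,
                   species_id = a$species_id)
    }
  }
  feats <- if (length(rows) > 0) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(feature_names(catalog, include_corners)),
           dimnames = list(NULL, feature_names(catalog, include_corners)))
  list(features = feats,
       meta = if (length(meta) > 0) do.call(rbind, meta) else
         data.frame(image_id = integer(0), instance_id = integer(0),
                    species_id = integer(0)))
}
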