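# Feature / target normalization schemes for the size regressor.
#
# Schemes: "none"; "standard_input" (z-score per feature);
# "minmax_input" (per-feature rescale of train min..max to 0..1, which is
# rank-preserving and keeps the shape of the distribution); "minmax_io"
# (min-max on features and on the target, with predictions inverse-mapped
# back to cm before any metric is computed). Parameters are always fitted on
# training rows only.

#' Fit a normalization specification
#'
#' @param features Training feature matrix (>= 2 rows).
#' @param targets Training target vector (cm); used only by `minmax_io`.
#' @param scheme One of `"none"`, `"standard_input"`, `"minmax_input"`,
#'   `"minmax_io"`.
#' @return A `normalization_spec`. Degenerate columns (zero range or zero
#'   standard deviation) are mapped to 0 for every input.
#' @export
fit_normalization <- function(features, targets = NULL,
                              scheme = c("none", "standard_input",
                                         "minmax_input", "minmax_io")) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  if (nrow(features) < 2) {
    stop_traymetry("traymetry_fit_error",
                   "normalization needs >= 2 training rows")
  }
  spec <- list(scheme = scheme, p = ncol(features), names = colnames(features))
  if (scheme == "standard_input") {
    spec$center <- apply(features, 2, mean)
    spec$scale <- apply(features, 2, sd)
    spec$degenerate <- spec$scale <= 0
  } else if (scheme %in% c("minmax_input", "minmax_io")) {
    mn <- apply(features, 2, min)
    mx <- apply(features, 2, max)
    spec$center <- mn
    spec$scale <- mx - mn
    spec$degenerate <- spec$scale <= 0
    if (scheme == "minmax_io") {
      if (is.null(targets)) {
        stop_traymetry("traymetry_fit_error",
                       "minmax_io needs training targets")
      }
      spec$y_min <- min(targets)
      spec$y_range <- max(targets) - min(targets)
      if (spec$y_range <= 0) spec$y_range <- 1
    }
  }
  structure(spec, class = "normalization_spec")
}

#' Apply a fitted normalization to features
#' @param spec A `normalization_spec`.
#' @param features Feature matrix with the fitted column layout.
#' @return Transformed matrix.
#' @export
apply_normalization <- function(spec, features) {
  features <- as.matrix(features)
  if (ncol(features) != spec$p) {
    stop_traymetry("traymetry_layout_error",
                   sprintf("feature layout mismatch: %d columns, spec has %d",
                           ncol(features), spec$p))
  }
  if (spec$scheme == "none") return(features)
  out <- sweep(sweep(features, 2, spec$center), 2,
               ifelse(spec$degenerate, 1, spec$scale), "/")
  if (any(spec$degenerate)) out[, spec$degenerate] <- 0
  colnames(out) <- colnames(features)
  out
}

normalize_targets <- function(spec, y) {
  if (spec$scheme != "minmax_io") return(y)
  (y - spec$y_min) / spec$y_range
}

denormalize_targets <- function(spec, y) {
  if (spec$scheme != "minmax_io") return(y)
  y * spec$y_range + spec$y_min
}
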