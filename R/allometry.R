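#' Allometric length-to-weight conversion
#'
#' Converts a fish length to biomass through the standard fisheries
#' length-weight relationship `W = a * L^b`, with species-specific
#' coefficients (`a` in g/cm^b, `b` dimensionless, typically near 3).
#'
#' @param length_cm Positive length(s) in cm.
#' @param species_id Species id(s), recycled against `length_cm`.
#' @param coefficients Data frame with columns `species_id`, `a`, `b`.
#' @return Weight(s) in grams; `NA` is never returned — a species without
#'   coefficients raises a missing-coefficient error (use
#'   [has_coefficients()] to pre-filter).
#' @examples
#' coef <- data.frame(species_id = 0, a = 0.01, b = 3)
#' allometric_weight(10, 0, coef)  # 10 g
#' @export
allometric_weight <- function(length_cm, species_id, coefficients) {
  if (any(length_cm <= 0)) {
    stop_traymetry("traymetry_validation_error", "length must be positive")
  }
  if (any(coefficients$a <= 0)) {
    stop_traymetry("traymetry_validation_error",
                   "allometric coefficient a must be positive")
  }
  idx <- match(species_id, coefficients$species_id)
  if (anyNA(idx)) {
    missing <- sort(unique(species_id[is.na(idx)]))
    stop_traymetry("traymetry_missing_coefficient",
                   sprintf("no length-weight coefficients for species: %s",
                           paste(missing, collapse = ", ")))
  }
  coefficients$a[idx] * length_cm^coefficients$b[idx]
}

#' Check coefficient coverage
#' @inheritParams allometric_weight
#' @return Logical vector: does each species have coefficients?
#' @export
has_coefficients <- function(species_id, coefficients) {
  species_id %in% coefficients$species_id
}
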