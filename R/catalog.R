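#' Species catalogs
#'
#' A species catalog fixes the mapping between integer species ids and names,
#' and thereby the column order of one-hot species encodings. Ids must be
#' unique and contiguous from 0; names must be unique. Real tray datasets of
#' this kind carry on the order of a dozen commercially relevant labels
#' (sexually dimorphic species may contribute two).
#'
#' @param names Character vector of species names, in id order (id 0 first).
#' @return A `species_catalog`: data frame with columns `species_id`, `name`.
#' @examples
#' species_catalog(c("sparus_aurata", "mullus_surmuletus"))
#' @export
species_catalog <- function(names) {
  names <- as.character(names)
  if (length(names) == 0) {
    stop_traymetry("traymetry_validation_error", "catalog needs >= 1 species")
  }
  if (anyDuplicated(names)) {
    stop_traymetry("traymetry_validation_error",
                   "species names must be unique")
  }
  out <- data.frame(species_id = seq_along(names) - 1L, name = names,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_catalog", "data.frame")
  out
}

#' Default 13-species catalog
#'
#' Generic placeholder labels for the 13-class setting typical of a
#' small-market tray dataset. Use [species_catalog()] with real names for
#' actual data.
#'
#' @param n Number of species labels.
#' @return A `species_catalog`.
#' @export
default_species_catalog <- function(n = 13L) {
  species_catalog(sprintf("species_%02d", seq_len(n)))
}

catalog_size <- function(catalog) nrow(catalog)

assert_species_in_catalog <- function(species_id, catalog, where = "annotation") {
  bad <- setdiff(unique(species_id), catalog$species_id)
  if (length(bad) > 0) {
    stop_traymetry(
      "traymetry_unknown_species",
      sprintf("%s species id(s) not in catalog: %s", where,
              paste(sort(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML configuration holding the tray's real-world dimensions, the species
#' catalog, and optional modelling choices. Tray dimensions live in the
#' configuration rather than the annotation file; the default 60 x 40 cm is
#' an explicitly arbitrary stand-in for whatever rectangle the labelled
#' handle corners describe.
#'
#' @param path Path to a YAML file with keys `tray: {width_cm, height_cm}`
#'   and `species: [name, ...]` (plus optional `model`, `scheme`, `k`,
#'   `repeats`, `seed`, `include_corners`).
#' @return A list with elements `tray` ([tray_geometry()]), `catalog`
#'   ([species_catalog()]) and any remaining keys.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tray <- tray_geometry(cfg$tray$width_cm %||% 60, cfg$tray$height_cm %||% 40)
  catalog <- if (!is.null(cfg$species)) {
    species_catalog(unlist(cfg$species))
  } else {
    default_species_catalog()
  }
  out <- cfg
  out$tray <- tray
  out$catalog <- catalog
  out
}
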