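# COCO-dialect instance annotation I/O.
#
# The on-disk format is plain COCO instance JSON (images / annotations /
# categories) with two optional extension keys that standard COCO readers
# ignore: per-image "tray_corners" ([[x,y]] * 4) and per-annotation
# "size_polyline" ([x1,y1,x2,y2,...], mouth to base of tail). Predictions use
# the same dialect plus a per-annotation "score".

#' Read a COCO-dialect tray annotation file
#'
#' Parses the extended COCO instance JSON into a list of
#' [tray_image_record()] objects, preserving file order. Images without
#' labelled tray corners get `corners = NULL`; annotations without a size
#' polyline get `size_polyline = NULL`. Polygon masks are kept as-is;
#' uncompressed RLE masks (integer run counts) are converted to an exact
#' multi-rectangle polygon. Annotations whose `category_id` is not in the
#' catalog are rejected as a unit.
#'
#' @param path Path to the JSON file.
#' @param catalog A [species_catalog()].
#' @return List of `tray_image_record`s.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, catalog) {
  doc <- parse_json_file(path)
  imgs <- doc$images %||% list()
  anns <- doc$annotations %||% list()

  sp <- vapply(anns, function(a) as.integer(a$category_id), integer(1))
  assert_species_in_catalog(sp, catalog)

  ann_by_img <- split(seq_along(anns),
                      factor(vapply(anns, function(a) as.integer(a$image_id),
                                    integer(1)),
                             levels = vapply(imgs, function(im)
                               as.integer(im$id), integer(1))))

  lapply(seq_along(imgs), function(i) {
    im <- imgs[[i]]
    corners <- NULL
    if (!is.null(im$tray_corners)) {
      pts <- do.call(rbind, lapply(im$tray_corners, unlist))
      corners <- corner_quad(pts)
    }
    idx <- ann_by_img[[i]]
    fish <- lapply(idx, function(j) {
      a <- anns[[j]]
      fish_annotation(
        instance_id = a$id,
        species_id = a$category_id,
        mask = parse_segmentation(a$segmentation),
        bbox = unlist(a$bbox),
        size_polyline = if (!is.null(a$size_polyline))
          as_polyline(unlist(a$size_polyline)) else NULL)
    })
    tray_image_record(im$id, im$width, im$height, corners, fish)
  })
}

parse_json_file <- function(path) {
  if (!file.exists(path)) {
    stop_traymetry("traymetry_io_error", sprintf("no such file: %s", path))
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ok <- jsonlite::validate(txt)
  if (!isTRUE(ok)) {
    stop_traymetry(
      "traymetry_parse_error",
      sprintf("malformed JSON in %s near byte %d: %s", path,
              locate_json_error(txt), attr(ok, "err") %||% "invalid"))
  }
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

# Approximate byte offset of the first JSON error: the shortest prefix whose
# failure is not a premature end of input.
locate_json_error <- function(txt) {
  n <- nchar(txt, type = "bytes")
  definite_error_at <- function(len) {
    v <- jsonlite::validate(substr(txt, 1, len))
    if (isTRUE(v)) return(FALSE)
    !grepl("premature EOF", attr(v, "err") %||% "")
  }
  if (!definite_error_at(n)) return(n)
  lo <- 1L; hi <- n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (definite_error_at(mid)) hi <- mid else lo <- mid + 1L
  }
  lo
}

parse_segmentation <- function(seg) {
  if (is.null(seg)) {
    stop_traymetry("traymetry_validation_error", "annotation without a mask")
  }
  if (!is.null(seg$counts)) {
    if (is.character(seg$counts)) {
      stop_traymetry("traymetry_validation_error",
                     "compressed RLE masks are not supported; store polygons or uncompressed counts")
    }
    return(rle_to_mask(unlist(seg$counts), unlist(seg$size)))
  }
  lapply(seg, function(ring) as_ring(unlist(ring)))
}

# Uncompressed COCO RLE (column-major, alternating background/foreground
# runs) -> exact mask as one unit-width rectangle ring per column segment.
rle_to_mask <- function(counts, size) {
  h <- size[1]
  ends <- cumsum(counts)
  starts <- c(0, head(ends, -1))
  fg <- seq_along(counts) %% 2 == 0
  rings <- list()
  for (k in which(fg)) {
    s <- starts[k]; e <- ends[k] - 1
    for (col in (s %/% h):(e %/% h)) {
      r1 <- if (col == s %/% h) s %% h else 0
      r2 <- if (col == e %/% h) e %% h else h - 1
      rings[[length(rings) + 1]] <-
        rbind(c(col, r1), c(col + 1, r1), c(col + 1, r2 + 1), c(col, r2 + 1))
    }
  }
  if (length(rings) == 0) {
    stop_traymetry("traymetry_empty_mask", "RLE mask has no foreground")
  }
  rings
}

#' Write records to the COCO-dialect JSON file
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(x))` reproduces
#' `x` exactly (coordinates are written at full precision). The output is
#' valid plain COCO; the extension keys are additive.
#'
#' @param records List of [tray_image_record()]s.
#' @param catalog A [species_catalog()].
#' @param path Output path.
#' @export
write_dataset <- function(records, catalog, path) {
  doc <- build_coco_doc(records, catalog)
  write_coco_doc(doc, path)
}

build_coco_doc <- function(records, catalog, scores = NULL) {
  images <- lapply(records, function(rec) {
    im <- list(id = rec$image_id, width = rec$width_px,
               height = rec$height_px,
               file_name = sprintf("tray_%06d.jpg", rec$image_id))
    if (!is.null(rec$corners)) {
      im$tray_corners <- lapply(seq_len(4), function(i)
        as.numeric(rec$corners[i, ]))
    }
    im
  })
  annotations <- list()
  for (rec in records) {
    for (a in rec$annotations) {
      ann <- list(
        id = a$instance_id, image_id = rec$image_id,
        category_id = a$species_id,
        segmentation = lapply(a$mask, function(r) as.numeric(t(r))),
        bbox = a$bbox, area = mask_area(a$mask), iscrowd = 0L)
      if (!is.null(a$size_polyline)) {
        ann$size_polyline <- as.numeric(t(a$size_polyline))
      }
      if (!is.null(a$confidence)) ann$score <- a$confidence
      annotations[[length(annotations) + 1]] <- ann
    }
  }
  categories <- lapply(seq_len(nrow(catalog)), function(i) {
    list(id = catalog$species_id[i], name = catalog$name[i],
         supercategory = "fish")
  })
  list(images = images, annotations = annotations, categories = categories)
}

write_coco_doc <- function(doc, path) {
  ok <- tryCatch({
    # 17 significant digits round-trips IEEE doubles exactly
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 17)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_traymetry("traymetry_io_error",
                   sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read a detections file
#'
#' Same dialect as [read_dataset()] with a per-annotation `score`; used for
#' the predictions of an external instance-segmentation model.
#'
#' @inheritParams read_dataset
#' @return Named list (names = image ids) of lists of
#'   [detection_instance()]s, in file image order.
#' @export
read_detections <- function(path, catalog) {
  doc <- parse_json_file(path)
  imgs <- doc$images %||% list()
  anns <- doc$annotations %||% list()
  sp <- vapply(anns, function(a) as.integer(a$category_id), integer(1))
  assert_species_in_catalog(sp, catalog, where = "detection")
  img_ids <- vapply(imgs, function(im) as.integer(im$id), integer(1))
  out <- setNames(vector("list", length(img_ids)), as.character(img_ids))
  for (id in as.character(img_ids)) out[[id]] <- list()
  for (a in anns) {
    key <- as.character(as.integer(a$image_id))
    det <- detection_instance(
      species_id = a$category_id,
      mask = parse_segmentation(a$segmentation),
      bbox = if (!is.null(a$bbox)) unlist(a$bbox) else NULL,
      confidence = a$score %||% 1,
      instance_id = a$id %||% NA_integer_)
    out[[key]] <- c(out[[key]], list(det))
  }
  out
}

#' Write detections to the COCO-dialect file
#'
#' @param detections Named list (by image id) of [detection_instance()] lists.
#' @param records The [tray_image_record()]s the detections refer to (for
#'   image dimensions).
#' @inheritParams write_dataset
#' @export
write_detections <- function(detections, records, catalog, path) {
  stripped <- lapply(records, function(rec) {
    dets <- detections[[as.character(rec$image_id)]] %||% list()
    dets <- lapply(seq_along(dets), function(i) {
      d <- dets[[i]]
      if (is.na(d$instance_id)) d$instance_id <- i
      d
    })
    tray_image_record(rec$image_id, rec$width_px, rec$height_px,
                      rec$corners, dets)
  })
  doc <- build_coco_doc(stripped, catalog)
  write_coco_doc(doc, path)
}
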