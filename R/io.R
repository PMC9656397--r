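# On-disk formats: 16-bit single-channel TIFF for cell labels, 8-bit PNG for
# the footprint, a flat key=value sidecar for metadata, and CSV for
# morphology record tables.

#' Write a labeled colony image to disk
#'
#' Writes `<prefix>_labels.tif` (16-bit label raster), `<prefix>_footprint.png`
#' (8-bit binary) and `<prefix>_meta.txt` (flat `key=value` sidecar with the
#' pixel size and metadata).
#'
#' @param image A [colony_image()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_colony_image <- function(image, prefix) {
  stopifnot(inherits(image, "colony_image"))
  if (max(image$cell_labels) > 65535L) abort("more than 65535 labels; cannot write 16-bit TIFF.")
  paths <- c(labels = paste0(prefix, "_labels.tif"),
             footprint = paste0(prefix, "_footprint.png"),
             meta = paste0(prefix, "_meta.txt"))
  tiff::writeTIFF(image$cell_labels / 65535, paths["labels"],
                  bits.per.sample = 16L, compression = "none")
  png::writePNG(image$footprint * 1, paths["footprint"])
  meta <- image$meta
  lines <- c(sprintf("pixel_size=%.10g", image$pixel_size),
             vapply(names(meta), function(k) {
               sprintf("%s=%s", k, as.character(meta[[k]] %||% "NA"))
             }, character(1)))
  writeLines(lines, paths["meta"])
  invisible(paths)
}

#' Read a labeled colony image written by [write_colony_image()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [colony_image()].
#' @export
read_colony_image <- function(prefix) {
  lab_path <- paste0(prefix, "_labels.tif")
  fp_path <- paste0(prefix, "_footprint.png")
  meta_path <- paste0(prefix, "_meta.txt")
  if (!file.exists(lab_path)) abort(sprintf("no such file: %s", lab_path))
  lab <- round(tiff::readTIFF(lab_path) * 65535)
  storage.mode(lab) <- "integer"
  fp <- png::readPNG(fp_path) > 0.5
  meta <- list()
  pixel_size <- 1
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) != 2) next
      if (p[1] == "pixel_size") pixel_size <- as.numeric(p[2])
      else meta[[p[1]]] <- if (p[1] %in% c("time_h", "passage")) {
        suppressWarnings(as.numeric(p[2]))
      } else p[2]
    }
  }
  colony_image(lab, fp, pixel_size = pixel_size, meta = meta)
}

record_columns <- function() {
  c("unit", meta_column_names(), "area", "perimeter", "minor_axis",
    "feret_d", "min_feret_d", "shape_factor", "ais")
}

#' Write morphology records to CSV
#'
#' @param records Morphology record tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_records_csv <- function(records, path) {
  cols <- intersect(record_columns(), names(records))
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Load a per-colony / per-cell parameter table
#'
#' Reads a CSV of measured morphology records, optionally renaming columns
#' through `column_mapping` (to absorb external column dialects), validates
#' the record invariants row by row (positive area and perimeter, shape
#' factor in (0, 1.05], `min_feret_d <= feret_d`, `minor_axis <= feret_d`
#' within a 1\% rasterization tolerance, non-negative `ais`), and drops
#' violating rows with a per-row report.
#'
#' @param path CSV file path.
#' @param column_mapping Named character vector `c(internal = "external")`
#'   renaming external columns to the internal names.
#' @param unit `"colony"`, `"cell"`, or `NULL` to take the unit from a
#'   `unit` column.
#' @param time_window Optional inclusive `[h_min, h_max]` filter on
#'   `time_h`.
#' @return Validated tibble of morphology records; rejected rows (with row
#'   indices and reasons) in attribute `"rejected"`.
#' @export
load_parameter_table <- function(path, column_mapping = NULL, unit = NULL,
                                 time_window = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_mapping)) {
    missing_src <- setdiff(unname(column_mapping), names(d))
    if (length(missing_src)) {
      abort(sprintf("mapped column(s) absent from file: %s.",
                    paste(missing_src, collapse = ", ")))
    }
    for (i in seq_along(column_mapping)) {
      names(d)[names(d) == column_mapping[[i]]] <- names(column_mapping)[i]
    }
  }
  if (!is.null(unit)) d$unit <- unit
  if (!"unit" %in% names(d)) {
    abort("no `unit` column; pass `unit = \"colony\"` or `\"cell\"` or map one.")
  }
  required <- c("area", "perimeter", "minor_axis", "feret_d", "min_feret_d",
                "shape_factor")
  missing_req <- setdiff(required, names(d))
  if (length(missing_req)) {
    abort(sprintf("required column(s) missing: %s.",
                  paste(missing_req, collapse = ", ")))
  }
  for (cn in c(required, "ais", "time_h", "passage")) {
    if (cn %in% names(d)) d[[cn]] <- suppressWarnings(as.numeric(d[[cn]]))
  }
  if (!"ais" %in% names(d)) d$ais <- NA_real_
  for (cn in meta_column_names()) if (!cn %in% names(d)) d[[cn]] <- NA
  tol <- 1.01
  reasons <- character(nrow(d))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond & reasons == ""] <<- why
  }
  bad(!is.finite(d$area) | d$area <= 0, "area not a positive number")
  bad(!is.finite(d$perimeter) | d$perimeter <= 0, "perimeter not a positive number")
  bad(!is.finite(d$shape_factor) | d$shape_factor <= 0 |
        d$shape_factor > 1.05, "shape factor outside (0, 1.05]")
  bad(d$min_feret_d > d$feret_d * tol, "min_feret_d exceeds feret_d")
  bad(d$minor_axis > d$feret_d * tol, "minor_axis exceeds feret_d")
  bad(!is.na(d$ais) & d$ais < 0, "negative ais")
  bad(!is.na(d$ais) & d$ais >= d$area, "ais not smaller than area")
  rej <- which(reasons != "")
  rejected <- tibble(row = rej, reason = reasons[rej])
  if (length(rej)) {
    warn(sprintf("dropped %d invalid row(s); see attr(, \"rejected\").",
                 length(rej)))
    d <- d[-rej, , drop = FALSE]
  }
  out <- as_tibble(d[, intersect(record_columns(), names(d))])
  if (!is.null(time_window)) {
    out <- out[!is.na(out$time_h) & out$time_h >= time_window[1] &
                 out$time_h <= time_window[2], ]
  }
  attr(out, "rejected") <- rejected
  out
}
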