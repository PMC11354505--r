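#' Annotation and measurement I/O
#'
#' Interchange formats: a JSON schema for contour annotations drawn on an
#' OCT B-scan raster (the device's on-screen tracings have no exportable
#' format, so the package defines a portable one), a paired-measurement CSV
#' for agreement analysis, and round-trip-safe result writers.
#'
#' @name annotation_io
NULL

#' Assemble an annotation stack
#'
#' The unit of volumetric measurement: the ordered B-scan annotations of one
#' acquisition, plus the raster geometry needed to turn areas into a volume.
#'
#' @param scans list of scan records; each a list with `scan_index`
#'   (0-based, strictly increasing), optional `lateral_offset_y` (mm;
#'   defaults to `scan_index * scan_spacing`) and `contours` (list of
#'   [contour()] objects)
#' @param scan_spacing distance between consecutive B-scans (mm), > 0
#' @param x_scale,z_scale mm per pixel, only needed when vertices arrive in
#'   pixel units
#' @param fovea_center optional list with `scan_index` and `x_mm`, the
#'   foveal centre used to auto-place the circular ROI
#' @param meta free-form provenance list (eye id, observer id, session id,
#'   entity label, ...)
#' @return an object of class `annotation_stack`
#' @export
annotation_stack <- function(scans, scan_spacing, x_scale = NULL,
                             z_scale = NULL, fovea_center = NULL,
                             meta = list()) {
  if (!is.numeric(scan_spacing) || !is.finite(scan_spacing) ||
      scan_spacing <= 0) {
    octvol_stop("scan_spacing must be a positive number (mm)",
                "octvol_unit_error")
  }
  if (!length(scans)) {
    octvol_stop("annotation stack needs at least one scan",
                "octvol_schema_error")
  }
  idx <- vapply(scans, function(s) as.integer(s$scan_index), integer(1))
  if (any(idx < 0L) || any(diff(idx) <= 0L)) {
    octvol_stop("scan_index must be >= 0 and strictly increasing",
                "octvol_schema_error")
  }
  scans <- lapply(scans, function(s) {
    s$scan_index <- as.integer(s$scan_index)
    if (is.null(s$lateral_offset_y)) {
      s$lateral_offset_y <- s$scan_index * scan_spacing
    }
    if (is.null(s$contours)) s$contours <- list()
    s
  })
  off <- vapply(scans, function(s) s$lateral_offset_y, numeric(1))
  # offsets may carry a constant shift (raster centred on the fovea) but
  # must advance by scan_spacing per index step
  if (length(off) > 1L) {
    step <- diff(off) / diff(idx)
    if (any(abs(step - scan_spacing) > 1e-6 + 1e-6 * scan_spacing)) {
      octvol_stop(
        "lateral_offset_y inconsistent with scan_index * scan_spacing",
        "octvol_schema_error")
    }
  }
  if (!is.null(fovea_center)) {
    if (is.null(fovea_center$scan_index) || is.null(fovea_center$x_mm)) {
      octvol_stop("fovea_center needs scan_index and x_mm",
                  "octvol_schema_error")
    }
  }
  structure(
    list(scan_spacing = as.numeric(scan_spacing),
         x_scale = x_scale, z_scale = z_scale,
         fovea_center = fovea_center, meta = meta, scans = scans),
    class = "annotation_stack"
  )
}

#' @export
print.annotation_stack <- function(x, ...) {
  nc <- sum(vapply(x$scans, function(s) length(s$contours), integer(1)))
  cat(sprintf(
    "<annotation_stack: %d scans, %d contours, spacing %.4g mm%s>\n",
    length(x$scans), nc, x$scan_spacing,
    if (is.null(x$fovea_center)) "" else ", fovea centred"))
  invisible(x)
}

scan_offsets <- function(stack) {
  vapply(stack$scans, function(s) s$lateral_offset_y, numeric(1))
}

#' Read an annotation stack from JSON
#'
#' Schema (all lengths in mm unless suffixed `_px`):
#' \preformatted{
#' {"scan_spacing_mm": float,
#'  "x_scale_mm_per_px": float|null, "z_scale_mm_per_px": float|null,
#'  "fovea_center": {"scan_index": int, "x_mm": float} | null,
#'  "meta": {...},
#'  "scans": [{"scan_index": int,
#'             "contours": [{"label": str,
#'                           "vertices_mm" | "vertices_px": [[x, z], ...]}]}]}
#' }
#'
#' Pixel-unit vertices are converted to mm on read using the per-axis
#' scales; pixel input without both scales is a unit error, never a silent
#' interpretation.
#'
#' @param path JSON file path
#' @param units units the vertices are expected in: `"mm"` (key
#'   `vertices_mm`) or `"px"` (key `vertices_px`)
#' @return an [annotation_stack()] with all vertices in mm
#' @export
read_annotation_stack <- function(path, units = c("mm", "px")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    octvol_stop(sprintf("annotation file not found: %s", path),
                "octvol_io_error")
  }
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) octvol_stop(
      sprintf("malformed JSON in %s: %s", path, conditionMessage(e)),
      "octvol_parse_error")
  )
  need <- function(key, where = doc) {
    if (is.null(where[[key]])) {
      octvol_stop(sprintf("missing key '%s' in %s", key, path),
                  "octvol_parse_error")
    }
    where[[key]]
  }
  spacing <- need("scan_spacing_mm")
  if (!is.numeric(spacing) || spacing <= 0) {
    octvol_stop(sprintf("scan_spacing_mm must be > 0 in %s", path),
                "octvol_unit_error")
  }
  x_scale <- doc$x_scale_mm_per_px
  z_scale <- doc$z_scale_mm_per_px
  vkey <- if (units == "mm") "vertices_mm" else "vertices_px"
  if (units == "px" && (is.null(x_scale) || is.null(z_scale))) {
    octvol_stop("pixel-unit vertices require x_scale_mm_per_px and z_scale_mm_per_px",
                "octvol_unit_error")
  }
  scans <- lapply(need("scans"), function(s) {
    si <- need("scan_index", s)
    contours <- lapply(if (is.null(s$contours)) list() else s$contours,
                       function(ct) {
      verts <- ct[[vkey]]
      if (is.null(verts)) {
        octvol_stop(sprintf("contour on scan %s lacks key '%s'", si, vkey),
                    "octvol_unit_error")
      }
      v <- do.call(rbind, lapply(verts, function(p) as.numeric(unlist(p))))
      if (is.null(v) || ncol(v) != 2L) {
        octvol_stop(sprintf("key '%s' on scan %s is not a list of [x, z] pairs",
                            vkey, si), "octvol_parse_error")
      }
      if (units == "px") {
        v[, 1L] <- v[, 1L] * x_scale
        v[, 2L] <- v[, 2L] * z_scale
      }
      contour(v, label = if (is.null(ct$label)) "entity" else ct$label,
              scan_index = si, validate = TRUE)
    })
    list(scan_index = si, lateral_offset_y = s$lateral_offset_y,
         contours = contours)
  })
  fc <- doc$fovea_center
  annotation_stack(scans, scan_spacing = spacing, x_scale = x_scale,
                   z_scale = z_scale, fovea_center = fc,
                   meta = if (is.null(doc$meta)) list() else doc$meta)
}

#' Write an annotation stack to JSON
#'
#' Inverse of [read_annotation_stack()]; vertices are written in mm at full
#' double precision so that read(write(x)) reproduces every coordinate.
#'
#' @param stack an [annotation_stack()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation_stack <- function(stack, path) {
  doc <- list(
    scan_spacing_mm = stack$scan_spacing,
    x_scale_mm_per_px = stack$x_scale,
    z_scale_mm_per_px = stack$z_scale,
    fovea_center = stack$fovea_center,
    meta = stack$meta,
    scans = lapply(stack$scans, function(s) {
      list(scan_index = s$scan_index,
           lateral_offset_y = s$lateral_offset_y,
           contours = lapply(s$contours, function(ct) {
             v <- ct$vertices
             list(label = ct$label,
                  vertices_mm = lapply(seq_len(nrow(v)),
                                       function(i) unname(v[i, ])))
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Paired measurements for agreement analysis
#'
#' @param value_a,value_b paired measurements (mm^3), method/observer A
#'   first; the Bland-Altman difference is `value_a - value_b`
#' @param subject subject identifiers (defaults to sequence)
#' @param method_a_label,method_b_label names of the two methods, used in
#'   the comparison name `"A-B"`
#' @return an object of class `paired_measurements` (a data frame with
#'   columns `subject`, `value_a`, `value_b`)
#' @export
paired_measurements <- function(value_a, value_b,
                                subject = seq_along(value_a),
                                method_a_label = "A",
                                method_b_label = "B") {
  if (length(value_a) != length(value_b)) {
    octvol_stop("value_a and value_b must have equal length",
                "octvol_schema_error")
  }
  keep <- is.finite(value_a) & is.finite(value_b)
  if (!all(keep)) {
    octvol_warn(sprintf("dropping %d incomplete pair(s)", sum(!keep)),
                "octvol_dropped_pairs")
  }
  df <- data.frame(subject = as.character(subject)[keep],
                   value_a = as.numeric(value_a)[keep],
                   value_b = as.numeric(value_b)[keep],
                   stringsAsFactors = FALSE)
  if (nrow(df) < 2L) {
    octvol_stop("need at least 2 complete pairs", "octvol_insufficient_data")
  }
  structure(df, class = c("paired_measurements", "data.frame"),
            method_a_label = method_a_label, method_b_label = method_b_label)
}

#' Read paired measurements from CSV
#'
#' Expected header: `subject,value_a,value_b` (UTF-8, "." decimal
#' separator). Rows with a missing value in either column are dropped with
#' a warning; a non-numeric entry is a parse error reporting the row.
#'
#' @param path CSV file path
#' @param method_a_label,method_b_label labels forwarded to
#'   [paired_measurements()]
#' @return a [paired_measurements()] object
#' @export
read_paired_csv <- function(path, method_a_label = "A",
                            method_b_label = "B") {
  if (!file.exists(path)) {
    octvol_stop(sprintf("paired CSV not found: %s", path), "octvol_io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) octvol_stop(
      sprintf("cannot read %s: %s", path, conditionMessage(e)),
      "octvol_parse_error")
  )
  if (!all(c("subject", "value_a", "value_b") %in% names(df))) {
    octvol_stop("CSV header must be subject,value_a,value_b",
                "octvol_parse_error")
  }
  if (!nrow(df)) {
    octvol_stop(sprintf("no pairs in %s", path), "octvol_insufficient_data")
  }
  to_num <- function(col) {
    x <- df[[col]]
    x[x == ""] <- NA_character_
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) {
      octvol_stop(sprintf("non-numeric %s '%s' at row %d of %s",
                          col, x[which(bad)[1L]], which(bad)[1L], path),
                  "octvol_parse_error")
    }
    suppressWarnings(as.numeric(x))
  }
  paired_measurements(to_num("value_a"), to_num("value_b"),
                      subject = df$subject,
                      method_a_label = method_a_label,
                      method_b_label = method_b_label)
}

#' Write a result object to CSV or JSON
#'
#' Round-trip safe: numbers are serialised at full double precision, and
#' [read_results()] reproduces every numeric field exactly.
#'
#' @param result a `volume_result`, `agreement_result`, or any list of
#'   scalars/vectors/data frames
#' @param path output path
#' @param format `"csv"` or `"json"`
#' @return `path`, invisibly
#' @export
write_results <- function(result, path, format = c("json", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) octvol_stop(
                       sprintf("unknown format '%s'", format[1L]),
                       "octvol_format_error"))
  payload <- as_result_list(result)
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                           null = "null", dataframe = "columns")
    } else {
      write_results_csv(payload, path)
    }
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    octvol_stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                "octvol_io_error")
  }
  invisible(path)
}

as_result_list <- function(result) {
  if (inherits(result, "volume_result")) {
    c(list(type = "volume_result"), unclass(result))
  } else if (inherits(result, "agreement_result")) {
    c(list(type = "agreement_result"), unclass(result))
  } else if (is.list(result)) {
    result
  } else {
    octvol_stop("unsupported result object", "octvol_format_error")
  }
}

# key,value CSV with full-precision numbers; vectors joined with ';',
# data frames flattened column-wise
write_results_csv <- function(payload, path) {
  fmt <- function(x) {
    if (is.numeric(x)) paste(sprintf("%.17g", x), collapse = ";")
    else paste(as.character(x), collapse = ";")
  }
  rows <- list()
  for (key in names(payload)) {
    val <- payload[[key]]
    if (is.null(val)) next
    if (is.data.frame(val)) {
      for (col in names(val)) {
        rows[[paste0(key, ".", col)]] <- fmt(val[[col]])
      }
    } else if (is.list(val)) {
      for (sub in names(val)) rows[[paste0(key, ".", sub)]] <- fmt(val[[sub]])
    } else {
      rows[[key]] <- fmt(val)
    }
  }
  df <- data.frame(key = names(rows), value = unlist(rows, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read back a result written by [write_results()]
#'
#' @param path file path
#' @param format `"csv"` or `"json"`
#' @return a named list; CSV results come back as a flat key/value list
#'   with numeric vectors restored
#' @export
read_results <- function(path, format = c("json", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) octvol_stop(
                       sprintf("unknown format '%s'", format[1L]),
                       "octvol_format_error"))
  if (!file.exists(path)) {
    octvol_stop(sprintf("results file not found: %s", path),
                "octvol_io_error")
  }
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    out <- lapply(df$value, function(v) {
      parts <- strsplit(v, ";", fixed = TRUE)[[1L]]
      num <- suppressWarnings(as.numeric(parts))
      if (!anyNA(num)) num else parts
    })
    names(out) <- df$key
    out
  }
}
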