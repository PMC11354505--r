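#' Volume of an annotated entity
#'
#' The core computation: per-scan cross-sectional areas integrated across
#' the raster, `V = sum(area_i) * scan_spacing`. Each B-scan is treated as a
#' slab of width `scan_spacing` centred on the scan (midpoint rule).
#'
#' @name volumetry
NULL

new_volume_result <- function(per_scan, scan_spacing, protocol, label) {
  total <- sum(per_scan$area * scan_spacing)  # the stated formula, verbatim
  structure(
    list(label = label,
         protocol = protocol,
         scan_spacing = scan_spacing,
         per_scan = per_scan,
         total_volume = total),
    class = "volume_result"
  )
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result '%s' (%s): %d scans, spacing %.4g mm>\n",
              x$label, x$protocol, nrow(x$per_scan), x$scan_spacing))
  cat(sprintf("  total volume: %.6f mm^3\n", x$total_volume))
  invisible(x)
}

#' Volume of a labelled entity (free protocol)
#'
#' Sums, for every scan, the areas of all contours carrying `label` (a
#' multi-lobed entity may have several per scan), then multiplies the area
#' sum by the inter-scan distance. Scans without the label contribute 0;
#' the label must occur somewhere in the stack.
#'
#' @param stack an [annotation_stack()]
#' @param label entity tag to measure
#' @return a `volume_result` with components `per_scan` (data frame of
#'   `scan_index`, `area` in mm^2) and `total_volume` (mm^3)
#' @examples
#' sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), label = "FS")
#' st <- annotation_stack(list(list(scan_index = 0L, contours = list(sq))),
#'                        scan_spacing = 0.1)
#' entity_volume(st, "FS")$total_volume  # 0.1 mm^3
#' @export
entity_volume <- function(stack, label) {
  areas <- vapply(stack$scans, function(s) {
    cts <- Filter(function(ct) ct$label == label, s$contours)
    if (!length(cts)) 0 else sum(vapply(cts, polygon_area, numeric(1)))
  }, numeric(1))
  any_label <- any(vapply(stack$scans, function(s)
    any(vapply(s$contours, function(ct) ct$label == label, logical(1))),
    logical(1)))
  if (!any_label) {
    octvol_stop(sprintf("no contour labelled '%s' in the stack", label),
                "octvol_empty_entity")
  }
  per_scan <- data.frame(
    scan_index = vapply(stack$scans, function(s) s$scan_index, integer(1)),
    area = areas)
  new_volume_result(per_scan, stack$scan_spacing, "free", label)
}

#' Foveal (circle-restricted) volume
#'
#' The retinal-volume protocol for eyes with a normal foveal profile: a
#' 1000-micron-diameter circle is centred on the fovea, every B-scan inside
#' the circle has its contour clipped to the vertical strip between the two
#' chord borders, and the clipped areas are integrated as in
#' [entity_volume()].
#'
#' @param stack an [annotation_stack()]; its `fovea_center` locates the ROI
#'   when `roi` is not given
#' @param label entity tag to measure
#' @param roi a [circular_roi()]; if `NULL`, built from
#'   `stack$fovea_center` with radius `radius`
#' @param radius ROI radius (mm) used when `roi` is `NULL`; default 0.5
#'   (the central ETDRS circle)
#' @return a `volume_result` with `protocol = "circular_roi"`; scans whose
#'   offset is at or beyond the tangent contribute 0. A raster too coarse
#'   for any scan to intersect the ROI yields volume 0 with a warning: that
#'   is a resolution fact, not a data fault.
#' @export
foveal_volume <- function(stack, label, roi = NULL, radius = 0.5) {
  if (is.null(roi)) {
    fc <- stack$fovea_center
    if (is.null(fc)) {
      octvol_stop("no ROI given and stack has no fovea_center",
                  "octvol_config_error")
    }
    idx <- vapply(stack$scans, function(s) s$scan_index, integer(1))
    pos <- match(as.integer(fc$scan_index), idx)
    if (is.na(pos)) {
      octvol_stop("fovea_center scan_index not present in the stack",
                  "octvol_config_error")
    }
    roi <- circular_roi(center_x = fc$x_mm,
                        center_y = stack$scans[[pos]]$lateral_offset_y,
                        radius = radius)
  }
  any_label <- FALSE
  areas <- vapply(stack$scans, function(s) {
    cts <- Filter(function(ct) ct$label == label, s$contours)
    if (length(cts)) any_label <<- TRUE
    w <- chord_halfwidth(roi, s$lateral_offset_y)
    if (!length(cts) || is.na(w)) return(0)
    sum(vapply(cts, function(ct) {
      cl <- clip_contour_to_strip(ct, roi$center_x - w, roi$center_x + w)
      if (is.null(cl)) 0 else polygon_area(cl)
    }, numeric(1)))
  }, numeric(1))
  if (!any_label) {
    octvol_stop(sprintf("no contour labelled '%s' in the stack", label),
                "octvol_empty_entity")
  }
  inside <- !is.na(chord_halfwidth(roi, scan_offsets(stack)))
  if (!any(inside)) {
    octvol_warn(sprintf(
      "no scan intersects the %.3g mm ROI (spacing %.3g mm); volume is 0",
      roi$radius, stack$scan_spacing), "octvol_coarse_raster")
  }
  per_scan <- data.frame(
    scan_index = vapply(stack$scans, function(s) s$scan_index, integer(1)),
    area = areas)
  new_volume_result(per_scan, stack$scan_spacing, "circular_roi", label)
}
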