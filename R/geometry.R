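#' Planar contour geometry
#'
#' The per-B-scan half of the volumetry method: polygon areas via the
#' shoelace formula, the chord a foveal circle induces on a B-scan, and
#' clipping of a contour to the vertical strip between the two chord
#' borders.
#'
#' @name geometry
NULL

#' Create a closed contour on one B-scan
#'
#' A contour is an ordered list of vertices in the plane of a single B-scan
#' (`x` lateral, `z` axial, both mm). The polygon is implicitly closed: the
#' last vertex connects back to the first. Contours must be simple
#' (non-self-intersecting); validation can be skipped for contours that are
#' simple by construction (e.g. phantom renderings).
#'
#' @param vertices numeric matrix (or 2-column coercible) of vertex
#'   coordinates, columns `x` and `z`, in mm
#' @param label entity tag, e.g. `"retina"`, `"FC"`, `"FS"`
#' @param scan_index 0-based index of the B-scan the contour was drawn on
#' @param validate check simplicity (segment-pair test)? Contours failing it
#'   are rejected, not repaired: a mis-traced polygon should surface.
#' @return an object of class `oct_contour`
#' @examples
#' sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), label = "retina")
#' polygon_area(sq)
#' @export
contour <- function(vertices, label = "entity", scan_index = 0L,
                    validate = TRUE) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    octvol_stop("contour vertices must be a numeric n x 2 matrix (x, z)",
                "octvol_degenerate_contour")
  }
  if (nrow(v) < 3L) {
    octvol_stop(sprintf("contour needs >= 3 vertices, got %d", nrow(v)),
                "octvol_degenerate_contour")
  }
  if (!all(is.finite(v))) {
    octvol_stop("contour vertices must be finite", "octvol_degenerate_contour")
  }
  colnames(v) <- c("x", "z")
  if (validate && !is_simple_polygon(v)) {
    octvol_stop("contour is self-intersecting", "octvol_invalid_contour")
  }
  structure(
    list(vertices = v, label = as.character(label),
         scan_index = as.integer(scan_index), validated = isTRUE(validate)),
    class = "oct_contour"
  )
}

#' @export
print.oct_contour <- function(x, ...) {
  cat(sprintf("<oct_contour '%s' scan %d: %d vertices, area %.6g mm^2>\n",
              x$label, x$scan_index, nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

contour_vertices <- function(contour) {
  if (inherits(contour, "oct_contour")) contour$vertices else {
    v <- as.matrix(contour)
    colnames(v) <- c("x", "z")
    v
  }
}

#' Test whether a closed polygon is simple
#'
#' Segment-pair test over all non-adjacent edge pairs; shared endpoints of
#' adjacent edges are permitted, any other contact (proper crossing, overlap,
#' or touch) is not.
#'
#' @param vertices n x 2 matrix of polygon vertices (implicitly closed)
#' @return logical
#' @export
is_simple_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  m <- nrow(v)
  if (m < 3L) return(FALSE)
  nxt <- c(2:m, 1L)
  a <- v
  b <- v[nxt, , drop = FALSE]
  # zero-length edges make adjacency ill-defined
  if (any(rowSums((b - a)^2) == 0)) return(FALSE)
  for (i in seq_len(m - 2L)) {
    js <- (i + 2L):m
    if (i == 1L) js <- js[js != m]   # edge m is adjacent to edge 1
    if (!length(js)) next
    if (any(segments_intersect(a[i, 1], a[i, 2], b[i, 1], b[i, 2],
                               a[js, 1], a[js, 2], b[js, 1], b[js, 2]))) {
      return(FALSE)
    }
  }
  TRUE
}

# vectorised over the second segment set; closed test (touching counts)
segments_intersect <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  o <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  d1 <- o(p1x, p1y, p2x, p2y, q1x, q1y)
  d2 <- o(p1x, p1y, p2x, p2y, q2x, q2y)
  d3 <- o(q1x, q1y, q2x, q2y, p1x, p1y)
  d4 <- o(q1x, q1y, q2x, q2y, p2x, p2y)
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  on_seg <- function(ax, ay, bx, by, cx, cy) {
    # c collinear with a-b: is it within the bounding box?
    (pmin(ax, bx) <= cx) & (cx <= pmax(ax, bx)) &
      (pmin(ay, by) <= cy) & (cy <= pmax(ay, by))
  }
  touch <- (d1 == 0 & on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) |
    (d2 == 0 & on_seg(p1x, p1y, p2x, p2y, q2x, q2y)) |
    (d3 == 0 & on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) |
    (d4 == 0 & on_seg(q1x, q1y, q2x, q2y, p2x, p2y))
  proper | touch
}

#' Polygon area by the shoelace formula
#'
#' \deqn{A = \frac{1}{2}\left|\sum_i (x_i z_{i+1} - x_{i+1} z_i)\right|}
#'
#' Orientation-independent (absolute value). This is the area the OCT
#' calliper reports for a traced perimeter.
#'
#' @param contour an [contour()] object or an n x 2 vertex matrix
#' @return area in mm^2 (non-negative)
#' @export
polygon_area <- function(contour) {
  if (inherits(contour, "oct_contour")) {
    v <- contour$vertices
    if (!isTRUE(contour$validated) && !is_simple_polygon(v)) {
      octvol_stop("contour is self-intersecting", "octvol_invalid_contour")
    }
  } else {
    v <- contour_vertices(contour)
    if (nrow(v) < 3L) {
      octvol_stop("polygon needs >= 3 vertices", "octvol_degenerate_contour")
    }
    if (!is_simple_polygon(v)) {
      octvol_stop("polygon is self-intersecting", "octvol_invalid_contour")
    }
  }
  shoelace(v)
}

# raw signed-sum kernel; no validation (hot path)
shoelace <- function(v) {
  x <- v[, 1L]; z <- v[, 2L]
  xn <- c(x[-1L], x[1L]); zn <- c(z[-1L], z[1L])
  abs(sum(x * zn - xn * z)) / 2
}

#' Circular region of interest centred on the fovea
#'
#' The foveal measurement restricts retinal volume to a circle of default
#' radius 0.5 mm (1000-micron diameter) centred on the foveal centre,
#' matching the central circle of the 1/3/6-mm ETDRS grid.
#'
#' @param center_x lateral position of the foveal centre on its B-scan (mm)
#' @param center_y raster offset of the foveal B-scan (mm)
#' @param radius circle radius (mm), default 0.5
#' @return an object of class `circular_roi`
#' @export
circular_roi <- function(center_x, center_y, radius = 0.5) {
  if (!is.finite(radius) || radius <= 0) {
    octvol_stop("ROI radius must be > 0", "octvol_invalid_roi")
  }
  structure(list(center_x = as.numeric(center_x),
                 center_y = as.numeric(center_y),
                 radius = as.numeric(radius)),
            class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi center (%.4g, %.4g) mm, radius %.4g mm>\n",
              x$center_x, x$center_y, x$radius))
  invisible(x)
}

#' Half-width of the chord a circular ROI induces on a B-scan
#'
#' A B-scan at raster offset `scan_offset_y` sees the foveal circle as a
#' chord. For `d = |scan_offset_y - center_y|` the half-width is
#' `sqrt(radius^2 - d^2)` when `d < radius`; scans at or beyond the tangent
#' (`d >= radius`) see no chord and are excluded (returned as `NA`).
#'
#' @param roi a [circular_roi()]
#' @param scan_offset_y lateral raster offset of the B-scan (mm)
#' @return chord half-width in mm, or `NA_real_` if the scan misses the ROI
#' @export
chord_halfwidth <- function(roi, scan_offset_y) {
  d <- abs(scan_offset_y - roi$center_y)
  ifelse(d < roi$radius, sqrt(pmax(roi$radius^2 - d^2, 0)), NA_real_)
}

#' Clip a contour to a vertical strip
#'
#' Reproduces the on-screen procedure of drawing two vertical reference
#' lines where the foveal circle crosses the B-scan and tracing only the
#' tissue between them: the polygon is intersected with the half-planes
#' `x >= x_min` and `x <= x_max` (Sutherland-Hodgman).
#'
#' For non-convex contours the clipped boundary may touch itself along the
#' clip lines; the enclosed area is still correct, so the result is not
#' re-validated for simplicity.
#'
#' @param contour an [contour()] object or vertex matrix
#' @param x_min,x_max strip borders (mm), `x_min < x_max`
#' @return the clipped `oct_contour`, or `NULL` if the intersection is empty
#' @export
clip_contour_to_strip <- function(contour, x_min, x_max) {
  if (!(x_min < x_max)) {
    octvol_stop("x_min must be < x_max", "octvol_invalid_roi")
  }
  is_ct <- inherits(contour, "oct_contour")
  v <- contour_vertices(contour)
  if (nrow(v) < 3L) {
    octvol_stop("polygon needs >= 3 vertices", "octvol_degenerate_contour")
  }
  if (is_ct && !isTRUE(contour$validated) && !is_simple_polygon(v)) {
    octvol_stop("contour is self-intersecting", "octvol_invalid_contour")
  }
  v <- clip_halfplane(v, x_min, keep_right = TRUE)
  if (is.null(v)) return(NULL)
  v <- clip_halfplane(v, x_max, keep_right = FALSE)
  if (is.null(v) || shoelace(v) == 0) return(NULL)
  out <- contour(v, label = if (is_ct) contour$label else "entity",
                 scan_index = if (is_ct) contour$scan_index else 0L,
                 validate = FALSE)
  # Sutherland-Hodgman output of a simple input encloses the right area
  # even when its boundary touches itself along the clip lines
  out$validated <- TRUE
  out
}

# Sutherland-Hodgman against the vertical line x = x0.
# keep_right: keep x >= x0, else keep x <= x0.
clip_halfplane <- function(v, x0, keep_right) {
  m <- nrow(v)
  inside <- if (keep_right) v[, 1L] >= x0 else v[, 1L] <= x0
  if (all(inside)) return(v)
  if (!any(inside)) return(NULL)
  out <- matrix(NA_real_, nrow = 2L * m, ncol = 2L)
  k <- 0L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    a <- v[i, ]; b <- v[j, ]
    if (inside[i]) {
      k <- k + 1L; out[k, ] <- a
    }
    if (inside[i] != inside[j]) {
      t <- (x0 - a[1L]) / (b[1L] - a[1L])
      k <- k + 1L; out[k, ] <- c(x0, a[2L] + t * (b[2L] - a[2L]))
    }
  }
  if (k < 3L) return(NULL)
  out <- out[seq_len(k), , drop = FALSE]
  colnames(out) <- c("x", "z")
  out
}
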