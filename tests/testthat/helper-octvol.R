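# Shared fixtures and independent oracles.
#
# The rasterization oracle deliberately shares no code with the shoelace /
# clipping implementation: it counts pixel centres inside the polygon by
# even-odd scanline crossings.

# area of a closed polygon by pixel counting at resolution px (mm per pixel)
raster_area <- function(vertices, px = 0.001) {
  v <- as.matrix(vertices)
  m <- nrow(v)
  x <- v[, 1L]; z <- v[, 2L]
  xn <- c(x[-1L], x[1L]); zn <- c(z[-1L], z[1L])
  z0 <- floor(min(z) / px) - 1L
  z1 <- ceiling(max(z) / px) + 1L
  total <- 0
  for (row in z0:z1) {
    zc <- (row + 0.5) * px
    # edges straddling the scanline (half-open rule avoids vertex double counts)
    cross <- (z <= zc & zn > zc) | (zn <= zc & z > zc)
    if (!any(cross)) next
    t <- (zc - z[cross]) / (zn[cross] - z[cross])
    xs <- sort(x[cross] + t * (xn[cross] - x[cross]))
    stopifnot(length(xs) %% 2L == 0L)
    for (k in seq(1L, length(xs), by = 2L)) {
      lo <- xs[k]; hi <- xs[k + 1L]
      # pixel centres (i + 0.5) * px within [lo, hi]
      n_in <- floor(hi / px - 0.5) - ceiling(lo / px - 0.5) + 1
      total <- total + max(n_in, 0)
    }
  }
  total * px^2
}

polygon_perimeter <- function(vertices) {
  v <- as.matrix(vertices)
  d <- diff(rbind(v, v[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# star-shaped polygon around a random centre: evenly spaced jittered angles
# keep every angular gap < pi, which guarantees simplicity
random_star_polygon <- function(n_vertices = 12L, r_min = 0.1, r_max = 0.6,
                                center = stats::runif(2, -0.2, 0.2)) {
  base <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  th <- base + stats::runif(n_vertices, 0, pi / n_vertices)
  r <- stats::runif(n_vertices, r_min, r_max)
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# regular k-gon inscribed in a circle
circle_polygon <- function(r, k, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# paired measurements whose differences have exactly the requested mean/sd
pairs_with_moments <- function(bias, sd, n) {
  base <- seq_len(n)
  d <- bias + sd * (base - mean(base)) / stats::sd(base)
  paired_measurements(d, rep(0, n),
                      method_a_label = "A", method_b_label = "B")
}

# minimal annotation JSON document as an R list (see read_annotation_stack)
minimal_stack_doc <- function(vertices_key = "vertices_mm",
                              verts = list(c(0, 0), c(1, 0), c(0, 1)),
                              scan_spacing = 0.1, x_scale = NULL,
                              z_scale = NULL) {
  doc <- list(
    scan_spacing_mm = scan_spacing,
    x_scale_mm_per_px = x_scale, z_scale_mm_per_px = z_scale,
    fovea_center = NULL, meta = list(eye = "synthetic"),
    scans = list(list(scan_index = 0L,
                      contours = list(list(label = "retina",
                                           vertices = verts)))))
  names(doc$scans[[1]]$contours[[1]])[2] <- vertices_key
  doc
}

write_stack_json <- function(doc, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

# Gauss-Hermite nodes/weights for E[f(U)], U ~ N(0,1) (Golub-Welsch on the
# probabilists' Hermite recurrence)
gauss_hermite_probabilist <- function(k) {
  J <- matrix(0, k, k)
  off <- sqrt(seq_len(k - 1))
  J[cbind(1:(k - 1), 2:k)] <- off
  J[cbind(2:k, 1:(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

scan_offsets_for_test <- function(stack) {
  vapply(stack$scans, function(s) s$lateral_offset_y, numeric(1))
}

table1_path <- function() {
  system.file("extdata", "table1_agreement_summary.csv", package = "octvol")
}
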