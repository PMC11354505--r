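#' Analytic phantoms and simulated observers
#'
#' Parametric 3-D shapes with closed-form volumes, rendered as annotation
#' stacks exactly as a human observer would trace them scan by scan, plus a
#' multiplicative observer-noise model. Together they make the volumetry
#' and agreement modules testable without any clinical data.
#'
#' @name phantom
NULL

phantom_shapes <- c("ellipsoid", "slab_cylinder", "paraboloid_pit", "lens")

#' Specify an analytic phantom
#'
#' Shapes and parameters (all mm):
#' \describe{
#'   \item{`ellipsoid`}{`a`, `b`, `c`: semi-axes along x (lateral), y
#'     (across scans), z (axial). Volume `4/3 pi a b c`.}
#'   \item{`slab_cylinder`}{`r`, `t`: a flat cylinder with a circular
#'     footprint of radius `r` in the x-y plane and axial thickness `t`
#'     (a uniform tissue slab over a disc). Volume `pi r^2 t`.}
#'   \item{`paraboloid_pit`}{`a`, `h`: solid between the paraboloid
#'     `z = h (x^2+y^2)/a^2` and the plane `z = h` (a foveal-pit-like
#'     bowl). Volume `pi a^2 h / 2`.}
#'   \item{`lens`}{`h`, `R`: symmetric biconvex lens, two spherical caps of
#'     height `h` cut from spheres of radius `R`, base to base (a
#'     schisis-cavity-like shape). Volume `2 pi h^2 (3R - h) / 3`.}
#' }
#'
#' The default raster emulates a dense macular acquisition: 49 horizontal
#' B-scans. The default spacing 0.12 mm is an assumption (device rasters
#' vary with scan angle); both are configurable.
#'
#' @param shape one of `"ellipsoid"`, `"slab_cylinder"`,
#'   `"paraboloid_pit"`, `"lens"`
#' @param params named numeric parameters, see above; all > 0
#' @param center `(x, y)` position of the shape centre (mm); the raster is
#'   centred on `center[2]`
#' @param scan_spacing inter-scan distance (mm)
#' @param n_scans number of B-scans in the raster
#' @param grid_phase lateral offset (mm) of the raster relative to the
#'   shape centre, so tests can marginalise over raster alignment
#' @param vertices_per_contour vertices of each rendered polygon
#' @param label entity tag written on rendered contours
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(shape = phantom_shapes,
                         params,
                         center = c(0, 0),
                         scan_spacing = 0.12,
                         n_scans = 49L,
                         grid_phase = 0,
                         vertices_per_contour = 128L,
                         label = "entity") {
  shape <- match.arg(shape)
  need <- switch(shape,
                 ellipsoid = c("a", "b", "c"),
                 slab_cylinder = c("r", "t"),
                 paraboloid_pit = c("a", "h"),
                 lens = c("h", "R"))
  if (!all(need %in% names(params))) {
    octvol_stop(sprintf("shape '%s' needs params %s", shape,
                        paste(need, collapse = ", ")),
                "octvol_config_error")
  }
  params <- lapply(params[need], as.numeric)
  if (any(unlist(params) <= 0) || !all(is.finite(unlist(params)))) {
    octvol_stop("all phantom dimensions must be positive and finite",
                "octvol_config_error")
  }
  if (shape == "lens" && params$h > params$R) {
    octvol_stop("lens cap height h must not exceed sphere radius R",
                "octvol_config_error")
  }
  if (scan_spacing <= 0 || n_scans < 1L) {
    octvol_stop("scan_spacing must be > 0 and n_scans >= 1",
                "octvol_config_error")
  }
  if (vertices_per_contour < 3L) {
    octvol_stop("vertices_per_contour must be >= 3", "octvol_config_error")
  }
  spec <- structure(
    list(shape = shape, params = params,
         center = as.numeric(center),
         scan_spacing = as.numeric(scan_spacing),
         n_scans = as.integer(n_scans),
         grid_phase = as.numeric(grid_phase),
         vertices_per_contour = as.integer(vertices_per_contour),
         label = label),
    class = "phantom_spec")
  span <- (spec$n_scans - 1L) * spec$scan_spacing / 2
  if (phantom_halfextent_y(spec) > span + abs(spec$grid_phase) + 1e-12) {
    octvol_warn("phantom extends beyond the raster span; rendered volume will be truncated",
                "octvol_raster_span")
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec %s (%s): %d scans @ %.4g mm, V = %.6f mm^3>\n",
              x$shape,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              x$n_scans, x$scan_spacing, analytic_volume(x)))
  invisible(x)
}

phantom_halfextent_y <- function(spec) {
  p <- spec$params
  switch(spec$shape,
         ellipsoid = p$b,
         slab_cylinder = p$r,
         paraboloid_pit = p$a,
         lens = sqrt(p$R^2 - (p$R - p$h)^2))
}

#' Closed-form phantom volume
#'
#' @param spec a [phantom_spec()]
#' @return volume in mm^3
#' @export
analytic_volume <- function(spec) {
  p <- spec$params
  switch(spec$shape,
         ellipsoid = 4 / 3 * pi * p$a * p$b * p$c,
         slab_cylinder = pi * p$r^2 * p$t,
         paraboloid_pit = pi * p$a^2 * p$h / 2,
         lens = 2 * pi * p$h^2 * (3 * p$R - p$h) / 3)
}

#' Exact cross-sectional area of a phantom at a scan plane
#'
#' Area of the intersection of the shape with the B-scan plane at raster
#' offset `scan_offset_y` (relative to the same origin as the spec's
#' `center`). Zero beyond the shape's extent.
#'
#' @param spec a [phantom_spec()]
#' @param scan_offset_y lateral offset of the scan plane (mm); vectorised
#' @return area(s) in mm^2
#' @export
analytic_cross_section <- function(spec, scan_offset_y) {
  p <- spec$params
  d <- scan_offset_y - spec$center[2L]
  vapply(d, function(di) {
    switch(spec$shape,
      ellipsoid = {
        if (abs(di) >= p$b) 0 else pi * p$a * p$c * (1 - di^2 / p$b^2)
      },
      slab_cylinder = {
        if (abs(di) >= p$r) 0 else 2 * sqrt(p$r^2 - di^2) * p$t
      },
      paraboloid_pit = {
        if (abs(di) >= p$a) 0 else {
          s <- sqrt(p$a^2 - di^2)
          4 * p$h * s^3 / (3 * p$a^2)
        }
      },
      lens = {
        rho2 <- p$R^2 - di^2
        cc <- p$R - p$h
        if (rho2 <= cc^2) 0 else {
          rho <- sqrt(rho2)
          2 * (rho2 * acos(cc / rho) - cc * sqrt(rho2 - cc^2))
        }
      })
  }, numeric(1))
}

# lateral offsets of the raster scans (mm)
phantom_offsets <- function(spec) {
  spec$center[2L] + spec$grid_phase +
    (seq_len(spec$n_scans) - 1 - (spec$n_scans - 1) / 2) * spec$scan_spacing
}

# polygon inscribed in the exact cross-section boundary at offset d from
# the shape centre; NULL when the plane misses the shape
phantom_section_polygon <- function(spec, d, k = spec$vertices_per_contour) {
  p <- spec$params
  cx <- spec$center[1L]
  switch(spec$shape,
    ellipsoid = {
      if (abs(d) >= p$b) return(NULL)
      f <- sqrt(1 - d^2 / p$b^2)
      th <- 2 * pi * (seq_len(k) - 1) / k
      cbind(cx + p$a * f * cos(th), p$c * f * sin(th))
    },
    slab_cylinder = {
      if (abs(d) >= p$r) return(NULL)
      w <- sqrt(p$r^2 - d^2)
      # the section is an exact rectangle; 4 corners represent it exactly
      cbind(cx + c(-w, w, w, -w), c(0, 0, p$t, p$t))
    },
    paraboloid_pit = {
      if (abs(d) >= p$a) return(NULL)
      s <- sqrt(p$a^2 - d^2)
      # the parabola endpoints lie at z = h, so sampling the floor from
      # -s to s and closing implicitly along the flat top suffices
      x <- cx + seq(-s, s, length.out = max(k, 3L))
      z <- p$h * ((x - cx)^2 + d^2) / p$a^2
      cbind(x, z)
    },
    lens = {
      rho2 <- p$R^2 - d^2
      cc <- p$R - p$h
      if (rho2 <= cc^2) return(NULL)
      rho <- sqrt(rho2)
      s <- sqrt(rho2 - cc^2)
      half <- max(3L, ceiling(k / 2))
      x <- seq(-s, s, length.out = half)
      upper <- cbind(cx + x, -cc + sqrt(pmax(rho2 - x^2, 0)))
      lower <- cbind(cx + rev(x), cc - sqrt(pmax(rho2 - rev(x)^2, 0)))
      rbind(upper, lower[-c(1L, nrow(lower)), , drop = FALSE])
    })
}

#' Render a phantom as an annotation stack
#'
#' For every raster scan that intersects the shape, an inscribed polygon
#' with `vertices_per_contour` vertices is drawn on the exact cross-section
#' boundary, so the polygon area converges to [analytic_cross_section()] as
#' the vertex count grows (error ~ 1/k^2 for smooth boundaries; rectangle
#' sections are exact with 4 corners).
#'
#' @param spec a [phantom_spec()]
#' @return an [annotation_stack()]; scans the shape misses carry no contour
#' @export
render_stack <- function(spec) {
  offs <- phantom_offsets(spec)
  scans <- lapply(seq_along(offs), function(i) {
    v <- phantom_section_polygon(spec, offs[i] - spec$center[2L])
    cts <- if (is.null(v)) list() else {
      ct <- contour(v, label = spec$label, scan_index = i - 1L,
                    validate = FALSE)
      ct$validated <- TRUE  # inscribed sections are simple by construction
      list(ct)
    }
    list(scan_index = i - 1L, lateral_offset_y = offs[i], contours = cts)
  })
  nearest <- which.min(abs(offs - spec$center[2L]))
  annotation_stack(
    scans, scan_spacing = spec$scan_spacing,
    fovea_center = list(scan_index = nearest - 1L, x_mm = spec$center[1L]),
    meta = list(phantom = spec$shape,
                params = spec$params,
                analytic_volume_mm3 = analytic_volume(spec)))
}

#' Simulated observer
#'
#' Observers perturb per-scan areas multiplicatively: observed area =
#' true area * (1 + area_bias + e), e ~ Normal(0, area_noise_sd), truncated
#' at zero. Area-level (rather than vertex-level) noise keeps the model
#' analytically tractable for parameter-recovery tests.
#'
#' @param area_bias relative systematic bias (fraction, e.g. 0.01 = +1%)
#' @param area_noise_sd relative noise SD (fraction), >= 0
#' @param seed optional observer-specific seed; when `NA` the simulation
#'   seed governs all draws
#' @return an object of class `observer_model`
#' @export
observer_model <- function(area_bias = 0, area_noise_sd = 0, seed = NA) {
  if (area_noise_sd < 0) {
    octvol_stop("area_noise_sd must be >= 0", "octvol_config_error")
  }
  structure(list(area_bias = as.numeric(area_bias),
                 area_noise_sd = as.numeric(area_noise_sd),
                 seed = seed),
            class = "observer_model")
}

#' Simulate a two-observer, repeated-session agreement study
#'
#' Emulates the validation design: `n_subjects` eyes, each a rescaled copy
#' of the phantom, measured by two observers in `sessions` sessions. Per
#' subject the shape's linear dimensions are scaled by `(1 + u)`,
#' `u ~ Normal(0, subject_size_jitter)`; the subject's stack is rendered
#' and its true per-scan areas and volume taken from [entity_volume()].
#' Each observer/session then re-measures every scan area under the
#' observer's noise model and volumes are recomputed with the same slab
#' sum.
#'
#' @param spec a [phantom_spec()] describing the population's base anatomy
#' @param obs1,obs2 [observer_model()]s
#' @param n_subjects number of simulated eyes, >= 3
#' @param sessions measurement sessions per observer (2 emulates a
#'   six-week re-acquisition)
#' @param subject_size_jitter SD of the relative size jitter (fraction)
#' @param seed simulation seed; identical seeds give bit-identical output
#' @return list with `true_volumes` (per subject), `volumes` (array
#'   subject x observer x session) and `comparisons`, a named list of
#'   [paired_measurements()]: `obs1_vs_obs2` (session 1),
#'   `obs1_s1_vs_s2`, `obs2_s1_vs_s2`, and `truth_vs_obs1`,
#'   `truth_vs_obs2` (analytic truth playing the automated-device role)
#' @export
simulate_observers <- function(spec, obs1, obs2, n_subjects,
                               sessions = 2L, subject_size_jitter = 0.05,
                               seed = 2024L) {
  if (n_subjects < 3L) {
    octvol_stop("n_subjects must be >= 3", "octvol_insufficient_data")
  }
  set.seed(as.integer(seed))
  observers <- list(obs1, obs2)
  vols <- array(NA_real_, dim = c(n_subjects, 2L, sessions))
  true_vols <- numeric(n_subjects)
  jitter <- stats::rnorm(n_subjects, 0, subject_size_jitter)
  jitter <- pmax(jitter, -0.9)
  for (subj in seq_len(n_subjects)) {
    f <- 1 + jitter[subj]
    sp <- spec
    sp$params <- lapply(spec$params, function(v) v * f)
    class(sp) <- "phantom_spec"
    st <- suppressWarnings(render_stack(sp))
    tv <- entity_volume(st, sp$label)
    areas <- tv$per_scan$area
    true_vols[subj] <- tv$total_volume
    for (k in 1:2) {
      ob <- observers[[k]]
      for (ses in seq_len(sessions)) {
        if (!is.na(ob$seed)) set.seed(as.integer(ob$seed) + subj * 131L + ses)
        eps <- stats::rnorm(length(areas), 0, ob$area_noise_sd)
        obs_areas <- pmax(areas * (1 + ob$area_bias + eps), 0)
        vols[subj, k, ses] <- sum(obs_areas * st$scan_spacing)
      }
    }
  }
  cmp <- list(
    obs1_vs_obs2 = paired_measurements(
      vols[, 1L, 1L], vols[, 2L, 1L],
      method_a_label = "Obs 1", method_b_label = "Obs 2"),
    truth_vs_obs1 = paired_measurements(
      true_vols, vols[, 1L, 1L],
      method_a_label = "Truth", method_b_label = "Obs 1"),
    truth_vs_obs2 = paired_measurements(
      true_vols, vols[, 2L, 1L],
      method_a_label = "Truth", method_b_label = "Obs 2"))
  if (sessions >= 2L) {
    cmp$obs1_s1_vs_s2 <- paired_measurements(
      vols[, 1L, 1L], vols[, 1L, 2L],
      method_a_label = "Obs 1 s1", method_b_label = "Obs 1 s2")
    cmp$obs2_s1_vs_s2 <- paired_measurements(
      vols[, 2L, 1L], vols[, 2L, 2L],
      method_a_label = "Obs 2 s1", method_b_label = "Obs 2 s2")
  }
  list(true_volumes = true_vols, volumes = vols, comparisons = cmp,
       seed = as.integer(seed))
}
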