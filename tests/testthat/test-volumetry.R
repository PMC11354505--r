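make_stack <- function(areas_by_scan, scan_spacing = 0.1, label = "FS") {
  # rectangle of the requested area on each scan
  scans <- lapply(seq_along(areas_by_scan), function(i) {
    a <- areas_by_scan[[i]]
    cts <- lapply(a, function(ai) {
      contour(rbind(c(0, 0), c(ai, 0), c(ai, 1), c(0, 1)), label = label,
              scan_index = i - 1L)
    })
    list(scan_index = i - 1L, contours = cts)
  })
  annotation_stack(scans, scan_spacing = scan_spacing)
}

test_that("entity_volume: hand sums and the exact formula invariant", {
  st <- make_stack(list(1.0), scan_spacing = 0.1)
  expect_equal(entity_volume(st, "FS")$total_volume, 0.1)

  st2 <- make_stack(list(0.02, 0.03), scan_spacing = 0.12)
  vr <- entity_volume(st2, "FS")
  expect_equal(vr$total_volume, 0.006)
  # bit-identical to the stated formula
  expect_identical(vr$total_volume, sum(vr$per_scan$area * vr$scan_spacing))
  expect_true(all(vr$per_scan$area >= 0))

  expect_error(entity_volume(st2, "FC"), class = "octvol_empty_entity")
})

test_that("multi-lobed contours sum; disjoint labels are additive", {
  st <- make_stack(list(c(0.02, 0.05), 0.03), scan_spacing = 0.1)
  vr <- entity_volume(st, "FS")
  expect_equal(vr$per_scan$area, c(0.07, 0.03))

  # two labels on the same raster: volumes add
  fc <- contour(rbind(c(2, 0), c(2.5, 0), c(2.5, 0.4), c(2, 0.4)),
                label = "FC")
  st$scans[[1]]$contours <- c(st$scans[[1]]$contours, list(fc))
  st2 <- annotation_stack(st$scans, scan_spacing = 0.1)
  v_fs <- entity_volume(st2, "FS")$total_volume
  v_fc <- entity_volume(st2, "FC")$total_volume
  both <- make_stack(list(c(0.02, 0.05, 0.2), 0.03), scan_spacing = 0.1)
  expect_equal(entity_volume(both, "FS")$total_volume, v_fs + v_fc)
})

test_that("scaling covariance: coordinates and spacing scaled by k give k^3", {
  sp <- phantom_spec("lens", list(h = 0.2, R = 0.5), n_scans = 21L,
                     scan_spacing = 0.06, vertices_per_contour = 40L)
  st <- render_stack(sp)
  v1 <- entity_volume(st, "entity")$total_volume
  k <- 1.7
  scans_k <- lapply(st$scans, function(s) {
    s$lateral_offset_y <- s$lateral_offset_y * k
    s$contours <- lapply(s$contours, function(ct) {
      contour(ct$vertices * k, label = ct$label, scan_index = ct$scan_index,
              validate = FALSE)
    })
    s
  })
  st_k <- annotation_stack(scans_k, scan_spacing = st$scan_spacing * k)
  expect_equal(entity_volume(st_k, "entity")$total_volume, k^3 * v1,
               tolerance = 1e-12)
})

test_that("phantom volumes converge to the analytic value with order >= 1", {
  for (case in list(
    list(shape = "ellipsoid", params = list(a = 0.5, b = 0.5, c = 0.5)),
    list(shape = "lens", params = list(h = 0.2, R = 0.5)))) {
    deltas <- c(0.2, 0.1, 0.05, 0.025)
    errs <- vapply(deltas, function(dl) {
      ns <- 2L * ceiling(0.8 / dl) + 1L
      sp <- phantom_spec(case$shape, case$params, scan_spacing = dl,
                         n_scans = ns, grid_phase = 0.37 * dl,
                         vertices_per_contour = 512L)
      v <- entity_volume(render_stack(sp), "entity")$total_volume
      abs(v - analytic_volume(sp))
    }, numeric(1))
    fit <- stats::lm(log(errs) ~ log(deltas))
    expect_gte(unname(stats::coef(fit)[2]), 1)
  }
})

test_that("foveal_volume clips to the chord strip and recovers a cylinder", {
  # wide uniform slab, ROI radius 0.5: volume -> pi r^2 t as spacing -> 0
  roi <- circular_roi(0, 0, 0.5)
  dl <- 0.02
  sp <- phantom_spec("slab_cylinder", list(r = 1.0, t = 0.3),
                     scan_spacing = dl,
                     n_scans = 2L * ceiling(1.2 / dl) + 1L,
                     grid_phase = 0.37 * dl, vertices_per_contour = 64L)
  st <- render_stack(sp)
  vr <- foveal_volume(st, "entity", roi = roi)
  expect_equal(vr$protocol, "circular_roi")
  expect_equal(vr$total_volume, pi * 0.25 * 0.3, tolerance = 2e-3)
  # scans beyond the tangent contribute exactly 0
  outside <- abs(scan_offsets_for_test(st)) >= 0.5
  expect_true(all(vr$per_scan$area[outside] == 0))

  # ellipsoid centred on the fovea: per-scan clipped areas match a
  # quadrature oracle of the clipped cross-section
  sp2 <- phantom_spec("ellipsoid", list(a = 0.8, b = 0.6, c = 0.25),
                      scan_spacing = 0.1, n_scans = 13L,
                      vertices_per_contour = 2000L)
  st2 <- render_stack(sp2)
  vr2 <- foveal_volume(st2, "entity", roi = circular_roi(0, 0, 0.5))
  offs <- scan_offsets_for_test(st2)
  for (i in seq_along(offs)) {
    d <- abs(offs[i])
    if (d >= 0.6) next
    w <- chord_halfwidth(circular_roi(0, 0, 0.5), offs[i])
    ax <- 0.8 * sqrt(1 - d^2 / 0.36)
    cz <- 0.25 * sqrt(1 - d^2 / 0.36)
    lim <- if (is.na(w)) 0 else min(w, ax)
    oracle <- if (lim <= 0) 0 else
      stats::integrate(function(x) 2 * cz * sqrt(pmax(1 - x^2 / ax^2, 0)),
                       -lim, lim, rel.tol = 1e-10)$value
    expect_equal(vr2$per_scan$area[i], oracle, tolerance = 1e-4)
  }
})

test_that("foveal_volume configuration and degenerate rasters", {
  sp <- phantom_spec("slab_cylinder", list(r = 1.0, t = 0.3),
                     scan_spacing = 0.1, n_scans = 21L)
  st <- render_stack(sp)
  # fovea_center provided by the phantom: auto-ROI works
  v_auto <- foveal_volume(st, "entity", radius = 0.5)$total_volume
  v_roi <- foveal_volume(st, "entity",
                         roi = circular_roi(0, 0, 0.5))$total_volume
  expect_equal(v_auto, v_roi)

  st$fovea_center <- NULL
  expect_error(foveal_volume(st, "entity"), class = "octvol_config_error")

  # raster so coarse no scan hits the ROI: volume 0 with a warning
  sp2 <- phantom_spec("slab_cylinder", list(r = 1.0, t = 0.3),
                      scan_spacing = 0.5, n_scans = 5L,
                      vertices_per_contour = 16L)
  st2 <- render_stack(sp2)
  expect_warning(
    v0 <- foveal_volume(st2, "entity",
                        roi = circular_roi(0, 0.25, 0.2)),
    class = "octvol_coarse_raster")
  expect_equal(v0$total_volume, 0)
})

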