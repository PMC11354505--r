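test_that("analytic volumes: closed forms and quadrature self-check", {
  sphere <- phantom_spec("ellipsoid", list(a = 0.5, b = 0.5, c = 0.5))
  expect_equal(analytic_volume(sphere), 4 / 3 * pi * 0.5^3)
  expect_equal(round(analytic_volume(sphere), 6), 0.523599)
  cyl <- phantom_spec("slab_cylinder", list(r = 0.5, t = 0.3))
  expect_equal(analytic_volume(cyl), pi * 0.5^2 * 0.3)
  expect_equal(round(analytic_volume(cyl), 6), 0.235619)
  lens <- phantom_spec("lens", list(h = 0.2, R = 0.5))
  # 2 * (pi h^2 (3R - h) / 3), verified by 1-D quadrature below
  expect_equal(round(analytic_volume(lens), 6), 0.108909)
  pit <- phantom_spec("paraboloid_pit", list(a = 0.6, h = 0.25))
  expect_equal(analytic_volume(pit), pi * 0.36 * 0.25 / 2)

  # integral of the cross-section over y equals the volume for every shape
  for (sp in list(sphere, cyl, lens, pit)) {
    q <- stats::integrate(function(y) analytic_cross_section(sp, y),
                          -1, 1, rel.tol = 1e-10,
                          subdivisions = 1000L)$value
    expect_equal(q, analytic_volume(sp), tolerance = 1e-6)
  }
})

test_that("cross-sections: equatorial closed forms and support", {
  ell <- phantom_spec("ellipsoid", list(a = 0.4, b = 0.3, c = 0.2))
  expect_equal(analytic_cross_section(ell, 0), pi * 0.4 * 0.2)
  expect_equal(analytic_cross_section(ell, 0.3), 0)   # at the extent
  expect_equal(analytic_cross_section(ell, 5), 0)     # far beyond
  expect_equal(analytic_cross_section(ell, 0.15),
               pi * 0.4 * 0.2 * (1 - 0.15^2 / 0.09))
  cyl <- phantom_spec("slab_cylinder", list(r = 0.5, t = 0.3))
  expect_equal(analytic_cross_section(cyl, 0.3), 2 * 0.4 * 0.3)
})

test_that("rendered polygons are inscribed and converge as 1/k^2", {
  # 4 vertices on a circular section -> inscribed square, area 2 r^2
  sp4 <- suppressWarnings(
    phantom_spec("ellipsoid", list(a = 0.5, b = 0.3, c = 0.5),
                 vertices_per_contour = 4L, n_scans = 1L,
                 scan_spacing = 0.1))
  st4 <- render_stack(sp4)
  expect_equal(polygon_area(st4$scans[[1]]$contours[[1]]), 2 * 0.25)

  ks <- c(16L, 32L, 64L, 128L)
  errs <- vapply(ks, function(k) {
    sp <- suppressWarnings(
      phantom_spec("ellipsoid", list(a = 0.5, b = 0.3, c = 0.5),
                   vertices_per_contour = k, n_scans = 1L,
                   scan_spacing = 0.1))
    st <- render_stack(sp)
    a <- polygon_area(st$scans[[1]]$contours[[1]])
    exact <- analytic_cross_section(sp, 0)
    expect_lte(a, exact)              # inscribed: never overestimates
    exact - a
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(as.numeric(ks))))[2]
  expect_equal(unname(slope), -2, tolerance = 0.05)

  # lens and paraboloid sections are inscribed too
  for (shape in list(list("lens", list(h = 0.2, R = 0.5)),
                     list("paraboloid_pit", list(a = 0.6, h = 0.25)))) {
    sp <- suppressWarnings(
      phantom_spec(shape[[1]], shape[[2]], n_scans = 9L,
                   scan_spacing = 0.1, vertices_per_contour = 256L))
    st <- render_stack(sp)
    for (s in st$scans) {
      if (!length(s$contours)) next
      a <- polygon_area(s$contours[[1]])
      exact <- analytic_cross_section(sp, s$lateral_offset_y)
      expect_lte(a, exact + 1e-12)
      expect_equal(a, exact, tolerance = 1e-3)
    }
  }
})

test_that("render -> measure reproduces the analytic volume end to end", {
  sp <- phantom_spec("lens", list(h = 0.2, R = 0.5), scan_spacing = 0.02,
                     n_scans = 61L, grid_phase = 0.007,
                     vertices_per_contour = 256L)
  v <- entity_volume(render_stack(sp), "entity")$total_volume
  expect_equal(v, analytic_volume(sp), tolerance = 2e-3)
})

test_that("phantom_spec validates its inputs", {
  expect_error(phantom_spec("ellipsoid", list(a = 1)),
               class = "octvol_config_error")
  expect_error(phantom_spec("lens", list(h = 0.6, R = 0.5)),
               class = "octvol_config_error")
  expect_error(phantom_spec("slab_cylinder", list(r = -1, t = 0.1)),
               class = "octvol_config_error")
  expect_warning(phantom_spec("ellipsoid", list(a = 0.5, b = 3, c = 0.5)),
                 class = "octvol_raster_span")
})

test_that("simulated observers: deterministic bias propagation", {
  sp <- phantom_spec("lens", list(h = 0.2, R = 0.5), n_scans = 21L,
                     scan_spacing = 0.06, vertices_per_contour = 48L)
  # noise-free, bias-free: all paired differences exactly 0
  s0 <- simulate_observers(sp, observer_model(0, 0), observer_model(0, 0),
                           n_subjects = 5, seed = 1)
  expect_identical(s0$comparisons$obs1_vs_obs2$value_a,
                   s0$comparisons$obs1_vs_obs2$value_b)
  expect_identical(s0$comparisons$truth_vs_obs1$value_a, s0$true_volumes)

  # obs1 +1% area bias, obs2 unbiased, no noise:
  # every volume difference is exactly +1% of the true volume
  s1 <- simulate_observers(sp, observer_model(0.01, 0),
                           observer_model(0, 0), n_subjects = 5, seed = 1)
  d <- s1$comparisons$obs1_vs_obs2$value_a -
    s1$comparisons$obs1_vs_obs2$value_b
  expect_equal(d, 0.01 * s1$true_volumes, tolerance = 1e-12)
})

test_that("simulation is seed-reproducible bit for bit", {
  sp <- phantom_spec("lens", list(h = 0.2, R = 0.5), n_scans = 15L,
                     scan_spacing = 0.08, vertices_per_contour = 32L)
  a <- simulate_observers(sp, observer_model(0.01, 0.02),
                          observer_model(0, 0.02), n_subjects = 6,
                          seed = 77)
  b <- simulate_observers(sp, observer_model(0.01, 0.02),
                          observer_model(0, 0.02), n_subjects = 6,
                          seed = 77)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$true_volumes, b$true_volumes)
  c2 <- simulate_observers(sp, observer_model(0.01, 0.02),
                           observer_model(0, 0.02), n_subjects = 6,
                           seed = 78)
  expect_false(identical(a$volumes, c2$volumes))
})
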