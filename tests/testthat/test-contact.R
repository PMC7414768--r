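test_that("default grid has 7326 elements with 46 percent meniscus cover", {
  expect_identical(default_grid$n, 7326L)
  expect_lt(abs(default_grid$coverage - 0.46), 0.01)
  # covered elements form the outer annulus
  a <- default_geom$footprint_ap; b <- default_geom$footprint_ml
  p <- default_geom$footprint_exponent
  rho <- (abs(default_grid$x) / a)^p + (abs(default_grid$y) / b)^p
  expect_gt(min(rho[default_grid$covered]), max(rho[!default_grid$covered]) - 1e-12)
})

test_that("element count scales with the inverse square of the spacing", {
  fine <- build_grid(knee_geometry(element_spacing = 1.0))
  expect_lt(abs(fine$n - 7326 / 4) / (7326 / 4), 0.02)
  expect_error(build_grid(knee_geometry(footprint_ap = 0.1,
                                        footprint_ml = 0.1)),
               "too small")
})

test_that("element stress follows the logarithmic spring law", {
  expect_equal(element_stress(4.0, 0), 0)
  expect_equal(element_stress(4.0, 0.5), 2.772589, tolerance = 1e-6)
  # small-strain linearisation
  expect_equal(element_stress(8.6, 0.01), 8.6 * 0.01, tolerance = 1e-2)
  expect_equal(element_stress(8.6, 0.01), 0.08643289, tolerance = 1e-6)
  # strictly increasing and convex
  eps <- seq(0.05, 0.9, by = 0.05)
  s <- element_stress(4, eps)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(diff(s)) > 0))
  expect_error(element_stress(4, 1), "strain")
  expect_error(element_stress(4, -0.1), "strain")
})

test_that("femoral surface is tangent, symmetric, and continuous across the arc transition", {
  h <- default_geom$thickness
  # apex tangency at axis_height = h
  expect_equal(femur_surface_gap(0, 0, 20, h, default_geom), 0,
               tolerance = 1e-12)
  # mediolateral symmetry of the arcs
  y <- seq(0.5, 12, by = 0.5)
  expect_equal(femur_surface_gap(0, y, 20, h, default_geom),
               femur_surface_gap(0, -y, 20, h, default_geom))
  # no jump in the surface when flexion crosses the transition angle
  al <- default_geom$transition_angle
  x <- seq(-20, 20, by = 0.5)
  g_lo <- femur_surface_gap(x, 0, al - 1e-6, h, default_geom)
  g_hi <- femur_surface_gap(x, 0, al + 1e-6, h, default_geom)
  expect_lt(max(abs(g_hi - g_lo)), 1e-5)
  expect_error(femur_surface_gap(100, 0, 20, h, default_geom), "footprint")
  expect_error(femur_surface_gap(0, 0, 95, h, default_geom), "flexion")
})

test_that("contact solver matches the target force and is deterministic", {
  sol0 <- solve_contact(default_grid, 20, 0)
  expect_equal(sol0$peak_strain, 0)
  expect_true(all(sol0$compression == 0))

  sol <- solve_contact(default_grid, 20, 1960)
  # residual oracle: recompute the force from the strain field
  f_check <- sol$grid$area * sum(-sol$grid$E * log1p(-sol$strain))
  expect_equal(f_check, 1960, tolerance = 1e-6)
  expect_true(all(sol$strain >= 0 & sol$strain < 1))
  expect_equal(sol$peak_strain, max(sol$strain))

  sol_b <- solve_contact(default_grid, 20, 1960)
  expect_identical(sol$axis_height, sol_b$axis_height)
  expect_error(solve_contact(default_grid, 20, 1e9), "unreachable")
})

test_that("total force increases as the axis height decreases", {
  heights <- seq(4.5, 2.5, by = -0.5)
  f <- vapply(heights, function(ah) force_at_height(default_grid, 20, ah), 1)
  expect_true(all(diff(f) > 0))
})

test_that("halving the element spacing changes the force by < 1 percent", {
  sol <- solve_contact(default_grid, 20, 1960)
  fine <- build_grid(knee_geometry(element_spacing = 0.25))
  f_fine <- force_at_height(fine, 20, sol$axis_height)
  expect_lt(abs(f_fine - sol$force) / sol$force, 0.01)
})

test_that("a stiffer bed at the same force lowers the peak strain", {
  base <- solve_contact(default_grid, 40, 3778)
  stiff <- solve_contact(default_grid, 40, 3778, modulus_scale = 1.2)
  expect_lt(stiff$peak_strain, base$peak_strain)
})

test_that("flexion angle changes which elements load", {
  walk <- solve_contact(default_grid, 20, 1960)
  run <- solve_contact(default_grid, 40, 1960)
  expect_false(identical(walk$strain > 0, run$strain > 0))
  # deeper flexion engages the smaller posterior arc: smaller loaded area
  expect_lt(run$n_loaded, walk$n_loaded)
})

test_that("peak strain equals a brute-force scan of the exported field", {
  sol <- solve_contact(default_grid, 20, 1500)
  df <- as.data.frame(sol)
  expect_equal(peak_strain(sol), max(df$strain))
  expect_equal(nrow(df), 7326L)
  # single loaded element arithmetic: strain is compression over thickness
  expect_equal(df$strain, df$compression_mm / default_geom$thickness)
})

test_that("series modulus mode yields a softer bed than tibial mode", {
  g_series <- knee_geometry(modulus_mode = "series")
  sol_s <- solve_contact(g_series, 20, 1000)
  sol_t <- solve_contact(default_grid, 20, 1000)
  expect_gt(sol_s$peak_strain, sol_t$peak_strain)
})
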