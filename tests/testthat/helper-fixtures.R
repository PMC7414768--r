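# Shared fixtures: a small seeded cohort and the default geometry/grid.

default_geom <- knee_geometry()
default_grid <- build_grid(default_geom)

small_cohort <- function(n = 4, seed = 11) {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed))
}

# force on the default grid at a fixed axis height, for monotonicity and
# mesh-refinement checks (independent of the solver)
force_at_height <- function(grid, flexion_deg, axis_height, scale = 1) {
  geom <- grid$geometry
  gap <- femur_surface_gap(grid$x, grid$y, flexion_deg, axis_height, geom)
  eps <- pmax(0, -gap) / geom$thickness
  sum(grid$area * -grid$E[eps > 0] * scale * log1p(-eps[eps > 0]))
}
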