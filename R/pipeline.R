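# Cohort-level glue: strains and failure curves for every subject of a
# synthetic cohort under walking / walking+running exposure scenarios.

cohort_rows <- function(cohort, gait) {
  rows <- cohort[cohort$gait == gait, , drop = FALSE]
  if (!nrow(rows)) stop("cohort has no rows for gait '", gait, "'")
  rows[order(rows$subject_id), , drop = FALSE]
}

#' Peak medial cartilage strains for every subject of a cohort
#'
#' Solves the contact model once per subject and gait at the subject's
#' stored peak medial force and flexion angle. Walking strains use the
#' baseline moduli; running strains are computed both with the baseline
#' moduli and with the running modulus scale (stiffer dynamic response).
#'
#' @param cohort a `knee_cohort` (see [generate_cohort()])
#' @param geometry a [knee_geometry()]
#' @return data frame with one row per subject: `subject_id`,
#'   `strain_walk`, `strain_run`, `strain_run_stiff`, plus the peak forces
#'   used
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 1))
#' cohort_strains(coh, knee_geometry())
#' }
cohort_strains <- function(cohort, geometry = knee_geometry()) {
  grid <- build_grid(geometry)
  walk <- cohort_rows(cohort, "walk")
  run <- cohort_rows(cohort, "run")
  stopifnot(identical(walk$subject_id, run$subject_id))
  scale_run <- geometry$running_modulus_scale
  solve_peak <- function(force, flexion, scale)
    peak_strain(solve_contact(grid, flexion, force, modulus_scale = scale))
  data.frame(
    subject_id = walk$subject_id,
    force_walk_n = walk$peak_force_n,
    force_run_n = run$peak_force_n,
    strain_walk = mapply(solve_peak, walk$peak_force_n, walk$flexion_deg, 1.0),
    strain_run = mapply(solve_peak, run$peak_force_n, run$flexion_deg, 1.0),
    strain_run_stiff = mapply(solve_peak, run$peak_force_n, run$flexion_deg,
                              scale_run)
  )
}

#' Per-subject failure curves for an exposure scenario
#'
#' For each subject, solves the contact model under the (optionally
#' adapted) geometry and builds the joint failure curve for the scenario:
#' `"walk"` is walking the full daily distance; `"walkrun"` splits the
#' daily distance equally between walking and running. Running strains use
#' the running modulus scale; walking strains the baseline moduli.
#'
#' @param cohort a `knee_cohort`
#' @param geometry baseline [knee_geometry()]
#' @param params [fatigue_params()]; `params$daily_distance` is the total
#'   daily distance
#' @param scenario `"walk"` or `"walkrun"`
#' @param delta_modulus,delta_thickness,delta_radii adaptation applied to
#'   the geometry (SD multiples, see [apply_adaptation()])
#' @param aggregate element-to-joint aggregation, see [failure_curve()]
#' @param horizon,dt simulation grid, years
#' @return list of per-subject [failure_curve()] objects
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 1))
#' curves <- cohort_failure_curves(coh, scenario = "walk")
#' cohort_report(curves, snapshot_age = 55)
#' }
cohort_failure_curves <- function(cohort, geometry = knee_geometry(),
                                  params = fatigue_params(),
                                  scenario = c("walk", "walkrun"),
                                  delta_modulus = 0, delta_thickness = 0,
                                  delta_radii = 0,
                                  aggregate = "peak",
                                  horizon = 60, dt = 0.05) {
  scenario <- match.arg(scenario)
  geom <- apply_adaptation(geometry, delta_modulus, delta_thickness,
                           delta_radii, sd_table = adaptation_sd(geometry))
  grid <- build_grid(geom)
  walk <- cohort_rows(cohort, "walk")
  run <- cohort_rows(cohort, "run")
  stopifnot(identical(walk$subject_id, run$subject_id))
  dist <- params$daily_distance

  lapply(seq_len(nrow(walk)), function(i) {
    if (scenario == "walk") {
      sol_w <- solve_contact(grid, walk$flexion_deg[i], walk$peak_force_n[i])
      acts <- list(activity("walk", dist, walk$stride_m[i], sol_w))
    } else {
      sol_w <- solve_contact(grid, walk$flexion_deg[i], walk$peak_force_n[i])
      sol_r <- solve_contact(grid, run$flexion_deg[i], run$peak_force_n[i],
                             modulus_scale = geom$running_modulus_scale)
      acts <- list(activity("walk", dist / 2, walk$stride_m[i], sol_w),
                   activity("run", dist / 2, run$stride_m[i], sol_r))
    }
    failure_curve(acts, params, aggregate = aggregate,
                  horizon = horizon, dt = dt)
  })
}

mean_lifetime_p <- function(curves, use_repair = TRUE) {
  field <- if (use_repair) "p_fail_repair" else "p_fail"
  mean(vapply(curves, function(x) x[[field]][length(x$time)], 1))
}

#' Minimal adaptation equalising walk+run and walk-only failure risk
#'
#' Sweeps the adaptation magnitude upward in `step` increments of the
#' between-subject SDs, recomputing strains and failure curves at each
#' step, until the cohort mean lifetime failure probability (with repair)
#' of walking+running half the daily distance each drops to the threshold
#' - by default the mean for walking the full distance with unadapted
#' parameters. `mode` selects which parameters adapt: one of `"modulus"`,
#' `"thickness"`, `"radii"`, or `"all"` (all three simultaneously).
#'
#' @param cohort a `knee_cohort`
#' @param geometry baseline [knee_geometry()]
#' @param params [fatigue_params()]
#' @param mode which parameter(s) to adapt
#' @param step sweep increment, SD multiples
#' @param max_delta sweep cap, SD multiples
#' @param threshold target mean probability; default the unadapted
#'   walk-only mean lifetime probability with repair
#' @param use_repair compare with-repair probabilities (default)
#' @param aggregate element-to-joint aggregation, see [failure_curve()]
#' @param horizon,dt simulation grid, years
#' @return list of class `adaptation_sweep`: `crossing` (first delta at or
#'   below threshold, `NA` if the cap was reached), `threshold`, `mode`,
#'   and `path` (data frame of `delta`, `mean_p`)
#' @export
sweep_required_adaptation <- function(cohort, geometry = knee_geometry(),
                                      params = fatigue_params(),
                                      mode = c("all", "modulus", "thickness", "radii"),
                                      step = 0.05, max_delta = 10,
                                      threshold = NULL, use_repair = TRUE,
                                      aggregate = "peak",
                                      horizon = 60, dt = 0.05) {
  mode <- match.arg(mode)
  stopifnot(step > 0, max_delta >= step)
  if (is.null(threshold)) {
    base <- cohort_failure_curves(cohort, geometry, params, "walk",
                                  aggregate = aggregate,
                                  horizon = horizon, dt = dt)
    threshold <- mean_lifetime_p(base, use_repair)
  }
  deltas <- function(d) {
    on <- switch(mode,
                 all = c(1, 1, 1), modulus = c(1, 0, 0),
                 thickness = c(0, 1, 0), radii = c(0, 0, 1))
    d * on
  }
  path <- data.frame(delta = numeric(0), mean_p = numeric(0))
  crossing <- NA_real_
  for (d in seq(0, max_delta, by = step)) {
    dd <- deltas(d)
    curves <- cohort_failure_curves(cohort, geometry, params, "walkrun",
                                    delta_modulus = dd[1],
                                    delta_thickness = dd[2],
                                    delta_radii = dd[3],
                                    aggregate = aggregate,
                                    horizon = horizon, dt = dt)
    p <- mean_lifetime_p(curves, use_repair)
    path <- rbind(path, data.frame(delta = d, mean_p = p))
    if (p <= threshold) { crossing <- d; break }
  }
  if (is.na(crossing))
    warning("sweep cap of ", max_delta,
            " SD reached without crossing the threshold")
  structure(list(crossing = crossing, threshold = threshold, mode = mode,
                 path = path, use_repair = use_repair),
            class = "adaptation_sweep")
}

#' @export
print.adaptation_sweep <- function(x, ...) {
  cat(sprintf("Adaptation sweep (mode '%s', threshold %.3f):\n",
              x$mode, x$threshold))
  if (is.na(x$crossing)) {
    cat("  threshold not reached before the sweep cap\n")
  } else {
    cat(sprintf("  threshold reached at +%.2f SD (mean P = %.3f)\n",
                x$crossing, x$path$mean_p[nrow(x$path)]))
  }
  invisible(x)
}
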