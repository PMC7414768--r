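# Geometry and material parameters of the medial compartment contact model,
# plus the adaptation arithmetic applied to them.

#' Medial knee contact model geometry and material parameters
#'
#' The medial femoral condyle is a rigid body bounded by two circular arcs
#' in the sagittal plane (a larger anterior arc and a smaller posterior arc,
#' tangent at the transition angle) and a single arc in the frontal plane.
#' The tibial plateau is a concave bowl (one sagittal and one frontal
#' radius) carrying a regular grid of nonlinear compressive springs spaced
#' `element_spacing` apart over a superelliptical footprint. Coordinates:
#' plateau centre origin, x anterior, y lateral, z up (mm).
#'
#' Moduli and their between-subject SDs (for adaptation, see
#' [apply_adaptation()]) are referenced cartilage/meniscus means: femoral
#' 8.6, uncovered tibial 4.0, covered tibial 10.1, meniscus 1.3 MPa; the
#' meniscus covers the outer 46 percent of plateau elements. The combined
#' unloaded (femoral + tibial) cartilage thickness is 5.0 mm, the sagittal
#' anterior femoral radius 35.0 mm and the frontal tibial radius 21.0 mm.
#'
#' The remaining geometric parameters (posterior sagittal femoral radius,
#' frontal femoral radius, sagittal tibial radius, transition angle,
#' footprint half-lengths) are not published for the source cadaver
#' geometry. The defaults here are *calibrated*, not sourced: they were
#' chosen jointly so that (a) the default grid contains 7,326 elements at
#' 0.5 mm spacing, and (b) the cohort-mean walking and running loads produce
#' peak compressive strains of about 0.23 and 0.40 at the default flexion
#' angles (see `scripts/calibrate_geometry.R` in the source repository).
#'
#' `poisson_ratio` is stored and reported for completeness but is unused by
#' the one-dimensional spring law.
#'
#' @param sagittal_femur_radius_anterior,sagittal_femur_radius_posterior mm
#' @param frontal_femur_radius mm (convex)
#' @param frontal_tibia_radius,sagittal_tibia_radius mm (concave)
#' @param transition_angle degrees; flexion angle at which the contact arc
#'   switches from anterior to posterior
#' @param footprint_ap,footprint_ml mm; half-lengths of the plateau
#'   footprint in the anteroposterior and mediolateral directions
#' @param footprint_exponent superellipse exponent of the footprint outline
#' @param element_spacing mm; contact element spacing d
#' @param thickness mm; unloaded combined cartilage thickness h
#' @param E_femoral,E_tibial_uncovered,E_tibial_covered,E_meniscus MPa
#' @param meniscus_coverage fraction of elements covered by the meniscus
#' @param poisson_ratio stored, unused by the spring law
#' @param running_modulus_scale modulus multiplier for running loading rates
#' @param modulus_mode `"tibial"` (default): each element carries the
#'   tibial-side region modulus (uncovered or meniscus-covered tibial
#'   cartilage), the only assignment under which the reference loads are
#'   reachable at the printed strain levels; `"series"`: the series
#'   combination of the layers above the element (femoral + tibial, or
#'   femoral + meniscus + covered tibial, equal thickness shares), a
#'   markedly softer bed
#' @return list of class `knee_geometry`
#' @export
#' @examples
#' geom <- knee_geometry()
#' grid <- build_grid(geom)
#' grid$n
knee_geometry <- function(sagittal_femur_radius_anterior = 35.0,
                          sagittal_femur_radius_posterior = 21.3,
                          frontal_femur_radius = 20.6,
                          frontal_tibia_radius = 21.0,
                          sagittal_tibia_radius = 35.3,
                          transition_angle = 30,
                          footprint_ap = 30.5,
                          footprint_ml = 16.13,
                          footprint_exponent = 4,
                          element_spacing = 0.5,
                          thickness = 5.0,
                          E_femoral = 8.6,
                          E_tibial_uncovered = 4.0,
                          E_tibial_covered = 10.1,
                          E_meniscus = 1.3,
                          meniscus_coverage = 0.46,
                          poisson_ratio = 0.45,
                          running_modulus_scale = 1.2,
                          modulus_mode = c("tibial", "series")) {
  geom <- list(
    sagittal_femur_radius_anterior = sagittal_femur_radius_anterior,
    sagittal_femur_radius_posterior = sagittal_femur_radius_posterior,
    frontal_femur_radius = frontal_femur_radius,
    frontal_tibia_radius = frontal_tibia_radius,
    sagittal_tibia_radius = sagittal_tibia_radius,
    transition_angle = transition_angle,
    footprint_ap = footprint_ap,
    footprint_ml = footprint_ml,
    footprint_exponent = footprint_exponent,
    element_spacing = element_spacing,
    thickness = thickness,
    E_femoral = E_femoral,
    E_tibial_uncovered = E_tibial_uncovered,
    E_tibial_covered = E_tibial_covered,
    E_meniscus = E_meniscus,
    meniscus_coverage = meniscus_coverage,
    poisson_ratio = poisson_ratio,
    running_modulus_scale = running_modulus_scale,
    modulus_mode = match.arg(modulus_mode)
  )
  radii <- geom[grepl("radius", names(geom)) & names(geom) != "poisson_ratio"]
  if (any(unlist(radii) <= 0)) stop("all radii must be > 0")
  moduli <- geom[grepl("^E_", names(geom))]
  if (any(unlist(moduli) <= 0)) stop("all moduli must be > 0")
  if (geom$element_spacing <= 0) stop("element spacing d must be > 0")
  if (geom$thickness <= 0) stop("unloaded thickness h must be > 0")
  if (geom$meniscus_coverage <= 0 || geom$meniscus_coverage >= 1)
    stop("meniscus coverage must lie in (0, 1)")
  if (geom$transition_angle < 0 || geom$transition_angle > 90)
    stop("transition angle must lie in [0, 90] degrees")
  structure(geom, class = "knee_geometry")
}

#' @export
print.knee_geometry <- function(x, ...) {
  cat("Medial knee contact geometry\n")
  cat(sprintf("  femur radii (mm): sagittal %.1f (ant) / %.1f (post), frontal %.1f; transition %.0f deg\n",
              x$sagittal_femur_radius_anterior, x$sagittal_femur_radius_posterior,
              x$frontal_femur_radius, x$transition_angle))
  cat(sprintf("  tibia radii (mm): sagittal %.1f, frontal %.1f (concave bowl)\n",
              x$sagittal_tibia_radius, x$frontal_tibia_radius))
  cat(sprintf("  footprint half-lengths (mm): AP %.2f, ML %.2f (exponent %g); d = %.2f mm; h = %.1f mm\n",
              x$footprint_ap, x$footprint_ml, x$footprint_exponent,
              x$element_spacing, x$thickness))
  cat(sprintf("  moduli (MPa): femoral %.1f, tibial %.1f (uncovered) / %.1f (covered), meniscus %.1f; coverage %.2f; mode '%s'\n",
              x$E_femoral, x$E_tibial_uncovered, x$E_tibial_covered,
              x$E_meniscus, x$meniscus_coverage, x$modulus_mode))
  invisible(x)
}

#' Between-subject standard deviations of the adaptable parameters
#'
#' Referenced SDs: femoral modulus 2.3, covered tibial modulus 2.2,
#' uncovered tibial modulus 1.6, meniscus modulus 0.6 MPa; thickness
#' 1.5 mm; sagittal anterior femoral radius 4.1 mm (11.7 percent of the
#' mean). Radii of curvature all share that relative SD (11.7 percent of
#' each radius's own mean): a radius adaptation then scales the whole
#' articulating geometry uniformly, so joint congruence improves
#' monotonically with the adaptation magnitude and the published anterior
#' femoral radius examples are reproduced exactly. The published frontal
#' tibial SD (2.3 mm, 11.0 percent) is within 1 percentage point of the
#' shared value.
#'
#' @param geometry a [knee_geometry()]
#' @return named vector of SDs in the units of each parameter
#' @export
adaptation_sd <- function(geometry = knee_geometry()) {
  cv_radius <- 4.1 / 35.0
  c(E_femoral = 2.3,
    E_tibial_covered = 2.2,
    E_tibial_uncovered = 1.6,
    E_meniscus = 0.6,
    thickness = 1.5,
    sagittal_femur_radius_anterior = 4.1,
    frontal_tibia_radius = cv_radius * geometry$frontal_tibia_radius,
    sagittal_femur_radius_posterior = cv_radius * geometry$sagittal_femur_radius_posterior,
    frontal_femur_radius = cv_radius * geometry$frontal_femur_radius,
    sagittal_tibia_radius = cv_radius * geometry$sagittal_tibia_radius)
}

#' Apply a positive adaptation to the contact geometry
#'
#' Each targeted parameter is increased in a single step to
#' `mean + delta * SD`, before any failure simulation: `delta_modulus`
#' raises all four moduli by their own SDs, `delta_thickness` the unloaded
#' cartilage thickness, and `delta_radii` all femoral and tibial radii of
#' curvature by their own SDs (increasing congruence of the joint).
#'
#' @param geometry a [knee_geometry()] (adaptation is always applied to the
#'   supplied baseline, not compounded)
#' @param delta_modulus,delta_thickness,delta_radii adaptation magnitudes in
#'   SD multiples (>= 0)
#' @param sd_table named SD vector, defaults to [adaptation_sd()] of the
#'   baseline geometry
#' @return the adapted `knee_geometry`
#' @export
#' @examples
#' g <- apply_adaptation(knee_geometry(), delta_modulus = 2.60)
#' g$E_tibial_covered # 10.1 + 2.60 * 2.2 = 15.8 MPa
apply_adaptation <- function(geometry, delta_modulus = 0, delta_thickness = 0,
                             delta_radii = 0, sd_table = adaptation_sd(geometry)) {
  stopifnot(delta_modulus >= 0, delta_thickness >= 0, delta_radii >= 0,
            all(sd_table > 0))
  g <- unclass(geometry)
  bump <- function(field, delta) g[[field]] + delta * sd_table[[field]]
  for (f in c("E_femoral", "E_tibial_covered", "E_tibial_uncovered", "E_meniscus"))
    g[[f]] <- bump(f, delta_modulus)
  g[["thickness"]] <- bump("thickness", delta_thickness)
  for (f in c("sagittal_femur_radius_anterior", "sagittal_femur_radius_posterior",
              "frontal_femur_radius", "frontal_tibia_radius", "sagittal_tibia_radius"))
    g[[f]] <- bump(f, delta_radii)
  structure(g, class = "knee_geometry")
}
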