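# Discrete-element (elastic foundation) contact model of the medial
# tibiofemoral compartment. A rigid femoral condyle is pressed into a bed
# of independent nonlinear compressive springs on the tibial plateau; the
# flexion-axis height is solved so that the summed spring forces match a
# target contact force, yielding the compressive strain field.

#' Build the contact element grid on the tibial plateau
#'
#' Elements are laid on a regular grid with spacing `d` (x anterior on
#' half-offset positions, y lateral on integer offsets) inside the
#' superelliptical plateau footprint. The outer annulus of elements (by
#' normalised footprint radius) is labelled meniscus-covered so that the
#' covered element fraction is as close as possible to the nominal
#' coverage. Each element's modulus is the series combination of the
#' cartilage (and meniscus) layers above it, sharing the unloaded
#' thickness `h` equally; with `modulus_mode = "tibial"` the tibial-side
#' modulus is used directly.
#'
#' With the default geometry the grid has exactly 7,326 elements at
#' d = 0.5 mm.
#'
#' @param geometry a [knee_geometry()]
#' @return list of class `element_grid`: `x`, `y` (mm), `covered`
#'   (logical), `E` (MPa), `area` (mm^2), `n`, `coverage` (achieved
#'   fraction), `geometry`
#' @export
#' @examples
#' grid <- build_grid(knee_geometry())
#' c(grid$n, grid$coverage)
build_grid <- function(geometry) {
  stopifnot(inherits(geometry, "knee_geometry"))
  d <- geometry$element_spacing
  a <- geometry$footprint_ap
  b <- geometry$footprint_ml
  p <- geometry$footprint_exponent

  kx <- ceiling(a / d)
  ky <- ceiling(b / d)
  xs <- (seq(-kx, kx - 1L) + 0.5) * d
  ys <- seq(-ky, ky) * d
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  rho <- (abs(g$x) / a)^p + (abs(g$y) / b)^p
  inside <- rho <= 1
  if (!any(inside)) stop("footprint too small to contain any element")
  x <- g$x[inside]; y <- g$y[inside]; rho <- rho[inside]
  n <- length(x)

  n_cov <- round(geometry$meniscus_coverage * n)
  # covered = outer annulus by normalised radius, sized by element count
  covered <- rank(rho, ties.method = "first") > (n - n_cov)

  E <- element_modulus(geometry, covered)
  structure(list(x = x, y = y, covered = covered, E = E,
                 area = d^2, n = n, coverage = mean(covered),
                 geometry = geometry),
            class = "element_grid")
}

element_modulus <- function(geometry, covered) {
  series <- function(...) {
    mods <- c(...)
    length(mods) / sum(1 / mods)
  }
  if (geometry$modulus_mode == "series") {
    e_unc <- series(geometry$E_femoral, geometry$E_tibial_uncovered)
    e_cov <- series(geometry$E_femoral, geometry$E_meniscus,
                    geometry$E_tibial_covered)
  } else {
    e_unc <- geometry$E_tibial_uncovered
    e_cov <- geometry$E_tibial_covered
  }
  ifelse(covered, e_cov, e_unc)
}

#' Nonlinear element stress-strain law
#'
#' `sigma = -E * log(1 - strain)`: strictly increasing and convex in the
#' strain, asymptoting as the strain approaches 1, and reducing to
#' `E * strain` in the small-strain limit.
#'
#' @param E element modulus, MPa
#' @param strain compressive strain in `[0, 1)`
#' @return contact stress, MPa
#' @export
#' @examples
#' element_stress(4.0, 0.5) # 2.7726 MPa
element_stress <- function(E, strain) {
  if (any(strain < 0 | strain >= 1)) stop("strain must lie in [0, 1)")
  -E * log(1 - strain)
}

# Vertical position of the femoral surface above the plateau origin, minus
# the axis height: the full femoral surface is z = axis_height + fem_profile.
# The sagittal section is the anterior arc (radius Ra, centred on the
# flexion axis for flexion <= alpha) joined tangentially to the posterior
# arc (radius Rp); flexing by theta rotates the posterior arc centre about
# the anterior one, so the surface is continuous in both x and theta.
# axis_height is expressed so that at flexion <= alpha the condyle apex
# sits exactly at z = axis_height.
femur_profile <- function(x, y, flexion_deg, geometry) {
  ra <- geometry$sagittal_femur_radius_anterior
  rp <- geometry$sagittal_femur_radius_posterior
  rf <- geometry$frontal_femur_radius
  alpha <- geometry$transition_angle * pi / 180
  theta <- flexion_deg * pi / 180

  phi <- theta - alpha
  x_t <- ra * sin(phi)                      # arc transition, tibia frame
  cx <- (ra - rp) * sin(phi)                # posterior arc centre
  cz <- ra - (ra - rp) * cos(phi)          # relative to z_axis - ra

  z <- rep(Inf, length(x))
  ant <- x >= x_t & abs(x) < ra
  z[ant] <- ra - sqrt(ra^2 - x[ant]^2)
  post <- x < x_t & abs(x - cx) < rp
  z[post] <- cz - sqrt(rp^2 - (x[post] - cx)^2)

  drop_y <- rf - sqrt(pmax(0, rf^2 - y^2))
  drop_y[abs(y) >= rf] <- Inf
  z + drop_y
}

# Height of the subchondral tibial bowl above the plateau origin.
tibia_profile <- function(x, y, geometry) {
  rs <- geometry$sagittal_tibia_radius
  rt <- geometry$frontal_tibia_radius
  (rs - sqrt(rs^2 - x^2)) + (rt - sqrt(rt^2 - y^2))
}

#' Gap between the femoral surface and the unloaded cartilage top
#'
#' Signed vertical distance (mm) at plateau position `(x, y)` between the
#' femoral bone surface and the top of the undeformed cartilage layer
#' (tibial bowl + unloaded thickness `h`). Negative gaps are spring
#' compressions. `axis_height` is the height of the condyle apex above the
#' plateau centre bone surface (for flexion at or below the transition
#' angle); with `axis_height = h` the apex exactly touches the cartilage
#' top.
#'
#' @param x,y element coordinates, mm (must lie inside the footprint)
#' @param flexion_deg knee flexion angle in `[0, 90]` degrees
#' @param axis_height mm
#' @param geometry a [knee_geometry()]
#' @return signed gap, mm (`Inf` where the femoral arcs do not cover the
#'   point)
#' @export
#' @examples
#' g <- knee_geometry()
#' femur_surface_gap(0, 0, 20, g$thickness, g) # tangent: zero gap
femur_surface_gap <- function(x, y, flexion_deg, axis_height, geometry) {
  if (any(flexion_deg < 0 | flexion_deg > 90))
    stop("flexion angle must lie in [0, 90] degrees")
  p <- geometry$footprint_exponent
  out_fp <- (abs(x) / geometry$footprint_ap)^p +
    (abs(y) / geometry$footprint_ml)^p > 1 + 1e-9
  if (any(out_fp)) stop("point outside the plateau footprint")
  fem <- axis_height + femur_profile(x, y, flexion_deg, geometry)
  fem - (tibia_profile(x, y, geometry) + geometry$thickness)
}

#' Solve the contact problem for a target medial contact force
#'
#' Per-element compressions are `max(0, -gap)`; strains are compression
#' over the unloaded thickness `h`; stresses follow [element_stress()];
#' and the total force is `d^2 * sum(sigma_i)` (MPa * mm^2 = N). The
#' flexion-axis height is found by a bracketing root search so the total
#' force matches `target_force` to relative tolerance `tol`. The flexion
#' angle selects the contacting femoral arc and therefore the loaded area.
#'
#' @param geometry a [knee_geometry()], or a prebuilt [build_grid()]
#'   (reusing a grid across solves avoids rebuilding it)
#' @param flexion_deg knee flexion angle, degrees
#' @param target_force N (>= 0)
#' @param modulus_scale multiplier on all element moduli (1.2 emulates the
#'   stiffer dynamic response at running loading rates)
#' @param tol relative force tolerance
#' @return list of class `contact_solution`: `compression`, `strain`,
#'   `stress` per element; `force` (achieved, N), `peak_strain`,
#'   `axis_height` (mm), `n_loaded`, `element_volume` (mm^3, d^2 * h for
#'   loaded elements), `grid`, `flexion_deg`, `modulus_scale`
#' @export
#' @examples
#' sol <- solve_contact(knee_geometry(), 20, 1960)
#' sol$peak_strain
solve_contact <- function(geometry, flexion_deg, target_force,
                          modulus_scale = 1.0, tol = 1e-6) {
  grid <- if (inherits(geometry, "element_grid")) geometry else build_grid(geometry)
  geom <- grid$geometry
  if (target_force < 0) stop("target force must be >= 0")
  h <- geom$thickness
  E <- grid$E * modulus_scale

  # gap offset at axis_height = 0; compression(ah) = pmax(0, K - ah)
  K <- -femur_surface_gap(grid$x, grid$y, flexion_deg, 0, geom)
  k_max <- max(K)

  force_at <- function(ah) {
    eps <- pmax(0, K - ah) / h
    grid$area * sum(-E[eps > 0] * log1p(-eps[eps > 0]))
  }

  if (target_force == 0) {
    ah <- k_max
  } else {
    lo <- k_max - h * (1 - 1e-12)
    f_lo <- force_at(lo)
    if (f_lo < target_force)
      stop(sprintf("target force unreachable before full compression (max achievable %.1f N)", f_lo))
    root <- uniroot(function(ah) force_at(ah) - target_force,
                    lower = lo, upper = k_max,
                    tol = .Machine$double.eps^0.5 * h)
    ah <- root$root
    # polish with a couple of Newton steps on the smooth force function
    for (i in 1:5) {
      f <- force_at(ah)
      if (abs(f - target_force) <= tol * target_force) break
      dah <- 1e-7 * h
      dfda <- (force_at(ah + dah) - f) / dah
      ah <- ah - (f - target_force) / dfda
    }
    if (abs(force_at(ah) - target_force) > tol * target_force)
      stop("contact solver failed to reach the force tolerance")
  }

  compression <- pmax(0, K - ah)
  strain <- compression / h
  stress <- ifelse(strain > 0, -E * log1p(-strain), 0)
  loaded <- strain > 0
  structure(list(compression = compression, strain = strain, stress = stress,
                 force = grid$area * sum(stress), peak_strain = max(strain),
                 axis_height = ah, n_loaded = sum(loaded),
                 element_volume = grid$area * h,
                 grid = grid, flexion_deg = flexion_deg,
                 modulus_scale = modulus_scale,
                 target_force = target_force),
            class = "contact_solution")
}

#' Peak compressive strain of a contact solution
#'
#' The greatest strain in any element.
#'
#' @param solution a [solve_contact()] result
#' @return dimensionless strain
#' @export
peak_strain <- function(solution) {
  stopifnot(inherits(solution, "contact_solution"))
  if (!length(solution$strain)) stop("empty element grid")
  max(solution$strain)
}

#' @export
print.contact_solution <- function(x, ...) {
  cat(sprintf("Contact solution: %.1f N at %.0f deg flexion (modulus scale %.1f)\n",
              x$force, x$flexion_deg, x$modulus_scale))
  cat(sprintf("  peak strain %.3f; %d/%d elements loaded; axis height %.3f mm\n",
              x$peak_strain, x$n_loaded, x$grid$n, x$axis_height))
  invisible(x)
}

#' @export
summary.contact_solution <- function(object, ...) {
  s <- object$strain[object$strain > 0]
  out <- list(force = object$force, peak_strain = object$peak_strain,
              mean_loaded_strain = if (length(s)) mean(s) else 0,
              n_loaded = object$n_loaded,
              loaded_area = object$n_loaded * object$grid$area,
              loaded_volume = object$n_loaded * object$element_volume)
  class(out) <- "summary.contact_solution"
  out
}

#' @export
print.summary.contact_solution <- function(x, ...) {
  cat(sprintf("force %.1f N | peak strain %.3f | mean loaded strain %.3f\n",
              x$force, x$peak_strain, x$mean_loaded_strain))
  cat(sprintf("loaded: %d elements, %.0f mm^2, %.0f mm^3\n",
              x$n_loaded, x$loaded_area, x$loaded_volume))
  invisible(x)
}

#' Export a strain field as a data frame
#'
#' One row per element with position, meniscus-coverage region, strain and
#' stress; suitable for `write.csv`.
#'
#' @param x a `contact_solution`
#' @param ... unused
#' @return data frame with columns `x_mm`, `y_mm`, `region`, `compression_mm`,
#'   `strain`, `stress_mpa`
#' @export
as.data.frame.contact_solution <- function(x, ...) {
  data.frame(x_mm = x$grid$x, y_mm = x$grid$y,
             region = ifelse(x$grid$covered, "covered", "uncovered"),
             compression_mm = x$compression,
             strain = x$strain, stress_mpa = x$stress)
}

#' @export
plot.contact_solution <- function(x, what = c("strain", "stress"), ...) {
  what <- match.arg(what)
  xs <- sort(unique(x$grid$x)); ys <- sort(unique(x$grid$y))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(x$grid$x, xs), match(x$grid$y, ys))] <- x[[what]]
  image(xs, ys, z, xlab = "x (anterior, mm)", ylab = "y (lateral, mm)",
        main = sprintf("%s field, %.0f N at %.0f deg", what, x$force,
                       x$flexion_deg), ...)
  invisible(x)
}
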