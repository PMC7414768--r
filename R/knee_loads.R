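# Reduction model of medial knee loading.
#
# Joint moments are resolved into a small set of muscle forces using
# moment arms and PCSA weighting, then the medial/lateral split of the
# axial tibiofemoral force follows from a frontal-plane moment balance
# about the lateral contact point.
#
# Sign conventions: knee extension, hip extension, ankle plantarflexion,
# and knee adduction moments are positive; moments are expressed in the
# shank reference frame. Negative computed forces are clamped at zero.

#' Musculoskeletal parameters for the knee load reduction model
#'
#' Moment arms are quadratic functions of the relevant joint angle,
#' `arm(theta) = a0 + a1*theta + a2*theta^2` (metres, theta in degrees).
#' The Achilles and patellar tendon arms additionally lengthen linearly
#' with tendon force up to a cap of 1.0 cm. The default coefficient tables
#' are editable stand-ins producing physiologic arm magnitudes (patellar
#' tendon ~4-5 cm, Achilles ~5 cm); they are not measurements from any
#' specific source and can be replaced via the `moment_arms` argument or a
#' CSV with columns `muscle, a0, a1, a2`.
#'
#' @param specific_tension muscle specific tension, N/cm^2 (typical range
#'   20-60; used only to cap muscle forces at PCSA * specific tension)
#' @param pcsa named vector of group physiological cross-sectional areas,
#'   cm^2
#' @param moment_arms data frame with columns `muscle, a0, a1, a2`; rows
#'   `patellar_tendon` (knee angle), `hamstrings_hip` (hip angle),
#'   `hamstrings_knee`, `gastrocnemius_knee` (knee angle),
#'   `achilles` (ankle angle)
#' @param tendon_arm_gain m/N; force-dependent lengthening of the patellar
#'   and Achilles tendon arms
#' @param tendon_arm_cap m; maximum force-dependent lengthening (1.0 cm)
#' @param medial_offset,lateral_offset m; frontal-plane lever arms of the
#'   medial and lateral contact points about the joint centre
#' @param ligaments optional data frame of piecewise-linear ligament force
#'   rules (columns `ligament, axial_fraction`); `NULL` (default) applies
#'   zero ligament force
#' @return list of class `msk_params`
#' @export
msk_params <- function(specific_tension = 40,
                       pcsa = c(quadriceps = 180, hamstrings = 120,
                                triceps_surae = 180),
                       moment_arms = default_moment_arms(),
                       tendon_arm_gain = 2e-6,
                       tendon_arm_cap = 0.01,
                       medial_offset = 0.025,
                       lateral_offset = 0.025,
                       ligaments = NULL) {
  stopifnot(specific_tension >= 20, specific_tension <= 60,
            all(pcsa > 0), medial_offset > 0, lateral_offset > 0,
            tendon_arm_cap <= 0.01 + 1e-12)
  need <- c("patellar_tendon", "hamstrings_hip", "hamstrings_knee",
            "gastrocnemius_knee", "achilles")
  if (!all(need %in% moment_arms$muscle))
    stop("moment_arms must define rows: ", paste(need, collapse = ", "))
  structure(list(specific_tension = specific_tension, pcsa = pcsa,
                 moment_arms = moment_arms,
                 tendon_arm_gain = tendon_arm_gain,
                 tendon_arm_cap = tendon_arm_cap,
                 medial_offset = medial_offset,
                 lateral_offset = lateral_offset,
                 ligaments = ligaments),
            class = "msk_params")
}

#' @rdname msk_params
#' @export
default_moment_arms <- function() {
  data.frame(
    muscle = c("patellar_tendon", "hamstrings_hip", "hamstrings_knee",
               "gastrocnemius_knee", "achilles"),
    a0 = c(0.045, 0.060, 0.030, 0.020, 0.050),
    a1 = c(-1.5e-4, 0, 0, 0, 0),
    a2 = c(0, 0, 0, 0, 0)
  )
}

moment_arm <- function(params, muscle, angle_deg) {
  row <- params$moment_arms[params$moment_arms$muscle == muscle, , drop = FALSE]
  if (nrow(row) != 1L) stop("no moment arm defined for ", muscle)
  arm <- row$a0 + row$a1 * angle_deg + row$a2 * angle_deg^2
  if (any(arm <= 0)) stop("moment arm for ", muscle,
                          " is non-positive over the motion range")
  arm
}

# Solve F = M / (arm0 + min(gain*F, cap)) per sample by damped fixed-point
# iteration; the map is a contraction for gain*M/arm0^2 < 1, which holds
# comfortably for physiologic gains.
tendon_force_fixed_point <- function(moment, arm0, gain, cap,
                                     tol = 1e-6, max_iter = 100) {
  m <- pmax(0, moment)
  f <- m / arm0
  for (i in seq_len(max_iter)) {
    f_new <- m / (arm0 + pmin(gain * f, cap))
    done <- all(abs(f_new - f) <= tol * pmax(f_new, 1e-9))
    f <- f_new
    if (done) return(f)
  }
  stop("tendon moment-arm fixed point failed to converge in ",
       max_iter, " iterations")
}

#' Patellar tendon force from the net knee extension moment
#'
#' Divides the knee extension moment, after subtracting antagonist knee
#' flexion moments, by the (force-dependent) patellar tendon moment arm.
#' The force-dependent arm is solved by fixed-point iteration to relative
#' tolerance 1e-6; non-convergence within 100 iterations is an error.
#'
#' @param knee_ext_nm knee extension moment trace, N*m (net of antagonists)
#' @param knee_angle_deg knee flexion angle trace, degrees
#' @param params [msk_params()]
#' @return patellar tendon force trace, N (clamped at >= 0)
#' @export
#' @examples
#' p <- msk_params(tendon_arm_gain = 0)
#' patellar_tendon_force(40, 0, p) # 40 / 0.045
patellar_tendon_force <- function(knee_ext_nm, knee_angle_deg, params = msk_params()) {
  arm0 <- moment_arm(params, "patellar_tendon", knee_angle_deg)
  tendon_force_fixed_point(knee_ext_nm, arm0,
                           params$tendon_arm_gain, params$tendon_arm_cap)
}

#' Distribute a joint moment into agonist muscle forces by PCSA weighting
#'
#' Forces are proportional to physiological cross-sectional area and
#' together reconstruct the input moment exactly:
#' `F_i = M * w_i / sum_j(w_j * arm_j)` with `w` the PCSA shares, so that
#' `sum(F_i * arm_i) = M`.
#'
#' @param moment_nm joint moment, N*m
#' @param pcsa vector of muscle PCSAs, cm^2
#' @param arms vector of muscle moment arms, m
#' @return vector of muscle forces, N
#' @export
#' @examples
#' distribute_muscle_forces(10, c(1, 1), c(0.05, 0.05)) # 100 N each
distribute_muscle_forces <- function(moment_nm, pcsa, arms) {
  stopifnot(length(pcsa) == length(arms), all(arms > 0))
  if (all(pcsa == 0)) stop("all-zero PCSA weights")
  w <- pcsa / sum(pcsa)
  moment_nm * w / sum(w * arms)
}

#' Medial and lateral knee contact forces from a moment trace
#'
#' Computes the muscle forces of the reduction model (patellar tendon from
#' the knee extension moment net of hamstrings and gastrocnemius
#' antagonism, hamstrings from the hip extension moment, gastrocnemius
#' from the ankle plantarflexion moment), sums them into the axial
#' tibiofemoral force, and splits it between compartments by balancing
#' moments about the lateral contact point:
#' `F_med = (M_add + F_ax * d_lat) / (d_med + d_lat)`, `F_lat = F_ax - F_med`,
#' both clamped at zero. Ligament forces default to zero unless a rule
#' table is supplied in `params$ligaments`.
#'
#' @param trace a `moment_trace` (see [generate_moment_traces()]) or data
#'   frame with the same columns
#' @param params [msk_params()]
#' @return data frame with columns `time_s`, `patellar_n`, `hamstrings_n`,
#'   `gastrocnemius_n`, `axial_n`, `medial_n`, `lateral_n`
#' @export
medial_contact_force <- function(trace, params = msk_params()) {
  tr <- as.data.frame(trace)
  need <- c("time_s", "knee_ext_nm", "hip_ext_nm", "ankle_pf_nm",
            "knee_add_nm", "knee_angle_deg", "hip_angle_deg", "ankle_angle_deg")
  missing <- setdiff(need, names(tr))
  if (length(missing)) stop("trace lacks columns: ", paste(missing, collapse = ", "))

  f_ham <- pmax(0, tr$hip_ext_nm) / moment_arm(params, "hamstrings_hip", tr$hip_angle_deg)
  f_gas <- tendon_force_fixed_point(
    tr$ankle_pf_nm, moment_arm(params, "achilles", tr$ankle_angle_deg),
    params$tendon_arm_gain, params$tendon_arm_cap)

  antagonist_nm <- f_ham * moment_arm(params, "hamstrings_knee", tr$knee_angle_deg) +
    f_gas * moment_arm(params, "gastrocnemius_knee", tr$knee_angle_deg)
  f_pt <- patellar_tendon_force(tr$knee_ext_nm - antagonist_nm,
                                tr$knee_angle_deg, params)

  # cap at maximum isometric force (PCSA * specific tension, cm^2 * N/cm^2)
  caps <- params$pcsa * params$specific_tension
  f_pt <- pmin(f_pt, caps[["quadriceps"]])
  f_ham <- pmin(f_ham, caps[["hamstrings"]])
  f_gas <- pmin(f_gas, caps[["triceps_surae"]])

  f_lig <- 0
  if (!is.null(params$ligaments)) {
    f_lig <- sum(pmax(0, params$ligaments$axial_fraction)) * (f_pt + f_ham + f_gas)
  }

  f_ax <- f_pt + f_ham + f_gas + f_lig
  d_m <- params$medial_offset
  d_l <- params$lateral_offset
  if (d_m + d_l <= 0) stop("degenerate inter-contact distance")
  f_med <- pmax(0, (tr$knee_add_nm + f_ax * d_l) / (d_m + d_l))
  f_lat <- pmax(0, f_ax - f_med)

  data.frame(time_s = tr$time_s, patellar_n = f_pt, hamstrings_n = f_ham,
             gastrocnemius_n = f_gas, axial_n = f_ax,
             medial_n = f_med, lateral_n = f_lat)
}

#' Cumulative medial knee load per unit distance
#'
#' The stride-average medial contact force, in bodyweights, divided by the
#' stride length: `(mean_force / bodyweight) / stride_length` in BW/m.
#'
#' @param mean_force_n stride-average medial contact force, N
#' @param stride_m stride length, m (> 0)
#' @param bodyweight_n subject bodyweight, N
#' @return cumulative load, BW/m
#' @export
#' @examples
#' cumulative_load(676, 1.55, 676) # 1 BW mean force -> 0.645 BW/m
cumulative_load <- function(mean_force_n, stride_m, bodyweight_n) {
  stopifnot(all(bodyweight_n > 0))
  if (any(stride_m <= 0)) stop("stride length must be > 0")
  (mean_force_n / bodyweight_n) / stride_m
}
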