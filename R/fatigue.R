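# Probabilistic fatigue of cartilage under cyclic gait loading: Weibull
# damage with stressed-volume scaling, a strain-life power law, competing
# repair, and linear (Miner) accumulation across activities.

#' Failure probability model parameters
#'
#' Defaults are the reference parameter set: power-law coefficient C = 1.0
#' and exponent n = 12.9 (cycles to failure `N_f = C * eps^-n`), Weibull
#' coefficient b = 1.03 and exponent m = 14.3, reference stressed volume
#' 78.5 mm^3, repair time constant 5.0 years with repair exponent 5.2, and
#' a daily travel distance of 6,000 m/day. The time base is 365 days/year;
#' one loading cycle per knee per stride, so steps/day is twice the
#' cycles/day of one knee.
#'
#' @param C power-law coefficient (cycles)
#' @param n power-law exponent (> 1)
#' @param b Weibull coefficient (strain offset factor)
#' @param m Weibull exponent (> 1; scatter of the failure data)
#' @param V_ref reference stressed volume, mm^3
#' @param t_r repair time constant, years (63.2 percent of damage repaired
#'   by `t_r`); `Inf` disables repair
#' @param v repair exponent
#' @param daily_distance default total distance travelled, m/day
#' @return list of class `fatigue_params`
#' @export
fatigue_params <- function(C = 1.0, n = 12.9, b = 1.03, m = 14.3,
                           V_ref = 78.5, t_r = 5.0, v = 5.2,
                           daily_distance = 6000) {
  stopifnot(C > 0, n > 1, b > 0, m > 1, V_ref > 0, t_r > 0, v > 0,
            daily_distance >= 0)
  structure(list(C = C, n = n, b = b, m = m, V_ref = V_ref,
                 t_r = t_r, v = v, daily_distance = daily_distance),
            class = "fatigue_params")
}

#' Loading cycles per day for a daily distance and stride length
#'
#' One knee is loaded once per stride: `cycles/day = distance / stride`.
#' Steps per day (both limbs) is twice this value.
#'
#' @param daily_distance m/day (>= 0)
#' @param stride_m stride length, m (> 0)
#' @return cycles per day (per knee)
#' @export
#' @examples
#' cycles_per_day(6000, 1.55) # 3871 cycles/day = 7742 steps/day
cycles_per_day <- function(daily_distance, stride_m) {
  if (any(stride_m <= 0)) stop("stride length must be > 0")
  stopifnot(all(daily_distance >= 0))
  daily_distance / stride_m
}

#' Time to failure from the strain-life power law
#'
#' `t_f = C * (b * strain)^-n / cycles_per_day`, converted to years at
#' 365 days/year. Zero cycles or zero strain give an infinite fatigue
#' life; `b * strain >= 1` (sub-single-cycle life) is allowed but flagged
#' with a warning.
#'
#' @param strain peak element compressive strain in `(0, 1)`
#' @param params [fatigue_params()]
#' @param cycles cycles per day, see [cycles_per_day()]
#' @return years until 63.2 percent failure probability at reference volume
#' @export
#' @examples
#' time_to_failure(0.23, fatigue_params(), 5000) # ~64 years
time_to_failure <- function(strain, params = fatigue_params(), cycles) {
  stopifnot(all(strain >= 0 & strain < 1), all(cycles >= 0))
  if (any(params$b * strain >= 1))
    warning("b * strain >= 1: predicted life is below one loading cycle")
  ifelse(strain > 0 & cycles > 0,
         params$C * (params$b * strain)^(-params$n) / (cycles * 365),
         Inf)
}

#' Cumulative failure probability without repair
#'
#' `P_f(t) = 1 - exp(-(V/V_ref) * (t/t_f)^(m/n))`: a Weibull cumulative
#' distribution in time with shape `m/n`, scale `t_f`, and weakest-link
#' scaling by the stressed volume `V`.
#'
#' @param t time, years (>= 0)
#' @param t_f time to failure, years (> 0)
#' @param V stressed volume, mm^3 (> 0)
#' @param params [fatigue_params()]
#' @return probability in `[0, 1)`
#' @export
#' @examples
#' p_fail(64.1, 64.1, 78.5) # 0.632 at t = t_f, V = V_ref
p_fail <- function(t, t_f, V, params = fatigue_params()) {
  stopifnot(all(t >= 0), all(t_f > 0), all(V > 0))
  1 - exp(-(V / params$V_ref) * (t / t_f)^(params$m / params$n))
}

#' Instantaneous failure probability density
#'
#' The time derivative of [p_fail()]:
#' `Q_f(t) = (V*m / (n*V_ref*t_f)) * (t/t_f)^(m/n - 1) *
#'  exp(-(V/V_ref)*(t/t_f)^(m/n))`, in 1/years.
#'
#' @inheritParams p_fail
#' @return density, 1/years
#' @export
q_fail <- function(t, t_f, V, params = fatigue_params()) {
  stopifnot(all(t >= 0), all(t_f > 0), all(V > 0))
  kappa <- params$m / params$n
  ratio <- t / t_f
  # guard t = 0 (kappa > 1 for the defaults, so the density vanishes there)
  dens <- (V * params$m / (params$n * params$V_ref * t_f)) *
    ifelse(ratio > 0, ratio^(kappa - 1), if (kappa > 1) 0 else NA_real_) *
    exp(-(V / params$V_ref) * ratio^kappa)
  dens
}

#' Cumulative probability of natural repair
#'
#' `P_r(t) = 1 - exp(-(t/t_r)^v)`: 63.2 percent of damage is expected to
#' have repaired after the repair time constant `t_r`.
#'
#' @param t time, years (>= 0)
#' @param params [fatigue_params()]
#' @return probability in `[0, 1)`
#' @export
#' @examples
#' p_repair(5, fatigue_params()) # 0.632 at t = t_r
p_repair <- function(t, params = fatigue_params()) {
  stopifnot(all(t >= 0))
  if (!is.finite(params$t_r)) return(rep(0, length(t)))
  1 - exp(-(t / params$t_r)^params$v)
}

# Cumulative integral of Q_f(tau) * (1 - P_r(tau)) on the grid t, for a
# Weibull hazard H(tau) = K * tau^kappa. Evaluated by substituting
# u = P_f(tau) = 1 - exp(-K tau^kappa), under which the failure density
# becomes uniform: integral = int_0^{P_f(t)} (1 - P_r(tau(u))) du. This is
# exact for any K, including the short-fatigue-life regime where the
# failure density is a spike far inside the first time step. Composite
# Simpson with midpoints on a fixed fine u-grid, then interpolated back to
# the requested times.
cum_repair_integral <- function(K, kappa, t, params, n_grid = 4000) {
  u_max <- -expm1(-K * max(t)^kappa)
  if (u_max <= 0) return(numeric(length(t)))
  tau_of <- function(u) (-log1p(-u) / K)^(1 / kappa)
  u <- seq(0, u_max, length.out = n_grid + 1)
  um <- (u[-1] + u[-length(u)]) / 2
  g <- function(uu) 1 - p_repair(tau_of(uu), params)
  inc <- (diff(u) / 6) * (g(u[-length(u)]) + 4 * g(um) + g(u[-1]))
  G <- c(0, cumsum(inc))
  u_t <- -expm1(-K * t^kappa)
  out <- approx(u, G, xout = pmin(u_t, u_max), rule = 2)$y
  out[t == 0] <- 0
  pmin(out, 1)
}

#' Failure probability with competing repair
#'
#' Integrates the instantaneous failure density multiplied by the
#' probability that repair has not yet occurred:
#' `P_fr(t) = integral_0^t Q_f * (1 - P_r) dt`. The integral is evaluated
#' under the substitution `u = P_f(tau)`, which renders the failure
#' density uniform and resolves arbitrarily short fatigue lives exactly;
#' see the methods vignette. `P_fr <= P_f` pointwise; with repair disabled
#' (`t_r = Inf`) the closed form [p_fail()] is returned exactly.
#'
#' @param t monotone increasing time grid starting at 0, years
#' @inheritParams p_fail
#' @return vector of probabilities on `t`
#' @export
p_fail_with_repair <- function(t, t_f, V, params = fatigue_params()) {
  if (length(t) < 2 || any(diff(t) <= 0)) stop("time grid must be monotone increasing")
  if (t[1] != 0) stop("time grid must start at 0")
  if (!is.finite(params$t_r)) return(p_fail(t, t_f, V, params))
  kappa <- params$m / params$n
  K <- (V / params$V_ref) / t_f^kappa
  cum_repair_integral(K, kappa, t, params)
}

#' Define an activity for the fatigue model
#'
#' An activity couples a daily distance and stride length (hence a cycle
#' rate) to the strain field it imposes, either a [solve_contact()]
#' solution or a numeric strain vector/scalar.
#'
#' @param label activity name
#' @param daily_distance m/day (>= 0)
#' @param stride_m stride length, m
#' @param strain a `contact_solution` or numeric strains in `[0, 1)`
#' @return list of class `knee_activity`
#' @export
#' @examples
#' act <- activity("walk", 6000, 1.55, 0.23)
activity <- function(label, daily_distance, stride_m, strain) {
  if (inherits(strain, "contact_solution")) {
    strains <- strain$strain
    volumes <- rep(strain$element_volume, length(strains))
  } else {
    stopifnot(is.numeric(strain), all(strain >= 0 & strain < 1))
    strains <- strain
    volumes <- NULL
  }
  stopifnot(daily_distance >= 0, stride_m > 0)
  structure(list(label = label, daily_distance = daily_distance,
                 stride_m = stride_m, strain = strains,
                 element_volume = volumes,
                 cycles = cycles_per_day(daily_distance, stride_m)),
            class = "knee_activity")
}

#' Joint failure probability curve over an adult lifespan
#'
#' Combines one or more activities into the cumulative failure probability
#' of the whole medial cartilage over `horizon` years, with and without
#' repair. Damage from different activities accumulates linearly in the
#' Miner sense: the per-element damage fraction is
#' `D_i(t) = sum_a t / t_f(i, a)`, and the element hazard exponent is
#' `H_i(t) = (V_i / V_ref) * D_i(t)^(m/n)`, which reduces exactly to the
#' single-activity Weibull form and makes splitting one activity into two
#' identical halves a no-op.
#'
#' Element-to-joint aggregation (the published per-subject probabilities do
#' not state a combination rule):
#' \describe{
#'   \item{`"peak"` (default)}{the joint fails as its most strained
#'     element: each activity is reduced to its peak element strain and the
#'     stressed volume is `stressed_volume` (defaulting to the reference
#'     volume `V_ref`, i.e. the strain concentration of the joint is taken
#'     comparable to the fatigue specimens the parameters were fitted on).}
#'   \item{`"weakest_link"`}{Weibull weakest-link over all elements: joint
#'     `P_f(t) = 1 - exp(-sum_i H_i(t))` with per-element volumes
#'     `d^2 * h`. Requires equal-length strain fields per activity. This
#'     mode treats every element as an independent specimen and yields
#'     substantially higher joint probabilities.}
#' }
#'
#' @param activities a `knee_activity` or list of them
#' @param params [fatigue_params()]
#' @param aggregate `"peak"` or `"weakest_link"`
#' @param stressed_volume mm^3; stressed volume for `"peak"` aggregation
#'   (default `params$V_ref`)
#' @param horizon simulation horizon, years (time 0 = start of adult
#'   exposure, cohort mean age 23)
#' @param dt time step of the output grid, years
#' @param start_age age at time 0, years (for the age axis)
#' @return object of class `failure_curve`: list with `time` (years),
#'   `age`, `p_fail`, `p_fail_repair`, `hazard_scale` (K in
#'   `P_f = 1 - exp(-K t^(m/n))`), `kappa`, `cycles` (per activity),
#'   `params`
#' @export
#' @examples
#' act <- activity("walk", 6000, 1.55, 0.23)
#' fc <- failure_curve(act)
#' predict(fc, t = c(32, 60))
failure_curve <- function(activities, params = fatigue_params(),
                          aggregate = c("peak", "weakest_link"),
                          stressed_volume = NULL,
                          horizon = 60, dt = 0.05, start_age = 23) {
  aggregate <- match.arg(aggregate)
  if (inherits(activities, "knee_activity")) activities <- list(activities)
  if (!length(activities)) stop("at least one activity is required")
  stopifnot(all(vapply(activities, inherits, TRUE, "knee_activity")))
  if (!any(vapply(activities, function(a) a$daily_distance, 1) > 0))
    stop("at least one activity must have a positive daily distance")
  kappa <- params$m / params$n

  if (aggregate == "peak") {
    # effective damage rate 1/t_f summed across activities at each
    # activity's peak strain
    rate <- sum(vapply(activities, function(a) {
      eps <- if (length(a$strain)) max(a$strain) else 0
      1 / time_to_failure(eps, params, a$cycles)
    }, 1))
    V <- stressed_volume %||% params$V_ref
    K <- (V / params$V_ref) * rate^kappa
  } else {
    lens <- vapply(activities, function(a) length(a$strain), 1L)
    if (any(lens == 0)) stop("empty strain field")
    if (length(unique(lens)) != 1)
      stop("weakest-link aggregation requires equal-length strain fields")
    rate_i <- Reduce(`+`, lapply(activities, function(a)
      1 / time_to_failure(a$strain, params, a$cycles)))
    v_i <- activities[[1]]$element_volume %||%
      rep(stressed_volume %||% params$V_ref, lens[1])
    K <- sum((v_i / params$V_ref) * rate_i^kappa)
  }

  t <- seq(0, horizon, by = dt)
  p_f <- -expm1(-K * t^kappa)
  p_fr <- if (is.finite(params$t_r)) {
    cum_repair_integral(K, kappa, t, params)
  } else {
    p_f
  }

  structure(list(time = t, age = start_age + t, p_fail = p_f,
                 p_fail_repair = p_fr, hazard_scale = K, kappa = kappa,
                 cycles = vapply(activities, function(a) a$cycles, 1),
                 labels = vapply(activities, function(a) a$label, ""),
                 aggregate = aggregate, params = params),
            class = "failure_curve")
}

#' @export
print.failure_curve <- function(x, ...) {
  end <- length(x$time)
  cat(sprintf("Failure curve over %.0f years (%s aggregation)\n",
              max(x$time), x$aggregate))
  cat(sprintf("  activities: %s (%.0f cycles/day)\n",
              paste(x$labels, collapse = " + "), sum(x$cycles)))
  cat(sprintf("  P_f(%.0f y) = %.3f without repair, %.3f with repair\n",
              max(x$time), x$p_fail[end], x$p_fail_repair[end]))
  invisible(x)
}

#' Interpolate a failure curve at chosen times or ages
#'
#' @param object a `failure_curve`
#' @param t times in years since exposure start (or use `age`)
#' @param age ages in years
#' @param ... unused
#' @return data frame with `time`, `age`, `p_fail`, `p_fail_repair`
#' @export
predict.failure_curve <- function(object, t = NULL, age = NULL, ...) {
  if (is.null(t)) {
    if (is.null(age)) stop("supply t or age")
    t <- age - object$age[1]
  }
  if (any(t < 0 | t > max(object$time))) stop("time outside the simulated grid")
  data.frame(time = t, age = object$age[1] + t,
             p_fail = approx(object$time, object$p_fail, t)$y,
             p_fail_repair = approx(object$time, object$p_fail_repair, t)$y)
}

#' @export
plot.failure_curve <- function(x, ...) {
  plot(x$age, x$p_fail, type = "l", ylim = c(0, 1),
       xlab = "age (years)", ylab = "cumulative failure probability", ...)
  lines(x$age, x$p_fail_repair, lty = 2)
  legend("topleft", c("without repair", "with repair"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Export a failure curve as a data frame
#' @param x a `failure_curve`
#' @param ... unused
#' @return data frame with columns `time`, `age`, `p_fail`, `p_fail_repair`
#' @export
as.data.frame.failure_curve <- function(x, ...) {
  data.frame(time = x$time, age = x$age, p_fail = x$p_fail,
             p_fail_repair = x$p_fail_repair)
}
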