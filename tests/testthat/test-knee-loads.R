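flat_arms <- function(pt = 0.04) {
  ma <- default_moment_arms()
  ma$a1 <- 0
  ma$a0[ma$muscle == "patellar_tendon"] <- pt
  ma
}

test_that("patellar tendon force is the moment over the arm", {
  p <- msk_params(moment_arms = flat_arms(0.04), tendon_arm_gain = 0)
  expect_equal(patellar_tendon_force(0, 0, p), 0)
  expect_equal(patellar_tendon_force(40, 0, p), 1000)
  expect_equal(patellar_tendon_force(-10, 0, p), 0)  # clamped
})

test_that("force-dependent arm solution matches a bisection oracle", {
  p <- msk_params(moment_arms = flat_arms(0.04), tendon_arm_gain = 5e-6)
  for (m in c(10, 40, 120, 400)) {
    f <- patellar_tendon_force(m, 0, p)
    # independent bisection on F * (a0 + min(g F, cap)) = M
    oracle <- uniroot(function(ff) ff * (0.04 + pmin(5e-6 * ff, 0.01)) - m,
                      c(0, m / 0.04), tol = 1e-10)$root
    expect_equal(f, oracle, tolerance = 1e-6)
    # cap: the arm never grows beyond 1.0 cm
    expect_gte(f, m / (0.04 + 0.01))
  }
})

test_that("PCSA weighting distributes forces and reconstructs the moment", {
  expect_equal(distribute_muscle_forces(10, c(1, 1), c(0.05, 0.05)),
               c(100, 100))
  f <- distribute_muscle_forces(10, c(2, 1), c(0.05, 0.05))
  expect_equal(f[1] / f[2], 2)
  set.seed(4)
  for (i in 1:10) {
    pcsa <- runif(5, 1, 40)
    arms <- runif(5, 0.01, 0.08)
    m <- runif(1, -50, 50)
    f <- distribute_muscle_forces(m, pcsa, arms)
    expect_equal(sum(f * arms), m, tolerance = 1e-9)
  }
  expect_error(distribute_muscle_forces(10, c(0, 0), c(0.05, 0.05)),
               "all-zero")
})

balance_trace <- function(knee_ext, knee_add) {
  data.frame(time_s = 0, knee_ext_nm = knee_ext, hip_ext_nm = 0,
             ankle_pf_nm = 0, knee_add_nm = knee_add,
             knee_angle_deg = 0, hip_angle_deg = 0, ankle_angle_deg = 0)
}

test_that("frontal-plane moment balance splits the axial force", {
  p <- msk_params(moment_arms = flat_arms(0.04), tendon_arm_gain = 0)
  # 1000 N axial, no adduction moment, symmetric offsets -> 500/500
  out <- medial_contact_force(balance_trace(40, 0), p)
  expect_equal(out$axial_n, 1000)
  expect_equal(out$medial_n, 500)
  expect_equal(out$lateral_n, 500)
  # hand moment balance: axial 1000 N + 25 N*m adduction, offsets 25 mm
  out <- medial_contact_force(balance_trace(40, 25), p)
  expect_equal(out$medial_n, 1000)
  expect_equal(out$lateral_n, 0)
})

test_that("medial and lateral forces sum to the axial force when both compartments load", {
  coh <- small_cohort()
  tr <- generate_moment_traces(coh[1, ])
  out <- medial_contact_force(tr)
  both <- out$lateral_n > 0 & out$medial_n > 0
  expect_true(any(both))
  expect_equal(out$medial_n[both] + out$lateral_n[both], out$axial_n[both],
               tolerance = 1e-9)
  # lateral lift-off (clamp at zero) can only push the sum above the axial
  expect_true(all(out$medial_n + out$lateral_n >= out$axial_n - 1e-9))
})

test_that("peak medial force rises monotonically with the adduction moment", {
  p <- msk_params(moment_arms = flat_arms(0.04), tendon_arm_gain = 0)
  peaks <- vapply(c(0, 10, 20, 40), function(m)
    max(medial_contact_force(balance_trace(40, m), p)$medial_n), 1)
  expect_true(all(diff(peaks) > 0))
})

test_that("specific tension barely affects the peak medial force", {
  coh <- small_cohort()
  tr <- generate_moment_traces(coh[coh$gait == "run", ][1, ])
  peaks <- vapply(c(20, 40, 60), function(st)
    max(medial_contact_force(tr, msk_params(specific_tension = st))$medial_n), 1)
  expect_lt(diff(range(peaks)) / peaks[2], 0.01)
})

test_that("cumulative load is force in BW over stride length", {
  expect_equal(cumulative_load(676, 1.55, 676), 1 / 1.55)
  expect_equal(cumulative_load(0, 1.55, 676), 0)
  expect_error(cumulative_load(100, 0, 676), "stride")
  # reference-mean walking inputs give ~0.64 BW/m
  spec <- cohort_spec()
  mean_force_bw <- 2.90 * spec$stance_mean_ratio * spec$stance_walk
  expect_equal(cumulative_load(mean_force_bw * 676, 1.55, 676), 0.64,
               tolerance = 0.01)
})

test_that("the shipped moment-arm CSV matches the built-in defaults", {
  path <- system.file("extdata", "moment_arms_default.csv",
                      package = "kneefatigue")
  expect_equal(utils::read.csv(path), default_moment_arms(),
               tolerance = 1e-12)
})
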