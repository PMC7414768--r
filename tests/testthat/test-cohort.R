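test_that("zero-variance spec reproduces the means exactly", {
  spec <- cohort_spec(n_subjects = 5, seed = 3,
                      mass_sd = 0, walk_speed_sd = 0, walk_stride_sd = 0,
                      walk_force_sd = 0, run_speed_sd = 0, run_stride_sd = 0,
                      run_force_sd = 0)
  coh <- generate_cohort(spec)
  walk <- coh[coh$gait == "walk", ]
  expect_true(all(walk$mass_kg == 68.9))
  expect_true(all(walk$stride_m == 1.55))
  expect_true(all(walk$peak_force_bw == 2.90))
  expect_equal(walk$peak_force_n, rep(2.90 * 68.9 * 9.81, 5))
  run <- coh[coh$gait == "run", ]
  expect_true(all(run$peak_force_bw == 5.59))
})

test_that("cohort generation is seed-reproducible and seed-sensitive", {
  a <- generate_cohort(cohort_spec(seed = 99))
  b <- generate_cohort(cohort_spec(seed = 99))
  c <- generate_cohort(cohort_spec(seed = 100))
  expect_identical(a, b)
  expect_false(identical(a$mass_kg, c$mass_kg))
})

test_that("cohort sample means track the target distribution", {
  # 22 subjects at the reference means: sample means within 2 SE
  coh <- generate_cohort(cohort_spec(seed = 5))
  walk <- coh[coh$gait == "walk", ]
  run <- coh[coh$gait == "run", ]
  expect_lt(abs(mean(walk$peak_force_bw) - 2.90), 2 * 0.55 / sqrt(22))
  expect_lt(abs(mean(run$peak_force_bw) - 5.59), 2 * 0.99 / sqrt(22))
  # large-sample convergence of the generator itself
  big <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 8))
  expect_lt(abs(mean(big$stride_m[big$gait == "walk"]) - 1.55) / 1.55, 0.005)
})

test_that("truncation at zero never yields negative draws", {
  for (s in 1:5) {
    spec <- cohort_spec(n_subjects = 50, seed = s,
                        mass_mean = 5, mass_sd = 20,
                        walk_force_mean = 0.5, walk_force_sd = 2)
    coh <- generate_cohort(spec)
    expect_true(all(coh$mass_kg > 0))
    expect_true(all(coh$peak_force_n > 0))
    expect_true(all(coh$stride_m > 0))
  }
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_subjects = 0), "positive count")
  expect_error(cohort_spec(mass_sd = -1), "SDs")
  expect_error(cohort_spec(walk_speed_mean = 0), "strictly positive")
  expect_error(cohort_spec(flexion_walk = 120), "flexion")
})

test_that("cohort CSV round-trips", {
  coh <- small_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("moment traces have stance-phase duration and zero-force limit", {
  coh <- small_cohort()
  s <- coh[coh$gait == "walk", ][1, ]
  tr <- generate_moment_traces(s)
  expect_equal(max(tr$time_s), s$stance_fraction * s$stride_m / s$speed_ms)
  s0 <- s
  s0$peak_force_n <- 0
  tr0 <- generate_moment_traces(s0)
  expect_true(all(tr0$knee_ext_nm == 0))
  expect_true(all(medial_contact_force(tr0)$medial_n == 0))
  expect_error(generate_moment_traces(within(as.list(s), gait <- "hop")),
               "unknown gait")
})

test_that("moment traces close the loop with the reduction model", {
  # the generated traces must reproduce each subject's stored peak medial
  # force through the full muscle-force pathway
  coh <- generate_cohort(cohort_spec(n_subjects = 50, seed = 21))
  for (i in seq_len(nrow(coh))) {
    s <- coh[i, ]
    tr <- generate_moment_traces(s)
    peak <- max(medial_contact_force(tr)$medial_n)
    expect_lt(abs(peak - s$peak_force_n) / s$peak_force_n, 0.02)
  }
  # the angle at the force peak is the stored flexion angle
  s <- coh[1, ]
  tr <- generate_moment_traces(s)
  fm <- medial_contact_force(tr)
  expect_equal(tr$knee_angle_deg[which.max(fm$medial_n)], s$flexion_deg,
               tolerance = 0.05)
})
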