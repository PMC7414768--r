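fp <- fatigue_params()

test_that("cycle bookkeeping follows distance over stride", {
  expect_equal(cycles_per_day(6000, 1.55), 3871.0, tolerance = 1e-4)
  expect_equal(cycles_per_day(3000, 1.95), 1538.5, tolerance = 1e-4)
  expect_equal(cycles_per_day(0, 1.55), 0)
  expect_error(cycles_per_day(6000, 0), "stride")
})

test_that("strain-life law gives the expected failure times", {
  # walking-level strain at 10,000 steps/day (5,000 cycles per knee)
  expect_equal(time_to_failure(0.23, fp, 5000), 64.1, tolerance = 1e-3)
  expect_equal(time_to_failure(0.30, fp, 5000), 2.081, tolerance = 1e-3)
  # exact power-law ratio identity
  t1 <- time_to_failure(0.2, fp, 1000)
  t2 <- time_to_failure(0.4, fp, 1000)
  expect_equal(t1 / t2, 2^fp$n, tolerance = 1e-12)
  # infinite-life sentinels
  expect_identical(time_to_failure(0.23, fp, 0), Inf)
  expect_identical(time_to_failure(0, fp, 5000), Inf)
  expect_warning(time_to_failure(0.99, fp, 5000), "below one loading cycle")
})

test_that("log fatigue life against log strain has slope -n", {
  eps <- seq(0.1, 0.5, length.out = 20)
  tf <- time_to_failure(eps, fp, 5000)
  slope <- coef(lm(log(tf) ~ log(eps)))[2]
  expect_equal(unname(slope), -fp$n, tolerance = 1e-9)
})

test_that("failure probability has the Weibull scale identities", {
  tf <- 64.1
  expect_equal(p_fail(tf, tf, fp$V_ref, fp), 1 - exp(-1))
  expect_equal(p_fail(0, tf, fp$V_ref, fp), 0)
  expect_equal(p_fail(tf, tf, 2 * fp$V_ref, fp), 1 - exp(-2))
  # monotone in time, volume and (through t_f) strain
  t <- seq(0, 60, by = 1)
  expect_true(all(diff(p_fail(t, tf, fp$V_ref, fp)) > 0))
  expect_gt(p_fail(30, tf, 2 * fp$V_ref, fp), p_fail(30, tf, fp$V_ref, fp))
  expect_gt(p_fail(30, 30, fp$V_ref, fp), p_fail(30, 60, fp$V_ref, fp))
})

test_that("failure density integrates back to the closed form", {
  tf <- 20
  for (tt in c(5, 20, 50)) {
    integral <- integrate(q_fail, 0, tt, t_f = tf, V = fp$V_ref, params = fp,
                          rel.tol = 1e-9)$value
    expect_equal(integral, p_fail(tt, tf, fp$V_ref, fp), tolerance = 1e-6)
  }
  t <- seq(0, 60, by = 0.1)
  expect_true(all(q_fail(t, tf, fp$V_ref, fp) >= 0))
  # central finite difference of P_f reproduces Q_f on interior points
  dd <- 1e-4
  ti <- seq(1, 59, by = 2)
  fd <- (p_fail(ti + dd, tf, fp$V_ref, fp) -
           p_fail(ti - dd, tf, fp$V_ref, fp)) / (2 * dd)
  expect_equal(fd, q_fail(ti, tf, fp$V_ref, fp), tolerance = 1e-6)
})

test_that("repair probability is a Weibull in time with scale t_r", {
  expect_equal(p_repair(5, fp), 1 - exp(-1))
  expect_equal(p_repair(0, fp), 0)
  expect_equal(p_repair(10, fp), 1 - exp(-2^5.2))
  expect_true(all(diff(p_repair(seq(0, 30, 0.5), fp)) >= 0))
})

test_that("repair never increases failure and vanishes as t_r grows", {
  t <- seq(0, 60, by = 0.05)
  tf <- 30
  pfr <- p_fail_with_repair(t, tf, fp$V_ref, fp)
  pf <- p_fail(t, tf, fp$V_ref, fp)
  expect_true(all(pfr <= pf + 1e-12))
  expect_true(all(diff(pfr) >= -1e-12))
  # repair disabled recovers the closed form exactly
  no_rep <- fatigue_params(t_r = Inf)
  expect_equal(p_fail_with_repair(t, tf, fp$V_ref, no_rep), pf,
               tolerance = 1e-9)
  # grid-refinement oracle
  t_fine <- seq(0, 60, by = 0.005)
  pfr_fine <- p_fail_with_repair(t_fine, tf, fp$V_ref, fp)
  expect_equal(pfr[length(pfr)], pfr_fine[length(pfr_fine)],
               tolerance = 1e-6)
  expect_error(p_fail_with_repair(c(0, 2, 1), tf, fp$V_ref, fp), "monotone")
})

test_that("single-element curve reduces to the closed-form probabilities", {
  act <- activity("walk", 6000, 1.55, 0.23)
  fc <- failure_curve(act, fp)
  tf <- time_to_failure(0.23, fp, cycles_per_day(6000, 1.55))
  expect_equal(fc$p_fail, p_fail(fc$time, tf, fp$V_ref, fp), tolerance = 1e-12)
  expect_equal(fc$p_fail_repair,
               p_fail_with_repair(fc$time, tf, fp$V_ref, fp),
               tolerance = 1e-9)
  expect_true(all(fc$p_fail_repair <= fc$p_fail + 1e-12))
})

test_that("splitting an activity into identical halves changes nothing", {
  one <- failure_curve(activity("walk", 6000, 1.55, 0.25), fp)
  two <- failure_curve(list(activity("a", 3000, 1.55, 0.25),
                            activity("b", 3000, 1.55, 0.25)), fp)
  expect_equal(two$hazard_scale, one$hazard_scale, tolerance = 1e-12)
  expect_equal(two$p_fail, one$p_fail, tolerance = 1e-12)
})

test_that("weakest-link aggregation ignores unloaded elements", {
  eps <- c(0.25, 0.2, 0.15)
  a1 <- activity("walk", 6000, 1.55, eps)
  a2 <- activity("walk", 6000, 1.55, c(eps, 0, 0))
  f1 <- failure_curve(a1, fp, aggregate = "weakest_link", stressed_volume = 1.25)
  f2 <- failure_curve(a2, fp, aggregate = "weakest_link", stressed_volume = 1.25)
  expect_equal(f1$p_fail, f2$p_fail, tolerance = 1e-12)
  # and exceeds the peak-element-only probability at equal volume
  fpk <- failure_curve(a1, fp, aggregate = "peak", stressed_volume = 1.25)
  expect_gt(f1$p_fail[1201], fpk$p_fail[1201])
})

test_that("failure curves respond monotonically to exposure and strain", {
  end_p <- function(dist, eps) {
    fc <- failure_curve(activity("walk", dist, 1.55, eps), fp)
    fc$p_fail[length(fc$time)]
  }
  expect_true(all(diff(vapply(c(2000, 4000, 8000), end_p, 1, eps = 0.25)) > 0))
  expect_true(all(diff(vapply(c(0.2, 0.25, 0.3), end_p, 1, dist = 6000)) > 0))
})

test_that("failure curve interface validates input and interpolates", {
  expect_error(failure_curve(list()), "at least one activity")
  expect_error(activity("walk", -1, 1.55, 0.2), "daily_distance")
  fc <- failure_curve(activity("walk", 6000, 1.55, 0.23), fp)
  pr <- predict(fc, age = 55)
  expect_equal(pr$time, 32)
  expect_equal(pr$p_fail, approx(fc$age, fc$p_fail, 55)$y)
  expect_error(predict(fc, t = 100), "outside")
})
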