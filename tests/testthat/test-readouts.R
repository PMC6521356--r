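test_that("interval integration matches closed forms and is additive", {
  times <- seq(0, 48, by = 0.1)
  traj <- synthetic_trajectory(times, list(
    const2 = rep(2, length(times)),
    ramp = times))
  expect_equal(integrate_interval(traj, "const2", 0, 12), 24)
  expect_equal(integrate_interval(traj, "ramp", 0, 4), 8)
  expect_error(integrate_interval(traj, "const2", 0, 60), "outside")
  full <- fx_dose_trajs()$d20
  total <- integrate_interval(full, "casein_mRNA_c", 0, 48)
  parts <- integrate_interval(full, "casein_mRNA_c", 0, 12) +
           integrate_interval(full, "casein_mRNA_c", 12, 24) +
           integrate_interval(full, "casein_mRNA_c", 24, 48)
  expect_rel_equal(parts, total, 1e-9)
})

test_that("switch ratio compares early and late windows", {
  times <- seq(0, 48, by = 0.1)
  prof <- ifelse(times <= 12, 3, 1)  # 36 nM h in each window
  traj <- synthetic_trajectory(times, list(casein_mRNA_c = prof))
  # the step at t = 12 costs half a grid cell under trapezoidal quadrature
  expect_equal(switch_ratio(traj), 1.0, tolerance = 0.005)
  expect_equal(switch_ratio(traj, invert = TRUE), 1.0, tolerance = 0.005)
  early_only <- synthetic_trajectory(times, list(
    casein_mRNA_c = ifelse(times < 12, 3, 0)))
  expect_error(switch_ratio(early_only), "degenerate")
})

test_that("transcription delay recovers constructed peak separations", {
  times <- seq(0, 48, by = 0.01)
  gauss <- function(mu, sd = 0.8) exp(-((times - mu) / sd)^2 / 2)
  traj <- synthetic_trajectory(times, list(
    STATdim_n = gauss(1), casein_mRNA_c = gauss(4)))
  expect_equal(transcription_delay(traj), 3.0, tolerance = 1e-6)
  same <- synthetic_trajectory(times, list(
    STATdim_n = gauss(5), casein_mRNA_c = gauss(5)))
  expect_equal(transcription_delay(same), 0.0, tolerance = 1e-9)
  # sub-grid localization: true peaks off the grid still recovered
  coarse <- seq(0, 48, by = 0.5)
  g2 <- function(mu) exp(-((coarse - mu) / 3)^2 / 2)
  t2 <- synthetic_trajectory(coarse, list(STATdim_n = g2(10.13),
                                          casein_mRNA_c = g2(12.87)))
  expect_equal(transcription_delay(t2), 2.74, tolerance = 0.01)
  monotone <- synthetic_trajectory(times, list(
    STATdim_n = times, casein_mRNA_c = gauss(4)))
  expect_error(transcription_delay(monotone), "no interior peak")
  expect_equal(
    transcription_delay(monotone, allow_boundary = TRUE), 4 - 48,
    tolerance = 1e-6)
})

test_that("control normalization is a scale-invariant fold change", {
  expect_equal(normalize_to_control(4, 2), 2)
  expect_equal(normalize_to_control(7.3, 7.3), 1)
  expect_error(normalize_to_control(1, 0), "control")
  for (c_ in c(0.1, 1, 17)) # scale invariance
    expect_equal(normalize_to_control(3 * c_, 2 * c_),
                 normalize_to_control(3, 2))
})

test_that("dose trend reports the Theil-Sen sign with a deadband", {
  expect_equal(dose_trend(c(10, 8, 6), c(10, 20, 50)), -1L)
  expect_equal(dose_trend(c(5, 5, 5), c(10, 20, 50)), 0L)
  expect_equal(dose_trend(c(1, 0.9, 3), c(10, 20, 50)), 1L)  # robust to dip
  expect_equal(dose_trend(c(5, 5 * (1 + 1e-6), 5), c(10, 20, 50)), 0L)
  expect_error(dose_trend(c(1, 2), c(10, 20)), ">= 3")
})

test_that("ensemble summary returns mean, SD, SEM and member count", {
  s <- ensemble_summary(c(1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$sem, 1)
  expect_equal(s$n, 2L)
  expect_equal(ensemble_summary(rep(4, 6))$sd, 0)
  expect_error(ensemble_summary(c(1)), ">= 2")
})

test_that("readout sets satisfy their internal identities on the full model", {
  r <- readout_set(fx_dose_trajs()$d10)
  expect_gte(r$integral_0_12, 0)
  expect_rel_equal(r$integral_total_0_48,
                   r$integral_0_12 + r$integral_12_24 + r$integral_24_48, 1e-9)
  expect_gt(r$switch_ratio, 0)
  expect_true(is.finite(r$delay_h))
})
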