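test_that("integrator matches the toy-decay closed form to 1e-6 relative", {
  toy <- toy_decay_network(k1 = 1, k2 = 2, A0 = 100)
  tr <- run_timecourse(toy$net, dose = 0, t_end = 8, output_step = 0.01)
  cf <- toy$closed_form(tr$times)
  expect_rel_equal(species_profile(tr, "A"), cf$A, 1e-6)
  scale <- max(cf$B)  # B passes through zero; compare on the profile scale
  expect_lt(max(abs(species_profile(tr, "B") - cf$B)) / scale, 1e-6)
  # half-life check: A(1 h) = 50 nM for k = ln 2
  toy2 <- toy_decay_network(k1 = log(2), k2 = 1, A0 = 100)
  tr2 <- run_timecourse(toy2$net, dose = 0, t_end = 2, output_step = 0.01)
  expect_rel_equal(species_profile(tr2, "A")[tr2$times == 1], 50, 1e-6)
  # conservation in the pure-transfer limit
  toy3 <- toy_decay_network(k1 = log(2), k2 = 0, A0 = 100)
  tr3 <- run_timecourse(toy3$net, dose = 0, t_end = 2, output_step = 0.01)
  expect_rel_equal(species_profile(tr3, "A") + species_profile(tr3, "B"),
                   rep(100, length(tr3$times)), 1e-8)
})

test_that("trajectory starts at the initial amounts with the dose applied", {
  tr <- fx_dose_trajs()$d20
  net <- fx_full()
  y0 <- setNames(net$species$initial_amount, net$species$id)
  y0[["NRG"]] <- 20
  expect_equal(tr$conc[, 1], y0)
  expect_equal(tr$times[1], 0)
  expect_true(all(diff(tr$times) > 0))
  expect_true(min(tr$conc) >= 0)
})

test_that("identical inputs give bitwise-identical trajectories", {
  net <- fx_full()
  tr1 <- run_timecourse(net, dose = 10, t_end = 6, output_step = 0.05)
  tr2 <- run_timecourse(net, dose = 10, t_end = 6, output_step = 0.05)
  expect_identical(tr1$conc, tr2$conc)
  expect_identical(tr1$times, tr2$times)
})

test_that("dose series returns one trajectory per dose on a common grid", {
  net <- fx_full()
  protocol <- dose_protocol(c(0, 10, 20, 50), t_end = 2, output_step = 0.05)
  trs <- run_dose_series(net, protocol, rtol = 1e-6, atol = 1e-9)
  expect_length(trs, 4L)
  expect_named(trs, c("dose_0", "dose_10", "dose_20", "dose_50"))
  for (tr in trs) expect_identical(tr$times, trs[[1]]$times)
  # zero dose: no flux through any ligand-consuming reaction, ever
  d0 <- trs$dose_0
  expect_true(all(species_profile(d0, "NRG") == 0))
  expect_true(all(species_profile(d0, "aHER4_JAK") == 0))
  expect_true(all(species_profile(d0, "STATdim_n") == 0))
  # only the basal (HC/GR) transcription operates without ligand
  expect_true(all(species_profile(d0, "casein_mRNA_c") <
                  1.01 * 0.25 * 0.05 / fx_full()$parameters[["kR46"]]))
})

test_that("readouts are robust to halving the solver tolerances", {
  net <- fx_full()
  r1 <- readout_set(run_timecourse(net, 20, 48, 0.02))
  r2 <- readout_set(run_timecourse(net, 20, 48, 0.02, rtol = 5e-9, atol = 5e-11))
  for (f in c("integral_0_12", "integral_12_24", "integral_24_48",
              "switch_ratio", "delay_h"))
    expect_rel_equal(r2[[f]], r1[[f]], 1e-3)
})

test_that("LHS ensembles are deterministic and collapse at zero-width bounds", {
  net <- fx_full()
  protocol <- dose_protocol(c(0, 20), t_end = 6, output_step = 0.1)
  space <- default_parameter_space(net, parameters = fx_flagged[1:4])
  e1 <- run_ensemble(net, protocol, space, n_members = 5, seed = 3,
                     rtol = 1e-6, atol = 1e-9)
  e2 <- run_ensemble(net, protocol, space, n_members = 5, seed = 3,
                     rtol = 1e-6, atol = 1e-9)
  expect_identical(
    lapply(e1$members, function(m) m$trajectories$dose_20$conc),
    lapply(e2$members, function(m) m$trajectories$dose_20$conc))
  # near-degenerate bounds: every member reproduces the baseline run
  eps <- 1e-9
  pv <- net$parameters[fx_flagged[1:4]]
  tight <- parameter_space(names(pv), pv * (1 - eps), pv * (1 + eps), "linear")
  e3 <- run_ensemble(net, protocol, tight, n_members = 3, seed = 1,
                     rtol = 1e-6, atol = 1e-9)
  base <- run_dose_series(net, protocol, rtol = 1e-6, atol = 1e-9)
  for (m in e3$members)
    expect_rel_equal(m$trajectories$dose_20$conc + 1,
                     base$dose_20$conc + 1, 1e-5)
})

test_that("ensemble summaries have finite dispersion in every cell", {
  net <- fx_full()
  protocol <- dose_protocol(c(0, 10, 20, 50), t_end = 48, output_step = 0.1)
  space <- default_parameter_space(net, parameters = fx_flagged)
  # one extreme tenfold-bounds member grazes the negativity clip threshold;
  # the warning is the designed behavior, not a failure of this check
  ens <- suppressWarnings(
    run_ensemble(net, protocol, space, n_members = 12, seed = 5))
  s <- ensemble_readout_summary(ens)
  expect_equal(nrow(s), 4L * 3L)
  expect_true(all(is.finite(s$mean) & is.finite(s$sd) & s$n >= 2))
})
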