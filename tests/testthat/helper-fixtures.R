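# Shared fixtures. Expensive objects (networks, baseline trajectories) are
# built once per test run and memoized here; simulations used by several
# files run on a 0.02 h grid, fine enough for peak localization.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

fx_canonical <- function() memo("canonical", build_canonical_network)
fx_full <- function() memo("full", build_full_network)

fx_dose_trajs <- function() memo("dose_trajs", function() {
  lapply(setNames(c(0, 10, 20, 50), c("d0", "d10", "d20", "d50")),
         function(d) run_timecourse(fx_full(), dose = d, t_end = 48,
                                    output_step = 0.02))
})

fx_flagged <- c("n_transc", "V_transc", "K_transc", "kR45", "kR15", "kfR41",
                "kfR42", "kfR43", "kfR36", "kR37", "kR39", "SOCS_Binding_Rate")

# Hand-built trajectory with analytic profiles, for readout unit tests.
synthetic_trajectory <- function(times, profiles, dose = 10) {
  conc <- do.call(rbind, profiles)
  rownames(conc) <- names(profiles)
  structure(list(times = times, conc = conc, dose = dose,
                 params_used = list()), class = "trajectory")
}

expect_rel_equal <- function(actual, expected, rtol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), rtol)
}
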