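test_that("canonical network has two compartments and resolvable rate laws", {
  net <- fx_canonical()
  expect_equal(nrow(net$compartments), 2L)
  expect_setequal(net$compartments$id, c("cytoplasm", "nucleus"))
  expect_false(net$flags$heterodimerization_on)
  expect_false(net$flags$jak_independent_on)
  for (rxn in net$reactions)
    expect_true(all(rxn$rate_law$params %in% names(net$parameters)),
                label = paste("parameters of", rxn$id, "resolve"))
  S <- stoichiometry_matrix(net)
  expect_equal(dim(S), c(nrow(net$species), length(net$reactions)))
})

test_that("total STAT5 lies in the left null space of the stoichiometry matrix", {
  # independent oracle: weight vector w with w . S_eff = 0 found by generic
  # linear algebra must include the STAT5 moiety (nuclear species weighted by
  # the compartment volume ratio)
  net <- fx_full()
  S <- effective_stoichiometry(net)
  stat_weights <- setNames(numeric(nrow(net$species)), net$species$id)
  vr <- net$compartments$volume[net$compartments$id == "nucleus"]
  stat_weights[c("STATc", "STATc_p")] <- 1
  stat_weights["STATdim_c"] <- 2
  stat_weights[c("STATdim_n", "STATdim_PPN")] <- 2 * vr
  stat_weights["STATn"] <- 1 * vr
  expect_lt(max(abs(drop(stat_weights %*% S))), 1e-12)
  # and the numerically computed null space spans it
  N <- conserved_moieties(net)
  resid <- stat_weights - N %*% (crossprod(N, stat_weights))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("heterodimerization adds exactly three competing reactions", {
  net <- fx_canonical()
  net2 <- add_heterodimerization(net)
  expect_equal(length(net2$reactions), length(net$reactions) + 3L)
  expect_true(net2$flags$heterodimerization_on)
  ids <- vapply(net2$reactions, `[[`, "", "id")
  r01 <- net2$reactions[[which(ids == "R01")]]
  r41 <- net2$reactions[[which(ids == "R41")]]
  expect_true("HER4" %in% names(r01$reactants))
  expect_true("HER4" %in% names(r41$reactants))
  expect_error(add_heterodimerization(net2), "already present")
})

test_that("JAK-independent branch is slower and escapes SOCS feedback", {
  net <- fx_canonical()
  net2 <- add_jak_independent_branch(net)
  expect_equal(length(net2$reactions), length(net$reactions) + 3L)
  expect_lt(net2$parameters[["kR39"]], net2$parameters[["kR06"]])
  ids <- vapply(net2$reactions, `[[`, "", "id")
  socs_fb <- net2$reactions[ids %in% c("R30", "R29")]
  for (rxn in socs_fb)
    expect_false(any(grepl("^s80", c(names(rxn$reactants), rxn$modifiers))))
  expect_error(add_jak_independent_branch(net2), "already present")
})

test_that("reaction_rate implements the stated kinetic forms", {
  params <- c(k = 2, V = 5, K = 1.5, n = 2)
  ma <- reaction("T1", "A+B->C", c(A = 1, B = 1), c(C = 1),
                 rate_law("mass_action_irreversible", c(kf = "k")))
  st <- c(A = 3, B = 4, C = 0, M = 0)
  expect_equal(reaction_rate(ma, st, params), 24)
  expect_equal(reaction_rate(ma, c(A = 0, B = 4, C = 1, M = 0), params), 0)
  hill <- reaction("T2", "transcription", products = c(C = 1),
                   rate_law = rate_law("hill_activation",
                     c(V_transc = "V", K_transc = "K", n_transc = "n")),
                   modifiers = "M")
  expect_equal(reaction_rate(hill, c(A = 0, B = 0, C = 0, M = 1.5), params),
               5 / 2)
  # bounded by V for any non-negative modifier level
  for (M in c(0, 0.01, 0.7, 1.5, 40, 1e6)) {
    r <- reaction_rate(hill, c(A = 0, B = 0, C = 0, M = M), params)
    expect_gte(r, 0); expect_lte(r, 5)
  }
  expect_error(reaction_rate(ma, c(A = -1, B = 4, C = 0, M = 0), params),
               "negative")
})

test_that("ode_rhs assembles stoichiometry times rates", {
  toy <- toy_decay_network(k1 = 0.5, k2 = 0)$net
  toy$parameters[["k2"]] <- 0
  d <- ode_rhs(toy, c(NRG = 0, A = 10, B = 0))
  expect_equal(unname(d[c("A", "B")]), c(-5, 5))
  expect_equal(unname(ode_rhs(toy, c(NRG = 0, A = 0, B = 0))), c(0, 0, 0))
  expect_error(ode_rhs(fx_full(), rep(NaN, nrow(fx_full()$species))), "NaN")
  # derivative of every conserved moiety vanishes at a generic state
  net <- fx_full()
  set.seed(11)
  st <- stats::runif(nrow(net$species), 0, 5)
  d <- ode_rhs(net, st)
  N <- conserved_moieties(net)
  expect_lt(max(abs(crossprod(N, d))), 1e-9)
})

test_that("compiled right-hand side agrees with the R reference", {
  net <- fx_full()
  traj <- fx_dose_trajs()$d20
  for (col in c(10L, 400L, 2000L)) {
    st <- traj$conc[, col]
    r_rhs <- ode_rhs(net, st)
    enc <- her4switch:::encode_network(net)
    # evaluate compiled derivs through a one-step deSolve call at tiny dt
    out <- deSolve::lsoda(y = st, times = c(0, 1e-9), func = "her4_derivs",
                          parms = enc, dllname = "her4switch",
                          initfunc = "her4_initparms")
    c_rhs <- (out[2, -1] - out[1, -1]) / 1e-9
    expect_lt(max(abs(c_rhs - r_rhs)), 1e-5 * (1 + max(abs(r_rhs))))
  }
})

test_that("JAK-channel activity is non-increasing in the heterodimerization rate", {
  net <- fx_full()
  act <- vapply(c(0.5, 1, 2, 4), function(f) {
    neti <- set_parameters(net, params = c(kfR41 = net$parameters[["kfR41"]] * f))
    tr <- run_timecourse(neti, dose = 20, t_end = 12, output_step = 0.05,
                         rtol = 1e-6, atol = 1e-9)
    integrate_interval(tr, "aHER4_JAK", 0, 12)
  }, 0.0)
  expect_true(all(diff(act) <= 1e-9))
})
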