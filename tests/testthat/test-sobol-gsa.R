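# The Saltelli product estimators are validated three ways: against closed
# forms derived by independent variance algebra (Ishigami, additive models),
# against a brute-force double-loop Monte Carlo oracle, and through their
# structural properties (plumbing identities, affine invariance).

test_that("design evaluation is the identity plumbing over the evaluator", {
  fn <- additive_linear(3)
  d <- saltelli_design(unit_space(fn), N = 8)
  b <- evaluate_design(d, fn$evaluator)
  expect_length(b$fA, 8)
  expect_length(b$fAB, 3)
  expect_length(b$fBA, 3)
  expect_equal(b$fA, apply(scale_to_space(d$A, unit_space(fn)), 1, fn$evaluator))
  expect_equal(b$fAB[[2]],
               apply(scale_to_space(d$AB[[2]], unit_space(fn)), 1, fn$evaluator))
})

test_that("constant outputs are refused (no variance to decompose)", {
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1), "linear")
  d <- saltelli_design(sp, N = 16)
  b <- evaluate_design(d, function(row) 42)
  expect_error(analyze_bundle(b), "no variance")
  expect_error(first_order_index(rep(1, 4), rep(1, 4), 1, 0), "no variance")
})

test_that("a single active input captures all variance", {
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1), "linear")
  d <- saltelli_design(sp, N = 8192)
  b <- evaluate_design(d, function(row) row[["x1"]])
  r <- analyze_bundle(b)
  expect_equal(r$S1[1], 1, tolerance = 0.02)
  expect_equal(r$S1[2], 0, tolerance = 0.02)
  expect_equal(r$ST[1], 1, tolerance = 0.02)
  expect_equal(r$ST[2], 0, tolerance = 0.02)
})

test_that("additive models satisfy the decomposition identity and ST = S1", {
  r <- benchmark_gsa(additive_linear(3), N = 8192)
  expect_equal(sum(r$S1), 1, tolerance = 0.02)
  expect_equal(r$S1, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(r$ST, r$S1, tolerance = 0.02)
})

test_that("Ishigami indices match the closed-form oracle within 0.02", {
  fn <- ishigami_function()
  r <- benchmark_gsa(fn, N = 8192)
  expect_equal(r$S1, fn$closed_form_S1, tolerance = 0.02)
  expect_equal(r$ST, fn$closed_form_ST, tolerance = 0.02)
  # x3 acts only through its interaction with x1
  expect_lt(abs(r$S1[3]), 0.02)
  expect_gt(r$ST[3] - r$S1[3], 0.2)
  expect_true(all(r$ST >= r$S1 - 0.02))
})

test_that("Saltelli estimates agree with double-loop Monte Carlo", {
  fn <- ishigami_function()
  saltelli <- benchmark_gsa(fn, N = 8192)
  oracle <- double_loop_indices(fn, seed = 2)
  expect_equal(saltelli$S1, oracle$S1, tolerance = 0.03)
  expect_equal(saltelli$ST, oracle$ST, tolerance = 0.03)
})

test_that("indices are invariant under affine output transformations", {
  fn <- ishigami_function()
  d <- saltelli_design(unit_space(fn), N = 4096)
  r1 <- analyze_bundle(evaluate_design(d, fn$evaluator))
  r2 <- analyze_bundle(evaluate_design(d, function(u) -2.5 * fn$evaluator(u) + 7))
  # exact invariance holds in expectation; finite-N estimates agree to the
  # Monte Carlo noise floor
  expect_equal(r1$S1, r2$S1, tolerance = 0.005)
  expect_equal(r1$ST, r2$ST, tolerance = 0.005)
})

test_that("ranking sorts by clipped total effect with stable tie-breaks", {
  r <- structure(list(parameter = c("p1", "p2", "p3"),
                      S1 = c(0.4, 0.05, 0.25), ST = c(0.5, 0.1, 0.3),
                      f0 = 0, VY = 1, N = 8, output_name = "x", dose_nM = NA),
                 class = "sensitivity_result")
  expect_equal(rank_top(r)$parameter, c("p1", "p3", "p2"))
  expect_equal(nrow(rank_top(r, n = 2)), 2L)
  expect_equal(nrow(rank_top(r, n = 10)), 3L)
  r$ST <- c(0.3, 0.3, 0.3)
  expect_equal(rank_top(r)$parameter, c("p1", "p2", "p3"))
  r$ST <- c(-0.1, -0.2, 0.3)  # negative estimates rank after zero, by id
  expect_equal(rank_top(r)$parameter, c("p3", "p1", "p2"))
})

test_that("network evaluator plugs simulations into the design machinery", {
  net <- fx_full()
  space <- default_parameter_space(net, parameters = c("kR45", "V_transc"))
  d <- saltelli_design(space, N = 4)
  ev <- network_evaluator(net, output = "integrated_casein", dose = 20,
                          space = space, t_end = 12, output_step = 0.1)
  b <- evaluate_design(d, ev)
  expect_length(b$fAB, 2)
  expect_length(b$fBA, 2)
  expect_true(all(is.finite(b$fA)) && all(b$fA > 0))
  r <- analyze_bundle(b, output_name = "integrated_casein", dose_nM = 20)
  expect_length(r$S1, 2)
  expect_gt(r$VY, 0)
})

test_that("optional bootstrap reports index standard errors", {
  fn <- ishigami_function()
  d <- saltelli_design(unit_space(fn), N = 1024)
  b <- evaluate_design(d, fn$evaluator)
  r <- analyze_bundle(b, n_boot = 50, boot_seed = 4)
  expect_length(r$S1_se, 3)
  expect_true(all(r$S1_se > 0) && all(r$ST_se > 0))
  expect_true(all(r$S1_se < 0.2))
  # estimates unchanged by requesting the CI
  r0 <- analyze_bundle(b)
  expect_identical(r$S1, r0$S1)
  expect_identical(r$ST, r0$ST)
  expect_null(r0$S1_se)
})
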