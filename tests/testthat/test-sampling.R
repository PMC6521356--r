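test_that("latin hypercube samples are stratified and deterministic", {
  for (case in list(c(1, 3), c(4, 2), c(17, 5), c(64, 12))) {
    n <- case[1]; k <- case[2]
    u <- latin_hypercube(n, k, seed = 100 + n)
    expect_equal(dim(u), c(n, k))
    expect_true(all(u >= 0 & u < 1))
    for (j in seq_len(k))
      expect_equal(tabulate(floor(u[, j] * n) + 1L, n), rep(1L, n),
                   label = sprintf("one point per stratum (n=%d, col %d)", n, j))
  }
  expect_identical(latin_hypercube(8, 3, seed = 7), latin_hypercube(8, 3, seed = 7))
  expect_false(identical(latin_hypercube(8, 3, seed = 7),
                         latin_hypercube(8, 3, seed = 8)))
})

test_that("Sobol sequence projections are dyadically equidistributed", {
  for (m in c(3L, 6L, 10L)) {
    n <- 2L^m
    s <- sobol_sequence(n, 20)
    expect_true(all(s >= 0 & s < 1))
    for (j in seq_len(ncol(s)))
      expect_equal(tabulate(floor(s[, j] * n) + 1L, n), rep(1L, n),
                   label = sprintf("dyadic bins (m=%d, dim %d)", m, j))
  }
  expect_equal(nrow(sobol_sequence(0, 4)), 0L)
  expect_error(sobol_sequence(8, 200), "exceeds")
  expect_identical(sobol_sequence(32, 6, skip = 32), sobol_sequence(32, 6, skip = 32))
})

test_that("Sobol points beat pseudo-random uniformity on the 1-D bin proxy", {
  # proxy for star discrepancy: worst absolute deviation of 1-D bin counts
  # from their expectation, over 16 bins and all dims
  bin_dev <- function(m) {
    max(abs(apply(m, 2, function(col) tabulate(floor(col * 16) + 1L, 16)) -
            nrow(m) / 16))
  }
  s <- bin_dev(sobol_sequence(256, 5))
  set.seed(42)
  r <- replicate(100, bin_dev(matrix(stats::runif(256 * 5), ncol = 5)))
  expect_lt(s, stats::median(r))
})

test_that("scaling maps the unit cube onto parameter bounds", {
  sp <- parameter_space(c("a", "b"), c(0, 0.1), c(10, 10),
                        scale = c("linear", "log10"))
  v <- scale_to_space(rbind(c(0, 0), c(0.5, 0.5)), sp)
  expect_equal(v[1, ], c(a = 0, b = 0.1))
  expect_equal(v[2, "a"], c(a = 5))
  expect_equal(v[2, "b"], c(b = 1.0))  # geometric midpoint of [0.1, 10]
  expect_error(parameter_space("a", 1, 1), "lower < upper")
  expect_error(parameter_space("a", 0, 1, "log10"), "log10")
  expect_error(scale_to_space(matrix(0.5, 1, 3), sp), "columns")
})

test_that("Saltelli designs satisfy the column-swap structure", {
  sp <- parameter_space(paste0("p", 1:3), rep(0, 3), rep(1, 3), "linear")
  d <- saltelli_design(sp, N = 4)
  expect_equal(dim(d$A), c(4, 3))
  expect_length(d$AB, 3)
  expect_length(d$BA, 3)
  for (i in 1:3) {
    expect_equal(d$AB[[i]][, i], d$B[, i])
    expect_equal(d$AB[[i]][, -i], d$A[, -i])
    expect_equal(d$BA[[i]][, i], d$A[, i])
    expect_equal(d$BA[[i]][, -i], d$B[, -i])
  }
  expect_true(all(d$A >= 0 & d$A < 1) && all(d$B >= 0 & d$B < 1))
  # N(2k+2) implied evaluations; identical skip reproduces the design
  expect_equal(d$N * (2 * d$k + 2), 32)
  d2 <- saltelli_design(sp, N = 4, skip = d$skip)
  expect_identical(d$A, d2$A)
  expect_identical(d$B, d2$B)
  # A and B come from disjoint coordinate blocks: not identical
  expect_false(isTRUE(all.equal(d$A, d$B)))
})

test_that("default parameter space uses log10 rates and linear initials", {
  net <- fx_full()
  sp <- default_parameter_space(net, parameters = c("kfR41", "kR45"),
                                initials = c("HER4", "HER2_3"))
  expect_equal(sp$k, 4L)
  expect_equal(sp$entries$scale, c("log10", "log10", "linear", "linear"))
  kfR41 <- net$parameters[["kfR41"]]
  expect_equal(sp$entries$lower[1], kfR41 / 10)
  expect_equal(sp$entries$upper[1], kfR41 * 10)
  her4 <- net$species$initial_amount[net$species$id == "HER4"]
  expect_equal(sp$entries$lower[3], her4 * 0.5)
  expect_equal(sp$entries$upper[3], her4 * 2)
})

test_that("designs round trip through CSV with invariants re-asserted", {
  sp <- parameter_space(c("a", "b"), c(0.1, 1), c(10, 2),
                        scale = c("log10", "linear"))
  d <- saltelli_design(sp, N = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  save_design(d, f)
  expect_true(file.exists(paste0(f, ".json")))
  d2 <- load_design(f)
  expect_equal(d2$A, d$A)
  expect_equal(d2$B, d$B)
  expect_equal(d2$AB, d$AB)
  expect_equal(d2$space$entries, d$space$entries)
  # corrupt one hybrid column: the re-asserted invariant must catch it
  tab <- read.csv(f, check.names = FALSE)
  tab[tab$block == "AB1", "a"] <- 0.123
  write.csv(tab, f, row.names = FALSE)
  expect_error(load_design(f))
})
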