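#' Evaluate a model over a Saltelli design
#'
#' Scales every row of the design's `A`, `B`, `AB[[i]]`, `BA[[i]]` matrices
#' to parameter values, evaluates the model for each, and collects the
#' output vectors that feed the index estimators. The evaluator is
#' injectable: the default simulates the reaction network and computes one of
#' the three dynamical readouts, but any function mapping a named parameter
#' row to a scalar can be passed (used by the analytic benchmark functions).
#'
#' @param design A [saltelli_design()].
#' @param evaluator Function `(values_row) -> scalar`, where `values_row` is
#'   a named numeric vector of parameter values. See [network_evaluator()].
#' @param max_failure_frac Error out when the failed fraction of evaluations
#'   exceeds this (default 0.2: bounds are then likely pathological).
#' @return An `evaluation_bundle`: `fA`, `fB` (length N), `fAB`, `fBA`
#'   (lists of k vectors), `failures` (indices removed pairwise across all
#'   vectors), `N_effective`.
#' @export
evaluate_design <- function(design, evaluator, max_failure_frac = 0.2) {
  space <- design$space
  eval_matrix <- function(u) {
    vals <- scale_to_space(u, space)
    vapply(seq_len(nrow(vals)), function(i)
      tryCatch(as.numeric(evaluator(vals[i, ])),
               error = function(e) NA_real_), 0.0)
  }
  fA <- eval_matrix(design$A)
  fB <- eval_matrix(design$B)
  fAB <- lapply(design$AB, eval_matrix)
  fBA <- lapply(design$BA, eval_matrix)
  bad <- !is.finite(fA) | !is.finite(fB)
  for (i in seq_len(design$k)) bad <- bad | !is.finite(fAB[[i]]) | !is.finite(fBA[[i]])
  frac <- mean(bad)
  if (frac > max_failure_frac)
    stop(sprintf("%.0f%% of design evaluations failed; parameter bounds likely pathological",
                 100 * frac))
  keep <- !bad
  structure(list(fA = fA[keep], fB = fB[keep],
                 fAB = lapply(fAB, `[`, keep), fBA = lapply(fBA, `[`, keep),
                 failures = which(bad), N_effective = sum(keep),
                 k = design$k, ids = space$entries$id),
            class = "evaluation_bundle")
}

#' Simulation-backed evaluator for the GSA driver
#'
#' Returns a closure that applies a sampled parameter row to the network,
#' simulates one NRG dose, and computes the selected readout.
#'
#' @param net A `reaction_network`.
#' @param output One of `"integrated_casein"` (total 0-48 h integral),
#'   `"switch_ratio"`, `"delay"`.
#' @param dose NRG dose in nM.
#' @param space The [parameter_space()] the rows come from (needed to route
#'   entries to rate constants vs initial amounts).
#' @param t_end,output_step,rtol,atol Simulation settings; the GSA driver
#'   defaults to a 0.02 h grid, fine enough for peak localization at the
#'   delays the model produces.
#' @return Function `(values_row) -> scalar`.
#' @export
network_evaluator <- function(net, output = c("integrated_casein",
                                              "switch_ratio", "delay"),
                              dose, space, t_end = 48, output_step = 0.02,
                              rtol = 1e-6, atol = 1e-9) {
  output <- match.arg(output)
  function(row) {
    net_i <- apply_parameter_row(net, space, row)
    traj <- run_timecourse(net_i, dose = dose, t_end = t_end,
                           output_step = output_step, rtol = rtol, atol = atol)
    switch(output,
      integrated_casein = integrate_interval(traj, "casein_mRNA_c", 0, t_end),
      switch_ratio = switch_ratio(traj),
      delay = transcription_delay(traj, allow_boundary = TRUE))
  }
}

#' First-order Sobol index (product estimator)
#'
#' `S_i = [ (1/N) * sum_j fA_j * fBA_i_j - f0^2 ] / VY`.
#'
#' @param fA Output vector over the `A` matrix.
#' @param fBA_i Output vector over `B` with column `i` taken from `A`.
#' @param f0sq Estimate of the squared output mean (see [analyze_bundle()]).
#' @param VY Output variance (> 0).
#' @return The estimated first-order index (reported raw; may fall slightly
#'   below 0 or above 1 by Monte Carlo noise).
#' @export
first_order_index <- function(fA, fBA_i, f0sq, VY) {
  if (VY <= 0) stop("output has no variance")
  (mean(fA * fBA_i) - f0sq) / VY
}

#' Total-effect Sobol index (product estimator)
#'
#' `ST_i = 1 - [ (1/N) * sum_j fA_j * fAB_i_j - f0^2 ] / VY`.
#'
#' @param fA Output vector over the `A` matrix.
#' @param fAB_i Output vector over `A` with column `i` taken from `B`.
#' @inheritParams first_order_index
#' @export
total_effect_index <- function(fA, fAB_i, f0sq, VY) {
  if (VY <= 0) stop("output has no variance")
  1 - (mean(fA * fAB_i) - f0sq) / VY
}

#' Assemble Sobol indices from an evaluation bundle
#'
#' `f0^2` is estimated as `mean(fA) * mean(fB)` and `V(Y)` as the sample
#' variance of the concatenation of `fA` and `fB`; this pairing keeps the
#' bias of the product estimators small. Indices are stored raw (no
#' clipping); clipping at zero is applied only when ranking.
#'
#' @param bundle An `evaluation_bundle` from [evaluate_design()].
#' @param output_name Label stored in the result.
#' @param dose_nM Dose annotation (NA for analytic benchmarks).
#' @param n_boot Optional resampling-CI flag: when > 0, design rows are
#'   resampled with replacement (jointly across all vectors, preserving the
#'   pairing the estimators rely on) and the standard error of every index
#'   is reported in `S1_se`/`ST_se`. Off by default.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `sensitivity_result`: `parameter` (ids), `S1`, `ST`, `f0`, `VY`,
#'   `N`, `output_name`, `dose_nM` (plus `S1_se`, `ST_se` when `n_boot > 0`).
#' @export
analyze_bundle <- function(bundle, output_name = "output", dose_nM = NA_real_,
                           n_boot = 0, boot_seed = 1) {
  indices_of <- function(rows) {
    fA <- bundle$fA[rows]; fB <- bundle$fB[rows]
    f0sq <- mean(fA) * mean(fB)
    VY <- stats::var(c(fA, fB))
    if (!is.finite(VY) || VY <= 0) stop("output has no variance")
    list(
      S1 = vapply(seq_len(bundle$k), function(i)
        first_order_index(fA, bundle$fBA[[i]][rows], f0sq, VY), 0.0),
      ST = vapply(seq_len(bundle$k), function(i)
        total_effect_index(fA, bundle$fAB[[i]][rows], f0sq, VY), 0.0),
      f0 = mean(c(fA, fB)), VY = VY)
  }
  est <- indices_of(seq_along(bundle$fA))
  res <- structure(list(parameter = bundle$ids, S1 = est$S1, ST = est$ST,
                        f0 = est$f0, VY = est$VY,
                        N = bundle$N_effective, output_name = output_name,
                        dose_nM = dose_nM),
                   class = "sensitivity_result")
  if (n_boot > 0) {
    reps <- withr::with_seed(boot_seed, lapply(seq_len(n_boot), function(b)
      indices_of(sample.int(length(bundle$fA), replace = TRUE))))
    res$S1_se <- apply(do.call(rbind, lapply(reps, `[[`, "S1")), 2, stats::sd)
    res$ST_se <- apply(do.call(rbind, lapply(reps, `[[`, "ST")), 2, stats::sd)
  }
  res
}

#' Rank parameters by total-effect index
#'
#' Sorted by `ST` descending with negative estimates clipped to zero for
#' ordering only; ties broken by parameter id.
#'
#' @param result A `sensitivity_result`.
#' @param n Number of rows to keep (default 10; all if `n > k`).
#' @return data.frame with columns parameter, S1, ST.
#' @export
rank_top <- function(result, n = 10) {
  stc <- pmax(result$ST, 0)
  ord <- order(-stc, result$parameter)
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(parameter = result$parameter[ord], S1 = result$S1[ord],
             ST = result$ST[ord], row.names = NULL)
}

#' Full Sobol GSA for one model output
#'
#' Builds the Saltelli design, evaluates the network, and assembles indices.
#'
#' @param net A `reaction_network`.
#' @param space A [parameter_space()].
#' @param output Readout selector (see [network_evaluator()]).
#' @param dose NRG dose in nM.
#' @param N Base sample count.
#' @param skip Sequence burn-in; default next power of two `>= N`.
#' @param ... Passed to [network_evaluator()].
#' @return A `sensitivity_result`.
#' @export
sobol_gsa <- function(net, space, output = "integrated_casein", dose = 20,
                      N = 128, skip = NULL, ...) {
  design <- saltelli_design(space, N, skip = skip)
  ev <- network_evaluator(net, output = output, dose = dose, space = space, ...)
  bundle <- evaluate_design(design, ev)
  analyze_bundle(bundle, output_name = output, dose_nM = dose)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sobol sensitivity: output '%s', dose %s nM, N = %d, f0 = %.4g, V(Y) = %.4g\n",
              x$output_name, format(x$dose_nM), x$N, x$f0, x$VY))
  print(utils::head(rank_top(x, n = length(x$parameter)), 10L))
  invisible(x)
}

#' Sensitivity result as a data.frame
#'
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @export
as.data.frame.sensitivity_result <- function(x, ...) {
  data.frame(parameter = x$parameter, S1 = x$S1, ST = x$ST, N = x$N,
             output_name = x$output_name, dose_nM = x$dose_nM,
             row.names = NULL)
}
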