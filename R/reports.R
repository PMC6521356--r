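# Pipeline drivers: validated run configuration plus report commands that
# tie network construction, simulation, readouts and GSA together and emit
# CSV tables and figures. A thin command-line wrapper over these functions
# ships in inst/cli/her4switch.R.

#' Default run configuration
#'
#' @return Named list understood by [validate_config()] and the `cmd_*`
#'   drivers: network flags, dose protocol, ensemble settings, GSA settings,
#'   optional SBML override path, output directory.
#' @export
default_config <- function() {
  list(
    network = list(heterodimerization_on = TRUE, jak_independent_on = TRUE,
                   sbml = NULL),
    doses = c(0, 10, 20, 50),
    t_end = 48, output_step = 0.01,
    ensemble = list(n_members = 50, seed = 1,
                    parameters = c("n_transc", "V_transc", "K_transc", "kR45",
                                   "kR15", "kfR41", "kfR42", "kfR43", "kfR36",
                                   "kR37", "kR39", "SOCS_Binding_Rate")),
    gsa = list(N = 128, skip = NULL, outputs = c("integrated_casein",
                                                 "switch_ratio", "delay"),
               dose = 20,
               parameters = c("n_transc", "V_transc", "K_transc", "kR45",
                              "kR15", "kfR41", "kfR42", "kfR43", "kfR36",
                              "kR37", "kR39", "SOCS_Binding_Rate"),
               initials = character()),
    out_dir = "her4switch_out")
}

#' Validate a run configuration
#'
#' Merges a partial configuration over [default_config()] and checks types,
#' ranges and file existence.
#'
#' @param config Partial configuration list (e.g. from [read_config()]).
#' @return The merged, validated configuration.
#' @export
validate_config <- function(config = list()) {
  merged <- utils::modifyList(default_config(), config)
  with(merged, {
    stopifnot(is.logical(network$heterodimerization_on),
              is.logical(network$jak_independent_on),
              all(doses >= 0), t_end > 0, output_step > 0,
              ensemble$n_members >= 2, gsa$N >= 2,
              all(gsa$outputs %in% c("integrated_casein", "switch_ratio", "delay")))
    if (!is.null(network$sbml) && !file.exists(network$sbml))
      stop("configured SBML file does not exist: ", network$sbml)
  })
  merged
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Validated configuration.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

config_network <- function(config) {
  net <- if (!is.null(config$network$sbml)) read_sbml(config$network$sbml)
         else build_canonical_network()
  if (config$network$heterodimerization_on && !net$flags$heterodimerization_on)
    net <- add_heterodimerization(net)
  if (config$network$jak_independent_on && !net$flags$jak_independent_on)
    net <- add_jak_independent_branch(net)
  net
}

config_space <- function(net, ids, initials = character()) {
  default_parameter_space(net, parameters = intersect(ids, names(net$parameters)),
                          initials = initials)
}

ensure_out <- function(config, ...) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, ...)
}

echo_config <- function(config) {
  yaml::write_yaml(config, ensure_out(config, "run_config.yaml"))
}

#' Simulate the dose series and emit trajectory CSVs plus the
#' instantaneous-profile figure
#'
#' @param config Run configuration (validated via [validate_config()]).
#' @param species Species plotted/exported (default the cytoplasmic
#'   beta-casein mRNA).
#' @return Invisibly, the list of trajectories.
#' @export
cmd_simulate <- function(config = list(), species = "casein_mRNA_c") {
  config <- validate_config(config)
  echo_config(config)
  net <- config_network(config)
  protocol <- dose_protocol(config$doses, config$t_end, config$output_step)
  trajs <- run_dose_series(net, protocol)
  for (tr in trajs)
    write.csv(trajectory_table(tr, species = species),
              ensure_out(config, sprintf("trajectory_dose_%g.csv", tr$dose)),
              row.names = FALSE)
  tab <- trajectory_table(trajs, species = species)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = time_h, y = conc_nM,
                                         colour = factor(dose_nM))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)",
                  colour = "NRG (nM)",
                  title = paste("Instantaneous", species, "profiles")) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(ensure_out(config, "instantaneous_profiles.svg"), p, device = grDevices::svg,
                  width = 7, height = 4.5)
  invisible(trajs)
}

#' Interval-integral switch report with ensemble error bars
#'
#' Runs the Latin-hypercube ensemble over the configured dose protocol,
#' writes the per-member readout table and the per-dose/interval summary
#' (mean, SD, SEM), emits the three-panel interval bar figure, and reports
#' the early (0-12 h) and late (24-48 h) dose-trend signs.
#'
#' @param config Run configuration.
#' @return Invisibly, list with `readouts`, `summary`, `trend_early`,
#'   `trend_late`.
#' @export
cmd_switch <- function(config = list()) {
  config <- validate_config(config)
  echo_config(config)
  net <- config_network(config)
  protocol <- dose_protocol(config$doses, config$t_end, config$output_step)
  space <- config_space(net, config$ensemble$parameters)
  ens <- run_ensemble(net, protocol, space, config$ensemble$n_members,
                      seed = config$ensemble$seed)
  readouts <- do.call(rbind, lapply(seq_along(ens$members), function(i)
    readout_table(ens$members[[i]]$trajectories, member_id = i)))
  summary <- ensemble_readout_summary(ens)
  write.csv(readouts, ensure_out(config, "readouts.csv"), row.names = FALSE)
  write.csv(summary, ensure_out(config, "readout_summary.csv"), row.names = FALSE)
  base <- readout_table(run_dose_series(net, protocol))
  doses <- base$dose_nM[base$dose_nM > 0]
  trend_early <- dose_trend(base$integral_0_12[base$dose_nM > 0], doses)
  trend_late <- dose_trend(base$integral_24_48[base$dose_nM > 0], doses)
  writeLines(c(sprintf("trend_0_12: %+d", trend_early),
               sprintf("trend_24_48: %+d", trend_late)),
             ensure_out(config, "trends.txt"))
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = factor(dose_nM), y = mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~interval, scales = "free_y") +
    ggplot2::labs(x = "NRG dose (nM)", y = "integrated beta-casein mRNA (nM h)",
                  title = "Interval-integrated expression (ensemble mean +/- SD)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(ensure_out(config, "interval_integrals.svg"), p, device = grDevices::svg,
                  width = 8, height = 4)
  invisible(list(readouts = readouts, summary = summary,
                 trend_early = trend_early, trend_late = trend_late))
}

#' Transport-rate sweep reproducing the transcription-delay mechanism
#'
#' Sweeps `kR45` (beta-casein mRNA nuclear export) and `kR15` (STAT5 dimer
#' nuclear import) over fractions of baseline and reports the STAT5-to-mRNA
#' peak gap and the absolute mRNA peak time at the configured GSA dose.
#'
#' @param config Run configuration.
#' @param fractions Multipliers applied to the baseline rate.
#' @return Invisibly, the sweep data.frame.
#' @export
cmd_delay_sweep <- function(config = list(), fractions = c(0.1, 0.2, 0.5, 1)) {
  config <- validate_config(config)
  echo_config(config)
  net <- config_network(config)
  rows <- list()
  for (par in c("kR45", "kR15")) for (f in fractions) {
    neti <- set_parameters(net, params = setNames(net$parameters[[par]] * f, par))
    tr <- run_timecourse(neti, dose = config$gsa$dose, t_end = config$t_end,
                         output_step = config$output_step)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = par, fraction = f,
      delay_h = transcription_delay(tr),
      mrna_peak_h = peak_time(tr$times, species_profile(tr, "casein_mRNA_c")))
  }
  sweep <- do.call(rbind, rows)
  write.csv(sweep, ensure_out(config, "delay_sweep.csv"), row.names = FALSE)
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = fraction, y = delay_h)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fraction of baseline rate", y = "STAT5 -> mRNA delay (h)",
                  title = "Transcription delay under transport-rate reduction") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(ensure_out(config, "delay_sweep.svg"), p, device = grDevices::svg, width = 7, height = 4)
  invisible(sweep)
}

#' Sobol GSA report: index CSVs and twin bar charts
#'
#' Runs the Saltelli-design GSA for every configured output quantity at the
#' configured NRG dose, writes one CSV per output, and emits a two-panel
#' figure (species initial amounts vs kinetic rate constants) of the top
#' parameters ranked by total effect.
#'
#' @param config Run configuration.
#' @return Invisibly, named list of `sensitivity_result`s.
#' @export
cmd_gsa <- function(config = list()) {
  config <- validate_config(config)
  echo_config(config)
  if (!is_power_of_two(config$gsa$N))
    message("GSA N = ", config$gsa$N,
            " is not a power of two; Sobol uniformity is best at powers of two")
  net <- config_network(config)
  space <- config_space(net, config$gsa$parameters, config$gsa$initials)
  results <- list()
  for (out in config$gsa$outputs) {
    r <- sobol_gsa(net, space, output = out, dose = config$gsa$dose,
                   N = config$gsa$N, skip = config$gsa$skip)
    results[[out]] <- r
    write.csv(as.data.frame(r),
              ensure_out(config, sprintf("sobol_%s.csv", out)), row.names = FALSE)
    top <- rank_top(r, 10)
    top$panel <- ifelse(startsWith(as.character(top$parameter), "init:"),
                        "species", "parameters")
    long <- rbind(data.frame(top[c("parameter", "panel")], index = "S1",
                             value = top$S1),
                  data.frame(top[c("parameter", "panel")], index = "ST",
                             value = top$ST))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(parameter, value),
                                            y = value, fill = index)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::coord_flip() +
      ggplot2::facet_wrap(~panel, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "Sobol index",
                    title = sprintf("Sensitivity of %s (dose %g nM, N = %d)",
                                    out, config$gsa$dose, r$N)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(ensure_out(config, sprintf("sobol_%s.svg", out)), p,
                    device = grDevices::svg, width = 8, height = 4.5)
  }
  invisible(results)
}

#' Estimator benchmark report
#'
#' Runs the Saltelli estimators on an analytic test function and writes the
#' estimated versus closed-form indices.
#'
#' @param config Run configuration.
#' @param bench `"ishigami"` or `"additive"`.
#' @param N Base sample count.
#' @return Invisibly, the comparison data.frame.
#' @export
cmd_bench <- function(config = list(), bench = c("ishigami", "additive"),
                      N = 8192) {
  config <- validate_config(config)
  echo_config(config)
  bench <- match.arg(bench)
  fn <- if (bench == "ishigami") ishigami_function() else additive_linear(3)
  r <- benchmark_gsa(fn, N = N)
  out <- data.frame(parameter = r$parameter, S1 = r$S1, ST = r$ST,
                    S1_closed_form = fn$closed_form_S1,
                    ST_closed_form = fn$closed_form_ST)
  write.csv(out, ensure_out(config, sprintf("bench_%s.csv", bench)),
            row.names = FALSE)
  invisible(out)
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
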