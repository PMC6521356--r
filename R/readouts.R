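#' Trapezoidal interval integral of one species
#'
#' @param traj A `trajectory`.
#' @param species_id Species id (default the cytoplasmic beta-casein mRNA,
#'   the model's primary readout).
#' @param t0,t1 Interval bounds in hours, `0 <= t0 < t1 <= t_end`.
#' @return Integral in nM*h.
#' @export
integrate_interval <- function(traj, species_id = "casein_mRNA_c", t0, t1) {
  stopifnot(t0 >= 0, t1 > t0)
  if (t1 > max(traj$times) + 1e-9)
    stop("interval [", t0, ", ", t1, "] outside the trajectory grid")
  y <- species_profile(traj, species_id)
  sel <- traj$times >= t0 - 1e-12 & traj$times <= t1 + 1e-12
  pracma::trapz(traj$times[sel], y[sel])
}

#' Early/late pathway switch ratio
#'
#' Integrated cytoplasmic beta-casein mRNA over the early window (0-12 h,
#' where the JAK-dependent branch operates) divided by the late window
#' (12-48 h, where the slower JAK-independent branch takes over). A ratio
#' near one indicates equal contributions of the two branches; a large ratio
#' means expression is dominated by the early JAK-dependent phase, i.e. no
#' time-dependent switch. Set `invert = TRUE` for the late/early convention.
#'
#' @param traj A `trajectory`.
#' @param species_id Readout species.
#' @param split Boundary between the windows (h), default 12.
#' @param invert Return late/early instead of early/late.
#' @return Positive ratio (dimensionless).
#' @export
switch_ratio <- function(traj, species_id = "casein_mRNA_c", split = 12,
                         invert = FALSE) {
  early <- integrate_interval(traj, species_id, 0, split)
  late <- integrate_interval(traj, species_id, split, max(traj$times))
  num <- if (invert) late else early
  den <- if (invert) early else late
  if (den <= .Machine$double.eps * abs(num))
    stop("degenerate switch ratio: denominator window has no expression")
  num / den
}

# Quadratic interpolation of the peak through the three grid points around
# the discrete argmax; reported delays (~3 h) are comparable to what coarse
# grids alias, so sub-grid localization matters. With `allow_boundary` a
# profile still rising (or falling) at the end of the window reports the
# boundary time instead of erroring; the sensitivity driver uses this so the
# delay functional is defined over the whole sampled parameter box.
peak_time <- function(times, y, allow_boundary = FALSE) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    if (allow_boundary) return(times[i])
    stop("no interior peak: profile is monotone over the grid")
  }
  t3 <- times[(i - 1L):(i + 1L)]; y3 <- y[(i - 1L):(i + 1L)]
  denom <- (y3[1] - 2 * y3[2] + y3[3])
  if (denom == 0) return(t3[2])
  h <- t3[2] - t3[1]
  t3[2] + 0.5 * h * (y3[1] - y3[3]) / denom
}

#' Transcription time delay
#'
#' Difference between the peak time of cytoplasmic beta-casein mRNA and the
#' peak time of the nuclear activated STAT5 dimer, each localized by
#' quadratic interpolation around the discrete argmax.
#'
#' @param traj A `trajectory`.
#' @param mrna_id,stat_id Species ids of the mRNA and the nuclear STAT5 dimer.
#' @param allow_boundary Accept a boundary argmax instead of raising on
#'   profiles with no interior peak (used by the GSA driver, where wide
#'   parameter bounds produce profiles still rising at 48 h).
#' @return Delay in hours (mRNA peak minus STAT5 peak).
#' @export
transcription_delay <- function(traj, mrna_id = "casein_mRNA_c",
                                stat_id = "STATdim_n",
                                allow_boundary = FALSE) {
  t_stat <- peak_time(traj$times, species_profile(traj, stat_id), allow_boundary)
  t_mrna <- peak_time(traj$times, species_profile(traj, mrna_id), allow_boundary)
  t_mrna - t_stat
}

#' Fold change relative to the zero-NRG control
#'
#' @param value Readout value.
#' @param control_value Same readout in the control (HC-only, zero-NRG) run;
#'   must be positive.
#' @return `value / control_value`.
#' @export
normalize_to_control <- function(value, control_value) {
  if (any(control_value <= 0)) stop("control value must be > 0")
  value / control_value
}

#' Sign of the dose trend of a readout
#'
#' Theil-Sen slope (median of pairwise slopes) of readout versus dose,
#' mapped to a sign. Robust to a non-monotone middle dose. A deadband
#' declares the trend flat when the absolute slope falls below
#' `deadband * mean(values) / 10` per nM (i.e. a relative threshold per
#' 10 nM of dose).
#'
#' @param values Readout values, one per dose (>= 3 doses).
#' @param doses NRG doses (nM), same length.
#' @param deadband Relative flatness threshold, default 1e-3.
#' @return -1, 0 or +1.
#' @export
dose_trend <- function(values, doses, deadband = 1e-3) {
  if (length(values) < 3L || length(doses) != length(values))
    stop("dose_trend needs >= 3 matched (dose, value) pairs")
  ij <- utils::combn(length(doses), 2L)
  slopes <- (values[ij[2, ]] - values[ij[1, ]]) /
            (doses[ij[2, ]] - doses[ij[1, ]])
  slope <- stats::median(slopes)
  threshold <- deadband * mean(abs(values)) / 10
  if (abs(slope) <= threshold) 0L else as.integer(sign(slope))
}

#' All three readouts for one trajectory
#'
#' @param traj A `trajectory`.
#' @param species_id Readout species.
#' @return A `readout_set`: interval integrals over 0-12, 12-24, 24-48 h and
#'   their total, the switch ratio, the transcription delay (NA when either
#'   profile has no interior peak), and the dose.
#' @export
readout_set <- function(traj, species_id = "casein_mRNA_c") {
  i1 <- integrate_interval(traj, species_id, 0, 12)
  i2 <- integrate_interval(traj, species_id, 12, 24)
  i3 <- integrate_interval(traj, species_id, 24, 48)
  delay <- tryCatch(transcription_delay(traj, mrna_id = species_id),
                    error = function(e) NA_real_)
  ratio <- tryCatch(switch_ratio(traj, species_id),
                    error = function(e) NA_real_)
  structure(list(integral_0_12 = i1, integral_12_24 = i2, integral_24_48 = i3,
                 integral_total_0_48 = i1 + i2 + i3,
                 switch_ratio = ratio, delay_h = delay, dose = traj$dose),
            class = "readout_set")
}

#' Readout table for a dose series or ensemble
#'
#' @param trajs List of `trajectory` objects.
#' @param member_id Member id recorded per row.
#' @return data.frame with one row per trajectory.
#' @export
readout_table <- function(trajs, member_id = NA) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  do.call(rbind, lapply(trajs, function(tr) {
    r <- readout_set(tr)
    data.frame(member_id = member_id, dose_nM = r$dose,
               integral_0_12 = r$integral_0_12,
               integral_12_24 = r$integral_12_24,
               integral_24_48 = r$integral_24_48,
               integral_total_0_48 = r$integral_total_0_48,
               switch_ratio = r$switch_ratio, delay_h = r$delay_h,
               row.names = NULL)
  }))
}

#' Mean and dispersion of ensemble readouts
#'
#' @param values Numeric vector of one readout across surviving ensemble
#'   members (>= 2).
#' @return List with `mean`, `sd`, `sem`, `n`.
#' @export
ensemble_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("ensemble summary needs >= 2 surviving members")
  s <- stats::sd(values)
  list(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Interval-integral summary across an ensemble
#'
#' @param ensemble Result of [run_ensemble()].
#' @return data.frame with one row per (dose, interval): mean, sd, sem, n.
#' @export
ensemble_readout_summary <- function(ensemble) {
  tabs <- lapply(seq_along(ensemble$members), function(i)
    readout_table(ensemble$members[[i]]$trajectories, member_id = i))
  all <- do.call(rbind, tabs)
  cells <- expand.grid(dose_nM = sort(unique(all$dose_nM)),
                       interval = c("integral_0_12", "integral_12_24",
                                    "integral_24_48"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    v <- all[all$dose_nM == cells$dose_nM[r], cells$interval[r]]
    s <- ensemble_summary(v)
    data.frame(dose_nM = cells$dose_nM[r], interval = cells$interval[r],
               mean = s$mean, sd = s$sd, sem = s$sem, n = s$n)
  }))
}
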