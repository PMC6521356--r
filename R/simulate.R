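HER4_PARMS_LEN <- 8192L

# Flatten a network into the double vector consumed by the compiled
# right-hand side in src/her4_rhs.c. Layout documented there.
encode_network <- function(net, params = net$parameters) {
  kinds <- c(mass_action_irreversible = 0, mass_action_reversible = 1,
             hill_activation = 2, first_order_transport = 3)
  idx <- function(ids) match(ids, net$species$id) - 1L
  blocks <- lapply(net$reactions, function(rxn) {
    kd <- kinds[[rxn$rate_law$kind]]
    p <- function(role) params[[rxn$rate_law$params[[role]]]]
    pvals <- switch(rxn$rate_law$kind,
      mass_action_irreversible = c(p("kf"), 0, 0),
      mass_action_reversible   = c(p("kf"), p("kr"), 0),
      hill_activation          = c(p("V_transc"), p("K_transc"), p("n_transc")),
      first_order_transport    = c(p("k_transport"), 0, 0))
    re <- rbind(idx(names(rxn$reactants)), as.numeric(rxn$reactants))
    pr <- rbind(idx(names(rxn$products)), as.numeric(rxn$products))
    c(kd, pvals,
      length(rxn$reactants), as.numeric(re),
      length(rxn$products), as.numeric(pr),
      length(rxn$modifiers), idx(rxn$modifiers))
  })
  S <- effective_stoichiometry(net)
  body <- c(nrow(net$species), length(net$reactions), NA_real_,
            unlist(blocks))
  s_offset <- length(body)
  body[3] <- s_offset
  enc <- c(body, as.numeric(S))
  if (length(enc) > HER4_PARMS_LEN)
    stop("network too large for compiled solver encoding")
  c(enc, numeric(HER4_PARMS_LEN - length(enc)))
}

new_trajectory <- function(times, conc, dose, params_used) {
  structure(list(times = times, conc = conc, dose = dose,
                 params_used = params_used), class = "trajectory")
}

#' Integrate the network over time
#'
#' Sets the NRG initial amount to `dose`, integrates the mass-action/Hill ODE
#' system with a stiff solver (`deSolve::lsoda` driving the package's
#' compiled right-hand side) and returns concentrations on a uniform output
#' grid. Defaults follow the package's numerical policy: `rtol = 1e-8`,
#' `atol = 1e-10` nM, output every 0.01 h over 0-48 h.
#'
#' @param net A `reaction_network`.
#' @param dose NRG dose in nM (set as the NRG initial amount; single bolus at
#'   t = 0).
#' @param t_end End time (h).
#' @param output_step Uniform output grid step (h).
#' @param params Optional full parameter map overriding `net$parameters`.
#' @param rtol,atol Solver tolerances.
#' @return A `trajectory`: list with `times`, `conc` (n_species x n_times
#'   matrix, clipped at 0), `dose`, `params_used`.
#' @export
run_timecourse <- function(net, dose = 0, t_end = 48, output_step = 0.01,
                           params = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(dose >= 0, t_end > 0, output_step > 0)
  if (is.null(params)) params <- net$parameters
  y0 <- setNames(net$species$initial_amount, net$species$id)
  if (!"NRG" %in% names(y0))
    stop("network has no NRG ligand species")
  y0[["NRG"]] <- dose
  times <- seq(0, t_end, by = output_step)
  enc <- encode_network(net, params)
  out <- deSolve::lsoda(y = y0, times = times, func = "her4_derivs",
                        parms = enc, dllname = "her4switch",
                        initfunc = "her4_initparms",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop(structure(class = c("her4_integration_error", "error", "condition"),
                   list(message = paste0("integration failed at dose ", dose),
                        call = sys.call(-1), params = params)))
  conc <- t(unname(out[, -1, drop = FALSE]))
  if (any(!is.finite(conc))) stop("non-finite concentrations in trajectory")
  if (min(conc) < -1e-9)
    warning("pre-clip negative concentration of ", min(conc), " nM")
  conc <- pmax(conc, 0)
  rownames(conc) <- net$species$id
  new_trajectory(times, conc, dose, params)
}

#' Dose protocol constructor
#'
#' @param nrg_doses Non-negative NRG doses (nM); sorted ascending.
#' @param t_end End time (h), default 48 as in the 0-48 h experimental window.
#' @param output_step Output grid step (h), default 0.01.
#' @export
dose_protocol <- function(nrg_doses = c(0, 10, 20, 50), t_end = 48,
                          output_step = 0.01) {
  stopifnot(all(nrg_doses >= 0), t_end > 0, output_step > 0)
  structure(list(nrg_doses = sort(nrg_doses), t_end = t_end,
                 output_step = output_step), class = "dose_protocol")
}

#' Run a series of NRG doses
#'
#' @param net A `reaction_network`.
#' @param protocol A [dose_protocol()].
#' @param ... Passed to [run_timecourse()].
#' @return Named list of `trajectory` objects (one per dose, identical time
#'   grids), names `"dose_<nM>"`.
#' @export
run_dose_series <- function(net, protocol = dose_protocol(), ...) {
  out <- lapply(protocol$nrg_doses, function(d)
    run_timecourse(net, dose = d, t_end = protocol$t_end,
                   output_step = protocol$output_step, ...))
  names(out) <- paste0("dose_", protocol$nrg_doses)
  out
}

#' Latin-hypercube parameter ensemble
#'
#' Draws `n_members` parameter sets from `space` with [latin_hypercube()],
#' runs the dose protocol for each, and collects the surviving members.
#' Members whose integration fails at any dose are dropped (never imputed)
#' and counted; if the dropout fraction exceeds `max_dropout` the summary is
#' refused with an error.
#'
#' @param net A `reaction_network`.
#' @param protocol A [dose_protocol()].
#' @param space A [parameter_space()].
#' @param n_members Number of LHS draws (>= 2).
#' @param seed Integer seed making the draw deterministic.
#' @param max_dropout Maximum tolerated failed-member fraction (default 0.05).
#' @param ... Passed to [run_timecourse()].
#' @return List with `members` (list of `list(params, trajectories)`),
#'   `n_failed`, `failed_idx`.
#' @export
run_ensemble <- function(net, protocol, space, n_members, seed,
                         max_dropout = 0.05, ...) {
  stopifnot(n_members >= 2)
  u <- latin_hypercube(n_members, space$k, seed = seed)
  vals <- scale_to_space(u, space)
  members <- vector("list", n_members)
  failed <- logical(n_members)
  for (i in seq_len(n_members)) {
    net_i <- apply_parameter_row(net, space, vals[i, ])
    trajs <- tryCatch(run_dose_series(net_i, protocol, ...),
                      error = function(e) NULL)
    if (is.null(trajs)) failed[i] <- TRUE
    else members[[i]] <- list(params = net_i$parameters,
                              initial = setNames(net_i$species$initial_amount,
                                                 net_i$species$id),
                              trajectories = trajs)
  }
  n_failed <- sum(failed)
  if (n_failed == n_members) stop("all ensemble members failed to integrate")
  if (n_failed / n_members > max_dropout)
    stop(sprintf("ensemble dropout fraction %.2f exceeds %.2f",
                 n_failed / n_members, max_dropout))
  if (n_failed > 0)
    message(n_failed, " of ", n_members, " ensemble members dropped")
  list(members = members[!failed], n_failed = n_failed,
       failed_idx = which(failed))
}

# A sampled row of a parameter space may address either a rate constant or a
# species initial amount (entries named "init:<species>").
apply_parameter_row <- function(net, space, row) {
  ids <- space$entries$id
  is_init <- startsWith(ids, "init:")
  params <- setNames(row[!is_init], ids[!is_init])
  initial <- setNames(row[is_init], sub("^init:", "", ids[is_init]))
  set_parameters(net,
                 params = if (length(params)) params else NULL,
                 initial = if (length(initial)) initial else NULL)
}

#' Extract one species profile from a trajectory
#'
#' @param traj A `trajectory`.
#' @param species_id Species id.
#' @return Numeric vector over the time grid.
#' @export
species_profile <- function(traj, species_id) {
  if (!species_id %in% rownames(traj$conc))
    stop("species '", species_id, "' not in trajectory")
  traj$conc[species_id, ]
}

#' Export a trajectory (or list of trajectories) as a tidy table
#'
#' @param trajs A `trajectory` or list of them.
#' @param species Optional character vector restricting species.
#' @param member_id Optional member id recorded per row.
#' @return data.frame with columns time_h, species_id, conc_nM, dose_nM,
#'   member_id.
#' @export
trajectory_table <- function(trajs, species = NULL, member_id = NA) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  do.call(rbind, lapply(trajs, function(tr) {
    ids <- if (is.null(species)) rownames(tr$conc) else species
    do.call(rbind, lapply(ids, function(s)
      data.frame(time_h = tr$times, species_id = s,
                 conc_nM = tr$conc[s, ], dose_nM = tr$dose,
                 member_id = member_id, row.names = NULL)))
  }))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d species x %d times (0-%g h), NRG dose %g nM\n",
              nrow(x$conc), length(x$times), max(x$times), x$dose))
  invisible(x)
}
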