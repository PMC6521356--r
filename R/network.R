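#' @useDynLib her4switch, .registration = TRUE
#' @importFrom stats var sd setNames
#' @importFrom utils read.delim write.csv
NULL

RATE_LAW_KINDS <- c("mass_action_irreversible", "mass_action_reversible",
                    "hill_activation", "first_order_transport")

#' Construct a rate law
#'
#' A rate law pairs a kinetic form with the parameter ids that feed it.
#' Supported forms are irreversible and reversible mass action, activating
#' Hill kinetics (for STAT5-driven transcription), and first-order transport
#' between compartments.
#'
#' @param kind One of `"mass_action_irreversible"`, `"mass_action_reversible"`,
#'   `"hill_activation"`, `"first_order_transport"`.
#' @param params Named character vector mapping parameter roles to parameter
#'   ids. Roles: `kf`/`kr` for mass action, `V_transc`/`K_transc`/`n_transc`
#'   for Hill, `k_transport` for transport.
#' @return A `rate_law` object.
#' @export
rate_law <- function(kind, params) {
  kind <- match.arg(kind, RATE_LAW_KINDS)
  params <- unlist(params)
  need <- switch(kind,
    mass_action_irreversible = "kf",
    mass_action_reversible   = c("kf", "kr"),
    hill_activation          = c("V_transc", "K_transc", "n_transc"),
    first_order_transport    = "k_transport")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0L)
    stop("rate law '", kind, "' requires parameter roles: ",
         paste(missing, collapse = ", "))
  structure(list(kind = kind, params = params[need]), class = "rate_law")
}

#' Construct a reaction
#'
#' @param id Short reaction id (e.g. `"R41"`).
#' @param name Human-readable reaction name.
#' @param reactants,products Named numeric vectors of positive integer
#'   stoichiometries keyed by species id; may be empty (e.g. transcription has
#'   no consumed reactant).
#' @param rate_law A [rate_law()] object.
#' @param modifiers Character vector of species ids that appear in the rate
#'   law without being consumed (e.g. the nuclear STAT5 dimer driving
#'   transcription, or a catalytic kinase).
#' @return A `reaction` object.
#' @export
reaction <- function(id, name, reactants = numeric(), products = numeric(),
                     rate_law, modifiers = character()) {
  stopifnot(is.character(id), length(id) == 1L, inherits(rate_law, "rate_law"))
  chk <- function(x, what) {
    if (length(x) > 0L) {
      if (is.null(names(x)) || any(names(x) == ""))
        stop("reaction ", id, ": ", what, " must be a named vector")
      if (any(x <= 0) || any(x != round(x)))
        stop("reaction ", id, ": ", what, " stoichiometries must be positive integers")
    }
    x
  }
  structure(list(id = id, name = name,
                 reactants = chk(reactants, "reactants"),
                 products = chk(products, "products"),
                 modifiers = modifiers, rate_law = rate_law),
            class = "reaction")
}

baseline_tables <- function() {
  pfile <- system.file("extdata", "baseline_parameters.tsv", package = "her4switch")
  sfile <- system.file("extdata", "baseline_species.tsv", package = "her4switch")
  list(parameters = read.delim(pfile, stringsAsFactors = FALSE),
       species = read.delim(sfile, stringsAsFactors = FALSE))
}

new_network <- function(compartments, species, reactions, parameters, flags) {
  net <- structure(list(compartments = compartments, species = species,
                        reactions = reactions, parameters = parameters,
                        flags = flags),
                   class = "reaction_network")
  validate_network(net)
}

#' Validate a reaction network
#'
#' Checks id uniqueness, that every species and parameter referenced by a
#' reaction resolves, and that transport reactions connect two distinct
#' compartments.
#'
#' @param net A `reaction_network`.
#' @return The network, invisibly unchanged, or an error.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (any(duplicated(net$species$id))) stop("duplicate species ids")
  if (any(duplicated(net$compartments$id))) stop("duplicate compartment ids")
  rids <- vapply(net$reactions, `[[`, "", "id")
  if (any(duplicated(rids)))
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  if (any(net$compartments$volume <= 0)) stop("compartment volumes must be > 0")
  if (any(net$species$initial_amount < 0)) stop("initial amounts must be >= 0")
  if (!all(net$species$compartment %in% net$compartments$id))
    stop("species reference unknown compartments")
  for (rxn in net$reactions) {
    sp <- c(names(rxn$reactants), names(rxn$products), rxn$modifiers)
    bad <- setdiff(sp, net$species$id)
    if (length(bad) > 0L)
      stop("reaction ", rxn$id, " references unknown species: ",
           paste(bad, collapse = ", "))
    bad <- setdiff(rxn$rate_law$params, names(net$parameters))
    if (length(bad) > 0L)
      stop("reaction ", rxn$id, " references unknown parameters: ",
           paste(bad, collapse = ", "))
    if (rxn$rate_law$kind == "first_order_transport") {
      if (length(rxn$reactants) != 1L || length(rxn$products) != 1L)
        stop("transport reaction ", rxn$id, " must have one reactant and one product")
      cr <- species_compartment(net, names(rxn$reactants))
      cp <- species_compartment(net, names(rxn$products))
      if (cr == cp)
        stop("transport reaction ", rxn$id, " must cross compartments")
    }
    if (rxn$rate_law$kind == "hill_activation") {
      if (length(rxn$modifiers) != 1L)
        stop("hill reaction ", rxn$id, " needs exactly one modifier")
      K <- net$parameters[[rxn$rate_law$params[["K_transc"]]]]
      n <- net$parameters[[rxn$rate_law$params[["n_transc"]]]]
      if (K <= 0) stop("K_transc must be > 0")
      if (n < 1) stop("n_transc must be >= 1")
    }
  }
  invisible(net)
}

species_compartment <- function(net, species_id) {
  net$species$compartment[match(species_id, net$species$id)]
}

#' Build the canonical HER4-JAK2-STAT5 network
#'
#' Constructs the two-compartment (cytoplasm + nucleus) JAK-dependent core of
#' the pathway: HER4-JAK2 binding and ligand (NRG) activation, JAK-dependent
#' STAT5 phosphorylation, STAT5 dimerization and nuclear import, nuclear
#' dephosphorylation through PPN and export of monomeric STAT5, cytoplasmic
#' phosphatases SHP (acting on the active receptor complex) and PPX (acting on
#' phospho-STAT5), Hill-type transcription of SOCS and beta-casein driven by
#' the nuclear STAT5 dimer, mRNA export and degradation, translation, and
#' SOCS-mediated negative feedback that removes the active HER4-JAK complex.
#'
#' Baseline rate constants and initial amounts are read from the packaged
#' parameter file (`inst/extdata`); both feature branches
#' (`heterodimerization_on`, `jak_independent_on`) start switched off and are
#' added by [add_heterodimerization()] and [add_jak_independent_branch()].
#'
#' @param nucleus_volume_ratio Nuclear-to-cytoplasmic relative volume used to
#'   scale transport fluxes so that amounts (not concentrations) are conserved
#'   across compartments. Default 0.25.
#' @return A `reaction_network`.
#' @export
build_canonical_network <- function(nucleus_volume_ratio = 0.25) {
  tb <- baseline_tables()
  sp <- tb$species[tb$species$module == "canonical", ]
  pars <- tb$parameters[tb$parameters$module == "canonical", ]
  parameters <- setNames(pars$value, pars$parameter)
  compartments <- data.frame(id = c("cytoplasm", "nucleus"),
                             name = c("Cytoplasm", "Nucleus"),
                             volume = c(1, nucleus_volume_ratio),
                             stringsAsFactors = FALSE)
  species <- data.frame(id = sp$id, name = sp$name, compartment = sp$compartment,
                        initial_amount = sp$initial_nM, role = sp$role,
                        stringsAsFactors = FALSE)
  ma  <- function(kf) rate_law("mass_action_irreversible", c(kf = kf))
  mar <- function(kf, kr) rate_law("mass_action_reversible", c(kf = kf, kr = kr))
  tr  <- function(k) rate_law("first_order_transport", c(k_transport = k))
  hill <- rate_law("hill_activation", c(V_transc = "V_transc",
                                        K_transc = "K_transc",
                                        n_transc = "n_transc"))
  reactions <- list(
    reaction("R01", "HER4 JAK Binding",
             c(HER4 = 1, JAK = 1), c(HER4_JAK = 1), mar("kfR01", "krR01")),
    reaction("R02", "HER4 JAK Ligand Activation",
             c(NRG = 1, HER4_JAK = 1), c(aHER4_JAK = 1), ma("kfR02")),
    reaction("R06", "STATc Phosphorylation JAK Dependent",
             c(STATc = 1), c(STATc_p = 1), ma("kR06"), modifiers = "aHER4_JAK"),
    reaction("R10", "STAT Dimerization",
             c(STATc_p = 2), c(STATdim_c = 1), ma("kfR10")),
    reaction("R15", "STAT Dimer Nuclear Translocation",
             c(STATdim_c = 1), c(STATdim_n = 1), tr("kR15")),
    reaction("R17", "STATc Dephosphorylation PPX",
             c(STATc_p = 1), c(STATc = 1), ma("kR17"), modifiers = "PPX"),
    reaction("R19", "Nuclear STAT Dimer PPN Binding",
             c(STATdim_n = 1, PPN = 1), c(STATdim_PPN = 1), ma("kfR19")),
    reaction("R20", "Nuclear STAT Dimer Dephosphorylation",
             c(STATdim_PPN = 1), c(PPN = 1, STATn = 2), ma("kR20")),
    reaction("R21", "STAT Nuclear Export",
             c(STATn = 1), c(STATc = 1), tr("kR21")),
    reaction("R22", "Transcription SOCS",
             products = c(SOCS_mRNA_n = 1), rate_law = hill,
             modifiers = "STATdim_n"),
    reaction("R24", "mRNA Nuclear Export",
             c(SOCS_mRNA_n = 1), c(SOCS_mRNA_c = 1), tr("kR24")),
    reaction("R25", "Translation SOCS",
             products = c(SOCS = 1), rate_law = ma("kR25"),
             modifiers = "SOCS_mRNA_c"),
    reaction("R26", "mRNA Degradation SOCS",
             c(SOCS_mRNA_c = 1), rate_law = ma("kR26")),
    reaction("R27", "Active HER4 JAK SHP Binding",
             c(aHER4_JAK = 1, SHP = 1), c(aHER4_JAK_SHP = 1), ma("kfR27")),
    reaction("R28", "Receptor Dephosphorylation SHP",
             c(aHER4_JAK_SHP = 1), c(HER4_JAK = 1, SHP = 1), ma("kR28")),
    reaction("R30", "SOCS Binding",
             c(SOCS = 1, aHER4_JAK = 1), c(SOCS_HER4_JAK = 1),
             ma("SOCS_Binding_Rate")),
    reaction("R29", "STATc SOCS HER4 JAK SHP Binding",
             c(SOCS_HER4_JAK = 1, SHP = 1), c(SHP = 1), ma("kfR29")),
    reaction("R31", "SOCS Degradation",
             c(SOCS = 1), rate_law = ma("kR31")),
    reaction("R44", "Transcription Casein",
             products = c(casein_mRNA_n = 1), rate_law = hill,
             modifiers = "STATdim_n"),
    # NRG-independent basal transcription: stands in for the HC/GR-driven
    # expression that defines the experimental control; keeps the zero-NRG
    # fold-change normalization finite
    reaction("R48", "Transcription Casein Basal",
             products = c(casein_mRNA_n = 1), rate_law = ma("V_basal_transc")),
    reaction("R45", "mRNA Nuclear Export Casein",
             c(casein_mRNA_n = 1), c(casein_mRNA_c = 1), tr("kR45")),
    reaction("R46", "mRNA Degradation Casein",
             c(casein_mRNA_c = 1), rate_law = ma("kR46")),
    reaction("R47", "Translation Casein",
             products = c(casein = 1), rate_law = ma("kR25"),
             modifiers = "casein_mRNA_c")
  )
  new_network(compartments, species, reactions, parameters,
              flags = list(heterodimerization_on = FALSE, jak_independent_on = FALSE))
}

add_module_species <- function(net, module) {
  tb <- baseline_tables()
  sp <- tb$species[tb$species$module == module, ]
  pars <- tb$parameters[tb$parameters$module == module, ]
  net$species <- rbind(net$species,
                       data.frame(id = sp$id, name = sp$name,
                                  compartment = sp$compartment,
                                  initial_amount = sp$initial_nM, role = sp$role,
                                  stringsAsFactors = FALSE))
  net$parameters <- c(net$parameters, setNames(pars$value, pars$parameter))
  net
}

#' Add competitive HER4 heterodimerization
#'
#' Adds the three reactions through which ligand-stimulated HER4 pairs with
#' the other ErbB receptors (a lumped HER2/HER3 partner pool): ligand-dependent
#' heterodimerization, constitutive heterodimerization, and NRG binding to the
#' preformed heterodimer. All three drain the free HER4 pool and therefore
#' compete with HER4-JAK2 binding; at stimulating NRG doses the
#' heterodimerization capture flux exceeds the JAK capture flux, which is what
#' makes NRG act as an early-time antagonist of beta-casein expression.
#'
#' @param net A `reaction_network` with `heterodimerization_on = FALSE`.
#' @return The extended network with `heterodimerization_on = TRUE`.
#' @export
add_heterodimerization <- function(net) {
  if (isTRUE(net$flags$heterodimerization_on))
    stop("heterodimerization reactions already present (duplicate reaction ids)")
  net <- add_module_species(net, "heterodimerization")
  ma <- function(kf) rate_law("mass_action_irreversible", c(kf = kf))
  net$reactions <- c(net$reactions, list(
    reaction("R41", "HER4 Heterodimerization",
             c(NRG = 1, HER4 = 1, HER2_3 = 1), c(HET_L = 1), ma("kfR41")),
    reaction("R42", "HER4 Heterodimerization Constitutive",
             c(HER4 = 1, HER2_3 = 1), c(HET = 1), ma("kfR42")),
    reaction("R43", "HER4 Heterodimer Ligand Binding",
             c(NRG = 1, HET = 1), c(HET_L = 1), ma("kfR43"))
  ))
  net$flags$heterodimerization_on <- TRUE
  validate_network(net)
  net
}

#' Add the JAK2-independent STAT5 activation branch
#'
#' Adds the slower parallel pathway in which ligand-activated HER4 is cleaved
#' to its s80/4ICD fragment (called IFNR in the parameter table), the fragment
#' is activated, and active s80 phosphorylates cytoplasmic STAT5 directly,
#' without JAK2. Because no JAK2 is present in the s80 complex, this branch is
#' not subject to SOCS negative feedback, and its baseline phosphorylation
#' rate `kR39` is ten-fold below the JAK-dependent `kR06`.
#'
#' @param net A `reaction_network` with `jak_independent_on = FALSE`.
#' @return The extended network with `jak_independent_on = TRUE`.
#' @export
add_jak_independent_branch <- function(net) {
  if (isTRUE(net$flags$jak_independent_on))
    stop("JAK-independent branch already present (duplicate reaction ids)")
  net <- add_module_species(net, "jak_independent")
  ma <- function(kf) rate_law("mass_action_irreversible", c(kf = kf))
  net$reactions <- c(net$reactions, list(
    reaction("R36", "IFNR (HER4 s80) Formation",
             c(NRG = 1, HER4 = 1), c(s80 = 1), ma("kfR36")),
    reaction("R37", "IFNR (HER4 s80) Activation",
             c(s80 = 1), c(s80_a = 1), ma("kR37")),
    reaction("R39", "STATc Phosphorylation JAK independent",
             c(STATc = 1), c(STATc_p = 1), ma("kR39"), modifiers = "s80_a")
  ))
  net$flags$jak_independent_on <- TRUE
  validate_network(net)
  net
}

#' Build the full switching model
#'
#' Canonical core plus both extension branches (competitive
#' heterodimerization and the JAK-independent s80 branch). This is the
#' parameterization that reproduces the time-dependent antagonist/agonist
#' switch in beta-casein expression.
#'
#' @inheritParams build_canonical_network
#' @export
build_full_network <- function(nucleus_volume_ratio = 0.25) {
  add_jak_independent_branch(
    add_heterodimerization(build_canonical_network(nucleus_volume_ratio)))
}

#' Raw stoichiometry matrix
#'
#' @param net A `reaction_network`.
#' @return Integer matrix of shape n_species x n_reactions (products minus
#'   reactants), with dimnames.
#' @export
stoichiometry_matrix <- function(net) {
  ns <- nrow(net$species); nr <- length(net$reactions)
  S <- matrix(0, ns, nr,
              dimnames = list(net$species$id,
                              vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_len(nr)) {
    rxn <- net$reactions[[j]]
    for (s in names(rxn$reactants))
      S[s, j] <- S[s, j] - rxn$reactants[[s]]
    for (s in names(rxn$products))
      S[s, j] <- S[s, j] + rxn$products[[s]]
  }
  S
}

reaction_compartment <- function(net, rxn) {
  ref <- c(names(rxn$reactants), rxn$modifiers, names(rxn$products))
  if (length(ref) == 0L) return(net$compartments$id[[1L]])
  species_compartment(net, ref[[1L]])
}

#' Volume-scaled stoichiometry matrix
#'
#' Rate laws are evaluated in the concentration units of the compartment the
#' reaction takes place in; converting a reaction flux into concentration
#' derivatives of its participating species requires scaling each entry by the
#' ratio of the reaction compartment volume to the species compartment volume,
#' so that *amounts* are conserved across compartments (a nuclear import flux
#' raises nuclear concentration by the cytoplasm:nucleus volume ratio).
#'
#' @param net A `reaction_network`.
#' @return Numeric matrix n_species x n_reactions.
#' @export
effective_stoichiometry <- function(net) {
  S <- stoichiometry_matrix(net)
  vol <- setNames(net$compartments$volume, net$compartments$id)
  spvol <- vol[net$species$compartment]
  for (j in seq_along(net$reactions)) {
    vr <- vol[[reaction_compartment(net, net$reactions[[j]])]]
    S[, j] <- S[, j] * vr / spvol
  }
  S
}

#' Conserved moieties of the network
#'
#' Left null space of the volume-scaled stoichiometry matrix: every column is
#' a weight vector over species whose weighted concentration sum is constant
#' along any trajectory (e.g. total STAT5 across free, phosphorylated,
#' dimeric, complexed and nuclear forms, with nuclear species weighted by the
#' compartment volume ratio).
#'
#' @param net A `reaction_network`.
#' @return Matrix with one row per species and one column per conservation law
#'   (possibly zero columns).
#' @export
conserved_moieties <- function(net) {
  S <- effective_stoichiometry(net)
  N <- MASS::Null(S)  # null space of t(t(S)), i.e. vectors w with t(S) %*% w = 0
  if (length(N) == 0L) N <- matrix(0, nrow(S), 0L)
  rownames(N) <- rownames(S)
  N
}

#' Evaluate one reaction rate
#'
#' Mass action: `kf * prod([reactant]^stoich)` (minus the symmetric product
#' term over products when reversible), with catalytic modifiers entering as
#' first-order factors. Hill activation: `V * M^n / (K^n + M^n)` with `M` the
#' modifier concentration. Transport: `k * [reactant]`.
#'
#' @param rxn A `reaction`.
#' @param state Named non-negative concentration vector (nM).
#' @param params Named parameter values.
#' @param tol Negative concentrations beyond `-tol` raise an error; small
#'   violations are clamped to zero.
#' @return Reaction rate in nM/h (concentration units of the reaction's
#'   compartment).
#' @export
reaction_rate <- function(rxn, state, params, tol = 1e-9) {
  if (any(!is.finite(state))) stop("non-finite concentration in state")
  if (any(state < -tol))
    stop("negative concentration in state: min = ", min(state))
  state <- pmax(state, 0)
  p <- function(role) params[[rxn$rate_law$params[[role]]]]
  modfac <- function() {
    if (length(rxn$modifiers) == 0L) 1 else prod(state[rxn$modifiers])
  }
  switch(rxn$rate_law$kind,
    mass_action_irreversible = {
      f <- if (length(rxn$reactants) == 0L) 1 else
        prod(state[names(rxn$reactants)]^rxn$reactants)
      p("kf") * f * modfac()
    },
    mass_action_reversible = {
      f <- if (length(rxn$reactants) == 0L) 1 else
        prod(state[names(rxn$reactants)]^rxn$reactants)
      b <- if (length(rxn$products) == 0L) 1 else
        prod(state[names(rxn$products)]^rxn$products)
      (p("kf") * f - p("kr") * b) * modfac()
    },
    hill_activation = {
      M <- state[[rxn$modifiers]]
      V <- p("V_transc"); K <- p("K_transc"); n <- p("n_transc")
      V * M^n / (K^n + M^n)
    },
    first_order_transport = p("k_transport") * state[[names(rxn$reactants)]]
  )
}

#' ODE right-hand side (reference R implementation)
#'
#' `dC/dt = S_eff %*% v(C)` with `S_eff` the volume-scaled stoichiometry
#' matrix and `v` the vector of reaction rates. This is the reference
#' implementation; [run_timecourse()] integrates an equivalent compiled form
#' for speed, and the two are cross-checked in the test suite.
#'
#' @param net A `reaction_network`.
#' @param state Concentration vector, length n_species, ordered as
#'   `net$species$id` (names optional).
#' @param t Time in hours (unused: the system is autonomous; kept for ODE
#'   solver signatures).
#' @param params Optional parameter override; defaults to `net$parameters`.
#' @return Named derivative vector (nM/h).
#' @export
ode_rhs <- function(net, state, t = 0, params = net$parameters) {
  if (length(state) != nrow(net$species))
    stop("state length ", length(state), " != n_species ", nrow(net$species))
  if (any(!is.finite(state))) stop("NaN/Inf in state")
  state <- setNames(as.numeric(state), net$species$id)
  v <- vapply(net$reactions, reaction_rate, 0.0, state = state, params = params)
  drop(effective_stoichiometry(net) %*% v)
}

#' Override network parameters and initial amounts
#'
#' @param net A `reaction_network`.
#' @param params Named numeric vector of parameter values to replace.
#' @param initial Named numeric vector of species initial amounts to replace.
#' @return The modified network.
#' @export
set_parameters <- function(net, params = NULL, initial = NULL) {
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(net$parameters))
    if (length(bad) > 0L) stop("unknown parameters: ", paste(bad, collapse = ", "))
    net$parameters[names(params)] <- params
  }
  if (!is.null(initial)) {
    idx <- match(names(initial), net$species$id)
    if (anyNA(idx)) stop("unknown species: ",
                         paste(names(initial)[is.na(idx)], collapse = ", "))
    if (any(initial < 0)) stop("initial amounts must be >= 0")
    net$species$initial_amount[idx] <- initial
  }
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("HER4-JAK2-STAT5 reaction network\n")
  cat(sprintf("  compartments: %d | species: %d | reactions: %d | parameters: %d\n",
              nrow(x$compartments), nrow(x$species), length(x$reactions),
              length(x$parameters)))
  cat(sprintf("  heterodimerization_on: %s | jak_independent_on: %s\n",
              x$flags$heterodimerization_on, x$flags$jak_independent_on))
  invisible(x)
}
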