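# SBML Level 3 Version 1 export / import of the reaction network, plus a
# human-editable YAML serialization. The SBML subset handled is what the
# model uses: compartments, species with initial concentrations, global
# parameters, reactions with reactants/products/modifiers and kinetic laws
# that are mass action (optionally reversible), first-order transport, or
# activating Hill kinetics. Events, rules and constraints are rejected.

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

mathml_ci <- function(x) paste0("<ci> ", x, " </ci>")
mathml_cn <- function(x) {
  if (x == round(x)) paste0('<cn type="integer"> ', format(x), " </cn>")
  else paste0("<cn> ", format(x), " </cn>")
}
mathml_apply <- function(op, args)
  paste0("<apply><", op, "/>", paste(args, collapse = ""), "</apply>")
mathml_pow <- function(base, expo)
  mathml_apply("power", c(base, expo))

mathml_product <- function(factors) {
  if (length(factors) == 1L) factors else mathml_apply("times", factors)
}

species_factors <- function(sp) {
  unlist(lapply(names(sp), function(s) {
    if (sp[[s]] == 1) mathml_ci(s) else mathml_pow(mathml_ci(s), mathml_cn(sp[[s]]))
  }))
}

rate_law_mathml <- function(rxn) {
  pid <- rxn$rate_law$params
  switch(rxn$rate_law$kind,
    mass_action_irreversible = mathml_product(
      c(mathml_ci(pid[["kf"]]), species_factors(rxn$reactants),
        vapply(rxn$modifiers, mathml_ci, ""))),
    first_order_transport = mathml_product(
      c(mathml_ci(pid[["k_transport"]]), species_factors(rxn$reactants))),
    mass_action_reversible = mathml_apply("minus", c(
      mathml_product(c(mathml_ci(pid[["kf"]]), species_factors(rxn$reactants),
                       vapply(rxn$modifiers, mathml_ci, ""))),
      mathml_product(c(mathml_ci(pid[["kr"]]), species_factors(rxn$products),
                       vapply(rxn$modifiers, mathml_ci, ""))))),
    hill_activation = {
      M <- mathml_ci(rxn$modifiers[[1L]])
      n <- mathml_ci(pid[["n_transc"]])
      mathml_apply("divide", c(
        mathml_product(c(mathml_ci(pid[["V_transc"]]), mathml_pow(M, n))),
        mathml_apply("plus", c(mathml_pow(mathml_ci(pid[["K_transc"]]), n),
                               mathml_pow(M, n)))))
    })
}

#' Write a network as SBML Level 3 Version 1
#'
#' @param net A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_L3_NS),
    sprintf('<model id="her4_jak2_stat5" name="HER4-JAK2-STAT5 pathway" her4switch_heterodimerization="%s" her4switch_jak_independent="%s">',
            tolower(net$flags$heterodimerization_on),
            tolower(net$flags$jak_independent_on)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" name="%s" size="%g" constant="true"/>',
            net$compartments$id, esc(net$compartments$name),
            net$compartments$volume),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="%s" name="%s" compartment="%s" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" her4switch_role="%s"/>',
            net$species$id, esc(net$species$name), net$species$compartment,
            net$species$initial_amount, net$species$role),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%.17g" constant="true"/>',
            names(net$parameters), unname(net$parameters)),
    "</listOfParameters>",
    "<listOfReactions>")
  for (rxn in net$reactions) {
    rev <- rxn$rate_law$kind == "mass_action_reversible"
    lines <- c(lines, sprintf('<reaction id="%s" name="%s" reversible="%s" fast="false">',
                              rxn$id, esc(rxn$name), tolower(rev)))
    if (length(rxn$reactants) > 0L)
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
                         names(rxn$reactants), unname(rxn$reactants)),
                 "</listOfReactants>")
    if (length(rxn$products) > 0L)
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
                         names(rxn$products), unname(rxn$products)),
                 "</listOfProducts>")
    if (length(rxn$modifiers) > 0L)
      lines <- c(lines, "<listOfModifiers>",
                 sprintf('<modifierSpeciesReference species="%s"/>', rxn$modifiers),
                 "</listOfModifiers>")
    lines <- c(lines, "<kineticLaw>",
               sprintf('<math xmlns="%s">', MATHML_NS),
               rate_law_mathml(rxn),
               "</math>", "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

# ---- MathML parsing into R expression trees -------------------------------

parse_mathml_node <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    ch <- xml2::xml_children(node)
    op <- xml2::xml_name(ch[[1L]])
    args <- lapply(ch[-1L], parse_mathml_node)
    fun <- switch(op, times = "*", plus = "+", minus = "-", divide = "/",
                  power = "^",
                  stop("unsupported MathML operator: ", op))
    Reduce(function(a, b) call(fun, a, b), args)
  } else stop("unsupported MathML node: ", nm)
}

# Flatten nested products into a list of factors.
flatten_product <- function(e) {
  if (is.call(e) && identical(e[[1L]], as.name("*")))
    c(flatten_product(e[[2L]]), flatten_product(e[[3L]]))
  else list(e)
}

# Classify a factor as (id, exponent): a bare symbol or symbol^number.
factor_id_exp <- function(f) {
  if (is.name(f)) return(list(id = as.character(f), exp = 1))
  if (is.call(f) && identical(f[[1L]], as.name("^")) && is.name(f[[2L]]))
    return(list(id = as.character(f[[2L]]),
                exp = if (is.numeric(f[[3L]])) f[[3L]] else NA))
  NULL
}

classify_mass_action_side <- function(expr, param_ids) {
  parts <- lapply(flatten_product(expr), factor_id_exp)
  if (any(vapply(parts, is.null, TRUE))) return(NULL)
  ids <- vapply(parts, `[[`, "", "id")
  exps <- vapply(parts, function(p) as.numeric(p$exp), 0.0)
  is_par <- ids %in% param_ids
  if (sum(is_par) != 1L || any(exps[is_par] != 1)) return(NULL)
  list(param = ids[is_par],
       species = setNames(exps[!is_par], ids[!is_par]))
}

# Recognize V * M^n / (K^n + M^n)
classify_hill <- function(expr, param_ids) {
  if (!(is.call(expr) && identical(expr[[1L]], as.name("/")))) return(NULL)
  num <- classify_mass_action_side(expr[[2L]], param_ids)
  den <- expr[[3L]]
  if (is.null(num) || length(num$species) != 1L) return(NULL)
  if (!(is.call(den) && identical(den[[1L]], as.name("+")))) return(NULL)
  terms <- list(den[[2L]], den[[3L]])
  getpow <- function(t) {
    if (is.call(t) && identical(t[[1L]], as.name("^")) && is.name(t[[2L]]))
      list(base = as.character(t[[2L]]),
           exp = if (is.name(t[[3L]])) as.character(t[[3L]]) else t[[3L]])
    else NULL
  }
  p1 <- getpow(terms[[1L]]); p2 <- getpow(terms[[2L]])
  if (is.null(p1) || is.null(p2)) return(NULL)
  M <- names(num$species)
  Kterm <- if (p1$base %in% param_ids) p1 else if (p2$base %in% param_ids) p2 else return(NULL)
  Mterm <- if (identical(p1$base, M)) p1 else if (identical(p2$base, M)) p2 else return(NULL)
  # the numerator exponent of M must be the Hill coefficient parameter id
  nM <- num$species[[M]]
  n_id <- if (is.character(Mterm$exp)) Mterm$exp else NA
  if (is.na(n_id) || !identical(Kterm$exp, n_id)) return(NULL)
  list(V = num$param, K = Kterm$base, n = n_id, M = M)
}

#' Read a reaction network from SBML
#'
#' Accepts SBML Level 3 (as written by [write_sbml()]) and Level 2 documents
#' restricted to the supported construct subset. Kinetic laws are classified
#' structurally from their MathML (mass action, reversible mass action as a
#' difference of two products, activating Hill, first-order transport);
#' events, rules, constraints, function definitions and unrecognized rate
#' laws raise an error.
#'
#' @param path SBML file path.
#' @return A `reaction_network`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  for (bad in c("listOfEvents", "listOfRules", "listOfConstraints",
                "listOfFunctionDefinitions")) {
    if (length(xml2::xml_find_all(doc, paste0("//", bad))) > 0L)
      stop("unsupported SBML construct: ", bad)
  }
  model <- xml2::xml_find_first(doc, "//model")
  att <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a); if (is.na(v)) default else v
  }
  comp_nodes <- xml2::xml_find_all(doc, "//listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    name = vapply(comp_nodes, function(n) att(n, "name", xml2::xml_attr(n, "id")), ""),
    volume = as.numeric(vapply(comp_nodes, function(n)
      att(n, "size", att(n, "volume", "1")), "")),
    stringsAsFactors = FALSE)
  sp_nodes <- xml2::xml_find_all(doc, "//listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = vapply(sp_nodes, function(n) att(n, "name", xml2::xml_attr(n, "id")), ""),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    initial_amount = as.numeric(vapply(sp_nodes, function(n)
      att(n, "initialConcentration", att(n, "initialAmount", "0")), "")),
    role = vapply(sp_nodes, function(n) att(n, "her4switch_role", "protein"), ""),
    stringsAsFactors = FALSE)
  par_nodes <- xml2::xml_find_all(doc, "//listOfParameters/parameter")
  parameters <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                         xml2::xml_attr(par_nodes, "id"))
  param_ids <- names(parameters)

  rxn_nodes <- xml2::xml_find_all(doc, "//listOfReactions/reaction")
  reactions <- lapply(rxn_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(rn, xp)
      if (length(nodes) == 0L) return(numeric())
      setNames(as.numeric(vapply(nodes, function(n) att(n, "stoichiometry", "1"), "")),
               xml2::xml_attr(nodes, "species"))
    }
    reactants <- refs("listOfReactants/speciesReference")
    products <- refs("listOfProducts/speciesReference")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(rn, "listOfModifiers/modifierSpeciesReference"), "species")
    math <- xml2::xml_find_first(rn, "kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop("reaction ", rid, " has no kinetic law")
    if (length(xml2::xml_find_all(rn, "kineticLaw/listOfParameters/parameter")) > 0L ||
        length(xml2::xml_find_all(rn, "kineticLaw/listOfLocalParameters/localParameter")) > 0L)
      stop("reaction ", rid, ": local kinetic-law parameters are not supported")
    expr <- parse_mathml_node(xml2::xml_child(math))
    hill <- classify_hill(expr, param_ids)
    rl <- NULL
    if (!is.null(hill)) {
      rl <- rate_law("hill_activation", c(V_transc = hill$V, K_transc = hill$K,
                                          n_transc = hill$n))
      modifiers <- union(modifiers, hill$M)
    } else if (is.call(expr) && identical(expr[[1L]], as.name("-"))) {
      fwd <- classify_mass_action_side(expr[[2L]], param_ids)
      bwd <- classify_mass_action_side(expr[[3L]], param_ids)
      if (is.null(fwd) || is.null(bwd))
        stop("reaction ", rid, ": unsupported rate-law kind")
      rl <- rate_law("mass_action_reversible", c(kf = fwd$param, kr = bwd$param))
    } else {
      ma <- classify_mass_action_side(expr, param_ids)
      if (is.null(ma)) stop("reaction ", rid, ": unsupported rate-law kind")
      transport <- length(reactants) == 1L && length(products) == 1L &&
        identical(names(ma$species), names(reactants)) &&
        ma$species[[1L]] == 1 &&
        species$compartment[match(names(reactants), species$id)] !=
          species$compartment[match(names(products), species$id)]
      rl <- if (transport)
        rate_law("first_order_transport", c(k_transport = ma$param))
      else rate_law("mass_action_irreversible", c(kf = ma$param))
    }
    reaction(rid, att(rn, "name", rid), reactants, products, rl,
             modifiers = modifiers)
  })
  flags <- list(
    heterodimerization_on = identical(att(model, "her4switch_heterodimerization"), "true"),
    jak_independent_on = identical(att(model, "her4switch_jak_independent"), "true"))
  new_network(compartments, species, reactions, parameters, flags)
}

#' Serialize a network to a human-editable YAML config
#'
#' @param net A `reaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(net, path) {
  cfg <- list(
    compartments = lapply(seq_len(nrow(net$compartments)), function(i)
      as.list(net$compartments[i, ])),
    species = lapply(seq_len(nrow(net$species)), function(i)
      as.list(net$species[i, ])),
    reactions = lapply(net$reactions, function(rxn) list(
      id = rxn$id, name = rxn$name,
      reactants = as.list(rxn$reactants), products = as.list(rxn$products),
      modifiers = as.list(rxn$modifiers),
      rate_law = list(kind = rxn$rate_law$kind,
                      params = as.list(rxn$rate_law$params)))),
    parameters = as.list(net$parameters),
    flags = net$flags)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a network from a YAML config written by [write_network_config()]
#'
#' @param path Config path.
#' @return A `reaction_network`.
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  compartments <- do.call(rbind, lapply(cfg$compartments, as.data.frame))
  species <- do.call(rbind, lapply(cfg$species, as.data.frame))
  reactions <- lapply(cfg$reactions, function(r)
    reaction(r$id, r$name, unlist(r$reactants), unlist(r$products),
             rate_law(r$rate_law$kind, unlist(r$rate_law$params)),
             modifiers = as.character(unlist(r$modifiers))))
  new_network(compartments, species, reactions, unlist(cfg$parameters),
              flags = cfg$flags)
}
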