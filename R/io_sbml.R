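# SBML Level 3 export/import for cross-validation against deposited models.
# The exporter writes mass-action kinetic laws (a product of the rate
# parameter, the enzyme and the reactants), time-triggered events for the
# activation scheme, and a small annotation block carrying the container
# details SBML core does not represent (species roles, binding pairs, the
# activation scheme). The importer refuses kinetic laws that are not plain
# mass-action products, naming the offending reaction.

PICYCLE_NS <- "urn:picycle:annotation"

sbml_math_product <- function(factors) {
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         if (length(factors) == 1) paste0("<ci> ", factors, " </ci>") else
           paste0("<apply><times/>",
                  paste0("<ci> ", factors, " </ci>", collapse = ""),
                  "</apply>"),
         "</math>")
}

#' Write a model as SBML Level 3
#'
#' @param model a `pi_model`.
#' @param path destination path.
#' @export
write_sbml <- function(model, path) {
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  add("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
      "level=\"3\" version=\"2\">")
  id <- model$metadata$cell_type
  if (is.null(id)) id <- "picycle_model"
  add("<model id=\"", gsub("[^A-Za-z0-9_]", "_", id), "\">")
  # container details SBML core cannot carry
  add("<annotation><picycle xmlns=\"", PICYCLE_NS, "\">")
  for (i in seq_len(nrow(model$binding_pairs))) {
    b <- model$binding_pairs[i, ]
    add("<bindingPair lipid=\"", b$lipid, "\" bp=\"", b$bp,
        "\" complex=\"", b$complex, "\" kon=\"", b$kon,
        "\" koff=\"", b$koff, "\" bp_total=\"", num(b$bp_total), "\"/>")
  }
  a <- model$activation
  if (!is.null(a))
    add("<activation t_activation=\"", num(a$t_activation),
        "\" receptor_count=\"", num(a$receptor_count),
        "\" rate_switches=\"", paste(a$rate_switches, collapse = " "),
        "\" termination=\"", a$termination,
        "\" termination_timescale=\"", num(a$termination_timescale), "\"/>")
  for (k in names(model$metadata))
    add("<meta key=\"", k, "\" value=\"", model$metadata[[k]], "\"/>")
  add("</picycle></annotation>")
  add("<listOfCompartments>")
  for (i in seq_len(nrow(model$compartments)))
    add("<compartment id=\"", model$compartments$name[i], "\" size=\"",
        num(model$compartments$volume[i]),
        "\" spatialDimensions=\"3\" constant=\"true\"/>")
  add("</listOfCompartments>")
  add("<listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    add("<species id=\"", s$name, "\" compartment=\"", s$compartment,
        "\" initialAmount=\"", num(s$initial),
        "\" hasOnlySubstanceUnits=\"true\" boundaryCondition=\"false\"",
        " constant=\"false\">",
        "<annotation><picycle xmlns=\"", PICYCLE_NS, "\" role=\"", s$role,
        "\"/></annotation></species>")
  }
  add("</listOfSpecies>")
  add("<listOfParameters>")
  for (i in seq_len(nrow(model$rates))) {
    r <- model$rates[i, ]
    add("<parameter id=\"", r$id, "\" value=\"", num(r$basal),
        "\" constant=\"", if (is.na(r$activated)) "true" else "false",
        "\"/>")
    if (!is.na(r$activated)) {
      add("<parameter id=\"", r$id, "__activated\" value=\"",
          num(r$activated), "\" constant=\"true\"/>")
      add("<parameter id=\"", r$id, "__basal\" value=\"", num(r$basal),
          "\" constant=\"true\"/>")
    }
  }
  add("</listOfParameters>")
  add("<listOfReactions>")
  for (r in model$reactions) {
    add("<reaction id=\"", r$id, "\" reversible=\"false\">")
    add("<listOfReactants>")
    for (s in names(r$reactants))
      add("<speciesReference species=\"", s, "\" stoichiometry=\"",
          num(r$reactants[[s]]), "\" constant=\"true\"/>")
    add("</listOfReactants>")
    add("<listOfProducts>")
    for (s in names(r$products))
      add("<speciesReference species=\"", s, "\" stoichiometry=\"",
          num(r$products[[s]]), "\" constant=\"true\"/>")
    add("</listOfProducts>")
    if (!is.na(r$enzyme))
      add("<listOfModifiers><modifierSpeciesReference species=\"", r$enzyme,
          "\"/></listOfModifiers>")
    factors <- c(r$rate, if (!is.na(r$enzyme)) r$enzyme,
                 rep(names(r$reactants), times = r$reactants))
    add("<kineticLaw>", sbml_math_product(factors), "</kineticLaw>")
    add("</reaction>")
  }
  add("</listOfReactions>")
  if (!is.null(a)) {
    add("<listOfEvents>")
    trig <- function(t) paste0(
      "<trigger initialValue=\"true\" persistent=\"true\">",
      "<math xmlns=\"http://www.w3.org/1998/Math/MathML\"><apply><geq/>",
      "<csymbol cd=\"\" definitionURL=",
      "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>",
      "<cn> ", num(t), " </cn></apply></math></trigger>")
    ea <- function(var, mathml)
      paste0("<eventAssignment variable=\"", var, "\">", mathml,
             "</eventAssignment>")
    add("<event id=\"activation\" useValuesFromTriggerTime=\"true\">",
        trig(a$t_activation), "<listOfEventAssignments>")
    add(ea("GPCR_a", paste0(
      "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
      "<apply><plus/><ci> GPCR_a </ci><ci> GPCR </ci></apply></math>")))
    add(ea("GPCR", paste0("<math xmlns=\"http://www.w3.org/1998/",
                          "Math/MathML\"><cn> 0 </cn></math>")))
    for (k in a$rate_switches)
      add(ea(k, sbml_math_product(paste0(k, "__activated"))))
    add("</listOfEventAssignments></event>")
    add("<event id=\"termination\" useValuesFromTriggerTime=\"true\">",
        trig(a$t_activation + a$termination_timescale),
        "<listOfEventAssignments>")
    for (k in a$rate_switches)
      add(ea(k, sbml_math_product(paste0(k, "__basal"))))
    add("</listOfEventAssignments></event>")
    add("</listOfEvents>")
  }
  add("</model>")
  add("</sbml>")
  writeLines(L, path)
  invisible(path)
}

xattr <- function(node, name) xml2::xml_attr(node, name)

#' Read an SBML Level 3 model
#'
#' Supports mass-action kinetic laws only (a product of one rate parameter,
#' optional enzyme modifier and the reactant species); any other law raises
#' an error naming the reaction. Time-triggered activation events written by
#' [write_sbml()] are reconstructed from the accompanying annotation.
#'
#' @param path an SBML file.
#' @return a `pi_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  q <- function(xp, node = doc)
    xml2::xml_find_all(node, xp)
  comp_nodes <- q(".//*[local-name()='compartment']")
  comp <- data.frame(name = xattr(comp_nodes, "id"),
                     volume = as.numeric(xattr(comp_nodes, "size")),
                     stringsAsFactors = FALSE)
  sp_nodes <- q(".//*[local-name()='species']")
  roles <- vapply(sp_nodes, function(n) {
    ann <- q(".//*[local-name()='picycle']", n)
    if (length(ann)) xml2::xml_attr(ann[[1]], "role") else "enzyme"
  }, "")
  species <- data.frame(name = xattr(sp_nodes, "id"),
                        compartment = xattr(sp_nodes, "compartment"),
                        initial = as.numeric(xattr(sp_nodes, "initialAmount")),
                        role = roles, stringsAsFactors = FALSE)
  par_nodes <- q(".//*[local-name()='listOfParameters']/*")
  pid <- xattr(par_nodes, "id")
  pval <- as.numeric(xattr(par_nodes, "value"))
  main <- !grepl("__(activated|basal)$", pid)
  act_val <- stats::setNames(rep(NA_real_, sum(main)), pid[main])
  has_act <- paste0(pid[main], "__activated") %in% pid
  act_val[has_act] <- pval[match(paste0(pid[main][has_act], "__activated"),
                                 pid)]
  rates <- data.frame(id = pid[main], basal = pval[main],
                      activated = unname(act_val), stringsAsFactors = FALSE)
  rxn_nodes <- q(".//*[local-name()='reaction']")
  reactions <- lapply(rxn_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    getrefs <- function(kind) {
      refs <- q(paste0(".//*[local-name()='", kind,
                       "']/*[local-name()='speciesReference']"), n)
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(refs, "species"))
    }
    reactants <- getrefs("listOfReactants")
    products <- getrefs("listOfProducts")
    mods <- q(".//*[local-name()='modifierSpeciesReference']", n)
    enzyme <- if (length(mods)) xml2::xml_attr(mods[[1]], "species") else
      NA_character_
    math <- q(".//*[local-name()='kineticLaw']//*[local-name()='math']", n)
    if (!length(math)) stop("reaction ", id, " lacks a kinetic law")
    top <- xml2::xml_children(math[[1]])
    unsupported <- function()
      stop("unsupported (non-mass-action) kinetic law in reaction ", id,
           call. = FALSE)
    cis <- if (length(top) == 1 &&
               xml2::xml_name(top[[1]]) == "ci") {
      trimws(xml2::xml_text(top[[1]]))
    } else {
      if (length(top) != 1 || xml2::xml_name(top[[1]]) != "apply")
        unsupported()
      kids <- xml2::xml_children(top[[1]])
      if (xml2::xml_name(kids[[1]]) != "times") unsupported()
      rest <- kids[-1]
      if (!all(xml2::xml_name(rest) == "ci")) unsupported()
      trimws(xml2::xml_text(rest))
    }
    rate <- intersect(cis, pid[main])
    if (length(rate) != 1) unsupported()
    expected <- sort(c(rate, if (!is.na(enzyme)) enzyme,
                       rep(names(reactants), times = reactants)))
    if (!identical(sort(cis), expected)) unsupported()
    list(id = id, reactants = reactants, products = products,
         rate = rate, enzyme = enzyme)
  })
  bp_nodes <- q(".//*[local-name()='bindingPair']")
  binding <- if (!length(bp_nodes)) empty_binding_pairs() else
    data.frame(lipid = xattr(bp_nodes, "lipid"), bp = xattr(bp_nodes, "bp"),
               complex = xattr(bp_nodes, "complex"),
               kon = xattr(bp_nodes, "kon"), koff = xattr(bp_nodes, "koff"),
               bp_total = as.numeric(xattr(bp_nodes, "bp_total")),
               stringsAsFactors = FALSE)
  act_nodes <- q(".//*[local-name()='activation']")
  act <- if (!length(act_nodes)) NULL else {
    n <- act_nodes[[1]]
    activation_scheme(
      t_activation = as.numeric(xml2::xml_attr(n, "t_activation")),
      receptor_count = as.numeric(xml2::xml_attr(n, "receptor_count")),
      rate_switches = strsplit(xml2::xml_attr(n, "rate_switches"), " ")[[1]],
      termination = xml2::xml_attr(n, "termination"),
      termination_timescale =
        as.numeric(xml2::xml_attr(n, "termination_timescale")))
  }
  meta_nodes <- q(".//*[local-name()='meta']")
  metadata <- stats::setNames(as.list(xattr(meta_nodes, "value")),
                              xattr(meta_nodes, "key"))
  pi_model(compartments = comp, species = species, reactions = reactions,
           rates = rates, binding_pairs = binding, activation = act,
           metadata = metadata)
}
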