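#' picycle: kinetic modelling of the phosphoinositide cycle
#'
#' Tools to build, simulate, calibrate and interrogate a mass-action model of
#' the PI cycle downstream of Gq-coupled receptors, expressed in molecule
#' copy numbers per cell across three compartments (plasma membrane, cytosol,
#' organelles).
#'
#' @keywords internal
"_PACKAGE"

#' The twelve key proteins of the PI-cycle model
#'
#' Lumped protein pools whose copy numbers parameterise the model: the Gq
#' alpha subunit, small G proteins (smG), PLC-beta, the combined IP3-modifying
#' enzymes (IP3 3-kinase B plus INPP5, lumped as `IP3ME`), DAG kinase,
#' lipid phosphate phosphatase, PI synthase (CDIPT), OCRL1, PI 4-kinase,
#' PIP 5-kinase, SAC1 and cPLA2.
#'
#' @format Character vector of length 12, in the fixed order used by
#'   [mix_and_match()] bitmask enumeration.
#' @export
pi_key_proteins <- c("Gq", "smG", "PLCb", "IP3ME", "DGK", "LPP",
                     "CDIPT", "OCRL1", "PI4K", "PIP5K", "SAC1", "cPLA2")

#' Observables monitored by the model
#'
#' The phospholipid and inositol-phosphate outputs surveyed in every
#' experiment: membrane PI, PI4P, PI(4,5)P2, IP3, DAG, PA and free inositol.
#' Lipid observables are totals (free plus binding-protein-bound).
#'
#' @export
pi_observables <- c("PI", "PI4P", "PI45P2", "IP3", "DAG", "PA", "Ins")

#' Lipid pools required to build the core model
#' @keywords internal
pi_lipid_inits_required <- c("PI", "PI_org", "PI4P", "PI45P2", "DAG", "PA",
                             "IP3", "Ins")

species_roles <- c("lipid", "inositol_phosphate", "enzyme", "receptor",
                   "g_protein", "binding_protein", "complex", "intermediate")

#' Construct a model definition
#'
#' Low-level constructor for the declarative model container. Most users
#' build models through [build_core_model()] or [pi_platelet_model()].
#'
#' @param compartments data.frame with columns `name`, `volume` (femtolitres).
#'   Exactly three compartments (`plasma_membrane`, `cytosol`, `organelles`).
#' @param species data.frame with columns `name`, `compartment`, `initial`,
#'   `role`.
#' @param reactions list of reactions; each a list with elements `id`,
#'   `reactants` (named numeric, stoichiometries), `products` (named numeric),
#'   `rate` (rate-constant id) and `enzyme` (species name or `NA`). An enzyme
#'   enters the rate multiplicatively and is conserved by the reaction.
#' @param rates data.frame with columns `id`, `basal`, `activated`
#'   (`NA` means the constant is unchanged by activation, as for SAC1's `k17`).
#' @param binding_pairs data.frame describing reversible lipid/binding-protein
#'   pairs: columns `lipid`, `bp`, `complex`, `kon`, `koff` (rate ids),
#'   `bp_total`.
#' @param activation an activation scheme from [activation_scheme()], or NULL.
#' @param metadata named list (cell type label, provenance notes).
#' @return An object of class `pi_model`.
#' @export
pi_model <- function(compartments, species, reactions, rates,
                     binding_pairs = empty_binding_pairs(),
                     activation = NULL, metadata = list()) {
  m <- structure(list(compartments = compartments, species = species,
                      reactions = reactions, rates = rates,
                      binding_pairs = binding_pairs, activation = activation,
                      metadata = metadata),
                 class = "pi_model")
  validate_model(m)
  m
}

empty_binding_pairs <- function() {
  data.frame(lipid = character(), bp = character(), complex = character(),
             kon = character(), koff = character(), bp_total = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate referential integrity of a model definition
#'
#' Checks the invariants of the container: exactly three positive-volume
#' compartments, non-negative initial amounts, known roles, every reaction
#' referencing existing species and rate constants, strictly positive rate
#' values, and binding pairs that reference existing species and rates.
#'
#' @param m a `pi_model`.
#' @return `m`, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "pi_model"))
  comp <- m$compartments
  if (nrow(comp) != 3L ||
      !setequal(comp$name, c("plasma_membrane", "cytosol", "organelles")))
    stop("model must have exactly the three compartments ",
         "plasma_membrane, cytosol, organelles")
  if (any(comp$volume <= 0)) stop("compartment volumes must be positive")
  sp <- m$species
  if (anyDuplicated(sp$name)) stop("duplicate species names")
  if (any(sp$initial < 0)) stop("negative initial amounts: ",
                                paste(sp$name[sp$initial < 0], collapse = ", "))
  if (!all(sp$role %in% species_roles)) stop("unknown species role")
  if (!all(sp$compartment %in% comp$name)) stop("species in unknown compartment")
  if (anyDuplicated(m$rates$id)) stop("duplicate rate ids")
  if (any(m$rates$basal <= 0)) stop("rate constants must be strictly positive")
  if (any(!is.na(m$rates$activated) & m$rates$activated <= 0))
    stop("activated rate constants must be strictly positive")
  if ("k17" %in% m$rates$id && !is.na(m$rates$activated[m$rates$id == "k17"]))
    stop("k17 (SAC1) must remain unchanged after activation")
  for (r in m$reactions) {
    refs <- c(names(r$reactants), names(r$products),
              if (!is.na(r$enzyme)) r$enzyme)
    bad <- setdiff(refs, sp$name)
    if (length(bad)) stop("reaction ", r$id, " references unknown species: ",
                          paste(bad, collapse = ", "))
    if (!r$rate %in% m$rates$id)
      stop("reaction ", r$id, " references unknown rate ", r$rate)
  }
  bp <- m$binding_pairs
  if (nrow(bp)) {
    bad <- setdiff(c(bp$lipid, bp$bp, bp$complex), sp$name)
    if (length(bad)) stop("binding pair references unknown species: ",
                          paste(bad, collapse = ", "))
    if (!all(c(bp$kon, bp$koff) %in% m$rates$id))
      stop("binding pair references unknown rate constant")
    if (any(bp$bp_total < 0)) stop("bp_total must be non-negative")
  }
  if (!is.null(m$activation)) validate_activation(m$activation, m)
  invisible(m)
}

#' Define a receptor activation scheme
#'
#' A time-triggered activation event: at `t_activation`, `receptor_count`
#' quiescent Gq-coupled receptors are converted to their active form (which
#' then drives Gq and PLC-beta activation through the model's reaction chain)
#' and the rate constants named in `rate_switches` jump from basal to
#' activated values. Signalling terminates on `termination_timescale`:
#' with `termination = "inactivation"` active receptors additionally decay
#' first-order into an inactive species at rate `1/termination_timescale`,
#' and in both modes the switched constants are reset to basal (and active
#' receptors cleared under `"reset"`) at
#' `t_activation + termination_timescale`.
#'
#' SAC1's constant `k17` is refused in `rate_switches`: its activity is not
#' modified by activation.
#'
#' @param t_activation seconds, > 0.
#' @param receptor_count number of Gq-coupled receptors activated (RGq).
#' @param rate_switches character vector of rate-constant ids switched to
#'   their activated values.
#' @param termination `"inactivation"` or `"reset"`.
#' @param termination_timescale seconds.
#' @return a list of class `pi_activation`.
#' @export
activation_scheme <- function(t_activation = 100, receptor_count = 5000,
                              rate_switches = c("k14", "k15", "k16"),
                              termination = c("inactivation", "reset"),
                              termination_timescale = 45) {
  termination <- match.arg(termination)
  if (t_activation <= 0) stop("t_activation must be > 0")
  if (receptor_count < 0) stop("receptor_count must be >= 0")
  if ("k17" %in% rate_switches)
    stop("rate_switches must not include k17: SAC1 is unchanged by activation")
  if (termination_timescale <= 0) stop("termination_timescale must be > 0")
  structure(list(t_activation = t_activation,
                 receptor_count = receptor_count,
                 rate_switches = rate_switches,
                 termination = termination,
                 termination_timescale = termination_timescale),
            class = "pi_activation")
}

validate_activation <- function(a, m) {
  stopifnot(inherits(a, "pi_activation"))
  if ("k17" %in% a$rate_switches) stop("activation must not switch k17")
  bad <- setdiff(a$rate_switches, m$rates$id)
  if (length(bad)) stop("rate_switches name unknown constants: ",
                        paste(bad, collapse = ", "))
  sw <- m$rates$id %in% a$rate_switches
  if (any(is.na(m$rates$activated[sw])))
    stop("switched constants lack activated values: ",
         paste(m$rates$id[sw][is.na(m$rates$activated[sw])], collapse = ", "))
  invisible(a)
}

#' Attach an activation scheme to a model
#'
#' Returns a copy of the model whose event list converts `receptor_count`
#' receptors to the active form at `t_activation` and switches the named rate
#' constants to their activated (primed) values, terminating per the scheme.
#' The quiescent receptor pool (`GPCR`) is set to the scheme's receptor count.
#'
#' @param model a `pi_model`.
#' @param scheme from [activation_scheme()].
#' @return the activated `pi_model`.
#' @export
apply_activation <- function(model, scheme) {
  validate_activation(scheme, model)
  model$activation <- scheme
  i <- match("GPCR", model$species$name)
  if (!is.na(i)) model$species$initial[i] <- scheme$receptor_count
  j <- match("GPCR_a", model$species$name)
  if (!is.na(j)) model$species$initial[j] <- 0
  validate_model(model)
}

#' Mass-action flux of a single reaction
#'
#' Evaluates `k * prod(reactant amounts ^ stoichiometry) * enzyme amount`
#' at a given state. Bimolecular and higher-order constants are stored
#' already folded with their compartment volume, so no explicit volume
#' factor appears here; state and flux are in molecules and molecules/second.
#'
#' @param reaction one element of a model's `reactions` list.
#' @param state named numeric vector of species amounts (molecules); must be
#'   non-negative.
#' @param k the value of the reaction's rate constant.
#' @return flux in molecules/second (non-negative).
#' @export
mass_action_rate <- function(reaction, state, k) {
  amounts <- state[names(reaction$reactants)]
  if (anyNA(amounts)) stop("state is missing reactant species")
  if (any(amounts < 0)) stop("negative species amount in state")
  f <- k * prod(amounts ^ reaction$reactants)
  if (!is.na(reaction$enzyme)) {
    e <- state[[reaction$enzyme]]
    if (is.null(e) || is.na(e)) stop("state is missing enzyme species")
    if (e < 0) stop("negative enzyme amount in state")
    f <- f * e
  }
  unname(f)
}

#' Equilibrium partition of a reversible lipid/binding-protein pair
#'
#' For L + B <-> C with totals `l_total`, `b_total` and constants `kon`,
#' `koff`, returns the complex amount at equilibrium, the physical root of
#' `kon (L-C)(B-C) = koff C`.
#'
#' @keywords internal
binding_equilibrium <- function(l_total, b_total, kon, koff) {
  if (l_total <= 0 || b_total <= 0) return(0)
  kd <- koff / kon
  b <- l_total + b_total + kd
  c <- l_total * b_total
  # smaller quadratic root, numerically stable form
  2 * c / (b + sqrt(b * b - 4 * c))
}
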