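# Shared fixtures, all built in code.

.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

std_compartments <- function()
  data.frame(name = c("plasma_membrane", "cytosol", "organelles"),
             volume = c(1, 1, 0.5), stringsAsFactors = FALSE)

# minimal model builder for toys
toy_model <- function(species, reactions, rates, binding = NULL,
                      activation = NULL) {
  pi_model(compartments = std_compartments(), species = species,
           reactions = reactions, rates = rates,
           binding_pairs = if (is.null(binding))
             picycle:::empty_binding_pairs() else binding,
           activation = activation)
}

# A -> B first-order decay, k = 0.1/s
decay_model <- function(k = 0.1, a0 = 1000) {
  toy_model(
    species = data.frame(name = c("A", "B"), compartment = "cytosol",
                         initial = c(a0, 0), role = "intermediate",
                         stringsAsFactors = FALSE),
    reactions = list(list(id = "decay", reactants = c(A = 1),
                          products = c(B = 1), rate = "k",
                          enzyme = NA_character_)),
    rates = data.frame(id = "k", basal = k, activated = NA_real_,
                       stringsAsFactors = FALSE))
}

# isolated reversible binding pair L + BP <-> C
binding_model <- function(l0 = 1000, b0 = 600, kon = 1e-3, koff = 0.05) {
  toy_model(
    species = data.frame(
      name = c("L", "BP", "C"), compartment = "plasma_membrane",
      initial = c(l0, b0, 0),
      role = c("lipid", "binding_protein", "complex"),
      stringsAsFactors = FALSE),
    reactions = list(
      list(id = "bind", reactants = c(L = 1, BP = 1), products = c(C = 1),
           rate = "kon", enzyme = NA_character_),
      list(id = "unbind", reactants = c(C = 1), products = c(L = 1, BP = 1),
           rate = "koff", enzyme = NA_character_)),
    rates = data.frame(id = c("kon", "koff"), basal = c(kon, koff),
                       activated = NA_real_, stringsAsFactors = FALSE),
    binding = data.frame(lipid = "L", bp = "BP", complex = "C",
                         kon = "kon", koff = "koff", bp_total = b0,
                         stringsAsFactors = FALSE))
}

platelet <- function() cached("platelet", pi_platelet_model(activated = FALSE))
platelet_act <- function() cached("platelet_act", pi_platelet_model())

# variant with the cPLA2 deacylation loop switched off: the remaining
# network conserves the inositol moiety exactly
closed_variant <- function(m = platelet()) {
  m$rates$basal[m$rates$id %in% c("k_cpla2", "k_reacyl")] <- 1e-300
  m
}

moiety_species <- c("PI", "PI_org", "PI4P", "PI45P2", "IP3", "IPx", "Ins",
                    "C_PI4P", "C_PI45P2")

# enzymes that are strictly constant, and conserved activation pairs
static_enzymes <- c("PI4K", "PIP5K", "OCRL1", "SAC1", "DGK", "LPP",
                    "CDIPT", "IP3ME", "cPLA2", "smG")

conserved_groups <- list(c("PLCb", "PLCb_a"), c("Gq", "Gq_a"),
                         c("GPCR", "GPCR_a", "GPCR_i"))

hela_reference <- function() cached("hela_reference", {
  nucleated_reference(platelet())
})
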