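# Canonical PI-cycle network for the human platelet and its builder.
#
# Reaction set (enzyme in parentheses; k14-k17 follow the field's labels for
# the PI4P/PI45P2 axis):
#   pi4k        PI      -> PI4P      (PI4K,  k16 / k16')
#   pip5k       PI4P    -> PI45P2    (PIP5K, k14 / k14')
#   ocrl1       PI45P2  -> PI4P      (OCRL1, k15 / k15')
#   sac1        PI4P    -> PI        (SAC1,  k17, unchanged by activation)
#   plcb_basal  PI45P2  -> IP3 + DAG (PLCb, constitutive turnover)
#   plcb_active PI45P2  -> IP3 + DAG (PLCb_a)
#   ip3_removal IP3     -> IPx       (IP3ME; fast lumped IP3Kb/INPP5 step)
#   ipx_to_ins  IPx     -> Ins       (slow lumped step)
#   dgk         DAG     -> PA        (DGK)
#   lpp         PA      -> DAG      (LPP)
#   pi_synthesis PA + Ins -> PI_org  (CDIPT; lumped CDS/CDIPT resynthesis)
#   pi_transfer PI_org  -> PI        (transfer; NOT modified by activation)
#   cpla2       PI      -> LPI       (cPLA2; slow deacylation)
#   reacylation LPI     -> PI        (slow return, closes the Lands-type loop)
#   gq_activation        Gq -> Gq_a           (GPCR_a)
#   gq_inactivation      Gq_a -> Gq
#   plcb_activation      Gq_a + PLCb -> Gq_a + PLCb_a  (smG)
#   plcb_inactivation    PLCb_a -> PLCb
#   receptor_inactivation GPCR_a -> GPCR_i
#   bind_*/unbind_*      four reversible lipid/binding-protein pairs
#                        (PI45P2, PI4P, PA, DAG)

platelet_reactions <- function() {
  rxn <- function(id, reactants, products, rate, enzyme = NA_character_)
    list(id = id, reactants = reactants, products = products,
         rate = rate, enzyme = enzyme)
  list(
    rxn("pi4k", c(PI = 1), c(PI4P = 1), "k16", "PI4K"),
    rxn("pip5k", c(PI4P = 1), c(PI45P2 = 1), "k14", "PIP5K"),
    rxn("ocrl1", c(PI45P2 = 1), c(PI4P = 1), "k15", "OCRL1"),
    rxn("sac1", c(PI4P = 1), c(PI = 1), "k17", "SAC1"),
    rxn("plcb_basal", c(PI45P2 = 1), c(IP3 = 1, DAG = 1), "k_plcb_basal",
        "PLCb"),
    rxn("plcb_active", c(PI45P2 = 1), c(IP3 = 1, DAG = 1), "k_plcb_act",
        "PLCb_a"),
    rxn("ip3_removal", c(IP3 = 1), c(IPx = 1), "k_ip3_rm", "IP3ME"),
    rxn("ipx_to_ins", c(IPx = 1), c(Ins = 1), "k_ipx_ins"),
    rxn("dgk", c(DAG = 1), c(PA = 1), "k_dgk", "DGK"),
    rxn("lpp", c(PA = 1), c(DAG = 1), "k_lpp", "LPP"),
    rxn("pi_synthesis", c(PA = 1, Ins = 1), c(PI_org = 1), "k_cdipt", "CDIPT"),
    rxn("pi_transfer", c(PI_org = 1), c(PI = 1), "k_pitp"),
    rxn("cpla2", c(PI = 1), c(LPI = 1), "k_cpla2", "cPLA2"),
    rxn("reacylation", c(LPI = 1), c(PI = 1), "k_reacyl"),
    rxn("gq_activation", c(Gq = 1), c(Gq_a = 1), "k_gq_act", "GPCR_a"),
    rxn("gq_inactivation", c(Gq_a = 1), c(Gq = 1), "k_gq_inact"),
    rxn("plcb_activation", c(Gq_a = 1, PLCb = 1), c(Gq_a = 1, PLCb_a = 1),
        "k_plcb_on", "smG"),
    rxn("plcb_inactivation", c(PLCb_a = 1), c(PLCb = 1), "k_plcb_off"),
    rxn("receptor_inactivation", c(GPCR_a = 1), c(GPCR_i = 1), "k_r_inact"),
    rxn("bind_PI45P2", c(PI45P2 = 1, BP_PI45P2 = 1), c(C_PI45P2 = 1),
        "kon_PI45P2"),
    rxn("unbind_PI45P2", c(C_PI45P2 = 1), c(PI45P2 = 1, BP_PI45P2 = 1),
        "koff_PI45P2"),
    rxn("bind_PI4P", c(PI4P = 1, BP_PI4P = 1), c(C_PI4P = 1), "kon_PI4P"),
    rxn("unbind_PI4P", c(C_PI4P = 1), c(PI4P = 1, BP_PI4P = 1), "koff_PI4P"),
    rxn("bind_PA", c(PA = 1, BP_PA = 1), c(C_PA = 1), "kon_PA"),
    rxn("unbind_PA", c(C_PA = 1), c(PA = 1, BP_PA = 1), "koff_PA"),
    rxn("bind_DAG", c(DAG = 1, BP_DAG = 1), c(C_DAG = 1), "kon_DAG"),
    rxn("unbind_DAG", c(C_DAG = 1), c(DAG = 1, BP_DAG = 1), "koff_DAG")
  )
}

# Calibrated rate constants for the human platelet (molecules/cell units,
# bimolecular and higher-order constants folded with compartment volume).
# Derived in-package by staged scan calibration against the homeostatic pool
# sizes and post-activation dynamics; see the methods vignette.
platelet_rate_table <- function() {
  r <- function(id, basal, activated = NA_real_)
    data.frame(id = id, basal = basal, activated = activated,
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    r("k16", 2.0e-8, 9.0e-6),       # PI4K, ~60x on activation
    r("k14", 2.1e-6, 5.0e-5),        # PIP5K
    r("k15", 5.0e-6, 5.0e-5),       # OCRL1, regulated in concert
    r("k17", 3.1e-7),               # SAC1, unchanged
    r("k_plcb_basal", 1.333e-8),
    r("k_plcb_act", 5.0e-5),
    r("k_ip3_rm", 7.5e-6),
    r("k_ipx_ins", 2.0e-3),
    r("k_dgk", 7.0e-7),
    r("k_lpp", 4.0e-7),
    r("k_cdipt", 1.2e-14),
    r("k_pitp", 2.0e-5),
    r("k_cpla2", 3.33e-10),
    r("k_reacyl", 2.0e-4),
    r("k_gq_act", 4.5e-6),
    r("k_gq_inact", 0.05),
    r("k_plcb_on", 7.0e-11),
    r("k_plcb_off", 0.05),
    r("k_r_inact", 3.3e-2),
    r("kon_PI45P2", 2.0e-6), r("koff_PI45P2", 0.05),
    r("kon_PI4P", 2.0e-6), r("koff_PI4P", 0.05),
    r("kon_PA", 2.0e-7), r("koff_PA", 0.05),
    r("kon_DAG", 9.0e-7), r("koff_DAG", 0.05)
  ))
}

platelet_binding_table <- function() {
  data.frame(
    lipid = c("PI45P2", "PI4P", "PA", "DAG"),
    bp = c("BP_PI45P2", "BP_PI4P", "BP_PA", "BP_DAG"),
    complex = c("C_PI45P2", "C_PI4P", "C_PA", "C_DAG"),
    kon = c("kon_PI45P2", "kon_PI4P", "kon_PA", "kon_DAG"),
    koff = c("koff_PI45P2", "koff_PI4P", "koff_PA", "koff_DAG"),
    bp_total = c(1.3e6, 1.2e6, 1.5e6, 3.0e5),
    stringsAsFactors = FALSE)
}

#' Default human platelet lipid pools (molecules/cell)
#'
#' Total pools (free plus binding-protein-bound for buffered lipids):
#' plasma-membrane PI around 6e6, PI4P and PI45P2 around 1.5e6 each, an
#' organelle PI reserve, and modest basal DAG/PA with a large cytosolic
#' inositol pool.
#'
#' @export
platelet_lipid_inits <- function() {
  c(PI = 6e6, PI_org = 2e6, PI4P = 1.5e6, PI45P2 = 1.5e6,
    DAG = 1.0e5, PA = 3.0e5, IP3 = 0, Ins = 5e6)
}

#' Build the core PI-cycle model
#'
#' Assembles the canonical reaction network (PI/PI4P/PI45P2 axis with
#' differentially regulated PI4K/PIP5K/OCRL1 and an activation-insensitive
#' SAC1, PLC-beta signalling with the two-step IP3 -> IPx -> Ins removal,
#' DAG/PA interconversion and CDIPT-mediated resynthesis, organelle-to-
#' membrane PI transfer, a slow cPLA2 deacylation loop, the receptor ->
#' Gq -> PLC-beta activation chain, and four lipid/binding-protein pairs)
#' from a proteome, lipid pools and compartment volumes.
#'
#' Buffered lipid pools are interpreted as totals and partitioned between
#' free lipid and complex at binding equilibrium, so initial pools match the
#' inputs exactly.
#'
#' @param proteome named numeric vector or [proteome_table()] covering the 12
#'   key proteins (see [pi_key_proteins]); missing entries raise an error
#'   naming every absentee.
#' @param lipid_inits named vector covering
#'   `PI, PI_org, PI4P, PI45P2, DAG, PA, IP3, Ins` (molecules/cell, totals).
#' @param volumes named vector `c(plasma_membrane=, cytosol=, organelles=)`
#'   in femtolitres.
#' @param rates rate-constant table; defaults to the calibrated platelet set.
#' @param binding binding-pair table (ids and `bp_total` per pair).
#' @param extra_inits named vector for species outside the two groups
#'   (e.g. `IPx`, `LPI`); defaults to small calibrated pools.
#' @param receptor_count quiescent Gq-coupled receptor pool (RGq).
#' @param metadata named list stored on the model.
#' @return a `pi_model`.
#' @export
build_core_model <- function(proteome, lipid_inits,
                             volumes = c(plasma_membrane = 1, cytosol = 1,
                                         organelles = 0.5),
                             rates = platelet_rate_table(),
                             binding = platelet_binding_table(),
                             extra_inits = c(IPx = 2e4, LPI = 1e5),
                             receptor_count = 5000,
                             metadata = list(cell_type = "human_platelet")) {
  if (is.data.frame(proteome)) {
    pv <- stats::setNames(proteome$copies_per_cell, proteome$protein)
  } else pv <- proteome
  missing_p <- setdiff(pi_key_proteins, names(pv)[!is.na(pv)])
  if (length(missing_p))
    stop("proteome is missing required proteins: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  missing_l <- setdiff(pi_lipid_inits_required, names(lipid_inits))
  if (length(missing_l))
    stop("lipid_inits is missing pools: ",
         paste(missing_l, collapse = ", "), call. = FALSE)

  comp <- data.frame(name = c("plasma_membrane", "cytosol", "organelles"),
                     volume = unname(volumes[c("plasma_membrane", "cytosol",
                                               "organelles")]),
                     stringsAsFactors = FALSE)

  kval <- stats::setNames(rates$basal, rates$id)
  sp <- list()
  add <- function(name, compartment, initial, role)
    sp[[length(sp) + 1L]] <<- data.frame(name = name, compartment = compartment,
                                         initial = initial, role = role,
                                         stringsAsFactors = FALSE)
  # buffered lipids: partition totals at binding equilibrium
  free <- c(lipid_inits[c("PI", "PI4P", "PI45P2", "DAG", "PA")])
  bound <- stats::setNames(numeric(nrow(binding)), binding$lipid)
  for (i in seq_len(nrow(binding))) {
    l <- binding$lipid[i]
    cplx <- binding_equilibrium(lipid_inits[[l]], binding$bp_total[i],
                                kval[[binding$kon[i]]], kval[[binding$koff[i]]])
    bound[l] <- cplx
    free[l] <- lipid_inits[[l]] - cplx
  }
  add("PI", "plasma_membrane", free[["PI"]], "lipid")
  add("PI4P", "plasma_membrane", free[["PI4P"]], "lipid")
  add("PI45P2", "plasma_membrane", free[["PI45P2"]], "lipid")
  add("DAG", "plasma_membrane", free[["DAG"]], "lipid")
  add("PA", "plasma_membrane", free[["PA"]], "lipid")
  add("LPI", "plasma_membrane",
      if ("LPI" %in% names(extra_inits)) extra_inits[["LPI"]] else 0, "lipid")
  add("PI_org", "organelles", lipid_inits[["PI_org"]], "lipid")
  add("IP3", "cytosol", lipid_inits[["IP3"]], "inositol_phosphate")
  add("IPx", "cytosol",
      if ("IPx" %in% names(extra_inits)) extra_inits[["IPx"]] else 0,
      "intermediate")
  add("Ins", "cytosol", lipid_inits[["Ins"]], "inositol_phosphate")
  # proteins
  add("PI4K", "plasma_membrane", pv[["PI4K"]], "enzyme")
  add("PIP5K", "plasma_membrane", pv[["PIP5K"]], "enzyme")
  add("OCRL1", "plasma_membrane", pv[["OCRL1"]], "enzyme")
  add("SAC1", "plasma_membrane", pv[["SAC1"]], "enzyme")
  add("cPLA2", "plasma_membrane", pv[["cPLA2"]], "enzyme")
  add("DGK", "plasma_membrane", pv[["DGK"]], "enzyme")
  add("LPP", "plasma_membrane", pv[["LPP"]], "enzyme")
  add("CDIPT", "organelles", pv[["CDIPT"]], "enzyme")
  add("IP3ME", "cytosol", pv[["IP3ME"]], "enzyme")
  add("PLCb", "cytosol", pv[["PLCb"]], "enzyme")
  add("PLCb_a", "cytosol", 0, "enzyme")
  add("Gq", "cytosol", pv[["Gq"]], "g_protein")
  add("Gq_a", "cytosol", 0, "g_protein")
  add("smG", "cytosol", pv[["smG"]], "g_protein")
  add("GPCR", "plasma_membrane", receptor_count, "receptor")
  add("GPCR_a", "plasma_membrane", 0, "receptor")
  add("GPCR_i", "plasma_membrane", 0, "receptor")
  # binding proteins and complexes
  for (i in seq_len(nrow(binding))) {
    add(binding$bp[i], "plasma_membrane",
        binding$bp_total[i] - bound[[binding$lipid[i]]], "binding_protein")
    add(binding$complex[i], "plasma_membrane", bound[[binding$lipid[i]]],
        "complex")
  }
  species <- do.call(rbind, sp)

  pi_model(compartments = comp, species = species,
           reactions = platelet_reactions(), rates = rates,
           binding_pairs = binding, activation = NULL, metadata = metadata)
}

#' Synthetic stand-in human platelet proteome (copies/cell)
#'
#' Copy numbers of the 12 lumped key proteins at magnitudes typical of
#' quantitative platelet proteomics. These are synthetic stand-in values,
#' not transcriptions of any published table.
#'
#' @export
platelet_proteome <- function() {
  c(Gq = 6000, smG = 50000, PLCb = 10000, IP3ME = 20000, DGK = 10000,
    LPP = 5000, CDIPT = 8000, OCRL1 = 2000, PI4K = 3000, PIP5K = 5000,
    SAC1 = 4000, cPLA2 = 10000)
}

#' The calibrated human platelet PI-cycle model
#'
#' Loads the shipped calibrated model (initial amounts at the pre-activation
#' steady state) from the package's model file.
#'
#' @param activated if TRUE (default), the standard thrombin activation
#'   scheme (RGq = 5000 receptors activated at 100 s) is attached.
#' @return a `pi_model`.
#' @export
pi_platelet_model <- function(activated = TRUE) {
  path <- system.file("extdata", "platelet_core_model.yaml",
                      package = "picycle", mustWork = TRUE)
  m <- read_model_file(path)
  if (activated && is.null(m$activation))
    m <- apply_activation(m, activation_scheme())
  m
}
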