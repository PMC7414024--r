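# Rescaling the calibrated platelet model to other cell types: reaction
# structure and per-concentration kinetics are frozen; compartment volumes,
# protein copy numbers and lipid/binding-protein pools are swapped.

#' Cell geometries
#'
#' Reaction-compartment volumes in femtolitres. The human platelet uses
#' roughly 1 fl each for the plasma membrane (including the open canalicular
#' system) and reaction cytosol; the mouse platelet about a quarter of each;
#' a generic nucleated cell about 17 fl each, derived from a 2000 fl overall
#' cell volume. Organelle reaction volumes are kept proportional.
#'
#' @param membrane,cytosol,organelles volumes in fl (> 0).
#' @return named numeric vector of class `pi_geometry`.
#' @export
cell_geometry <- function(membrane, cytosol, organelles) {
  v <- c(plasma_membrane = membrane, cytosol = cytosol,
         organelles = organelles)
  if (any(v <= 0)) stop("volumes must be strictly positive")
  structure(v, class = "pi_geometry")
}

#' @rdname cell_geometry
#' @export
human_platelet_geometry <- function() cell_geometry(1, 1, 0.5)

#' @rdname cell_geometry
#' @export
mouse_platelet_geometry <- function() cell_geometry(0.25, 0.25, 0.125)

#' @rdname cell_geometry
#' @export
nucleated_cell_geometry <- function() cell_geometry(17, 17, 8.5)

#' Construct a proteome table
#'
#' @param cell_type label.
#' @param copies named numeric vector, protein -> copies/cell (>= 0).
#' @param provenance per-entry provenance: `"native"`, `"borrowed:<donor>"`
#'   or `"scanned"`; recycled if length 1.
#' @return data.frame of class `pi_proteome` with columns `cell_type`,
#'   `protein`, `copies_per_cell`, `provenance`.
#' @export
proteome_table <- function(cell_type, copies, provenance = "native") {
  if (any(copies < 0, na.rm = TRUE)) stop("copies must be >= 0")
  structure(data.frame(cell_type = cell_type, protein = names(copies),
                       copies_per_cell = unname(copies),
                       provenance = provenance, stringsAsFactors = FALSE),
            class = c("pi_proteome", "data.frame"))
}

#' List the key proteins missing from a proteome table
#' @param proteome a `pi_proteome`.
#' @return character vector of missing protein names (possibly empty).
#' @export
proteome_gaps <- function(proteome) {
  have <- proteome$protein[!is.na(proteome$copies_per_cell)]
  setdiff(pi_key_proteins, have)
}

proteome_vector <- function(proteome) {
  stats::setNames(proteome$copies_per_cell, proteome$protein)
}

# Reaction "order" (total molecularity including the enzyme) determines how
# a folded rate constant rescales with volume: k -> k / ratio^(order-1),
# using the volume ratio of the reaction's compartment (first reactant).
reaction_orders <- function(model) {
  sp <- model$species
  vapply(model$reactions, function(r) {
    ord <- sum(r$reactants) + !is.na(r$enzyme)
    comp <- sp$compartment[match(names(r$reactants)[1], sp$name)]
    c(order = ord, comp = match(comp, model$compartments$name))
  }, c(order = 0, comp = 0))
}

#' Rescale the core model to another cell type
#'
#' Swaps compartment volumes, protein copy numbers and the receptor count
#' while freezing the reaction structure and per-concentration kinetics:
#' lipid, binding-protein and soluble pools are scaled from the reference
#' model in proportion to their compartment's volume ratio, and folded
#' bimolecular (and higher-order) rate constants are divided by
#' `ratio^(order-1)` so that concentration-space kinetics are invariant.
#' Buffered lipid pools are re-partitioned at binding equilibrium.
#'
#' @param core the calibrated reference `pi_model` (human platelet).
#' @param geometry a [cell_geometry()].
#' @param proteome a [proteome_table()] or named vector covering the 12 key
#'   proteins; gaps raise an error naming them (callers may first borrow via
#'   [complete_proteome()] or scan via [scan_missing_proteins()]).
#' @param receptor_count Gq-coupled receptors for this cell type (85,000 for
#'   nucleated-cell comparisons, matching the platelet receptor
#'   concentration).
#' @param cell_type metadata label.
#' @return a rescaled `pi_model` (no activation scheme attached).
#' @export
rescale_model <- function(core, geometry, proteome, receptor_count,
                          cell_type = "rescaled") {
  if (is.data.frame(proteome)) {
    gaps <- proteome_gaps(proteome)
    if (length(gaps))
      stop("proteome is missing required proteins: ",
           paste(gaps, collapse = ", "), call. = FALSE)
    pv <- proteome_vector(proteome)
  } else {
    gaps <- setdiff(pi_key_proteins, names(proteome)[!is.na(proteome)])
    if (length(gaps))
      stop("proteome is missing required proteins: ",
           paste(gaps, collapse = ", "), call. = FALSE)
    pv <- proteome
  }
  m <- core
  m$activation <- NULL
  ref_vol <- stats::setNames(core$compartments$volume, core$compartments$name)
  ratio <- unclass(geometry)[names(ref_vol)] / ref_vol
  m$compartments$volume <- unname(unclass(geometry)[m$compartments$name])

  # scale all pools by their compartment's ratio, then overwrite proteins
  sp <- m$species
  r_sp <- ratio[sp$compartment]
  m$species$initial <- sp$initial * r_sp
  prot <- intersect(names(pv), sp$name)
  m$species$initial[match(prot, sp$name)] <- unname(pv[prot])
  i <- match("GPCR", sp$name)
  m$species$initial[i] <- receptor_count
  m$species$initial[match(c("GPCR_a", "GPCR_i"), sp$name)] <- 0

  # rescale folded constants
  ords <- reaction_orders(core)
  for (j in seq_along(m$reactions)) {
    ord <- ords["order", j]
    if (ord <= 1) next
    f <- ratio[[ords["comp", j]]] ^ (ord - 1)
    rid <- m$reactions[[j]]$rate
    i <- match(rid, m$rates$id)
    m$rates$basal[i] <- core$rates$basal[i] / f
    if (!is.na(m$rates$activated[i]))
      m$rates$activated[i] <- core$rates$activated[i] / f
  }
  # re-partition buffered pools at equilibrium with the rescaled constants
  for (l in m$binding_pairs$lipid) {
    i <- match(l, m$binding_pairs$lipid)
    m$binding_pairs$bp_total[i] <- m$binding_pairs$bp_total[i] *
      ratio[["plasma_membrane"]]
    m <- set_parameter(m, paste0("bp_total:", l),
                       m$binding_pairs$bp_total[i])
  }
  m$metadata$cell_type <- cell_type
  validate_model(m)
  m
}

#' Fill proteome gaps from a donor cell type
#'
#' Missing key-protein entries in `partial` are filled with the donor's
#' values, tagged `borrowed:<donor cell type>` — the mosaic completion
#' strategy.
#'
#' @param partial a `pi_proteome` with gaps.
#' @param donor a complete `pi_proteome`.
#' @return completed `pi_proteome`.
#' @export
complete_proteome <- function(partial, donor) {
  gaps <- proteome_gaps(partial)
  if (!length(gaps)) return(partial)
  dv <- proteome_vector(donor)
  still <- setdiff(gaps, names(dv)[!is.na(dv)])
  if (length(still))
    stop("donor proteome also missing: ", paste(still, collapse = ", "))
  keep <- partial[!partial$protein %in% gaps, ]
  add <- data.frame(cell_type = partial$cell_type[1], protein = gaps,
                    copies_per_cell = unname(dv[gaps]),
                    provenance = paste0("borrowed:", donor$cell_type[1]),
                    stringsAsFactors = FALSE)
  zero <- add$protein[add$copies_per_cell == 0]
  if (length(zero))
    message("donor provided zero copies for: ", paste(zero, collapse = ", "))
  structure(rbind(keep, add), class = c("pi_proteome", "data.frame"))
}

#' Estimate missing protein numbers by scanning against a reference
#'
#' For each key protein absent from `partial`, scans its copy number on a
#' log grid and keeps the value minimising the worst-observable deviation of
#' the resulting simulation from a reference behaviour (the workflow that
#' produced the "scanned" completed tables). Scanned entries are tagged
#' `provenance = "scanned"`. A flat objective (the monitored outputs do not
#' depend on the protein) is detected, the tie broken toward the grid
#' minimum, and the entry flagged in the result's `flat` attribute.
#'
#' @param partial a `pi_proteome` with gaps.
#' @param reference a `pi_timecourse` of the reference behaviour (same grid
#'   and activation design as the candidate simulations).
#' @param core calibrated reference model for [rescale_model()].
#' @param geometry,receptor_count cell geometry and receptor count of the
#'   candidate cell.
#' @param scheme activation scheme used for candidate simulations.
#' @param center named starting values for the gaps; defaults to the
#'   reference model's (volume-scaled) protein levels.
#' @param passes list of `c(span, points_per_decade)` pairs: coordinate
#'   scans are repeated over the gaps with progressively narrower, denser
#'   grids around the running best values. Gaps are scanned in a fixed
#'   order: PI4P/PI45P2-axis enzymes first (they are pinned almost
#'   independently by the pre-activation drift), then the signalling chain,
#'   then the remaining proteins.
#' @param threshold acceptance threshold; if the final worst deviation
#'   exceeds it the result carries `accepted = FALSE` (best effort).
#' @param atol,rtol solver tolerances for the scan's integrations.
#' @return completed `pi_proteome` with attributes `worst`, `accepted`,
#'   `flat`.
#' @export
scan_missing_proteins <- function(partial, reference, core, geometry,
                                  receptor_count = 85000,
                                  scheme = activation_scheme(
                                    t_activation = 1000,
                                    receptor_count = 85000),
                                  center = NULL,
                                  passes = list(c(1.5, 4), c(0.75, 8),
                                                c(0.25, 16), c(0.1, 40)),
                                  threshold = 0.20,
                                  atol = 1e-2, rtol = 1e-6) {
  gaps <- proteome_gaps(partial)
  if (!length(gaps)) return(partial)
  scan_order <- c("PI4K", "PIP5K", "OCRL1", "SAC1", "Gq", "smG", "PLCb",
                  "IP3ME", "DGK", "LPP", "CDIPT", "cPLA2")
  gaps <- intersect(scan_order, gaps)
  ref_data <- timecourse_to_dataset(reference)
  pv <- proteome_vector(partial)[setdiff(names(proteome_vector(partial)),
                                         gaps)]
  ratio <- geometry[["plasma_membrane"]] /
    core$compartments$volume[core$compartments$name == "plasma_membrane"]
  core_p <- stats::setNames(core$species$initial, core$species$name)
  if (is.null(center)) center <- core_p[gaps] * ratio
  cand <- c(pv, center[gaps])
  t_end <- max(reference$times)
  devof <- function(cand) {
    m <- rescale_model(core, geometry, cand, receptor_count)
    m <- set_initial_state(m, nonprotein_state(reference))
    m <- apply_activation(m, scheme)
    tc <- try(simulate_model(m, t_end, times = reference$times,
                             atol = atol, rtol = rtol), silent = TRUE)
    if (inherits(tc, "try-error")) return(NA_real_)
    max(deviation(tc, ref_data))
  }
  flat <- character(0)
  for (p in passes) for (g in gaps) {
    grid <- scan_grid(scan_spec(paste0("init:", g), cand[[g]], p[1], p[2]))
    devs <- vapply(grid, function(v) { cand[g] <- v; devof(cand) },
                   numeric(1))
    if (all(is.na(devs))) stop("all scan points failed for ", g)
    if (diff(range(devs, na.rm = TRUE)) < 1e-3) {
      flat <- union(flat, g)
      best <- which(!is.na(devs))[1]   # flat objective: grid minimum
    } else best <- which.min(devs)
    cand[g] <- grid[best]
  }
  worst <- devof(cand)
  out <- rbind(
    partial[!partial$protein %in% gaps, ],
    data.frame(cell_type = partial$cell_type[1], protein = gaps,
               copies_per_cell = unname(cand[gaps]), provenance = "scanned",
               stringsAsFactors = FALSE))
  structure(out, class = c("pi_proteome", "data.frame"),
            worst = worst, accepted = isTRUE(worst <= threshold), flat = flat)
}

#' Build a cell-type model at its own homeostasis
#'
#' Rescales the core model to a geometry/proteome/receptor complement and
#' relaxes the lipid side to the resulting cell's own pre-activation steady
#' state, so that simulations start from that cell's homeostatic pools
#' (protein copy numbers are conserved quantities and are not altered by the
#' relaxation).
#'
#' @inheritParams rescale_model
#' @param relax if FALSE, skip the steady-state relaxation.
#' @return a `pi_model`.
#' @export
celltype_model <- function(core, geometry, proteome, receptor_count,
                           cell_type = "rescaled", relax = TRUE) {
  m <- rescale_model(core, geometry, proteome, receptor_count, cell_type)
  if (relax) {
    ss <- find_steady_state(m, tol = max(1e-6 * max(m$species$initial), 1))
    m <- set_initial_state(m, ss$amounts)
  }
  m
}

# First-row state of a reference trajectory restricted to the non-protein
# side (lipids, complexes, binding proteins, solubles); used to start mosaic
# candidates from the reference cell's homeostatic pools.
nonprotein_state <- function(reference) {
  y <- reference$amounts[1, ]
  drop <- c(pi_key_proteins, "GPCR", "GPCR_a", "GPCR_i", "PLCb", "PLCb_a",
            "Gq", "Gq_a")
  y[setdiff(names(y), drop)]
}

# Convert a reference trajectory's observables into a dataset for deviation()
timecourse_to_dataset <- function(tc, observables = pi_observables,
                                  times = NULL) {
  if (is.null(times)) times <- tc$times
  do.call(rbind, lapply(observables, function(o)
    data.frame(observable = o, time = times,
               mean = timecourse_at(tc, o, times), sem = 0, n = 1,
               stringsAsFactors = FALSE)))
}
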