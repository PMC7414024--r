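# End-to-end workflows tying the modules into the study designs: the
# nucleated-cell reference run, the scanned completion of the partial U2OS
# table, and the full mix-and-match experiment.

#' Shipped synthetic proteome tables
#'
#' Reads the package's proteome file: the human platelet table (the
#' calibration reference), and synthetic stand-in tables for the mouse
#' platelet, a HeLa-like nucleated cell and a U2OS-like nucleated cell with
#' the five canonical gaps (Gq, the lumped IP3-modifying enzymes, OCRL1,
#' PI4K, cPLA2). The synthetic tables are generated by
#' [generate_proteome()] under fixed seeds (101 for HeLa from the
#' concentration-matched enlarged platelet at fold sd 1.2; 202 for U2OS from
#' HeLa at fold sd 1.0; 303 for mouse from the quarter-volume platelet at
#' fold sd 0.8) and are stand-ins, not published values.
#'
#' @param cell_type one of `"human_platelet"`, `"mouse_platelet_synthetic"`,
#'   `"HeLa_synthetic"`, `"U2OS_synthetic"`, or NULL for the whole file.
#' @return a [proteome_table()] (with gaps for U2OS).
#' @export
pi_proteomes <- function(cell_type = NULL) {
  path <- system.file("extdata", "proteomes_synthetic.csv",
                      package = "picycle", mustWork = TRUE)
  read_proteome_csv(path, cell_type)
}

#' The nucleated-cell reference simulation
#'
#' Builds a cell-type model at its own homeostasis, attaches the standard
#' nucleated activation design (85,000 receptors activated at 1000 s) and
#' simulates to 5000 s — the reference behaviour against which mosaic
#' combinations are judged.
#'
#' @param core calibrated platelet model; defaults to the shipped one.
#' @param proteome proteome for the reference cell; defaults to the shipped
#'   HeLa-like table.
#' @param times output grid.
#' @param atol,rtol solver tolerances.
#' @return list with `model` (activated) and `timecourse`.
#' @export
nucleated_reference <- function(core = pi_platelet_model(activated = FALSE),
                                proteome = pi_proteomes("HeLa_synthetic"),
                                times = seq(0, 5000, by = 25),
                                atol = 1e-2, rtol = 1e-6) {
  scheme <- activation_scheme(t_activation = 1000, receptor_count = 85000)
  m <- celltype_model(core, nucleated_cell_geometry(), proteome, 85000,
                      if (is.data.frame(proteome)) proteome$cell_type[1]
                      else "reference")
  ma <- apply_activation(m, scheme)
  list(model = ma,
       timecourse = simulate_model(ma, max(times), times = times,
                                   atol = atol, rtol = rtol))
}

#' Run the full mosaic mix-and-match experiment
#'
#' The complete workflow: simulate the HeLa-like reference, complete the
#' partial U2OS-like table by scanning its five gaps against that reference,
#' then exhaustively mix the 12 key proteins between the two tables and
#' classify all 4096 combinations.
#'
#' @param core calibrated platelet model.
#' @param hela,u2os_partial source tables (defaults: shipped synthetic).
#' @param config classifier configuration.
#' @param progress forwarded to [mix_and_match()].
#' @return the [mix_and_match()] summary, with the scanned U2OS table
#'   attached as `$u2os_scanned` and the reference as `$reference`.
#' @export
run_mosaic_experiment <- function(core = pi_platelet_model(activated = FALSE),
                                  hela = pi_proteomes("HeLa_synthetic"),
                                  u2os_partial = pi_proteomes("U2OS_synthetic"),
                                  config = classifier_config(),
                                  progress = FALSE) {
  ref <- nucleated_reference(core, hela)
  u2os <- scan_missing_proteins(u2os_partial, ref$timecourse, core,
                                nucleated_cell_geometry())
  out <- mix_and_match(core, hela, u2os, ref$timecourse, config = config,
                       progress = progress)
  out$u2os_scanned <- u2os
  out$reference <- ref$timecourse
  out
}
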