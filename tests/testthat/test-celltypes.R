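test_that("proteome tables track gaps, borrowing and provenance", {
  full <- proteome_table("hela", stats::setNames(1:12, pi_key_proteins))
  expect_length(proteome_gaps(full), 0)
  part <- full[full$protein != "OCRL1", ]
  class(part) <- class(full)
  expect_equal(proteome_gaps(part), "OCRL1")
  done <- complete_proteome(part, full)
  expect_setequal(done$protein, pi_key_proteins)
  expect_equal(done$provenance[done$protein == "OCRL1"], "borrowed:hela")
  # identity when nothing is missing
  expect_identical(complete_proteome(full, full), full)
  # donor also missing the entry
  donor2 <- part
  expect_error(complete_proteome(part, donor2), "OCRL1")
  # donor with zero copies: filled and flagged
  donor3 <- full
  donor3$copies_per_cell[donor3$protein == "OCRL1"] <- 0
  expect_message(done0 <- complete_proteome(part, donor3), "OCRL1")
  expect_equal(done0$copies_per_cell[done0$protein == "OCRL1"], 0)
})

test_that("rescaling freezes structure and rescales folded constants", {
  core <- platelet()
  geo <- nucleated_cell_geometry()
  m <- rescale_model(core, geo, platelet_proteome() * 17, 85000)
  expect_error(rescale_model(core, geo, platelet_proteome()[-1], 85000),
               "Gq")
  # identical reaction structure
  expect_identical(lapply(m$reactions, `[`, c("id", "reactants", "products",
                                              "rate", "enzyme")),
                   lapply(core$reactions, `[`, c("id", "reactants",
                                                 "products", "rate",
                                                 "enzyme")))
  # second-order folded constants divided by the volume ratio
  expect_equal(m$rates$basal[m$rates$id == "k16"],
               core$rates$basal[core$rates$id == "k16"] / 17)
  # third-order constants by the ratio squared
  expect_equal(m$rates$basal[m$rates$id == "k_cdipt"],
               core$rates$basal[core$rates$id == "k_cdipt"] / 17^2)
  # first-order constants untouched
  expect_equal(m$rates$basal[m$rates$id == "k_ipx_ins"],
               core$rates$basal[core$rates$id == "k_ipx_ins"])
  expect_equal(unname(m$compartments$volume),
               unname(unclass(geo)[m$compartments$name]))
})

test_that("pltx17 scaling symmetry is exact to solver tolerance", {
  core <- platelet()
  plt17 <- rescale_model(core, nucleated_cell_geometry(),
                         platelet_proteome() * 17, 5000 * 17, "pltx17")
  tt <- seq(0, 2000, by = 20)
  a <- simulate_model(apply_activation(plt17, activation_scheme(
    100, 5000 * 17)), 2000, times = tt)
  b <- simulate_model(apply_activation(core, activation_scheme(100, 5000)),
                      2000, times = tt)
  rel <- abs(a$amounts / 17 - b$amounts) / pmax(abs(b$amounts), 1)
  expect_lt(max(rel), 1e-5)
})

test_that("the mouse platelet keeps the human temporal pattern", {
  core <- platelet()
  mouse <- pi_proteomes("mouse_platelet_synthetic")
  mm <- celltype_model(core, mouse_platelet_geometry(), mouse, 1250,
                       "mouse_platelet")
  ma <- apply_activation(mm, activation_scheme(100, 1250))
  tt <- seq(0, 2000, by = 20)
  tcm <- simulate_model(ma, 2000, times = tt)
  tch <- simulate_model(apply_activation(core, activation_scheme(100, 5000)),
                        2000, times = tt)
  # same response directions for every observable
  fm <- picycle:::behaviour_features(tcm, 100)
  fh <- picycle:::behaviour_features(tch, 100)
  dir_of <- function(f) if (f$up >= f$down) "rise" else "fall"
  for (o in c("PI", "PI45P2", "IP3", "DAG", "PA", "Ins"))
    expect_equal(dir_of(fm[[o]]), dir_of(fh[[o]]), info = o)
  # levels in line with the smaller pools: quarter-scale PI depletion
  expect_lt(tcm$observables[1, "PI"], 0.5 * tch$observables[1, "PI"])
})

test_that("scanning recovers deleted proteome entries against a reference", {
  ref <- hela_reference()
  hela <- pi_proteomes("HeLa_synthetic")
  part <- hela[!hela$protein %in% c("Gq", "PI4K"), ]
  class(part) <- class(hela)
  out <- scan_missing_proteins(part, ref$timecourse, platelet(),
                               nucleated_cell_geometry(),
                               passes = list(c(1.5, 4), c(0.5, 8),
                                             c(0.2, 20)))
  expect_setequal(out$protein, pi_key_proteins)
  expect_equal(sort(out$protein[out$provenance == "scanned"]),
               c("Gq", "PI4K"))
  hv <- stats::setNames(hela$copies_per_cell, hela$protein)
  sv <- stats::setNames(out$copies_per_cell, out$protein)
  # recovered within a factor ~2 of the deleted truth, and the completed
  # table reproduces the reference within the acceptance rule
  for (p in c("Gq", "PI4K"))
    expect_lt(abs(log10(sv[[p]] / hv[[p]])), 0.35)
  expect_lt(attr(out, "worst"), 0.20)
  # zero gaps: identity
  expect_identical(scan_missing_proteins(hela, ref$timecourse, platelet(),
                                         nucleated_cell_geometry()), hela)
})

test_that("a gap with no influence on the outputs is flagged as flat", {
  ref <- hela_reference()
  core <- platelet()
  # make cPLA2 inert by removing its only reaction's throughput
  core$rates$basal[core$rates$id %in% c("k_cpla2", "k_reacyl")] <- 1e-300
  hela <- pi_proteomes("HeLa_synthetic")
  part <- hela[hela$protein != "cPLA2", ]
  class(part) <- class(hela)
  ref2 <- nucleated_reference(core)
  out <- scan_missing_proteins(part, ref2$timecourse, core,
                               nucleated_cell_geometry(),
                               passes = list(c(1, 4)))
  expect_true("cPLA2" %in% attr(out, "flat"))
  # tie broken to the grid minimum
  grid <- picycle:::scan_grid(scan_spec("x", 17 * 10000, 1, 4))
  expect_equal(out$copies_per_cell[out$protein == "cPLA2"], min(grid))
})
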