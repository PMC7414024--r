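test_that("model validation enforces the container invariants", {
  m <- platelet()
  expect_s3_class(m, "pi_model")
  expect_silent(validate_model(m))

  bad <- m
  bad$compartments$volume[1] <- -1
  expect_error(validate_model(bad), "positive")

  bad <- m
  bad$species$initial[1] <- -5
  expect_error(validate_model(bad), "negative initial")

  bad <- m
  bad$rates$activated[bad$rates$id == "k17"] <- 1e-6
  expect_error(validate_model(bad), "k17")

  bad <- m
  bad$reactions[[1]]$rate <- "nope"
  expect_error(validate_model(bad), "unknown rate")
})

test_that("build_core_model reports every missing protein and lipid by name", {
  pr <- platelet_proteome()
  li <- platelet_lipid_inits()
  expect_error(build_core_model(pr[setdiff(names(pr), "OCRL1")], li), "OCRL1")
  err <- tryCatch(
    build_core_model(pr[setdiff(names(pr), c("Gq", "IP3ME", "OCRL1", "PI4K",
                                             "cPLA2"))], li),
    error = conditionMessage)
  for (p in c("Gq", "IP3ME", "OCRL1", "PI4K", "cPLA2"))
    expect_match(err, p)
  expect_error(build_core_model(pr, li[setdiff(names(li), "PA")]), "PA")
})

test_that("initial lipid pools match the requested totals exactly", {
  m <- build_core_model(platelet_proteome(), platelet_lipid_inits())
  sp <- stats::setNames(m$species$initial, m$species$name)
  li <- platelet_lipid_inits()
  expect_equal(sp[["PI"]], li[["PI"]])
  expect_equal(sp[["PI45P2"]] + sp[["C_PI45P2"]], li[["PI45P2"]])
  expect_equal(sp[["PI4P"]] + sp[["C_PI4P"]], li[["PI4P"]])
  expect_equal(sp[["PA"]] + sp[["C_PA"]], li[["PA"]])
  expect_equal(sp[["DAG"]] + sp[["C_DAG"]], li[["DAG"]])
  # complexes start at the binding equilibrium of the pair
  bp <- m$binding_pairs[m$binding_pairs$lipid == "PI45P2", ]
  kv <- stats::setNames(m$rates$basal, m$rates$id)
  expect_equal(sp[["C_PI45P2"]],
               picycle:::binding_equilibrium(li[["PI45P2"]], bp$bp_total,
                                             kv[[bp$kon]], kv[[bp$koff]]))
})

test_that("all-zero lipid pools give an absorbing zero lipid state", {
  li <- platelet_lipid_inits() * 0
  m <- build_core_model(platelet_proteome(), li,
                        extra_inits = c(IPx = 0, LPI = 0))
  tc <- simulate_model(m, 100, times = seq(0, 100, by = 10))
  for (s in c("PI", "PI4P", "PI45P2", "IP3", "DAG", "PA", "Ins"))
    expect_true(all(tc$amounts[, s] == 0), info = s)
})

test_that("mass-action flux matches a brute-force product oracle", {
  m <- platelet()
  kv <- stats::setNames(m$rates$basal, m$rates$id)
  set.seed(42)
  for (rep in 1:20) {
    state <- stats::setNames(stats::runif(nrow(m$species), 0, 1e5),
                             m$species$name)
    r <- m$reactions[[sample(length(m$reactions), 1)]]
    # independent oracle: explicit loop over reactant factors
    f <- kv[[r$rate]]
    for (s in names(r$reactants))
      for (i in seq_len(r$reactants[[s]])) f <- f * state[[s]]
    if (!is.na(r$enzyme)) f <- f * state[[r$enzyme]]
    expect_equal(mass_action_rate(r, state, kv[[r$rate]]), unname(f))
  }
  # forced-by-definition cases
  rx <- list(id = "x", reactants = c(S = 1), products = c(P = 1),
             rate = "k", enzyme = NA_character_)
  expect_equal(mass_action_rate(rx, c(S = 5, P = 0), 2), 10)
  expect_equal(mass_action_rate(rx, c(S = 0, P = 3), 2), 0)
  expect_error(mass_action_rate(rx, c(S = -1, P = 0), 2), "negative")
})

test_that("binding_equilibrium solves the conservation quadratic", {
  # oracle: direct root of kon (L - C)(B - C) = koff C via polyroot
  set.seed(7)
  for (i in 1:10) {
    l <- stats::runif(1, 10, 1e6); b <- stats::runif(1, 10, 1e6)
    kon <- 10^stats::runif(1, -8, -2); koff <- 10^stats::runif(1, -3, 0)
    roots <- Re(polyroot(c(kon * l * b, -(kon * (l + b) + koff), kon)))
    expect_equal(picycle:::binding_equilibrium(l, b, kon, koff),
                 min(roots), tolerance = 1e-9)
  }
})

test_that("activation schemes refuse k17 and apply cleanly", {
  expect_error(activation_scheme(rate_switches = c("k14", "k17")), "k17")
  m <- platelet()
  sch <- activation_scheme(t_activation = 100, receptor_count = 5000)
  ma <- apply_activation(m, sch)
  expect_equal(ma$activation$t_activation, 100)
  expect_equal(ma$species$initial[ma$species$name == "GPCR"], 5000)
  bad <- sch
  bad$rate_switches <- c("k14", "k17")
  expect_error(apply_activation(m, bad), "k17")
})

test_that("zero receptors leave the trajectory unactivated", {
  m <- platelet()
  tt <- seq(0, 500, by = 10)
  base <- simulate_model(m, 500, times = tt)
  ma <- apply_activation(m, activation_scheme(100, receptor_count = 0,
                                              rate_switches = character(0)))
  act <- simulate_model(ma, 500, times = tt)
  expect_equal(act$amounts[, setdiff(colnames(act$amounts), "GPCR")],
               base$amounts[, setdiff(colnames(base$amounts), "GPCR")],
               tolerance = 1e-6)
})

test_that("reset termination restores receptors and basal constants", {
  m <- platelet()
  ma <- apply_activation(m, activation_scheme(
    100, 5000, termination = "reset", termination_timescale = 50))
  tc <- simulate_model(ma, 400, times = seq(0, 400, by = 5))
  i_end <- nrow(tc$amounts)
  # active receptors cleared at termination, quiescent pool restored
  expect_equal(unname(tc$amounts[i_end, "GPCR_a"]), 0)
  expect_equal(unname(tc$amounts[i_end, "GPCR"]), 5000)
  expect_equal(unname(tc$amounts[i_end, "GPCR_i"]), 0)
})
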