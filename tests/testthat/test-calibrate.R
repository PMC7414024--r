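test_that("deviation matches a brute-force loop oracle and the 20% rule", {
  tc <- simulate_model(platelet(), 100, times = seq(0, 100, by = 5))
  # identical means: zero deviation everywhere, accepted
  d0 <- picycle:::timecourse_to_dataset(tc, times = seq(0, 100, by = 20))
  expect_true(all(deviation(tc, d0) == 0))
  # sim = 1.25 x mean: deviation 0.25, above threshold
  d125 <- d0
  d125$mean <- d125$mean / 1.25
  dev <- deviation(tc, d125)
  big <- vapply(split(d125$mean, d125$observable), function(x) max(abs(x)),
                0) > 0
  expect_equal(unname(dev[names(big)[big]]),
               rep(0.25, sum(big)), tolerance = 1e-9)
  # random sim vs random data on 5 points equals an explicit loop
  set.seed(3)
  d <- data.frame(observable = rep(c("PI", "IP3"), each = 5),
                  time = rep(seq(10, 90, by = 20), 2),
                  mean = stats::runif(10, 0, 2e6), sem = 0, n = 1)
  got <- deviation(tc, d)
  for (o in c("PI", "IP3")) {
    dd <- d[d$observable == o, ]
    fl <- 0.01 * max(abs(dd$mean))
    worst <- 0
    for (i in seq_len(nrow(dd))) {
      sim <- picycle:::timecourse_at(tc, o, dd$time[i])
      worst <- max(worst, abs(sim - dd$mean[i]) / max(abs(dd$mean[i]), fl))
    }
    expect_equal(got[[o]], worst)
  }
  expect_error(deviation(tc, d[0, ]), "empty")
  expect_error(deviation(tc, transform(d, time = time + 1000)), "outside")
})

test_that("scan grids count points and order deterministically", {
  s <- scan_spec("k16", 1e-7, span = 2, points_per_decade = 5)
  expect_length(picycle:::scan_grid(s), 21)  # endpoints inclusive
  expect_error(scan_spec("k16", 1e-7, span = 0), "span")
  expect_error(scan_spec("k16", 1e-7, points_per_decade = 2), ">= 3")
})

test_that("parameter getters and setters address rates, inits, bp totals", {
  m <- platelet()
  m2 <- set_parameter(m, "k16", 1e-6)
  expect_equal(get_parameter(m2, "k16"), 1e-6)
  m2 <- set_parameter(m, "k14:activated", 1e-4)
  expect_equal(get_parameter(m2, "k14:activated"), 1e-4)
  m2 <- set_parameter(m, "init:PLCb", 12345)
  expect_equal(get_parameter(m2, "init:PLCb"), 12345)
  m2 <- set_parameter(m, "bp_total:PI45P2", 2e6)
  expect_equal(get_parameter(m2, "bp_total:PI45P2"), 2e6)
  # total lipid pool is preserved under re-partition
  sp <- stats::setNames(m$species$initial, m$species$name)
  sp2 <- stats::setNames(m2$species$initial, m2$species$name)
  expect_equal(sp2[["PI45P2"]] + sp2[["C_PI45P2"]],
               sp[["PI45P2"]] + sp[["C_PI45P2"]])
  expect_equal(sp2[["BP_PI45P2"]] + sp2[["C_PI45P2"]], 2e6)
  expect_error(get_parameter(m, "init:nope"), "unknown species")
})

test_that("scanning recovers a known rate constant from noise-free data", {
  truth <- platelet_act()
  tt <- c(seq(0, 90, by = 30), seq(100, 400, by = 20), seq(500, 1500, by = 100))
  data <- picycle:::timecourse_to_dataset(
    simulate_model(truth, 1500, times = sort(unique(c(tt, 1500)))),
    observables = c("PI", "PI4P", "PI45P2", "IP3"), times = tt)
  k_true <- get_parameter(truth, "k16")
  # scan centered off-truth; best grid point must bracket truth within a step
  res <- scan_parameter(truth, scan_spec("k16", k_true * 1.3, span = 1,
                                         points_per_decade = 5), data)
  expect_lt(abs(log10(res$value[1] / k_true)), 0.2 + 1e-9)
  expect_true(res$accepted[1])
  # deviations strictly order: truth-adjacent beats far-off values
  expect_lt(res$worst[1], res$worst[nrow(res)])
})

test_that("scanning an inert parameter yields equal deviations", {
  truth <- platelet_act()
  tt <- seq(0, 500, by = 50)
  data <- picycle:::timecourse_to_dataset(
    simulate_model(truth, 500, times = tt),
    observables = c("PI", "PI45P2"), times = tt[-1])
  # the reacylation return acts on an isolated loop, invisible to PI over
  # short horizons only if its partner drain is off
  m <- truth
  m$rates$basal[m$rates$id == "k_cpla2"] <- 1e-300
  m$species$initial[m$species$name == "LPI"] <- 0
  res <- scan_parameter(m, scan_spec("k_reacyl", 2e-4, span = 1,
                                     points_per_decade = 3), data)
  expect_lt(diff(range(res$worst)), 1e-6)
  # ties broken toward the smaller parameter value
  expect_equal(res$value[1], min(res$value))
})

test_that("binding-protein scan recovers the shipped copy number", {
  m <- platelet_act()
  truth <- synthetic_truth(m, noise_sd = 0, seed = 5)
  tt <- c(seq(20, 80, by = 30), seq(100, 300, by = 20),
          seq(350, 1500, by = 75))
  data <- generate_timecourses(truth, observables = c("PI45P2", "PI4P"),
                               times = tt)
  res <- scan_binding_protein_number(m, "PI45P2", data, center = 1e6,
                                     span = 1)
  b_true <- m$binding_pairs$bp_total[m$binding_pairs$lipid == "PI45P2"]
  expect_lt(abs(log10(res$bp_total / b_true)), 0.2 + 1e-9)
  expect_error(scan_binding_protein_number(m, "PI45P2", data[
    data$observable == "PI4P", ]), "lacks")
})

test_that("removing the buffer produces a rejected, exaggerated excursion", {
  m <- platelet_act()
  tt <- c(seq(0, 90, by = 30), seq(100, 400, by = 15))
  data <- picycle:::timecourse_to_dataset(
    simulate_model(m, 400, times = tt), observables = "PI45P2", times = tt)
  m0 <- set_parameter(m, "bp_total:PI45P2", 1e-9)
  tc0 <- simulate_model(m0, 400, times = tt)
  dev <- deviation(tc0, data)
  expect_gt(dev[["PI45P2"]], 0.20)
})

test_that("staged fitting enforces order and recovers perturbed constants", {
  expect_error(fit_iteration(3, data.frame(), platelet_act()), "order")

  truth <- platelet_act()
  tt <- c(seq(0, 90, by = 30), seq(100, 400, by = 20),
          seq(500, 2000, by = 125))
  data <- picycle:::timecourse_to_dataset(
    simulate_model(truth, 2000, times = sort(unique(c(tt, 2000)))),
    times = tt)
  params <- unlist(picycle:::stage_params)

  # started at truth, the staged run keeps every parameter and accepts
  m0 <- run_staged_calibration(data, truth, polish_passes = 0)
  for (p in params)
    expect_equal(get_parameter(m0, p), get_parameter(truth, p),
                 tolerance = 1e-12)
  expect_true(attr(m0, "accepted"))

  # a single displaced constant is pulled back within one grid step,
  # without dislodging the others
  for (p0 in c("k16", "k_ipx_ins")) {
    perturbed <- set_parameter(truth, p0, get_parameter(truth, p0) * 2.5)
    m <- perturbed
    for (s in 1:4) m <- fit_iteration(s, data, m, points_per_decade = 5)
    for (p in params)
      expect_lt(abs(log10(get_parameter(m, p) / get_parameter(truth, p))),
                0.2 + 1e-9)
  }
})

test_that("a single direct IP3 to Ins step cannot match the two-step data", {
  truth <- platelet_act()
  tt <- c(seq(0, 90, by = 30), seq(100, 400, by = 20),
          seq(500, 2000, by = 125))
  data <- picycle:::timecourse_to_dataset(
    simulate_model(truth, 2000, times = sort(unique(c(tt, 2000)))),
    times = tt)
  m3 <- structure(truth, stage = 3L)
  m4 <- fit_iteration(4, data, m3, force_direct_ins = TRUE)
  fit <- attr(m4, "fit")
  # the stage cannot reach acceptance: IP3 or Ins stays off by > 20%
  expect_false(attr(m4, "accepted"))
  expect_gt(max(fit$worst), 0.20)
})
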