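test_that("first-order decay matches the closed-form exponential", {
  m <- decay_model(k = 0.1, a0 = 1000)
  tt <- seq(0, 60, by = 1)
  tc <- simulate_model(m, 60, times = tt)
  expect_equal(tc$amounts[, "A"], 1000 * exp(-0.1 * tt), tolerance = 1e-6)
  expect_equal(tc$amounts[, "B"], 1000 - tc$amounts[, "A"], tolerance = 1e-6)
  expect_equal(unname(tc$amounts[1, ]), c(1000, 0))
})

test_that("trajectory times are strictly increasing and first row is y0", {
  tc <- simulate_model(platelet(), 100, times = c(50, 0, 25, 100, 25))
  expect_true(all(diff(tc$times) > 0))
  expect_equal(unname(tc$amounts[1, ]),
               unname(platelet()$species$initial))
})

test_that("the shipped platelet model is at homeostasis", {
  ss <- find_steady_state(platelet(), tol = 1)
  expect_true(ss$converged)
  # homeostatic pool ranges: PI4P/PI45P2 totals 1.2-1.8e6, membrane PI ~6e6
  tot <- function(a, b) ss$amounts[[a]] + ss$amounts[[b]]
  expect_gt(tot("PI45P2", "C_PI45P2"), 1.2e6)
  expect_lt(tot("PI45P2", "C_PI45P2"), 1.8e6)
  expect_gt(tot("PI4P", "C_PI4P"), 1.2e6)
  expect_lt(tot("PI4P", "C_PI4P"), 1.8e6)
  expect_gt(ss$amounts[["PI"]], 5e6)
  expect_lt(ss$amounts[["PI"]], 7e6)

  # unactivated run from the steady state stays flat to 0.1%
  tc <- simulate_model(platelet(), 1000, times = seq(0, 1000, by = 50))
  drift <- apply(abs(tc$amounts - rep(tc$amounts[1, ],
                                      each = nrow(tc$amounts))), 2, max)
  expect_true(all(drift <= 1e-3 * pmax(tc$amounts[1, ], 1)))
})

test_that("steady state of an isolated binding pair matches the quadratic", {
  m <- binding_model(l0 = 1000, b0 = 600, kon = 1e-3, koff = 0.05)
  ss <- find_steady_state(m, tol = 1e-9, t_relax = 1e4)
  expect_equal(ss$amounts[["C"]],
               picycle:::binding_equilibrium(1000, 600, 1e-3, 0.05),
               tolerance = 1e-6)
})

test_that("a model with negligible rates stays at its initial amounts", {
  m <- decay_model(k = 1e-300, a0 = 500)
  ss <- find_steady_state(m, tol = 1e-6, t_relax = 100)
  expect_equal(unname(ss$amounts), c(500, 0))
})

test_that("conservation laws hold along the activated trajectory", {
  tc <- simulate_model(platelet_act(), 2000, times = seq(0, 2000, by = 20))
  for (e in static_enzymes) {
    v <- tc$amounts[, e]
    expect_lt(max(abs(v - v[1])) / v[1], 1e-6)
  }
  for (grp in conserved_groups) {
    v <- rowSums(tc$amounts[, grp, drop = FALSE])
    expect_lt(max(abs(v - v[1])) / max(v[1], 1), 1e-6)
  }
  bp <- platelet()$binding_pairs
  for (i in seq_len(nrow(bp))) {
    v <- tc$amounts[, bp$bp[i]] + tc$amounts[, bp$complex[i]]
    expect_lt(max(abs(v - v[1])) / v[1], 1e-6)
  }
})

test_that("the closed variant conserves the total inositol moiety", {
  m <- closed_variant(platelet_act())
  tc <- simulate_model(m, 2000, times = seq(0, 2000, by = 20))
  v <- rowSums(tc$amounts[, moiety_species])
  expect_lt(max(abs(v - v[1])) / v[1], 1e-6)
})

test_that("halving solver tolerances moves peaks by far less than 0.1%", {
  tt <- seq(0, 600, by = 2)
  a <- simulate_model(platelet_act(), 600, times = tt)
  b <- simulate_model(platelet_act(), 600, times = tt,
                      atol = 5e-7, rtol = 5e-9)
  for (o in c("IP3", "PI45P2", "PI4P", "DAG")) {
    pa <- summarize_timecourse(a, o, c(100, 600))$peak
    pb <- summarize_timecourse(b, o, c(100, 600))$peak
    expect_lt(abs(pa - pb) / pb, 1e-3)
  }
})

test_that("post-activation dynamics show the documented burst-and-return", {
  tc <- simulate_model(platelet_act(), 2000,
                       times = sort(unique(c(seq(0, 2000, by = 10),
                                             seq(100, 200, by = 1)))))
  # PI4P and PI45P2 show a short, synchronised burst after activation
  peaks <- vapply(c("PI4P", "PI45P2"), function(o) {
    s <- summarize_timecourse(tc, o, c(100, 200))
    expect_lt(s$time_of_peak, 150)
    expect_gt(s$ratio_to_initial, 1.05)
    # then return toward initial levels
    late <- picycle:::timecourse_at(tc, o, 2000) /
      tc$observables[1, o]
    expect_gt(late, 0.75)
    expect_lt(late, 1.25)
    s$time_of_peak
  }, 0)
  expect_lt(abs(diff(peaks)), 10)   # synchronised
  # IP3 peaks within tens of seconds of activation
  s <- summarize_timecourse(tc, "IP3", c(100, 2000))
  expect_gt(s$time_of_peak, 100)
  expect_lt(s$time_of_peak, 200)
})

test_that("summarize_timecourse agrees with a direct array scan", {
  # synthetic triangle wave
  tt <- 0:100
  tc <- structure(list(
    times = tt,
    amounts = cbind(X = c(seq(0, 50), seq(49, 0))),
    binding_pairs = NULL), class = "pi_timecourse")
  tc$observables <- picycle:::observable_matrix(tc)
  s <- summarize_timecourse(tc, "X", c(10, 90))
  w <- tt >= 10 & tt <= 90
  expect_equal(s$peak, max(tc$amounts[w, "X"]))
  expect_equal(s$time_of_peak, tt[w][which.max(tc$amounts[w, "X"])])
  expect_error(summarize_timecourse(tc, "nope", c(0, 10)), "unknown")
  expect_error(summarize_timecourse(tc, "X", c(-5, 10)), "window")
  # constant trajectory: peak equals initial, ratio one
  tc2 <- tc; tc2$amounts[, "X"] <- 7
  s2 <- summarize_timecourse(tc2, "X", c(0, 100))
  expect_equal(s2$peak, 7)
  expect_equal(s2$ratio_to_initial, 1)
})

test_that("timecourse export and re-import round-trips", {
  tc <- simulate_model(platelet(), 50, times = seq(0, 50, by = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tc, path)
  tc2 <- read_timecourse_csv(path)
  expect_equal(tc2$times, tc$times)
  expect_equal(tc2$amounts[, colnames(tc$amounts)], tc$amounts,
               tolerance = 1e-12)
})
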