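test_that("operator motifs have their structural reaction counts", {
  counts <- operator_reaction_counts()
  expect_identical(counts[["gain"]], 2L)
  expect_identical(counts[["summation3"]], 3L)
  expect_identical(counts[["subtraction_onesided"]], 4L)
  expect_identical(counts[["division"]], 2L)
  expect_identical(counts[["integrator"]], 1L)
  expect_identical(counts[["proportional"]], 2L)
  expect_identical(counts[["summation_dualrail"]], 9L)
  expect_identical(counts[["subtraction_dualrail"]], 9L)

  built <- list(
    gain = make_gain(1, 1),
    summation3 = make_summation3(1),
    subtraction_onesided = make_subtraction_onesided(1),
    division = make_division(1),
    integrator = make_integrator(1),
    proportional = make_proportional(0.02, 1),
    summation_dualrail = make_dualrail("summation", 1),
    subtraction_dualrail = make_dualrail("subtraction", 1)
  )
  for (kind in names(built)) {
    expect_identical(length(built[[kind]]$reactions), counts[[kind]],
                     info = kind)
  }
})

test_that("gain operator equilibria cover the spec examples", {
  # alpha gain at the nominal design point: x1 -> alpha * r
  inv <- inversion_constants(process_params())
  g <- make_gain(inv$alpha, 1, input = "r", output = "x1")
  ss <- steady_state(g, inputs = list(r = 4), horizon = 200)
  expect_equal(ss$state[["x1"]], 0.00512, tolerance = 1e-8)

  # identity follower and zero gain
  ss1 <- steady_state(make_gain(1, 2), inputs = list(u = 3.3), horizon = 50)
  expect_equal(ss1$state[["y"]], 3.3, tolerance = 1e-8)
  ss0 <- steady_state(make_gain(0, 1), x0 = c(y = 2), inputs = list(u = 3),
                      horizon = 100)
  expect_equal(ss0$state[["y"]], 0, tolerance = 1e-8)
  expect_error(make_gain(-1, 1), "non-negative")
})

test_that("summation, division, integrator equilibria match closed forms", {
  s <- make_summation3(1)
  expect_equal(steady_state(s, inputs = list(x1 = 2, x2 = 3),
                            horizon = 100)$state[["y"]], 5,
               tolerance = 1e-8)
  expect_equal(steady_state(s, inputs = list(x1 = 0, x2 = 0),
                            horizon = 100)$state[["y"]], 0,
               tolerance = 1e-10)

  d <- make_division(1)
  expect_equal(steady_state(d, inputs = list(x1 = 6, x3 = 3),
                            horizon = 200)$state[["x4"]], 2,
               tolerance = 1e-8)
  expect_equal(steady_state(d, inputs = list(x1 = 0, x3 = 3),
                            horizon = 200)$state[["x4"]], 0,
               tolerance = 1e-10)
  # denominator -> 0+: output drifts, flagged non-convergent
  ssd <- steady_state(d, inputs = list(x1 = 6, x3 = 1e-8), horizon = 100)
  expect_false(ssd$converged)

  # integrator: out(T) = KI * in * T, and in = 0 freezes the output
  i <- make_integrator(2.5e-8)
  tri <- simulate(mass_action_system(i), inputs = list(u = 1), t_end = 1e4,
                  t_grid = c(0, 1e4))
  expect_equal(tri$x[2L, "y"], 2.5e-4, tolerance = 1e-8,
               ignore_attr = TRUE)
  tr0 <- simulate(mass_action_system(i), x0 = c(y = 0.7),
                  inputs = list(u = 0), t_end = 1e4, t_grid = c(0, 1e4))
  expect_equal(tr0$x[2L, "y"], 0.7, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("one-sided subtraction clips at zero; dual-rail does not", {
  sub <- make_subtraction_onesided(1)
  tr <- simulate(mass_action_system(sub), inputs = list(xi1 = 2, xi2 = 5),
                 t_end = 2000)
  expect_true(all(tr$x[, "xo"] >= 0))
  expect_lt(tr$x[nrow(tr$x), "xo"], 0.05)

  # dual-rail subtraction represents the negative difference exactly
  dr <- make_dualrail("subtraction", gamma = 1)
  ss <- steady_state(dr, inputs = list(xi1p = 2, xi1m = 0,
                                       xi2p = 5, xi2m = 0), horizon = 100)
  expect_true(ss$converged)
  expect_equal(ss$state[["xop"]] - ss$state[["xom"]], -3, tolerance = 1e-6)

  drs <- make_dualrail("summation", gamma = 1)
  sss <- steady_state(drs, inputs = list(xi1p = 2, xi1m = 0,
                                         xi2p = 3, xi2m = 0), horizon = 100)
  expect_equal(sss$state[["xop"]] - sss$state[["xom"]], 5, tolerance = 1e-6)

  expect_warning(make_dualrail("subtraction", gamma = 1, eta = 0.5),
                 "degraded")
  expect_warning(make_dualrail("subtraction", gamma = 1, eta = 50),
                 "eta < 100")
})

test_that("dual-rail annihilation residue shrinks as eta/gamma grows", {
  resid <- vapply(c(10, 100, 1000), function(ratio) {
    dr <- suppressWarnings(make_dualrail("subtraction", gamma = 1,
                                         eta = ratio))
    ss <- steady_state(dr, inputs = list(xi1p = 2, xi1m = 0,
                                         xi2p = 5, xi2m = 0),
                       horizon = 100)
    min(ss$state[c("xop", "xom")])
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})

test_that("no single-rail motif in the library reaches a negative output", {
  # the library-level restatement of the two-sided-subtraction impossibility:
  # whatever the (non-negative) constant inputs, every standard motif's
  # output concentration stays >= 0 -- negative differences are unreachable
  set.seed(11)
  for (i in 1:10) {
    a <- stats::runif(1, 0, 10)
    b <- stats::runif(1, 0, 10)
    motifs <- list(
      list(make_gain(stats::runif(1, 0, 3), 1), list(u = a), "y"),
      list(make_summation3(1), list(x1 = a, x2 = b), "y"),
      list(make_subtraction_onesided(1), list(xi1 = a, xi2 = b), "xo"),
      list(make_division(1), list(x1 = a, x3 = b + 0.1), "x4")
    )
    for (m in motifs) {
      tr <- simulate(mass_action_system(m[[1L]]), inputs = m[[2L]],
                     t_end = 300)
      expect_true(all(tr$x[, m[[3L]]] >= 0))
      expect_lt(tr$metadata$clip_magnitude, 1e-6)
    }
  }
})
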