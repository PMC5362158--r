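test_that("reaction and CRN construction validate their inputs", {
  r <- reaction(c("xi1"), c("xi1", "xo"), rate = 2, name = "g")
  expect_s3_class(r, "crn_reaction")
  expect_identical(r$reactants, c(xi1 = 1L))
  expect_identical(r$products, c(xi1 = 1L, xo = 1L))

  expect_error(reaction("a", "b", rate = -1), "negative rate")
  expect_error(reaction(c("a", "b", "c"), character()), "bimolecular")
  expect_s3_class(reaction(c("a", "b", "c"), character(),
                           allow_termolecular = TRUE), "crn_reaction")

  # the four-reaction one-sided subtraction motif
  net <- make_subtraction_onesided(1)
  expect_identical(length(net$species), 4L)
  expect_identical(length(net$reactions), 4L)
  expect_setequal(net$species, c("xi1", "xi2", "xo", "xitd"))

  empty <- crn()
  expect_identical(length(empty$species), 0L)
  expect_identical(length(empty$reactions), 0L)

  expect_error(crn(list(reaction("a", "b")), clamped = "zz"),
               "clamped species")
})

test_that("stoichiometric matrix handles catalysts, degradation, clamping", {
  # catalytic appearance cancels
  net <- crn(list(reaction("xi1", c("xi1", "xo"), rate = 1, name = "g")))
  P <- stoich_matrix(net)
  expect_identical(P["xi1", 1L], 0L)
  expect_identical(P["xo", 1L], 1L)

  net2 <- crn(list(reaction("xo", character(), rate = 1, name = "g")))
  expect_identical(stoich_matrix(net2)["xo", 1L], -1L)

  # enzymatic process, no clamping: 4 species x 3 reactions
  proc <- make_process(process_params(), input = "xin", output = "xout",
                       clamp_input = FALSE)
  P3 <- stoich_matrix(proc)
  expect_identical(dim(P3), c(4L, 3L))
  expect_identical(P3[c("xin", "xe", "xi", "xout"), 1L],
                   c(xin = -1L, xe = -1L, xi = 1L, xout = 0L))

  # clamped species lose their row
  sub <- make_subtraction_onesided(1)
  expect_identical(rownames(stoich_matrix(sub)), c("xo", "xitd"))
  expect_identical(nrow(stoich_matrix(sub, full = TRUE)), 4L)
})

test_that("mass-action rates follow the product law", {
  net <- crn(list(reaction(c("X", "Y"), character(), rate = 1, name = "g")))
  expect_equal(mass_action_rates(net, c(X = 2, Y = 3)), 6)

  net2 <- crn(list(reaction("X", c("X", "Y"), rate = 2, name = "g")))
  expect_equal(mass_action_rates(net2, c(X = 5, Y = 0)), 10)
  expect_equal(mass_action_rates(net2, c(X = 0, Y = 0)), 0)

  # squared species
  net3 <- crn(list(reaction(c(X = 2), "Z", rate = 3, name = "g")))
  expect_equal(mass_action_rates(net3, c(X = 2, Z = 0)), 12)

  expect_error(mass_action_rates(net, c(X = -1, Y = 1)), "negative")
})

test_that("compiled RHS reproduces the hand-written operator ODEs", {
  # one-sided subtraction
  sub <- make_subtraction_onesided(1.7)
  expect_rhs_matches(mass_action_system(sub), function(x) {
    rhs_subtraction1(x, x[["xi1"]], x[["xi2"]], 1.7)
  })

  # dual-rail summation and subtraction
  for (kind in c("summation", "subtraction")) {
    op <- suppressWarnings(make_dualrail(kind, gamma = 0.8, eta = 450))
    oracle <- if (kind == "summation") rhs_dualrail_sum else rhs_dualrail_sub
    expect_rhs_matches(mass_action_system(op), function(x) {
      oracle(x, x[["xi1p"]], x[["xi1m"]], x[["xi2p"]], x[["xi2m"]],
             0.8, 450)
    })
  }

  # enzymatic process
  p <- process_params()
  proc <- make_process(p)
  expect_rhs_matches(mass_action_system(proc), function(x) {
    rhs_process(x, x[["x5"]], p)
  })

  # empty CRN: RHS identically zero
  expect_length(ma_rhs(mass_action_system(crn()), numeric(0)), 0L)
})

test_that("RHS equals P f(x) and matches the compiled integrator", {
  net <- make_subtraction_onesided(1.3)
  sys <- mass_action_system(net)
  set.seed(4)
  for (i in 1:10) {
    x <- stats::setNames(stats::runif(4, 0, 8), sys$species)
    manual <- drop(sys$P %*% mass_action_rates(net, x))
    expect_equal(ma_rhs(sys, x), manual, tolerance = 1e-14)
  }

  # central finite difference of the C++ trajectory approximates the RHS
  x0 <- c(xo = 1, xitd = 0.5)
  inp <- list(xi1 = 5, xi2 = 3)
  h <- 1e-4
  tr <- simulate(sys, x0 = x0, inputs = inp, t_end = 2 * h,
                 t_grid = c(0, h, 2 * h), rtol = 1e-10, atol = 1e-12)
  fd <- (tr$x[3L, c("xo", "xitd")] - tr$x[1L, c("xo", "xitd")]) / (2 * h)
  rhs <- ma_rhs(sys, tr$x[2L, ])
  expect_equal(fd, rhs[c("xo", "xitd")], tolerance = 1e-5)
})

test_that("simulation reproduces closed forms and conserves mass", {
  # exponential decay
  d <- crn(list(reaction("X", character(), rate = 1, name = "g")))
  tr <- simulate(d, x0 = c(X = 1), t_end = 5, t_grid = c(0, 5))
  expect_equal(tr$x[2L, "X"], exp(-5), tolerance = 1e-4,
               ignore_attr = TRUE)

  # subtraction steady states: positive difference settles, deficit drifts
  sub <- mass_action_system(make_subtraction_onesided(1))
  ss <- steady_state(sub, inputs = list(xi1 = 5, xi2 = 3), horizon = 400)
  expect_true(ss$converged)
  expect_equal(ss$state[["xo"]], 2, tolerance = 1e-6)

  ss2 <- steady_state(sub, inputs = list(xi1 = 3, xi2 = 5), horizon = 5000)
  expect_false(ss2$converged)
  expect_lt(ss2$state[["xo"]], 0.05)
  expect_gt(ss2$state[["xitd"]], 100)  # intermediate grows without settling

  # equal inputs: no finite fixed point either
  ss3 <- steady_state(sub, inputs = list(xi1 = 4, xi2 = 4), horizon = 5000)
  expect_false(ss3$converged)

  # gain equilibrium r = 4, alpha = 1: x1 -> 4
  g <- make_gain(1, 1, input = "r", output = "x1")
  ssg <- steady_state(g, inputs = list(r = 4), horizon = 200)
  expect_true(ssg$converged)
  expect_equal(ssg$state[["x1"]], 4, tolerance = 1e-8)

  # enzyme conservation along a driven process trajectory
  p <- process_params()
  proc <- make_process(p)
  trp <- simulate(mass_action_system(proc), x0 = c(xe = p$xT),
                  inputs = list(x5 = 0.2), t_end = 20000)
  tot <- trp$x[, "xe"] + trp$x[, "xi"]
  expect_lt(max(abs(tot - p$xT)), 1e-6)

  # non-negativity: output clipping never exceeds solver tolerance scale
  expect_lt(trp$metadata$clip_magnitude, 1e-6)

  # decay system converges to zero
  ssd <- steady_state(d, x0 = c(X = 1), horizon = 100)
  expect_true(ssd$converged)
  expect_equal(ssd$state[["X"]], 0, tolerance = 1e-8)
})

test_that("piecewise inputs, grids and failure modes behave", {
  g <- make_gain(1, 0.05, input = "r", output = "y")
  steps <- cbind(c(0, 500), c(2, 6))
  tr <- simulate(mass_action_system(g), inputs = list(r = steps),
                 t_end = 1500, t_grid = seq(0, 1500, by = 10))
  expect_equal(traj_value(tr, "y", 490), 2, tolerance = 1e-3)
  expect_equal(traj_value(tr, "y", 1500), 6, tolerance = 1e-3)
  expect_true(all(diff(tr$t) > 0))

  expect_error(simulate(mass_action_system(g), inputs = list(bad = 1),
                        t_end = 1), "non-clamped")
  expect_error(simulate(mass_action_system(g),
                        inputs = list(r = cbind(10, 1)), t_end = 20),
               "before time 0")

  # divergence bound reported with last valid time
  boom <- crn(list(reaction("X", c(X = 2L), rate = 1, name = "g")))
  expect_error(simulate(boom, x0 = c(X = 1), t_end = 100,
                        diverge_bound = 1e4),
               "diverged")
  trb <- simulate(boom, x0 = c(X = 1), t_end = 100, diverge_bound = 1e4,
                  fail = "return")
  expect_identical(trb$metadata$status_label, "diverged")
  expect_lt(trb$metadata$t_last, 100)
})
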