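test_that("DSD compilation structure: 2 steps per uni, 3 per bi", {
  params <- dsd_params(C_max = 1e4, q_max = 1e3)

  uni <- reaction("x7", c("x7", "x8"), rate = 2.5e-8, name = "KI")
  cu <- compile_unimolecular(uni, params, index = 1L)
  expect_identical(cu$n_steps, 2L)
  expect_identical(nrow(cu$aux), 3L)
  expect_setequal(cu$aux$role, c("fuel", "intermediate"))
  expect_equal(cu$steps[[1L]]$rate_value, 2.5e-8 / 1e4)

  bi <- reaction(c("xitd", "xo"), character(), rate = 1, name = "g")
  cb <- compile_bimolecular(bi, params, index = 2L)
  expect_identical(cb$n_steps, 3L)
  expect_identical(nrow(cb$aux), 5L)
  # first step reversible with backward rate q_max
  expect_equal(cb$steps[[1L]]$rate_value, 1)
  expect_equal(cb$steps[[2L]]$rate_value, 1e3)
  expect_identical(names(cb$steps[[2L]]$products),
                   names(cb$steps[[1L]]$reactants))

  expect_error(compile_unimolecular(bi, params), "not unimolecular")
  expect_error(compile_bimolecular(uni, params), "not bimolecular")

  # one-sided subtraction: 3 uni + 1 bi -> 2*3 + 3*1 = 9 steps
  prog <- compile_dsd(make_subtraction_onesided(1), params)
  expect_identical(prog$n_steps, 9L)
  expect_identical(length(prog$map), 4L)

  # the simplified closed loop: 17 uni + 1 bi among its 18 reactions
  simp <- nominal_circuit("simplified_ff")
  molec <- vapply(simp$crn$reactions, function(r) sum(r$reactants),
                  integer(1))
  progc <- compile_dsd(simp$crn)
  expect_identical(progc$n_steps,
                   2L * sum(molec == 1L) + 3L * sum(molec == 2L))

  # empty CRN -> empty program
  expect_identical(compile_dsd(crn(), params)$n_steps, 0L)

  # termolecular reactions are rejected by name
  ter <- crn(list(reaction(c("a", "b", "c"), character(), rate = 1,
                           name = "k", allow_termolecular = TRUE)))
  expect_error(compile_dsd(ter, params), "reaction 1")

  # rates beyond q_max cannot be emulated
  fast <- crn(list(reaction(c("a", "b"), "c", rate = 1e5, name = "k")))
  expect_error(compile_dsd(fast, dsd_params(C_max = 1e4, q_max = 1e3)),
               "q_max")
})

test_that("compiled kinetics converge to source kinetics as C_max grows", {
  # unimolecular decay
  src <- crn(list(reaction("X", character(), rate = 1, name = "g")))
  grid <- seq(0, 5, by = 0.1)
  dev_uni <- vapply(c(1e2, 1e3, 1e4), function(cm) {
    prog <- compile_dsd(src, dsd_params(C_max = cm, q_max = 1e3))
    tr <- simulate_dsd(prog, x0 = c(X = 1), t_end = 5, t_grid = grid)
    max(abs(tr$x[, "X"] - exp(-tr$t)))
  }, numeric(1))
  expect_true(all(diff(dev_uni) < 0))
  expect_lt(dev_uni[3L], 0.01)

  # bimolecular association against the directly integrated source
  src2 <- crn(list(reaction(c("X", "Y"), "Z", rate = 0.5, name = "k")))
  ref <- simulate(mass_action_system(src2), x0 = c(X = 1, Y = 0.8),
                  t_end = 10, t_grid = seq(0, 10, by = 0.2))
  dev_bi <- vapply(c(1e2, 1e3, 1e4), function(cm) {
    prog <- compile_dsd(src2, dsd_params(C_max = cm, q_max = 500))
    tr <- simulate_dsd(prog, x0 = c(X = 1, Y = 0.8), t_end = 10,
                       t_grid = seq(0, 10, by = 0.2))
    max(abs(tr$x[, "Z"] - ref$x[, "Z"]))
  }, numeric(1))
  expect_true(all(diff(dev_bi) < 0))
  expect_lt(dev_bi[3L], 0.01)

  # a zero-rate source compiles to an inert module
  inert <- compile_dsd(crn(list(reaction("X", "Y", rate = 0, name = "g"))),
                       dsd_params(C_max = 1e3, q_max = 1e3))
  tri <- simulate_dsd(inert, x0 = c(X = 1), t_end = 10)
  expect_equal(tri$x[nrow(tri$x), "X"], 1, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fuel strands only deplete, and depletion is flagged", {
  src <- crn(list(reaction("X", character(), rate = 1, name = "g")))
  prog <- compile_dsd(src, dsd_params(C_max = 100, q_max = 1e3))
  tr <- simulate_dsd(prog, x0 = c(X = 1), t_end = 5)
  for (s in prog$aux$species[prog$aux$role == "fuel"]) {
    expect_true(all(diff(tr$x[, s]) <= 1e-9), info = s)
  }
  expect_false(any(check_depletion(tr, prog)$depleted))

  # tiny C_max relative to the signal: fuels visibly deplete
  prog2 <- compile_dsd(src, dsd_params(C_max = 1, q_max = 1e3))
  tr2 <- simulate_dsd(prog2, x0 = c(X = 1), t_end = 5)
  expect_true(any(check_depletion(tr2, prog2)$depleted))
})
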