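make_fake_traj <- function(y40, y80) {
  tt <- c(0, 40000, 80000)
  x <- matrix(c(0, y40, y80), 3L, 1L, dimnames = list(NULL, "x6"))
  structure(list(t = tt, x = x, species = "x6",
                 metadata = list(status = 0L, status_label = "ok")),
            class = "crn_trajectory")
}

test_that("relative steady-state error matches direct arithmetic", {
  ref <- reference_signal()
  expect_equal(relative_ess(make_fake_traj(4, 1), ref),
               c(e_U = 0, e_D = 0))
  expect_equal(relative_ess(make_fake_traj(8, 1), ref)[["e_U"]], 50)
  expect_equal(relative_ess(make_fake_traj(4, 1.3), ref)[["e_D"]],
               100 * 0.3 / 1.3, tolerance = 1e-12)
  # signed: undershoot gives negative errors
  expect_lt(relative_ess(make_fake_traj(2, 1), ref)[["e_U"]], 0)
  # zero output -> undefined
  expect_true(is.na(relative_ess(make_fake_traj(0, 1), ref)[["e_U"]]))

  expect_error(reference_signal(c(5, 10), c(1, 2)), "begin at 0")
  expect_error(reference_signal(c(0, 10), c(1, -2)), ">= 0")
})

test_that("Chernoff bound sample sizes", {
  # oracle: direct evaluation of ceil(log(2/(1-c)) / (2 eps^2))
  cases <- list(c(0.05, 0.99), c(0.5, 0.99), c(1, 0.99), c(0.1, 0.95))
  for (cs in cases) {
    expect_identical(chernoff_sample_size(cs[1L], cs[2L]),
                     as.integer(ceiling(log(2 / (1 - cs[2L])) /
                                          (2 * cs[1L]^2))))
  }
  expect_identical(chernoff_sample_size(0.05, 0.99), 1060L)
  expect_identical(chernoff_sample_size(0.5, 0.99), 11L)
  expect_identical(chernoff_sample_size(1, 0.99), 3L)
  expect_error(chernoff_sample_size(0, 0.99))
})

test_that("perturbation targets split rates per ODE-term occurrence", {
  full <- nominal_circuit("full_ff")
  tg <- perturbation_targets(full)
  # index sets: i in 1:2, j in 1:5, k in 1:3 per the published splitting
  expect_identical(sum(grepl("^gSbII_", tg$name)), 5L)
  expect_identical(sum(grepl("^gSbI_", tg$name)), 5L)
  expect_identical(sum(grepl("^gSmII_", tg$name)), 3L)
  expect_identical(sum(grepl("^gSmI_", tg$name)), 3L)
  expect_identical(sum(grepl("^gGa_", tg$name)), 2L)
  expect_true(all(c("KP", "KI", "kr1", "kr2", "kr3") %in% tg$name))

  simp <- nominal_circuit("simplified_ff")
  tgs <- perturbation_targets(simp)
  expect_identical(sum(grepl("^gG_", tgs$name)), 2L)
  expect_false(any(grepl("^gGa_|^gSbI_|^gD_", tgs$name)))

  # a term factor rescales exactly one stoichiometric entry
  M <- term_scale_matrix(full, c(gSbII_1 = 2))
  expect_identical(sum(M != 1), 1L)
  expect_identical(unname(M["x7", tg["gSbII_1", "rxn"]]), 2)
  # a rate factor rescales a whole reaction column
  Mr <- term_scale_matrix(full, c(kr2 = 0.5))
  expect_true(all(Mr[, tg["kr2", "rxn"]] == 0.5))
  expect_error(term_scale_matrix(full, c(nope = 2)), "unknown")
})

test_that("uniform operator-rate scaling preserves exactness, uneven breaks it", {
  full <- nominal_circuit("full_ff")
  ref <- reference_signal()
  e_nom <- relative_ess(nominal_tracking("full_ff"), ref)

  # all Subtraction II and Summation II terms scaled together: the operator
  # still computes exact subtraction/summation, so the error stays nominal
  even <- stats::setNames(rep(1.7, 8),
                          c(paste0("gSbII_", 1:5), paste0("gSmII_", 1:3)))
  e_even <- relative_ess(run_tracking(full, factors = even, n_out = 41),
                         ref)
  expect_lt(abs(e_even[["e_U"]] - e_nom[["e_U"]]), 0.5)

  # one term alone: the summation becomes inexact and the error is large
  e_uneven <- relative_ess(run_tracking(full, factors = c(gSmII_1 = 1.7),
                                        n_out = 41), ref)
  expect_gt(abs(e_uneven[["e_U"]]), 5)
})

test_that("Monte Carlo envelopes are reproducible, containing and nested", {
  full <- nominal_circuit("full_ff")
  a <- monte_carlo_robustness(full, scale = 0.1, n = 8, seed = 5)
  b <- monte_carlo_robustness(full, scale = 0.1, n = 8, seed = 5)
  expect_identical(a$min, b$min)
  expect_identical(a$max, b$max)

  # nominal trajectory inside the envelope
  expect_true(all(a$min <= a$nominal + 1e-9))
  expect_true(all(a$nominal <= a$max + 1e-9))

  # same seeds, larger scale: envelope at least as wide pointwise
  w <- monte_carlo_robustness(full, scale = 1.0, n = 8, seed = 5)
  expect_true(all(a$max - a$min <= w$max - w$min + 1e-9))

  # zero scale collapses onto the nominal trajectory
  z <- monte_carlo_robustness(full, scale = 0, n = 2, seed = 5)
  expect_equal(z$min, z$nominal, tolerance = 1e-8)
  expect_equal(z$max, z$nominal, tolerance = 1e-8)
})

test_that("sensitivity sweep at factor 1 reproduces the nominal error", {
  full <- nominal_circuit("full_ff")
  rep1 <- sensitivity_sweep(full, parameters = c("gSmII_1", "KP"),
                            factors = 1)
  e_nom <- relative_ess(nominal_tracking("full_ff"))
  expect_equal(rep1$e_U, rep(e_nom[["e_U"]], 2), tolerance = 1e-4)
  expect_lt(max(abs(rep1$e_U)), 0.5)
})

test_that("process regime endpoints reproduce the published verdicts", {
  # slow degradation (kr3 = 1e-5) defeats tracking even with adjustments;
  # fast degradation with decreased PI gains tracks
  cfg <- controller_config()
  sub <- function(mode, kr1, kr2, kr3, remark_cfg) {
    circ <- assemble_closed_loop(mode, remark_cfg,
                                 process_params(kr1 = kr1, kr2 = kr2,
                                                kr3 = kr3))
    traj <- run_tracking(circ, n_out = 41, rtol = 1e-6, atol = 1e-10,
                         fail = "return")
    relative_ess(traj)
  }
  # (-,-,-) unadjusted: fails badly
  e1 <- sub("full_ff", 1e-9, 1e-2, 1e-5, cfg)
  expect_gt(max(abs(e1), na.rm = TRUE), 10)
  # (+,+,+) with decreased KP and KI: tracks
  cfg_dec <- controller_config(KP = 0.02 * 1e-12, KI = 2.5e-8 * 1e-12)
  e2 <- sub("full_ff", 1e6, 1e2, 1e-3, cfg_dec)
  expect_lt(max(abs(e2)), 10)
  # kr3 = 1e-5 with the same decreased gains: still fails
  e3 <- sub("full_ff", 1e6, 1e2, 1e-5, cfg_dec)
  expect_gt(max(abs(e3), na.rm = TRUE), 10)
})
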