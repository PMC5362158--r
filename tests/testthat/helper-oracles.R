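# Hand-coded ODE right-hand sides for the reference networks, written
# directly from the published closed forms. These are the independent route
# against which the CRN compiler is checked term by term.

# one-sided subtraction (inputs clamped)
rhs_subtraction1 <- function(x, xi1, xi2, g) {
  c(xo = g * (xi1 - x[["xo"]] * x[["xitd"]] - x[["xo"]]),
    xitd = g * (xi2 - x[["xo"]] * x[["xitd"]]))
}

# dual-rail summation (inputs clamped)
rhs_dualrail_sum <- function(x, i1p, i1m, i2p, i2m, g, eta) {
  ann <- eta * x[["xop"]] * x[["xom"]]
  c(xop = g * (i1p + i2p - x[["xop"]]) - ann,
    xom = g * (i1m + i2m - x[["xom"]]) - ann)
}

# dual-rail subtraction (inputs clamped)
rhs_dualrail_sub <- function(x, i1p, i1m, i2p, i2m, g, eta) {
  ann <- eta * x[["xop"]] * x[["xom"]]
  c(xop = g * (i1p + i2m - x[["xop"]]) - ann,
    xom = g * (i1m + i2p - x[["xom"]]) - ann)
}

# enzymatic process, input clamped; xe kept as a state (conservation
# partner of xi)
rhs_process <- function(x, xin, p) {
  bind <- p$kr1 * xin * x[["xe"]]
  c(xi = bind - p$kr2 * x[["xi"]],
    x6 = p$kr2 * x[["xi"]] - p$kr3 * x[["x6"]],
    xe = -bind + p$kr2 * x[["xi"]])
}

# full closed loop (r, beta clamped); state must carry every dynamic species
rhs_closed_loop <- function(x, r, beta_v, cfg, inv, p,
                            mode = "full_ff", retroactivity = FALSE) {
  out <- c()
  if (mode == "full_ff") {
    out <- c(out,
      x1 = cfg$gGa * (inv$alpha * r - x[["x1"]]),
      x2 = cfg$gGd * (inv$delta * r - x[["x2"]]),
      x3 = cfg$gSbI * (beta_v - x[["xs"]] * x[["x3"]] - x[["x3"]]),
      xs = cfg$gSbI * (x[["x2"]] - x[["xs"]] * x[["x3"]]),
      x4 = cfg$gD * (x[["x1"]] - x[["x3"]] * x[["x4"]]))
  } else if (mode == "simplified_ff") {
    out <- c(out,
      x4 = cfg$gG * (inv$alpha / inv$beta * r - x[["x4"]]))
  }
  bind <- p$kr1 * x[["x5"]] * x[["xe"]]
  c(out,
    x8 = cfg$KI * x[["x7"]],
    x9 = cfg$gGKP * (cfg$KP * x[["x7"]] - x[["x9"]]),
    x10 = cfg$gSmI * (x[["x8"]] + x[["x9"]] - x[["x10"]]),
    x7 = cfg$gSbII * (r - x[["xt"]] * x[["x7"]] - x[["x7"]]),
    xt = cfg$gSbII * (x[["x6"]] - x[["xt"]] * x[["x7"]]),
    x5 = cfg$gSmII * (x[["x4"]] + x[["x10"]] - x[["x5"]]) -
      (if (retroactivity) bind else 0),
    xi = bind - p$kr2 * x[["xi"]],
    x6 = p$kr2 * x[["xi"]] - p$kr3 * x[["x6"]],
    xe = -bind + p$kr2 * x[["xi"]])
}

# compare compiled RHS against an oracle at random non-negative states
expect_rhs_matches <- function(sys, oracle_fn, n_states = 20, seed = 1,
                               scale = 5, tol = 1e-12) {
  set.seed(seed)
  for (i in seq_len(n_states)) {
    x <- stats::setNames(stats::runif(length(sys$species), 0, scale),
                         sys$species)
    got <- ma_rhs(sys, x)
    want <- oracle_fn(x)
    expect_equal(got[names(want)], want, tolerance = tol)
  }
}

nominal_circuit <- local({
  cache <- list()
  function(mode = "full_ff", retroactivity = FALSE) {
    key <- paste(mode, retroactivity)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- assemble_closed_loop(mode,
                                            retroactivity = retroactivity)
    }
    cache[[key]]
  }
})

# cached nominal tracking runs shared across test files
nominal_tracking <- local({
  cache <- list()
  function(mode = "full_ff", retroactivity = FALSE) {
    key <- paste(mode, retroactivity)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- run_tracking(nominal_circuit(mode, retroactivity))
    }
    cache[[key]]
  }
})
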