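#' Controller configuration
#'
#' Rates and gains of the tracking controller. The defaults are the nominal
#' design values: all operator rates 1.0 except the Summation I rate
#' (`gSmI = 4e-4`) and the Subtraction II rate (`gSbII = 3.0`); PI gains
#' `KP = 0.02`, `KI = 2.5e-8`. `gG` is the gain rate of the Taylor-simplified
#' feedforward operator.
#'
#' @param gGa,gGd Feedforward gain operator rates (alpha and delta branches).
#' @param gSbI Subtraction I rate.
#' @param gD Division rate.
#' @param gGKP Proportional gain operator rate.
#' @param KP Proportional gain.
#' @param KI Integral gain.
#' @param gSmI Summation I rate.
#' @param gSbII Subtraction II rate.
#' @param gSmII Summation II rate.
#' @param gG Simplified feedforward gain rate.
#' @param mode One of `"full_ff"`, `"simplified_ff"`, `"pi_only"`.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(gGa = 1, gGd = 1, gSbI = 1, gD = 1,
                              gGKP = 1, KP = 0.02, KI = 2.5e-8,
                              gSmI = 4e-4, gSbII = 3, gSmII = 1, gG = 1,
                              mode = c("full_ff", "simplified_ff",
                                       "pi_only")) {
  mode <- match.arg(mode)
  vals <- c(gGa = gGa, gGd = gGd, gSbI = gSbI, gD = gD, gGKP = gGKP,
            KP = KP, KI = KI, gSmI = gSmI, gSbII = gSbII, gSmII = gSmII,
            gG = gG)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all controller rates and gains must be positive", call. = FALSE)
  }
  structure(c(as.list(vals), list(mode = mode)),
            class = "controller_config")
}

#' Inverse-feedforward control law
#'
#' The open-loop input that makes the process output equal `r` at steady
#' state: `u = alpha * r / (beta - delta * r)`.
#'
#' @param r Reference value(s), `0 <= r < beta / delta`.
#' @param inv An [inversion_constants()].
#' @return Control input `u`.
#' @export
ff_law <- function(r, inv) {
  stopifnot(inherits(inv, "inversion_constants"))
  if (any(r < 0)) stop("reference must be non-negative", call. = FALSE)
  if (any(r >= inv$feasible_max)) {
    stop("inversion infeasible: reference >= beta/delta = ",
         format(inv$feasible_max), call. = FALSE)
  }
  inv$alpha * r / (inv$beta - inv$delta * r)
}

#' Taylor approximation of the feedforward law
#'
#' Second-order Taylor expansion of `u(r)` at `r* = 0`:
#' `u ~ Gamma1 * r + Gamma2 * r^2` with `Gamma1 = alpha / beta` and
#' `Gamma2 = alpha * delta / beta^2`. The simplified feedforward controller
#' keeps only the linear coefficient.
#'
#' @param inv An [inversion_constants()].
#' @return List with `Gamma1`, `Gamma2` and `order = 2`, class `taylor_ff`.
#' @export
taylor_ff <- function(inv) {
  stopifnot(inherits(inv, "inversion_constants"))
  structure(list(Gamma1 = inv$alpha / inv$beta,
                 Gamma2 = inv$alpha * inv$delta / inv$beta^2,
                 order = 2L),
            class = "taylor_ff")
}

#' Build the full inverse-feedforward controller CRN
#'
#' Ten reactions in four operator blocks computing
#' `x4 = alpha * r / (beta - delta * r)` at equilibrium:
#' gain alpha (`r -> x1`, 2 reactions), gain delta (`r -> x2`, 2),
#' Subtraction I (`x3 = beta - x2`, 4, with intermediate `xs` and the
#' inversion constant `beta` as a clamped source species), and Division
#' (`x4 = x1 / x3`, 2).
#'
#' @param config A [controller_config()].
#' @param inv An [inversion_constants()].
#' @return A [crn()] (clamped: `r`, `beta`) with a `blocks` attribute.
#' @export
build_full_ff <- function(config, inv) {
  stopifnot(inherits(config, "controller_config"),
            inherits(inv, "inversion_constants"))
  ga <- make_gain(inv$alpha, config$gGa, input = "r", output = "x1",
                  rate_name = "gGa", clamp_inputs = FALSE)
  gd <- make_gain(inv$delta, config$gGd, input = "r", output = "x2",
                  rate_name = "gGd", clamp_inputs = FALSE)
  sb1 <- make_subtraction_onesided(config$gSbI, in1 = "beta", in2 = "x2",
                                   output = "x3", intermediate = "xs",
                                   rate_name = "gSbI", clamp_inputs = FALSE)
  dv <- make_division(config$gD, num = "x1", den = "x3", output = "x4",
                      rate_name = "gD", clamp_inputs = FALSE)
  out <- combine_crn(ga, gd, sb1, dv)
  out$clamped <- c("r", "beta")
  attr(out, "blocks") <- rep(c("gain_alpha", "gain_delta", "subtraction_I",
                               "division"), c(2L, 2L, 4L, 2L))
  attr(out, "beta_value") <- inv$beta
  out
}

#' Build the Taylor-simplified feedforward controller CRN
#'
#' A single gain operator, two reactions: `r -> r + x4` at `Gamma1 * gG` and
#' `x4 -> empty` at `gG`, so `x4 = Gamma1 * r` at equilibrium.
#'
#' @param config A [controller_config()].
#' @param Gamma1 Linear Taylor coefficient (from [taylor_ff()]).
#' @return A [crn()] (clamped: `r`) with a `blocks` attribute.
#' @export
build_simplified_ff <- function(config, Gamma1) {
  stopifnot(inherits(config, "controller_config"))
  out <- make_gain(Gamma1, config$gG, input = "r", output = "x4",
                   rate_name = "gG", clamp_inputs = TRUE)
  attr(out, "blocks") <- rep("gain_simplified", 2L)
  out
}

#' Build the PI feedback chain CRN
#'
#' Thirteen reactions in five blocks: integral gain (`x7 -> x8`, 1),
#' proportional gain (`x7 -> x9`, 2), Summation I (`x10 = x8 + x9`, 3),
#' Subtraction II (`x7 = r - x6`, one-sided, intermediate `xt`, 4), and
#' Summation II (`x5 = x4 + x10`, 3).
#'
#' @param config A [controller_config()].
#' @return A [crn()] with a `blocks` attribute.
#' @export
build_pi_chain <- function(config) {
  stopifnot(inherits(config, "controller_config"))
  ig <- make_integrator(config$KI, input = "x7", output = "x8",
                        rate_name = "KI", clamp_inputs = FALSE)
  pg <- make_proportional(config$KP, config$gGKP, input = "x7",
                          output = "x9", rate_name = "gGKP",
                          clamp_inputs = FALSE)
  sm1 <- make_summation3(config$gSmI, in1 = "x8", in2 = "x9",
                         output = "x10", rate_name = "gSmI",
                         clamp_inputs = FALSE)
  sb2 <- make_subtraction_onesided(config$gSbII, in1 = "r", in2 = "x6",
                                   output = "x7", intermediate = "xt",
                                   rate_name = "gSbII", clamp_inputs = FALSE)
  sm2 <- make_summation3(config$gSmII, in1 = "x4", in2 = "x10",
                         output = "x5", rate_name = "gSmII",
                         clamp_inputs = FALSE)
  out <- combine_crn(ig, pg, sm1, sb2, sm2)
  attr(out, "blocks") <- rep(c("integral", "proportional", "summation_I",
                               "subtraction_II", "summation_II"),
                             c(1L, 2L, 3L, 4L, 3L))
  out
}

#' Assemble the closed-loop tracking circuit
#'
#' Wires controller and process into a single CRN. The reference `r` (and
#' for the full feedforward mode the inversion constant `beta`) are clamped
#' source species; the control species `x5` drives the process binding
#' reaction, catalytically under ideal modularity or consumptively when
#' `retroactivity = TRUE`.
#'
#' Reaction counts: 26 (`full_ff`), 18 (`simplified_ff`), 16 (`pi_only`:
#' the 13-reaction PI chain plus the 3-reaction process; the feedforward
#' branch is absent and its summand `x4` is an inert species at 0).
#'
#' @param mode `"full_ff"`, `"simplified_ff"` or `"pi_only"` (defaults to
#'   `config$mode`).
#' @param config A [controller_config()].
#' @param params A [process_params()]. The inversion constants used by the
#'   feedforward branch are derived from these (the design procedure), while
#'   any later perturbation of the process parameters leaves the controller
#'   at its design values (model mismatch).
#' @param retroactivity Model the plant's loading of the control species.
#' @param inv Optional [inversion_constants()] to use for the controller
#'   design instead of `inversion_constants(params)` (regime-sweep
#'   adjustments).
#' @return An object of class `closed_loop_circuit`: list with `crn`,
#'   `mode`, `wiring`, `config`, `params`, `inv`, `retroactivity`,
#'   `reaction_count`, `blocks` and `init` (initial state: everything 0
#'   except the free enzyme at `xT`).
#' @export
assemble_closed_loop <- function(mode = NULL, config = controller_config(),
                                 params = process_params(),
                                 retroactivity = FALSE, inv = NULL) {
  stopifnot(inherits(config, "controller_config"),
            inherits(params, "process_params"))
  if (is.null(mode)) mode <- config$mode
  mode <- match.arg(mode, c("full_ff", "simplified_ff", "pi_only"))
  if (is.null(inv)) inv <- inversion_constants(params)

  ff <- switch(mode,
    full_ff = build_full_ff(config, inv),
    simplified_ff = build_simplified_ff(config, taylor_ff(inv)$Gamma1),
    pi_only = NULL)
  pi <- build_pi_chain(config)
  proc <- make_process(params, input = "x5", output = "x6",
                       catalytic_input = !retroactivity, clamp_input = FALSE)

  net <- if (is.null(ff)) combine_crn(pi, proc) else combine_crn(ff, pi, proc)
  clamped <- "r"
  if (mode == "full_ff") clamped <- c("r", "beta")
  net$clamped <- clamped

  blocks <- c(if (!is.null(ff)) attr(ff, "blocks"), attr(pi, "blocks"),
              rep("process", 3L))
  init <- stats::setNames(rep(0, length(net$species)), net$species)
  init["xe"] <- params$xT
  if (mode == "full_ff") init["beta"] <- inv$beta

  structure(
    list(crn = net, mode = mode,
         wiring = list(reference = "r", control = "x5", output = "x6",
                       ff_out = "x4", pi_out = "x10", error = "x7"),
         config = config, params = params, inv = inv,
         retroactivity = retroactivity,
         reaction_count = length(net$reactions),
         blocks = blocks, init = init),
    class = "closed_loop_circuit"
  )
}

#' @export
print.closed_loop_circuit <- function(x, ...) {
  cat(sprintf(
    "closed-loop circuit [%s]: %d reactions, %d species%s\n", x$mode,
    x$reaction_count, length(x$crn$species),
    if (x$retroactivity) ", retroactivity on" else ""))
  invisible(x)
}

#' Count reactions in a circuit, per operator block
#'
#' @param circuit A `closed_loop_circuit` (or a `crn`).
#' @return List with `total` and `by_block` (named integer vector; single
#'   block `"crn"` for a bare CRN).
#' @export
count_reactions <- function(circuit) {
  if (inherits(circuit, "crn")) {
    blocks <- attr(circuit, "blocks")
    if (is.null(blocks)) blocks <- rep("crn", length(circuit$reactions))
    tab <- table(factor(blocks, levels = unique(blocks)))
    return(list(total = length(circuit$reactions),
                by_block = stats::setNames(as.integer(tab), names(tab))))
  }
  stopifnot(inherits(circuit, "closed_loop_circuit"))
  tab <- table(factor(circuit$blocks, levels = unique(circuit$blocks)))
  list(total = circuit$reaction_count,
       by_block = stats::setNames(as.integer(tab), names(tab)))
}

#' Percent reduction in reaction count
#'
#' `round((a - b) / a * 100)`, e.g. 26 -> 18 reactions is a 31% reduction.
#'
#' @param a,b Reaction counts (before, after).
#' @return Integer percentage.
#' @export
percent_reduction <- function(a, b) {
  stopifnot(a > 0)
  as.integer(round((a - b) / a * 100))
}
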