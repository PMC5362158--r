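#' Enzymatic reaction process parameters
#'
#' The controlled plant is the minimal enzymatic reaction process: substrate
#' `x_in` binds free enzyme `x_e` to form the complex `x_i` (rate `kr1`), the
#' complex turns over into product `x_out` releasing the enzyme (rate `kr2`),
#' and the product degrades (rate `kr3`). Total enzyme `x_T = x_e + x_i` is
#' conserved. Literature values span several orders of magnitude: `kr1` in
#' [1e-9, 1e6], `kr2` in [1e-2, 1e2], `kr3` in [1e-5, 1e-3].
#'
#' @param kr1 Binding rate (> 0).
#' @param kr2 Catalytic rate (> 0).
#' @param kr3 Degradation rate (> 0).
#' @param xT Total enzyme concentration (> 0).
#' @return An object of class `process_params`. Defaults are the nominal
#'   design values.
#' @export
process_params <- function(kr1 = 0.005, kr2 = 1.6, kr3 = 0.0008, xT = 5.5) {
  vals <- c(kr1 = kr1, kr2 = kr2, kr3 = kr3, xT = xT)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all process parameters (kr1, kr2, kr3, xT) must be positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("enzymatic process: kr1=%g kr2=%g kr3=%g xT=%g\n",
              x$kr1, x$kr2, x$kr3, x$xT))
  invisible(x)
}

#' Build the enzymatic process CRN
#'
#' Three reactions: `input + enzyme -> complex` (`kr1`),
#' `complex -> output + enzyme` (`kr2`), `output -> empty` (`kr3`). The
#' enzyme starts at `xT` (see the `init` attribute) and `x_e + x_i` is
#' conserved along every trajectory.
#'
#' When the process is wired downstream of a controller, `catalytic_input =
#' TRUE` makes the binding reaction read the input catalytically
#' (`input + enzyme -> complex + input`), i.e. the ideal-modularity
#' assumption in which the controller output is buffered and the plant does
#' not load it. With `catalytic_input = FALSE` the binding reaction consumes
#' the input, which adds the retroactivity term `-kr1 * input * x_e` to the
#' input's own dynamics.
#'
#' @param params A [process_params()].
#' @param input,output,enzyme,complex Species names (defaults follow the
#'   closed-loop wiring `x5 -> x6`).
#' @param catalytic_input See description.
#' @param clamp_input Clamp the input (open-loop use).
#' @return A [crn()] with an `init` attribute (named initial concentrations).
#' @export
make_process <- function(params, input = "x5", output = "x6",
                         enzyme = "xe", complex = "xi",
                         catalytic_input = FALSE, clamp_input = TRUE) {
  stopifnot(inherits(params, "process_params"))
  bind_products <- if (catalytic_input) c(complex, input) else complex
  x <- crn(list(
    reaction(c(input, enzyme), bind_products, rate = params$kr1,
             name = "kr1"),
    reaction(complex, c(output, enzyme), rate = params$kr2, name = "kr2"),
    reaction(output, character(), rate = params$kr3, name = "kr3")
  ), clamped = if (clamp_input) input else character())
  attr(x, "init") <- stats::setNames(params$xT, enzyme)
  attr(x, "process") <- list(params = params, input = input, output = output,
                             enzyme = enzyme, complex = complex,
                             catalytic_input = catalytic_input)
  x
}

#' Steady-state inversion constants of the enzymatic process
#'
#' At steady state the process input-output map is
#' `x_in = alpha * x_out / (beta - delta * x_out)` with
#' `alpha = kr2 * kr3`, `beta = kr1 * kr2 * xT`, `delta = kr1 * kr3`.
#' Feasible outputs satisfy `x_out < beta / delta = kr2 * xT / kr3`.
#'
#' @param params A [process_params()].
#' @return An object of class `inversion_constants`: list with `alpha`,
#'   `beta`, `delta` and `feasible_max = beta / delta`.
#' @export
inversion_constants <- function(params) {
  stopifnot(inherits(params, "process_params"))
  alpha <- params$kr2 * params$kr3
  beta <- params$kr1 * params$kr2 * params$xT
  delta <- params$kr1 * params$kr3
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 feasible_max = beta / delta),
            class = "inversion_constants")
}

#' @export
print.inversion_constants <- function(x, ...) {
  cat(sprintf(
    "inversion constants: alpha=%g beta=%g delta=%g (feasible x_out < %g)\n",
    x$alpha, x$beta, x$delta, x$feasible_max))
  invisible(x)
}

#' Toggle retroactivity on an assembled closed-loop circuit
#'
#' Rebuilds the circuit with the plant's binding reaction consuming the
#' control species directly (retroactivity on) or reading it catalytically
#' (ideal modularity, the default in [assemble_closed_loop()]). With
#' retroactivity on, the control species' ODE gains the loading term
#' `-kr1 * x5 * x_e`.
#'
#' @param circuit A `closed_loop_circuit`.
#' @param retroactivity Logical.
#' @return A `closed_loop_circuit`.
#' @export
add_retroactivity <- function(circuit, retroactivity = TRUE) {
  stopifnot(inherits(circuit, "closed_loop_circuit"))
  assemble_closed_loop(mode = circuit$mode, config = circuit$config,
                       params = circuit$params,
                       retroactivity = retroactivity)
}
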