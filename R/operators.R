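#' Biomolecular arithmetic operator motifs
#'
#' Factories for the CRN motifs that realise arithmetic on concentrations:
#' gain (scalar multiplication), three-reaction summation, one-sided
#' subtraction, division, pure integration, proportional gain, and the
#' dual-rail (positive/negative component) summation and subtraction. Each
#' factory returns a [crn()] whose equilibrium implements the operation for
#' constant inputs; the input species are clamped by default so a motif can
#' be studied in isolation, and left free (`clamp_inputs = FALSE`) when the
#' motif is wired into a larger circuit.
#'
#' Reaction counts per motif are structural: gain 2, summation 3, one-sided
#' subtraction 4, division 2, integrator 1, proportional 2, dual-rail kinds
#' 9 each.
#'
#' @name operators
NULL

operator_attr <- function(x, kind, io, label = NULL) {
  attr(x, "operator") <- list(kind = kind, io = io, label = label)
  x
}

#' Reaction counts of the operator motifs
#' @return Named integer vector.
#' @export
operator_reaction_counts <- function() {
  c(gain = 2L, summation3 = 3L, subtraction_onesided = 4L, division = 2L,
    integrator = 1L, proportional = 2L, summation_dualrail = 9L,
    subtraction_dualrail = 9L)
}

#' @describeIn operators Gain: equilibrium `out = k * in`. Two reactions,
#'   `in -> in + out` at rate `k * gamma` and `out -> empty` at `gamma`, so
#'   d(out)/dt = gamma (k in - out).
#' @param k Gain constant (>= 0).
#' @param gamma Operator reaction rate (> 0).
#' @param input,output Species names.
#' @param rate_name Base name for the rate constants.
#' @param clamp_inputs Clamp the input species (default `TRUE`).
#' @export
make_gain <- function(k, gamma, input = "u", output = "y",
                      rate_name = "gG", clamp_inputs = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop("gain constant `k` must be a single non-negative number",
         call. = FALSE)
  }
  stopifnot(gamma > 0)
  x <- crn(list(
    reaction(input, c(input, output), rate = k * gamma,
             name = paste0(rate_name, "_k")),
    reaction(output, character(), rate = gamma, name = rate_name)
  ), clamped = if (clamp_inputs) input else character())
  operator_attr(x, "gain", list(input = input, output = output, k = k,
                                gamma = gamma))
}

#' @describeIn operators Proportional gain: structurally identical to
#'   [make_gain()] with `k = KP`.
#' @param KP Proportional gain.
#' @export
make_proportional <- function(KP, gamma, input = "u", output = "y",
                              rate_name = "gGKP", clamp_inputs = TRUE) {
  x <- make_gain(KP, gamma, input = input, output = output,
                 rate_name = rate_name, clamp_inputs = clamp_inputs)
  operator_attr(x, "proportional", attr(x, "operator")$io)
}

#' @describeIn operators Three-reaction summation: equilibrium
#'   `out = in1 + in2` without any dual-rail encoding, via
#'   `in1 -> in1 + out`, `in2 -> in2 + out`, `out -> empty`, all at `gamma`.
#' @param in1,in2 Input species names.
#' @export
make_summation3 <- function(gamma, in1 = "x1", in2 = "x2", output = "y",
                            rate_name = "gSm", clamp_inputs = TRUE) {
  stopifnot(gamma > 0)
  x <- crn(list(
    reaction(in1, c(in1, output), rate = gamma, name = rate_name),
    reaction(in2, c(in2, output), rate = gamma, name = rate_name),
    reaction(output, character(), rate = gamma, name = rate_name)
  ), clamped = if (clamp_inputs) c(in1, in2) else character())
  operator_attr(x, "summation3",
                list(in1 = in1, in2 = in2, output = output, gamma = gamma))
}

#' @describeIn operators One-sided subtraction: four reactions whose
#'   equilibrium is `out = in1 - in2` when `in1 >= in2` and `out -> 0`
#'   otherwise. In the deficit case the intermediate species grows without
#'   settling: there is no finite fixed point, and [steady_state()] reports
#'   `converged = FALSE`. This clipping is structural -- no standard
#'   single-rail CRN motif can produce a negative equilibrium concentration,
#'   which is the limitation the dual-rail encoding works around.
#' @param intermediate Name of the intermediate species.
#' @export
make_subtraction_onesided <- function(gamma, in1 = "xi1", in2 = "xi2",
                                      output = "xo", intermediate = "xitd",
                                      rate_name = "gSb",
                                      clamp_inputs = TRUE) {
  stopifnot(gamma > 0)
  x <- crn(list(
    reaction(in1, c(in1, output), rate = gamma, name = rate_name),
    reaction(c(intermediate, output), character(), rate = gamma,
             name = rate_name),
    reaction(in2, c(in2, intermediate), rate = gamma, name = rate_name),
    reaction(output, character(), rate = gamma, name = rate_name)
  ), clamped = if (clamp_inputs) c(in1, in2) else character())
  operator_attr(x, "subtraction_onesided",
                list(in1 = in1, in2 = in2, output = output,
                     intermediate = intermediate, gamma = gamma))
}

#' @describeIn operators Division: two reactions with equilibrium
#'   `out = num / den` for constant `den > 0`
#'   (d(out)/dt = gamma (num - den * out)).
#' @param num,den Numerator / denominator species names.
#' @export
make_division <- function(gamma, num = "x1", den = "x3", output = "x4",
                          rate_name = "gD", clamp_inputs = TRUE) {
  stopifnot(gamma > 0)
  x <- crn(list(
    reaction(num, c(num, output), rate = gamma, name = rate_name),
    reaction(c(den, output), den, rate = gamma, name = rate_name)
  ), clamped = if (clamp_inputs) c(num, den) else character())
  operator_attr(x, "division",
                list(num = num, den = den, output = output, gamma = gamma))
}

#' @describeIn operators Pure integrator: a single catalytic reaction
#'   `in -> in + out` at rate `KI`, i.e. d(out)/dt = KI * in with no
#'   degradation.
#' @param KI Integral gain (> 0).
#' @export
make_integrator <- function(KI, input = "u", output = "y",
                            rate_name = "KI", clamp_inputs = TRUE) {
  stopifnot(KI > 0)
  x <- crn(list(
    reaction(input, c(input, output), rate = KI, name = rate_name)
  ), clamped = if (clamp_inputs) input else character())
  operator_attr(x, "integrator",
                list(input = input, output = output, KI = KI))
}

#' @describeIn operators Dual-rail summation or subtraction: every signal is
#'   encoded as the difference of a positive and a negative species
#'   (`u = u+ - u-`) with fast annihilation `u+ + u- -> empty` at rate
#'   `eta >> gamma`. Nine reactions per operator. For `kind = "subtraction"`
#'   the equilibrium of `out+ - out-` is `in1 - in2` regardless of sign,
#'   which is what the one-sided motif cannot do.
#' @param kind `"summation"` or `"subtraction"`.
#' @param eta Annihilation rate; the contract requires `eta >> gamma`
#'   (warning below `100 * gamma`; default `1000 * gamma`).
#' @param in1_pos,in1_neg,in2_pos,in2_neg,out_pos,out_neg Rail species names.
#' @export
make_dualrail <- function(kind = c("summation", "subtraction"), gamma,
                          eta = 1000 * gamma,
                          in1_pos = "xi1p", in1_neg = "xi1m",
                          in2_pos = "xi2p", in2_neg = "xi2m",
                          out_pos = "xop", out_neg = "xom",
                          rate_name = "g", clamp_inputs = TRUE) {
  kind <- match.arg(kind)
  stopifnot(gamma > 0, eta > 0)
  if (eta <= gamma) {
    warning("dual-rail contract degraded: eta <= gamma", call. = FALSE)
  } else if (eta < 100 * gamma) {
    warning("dual-rail annihilation rate eta < 100 * gamma; ",
            "equilibrium contract may be inaccurate", call. = FALSE)
  }
  # for subtraction the second input's rails feed the opposite output rails
  to_pos <- if (kind == "summation") out_pos else out_neg
  to_neg <- if (kind == "summation") out_neg else out_pos
  x <- crn(list(
    reaction(in1_pos, c(in1_pos, out_pos), rate = gamma, name = rate_name),
    reaction(in1_neg, c(in1_neg, out_neg), rate = gamma, name = rate_name),
    reaction(c(in1_pos, in1_neg), character(), rate = eta, name = "eta"),
    reaction(in2_pos, c(in2_pos, to_pos), rate = gamma, name = rate_name),
    reaction(in2_neg, c(in2_neg, to_neg), rate = gamma, name = rate_name),
    reaction(c(in2_pos, in2_neg), character(), rate = eta, name = "eta"),
    reaction(out_pos, character(), rate = gamma, name = rate_name),
    reaction(out_neg, character(), rate = gamma, name = rate_name),
    reaction(c(out_pos, out_neg), character(), rate = eta, name = "eta")
  ), clamped = if (clamp_inputs) c(in1_pos, in1_neg, in2_pos, in2_neg)
      else character())
  operator_attr(x, paste0(kind, "_dualrail"),
                list(in1 = c(in1_pos, in1_neg), in2 = c(in2_pos, in2_neg),
                     output = c(out_pos, out_neg), gamma = gamma, eta = eta))
}
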