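#' Perturbable parameters of a closed-loop circuit
#'
#' The robustness and sensitivity analyses perturb every occurrence of a
#' rate constant in the closed-loop ODEs independently: an operator rate that
#' appears in, say, five ODE terms (like the Subtraction II rate) is split
#' into five independently perturbable parameters, indexed in the order the
#' terms appear in the ODEs. This is finer than perturbing per reaction -- a
#' single bimolecular annihilation reaction contributes one term to each of
#' two state equations, and the two get independent multipliers -- so the
#' perturbation acts on per-(species, reaction) multipliers of the
#' stoichiometric matrix rather than on the rate constants. The PI gains and
#' the three process rates are single (unsplit) parameters.
#'
#' @param circuit A `closed_loop_circuit`.
#' @return Data frame with columns `name`, `type` (`"term"` or `"rate"`),
#'   `species` (for terms) and `rxn` (reaction index).
#' @export
perturbation_targets <- function(circuit) {
  stopifnot(inherits(circuit, "closed_loop_circuit"))
  net <- circuit$crn
  f <- function(reactants, products) find_rxn(net, reactants, products)
  term <- function(name, species, reactants, products) {
    data.frame(name = name, type = "term", species = species,
               rxn = f(reactants, products), stringsAsFactors = FALSE)
  }
  rate <- function(name, reactants, products) {
    data.frame(name = name, type = "rate", species = NA_character_,
               rxn = f(reactants, products), stringsAsFactors = FALSE)
  }

  pi_part <- rbind(
    term("gGKP_1", "x9", "x7", c("x7", "x9")),
    term("gGKP_2", "x9", "x9", character()),
    term("gSmI_1", "x10", "x8", c("x8", "x10")),
    term("gSmI_2", "x10", "x9", c("x9", "x10")),
    term("gSmI_3", "x10", "x10", character()),
    term("gSbII_1", "x7", "r", c("r", "x7")),
    term("gSbII_2", "x7", c("xt", "x7"), character()),
    term("gSbII_3", "x7", "x7", character()),
    term("gSbII_4", "xt", "x6", c("x6", "xt")),
    term("gSbII_5", "xt", c("xt", "x7"), character()),
    term("gSmII_1", "x5", "x4", c("x4", "x5")),
    term("gSmII_2", "x5", "x10", c("x10", "x5")),
    term("gSmII_3", "x5", "x5", character()),
    term("KP", "x9", "x7", c("x7", "x9")),
    term("KI", "x8", "x7", c("x7", "x8"))
  )

  bind_products <- if (circuit$retroactivity) "xi" else c("xi", "x5")
  proc_part <- rbind(
    rate("kr1", c("x5", "xe"), bind_products),
    rate("kr2", "xi", c("x6", "xe")),
    rate("kr3", "x6", character())
  )

  ff_part <- switch(circuit$mode,
    full_ff = rbind(
      term("gGa_1", "x1", "r", c("r", "x1")),
      term("gGa_2", "x1", "x1", character()),
      term("gGd_1", "x2", "r", c("r", "x2")),
      term("gGd_2", "x2", "x2", character()),
      term("gSbI_1", "x3", "beta", c("beta", "x3")),
      term("gSbI_2", "x3", c("xs", "x3"), character()),
      term("gSbI_3", "x3", "x3", character()),
      term("gSbI_4", "xs", "x2", c("x2", "xs")),
      term("gSbI_5", "xs", c("xs", "x3"), character()),
      term("gD_1", "x4", "x1", c("x1", "x4")),
      term("gD_2", "x4", c("x3", "x4"), "x3")
    ),
    simplified_ff = rbind(
      term("gG_1", "x4", "r", c("r", "x4")),
      term("gG_2", "x4", "x4", character())
    ),
    pi_only = NULL)

  out <- rbind(ff_part, pi_part, proc_part)
  rownames(out) <- out$name
  out
}

# exact multiset match of reactants (and products if given)
find_rxn <- function(net, reactants, products = NULL) {
  want_r <- as_species_multiset(reactants, "reactants")
  want_p <- if (is.null(products)) NULL else
    as_species_multiset(products, "products")
  same <- function(a, b) {
    length(a) == length(b) && setequal(names(a), names(b)) &&
      all(a[names(b)] == b)
  }
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (!same(r$reactants, want_r)) next
    if (!is.null(want_p) && !same(r$products, want_p)) next
    return(j)
  }
  stop("no reaction with reactants {",
       paste(names(want_r), collapse = ","), "} found", call. = FALSE)
}

#' Per-ODE-term multiplier matrix for a set of parameter factors
#'
#' Builds the (full species x reactions) multiplier matrix consumed by
#' [simulate()]'s `term_scale`: `"term"` parameters scale a single
#' (species, reaction) stoichiometric entry, `"rate"` parameters scale the
#' whole reaction column (equivalent to scaling the rate constant).
#'
#' @param circuit A `closed_loop_circuit`.
#' @param factors Named numeric vector of multiplicative factors; names must
#'   be parameter names from [perturbation_targets()].
#' @return Numeric matrix.
#' @export
term_scale_matrix <- function(circuit, factors) {
  targets <- perturbation_targets(circuit)
  unknown <- setdiff(names(factors), targets$name)
  if (length(unknown) > 0L) {
    stop("unknown perturbation parameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  net <- circuit$crn
  M <- matrix(1, length(net$species), length(net$reactions),
              dimnames = list(net$species, NULL))
  for (nm in names(factors)) {
    tg <- targets[targets$name == nm, ]
    if (tg$type == "term") {
      M[tg$species, tg$rxn] <- M[tg$species, tg$rxn] * factors[[nm]]
    } else {
      M[, tg$rxn] <- M[, tg$rxn] * factors[[nm]]
    }
  }
  M
}
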