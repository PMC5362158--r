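#' Define an abstract chemical reaction
#'
#' A reaction is a multiset of reactant species transformed into a multiset of
#' product species at a mass-action rate constant. Reactions are restricted to
#' at most two reactant molecules (unimolecular or bimolecular), the standard
#' setting for CRN-based circuit design and for DNA strand-displacement
#' implementation; higher orders are rejected unless explicitly allowed.
#'
#' @param reactants Reactant side: either a character vector of species names
#'   (repeats give stoichiometry, e.g. `c("X", "X")`) or a named integer
#'   vector of coefficients, e.g. `c(X = 2)`. Empty for a source reaction.
#' @param products Product side, same formats as `reactants`. Empty for a
#'   degradation reaction.
#' @param rate Non-negative rate constant.
#' @param name Identifier for the rate constant (e.g. `"gSbII"`). Defaults to
#'   `"k"`.
#' @param allow_termolecular If `TRUE`, skip the bimolecularity check.
#' @return An object of class `crn_reaction`.
#' @examples
#' reaction(c("xi1"), c("xi1", "xo"), rate = 1, name = "gamma")
#' reaction(c("xitd", "xo"), character(), rate = 1, name = "gamma")
#' @export
reaction <- function(reactants = character(), products = character(),
                     rate = 1, name = "k", allow_termolecular = FALSE) {
  reactants <- as_species_multiset(reactants, "reactants")
  products <- as_species_multiset(products, "products")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate)) {
    stop("`rate` must be a single number", call. = FALSE)
  }
  if (rate < 0) {
    stop("negative rate constant for reaction rate '", name, "'",
         call. = FALSE)
  }
  if (!allow_termolecular && sum(reactants) > 2L) {
    stop("reaction has ", sum(reactants), " reactant molecules; only ",
         "unimolecular and bimolecular reactions are supported ",
         "(set allow_termolecular = TRUE to override)", call. = FALSE)
  }
  structure(
    list(reactants = reactants, products = products,
         rate_name = as.character(name), rate_value = as.numeric(rate)),
    class = "crn_reaction"
  )
}

as_species_multiset <- function(x, what) {
  if (is.null(x) || length(x) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (is.character(x)) {
    tab <- table(x)
    out <- stats::setNames(as.integer(tab), names(tab))
    # preserve first-appearance order
    out <- out[unique(x)]
    return(out)
  }
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("`", what, "` given as numbers must be named by species",
           call. = FALSE)
    }
    if (any(x < 0) || any(x != round(x))) {
      stop("stoichiometric coefficients in `", what,
           "` must be non-negative integers", call. = FALSE)
    }
    x <- x[x > 0]
    return(stats::setNames(as.integer(x), names(x)))
  }
  stop("`", what, "` must be a character or named numeric vector",
       call. = FALSE)
}

#' @export
format.crn_reaction <- function(x, ...) {
  side <- function(s) {
    if (length(s) == 0L) return("empty")
    paste(ifelse(s > 1L, paste0(s, " ", names(s)), names(s)), collapse = " + ")
  }
  sprintf("%s -> %s @ %s=%g", side(x$reactants), side(x$products),
          x$rate_name, x$rate_value)
}

#' @export
print.crn_reaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build a chemical reaction network
#'
#' Collects reactions into a CRN with a deterministic species ordering
#' (first-appearance order over reactants then products, reaction by
#' reaction), so stoichiometric matrices are reproducible. Species listed in
#' `clamped` are held at a constant (or piecewise-constant, see
#' [simulate()]) concentration: they contribute to reaction rates but have no
#' state equation. This is how constant sources such as a reference signal
#' `r` enter the network catalytically.
#'
#' @param reactions List of [reaction()] objects (possibly empty).
#' @param clamped Character vector of species names to clamp. Each must occur
#'   in some reaction.
#' @param species Optional character vector of extra species to include (for
#'   species that appear in no reaction but should be tracked).
#' @return An object of class `crn`.
#' @export
crn <- function(reactions = list(), clamped = character(),
                species = character()) {
  if (inherits(reactions, "crn_reaction")) reactions <- list(reactions)
  if (!is.list(reactions) ||
      !all(vapply(reactions, inherits, logical(1), "crn_reaction"))) {
    stop("`reactions` must be a list of reaction() objects", call. = FALSE)
  }
  sp <- as.character(species)
  for (r in reactions) sp <- c(sp, names(r$reactants), names(r$products))
  sp <- unique(sp)
  clamped <- unique(as.character(clamped))
  unknown <- setdiff(clamped, sp)
  if (length(unknown) > 0L) {
    stop("clamped species not present in any reaction: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(species = sp, reactions = reactions, clamped = clamped),
    class = "crn"
  )
}

#' @export
print.crn <- function(x, ...) {
  cat(sprintf("CRN: %d species, %d reactions", length(x$species),
              length(x$reactions)))
  if (length(x$clamped) > 0L) {
    cat(" (clamped: ", paste(x$clamped, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  for (r in x$reactions) cat("  ", format(r), "\n", sep = "")
  invisible(x)
}

#' Number of reactions in a CRN or circuit
#' @param x A `crn` or `closed_loop_circuit`.
#' @return Integer count.
#' @export
n_reactions <- function(x) {
  if (inherits(x, "closed_loop_circuit")) x <- x$crn
  length(x$reactions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge several CRNs into one
#'
#' Species are merged by name (insertion order preserved), reactions
#' concatenated, clamped sets unioned. Shared species names are how operator
#' blocks are wired together.
#'
#' @param ... `crn` objects.
#' @return A `crn`.
#' @export
combine_crn <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  stopifnot(all(vapply(parts, inherits, logical(1), "crn")))
  rxns <- do.call(c, lapply(parts, function(p) p$reactions))
  clamped <- unique(do.call(c, lapply(parts, function(p) p$clamped)))
  extra <- unique(do.call(c, lapply(parts, function(p) p$species)))
  crn(rxns, clamped = clamped, species = extra)
}

#' Prefix the species of a CRN with an instance label
#'
#' Supports composing several copies of the same operator motif without name
#' collisions: every species except those in `except` (shared input/output
#' wires, clamped sources) is renamed to `label.species`.
#'
#' @param x A `crn`.
#' @param label Instance label (prefix).
#' @param except Species names to leave untouched.
#' @return A `crn` with renamed species.
#' @export
namespace_crn <- function(x, label, except = character()) {
  stopifnot(inherits(x, "crn"))
  ren <- function(nm) ifelse(nm %in% except, nm, paste0(label, ".", nm))
  rxns <- lapply(x$reactions, function(r) {
    names(r$reactants) <- ren(names(r$reactants))
    names(r$products) <- ren(names(r$products))
    r
  })
  crn(rxns, clamped = ren(x$clamped), species = ren(x$species))
}

#' Stoichiometric matrix of a CRN
#'
#' Entry (i, j) is the net production of species i in reaction j (products
#' minus reactants); purely catalytic appearances cancel to 0. By default the
#' rows are the non-clamped (dynamic) species, matching the state equations
#' dx/dt = P f(x); clamped sources have no row.
#'
#' @param x A `crn`.
#' @param full If `TRUE`, include rows for clamped species as well.
#' @return Integer matrix with species row names and reaction column names.
#' @export
stoich_matrix <- function(x, full = FALSE) {
  stopifnot(inherits(x, "crn"))
  n <- length(x$species)
  m <- length(x$reactions)
  P <- matrix(0L, n, m,
              dimnames = list(x$species,
                              if (m > 0) paste0("R", seq_len(m)) else NULL))
  for (j in seq_len(m)) {
    r <- x$reactions[[j]]
    P[names(r$reactants), j] <- P[names(r$reactants), j] - r$reactants
    P[names(r$products), j] <- P[names(r$products), j] + r$products
  }
  if (!full && length(x$clamped) > 0L) {
    P <- P[setdiff(x$species, x$clamped), , drop = FALSE]
  }
  P
}

#' Reactant-order matrix of a CRN
#'
#' Row j gives the reactant stoichiometry of reaction j; the mass-action rate
#' is `rate_j = k_j * prod(x ^ order[j, ])`.
#'
#' @param x A `crn`.
#' @return Integer matrix, reactions by species.
#' @export
order_matrix <- function(x) {
  stopifnot(inherits(x, "crn"))
  n <- length(x$species)
  m <- length(x$reactions)
  O <- matrix(0L, m, n,
              dimnames = list(if (m > 0) paste0("R", seq_len(m)) else NULL,
                              x$species))
  for (j in seq_len(m)) {
    r <- x$reactions[[j]]
    O[j, names(r$reactants)] <- r$reactants
  }
  O
}

#' Mass-action reaction rates at a state
#'
#' @param x A `crn`.
#' @param conc Concentration vector: either named, or positional in the order
#'   of `x$species`. All entries must be non-negative.
#' @return Numeric vector of length `n_reactions(x)`.
#' @export
mass_action_rates <- function(x, conc) {
  stopifnot(inherits(x, "crn"))
  conc <- full_state(x$species, conc)
  if (any(conc < 0)) {
    stop("negative concentration in `conc`", call. = FALSE)
  }
  O <- order_matrix(x)
  k <- vapply(x$reactions, function(r) r$rate_value, numeric(1))
  if (length(k) == 0L) return(numeric(0))
  as.numeric(k * apply(O, 1L, function(o) prod(conc^o)))
}

full_state <- function(species, conc, default = 0) {
  if (is.null(names(conc))) {
    if (length(conc) != length(species)) {
      stop("unnamed concentration vector must have length ", length(species),
           call. = FALSE)
    }
    return(stats::setNames(as.numeric(conc), species))
  }
  unknown <- setdiff(names(conc), species)
  if (length(unknown) > 0L) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep(as.numeric(default), length(species)), species)
  out[names(conc)] <- as.numeric(conc)
  out
}
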