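#' DNA strand-displacement compilation parameters
#'
#' Abstract uni/bimolecular reactions are emulated by toehold-mediated
#' strand displacement using auxiliary DNA species held in large excess
#' `C_max`. Partial displacement steps run at rate `q = k_b / C_max`, full
#' displacement at the maximum rate `q_max`; the emulation is kinetically
#' faithful in the limit `C_max >>` signal concentrations.
#'
#' @param C_max Auxiliary (fuel) initial concentration. Default: `1e4` times
#'   `signal_scale`.
#' @param q_max Maximum strand displacement rate. Default: `1e3` times
#'   `rate_scale`.
#' @param signal_scale Largest expected signal concentration.
#' @param rate_scale Largest source-reaction rate constant.
#' @return An object of class `dsd_params`.
#' @export
dsd_params <- function(C_max = 1e4 * signal_scale,
                       q_max = 1e3 * rate_scale,
                       signal_scale = 1, rate_scale = 1) {
  stopifnot(C_max > 0, q_max > 0)
  structure(list(C_max = C_max, q_max = q_max), class = "dsd_params")
}

aux_name <- function(index, what) sprintf("dsd%d.%s", index, what)

#' Compile one unimolecular reaction to strand displacement
#'
#' A source reaction `X -> products` at rate `k` becomes two implementation
#' steps with three auxiliaries G, O, T:
#' `X + G -> O` at `q` and `O + T -> products` at `q_max`. The fuels G and T
#' start at `C_max`, the intermediate O at 0, and `q` is chosen as
#' `k / C_max` so that the pseudo-first-order rate at `G ~ C_max` equals the
#' source rate.
#'
#' @param rxn A unimolecular [reaction()].
#' @param params A [dsd_params()].
#' @param index Source-reaction index (namespaces the auxiliaries).
#' @return List with `steps` (reactions), `aux` (data frame of auxiliary
#'   species with initial concentrations and roles) and `n_steps = 2`.
#' @export
compile_unimolecular <- function(rxn, params, index = 1L) {
  stopifnot(inherits(rxn, "crn_reaction"), inherits(params, "dsd_params"))
  if (sum(rxn$reactants) != 1L) {
    stop("not unimolecular: ", format(rxn), call. = FALSE)
  }
  X <- names(rxn$reactants)
  G <- aux_name(index, "G")
  O <- aux_name(index, "O")
  Tt <- aux_name(index, "T")
  q <- rxn$rate_value / params$C_max
  if (q > params$q_max) {
    stop("required q exceeds q_max for reaction ", format(rxn),
         call. = FALSE)
  }
  steps <- list(
    reaction(c(X, G), O, rate = q, name = paste0("q", index)),
    reaction(c(O, Tt), rxn$products, rate = params$q_max, name = "qmax")
  )
  aux <- data.frame(
    species = c(G, O, Tt),
    initial = c(params$C_max, 0, params$C_max),
    role = c("fuel", "intermediate", "fuel"),
    source = index, stringsAsFactors = FALSE)
  list(steps = steps, aux = aux, n_steps = 2L)
}

#' Compile one bimolecular reaction to strand displacement
#'
#' A source reaction `X + Y -> products` at rate `k` becomes three
#' implementation steps with five auxiliaries L, H, B, O, T, the first step
#' reversible:
#' `X + L <-> H + B` (forward `q`, backward `q_max`),
#' `Y + H -> O` at `q_max`, and `O + T -> products` at `q_max`.
#' The fuels L, B, T start at `C_max`, the intermediates H and O at 0, and
#' the forward constant is `q = k` (with the back-strand B buffered at
#' `C_max`, the net flux through the reversible step is `k * X * Y` in the
#' large-`C_max` limit).
#'
#' For `X + X -> products` the second molecule plays the role of Y.
#'
#' @inheritParams compile_unimolecular
#' @return List with `steps` (4 irreversible reactions realising 3 steps),
#'   `aux` and `n_steps = 3`.
#' @export
compile_bimolecular <- function(rxn, params, index = 1L) {
  stopifnot(inherits(rxn, "crn_reaction"), inherits(params, "dsd_params"))
  if (sum(rxn$reactants) != 2L) {
    stop("not bimolecular: ", format(rxn), call. = FALSE)
  }
  sp <- rep(names(rxn$reactants), rxn$reactants)
  X <- sp[1L]
  Y <- sp[2L]
  L <- aux_name(index, "L")
  H <- aux_name(index, "H")
  B <- aux_name(index, "B")
  O <- aux_name(index, "O")
  Tt <- aux_name(index, "T")
  q <- rxn$rate_value
  if (q > params$q_max) {
    stop("required q exceeds q_max for reaction ", format(rxn),
         call. = FALSE)
  }
  steps <- list(
    reaction(c(X, L), c(H, B), rate = q, name = paste0("q", index)),
    reaction(c(H, B), c(X, L), rate = params$q_max, name = "qmax"),
    reaction(c(Y, H), O, rate = params$q_max, name = "qmax"),
    reaction(c(O, Tt), rxn$products, rate = params$q_max, name = "qmax")
  )
  aux <- data.frame(
    species = c(L, H, B, O, Tt),
    initial = c(params$C_max, 0, params$C_max, 0, params$C_max),
    role = c("fuel", "intermediate", "fuel", "intermediate", "fuel"),
    source = index, stringsAsFactors = FALSE)
  list(steps = steps, aux = aux, n_steps = 3L)
}

#' Compile a CRN to a DNA strand-displacement implementation
#'
#' Compiles every (uni- or bimolecular) reaction of a CRN; each source
#' reaction gets its own fresh set of auxiliary species. Waste strands are
#' not tracked (they are dynamically inert).
#'
#' @param x A [crn()]. Every reaction must be uni- or bimolecular.
#' @param params A [dsd_params()]; by default sized from the CRN's largest
#'   rate constant.
#' @return A `dsd_program`: list with `crn` (the implementation network,
#'   clamping preserved), `aux` (auxiliary registry), `map` (per source
#'   reaction: implementation reaction indices), `n_steps` (2 per uni + 3
#'   per bi), `n_impl_reactions` (irreversible reaction count), `params`
#'   and `source` (the input CRN).
#' @export
compile_dsd <- function(x, params = NULL) {
  stopifnot(inherits(x, "crn"))
  if (is.null(params)) {
    kmax <- if (length(x$reactions) > 0)
      max(vapply(x$reactions, function(r) r$rate_value, numeric(1)), 1)
    else 1
    params <- dsd_params(rate_scale = kmax)
  }
  steps <- list()
  aux <- list()
  map <- list()
  n_steps <- 0L
  for (j in seq_along(x$reactions)) {
    r <- x$reactions[[j]]
    tot <- sum(r$reactants)
    comp <- if (tot == 1L) compile_unimolecular(r, params, index = j)
      else if (tot == 2L) compile_bimolecular(r, params, index = j)
      else stop("reaction ", j, " is neither uni- nor bimolecular: ",
                format(r), call. = FALSE)
    map[[j]] <- seq(length(steps) + 1L, length.out = length(comp$steps))
    steps <- c(steps, comp$steps)
    aux[[j]] <- comp$aux
    n_steps <- n_steps + comp$n_steps
  }
  aux <- if (length(aux) > 0) do.call(rbind, aux) else
    data.frame(species = character(), initial = numeric(),
               role = character(), source = integer())
  impl <- crn(steps, clamped = intersect(x$clamped,
                                         unlist(lapply(steps, function(s)
                                           c(names(s$reactants),
                                             names(s$products))))),
              species = x$species)
  structure(
    list(crn = impl, aux = aux, map = map, n_steps = n_steps,
         n_impl_reactions = length(steps), params = params, source = x),
    class = "dsd_program"
  )
}

#' @export
print.dsd_program <- function(x, ...) {
  cat(sprintf(
    "DSD program: %d source reactions -> %d steps (%d reactions), %d auxiliary species (C_max = %g)\n",
    length(x$map), x$n_steps, x$n_impl_reactions, nrow(x$aux),
    x$params$C_max))
  invisible(x)
}

#' Simulate a compiled DSD program
#'
#' Wraps [simulate()]: the auxiliary species are initialized at their
#' registry values (fuels at `C_max`, intermediates at 0) and merged with
#' the caller's initial signal concentrations.
#'
#' @param program A `dsd_program`.
#' @param x0 Named initial concentrations of the signal species.
#' @param t_end,... Passed to [simulate()].
#' @return A `crn_trajectory`.
#' @export
simulate_dsd <- function(program, x0 = NULL, t_end, ...) {
  stopifnot(inherits(program, "dsd_program"))
  init <- stats::setNames(rep(0, length(program$crn$species)),
                          program$crn$species)
  init[program$aux$species] <- program$aux$initial
  if (!is.null(x0)) {
    x0 <- full_state(program$crn$species, x0)
    sig <- setdiff(program$crn$species, program$aux$species)
    init[sig] <- x0[sig]
  }
  simulate(mass_action_system(program$crn), x0 = init, t_end = t_end, ...)
}

#' Check auxiliary (fuel) depletion in a DSD trajectory
#'
#' The compiled kinetics are only valid while the fuel strands remain close
#' to `C_max`. Flags every fuel species whose concentration falls below
#' `fraction * C_max` anywhere along the trajectory.
#'
#' @param traj Trajectory from [simulate_dsd()].
#' @param program The `dsd_program`.
#' @param fraction Depletion threshold (default 0.5).
#' @return Data frame of fuels with their minimum concentration and a
#'   `depleted` flag.
#' @export
check_depletion <- function(traj, program, fraction = 0.5) {
  stopifnot(inherits(traj, "crn_trajectory"),
            inherits(program, "dsd_program"))
  fuels <- program$aux$species[program$aux$role == "fuel"]
  mins <- vapply(fuels, function(s) min(traj$x[, s]), numeric(1))
  data.frame(species = fuels, min = unname(mins),
             depleted = unname(mins) < fraction * program$params$C_max,
             stringsAsFactors = FALSE)
}
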