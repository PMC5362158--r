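#' Compile a CRN to a generalized mass-action ODE system
#'
#' Produces the state-space form dx/dt = P f(x): `P` is the stoichiometric
#' matrix over the dynamic (non-clamped) species and `f` the mass-action rate
#' vector. Clamped species contribute to rates at fixed concentrations but
#' carry no state equation, which is how constant sources (reference `r`,
#' inversion constant `beta`) are modeled.
#'
#' @param x A [crn()].
#' @return An object of class `mass_action_system` with elements `crn`,
#'   `species`, `clamped`, `dynamic` (names of state species), `P` (dynamic
#'   stoichiometric matrix), `order` (reactant-order matrix), `k` (rate
#'   constants) and `rate_names`.
#' @export
mass_action_system <- function(x) {
  stopifnot(inherits(x, "crn"))
  dynamic <- setdiff(x$species, x$clamped)
  structure(
    list(
      crn = x,
      species = x$species,
      clamped = x$clamped,
      dynamic = dynamic,
      P = stoich_matrix(x, full = FALSE),
      P_full = stoich_matrix(x, full = TRUE),
      order = order_matrix(x),
      k = vapply(x$reactions, function(r) r$rate_value, numeric(1)),
      rate_names = vapply(x$reactions, function(r) r$rate_name, character(1))
    ),
    class = "mass_action_system"
  )
}

#' @export
print.mass_action_system <- function(x, ...) {
  cat(sprintf("mass-action system: %d state species, %d reactions",
              length(x$dynamic), length(x$k)))
  if (length(x$clamped) > 0L) {
    cat(", clamped inputs: ", paste(x$clamped, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Evaluate the right-hand side dx/dt = P f(x)
#'
#' This R-level evaluation is independent of the compiled integrator and is
#' used to cross-check it and the hand-written ODE forms.
#'
#' @param sys A `mass_action_system`.
#' @param conc Full concentration state (named, or positional over
#'   `sys$species`).
#' @return Named derivative vector over the dynamic species.
#' @export
ma_rhs <- function(sys, conc) {
  stopifnot(inherits(sys, "mass_action_system"))
  conc <- full_state(sys$species, conc)
  rates <- mass_action_rates(sys$crn, conc)
  if (length(rates) == 0L) {
    return(stats::setNames(rep(0, length(sys$dynamic)), sys$dynamic))
  }
  drop(sys$P %*% rates)
}

#' Deterministic simulation of a mass-action system
#'
#' Integrates the stiff ODE system with an adaptive Rosenbrock method
#' (analytic Jacobian, compiled). Clamped species may be driven by constant
#' or piecewise-constant inputs; the integrator is restarted at each input
#' breakpoint so discontinuities are handled exactly.
#'
#' @param sys A [mass_action_system()] (a [crn()] is accepted and compiled).
#' @param x0 Initial state: named numeric (unlisted species start at 0), or
#'   `NULL` for the all-zero unexcited state.
#' @param inputs Named list giving clamped-species values: each element a
#'   single number (constant) or a two-column matrix / data.frame of
#'   `(start_time, value)` rows defining a piecewise-constant signal whose
#'   first start time must be at or before the simulation start.
#' @param t_end End time (start is 0).
#' @param t_grid Output time grid; defaults to 401 equally spaced points.
#'   Input breakpoints and `t_end` are always included.
#' @param rtol,atol Relative / absolute integrator tolerances. The defaults
#'   (1e-8, 1e-10) resolve the slow integral-gain modes and fast annihilation
#'   present in these circuits.
#' @param hmax Maximum step size (default: half of the current segment).
#' @param term_scale Optional per-(species, reaction) multiplier matrix (full
#'   species x reactions) applied to the stoichiometric matrix; used by the
#'   per-ODE-term perturbation machinery. `NULL` for none.
#' @param diverge_bound Declare divergence if a state exceeds its bound: a
#'   single number (applied to every dynamic species) or a named vector
#'   (named species get their bound, unnamed ones are unchecked); `Inf`
#'   disables the check.
#' @param max_steps Step budget per input segment.
#' @param fail `"error"` to stop on integrator failure (the error names the
#'   last valid time), `"return"` to return the partial trajectory with
#'   status metadata (used by Monte Carlo analysis).
#' @return A `crn_trajectory`: list with `t`, matrix `x` (time points by
#'   species, clamped columns included at their driven values, concentrations
#'   clipped at 0 on output), and `metadata` (status, solver settings, clip
#'   magnitude, step counts).
#' @export
simulate <- function(sys, x0 = NULL, inputs = list(), t_end, t_grid = NULL,
                     rtol = 1e-8, atol = 1e-10, hmax = NULL,
                     term_scale = NULL, diverge_bound = Inf,
                     max_steps = 5e6, fail = c("error", "return")) {
  if (inherits(sys, "crn")) sys <- mass_action_system(sys)
  stopifnot(inherits(sys, "mass_action_system"))
  fail <- match.arg(fail)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end < 0) {
    stop("`t_end` must be a single non-negative time", call. = FALSE)
  }

  species <- sys$species
  x0 <- if (is.null(x0)) {
    stats::setNames(rep(0, length(species)), species)
  } else {
    full_state(species, x0)
  }
  if (any(x0 < 0)) stop("initial concentrations must be >= 0", call. = FALSE)

  inputs <- normalize_inputs(inputs, sys$clamped, t_end)
  breaks <- sort(unique(c(0, unlist(lapply(inputs, function(s) s[, 1L])),
                          t_end)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]

  if (is.null(t_grid)) t_grid <- seq(0, t_end, length.out = 401L)
  t_grid <- sort(unique(c(0, t_grid, breaks)))
  t_grid <- t_grid[t_grid >= 0 & t_grid <= t_end]

  Peff <- sys$P
  if (!is.null(term_scale)) {
    stopifnot(is.matrix(term_scale),
              nrow(term_scale) == length(species),
              ncol(term_scale) == length(sys$k))
    Peff <- Peff * term_scale[sys$dynamic, , drop = FALSE]
  }
  dyn_idx <- match(sys$dynamic, species) - 1L
  storage.mode(Peff) <- "double"

  if (is.null(names(diverge_bound))) {
    if (length(diverge_bound) != 1L) {
      stop("`diverge_bound` must be a scalar or a named vector",
           call. = FALSE)
    }
    db <- rep(diverge_bound, length(sys$dynamic))
  } else {
    db <- rep(Inf, length(sys$dynamic))
    names(db) <- sys$dynamic
    known <- intersect(names(diverge_bound), sys$dynamic)
    db[known] <- diverge_bound[known]
  }
  db[!is.finite(db)] <- -1

  nt <- length(t_grid)
  X <- matrix(NA_real_, nt, length(species),
              dimnames = list(NULL, species))
  state <- x0
  if (t_end == 0) {
    for (nm in names(inputs)) state[nm] <- inputs[[nm]][1L, 2L]
    X[1L, ] <- state
  }
  status <- 0L
  t_last <- 0
  nsteps <- 0
  seg_bounds <- breaks
  for (si in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[si]
    b <- seg_bounds[si + 1L]
    for (nm in names(inputs)) {
      seg <- inputs[[nm]]
      state[nm] <- seg[max(which(seg[, 1L] <= a + 1e-12)), 2L]
    }
    sel <- which(t_grid >= a - 1e-12 & t_grid <= b + 1e-12)
    tout <- unique(c(a, t_grid[sel], b))
    res <- .cpp_simulate(Peff, sys$order, sys$k, dyn_idx,
                         as.numeric(state), tout, rtol, atol,
                         if (is.null(hmax)) -1 else hmax,
                         max_steps, as.numeric(db))
    xs <- res$x
    colnames(xs) <- species
    X[sel, ] <- xs[match(t_grid[sel], tout), , drop = FALSE]
    state[] <- xs[nrow(xs), ]
    nsteps <- nsteps + res$nsteps
    t_last <- res$t_last
    if (res$status != 0L) {
      status <- res$status
      break
    }
  }
  if (status != 0L && fail == "error") {
    stop(sprintf("integration %s at t = %g",
                 c("failed (step size underflow)", "exceeded step budget",
                   "diverged (state exceeded bound)")[status], t_last),
         call. = FALSE)
  }
  if (status != 0L) {
    # freeze remaining grid rows at the last computed state
    bad <- which(is.na(X[, 1L]))
    if (length(bad) > 0L) X[bad, ] <- rep(state, each = length(bad))
  }

  clip <- -min(0, suppressWarnings(min(X, na.rm = TRUE)))
  X[X < 0] <- 0

  structure(
    list(
      t = t_grid,
      x = X,
      species = species,
      metadata = list(status = status,
                      status_label = c("ok", "step_failure", "max_steps",
                                       "diverged")[status + 1L],
                      t_last = t_last, rtol = rtol, atol = atol,
                      clip_magnitude = clip, nsteps = nsteps)
    ),
    class = "crn_trajectory"
  )
}

normalize_inputs <- function(inputs, clamped, t_end) {
  if (length(inputs) == 0L) return(list())
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    stop("`inputs` must be a named list (names = clamped species)",
         call. = FALSE)
  }
  unknown <- setdiff(names(inputs), clamped)
  if (length(unknown) > 0L) {
    stop("inputs given for non-clamped species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lapply(inputs, function(v) {
    if (is.data.frame(v)) v <- as.matrix(v)
    if (is.numeric(v) && is.null(dim(v)) && length(v) == 1L) {
      v <- matrix(c(0, v), 1L, 2L)
    }
    if (!is.matrix(v) || ncol(v) != 2L) {
      stop("each input must be a scalar or a 2-column (time, value) matrix",
           call. = FALSE)
    }
    if (is.unsorted(v[, 1L], strictly = TRUE)) {
      stop("input segment start times must be strictly increasing",
           call. = FALSE)
    }
    if (v[1L, 1L] > 0) {
      stop("first input segment must start at or before time 0",
           call. = FALSE)
    }
    if (any(v[, 2L] < 0)) {
      stop("input values must be non-negative", call. = FALSE)
    }
    v
  })
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points, %d species, t in [%g, %g] (%s)\n",
              length(x$t), ncol(x$x), min(x$t), max(x$t),
              x$metadata$status_label))
  invisible(x)
}

#' @export
as.data.frame.crn_trajectory <- function(x, ...) {
  data.frame(t = x$t, x$x, check.names = FALSE)
}

#' Value of one species at given times
#'
#' Exact if the time is on the trajectory grid, otherwise linearly
#' interpolated.
#'
#' @param traj A `crn_trajectory`.
#' @param species Species name.
#' @param at Times.
#' @return Numeric vector.
#' @export
traj_value <- function(traj, species, at) {
  stopifnot(inherits(traj, "crn_trajectory"))
  if (!species %in% colnames(traj$x)) {
    stop("unknown species: ", species, call. = FALSE)
  }
  stats::approx(traj$t, traj$x[, species], xout = at, rule = 2)$y
}

#' Integrate a species trajectory over time
#'
#' Trapezoidal time-integral of one concentration series; used e.g. to
#' compare total feedforward and feedback control effort.
#'
#' @inheritParams traj_value
#' @return A number.
#' @export
traj_integral <- function(traj, species) {
  y <- traj$x[, species]
  t <- traj$t
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Run to a long horizon and test for steady state
#'
#' Integrates with constant inputs to `horizon` and flags convergence if the
#' largest state derivative, relative to the state scale, is below `tol`.
#' Detection is by integration plus derivative test rather than root finding
#' because the one-sided subtraction motif has no finite fixed point when its
#' difference is non-positive: such states are flagged `converged = FALSE`,
#' not treated as errors.
#'
#' @inheritParams simulate
#' @param horizon Integration horizon.
#' @param tol Relative derivative threshold for convergence.
#' @param ... Passed to [simulate()].
#' @return List with `state` (named, full), `converged`, `derivative`
#'   (named, dynamic species) and `trajectory`.
#' @export
steady_state <- function(sys, x0 = NULL, inputs = list(), horizon = 1e3,
                         tol = 1e-6, ...) {
  if (inherits(sys, "crn")) sys <- mass_action_system(sys)
  for (v in inputs) {
    if (!(is.numeric(v) && length(v) == 1L)) {
      stop("steady_state() requires constant inputs", call. = FALSE)
    }
  }
  traj <- simulate(sys, x0 = x0, inputs = inputs, t_end = horizon,
                   t_grid = c(0, horizon), ...)
  state <- traj$x[nrow(traj$x), ]
  deriv <- ma_rhs(sys, state)
  scale <- max(1, max(abs(state[sys$dynamic])))
  list(state = state,
       converged = max(abs(deriv)) / scale < tol,
       derivative = deriv,
       trajectory = traj)
}
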