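#' Piecewise-constant reference signal
#'
#' The default is the benchmark tracking task: reference 4 on [0, 40000) s
#' and 1 on [40000, 80000] s, with the steady-state error evaluated at the
#' end of each segment.
#'
#' @param times Segment start times (strictly increasing, first must be 0).
#' @param values Segment values (>= 0).
#' @return An object of class `reference_signal`.
#' @export
reference_signal <- function(times = c(0, 40000), values = c(4, 1)) {
  if (length(times) != length(values) || length(times) == 0L) {
    stop("`times` and `values` must have equal positive length",
         call. = FALSE)
  }
  if (times[1L] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("segment start times must be strictly increasing and begin at 0",
         call. = FALSE)
  }
  if (any(values < 0)) stop("reference values must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "reference_signal")
}

#' Closed-loop reference-tracking simulation
#'
#' Simulates an assembled circuit with the reference applied as a clamped
#' piecewise-constant input (and, in full-feedforward mode, the inversion
#' constant `beta` held at its design value). The returned trajectory
#' contains every circuit species, in particular the output `x6` and the
#' controller contributions `x4` (feedforward) and `x10` (PI).
#'
#' @param circuit A `closed_loop_circuit` from [assemble_closed_loop()].
#' @param ref A [reference_signal()].
#' @param t_end End time (s).
#' @param n_out Number of output grid points.
#' @param factors Optional named factors for per-term perturbation (see
#'   [term_scale_matrix()]).
#' @param ... Passed to [simulate()] (tolerances, `fail`, `diverge_bound`).
#' @return A `crn_trajectory`.
#' @export
run_tracking <- function(circuit, ref = reference_signal(), t_end = 80000,
                         n_out = 401, factors = NULL, ...) {
  stopifnot(inherits(circuit, "closed_loop_circuit"),
            inherits(ref, "reference_signal"))
  inputs <- list(r = cbind(ref$times, ref$values))
  if ("beta" %in% circuit$crn$clamped) {
    inputs$beta <- unname(circuit$init["beta"])
  }
  term_scale <- if (is.null(factors)) NULL else
    term_scale_matrix(circuit, factors)
  simulate(mass_action_system(circuit$crn), x0 = circuit$init,
           inputs = inputs, t_end = t_end,
           t_grid = seq(0, t_end, length.out = n_out),
           term_scale = term_scale, ...)
}

#' Relative steady-state error at the segment evaluation times
#'
#' For each reference segment the output `y_hat` is read at the segment's
#' end time and the signed relative error `100 * (y_hat - target) / y_hat`
#' is computed. For the default benchmark reference this yields the step-up
#' error `e_U = 100 * (y_hat(40000) - 4) / y_hat(40000)` and the step-down
#' error `e_D = 100 * (y_hat(80000) - 1) / y_hat(80000)`. A zero output at
#' an evaluation time makes that error undefined (`NA`).
#'
#' @param traj Tracking trajectory (must cover all evaluation times).
#' @param ref The [reference_signal()] used.
#' @param output Output species name.
#' @return Named numeric vector of signed percentages (`e_U`, `e_D` for a
#'   two-segment reference, otherwise `e_1`, `e_2`, ...).
#' @export
relative_ess <- function(traj, ref = reference_signal(), output = "x6") {
  stopifnot(inherits(traj, "crn_trajectory"),
            inherits(ref, "reference_signal"))
  t_end <- max(traj$t)
  eval_times <- c(ref$times[-1L], t_end)
  if (max(eval_times) > t_end + 1e-9) {
    stop("trajectory does not cover all evaluation times", call. = FALSE)
  }
  y <- traj_value(traj, output, eval_times)
  e <- ifelse(y == 0, NA_real_, 100 * (y - ref$values) / y)
  names(e) <- if (length(e) == 2L) c("e_U", "e_D") else
    paste0("e_", seq_along(e))
  e
}

#' Chernoff-bound Monte Carlo sample size
#'
#' Smallest number of simulations `N` with
#' `N >= log(2 / (1 - confidence)) / (2 * accuracy^2)` (additive
#' Chernoff-Hoeffding bound), the standard sizing rule for randomized
#' robustness analysis. Accuracy 0.05 at confidence 0.99 gives 1060.
#'
#' @param accuracy Estimation accuracy epsilon in (0, 1).
#' @param confidence Confidence level in (0, 1).
#' @return Integer sample size.
#' @export
chernoff_sample_size <- function(accuracy, confidence) {
  stopifnot(accuracy > 0, accuracy <= 1, confidence > 0, confidence < 1)
  as.integer(ceiling(log(2 / (1 - confidence)) / (2 * accuracy^2)))
}

#' Monte Carlo robustness analysis
#'
#' Repeats the tracking simulation `n` times with every perturbable
#' parameter (see [perturbation_targets()]) independently scaled by
#' `1 + scale * Delta`, `Delta ~ U[-1, 1]`. Records the pointwise min/max
#' envelope of the output and flags per-run divergence (any state exceeding
#' `diverge_bound`, or integrator failure).
#'
#' @param circuit A `closed_loop_circuit`.
#' @param scale Relative perturbation scale (0.1 = +/-10%).
#' @param n Number of runs; defaults to the Chernoff size 1060 for accuracy
#'   0.05 at confidence 0.99 (reduce for quick checks).
#' @param seed RNG seed (required, for reproducibility).
#' @param ref,t_end,n_out As in [run_tracking()].
#' @param diverge_bound Divergence bound. It is applied to every state
#'   except the one-sided-subtraction intermediates (`xs`, `xt`): those grow
#'   without bound by design whenever the minuend falls below the
#'   subtrahend (the motif has no fixed point there), so their magnitude is
#'   not a stability property of the loop. Runs in which an intermediate
#'   alone crosses the bound are counted separately as
#'   `n_unbounded_intermediate`.
#' @param rtol,atol Integrator tolerances (the default here is mildly looser
#'   than nominal: the envelope is a min/max statistic).
#' @return An `envelope_report`: list with `t`, `min`, `max`, `nominal`
#'   (the unperturbed output), counts `n`, `n_diverged`, `n_failed`,
#'   `n_unbounded_intermediate`, the settings, and `ess` (matrix of per-run
#'   signed steady-state errors).
#' @export
monte_carlo_robustness <- function(circuit, scale = 0.1,
                                   n = chernoff_sample_size(0.05, 0.99),
                                   seed = 1, ref = reference_signal(),
                                   t_end = 80000, n_out = 161,
                                   diverge_bound = 1e6,
                                   rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(circuit, "closed_loop_circuit"), n >= 1)
  set.seed(seed)
  targets <- perturbation_targets(circuit)
  npar <- nrow(targets)

  species <- circuit$crn$species
  intermediates <- intersect(c("xs", "xt"), species)
  checked <- setdiff(setdiff(species, circuit$crn$clamped), intermediates)
  bounds <- stats::setNames(rep(diverge_bound, length(checked)), checked)

  nominal <- run_tracking(circuit, ref = ref, t_end = t_end, n_out = n_out,
                          rtol = rtol, atol = atol)
  tt <- nominal$t
  y_nom <- nominal$x[, "x6"]
  lo <- rep(Inf, length(tt))
  hi <- rep(-Inf, length(tt))
  n_div <- 0L
  n_fail <- 0L
  n_unb <- 0L
  ess <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("e_U", "e_D")))

  for (i in seq_len(n)) {
    delta <- stats::runif(npar, -1, 1)
    factors <- stats::setNames(1 + scale * delta, targets$name)
    traj <- run_tracking(circuit, ref = ref, t_end = t_end, n_out = n_out,
                         factors = factors, rtol = rtol, atol = atol,
                         diverge_bound = bounds, fail = "return")
    st <- traj$metadata$status
    if (st == 3L) n_div <- n_div + 1L
    else if (st != 0L) n_fail <- n_fail + 1L
    if (length(intermediates) > 0L &&
        max(traj$x[, intermediates]) > diverge_bound) {
      n_unb <- n_unb + 1L
    }
    y <- stats::approx(traj$t, traj$x[, "x6"], xout = tt, rule = 2)$y
    lo <- pmin(lo, y)
    hi <- pmax(hi, y)
    if (st == 0L) ess[i, ] <- relative_ess(traj, ref)
  }

  structure(
    list(t = tt, min = lo, max = hi, nominal = y_nom, n = n,
         n_diverged = n_div, n_failed = n_fail,
         n_unbounded_intermediate = n_unb, scale = scale, seed = seed,
         diverge_bound = diverge_bound, mode = circuit$mode, ess = ess),
    class = "envelope_report"
  )
}

#' @export
print.envelope_report <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo envelope [%s]: %d runs at +/-%g%%, %d diverged, %d failed\n",
    x$mode, x$n, 100 * x$scale, x$n_diverged, x$n_failed))
  invisible(x)
}

#' One-at-a-time parameter sensitivity sweep
#'
#' Each parameter in turn is multiplied by every factor in `factors` (all
#' others nominal), the tracking simulation is run, and the signed relative
#' steady-state errors at the step-up and step-down evaluation times are
#' computed. The report gives, per parameter, the maximum over factors of
#' the signed error at each evaluation time.
#'
#' @param circuit A `closed_loop_circuit`.
#' @param parameters Parameter names (default: all perturbable parameters of
#'   the circuit's mode).
#' @param factors Multiplicative factors (default 0.5 to 2.0 in steps of
#'   0.1, i.e. 16 factors).
#' @param ref,t_end As in [run_tracking()].
#' @param rtol,atol Integrator tolerances.
#' @return A `sensitivity_report`: data frame with columns `parameter`,
#'   `e_U`, `e_D` (max signed percentages); the full factor-by-factor grid
#'   is in the `grid` attribute.
#' @export
sensitivity_sweep <- function(circuit, parameters = NULL,
                              factors = seq(0.5, 2.0, by = 0.1),
                              ref = reference_signal(), t_end = 80000,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(circuit, "closed_loop_circuit"))
  targets <- perturbation_targets(circuit)
  if (is.null(parameters)) parameters <- targets$name
  unknown <- setdiff(parameters, targets$name)
  if (length(unknown) > 0L) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(parameter = parameters, factor = factors,
                      stringsAsFactors = FALSE)
  grid$e_U <- NA_real_
  grid$e_D <- NA_real_
  for (i in seq_len(nrow(grid))) {
    f <- stats::setNames(grid$factor[i], grid$parameter[i])
    traj <- run_tracking(circuit, ref = ref, t_end = t_end, n_out = 41,
                         factors = f, rtol = rtol, atol = atol)
    e <- relative_ess(traj, ref)
    grid$e_U[i] <- e[[1L]]
    grid$e_D[i] <- e[[2L]]
  }
  out <- do.call(rbind, lapply(parameters, function(p) {
    g <- grid[grid$parameter == p, ]
    data.frame(parameter = p, e_U = max(g$e_U), e_D = max(g$e_D),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "factors") <- factors
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Process-parameter regime sweep
#'
#' Evaluates reference tracking for all eight sign patterns of the process
#' parameters at their literature range endpoints (`kr1` in {1e-9, 1e6},
#' `kr2` in {1e-2, 1e2}, `kr3` in {1e-5, 1e-3}). For each scenario the
#' feedforward branch is re-derived from the scenario's process (the design
#' procedure), the operator rates and PI gains stay at their nominal values
#' unless the scenario's design remark prescribes an adjustment, and the
#' verdict is "Y" if the relative steady-state error is within `threshold`
#' percent at both evaluation times.
#'
#' Design-remark adjustments (magnitudes are package calibration choices;
#' the remarks themselves prescribe only the direction): "increase gamma"
#' multiplies the Subtraction I and Division rates by
#' `gamma_increase["gSbI"]` and `gamma_increase["gD"]` -- these are the
#' blocks whose effective speed collapses when `kr1` is tiny, the division
#' especially so because its effective rate is `gD * (beta - delta * r)`;
#' "increase KP/KI" and "decrease KP/KI" scale both PI gains by
#' `pi_increase` / `pi_decrease`.
#'
#' @param mode `"full_ff"` or `"simplified_ff"`.
#' @param config Nominal [controller_config()].
#' @param adjust Apply the per-scenario design-remark adjustments
#'   (`FALSE` = all scenarios at nominal controller settings).
#' @param threshold Tracking verdict threshold (percent).
#' @param ref,t_end As in [run_tracking()].
#' @param gamma_increase,pi_increase,pi_decrease Adjustment magnitudes.
#' @param rtol,atol Integrator tolerances.
#' @return A `regime_report` data frame: one row per scenario with the sign
#'   pattern, rates, adjustment, errors and verdict.
#' @export
process_regime_sweep <- function(mode = c("full_ff", "simplified_ff"),
                                 config = controller_config(),
                                 adjust = TRUE, threshold = 10,
                                 ref = reference_signal(), t_end = 80000,
                                 gamma_increase = c(gSbI = 1e6, gD = 1e8),
                                 pi_increase = 1e8, pi_decrease = 1e-12,
                                 rtol = 1e-6, atol = 1e-10) {
  mode <- match.arg(mode)
  pat <- expand.grid(s1 = c("-", "+"), s2 = c("-", "+"), s3 = c("-", "+"),
                     stringsAsFactors = FALSE)
  pat <- pat[order(pat$s3, pat$s1, pat$s2), ]
  ends <- list(kr1 = c("-" = 1e-9, "+" = 1e6),
               kr2 = c("-" = 1e-2, "+" = 1e2),
               kr3 = c("-" = 1e-5, "+" = 1e-3))

  remark_for <- function(s1, s3, mode) {
    if (s3 == "-") return("none")
    if (s1 == "+") return("decrease_pi")
    # s1 == "-", s3 == "+"
    if (mode == "full_ff") "increase_gamma" else
      if (identical(s1, "-")) "increase_pi" else "none"
  }

  rows <- lapply(seq_len(nrow(pat)), function(i) {
    s <- pat[i, ]
    params <- process_params(kr1 = ends$kr1[[s$s1]], kr2 = ends$kr2[[s$s2]],
                             kr3 = ends$kr3[[s$s3]], xT = 5.5)
    remark <- if (adjust) remark_for(s$s1, s$s3, mode) else "none"
    # simplified mode, (-,+,+): the remark is "no change"
    if (adjust && mode == "simplified_ff" && s$s1 == "-" && s$s2 == "+" &&
        s$s3 == "+") {
      remark <- "none"
    }
    cfg <- config
    if (remark == "increase_gamma") {
      cfg <- modify_config(cfg, gSbI = cfg$gSbI * gamma_increase[["gSbI"]],
                           gD = cfg$gD * gamma_increase[["gD"]])
    } else if (remark == "decrease_pi") {
      cfg <- modify_config(cfg, KP = cfg$KP * pi_decrease,
                           KI = cfg$KI * pi_decrease)
    } else if (remark == "increase_pi") {
      cfg <- modify_config(cfg, KP = cfg$KP * pi_increase,
                           KI = cfg$KI * pi_increase)
    }
    circuit <- assemble_closed_loop(mode, cfg, params)
    e <- tryCatch({
      traj <- run_tracking(circuit, ref = ref, t_end = t_end, n_out = 41,
                           rtol = rtol, atol = atol, fail = "return")
      if (traj$metadata$status == 0L) relative_ess(traj, ref)
      else c(e_U = NA_real_, e_D = NA_real_)
    }, error = function(err) c(e_U = NA_real_, e_D = NA_real_))
    tracks <- !any(is.na(e)) && all(abs(e) <= threshold)
    data.frame(pattern = paste0("(", s$s1, ",", s$s2, ",", s$s3, ")"),
               kr1 = params$kr1, kr2 = params$kr2, kr3 = params$kr3,
               adjustment = remark, e_U = e[[1L]], e_D = e[[2L]],
               tracks = if (tracks) "Y" else "N", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("regime_report", "data.frame")
  out
}

modify_config <- function(cfg, ...) {
  upd <- list(...)
  for (nm in names(upd)) cfg[[nm]] <- upd[[nm]]
  do.call(controller_config,
          cfg[c("gGa", "gGd", "gSbI", "gD", "gGKP", "KP", "KI", "gSmI",
                "gSbII", "gSmII", "gG", "mode")])
}
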