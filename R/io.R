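#' Parse a plain-text reaction list into a CRN
#'
#' Grammar, one reaction per line:
#' \preformatted{
#'   # comment
#'   xin + xe -> xi @ kr1=0.005
#'   xo -> empty @ g=1.0
#'   clamp: r, beta
#' }
#' Species are whitespace-separated names joined by `+`; `empty` (or `0`)
#' denotes an empty side; an optional integer multiplicity may prefix a
#' species (`2 A`). The `@` clause gives `rate_name=value` (a bare value
#' gets the name `k`). `clamp:` directives may appear on any line.
#'
#' @param text Character vector of lines, or a single string (split on
#'   newlines), or a file path via `file`.
#' @param file Optional path to read instead of `text`.
#' @param allow_termolecular Passed to [reaction()].
#' @return A [crn()].
#' @export
parse_reaction_list <- function(text = NULL, file = NULL,
                                allow_termolecular = FALSE) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (is.null(text)) stop("provide `text` or `file`", call. = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  reactions <- list()
  clamped <- character()
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[i])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^clamp\\s*:", line)) {
      sp <- trimws(strsplit(sub("^clamp\\s*:", "", line), ",")[[1L]])
      clamped <- c(clamped, sp[sp != ""])
      next
    }
    err <- function(msg) {
      stop(sprintf("line %d: %s: '%s'", i, msg, trimws(text[i])),
           call. = FALSE)
    }
    if (!grepl("->", line, fixed = TRUE)) err("missing '->'")
    halves <- strsplit(line, "->", fixed = TRUE)[[1L]]
    if (length(halves) != 2L) err("malformed reaction")
    rhs_rate <- strsplit(halves[2L], "@", fixed = TRUE)[[1L]]
    if (length(rhs_rate) != 2L) err("missing '@ rate' clause")
    rate_spec <- trimws(rhs_rate[2L])
    if (grepl("=", rate_spec, fixed = TRUE)) {
      kv <- trimws(strsplit(rate_spec, "=", fixed = TRUE)[[1L]])
      if (length(kv) != 2L || kv[1L] == "") err("malformed rate clause")
      rate_name <- kv[1L]
      rate_value <- suppressWarnings(as.numeric(kv[2L]))
    } else {
      rate_name <- "k"
      rate_value <- suppressWarnings(as.numeric(rate_spec))
    }
    if (is.na(rate_value)) err("non-numeric rate value")
    lhs <- parse_side(trimws(halves[1L]), err)
    rhs <- parse_side(trimws(rhs_rate[1L]), err)
    reactions[[length(reactions) + 1L]] <- tryCatch(
      reaction(lhs, rhs, rate = rate_value, name = rate_name,
               allow_termolecular = allow_termolecular),
      error = function(e) err(conditionMessage(e)))
  }
  crn(reactions, clamped = unique(clamped))
}

parse_side <- function(side, err) {
  if (side %in% c("empty", "0", "")) {
    return(stats::setNames(integer(0), character(0)))
  }
  parts <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
  out <- integer(0)
  for (p in parts) {
    if (p == "") err("empty species term")
    m <- regmatches(p, regexec("^([0-9]+)\\s+(\\S+)$", p))[[1L]]
    if (length(m) == 3L) {
      coef <- as.integer(m[2L])
      sp <- m[3L]
    } else if (grepl("\\s", p)) {
      err(paste0("malformed species term '", p, "'"))
    } else {
      coef <- 1L
      sp <- p
    }
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
  }
  out
}

#' Serialize a CRN to the plain-text reaction-list format
#'
#' Inverse of [parse_reaction_list()]: `parse(serialize(x))` is
#' semantically identical to `x` (same species, reactions, rates, clamping).
#'
#' @param x A [crn()].
#' @return Character vector of lines.
#' @export
serialize_reaction_list <- function(x) {
  stopifnot(inherits(x, "crn"))
  side <- function(s) {
    if (length(s) == 0L) return("empty")
    paste(ifelse(s > 1L, paste(s, names(s)), names(s)), collapse = " + ")
  }
  lines <- vapply(x$reactions, function(r) {
    sprintf("%s -> %s @ %s=%s", side(r$reactants), side(r$products),
            r$rate_name, format(r$rate_value, digits = 15))
  }, character(1))
  if (length(x$clamped) > 0L) {
    lines <- c(lines, paste0("clamp: ", paste(x$clamped, collapse = ", ")))
  }
  lines
}

#' Default run configuration (nominal experiment)
#'
#' The defaults reproduce the nominal closed-loop tracking experiment
#' end-to-end: nominal process and controller parameters, reference 4 then 1
#' with the step at 40000 s, integrator tolerances 1e-8/1e-10, Monte Carlo
#' at the Chernoff size 1060 with scale 0.1.
#'
#' @return A `run_config` list with sections `process`, `controller`,
#'   `reference`, `solver`, `analysis` and `dsd`.
#' @export
default_config <- function() {
  structure(list(
    process = list(kr1 = 0.005, kr2 = 1.6, kr3 = 0.0008, xT = 5.5),
    controller = list(gGa = 1, gGd = 1, gSbI = 1, gD = 1, gGKP = 1,
                      KP = 0.02, KI = 2.5e-8, gSmI = 4e-4, gSbII = 3,
                      gSmII = 1, gG = 1, mode = "full_ff"),
    reference = list(c(0, 4), c(40000, 1)),
    solver = list(rtol = 1e-8, atol = 1e-10, t_end = 80000),
    analysis = list(scale = 0.1, n = 1060L, seed = 1L,
                    factor_min = 0.5, factor_max = 2.0, factor_step = 0.1,
                    diverge_bound = 1e6, track_threshold = 10),
    dsd = list(C_max_mult = 1e4, q_max_mult = 1e3)
  ), class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Missing keys are filled from [default_config()]; all validation errors
#' are collected and reported at once.
#'
#' @param path Path to a JSON config file, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    raw <- readChar(path, file.size(path))
    user <- if (nchar(trimws(raw)) == 0) list() else
      jsonlite::fromJSON(raw, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    for (sec in names(user)) {
      if (sec == "reference") {
        cfg$reference <- lapply(user$reference, as.numeric)
        next
      }
      if (!sec %in% names(cfg)) {
        stop("unknown config section: ", sec, call. = FALSE)
      }
      for (key in names(user[[sec]])) {
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  errors <- character()
  need_pos <- function(section, keys) {
    for (k in keys) {
      v <- cfg[[section]][[k]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) ||
          v <= 0) {
        errors <<- c(errors, sprintf("%s.%s must be a positive number",
                                     section, k))
      }
    }
  }
  need_pos("process", c("kr1", "kr2", "kr3", "xT"))
  need_pos("controller", c("gGa", "gGd", "gSbI", "gD", "gGKP", "KP", "KI",
                           "gSmI", "gSbII", "gSmII", "gG"))
  if (!cfg$controller$mode %in% c("full_ff", "simplified_ff", "pi_only")) {
    errors <- c(errors, "controller.mode must be full_ff, simplified_ff or pi_only")
  }
  need_pos("solver", c("rtol", "atol", "t_end"))
  segs <- cfg$reference
  if (length(segs) == 0L ||
      !all(vapply(segs, function(s) length(s) == 2L && all(is.finite(s)),
                  logical(1)))) {
    errors <- c(errors, "reference must be a list of [start_time, value] pairs")
  } else {
    tt <- vapply(segs, `[`, numeric(1), 1L)
    vv <- vapply(segs, `[`, numeric(1), 2L)
    if (tt[1L] != 0 || is.unsorted(tt, strictly = TRUE) || any(vv < 0)) {
      errors <- c(errors,
                  "reference start times must increase from 0, values >= 0")
    }
  }
  if (!is.numeric(cfg$analysis$scale) || cfg$analysis$scale < 0) {
    errors <- c(errors, "analysis.scale must be >= 0")
  }
  if (length(errors) > 0L) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

config_reference <- function(cfg) {
  tt <- vapply(cfg$reference, `[`, numeric(1), 1L)
  vv <- vapply(cfg$reference, `[`, numeric(1), 2L)
  reference_signal(tt, vv)
}

config_controller <- function(cfg) {
  do.call(controller_config, cfg$controller)
}

config_process <- function(cfg) {
  do.call(process_params, cfg$process)
}

#' Write an analysis report or trajectory to disk
#'
#' Trajectories and envelope reports are written as CSV (deterministic
#' column order: `t` first), sensitivity and regime reports as CSV tables,
#' and any other report as JSON.
#'
#' @param report Object produced by the simulation/analysis functions.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default chosen by report type).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("unwritable path (no such directory): ", dir, call. = FALSE)
  }
  if (inherits(report, "crn_trajectory")) {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else if (inherits(report, "envelope_report")) {
    utils::write.csv(data.frame(t = report$t, min = report$min,
                                max = report$max, nominal = report$nominal),
                     path, row.names = FALSE)
  } else if (inherits(report, "sensitivity_report") ||
             inherits(report, "regime_report")) {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else if (identical(format, "csv") && is.data.frame(report)) {
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}
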