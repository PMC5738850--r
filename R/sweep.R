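# Declarative parameter sweeps: evaluate a registered formula over a 1D
# grid (accuracy curve) or a 2D grid (accuracy surface, typically the
# multi-population formula), producing tidy long-format tables.

# Parameters that are integer-valued by domain; grid values for these are
# rounded to the nearest integer and de-duplicated (the record count may
# shrink), rather than silently evaluating a fractional N or M.
.integer_params <- c("n_train", "m_markers", "n_a", "n_b")

check_axis <- function(entry, param, lo, hi, n_points, scale, axis = "x") {
  valid <- c(entry$required_params, entry$choice_params)
  if (!param %in% valid) {
    stop_validation(sprintf(
      "'%s_param' = '%s' is not a parameter of formula '%s' (valid: %s)",
      axis, param, entry$formula_id, paste(valid, collapse = ", ")))
  }
  if (!is_scalar_number(lo) || !is_scalar_number(hi) || lo >= hi) {
    stop_validation(sprintf("%s_min < %s_max is required (got %s, %s)",
                            axis, axis, format(lo), format(hi)))
  }
  check_param(param, lo)
  check_param(param, hi)
  if (!is_scalar_number(n_points) || n_points < 2 || n_points != round(n_points)) {
    stop_validation(sprintf("'%s_points' must be an integer >= 2", axis))
  }
  if (!scale %in% c("linear", "log")) {
    stop_validation(sprintf("'%s_scale' must be 'linear' or 'log'", axis))
  }
  if (scale == "log" && lo <= 0) {
    stop_validation(sprintf("log spacing requires %s_min > 0", axis))
  }
  invisible(NULL)
}

# The fixed set must cover exactly the required parameters minus the
# varying ones, honouring the goddard2011 b-or-M choice.
check_fixed_cover <- function(entry, fixed, varying) {
  fixed_names <- names(fixed)
  need <- setdiff(entry$required_params, varying)
  missing <- setdiff(need, fixed_names)
  if (length(missing)) {
    stop_validation(sprintf("fixed parameters missing for formula '%s': %s",
                            entry$formula_id, paste(missing, collapse = ", ")))
  }
  choice_fixed <- intersect(entry$choice_params, fixed_names)
  choice_varying <- intersect(entry$choice_params, varying)
  if (length(entry$choice_params)) {
    supplied <- length(choice_fixed) + length(choice_varying)
    if (supplied == 0L) {
      stop_validation(sprintf("formula '%s' needs one of %s fixed or varying",
                              entry$formula_id,
                              paste(entry$choice_params, collapse = ", ")))
    }
    if (supplied > 1L) {
      stop_validation(sprintf("formula '%s' accepts only one of %s",
                              entry$formula_id,
                              paste(entry$choice_params, collapse = ", ")))
    }
  }
  extra <- setdiff(fixed_names, c(need, choice_fixed))
  if (length(extra)) {
    stop_validation(sprintf("fixed parameters not used by formula '%s': %s",
                            entry$formula_id, paste(extra, collapse = ", ")))
  }
  for (nm in fixed_names) check_param(nm, fixed[[nm]])
  invisible(NULL)
}

#' Specify a one-dimensional parameter sweep
#'
#' Declares a sweep of one formula over one varying factor, all other
#' required parameters held fixed -- the programmatic analogue of picking
#' an x-axis factor and slider values.  Validation is eager: the formula
#' must exist, the varying factor must belong to it, the bounds must lie in
#' the factor's domain, and `fixed` must cover exactly the remaining
#' required parameters.
#'
#' @param formula_id Identifier from [formula_registry()].
#' @param x_param Varying factor; canonical name or alias (e.g. `"N"`,
#'   `"h2"`, `"Me"`).
#' @param x_min,x_max Grid bounds, `x_min < x_max`, both in the factor's
#'   domain.
#' @param n_points Number of grid points, integer >= 2.  Default 101.
#' @param scale `"linear"` (arithmetic grid) or `"log"` (geometric grid;
#'   requires `x_min > 0`).
#' @param fixed Named list of the remaining required parameters (canonical
#'   names or aliases).
#' @return An object of class `sweep_spec`.
#' @export
#' @examples
#' sweep_spec("daetwyler", "N", 100, 10000,
#'            n_points = 25, fixed = list(h2 = 0.5, Me = 1000))
sweep_spec <- function(formula_id, x_param, x_min, x_max, n_points = 101,
                       scale = c("linear", "log"), fixed = list()) {
  scale <- match.arg(scale)
  entry <- get_registry_entry(formula_id)
  x_param <- canonical_param(x_param)
  fixed <- canonicalize_params(fixed)
  check_axis(entry, x_param, x_min, x_max, n_points, scale, axis = "x")
  check_fixed_cover(entry, fixed, varying = x_param)
  structure(list(formula_id = formula_id, x_param = x_param,
                 x_min = x_min, x_max = x_max,
                 n_points = as.integer(n_points), scale = scale,
                 fixed = fixed),
            class = "sweep_spec")
}

#' Specify a two-dimensional parameter surface
#'
#' As [sweep_spec()] but with two distinct varying factors; the result of
#' [run_surface()] is a long-format table over the Cartesian grid, the
#' programmatic analogue of a 3D accuracy surface over parameters of two
#' training populations.
#'
#' @inheritParams sweep_spec
#' @param y_param Second varying factor, distinct from `x_param`.
#' @param y_min,y_max,y_points,y_scale Grid for the second factor.
#' @return An object of class `surface_spec`.
#' @export
#' @examples
#' surface_spec("wientjes", "NA", 100, 5000, "NB", 100, 5000,
#'              n_points = 11, y_points = 11,
#'              fixed = list(h2A = 0.4, h2B = 0.4, MeAC = 500, MeBC = 500,
#'                           rGAC = 0.8, rGBC = 0.8, rGAB = 0.6,
#'                           bAC = 0.9, bBC = 0.9))
surface_spec <- function(formula_id, x_param, x_min, x_max,
                         y_param, y_min, y_max,
                         n_points = 101, scale = c("linear", "log"),
                         y_points = n_points, y_scale = scale,
                         fixed = list()) {
  scale <- match.arg(scale)
  y_scale <- match.arg(y_scale, c("linear", "log"))
  entry <- get_registry_entry(formula_id)
  x_param <- canonical_param(x_param)
  y_param <- canonical_param(y_param)
  if (identical(x_param, y_param)) {
    stop_validation("'x_param' and 'y_param' must be distinct factors")
  }
  fixed <- canonicalize_params(fixed)
  check_axis(entry, x_param, x_min, x_max, n_points, scale, axis = "x")
  check_axis(entry, y_param, y_min, y_max, y_points, y_scale, axis = "y")
  check_fixed_cover(entry, fixed, varying = c(x_param, y_param))
  structure(list(formula_id = formula_id,
                 x_param = x_param, x_min = x_min, x_max = x_max,
                 n_points = as.integer(n_points), scale = scale,
                 y_param = y_param, y_min = y_min, y_max = y_max,
                 y_points = as.integer(y_points), y_scale = y_scale,
                 fixed = fixed),
            class = "surface_spec")
}

# Grid values for one axis: endpoints assigned exactly (never accumulated)
# to avoid floating-point drift; integer-domain factors rounded and
# de-duplicated.
axis_values <- function(param, lo, hi, n, scale) {
  v <- if (scale == "log") exp(seq(log(lo), log(hi), length.out = n))
       else seq(lo, hi, length.out = n)
  v[1] <- lo
  v[n] <- hi
  if (param %in% .integer_params) {
    v <- unique(round(v))
  }
  v
}

#' Materialize the parameter grid of a sweep specification
#'
#' Expands a [sweep_spec()] into the ordered list of fully-specified
#' parameter sets that [run_sweep()] will evaluate.  Linear spacing yields
#' an arithmetic sequence, log spacing a geometric one, both inclusive of
#' the exact endpoints.  Every grid point is validated through the
#' formula's own parameter checks; an out-of-domain point aborts with the
#' offending value named.
#'
#' @param spec A `sweep_spec`.
#' @return A list of named parameter lists, one per grid point.
#' @export
make_grid <- function(spec) {
  if (!inherits(spec, "sweep_spec")) stop_validation("'spec' must be a sweep_spec")
  entry <- get_registry_entry(spec$formula_id)
  vals <- axis_values(spec$x_param, spec$x_min, spec$x_max,
                      spec$n_points, spec$scale)
  lapply(vals, function(v) {
    p <- spec$fixed
    p[[spec$x_param]] <- v
    tryCatch(validate_params(spec$formula_id, p),
             gpasim_validation_error = function(e) {
               stop_validation(sprintf("grid point %s = %s: %s",
                                       spec$x_param, format(v),
                                       conditionMessage(e)))
             })
    p
  })
}

fixed_json_string <- function(fixed) {
  as.character(jsonlite::toJSON(fixed, auto_unbox = TRUE, digits = NA))
}

#' Run a one-dimensional sweep
#'
#' Evaluates the formula at every grid point of the specification and
#' returns a tidy table, one row per point.  The sweep is a pure function
#' of the spec: identical specs produce bit-identical tables.  Any
#' evaluation error aborts the whole sweep (no partial curves with silent
#' gaps), annotated with the grid index.
#'
#' @param spec A `sweep_spec`.
#' @return A `sweep_table`: a data frame with columns `formula`, `x_param`,
#'   `x_value`, `accuracy`, `fixed_json`, rows in increasing `x_value`.
#' @export
#' @examples
#' tab <- run_sweep(sweep_spec("daetwyler", "N", 100, 10000,
#'                             n_points = 5, fixed = list(h2 = 0.5, Me = 1000)))
#' tab$accuracy
run_sweep <- function(spec) {
  grid <- make_grid(spec)
  xs <- vapply(grid, function(p) p[[spec$x_param]], numeric(1))
  acc <- vapply(seq_along(grid), function(i) {
    tryCatch(evaluate_formula(spec$formula_id, grid[[i]]),
             gpasim_error = function(e) {
               stop_gpasim(sprintf("sweep aborted at grid index %d (%s = %s): %s",
                                   i, spec$x_param, format(xs[i]),
                                   conditionMessage(e)),
                           class(e)[1])
             })
  }, numeric(1))
  out <- data.frame(formula = spec$formula_id, x_param = spec$x_param,
                    x_value = xs, accuracy = acc,
                    fixed_json = fixed_json_string(spec$fixed))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Run a two-dimensional surface sweep
#'
#' Evaluates the formula over the Cartesian grid of the two varying
#' factors, row-major: the x factor varies slowest, the y factor fastest.
#' Transposing the two factors in the spec yields the transposed surface.
#'
#' @param spec A `surface_spec`.
#' @return A `sweep_table` data frame with columns `formula`, `x_param`,
#'   `x_value`, `y_param`, `y_value`, `accuracy`, `fixed_json`, one row per
#'   grid cell.
#' @export
run_surface <- function(spec) {
  if (!inherits(spec, "surface_spec")) stop_validation("'spec' must be a surface_spec")
  xv <- axis_values(spec$x_param, spec$x_min, spec$x_max, spec$n_points, spec$scale)
  yv <- axis_values(spec$y_param, spec$y_min, spec$y_max, spec$y_points, spec$y_scale)
  grid <- expand.grid(y_value = yv, x_value = xv)   # y fastest => row-major in x
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    p <- spec$fixed
    p[[spec$x_param]] <- grid$x_value[i]
    p[[spec$y_param]] <- grid$y_value[i]
    tryCatch({
      validate_params(spec$formula_id, p)
      evaluate_formula(spec$formula_id, p)
    }, gpasim_error = function(e) {
      stop_gpasim(sprintf("surface aborted at cell %d (%s = %s, %s = %s): %s",
                          i, spec$x_param, format(grid$x_value[i]),
                          spec$y_param, format(grid$y_value[i]),
                          conditionMessage(e)),
                  class(e)[1])
    })
  }, numeric(1))
  out <- data.frame(formula = spec$formula_id,
                    x_param = spec$x_param, x_value = grid$x_value,
                    y_param = spec$y_param, y_value = grid$y_value,
                    accuracy = acc,
                    fixed_json = fixed_json_string(spec$fixed))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("sweep_spec: %s, %s in [%s, %s], %d points (%s)\n",
              x$formula_id, x$x_param, format(x$x_min), format(x$x_max),
              x$n_points, x$scale))
  cat("  fixed:", fixed_json_string(x$fixed), "\n")
  invisible(x)
}

#' @export
print.surface_spec <- function(x, ...) {
  cat(sprintf("surface_spec: %s, %s in [%s, %s] x %s in [%s, %s], %d x %d points\n",
              x$formula_id, x$x_param, format(x$x_min), format(x$x_max),
              x$y_param, format(x$y_min), format(x$y_max),
              x$n_points, x$y_points))
  cat("  fixed:", fixed_json_string(x$fixed), "\n")
  invisible(x)
}

## ---- flat key = value config files --------------------------------------

#' Write a sweep or surface specification to a config file
#'
#' Flat `key = value` text, `#` for comments.  Keys: `formula`, `x_param`,
#' `x_min`, `x_max`, `x_points`, `x_scale`, optionally the `y_*`
#' counterparts, and one `fixed.<name>` line per fixed parameter.
#'
#' @param spec A `sweep_spec` or `surface_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_config <- function(spec, path) {
  if (!inherits(spec, c("sweep_spec", "surface_spec"))) {
    stop_validation("'spec' must be a sweep_spec or surface_spec")
  }
  lines <- c("# gpasim sweep configuration",
             paste("formula =", spec$formula_id),
             paste("x_param =", spec$x_param),
             paste("x_min =", fmt_shortest(spec$x_min)),
             paste("x_max =", fmt_shortest(spec$x_max)),
             paste("x_points =", spec$n_points),
             paste("x_scale =", spec$scale))
  if (inherits(spec, "surface_spec")) {
    lines <- c(lines,
               paste("y_param =", spec$y_param),
               paste("y_min =", fmt_shortest(spec$y_min)),
               paste("y_max =", fmt_shortest(spec$y_max)),
               paste("y_points =", spec$y_points),
               paste("y_scale =", spec$y_scale))
  }
  for (nm in names(spec$fixed)) {
    lines <- c(lines, sprintf("fixed.%s = %s", nm, fmt_shortest(spec$fixed[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sweep or surface specification from a config file
#'
#' Parses the format of [write_sweep_config()]; the presence of `y_param`
#' selects a surface.  The parsed spec is re-validated through
#' [sweep_spec()] / [surface_spec()].
#'
#' @param path Input file path.
#' @return A `sweep_spec` or `surface_spec`.
#' @export
read_sweep_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  kv <- regmatches(raw, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", raw))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) {
    stop_format(sprintf("'%s': malformed config line: '%s'", path, raw[bad[1]]))
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  conf <- stats::setNames(as.list(vals), keys)

  need <- function(k, numeric = TRUE) {
    v <- conf[[k]]
    if (is.null(v)) stop_format(sprintf("'%s': missing config key '%s'", path, k))
    if (numeric) {
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x)) stop_format(sprintf("'%s': key '%s' is not numeric: '%s'", path, k, v))
      x
    } else v
  }
  fixed_keys <- grep("^fixed\\.", keys, value = TRUE)
  fixed <- lapply(fixed_keys, function(k) need(k))
  names(fixed) <- sub("^fixed\\.", "", fixed_keys)

  if (!is.null(conf$y_param)) {
    surface_spec(need("formula", numeric = FALSE), need("x_param", numeric = FALSE),
                 need("x_min"), need("x_max"),
                 need("y_param", numeric = FALSE), need("y_min"), need("y_max"),
                 n_points = need("x_points"), scale = need("x_scale", numeric = FALSE),
                 y_points = need("y_points"), y_scale = need("y_scale", numeric = FALSE),
                 fixed = fixed)
  } else {
    sweep_spec(need("formula", numeric = FALSE), need("x_param", numeric = FALSE),
               need("x_min"), need("x_max"),
               n_points = need("x_points"), scale = need("x_scale", numeric = FALSE),
               fixed = fixed)
  }
}
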