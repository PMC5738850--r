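# Structured conditions and parameter-domain validation shared by all modules.
#
# Error classes:
#   gpasim_validation_error  -- out-of-domain or missing/ambiguous parameter
#   gpasim_domain_error      -- mathematically undefined input (e.g. h2 = 1 in
#                               the Rabier forms, negative radicand)
#   gpasim_lookup_error      -- unknown formula identifier
#   gpasim_linalg_error      -- singular / ill-conditioned linear system
#   gpasim_format_error      -- malformed file on read
#   gpasim_usage_error       -- CLI argument errors

stop_gpasim <- function(msg, class, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "gpasim_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

stop_validation <- function(msg, field = NULL) {
  stop_gpasim(msg, "gpasim_validation_error", field = field)
}

stop_domain <- function(msg) stop_gpasim(msg, "gpasim_domain_error")
stop_lookup <- function(msg) stop_gpasim(msg, "gpasim_lookup_error")
stop_linalg <- function(msg) stop_gpasim(msg, "gpasim_linalg_error")
stop_format <- function(msg) stop_gpasim(msg, "gpasim_format_error")
stop_usage  <- function(msg) stop_gpasim(msg, "gpasim_usage_error")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Domain table for every scalar design factor used by the formulas.  Each
# entry: check function and a human-readable description of the domain.
.param_domains <- list(
  n_train  = list(check = function(x) is_scalar_number(x) && x >= 1 && x == round(x),
                  desc  = "positive integer (training-set size N)"),
  h2       = list(check = function(x) is_scalar_number(x) && x > 0 && x <= 1,
                  desc  = "real in (0, 1] (heritability h2)"),
  h2_m     = list(check = function(x) is_scalar_number(x) && x > 0 && x <= 1,
                  desc  = "real in (0, 1] (genomic heritability h2M)"),
  me       = list(check = function(x) is_scalar_number(x) && x > 0,
                  desc  = "positive real (independent chromosome segments Me)"),
  ne       = list(check = function(x) is_scalar_number(x) && x > 0.5,
                  desc  = "real > 0.5 (effective population size Ne; ln(2Ne) must be positive)"),
  m_markers = list(check = function(x) is_scalar_number(x) && x >= 1 && x == round(x),
                  desc  = "positive integer (marker count M)"),
  b        = list(check = function(x) is_scalar_number(x) && x >= 0 && x <= 1,
                  desc  = "real in [0, 1] (proportion of genetic variance captured by markers)"),
  eterm    = list(check = function(x) is_scalar_number(x) && x >= 0,
                  desc  = "real >= 0 (expectation term E(||x'X'V^-1||^2))"),
  n_a      = list(check = function(x) is_scalar_number(x) && x >= 1 && x == round(x),
                  desc  = "positive integer (training-set size N_A)"),
  n_b      = list(check = function(x) is_scalar_number(x) && x >= 1 && x == round(x),
                  desc  = "positive integer (training-set size N_B)"),
  h2_a     = list(check = function(x) is_scalar_number(x) && x > 0 && x <= 1,
                  desc  = "real in (0, 1] (heritability in population A)"),
  h2_b     = list(check = function(x) is_scalar_number(x) && x > 0 && x <= 1,
                  desc  = "real in (0, 1] (heritability in population B)"),
  me_ac    = list(check = function(x) is_scalar_number(x) && x > 0,
                  desc  = "positive real (segments shared between A and C)"),
  me_bc    = list(check = function(x) is_scalar_number(x) && x > 0,
                  desc  = "positive real (segments shared between B and C)"),
  r_g_ac   = list(check = function(x) is_scalar_number(x) && x >= -1 && x <= 1,
                  desc  = "real in [-1, 1] (genetic correlation A-C)"),
  r_g_bc   = list(check = function(x) is_scalar_number(x) && x >= -1 && x <= 1,
                  desc  = "real in [-1, 1] (genetic correlation B-C)"),
  r_g_ab   = list(check = function(x) is_scalar_number(x) && x >= -1 && x <= 1,
                  desc  = "real in [-1, 1] (genetic correlation A-B)"),
  b_ac     = list(check = function(x) is_scalar_number(x) && x >= 0 && x <= 1,
                  desc  = "real in [0, 1] (sqrt of variance proportion, markers of A in C)"),
  b_bc     = list(check = function(x) is_scalar_number(x) && x >= 0 && x <= 1,
                  desc  = "real in [0, 1] (sqrt of variance proportion, markers of B in C)")
)

# Validate a single named parameter value; errors name the field.
check_param <- function(name, value) {
  dom <- .param_domains[[name]]
  if (is.null(dom)) {
    stop_validation(sprintf("unknown parameter '%s'", name), field = name)
  }
  if (is.null(value)) {
    stop_validation(sprintf("parameter '%s' is required but missing", name),
                    field = name)
  }
  if (!dom$check(value)) {
    stop_validation(sprintf("parameter '%s' = %s is out of domain: expected %s",
                            name, format(value), dom$desc),
                    field = name)
  }
  invisible(value)
}

# Validate that `params` (a named list) supplies every field in `required`,
# each in-domain.  Extra fields are ignored.
check_params <- function(params, required) {
  if (!is.list(params)) stop_validation("params must be a named list")
  for (nm in required) check_param(nm, params[[nm]])
  invisible(params)
}

#' Parameter domains
#'
#' Returns the domain table used to validate every scalar design factor:
#' one row per parameter with its canonical name and a description of the
#' accepted domain.
#'
#' @return A data frame with columns `param` and `domain`.
#' @export
#' @examples
#' param_domains()
param_domains <- function() {
  data.frame(
    param  = names(.param_domains),
    domain = vapply(.param_domains, function(d) d$desc, character(1)),
    row.names = NULL
  )
}
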