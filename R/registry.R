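# Formula registry: one entry per deterministic formula, ordered (a)-(h),
# with citation label, required parameters and assumption notes.  The
# registry is the single source of truth for dispatch, CLI listing and
# sweep validation.

.registry <- list(
  daetwyler = list(
    formula_id = "daetwyler",
    letter = "a",
    citation_label = "Daetwyler et al. (2008, 2010)",
    required_params = c("n_train", "h2", "me"),
    choice_params = character(0),
    assumptions = paste("markers fixed; independent QTL; complete marker-QTL LD;",
                        "one-locus-at-a-time regression with residual variance 1",
                        "and phenotypic variance 1"),
    fn = function(p) accuracy_daetwyler(p$n_train, p$h2, p$me)
  ),
  goddard2009 = list(
    formula_id = "goddard2009",
    letter = "b",
    citation_label = "Goddard (2009)",
    required_params = c("n_train", "h2", "me", "ne"),
    choice_params = character(0),
    assumptions = paste("markers random, effects normal; complete marker-QTL LD;",
                        "effect estimates equally accurate at high MAF QTL"),
    fn = function(p) accuracy_goddard2009(p$n_train, p$h2, p$me, p$ne)
  ),
  goddard2011 = list(
    formula_id = "goddard2011",
    letter = "c",
    citation_label = "Goddard et al. (2011)",
    required_params = c("n_train", "h2", "me"),
    choice_params = c("b", "m_markers"),
    assumptions = paste("incomplete marker-QTL LD; finite marker panel;",
                        "b = M/(M + Me); identical to Daetwyler at b = 1"),
    fn = function(p) accuracy_goddard2011(p$n_train, p$h2, p$me,
                                          b = p$b, m_markers = p$m_markers)
  ),
  rabier = list(
    formula_id = "rabier",
    letter = "d",
    citation_label = "Rabier et al. (2016)",
    required_params = c("n_train", "h2", "me"),
    choice_params = character(0),
    assumptions = paste("no unit-variance constraint: valid for any genetic and",
                        "residual variances; requires h2 < 1"),
    fn = function(p) accuracy_rabier(p$n_train, p$h2, p$me)
  ),
  rabier_eterm = list(
    formula_id = "rabier_eterm",
    letter = "e",
    citation_label = "Rabier et al. (2016), expectation-term form",
    required_params = c("h2", "eterm"),
    choice_params = character(0),
    assumptions = paste("ridge-regression BLUP fitting all markers jointly;",
                        "Me/N replaced by E(||x'X'V^-1||^2); for same-population",
                        "training/testing the estimated term is bounded by 1"),
    fn = function(p) accuracy_rabier_eterm(p$h2, p$eterm)
  ),
  deloscampos = list(
    formula_id = "deloscampos",
    letter = "f",
    citation_label = "de los Campos et al. (2013)",
    required_params = c("b", "h2"),
    choice_params = character(0),
    assumptions = paste("GBLUP; upper bound for achievable accuracy when marker-",
                        "based and causal-locus relationships differ; no Me needed"),
    fn = function(p) accuracy_deloscampos(p$b, p$h2)
  ),
  karaman = list(
    formula_id = "karaman",
    letter = "g",
    citation_label = "Karaman et al. (2016)",
    required_params = c("n_train", "h2_m", "me"),
    choice_params = character(0),
    assumptions = paste("accuracy as correlation between phenotypes and estimated",
                        "breeding values; h2M is the genomic heritability"),
    fn = function(p) accuracy_karaman(p$n_train, p$h2_m, p$me)
  ),
  wientjes = list(
    formula_id = "wientjes",
    letter = "h",
    citation_label = "Wientjes et al. (2016)",
    required_params = c("n_a", "n_b", "h2_a", "h2_b", "me_ac", "me_bc",
                        "r_g_ac", "r_g_bc", "r_g_ab", "b_ac", "b_bc"),
    choice_params = character(0),
    assumptions = paste("selection-index combination of two training populations",
                        "A and B predicting population C; multi-population,",
                        "multi-environment or multi-trait"),
    fn = function(p) accuracy_wientjes(p$n_a, p$n_b, p$h2_a, p$h2_b,
                                       p$me_ac, p$me_bc, p$r_g_ac, p$r_g_bc,
                                       p$r_g_ab, p$b_ac, p$b_bc)
  )
)

# CLI/user-facing aliases (field symbols) -> canonical parameter names.
.param_aliases <- c(
  N = "n_train", h2 = "h2", h2M = "h2_m", Me = "me", Ne = "ne",
  M = "m_markers", b = "b", eterm = "eterm",
  NA_ = "n_a", NB = "n_b", h2A = "h2_a", h2B = "h2_b",
  MeAC = "me_ac", MeBC = "me_bc",
  rGAC = "r_g_ac", rGBC = "r_g_bc", rGAB = "r_g_ab",
  bAC = "b_ac", bBC = "b_bc"
)
names(.param_aliases)[names(.param_aliases) == "NA_"] <- "NA"

# Map a user-supplied parameter name (alias or canonical) to canonical form.
canonical_param <- function(name) {
  if (name %in% names(.param_domains)) return(name)
  if (name %in% names(.param_aliases)) return(unname(.param_aliases[[name]]))
  stop_validation(sprintf(
    "unknown parameter '%s' (canonical names: %s; aliases: %s)",
    name,
    paste(names(.param_domains), collapse = ", "),
    paste(names(.param_aliases), collapse = ", ")), field = name)
}

canonicalize_params <- function(params) {
  if (length(params) == 0L) return(params)
  if (is.null(names(params)) || any(names(params) == "")) {
    stop_validation("all parameters must be named")
  }
  names(params) <- vapply(names(params), canonical_param, character(1))
  if (anyDuplicated(names(params))) {
    stop_validation(sprintf("duplicated parameter after alias resolution: %s",
                            names(params)[duplicated(names(params))][1]))
  }
  params
}

get_registry_entry <- function(formula_id) {
  entry <- .registry[[formula_id]]
  if (is.null(entry)) {
    stop_lookup(sprintf("unknown formula '%s'; valid identifiers: %s",
                        formula_id, paste(names(.registry), collapse = ", ")))
  }
  entry
}

# Validate a full parameter set for a formula without evaluating it.
# Handles the b/m_markers choice for goddard2011.
validate_params <- function(formula_id, params) {
  entry <- get_registry_entry(formula_id)
  params <- canonicalize_params(params)
  check_params(params, entry$required_params)
  if (length(entry$choice_params)) {
    supplied <- entry$choice_params[
      vapply(entry$choice_params, function(nm) !is.null(params[[nm]]), logical(1))]
    if (length(supplied) == 0L) {
      stop_validation(sprintf("formula '%s' requires one of: %s", formula_id,
                              paste(entry$choice_params, collapse = ", ")))
    }
    if (length(supplied) > 1L) {
      stop_validation(sprintf("formula '%s' accepts only one of: %s", formula_id,
                              paste(entry$choice_params, collapse = ", ")))
    }
    check_param(supplied, params[[supplied]])
  }
  invisible(params)
}

#' Formula registry
#'
#' Enumerates the eight deterministic accuracy formulas in their canonical
#' order (a)-(h): identifier, citation label, required parameters and
#' modelling assumptions.
#'
#' @return A data frame with one row per formula and columns `formula_id`,
#'   `letter`, `citation_label`, `required_params` (comma-separated, with
#'   `x|y` marking an either-or choice) and `assumptions`.
#' @export
#' @examples
#' formula_registry()$formula_id
formula_registry <- function() {
  rows <- lapply(.registry, function(e) {
    req <- e$required_params
    if (length(e$choice_params)) {
      req <- c(req, paste(e$choice_params, collapse = "|"))
    }
    data.frame(formula_id = e$formula_id, letter = e$letter,
               citation_label = e$citation_label,
               required_params = paste(req, collapse = ", "),
               assumptions = e$assumptions)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a registered formula by identifier
#'
#' Uniform dispatch over the formula registry: validates `params` against
#' the formula's requirements, then calls the matching `accuracy_*`
#' function.  Parameter names may be canonical (`n_train`, `h2_m`, `me`,
#' ...) or the field symbols used on the command line (`N`, `h2M`, `Me`,
#' `Ne`, `M`, `NA`, `NB`, `h2A`, `MeAC`, `rGAB`, `bAC`, ...).
#'
#' @param formula_id One of the identifiers in [formula_registry()].
#' @param params Named list of parameter values.
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' evaluate_formula("daetwyler", list(N = 1000, h2 = 0.5, Me = 500))
evaluate_formula <- function(formula_id, params) {
  entry <- get_registry_entry(formula_id)
  params <- validate_params(formula_id, params)
  entry$fn(params)
}
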