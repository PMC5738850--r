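# Genotype simulation and estimation of the ridge-regression expectation
# term E(||x' X' V^-1||^2), V = XX' + lambda*I, which links marker data to
# the effective number of independent chromosome segments: Me/N equals the
# expectation, so Me can be estimated as N times the empirical term.

#' Simulate unlinked genotype matrices for training and test sets
#'
#' Draws per-marker allele frequencies uniformly on `[freq_low, freq_high]`,
#' then draws each raw allele count as Binomial(2, p_j) independently across
#' individuals and markers -- i.e. unlinked loci under Hardy-Weinberg
#' proportions, with training and test individuals sampled from the same
#' population.  Centered matrices subtract the column mean under
#' Hardy-Weinberg, `2 p_j`; no variance standardization is applied, since
#' the estimator's X is plain allele content and rescaling would change the
#' scale of XX'.
#'
#' The seed fully determines the output: the random stream draws the
#' frequencies first, then the training matrix (column-major), then the
#' test matrix, so regeneration with the same seed and dimensions is
#' bit-identical.  The caller's RNG state is left untouched.
#'
#' @param n_train,n_test Numbers of training and test individuals, positive
#'   integers.
#' @param m_markers Number of markers, positive integer.
#' @param freq_low,freq_high Allele-frequency bounds, `0 < freq_low <=
#'   freq_high < 1`.  The default \[0.05, 0.95\] avoids near-monomorphic
#'   columns that destabilize XX'.
#' @param seed Integer seed.
#' @return An object of class `genotype_set`: a list with centered
#'   `train_matrix` and `test_matrix`, raw `{0,1,2}` matrices `raw_train`
#'   and `raw_test`, `allele_freqs`, and `seed`.
#' @export
#' @examples
#' g <- simulate_genotypes(50, 10, 200, seed = 1)
#' dim(g$train_matrix)
simulate_genotypes <- function(n_train, n_test, m_markers,
                               freq_low = 0.05, freq_high = 0.95, seed) {
  for (nm in c("n_train", "n_test", "m_markers")) {
    x <- get(nm)
    if (!is_scalar_number(x) || x < 1 || x != round(x)) {
      stop_validation(sprintf("'%s' must be a positive integer", nm), field = nm)
    }
  }
  if (!is_scalar_number(freq_low) || !is_scalar_number(freq_high) ||
      freq_low <= 0 || freq_high >= 1 || freq_low > freq_high) {
    stop_validation("allele-frequency bounds must satisfy 0 < freq_low <= freq_high < 1",
                    field = "freq_low")
  }
  if (!is_scalar_number(seed) || seed != round(seed)) {
    stop_validation("'seed' must be an integer", field = "seed")
  }

  sim <- withr::with_seed(as.integer(seed), {
    p <- stats::runif(m_markers, freq_low, freq_high)
    raw_train <- matrix(stats::rbinom(n_train * m_markers, 2L, rep(p, each = n_train)),
                        nrow = n_train, ncol = m_markers)
    raw_test <- matrix(stats::rbinom(n_test * m_markers, 2L, rep(p, each = n_test)),
                       nrow = n_test, ncol = m_markers)
    list(p = p, raw_train = raw_train, raw_test = raw_test)
  })

  dimnames(sim$raw_train) <- list(paste0("trn_", seq_len(n_train)),
                                  paste0("mk_", seq_len(m_markers)))
  dimnames(sim$raw_test) <- list(paste0("tst_", seq_len(n_test)),
                                 paste0("mk_", seq_len(m_markers)))
  center <- 2 * sim$p
  structure(list(
    train_matrix = sweep(sim$raw_train, 2L, center),
    test_matrix  = sweep(sim$raw_test, 2L, center),
    raw_train    = sim$raw_train,
    raw_test     = sim$raw_test,
    allele_freqs = sim$p,
    seed         = as.integer(seed)
  ), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d training + %d test individuals, %d markers (seed %d)\n",
              nrow(x$train_matrix), nrow(x$test_matrix),
              ncol(x$train_matrix), x$seed))
  cat(sprintf("  allele frequencies in [%.3f, %.3f]\n",
              min(x$allele_freqs), max(x$allele_freqs)))
  invisible(x)
}

#' Default ridge regularization parameter
#'
#' The standard ridge-regression BLUP shrinkage when each of M markers
#' carries variance \eqn{\sigma^2_g / M}: \eqn{\lambda = M (1 - h^2) / h^2}.
#' Used by [estimate_eterm()] when `lambda` is not given explicitly.
#'
#' @param m_markers Number of markers, positive integer.
#' @param h2 Heritability, strictly in (0, 1).
#' @return Positive scalar lambda.
#' @export
ridge_lambda <- function(m_markers, h2) {
  check_param("m_markers", m_markers)
  check_param("h2", h2)
  if (h2 >= 1) stop_domain("ridge_lambda requires h2 < 1 (lambda -> 0 as h2 -> 1)")
  m_markers * (1 - h2) / h2
}

#' Estimate the expectation term from genotype data
#'
#' For each test-individual marker row x', computes
#' \eqn{\lVert x' X' V^{-1}\rVert^2} with \eqn{V = XX' + \lambda I} built
#' from the centered training matrix X, and returns the plain mean over test
#' rows.  The expectation is taken over test individuals for the one fixed
#' training set in `geno`; averaging over training replicates, if wanted, is
#' a caller-level loop over seeds.  V is symmetric positive definite, so the
#' solve uses a Cholesky factorization rather than explicit inversion.
#'
#' When training and test individuals come from the same population the
#' estimate is bounded by 1, so N times the estimate (see [me_from_eterm()])
#' is bounded by N.
#'
#' @param geno A `genotype_set` from [simulate_genotypes()], or a list with
#'   centered `train_matrix` and `test_matrix` of identical column count.
#' @param lambda Ridge regularization parameter, positive real.  If `NULL`,
#'   derived from `h2` via [ridge_lambda()].
#' @param h2 Heritability used for the default lambda; ignored when `lambda`
#'   is supplied.
#' @return The expectation-term estimate, a scalar >= 0.
#' @export
#' @examples
#' g <- simulate_genotypes(100, 20, 500, seed = 7)
#' estimate_eterm(g, h2 = 0.5)
estimate_eterm <- function(geno, lambda = NULL, h2 = NULL) {
  X <- geno$train_matrix
  Z <- geno$test_matrix
  if (is.null(X) || is.null(Z) || !is.matrix(X) || !is.matrix(Z)) {
    stop_validation("'geno' must carry matrices 'train_matrix' and 'test_matrix'")
  }
  if (ncol(X) != ncol(Z)) {
    stop_validation(sprintf(
      "training and test matrices must have identical marker columns (%d vs %d)",
      ncol(X), ncol(Z)))
  }
  if (is.null(lambda)) {
    if (is.null(h2)) {
      stop_validation("supply 'lambda' directly or 'h2' for the default ridge shrinkage M(1-h2)/h2")
    }
    lambda <- ridge_lambda(ncol(X), h2)
  }
  if (!is_scalar_number(lambda) || lambda <= 0) {
    stop_validation("'lambda' must be a positive real", field = "lambda")
  }

  V <- tcrossprod(X)
  diag(V) <- diag(V) + lambda
  R <- tryCatch(chol(V), error = function(e) {
    stop_linalg(sprintf("Cholesky factorization of V failed: %s", conditionMessage(e)))
  })
  # rows of U are x' X' V^-1 for each test individual
  W <- tcrossprod(Z, X)                       # n_test x n_train
  U <- t(backsolve(R, forwardsolve(t(R), t(W))))
  mean(rowSums(U * U))
}

#' Effective number of chromosome segments from the expectation term
#'
#' Since \eqn{M_e / N} equals the expectation term, an estimate of the
#' effective number of independent chromosome segments is N times the
#' empirical term.  For same-population training/testing the result is
#' bounded by N.  Plugging the result into [accuracy_rabier()] reproduces
#' [accuracy_rabier_eterm()] exactly.
#'
#' @param eterm_estimate Expectation-term estimate, real >= 0.
#' @param n_train Training-set size N, positive integer.
#' @return Estimated Me, a scalar >= 0.
#' @export
me_from_eterm <- function(eterm_estimate, n_train) {
  check_param("eterm", eterm_estimate)
  check_param("n_train", n_train)
  n_train * eterm_estimate
}

#' Write a raw genotype matrix to delimited text
#'
#' Tab-delimited layout: header row of marker names preceded by an `id`
#' column, one row per individual with raw `{0,1,2}` allele counts.
#'
#' @param raw Integer matrix of raw allele counts with row and column names
#'   (e.g. `raw_train` from [simulate_genotypes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(raw, path) {
  if (!is.matrix(raw) || !all(raw %in% c(0L, 1L, 2L))) {
    stop_validation("'raw' must be a matrix of raw allele counts in {0, 1, 2}")
  }
  if (is.null(rownames(raw))) rownames(raw) <- paste0("ind_", seq_len(nrow(raw)))
  if (is.null(colnames(raw))) colnames(raw) <- paste0("mk_", seq_len(ncol(raw)))
  df <- data.frame(id = rownames(raw), raw, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw genotype matrix from delimited text
#'
#' Reads the layout written by [write_genotypes()] and returns the centered
#' allele-content matrix.  Centering uses `2 p_j` per marker, with
#' frequencies either supplied (e.g. training-set frequencies, for a test
#' file) or recomputed from the file as half the column means.
#'
#' @param path Input file path.
#' @param allele_freqs Optional per-marker frequencies in (0, 1); if `NULL`,
#'   recomputed from the file.
#' @return A list with `matrix` (centered), `raw`, and `allele_freqs`.
#' @export
read_genotypes <- function(path, allele_freqs = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "id") {
    stop_format(sprintf("'%s': expected an 'id' column followed by marker columns", path))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  rownames(raw) <- df$id
  if (!all(raw %in% c(0L, 1L, 2L))) {
    stop_format(sprintf("'%s': genotype entries must be raw allele counts in {0, 1, 2}", path))
  }
  if (is.null(allele_freqs)) {
    allele_freqs <- colMeans(raw) / 2
  } else if (length(allele_freqs) != ncol(raw)) {
    stop_validation("length of 'allele_freqs' must equal the number of marker columns")
  }
  list(matrix = sweep(raw, 2L, 2 * allele_freqs),
       raw = raw, allele_freqs = allele_freqs)
}
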