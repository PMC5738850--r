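# The eight deterministic prediction-accuracy formulas.
#
# All return the expected accuracy r, the correlation between true and
# predicted genomic values, as a function of scalar design factors.  Inputs
# are validated against the domain table in validate.R before any arithmetic
# runs.  Tiny negative radicands from floating-point round-off (magnitude
# <= 1e-12) are clamped to zero; anything larger raises a domain error.

.radicand_tol <- 1e-12

sqrt_clamped <- function(x, what = "radicand") {
  if (x < 0) {
    if (x < -.radicand_tol) {
      stop_domain(sprintf("negative %s (%.6g) beyond round-off tolerance", what, x))
    }
    x <- 0
  }
  sqrt(x)
}

#' Daetwyler accuracy formula
#'
#' Expected accuracy of genomic prediction when markers are treated as fixed
#' effects, QTL are independent and in complete LD with markers
#' (Daetwyler et al. 2008, 2010):
#' \deqn{r = \sqrt{\frac{N h^2}{N h^2 + M_e}}}
#' The derivation assumes unit residual variance and unit phenotypic
#' variance (\eqn{\sigma^2_\epsilon = 1}, \eqn{\sigma^2_g + \sigma^2_\epsilon = 1}).
#'
#' @param n_train Training (reference) population size N, positive integer.
#' @param h2 Narrow-sense heritability, in (0, 1].
#' @param me Effective number of independent chromosome segments, positive real.
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @seealso [accuracy_goddard2011()] which reduces to this formula at b = 1,
#'   [evaluate_formula()] for registry dispatch.
#' @export
#' @examples
#' accuracy_daetwyler(n_train = 1000, h2 = 0.5, me = 500) # sqrt(1/2)
accuracy_daetwyler <- function(n_train, h2, me) {
  check_param("n_train", n_train)
  check_param("h2", h2)
  check_param("me", me)
  sqrt(n_train * h2 / (n_train * h2 + me))
}

#' Intermediate terms of Goddard's 2009 formula
#'
#' Computes \eqn{\lambda = M_e / (h^2 \ln(2 N_e))} and
#' \eqn{\alpha = 1 + 2 M_e / (N h^2 \ln(2 N_e))}, the two intermediates of
#' [accuracy_goddard2009()].  Requires `ne > 0.5` so the logarithm is
#' positive; for in-domain inputs `alpha > 1` always.
#'
#' @inheritParams accuracy_daetwyler
#' @param ne Effective population size, real > 0.5.
#' @return A list with components `lambda` and `alpha`.
#' @export
goddard_terms <- function(n_train, h2, me, ne) {
  check_param("n_train", n_train)
  check_param("h2", h2)
  check_param("me", me)
  check_param("ne", ne)
  log2ne <- log(2 * ne)
  list(lambda = me / (h2 * log2ne),
       alpha  = 1 + 2 * me / (n_train * h2 * log2ne))
}

#' Goddard accuracy formula (markers random, complete LD)
#'
#' Goddard's (2009) formula treating marker effects as random draws from a
#' normal distribution, with complete LD between markers and QTL:
#' \deqn{r = \sqrt{1 - \frac{\lambda}{2N\sqrt{\alpha}}
#'   \ln\!\left(\frac{1+\alpha+2\sqrt{\alpha}}{1+\alpha-2\sqrt{\alpha}}\right)}}
#' with \eqn{\lambda} and \eqn{\alpha} as in [goddard_terms()].
#'
#' Because \eqn{1+\alpha\pm 2\sqrt{\alpha} = (\sqrt{\alpha}\pm 1)^2}, the log
#' term equals \eqn{2\ln((\sqrt{\alpha}+1)/(\sqrt{\alpha}-1))}; the default
#' evaluation uses this cancellation-free form.  The printed form is kept as
#' `form = "printed"` for verification only.
#'
#' @inheritParams goddard_terms
#' @param form Evaluation route: `"stable"` (default) or `"printed"`.
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' accuracy_goddard2009(n_train = 1000, h2 = 0.5, me = 500, ne = 100)
accuracy_goddard2009 <- function(n_train, h2, me, ne,
                                 form = c("stable", "printed")) {
  form <- match.arg(form)
  gt <- goddard_terms(n_train, h2, me, ne)
  sa <- sqrt(gt$alpha)
  log_term <- switch(form,
    stable  = 2 * log((sa + 1) / (sa - 1)),
    printed = log((1 + gt$alpha + 2 * sa) / (1 + gt$alpha - 2 * sa))
  )
  sqrt_clamped(1 - gt$lambda / (2 * n_train * sa) * log_term)
}

#' Goddard et al. accuracy formula (incomplete marker-QTL LD)
#'
#' Extension (Goddard et al. 2011) accounting for incomplete LD between a
#' finite marker panel and the QTL:
#' \deqn{r = \sqrt{b \, \frac{N b h^2 / M_e}{1 + N b h^2 / M_e}}, \qquad
#'       b = \frac{M}{M + M_e}}
#' where b is the proportion of genetic variance explained by the markers.
#' Supply either `b` directly or the marker count `m_markers` (from which
#' b is derived); supplying both is an error, because silent precedence
#' would hide an inconsistency between them.  At b = 1 the formula is
#' identical to [accuracy_daetwyler()].
#'
#' @inheritParams accuracy_daetwyler
#' @param b Proportion of genetic variance explained by markers, in \[0, 1\],
#'   or `NULL` to derive it from `m_markers`.
#' @param m_markers Number of markers M (positive integer), or `NULL`.
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' accuracy_goddard2011(n_train = 1000, h2 = 0.5, me = 500, m_markers = 500)
accuracy_goddard2011 <- function(n_train, h2, me, b = NULL, m_markers = NULL) {
  check_param("n_train", n_train)
  check_param("h2", h2)
  check_param("me", me)
  if (!is.null(b) && !is.null(m_markers)) {
    stop_validation("supply exactly one of 'b' and 'm_markers', not both",
                    field = "b")
  }
  if (is.null(b) && is.null(m_markers)) {
    stop_validation("one of 'b' or 'm_markers' is required", field = "b")
  }
  if (is.null(b)) {
    check_param("m_markers", m_markers)
    b <- m_markers / (m_markers + me)
  } else {
    check_param("b", b)
  }
  theta <- n_train * b * h2 / me
  sqrt(b * theta / (1 + theta))
}

#' Rabier accuracy formula (general variance components)
#'
#' Rabier et al.'s formula dropping the unit-variance assumptions of
#' Daetwyler et al., valid for any genetic and residual variances:
#' \deqn{r = \sqrt{\frac{h^2/(1-h^2)}{M_e/N + h^2/(1-h^2)}}}
#' Requires `h2` strictly below 1: at \eqn{h^2 = 1} the signal-to-noise
#' ratio \eqn{h^2/(1-h^2)} is undefined (the accuracy limit is 1); a domain
#' error is raised rather than silently returning the limit.
#'
#' @inheritParams accuracy_daetwyler
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @seealso [accuracy_rabier_eterm()] for the marker-data form.
#' @export
#' @examples
#' accuracy_rabier(n_train = 1000, h2 = 0.5, me = 500)
accuracy_rabier <- function(n_train, h2, me) {
  check_param("n_train", n_train)
  check_param("h2", h2)
  check_param("me", me)
  if (h2 >= 1) {
    stop_domain("accuracy_rabier requires h2 < 1: h2/(1 - h2) is undefined at h2 = 1 (the limiting accuracy is 1)")
  }
  snr <- h2 / (1 - h2)
  sqrt(snr / (me / n_train + snr))
}

#' Rabier accuracy formula, expectation-term form
#'
#' Alternative form of [accuracy_rabier()] for ridge-regression BLUP fitting
#' all markers simultaneously, replacing \eqn{M_e/N} by the expectation term
#' \eqn{E(\lVert x' X' V^{-1}\rVert^2)} over test-individual marker vectors
#' (with \eqn{V = XX' + \lambda I}):
#' \deqn{r = \sqrt{\frac{h^2/(1-h^2)}{E(\lVert x' X' V^{-1}\rVert^2) + h^2/(1-h^2)}}}
#' With `eterm = me / n_train` this equals [accuracy_rabier()] exactly.
#' The term can be estimated from genotype data with [estimate_eterm()].
#'
#' @param h2 Narrow-sense heritability, strictly in (0, 1).
#' @param eterm Expectation term, real >= 0.
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' accuracy_rabier_eterm(h2 = 0.5, eterm = 0.5)
accuracy_rabier_eterm <- function(h2, eterm) {
  check_param("h2", h2)
  check_param("eterm", eterm)
  if (h2 >= 1) {
    stop_domain("accuracy_rabier_eterm requires h2 < 1: h2/(1 - h2) is undefined at h2 = 1 (the limiting accuracy is 1)")
  }
  snr <- h2 / (1 - h2)
  sqrt(snr / (eterm + snr))
}

#' de los Campos accuracy upper bound
#'
#' Theoretical upper limit of achievable accuracy under GBLUP when marker-
#' based genomic relationships imperfectly track relationships at causal
#' loci (de los Campos et al. 2013):
#' \deqn{r = \sqrt{[1 - (1 - b)^2] h^2}}
#' where b is the average regression coefficient of marker-based genomic
#' relationships on relationships at QTL.  Does not depend on \eqn{M_e}.
#' Bounded above by \eqn{\sqrt{h^2}} (attained at b = 1).
#'
#' @param b Average regression coefficient, in \[0, 1\].
#' @param h2 Narrow-sense heritability, in (0, 1].
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' accuracy_deloscampos(b = 0.5, h2 = 0.64)
accuracy_deloscampos <- function(b, h2) {
  check_param("b", b)
  check_param("h2", h2)
  sqrt((1 - (1 - b)^2) * h2)
}

#' Karaman accuracy formula (phenotype scale)
#'
#' Karaman et al.'s re-expression of the Daetwyler/Goddard formulas as the
#' correlation between phenotypes and estimated breeding values, in terms of
#' the genomic heritability \eqn{h^2_M} (the proportion of phenotypic
#' variance explained by regression on markers):
#' \deqn{r = \sqrt{h^2_M \frac{N h^2_M}{N h^2_M + M_e}}}
#'
#' @inheritParams accuracy_daetwyler
#' @param h2_m Genomic heritability, in (0, 1].
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' accuracy_karaman(n_train = 1000, h2_m = 0.5, me = 500) # = 0.5
accuracy_karaman <- function(n_train, h2_m, me) {
  check_param("n_train", n_train)
  check_param("h2_m", h2_m)
  check_param("me", me)
  sqrt(h2_m * n_train * h2_m / (n_train * h2_m + me))
}

#' Wientjes multi-population accuracy formula
#'
#' Selection-index formula (Wientjes et al. 2016) for the accuracy of
#' predicting population C from two training populations A and B, covering
#' multi-population, multi-environment and multi-trait scenarios.  With
#' \deqn{a = \begin{pmatrix} b_{AC}\, r_{G_{AC}} \sqrt{h^2_A / M_{e_{A,C}}} \\
#'                           b_{BC}\, r_{G_{BC}} \sqrt{h^2_B / M_{e_{B,C}}}
#'           \end{pmatrix}, \quad
#'       P = \begin{pmatrix}
#'         h^2_A/M_{e_{A,C}} + 1/N_A &
#'           r_{G_{AB}} \sqrt{h^2_A h^2_B / (M_{e_{A,C}} M_{e_{B,C}})} \\
#'         \cdot & h^2_B/M_{e_{B,C}} + 1/N_B
#'       \end{pmatrix}}
#' the accuracy is the square root of the scalar quadratic form
#' \eqn{r = \sqrt{a^\top P^{-1} a}}.  The formula is invariant under
#' swapping all A-labels with all B-labels.  `b_ac` and `b_bc` are the
#' *square roots* of the proportions of genetic variance in C explained by
#' the markers of A and B (i.e. the squares of the b used in
#' [accuracy_goddard2011()]).
#'
#' `P` must be numerically invertible: a reciprocal condition estimate below
#' 1e-12 raises an error, since a near-singular coefficient matrix (e.g.
#' \eqn{|r_{G_{AB}}| \to 1} with vanishing 1/N terms) yields meaningless
#' accuracies.
#'
#' @param n_a,n_b Training-set sizes of populations A and B, positive integers.
#' @param h2_a,h2_b Heritabilities in populations A and B, in (0, 1].
#' @param me_ac,me_bc Effective numbers of chromosome segments shared between
#'   A and C, and between B and C; positive reals.
#' @param r_g_ac,r_g_bc,r_g_ab Genetic correlations A-C, B-C and A-B,
#'   each in \[-1, 1\].
#' @param b_ac,b_bc Square roots of the proportions of genetic variance in C
#'   explained by the markers of A and B, each in \[0, 1\].
#' @return Expected accuracy, a scalar in \[0, 1\].
#' @export
#' @examples
#' accuracy_wientjes(n_a = 1000, n_b = 1000, h2_a = 0.4, h2_b = 0.4,
#'                   me_ac = 500, me_bc = 500, r_g_ac = 0.8, r_g_bc = 0.8,
#'                   r_g_ab = 0.6, b_ac = 0.9, b_bc = 0.9)
accuracy_wientjes <- function(n_a, n_b, h2_a, h2_b, me_ac, me_bc,
                              r_g_ac, r_g_bc, r_g_ab, b_ac, b_bc) {
  for (nm in c("n_a", "n_b", "h2_a", "h2_b", "me_ac", "me_bc",
               "r_g_ac", "r_g_bc", "r_g_ab", "b_ac", "b_bc")) {
    check_param(nm, get(nm))
  }
  off <- r_g_ab * sqrt(h2_a * h2_b / (me_ac * me_bc))
  P <- matrix(c(h2_a / me_ac + 1 / n_a, off,
                off, h2_b / me_bc + 1 / n_b), 2L, 2L)
  a <- c(b_ac * r_g_ac * sqrt(h2_a / me_ac),
         b_bc * r_g_bc * sqrt(h2_b / me_bc))
  rc <- rcond_2x2(P)
  if (!is.finite(rc) || rc < 1e-12) {
    stop_linalg(sprintf(
      "coefficient matrix P is singular or ill-conditioned (reciprocal condition estimate %.3g)", rc))
  }
  q <- drop(crossprod(a, solve(P, a)))
  sqrt_clamped(q, what = "quadratic form a' P^-1 a")
}

# Reciprocal condition number (1-norm) of a symmetric 2x2 matrix.
rcond_2x2 <- function(P) {
  det_p <- P[1, 1] * P[2, 2] - P[1, 2] * P[2, 1]
  if (det_p == 0) return(0)
  norm1 <- max(abs(P[1, 1]) + abs(P[2, 1]), abs(P[1, 2]) + abs(P[2, 2]))
  Pinv <- matrix(c(P[2, 2], -P[2, 1], -P[1, 2], P[1, 1]), 2L, 2L) / det_p
  norm1_inv <- max(abs(Pinv[1, 1]) + abs(Pinv[2, 1]),
                   abs(Pinv[1, 2]) + abs(Pinv[2, 2]))
  1 / (norm1 * norm1_inv)
}
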