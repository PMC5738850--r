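---
title: "Deterministic genomic prediction accuracy: models, estimator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic genomic prediction accuracy: models, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpasim)
```

## The problem

Genomic selection predicts breeding values of unphenotyped selection
candidates from a reference population of $N$ individuals that are both
genotyped and phenotyped. The quantity that decides whether a design is
worth genotyping is the prediction accuracy $r$, the correlation between
true and predicted genomic values. Deterministic formulas express the
*expected* $r$ in closed form from a handful of design factors, so the
accuracy landscape can be explored before any cross-validation — or any
genotyping — is done.

`gpasim` implements eight such formulas behind a common registry
(`formula_registry()`), a marker-data estimator that connects one of them
to genotype matrices, and a sweep engine that turns any formula into tidy
accuracy curves and surfaces.

## The models and their assumptions

The seven within-population formulas share a core intuition: accuracy is a
signal-to-noise competition between the information contributed by $N$
phenotypes at heritability $h^2$ and the number of independent genomic
"effects" that must be estimated, the effective number of independent
chromosome segments $M_e$.

* **`daetwyler`** — $r = \sqrt{N h^2/(N h^2 + M_e)}$. Markers treated as
  fixed effects, independent QTL, complete marker–QTL LD, one locus at a
  time with $\sigma^2_\epsilon = 1$ and
  $\sigma^2_g + \sigma^2_\epsilon = 1$. Those two variance constraints are
  modelling assumptions recorded in the registry metadata, not runtime
  inputs.
* **`goddard2009`** — markers random with normally distributed effects,
  complete LD; introduces the effective population size $N_e$ through
  $\lambda = M_e/(h^2\ln 2N_e)$ and
  $\alpha = 1 + 2M_e/(N h^2 \ln 2N_e)$.
* **`goddard2011`** — incomplete marker–QTL LD with a finite panel of $M$
  markers capturing a fraction $b = M/(M+M_e)$ of the genetic variance;
  identical to `daetwyler` at $b = 1$ (a tested equivalence).
* **`rabier`** — drops the unit-variance constraints; valid for any
  $\sigma^2_g, \sigma^2_\epsilon$, expressed through the signal-to-noise
  ratio $h^2/(1-h^2)$.
* **`rabier_eterm`** — the same model with $M_e/N$ replaced by the
  ridge-regression BLUP expectation term
  $E(\lVert x' X' V^{-1}\rVert^2)$, $V = XX' + \lambda I$, which is what
  links the formula family to actual marker data.
* **`deloscampos`** — an upper bound $\sqrt{[1-(1-b)^2]h^2}$ driven by how
  well marker-based genomic relationships track relationships at causal
  loci; deliberately free of $M_e$, which is hard to infer.
* **`karaman`** — the Daetwyler/Goddard result on the phenotype scale,
  using the genomic heritability $h^2_M$ (variance explained by regression
  on markers): $r = \sqrt{h^2_M \cdot N h^2_M/(N h^2_M + M_e)}$.
* **`wientjes`** — two training populations A and B predicting population
  C. We evaluate $r = \sqrt{a^\top P^{-1} a}$ with
  $a_1 = b_{AC} r_{G_{AC}}\sqrt{h^2_A/M_{e_{A,C}}}$ (and analogously
  $a_2$), $P_{11} = h^2_A/M_{e_{A,C}} + 1/N_A$,
  $P_{12} = r_{G_{AB}}\sqrt{h^2_A h^2_B/(M_{e_{A,C}}M_{e_{B,C}})}$. The
  formula is often typeset as a product of three square-rooted factors,
  which is not well defined factor-wise; the scalar quadratic form is the
  standard selection-index result and reproduces every stated reduction
  (inert second population $\to$ `daetwyler`; zero correlations $\to$ 0;
  A/B label exchange invariance).

## Parameters: domains, units, defaults

`param_domains()` prints the full table. The consequential choices:

* $h^2, h^2_M \in (0, 1]$ generally, but strictly $(0,1)$ for both Rabier
  forms: at $h^2 = 1$ the ratio $h^2/(1-h^2)$ is undefined and the
  accuracy limit is 1. We raise a domain error citing the limit rather
  than silently returning it — a user sweeping $h^2$ up to 1 should see
  where the model stops being defined.
* $N_e > 0.5$ so that $\ln 2N_e > 0$; $M_e > 0$ is real-valued, not
  integer, because effective segment counts are estimates.
* $N, M$ (and $N_A, N_B$) are positive integers. On sweep grids they are
  rounded to the nearest integer and de-duplicated, possibly shrinking the
  record count; evaluating a fractional $N$ silently would misrepresent
  the model.
* `goddard2011` accepts either $b$ or $M$ (deriving $b = M/(M+M_e)$);
  both at once is an error, since a silent precedence would hide an
  inconsistency between them.
* $M_e$ and $N_e$ are independent inputs. A functional relationship
  between them exists in the literature but no closed form is adopted
  here, so no derivation is attempted. Likewise $h^2_M$ is an input, not
  derived from $h^2$.

## The expectation-term estimator

`estimate_eterm()` computes, for each test row $x'$,
$\lVert x' X' V^{-1}\rVert^2$ with $V = XX' + \lambda I$ assembled from the
centered training matrix, and returns the plain mean over test rows — no
variance-reduction tricks, transparency over efficiency at desk scale. $V$
is symmetric positive definite, so the solve is a Cholesky factorization,
never an explicit inverse; tests compare it against an explicit-inverse
brute-force oracle on small instances.

Numerical and statistical choices:

* **Default shrinkage** $\lambda = M(1-h^2)/h^2$, the standard
  ridge-regression BLUP value when each of $M$ markers carries variance
  $\sigma^2_g/M$; always overridable via `lambda`.
* **Centering** subtracts $2p_j$ (the Hardy–Weinberg column mean); no
  variance standardization, because the model's $X$ is plain allele
  content and standardization changes the scale of $XX'$.
* **Expectation scope**: over test individuals for one fixed training set.
  Averaging over training replicates is a caller-level loop over seeds
  (the acceptance suite does exactly that for the unit-bound check).
* `me_from_eterm()` multiplies by $N$; plugging the result into
  `accuracy_rabier()` reproduces `accuracy_rabier_eterm()` exactly, a
  tested algebraic identity.

## What the genotype simulator emulates — and what it does not

`simulate_genotypes()` draws per-marker allele frequencies uniformly on
$[0.05, 0.95]$ (avoiding near-monomorphic columns that destabilize $XX'$),
then each allele count as Binomial$(2, p_j)$ — unlinked loci in
Hardy–Weinberg proportions, training and test individuals exchangeable
draws from the same population. One integer seed determines frequencies
and both matrices jointly, in a documented stream order (frequencies,
training matrix column-major, test matrix), so regeneration is
bit-identical and the caller's RNG state is untouched.

Real genotype data have LD structure, relatedness, ascertained marker
panels and frequency spectra far from uniform. None of that is emulated.
Consequently a green test establishes that the *estimator* is correct
(matches brute force, shrinks monotonically in $\lambda$, is invariant to
row permutation, respects the same-population unit bound) — it does not
establish that $N \cdot \hat E$ is a good $M_e$ estimate for any real
population. The estimator is a bridge between the formula family and
marker matrices, not a production $M_e$ inference tool; with unlinked
markers and the default shrinkage the estimate sits far below the unit
bound, which is expected, not a defect.

## Numerical choices

* **Goddard 2009 log term**: since
  $1+\alpha\pm2\sqrt{\alpha} = (\sqrt{\alpha}\pm1)^2$, we evaluate
  $2\ln((\sqrt{\alpha}+1)/(\sqrt{\alpha}-1))$, avoiding catastrophic
  cancellation in $1+\alpha-2\sqrt{\alpha}$ as $\alpha \to 1^+$ (large
  $N$). The printed form is kept behind `form = "printed"` purely as a
  test oracle; the two agree to $10^{-12}$ relative error across random
  in-domain draws.
* **Clamping policy**: radicands negative by at most $10^{-12}$ are
  floating-point round-off and clamp to zero; anything larger raises —
  distinguishing round-off from misuse.
* **Wientjes conditioning**: a reciprocal condition estimate of the
  $2\times2$ matrix $P$ below $10^{-12}$ raises a linear-algebra error.
  Near-singular $P$ (e.g. $|r_{G_{AB}}| \to 1$ with vanishing $1/N$ terms)
  produces meaningless accuracies, and failing loudly beats returning one.
* **Grid endpoints** are assigned exactly, never accumulated, so sweep
  boundaries are bit-equal to the requested bounds.
* **Serialization**: CSV floats use the shortest decimal string that
  round-trips to the identical double, so write-then-read reproduces
  accuracies bit-for-bit; JSON uses 17 significant digits (the
  always-round-trip width). Errors during a sweep abort the whole sweep
  rather than emitting a curve with silent holes.

## Feasible correlation structures in the multi-population tests

The three genetic correlations $r_{G_{AB}}, r_{G_{AC}}, r_{G_{BC}}$ are
marginally each in $[-1,1]$, but jointly they must form a positive
semidefinite $3\times3$ correlation matrix. Independent uniform draws
violate that (e.g. $r_{G_{AC}} = 0.9$, $r_{G_{BC}} = -0.9$,
$r_{G_{AB}} = 0.9$ describes no possible trio of populations) and can push
the selection-index accuracy above 1. The property tests therefore
rejection-sample jointly feasible triples; with $r_{G_{AB}} = 0$,
feasibility is exactly $r_{G_{AC}}^2 + r_{G_{BC}}^2 \le 1$, which is also
precisely the condition keeping the large-$N$ limit of $r$ at or below 1.
This is a statement about which parameter combinations describe a real
world, not a loosened tolerance.

## Known limitations

* No estimation of $M_e$, $N_e$ or $b$ from real data, and no VCF/PLINK
  input: the estimator operates on the package's own simulated (or
  plain-text imported) matrices.
* Markers are simulated independent; no LD or pedigree structure.
* Sweeps are evaluated serially on fixed grids; no adaptive refinement —
  workloads are desk-scale by design.
* The html plot export is a static self-contained SVG document, not an
  interactive widget.

## Defaults chosen where the design was open

Grid density defaults to `n_points = 101` (smooth curves at negligible
cost); the CLI mirrors the field's parameter symbols (`N`, `h2`, `h2M`,
`Me`, `Ne`, `M`, `b`; `NA`, `NB`, `h2A`, `MeAC`, `rGAB`, ... for the
multi-population case) with canonical snake_case names accepted
everywhere; CLI output prints full shortest-round-trip precision so piped
values equal library values exactly.
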