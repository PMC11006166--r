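---
title: "Models and methods for combinatorial multi-gene phenotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for combinatorial multi-gene phenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avgmodel)
```

## The problem

A multi-gene system is a set of n genes, each with an active (wild-type) and
an inactive (null mutant) allele, jointly controlling one quantitative trait.
When all 2^n allele combinations are constructed and phenotyped, the data
invite a general linear model: one coefficient per nonempty gene subset, plus
an intercept. All such models fit the genotype cell means equally well --
with replication their fitted values and residuals are identical -- so the
choice between them is a choice of *decomposition*, and it decides whether
the coefficients are interpretable and stable.

A genotype is written either in full, with case carrying the allele state
(`"ABc"`: A and B active, C mutant), or by listing only the active genes
(`"AB"`, with `"-"` for the fully mutant state). `parse_genotype()` accepts
both and detects the dialect per token; an explicit `dialect` argument
overrides detection, which matters only in the corner case where an
omission-dialect string happens to have length n in universe order.

## The three decompositions

Let G denote a genotype with m active genes and S a gene subset of size k.
Each family predicts the genotype mean as the intercept (the fully mutant
phenotype) plus a weighted sum over the subsets S of G's active genes:

* **additive** (ANOVA with interaction): weight 1 everywhere. The classical
  choice; interactions are deviations from summed lower-order effects.
* **NR** (network reconstitution): weight 1 for 1-gene effects,
  1/C(m, k) for interactions -- the averaging principle applied from order 2
  upward, which leaves its order-2 interaction identical to the additive one.
* **averaging**: weight 1/C(m, k) at every order. Equivalently, the
  coefficient of S is the deviation of genotype S from the average of the
  |S| genotypes with one fewer active gene, so every coefficient is a
  function of observed means alone:

```{r}
means <- network_means(six_node_network())
averaging_coef_direct(c("A", "B", "C"), means, "ABC")
means[["ABC"]] - (means[["AB"]] + means[["AC"]] + means[["BC"]]) / 3
```

The averaging weight's closed form 1/C(m, k) follows from the recursion
w(m, m) = 1, w(k, m) = ((m - k)/m) w(k, m - 1), which encodes exactly that
deviation-from-parents reading; the test suite verifies the identity by
integer cross-multiplication up to order 10.

The reference state is deliberate: all models here are coded against the
*most disrupted* (fully mutant) genotype, because effects of *adding* active
genes to an empty system map onto mechanism far more directly than effects
of removing them from an intact one. The conventional mutant-allele view is
available through `recode_to_mutant()`, which relabels genotypes by their
complements rather than introducing a fourth model family.

## Why the additive model destabilizes

The additive coefficient of S is the Möbius inversion (inclusion-exclusion)
over the subset lattice, a signed sum of 2^|S| genotype means. For
independent means with variance v this gives coefficient variance 2^m v:
high-order interactions amplify noise exponentially. For phenotypes drawn
uniformly from (1, 10), v = 81/12, the 7-gene additive interaction is
approximately Gaussian with IQR 1.349 sqrt(128 v) ≈ 39.6, while each 1-gene
effect is a difference of two uniforms (triangular, IQR
2·9·(1 − sqrt(1/2)) ≈ 5.27) -- a ratio of about 7.5, and about 4.4 times the
phenotype range of 9. The averaging coefficient of order m instead has
variance v + v/m: nearly flat in m.

`run_uniform_study()` measures this directly. Because the same drawn means
are solved under every family, the 1-gene samples -- whose formulas coincide
across families -- are identical draw for draw, not merely equal in law:

```{r}
s <- run_uniform_study(n_genes = 5, reps = 2000, seed = 1)
round(c(additive = iqr_ratio(s, "additive", 5, 1),
        averaging = iqr_ratio(s, "averaging", 5, 1)), 2)
```

The package's headline study uses n = 7 with 10,000 repeats (about a second
of compute; repeats are adjustable), where the additive max/min IQR ratio
across orders exceeds 5 and the averaging ratio stays below 2. Whiskers in
plots use the 1.5 IQR convention; all reported statistics are quartiles.

## Exact solving and its oracles

On a complete lattice the full model matrix is lower triangular with unit
diagonal under the canonical (order, then lexicographic) ordering of
genotypes and terms, so `solve_means()` is a forward substitution -- exact,
O(4^n), and warning-free for every family at any n the dense path allows
(capped at 12 genes; the enumeration itself is capped at 16). Two
independent closed forms cross-check it: `mobius_additive_oracle()` for the
additive family and `averaging_coef_direct()` for the averaging family.
Weights come from exact binomial coefficients evaluated once, not from
accumulated floating-point products.

## Fitting replicated data

`fit_fixed()` performs least squares on the observation-expanded model
matrix. `fit_mixed()` adds nested random intercepts (e.g.
`~ 1 | replicate/flat/pot`) via REML in `nlme::lme`, the appropriate fit
when the design has grouping factors and unequal replication. Confidence
intervals and t-tests in both use residual degrees of freedom N − p. For
the mixed model this approximates the containment convention; at small
group counts the approximation makes intervals slightly narrow, a known
limitation accepted for its simplicity and documented here rather than
hidden. Holm correction is applied over all non-intercept terms of a single
fit -- one family per fit, never across datasets. A full-model fit with
zero residual degrees of freedom returns estimates with the inference
columns `NA` rather than fabricating standard errors.

Missing genotypes are fatal for full models (the solve is underdetermined)
but tolerated, with a warning, for reduced models whose design retains full
column rank.

## Gene screening, bundling, reduction

Because an averaging coefficient is a deviation from parent genotypes,
including a gene that never moves the phenotype distorts the decomposition.
`screen_genes()` tests, for each gene g, the 2^(n−1) cell-mean contrasts
between each background with and without g, using the coefficient
covariance of a one-mean-per-genotype fit (mixed if nesting is given) and
t-tests on its residual degrees of freedom.

The Benjamini-Hochberg family is a genuine design choice. Adjusting all
genes' contrasts together lets the small p-values of strongly involved
genes raise the discovery threshold for an uninvolved gene's contrasts,
inflating its false-keep rate well above the nominal level (to roughly 25%
in simulations with three strong genes and one null gene). The default is
therefore `bh_scope = "gene"`: each gene's contrasts form their own family,
which makes the keep/drop decision a per-gene test with type-I error near
alpha. `bh_scope = "dataset"` is available for strict compatibility with
analyses that pool all contrasts of a dataset into one family. Screening
runs once before model choice; re-screening after each removal is possible
but not the default.

A dropped gene is removed by `bundle_gene()`: every observation keeps its
row but its genotype label forgets the gene, merging the two allele states.
The operation is lossy and therefore irreversible by design.

`reduce_model()` truncates the term list at a lower order and refits by
least squares. Under the additive family the surviving low-order estimates
shift substantially when heavy high-order interactions are dropped; under
the averaging family the shift is close to nil -- the paired simulation in
the test suite (200 random mean tables, n = 4, dropping the top order)
checks exactly this contrast.

## Treatment designs

With a two-level treatment, the quantity of interest is the
genotype-specific treatment response. The exact historical construction
combining genotype-nested treatment fixed effects with a model design
matrix is not fully determined by its published description, so
`treatment_contrast()` implements a transparent equivalent: within each
genotype (and each innermost nesting cell), the treated-minus-control
difference of cell means. Genotype baselines and any random intercepts
shared by the paired observations cancel in the differencing; the contrasts
are then modeled like any phenotype table. The sign convention is treated
minus control with the control level named explicitly, so immunity-style
phenotypes (treatment inhibits growth) come out with interpretable signs.

## The synthetic-data generator

`generate_replicated_data()` emulates a replicated combinatorial mutant
experiment of the kind the models target: a plant-pathology layout in which
each of `n_rep` experimental replicates contains every genotype, pots sit
in flats of `flat_size`, and each genotype-replicate pair occupies one pot
with `plants_per_pot` measured plants. Observations are true genotype means
(from a known coefficient vector) plus Gaussian random intercepts per
replicate, flat and pot, plus Gaussian residual noise; an optional
treatment doubles each plant into a control/treated pair sharing its pot's
intercepts. Defaults -- residual sd 0.5, nested sds (0.25, 0.15, 0.1),
3 replicates, 2 plants per pot -- are fixed at values typical for log10
bacterial-count assays, giving 6 observations per genotype.

What it deliberately does not emulate: non-Gaussian or heteroscedastic
noise, crossed (non-nested) grouping, incomplete lattices, saturating
phenotype floors/ceilings, or correlated genotype effects. Tests passing on
this generator therefore certify the estimators' statistical behavior under
the stated design, not robustness to those departures.

A truly null gene -- one that never moves the phenotype in any genotype
context -- is expressed in *additive* coordinates (all additive terms
containing it set to zero). Setting a gene's *averaging* coefficients to
zero does not silence it, because the 1/C(m, k) weights of the remaining
terms change when the gene is added; the screening simulations are built on
the additive formulation for exactly this reason.

## Numerical and design choices

* Canonical ordering (order, then lexicographic by universe position)
  everywhere: makes matrices triangular and every output reproducible.
* Triangular forward substitution instead of generic inversion: exact and
  cheap at the supported sizes.
* One seeded generator per study; genotype means are drawn in canonical
  genotype order, so results are stable under reordering of downstream code.
* Interaction operators in output: `";"` for averaging terms, `":"` for
  additive and NR terms.
* Degenerate inputs: constant phenotypes solve to all-zero non-intercept
  coefficients; `low == high` in the uniform study is allowed and collapses
  every coefficient distribution to a point.
* Problem sizes in the shipped tests: oracle comparisons at n = 2..6 (200
  random tables), coverage at 500 synthetic datasets, screening at 200,
  stability at 10,000 repeats -- sizes chosen so the whole suite documents
  the claims at comfortable desk scale.

## Known limitations

* The NR family's 1-gene weight is taken as 1 at every genotype order,
  generalizing its printed 3-gene form; extensions beyond that convention
  are out of scope.
* Mixed-model degrees of freedom use N − p (see above).
* Reproducing published biological coefficient tables requires the original
  external dataset, which the package does not ship; the command-line `fit`
  subcommand can analyze it if supplied in the long tabular format.
* Only nested random effects and Gaussian responses are supported.
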