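# avgmodel

Analysis of quantitative phenotypes measured over **exhaustively
combinatorial genotypes** of a multi-gene system: n genes, each active
(wild type) or inactive (null mutant), all 2^n allele combinations
phenotyped. Such data arise in genetic dissection of signaling networks —
for example bacterial growth (log10 cfu/cm²) across the 16 combinatorial
knockouts of four plant-immunity signaling hubs.

Every general linear model on the subset lattice fits the genotype cell
means identically; what differs is the decomposition into gene effects and
interactions. `avgmodel` implements three, all referenced to the fully
mutant (most disrupted) genotype:

| family | weight of an order-k term in an m-active-gene genotype |
|---|---|
| additive (ANOVA with interaction) | 1 |
| NR (network reconstitution) | 1 for k = 1, 1/C(m,k) for k ≥ 2 |
| **averaging** | 1/C(m,k) at every order |

In the averaging model each coefficient is the deviation of its genotype
from the average of the genotypes with one fewer active gene — e.g.
`A;B;C = ABC − (AB + AC + BC)/3` — so it is a function of observed means
alone, is interpretable at every order as *the mean effect of the last
gene added*, and stays statistically stable where the additive model's
high-order interactions explode (their variance grows as 2^m under
independent noise).

The package provides exact solving on complete lattices, least-squares and
nested mixed-effects fitting (REML, `nlme`) with 95% CIs and Holm
correction, Benjamini–Hochberg gene-inclusion screening with genotype
bundling, model reduction, Monte-Carlo coefficient-stability studies, a
mechanistic network evaluator, and a synthetic replicated-data generator.

## Worked example

A six-node network with three mutable nodes: inputs nA = 5, nB = −3,
nX = 4, nY = 2; nC = nA + nB + nX; output nZ = nC + nY; a mutant gene
forces its node to 0.

```r
library(avgmodel)
net <- six_node_network()
means <- network_means(net)
means
#>   -   A   B   C  AB  AC  BC ABC
#>   2   2   2   6   2  11   3   8
solve_means(model_spec("averaging", "ABC"), means)
#> averaging-model coefficients (genes ABC, up to order 3)
#>         term order estimate
#>  (Intercept)     0    2.000
#>            A     1    0.000
#>            B     1    0.000
#>            C     1    4.000
#>          A;B     2    0.000
#>          A;C     2    7.000
#>          B;C     2   -1.000
#>        A;B;C     3    2.667
```

Read: a basal phenotype of 2 with all genes disrupted; A and B do nothing
alone; C contributes 4 on its own; adding A to a system containing C
raises the phenotype by 7 on average (`A;C`), adding B to C lowers it by 1
(`B;C`); the additive solve of the same means (`model_spec("additive", ...)`)
instead returns C = 4, A:C = 5, B:C = −3 and zero three-gene interaction,
recovering the wiring exactly because this network happens to be linear.

The stability contrast at 7 genes (128 genotypes, means drawn uniformly
from 1–10, 10,000 repeats):

```r
s <- run_uniform_study(n_genes = 7, reps = 10000, seed = 1)
iqr_ratio(s, "additive", 7, 1)
#> 7.68
```

the additive 7-gene interaction's interquartile range is ~7.5× that of a
1-gene effect; the same ratio for the averaging family is below 2.

For replicated experimental data:

```r
u <- gene_universe("JEPS")
dat <- read_phenotype_table("counts.tsv", u)          # genotype, value, replicate, flat, pot
scr <- screen_genes(dat, u, nesting = c("replicate", "flat", "pot"))
kept_genes(scr)                       # e.g. "J" "E" "P" "S" — all involved
# had a gene been uninvolved: dat <- bundle_gene(dat, "J", u)
fit <- fit_mixed(model_spec("averaging", u), dat,
                 nesting = c("replicate", "flat", "pot"))
plot(fit)
```

A command-line wrapper with subcommands `matrix`, `solve`, `simulate`,
`screen`, `fit` and `fixtures` ships at
`system.file("cli", "avgmodel.R", package = "avgmodel")`.

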