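# pasmatch

`pasmatch` asks a practical question from gynecologic-oncology genomics: given
a small set of tumor transcriptomes — here, ovarian clear-cell carcinoma
(OCCC) arising alongside endometriosis — which publicly profiled cell lines
are the best molecular models for them? Because tumors and cell lines come
from different studies, platforms and microenvironments, comparing raw
expression values is unreliable. The package instead compares samples through
a rank-truncated **pathway activity score (PAS)**, which depends only on each
sample's internal expression ranking, and is therefore invariant to any
monotone per-sample transform (library size, TPM vs counts, log scaling).

Alongside the matching workflow, the package implements the supporting
analyses such a study uses: mature-miRNA composition statistics and top-table
ranking, multi-database miRNA target consensus with hypergeometric
over-representation, Fisher's exact test, exact noncentral-t/F power
analyses, the 2^-ddCt qPCR fold-change method, and four-parameter
log-logistic IC50 fitting. Seeded generators simulate every input the
pipeline consumes, so the whole analysis is testable offline.

## The score

For one sample with expression profile *x* over *N* genes, sort *x* in
decreasing order and let *i_g* be the 1-based rank of gene *g*. For a pathway
*P* (a set of genes) and truncation hyperparameter *K*:

```
PAS(x, P, K) = Σ_{g ∈ P} max(K − i_g, 0) / (|P| · K)
```

Only pathway members ranked inside the top *K* contribute; scores lie in
[0, 1). *K* = 3000 is the whole-transcriptome default. Members absent from
the matrix stay in |P| but contribute 0, keeping scores comparable across
matrices with different gene coverage.

Downstream, class-predictive pathways are selected from PAS features by
L1-penalized multinomial (softmax) logistic regression; sample–sample
similarity is the Pearson correlation of selected-pathway PAS vectors; and
samples are clustered on distance 1 − PCC with average linkage.

## Worked example

The numbered scripts under `analysis/` run the full workflow on simulated
data (`Rscript analysis/01_simulate_cohort.R`, then 02 … 06, writing under
`results/`). Condensed, the core matching analysis is:

```r
library(pasmatch)

sim <- simulate_expression(seed = 7)       # 4000 genes, 3 classes x 30 samples,
                                           # 10 active pathways planted per class
pas <- pas_matrix(sim$expression, sim$sets, K = 1000)
labels <- setNames(sim$annotation$class_label, sim$annotation$sample_id)

sel <- select_pathways(pas, labels, penalty = "auto", seed = 7)
sm  <- similarity_matrix(pas, sel$selected)
cl  <- cluster_samples(sm)
table(cut_clusters(cl, 3), labels)
```

Running `analysis/02` and `analysis/03` prints:

```
PAS: 200 pathways x 90 samples, range [0.0000, 0.8834]
selected 28 pathways (penalty 0.004122); Jaccard vs planted = 0.933
       class
cluster classA classB classC
      1     30      0      0
      2      0     30      0
      3      0      0     30
adjusted Rand index (3 clusters vs class) = 1.000
```

i.e. cross-validated L1 selection recovers the planted pathway panel almost
exactly (Jaccard 0.93 against the 30 planted pathways, no false positives),
and correlation clustering of the selected-pathway PAS vectors reconstructs
the three sample classes perfectly. `analysis/06` prints the biostatistics:
the stage-distribution Fisher test (p = 1.0), 98.9% power for the d = 9.6,
n = 2/group t-test design, 82.2% power for the f = 0.7, N = 24 ANOVA design,
the 8-fold ddCt example, and IC50 recovery with R² = 0.97 between a
resistance marker and log IC50 across a simulated cell-line panel.

A configuration-driven runner, `run_pipeline()`, executes the same stages
from a YAML/list config (exclusion filtering → PAS → selection → similarity →
clustering → miRNA profiling → target consensus → enrichment) and writes a
manifest with per-output MD5 checksums; reruns with an identical
configuration reproduce identical checksums.

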