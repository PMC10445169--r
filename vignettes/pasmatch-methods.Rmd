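---
title: "Rank-truncated pathway activity scoring: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-truncated pathway activity scoring: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasmatch)
```

## The problem and the model

Matching a handful of tumor transcriptomes to candidate model cell lines is a
cross-study comparison: the two data sets differ in platform, normalization,
cellular purity and microenvironment. Absolute expression values are not
comparable across such gaps, but the *ordering* of genes within one sample is
far more stable. The pathway activity score used here reduces each sample to
its internal ranking and each pathway to a weighted count of how many of its
members sit near the top of that ranking:

$$\mathrm{PAS}(x, P, K) \;=\; \frac{\sum_{g \in P} \max(K - i_g,\, 0)}{|P| \cdot K},$$

where $i_g$ is the 1-based rank of gene $g$ when the profile $x$ is sorted in
decreasing order. A pathway whose members crowd the top ranks scores high; a
pathway whose members all sit below rank $K$ scores zero. Dividing by
$|P| \cdot K$ makes scores unit-free and bounded in $[0, 1)$: the maximum for
a pathway of size $m \le K$ is $(K - (m+1)/2)/K$, attained when its members
occupy ranks $1..m$.

Two consequences drive the design. First, PAS is invariant to any strictly
increasing transform of one sample's values, so TPM vs counts vs log-scale
inputs give identical scores — the single most important property for
cross-study comparison, and one the test suite asserts directly. Second, the
score is a sum of per-gene contributions, so promoting a member to a better
rank can only increase it (monotonicity, also asserted).

### Conventions the formula does not fix

* **Rank base and ties.** Ranks are 1-based (the top gene contributes
  $K - 1$, not $K$). Ties are broken by descending value, then ascending
  lexicographic gene identifier: arbitrary, but deterministic across runs and
  platforms. Either convention perturbs a score by at most $1/K$ per gene.
* **Missing pathway members.** A member absent from the matrix stays in
  $|P|$ but contributes 0. The alternative — shrinking $|P|$ to the covered
  subset — makes scores incomparable between matrices with different gene
  coverage, which is exactly the cross-study setting the score exists for.
* **Normalization placement.** The score is implemented as
  $\sum \max(K - i_g, 0) / (|P| K)$. Any fixed constant-factor choice cancels
  nowhere downstream except through the standardization applied before
  penalized selection, which removes per-pathway scale anyway; the chosen
  form keeps the raw scores interpretable as a fraction of the attainable
  maximum.
* **K.** The default is $K = 3000$ for whole-transcriptome profiles
  (roughly the top fifth of expressed genes). On the simulated 4000-gene
  cohorts used in the tests and analysis scripts we use $K = 1000$ so the
  truncation plays the same proportional role. $K$ trades sensitivity
  (small $K$: only the most extreme genes count) against discrimination
  (large $K$: scores saturate); rank invariance holds for every $K$.

## Pathway selection

Class-predictive pathways are selected by multinomial (softmax) logistic
regression with an L1 penalty on standardized PAS features (`glmnet`).
Standardization matters because L1 shrinkage is scale-sensitive and PAS
ranges vary with pathway size. The softmax formulation is used rather than
one-vs-rest, and a pathway is "selected" when any class coefficient exceeds
1e-8 in magnitude.

The penalty is chosen by 5-fold stratified cross-validation over `glmnet`'s
internal lambda path, taking `lambda.min` by default; fold assignment is a
deterministic function of the seed, so identical inputs and seed give
identical selections. `select_to_count()` instead bisects the penalty toward
a fixed panel size; because the lasso path changes support in jumps, the
exact target can be unreachable, in which case the largest achievable count
below it is returned with a warning flag — a fixed published panel size is
treated as an emergent property of data and penalty, never hard-coded.

## Similarity and clustering

Sample similarity is the Pearson correlation of selected-pathway PAS vectors;
distance is $1 - r$ (signed, not absolute, preserving anti-correlation
structure), clustered agglomeratively with average linkage by default — the
linkage is a reporting choice, not a modeling claim, and is configurable.
Samples with a constant PAS vector over the selected panel have no defined
correlation and are excluded with a warning rather than imputed.

## What the generators emulate — and what they do not

`simulate_expression()` produces the structure the analysis assumes: log-normal
baseline expression (gene means drawn once per simulation, SD 2 on the log2
scale), disjoint pathways, and for each class a set of "active" pathways whose
members gain a mean log2 shift (`effect`, default 2 ≈ 4-fold) before per-gene
noise (SD 0.2). Each pathway also receives an independent per-sample activity
fluctuation (SD 0.7, ≈ 1.6-fold): real pathway activity varies between
samples of the same class, and this variation is what lets the penalized
model see each planted pathway as independently informative instead of as
redundant copies of one class indicator. Defaults are 3 classes × 30
samples, 4000 genes, 200 pathways of size 8–15 with 10 planted per class —
sizes at which the full recovery analysis runs in well under a minute.

What the generator does *not* emulate: overlapping pathways (real canonical
collections share genes heavily), count-level sampling noise and dispersion,
batch effects, and contaminating stromal/immune signal — the very thing the
exclusion-list mechanism exists for on real data. Passing recovery tests
therefore demonstrate that the pipeline's inferential chain is sound under
its own assumptions, not that any particular published panel or dendrogram
would be reproduced; those depend on unpublished exclusion lists and penalty
values and on external databases.

`simulate_mirna_counts()` draws each sample's composition from a per-group
Dirichlet and its counts from a multinomial, so a species given 21.5% of the
concentration mass reappears at about that pooled fraction — the composition
structure of a strongly dominated miRNA pool. Group abundance pools counts
across samples by default (matching "X% of the miRNA molecules" phrasing);
a per-sample averaging mode is exposed because the two differ under uneven
library sizes. The "expressed" criterion defaults to a raw count of at least
1 in at least one sample. `simulate_target_lists()` builds three prediction
sources sharing a designed consensus plus disjoint extras; real prediction
databases drift by version, so consensus counts are treated as inputs, never
as constants to reproduce.

## Supporting statistics

* **Fisher's exact test** uses the conventional minimum-likelihood two-sided
  rule (sum of table probabilities not exceeding the observed one), the
  definition under which the clinical stage table `[[4,5],[5,5]]` gives
  exactly p = 1.
* **Power analyses** use exact noncentral t and F distributions
  (noncentrality $d\sqrt{n/2}$ and $f^2 N$), not normal approximations —
  at df = 2 the difference is material, and the tests cross-check both
  functions against large Monte-Carlo simulations. For the ANOVA design the
  package reports power at a given N and the minimal N reaching a target,
  without asserting any published N is minimal (published totals may reflect
  rounding to equal group sizes).
* **IC50** comes from a four-parameter log-logistic fit
  $b + (t - b) / (1 + (d/\mathrm{IC50})^h)$ via Levenberg–Marquardt least
  squares, with starting values from the data extremes and the dose nearest
  the half-maximal response. The IC50 reported is the dose at half-maximal
  inhibition between the fitted plateaus. Non-decreasing viability is flagged
  and the IC50 returned as `NA` rather than extrapolated. The fit is
  scale-equivariant in dose.
* **Over-representation** is an upper-tail hypergeometric test with the
  enrichment ratio $(k/n)/(K/N)$; the universe defaults to the genes of the
  DE table under analysis, and categories are corrected by Benjamini–
  Hochberg. Curated keep-lists (hand annotation of plausible targets) are
  treated as optional user input applied after the consensus, since automated
  pipelines cannot reproduce manual curation.

## Numerical and degenerate-input choices

Scores are plain double sums — no special accumulation is needed at these
magnitudes, and the suite checks bit-level agreement (1e-12) against a
direct per-gene oracle on random instances. Empty pathways, empty profiles,
constant vectors, single-class labels, exclusion lists that empty a matrix,
and inconsistent contingency or enrichment counts all raise immediate errors
naming the offense; the pipeline wrapper converts stage failures into errors
naming the stage. Generators save and restore the global random state, so
seeded simulation never perturbs a caller's RNG stream.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance computation run the 3-class / 200-
pathway / 90-sample recovery study described above, a 100-instance PAS oracle
comparison at 15 genes × 4 samples, a 20-permutation selection null, a
10-sample × 1e6-read composition check, and Monte-Carlo power cross-checks at
1e6 (t) and 1e5 (F) replicates — sizes chosen so the whole suite completes in
a few minutes on one CPU while leaving every estimate's Monte-Carlo error far
below the margins being asserted.
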