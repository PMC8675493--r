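---
title: "Scoring drug-response heterogeneity in single cells: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-response heterogeneity in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdrugsens)
```

## The problem

Tumours are heterogeneous: two cells from the same biopsy can respond very
differently to the same drug. Bulk expression-based drug-response predictors
average over this structure. `scdrugsens` works at single-cell resolution:
every cell of a preprocessed scRNA-seq experiment is scored against a
collection of drug signatures, and the population's response to each drug is
summarised by how homogeneously the cells fall on one side of the score
scale.

Two kinds of drug signature are supported, both represented as a pair of
gene sets — the UP genes and the DN genes of a differential-expression
contrast:

* **perturbation signatures**: genes up/down after treating cells with the
  drug (a control-vs-treated contrast). Scores read out how far each cell's
  transcriptional state resembles the treated state, and support
  signature-reversion reasoning (drugs inducing a response complementary to
  the disease state);
* **sensitivity signatures**: genes whose pre-treatment expression
  correlates with pharmacological response across cell-line panels, built
  with the area under the dose-response curve (AUC) as a continuous
  covariate. High scores predict resistance-associated expression for
  high-AUC lines, so the score orients cells along a predicted
  sensitivity-resistance axis.

Functional gene sets (pathways, hallmark programmes) fit the same mould,
usually as unidirectional signatures.

## The score and the switch point

For a signature with gene set $G$ and a cell $i$, the raw score is the mean
normalised log expression over the signature genes present in the matrix:

$$ r_i = \frac{1}{|G \cap M|} \sum_{g \in G \cap M} x_{ig} $$

where $M$ is the set of measured genes. Raw scores are then normalised in
three steps, each individually toggleable in `normalise_scores()`:

1. **zero penalty** — multiply $r_i$ by the detection fraction $f_i$, the
   share of present signature genes with $x_{ig} > 0$. Cells expressing few
   signature genes (dropout-heavy cells) are pulled towards zero rather
   than being scored on a handful of detected genes;
2. **winsorisation** across cells at the 1st/99th percentiles (defaults;
   configurable), damping outlier cells;
3. **median centring**, so a positive normalised score means
   above-typical gene-set activity in this dataset and the zero crossing
   is interpretable.

For a bidirectional signature the net score is $n_i = u_i - d_i$ (UP minus
DN normalised scores); unidirectional signatures use the single direction,
negated for DN-only sets. The net scores are min-max rescaled to $[0,1]$,
and the **switch point** (SP) is where zero net score lands on that scale:

$$ \mathrm{SP} = \mathrm{clamp}\left(\frac{0 - \min_i n_i}{\max_i n_i - \min_i n_i},\ 0,\ 1\right). $$

Cells above the SP are in the up-regulated state for that signature. If
every cell has positive net score the SP clamps to 0 (a uniformly
sensitive population, for sensitivity-oriented signatures); all-negative
clamps to 1 (uniformly resistant); intermediate SPs flag a heterogeneous
response worth dissecting. When the net score is constant across cells
there is no direction information and both the scaled scores and the SP
are set to 0.5 with a warning.

Note one boundary subtlety: the equivalence "scaled > SP exactly where net
> 0" is exact whenever the net scores straddle zero; when all cells share
a sign, the SP is clamped and the extreme cell sits exactly at the SP.

The exact normalisation recipe (which quantities are penalised and how) is
this package's own convention, chosen to satisfy three requirements —
penalise dropout-heavy cells, damp outliers, make the zero crossing
meaningful — while remaining fully specified and testable. The steps are
separately toggleable so users can approximate alternative conventions.

## Building signatures from pharmacogenomic tables

`de_statistic()` fits, gene by gene, an ordinary-least-squares model of
bulk expression on the drug term — a treated indicator for perturbation
contrasts, or the AUC as a continuous variable for sensitivity designs —
plus tissue-of-origin dummy variables, and returns the t-statistic of the
drug term. Tissue is included because cell-line panels confound lineage
with drug response; the test suite demonstrates that tissue-shifted genes
produce large unadjusted statistics and near-null adjusted ones. A plain
OLS t is used deliberately: the operative output is a gene *ranking*, and
at the panel sizes involved (dozens of lines) moderated-variance
refinements change little while adding machinery. `make_signature()` cuts
the top and bottom `n_top` genes into the UP/DN sets; the default
`n_top = 250` follows the established convention for expression-signature
length, and rankings are insensitive to the exact choice in the 50–500
range. Ties at the cut are broken lexicographically (smaller ids preferred
at the top cut, larger at the bottom) so the result is deterministic and
the two sets stay disjoint even for degenerate, fully tied statistics.

### Drug-background selection

Clustering all cells against thousands of drugs is wasteful because most
drugs induce cell-type-specific patterns while a minority act uniformly.
The drug specificity score of `drug_specificity()` captures this: each
signature is scored per cell-type group of a bulk reference panel (mean UP
minus DN expression over the group's profiles), and the score is one minus
the mean pairwise absolute difference of these per-type scores, rescaled
so the most discordant pattern observed in the collection anchors zero and
an identical pattern across types gives one. The exact functional form is
this package's convention; it preserves the defining contract (similar
induced patterns across cell types mean a high score) and is monotone in
pattern similarity. The first and last decile by specificity —
`ceiling(0.1 n)` signatures each, boundary ties broken by name — form the
reduced background collection used for therapeutic clustering.

## Removing unwanted variation

Scaled scores correlate with cell-level nuisance metrics (library size,
detected genes, cell-cycle phase) even after normalisation.
`regress_out()` removes them in two steps, following standard practice:
missing entries are first completed by k-nearest-neighbour imputation
(masked Euclidean distances over mutually finite signature columns,
`k = 10`), then per-signature residuals of the least-squares fit on an
intercept plus the chosen covariates are computed via the QR
decomposition. Categorical covariates are one-hot encoded with the first
level as reference. Residuals are kept signed and mean-zero — they are
*not* re-rescaled to $[0,1]$, and the switch point is retained from
scoring, because downstream prioritisation combines the SP (a property of
the scaled scale) with residual means (a property of the cleaned scale).

A caveat the synthetic experiments make vivid: covariates can absorb
biology. When a clone strongly downregulates many genes, its
detected-gene count drops for biological reasons, and regressing out
`nGene` then removes the clone signal itself. Regress the metrics you
believe are technical; in the packaged simulations that is `nUMI`, the
planted library-size factor.

## Therapeutic clusters

`reduce_scores()` runs PCA on the (residualised) score matrix — 20
components by default, clipped for small matrices — followed by a 2-D
UMAP for visualisation. `find_clusters()` groups cells on a
shared-nearest-neighbour graph (15 neighbours, Jaccard edge weights
pruned below 1/15) with Louvain community detection at resolution 0.4,
the standard single-cell construction applied to the score matrix rather
than the expression matrix; k-means is available as a deterministic
fallback when a cluster count is known. Cluster ids are relabelled by
decreasing size. All randomness flows from a single integer seed and
identical inputs reproduce labels and embedding exactly.

Because the clusters are computed from drug scores, they capture shared
*response*, not shared lineage: the test suite includes an instance where
planted response groups cut across expression clones and the score
clustering follows the response structure.

## Prioritising drugs

`signature_stats()` tabulates, per signature and cell group, the switch
point, mean, median, standard deviation, variance, minimum, maximum,
proportion of NaN and residuals' mean. `four_squares()` classifies each
signature on the residual-mean (x) versus switch-point (y) plane: the
bottom-right corner (SP ≤ 0.1, residual mean in the group's top decile)
holds the drugs the group is most sensitive to, the top-left corner
(SP ≥ 0.9, bottom decile) the least; intermediate SPs with extreme
residual means are differentially sensitive/insensitive relative to the
other groups. The SP cuts (0.1/0.9) and the decile rule are configurable
defaults — the quadrant picture fixes the geometry but not the cutoffs,
and deciles mirror the background-selection logic.

`rank_differential()` ranks signatures by the difference of group means of
residuals between two conditions, with a two-sided label-permutation test
(1000 permutations by default) and Benjamini–Hochberg adjustment across
signatures. A permutation test is used because scaled scores are bounded
and non-Gaussian; BH is the field-default multiplicity correction.
`correlation_modules()` groups signatures whose scaled scores co-vary
across cells (average-linkage clustering on $1 - |r|$, cut at 0.3 for the
default $|r| \ge 0.7$), a cheap view of shared mechanism among drugs.

## What the synthetic data emulates — and what it does not

`simulate_cells()` generates normalised log-scale expression directly:
gene means $\sim N(2, 0.5)$, cell-level noise $N(0, 1)$, floored at zero.
Clonal structure is planted by shifting each clone's signature UP genes by
$+e\sigma$ and DN genes by $-e\sigma$; dropout zeroes entries Bernoulli
(0.3 by default); a log-normal library-size factor (sd 0.2) scales every
gene and is recorded as the `nUMI` covariate, creating the score-nuisance
correlation the regression removes. The default configuration emulates
the regime the method actually runs in: 500 cells, two equal clones, a
background-sized panel of 20 bidirectional signatures of 100 genes per
direction, exactly one of which discriminates the clones (effect
$3\sigma$) while 19 act as null drugs. Signature breadth matters here:
drug genesets are hundreds of genes, and averaging over 100+ genes is
what lets gene-set scores shrug off 30% dropout; toy signatures of a
couple dozen genes understate the method's real signal-to-noise.
Simulating at the normalised log level (rather than negative-binomial
counts) is sufficient because scoring consumes normalised log expression;
count-level simulation is a documented extension point. The generator
does not emulate batch structure, doublets, ambient RNA, or
mean-variance coupling, so passing recovery tests show correctness of
the pipeline's logic, not robustness to every real-data artefact.

`simulate_pharmaco()` generates the bulk counterpart: AUC uniform per
(sample, drug) with a tissue-dependent shift (so tissue genuinely
confounds), planted resistance genes with expression
$\mathrm{base} + \mathrm{effect} \times \mathrm{AUC}$, and a block of
tissue-only offset genes for testing confounder adjustment.

## Numerical conventions

* Winsor limits default to the 1st/99th percentiles (type-7 quantiles).
* Degenerate constant signatures score 0.5 with SP 0.5, with a warning.
* A cell with zero detected signature genes still receives a (maximally
  penalised) score; NaN is reserved for signatures with zero gene
  coverage in the whole matrix, keeping the score matrix dense for
  clustering.
* KNN imputation breaks distance ties by cell order; genes with
  numerically zero variance get t-statistic 0; permutation p-values use
  the add-one estimator $(1 + \#\{|T^\pi| \ge |T|\})/(B + 1)$.
* Test-suite problem sizes (50–500 cells, hundreds to thousands of genes,
  200 null replicates) are chosen so the full suite runs in well under a
  minute while keeping every statistical check adequately powered.

## Limitations

* The SP is a population summary: it says nothing about *which* cells are
  sensitive without the accompanying scores.
* Scores are relative within a dataset (min-max rescaling); they are not
  comparable across datasets without a shared reference.
* Gene identifiers are matched exactly and case-sensitively (an optional
  uppercase fold exists in `read_gmt()`); no symbol/Ensembl conversion is
  attempted.
* The OLS t ranking assumes roughly homoscedastic expression across the
  response range; grossly heteroscedastic genes can over- or under-rank.
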