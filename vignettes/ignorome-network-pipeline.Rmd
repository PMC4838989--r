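---
title: "Methods: signature construction, ignorome partitioning and network topology"
author: "ignoromenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature construction, ignorome partitioning and network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignoromenet)
```

## The problem

Transcriptomic studies of the same disease rarely agree gene by gene:
platforms, strains, protocols and time points differ, and single-study gene
lists are dominated by the idiosyncrasies of each experiment. At the same
time, the literature on any disease is heavily concentrated on a small set of
"successful" genes, so that a large part of every disease signature has never
been studied in the disease context at all — its *ignorome*.

`ignoromenet` implements a pipeline that addresses both issues for a
collection of independent two-group comparisons (diseased vs control):

1. **Per-comparison differential expression** with a moderated t-statistic.
2. **Signature construction** by two complementary selections merged into a
   union list: a *pathway-driven* selection (genes of annotation terms
   enriched across comparisons) and a *gene-driven* selection (genes
   differentially expressed consistently across comparisons).
3. **Ignorome partitioning** of the signature against a frozen literature
   snapshot (publication counts plus disease-database flags).
4. **Network topology** of the signature mapped onto a protein–protein
   interaction network: Markov clusters, betweenness hubs, clique-attached
   peripheral genes, super-connectors, and inter-cluster connectivity.
5. **Validation statistics**: Fisher contingency comparisons of annotation
   rates, cross-platform fold-change correlation, median fold-change
   profiles, and a steroid-reversion classification.

Every input the pipeline consumes can be generated synthetically with
planted ground truth, so each stage's recovery behaviour is testable.

## Differential expression

Each study is quantile-normalized (after a log2 transform when the matrix
maximum exceeds 50, the heuristic for linear-scale intensities; the scale
can be forced via the `scale` argument). For gene $g$ with pooled variance
$s_g^2$ on $d_g$ residual degrees of freedom, the variance is shrunk toward
a prior $s_0^2$ with $d_0$ prior degrees of freedom:

$$ s_{\text{post}}^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t_g = \frac{\Delta_g}{s_{\text{post}}\sqrt{1/n_1 + 1/n_2}} \sim t_{d_0 + d_g}, $$

where $\Delta_g$ is the case-minus-control mean log2 difference. $(d_0,
s_0^2)$ are estimated from the ensemble of gene variances by the method of
moments under the scaled-F model $s_g^2 \sim s_0^2 F(d_g, d_0)$, which gives
a closed form for $d_0$ from the coefficient of variation of the $s_g^2$
(see `fit_variance_prior` in the source). When the observed variances are
less dispersed than any finite $d_0$ allows, the prior is degenerate and all
genes share the ensemble mean variance. This moment estimator is simpler
than the marginal-likelihood fit used by limma's `eBayes`; on simulated
data the two t-statistics agree to within 1% (checked in the test suite).
Genes with zero fold change and zero variance receive $p = 1$, never `NaN`,
so downstream set operations are total. Benjamini–Hochberg adjustment is
applied within each comparison.

## Signature construction

Both selections operate on the per-comparison DE sets
(`de_gene_set`: BH-adjusted $p <$ `alpha_de`, optional fold-change floor —
the default floor is 0 because consistently small changes are exactly what
multi-dataset analysis can rescue).

* **Pathway-driven** (`pathway_driven_select`): per comparison, each catalog
  term is tested for over-representation of the DE genes (hypergeometric
  upper tail against the measured universe, BH across terms). A term
  qualifies when enriched in at least `min_term_support` comparisons; the
  selection is the union over qualifying terms of (term genes ∩ DE genes of
  the comparisons where the term was enriched). A strongly DE gene outside
  every qualifying term is excluded — that is the point of the approach.
* **Gene-driven** (`gene_driven_select`): a gene qualifies when DE in at
  least `min_gene_support` comparisons with (by default) a consistent sign
  of change across all comparisons where it is DE.
* **Merge** (`merge_signature`): the union with provenance flags
  (`pathway`, `gene`, `both`); sizes obey inclusion–exclusion exactly.

Cross-comparison support thresholds have no canonical published values for
heterogeneous study collections; the defaults (`min_term_support = 2`,
`min_gene_support = 3`, `require_consistent_sign = TRUE`,
`alpha_enrich = 0.05`) encode "robust across independent experiments" and
are deliberately exposed in `signature_params()` rather than hard-coded.
The enrichment universe is the set of measured genes, not the genome, to
avoid platform bias. Gene identifiers are canonicalized (upper case,
trimmed) once, because mouse and human symbol casing differs.

## Ignorome partitioning

A signature gene is *annotated* when it has at least one publication in the
query context **or** carries any disease-database flag; otherwise it is
*ignorome*. The OR-semantics treats the literature and the databases as
complementary annotation sources. Counts are consumed from a static TSV
snapshot — never a live query — because reproducibility requires frozen
inputs. `literature_concentration` ranks genes by count (ties broken
lexicographically for determinism) and reports the publication share of the
top $k$; `coverage_histogram` bins genes by count with per-bin database
annotation fractions.

## Network topology

The signature's human orthologs (`map_orthologs`; unmapped genes are
reported, never dropped silently) induce a subgraph of a STRING-style edge
list (`build_network`), keeping edges with combined score ≥
`score_threshold` (default 400, STRING's "medium confidence").

**Clustering** is Markov Clustering (MCL) on the column-stochastic binary
adjacency with self-loops: alternate expansion (matrix square) and
inflation (entry-wise power `mcl_inflation`, column renormalization),
pruning entries below $10^{-8}$, until the maximum entry change falls below
$10^{-6}$ or 200 iterations (non-convergence yields a warning plus the
current partition — in practice convergence takes a few dozen iterations).
Clusters are the connected components of the limit matrix's support;
groups below `min_cluster_size` (default 5) are marked unclustered.

The inflation exponent is MCL's granularity knob. The default is **1.5**:
at the module scale this pipeline targets (clusters of tens of genes,
within-cluster density around 0.3) higher inflation systematically peels
dense substructures — in particular a clique plus its pendant gene — out of
their parent cluster into sub-threshold fragments, which destroys exactly
the peripheral-gene structure the topology stage is designed to find. At
1.5 the planted block structure of the synthetic generator is recovered
essentially perfectly (adjusted Rand index ≈ 1 in the acceptance checks)
while cliques stay embedded. Users clustering much larger or denser
networks may prefer higher values; the parameter is exposed in
`topology_params()`.

**Hubs** are, per cluster, the top `ceil(hub_fraction × size)` members by
betweenness centrality (global, unweighted — interaction scores only gate
the build; path lengths are hop counts), so every retained cluster has at
least one hub. Ties break by higher degree, then lexicographic identifier.

**Peripheral genes** are degree-1 nodes whose unique neighbor belongs to a
clique of at least `min_clique_size` nodes lying entirely inside the
neighbor's cluster; the reported witness is the largest such maximal
clique. Maximal cliques are enumerated exactly (igraph's branch-and-bound),
and the calls are verified in the test suite against exhaustive
subset-enumeration oracles on random graphs.

**Super-connectors** are genes whose own cluster plus their neighbors'
clusters number at least `superconnector_min_clusters` (default 5 —
"links at least five clusters"; unclustered neighbors are ignored).

**Inter-cluster connectivity** is the empirical block density matrix:
$S_{ij} = m_{ij} / (n_i n_j)$ for $i \ne j$ and
$S_{ii} = 2 m_{ii} / (n_i (n_i - 1))$, the natural scale-free measure of
relative connection strength between clusters.

Cluster-level term enrichment (`enrich_clusters`) reports, per cluster and
catalog, at most five terms with BH-adjusted $p < 0.05$, ordered by
ascending adjusted p-value.

## Validation statistics

* `annotation_category_comparison` builds the 2×2 table of two gene
  categories against a binary trait and applies the two-sided Fisher's
  exact test (point-probability convention — the convention under which the
  test reproduces published contingency p-values from their printed counts).
* `cross_platform_correlation` pairs mean microarray log2 fold changes with
  qPCR values per gene at a time point and reports Pearson r with the
  two-sided t-test p-value; genes present on one platform only are excluded
  and logged.
* `median_foldchange_profile` reports exact per-comparison medians of a
  gene set's log2 fold changes and their overall range. Note that with a
  dozen genes the sample median is itself noisy (asymptotic SE
  $1.253\,\sigma/\sqrt{n}$), so small planted shifts are localized only up
  to a few tenths of a log2 unit — the test suite checks the achievable
  concentration, computed from the order-statistic oracle, not an
  aspirational one.
* `classify_dex_response` formalizes steroid-reversion panels as a fixed
  rule cascade over three contrasts (disease vs control, treated vs
  control, treated vs disease) at a configurable `alpha` (default 0.05):
  not significantly deregulated → `not_changed`; treatment contrast not
  significant → `not_affected`; treatment pushing expression further from
  control (same sign, larger magnitude) → `further_downregulated`; treated
  arm indistinguishable from control → `completely_reverted`; otherwise
  `partially_reverted`. The cascade is a declared formalization — published
  figure panels do not state machine-checkable rules — and it takes the
  stricter reading that *partial* reversion still requires a significant
  treated-vs-disease contrast. The five categories partition all valid
  inputs.

## The synthetic-data generators

The generators produce every input with planted truth labels, and are pure
functions of their spec (including the seed): identical specs give
bit-identical output.

* **Expression** (`study_spec`, `generate_expression_study`): per-gene
  baselines uniform on log2 ∈ [6, 12] with Gaussian noise, emulating
  normalized small-n microarrays (defaults: 2000 genes, 5 per arm, 10
  comparisons, 5% DE at ±2 log2, noise SD 0.5, half the DE genes shared
  across comparisons with consistent sign). Generating directly on the log
  scale deliberately skips platform-specific preprocessing; the Gaussian
  log-scale model is a stand-in, not a claim about any real platform's
  variance structure. Probe-level artifacts, batch effects and covariates
  beyond the comparison identity are out of scope, so passing recovery
  tests demonstrate the pipeline's logic, not robustness to those
  real-data features.
* **Interaction network** (`network_spec`,
  `generate_interaction_network`): a stochastic block model (default 5 ×
  30 nodes, within-block density 0.3, between 0.01) with planted 4-cliques
  carrying one pendant gene each (6 by default) and planted connector nodes
  wired into 5 distinct blocks (2 by default); scores uniform in
  [400, 1000]. Truth labels describe the **realized** graph: with nonzero
  between-block density, background edges occasionally wire an ordinary
  node into five blocks, making it a genuine super-connector, so
  `is_superconnector` records the realized linked-block count while
  `is_planted_superconnector` marks the plant (with `p_between = 0` the two
  coincide).
* **Literature** (`literature_spec`, `generate_literature_counts`):
  zero-inflated discrete power law. The default zero fraction is 0.59 and
  the default tail exponent 2.5 is calibrated so that the 13 most-published
  genes of a 933-gene signature hold roughly one third of all publications
  — the concentration observed in real disease literature.

## Numerical choices and degenerate inputs

* Fisher's test errors on the all-zero table; enrichment validates count
  consistency; BH errors outside [0, 1]; correlation requires ≥ 3 pairs and
  errors (as "undefined-correlation") on zero variance.
* All ranking operations (hubs, concentration, witness cliques, enrichment
  report) carry deterministic tie-breaks, so reruns are byte-identical.
* The pipeline derives every stage seed from the single config seed;
  `summary.json` records seeds and parameters, and two runs with the same
  config are byte-identical (verified in the acceptance checks).
* Problem sizes in the test and acceptance suites (2000-gene single
  comparisons for calibration/power, 4-comparison signature recovery,
  150-node planted networks, ≥ 200 random oracle graphs of up to 25 nodes)
  were chosen as the smallest sizes at which the binomial/Monte-Carlo error
  bands quoted in the tests are meaningful.

## Limitations

* The published gene lists this design descends from are not reproducible
  from code alone — they depend on frozen external snapshots (expression
  repositories, literature queries, interaction databases, qPCR panels).
  The package therefore validates *properties* (calibration, planted-truth
  recovery, arithmetic identities) rather than re-deriving any published
  list.
* MCL granularity interacts with network scale; the 1.5 default is tuned to
  module-scale clusters, not to genome-scale interactomes.
* The moderated-t moment estimator assumes a common residual d.f. across
  genes (true for complete two-group designs, the only design supported).
* Literature counts are taken at face value; query construction, synonym
  resolution and text mining are explicitly out of scope.
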