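# ignoromenet

Multi-dataset gene-signature construction, literature-"ignorome"
partitioning, and interaction-network topology classification for
transcriptomic disease studies.

## What problem does this solve?

Independent transcriptomic studies of the same disease (different strains,
protocols, time points) rarely agree gene by gene, and the literature on any
disease concentrates on a few heavily studied genes. For researchers running
multi-dataset meta-analyses — e.g. of allergic-asthma mouse models — this
package builds a robust disease signature across comparisons, quantifies how
much of it the literature has ignored (the *ignorome*), and classifies the
signature's interaction-network topology to prioritize genes.

The pipeline has five stages, each usable on its own:

1. **Differential expression** per comparison: quantile normalization and an
   empirical-Bayes moderated t-statistic. Gene-wise variances are shrunk
   toward an ensemble prior, `s²_post = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, with
   (d₀, s₀²) estimated by the method of moments; p-values are BH-adjusted
   within each comparison.
2. **Signature construction**: a *pathway-driven* selection (DE genes of
   annotation terms with hypergeometric enrichment, BH-adjusted p < 0.05, in
   ≥ 2 comparisons) and a *gene-driven* selection (genes DE in ≥ 3
   comparisons with consistent sign), merged into a union list with
   provenance flags.
3. **Ignorome partition**: a signature gene is *annotated* if it has ≥ 1
   publication in the disease context or any disease-database flag;
   otherwise it belongs to the ignorome.
4. **Network topology**: the signature's human orthologs induce a subgraph
   of a STRING-style scored edge list (score ≥ 400 by default); Markov
   Clustering (inflation 1.5) finds clusters of ≥ 5 genes; per cluster the
   top 10% by betweenness centrality are *hubs*; degree-1 genes attached to
   an intra-cluster clique are *peripheral*; genes touching ≥ 5 clusters are
   *super-connectors*; inter-cluster connectivity is the empirical block
   density S_ij = m_ij/(n_i·n_j).
5. **Validation**: two-sided Fisher's exact comparisons of annotation rates
   between gene categories, cross-platform (microarray vs qPCR) Pearson
   correlation of log2 fold changes, median fold-change profiles, and a
   steroid-reversion rule cascade.

A first-class synthetic-data module generates every input with planted
ground truth (expression with planted DE genes, GMT catalogs with planted
terms, block-model networks with planted cliques/pendants/connectors,
zero-inflated power-law literature counts), so every stage's recovery
behaviour is tested, not assumed.

## Worked example

```r
library(ignoromenet)

# A published-style contingency question: 17/22 peripheral genes are
# inflammation-annotated vs 8/22 disease-annotated. Different?
fisher_exact_two_sided(matrix(c(8, 14, 17, 5), 2, byrow = TRUE))
#> [1] 0.01389734     # two-sided Fisher's exact p

# End-to-end synthetic run at the default configuration
run <- run_pipeline(outdir = "demo_run")
print(run)
#> Pipeline run (seed 1) in demo_run
#>   comparisons: 10 x 2000 genes
#>   signature: 54 genes (pathway 53, gene 51)
#>   ignorome: 29/54 (54%)
#>   network: 4 clusters, 6 hubs, 1 peripherals, 0 super-connectors
#>   validation: qPCR r = 0.989, median log2FC in [-1.175, -0.394]
```

The run directory contains each stage's outputs (per-comparison DE tables,
the signature TSV with provenance flags, the ignorome partition, cluster
assignments, a topology JSON with hubs/peripherals/super-connectors and
their witnesses, and `summary.json` with all counts, seeds and parameters).
Here 50 of the 54 signature genes are the planted cross-comparison DE
genes; 54% fall in the ignorome because the synthetic literature snapshot
plants a 59% zero-publication rate over the whole universe; and the network
counts refer to the signature's induced subgraph of the synthetic
interactome.

Topology classification on a planted network directly:

```r
net <- generate_interaction_network(network_spec(seed = 1))
g <- build_network(net$edges, net$truth$node,
                   topology_params(score_threshold = 0))
topology_report(g, topology_params(score_threshold = 0))
#> Topology report: 5 clusters, 20 hubs, 6 peripheral genes, 3 super-connectors
```

All five planted blocks, all six planted pendant genes and all realized
super-connectors (two planted, one arising from background edges) are
recovered exactly.

A thin command-line wrapper is installed at
`inst/cli/ignoromenet.R` (`system.file("cli", "ignoromenet.R", package =
"ignoromenet")`):

```sh
Rscript ignoromenet.R run --config cfg.yaml --outdir my_run --seed 7
```

## Documentation

The methods vignette
(`vignettes/ignorome-network-pipeline.Rmd`) describes the statistical model
of each stage, all tunable parameters with their defaults and rationale,
what the synthetic generators do and do not emulate, numerical choices, and
known limitations.
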