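#' Build a pipeline configuration
#'
#' Returns the default end-to-end configuration for a fully synthetic run,
#' optionally overridden from a YAML file or a named list. All randomness in
#' the pipeline flows from `seed`; per-stage seeds are derived from it, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config path to a YAML file, or a named list of overrides, or NULL
#'   for the defaults.
#' @param seed optional seed overriding the configured one.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL, seed = NULL) {
  defaults <- list(
    seed = 1L,
    study = list(n_genes = 2000, n_per_group = 5, n_comparisons = 10,
                 de_fraction = 0.05, effect_size_log2 = 2.0, noise_sd = 0.5,
                 shared_de_fraction = 0.5),
    catalog = list(n_terms = 50, size_range = c(10, 60), planted_term_size = 60),
    network = list(cluster_sizes = c(80, 80, 80, 80, 80), p_within = 0.3,
                   p_between = 0.01, n_pendant_on_clique = 6, clique_size = 4,
                   n_superconnectors = 2, k_sc = 5),
    literature = list(zero_fraction = 0.59, tail_exponent = 2.5, max_count = 10000),
    signature = list(alpha_enrich = 0.05, min_term_support = 2,
                     min_gene_support = 3, require_consistent_sign = TRUE,
                     alpha_de = 0.05, min_abs_log2fc = 0),
    topology = list(min_cluster_size = 5, hub_fraction = 0.10,
                    min_clique_size = 3, superconnector_min_clusters = 5,
                    mcl_inflation = 1.5, score_threshold = 400),
    validation = list(n_qpcr_genes = 12, qpcr_noise_sd = 0.3, timepoint = 72)
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaults, if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Run the analysis pipeline end to end on synthetic inputs
#'
#' Executes the stages in order — simulate, differential expression,
#' signature construction, ignorome partition, network topology, validation
#' — writing each stage's outputs under `outdir` and a machine-readable
#' `summary.json` recording per-stage counts, all seeds and parameter
#' values. A rerun with the same configuration produces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()], a YAML path, or NULL for defaults.
#' @param outdir run directory (created if needed).
#' @param last_stage run the pipeline only up to this stage (one of
#'   "simulate", "de", "signature", "ignorome", "network", "validate").
#' @return An `ignoromenet_run` object (invisibly): list with `summary`,
#'   `signature`, `partition`, `topology`, `config`, `outdir`.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("ignoromenet_run_"),
                         last_stage = "validate") {
  stages <- c("simulate", "de", "signature", "ignorome", "network", "validate")
  last_stage <- match.arg(last_stage, stages)
  n_stage <- match(last_stage, stages)
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = cfg$seed, parameters = unclass(cfg))
  run <- list(config = cfg, outdir = outdir)

  ## -- simulate ------------------------------------------------------------
  sspec <- do.call(study_spec, c(cfg$study, list(seed = stage_seed(cfg, 101))))
  sim <- generate_expression_study(sspec)
  universe <- sort(unique(sim$truth$gene_id))
  shared_de <- names(which(tapply(sim$truth$is_de, sim$truth$gene_id, all)))
  set.seed(stage_seed(cfg, 102))
  planted_term <- union(shared_de,
                        sample(setdiff(universe, shared_de),
                               max(0, cfg$catalog$planted_term_size - length(shared_de))))
  catalog <- generate_annotation_catalog(
    cfg$catalog$n_terms, cfg$catalog$size_range,
    planted_terms = list(PLANTED_TERM = planted_term),
    universe = universe, seed = stage_seed(cfg, 103))
  inputs_dir <- file.path(outdir, "inputs")
  dir.create(inputs_dir, showWarnings = FALSE)
  for (st in sim$studies) {
    write_expression_tsv(st, file.path(inputs_dir, paste0("expr_", st$comparison_id, ".tsv")))
  }
  write_gmt(catalog, file.path(inputs_dir, "catalog.gmt"))
  utils::write.table(sim$truth, file.path(inputs_dir, "truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$simulate <- list(n_comparisons = length(sim$studies),
                           n_genes = length(universe),
                           n_shared_de = length(shared_de))
  if (n_stage < 2) return(finish_run(run, summary))

  ## -- differential expression --------------------------------------------
  de_results <- lapply(sim$studies, function(st) {
    norm <- normalize_study(st$matrix, st$sample_groups, st$comparison_id)
    differential_expression(norm)
  })
  de_dir <- file.path(outdir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  for (res in de_results) {
    utils::write.table(res, file.path(de_dir, paste0("de_", res$comparison_id[1], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary$de <- list(
    n_de_per_comparison = vapply(de_results, function(r) {
      length(de_gene_set(r, cfg$signature$alpha_de, cfg$signature$min_abs_log2fc))
    }, integer(1)))
  if (n_stage < 3) return(finish_run(run, summary))

  ## -- signature -----------------------------------------------------------
  params <- do.call(signature_params, cfg$signature)
  de_sets <- lapply(de_results, de_gene_set, alpha = params$alpha_de,
                    min_abs_log2fc = params$min_abs_log2fc)
  pathway_set <- pathway_driven_select(de_sets, catalog, universe, params)
  gene_set <- gene_driven_select(de_results, params)
  signature <- merge_signature(pathway_set, gene_set, de_results, params)
  utils::write.table(signature, file.path(outdir, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run$signature <- signature
  summary$signature <- list(pathway_set_size = length(pathway_set),
                            gene_set_size = length(gene_set),
                            signature_size = nrow(signature))
  if (n_stage < 4) return(finish_run(run, summary))

  ## -- ignorome ------------------------------------------------------------
  lspec <- do.call(literature_spec, c(cfg$literature, list(seed = stage_seed(cfg, 104))))
  lit <- generate_literature_counts(lspec, universe, context = "disease")
  write_literature_tsv(lit, file.path(inputs_dir, "literature.tsv"))
  index <- literature_index(lit)
  partition <- classify_ignorome(signature, index)
  run$partition <- partition
  concentration13 <- tryCatch(
    literature_concentration(index, signature, min(13, nrow(signature))),
    error = function(e) NA_real_)
  utils::write.table(
    data.frame(gene_id = c(partition$annotated, partition$ignorome),
               status = rep(c("annotated", "ignorome"),
                            c(length(partition$annotated), length(partition$ignorome)))),
    file.path(outdir, "ignorome.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  summary$ignorome <- list(
    annotated = length(partition$annotated),
    ignorome = length(partition$ignorome),
    ignorome_fraction = length(partition$ignorome) / nrow(signature),
    top13_concentration = concentration13)
  if (n_stage < 5) return(finish_run(run, summary))

  ## -- network topology ----------------------------------------------------
  ortho <- data.frame(mouse_symbol = universe,
                      human_symbol = paste0("H_", universe),
                      stringsAsFactors = FALSE)
  write_ortholog_tsv(ortho, file.path(inputs_dir, "orthologs.tsv"))
  mapped <- map_orthologs(signature$gene_id, ortho)
  nspec <- do.call(network_spec, c(cfg$network, list(seed = stage_seed(cfg, 105))))
  n_nodes <- sum(nspec$cluster_sizes) + nspec$n_pendant_on_clique + nspec$n_superconnectors
  set.seed(stage_seed(cfg, 106))
  # the synthetic interactome contains all signature orthologs (scattered
  # across blocks) plus background genes, like a disease list mapped into a
  # genome-scale interaction database
  sig_h <- mapped$human_genes
  other_h <- setdiff(paste0("H_", universe), sig_h)
  pool <- c(sig_h, sample(other_h, max(0, n_nodes - length(sig_h))))
  net <- generate_interaction_network(nspec, node_names = sample(pool))
  write_edges_tsv(net$edges, file.path(inputs_dir, "network.tsv"))
  utils::write.table(net$truth, file.path(inputs_dir, "truth_network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tparams <- do.call(topology_params, cfg$topology)
  graph <- build_network(net$edges, sig_h, tparams)
  topo <- topology_report(graph, tparams)
  run$topology <- topo
  if (!is.null(topo$connectivity)) {
    utils::write.table(topo$connectivity, file.path(outdir, "connectivity.tsv"),
                       sep = "\t", quote = FALSE)
  }
  utils::write.table(
    data.frame(node = names(topo$clusters$membership),
               cluster = unname(topo$clusters$membership)),
    file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_report(
    list(hubs = topo$hubs,
         peripherals = if (nrow(topo$peripherals) > 0) {
           lapply(seq_len(nrow(topo$peripherals)), function(i) {
             list(gene_id = topo$peripherals$gene_id[i],
                  neighbor = topo$peripherals$neighbor[i],
                  cluster = topo$peripherals$cluster[i],
                  witness = topo$peripherals$witness[[i]])
           })
         } else list(),
         superconnectors = topo$superconnectors),
    file.path(outdir, "topology.json"))
  summary$network <- list(
    n_mapped_orthologs = length(mapped$human_genes),
    n_unmapped = length(mapped$unmapped),
    n_network_nodes = igraph::vcount(graph),
    n_network_edges = igraph::ecount(graph),
    n_clusters = length(topo$clusters$sizes),
    cluster_sizes = topo$clusters$sizes,
    n_hubs = length(unlist(topo$hubs)),
    n_peripherals = nrow(topo$peripherals),
    n_superconnectors = length(topo$superconnectors))
  if (n_stage < 6) return(finish_run(run, summary))

  ## -- validation ----------------------------------------------------------
  set.seed(stage_seed(cfg, 107))
  n_q <- min(cfg$validation$n_qpcr_genes, nrow(signature))
  qpcr_genes <- sort(sample(signature$gene_id, n_q))
  ma_mean <- vapply(qpcr_genes, function(g) {
    mean(vapply(de_results, function(r) r$log2fc[match(g, r$gene_id)], numeric(1)),
         na.rm = TRUE)
  }, numeric(1))
  fc_table <- rbind(
    data.frame(gene_id = qpcr_genes, platform = "microarray", log2fc = ma_mean,
               timepoint = cfg$validation$timepoint, stringsAsFactors = FALSE),
    data.frame(gene_id = qpcr_genes, platform = "qpcr",
               log2fc = ma_mean + stats::rnorm(n_q, sd = cfg$validation$qpcr_noise_sd),
               timepoint = cfg$validation$timepoint, stringsAsFactors = FALSE))
  corr <- suppressMessages(
    cross_platform_correlation(fc_table, cfg$validation$timepoint))
  profile <- suppressMessages(median_foldchange_profile(qpcr_genes, de_results))
  utils::write.table(profile, file.path(outdir, "median_foldchange.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$validation <- list(
    n_qpcr_genes = n_q,
    qpcr_correlation_r = corr$r,
    qpcr_correlation_p = corr$p_two_sided,
    median_fc_min = attr(profile, "range")[1],
    median_fc_max = attr(profile, "range")[2])
  finish_run(run, summary)
}

finish_run <- function(run, summary) {
  write_json_report(summary, file.path(run$outdir, "summary.json"))
  run$summary <- summary
  class(run) <- "ignoromenet_run"
  invisible(run)
}

#' @export
print.ignoromenet_run <- function(x, ...) {
  s <- x$summary
  cat("Pipeline run (seed ", s$seed, ") in ", x$outdir, "\n", sep = "")
  if (!is.null(s$simulate)) {
    cat(sprintf("  comparisons: %d x %d genes\n",
                s$simulate$n_comparisons, s$simulate$n_genes))
  }
  if (!is.null(s$signature)) {
    cat(sprintf("  signature: %d genes (pathway %d, gene %d)\n",
                s$signature$signature_size, s$signature$pathway_set_size,
                s$signature$gene_set_size))
  }
  if (!is.null(s$ignorome)) {
    cat(sprintf("  ignorome: %d/%d (%.0f%%)\n", s$ignorome$ignorome,
                s$ignorome$ignorome + s$ignorome$annotated,
                100 * s$ignorome$ignorome_fraction))
  }
  if (!is.null(s$network)) {
    cat(sprintf("  network: %d clusters, %d hubs, %d peripherals, %d super-connectors\n",
                s$network$n_clusters, s$network$n_hubs, s$network$n_peripherals,
                s$network$n_superconnectors))
  }
  if (!is.null(s$validation)) {
    cat(sprintf("  validation: qPCR r = %.3f, median log2FC in [%.3f, %.3f]\n",
                s$validation$qpcr_correlation_r, s$validation$median_fc_min,
                s$validation$median_fc_max))
  }
  invisible(x)
}

#' @export
summary.ignoromenet_run <- function(object, ...) object$summary
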