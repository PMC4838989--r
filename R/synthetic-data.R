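## Synthetic inputs with planted ground truth.
##
## Every generator is a pure function of its spec (including the seed):
## identical specs give bit-identical output, and every generated entity
## carries a truth label so recovery can be scored exactly.

#' Specification for a set of synthetic two-group expression comparisons
#'
#' Emulates several independent microarray studies of the same disease, each
#' contrasting diseased vs control animals, with a configurable fraction of
#' planted differentially expressed (DE) genes shared across all comparisons.
#' Expression is generated directly on the log2 scale with Gaussian noise.
#'
#' @param n_genes number of genes (rows) per study.
#' @param n_per_group samples per arm (control and case).
#' @param n_comparisons number of independent comparisons.
#' @param de_fraction fraction of genes planted as DE in each comparison.
#' @param effect_size_log2 mean planted log2 shift for DE genes (>= 0).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param shared_de_fraction fraction of each comparison's DE genes that are
#'   common to all comparisons (with a sign consistent across comparisons).
#' @param seed integer seed; fixes all randomness of the generator.
#' @return A `study_spec` list.
#' @export
study_spec <- function(n_genes = 2000, n_per_group = 5, n_comparisons = 10,
                       de_fraction = 0.05, effect_size_log2 = 2.0,
                       noise_sd = 0.5, shared_de_fraction = 0.5, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
               n_comparisons = as.integer(n_comparisons),
               de_fraction = de_fraction, effect_size_log2 = effect_size_log2,
               noise_sd = noise_sd, shared_de_fraction = shared_de_fraction,
               seed = as.integer(seed))
  if (spec$n_genes < 1 || spec$n_per_group < 1 || spec$n_comparisons < 1) {
    stop("invalid spec: dimensions must be positive", call. = FALSE)
  }
  if (de_fraction <= 0 || de_fraction >= 1 || de_fraction * spec$n_genes < 1) {
    stop("invalid spec: de_fraction must plant at least one gene", call. = FALSE)
  }
  if (shared_de_fraction < 0 || shared_de_fraction > 1) {
    stop("invalid spec: shared_de_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (effect_size_log2 < 0 || noise_sd <= 0) {
    stop("invalid spec: effect_size_log2 >= 0 and noise_sd > 0 required", call. = FALSE)
  }
  structure(spec, class = "study_spec")
}

#' Generate synthetic expression comparisons with planted DE genes
#'
#' Non-DE genes share a per-gene baseline (common to all comparisons) plus
#' Gaussian noise; DE genes are shifted in the case arm by
#' `effect_size_log2` with a random sign. Shared DE genes keep the same sign
#' in every comparison; comparison-specific DE genes are drawn fresh per
#' comparison from the remaining genes.
#'
#' @param spec a [study_spec()].
#' @return A list with elements `studies` (list of [expression_study()]
#'   objects, one per comparison) and `truth` (data.frame with columns
#'   `gene_id`, `comparison_id`, `is_de`, `sign` covering every gene in
#'   every comparison).
#' @export
generate_expression_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  comparisons <- make_comparison_ids(spec$n_comparisons)
  n_de <- round(spec$de_fraction * spec$n_genes)
  n_shared <- round(spec$shared_de_fraction * n_de)

  baseline <- stats::runif(spec$n_genes, min = 6, max = 12)
  names(baseline) <- genes
  shared_de <- sample(genes, n_shared)
  shared_sign <- stats::setNames(sample(c(-1, 1), n_shared, replace = TRUE), shared_de)

  n <- spec$n_per_group
  groups <- rep(c("control", "case"), each = n)
  studies <- vector("list", spec$n_comparisons)
  truth <- vector("list", spec$n_comparisons)
  for (k in seq_len(spec$n_comparisons)) {
    specific <- sample(setdiff(genes, shared_de), n_de - n_shared)
    de_genes <- c(shared_de, specific)
    sign_k <- stats::setNames(numeric(spec$n_genes), genes)
    sign_k[shared_de] <- shared_sign
    sign_k[specific] <- sample(c(-1, 1), length(specific), replace = TRUE)

    mat <- matrix(stats::rnorm(spec$n_genes * 2 * n, sd = spec$noise_sd),
                  nrow = spec$n_genes) + baseline
    shift <- sign_k * spec$effect_size_log2
    mat[, groups == "case"] <- mat[, groups == "case"] + shift
    dimnames(mat) <- list(genes, sprintf("%s_S%02d", comparisons[k], seq_len(2 * n)))

    studies[[k]] <- expression_study(mat, groups, comparisons[k])
    truth[[k]] <- data.frame(gene_id = genes, comparison_id = comparisons[k],
                             is_de = genes %in% de_genes, sign = unname(sign_k),
                             stringsAsFactors = FALSE)
  }
  names(studies) <- comparisons
  list(studies = studies, truth = do.call(rbind, truth))
}

make_comparison_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("C%03d", seq_len(n))
}

#' Generate a term-to-gene annotation catalog
#'
#' Planted terms are included verbatim; random terms draw genes uniformly
#' without replacement from the universe, with sizes uniform in
#' `size_range`. The catalog round-trips through GMT.
#'
#' @param n_terms number of random terms to add.
#' @param size_range length-2 integer vector, inclusive range of random term
#'   sizes.
#' @param planted_terms named list of character vectors (term -> genes),
#'   each a subset of `universe`. May be empty.
#' @param universe character vector of all gene identifiers.
#' @param seed integer seed.
#' @return Named list of character vectors (term -> genes).
#' @export
generate_annotation_catalog <- function(n_terms, size_range, planted_terms = list(),
                                        universe, seed = 1L) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(unlist(planted_terms) %in% universe)) {
    stop("planted term genes must be a subset of the universe", call. = FALSE)
  }
  set.seed(as.integer(seed))
  size_choices <- seq(size_range[1], size_range[2])
  sizes <- if (length(size_choices) == 1) {
    rep(size_choices, n_terms)
  } else {
    sample(size_choices, n_terms, replace = TRUE)
  }
  random_terms <- lapply(sizes, function(s) sample(universe, min(s, length(universe))))
  names(random_terms) <- sprintf("RAND_TERM_%03d", seq_len(n_terms))
  c(planted_terms, random_terms)
}

#' Specification for a synthetic interaction network with planted topology
#'
#' A stochastic block model (dense within blocks, sparse between) with three
#' kinds of planted features carrying ground-truth labels: cliques with a
#' pendant (degree-1) node attached, and super-connector nodes wired into
#' at least `k_sc` distinct blocks.
#'
#' @param cluster_sizes integer vector of block sizes.
#' @param p_within,p_between within-/between-block edge probabilities
#'   (`p_within > p_between` required).
#' @param n_pendant_on_clique number of planted degree-1 nodes, each attached
#'   to a planted clique inside a block.
#' @param clique_size size of each planted clique (>= 3).
#' @param n_superconnectors number of planted connector nodes.
#' @param k_sc number of distinct blocks each planted connector reaches.
#' @param seed integer seed.
#' @return A `network_spec` list.
#' @export
network_spec <- function(cluster_sizes = c(30, 30, 30, 30, 30),
                         p_within = 0.3, p_between = 0.01,
                         n_pendant_on_clique = 6, clique_size = 4,
                         n_superconnectors = 2, k_sc = 5, seed = 1L) {
  if (any(cluster_sizes < 1)) stop("invalid spec: cluster sizes must be positive", call. = FALSE)
  if (!(p_within > p_between)) stop("invalid spec: p_within must exceed p_between", call. = FALSE)
  if (clique_size < 3) stop("invalid spec: clique_size must be >= 3", call. = FALSE)
  if (k_sc > length(cluster_sizes)) {
    stop("invalid spec: k_sc cannot exceed the number of blocks", call. = FALSE)
  }
  if (clique_size > min(cluster_sizes)) {
    stop("invalid spec: clique_size larger than the smallest block", call. = FALSE)
  }
  structure(list(cluster_sizes = as.integer(cluster_sizes), p_within = p_within,
                 p_between = p_between,
                 n_pendant_on_clique = as.integer(n_pendant_on_clique),
                 clique_size = as.integer(clique_size),
                 n_superconnectors = as.integer(n_superconnectors),
                 k_sc = as.integer(k_sc), seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a synthetic interaction network with planted truth labels
#'
#' Block-model edges are sampled independently; each planted pendant has
#' degree exactly 1, attached to a member of a planted clique of
#' `clique_size` fully connected nodes inside one block; each planted
#' super-connector has exactly one neighbor in each of `k_sc` distinct
#' blocks. Edge scores are uniform integers in \[400, 1000\], mirroring
#' STRING combined scores at medium-or-better confidence.
#'
#' @param spec a [network_spec()].
#' @param node_names optional character vector of node names (length >=
#'   total nodes); defaults to `NODE0001`, ...
#' @return A list with `edges` (data.frame: node1, node2, combined_score),
#'   and `truth` (data.frame: node, cluster, is_pendant, is_superconnector,
#'   is_planted_superconnector, linked_blocks; pendants carry their host
#'   block id, planted connectors NA). `is_superconnector` is the realized
#'   label — TRUE for any node whose own-plus-neighbor blocks number at
#'   least `k_sc` — since background edges can create genuine connectors
#'   beyond the planted ones (never when `p_between = 0`).
#' @export
generate_interaction_network <- function(spec, node_names = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  n_block <- sum(spec$cluster_sizes)
  n_total <- n_block + spec$n_pendant_on_clique + spec$n_superconnectors
  if (is.null(node_names)) {
    node_names <- sprintf("NODE%04d", seq_len(n_total))
  } else if (length(node_names) < n_total) {
    stop("node_names shorter than the number of generated nodes", call. = FALSE)
  } else {
    node_names <- node_names[seq_len(n_total)]
  }
  block_of <- rep(seq_along(spec$cluster_sizes), spec$cluster_sizes)
  block_nodes <- node_names[seq_len(n_block)]

  # block-model edges: independent Bernoulli per unordered pair
  pairs <- utils::combn(n_block, 2)
  same <- block_of[pairs[1, ]] == block_of[pairs[2, ]]
  p <- ifelse(same, spec$p_within, spec$p_between)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(node1 = block_nodes[pairs[1, keep]],
                      node2 = block_nodes[pairs[2, keep]],
                      stringsAsFactors = FALSE)

  # planted cliques + pendants: pendant i attaches to a clique in block
  # (i mod n_blocks); clique edges are forced present
  is_pendant <- logical(n_total)
  pendant_cluster <- rep(NA_integer_, n_total)
  if (spec$n_pendant_on_clique > 0) {
    for (i in seq_len(spec$n_pendant_on_clique)) {
      host_block <- ((i - 1L) %% length(spec$cluster_sizes)) + 1L
      members <- sample(block_nodes[block_of == host_block], spec$clique_size)
      cl_pairs <- utils::combn(members, 2)
      edges <- rbind(edges, data.frame(node1 = cl_pairs[1, ], node2 = cl_pairs[2, ],
                                       stringsAsFactors = FALSE))
      pendant <- node_names[n_block + i]
      is_pendant[n_block + i] <- TRUE
      pendant_cluster[n_block + i] <- host_block
      edges <- rbind(edges, data.frame(node1 = pendant, node2 = members[1],
                                       stringsAsFactors = FALSE))
    }
  }

  # planted super-connectors: one neighbor in each of k_sc distinct blocks
  is_sc <- logical(n_total)
  if (spec$n_superconnectors > 0) {
    for (i in seq_len(spec$n_superconnectors)) {
      sc <- node_names[n_block + spec$n_pendant_on_clique + i]
      is_sc[n_block + spec$n_pendant_on_clique + i] <- TRUE
      target_blocks <- sample(seq_along(spec$cluster_sizes), spec$k_sc)
      nbrs <- vapply(target_blocks, function(b) {
        sample(block_nodes[block_of == b], 1)
      }, character(1))
      edges <- rbind(edges, data.frame(node1 = sc, node2 = nbrs,
                                       stringsAsFactors = FALSE))
    }
  }

  # dedupe (clique forcing may duplicate a sampled block edge), score edges
  key <- ifelse(edges$node1 < edges$node2,
                paste(edges$node1, edges$node2), paste(edges$node2, edges$node1))
  edges <- edges[!duplicated(key), ]
  edges$combined_score <- as.integer(round(stats::runif(nrow(edges), 400, 1000)))
  rownames(edges) <- NULL

  # realized linked-block count per node: own block plus neighbors' blocks.
  # Background edges can wire an ordinary block node into >= k_sc blocks by
  # chance, making it a genuine super-connector of the generated graph, so
  # the truth label reflects the realized graph, not just the plant.
  block_lookup <- stats::setNames(c(block_of, rep(NA_integer_,
                                                  n_total - n_block)), node_names)
  linked_blocks <- vapply(node_names, function(v) {
    nb <- c(edges$node2[edges$node1 == v], edges$node1[edges$node2 == v])
    length(unique(stats::na.omit(c(block_lookup[v], block_lookup[nb]))))
  }, integer(1))

  truth <- data.frame(node = node_names,
                      cluster = c(block_of, pendant_cluster[is_pendant],
                                  rep(NA_integer_, spec$n_superconnectors)),
                      is_pendant = is_pendant,
                      is_superconnector = unname(linked_blocks >= spec$k_sc),
                      is_planted_superconnector = is_sc,
                      linked_blocks = unname(linked_blocks),
                      stringsAsFactors = FALSE)
  list(edges = edges, truth = truth)
}

#' Specification for synthetic gene publication counts
#'
#' A zero-inflated, heavy-tailed model of literature coverage: a fraction of
#' genes have no publications at all; the rest draw counts from a discrete
#' power law truncated at `max_count`. The default exponent 2.5 is calibrated
#' so that, at the default 59% zero fraction over a signature-sized gene set,
#' the 13 most-published genes hold roughly one third of all publications —
#' the concentration seen in real disease literature.
#'
#' @param zero_fraction probability that a gene has zero publications.
#' @param tail_exponent power-law exponent (> 1) for nonzero counts.
#' @param max_count truncation cap for counts.
#' @param seed integer seed.
#' @return A `literature_spec` list.
#' @export
literature_spec <- function(zero_fraction = 0.59, tail_exponent = 2.5,
                            max_count = 10000, seed = 1L) {
  if (zero_fraction < 0 || zero_fraction > 1) {
    stop("zero_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (tail_exponent <= 1) stop("tail_exponent must exceed 1", call. = FALSE)
  if (max_count < 1) stop("max_count must be positive", call. = FALSE)
  structure(list(zero_fraction = zero_fraction, tail_exponent = tail_exponent,
                 max_count = as.integer(max_count), seed = as.integer(seed)),
            class = "literature_spec")
}

#' Generate synthetic per-gene publication counts
#'
#' @param spec a [literature_spec()].
#' @param genes character vector of gene identifiers (non-empty).
#' @param context query-context label attached to the output.
#' @return data.frame with columns `gene_id`, `context`, `count`.
#' @export
generate_literature_counts <- function(spec, genes, context = "disease") {
  stopifnot(inherits(spec, "literature_spec"))
  if (length(genes) == 0) stop("`genes` must be non-empty", call. = FALSE)
  set.seed(spec$seed)
  zero <- stats::runif(length(genes)) < spec$zero_fraction
  # discrete truncated power law by inverse-CDF lookup
  support <- seq_len(spec$max_count)
  pmf <- support^(-spec$tail_exponent)
  cdf <- cumsum(pmf) / sum(pmf)
  counts <- integer(length(genes))
  n_pos <- sum(!zero)
  if (n_pos > 0) {
    counts[!zero] <- findInterval(stats::runif(n_pos), cdf) + 1L
  }
  data.frame(gene_id = genes, context = context, count = counts,
             stringsAsFactors = FALSE)
}
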