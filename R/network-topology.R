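#' Parameters for interaction-network topology classification
#'
#' @param min_cluster_size smallest cluster retained after clustering;
#'   smaller groups are marked unclustered. Default 5.
#' @param hub_fraction fraction of each cluster called hubs (top of the
#'   betweenness ranking, ceil rounding so every cluster has >= 1 hub).
#'   Default 0.10.
#' @param min_clique_size minimum clique a peripheral gene's neighbor must
#'   belong to. Default 3 (a triangle).
#' @param superconnector_min_clusters minimum number of distinct clusters a
#'   super-connector must touch (its own plus its neighbors'). Default 5.
#' @param mcl_inflation Markov-clustering inflation exponent (> 1; larger =
#'   finer clusters). Default 1.5, calibrated to the coarse module scale of
#'   disease networks (clusters of tens of genes); higher values fragment
#'   dense substructures such as cliques out of their parent cluster.
#' @param score_threshold minimum interaction score (STRING combined-score
#'   scale, 0-1000) for an edge to enter the network. Default 400
#'   ("medium confidence").
#' @return A `topology_params` list.
#' @export
topology_params <- function(min_cluster_size = 5, hub_fraction = 0.10,
                            min_clique_size = 3, superconnector_min_clusters = 5,
                            mcl_inflation = 1.5, score_threshold = 400) {
  if (hub_fraction <= 0 || hub_fraction > 1) stop("hub_fraction must lie in (0, 1]", call. = FALSE)
  if (min_clique_size < 3) stop("min_clique_size must be >= 3", call. = FALSE)
  if (mcl_inflation <= 1) stop("mcl_inflation must exceed 1", call. = FALSE)
  if (score_threshold < 0 || score_threshold > 1000) {
    stop("score_threshold must lie in [0, 1000]", call. = FALSE)
  }
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 hub_fraction = hub_fraction,
                 min_clique_size = as.integer(min_clique_size),
                 superconnector_min_clusters = as.integer(superconnector_min_clusters),
                 mcl_inflation = mcl_inflation,
                 score_threshold = score_threshold),
            class = "topology_params")
}

#' Map mouse genes to human orthologs
#'
#' @param mouse_genes character vector of mouse gene symbols.
#' @param ortholog_table data.frame with columns `mouse_symbol`,
#'   `human_symbol`; one-to-many mappings allowed.
#' @return List with `human_genes` (unique mapped human symbols) and
#'   `unmapped` (mouse genes with no table entry — reported, never silently
#'   dropped).
#' @export
map_orthologs <- function(mouse_genes, ortholog_table) {
  if (nrow(ortholog_table) == 0) stop("empty ortholog table", call. = FALSE)
  stopifnot(all(c("mouse_symbol", "human_symbol") %in% names(ortholog_table)))
  mouse_genes <- unique(canonicalize_genes(mouse_genes))
  tab_mouse <- canonicalize_genes(ortholog_table$mouse_symbol)
  mapped <- mouse_genes %in% tab_mouse
  human <- unique(canonicalize_genes(
    ortholog_table$human_symbol[tab_mouse %in% mouse_genes]))
  list(human_genes = sort(human), unmapped = sort(mouse_genes[!mapped]))
}

#' Build the interaction network induced by a gene set
#'
#' Keeps edges with `combined_score >= score_threshold` whose two endpoints
#' both lie in `gene_set`; removes self-loops and duplicate edges (keeping
#' the highest score). Returns an undirected igraph graph with a `score`
#' edge attribute; all genes of `gene_set` present in the edge list become
#' nodes (isolated network genes outside every surviving edge are dropped).
#'
#' @param edges data.frame with columns `node1`, `node2`, `combined_score`
#'   (scores in \[0, 1000\]), e.g. from [read_edges_tsv()].
#' @param gene_set character vector of genes to induce the subgraph on.
#' @param params a [topology_params()].
#' @return An undirected igraph object.
#' @export
build_network <- function(edges, gene_set, params = topology_params()) {
  stopifnot(all(c("node1", "node2", "combined_score") %in% names(edges)))
  gene_set <- unique(canonicalize_genes(gene_set))
  e <- data.frame(node1 = canonicalize_genes(edges$node1),
                  node2 = canonicalize_genes(edges$node2),
                  score = edges$combined_score, stringsAsFactors = FALSE)
  e <- e[e$score >= params$score_threshold &
           e$node1 %in% gene_set & e$node2 %in% gene_set &
           e$node1 != e$node2, , drop = FALSE]
  # dedupe undirected pairs, keep max score
  key <- ifelse(e$node1 < e$node2, paste(e$node1, e$node2), paste(e$node2, e$node1))
  e <- e[order(key, -e$score), ]
  e <- e[!duplicated(ifelse(e$node1 < e$node2, paste(e$node1, e$node2),
                            paste(e$node2, e$node1))), , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("node1", "node2")], directed = FALSE)
  igraph::E(g)$score <- e$score
  g
}

#' Markov clustering (MCL) of an interaction network
#'
#' Runs Markov Clustering on the column-stochastic adjacency matrix with
#' self-loops added: alternately expand (matrix square) and inflate (raise
#' entries to `mcl_inflation`, renormalize columns), pruning entries below
#' 1e-8, until the largest entry change falls below 1e-6 or 200 iterations
#' (non-convergence yields a warning and the current partition). Clusters
#' are the connected components of the limit matrix's support; clusters
#' smaller than `min_cluster_size` are marked unclustered.
#'
#' @param network an igraph graph from [build_network()].
#' @param params a [topology_params()].
#' @return A `cluster_assignment`: list with `membership` (named integer
#'   vector, NA = unclustered), `sizes` (per retained cluster, decreasing),
#'   and `discarded` (list of node groups below the size threshold).
#' @export
detect_clusters <- function(network, params = topology_params()) {
  n <- igraph::vcount(network)
  if (n == 0) stop("empty network", call. = FALSE)
  nodes <- igraph::V(network)$name
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = TRUE))
  M <- A + diag(n)
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (iter in seq_len(200)) {
    M_new <- M %*% M                       # expansion
    M_new <- M_new^params$mcl_inflation    # inflation
    M_new[M_new < 1e-8] <- 0               # pruning
    M_new <- sweep(M_new, 2, colSums(M_new), "/")
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Markov clustering did not converge in 200 iterations; returning current partition")
  }
  support <- (M > 0) | (t(M) > 0)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(support, mode = "undirected", diag = FALSE))
  raw <- comp$membership
  names(raw) <- nodes

  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= params$min_cluster_size])
  discarded <- lapply(setdiff(unique(raw), keep), function(k) nodes[raw == k])
  membership <- rep(NA_integer_, n)
  names(membership) <- nodes
  # relabel retained clusters 1..K by decreasing size (ties: smallest member id)
  keep_sizes <- sizes[as.character(keep)]
  first_member <- vapply(keep, function(k) min(nodes[raw == k]), character(1))
  ord <- order(-as.integer(keep_sizes), first_member)
  for (i in seq_along(ord)) {
    membership[raw == keep[ord[i]]] <- i
  }
  structure(list(membership = membership,
                 sizes = as.integer(sort(table(membership), decreasing = TRUE)),
                 discarded = discarded),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d clusters (sizes %s), %d unclustered nodes\n",
              length(x$sizes), paste(x$sizes, collapse = ", "),
              sum(is.na(x$membership))))
  invisible(x)
}

#' Betweenness centrality on the unweighted network skeleton
#'
#' For node v, B(v) = sum over unordered pairs s != v != t of
#' sigma_st(v) / sigma_st, with shortest paths counted on the unweighted
#' skeleton (interaction scores affect only the build threshold, not path
#' lengths). Computed exactly; isolated nodes get 0.
#'
#' @param network an igraph graph.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(network) {
  b <- igraph::betweenness(network, directed = FALSE, weights = NA)
  stats::setNames(as.numeric(b), igraph::V(network)$name)
}

#' Per-cluster hub genes by betweenness ranking
#'
#' Each cluster's hubs are its top `ceil(hub_fraction * size)` members by
#' betweenness centrality, so every non-empty cluster has at least one hub.
#' Ties are broken by higher degree, then lexicographic gene id, making the
#' selection deterministic.
#'
#' @param network an igraph graph (used for the degree tie-break).
#' @param clusters a `cluster_assignment`.
#' @param betweenness named vector from [betweenness_centrality()].
#' @param params a [topology_params()].
#' @return Named list: cluster id -> character vector of hub genes.
#' @export
detect_hubs <- function(network, clusters, betweenness, params = topology_params()) {
  deg <- igraph::degree(network)
  cl_ids <- sort(unique(clusters$membership[!is.na(clusters$membership)]))
  if (length(cl_ids) == 0) return(list())
  out <- lapply(cl_ids, function(k) {
    members <- names(clusters$membership)[!is.na(clusters$membership) &
                                            clusters$membership == k]
    if (length(members) == 0) stop("empty cluster", call. = FALSE)
    ord <- order(-betweenness[members], -deg[members], members)
    n_hubs <- ceiling(params$hub_fraction * length(members))
    members[ord][seq_len(n_hubs)]
  })
  names(out) <- as.character(cl_ids)
  out
}

#' Peripheral genes: degree-1 nodes attached to a clique
#'
#' A gene is peripheral iff its degree is exactly 1 and its unique neighbor
#' belongs to at least one clique of `min_clique_size` or more nodes lying
#' entirely inside the neighbor's cluster. The witness reported for each
#' peripheral gene is the largest such maximal clique (ties broken by
#' lexicographic member order). Maximal cliques are enumerated exactly.
#'
#' @param network an igraph graph.
#' @param clusters a `cluster_assignment`.
#' @param params a [topology_params()].
#' @return data.frame with columns `gene_id`, `neighbor`, `cluster`, and a
#'   list-column `witness` holding one clique (character vector) per row.
#' @export
detect_peripheral <- function(network, clusters, params = topology_params()) {
  deg <- igraph::degree(network)
  pendants <- names(deg)[deg == 1]
  empty <- data.frame(gene_id = character(0), neighbor = character(0),
                      cluster = integer(0), stringsAsFactors = FALSE)
  empty$witness <- list()
  if (length(pendants) == 0) return(empty)
  rows <- list()
  for (p in pendants) {
    nb <- igraph::neighbors(network, p)$name
    cl <- clusters$membership[nb]
    if (is.na(cl)) next
    members <- setdiff(names(clusters$membership)[!is.na(clusters$membership) &
                                                    clusters$membership == cl], p)
    sub <- igraph::induced_subgraph(network, members)
    cliques <- igraph::max_cliques(sub, min = params$min_clique_size)
    witnesses <- Filter(function(cq) nb %in% cq,
                        lapply(cliques, function(cq) sort(igraph::V(sub)$name[cq])))
    if (length(witnesses) == 0) next
    ord <- order(-vapply(witnesses, length, integer(1)),
                 vapply(witnesses, function(w) paste(w, collapse = "|"), character(1)))
    rows[[p]] <- list(gene_id = p, neighbor = nb, cluster = unname(cl),
                      witness = witnesses[[ord[1]]])
  }
  if (length(rows) == 0) return(empty)
  out <- data.frame(gene_id = vapply(rows, `[[`, character(1), "gene_id"),
                    neighbor = vapply(rows, `[[`, character(1), "neighbor"),
                    cluster = vapply(rows, `[[`, integer(1), "cluster"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$witness <- lapply(rows, `[[`, "witness")
  out[order(out$gene_id), , drop = FALSE]
}

#' Super-connectors: genes touching many clusters
#'
#' For gene g, linked(g) is its own cluster (if clustered) together with the
#' clusters of its neighbors (unclustered neighbors are ignored). g is a
#' super-connector iff |linked(g)| >= `superconnector_min_clusters`.
#'
#' @param network an igraph graph.
#' @param clusters a `cluster_assignment`.
#' @param params a [topology_params()].
#' @return Named list: gene -> sorted integer vector of linked cluster ids,
#'   for qualifying genes only.
#' @export
detect_superconnectors <- function(network, clusters, params = topology_params()) {
  nodes <- igraph::V(network)$name
  linked <- lapply(nodes, function(g) {
    nb <- igraph::neighbors(network, g)$name
    cl <- c(clusters$membership[g], clusters$membership[nb])
    sort(unique(cl[!is.na(cl)]))
  })
  names(linked) <- nodes
  linked[vapply(linked, length, integer(1)) >= params$superconnector_min_clusters]
}

#' Inter-cluster connectivity strength matrix
#'
#' S_ij = (edges between clusters i and j) / (n_i * n_j) for i != j, and
#' S_ii = 2 * (edges within cluster i) / (n_i * (n_i - 1)): the empirical
#' edge densities of the block structure. Symmetric, entries in \[0, 1\].
#'
#' @param network an igraph graph.
#' @param clusters a `cluster_assignment` with at least 2 clusters.
#' @return K x K numeric matrix with cluster ids as dimnames.
#' @export
cluster_connectivity <- function(network, clusters) {
  cl_ids <- sort(unique(clusters$membership[!is.na(clusters$membership)]))
  if (length(cl_ids) < 2) stop("need at least 2 clusters", call. = FALSE)
  sizes <- vapply(cl_ids, function(k) sum(clusters$membership == k, na.rm = TRUE),
                  integer(1))
  el <- igraph::as_edgelist(network)
  c1 <- clusters$membership[el[, 1]]
  c2 <- clusters$membership[el[, 2]]
  K <- length(cl_ids)
  S <- matrix(0, K, K, dimnames = list(cl_ids, cl_ids))
  for (i in seq_len(K)) {
    for (j in i:K) {
      a <- cl_ids[i]; b <- cl_ids[j]
      m <- sum((c1 == a & c2 == b) | (c1 == b & c2 == a), na.rm = TRUE)
      S[i, j] <- S[j, i] <- if (i == j) {
        if (sizes[i] < 2) 0 else 2 * m / (sizes[i] * (sizes[i] - 1))
      } else {
        m / (sizes[i] * sizes[j])
      }
    }
  }
  S
}

#' Per-cluster term enrichment against one or more catalogs
#'
#' For each cluster and catalog: hypergeometric upper-tail p per term, BH
#' across the catalog's terms, then the terms with adjusted p < `alpha`
#' ordered by ascending adjusted p, capped at `max_terms`.
#'
#' @param clusters a `cluster_assignment`.
#' @param catalogs named list of catalogs; each catalog a named list
#'   (term -> gene vector).
#' @param universe character vector of all genes eligible for membership.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param max_terms report cap per cluster and catalog (default 5).
#' @return data.frame with columns `cluster`, `catalog`, `term`, `hits`,
#'   `term_size`, `p_adj`.
#' @export
enrich_clusters <- function(clusters, catalogs, universe, alpha = 0.05, max_terms = 5) {
  if (length(catalogs) == 0 || any(vapply(catalogs, length, integer(1)) == 0)) {
    stop("catalogs must be non-empty", call. = FALSE)
  }
  universe <- unique(canonicalize_genes(universe))
  cl_ids <- sort(unique(clusters$membership[!is.na(clusters$membership)]))
  out <- list()
  for (k in cl_ids) {
    members <- intersect(canonicalize_genes(
      names(clusters$membership)[!is.na(clusters$membership) &
                                   clusters$membership == k]), universe)
    for (cat_name in names(catalogs)) {
      cat_terms <- lapply(catalogs[[cat_name]],
                          function(g) intersect(canonicalize_genes(g), universe))
      hits <- vapply(cat_terms, function(tg) length(intersect(tg, members)), integer(1))
      tsize <- vapply(cat_terms, length, integer(1))
      ok <- tsize > 0
      if (!any(ok)) next
      p <- mapply(hypergeometric_enrichment, hits[ok], length(members),
                  tsize[ok], length(universe))
      p_adj <- bh_adjust(p)
      sig <- which(p_adj < alpha)
      if (length(sig) == 0) next
      sig <- sig[order(p_adj[sig], names(cat_terms)[ok][sig])]
      sig <- sig[seq_len(min(max_terms, length(sig)))]
      out[[length(out) + 1]] <- data.frame(
        cluster = k, catalog = cat_name, term = names(cat_terms)[ok][sig],
        hits = hits[ok][sig], term_size = tsize[ok][sig], p_adj = p_adj[sig],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster = integer(0), catalog = character(0),
                      term = character(0), hits = integer(0),
                      term_size = integer(0), p_adj = numeric(0)))
  }
  do.call(rbind, out)
}

#' Full topology classification of an interaction network
#'
#' Convenience wrapper chaining [detect_clusters()],
#' [betweenness_centrality()], [detect_hubs()], [detect_peripheral()],
#' [detect_superconnectors()] and [cluster_connectivity()].
#'
#' @param network an igraph graph from [build_network()].
#' @param params a [topology_params()].
#' @return A `topology_report`: list with `clusters`, `betweenness`, `hubs`,
#'   `peripherals`, `superconnectors`, `connectivity` (NULL when fewer than
#'   2 clusters).
#' @export
topology_report <- function(network, params = topology_params()) {
  clusters <- detect_clusters(network, params)
  btw <- betweenness_centrality(network)
  n_clusters <- length(clusters$sizes)
  structure(list(
    clusters = clusters,
    betweenness = btw,
    hubs = detect_hubs(network, clusters, btw, params),
    peripherals = detect_peripheral(network, clusters, params),
    superconnectors = detect_superconnectors(network, clusters, params),
    connectivity = if (n_clusters >= 2) cluster_connectivity(network, clusters) else NULL
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "Topology report: %d clusters, %d hubs, %d peripheral genes, %d super-connectors\n",
    length(x$clusters$sizes), length(unlist(x$hubs)),
    nrow(x$peripherals), length(x$superconnectors)))
  invisible(x)
}
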