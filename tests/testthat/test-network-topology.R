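params0 <- topology_params(score_threshold = 0)

graph_from_adj <- function(adj) {
  edges <- adjacency_to_edges(adj)
  build_network(edges, sprintf("N%02d", seq_len(nrow(adj))), params0)
}

test_that("ortholog mapping keeps paralogs, reports unmapped, rejects empty tables", {
  tab <- data.frame(mouse_symbol = c("Il6", "Il6", "Cd4"),
                    human_symbol = c("IL6", "IL6B", "CD4"))
  res <- map_orthologs(c("Il6", "Cd4", "Novel1"), tab)
  expect_setequal(res$human_genes, c("IL6", "IL6B", "CD4"))
  expect_equal(res$unmapped, "NOVEL1")
  ident <- data.frame(mouse_symbol = c("A", "B"), human_symbol = c("A", "B"))
  expect_setequal(map_orthologs(c("A", "B"), ident)$human_genes, c("A", "B"))
  expect_error(map_orthologs("A", tab[0, ]), "empty")
})

test_that("network build filters by score, induces on the gene set, dedupes", {
  edges <- data.frame(node1 = c("A", "A", "B", "C", "D", "A"),
                      node2 = c("B", "B", "C", "C", "E", "A"),
                      combined_score = c(500, 700, 300, 900, 800, 999))
  g <- build_network(edges, c("A", "B", "C", "D", "E"),
                     topology_params(score_threshold = 400))
  # A-B deduped (score 700 kept), B-C dropped (score), C-C self-loop and
  # A-A dropped, D-E kept
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::E(g)$score), c(700, 800))
  perfect <- build_network(edges, LETTERS[1:5], topology_params(score_threshold = 1000))
  expect_equal(igraph::ecount(perfect), 0)
  disjoint <- build_network(edges, c("X", "Y"), params0)
  expect_equal(igraph::vcount(disjoint), 0)
})

test_that("network build at threshold zero reproduces the generator's edge count", {
  net <- generate_interaction_network(network_spec(seed = 3))
  g <- build_network(net$edges, net$truth$node, params0)
  expect_equal(igraph::ecount(g), nrow(net$edges))
})

test_that("betweenness matches hand counts and closed forms", {
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  b <- betweenness_centrality(graph_from_adj(path3))
  expect_equal(unname(b[c("N01", "N02", "N03")]), c(0, 1, 0))
  # star: center lies on every leaf pair's unique shortest path
  k <- 7
  star <- matrix(0L, k + 1, k + 1); star[1, 2:(k + 1)] <- 1L
  star <- star + t(star)
  b_star <- betweenness_centrality(graph_from_adj(star))
  expect_equal(unname(b_star["N01"]), choose(k, 2))
  expect_true(all(b_star[-1] == 0))
})

test_that("betweenness equals the exhaustive BFS oracle on random graphs", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(6:20, 1)
    adj <- random_adjacency(n, runif(1, 0.15, 0.5))
    if (sum(adj) == 0) next
    g <- graph_from_adj(adj)
    present <- match(igraph::V(g)$name, sprintf("N%02d", seq_len(n)))
    b <- betweenness_centrality(g)
    expect_equal(unname(b), oracle_betweenness(adj)[present], tolerance = 1e-9)
  }
})

test_that("Markov clustering separates disjoint cliques and filters small groups", {
  adj <- matrix(0L, 20, 20)
  adj[1:10, 1:10] <- 1L; adj[11:20, 11:20] <- 1L
  diag(adj) <- 0L
  cl <- detect_clusters(graph_from_adj(adj), params0)
  expect_equal(length(cl$sizes), 2)
  expect_equal(cl$sizes, c(10, 10))
  # a 4-node component falls under the n >= 5 cluster-size floor
  adj4 <- matrix(0L, 4, 4); adj4[upper.tri(adj4)] <- 1L; adj4 <- adj4 + t(adj4)
  cl4 <- detect_clusters(graph_from_adj(adj4), params0)
  expect_equal(length(cl4$sizes), 0)
  expect_true(all(is.na(cl4$membership)))
  expect_length(cl4$discarded, 1)
})

test_that("Markov clustering recovers a planted five-block partition", {
  spec <- network_spec(cluster_sizes = rep(30, 5), p_within = 0.3,
                       p_between = 0.01, n_pendant_on_clique = 0,
                       n_superconnectors = 0, seed = 17)
  net <- generate_interaction_network(spec)
  g <- build_network(net$edges, net$truth$node, params0)
  cl <- detect_clusters(g, params0)
  memb <- cl$membership[net$truth$node]
  memb[is.na(memb)] <- -seq_len(sum(is.na(memb)))
  expect_gte(adjusted_rand_index(net$truth$cluster, memb), 0.9)
})

test_that("hub selection takes ceil(10%) per cluster with a stable tie-break", {
  # one 10-cluster with distinct betweenness: exactly the maximum is the hub
  spec <- network_spec(cluster_sizes = c(10, 10), p_within = 0.9, p_between = 0.05,
                       n_pendant_on_clique = 0, n_superconnectors = 0,
                       k_sc = 2, seed = 23)
  net <- generate_interaction_network(spec)
  g <- build_network(net$edges, net$truth$node, params0)
  cl <- detect_clusters(g, params0)
  btw <- betweenness_centrality(g)
  hubs <- detect_hubs(g, cl, btw, params0)
  expect_true(all(lengths(hubs) == 1))     # ceil(0.1 * 10) = 1
  for (k in names(hubs)) {
    members <- names(cl$membership)[!is.na(cl$membership) & cl$membership == as.integer(k)]
    expect_equal(unname(btw[hubs[[k]]]), max(btw[members]))
    expect_true(hubs[[k]] %in% members)
  }

  # all-equal scores in a 20-cluster: 2 hubs, chosen deterministically
  adj <- matrix(1L, 20, 20); diag(adj) <- 0L
  g20 <- graph_from_adj(adj)
  cl20 <- detect_clusters(g20, params0)
  b20 <- betweenness_centrality(g20)
  expect_true(all(b20 == 0))
  h1 <- detect_hubs(g20, cl20, b20, params0)
  h2 <- detect_hubs(g20, cl20, b20, params0)
  expect_identical(h1, h2)
  expect_equal(h1[["1"]], c("N01", "N02"))  # degree ties resolved by gene id
})

test_that("hub fraction ceil gives every small cluster at least one hub", {
  spec <- network_spec(cluster_sizes = c(5, 5), p_within = 1, p_between = 0,
                       n_pendant_on_clique = 0, n_superconnectors = 0,
                       k_sc = 2, clique_size = 3, seed = 2)
  net <- generate_interaction_network(spec)
  g <- build_network(net$edges, net$truth$node, params0)
  cl <- detect_clusters(g, params0)
  hubs <- detect_hubs(g, cl, betweenness_centrality(g), params0)
  expect_true(all(lengths(hubs) == 1))     # ceil(0.5) = 1 per 5-cluster
})

test_that("peripheral detection requires a clique inside the neighbor's cluster", {
  # triangle 1-2-3 inside a 6-node cluster, pendant 7 on node 1;
  # pendant 8 hangs off a path node with no triangle around it
  adj <- matrix(0L, 9, 9)
  link <- function(i, j) { adj[i, j] <<- 1L; adj[j, i] <<- 1L }
  link(1, 2); link(2, 3); link(1, 3)          # clique
  link(3, 4); link(4, 5); link(5, 6); link(6, 1); link(2, 5)
  link(1, 7)                                   # pendant on clique member
  link(4, 9)                                   # path-like attachment
  link(9, 8)                                   # pendant 8 on degree-2 node 9
  g <- graph_from_adj(adj)
  cl <- detect_clusters(g, params0)
  per <- detect_peripheral(g, cl, params0)
  expect_true("N07" %in% per$gene_id)
  w <- per$witness[[which(per$gene_id == "N07")]]
  expect_true(all(c("N01", "N02", "N03") %in% w))
  expect_false("N08" %in% per$gene_id)
})

test_that("peripheral calls match exhaustive clique enumeration on random graphs", {
  set.seed(31)
  checked <- 0
  for (i in 1:60) {
    n <- sample(8:14, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.5))
    deg <- rowSums(adj)
    if (!any(deg == 1)) next
    g <- graph_from_adj(adj)
    cl <- detect_clusters(g, topology_params(score_threshold = 0, min_cluster_size = 3))
    per <- detect_peripheral(g, cl, topology_params(score_threshold = 0,
                                                    min_cluster_size = 3))
    nodes <- sprintf("N%02d", seq_len(n))
    for (v in which(deg == 1)) {
      nb <- which(adj[v, ] == 1)
      cl_nb <- cl$membership[nodes[nb]]
      expected <- FALSE
      if (!is.na(cl_nb)) {
        members <- setdiff(which(!is.na(cl$membership[nodes]) &
                                   cl$membership[nodes] == cl_nb), v)
        sub <- adj[members, members, drop = FALSE]
        cliques <- oracle_max_cliques(sub, min_size = 3)
        expected <- any(vapply(cliques, function(cq) {
          which(members == nb) %in% cq
        }, logical(1)))
      }
      expect_equal(nodes[v] %in% per$gene_id, expected)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 10)
})

test_that("super-connector rule counts own plus neighboring clusters", {
  # five 5-cliques; hub node 26 wired to one node in each
  adj <- matrix(0L, 26, 26)
  for (b in 0:4) {
    idx <- (b * 5 + 1):(b * 5 + 5)
    adj[idx, idx] <- 1L
    adj[26, b * 5 + 1] <- 1L; adj[b * 5 + 1, 26] <- 1L
  }
  diag(adj) <- 0L
  g <- graph_from_adj(adj)
  # fix the cluster assignment explicitly: the test targets the linking rule
  memb <- setNames(c(rep(1:5, each = 5), NA)[match(igraph::V(g)$name,
                                                   sprintf("N%02d", 1:26))],
                   igraph::V(g)$name)
  cl <- structure(list(membership = memb, sizes = rep(5L, 5), discarded = list()),
                  class = "cluster_assignment")
  sc <- detect_superconnectors(g, cl, params0)
  expect_equal(names(sc), "N26")
  expect_equal(sc$N26, 1:5)
  # a node whose neighbors all share its cluster can never qualify
  inner <- detect_superconnectors(g, cl, topology_params(score_threshold = 0,
                                                         superconnector_min_clusters = 2))
  expect_false("N02" %in% names(inner))
})

test_that("adding an edge never shrinks a node's linked-cluster count", {
  set.seed(41)
  spec <- network_spec(cluster_sizes = rep(10, 4), p_within = 0.8,
                       p_between = 0.02, n_pendant_on_clique = 0,
                       n_superconnectors = 0, k_sc = 4, seed = 41)
  net <- generate_interaction_network(spec)
  g <- build_network(net$edges, net$truth$node, params0)
  cl <- detect_clusters(g, params0)
  linked_count <- function(graph, node) {
    nb <- igraph::neighbors(graph, node)$name
    length(unique(na.omit(c(cl$membership[node], cl$membership[nb]))))
  }
  v <- igraph::V(g)$name
  pair <- sample(v, 2)
  before <- vapply(pair, linked_count, integer(1), graph = g)
  g2 <- igraph::add_edges(g, pair)
  after <- vapply(pair, linked_count, integer(1), graph = g2)
  expect_true(all(after >= before))
})

test_that("connectivity matrix holds exact block densities", {
  # two triangles joined by one edge
  adj <- matrix(0L, 6, 6)
  adj[1:3, 1:3] <- 1L; adj[4:6, 4:6] <- 1L; diag(adj) <- 0L
  adj[3, 4] <- 1L; adj[4, 3] <- 1L
  g <- graph_from_adj(adj)
  cl <- detect_clusters(g, topology_params(score_threshold = 0, min_cluster_size = 3))
  S <- cluster_connectivity(g, cl)
  expect_equal(unname(diag(S)), c(1, 1))
  expect_equal(S[1, 2], 1 / 9)
  expect_true(isSymmetric(S))

  # no cross edges -> zero off-diagonal
  adj0 <- adj; adj0[3, 4] <- 0L; adj0[4, 3] <- 0L
  g0 <- graph_from_adj(adj0)
  cl0 <- detect_clusters(g0, topology_params(score_threshold = 0, min_cluster_size = 3))
  expect_equal(cluster_connectivity(g0, cl0)[1, 2], 0)
  expect_error(cluster_connectivity(g, structure(
    list(membership = setNames(rep(1L, 6), igraph::V(g)$name), sizes = 6L,
         discarded = list()), class = "cluster_assignment")), "2 clusters")
})

test_that("connectivity estimates concentrate near block-model probabilities", {
  spec <- network_spec(cluster_sizes = rep(40, 3), p_within = 0.3,
                       p_between = 0.02, n_pendant_on_clique = 0,
                       n_superconnectors = 0, k_sc = 3, seed = 53)
  net <- generate_interaction_network(spec)
  g <- build_network(net$edges, net$truth$node, params0)
  cl <- detect_clusters(g, params0)
  S <- cluster_connectivity(g, cl)
  expect_true(all(abs(diag(S) - 0.3) < 0.06))
  expect_true(all(abs(S[upper.tri(S)] - 0.02) < 0.02))
})

test_that("cluster enrichment ranks a planted covering term first and caps output", {
  spec <- network_spec(cluster_sizes = c(20, 20), p_within = 0.8, p_between = 0.02,
                       n_pendant_on_clique = 0, n_superconnectors = 0,
                       k_sc = 2, seed = 61)
  net <- generate_interaction_network(spec)
  g <- build_network(net$edges, net$truth$node, params0)
  cl <- detect_clusters(g, params0)
  cluster1 <- names(cl$membership)[!is.na(cl$membership) & cl$membership == 1]
  universe <- c(net$truth$node, sprintf("BG%03d", 1:300))
  catalog <- c(list(COVERING = cluster1),
               generate_annotation_catalog(20, c(10, 30), list(), universe, seed = 62))
  enr <- enrich_clusters(cl, list(main = catalog), universe)
  first_cl1 <- enr[enr$cluster == 1, ][1, ]
  expect_equal(first_cl1$term, "COVERING")
  expect_true(all(table(enr$cluster, enr$catalog) <= 5))

  # no overlap with any catalog -> empty report
  off_catalog <- list(ONLY = sprintf("ZZ%02d", 1:10))
  enr0 <- enrich_clusters(cl, list(off = off_catalog),
                          c(net$truth$node, off_catalog$ONLY))
  expect_equal(nrow(enr0), 0)
})
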