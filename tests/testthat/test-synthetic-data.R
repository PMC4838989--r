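test_that("expression generator is deterministic and plants the stated DE counts", {
  spec <- study_spec(n_genes = 2000, n_per_group = 3, n_comparisons = 4,
                     de_fraction = 0.05, seed = 99)
  sim1 <- generate_expression_study(spec)
  sim2 <- generate_expression_study(spec)
  expect_identical(sim1, sim2)
  # exactly 100 planted DE genes in every comparison
  planted <- tapply(sim1$truth$is_de, sim1$truth$comparison_id, sum)
  expect_true(all(planted == 100))
  # truth covers every gene in every comparison
  expect_equal(nrow(sim1$truth), 2000 * 4)
  # every study has 2 * n_per_group samples
  expect_true(all(vapply(sim1$studies, function(s) ncol(s$matrix), numeric(1)) == 6))
})

test_that("shared DE genes keep a consistent planted sign across comparisons", {
  spec <- study_spec(n_genes = 500, n_comparisons = 5, shared_de_fraction = 1,
                     seed = 12)
  sim <- generate_expression_study(spec)
  de <- sim$truth[sim$truth$is_de, ]
  signs_per_gene <- tapply(de$sign, de$gene_id, function(s) length(unique(s)))
  expect_true(all(signs_per_gene == 1))
  # shared_de_fraction = 1: the same genes are DE everywhere
  expect_equal(length(unique(de$gene_id)), 25)
})

test_that("zero effect size leaves group means apart only by noise", {
  spec <- study_spec(n_genes = 400, n_per_group = 10, n_comparisons = 1,
                     effect_size_log2 = 0, noise_sd = 0.5, seed = 21)
  sim <- generate_expression_study(spec)
  st <- sim$studies[[1]]
  fc <- rowMeans(st$matrix[, st$sample_groups == "case"]) -
    rowMeans(st$matrix[, st$sample_groups == "control"])
  # mean difference ~ N(0, sd * sqrt(2/10)): all |fc| within 5 sigma
  expect_true(all(abs(fc) < 5 * 0.5 * sqrt(2 / 10)))
  expect_error(study_spec(n_genes = 0), "positive")
  expect_error(study_spec(de_fraction = 1e-5), "at least one gene")
})

test_that("annotation catalog plants terms verbatim and respects size_range", {
  universe <- sprintf("G%03d", 1:200)
  planted <- list(MY_TERM = universe[1:50])
  cat1 <- generate_annotation_catalog(20, c(5, 5), planted, universe, seed = 4)
  expect_identical(cat1$MY_TERM, planted$MY_TERM)
  expect_true(all(vapply(cat1[-1], length, integer(1)) == 5))
  expect_identical(cat1, generate_annotation_catalog(20, c(5, 5), planted,
                                                     universe, seed = 4))
  expect_error(generate_annotation_catalog(5, c(3, 6), list(), character(0)),
               "empty universe")
  expect_error(generate_annotation_catalog(5, c(3, 6), list(A = "X"), c("Y", "Z")),
               "subset")
})

test_that("network generator honours blocks, pendants and connectors by construction", {
  spec <- network_spec(cluster_sizes = c(30, 30, 30, 30, 30),
                       n_superconnectors = 2, k_sc = 5, seed = 31)
  net <- generate_interaction_network(spec)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$truth$node)
  deg <- igraph::degree(g)
  pend <- net$truth$node[net$truth$is_pendant]
  expect_true(all(deg[pend] == 1))
  # planted connectors reach >= k_sc distinct blocks
  sc <- net$truth$node[net$truth$is_planted_superconnector]
  for (s in sc) {
    nb <- igraph::neighbors(g, s)$name
    blocks <- net$truth$cluster[match(nb, net$truth$node)]
    expect_gte(length(unique(blocks[!is.na(blocks)])), 5)
    expect_true(all(net$truth$is_superconnector[net$truth$node %in% s]))
  }
  # simple graph: no duplicate edges, no self loops
  expect_false(igraph::any_multiple(g))
  expect_equal(sum(igraph::which_loop(g)), 0)
  expect_error(network_spec(clique_size = 2), "clique_size")
  expect_error(network_spec(p_within = 0.1, p_between = 0.2), "exceed")
})

test_that("p_between = 0 makes connected components coincide with blocks", {
  spec <- network_spec(cluster_sizes = c(20, 20, 20), p_between = 0,
                       n_pendant_on_clique = 0, n_superconnectors = 0,
                       k_sc = 3, seed = 8)
  net <- generate_interaction_network(spec)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$truth$node)
  comp <- igraph::components(g)$membership
  expect_equal(adjusted_rand_index(comp[net$truth$node], net$truth$cluster), 1)
  # with no background edges nothing but the plant can be a super-connector
  expect_false(any(net$truth$is_superconnector))
})

test_that("realized block densities stay within 3 SD of the sampling probabilities", {
  spec <- network_spec(cluster_sizes = c(40, 40), p_within = 0.3,
                       p_between = 0.05, n_pendant_on_clique = 0,
                       n_superconnectors = 0, k_sc = 2, seed = 77)
  net <- generate_interaction_network(spec)
  truth <- net$truth
  e <- net$edges
  b1 <- truth$cluster[match(e$node1, truth$node)]
  b2 <- truth$cluster[match(e$node2, truth$node)]
  n_within <- sum(b1 == b2)
  n_between <- sum(b1 != b2)
  trials_within <- 2 * choose(40, 2)
  trials_between <- 40 * 40
  expect_lt(abs(n_within - 0.3 * trials_within),
            3 * sqrt(trials_within * 0.3 * 0.7))
  expect_lt(abs(n_between - 0.05 * trials_between),
            3 * sqrt(trials_between * 0.05 * 0.95))
})

test_that("literature counts honour the zero fraction and power-law truncation", {
  genes <- sprintf("G%04d", 1:933)
  all_zero <- generate_literature_counts(literature_spec(zero_fraction = 1, seed = 2),
                                         genes)
  expect_true(all(all_zero$count == 0))
  spec <- literature_spec(zero_fraction = 0.59, tail_exponent = 2, seed = 5)
  lit <- generate_literature_counts(spec, genes)
  expect_identical(lit, generate_literature_counts(spec, genes))
  n_zero <- sum(lit$count == 0)
  expect_lt(abs(n_zero - 933 * 0.59), 3 * sqrt(933 * 0.59 * 0.41))
  expect_true(all(lit$count >= 0 & lit$count <= spec$max_count))
  expect_error(literature_spec(tail_exponent = 1), "exceed 1")
  expect_error(generate_literature_counts(spec, character(0)), "non-empty")
})
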