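# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, summing hypergeometric point probabilities <= that of the
# observed table (relative tie tolerance 1e-7).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by direct PMF summation.
oracle_hyper_p <- function(hits, query, term, universe) {
  ks <- hits:min(query, term)
  sum(vapply(ks, function(k) {
    exp(lchoose(term, k) + lchoose(universe - term, query - k) -
          lchoose(universe, query))
  }, numeric(1)))
}

# Exact betweenness by per-source BFS with shortest-path counting, written
# directly from the definition: B(v) = sum over unordered pairs s != v != t
# of sigma_st(v) / sigma_st.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in which(adj[u, ] == 1)) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- dist[s, u] + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == dist[s, u] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, u]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

# All maximal cliques by exhaustive subset enumeration (feasible for n <= 15).
oracle_max_cliques <- function(adj, min_size = 1) {
  n <- nrow(adj)
  is_clique <- function(members) {
    if (length(members) < 2) return(TRUE)
    all(adj[members, members][upper.tri(diag(length(members)))] == 1)
  }
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < min_size || !is_clique(members)) next
    # maximal iff no outside vertex is adjacent to all members
    outside <- setdiff(seq_len(n), members)
    if (all(vapply(outside, function(o) any(adj[o, members] == 0), logical(1)))) {
      cliques[[length(cliques) + 1]] <- members
    }
  }
  cliques
}

# Random simple undirected graph as a 0/1 adjacency matrix.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

adjacency_to_edges <- function(adj, names = sprintf("N%02d", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  data.frame(node1 = names[idx[, 1]], node2 = names[idx[, 2]],
             combined_score = 900L, stringsAsFactors = FALSE)
}

# Small helper: a tiny two-group study with chosen per-gene case shifts.
make_tiny_study <- function(shifts, n_per_group = 4, sd = 0.4, seed = 42,
                            comparison_id = "A") {
  set.seed(seed)
  n_genes <- length(shifts)
  groups <- rep(c("control", "case"), each = n_per_group)
  mat <- matrix(stats::rnorm(n_genes * 2 * n_per_group, mean = 8, sd = sd),
                nrow = n_genes)
  mat[, groups == "case"] <- mat[, groups == "case"] + shifts
  rownames(mat) <- sprintf("G%03d", seq_len(n_genes))
  colnames(mat) <- sprintf("S%02d", seq_len(2 * n_per_group))
  expression_study(mat, groups, comparison_id)
}
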