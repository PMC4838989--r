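#' Parameters for cross-comparison signature construction
#'
#' Defaults encode "robust across independent experiments": a term must be
#' enriched in at least 2 comparisons, a gene differentially expressed in at
#' least 3, with a consistent direction of change. All are configurable; no
#' single canonical setting exists for heterogeneous study collections.
#'
#' @param alpha_enrich BH-adjusted p threshold for term enrichment.
#' @param min_term_support number of comparisons in which a term must be
#'   enriched for the pathway-driven approach.
#' @param min_gene_support number of comparisons in which a gene must be DE
#'   for the gene-driven approach.
#' @param require_consistent_sign require the log2 fold-change sign to agree
#'   across all comparisons where the gene is DE.
#' @param alpha_de,min_abs_log2fc thresholds passed to [de_gene_set()].
#' @return A `signature_params` list.
#' @export
signature_params <- function(alpha_enrich = 0.05, min_term_support = 2,
                             min_gene_support = 3,
                             require_consistent_sign = TRUE,
                             alpha_de = 0.05, min_abs_log2fc = 0) {
  if (alpha_enrich <= 0 || alpha_enrich >= 1) {
    stop("alpha_enrich must lie in (0, 1)", call. = FALSE)
  }
  if (min_term_support < 1 || min_gene_support < 1) {
    stop("support thresholds must be >= 1", call. = FALSE)
  }
  structure(list(alpha_enrich = alpha_enrich,
                 min_term_support = as.integer(min_term_support),
                 min_gene_support = as.integer(min_gene_support),
                 require_consistent_sign = isTRUE(require_consistent_sign),
                 alpha_de = alpha_de, min_abs_log2fc = min_abs_log2fc),
            class = "signature_params")
}

#' Canonicalize gene identifiers
#'
#' Upper-cases and strips surrounding whitespace, so mouse/human symbol
#' casing differences do not break joins.
#'
#' @param x character vector of gene identifiers.
#' @return Canonical identifiers.
#' @export
canonicalize_genes <- function(x) toupper(trimws(x))

#' Pathway-driven signature selection
#'
#' For each comparison, terms of the catalog are tested for
#' over-representation of the comparison's DE genes (hypergeometric
#' upper-tail, BH across terms). A term qualifies if enriched (adjusted p <
#' `alpha_enrich`) in at least `min_term_support` comparisons. The selected
#' set is the union, over qualifying terms, of the term's genes intersected
#' with the DE genes of the comparisons where that term was enriched — so a
#' DE gene not annotated to any qualifying term is excluded however strong
#' its change.
#'
#' @param de_sets named list (comparison -> character vector of DE genes).
#' @param catalog named list (term -> character vector of genes).
#' @param universe character vector of all measured genes.
#' @param params a [signature_params()].
#' @return Character vector of selected genes (canonicalized).
#' @export
pathway_driven_select <- function(de_sets, catalog, universe, params = signature_params()) {
  if (length(catalog) == 0) stop("empty annotation catalog", call. = FALSE)
  universe <- unique(canonicalize_genes(universe))
  catalog <- lapply(catalog, function(g) intersect(canonicalize_genes(g), universe))
  de_sets <- lapply(de_sets, function(g) intersect(canonicalize_genes(g), universe))

  terms <- names(catalog)
  enriched <- matrix(FALSE, nrow = length(terms), ncol = length(de_sets),
                     dimnames = list(terms, names(de_sets)))
  for (k in seq_along(de_sets)) {
    de <- de_sets[[k]]
    p <- vapply(catalog, function(tg) {
      hypergeometric_enrichment(length(intersect(tg, de)), length(de),
                                length(tg), length(universe))
    }, numeric(1))
    enriched[, k] <- bh_adjust(p) < params$alpha_enrich
  }
  support <- rowSums(enriched)
  qualifying <- terms[support >= params$min_term_support]

  selected <- character(0)
  for (tm in qualifying) {
    for (k in which(enriched[tm, ])) {
      selected <- union(selected, intersect(catalog[[tm]], de_sets[[k]]))
    }
  }
  sort(selected)
}

#' Gene-driven signature selection
#'
#' A gene is selected iff it is DE (per [de_gene_set()] at the params'
#' thresholds) in at least `min_gene_support` comparisons and — when
#' `require_consistent_sign` — its log2 fold-change sign agrees across all
#' comparisons in which it is DE.
#'
#' @param de_results list of `de_result` data.frames, one per comparison.
#'   Comparisons may have different gene universes (absent = not DE).
#' @param params a [signature_params()].
#' @return Character vector of selected genes (canonicalized).
#' @export
gene_driven_select <- function(de_results, params = signature_params()) {
  if (params$min_gene_support > length(de_results)) {
    stop("min_gene_support exceeds the number of comparisons", call. = FALSE)
  }
  flags <- lapply(de_results, function(res) {
    de <- de_gene_set(res, params$alpha_de, params$min_abs_log2fc)
    sgn <- sign(res$log2fc[match(de, res$gene_id)])
    stats::setNames(sgn, canonicalize_genes(de))
  })
  all_de <- unique(unlist(lapply(flags, names)))
  selected <- vapply(all_de, function(g) {
    signs <- unlist(lapply(flags, function(f) unname(f[g])))
    signs <- signs[!is.na(signs)]
    length(signs) >= params$min_gene_support &&
      (!params$require_consistent_sign ||
         length(unique(signs[signs != 0])) <= 1)
  }, logical(1))
  sort(all_de[selected])
}

#' Merge the pathway-driven and gene-driven selections into a signature
#'
#' The final signature is the union of both selections, with a provenance
#' flag per gene (`pathway`, `gene`, or `both`). Sizes obey inclusion-
#' exclusion exactly: |union| = |A| + |B| - |A intersect B|.
#'
#' @param pathway_set,gene_set character vectors of gene identifiers from
#'   the two approaches (same universe).
#' @param de_results optional list of `de_result` data.frames used to fill
#'   per-gene DE support counts and the consensus fold-change sign.
#' @param params a [signature_params()] (used only with `de_results`).
#' @return data.frame of class `signature_list` with columns `gene_id`,
#'   `source`, `n_comparisons_de`, `sign_consensus`.
#' @export
merge_signature <- function(pathway_set, gene_set, de_results = NULL,
                            params = signature_params()) {
  pathway_set <- unique(canonicalize_genes(pathway_set))
  gene_set <- unique(canonicalize_genes(gene_set))
  genes <- sort(union(pathway_set, gene_set))
  source <- ifelse(genes %in% pathway_set & genes %in% gene_set, "both",
                   ifelse(genes %in% pathway_set, "pathway", "gene"))
  n_de <- rep(NA_integer_, length(genes))
  sign_consensus <- rep(NA_integer_, length(genes))
  if (!is.null(de_results)) {
    flags <- lapply(de_results, function(res) {
      de <- de_gene_set(res, params$alpha_de, params$min_abs_log2fc)
      sgn <- sign(res$log2fc[match(de, res$gene_id)])
      stats::setNames(sgn, canonicalize_genes(de))
    })
    for (i in seq_along(genes)) {
      signs <- unlist(lapply(flags, function(f) unname(f[genes[i]])))
      signs <- signs[!is.na(signs)]
      n_de[i] <- length(signs)
      sign_consensus[i] <- if (length(signs) == 0 || length(unique(sign(signs))) > 1) {
        0L
      } else {
        as.integer(unique(sign(signs)))
      }
    }
  }
  res <- data.frame(gene_id = genes, source = source, n_comparisons_de = n_de,
                    sign_consensus = sign_consensus, stringsAsFactors = FALSE)
  class(res) <- c("signature_list", "data.frame")
  res
}

#' @export
print.signature_list <- function(x, ...) {
  tab <- table(factor(x$source, c("pathway", "gene", "both")))
  cat(sprintf(
    "Gene signature: %d genes (%d pathway-only, %d gene-only, %d both)\n",
    nrow(x), tab[["pathway"]], tab[["gene"]], tab[["both"]]))
  invisible(x)
}
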