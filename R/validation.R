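#' Compare the annotation rates of two gene categories
#'
#' Builds the 2x2 contingency table (rows = the two gene sets, columns =
#' trait present/absent) and tests it with the two-sided Fisher's exact
#' test. Typical use: hub genes vs peripheral genes on "has been associated
#' with the disease in the literature".
#'
#' @param set_a,set_b character vectors of gene identifiers (non-empty).
#' @param trait_flags named logical vector; must cover every gene in both
#'   sets.
#' @return List with `table` (2x2 matrix) and `p` (Fisher p-value).
#' @export
annotation_category_comparison <- function(set_a, set_b, trait_flags) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  set_a <- canonicalize_genes(set_a); set_b <- canonicalize_genes(set_b)
  names(trait_flags) <- canonicalize_genes(names(trait_flags))
  if (!all(c(set_a, set_b) %in% names(trait_flags))) {
    stop("trait_flags must be defined for every gene in both sets", call. = FALSE)
  }
  tab <- matrix(c(sum(trait_flags[set_a]), sum(!trait_flags[set_a]),
                  sum(trait_flags[set_b]), sum(!trait_flags[set_b])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("set_a", "set_b"), c("trait", "no_trait")))
  list(table = tab, p = fisher_exact_two_sided(tab))
}

#' Cross-platform fold-change correlation at one timepoint
#'
#' Pairs each gene's mean microarray log2 fold change with its qPCR log2
#' fold change at the given timepoint and computes the Pearson correlation
#' with two-sided significance. Genes present on only one platform are
#' excluded and reported via a message.
#'
#' @param fold_changes data.frame with columns `gene_id`, `platform`
#'   ("microarray" or "qpcr"), `log2fc`, `timepoint`.
#' @param timepoint timepoint (hours) to correlate at.
#' @return A `correlation_result` (see [pearson_correlation()]).
#' @export
cross_platform_correlation <- function(fold_changes, timepoint) {
  stopifnot(all(c("gene_id", "platform", "log2fc", "timepoint") %in% names(fold_changes)))
  fc <- fold_changes[fold_changes$timepoint == timepoint, , drop = FALSE]
  fc$gene_id <- canonicalize_genes(fc$gene_id)
  mean_by_gene <- function(platform) {
    rows <- fc[fc$platform == platform, , drop = FALSE]
    tapply(rows$log2fc, rows$gene_id, mean)
  }
  ma <- mean_by_gene("microarray")
  qp <- mean_by_gene("qpcr")
  shared <- intersect(names(ma), names(qp))
  dropped <- setdiff(union(names(ma), names(qp)), shared)
  if (length(dropped) > 0) {
    message(length(dropped), " gene(s) present on only one platform excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  if (length(shared) < 3) stop("fewer than 3 genes shared across platforms", call. = FALSE)
  pearson_correlation(as.numeric(ma[shared]), as.numeric(qp[shared]))
}

#' Median log2 fold change of a gene set across comparisons
#'
#' @param genes character vector of genes.
#' @param de_results list of `de_result` data.frames, one per comparison.
#' @return data.frame with columns `comparison_id`, `median_log2fc`,
#'   `n_genes`; the range of the medians is attached as attribute `range`.
#' @export
median_foldchange_profile <- function(genes, de_results) {
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  genes <- canonicalize_genes(genes)
  rows <- lapply(de_results, function(res) {
    i <- match(genes, canonicalize_genes(res$gene_id))
    if (anyNA(i)) {
      message(sum(is.na(i)), " gene(s) missing from comparison ",
              res$comparison_id[1])
    }
    data.frame(comparison_id = res$comparison_id[1],
               median_log2fc = stats::median(res$log2fc[i[!is.na(i)]]),
               n_genes = sum(!is.na(i)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "range") <- range(out$median_log2fc)
  out
}

#' Classify each gene's response to steroid (dexamethasone) treatment
#'
#' Applies a fixed rule cascade per gene, using three contrasts (disease vs
#' control, treated vs control, treated vs disease) at level `alpha`:
#' \enumerate{
#'   \item not significantly deregulated in disease -> `not_changed`;
#'   \item treated-vs-disease contrast not significant -> `not_affected`;
#'   \item treatment moves expression further from control (same sign,
#'     larger magnitude) -> `further_downregulated` (the symmetric
#'     up-regulated case carries the same label);
#'   \item treated arm no longer differs from control -> `completely_reverted`;
#'   \item otherwise -> `partially_reverted`.
#' }
#' The five categories partition all valid inputs; exactly one is assigned.
#'
#' @param contrasts data.frame with columns `gene_id`,
#'   `log2fc_disease`, `p_disease` (disease vs control),
#'   `log2fc_dex`, `p_dex` (treated vs control), and `p_dex_vs_disease`.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `gene_id`, `category`.
#' @export
classify_dex_response <- function(contrasts, alpha = 0.05) {
  need <- c("gene_id", "log2fc_disease", "p_disease", "log2fc_dex", "p_dex",
            "p_dex_vs_disease")
  if (!all(need %in% names(contrasts))) {
    stop("missing contrast column(s): ",
         paste(setdiff(need, names(contrasts)), collapse = ", "), call. = FALSE)
  }
  if (anyNA(contrasts[need])) stop("missing contrast values", call. = FALSE)
  category <- character(nrow(contrasts))
  for (i in seq_len(nrow(contrasts))) {
    x <- contrasts[i, ]
    category[i] <-
      if (x$p_disease >= alpha) "not_changed"
      else if (x$p_dex_vs_disease >= alpha) "not_affected"
      else if (sign(x$log2fc_dex) == sign(x$log2fc_disease) &&
                 abs(x$log2fc_dex) > abs(x$log2fc_disease)) "further_downregulated"
      else if (x$p_dex >= alpha) "completely_reverted"
      else "partially_reverted"
  }
  data.frame(gene_id = contrasts$gene_id,
             category = factor(category,
                               levels = c("completely_reverted", "partially_reverted",
                                          "further_downregulated", "not_affected",
                                          "not_changed")),
             stringsAsFactors = FALSE)
}
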