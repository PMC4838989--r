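#' Construct a literature index for one query context
#'
#' Holds per-gene publication counts for a query context (e.g. "asthma" or
#' "inflammation OR immunity") plus boolean flags from gene-disease
#' association databases. Consumed from static snapshots only; the package
#' never queries a live service, so analyses are reproducible against a
#' pinned snapshot date.
#'
#' @param counts data.frame with columns `gene_id`, `count` (and optionally
#'   `context`, `ctd_flag`, `malacards_flag`), or a named numeric vector.
#' @param context query label; defaults to the one in `counts` if present.
#' @return A `literature_index` object.
#' @export
literature_index <- function(counts, context = NULL) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- data.frame(gene_id = names(counts), count = unname(counts),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(counts), all(c("gene_id", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("publication counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(context)) {
    context <- if ("context" %in% names(counts)) counts$context[1] else "disease"
  }
  counts$gene_id <- canonicalize_genes(counts$gene_id)
  if (anyDuplicated(counts$gene_id)) {
    stop("duplicate gene identifiers in literature counts", call. = FALSE)
  }
  if (is.null(counts$ctd_flag)) counts$ctd_flag <- FALSE
  if (is.null(counts$malacards_flag)) counts$malacards_flag <- FALSE
  structure(list(context = context,
                 table = counts[, c("gene_id", "count", "ctd_flag", "malacards_flag")]),
            class = "literature_index")
}

# counts/flags for a gene set; genes absent from the index -> 0/FALSE, logged
index_lookup <- function(index, genes) {
  genes <- canonicalize_genes(genes)
  i <- match(genes, index$table$gene_id)
  missing <- genes[is.na(i)]
  if (length(missing) > 0) {
    message(length(missing), " gene(s) absent from literature index, treated as 0/unflagged: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  data.frame(
    gene_id = genes,
    count = ifelse(is.na(i), 0L, index$table$count[i]),
    db_flag = ifelse(is.na(i), FALSE,
                     index$table$ctd_flag[i] | index$table$malacards_flag[i]),
    stringsAsFactors = FALSE
  )
}

#' Partition a signature into annotated and ignorome genes
#'
#' A gene counts as annotated iff it has at least one publication in the
#' index's context OR it carries any disease-database flag (the sources are
#' treated as complementary annotation). Everything else is the "ignorome":
#' signature genes the literature has not yet connected to the disease.
#'
#' @param signature a `signature_list` or character vector of genes.
#' @param index a [literature_index()].
#' @return An `ignorome_partition`: list with disjoint character vectors
#'   `annotated` and `ignorome` whose union is the signature, plus `context`.
#' @export
classify_ignorome <- function(signature, index) {
  genes <- if (inherits(signature, "signature_list")) signature$gene_id else signature
  genes <- unique(canonicalize_genes(genes))
  lk <- index_lookup(index, genes)
  annotated <- lk$gene_id[lk$count >= 1 | lk$db_flag]
  structure(list(annotated = annotated,
                 ignorome = setdiff(genes, annotated),
                 context = index$context),
            class = "ignorome_partition")
}

#' @export
print.ignorome_partition <- function(x, ...) {
  n <- length(x$annotated) + length(x$ignorome)
  cat(sprintf("Ignorome partition ('%s'): %d/%d annotated (%.0f%%), %d/%d ignorome (%.0f%%)\n",
              x$context, length(x$annotated), n, 100 * length(x$annotated) / n,
              length(x$ignorome), n, 100 * length(x$ignorome) / n))
  invisible(x)
}

#' Literature concentration: publication share of the top-k genes
#'
#' Fraction of all publications (over the signature, in the index's context)
#' held by the k most-published genes. Ties in the ranking are broken
#' lexicographically by gene identifier for determinism.
#'
#' @param index a [literature_index()].
#' @param signature a `signature_list` or character vector of genes.
#' @param k number of top genes, `1 <= k <= |signature|`.
#' @return Fraction in (0, 1].
#' @export
literature_concentration <- function(index, signature, k) {
  genes <- if (inherits(signature, "signature_list")) signature$gene_id else signature
  genes <- unique(canonicalize_genes(genes))
  if (k < 1 || k > length(genes)) stop("k must lie in [1, |signature|]", call. = FALSE)
  lk <- suppressMessages(index_lookup(index, genes))
  total <- sum(lk$count)
  if (total == 0) stop("undefined-concentration: no publications in total", call. = FALSE)
  ord <- order(-lk$count, lk$gene_id)
  sum(lk$count[ord][seq_len(k)]) / total
}

#' Histogram of literature coverage with per-bin database annotation
#'
#' Bins genes by publication count; reports per-bin gene counts and the
#' fraction of each bin's genes carrying any disease-database flag. Bin i
#' covers counts in \[edge_i, edge_{i+1}) with the last bin closed on the
#' right.
#'
#' @param index a [literature_index()].
#' @param signature a `signature_list` or character vector of genes.
#' @param bin_edges strictly increasing numeric vector covering
#'   \[0, max(count)\].
#' @return data.frame with columns `bin_low`, `bin_high`, `n_genes`,
#'   `db_fraction`.
#' @export
coverage_histogram <- function(index, signature, bin_edges) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
  genes <- if (inherits(signature, "signature_list")) signature$gene_id else signature
  genes <- unique(canonicalize_genes(genes))
  lk <- suppressMessages(index_lookup(index, genes))
  if (min(lk$count) < bin_edges[1] || max(lk$count) > bin_edges[length(bin_edges)]) {
    stop("bin edges must cover [0, max count]", call. = FALSE)
  }
  bin <- findInterval(lk$count, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1
  data.frame(
    bin_low = bin_edges[seq_len(nb)],
    bin_high = bin_edges[-1],
    n_genes = vapply(seq_len(nb), function(b) sum(bin == b), integer(1)),
    db_fraction = vapply(seq_len(nb), function(b) {
      if (sum(bin == b) == 0) return(NA_real_)
      mean(lk$db_flag[bin == b])
    }, numeric(1))
  )
}
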