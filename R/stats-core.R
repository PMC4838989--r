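#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Computes the two-sided p-value by the point-probability convention: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table (the convention of [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts. Rows index the two
#'   groups being compared, columns trait present/absent.
#' @return The two-sided p-value, a single number in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(8, 14, 17, 5), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be a 2x2 matrix", call. = FALSE)
  }
  if (any(!is.finite(table)) || any(table < 0) || any(table != round(table))) {
    stop("`table` cells must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) {
    stop("all-zero contingency table: no observations", call. = FALSE)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= hits) where X counts the overlap of a random query of size
#' `query_size` with a term of `term_size` genes inside a universe of
#' `universe_size` genes. One-sided: over-representation only.
#'
#' @param hits observed overlap between query and term.
#' @param query_size number of genes in the query set.
#' @param term_size number of genes annotated to the term.
#' @param universe_size number of genes in the universe.
#' @return Enrichment p-value in (0, 1].
#' @export
hypergeometric_enrichment <- function(hits, query_size, term_size, universe_size) {
  vals <- c(hits, query_size, term_size, universe_size)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  if (hits > min(query_size, term_size) || term_size > universe_size ||
      query_size > universe_size) {
    stop("inconsistent counts: hits <= min(query, term) <= universe required",
         call. = FALSE)
  }
  stats::phyper(hits - 1, term_size, universe_size - term_size, query_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values in \[0, 1\]; names are preserved.
#' @return Vector of BH-adjusted p-values, same length and names.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided significance
#'
#' r is the sample Pearson coefficient; the p-value comes from
#' t = r * sqrt((n - 2) / (1 - r^2)) against Student's t with n - 2 d.f.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return An object of class `correlation_result`: a list with elements
#'   `r`, `p_two_sided` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, two-sided p = %.3g)\n",
              x$r, x$n, x$p_two_sided))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted cluster structure. Items unlabelled
#' (NA) in either partition are dropped before comparison.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(NA_real_)
  tab <- table(a, b)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
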