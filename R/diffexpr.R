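#' Construct an expression study (one two-group comparison)
#'
#' @param matrix numeric genes x samples matrix on the log2 scale, with gene
#'   identifiers as rownames.
#' @param sample_groups character vector, one of "control"/"case" per column.
#' @param comparison_id label for the comparison (e.g. "A").
#' @return An `expression_study` object.
#' @export
expression_study <- function(matrix, sample_groups, comparison_id) {
  if (is.null(rownames(matrix)) || anyNA(rownames(matrix))) {
    stop("matrix must carry gene identifiers as rownames", call. = FALSE)
  }
  if (length(sample_groups) != ncol(matrix)) {
    stop("one group label per sample column required", call. = FALSE)
  }
  if (!all(sample_groups %in% c("control", "case"))) {
    stop('sample_groups must be "control" or "case"', call. = FALSE)
  }
  if (min(table(factor(sample_groups, c("control", "case")))) < 2) {
    stop("at least 2 samples per group required", call. = FALSE)
  }
  structure(list(matrix = matrix, gene_ids = rownames(matrix),
                 sample_groups = sample_groups, comparison_id = comparison_id),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study '%s': %d genes, %d control vs %d case samples\n",
              x$comparison_id, nrow(x$matrix),
              sum(x$sample_groups == "control"), sum(x$sample_groups == "case")))
  invisible(x)
}

#' Normalize one study: log2 transform (if needed) and quantile normalization
#'
#' The input scale is auto-detected: a matrix whose maximum exceeds
#' `linear_threshold` is treated as linear intensities and transformed with
#' log2(x + 1); otherwise it is assumed to be on the log2 scale already.
#' Columns are then quantile-normalized so that every sample shares the same
#' empirical distribution (up to ties).
#'
#' @param raw numeric genes x samples matrix (rownames = gene ids).
#' @param sample_groups,comparison_id as in [expression_study()].
#' @param scale "auto" (default), "linear" or "log2" to override detection.
#' @param linear_threshold matrix maximum above which input is treated as
#'   linear-scale. Default 50.
#' @return A normalized [expression_study()].
#' @export
normalize_study <- function(raw, sample_groups, comparison_id,
                            scale = c("auto", "linear", "log2"),
                            linear_threshold = 50) {
  scale <- match.arg(scale)
  if (scale == "auto") {
    scale <- if (max(raw, na.rm = TRUE) > linear_threshold) "linear" else "log2"
  }
  if (scale == "linear") {
    if (any(raw < 0)) stop("linear-scale intensities must be non-negative", call. = FALSE)
    raw <- log2(raw + 1)
  }
  norm <- limma::normalizeQuantiles(raw)
  dimnames(norm) <- dimnames(raw)
  if (any(!is.finite(norm))) stop("matrix not finite after normalization", call. = FALSE)
  expression_study(norm, sample_groups, comparison_id)
}

#' Per-gene differential expression with empirical-Bayes variance moderation
#'
#' For each gene the log2 fold change is the case-minus-control mean
#' difference. With `moderation = TRUE` (the default) the gene-wise pooled
#' variance s_g^2 (d_g residual d.f.) is shrunk toward a prior s_0^2 with
#' d_0 prior d.f.:
#'
#'   s_post^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)
#'
#' where (d_0, s_0^2) are estimated from the ensemble of gene variances by
#' the method of moments under the scaled-F model s_g^2 ~ s_0^2 F(d_g, d_0).
#' The moderated t = log2fc / (s_post sqrt(1/n1 + 1/n2)) is referred to a t
#' distribution with d_0 + d_g degrees of freedom. With `moderation = FALSE`
#' the ordinary pooled-variance t-test is used. Genes with zero fold change
#' and zero variance get p = 1 so downstream set operations are total.
#'
#' @param study a normalized [expression_study()].
#' @param moderation logical; shrink variances toward the ensemble prior.
#' @return data.frame of class `de_result` with columns `gene_id`, `log2fc`,
#'   `t`, `p_raw`, `p_adj` (BH within the comparison), `comparison_id`.
#' @export
differential_expression <- function(study, moderation = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  grp <- study$sample_groups
  x1 <- study$matrix[, grp == "control", drop = FALSE]
  x2 <- study$matrix[, grp == "case", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  d_g <- n1 + n2 - 2
  if (d_g < 1) stop("zero residual degrees of freedom", call. = FALSE)

  fc <- rowMeans(x2) - rowMeans(x1)
  ss1 <- rowSums((x1 - rowMeans(x1))^2)
  ss2 <- rowSums((x2 - rowMeans(x2))^2)
  s2 <- (ss1 + ss2) / d_g

  if (moderation) {
    prior <- fit_variance_prior(s2, d_g)
    d0 <- prior$d0; s02 <- prior$s02
    if (is.infinite(d0)) {
      s2_post <- rep(s02, length(s2))
      df <- Inf
    } else {
      s2_post <- (d0 * s02 + d_g * s2) / (d0 + d_g)
      df <- d0 + d_g
    }
  } else {
    s2_post <- s2
    df <- d_g
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p_raw <- 2 * stats::pt(-abs(t_stat), df = df)
  p_raw[se == 0 & fc == 0] <- 1

  res <- data.frame(gene_id = study$gene_ids, log2fc = unname(fc),
                    t = unname(t_stat), p_raw = unname(p_raw),
                    p_adj = bh_adjust(unname(p_raw)),
                    comparison_id = study$comparison_id,
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

# Method-of-moments fit of the scaled-F variance prior.
# Under s_g^2 ~ s0^2 F(d_g, d0): E = s0^2 d0/(d0-2) and
# Var/E^2 = 2 (d_g + d0 - 2) / (d_g (d0 - 4)), giving a closed form for d0
# from the coefficient of variation r of the gene variances:
#   d0 = (2 d_g - 4 + 4 r d_g) / (r d_g - 2),   r = Var(s^2)/Mean(s^2)^2.
# r d_g <= 2 means the variances are less dispersed than any finite-d0 F
# allows: the prior is degenerate (d0 = Inf) and full shrinkage applies.
fit_variance_prior <- function(s2, d_g) {
  m1 <- mean(s2)
  if (m1 == 0) return(list(d0 = Inf, s02 = 0))
  r <- stats::var(s2) / m1^2
  if (!is.finite(r) || r * d_g <= 2) return(list(d0 = Inf, s02 = m1))
  d0 <- (2 * d_g - 4 + 4 * r * d_g) / (r * d_g - 2)
  list(d0 = d0, s02 = m1 * (d0 - 2) / d0)
}

#' Threshold differential-expression results into a gene set
#'
#' @param results a `de_result` data.frame for one comparison.
#' @param alpha BH-adjusted p-value threshold in (0, 1]; `alpha = 1`
#'   disables the significance filter.
#' @param min_abs_log2fc minimum absolute log2 fold change (default 0: no
#'   fold-change filter, so that small-but-consistent changes are retained).
#' @return Character vector of gene identifiers.
#' @export
de_gene_set <- function(results, alpha = 0.05, min_abs_log2fc = 0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  sig <- if (alpha >= 1) rep(TRUE, nrow(results)) else results$p_adj < alpha
  results$gene_id[sig & abs(results$log2fc) >= min_abs_log2fc]
}
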