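## File adapters. All formats are plain text, tab-separated, UTF-8 with a
## header row; GMT follows the usual term<TAB>description<TAB>gene... layout
## with '#' comment lines ignored. Every writer has a matching reader with
## read(write(x)) = x.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write / read an expression matrix with its group sidecar
#'
#' The matrix TSV has a `gene_id` first column and one column per sample;
#' the sidecar TSV has columns `sample`, `group`.
#'
#' @param study an [expression_study()].
#' @param path matrix TSV path; the sidecar is written to
#'   `<path minus extension>_groups.tsv` unless `groups_path` is given.
#' @param groups_path optional explicit sidecar path.
#' @return `write_expression_tsv`: the two paths, invisibly.
#'   `read_expression_tsv`: an [expression_study()].
#' @export
write_expression_tsv <- function(study, path, groups_path = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(groups_path)) groups_path <- sidecar_path(path)
  df <- data.frame(gene_id = study$gene_ids, study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(study$matrix), group = study$sample_groups),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, groups_path))
}

sidecar_path <- function(path) sub("\\.tsv$", "", path) |> paste0("_groups.tsv")

#' @param comparison_id comparison label for the study read back.
#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, groups_path = NULL, comparison_id = "A") {
  if (is.null(groups_path)) groups_path <- sidecar_path(path)
  df <- read_tsv_checked(path, "gene_id")
  groups <- read_tsv_checked(groups_path, c("sample", "group"))
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(mat) <- df$gene_id
  if (!identical(colnames(mat), groups$sample)) {
    stop(groups_path, ": sample order disagrees with the matrix columns", call. = FALSE)
  }
  expression_study(mat, groups$group, comparison_id)
}

#' Write / read a term-to-gene catalog in GMT format
#'
#' @param catalog named list of character vectors (term -> genes).
#' @param path GMT file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog), function(tm) {
    paste(c(tm, "na", catalog[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(path, " line ", i, ": GMT lines need term, description and >= 1 gene",
           call. = FALSE)
    }
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' Write / read an interaction edge list (STRING-style TSV)
#'
#' Columns `node1`, `node2`, `combined_score` with scores in \[0, 1000\].
#' Malformed rows are rejected with their line number.
#'
#' @param edges data.frame with the three columns above.
#' @param path TSV path.
#' @return `read_edges_tsv`: the validated data.frame.
#' @export
write_edges_tsv <- function(edges, path) {
  stopifnot(all(c("node1", "node2", "combined_score") %in% names(edges)))
  utils::write.table(edges[, c("node1", "node2", "combined_score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  df <- read_tsv_checked(path, c("node1", "node2", "combined_score"))
  bad <- which(!is.finite(df$combined_score) | df$combined_score < 0 |
                 df$combined_score > 1000)
  if (length(bad) > 0) {
    stop(path, " line ", bad[1] + 1L,  # +1 for the header row
         ": combined_score outside [0, 1000]", call. = FALSE)
  }
  df
}

#' Write / read a mouse-to-human ortholog table
#'
#' @param table data.frame with columns `mouse_symbol`, `human_symbol`.
#' @param path TSV path.
#' @return `read_ortholog_tsv`: the data.frame.
#' @export
write_ortholog_tsv <- function(table, path) {
  stopifnot(all(c("mouse_symbol", "human_symbol") %in% names(table)))
  utils::write.table(table[, c("mouse_symbol", "human_symbol")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_tsv
#' @export
read_ortholog_tsv <- function(path) {
  read_tsv_checked(path, c("mouse_symbol", "human_symbol"))
}

#' Write / read a literature snapshot table
#'
#' Columns `gene_id`, `context`, `count`, `ctd_flag`, `malacards_flag`.
#'
#' @param table data.frame with the columns above (flags optional on write,
#'   defaulted to FALSE).
#' @param path TSV path.
#' @return `read_literature_tsv`: the data.frame with logical flags.
#' @export
write_literature_tsv <- function(table, path) {
  stopifnot(all(c("gene_id", "context", "count") %in% names(table)))
  if (is.null(table$ctd_flag)) table$ctd_flag <- FALSE
  if (is.null(table$malacards_flag)) table$malacards_flag <- FALSE
  utils::write.table(
    table[, c("gene_id", "context", "count", "ctd_flag", "malacards_flag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_literature_tsv
#' @export
read_literature_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "context", "count"))
  if (is.null(df$ctd_flag)) df$ctd_flag <- FALSE
  if (is.null(df$malacards_flag)) df$malacards_flag <- FALSE
  df$ctd_flag <- as.logical(df$ctd_flag)
  df$malacards_flag <- as.logical(df$malacards_flag)
  if (any(!is.finite(df$count) | df$count < 0)) {
    stop(path, " line ",
         which(!is.finite(df$count) | df$count < 0)[1] + 1L,
         ": negative or missing count", call. = FALSE)
  }
  df
}

#' Write a machine-readable JSON report
#'
#' @param x a list of scalars / vectors / data.frames.
#' @param path JSON path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
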