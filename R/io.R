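# Reading and writing the package's TSV dialects.
#
# Abundance TSV: first column `protein_id`, remaining columns sample ids,
# tab-separated, UTF-8, NA for missing.  Clinical TSV: columns `sample_id`,
# `group`, `batch`, optionally `os_months`, `os_event` and further
# covariates.

#' Read a protein abundance TSV
#'
#' @param path TSV with first column \code{protein_id} and one numeric
#'   column per sample.
#' @return numeric matrix, proteins in rows, with dimnames.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop_input("abundance file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "protein_id")
    stop_input("malformed header: first column must be 'protein_id'")
  if (anyDuplicated(df$protein_id))
    stop_input("duplicate protein_id: %s",
               df$protein_id[anyDuplicated(df$protein_id)])
  if (anyDuplicated(names(df)[-1L]))
    stop_input("duplicate sample id in header")
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad)) {
    # locate first offending cell for the error message
    col <- names(vals)[bad][1L]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))) &
                   !is.na(vals[[col]]) & vals[[col]] != "NA")[1L]
    stop_input("non-numeric value in column '%s' (line %d)", col,
               if (is.na(row)) -1L else row + 1L)
  }
  x <- as.matrix(vals)
  rownames(x) <- df$protein_id
  x
}

#' Write a protein abundance TSV
#'
#' @param x abundance matrix with dimnames.
#' @param path output path.
#' @param digits significant digits (\code{NA} writes full precision for
#'   bit-exact round-trips).
#' @export
write_abundance <- function(x, path, digits = NA) {
  check_matrix(x, "abundance matrix")
  vals <- if (is.na(digits)) x else signif(x, digits)
  df <- data.frame(protein_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation TSV
#'
#' Requires \code{sample_id}; optional columns \code{group}, \code{batch},
#' \code{os_months}, \code{os_event} and arbitrary covariates are passed
#' through.  \code{os_event}, when present, must be coded 0/1.
#'
#' @param path TSV path.
#' @param sample_ids optional vector (e.g. abundance column names) that the
#'   clinical \code{sample_id}s must match exactly (as sets).
#' @return data.frame, one row per sample.
#' @export
read_clinical <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop_input("clinical file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop_input("missing required column: sample_id")
  if (anyDuplicated(df$sample_id)) stop_input("duplicate sample_id in clinical table")
  if ("os_event" %in% names(df) && !all(df$os_event %in% c(0, 1, NA)))
    stop_input("os_event must be coded 0/1")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, df$sample_id)
    extra <- setdiff(df$sample_id, sample_ids)
    if (length(missing) || length(extra))
      stop_input("sample ids do not match the abundance matrix (missing: %s; extra: %s)",
                 paste(missing, collapse = ",") %|blank|% "none",
                 paste(extra, collapse = ",") %|blank|% "none")
    df <- df[match(sample_ids, df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

`%|blank|%` <- function(a, b) if (nzchar(a)) a else b

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a module graph as an edge-list TSV and GraphML
#'
#' @param graph \code{igraph} graph from \code{\link{module_graph}}.
#' @param edge_path edge-list TSV (\code{protein_a}, \code{protein_b},
#'   \code{weight}).
#' @param graphml_path optional GraphML output.
#' @export
write_module_graph <- function(graph, edge_path, graphml_path = NULL) {
  edges <- igraph::as_data_frame(graph, what = "edges")
  names(edges)[1:2] <- c("protein_a", "protein_b")
  write_tsv(edges, edge_path)
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  invisible(edge_path)
}
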