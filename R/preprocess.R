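# Normalization and feature selection for TMT-style protein abundance
# matrices (proteins x samples).

#' Normalize linear TMT ratios to log2 protein abundance
#'
#' Reproduces the standard TMT ratio-to-pool normalization arithmetic:
#' each sample (column) is divided by its median ratio, values are log2
#' transformed, and each protein (row) is mean-centered within each TMT
#' set (batch).  After this, anti-log sample medians are 1 and every
#' protein's within-batch mean is 0.
#'
#' @param ratios numeric matrix of strictly positive linear ratios to the
#'   pooled reference, proteins in rows, samples in columns; dimnames
#'   identify proteins and samples.
#' @param batch batch (TMT set) label per sample; a single batch is assumed
#'   when omitted.
#' @return log2 abundance matrix of the same shape.
#' @export
normalize_abundance <- function(ratios, batch = NULL) {
  check_matrix(ratios, "ratios")
  if (anyNA(ratios)) stop_input("ratios contain missing values; run filter_complete first")
  if (any(ratios <= 0)) {
    bad <- which(ratios <= 0, arr.ind = TRUE)[1L, ]
    stop_input("nonpositive ratio at protein %s, sample %s",
               rownames(ratios)[bad[1L]] %||% bad[1L],
               colnames(ratios)[bad[2L]] %||% bad[2L])
  }
  if (is.null(batch)) batch <- rep("1", ncol(ratios))
  if (length(batch) != ncol(ratios))
    stop_input("batch must have one label per sample (%d != %d)",
               length(batch), ncol(ratios))
  med <- apply(ratios, 2L, stats::median)
  x <- log2(sweep(ratios, 2L, med, "/"))
  center_by_batch(x, batch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-protein, per-batch mean centering on the log2 scale (idempotent).
center_by_batch <- function(x, batch) {
  for (b in unique(batch)) {
    idx <- which(batch == b)
    x[, idx] <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE])
  }
  x
}

#' Keep proteins quantified in every sample
#'
#' Retains only rows without missing values, preserving order; emits a
#' warning when every row is dropped.
#'
#' @param x numeric abundance matrix, proteins in rows.
#' @return the complete-case submatrix.
#' @export
filter_complete <- function(x) {
  check_matrix(x, "abundance matrix")
  keep <- !apply(x, 1L, anyNA)
  if (!any(keep)) warning("no protein is quantified in every sample; empty matrix")
  x[keep, , drop = FALSE]
}

#' Select the most variable proteins
#'
#' Computes the per-protein sample variance and keeps the
#' \code{ceiling(fraction * nrow(x))} rows with the largest variance.
#' Variance ties are broken by protein id (lexicographic), and the retained
#' rows keep their original order.
#'
#' @param x numeric abundance matrix with protein ids as rownames.
#' @param fraction fraction of rows to keep, in (0, 1]. The conventional
#'   network input is the top quarter (\code{fraction = 0.25}).
#' @return the filtered matrix.
#' @export
select_top_variable <- function(x, fraction = 0.25) {
  check_matrix(x, "abundance matrix")
  if (nrow(x) == 0L) stop_input("empty abundance matrix")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop_input("fraction must be in (0, 1]")
  n_keep <- as.integer(ceiling(fraction * nrow(x)))
  v <- apply(x, 1L, stats::var)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  ord <- order(-v, ids)
  keep <- sort(ord[seq_len(n_keep)])
  x[keep, , drop = FALSE]
}
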