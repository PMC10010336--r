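# Two-group and enrichment statistics: Wilcoxon rank-sum differential
# expression with Benjamini-Hochberg adjustment, Fisher's exact test,
# Kruskal-Wallis, Welch t, and hypergeometric gene-set over-representation.

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; tie-corrected normal approximation (no continuity
#' correction) otherwise.  Two-sided.
#'
#' @param x,y numeric value vectors (each non-empty).
#' @return \code{htest} with the rank-sum statistic W and two-sided p.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop_input("both groups must be non-empty")
  exact <- (length(x) + length(y)) <= 12L && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  ht$method <- if (exact) "Wilcoxon rank-sum test (exact)" else
    "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  ht
}

#' Welch two-sample t test
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return \code{htest}.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_input("each group needs >= 2 values")
  stats::t.test(x, y, var.equal = FALSE)
}

#' Kruskal-Wallis test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on
#' (groups - 1) df.  A degenerate pooled sample (all values identical)
#' returns H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return \code{htest}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups)) stop_input("values and groups must align")
  if (nlevels(groups) < 2L) stop_input("at least 2 groups are required")
  if (length(unique(values)) == 1L) {
    return(structure(list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                          parameter = c(df = nlevels(groups) - 1L),
                          p.value = 1,
                          method = "Kruskal-Wallis rank sum test",
                          data.name = "values by group"),
                     class = "htest"))
  }
  stats::kruskal.test(values, groups)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; never decreases a p-value, caps
#' at 1, and is invariant to input order.
#'
#' @param pvals p-values in [0, 1] (NA allowed and propagated).
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional two-sided p (probability-mass rule: the sum over tables at
#' most as probable as the observed one) and the sample odds ratio
#' \eqn{ad/bc}.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return \code{htest} with the sample odds ratio in \code{estimate}
#'   (Inf/0 when a margin cell is empty, with a warning).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop_input("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop_input("counts must be non-negative integers")
  ht <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (!is.finite(or)) warning("degenerate sample odds ratio (zero cell)")
  ht$estimate <- c(`sample odds ratio` = or)
  ht$method <- "Fisher's exact test (two-sided, probability-mass rule)"
  ht
}

#' Wilcoxon differential expression between two sample groups
#'
#' Per protein: log2 fold change as the difference of group means (the
#' matrix is already on the log2 scale), a Wilcoxon rank-sum p, and
#' Benjamini-Hochberg adjustment across all tested proteins.
#'
#' @param x log2 abundance matrix, proteins in rows.
#' @param group_a,group_b disjoint vectors of sample ids (or column
#'   indices), each of at least 2 samples.
#' @return data.frame with columns \code{protein}, \code{log2fc},
#'   \code{p_value}, \code{p_adjusted}, ordered as the input rows.
#' @export
differential_expression <- function(x, group_a, group_b) {
  check_matrix(x, "abundance matrix")
  ia <- if (is.character(group_a)) match(group_a, colnames(x)) else as.integer(group_a)
  ib <- if (is.character(group_b)) match(group_b, colnames(x)) else as.integer(group_b)
  if (anyNA(ia) || anyNA(ib)) stop_input("unknown sample id in group definition")
  if (length(ia) < 2L || length(ib) < 2L) stop_input("each group needs >= 2 samples")
  if (length(intersect(ia, ib))) stop_input("groups overlap")
  a <- x[, ia, drop = FALSE]
  b <- x[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(x)), function(i) {
    if (length(unique(c(a[i, ], b[i, ]))) == 1L) return(1)
    wilcoxon_rank_sum(a[i, ], b[i, ])$p.value
  }, numeric(1L))
  data.frame(protein = rownames(x) %||% as.character(seq_len(nrow(x))),
             log2fc = rowMeans(a) - rowMeans(b),
             p_value = p, p_adjusted = bh_adjust(p), row.names = NULL)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated name, description,
#'   members.
#' @return named list of character member vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap when drawing \code{length(query)} proteins from
#' the universe, with BH adjustment across sets.  Set members outside the
#' universe are ignored.
#'
#' @param query character vector of proteins (must be a subset of
#'   \code{universe}).
#' @param universe character vector: all quantifiable proteins.
#' @param sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @return data.frame with columns \code{set}, \code{set_size} (in
#'   universe), \code{overlap}, \code{p_value}, \code{p_adjusted}, ordered
#'   by increasing p.
#' @export
enrich_hypergeometric <- function(query, universe, sets) {
  query <- unique(query); universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_input("query proteins outside the universe: %s",
               paste(utils::head(outside, 5L), collapse = ", "))
  if (!length(sets) || is.null(names(sets))) stop_input("sets must be a named list")
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1L, length(members), n_u - length(members), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(members), overlap = k, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out[order(out$p_value, out$set), , drop = FALSE]
}
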