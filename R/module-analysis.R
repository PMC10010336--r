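# Module characterization: eigenproteins, module membership (kME),
# intramodular hubs, module-trait association, sample clustering and
# thresholded module graphs.

#' Module eigenproteins
#'
#' The eigenprotein (ME) of a module is the first principal component of
#' its standardized protein x sample submatrix: the single sample-space
#' profile explaining the most member variance, the module's representative
#' profile.  Each ME is standardized to zero mean and unit variance across
#' samples and sign-flipped so that its mean correlation with the member
#' profiles is non-negative.
#'
#' @param x abundance matrix, proteins in rows.
#' @param assignments module labels per protein (0 = unassigned).
#' @return modules x samples matrix, rows named \code{M1}, \code{M2}, ...
#'   in ascending label order, with attribute \code{explained} giving the
#'   fraction of member variance the ME explains per module.
#' @export
module_eigenproteins <- function(x, assignments) {
  check_matrix(x, "abundance matrix")
  if (length(assignments) != nrow(x))
    stop_input("assignments must have one label per protein")
  mods <- sort(unique(assignments[assignments != 0L]))
  if (!length(mods)) stop_input("no assigned module")
  me <- matrix(NA_real_, length(mods), ncol(x),
               dimnames = list(paste0("M", mods), colnames(x)))
  explained <- stats::setNames(numeric(length(mods)), rownames(me))
  for (i in seq_along(mods)) {
    sub <- x[assignments == mods[i], , drop = FALSE]
    if (nrow(sub) == 1L) {
      warning(sprintf("module %d has a single protein; ME is its standardized profile",
                      mods[i]))
      v <- drop(sub)
      me[i, ] <- (v - mean(v)) / stats::sd(v)
      explained[i] <- 1
      next
    }
    z <- t(scale(t(sub)))                    # standardize each protein profile
    z[is.nan(z)] <- 0                        # constant member profiles
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (sv$d[1L] < sqrt(.Machine$double.eps) || stats::sd(e) == 0) {
      warning(sprintf("module %d is degenerate (no sample variation); ME set to 0",
                      mods[i]))
      me[i, ] <- 0
      explained[i] <- 0
      next
    }
    e <- (e - mean(e)) / stats::sd(e)
    member_cor <- suppressWarnings(stats::cor(t(sub), e))
    if (mean(member_cor, na.rm = TRUE) < 0) e <- -e
    me[i, ] <- e
    explained[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(me, "explained") <- explained
  me
}

#' Module membership (kME)
#'
#' Pearson correlation of every protein profile (assigned or not) with
#' every module eigenprotein.
#'
#' @param x abundance matrix, proteins in rows.
#' @param me eigenprotein matrix from \code{\link{module_eigenproteins}}.
#' @return proteins x modules matrix of correlations in [-1, 1]; constant
#'   proteins get kME 0 with a warning.
#' @export
kme <- function(x, me) {
  check_matrix(x, "abundance matrix")
  check_matrix(me, "eigenprotein matrix")
  if (ncol(x) != ncol(me)) stop_input("x and me must share their sample columns")
  constant <- apply(x, 1L, stats::sd) == 0
  k <- matrix(0, nrow(x), nrow(me), dimnames = list(rownames(x), rownames(me)))
  if (any(!constant))
    k[!constant, ] <- stats::cor(t(x[!constant, , drop = FALSE]), t(me))
  if (any(constant))
    warning(sprintf("%d constant protein(s); kME set to 0", sum(constant)))
  k
}

#' Intramodular hub proteins
#'
#' The \code{n} members of a module with the largest kME to that module's
#' eigenprotein, in descending kME order (ties by protein id).  The top-50
#' list is the conventional survival signature.
#'
#' @param kme_matrix proteins x modules kME matrix.
#' @param assignments module labels per protein, aligned with
#'   \code{kme_matrix} rows.
#' @param module module label (integer) to extract hubs from.
#' @param n number of hubs; when the module is smaller, all members are
#'   returned with a warning.
#' @return character vector of protein ids.
#' @export
hub_proteins <- function(kme_matrix, assignments, module, n = 50) {
  check_matrix(kme_matrix, "kME matrix")
  if (n < 1) stop_input("n must be >= 1")
  col <- paste0("M", module)
  if (!col %in% colnames(kme_matrix)) stop_input("module %s not present", col)
  idx <- which(assignments == module)
  if (!length(idx)) stop_input("module %s has no members", col)
  if (n > length(idx)) {
    warning(sprintf("module %s has only %d members; returning all", col, length(idx)))
    n <- length(idx)
  }
  ids <- rownames(kme_matrix)[idx] %||% as.character(idx)
  ord <- order(-kme_matrix[idx, col], ids)
  ids[ord][seq_len(n)]
}

#' Module eigenprotein vs sample-group association
#'
#' Kruskal-Wallis test of each eigenprotein across sample groups, the
#' standard nonparametric check that a module tracks tissue composition.
#'
#' @param me eigenprotein matrix (modules x samples).
#' @param groups group label per sample (at least 2 groups of 2).
#' @return data.frame with columns \code{module}, \code{statistic} (the
#'   tie-corrected H), \code{df} and \code{p_value}.
#' @export
me_trait_association <- function(me, groups) {
  check_matrix(me, "eigenprotein matrix")
  groups <- as.factor(groups)
  if (length(groups) != ncol(me)) stop_input("one group label per sample is required")
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop_input("at least 2 groups with at least 2 samples each are required")
  rows <- lapply(seq_len(nrow(me)), function(i) {
    kw <- kruskal_wallis(me[i, ], groups)
    data.frame(module = rownames(me)[i], statistic = unname(kw$statistic),
               df = unname(kw$parameter), p_value = kw$p.value)
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of samples
#'
#' Clusters samples on 1 - Pearson correlation over proteins (complete
#' linkage by default) and cuts into \code{k} groups, labelled in
#' decreasing size order.
#'
#' @param x abundance matrix, proteins in rows.
#' @param k number of sample clusters.
#' @param method linkage passed to \code{\link[stats]{hclust}}.
#' @return integer cluster label per sample, named by sample id.
#' @export
sample_clusters <- function(x, k, method = "complete") {
  check_matrix(x, "abundance matrix")
  if (k < 2) stop_input("k must be >= 2")
  if (k > ncol(x)) stop_input("k exceeds the number of samples")
  d <- stats::as.dist(1 - stats::cor(x))
  tree <- stats::hclust(d, method = method)
  labels <- stats::cutree(tree, k = k)
  out <- relabel_by_size(as.integer(labels))
  names(out) <- colnames(x)
  out
}

#' Thresholded module graph
#'
#' The drug-target style network view of a module: nodes are members whose
#' kME exceeds \code{kme_min}, edges connect pairs whose pairwise
#' correlation exceeds \code{cor_min} (strict inequalities), edge weight is
#' the correlation and node degree is recorded.  Isolated nodes are kept.
#'
#' @param x abundance matrix, proteins in rows.
#' @param kme_matrix proteins x modules kME matrix aligned with \code{x}.
#' @param assignments module labels per protein.
#' @param module module label (integer).
#' @param kme_min minimum kME for node inclusion (default 0.7).
#' @param cor_min minimum pairwise correlation for an edge (default 0.3).
#' @param cor_method correlation for the edges, "pearson" (default) or
#'   "bicor".
#' @return \code{\link[igraph]{igraph}} graph with vertex attributes
#'   \code{kme} and \code{degree} and edge attribute \code{weight}; graph
#'   attributes record the thresholds.
#' @export
module_graph <- function(x, kme_matrix, assignments, module,
                         kme_min = 0.7, cor_min = 0.3,
                         cor_method = c("pearson", "bicor")) {
  check_matrix(x, "abundance matrix")
  cor_method <- match.arg(cor_method)
  col <- paste0("M", module)
  if (!col %in% colnames(kme_matrix)) stop_input("module %s not present", col)
  keep <- which(assignments == module & kme_matrix[, col] > kme_min)
  if (!length(keep)) {
    warning(sprintf("no member of %s passes kME > %g; empty graph", col, kme_min))
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    sub <- x[keep, , drop = FALSE]
    cc <- correlation_matrix(sub, method = cor_method)
    cc[cc <= cor_min] <- 0
    diag(cc) <- 0
    g <- igraph::graph_from_adjacency_matrix(cc, mode = "undirected",
                                             weighted = TRUE)
    igraph::V(g)$kme <- unname(kme_matrix[keep, col])
    igraph::V(g)$degree <- igraph::degree(g)
  }
  g <- igraph::set_graph_attr(g, "module", col)
  g <- igraph::set_graph_attr(g, "kme_min", kme_min)
  igraph::set_graph_attr(g, "cor_min", cor_min)
}
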