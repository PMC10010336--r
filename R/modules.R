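# Module detection on the TOM dendrogram: a simplified dynamic-hybrid tree
# cut (static cut, then recursive branch splitting guided by merge-height
# gaps) followed by eigenprotein-similarity module merging.

# Per-node bookkeeping for an hclust tree.  Nodes are indexed 1..n-1 for
# internal merges; leaves are carried as negative indices, as in $merge.
tree_members <- function(tree) {
  n <- length(tree$order)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    left <- tree$merge[i, 1L]
    right <- tree$merge[i, 2L]
    members[[i]] <- c(if (left < 0L) -left else members[[left]],
                      if (right < 0L) -right else members[[right]])
  }
  members
}

node_height <- function(tree, node) if (node < 0L) 0 else tree$height[node]
node_size <- function(members, node) if (node < 0L) 1L else length(members[[node]])

#' Cut a TOM dendrogram into coexpression modules
#'
#' Simplified dynamic-hybrid cut.  (1) A static cut at \code{cut_height}
#' yields candidate branches.  (2) Each branch with at least
#' \code{2 * min_size} leaves is decomposed by spine descent: walk down from
#' the branch root, shedding sub-\code{min_size} side twigs (outliers and
#' noise proteins chain onto a branch near its root under average linkage),
#' until a split point is reached where both children hold at least
#' \code{min_size} leaves and the merge-height drop exceeds
#' \code{split_sensitivity}; the two children are then decomposed
#' recursively and the shed twigs become unassigned.  When no split point
#' exists the branch is kept whole, twigs included, so module interiors are
#' never eroded.  (3) Branches of at least \code{min_size} leaves become
#' modules; everything else is unassigned (label 0, the conventional M0).
#' Module labels 1..k are assigned in decreasing size order, so module 1 is
#' always the largest.
#'
#' @param tree \code{hclust} tree from \code{\link{build_dendrogram}}.
#' @param min_size minimum module size (default 50, the usual proteome
#'   network setting).
#' @param cut_height static cut height; default is the 0.99 quantile of the
#'   merge heights.
#' @param split_sensitivity minimum merge-height gap (on the 1 - TOM scale)
#'   required to accept a split point.  Average linkage compresses TOM
#'   dissimilarities into a narrow band near their maximum, so meaningful
#'   gaps are small; the default 0 accepts any positive drop and relies on
#'   eigenprotein merging to undo over-splitting.
#' @return integer vector of module labels (0 = unassigned), named by
#'   protein id when the tree has labels.
#' @export
cut_modules <- function(tree, min_size = 50, cut_height = NULL,
                        split_sensitivity = 0) {
  if (!inherits(tree, "hclust")) stop_input("tree must be an hclust object")
  if (min_size < 1) stop_input("min_size must be >= 1")
  n <- length(tree$order)
  labels <- rep(0L, n)
  names(labels) <- tree$labels
  if (min_size > n) {
    warning("min_size exceeds the number of proteins; all unassigned")
    return(labels)
  }
  if (n == 1L) {
    labels[] <- if (min_size <= 1L) 1L else 0L
    return(labels)
  }
  if (is.null(cut_height)) cut_height <- stats::quantile(tree$height, 0.99, names = FALSE)
  members <- tree_members(tree)

  # Static cut: maximal nodes with merge height <= cut_height.
  branches <- list()
  stack <- list(n - 1L)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node < 0L || tree$height[node] <= cut_height) {
      branches[[length(branches) + 1L]] <- node
    } else {
      stack <- c(stack, list(tree$merge[node, 1L], tree$merge[node, 2L]))
    }
  }

  # Spine-descent decomposition of large branches: shed sub-min_size twigs
  # while walking down until a genuine two-module split point appears; keep
  # the branch whole (twigs included) when none does.
  final <- list()
  stack <- branches
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node < 0L || node_size(members, node) < 2L * min_size) {
      final[[length(final) + 1L]] <- node
      next
    }
    cur <- node
    shed <- list()
    split_at <- NULL
    while (cur > 0L && node_size(members, cur) >= 2L * min_size) {
      left <- tree$merge[cur, 1L]
      right <- tree$merge[cur, 2L]
      sl <- node_size(members, left)
      sr <- node_size(members, right)
      gap <- tree$height[cur] - max(node_height(tree, left), node_height(tree, right))
      if (sl >= min_size && sr >= min_size && gap > split_sensitivity) {
        split_at <- c(left, right)
        break
      }
      if (sl >= sr) { shed <- c(shed, list(right)); cur <- left }
      else          { shed <- c(shed, list(left));  cur <- right }
    }
    if (is.null(split_at)) {
      final[[length(final) + 1L]] <- node      # no module substructure: keep whole
    } else {
      stack <- c(stack, as.list(split_at), shed)
    }
  }

  nxt <- 0L
  for (node in final) {
    idx <- if (node < 0L) -node else members[[node]]
    if (length(idx) >= min_size) {
      nxt <- nxt + 1L
      labels[idx] <- nxt
    }
  }
  relabel_by_size(labels)
}

#' Merge modules with near-identical eigenproteins
#'
#' Iteratively merges the module pair whose eigenproteins correlate at or
#' above \code{1 - merge_height}, relabelling by size after reaching the
#' fixpoint.  This is the conventional post-processing that collapses
#' branches the tree cut split despite carrying the same signal.
#'
#' @param assignments integer module labels (0 = unassigned).
#' @param x abundance matrix the modules were detected on.
#' @param merge_height eigenprotein dissimilarity below which modules merge
#'   (default 0.15, i.e. correlation >= 0.85).
#' @return merged label vector, relabelled so module 1 is largest.
#' @export
merge_modules <- function(assignments, x, merge_height = 0.15) {
  check_matrix(x, "abundance matrix")
  if (length(assignments) != nrow(x))
    stop_input("assignments must have one label per protein")
  repeat {
    mods <- sort(unique(assignments[assignments != 0L]))
    if (length(mods) < 2L) break
    me <- module_eigenproteins(x, assignments)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[best[1L], best[2L]] < 1 - merge_height) break
    keep <- mods[min(best)]
    drop <- mods[max(best)]
    assignments[assignments == drop] <- keep
  }
  relabel_by_size(assignments)
}
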