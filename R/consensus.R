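# Subsampled k-means consensus clustering and module-signature sample
# stratification.

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ], "-")^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[i + 1L] <- sample.int(n, 1L)
    } else {
      centers[i + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[i + 1L], ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

# One k-means run: best of `restarts` k-means++ seedings, Lloyd updates.
# Items with no variation at all cannot be partitioned meaningfully; they
# are put into one cluster (the consensus stage flags such runs).
kmeans_run <- function(x, k, restarts = 10L) {
  if (diff(range(x)) < 1e-12) return(rep(1L, nrow(x)))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers + stats::rnorm(length(centers), sd = 1e-9)  # guard duplicates
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd")
      ),
      error = function(e) NULL                 # e.g. an emptied cluster
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (is.null(best)) return(rep(1L, nrow(x)))
  best$cluster
}

#' Subsampled k-means consensus matrix
#'
#' Runs \code{iterations} rounds of k-means, each on a random subsample of
#' \code{floor(item_fraction * n)} samples and
#' \code{floor(feature_fraction * p)} features (without replacement, features
#' standardized per subsample), and records for every sample pair the
#' fraction of co-sampled rounds in which the pair co-clustered.
#'
#' @param x samples x features matrix (note the orientation: items to be
#'   clustered are rows).
#' @param k number of clusters per round (>= 2).
#' @param iterations number of rounds (>= 1); the conventional setting is
#'   1000.
#' @param item_fraction,feature_fraction subsampling fractions in (0, 1];
#'   the conventional setting is 0.8 with a 20\% hold-out.
#' @param seed integer seed making the whole procedure deterministic.
#' @param restarts k-means restarts per round (k-means++ seeding).
#' @return object of class \code{consensus_result}: list with
#'   \code{consensus} (samples x samples, in [0, 1]),
#'   \code{co_sampled_counts}, \code{k}, \code{iterations}, the fractions,
#'   and \code{labels = NULL} until \code{\link{cut_consensus}} is applied.
#' @export
consensus_matrix <- function(x, k, iterations = 1000L,
                             item_fraction = 0.8, feature_fraction = 0.8,
                             seed = 1L, restarts = 10L) {
  check_matrix(x, "data matrix")
  n <- nrow(x); p <- ncol(x)
  if (k < 2) stop_input("k must be >= 2")
  if (iterations < 1) stop_input("iterations must be >= 1")
  if (item_fraction <= 0 || item_fraction > 1 ||
      feature_fraction <= 0 || feature_fraction > 1)
    stop_input("subsampling fractions must be in (0, 1]")
  n_items <- max(1L, floor(item_fraction * n))
  n_feats <- max(1L, floor(feature_fraction * p))
  if (n_items < k) stop_input("subsample of %d items cannot hold %d clusters",
                              n_items, k)
  co_clustered <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  set.seed(stream_seed(seed, "consensus"))
  for (it in seq_len(iterations)) {
    items <- sort(sample.int(n, n_items))
    feats <- sort(sample.int(p, n_feats))
    sub <- scale(x[items, feats, drop = FALSE])
    sub[is.nan(sub)] <- 0
    cl <- kmeans_run(sub, k, restarts = restarts)
    co_sampled[items, items] <- co_sampled[items, items] + 1
    for (g in seq_len(k)) {
      members <- items[cl == g]
      co_clustered[members, members] <- co_clustered[members, members] + 1
    }
  }
  consensus <- ifelse(co_sampled > 0, co_clustered / co_sampled, 0)
  never <- sum(co_sampled[upper.tri(co_sampled)] == 0)
  if (never > 0)
    warning(sprintf("%d sample pair(s) never co-sampled; their consensus is 0", never))
  dimnames(consensus) <- list(rownames(x), rownames(x))
  structure(list(consensus = consensus, co_sampled_counts = co_sampled,
                 k = as.integer(k), iterations = as.integer(iterations),
                 item_fraction = item_fraction, feature_fraction = feature_fraction,
                 never_co_sampled = never, labels = NULL),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering: %d samples, k = %d, %d iterations (%g/%g subsampling)\n",
              nrow(x$consensus), x$k, x$iterations,
              x$item_fraction, x$feature_fraction))
  off <- x$consensus[upper.tri(x$consensus)]
  cat(sprintf("  mean off-diagonal consensus: %.3f\n", mean(off)))
  if (!is.null(x$labels))
    cat(sprintf("  cluster sizes: %s\n",
                paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Cut a consensus matrix into final clusters
#'
#' Complete-linkage hierarchical clustering on 1 - consensus, cut into
#' \code{k} clusters labelled in decreasing size order.
#'
#' @param result \code{consensus_result} from \code{\link{consensus_matrix}},
#'   or a raw consensus matrix.
#' @param k number of clusters.
#' @return integer label vector, named by sample id when available.
#' @export
cut_consensus <- function(result, k) {
  cons <- if (inherits(result, "consensus_result")) result$consensus else result
  check_matrix(cons, "consensus matrix")
  if (k > nrow(cons)) stop_input("k exceeds the number of samples")
  tree <- stats::hclust(stats::as.dist(1 - cons), method = "complete")
  labels <- relabel_by_size(as.integer(stats::cutree(tree, k = k)))
  stats::setNames(labels, rownames(cons))
}

#' Consensus CDF report over a range of k
#'
#' Empirical CDF of the consensus entries and the area under it per k,
#' with the incremental area gain — the standard (informational) aid for
#' judging cluster-number stability.  Nothing is auto-selected.
#'
#' @param x samples x features matrix.
#' @param ks candidate cluster numbers.
#' @param ... passed to \code{\link{consensus_matrix}}.
#' @return data.frame with columns \code{k}, \code{auc}, \code{delta_auc}.
#' @export
consensus_cdf_report <- function(x, ks = 2:6, ...) {
  aucs <- vapply(ks, function(k) {
    res <- consensus_matrix(x, k = k, ...)
    off <- sort(res$consensus[upper.tri(res$consensus)])
    grid <- seq(0, 1, length.out = 101L)
    cdf <- vapply(grid, function(g) mean(off <= g), numeric(1L))
    sum(diff(grid) * cdf[-1L])
  }, numeric(1L))
  data.frame(k = ks, auc = aucs, delta_auc = c(NA, diff(aucs)))
}

#' Stratify samples on a module's hub-protein signature
#'
#' The survival-stratification procedure: take the module's top \code{n_top}
#' kME proteins (the signature), consensus-cluster the samples on that
#' signature, and label the resulting clusters by mean signature abundance
#' ("high"/"low" for k = 2, otherwise ranks 1..k in descending mean).
#'
#' @param x abundance matrix, proteins in rows.
#' @param kme_matrix proteins x modules kME matrix aligned with \code{x}.
#' @param assignments module labels per protein.
#' @param module module label (integer) providing the signature.
#' @param n_top signature size (default 50).
#' @param k number of strata (default 2).
#' @param iterations,item_fraction,feature_fraction,seed,restarts consensus
#'   parameters, see \code{\link{consensus_matrix}}.
#' @return list with \code{labels} (character per sample: "high"/"low" or
#'   rank), \code{signature} (protein ids), \code{consensus_result}, and
#'   \code{unstable} (TRUE when all samples are effectively identical and
#'   the split is arbitrary; mean off-diagonal consensus is attached).
#' @export
stratify_module_signature <- function(x, kme_matrix, assignments, module,
                                      n_top = 50, k = 2, iterations = 1000L,
                                      item_fraction = 0.8, feature_fraction = 0.8,
                                      seed = 1L, restarts = 10L) {
  check_matrix(x, "abundance matrix")
  signature <- hub_proteins(kme_matrix, assignments, module, n = n_top)
  sig_idx <- match(signature, rownames(x))
  sub <- t(x[sig_idx, , drop = FALSE])      # samples x signature proteins
  res <- consensus_matrix(sub, k = k, iterations = iterations,
                          item_fraction = item_fraction,
                          feature_fraction = feature_fraction,
                          seed = seed, restarts = restarts)
  cl <- cut_consensus(res, k)
  res$labels <- cl
  mean_sig <- rowMeans(sub)
  cluster_mean <- tapply(mean_sig, cl, mean)
  ord <- order(-cluster_mean)               # rank clusters by mean signature level
  rank_of <- match(cl, as.integer(names(cluster_mean))[ord])
  labels <- if (k == 2L) c("high", "low")[rank_of] else as.character(rank_of)
  names(labels) <- colnames(x)
  off <- res$consensus[upper.tri(res$consensus)]
  spread <- diff(range(mean_sig))
  unstable <- spread < 1e-8
  if (unstable)
    warning(sprintf("samples are indistinguishable on the signature (mean off-diagonal consensus %.3f); labels are arbitrary",
                    mean(off)))
  list(labels = labels, signature = signature, consensus_result = res,
       unstable = unstable, mean_offdiag_consensus = mean(off))
}
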