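# Signed weighted network construction: adjacency, scale-free topology fit,
# soft-threshold selection and topological overlap.

#' Signed weighted adjacency from a correlation matrix
#'
#' \eqn{a_{ij} = ((1 + cor_{ij}) / 2)^\beta}: perfectly anti-correlated
#' proteins get adjacency 0, perfectly correlated 1.  The diagonal is set
#' to 1.
#'
#' @param cor symmetric correlation matrix in [-1, 1].
#' @param beta soft-threshold power, >= 1.
#' @return adjacency matrix in [0, 1] with attribute \code{beta}.
#' @export
signed_adjacency <- function(cor, beta) {
  check_matrix(cor, "correlation matrix")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1)
    stop_input("beta must be a single power >= 1")
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Bins the connectivities \eqn{k_i = \sum_{j \ne i} a_{ij}} into
#' \code{n_bins} equal-width bins and regresses log10 frequency on log10
#' mean connectivity over non-empty bins.  The returned \code{r_squared} is
#' signed by the negated slope sign, so a decreasing (scale-free-like)
#' degree distribution yields a positive index.
#'
#' @param adj adjacency matrix (at least 20 proteins).
#' @param n_bins number of connectivity bins.
#' @return list with \code{r_squared} (signed), \code{slope} and
#'   \code{mean_connectivity}.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  check_matrix(adj, "adjacency matrix")
  if (nrow(adj) < 20L) stop_input("at least 20 proteins are required")
  k <- rowSums(adj) - diag(adj)
  if (diff(range(k)) < .Machine$double.eps^0.5) {
    warning("all connectivities identical; scale-free fit undefined")
    return(list(r_squared = 0, slope = NA_real_, mean_connectivity = mean(k)))
  }
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & kmean > 0
  freq <- freq[ok] / length(k)
  kmean <- kmean[ok]
  if (length(freq) < 3L) {
    warning("fewer than 3 populated connectivity bins; scale-free fit undefined")
    return(list(r_squared = 0, slope = NA_real_, mean_connectivity = mean(k)))
  }
  fit <- stats::lm(log10(freq) ~ log10(kmean))
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope, mean_connectivity = mean(k))
}

#' Soft-threshold power scan
#'
#' Evaluates the signed scale-free fit index for each candidate power and
#' picks the smallest power whose index reaches \code{r2_target}; when no
#' power reaches the target, the power maximizing the index is chosen.
#'
#' @param cor correlation matrix.
#' @param betas candidate powers.
#' @param r2_target required signed fit index.
#' @return object of class \code{soft_threshold_scan}: a data.frame with
#'   columns \code{beta}, \code{r_squared}, \code{slope},
#'   \code{mean_connectivity} and attribute \code{chosen_beta}.
#' @export
pick_soft_threshold <- function(cor, betas = 1:20, r2_target = 0.8) {
  check_matrix(cor, "correlation matrix")
  rows <- lapply(betas, function(b) {
    fit <- scale_free_fit(signed_adjacency(cor, b))
    data.frame(beta = b, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = fit$mean_connectivity)
  })
  scan <- do.call(rbind, rows)
  hit <- which(scan$r_squared >= r2_target)
  chosen <- if (length(hit)) scan$beta[hit[1L]] else scan$beta[which.max(scan$r_squared)]
  attr(scan, "chosen_beta") <- chosen
  attr(scan, "r2_target") <- r2_target
  class(scan) <- c("soft_threshold_scan", "data.frame")
  scan
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (signed scale-free fit index)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  cat(sprintf("chosen beta: %d (target R^2 = %g)\n",
              attr(x, "chosen_beta"), attr(x, "r2_target")))
  invisible(x)
}

#' Signed topological overlap matrix
#'
#' \eqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})} with
#' \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1.  Two proteins get
#' high overlap when they are strongly connected to each other and share
#' their network neighborhood.
#'
#' @param adj adjacency matrix in [0, 1].
#' @return TOM similarity matrix in [0, 1]; dissimilarity is \code{1 - TOM}.
#' @export
compute_tom <- function(adj) {
  check_matrix(adj, "adjacency matrix")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # diag(a)=0 already excludes u = i and u = j
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Average-linkage dendrogram on topological overlap dissimilarity
#'
#' @param tom TOM similarity matrix.
#' @return \code{\link[stats]{hclust}} tree built on \code{1 - TOM}.
#' @export
build_dendrogram <- function(tom) {
  check_matrix(tom, "TOM matrix")
  d <- stats::as.dist(1 - tom)
  stats::hclust(d, method = "average")
}
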