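# Robust correlation for coexpression networks.
#
# Biweight midcorrelation (bicor): deviations from the median are
# down-weighted by Tukey's biweight with the usual 9*mad bandwidth, so a
# single outlying sample cannot dominate a protein-protein correlation the
# way it can with Pearson.  A vector whose median absolute deviation is zero
# gets Pearson treatment (mean-centered, unit weights) for that vector only.

bicor_terms <- function(x) {
  m <- stats::median(x)
  s <- stats::mad(x, constant = 1)
  if (s == 0) {
    d <- x - mean(x)        # Pearson fallback for this vector
  } else {
    u <- (x - m) / (9 * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    d <- (x - m) * w
  }
  d
}

#' Biweight midcorrelation of two sample vectors
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return correlation in [-1, 1]; 0 (with a warning) when either vector has
#'   zero variance after weighting.
#' @export
bicor_pair <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("at least 3 samples are required")
  dx <- bicor_terms(x)
  dy <- bicor_terms(y)
  nx <- sqrt(sum(dx^2))
  ny <- sqrt(sum(dy^2))
  if (nx == 0 || ny == 0) {
    warning("zero variance after biweight weighting; returning 0")
    return(0)
  }
  max(-1, min(1, sum(dx * dy) / (nx * ny)))
}

#' All pairwise protein correlations
#'
#' Computes the proteins x proteins correlation matrix of an abundance
#' matrix, using the biweight midcorrelation by default (Pearson available
#' for comparison).  The result is symmetric with unit diagonal.
#'
#' @param x abundance matrix, proteins in rows, samples in columns
#'   (at least 3 samples).
#' @param method "bicor" (default) or "pearson".
#' @return correlation matrix with protein ids as dimnames.
#' @export
correlation_matrix <- function(x, method = c("bicor", "pearson")) {
  check_matrix(x, "abundance matrix")
  method <- match.arg(method)
  if (ncol(x) < 3L) stop_input("at least 3 samples are required")
  if (method == "pearson") {
    d <- x - rowMeans(x)
  } else {
    d <- t(apply(x, 1L, bicor_terms))
  }
  nrm <- sqrt(rowSums(d^2))
  degenerate <- nrm == 0
  if (any(degenerate)) {
    warning(sprintf("%d constant protein(s); their correlations are set to 0",
                    sum(degenerate)))
    nrm[degenerate] <- 1  # rows are all zero, correlations come out 0
  }
  d <- d / nrm
  r <- tcrossprod(d)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(x), rownames(x))
  attr(r, "method") <- method
  r
}
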