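# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Input-contract failure: stop() with a consistent class so callers/tests can
# distinguish contract violations from programming errors.
stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("wpcna_input_error", "error")))
}

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input("%s must be a numeric matrix", what)
  invisible(x)
}

# Deterministic per-stage seed derived from one global seed and a stream name,
# so adding a downstream stage never perturbs earlier draws.  Plain polynomial
# string hash folded into the 32-bit signed range.
stream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

# Relabel integer cluster labels so that label 1 is the largest cluster,
# 2 the next, ...; label 0 (unassigned) is preserved.  Ties broken by the
# original label order for determinism.
relabel_by_size <- function(labels) {
  assigned <- labels != 0L
  if (!any(assigned)) return(labels)
  tab <- table(labels[assigned])
  ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
  map <- stats::setNames(seq_along(ord), ord)
  out <- labels
  out[assigned] <- as.integer(map[as.character(labels[assigned])])
  out
}

# Adjusted Rand index between two label vectors (Hubert & Arabie).
# Small and self-contained; used by tests, the acceptance script and examples.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used throughout the package to score recovery of planted structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in (-1, 1]; 1 means identical partitions, 0 is the
#'   expected agreement of random partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
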