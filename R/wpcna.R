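# The central estimator: fit a signed weighted coexpression network to a
# protein abundance matrix and detect modules.

#' Fit a weighted protein coexpression network
#'
#' Runs the full network pipeline on a log2 abundance matrix: optional
#' top-variance feature selection, pairwise correlation (biweight
#' midcorrelation by default), soft-threshold selection by the scale-free
#' topology criterion, signed adjacency, topological overlap, average-linkage
#' clustering of 1 - TOM, dynamic branch cutting with a minimum module size,
#' and merging of modules with near-identical eigenproteins.  Module
#' eigenproteins and kME module membership are computed on the fitted
#' modules.
#'
#' @param x numeric matrix of log2 abundances, proteins in rows, samples in
#'   columns, with protein ids as rownames.
#' @param top_fraction optional fraction in (0, 1]; when given, only the top
#'   \code{top_fraction} most variable proteins enter the network (the
#'   conventional setting is 0.25).
#' @param cor_method "bicor" (robust, default) or "pearson".
#' @param beta soft-threshold power; \code{NULL} (default) selects it
#'   automatically from \code{betas} by the scale-free fit criterion.
#' @param betas candidate powers for automatic selection.
#' @param r2_target signed scale-free fit index a power must reach.
#' @param min_size minimum module size (default 50).
#' @param cut_height static cut height on the 1 - TOM scale; default the
#'   0.99 quantile of the merge heights.
#' @param split_sensitivity merge-height gap required to split a branch.
#' @param merge_height eigenprotein dissimilarity below which modules merge.
#' @param keep_tom keep the TOM matrix in the returned object (memory heavy
#'   for large networks).
#' @return An object of class \code{wpcna}: a list with elements
#'   \code{modules} (named label vector, 0 = unassigned), \code{sizes},
#'   \code{eigenproteins}, \code{kme}, \code{dendrogram}, \code{beta},
#'   \code{scan} (when the power was selected automatically),
#'   \code{cor_method}, \code{data} (the network input matrix) and
#'   \code{call}.
#' @seealso \code{\link{cut_modules}}, \code{\link{module_eigenproteins}},
#'   \code{\link{stratify_module_signature}}
#' @examples
#' sim <- simulate_proteome(sim_config(n_proteins = 120, n_samples = 30,
#'                                     module_sizes = c(60, 40), seed = 1))
#' fit <- wpcna(sim$abundance, beta = 6, min_size = 20)
#' fit
#' @export
wpcna <- function(x, top_fraction = NULL, cor_method = c("bicor", "pearson"),
                  beta = NULL, betas = 1:20, r2_target = 0.8,
                  min_size = 50, cut_height = NULL, split_sensitivity = 0,
                  merge_height = 0.15, keep_tom = FALSE) {
  cl <- match.call()
  check_matrix(x, "abundance matrix")
  cor_method <- match.arg(cor_method)
  if (!is.null(top_fraction)) x <- select_top_variable(x, top_fraction)
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))

  cc <- correlation_matrix(x, method = cor_method)
  scan <- NULL
  if (is.null(beta)) {
    scan <- pick_soft_threshold(cc, betas = betas, r2_target = r2_target)
    beta <- attr(scan, "chosen_beta")
  }
  adj <- signed_adjacency(cc, beta)
  tom <- compute_tom(adj)
  tree <- build_dendrogram(tom)
  labels <- cut_modules(tree, min_size = min_size, cut_height = cut_height,
                        split_sensitivity = split_sensitivity)
  if (any(labels != 0L))
    labels <- merge_modules(labels, x, merge_height = merge_height)
  names(labels) <- rownames(x)

  me <- if (any(labels != 0L)) module_eigenproteins(x, labels) else NULL
  km <- if (!is.null(me)) kme(x, me) else NULL
  sizes <- if (any(labels != 0L)) table(factor(labels[labels != 0L])) else table(integer())

  structure(list(
    modules = labels,
    sizes = stats::setNames(as.integer(sizes), paste0("M", names(sizes))),
    n_unassigned = sum(labels == 0L),
    eigenproteins = me,
    kme = km,
    dendrogram = tree,
    beta = beta,
    scan = scan,
    cor_method = cor_method,
    data = x,
    tom = if (keep_tom) tom else NULL,
    call = cl
  ), class = "wpcna")
}

#' @export
print.wpcna <- function(x, ...) {
  cat("Weighted protein coexpression network\n")
  cat(sprintf("  proteins: %d, samples: %d\n", nrow(x$data), ncol(x$data)))
  cat(sprintf("  correlation: %s, soft-threshold beta: %d%s\n",
              x$cor_method, x$beta,
              if (!is.null(x$scan)) " (auto-selected)" else ""))
  cat(sprintf("  modules: %d (%s), unassigned (M0): %d\n",
              length(x$sizes),
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
              x$n_unassigned))
  invisible(x)
}

#' @export
summary.wpcna <- function(object, ...) {
  expl <- attr(object$eigenproteins, "explained")
  hubs <- vapply(seq_along(object$sizes), function(m) {
    hub_proteins(object$kme, object$modules, m, n = 1L)
  }, character(1L))
  out <- data.frame(
    module = names(object$sizes),
    size = unname(object$sizes),
    explained_variance = if (is.null(expl)) NA_real_ else unname(expl),
    top_hub = hubs,
    row.names = NULL
  )
  structure(list(table = out, beta = object$beta,
                 n_unassigned = object$n_unassigned,
                 cor_method = object$cor_method),
            class = "summary.wpcna")
}

#' @export
print.summary.wpcna <- function(x, ...) {
  cat(sprintf("Coexpression modules (%s, beta = %d)\n", x$cor_method, x$beta))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("unassigned (M0): %d\n", x$n_unassigned))
  invisible(x)
}

#' Plot a fitted coexpression network
#'
#' Draws the TOM dendrogram with a module color strip underneath, plus the
#' soft-threshold scan when the power was selected automatically.
#'
#' @param x a \code{wpcna} fit.
#' @param which "dendrogram", "scan" or "both".
#' @param ... ignored.
#' @export
plot.wpcna <- function(x, which = c("dendrogram", "scan", "both"), ...) {
  which <- match.arg(which)
  draw_dend <- which %in% c("dendrogram", "both")
  draw_scan <- which %in% c("scan", "both") && !is.null(x$scan)
  if (draw_dend && draw_scan) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (draw_dend) {
    old2 <- graphics::par(mar = c(5, 4, 4, 2))
    graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                   main = "TOM dendrogram", xlab = "", sub = "",
                   ylab = "1 - TOM")
    cols <- c("grey", grDevices::hcl.colors(max(1L, length(x$sizes)), "Dark 3"))
    ord <- x$dendrogram$order
    graphics::points(seq_along(ord), rep(graphics::par("usr")[3], length(ord)),
                     pch = 15, col = cols[x$modules[ord] + 1L], xpd = NA, cex = 0.6)
    graphics::par(old2)
  }
  if (draw_scan) {
    graphics::plot(x$scan$beta, x$scan$r_squared, type = "b", pch = 19,
                   xlab = "soft-threshold power", ylab = "signed scale-free R^2",
                   main = "Soft-threshold scan")
    graphics::abline(h = attr(x$scan, "r2_target"), lty = 2)
    graphics::abline(v = x$beta, lty = 3)
  }
  invisible(x)
}

#' Assign new protein profiles to fitted modules
#'
#' Computes kME of each new profile against the fitted eigenproteins and
#' assigns the module with the largest kME, or 0 when no kME reaches
#' \code{kme_min}.
#'
#' @param object a \code{wpcna} fit.
#' @param newdata matrix of profiles over the same samples (columns) as the
#'   fitted data; defaults to the training matrix.
#' @param kme_min minimum kME for assignment.
#' @param ... ignored.
#' @return named integer vector of module labels.
#' @export
predict.wpcna <- function(object, newdata = NULL, kme_min = 0.5, ...) {
  if (is.null(object$eigenproteins)) stop_input("fit has no modules")
  if (is.null(newdata)) newdata <- object$data
  check_matrix(newdata, "newdata")
  if (ncol(newdata) != ncol(object$data))
    stop_input("newdata must have the fit's %d samples", ncol(object$data))
  k <- kme(newdata, object$eigenproteins)
  best <- max.col(k, ties.method = "first")
  out <- ifelse(k[cbind(seq_len(nrow(k)), best)] >= kme_min, best, 0L)
  stats::setNames(as.integer(out), rownames(newdata))
}
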