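# End-to-end orchestration: abundance + clinical in, network, modules,
# signature stratification, survival, differential expression and
# enrichment out.

#' Run the full coexpression/survival pipeline
#'
#' Executes the complete analysis in the conventional order: complete-case
#' filtering, optional ratio normalization, top-variance selection, network
#' fit (correlation, soft threshold, TOM, dynamic cut, merging),
#' eigenproteins/kME, module-trait association, hub-signature consensus
#' stratification of samples, survival comparison of the strata, Wilcoxon
#' differential expression between strata, and optional gene-set
#' over-representation per module.
#'
#' @param abundance proteins x samples matrix (log2 unless
#'   \code{normalize = TRUE}), or a path to an abundance TSV.
#' @param clinical data.frame with \code{sample_id} and optional
#'   \code{group}, \code{batch}, \code{os_months}, \code{os_event}, or a
#'   path to a clinical TSV; may be \code{NULL} (network-only run).
#' @param normalize when TRUE, \code{abundance} holds linear ratios to the
#'   pool and \code{\link{normalize_abundance}} is applied first (using the
#'   clinical \code{batch} column when present).
#' @param top_fraction fraction of most-variable proteins entering the
#'   network (default 0.25).
#' @param beta soft-threshold power, \code{NULL} for automatic selection.
#' @param min_size minimum module size (default 50).
#' @param signature_module module whose hub signature stratifies the
#'   samples; \code{NULL} picks the module whose stratification gives the
#'   smallest log-rank p (requires survival columns).
#' @param n_top signature size (default 50).
#' @param k number of strata (default 2, "high"/"low").
#' @param iterations consensus iterations (default 1000).
#' @param gene_sets optional named list of protein sets (e.g.
#'   \code{\link{read_gmt}}) for per-module over-representation.
#' @param seed global seed; per-stage streams are derived from it.
#' @param out_dir optional directory; when given, all artifacts
#'   (modules.tsv, eigenproteins.tsv, kme.tsv, soft_threshold_scan.tsv,
#'   module_trait.tsv, signature_labels.tsv, consensus_matrix.tsv,
#'   de_table.tsv, enrichment.tsv, report.json) are written there.
#' @param ... further arguments passed to \code{\link{wpcna}}.
#' @return object of class \code{wpcna_pipeline}: list with the
#'   \code{network} fit, \code{trait_association}, \code{stratification},
#'   \code{survival} (log-rank + KM per stratum + Cox on the stratum
#'   indicator), \code{de}, \code{enrichment} and \code{report}.
#' @export
run_pipeline <- function(abundance, clinical = NULL, normalize = FALSE,
                         top_fraction = 0.25, beta = NULL, min_size = 50,
                         signature_module = NULL, n_top = 50, k = 2,
                         iterations = 1000L, gene_sets = NULL, seed = 1L,
                         out_dir = NULL, ...) {
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  check_matrix(abundance, "abundance matrix")
  if (is.character(clinical)) clinical <- read_clinical(clinical, colnames(abundance))
  if (!is.null(clinical)) {
    missing <- setdiff(colnames(abundance), clinical$sample_id)
    if (length(missing))
      stop_input("pipeline stage 'clinical': samples without annotation: %s",
                 paste(utils::head(missing, 5L), collapse = ", "))
    clinical <- clinical[match(colnames(abundance), clinical$sample_id), , drop = FALSE]
  }

  x <- filter_complete(abundance)
  if (normalize) {
    batch <- if (!is.null(clinical) && "batch" %in% names(clinical))
      clinical$batch else NULL
    x <- normalize_abundance(x, batch)
  }
  fit <- wpcna(x, top_fraction = top_fraction, beta = beta,
               min_size = min_size, ...)

  trait <- NULL
  if (!is.null(clinical) && "group" %in% names(clinical) &&
      !is.null(fit$eigenproteins)) {
    grp <- clinical$group
    if (length(unique(grp)) >= 2L && all(table(grp) >= 2L))
      trait <- me_trait_association(fit$eigenproteins, grp)
  }

  has_surv <- !is.null(clinical) &&
    all(c("os_months", "os_event") %in% names(clinical))
  strat <- surv_res <- de <- NULL
  sig_module <- signature_module
  if (!is.null(fit$eigenproteins)) {
    candidates <- if (is.null(sig_module)) seq_along(fit$sizes) else sig_module
    results <- lapply(candidates, function(m) {
      s <- stratify_module_signature(fit$data, fit$kme, fit$modules, m,
                                     n_top = n_top, k = k,
                                     iterations = iterations, seed = seed)
      p <- if (has_surv && length(unique(s$labels)) >= 2L)
        logrank_test(clinical$os_months, clinical$os_event, s$labels)$p.value
      else NA_real_
      list(module = m, strat = s, logrank_p = p)
    })
    pick <- if (length(results) == 1L) 1L else {
      ps <- vapply(results, function(r) r$logrank_p, numeric(1L))
      if (all(is.na(ps))) 1L else which.min(ps)
    }
    sig_module <- results[[pick]]$module
    strat <- results[[pick]]$strat
    strat$module <- sig_module
    strat$logrank_p_by_module <- stats::setNames(
      vapply(results, function(r) r$logrank_p, numeric(1L)),
      paste0("M", candidates))

    if (has_surv && length(unique(strat$labels)) >= 2L) {
      lr <- logrank_test(clinical$os_months, clinical$os_event, strat$labels)
      km_by <- lapply(split(seq_along(strat$labels), strat$labels), function(idx) {
        km_estimate(clinical$os_months[idx], clinical$os_event[idx])
      })
      cox <- cox_fit(clinical$os_months, clinical$os_event,
                     data.frame(signature = factor(strat$labels,
                                                   levels = sort(unique(strat$labels)))))
      surv_res <- list(logrank = lr, km = km_by, cox = cox)
    }
    lv <- sort(unique(strat$labels))
    if ("high" %in% lv) lv <- c("high", setdiff(lv, "high"))
    if (sum(strat$labels == lv[1L]) >= 2L && sum(strat$labels != lv[1L]) >= 2L)
      de <- differential_expression(fit$data, which(strat$labels == lv[1L]),
                                    which(strat$labels != lv[1L]))
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && !is.null(fit$eigenproteins)) {
    universe <- rownames(abundance)
    enrichment <- lapply(stats::setNames(seq_along(fit$sizes),
                                         names(fit$sizes)), function(m) {
      enrich_hypergeometric(names(fit$modules)[fit$modules == m],
                            universe, gene_sets)
    })
  }

  report <- list(
    n_proteins_input = nrow(abundance),
    n_samples = ncol(abundance),
    n_proteins_network = nrow(fit$data),
    beta = fit$beta,
    module_sizes = as.list(fit$sizes),
    n_unassigned = fit$n_unassigned,
    signature_module = if (!is.null(strat)) paste0("M", sig_module) else NULL,
    logrank_p = if (!is.null(surv_res)) surv_res$logrank$p.value else NULL,
    seed = seed,
    parameters = list(top_fraction = top_fraction, min_size = min_size,
                      n_top = n_top, k = k, iterations = iterations)
  )

  out <- structure(list(network = fit, trait_association = trait,
                        stratification = strat, survival = surv_res,
                        de = de, enrichment = enrichment, clinical = clinical,
                        report = report),
                   class = "wpcna_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.wpcna_pipeline <- function(x, ...) {
  cat("Coexpression pipeline run\n")
  print(x$network)
  if (!is.null(x$survival))
    cat(sprintf("  signature %s stratification: log-rank p = %.4g\n",
                x$report$signature_module, x$survival$logrank$p.value))
  invisible(x)
}

# Write every artifact of a pipeline run into a directory.
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- res$network
  write_tsv(data.frame(protein_id = names(fit$modules),
                       module_label = paste0("M", fit$modules)),
            file.path(out_dir, "modules.tsv"))
  if (!is.null(fit$scan))
    write_tsv(as.data.frame(fit$scan), file.path(out_dir, "soft_threshold_scan.tsv"))
  if (!is.null(fit$eigenproteins)) {
    write_tsv(data.frame(module = rownames(fit$eigenproteins),
                         fit$eigenproteins, check.names = FALSE),
              file.path(out_dir, "eigenproteins.tsv"))
    write_tsv(data.frame(protein_id = rownames(fit$kme), fit$kme,
                         check.names = FALSE),
              file.path(out_dir, "kme.tsv"))
  }
  if (!is.null(res$trait_association))
    write_tsv(res$trait_association, file.path(out_dir, "module_trait.tsv"))
  if (!is.null(res$stratification)) {
    write_tsv(data.frame(sample_id = names(res$stratification$labels),
                         label = res$stratification$labels),
              file.path(out_dir, "signature_labels.tsv"))
    writeLines(res$stratification$signature,
               file.path(out_dir, "signature_proteins.txt"))
    cons <- res$stratification$consensus_result$consensus
    write_tsv(data.frame(sample_id = rownames(cons), cons, check.names = FALSE),
              file.path(out_dir, "consensus_matrix.tsv"))
  }
  if (!is.null(res$de)) write_tsv(res$de, file.path(out_dir, "de_table.tsv"))
  if (!is.null(res$enrichment)) {
    enr <- do.call(rbind, lapply(names(res$enrichment), function(m) {
      cbind(module = m, res$enrichment[[m]])
    }))
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
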