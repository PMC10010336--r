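# Synthetic proteome generator with planted coexpression modules, sample
# groups, TMT-style batch offsets and module-linked survival.  Used to
# validate every pipeline stage against known ground truth.

#' Simulation configuration
#'
#' Describes a synthetic proteome: planted modules (factor structure with a
#' controllable correlation-to-factor), sample groups with per-module factor
#' mean shifts, batch offsets, and survival linked to one module's factor.
#' The defaults emulate the scale of a TMT pancreatic-tissue cohort:
#' a complete log2-ratio matrix of 7,699 proteins by 60 samples with five
#' planted modules of sizes 635/293/279/274/188, three tissue-like sample
#' groups, five TMT batches, and survival driven by module 2.
#'
#' @param n_proteins total proteins (rows).
#' @param n_samples total samples (columns).
#' @param module_sizes planted module sizes; proteins beyond their sum are
#'   background noise.
#' @param background_count proteins in no module; defaults to
#'   \code{n_proteins - sum(module_sizes)} and must match it.
#' @param kme_target expected correlation of a member protein with its
#'   module factor, strictly in (0, 1); scalar or one value per module.
#' @param group_shifts numeric matrix (groups x modules) of factor mean
#'   shifts on the log2 scale, rownames = group labels; \code{NULL} means a
#'   single unshifted group.
#' @param n_batches number of TMT batches; samples are interleaved across
#'   batches so batch is not confounded with group.
#' @param batch_sd standard deviation of the per-protein, per-batch constant
#'   offsets (log2 units).
#' @param noise_sd standard deviation of background-protein noise (log2
#'   units).
#' @param survival list with \code{linked_module} (module index),
#'   \code{log_hazard_per_unit}, \code{baseline_scale} (months) and
#'   \code{censor_rate} (fraction in [0, 1)).
#' @param seed integer; one global seed feeds named substreams (factors /
#'   noise / batch / survival) so adding a stage never perturbs earlier
#'   draws.
#' @return validated object of class \code{sim_config}.
#' @export
sim_config <- function(n_proteins = 7699L, n_samples = 60L,
                       module_sizes = c(635L, 293L, 279L, 274L, 188L),
                       background_count = NULL,
                       kme_target = 0.8,
                       group_shifts = default_group_shifts(length(module_sizes)),
                       n_batches = 5L, batch_sd = 0.3, noise_sd = 1,
                       survival = list(linked_module = 2L,
                                       log_hazard_per_unit = 1.0,
                                       baseline_scale = 20,
                                       censor_rate = 0.2),
                       seed = 1L) {
  if (is.null(background_count))
    background_count <- n_proteins - sum(module_sizes)
  if (sum(module_sizes) + background_count != n_proteins)
    stop_input("module_sizes (+ background_count) must sum to n_proteins: %d + %d != %d",
               sum(module_sizes), background_count, n_proteins)
  if (background_count < 0) stop_input("background_count is negative")
  if (any(module_sizes < 1)) stop_input("every module_size must be >= 1")
  kme_target <- rep_len(kme_target, length(module_sizes))
  if (any(kme_target <= 0 | kme_target >= 1))
    stop_input("kme_target must be strictly between 0 and 1")
  if (!is.null(group_shifts)) {
    group_shifts <- as.matrix(group_shifts)
    if (ncol(group_shifts) != length(module_sizes))
      stop_input("group_shifts needs one column per module (%d != %d)",
                 ncol(group_shifts), length(module_sizes))
    if (is.null(rownames(group_shifts)))
      rownames(group_shifts) <- paste0("G", seq_len(nrow(group_shifts)))
  }
  if (n_batches < 1) stop_input("n_batches must be >= 1")
  if (batch_sd < 0 || noise_sd < 0) stop_input("standard deviations must be >= 0")
  if (!is.null(survival)) {
    needed <- c("linked_module", "log_hazard_per_unit", "baseline_scale", "censor_rate")
    missing <- setdiff(needed, names(survival))
    if (length(missing)) stop_input("survival config lacks: %s", paste(missing, collapse = ", "))
    if (survival$linked_module < 1 || survival$linked_module > length(module_sizes))
      stop_input("survival$linked_module must index a planted module")
    if (survival$censor_rate < 0 || survival$censor_rate >= 1)
      stop_input("survival$censor_rate must be in [0, 1)")
    if (survival$baseline_scale <= 0) stop_input("survival$baseline_scale must be positive")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples = as.integer(n_samples),
                 module_sizes = as.integer(module_sizes),
                 background_count = as.integer(background_count),
                 kme_target = kme_target, group_shifts = group_shifts,
                 n_batches = as.integer(n_batches), batch_sd = batch_sd,
                 noise_sd = noise_sd, survival = survival,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Three tissue-like groups: module 1 high in the normal-like group, modules
# 2 and 4 tumor-specific, modules 3 and 5 shared by tumor and fibrous.
# Magnitudes stay near 1 log2 unit and no two modules share an identical
# shift pattern, so the planted factors remain distinguishable.
default_group_shifts <- function(n_modules) {
  base <- rbind(tumor       = c(-1.2,  1.2,  0.8,  1.2,  0.8),
                fibrous     = c(-0.8,  0.2,  1.2, -0.2,  0.6),
                normal_like = c( 1.2, -1.0, -0.8, -1.0, -0.8))
  if (n_modules <= 5L) return(base[, seq_len(n_modules), drop = FALSE])
  cbind(base, matrix(0, 3L, n_modules - 5L))
}

#' Generate a synthetic proteome dataset
#'
#' Protein i of module m gets abundance \eqn{x_{is} = f_m(s) + \epsilon_{is}}
#' with unit loading and noise standard deviation
#' \eqn{\sqrt{1/kme^2 - 1}}, so the expected Pearson correlation of the
#' profile with the factor equals \code{kme_target}.  Background proteins
#' are pure noise.  Group mean shifts are added to the factors, and
#' per-protein, per-batch offsets with standard deviation \code{batch_sd}
#' (constant across the samples of a batch) emulate TMT set effects.
#' Deterministic for a fixed seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{abundance} (proteins x samples log2 matrix),
#'   \code{clinical} (data.frame: sample_id, group, batch, and, when a
#'   survival block is configured, os_months and os_event) and \code{truth}
#'   (list: module_of_protein, factor_matrix, group_of_sample,
#'   survival_link).
#' @export
simulate_proteome <- function(config) {
  if (!inherits(config, "sim_config")) stop_input("config must come from sim_config()")
  n <- config$n_samples; p <- config$n_proteins
  m <- length(config$module_sizes)
  protein_ids <- sprintf("P%05d", seq_len(p))
  sample_ids <- sprintf("S%03d", seq_len(n))
  module_of <- rep.int(c(seq_len(m), 0L), c(config$module_sizes, config$background_count))

  if (is.null(config$group_shifts)) {
    group_of <- rep("all", n)
    shifts <- matrix(0, 1L, m, dimnames = list("all", NULL))
  } else {
    shifts <- config$group_shifts
    group_of <- rownames(shifts)[rep_len(seq_len(nrow(shifts)), n)]
    group_of <- sort(group_of)               # contiguous, near-equal groups
  }
  batch_of <- rep_len(seq_len(config$n_batches), n)

  set.seed(stream_seed(config$seed, "factors"))
  factors <- matrix(stats::rnorm(m * n), m, n)
  for (g in rownames(shifts))
    factors[, group_of == g] <- factors[, group_of == g] + shifts[g, ]

  set.seed(stream_seed(config$seed, "noise"))
  x <- matrix(0, p, n, dimnames = list(protein_ids, sample_ids))
  member_sd <- sqrt(1 / config$kme_target^2 - 1)
  for (i in seq_len(p)) {
    mod <- module_of[i]
    x[i, ] <- if (mod == 0L) stats::rnorm(n, sd = config$noise_sd)
              else factors[mod, ] + stats::rnorm(n, sd = member_sd[mod])
  }

  if (config$batch_sd > 0 && config$n_batches > 1L) {
    set.seed(stream_seed(config$seed, "batch"))
    offsets <- matrix(stats::rnorm(p * config$n_batches, sd = config$batch_sd),
                      p, config$n_batches)
    x <- x + offsets[, batch_of]
  }

  truth <- list(module_of_protein = stats::setNames(module_of, protein_ids),
                factor_matrix = factors,
                group_of_sample = stats::setNames(group_of, sample_ids),
                survival_link = if (is.null(config$survival)) NULL else
                  c(module = config$survival$linked_module,
                    log_hazard_per_unit = config$survival$log_hazard_per_unit))
  clinical <- data.frame(sample_id = sample_ids, group = group_of,
                         batch = paste0("B", batch_of),
                         stringsAsFactors = FALSE)
  if (!is.null(config$survival)) {
    surv <- simulate_survival(truth, config)
    clinical$os_months <- surv$os_months
    clinical$os_event <- surv$os_event
  }
  list(abundance = x, clinical = clinical, truth = truth)
}

# Uniform-censoring upper bound c such that the expected censored fraction
# hits the target: P(C < T | hazard h) = (1 - exp(-h c)) / (h c) for
# C ~ U(0, c), T ~ Exp(h), averaged over samples.  Solved to 1e-3.
solve_censor_bound <- function(hazard, censor_rate) {
  expected <- function(cc) {
    z <- hazard * cc
    mean(ifelse(z < 1e-12, 1, (1 - exp(-z)) / z)) - censor_rate
  }
  upper <- 1 / min(hazard)
  while (expected(upper) > 0) upper <- upper * 2
  stats::uniroot(expected, c(1e-9, upper), tol = 1e-3)$root
}

#' Simulate module-linked survival outcomes
#'
#' Exponential survival with hazard
#' \eqn{h(s) = \exp(\beta f(s)) / scale} where \eqn{f} is the linked
#' module's factor, with independent uniform censoring calibrated
#' numerically (tolerance 1e-3) to the requested censored fraction.
#'
#' @param truth truth list from \code{\link{simulate_proteome}}.
#' @param config the same \code{\link{sim_config}}.
#' @return data.frame with \code{os_months} and \code{os_event} per sample.
#' @export
simulate_survival <- function(truth, config) {
  if (is.null(config$survival)) stop_input("config has no survival block")
  link <- config$survival$linked_module
  if (link > nrow(truth$factor_matrix)) stop_input("linked module %d not in truth", link)
  f <- truth$factor_matrix[link, ]
  hazard <- exp(config$survival$log_hazard_per_unit * f) / config$survival$baseline_scale
  set.seed(stream_seed(config$seed, "survival"))
  t_death <- stats::rexp(length(f), rate = hazard)
  if (config$survival$censor_rate == 0) {
    return(data.frame(os_months = t_death, os_event = 1L))
  }
  cc <- solve_censor_bound(hazard, config$survival$censor_rate)
  t_censor <- stats::runif(length(f), 0, cc)
  data.frame(os_months = pmin(t_death, t_censor),
             os_event = as.integer(t_death <= t_censor))
}
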