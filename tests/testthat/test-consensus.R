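# Subsampled k-means consensus clustering and signature stratification.

two_blobs <- function(n_per = 20, p = 10, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p, 0), n_per),
             matrix(rnorm(n_per * p, sep), n_per))
  rownames(x) <- paste0("s", seq_len(2 * n_per))
  x
}

test_that("fully-sampled separable data gives a 0/1 consensus matrix", {
  x <- two_blobs(10, p = 4)
  res <- consensus_matrix(x, k = 2, iterations = 20,
                          item_fraction = 1, feature_fraction = 1, seed = 2)
  truth <- rep(1:2, each = 10)
  same <- outer(truth, truth, "==")
  expect_equal(res$consensus[same & upper.tri(same)], rep(1, sum(same & upper.tri(same))))
  expect_equal(res$consensus[!same], rep(0, sum(!same)))
})

test_that("consensus entries are valid, symmetric and deterministic", {
  x <- two_blobs(12, sep = 3, seed = 3)
  res <- consensus_matrix(x, k = 2, iterations = 40, seed = 5)
  res2 <- consensus_matrix(x, k = 2, iterations = 40, seed = 5)
  expect_identical(res$consensus, res2$consensus)
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  expect_equal(res$consensus, t(res$consensus))
  # co-clustered counts are integers
  counts <- res$consensus * res$co_sampled_counts
  expect_lt(max(abs(counts - round(counts))), 1e-9)
  expect_input_error(consensus_matrix(x, k = 2, iterations = 0))
  expect_input_error(consensus_matrix(x, k = 30, iterations = 10))
})

test_that("well-separated blobs give sharp consensus and an exact cut", {
  x <- two_blobs(20, sep = 6, seed = 4)
  res <- consensus_matrix(x, k = 2, iterations = 250, seed = 6)
  truth <- rep(1:2, each = 20)
  same <- outer(truth, truth, "==") & upper.tri(res$consensus)
  diff <- outer(truth, truth, "!=") & upper.tri(res$consensus)
  expect_gte(mean(res$consensus[same]), 0.9)
  expect_lte(mean(res$consensus[diff]), 0.1)
  cl <- cut_consensus(res, 2)
  expect_equal(adjusted_rand_index(cl, truth), 1)
})

test_that("cut_consensus recovers block structure and orders labels by size", {
  cons <- matrix(0, 7, 7)
  cons[1:4, 1:4] <- 1; cons[5:7, 5:7] <- 1
  rownames(cons) <- colnames(cons) <- paste0("s", 1:7)
  cl <- cut_consensus(cons, 2)
  expect_equal(unname(cl), c(1, 1, 1, 1, 2, 2, 2))
  expect_equal(length(unique(cut_consensus(cons, 7))), 7L)
  expect_input_error(cut_consensus(cons, 8))
})

test_that("consensus labelling is invariant to sample permutation", {
  x <- two_blobs(15, sep = 6, seed = 7)
  res1 <- cut_consensus(consensus_matrix(x, 2, iterations = 100, seed = 8), 2)
  set.seed(1); perm <- sample(nrow(x))
  res2 <- cut_consensus(consensus_matrix(x[perm, ], 2, iterations = 100, seed = 8), 2)
  expect_equal(adjusted_rand_index(res2, res1[perm]), 1)
})

test_that("signature stratification labels high and low by mean abundance", {
  set.seed(9)
  n <- 30; p_sig <- 60
  shift <- rep(c(2, -2), each = n / 2)
  x <- rbind(t(replicate(p_sig, shift + rnorm(n, sd = 0.5))),
             matrix(rnorm(40 * n), 40, n))
  rownames(x) <- paste0("p", seq_len(nrow(x)))
  colnames(x) <- paste0("s", seq_len(n))
  lab <- rep(c(1L, 0L), c(p_sig, 40))
  me <- module_eigenproteins(x, lab)
  k <- kme(x, me)
  strat <- stratify_module_signature(x, k, lab, 1, n_top = 50, k = 2,
                                     iterations = 100, seed = 10)
  expect_equal(unname(strat$labels), rep(c("high", "low"), each = n / 2))
  expect_equal(length(strat$signature), 50L)
  expect_false(strat$unstable)
})

test_that("degenerate identical samples are flagged unstable", {
  x <- matrix(rep(rnorm(60), 12), 60, 12,
              dimnames = list(paste0("p", 1:60), paste0("s", 1:12)))
  lab <- rep(1L, 60)
  me <- suppressWarnings(module_eigenproteins(x, lab))
  k <- matrix(1, 60, 1, dimnames = list(rownames(x), "M1"))
  expect_warning(
    strat <- stratify_module_signature(x, k, lab, 1, n_top = 20, k = 2,
                                       iterations = 30, seed = 11),
    "indistinguishable")
  expect_true(strat$unstable)
  expect_equal(length(strat$labels), 12L)
})

test_that("stratification recovers the sign of a planted factor", {
  cfg <- sim_config(n_proteins = 160, n_samples = 60, module_sizes = c(120),
                    background_count = 40, kme_target = 0.85,
                    group_shifts = matrix(c(1.5, -1.5), 2, 1,
                                          dimnames = list(c("up", "down"), NULL)),
                    n_batches = 1, batch_sd = 0, survival = NULL, seed = 12)
  sim <- simulate_proteome(cfg)
  lab <- unname(sim$truth$module_of_protein)
  me <- module_eigenproteins(sim$abundance, lab)
  k <- kme(sim$abundance, me)
  strat <- stratify_module_signature(sim$abundance, k, lab, 1, n_top = 50,
                                     k = 2, iterations = 150, seed = 13)
  agree <- mean((strat$labels == "high") ==
                  (sim$truth$group_of_sample == "up"))
  expect_gte(max(agree, 1 - agree), 0.9)
})

test_that("consensus CDF report covers the requested k range", {
  x <- two_blobs(10, sep = 4, seed = 14)
  rep_df <- consensus_cdf_report(x, ks = 2:4, iterations = 30, seed = 15)
  expect_equal(rep_df$k, 2:4)
  expect_true(all(rep_df$auc >= 0 & rep_df$auc <= 1))
})
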