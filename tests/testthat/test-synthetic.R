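# Synthetic proteome generator: bookkeeping, determinism, calibration and
# the survival model.

test_that("generated matrices honour the configured sizes and labels", {
  sim <- plain_sim(c(100, 80, 60), background = 60, n_samples = 30, seed = 2)
  expect_equal(dim(sim$abundance), c(300L, 30L))
  counts <- table(sim$truth$module_of_protein)
  expect_equal(as.integer(counts[c("1", "2", "3", "0")]), c(100L, 80L, 60L, 60L))
  expect_equal(length(sim$truth$module_of_protein), 300L)
  expect_false(anyNA(sim$abundance))
})

test_that("invalid configurations fail the input contract by name", {
  expect_input_error(sim_config(n_proteins = 100, module_sizes = c(60, 50),
                                background_count = 0))
  expect_input_error(sim_config(n_proteins = 10, module_sizes = c(10),
                                background_count = 0, kme_target = 1))
  expect_input_error(sim_config(n_proteins = 10, module_sizes = c(10),
                                background_count = 0,
                                survival = list(linked_module = 1,
                                                log_hazard_per_unit = 1,
                                                baseline_scale = 20,
                                                censor_rate = 1)))
  err <- tryCatch(sim_config(n_proteins = 100, module_sizes = c(60, 50),
                             background_count = 0),
                  error = conditionMessage)
  expect_match(err, "n_proteins")
})

test_that("a fixed seed reproduces bit-identical output", {
  cfg <- sim_config(n_proteins = 120, n_samples = 20, module_sizes = c(60, 40),
                    background_count = 20, n_batches = 2, batch_sd = 0.3,
                    seed = 9)
  a <- simulate_proteome(cfg)
  b <- simulate_proteome(cfg)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$clinical, b$clinical)
})

test_that("member-factor correlation is calibrated to kme_target", {
  sim <- plain_sim(c(100), n_samples = 60, kme_target = 0.8, seed = 3)
  f <- sim$truth$factor_matrix[1, ]
  cors <- abs(cor(t(sim$abundance[1:100, ]), f))
  expect_lt(abs(mean(cors) - 0.8), 0.05)
})

test_that("within-module correlation increases with kme_target", {
  mean_cor <- vapply(c(0.5, 0.7, 0.9), function(k) {
    sim <- plain_sim(c(80), n_samples = 50, kme_target = k, seed = 4)
    cc <- cor(t(sim$abundance))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_true(all(diff(mean_cor) > 0))
})

test_that("without batch or group structure per-protein means are near zero", {
  sim <- plain_sim(c(60), background = 140, n_samples = 80, seed = 5)
  bg <- sim$abundance[sim$truth$module_of_protein == 0, ]
  bound <- 3 * 1 / sqrt(80)          # noise_sd = 1
  frac_within <- mean(abs(rowMeans(bg)) <= bound)
  expect_gte(frac_within, 0.99)
})

test_that("batch offsets are constant within batch and removable by centering", {
  cfg <- sim_config(n_proteins = 60, n_samples = 24, module_sizes = c(30),
                    background_count = 30, group_shifts = NULL,
                    n_batches = 3, batch_sd = 1, survival = NULL, seed = 6)
  with_b <- simulate_proteome(cfg)
  cfg0 <- sim_config(n_proteins = 60, n_samples = 24, module_sizes = c(30),
                     background_count = 30, group_shifts = NULL,
                     n_batches = 3, batch_sd = 0, survival = NULL, seed = 6)
  no_b <- simulate_proteome(cfg0)
  diffm <- with_b$abundance - no_b$abundance
  batch <- with_b$clinical$batch
  for (b in unique(batch)) {
    sub <- diffm[, batch == b, drop = FALSE]
    expect_lt(max(apply(sub, 1, function(r) diff(range(r)))), 1e-12)
  }
})

test_that("survival generator recovers the planted log hazard ratio", {
  est <- vapply(1:20, function(s) {
    cfg <- sim_config(n_proteins = 2, n_samples = 200, module_sizes = c(1),
                      background_count = 1, group_shifts = NULL, n_batches = 1,
                      batch_sd = 0,
                      survival = list(linked_module = 1, log_hazard_per_unit = 1.0,
                                      baseline_scale = 20, censor_rate = 0.2),
                      seed = s)
    sim <- simulate_proteome(cfg)
    f <- sim$truth$factor_matrix[1, ]
    unname(coef(cox_fit(sim$clinical$os_months, sim$clinical$os_event,
                        data.frame(f = f)))[1])
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 0.15)
})

test_that("censoring is calibrated and zero censoring means all events", {
  cfg <- sim_config(n_proteins = 2, n_samples = 400, module_sizes = c(1),
                    background_count = 1, group_shifts = NULL, n_batches = 1,
                    batch_sd = 0,
                    survival = list(linked_module = 1, log_hazard_per_unit = 0.5,
                                    baseline_scale = 20, censor_rate = 0.3),
                    seed = 8)
  sim <- simulate_proteome(cfg)
  expect_lt(abs(mean(1 - sim$clinical$os_event) - 0.3), 0.08)

  cfg0 <- sim_config(n_proteins = 2, n_samples = 50, module_sizes = c(1),
                     background_count = 1, group_shifts = NULL, n_batches = 1,
                     batch_sd = 0,
                     survival = list(linked_module = 1, log_hazard_per_unit = 0.5,
                                     baseline_scale = 20, censor_rate = 0),
                     seed = 8)
  sim0 <- simulate_proteome(cfg0)
  expect_true(all(sim0$clinical$os_event == 1L))
})

test_that("a null hazard link yields uniform log-rank p over replicates", {
  ps <- vapply(1:40, function(s) {
    cfg <- sim_config(n_proteins = 2, n_samples = 60, module_sizes = c(1),
                      background_count = 1, group_shifts = NULL, n_batches = 1,
                      batch_sd = 0,
                      survival = list(linked_module = 1, log_hazard_per_unit = 0,
                                      baseline_scale = 20, censor_rate = 0.2),
                      seed = s)
    sim <- simulate_proteome(cfg)
    halves <- ifelse(sim$truth$factor_matrix[1, ] > 0, "hi", "lo")
    logrank_test(sim$clinical$os_months, sim$clinical$os_event, halves)$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
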