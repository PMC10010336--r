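# Eigenproteins, kME, hubs, trait association, sample clustering and
# module graphs.

test_that("eigenproteins summarize member profiles with the sign convention", {
  set.seed(1)
  v <- rnorm(20)
  x <- rbind(a = v, b = v, c = v)
  me <- module_eigenproteins(x, c(1, 1, 1))
  vstd <- (v - mean(v)) / sd(v)
  expect_equal(unname(me["M1", ]), vstd, tolerance = 1e-8)
  expect_equal(unname(attr(me, "explained")["M1"]), 1)

  # x and -x: orientation has non-negative mean member correlation
  x2 <- rbind(a = v, b = -v)
  me2 <- module_eigenproteins(x2, c(1, 1))
  expect_gte(mean(cor(t(x2), me2["M1", ])), 0)
  expect_equal(abs(cor(me2["M1", ], v)), 1, tolerance = 1e-8)
})

test_that("the eigenprotein recovers a planted factor", {
  sim <- plain_sim(c(100), n_samples = 40, kme_target = 0.9, seed = 5)
  me <- module_eigenproteins(sim$abundance[1:100, ], rep(1, 100))
  r2 <- cor(me["M1", ], sim$truth$factor_matrix[1, ])^2
  expect_gte(r2, 0.9)
})

test_that("the eigenprotein beats random directions at explaining variance", {
  sim <- plain_sim(c(60), n_samples = 30, kme_target = 0.8, seed = 6)
  sub <- sim$abundance[1:60, ]
  z <- t(scale(t(sub)))
  me <- module_eigenproteins(sub, rep(1, 60))
  explained <- function(dir) sum((z %*% dir)^2 / sum(dir^2))
  e_me <- explained(cbind(me["M1", ]))
  set.seed(7)
  for (i in 1:100) {
    d <- rnorm(ncol(sub))
    expect_gte(e_me, explained(cbind(d)) - 1e-8)
  }
})

test_that("kME is the Pearson correlation with the eigenprotein", {
  sim <- plain_sim(c(50, 40), n_samples = 35, seed = 8)
  x <- sim$abundance
  me <- module_eigenproteins(x, sim$truth$module_of_protein)
  k <- kme(x, me)
  expect_true(all(k >= -1 & k <= 1))
  # direct formula evaluation
  i <- 7; m <- 2
  expect_equal(k[i, m], cor(x[i, ], me[m, ]), tolerance = 1e-12)
  # a protein equal to an ME has kME 1
  x2 <- rbind(x, ME_COPY = me[1, ])
  expect_equal(kme(x2, me)["ME_COPY", 1], 1, tolerance = 1e-12)
  # member kME to its own module dominates its kME to the other
  own <- k[cbind(1:90, sim$truth$module_of_protein[1:90])]
  other <- k[cbind(1:90, 3 - sim$truth$module_of_protein[1:90])]
  expect_gt(mean(own > other), 0.95)
})

test_that("pure noise has small kME everywhere at large n", {
  sim <- plain_sim(c(30), background = 1, n_samples = 500, seed = 9)
  x <- sim$abundance
  me <- module_eigenproteins(x, sim$truth$module_of_protein)
  k <- kme(x[31, , drop = FALSE], me)
  expect_lt(max(abs(k)), 0.15)
})

test_that("hub extraction orders by kME and caps at module size", {
  set.seed(10)
  n <- 30
  f <- rnorm(n)
  x <- rbind(hub = f, t(replicate(9, f + rnorm(n, sd = 1))))
  rownames(x)[2:10] <- paste0("p", 1:9)
  lab <- rep(1, 10)
  me <- module_eigenproteins(x, lab)
  k <- kme(x, me)
  expect_equal(hub_proteins(k, lab, 1, n = 1), "hub")
  expect_equal(sort(hub_proteins(k, lab, 1, n = 10)), sort(rownames(x)))
  expect_warning(all10 <- hub_proteins(k, lab, 1, n = 50), "only")
  expect_equal(length(all10), 10L)
  # descending kME order
  h <- hub_proteins(k, lab, 1, n = 5)
  expect_equal(h, h[order(-k[h, 1])])
})

test_that("trait association detects shifted eigenproteins and is calibrated", {
  # strong shifts
  set.seed(11)
  me <- matrix(c(rnorm(15, 2), rnorm(15, 0), rnorm(15, -2)), 1, 45,
               dimnames = list("M1", NULL))
  groups <- rep(c("a", "b", "c"), each = 15)
  out <- me_trait_association(me, groups)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$df, 2)

  # hand-computed two-group case: {1,2,3} vs {4,5,6} gives H = 27/7
  me2 <- matrix(1:6, 1, 6, dimnames = list("M1", NULL))
  out2 <- me_trait_association(me2, rep(c("g1", "g2"), each = 3))
  expect_equal(out2$statistic, 27 / 7, tolerance = 1e-10)

  expect_input_error(me_trait_association(me, rep("a", 45)))
})

test_that("sample clustering splits duplicated profiles and recovers groups", {
  set.seed(12)
  prof1 <- rnorm(50); prof2 <- rnorm(50)
  x <- cbind(matrix(prof1, 50, 5) + rnorm(250, sd = 1e-4),
             matrix(prof2, 50, 5) + rnorm(250, sd = 1e-4))
  colnames(x) <- paste0("s", 1:10)
  cl <- sample_clusters(x, 2)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 5)), 1)
  expect_equal(length(unique(sample_clusters(x, 10))), 10L)
  expect_input_error(sample_clusters(x, 11))

  # synthetic 3-group data, shifts ±1.5: groups are recovered up to the
  # occasional boundary sample whose factor noise exceeds the shift
  shifts <- rbind(tumor   = c(-1.5,  1.5,  1.5,  1.5,  1.5),
                  fibrous = c(-1.5, -1.5,  1.5, -1.5,  1.5),
                  normal  = c( 1.5, -1.5, -1.5, -1.5, -1.5))
  aris <- vapply(13:22, function(s) {
    cfg <- sim_config(n_proteins = 500, n_samples = 45,
                      module_sizes = c(120, 100, 90, 80, 60),
                      background_count = 50, kme_target = 0.8,
                      group_shifts = shifts, n_batches = 1, batch_sd = 0,
                      survival = NULL, seed = s)
    sim <- simulate_proteome(cfg)
    adjusted_rand_index(sample_clusters(sim$abundance, 3),
                        sim$truth$group_of_sample)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("module graphs honour the strict kME and correlation thresholds", {
  set.seed(14)
  n <- 30
  f <- rnorm(n)
  x <- rbind(t(replicate(4, f + rnorm(n, sd = 0.1))),  # tight clique
             weak = f + rnorm(n, sd = 2))              # low kME member
  rownames(x)[1:4] <- paste0("p", 1:4)
  lab <- rep(1, 5)
  me <- module_eigenproteins(x, lab)
  k <- kme(x, me)
  expect_lt(k["weak", 1], 0.7)
  g <- module_graph(x, k, lab, 1, kme_min = 0.7, cor_min = 0.3)
  expect_false("weak" %in% igraph::V(g)$name)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 6L)                  # complete K4
  expect_equal(igraph::V(g)$degree, rep(3, 4))

  # strict inequality: correlation exactly at the threshold gives no edge
  x2 <- matrix(rnorm(60), 2, 30)
  k2 <- matrix(0.9, 2, 1, dimnames = list(c("a", "b"), "M1"))
  cc <- correlation_matrix(x2, "pearson")[1, 2]
  g2 <- module_graph(x2, k2, c(1, 1), 1, kme_min = 0.5, cor_min = abs(cc) + 1e-9)
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::vcount(g2), 2L)                 # isolated nodes retained
})
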