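# Shared fixtures and independent oracles, built in code at test time.

# Small planted-module dataset without group/batch/survival structure.
plain_sim <- function(module_sizes, background = 0, n_samples = 40,
                      kme_target = 0.85, seed = 1) {
  cfg <- sim_config(n_proteins = sum(module_sizes) + background,
                    n_samples = n_samples, module_sizes = module_sizes,
                    background_count = background, kme_target = kme_target,
                    group_shifts = NULL, n_batches = 1, batch_sd = 0,
                    survival = NULL, seed = seed)
  simulate_proteome(cfg)
}

# Brute-force biweight midcorrelation, straight from the weight formula.
bicor_brute <- function(x, y) {
  term <- function(v) {
    m <- stats::median(v)
    s <- stats::mad(v, constant = 1)
    u <- (v - m) / (9 * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - m) * w
  }
  dx <- term(x); dy <- term(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Triple-loop TOM oracle, independent of the matrix-product implementation.
tom_brute <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# Random symmetric signed adjacency with unit diagonal.
random_adjacency <- function(n, beta = 6) {
  r <- matrix(stats::runif(n * n, -1, 1), n, n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  signed_adjacency(r, beta)
}

expect_input_error <- function(expr) {
  expect_error(expr, class = "wpcna_input_error")
}
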