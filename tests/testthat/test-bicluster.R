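test_that("mean_pairwise_correlation handles exact cases", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  colnames(m) <- paste0("a", 1:4)
  expect_equal(mean_pairwise_correlation(m, c("g1", "g2")), 1.0)
  expect_equal(mean_pairwise_correlation(m, c("g1", "g3")), -1.0)
  # pairwise correlations (1, -1, -1) -> mean -1/3
  expect_equal(mean_pairwise_correlation(m), -1 / 3)
  expect_equal(mean_pairwise_correlation(m, kind = "spearman"), -1 / 3)
})

test_that("mean_pairwise_correlation validates inputs and degenerate pairs", {
  m <- rand_matrix(4, 5, seed = 1)
  expect_error(mean_pairwise_correlation(m, "g01"), "at least 2 genes")
  expect_error(mean_pairwise_correlation(m, c("g01", "gX")), "gX")
  expect_error(mean_pairwise_correlation(m, arrays = c("a01", "a02")),
               "at least 3 arrays")
  m2 <- m
  m2["g02", ] <- c(NA, NA, NA, 1, 2)  # shares only 2 observed arrays
  m2["g01", 4:5] <- NA
  expect_error(mean_pairwise_correlation(m2, c("g01", "g02")),
               "g01.*g02.*fewer than 3")
  flat <- rbind(g1 = rep(1, 4), g2 = c(1, 2, 3, 4))
  colnames(flat) <- paste0("a", 1:4)
  expect_warning(v <- mean_pairwise_correlation(flat), "zero-variance")
  expect_equal(v, 0)
})

test_that("mean_pairwise_correlation matches the brute-force oracle", {
  for (s in 1:10) {
    m <- rand_matrix(6, 8, missing = 0.1, seed = s)
    got <- try(suppressWarnings(mean_pairwise_correlation(m)), silent = TRUE)
    if (inherits(got, "try-error")) next  # overlap precondition violated
    expect_equal(got, oracle_mpc(m, rownames(m), colnames(m)),
                 tolerance = 1e-12)
  }
})

test_that("reduce_arrays stops immediately when seeds already meet C_T", {
  m <- rbind(s1 = 1:6, s2 = 2 * (1:6) + 0.01, bg = rnorm(6))
  colnames(m) <- paste0("a", 1:6)
  res <- reduce_arrays(m, c("s1", "s2"))
  expect_identical(res$arrays, colnames(m))
  expect_identical(res$stop_reason, "threshold")
  expect_identical(nrow(res$trace), 0L)
})

test_that("reduce_arrays removes a ranking-flipping outlier array first", {
  base <- c(1, 2, 3, 4, 5)
  m <- rbind(s1 = c(base, 10), s2 = c(base + 0.1, -10))
  colnames(m) <- paste0("a", 1:6)
  res <- reduce_arrays(m, c("s1", "s2"),
                       config = bicluster_config(c_threshold = 0.75))
  expect_identical(res$trace$array[1], "a6")
  expect_gte(mean_pairwise_correlation(m, c("s1", "s2"), res$arrays), 0.75)
  # accepted removals strictly increase the seed correlation
  expect_true(all(res$trace$c_after > res$trace$c_before))
})

test_that("reduce_arrays respects the removal budget and validates seeds", {
  set.seed(9)
  m <- matrix(rnorm(3 * 10), 3, 10,
              dimnames = list(c("s1", "s2", "s3"), sprintf("a%02d", 1:10)))
  res <- reduce_arrays(m, c("s1", "s2", "s3"),
                       config = bicluster_config(c_threshold = 0.999))
  expect_lte(nrow(res$trace), floor(0.5 * 10))
  expect_gte(length(res$arrays), 5L)
  expect_error(reduce_arrays(m, c("s1", "nope")), "nope")
})

test_that("grow_genes enforces the strict-increase rule", {
  m <- rbind(s1 = 1:5, s2 = 1:5, pool1 = 1:5, pool2 = 5:1)
  colnames(m) <- paste0("a", 1:5)
  # current list already at 1.0: an identical pool gene cannot strictly improve
  res <- grow_genes(m, c("s1", "s2"), c("pool1", "pool2"))
  expect_identical(res$genes, c("s1", "s2"))
  expect_identical(nrow(res$trace), 0L)
  # empty pool -> unchanged
  expect_identical(grow_genes(m, c("s1", "s2"), character())$genes,
                   c("s1", "s2"))
  expect_warning(grow_genes(m, c("s1", "s2"), c("s1", "pool2")),
                 "already in the current list")
})

test_that("grow_genes replays the brute-force greedy on random instances", {
  for (s in 1:10) {
    set.seed(s)
    m <- rand_matrix(8, 7, seed = s)
    seeds <- rownames(m)[1:3]
    pool <- rownames(m)[4:8]
    got <- grow_genes(m, seeds, pool)
    want <- oracle_grow_genes(m, seeds, pool, colnames(m))
    expect_identical(got$genes, want$genes)
    if (nrow(got$trace)) {
      expect_identical(got$trace$gene,
                       vapply(want$trace, `[[`, character(1), "gene"))
      expect_true(all(got$trace$c_after > got$trace$c_before))
    }
  }
})

test_that("run_bicluster reaches a fixed point and is deterministic", {
  m <- rbind(s1 = 1:6, s2 = 2 * (1:6), s3 = 3 * (1:6) + 0.001,
             bg = c(0, 5, 1, 4, 2, 3))
  colnames(m) <- paste0("a", 1:6)
  bc <- run_bicluster(m, c("s1", "s2"), character())
  expect_identical(bc$genes, c("s1", "s2"))
  expect_identical(bc$arrays, colnames(m))
  expect_equal(bc$mean_correlation, 1.0)
  expect_identical(bc$n_cycles, 1L)

  sim <- make_bicluster_matrix(bicluster_sim_params(
    n_genes = 30, n_arrays = 20, module_genes = 6, module_arrays = 10,
    rng_seed = 11))
  seeds <- sim$truth$module_genes[1:3]
  pool <- setdiff(rownames(sim$matrix), seeds)[1:10]
  b1 <- run_bicluster(sim$matrix, seeds, pool)
  b2 <- run_bicluster(sim$matrix, seeds, pool)
  expect_identical(b1[names(b1) != "config"], b2[names(b2) != "config"])
  # invariants: seeds retained, arrays >= half, recomputed correlation
  expect_true(all(seeds %in% b1$genes))
  expect_gte(length(b1$arrays), ceiling(ncol(sim$matrix) / 2))
  expect_equal(b1$mean_correlation,
               mean_pairwise_correlation(sim$matrix, b1$genes, b1$arrays),
               tolerance = 1e-12)
})
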