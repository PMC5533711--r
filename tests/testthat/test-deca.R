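make_de <- function(de, p) {
  dimnames(p) <- dimnames(de)
  de_matrix(de, p)
}

test_that("reduce_comparisons applies the strict p < alpha rule", {
  de <- matrix(1, 2, 4, dimnames = list(c("s", "g"), paste0("c", 1:4)))
  p <- rbind(c(0.005, 0.5, 0.009, 1), c(0.5, 0.5, 0.5, 0.5))
  dm <- make_de(de, p)
  expect_identical(reduce_comparisons(dm, "s", min_reduced = 2),
                   c("c1", "c3"))
  # p exactly 0.01 is excluded; missing DE excludes the comparison
  p2 <- rbind(c(0.005, 0.01, 0.009, 0.002), c(1, 1, 1, 1))
  de2 <- de; de2["s", 4] <- NA
  expect_identical(reduce_comparisons(make_de(de2, p2), "s", min_reduced = 2),
                   c("c1", "c3"))
  # seed significant nowhere -> error advising a different seed
  expect_error(reduce_comparisons(dm, "g"), "different seed")
  expect_error(reduce_comparisons(dm, "absent"), "not in DE matrix")
})

test_that("seed_profile computes correlations and significance fractions", {
  set.seed(1)
  nc <- 10
  de <- rbind(s = rnorm(nc), twin = 0, anti = 0, null = rnorm(nc))
  de["twin", ] <- de["s", ]
  de["anti", ] <- -2 * de["s", ]
  colnames(de) <- paste0("c", 1:nc)
  p <- matrix(1, 4, nc)
  p[1, ] <- 0.001                     # all comparisons reduced
  p[2, 1:4] <- 0.005                  # significant in 4 of 10
  dm <- make_de(de, p)
  pr <- seed_profile(dm, "s")
  expect_equal(pr$correlation[["twin"]], 1.0)
  expect_equal(pr$correlation[["anti"]], -1.0)
  expect_equal(pr$significance_fraction[["twin"]], 0.4)
  # all p = 1 (imputed missing) can never be significant
  expect_equal(pr$significance_fraction[["null"]], 0)
  expect_false("s" %in% names(pr$correlation))
})

test_that("select_candidates uses strict thresholds on |corr| OR fraction", {
  prof <- function(corr, frac, seed = "s") {
    structure(list(seed = seed, comparisons = paste0("c", 1:3),
                   correlation = corr, significance_fraction = frac),
              class = "seed_profile")
  }
  genes <- c("hi", "edge", "neg", "lo")
  p1 <- prof(stats::setNames(c(0.65, 0.60, -0.7, 0.1), genes),
             stats::setNames(c(0.2, 0.60, 0.0, 0.2), genes))
  expect_identical(select_candidates(list(p1)), c("hi", "neg"))

  # every_seed demands the criterion for each seed
  p2 <- prof(stats::setNames(c(0.9, 0.9, 0.0, 0.9), genes),
             stats::setNames(rep(0, 4), genes), seed = "s2")
  cfg <- deca_config(selection_mode = "every_seed")
  expect_identical(select_candidates(list(p1, p2), cfg), "hi")
})

test_that("raising the selection threshold never grows the selected set", {
  inst <- rand_deca_instance(3, n_genes = 10, n_comps = 10, n_seeds = 2)
  profs <- lapply(inst$seeds, function(s)
    suppressWarnings(seed_profile(inst$de, s, deca_config(
      selection_threshold = 0.2))))
  prev <- select_candidates(profs, deca_config(selection_threshold = 0.1))
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- select_candidates(profs, deca_config(selection_threshold = thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("rank_candidates assigns 2n midranks and geometric-mean finals", {
  pr <- structure(list(
    seed = "s", comparisons = paste0("c", 1:3),
    correlation = c(A = 0.9, B = 0.7),
    significance_fraction = c(A = 0.9, B = 0.7)), class = "seed_profile")
  rk <- rank_candidates(list(pr), c("A", "B"))
  expect_equal(unname(rk$ranks["A", ]), c(1, 1))
  expect_equal(unname(rk$final_rank[c("A", "B")]), c(1, 2))
  expect_identical(rk$ranking, c("A", "B"))

  # ties on one criterion get the average rank (m + 1) / 2
  pr2 <- structure(list(
    seed = "s", comparisons = paste0("c", 1:3),
    correlation = c(A = 0.5, B = 0.5, C = 0.5),
    significance_fraction = c(A = 0.9, B = 0.5, C = 0.1)),
    class = "seed_profile")
  rk2 <- rank_candidates(list(pr2), c("A", "B", "C"))
  expect_equal(unname(rk2$ranks[, "s.corr"]), rep(2, 3))
  expect_equal(rk2$final_rank[["B"]], sqrt(2 * 2))
})

test_that("run_deca produces 2n ranks per seed count and excludes seeds", {
  for (ns in c(3, 2)) {   # Nrf2-style (3 seeds) and AhR-style (2 seeds)
    inst <- rand_deca_instance(ns + 10, n_genes = 10, n_comps = 12,
                               n_seeds = ns)
    res <- suppressWarnings(run_deca(inst$de, inst$seeds))
    expect_identical(ncol(res$ranks), as.integer(2 * ns))
    expect_false(any(inst$seeds %in% res$selected))
    m <- length(res$selected)
    if (m) {
      expect_true(all(res$final_rank >= 1 & res$final_rank <= m))
      # each component ranking's ranks sum to m(m+1)/2
      expect_true(all(abs(colSums(res$ranks) - m * (m + 1) / 2) < 1e-9))
    }
  }
})

test_that("run_deca matches the brute-force oracle and ignores input order", {
  for (s in 1:10) {
    inst <- rand_deca_instance(100 + s)
    res <- suppressWarnings(run_deca(inst$de, inst$seeds))
    want <- oracle_deca(inst$de$de, inst$de$p, inst$seeds)
    expect_identical(res$selected, want$selected)
    if (length(want$selected)) {
      expect_equal(res$final_rank[want$selected], want$final,
                   tolerance = 1e-12)
      expect_identical(res$ranking, want$ranking)
    }
    # permutation invariance: shuffle gene and comparison order
    set.seed(s)
    gperm <- sample(nrow(inst$de$de))
    cperm <- sample(ncol(inst$de$de))
    shuffled <- de_matrix(inst$de$de[gperm, cperm],
                          inst$de$p[gperm, cperm])
    res2 <- suppressWarnings(run_deca(shuffled, inst$seeds))
    expect_identical(res2$ranking, res$ranking)
    expect_equal(res2$final_rank[names(res$final_rank)], res$final_rank)
    expect_setequal(res2$selected, res$selected)
  }
  expect_error(suppressWarnings(
    run_deca(rand_deca_instance(4)$de, "nonexistent")), "nonexistent")
})
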