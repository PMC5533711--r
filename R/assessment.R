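# In silico assessment of DECA: for each pathway, repeatedly draw random
# eligible seed genes, run DECA, and measure how many of the pathway's
# remaining genes land in the top fraction of the ranking, plus a Welch
# t-test asking whether pathway members get better (lower) final ranks
# than non-members.

#' Assessment configuration
#'
#' @param n_seeds_per_run seeds drawn per run, default 3.
#' @param min_sig_experiments minimum number of comparisons with
#'   significant DE a gene needs to be seed-eligible, default 15
#'   (inclusive "at least").
#' @param top_fraction fraction of the ranking counted as recovered,
#'   default 0.10.
#' @param n_runs runs per pathway, default 10.
#' @param rng_seed integer seed driving the random seed-gene draws.
#' @param sig_alpha significance level used both for eligibility counting
#'   and inside DECA, default 0.01.
#' @param fold_gate optional absolute-DE gate added to the eligibility
#'   criterion (`NULL`, the default, disables it).
#' @return list of class `assessment_config`.
#' @export
assessment_config <- function(n_seeds_per_run = 3L, min_sig_experiments = 15L,
                              top_fraction = 0.10, n_runs = 10L,
                              rng_seed = 1L, sig_alpha = 0.01,
                              fold_gate = NULL) {
  .assert(top_fraction > 0 && top_fraction <= 1,
          "top_fraction must be in (0, 1]")
  .assert(n_seeds_per_run >= 1, "n_seeds_per_run must be >= 1")
  .assert(min_sig_experiments >= 1, "min_sig_experiments must be >= 1")
  .assert(n_runs >= 1, "n_runs must be >= 1")
  structure(list(n_seeds_per_run = as.integer(n_seeds_per_run),
                 min_sig_experiments = as.integer(min_sig_experiments),
                 top_fraction = top_fraction, n_runs = as.integer(n_runs),
                 rng_seed = as.integer(rng_seed), sig_alpha = sig_alpha,
                 fold_gate = fold_gate),
            class = "assessment_config")
}

#' Seed-eligible genes of a pathway
#'
#' Pathway members present in the DE matrix whose number of comparisons
#' with significant DE (p < `sig_alpha`, DE value observed, and optionally
#' |DE| >= `fold_gate`) is at least `min_sig_experiments`.
#'
#' @param de a [de_matrix()].
#' @param pathway a [gene_set()].
#' @param config an [assessment_config()].
#' @return character vector of eligible gene ids.
#' @export
eligible_seed_genes <- function(de, pathway, config = assessment_config()) {
  .assert(inherits(pathway, "gene_set"), "pathway must be a gene_set")
  .assert(length(pathway$genes) >= 1L, "pathway '%s' is empty", pathway$name)
  members <- intersect(pathway$genes, rownames(de$de))
  sig <- de$p[members, , drop = FALSE] < config$sig_alpha &
    !is.na(de$de[members, , drop = FALSE])
  if (!is.null(config$fold_gate)) {
    big <- abs(de$de[members, , drop = FALSE]) >= config$fold_gate
    big[is.na(big)] <- FALSE
    sig <- sig & big
  }
  eligible <- members[rowSums(sig) >= config$min_sig_experiments]
  .assert(length(eligible) >= config$n_seeds_per_run,
          "pathway '%s' has %d eligible seed gene(s); need >= %d",
          pathway$name, length(eligible), config$n_seeds_per_run)
  eligible
}

#' Pathway recovery fraction
#'
#' Fraction of the pathway's non-seed genes (restricted to genes present in
#' the analysed DE matrix) found in the top `ceiling(top_fraction * m)`
#' genes of the ranking of `m` selected genes. Seeds are excluded from
#' both numerator and denominator; recovering a seed would be trivial.
#'
#' @param result a [run_deca()] result.
#' @param pathway a [gene_set()].
#' @param top_fraction fraction of the ranking counted, default 0.10.
#' @return recovery fraction in \[0, 1\] (`NaN` when no non-seed pathway
#'   gene is present in the DE matrix).
#' @export
pathway_recovery <- function(result, pathway, top_fraction = 0.10) {
  .assert(inherits(result, "deca_result"), "result must be a deca_result")
  .assert(length(result$ranking) >= 1L, "ranking is empty")
  top <- utils::head(result$ranking, ceiling(top_fraction * length(result$ranking)))
  pw <- setdiff(as_gene_ids(pathway), result$seeds)
  length(intersect(top, pw)) / length(intersect(pw, result$genes))
}

# Welch two-sample t statistic, Welch-Satterthwaite df, one-sided p for
# mean(x) < mean(y). Implemented from the closed form; stats::t.test is
# kept as an independent oracle in the test suite.
.welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  .assert(nx >= 2L && ny >= 2L, "each group needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  .assert(se2 > 0, "zero variance in both groups")
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = stats::pt(t, df))
}

#' Welch rank-enrichment test
#'
#' Welch unequal-variance t-test comparing the final DECA ranks of selected
#' pathway members against selected non-members, one-sided for the pathway
#' group having the better (lower) mean rank.
#'
#' @param result a [run_deca()] result.
#' @param pathway a [gene_set()].
#' @return list with `t`, `df`, `p`.
#' @export
rank_enrichment_test <- function(result, pathway) {
  .assert(inherits(result, "deca_result"), "result must be a deca_result")
  pw <- setdiff(as_gene_ids(pathway), result$seeds)
  in_pw <- names(result$final_rank) %in% pw
  .assert(sum(in_pw) >= 2L && sum(!in_pw) >= 2L,
          "need >= 2 pathway and >= 2 non-pathway genes in the ranking")
  .welch_test(result$final_rank[in_pw], result$final_rank[!in_pw])
}

#' Run the full assessment protocol
#'
#' For each pathway and each of `n_runs` runs: draw `n_seeds_per_run`
#' eligible seed genes without replacement (seeded RNG, deterministic given
#' `rng_seed`), run DECA, and record the recovery fraction and the Welch
#' rank-enrichment test. Per-run failures (e.g. too few eligible seeds or
#' too small Welch groups) are recorded in the row's `error` column and do
#' not abort other pathways.
#'
#' @param de a [de_matrix()].
#' @param pathways list of [gene_set()] objects.
#' @param config an [assessment_config()].
#' @param dconfig a [deca_config()] used for the DECA runs; its `sig_alpha`
#'   is overridden by `config$sig_alpha`.
#' @return data frame with one row per (pathway, run): `pathway`, `run`,
#'   `seeds` (comma-separated), `n_selected`, `recovery_fraction`,
#'   `welch_t`, `welch_p`, `error`.
#' @export
run_assessment <- function(de, pathways, config = assessment_config(),
                           dconfig = deca_config()) {
  dconfig$sig_alpha <- config$sig_alpha
  rows <- list()
  for (i in seq_along(pathways)) {
    pw <- pathways[[i]]
    for (j in seq_len(config$n_runs)) {
      row <- data.frame(pathway = pw$name, run = j, seeds = NA_character_,
                        n_selected = NA_integer_,
                        recovery_fraction = NA_real_, welch_t = NA_real_,
                        welch_p = NA_real_, error = NA_character_,
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        eligible <- eligible_seed_genes(de, pw, config)
        set.seed(.derive_seed(config$rng_seed, i, j))
        seeds <- sample(eligible, config$n_seeds_per_run)
        dr <- run_deca(de, seeds, dconfig)
        row$seeds <- paste(seeds, collapse = ",")
        row$n_selected <- length(dr$selected)
        row$recovery_fraction <-
          pathway_recovery(dr, pw, config$top_fraction)
        wt <- rank_enrichment_test(dr, pw)
        row$welch_t <- wt$t
        row$welch_p <- wt$p
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
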