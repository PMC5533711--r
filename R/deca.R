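# Differential Expression Correlation Analysis (DECA). For each seed gene
# the DE matrix is reduced to the comparisons where the seed itself is
# significantly differentially expressed; every other gene is then scored
# against the seed by (i) correlation of DE values over those comparisons
# and (ii) the significance fraction -- the share of the reduced comparisons
# in which the gene is itself significant. Genes passing the selection
# threshold on any seed are ranked per seed on both criteria (2n rankings
# for n seeds) and aggregated by the geometric mean of their 2n ranks.

#' DECA configuration
#'
#' @param sig_alpha significance level for differential expression,
#'   default 0.01 (strict `<`).
#' @param selection_threshold selection cut-off on absolute correlation or
#'   significance fraction, default 0.6 (strict `>`).
#' @param selection_mode `"any_seed"` (default: the criterion must hold for
#'   at least one seed) or `"every_seed"`.
#' @param correlation_kind `"pearson"` (default) or `"spearman"`.
#' @param min_reduced_comparisons minimum number of significant comparisons
#'   a seed must have, default 3.
#' @return list of class `deca_config`.
#' @export
deca_config <- function(sig_alpha = 0.01, selection_threshold = 0.6,
                        selection_mode = c("any_seed", "every_seed"),
                        correlation_kind = c("pearson", "spearman"),
                        min_reduced_comparisons = 3L) {
  selection_mode <- match.arg(selection_mode)
  correlation_kind <- match.arg(correlation_kind)
  .assert(sig_alpha > 0 && sig_alpha < 1, "sig_alpha must be in (0, 1)")
  .assert(selection_threshold > 0 && selection_threshold < 1,
          "selection_threshold must be in (0, 1)")
  .assert(min_reduced_comparisons >= 1, "min_reduced_comparisons must be >= 1")
  structure(list(sig_alpha = sig_alpha,
                 selection_threshold = selection_threshold,
                 selection_mode = selection_mode,
                 correlation_kind = correlation_kind,
                 min_reduced_comparisons = as.integer(min_reduced_comparisons)),
            class = "deca_config")
}

#' Reduce comparisons for a seed gene
#'
#' Returns the comparisons in which the seed is significantly
#' differentially expressed: p-value strictly below `sig_alpha` and DE
#' value non-missing.
#'
#' @param de a [de_matrix()].
#' @param seed seed gene id (present in `de`).
#' @param sig_alpha significance level, default 0.01.
#' @param min_reduced minimum acceptable number of comparisons, default 3.
#' @return character vector of comparison ids.
#' @export
reduce_comparisons <- function(de, seed, sig_alpha = 0.01, min_reduced = 3L) {
  .assert(inherits(de, "de_matrix"), "de must be a de_matrix")
  .assert(seed %in% rownames(de$de), "seed gene '%s' not in DE matrix", seed)
  keep <- de$p[seed, ] < sig_alpha & !is.na(de$de[seed, ])
  comps <- colnames(de$de)[keep]
  .assert(length(comps) >= min_reduced,
          paste0("seed '%s' is significant in only %d comparison(s) ",
                 "(need >= %d); choose a different seed"),
          seed, length(comps), min_reduced)
  comps
}

#' Per-seed DECA profile
#'
#' For every gene other than the seed, computes the correlation of DE
#' values with the seed across the seed's reduced comparisons
#' (pairwise-complete; undefined correlations become 0 with a warning) and
#' the significance fraction (share of reduced comparisons with gene
#' p < `sig_alpha`). Missing p-values were substituted with 1 on load, so
#' imputed entries can never count as significant.
#'
#' @param de a [de_matrix()].
#' @param seed seed gene id.
#' @param config a [deca_config()].
#' @return object of class `seed_profile`: `seed`, `comparisons`,
#'   `correlation` and `significance_fraction` (named vectors over all
#'   non-seed genes).
#' @export
seed_profile <- function(de, seed, config = deca_config()) {
  comps <- reduce_comparisons(de, seed, config$sig_alpha,
                              config$min_reduced_comparisons)
  genes <- setdiff(rownames(de$de), seed)
  x <- de$de[seed, comps]
  sub <- de$de[genes, comps, drop = FALSE]
  corr <- suppressWarnings(stats::cor(t(sub), x,
                                      use = "pairwise.complete.obs",
                                      method = config$correlation_kind))[, 1L]
  if (any(!is.finite(corr))) {
    warning("undefined correlation(s) treated as 0", call. = FALSE)
    corr[!is.finite(corr)] <- 0
  }
  # round away float jitter so exact ties (e.g. two genes duplicating the
  # seed) rank identically regardless of summation order
  corr <- round(corr, 12)
  frac <- rowMeans(de$p[genes, comps, drop = FALSE] < config$sig_alpha)
  structure(list(seed = seed, comparisons = comps,
                 correlation = stats::setNames(corr, genes),
                 significance_fraction = stats::setNames(frac, genes)),
            class = "seed_profile")
}

#' Select candidate genes from seed profiles
#'
#' Under `any_seed` mode a gene is selected iff, for at least one seed,
#' its absolute correlation OR its significance fraction strictly exceeds
#' `selection_threshold`; under `every_seed` the condition must hold for
#' each seed. Seed genes themselves are never candidates.
#'
#' @param profiles list of [seed_profile()] objects.
#' @param config a [deca_config()].
#' @return character vector of selected gene ids (input gene order).
#' @export
select_candidates <- function(profiles, config = deca_config()) {
  .assert(length(profiles) >= 1L, "need at least one seed profile")
  seeds <- vapply(profiles, `[[`, character(1L), "seed")
  candidates <- setdiff(names(profiles[[1L]]$correlation), seeds)
  thr <- config$selection_threshold
  hits <- vapply(profiles, function(pr) {
    abs(pr$correlation[candidates]) > thr |
      pr$significance_fraction[candidates] > thr
  }, logical(length(candidates)))
  hits <- matrix(hits, nrow = length(candidates))
  sel <- if (config$selection_mode == "any_seed") {
    rowSums(hits) > 0L
  } else {
    rowSums(hits) == length(profiles)
  }
  candidates[sel]
}

#' Rank selected genes and aggregate by geometric mean
#'
#' For each seed, selected genes are ranked twice: by absolute correlation
#' (descending) and by significance fraction (descending); rank 1 is best,
#' ties receive the average of the tied positions. With n seeds this gives
#' 2n component ranks per gene; the final rank is their geometric mean.
#' The output ordering is ascending by final rank, ties broken
#' lexicographically by gene id.
#'
#' @param profiles list of [seed_profile()] objects.
#' @param selected nonempty character vector of selected gene ids.
#' @return list with `ranks` (genes x 2n matrix, columns
#'   `<seed>.corr` / `<seed>.frac`), `final_rank` (named vector), and
#'   `ranking` (gene ids sorted by final rank).
#' @export
rank_candidates <- function(profiles, selected) {
  .assert(length(selected) >= 1L, "no selected genes to rank")
  cols <- lapply(profiles, function(pr) {
    cbind(.rank_desc(abs(pr$correlation[selected])),
          .rank_desc(pr$significance_fraction[selected]))
  })
  ranks <- do.call(cbind, cols)
  dimnames(ranks) <- list(
    selected,
    as.vector(vapply(profiles, function(pr)
      paste(pr$seed, c("corr", "frac"), sep = "."), character(2L))))
  # rounded so that permuted component ranks giving the same geometric
  # mean compare as exact ties (ordering then falls back to gene id)
  final <- round(apply(ranks, 1L, geometric_mean), 12)
  list(ranks = ranks,
       final_rank = final,
       ranking = selected[order(final, selected)])
}

#' Run DECA end to end
#'
#' Composes [seed_profile()], [select_candidates()] and
#' [rank_candidates()]. Every seed must be significant in at least
#' `min_reduced_comparisons` comparisons; a failing seed aborts the run
#' with an error naming it. Seed genes are excluded from the candidate
#' list. The result is fully deterministic.
#'
#' @param de a [de_matrix()].
#' @param seeds character vector of seed gene ids (>= 1).
#' @param config a [deca_config()].
#' @return object of class `deca_result`: `seeds`, `genes` (the full gene
#'   universe of `de`), `profiles`, `selected`, `ranks`, `final_rank`,
#'   `ranking`, `config`. With no gene selected, `selected` and `ranking`
#'   are empty.
#' @export
run_deca <- function(de, seeds, config = deca_config()) {
  seeds <- as_gene_ids(seeds)
  .assert(length(seeds) >= 1L, "need at least one seed gene")
  .assert(!anyDuplicated(seeds), "duplicate seed gene ids")
  profiles <- stats::setNames(
    lapply(seeds, function(s) seed_profile(de, s, config)), seeds)
  selected <- select_candidates(profiles, config)
  if (length(selected)) {
    rk <- rank_candidates(profiles, selected)
  } else {
    rk <- list(ranks = matrix(numeric(), 0L, 2L * length(seeds)),
               final_rank = stats::setNames(numeric(), character()),
               ranking = character())
  }
  structure(list(seeds = seeds, genes = rownames(de$de),
                 profiles = profiles, selected = selected,
                 ranks = rk$ranks, final_rank = rk$final_rank,
                 ranking = rk$ranking, config = config),
            class = "deca_result")
}

#' @export
print.deca_result <- function(x, ...) {
  cat(sprintf(paste0("deca_result: %d seed(s), %d of %d candidate genes ",
                     "selected\n"),
              length(x$seeds), length(x$selected),
              length(x$genes) - length(x$seeds)))
  if (length(x$ranking)) {
    top <- utils::head(x$ranking, 5L)
    cat("  top:", paste(sprintf("%s (%.2f)", top, x$final_rank[top]),
                        collapse = ", "), "\n")
  }
  invisible(x)
}
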