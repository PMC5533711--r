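# Seed-gene biclustering: starting from genes known to respond to a pathway
# (seed genes), iteratively remove arrays to maximise the seeds' mean
# pairwise correlation (array reduction), then greedily add genes from a
# candidate pool whenever doing so raises the full-list mean pairwise
# correlation (gene addition). The two phases alternate until a fixed point.

#' Biclustering configuration
#'
#' @param c_threshold target mean pairwise seed correlation at which array
#'   reduction stops (the field's C_T); default 0.75. A more stringent 0.8
#'   is appropriate when only few seed genes are available.
#' @param max_removed_fraction maximum fraction of the initial arrays that
#'   may be removed; default 0.5 ("half of the initial arrays").
#' @param correlation_kind `"pearson"` (default) or `"spearman"`.
#' @param max_outer_iterations cap on reduce/grow alternation cycles;
#'   default 10.
#' @return list of class `bicluster_config`.
#' @export
bicluster_config <- function(c_threshold = 0.75, max_removed_fraction = 0.5,
                             correlation_kind = c("pearson", "spearman"),
                             max_outer_iterations = 10L) {
  correlation_kind <- match.arg(correlation_kind)
  .assert(c_threshold > 0 && c_threshold <= 1, "c_threshold must be in (0, 1]")
  .assert(max_removed_fraction > 0 && max_removed_fraction <= 0.5 + 1e-9,
          "max_removed_fraction must be in (0, 0.5]")
  .assert(max_outer_iterations >= 1, "max_outer_iterations must be >= 1")
  structure(list(c_threshold = c_threshold,
                 max_removed_fraction = max_removed_fraction,
                 correlation_kind = correlation_kind,
                 max_outer_iterations = as.integer(max_outer_iterations)),
            class = "bicluster_config")
}

#' Mean pairwise correlation of a gene set over a set of arrays
#'
#' Unweighted mean over all unordered gene pairs of the correlation of
#' their profiles across `arrays` (pairwise-complete observations). A pair
#' with zero variance (undefined correlation) contributes 0, with a
#' warning. Every gene pair must share at least 3 observed arrays.
#'
#' @param m numeric genes x arrays matrix.
#' @param genes gene ids (>= 2, present in `m`).
#' @param arrays array ids (>= 3, present in `m`).
#' @param kind `"pearson"` or `"spearman"`.
#' @return mean pairwise correlation in \[-1, 1\].
#' @export
mean_pairwise_correlation <- function(m, genes = rownames(m),
                                      arrays = colnames(m),
                                      kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  genes <- as_gene_ids(genes)
  missing_g <- setdiff(genes, rownames(m))
  .assert(length(missing_g) == 0L, "gene(s) not in matrix: %s",
          paste(missing_g, collapse = ", "))
  missing_a <- setdiff(arrays, colnames(m))
  .assert(length(missing_a) == 0L, "array(s) not in matrix: %s",
          paste(missing_a, collapse = ", "))
  .assert(length(genes) >= 2L, "need at least 2 genes")
  .assert(length(arrays) >= 3L, "need at least 3 arrays")
  sub <- m[genes, arrays, drop = FALSE]
  if (anyNA(sub)) {
    sh <- tcrossprod((!is.na(sub)) * 1)
    bad <- which(sh < 3 & upper.tri(sh), arr.ind = TRUE)
    .assert(nrow(bad) == 0L,
            "gene pair (%s, %s) shares fewer than 3 observed arrays",
            genes[bad[1L, 1L]], genes[bad[1L, 2L]])
  }
  cm <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs",
                                    method = kind))
  v <- cm[upper.tri(cm)]
  if (any(!is.finite(v))) {
    warning("zero-variance gene pair(s): correlation treated as 0",
            call. = FALSE)
    v[!is.finite(v)] <- 0
  }
  mean(v)
}

# As above, but returns -Inf instead of raising when a pair overlap or
# variance precondition fails; used while scoring candidate moves.
.mpc_or_neg_inf <- function(m, genes, arrays, kind) {
  tryCatch(suppressWarnings(
    mean_pairwise_correlation(m, genes, arrays, kind)),
    error = function(e) -Inf)
}

#' Array reduction phase
#'
#' Repeatedly evaluates, for every retained array, the seed mean pairwise
#' correlation without that array, and permanently removes the array whose
#' removal yields the largest strict increase (ties broken by array id for
#' determinism). Stops when the correlation reaches `c_threshold`, when the
#' removal budget (`floor(max_removed_fraction * N)` of the `N` input
#' arrays) is exhausted, or when no single removal strictly increases the
#' correlation.
#'
#' @param m numeric genes x arrays matrix.
#' @param seeds seed gene ids (all present in `m`).
#' @param arrays array ids to start from; default all columns (>= 4).
#' @param config a [bicluster_config()].
#' @param max_removals optional absolute removal budget overriding the
#'   fraction (used by [run_bicluster()] to enforce a global budget).
#' @return list with `arrays` (retained ids), `trace` (data frame with one
#'   row per removal: iteration, array, `c_before`, `c_after`), and
#'   `stop_reason`.
#' @export
reduce_arrays <- function(m, seeds, arrays = colnames(m),
                          config = bicluster_config(), max_removals = NULL) {
  seeds <- as_gene_ids(seeds)
  absent <- setdiff(seeds, rownames(m))
  .assert(length(absent) == 0L, "seed gene(s) not in matrix: %s",
          paste(absent, collapse = ", "))
  .assert(length(arrays) >= 4L, "need at least 4 arrays")
  budget <- max_removals %||% floor(config$max_removed_fraction * length(arrays))
  retained <- arrays
  trace <- list()
  stop_reason <- NA_character_
  iter <- 0L
  repeat {
    cur <- mean_pairwise_correlation(m, seeds, retained,
                                     config$correlation_kind)
    if (cur >= config$c_threshold) { stop_reason <- "threshold"; break }
    if (iter >= budget) { stop_reason <- "max_removed"; break }
    if (length(retained) <= 3L) { stop_reason <- "min_arrays"; break }
    cand <- vapply(retained, function(a)
      .mpc_or_neg_inf(m, seeds, setdiff(retained, a),
                      config$correlation_kind), numeric(1L))
    best <- retained[order(-cand, retained)][1L]
    if (!(cand[[best]] > cur)) { stop_reason <- "no_improvement"; break }
    iter <- iter + 1L
    trace[[iter]] <- data.frame(iteration = iter, array = best,
                                c_before = cur, c_after = cand[[best]],
                                stringsAsFactors = FALSE)
    retained <- setdiff(retained, best)
  }
  list(arrays = retained,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(iteration = integer(), array = character(),
                    c_before = numeric(), c_after = numeric()),
       stop_reason = stop_reason)
}

#' Gene addition phase
#'
#' Candidates from the pool are visited in deterministic order (descending
#' mean correlation to the current gene list over `arrays`, ties broken
#' lexicographically). A candidate is added iff the mean pairwise
#' correlation of the enlarged list strictly exceeds that of the current
#' list; the list updates immediately on addition. Full passes over the
#' remaining candidates repeat until a pass adds nothing.
#'
#' @param m numeric genes x arrays matrix.
#' @param current_genes current gene list (>= 2 genes, typically the seeds).
#' @param pool a [gene_set()] or character vector of candidate gene ids;
#'   candidates absent from `m` or overlapping `current_genes` are dropped
#'   with a warning.
#' @param arrays array ids over which correlations are computed.
#' @param config a [bicluster_config()].
#' @return list with `genes` (grown list, input genes first, additions in
#'   acceptance order), `trace` (pass, gene, `c_before`, `c_after`), and
#'   `mean_correlation` of the final list.
#' @export
grow_genes <- function(m, current_genes, pool, arrays = colnames(m),
                       config = bicluster_config()) {
  current <- as_gene_ids(current_genes)
  .assert(length(current) >= 2L, "current gene list needs >= 2 genes")
  pool <- as_gene_ids(pool)
  absent <- setdiff(pool, rownames(m))
  if (length(absent)) {
    warning(sprintf("%d pool gene(s) absent from matrix dropped",
                    length(absent)), call. = FALSE)
    pool <- setdiff(pool, absent)
  }
  overlap <- intersect(pool, current)
  if (length(overlap)) {
    warning(sprintf("%d pool gene(s) already in the current list dropped",
                    length(overlap)), call. = FALSE)
    pool <- setdiff(pool, overlap)
  }
  kind <- config$correlation_kind
  c_cur <- mean_pairwise_correlation(m, current, arrays, kind)
  trace <- list()
  pass <- 0L
  repeat {
    remaining <- setdiff(pool, current)
    if (length(remaining) == 0L) break
    pass <- pass + 1L
    # candidate order: descending mean correlation to the current list
    affinity <- vapply(remaining, function(g) {
      v <- suppressWarnings(stats::cor(
        t(m[current, arrays, drop = FALSE]), m[g, arrays],
        use = "pairwise.complete.obs", method = kind))
      v[!is.finite(v)] <- 0
      mean(v)
    }, numeric(1L))
    added <- FALSE
    for (g in remaining[order(-affinity, remaining)]) {
      c_new <- .mpc_or_neg_inf(m, c(current, g), arrays, kind)
      if (c_new > c_cur) {
        trace[[length(trace) + 1L]] <-
          data.frame(pass = pass, gene = g, c_before = c_cur,
                     c_after = c_new, stringsAsFactors = FALSE)
        current <- c(current, g)
        c_cur <- c_new
        added <- TRUE
      }
    }
    if (!added) break
  }
  list(genes = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(pass = integer(), gene = character(),
                    c_before = numeric(), c_after = numeric()),
       mean_correlation = c_cur)
}

#' Run the full biclustering algorithm
#'
#' Alternates [reduce_arrays()] (on the current gene list) and
#' [grow_genes()] (on the current array list) until a full cycle changes
#' neither, or `max_outer_iterations` cycles have run. The removal budget
#' (`floor(max_removed_fraction * N)` of the initial `N` arrays) is global
#' across cycles, so at least half of the input arrays are always retained.
#'
#' @param m numeric genes x arrays matrix.
#' @param seeds seed gene ids.
#' @param pool candidate [gene_set()] or id vector.
#' @param config a [bicluster_config()].
#' @return object of class `bicluster`: `genes` (seeds first),
#'   `seeds`, `arrays`, `mean_correlation` (full list, recomputed),
#'   `seed_correlation` (seeds only, recomputed), `n_cycles`, and `trace`
#'   (per-cycle array/gene traces).
#' @export
run_bicluster <- function(m, seeds, pool, config = bicluster_config()) {
  seeds <- as_gene_ids(seeds)
  arrays <- colnames(m)
  budget <- floor(config$max_removed_fraction * length(arrays))
  genes <- seeds
  removed <- 0L
  cycles <- list()
  for (cycle in seq_len(config$max_outer_iterations)) {
    red <- reduce_arrays(m, genes, arrays, config,
                         max_removals = budget - removed)
    removed <- removed + nrow(red$trace)
    grw <- grow_genes(m, genes, setdiff(as_gene_ids(pool), genes),
                      red$arrays, config)
    changed <- length(red$arrays) < length(arrays) ||
      length(grw$genes) > length(genes)
    arrays <- red$arrays
    genes <- grw$genes
    cycles[[cycle]] <- list(cycle = cycle, array_trace = red$trace,
                            array_stop = red$stop_reason,
                            gene_trace = grw$trace)
    if (!changed) break
  }
  structure(list(
    genes = genes, seeds = seeds, arrays = arrays,
    mean_correlation = mean_pairwise_correlation(
      m, genes, arrays, config$correlation_kind),
    seed_correlation = mean_pairwise_correlation(
      m, seeds, arrays, config$correlation_kind),
    n_cycles = length(cycles), trace = cycles, config = config),
    class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf(paste0("bicluster: %d genes (%d seeds + %d added) over %d",
                     " arrays\n  mean correlation %.4f (seeds only %.4f),",
                     " %d cycle(s)\n"),
              length(x$genes), length(x$seeds),
              length(x$genes) - length(x$seeds), length(x$arrays),
              x$mean_correlation, x$seed_correlation, x$n_cycles))
  invisible(x)
}
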