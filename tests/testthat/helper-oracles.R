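# Independent brute-force oracles and small fixture builders. Oracles use
# scalar arithmetic / explicit loops, never the package's code paths.

# Pearson correlation from the defining formula; undefined -> 0.
oracle_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (length(x) < 2 || sx == 0 || sy == 0) return(0)
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

oracle_mpc <- function(m, genes, arrays, method = "pearson") {
  vals <- numeric()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      x <- m[genes[i], arrays]; y <- m[genes[j], arrays]
      if (method == "spearman") {
        ok <- !is.na(x) & !is.na(y)
        r <- oracle_cor(rank(x[ok]), rank(y[ok]))
      } else {
        r <- oracle_cor(x, y)
      }
      vals <- c(vals, r)
    }
  }
  mean(vals)
}

# Exhaustive replay of the array-reduction greedy: at each step evaluate
# every single-array removal with oracle_mpc, remove the best strict
# improvement (ties by array id), honouring threshold / budget stops.
oracle_reduce_arrays <- function(m, seeds, arrays, c_threshold = 0.75,
                                 max_removed_fraction = 0.5) {
  budget <- floor(max_removed_fraction * length(arrays))
  retained <- arrays
  trace <- list()
  repeat {
    cur <- oracle_mpc(m, seeds, retained)
    if (cur >= c_threshold || length(trace) >= budget ||
        length(retained) <= 3) break
    scores <- vapply(retained, function(a)
      oracle_mpc(m, seeds, setdiff(retained, a)), numeric(1))
    best <- retained[order(-scores, retained)][1]
    if (!(scores[[best]] > cur)) break
    trace[[length(trace) + 1]] <- list(array = best, c_before = cur,
                                       c_after = scores[[best]])
    retained <- setdiff(retained, best)
  }
  list(arrays = retained, trace = trace)
}

# Exhaustive replay of gene addition: repeated passes; candidates ordered
# by descending mean correlation to the current list (lexicographic ties);
# accept iff the enlarged-list mean strictly increases.
oracle_grow_genes <- function(m, current, pool, arrays) {
  pool <- setdiff(intersect(pool, rownames(m)), current)
  c_cur <- oracle_mpc(m, current, arrays)
  trace <- list()
  repeat {
    remaining <- setdiff(pool, current)
    if (!length(remaining)) break
    aff <- vapply(remaining, function(g)
      mean(vapply(current, function(h)
        oracle_cor(m[g, arrays], m[h, arrays]), numeric(1))), numeric(1))
    added <- FALSE
    for (g in remaining[order(-aff, remaining)]) {
      c_new <- oracle_mpc(m, c(current, g), arrays)
      if (c_new > c_cur) {
        trace[[length(trace) + 1]] <- list(gene = g, c_before = c_cur,
                                           c_after = c_new)
        current <- c(current, g)
        c_cur <- c_new
        added <- TRUE
      }
    }
    if (!added) break
  }
  list(genes = current, trace = trace)
}

# From-scratch DECA recomputation with scalar loops.
oracle_deca <- function(de_vals, p_vals, seeds, alpha = 0.01, thr = 0.6) {
  genes <- rownames(de_vals)
  candidates <- setdiff(genes, seeds)
  prof <- lapply(seeds, function(s) {
    comps <- colnames(de_vals)[p_vals[s, ] < alpha & !is.na(de_vals[s, ])]
    corr <- round(vapply(candidates, function(g)
      oracle_cor(de_vals[g, comps], de_vals[s, comps]), numeric(1)), 12)
    frac <- vapply(candidates, function(g)
      mean(p_vals[g, comps] < alpha), numeric(1))
    list(seed = s, comps = comps, corr = corr, frac = frac)
  })
  sel <- candidates[vapply(candidates, function(g)
    any(vapply(prof, function(pr)
      abs(pr$corr[[g]]) > thr || pr$frac[[g]] > thr, logical(1))),
    logical(1))]
  if (!length(sel)) return(list(profiles = prof, selected = sel))
  ranks <- do.call(cbind, lapply(prof, function(pr)
    cbind(rank(-abs(pr$corr[sel]), ties.method = "average"),
          rank(-pr$frac[sel], ties.method = "average"))))
  final <- round(apply(ranks, 1, function(r) prod(r)^(1 / length(r))), 12)
  names(final) <- sel
  list(profiles = prof, selected = sel, ranks = ranks, final = final,
       ranking = sel[order(final, sel)])
}

# Adjacency-matrix topology computation.
oracle_topology <- function(el) {
  nodes <- sort(unique(c(el$gene_a, el$gene_b)))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(el))) {
    i <- el$gene_a[k]; j <- el$gene_b[k]
    A[i, j] <- 1L; A[j, i] <- 1L
  }
  reach <- (diag(n) + A) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- length(unique(apply(reach, 1, paste, collapse = "")))
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2) 0 else sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  deg <- rowSums(A)
  dx <- dy <- numeric()
  for (k in seq_len(nrow(el))) {
    da <- deg[[el$gene_a[k]]]; db <- deg[[el$gene_b[k]]]
    dx <- c(dx, da, db); dy <- c(dy, db, da)
  }
  assort <- if (length(dx) && stats::sd(dx) > 0) stats::cor(dx, dy) else NA_real_
  list(n_nodes = n, n_edges = nrow(el), n_components = comp,
       avg_clustering = mean(cc), degree_assortativity = assort)
}

# --- fixture builders ------------------------------------------------------

rand_matrix <- function(n_genes, n_arrays, missing = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_arrays), n_genes, n_arrays,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("a%02d", seq_len(n_arrays))))
  if (missing > 0) m[sample(length(m), round(missing * length(m)))] <- NA
  m
}

# Small random DECA instance whose first `n_seeds` genes are guaranteed to
# be significant in >= 3 comparisons, with some genes correlated to seeds.
rand_deca_instance <- function(seed, n_genes = NULL, n_comps = NULL,
                               n_seeds = NULL) {
  set.seed(seed)
  ng <- n_genes %||% sample(5:10, 1)
  nc <- n_comps %||% sample(6:12, 1)
  ns <- n_seeds %||% sample(1:2, 1)
  genes <- sprintf("g%02d", seq_len(ng))
  comps <- sprintf("c%02d", seq_len(nc))
  de <- matrix(rnorm(ng * nc), ng, nc, dimnames = list(genes, comps))
  p <- matrix(runif(ng * nc), ng, nc, dimnames = list(genes, comps))
  seeds <- genes[seq_len(ns)]
  for (s in seeds) {
    nsig <- if (nc %/% 2 <= 3) 3 else sample(3:(nc %/% 2), 1)
    p[s, sample(nc, nsig)] <- runif(nsig, 0, 0.009)
  }
  # plant a couple of seed-correlated genes so ranking is exercised
  followers <- genes[(ns + 1):min(ng, ns + 2)]
  for (i in seq_along(followers)) {
    s <- seeds[(i - 1) %% ns + 1]
    de[followers[i], ] <- de[s, ] + rnorm(nc, sd = 0.2)
    p[followers[i], ] <- pmin(p[s, ] + runif(nc, 0, 0.2), 1)
  }
  # sprinkle missing DE values and missing p-values (substituted on build)
  # in non-seed rows only, so seeds always satisfy the reduction minimum
  nonseed_cells <- as.vector(outer((ns + 1):ng, (seq_len(nc) - 1) * ng, `+`))
  de[sample(nonseed_cells, max(1, length(nonseed_cells) %/% 20))] <- NA
  praw <- p
  praw[sample(nonseed_cells, max(1, length(nonseed_cells) %/% 20))] <- NA
  list(de = de_matrix(de, praw), de_raw = de,
       p_raw = ifelse(is.na(praw), 1, praw), seeds = seeds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_matrix_fixture <- function(m, path) {
  decanet::write_matrix(m, path)
  path
}

fake_deca_result <- function(ranking, final_rank = NULL, seeds = character(),
                             genes = NULL) {
  structure(list(seeds = seeds, genes = genes %||% c(seeds, ranking),
                 selected = ranking,
                 final_rank = final_rank %||%
                   stats::setNames(seq_along(ranking), ranking),
                 ranking = ranking),
            class = "deca_result")
}
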