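# Synthetic-data generators with truth labels. Both algorithms score mean
# pairwise correlation, so planted structure uses a latent-factor
# construction (shared profile + independent Gaussian noise), which gives an
# analytically controllable expected correlation:
# rho = var_latent / (var_latent + noise_sd^2).

#' Parameters for a planted-bicluster expression matrix
#'
#' Defaults describe the scale at which the biclustering recovery claims
#' are evaluated: 200 genes x 60 arrays with a 12-gene module planted over
#' 30 arrays at a within-module correlation of ~0.9
#' (`within_noise_sd = sqrt(1/0.9 - 1)` with unit-variance latent profile).
#'
#' @param n_genes,n_arrays matrix dimensions.
#' @param module_genes,module_arrays size of the planted block.
#' @param within_noise_sd s.d. of the noise added to the shared module
#'   profile.
#' @param background_sd s.d. of the independent background cells.
#' @param rng_seed integer seed; generators are pure functions of their
#'   params.
#' @return list of class `bicluster_sim_params`.
#' @export
bicluster_sim_params <- function(n_genes = 200L, n_arrays = 60L,
                                 module_genes = 12L, module_arrays = 30L,
                                 within_noise_sd = sqrt(1 / 0.9 - 1),
                                 background_sd = 1, rng_seed = 1L) {
  .assert(module_genes <= n_genes, "module_genes exceeds n_genes")
  .assert(module_arrays <= n_arrays, "module_arrays exceeds n_arrays")
  .assert(module_genes >= 2L && n_genes >= 2L, "need >= 2 genes")
  .assert(within_noise_sd >= 0, "within_noise_sd must be >= 0")
  .assert(background_sd > 0, "background_sd must be > 0")
  structure(as.list(environment()), class = "bicluster_sim_params")
}

#' Generate an expression matrix with a planted co-expressed block
#'
#' Module genes share, over the module arrays, a common standard-normal
#' latent profile plus independent `N(0, within_noise_sd^2)` noise; every
#' other cell is independent `N(0, background_sd^2)`. Module gene and array
#' positions are drawn at random. Deterministic given `rng_seed`.
#'
#' @param params a [bicluster_sim_params()].
#' @return list with `matrix` (genes x arrays, no missing values) and
#'   `truth`: `module_genes`, `module_arrays`, and `roles` (named vector,
#'   `"module"` / `"background"`).
#' @export
make_bicluster_matrix <- function(params = bicluster_sim_params()) {
  .assert(inherits(params, "bicluster_sim_params"), "invalid params")
  set.seed(params$rng_seed)
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  arrays <- sprintf("a%03d", seq_len(params$n_arrays))
  m <- matrix(stats::rnorm(params$n_genes * params$n_arrays,
                           sd = params$background_sd),
              params$n_genes, params$n_arrays, dimnames = list(genes, arrays))
  mg <- sort(sample(genes, params$module_genes))
  ma <- sort(sample(arrays, params$module_arrays))
  latent <- stats::rnorm(params$module_arrays)
  m[mg, ma] <- matrix(latent, params$module_genes, params$module_arrays,
                      byrow = TRUE) +
    stats::rnorm(params$module_genes * params$module_arrays,
                 sd = params$within_noise_sd)
  roles <- stats::setNames(ifelse(genes %in% mg, "module", "background"),
                           genes)
  list(matrix = m,
       truth = list(module_genes = mg, module_arrays = ma, roles = roles))
}

#' Parameters for a planted-target DE matrix
#'
#' Defaults describe the scale at which the DECA recovery claims are
#' evaluated: 1000 genes x 80 comparisons, 3 seeds active on 30 shared
#' comparisons, 20 target genes correlated with their seed at rho = 0.8.
#' `sig_effect` is the absolute DE (log2 fold change) magnitude treated as
#' clearly differential; 1 (two-fold) is the field's customary gate.
#'
#' @param n_genes,n_comparisons matrix dimensions.
#' @param n_seeds,n_targets planted seed and target gene counts.
#' @param seed_active_comparisons number of comparisons on which seeds are
#'   significantly differentially expressed (shared by all seeds, as for a
#'   single perturbed pathway).
#' @param target_correlation expected DE correlation between a target and
#'   its seed over the active comparisons, in (0, 1\].
#' @param noise_sd s.d. of null DE values.
#' @param sig_effect minimum |DE| of seed values on active comparisons.
#' @param missing_rate fraction of DE cells set missing (their p-values are
#'   substituted with 1, exercising the load rule).
#' @param rng_seed integer seed.
#' @return list of class `deca_sim_params`.
#' @export
deca_sim_params <- function(n_genes = 1000L, n_comparisons = 80L,
                            n_seeds = 3L, n_targets = 20L,
                            seed_active_comparisons = 30L,
                            target_correlation = 0.8, noise_sd = 1,
                            sig_effect = 1, missing_rate = 0.05,
                            rng_seed = 1L) {
  .assert(n_seeds + n_targets <= n_genes, "n_seeds + n_targets > n_genes")
  .assert(seed_active_comparisons <= n_comparisons,
          "seed_active_comparisons > n_comparisons")
  .assert(target_correlation > 0 && target_correlation <= 1,
          "target_correlation must be in (0, 1]")
  .assert(missing_rate >= 0 && missing_rate < 1,
          "missing_rate must be in [0, 1)")
  structure(as.list(environment()), class = "deca_sim_params")
}

#' Generate a DE matrix with planted seed-correlated targets
#'
#' Seeds get DE values of magnitude >= `sig_effect` with p < 0.01 on the
#' active comparisons and null values (p ~ Uniform(0.05, 1]) elsewhere.
#' Each target copies its seed's active-comparison profile plus Gaussian
#' noise calibrated so the expected correlation is `target_correlation`
#' (noise s.d. = sd(seed profile) * sqrt(1/rho^2 - 1)); a target cell is
#' significant (p < 0.01) wherever its |DE| >= `sig_effect`. Background
#' genes are independent null noise. Missing cells are injected at
#' `missing_rate` (their p-values substituted with 1 by the [de_matrix()]
#' constructor). Deterministic given `rng_seed`.
#'
#' @param params a [deca_sim_params()].
#' @return list with `de` (a [de_matrix()]) and `truth`: `seeds`,
#'   `targets`, `target_seed` (named: which seed each target follows),
#'   `active_comparisons`, and `roles` (`"seed"` / `"target"` /
#'   `"background"`).
#' @export
make_deca_matrix <- function(params = deca_sim_params()) {
  .assert(inherits(params, "deca_sim_params"), "invalid params")
  set.seed(params$rng_seed)
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  comps <- sprintf("c%03d", seq_len(params$n_comparisons))
  nG <- params$n_genes; nC <- params$n_comparisons
  de <- matrix(stats::rnorm(nG * nC, sd = params$noise_sd), nG, nC,
               dimnames = list(genes, comps))
  p <- matrix(stats::runif(nG * nC, 0.05, 1), nG, nC,
              dimnames = list(genes, comps))
  seed_ids <- sample(genes, params$n_seeds)
  target_ids <- sample(setdiff(genes, seed_ids), params$n_targets)
  active <- sort(sample(comps, params$seed_active_comparisons))
  nA <- length(active)
  for (s in seed_ids) {
    a <- stats::rnorm(nA)
    de[s, active] <- sign(a) * (params$sig_effect + abs(a))
    p[s, active] <- stats::runif(nA, 0, 0.01)
  }
  target_seed <- stats::setNames(
    seed_ids[(seq_len(params$n_targets) - 1L) %% params$n_seeds + 1L],
    target_ids)
  rho <- params$target_correlation
  for (t in target_ids) {
    x <- de[target_seed[[t]], active]
    noise_sd <- stats::sd(x) * sqrt(1 / rho^2 - 1)
    v <- x + stats::rnorm(nA, sd = noise_sd)
    de[t, active] <- v
    sig <- abs(v) >= params$sig_effect
    p[t, active] <- ifelse(sig, stats::runif(nA, 0, 0.01),
                           stats::runif(nA, 0.05, 1))
  }
  if (params$missing_rate > 0) {
    nmiss <- round(params$missing_rate * nG * nC)
    miss <- sample.int(nG * nC, nmiss)
    de[miss] <- NA_real_
    p[miss] <- NA_real_  # substituted with 1 by the constructor
  }
  roles <- stats::setNames(rep("background", nG), genes)
  roles[seed_ids] <- "seed"
  roles[target_ids] <- "target"
  list(de = de_matrix(de, p),
       truth = list(seeds = seed_ids, targets = target_ids,
                    target_seed = target_seed,
                    active_comparisons = active, roles = roles))
}

#' Generate a random scored network
#'
#' Erdos-Renyi undirected graph over `n_nodes` labelled nodes with
#' independent edge probability `edge_prob` and uniform integer combined
#' scores in `score_range`. Deterministic given `rng_seed`.
#'
#' @param n_nodes node count.
#' @param edge_prob edge probability in \[0, 1\].
#' @param score_range integer score bounds, default `c(150, 999)`.
#' @param rng_seed integer seed.
#' @return an [edge_list()].
#' @export
make_toy_network <- function(n_nodes, edge_prob, score_range = c(150, 999),
                             rng_seed = 1L) {
  .assert(edge_prob >= 0 && edge_prob <= 1, "edge_prob must be in [0, 1]")
  .assert(n_nodes >= 1, "n_nodes must be >= 1")
  set.seed(rng_seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < edge_prob
  idx <- idx[keep, , drop = FALSE]
  scores <- sample(seq(score_range[1L], score_range[2L]), nrow(idx),
                   replace = TRUE)
  edge_list(nodes[idx[, 1L]], nodes[idx[, 2L]], scores)
}
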