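# Expression-call filtering from UPC scores, missingness filtering, and KNN
# imputation. Boundary conventions are strict on purpose: a gene is called
# expressed only when some UPC score strictly exceeds the threshold, and a
# gene is dropped only when its missing count strictly exceeds the cut-off
# (so at exactly half of 341 arrays, i.e. 170 missing, a gene is kept).

#' Call expressed genes from a UPC score matrix
#'
#' A gene is considered expressed when its UPC (Universal exPression Code)
#' score strictly exceeds `threshold` in at least one array. Genes whose
#' scores are all missing are excluded.
#'
#' @param upc numeric genes x arrays matrix of scores in \[0, 1\] (`NA` =
#'   missing), as from `read_matrix(kind = "upc")`.
#' @param threshold call threshold in \[0, 1\]; default 0.5.
#' @return a [gene_set()] of expressed gene ids (in input row order).
#' @export
call_expressed_genes <- function(upc, threshold = 0.5) {
  .assert(is.matrix(upc) && nrow(upc) >= 1L && ncol(upc) >= 1L,
          "UPC matrix is empty")
  .assert(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  mx <- suppressWarnings(apply(upc, 1L, max, na.rm = TRUE))  # all-NA row -> -Inf
  gene_set("expressed_genes", rownames(upc)[mx > threshold],
           description = sprintf("UPC > %g in at least one array", threshold))
}

#' Drop genes with too many missing values
#'
#' A gene is dropped iff its missing count strictly exceeds the cut-off:
#' either `max_missing` (an absolute count, when given) or
#' `floor(max_missing_fraction * n_columns)`.
#'
#' @param x numeric matrix (genes x columns) or a [de_matrix()]
#'   (missingness judged on the DE values).
#' @param max_missing_fraction fraction of columns, default 0.5 ("more than
#'   half").
#' @param max_missing optional absolute cut-off overriding the fraction.
#' @return list with `matrix` (same type as `x`, offending genes removed)
#'   and `dropped` (character vector of removed gene ids).
#' @export
filter_missing_genes <- function(x, max_missing_fraction = 0.5,
                                 max_missing = NULL) {
  UseMethod("filter_missing_genes")
}

.missing_cutoff <- function(ncol, frac, abs) {
  .assert(is.null(abs) || abs >= 0, "max_missing must be >= 0")
  .assert(frac >= 0 && frac <= 1, "max_missing_fraction must be in [0, 1]")
  if (!is.null(abs)) abs else floor(frac * ncol)
}

#' @export
filter_missing_genes.default <- function(x, max_missing_fraction = 0.5,
                                         max_missing = NULL) {
  .assert(is.matrix(x), "x must be a matrix or de_matrix")
  cutoff <- .missing_cutoff(ncol(x), max_missing_fraction, max_missing)
  nmiss <- rowSums(is.na(x))
  drop <- nmiss > cutoff
  list(matrix = x[!drop, , drop = FALSE], dropped = rownames(x)[drop])
}

#' @export
filter_missing_genes.de_matrix <- function(x, max_missing_fraction = 0.5,
                                           max_missing = NULL) {
  cutoff <- .missing_cutoff(ncol(x$de), max_missing_fraction, max_missing)
  nmiss <- rowSums(is.na(x$de))
  drop <- nmiss > cutoff
  list(matrix = de_matrix(x$de[!drop, , drop = FALSE],
                          x$p[!drop, , drop = FALSE]),
       dropped = rownames(x$de)[drop])
}

#' KNN imputation of missing values
#'
#' Each missing cell (g, c) is replaced by the unweighted mean of the values
#' at column c of the k nearest genes. Distance between genes is the mean
#' squared difference over the columns observed in both (so genes with
#' different missingness remain comparable); candidate neighbours must be
#' observed at column c. With fewer than k eligible neighbours all eligible
#' ones are used; with none, the column mean of observed values is used.
#' Observed cells are returned unchanged.
#'
#' @param x numeric matrix (genes as rows) or a [de_matrix()] (only the DE
#'   values are imputed; p-values are never missing by construction).
#' @param k number of neighbours, default 10.
#' @return fully observed object of the same type as `x`.
#' @export
knn_impute <- function(x, k = 10) UseMethod("knn_impute")

#' @export
knn_impute.default <- function(x, k = 10) {
  .assert(is.matrix(x), "x must be a matrix or de_matrix")
  .assert(k >= 1, "k must be >= 1")
  obs <- !is.na(x)
  bad_col <- which(colSums(obs) == 0L)
  .assert(length(bad_col) == 0L, "column '%s' has no observed values",
          colnames(x)[bad_col[1L]])
  bad_row <- which(rowSums(obs) == 0L)
  .assert(length(bad_row) == 0L, "gene '%s' has no observed values",
          rownames(x)[bad_row[1L]])
  out <- x
  col_means <- colMeans(x, na.rm = TRUE)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  for (i in which(rowSums(!obs) > 0L)) {
    xi <- x[i, ]
    oi <- obs[i, ]
    d2 <- sweep(x, 2L, xi)^2
    shared <- obs & matrix(oi, nrow(x), ncol(x), byrow = TRUE)
    d2[!shared] <- 0
    nsh <- rowSums(shared)
    d <- ifelse(nsh > 0L, rowSums(d2, na.rm = TRUE) / nsh, Inf)
    d[i] <- Inf
    for (cc in which(!oi)) {
      elig <- which(obs[, cc] & is.finite(d))
      if (length(elig) == 0L) {
        out[i, cc] <- col_means[cc]
      } else {
        nb <- elig[order(d[elig], ids[elig])][seq_len(min(k, length(elig)))]
        out[i, cc] <- mean(x[nb, cc])
      }
    }
  }
  out
}

#' @export
knn_impute.de_matrix <- function(x, k = 10) {
  de_matrix(knn_impute(x$de, k = k), x$p)
}
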