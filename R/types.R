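#' Gene set
#'
#' A named collection of unique gene identifiers, as read from one line of a
#' GMT file. Identifiers are opaque strings (typically Entrez Ids).
#'
#' @param name set name.
#' @param genes character vector of member identifiers; duplicates are
#'   collapsed.
#' @param description free-text description (second GMT column).
#' @return An object of class `gene_set` with fields `name`, `description`
#'   and `genes`.
#' @export
gene_set <- function(name, genes, description = "") {
  .assert(is.character(name) && length(name) == 1L, "name must be a single string")
  genes <- unique(as.character(genes))
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Coerce to a vector of gene identifiers
#'
#' Accepts a `gene_set` or a plain character vector.
#'
#' @param x a `gene_set` or character vector.
#' @return character vector of identifiers.
#' @export
as_gene_ids <- function(x) {
  if (inherits(x, "gene_set")) x$genes else as.character(x)
}

#' Differential-expression matrix with paired p-values
#'
#' Pairs a genes x comparisons matrix of DE values (log fold changes,
#' possibly missing) with a p-value matrix of identical shape. Missing
#' p-values are substituted with 1 on construction, so a cell whose
#' evidence is absent can never count as significant.
#'
#' @param de numeric matrix, genes as rows (rownames), comparisons as
#'   columns (colnames); `NA` marks missing values.
#' @param p numeric matrix of p-values with identical dimnames; entries in
#'   \[0, 1\] or `NA` (replaced by 1).
#' @return An object of class `de_matrix` with elements `de` and `p`.
#' @export
de_matrix <- function(de, p) {
  .assert(is.matrix(de) && is.matrix(p), "de and p must be matrices")
  .assert(!is.null(rownames(de)) && !is.null(colnames(de)),
          "de matrix needs gene rownames and comparison colnames")
  .assert(identical(dim(de), dim(p)), "de and p shapes differ")
  .assert(identical(rownames(de), rownames(p)) &&
          identical(colnames(de), colnames(p)),
          "de and p dimnames differ")
  .assert(!anyDuplicated(rownames(de)), "duplicate gene ids")
  .assert(!anyDuplicated(colnames(de)), "duplicate comparison ids")
  p[is.na(p)] <- 1
  .assert(all(p >= 0 & p <= 1), "p-values outside [0, 1]")
  structure(list(de = de, p = p), class = "de_matrix")
}

#' @export
print.de_matrix <- function(x, ...) {
  cat(sprintf("de_matrix: %d genes x %d comparisons (%d missing DE values)\n",
              nrow(x$de), ncol(x$de), sum(is.na(x$de))))
  invisible(x)
}

#' @export
dim.de_matrix <- function(x) dim(x$de)

#' Scored undirected edge list
#'
#' Canonical container for gene-gene association edges. Edges are
#' undirected: each pair is stored with `gene_a` < `gene_b`
#' lexicographically, self-loops are removed, and duplicate pairs are
#' collapsed keeping the maximum score.
#'
#' @param gene_a,gene_b character vectors of endpoint identifiers.
#' @param score integer combined scores in \[0, 1000\], or `NA` when scores
#'   are absent (e.g. after filtering).
#' @return A `data.frame` of class `edge_list` with columns `gene_a`,
#'   `gene_b`, `score`, ordered lexicographically.
#' @export
edge_list <- function(gene_a = character(), gene_b = character(),
                      score = rep(NA_real_, length(gene_a))) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  score <- as.numeric(score)
  .assert(length(gene_a) == length(gene_b) && length(gene_a) == length(score),
          "edge columns have unequal lengths")
  keep <- gene_a != gene_b
  a <- pmin(gene_a[keep], gene_b[keep])
  b <- pmax(gene_a[keep], gene_b[keep])
  s <- score[keep]
  # collapse duplicate undirected pairs, keeping the maximum score
  ord <- order(a, b, -ifelse(is.na(s), -Inf, s))
  a <- a[ord]; b <- b[ord]; s <- s[ord]
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(gene_a = a[first], gene_b = b[first], score = s[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("edge_list: %d edges over %d nodes\n", nrow(x),
              length(unique(c(x$gene_a, x$gene_b)))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
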