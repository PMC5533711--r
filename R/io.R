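# Readers and writers for the external formats: expression/UPC/DE matrix TSVs,
# STRING-style link files, GMT gene sets, and the edgelist output convention.
#
# Matrix TSV dialect: tab-separated, UTF-8, first row holds array/comparison
# ids, first column holds gene ids (an optional corner label is tolerated);
# an empty cell or "NA" means missing.

.split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

# strsplit drops trailing empty fields; matrix rows need them kept (a
# missing value in the last column is written as a trailing tab).
.split_tsv_keep <- function(lines) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  Map(function(p, n) c(p, rep("", n - length(p))), parts, nf)
}

.read_tsv_matrix <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 2L, "matrix file %s needs a header and >=1 gene row", path)
  cells <- .split_tsv_keep(lines)
  header <- cells[[1L]]
  body <- cells[-1L]
  ncol_body <- lengths(body)
  .assert(all(ncol_body == ncol_body[1L]),
          "ragged rows in %s (row %d has %d fields, expected %d)",
          path, which(ncol_body != ncol_body[1L])[1L] + 1L,
          ncol_body[ncol_body != ncol_body[1L]][1L], ncol_body[1L])
  n_data_cols <- ncol_body[1L] - 1L
  .assert(n_data_cols >= 1L, "no data columns in %s", path)
  if (length(header) == n_data_cols + 1L) {
    col_ids <- header[-1L]            # corner label present
  } else if (length(header) == n_data_cols) {
    col_ids <- header                 # headerless corner (R write.table style)
  } else {
    stop(sprintf("header of %s has %d fields but rows have %d",
                 path, length(header), n_data_cols + 1L), call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- gene_ids[duplicated(gene_ids)]
  .assert(length(dup) == 0L, "duplicate gene id(s) in %s: %s",
          path, paste(unique(dup), collapse = ", "))
  .assert(!anyDuplicated(col_ids), "duplicate column id(s) in %s", path)
  raw <- t(vapply(body, function(r) r[-1L], character(n_data_cols)))
  if (n_data_cols == 1L) raw <- matrix(raw, ncol = 1L)
  missing <- raw == "" | raw == "NA"
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!missing & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene '%s', column '%s' in %s",
                 raw[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 col_ids[bad[1L, 2L]], path), call. = FALSE)
  }
  num[missing] <- NA_real_
  dimnames(num) <- list(gene_ids, col_ids)
  num
}

#' Read an expression or UPC matrix from TSV
#'
#' Reads a genes x arrays matrix. The first row holds array ids, the first
#' column gene ids; empty cells and `"NA"` are missing. For `kind = "upc"`
#' all non-missing scores must lie in \[0, 1\].
#'
#' @param path path to a TSV file.
#' @param kind `"expression"` (any real values) or `"upc"` (scores in
#'   \[0, 1\]).
#' @return numeric matrix with gene rownames and array colnames; `NA` marks
#'   missing cells.
#' @export
read_matrix <- function(path, kind = c("expression", "upc")) {
  kind <- match.arg(kind)
  m <- .read_tsv_matrix(path)
  if (kind == "upc") {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("UPC score %g outside [0, 1] at gene '%s', array '%s'",
                   m[bad[1L, 1L], bad[1L, 2L]], rownames(m)[bad[1L, 1L]],
                   colnames(m)[bad[1L, 2L]]), call. = FALSE)
    }
  }
  m
}

#' Write a matrix to TSV
#'
#' Inverse of [read_matrix()]: tab-separated with a `gene_id` corner label,
#' missing values written as empty cells.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  .assert(!is.null(rownames(m)) && !is.null(colnames(m)), "matrix needs dimnames")
  chr <- format(m, trim = TRUE, digits = 15, scientific = FALSE)
  chr[is.na(m)] <- ""
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  if (nrow(m) == 0L) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}

#' Read a DE matrix with its paired p-value matrix
#'
#' Both files use the matrix TSV dialect and must contain the same gene and
#' comparison ids (order-insensitive; the p-value matrix is aligned to the
#' DE matrix on load). Missing p-values are substituted with 1; missing DE
#' values are preserved.
#'
#' @param values_path TSV of DE values (log fold changes).
#' @param pvalues_path TSV of p-values in \[0, 1\].
#' @return a [de_matrix()].
#' @export
read_de_matrix <- function(values_path, pvalues_path) {
  de <- .read_tsv_matrix(values_path)
  p <- .read_tsv_matrix(pvalues_path)
  .assert(setequal(rownames(de), rownames(p)),
          "gene ids differ between %s and %s", values_path, pvalues_path)
  .assert(setequal(colnames(de), colnames(p)),
          "comparison ids differ between %s and %s", values_path, pvalues_path)
  p <- p[rownames(de), colnames(de), drop = FALSE]
  de_matrix(de, p)
}

#' Read a STRING-style link file
#'
#' Parses whitespace-separated `node1 node2 combined_score` lines (a header
#' line whose third token is non-numeric is skipped). Edges with score >=
#' `score_min` are kept (the cut-off is inclusive, STRING's "high
#' confidence" convention), self-loops are removed, and duplicate
#' undirected pairs are collapsed keeping the maximum score. Lines with
#' only two tokens (scoreless edgelists, as written by [write_edgelist()])
#' are kept only when `score_min <= 0`.
#'
#' @param path link file path.
#' @param score_min minimum combined score, default 700.
#' @param mapping optional named character vector mapping input node ids to
#'   gene ids (e.g. protein -> Entrez); edges with an unmapped endpoint are
#'   dropped and the drop count reported via `message()`.
#' @return an [edge_list()].
#' @export
read_string_links <- function(path, score_min = 700, mapping = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "[ \t]+")
  if (length(toks)) {
    t1 <- toks[[1L]]
    if (length(t1) >= 3L && is.na(suppressWarnings(as.numeric(t1[3L])))) {
      toks <- toks[-1L]               # header line
    }
  }
  .assert(length(toks) > 0L, "no parseable data lines in %s", path)
  n <- lengths(toks)
  .assert(all(n >= 2L), "line %d of %s has fewer than 2 fields",
          which(n < 2L)[1L], path)
  a <- vapply(toks, `[[`, character(1L), 1L)
  b <- vapply(toks, `[[`, character(1L), 2L)
  s <- vapply(toks, function(t) {
    if (length(t) >= 3L) suppressWarnings(as.numeric(t[3L])) else NA_real_
  }, numeric(1L))
  if (!is.null(mapping)) {
    .assert(!is.null(names(mapping)), "mapping must be a named character vector")
    ok <- a %in% names(mapping) & b %in% names(mapping)
    if (any(!ok)) message(sum(!ok), " edge(s) dropped: unmapped endpoint")
    a <- unname(mapping[a[ok]]); b <- unname(mapping[b[ok]]); s <- s[ok]
  }
  pass <- ifelse(is.na(s), score_min <= 0, s >= score_min)
  edge_list(a[pass], b[pass], s[pass])
}

#' Read an id mapping file
#'
#' Two tab-separated columns: source id, target id.
#'
#' @param path TSV path.
#' @return named character vector (`names` = source ids).
#' @export
read_id_mapping <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  toks <- .split_tsv(readLines(path, encoding = "UTF-8"))
  toks <- toks[lengths(toks) > 0L]
  .assert(all(lengths(toks) >= 2L), "mapping lines need 2 columns")
  stats::setNames(vapply(toks, `[[`, character(1L), 2L),
                  vapply(toks, `[[`, character(1L), 1L))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: tab-separated `name`, `description`, then members.
#' Duplicate members within a line are collapsed with a warning.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  sets <- vector("list", sum(keep))
  idx <- which(keep)
  for (k in seq_along(idx)) {
    f <- .split_tsv(lines[idx[k]])[[1L]]
    .assert(length(f) >= 3L, "GMT line %d has %d field(s); need >= 3",
            idx[k], length(f))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in gene set '%s' collapsed", f[1L]),
              call. = FALSE)
    }
    sets[[k]] <- gene_set(f[1L], members, description = f[2L])
  }
  stats::setNames(sets, vapply(sets, `[[`, character(1L), "name"))
}

#' Write a network in edgelist format
#'
#' Tab-separated lines `gene_a<TAB>gene_b<TAB>` with an empty third (weight)
#' column, in deterministic lexicographic edge order.
#'
#' @param network an [edge_list()].
#' @param path output path.
#' @export
write_edgelist <- function(network, path) {
  .assert(inherits(network, "edge_list"), "network must be an edge_list")
  ord <- order(network$gene_a, network$gene_b)
  lines <- if (nrow(network)) {
    paste0(network$gene_a[ord], "\t", network$gene_b[ord], "\t")
  } else {
    character()  # paste0 would recycle zero-length columns to ""
  }
  writeLines(lines, path)
  invisible(path)
}
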