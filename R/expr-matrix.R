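#' Coerce to a gene-by-sample expression matrix
#'
#' The canonical in-memory container for expression data in reotools is a
#' numeric matrix with genes in rows (rownames are Entrez gene IDs, stored as
#' the decimal string of the integer ID) and samples in columns. Every
#' rank-based operation in the package works on this layout.
#'
#' Accepted inputs are a numeric matrix with rownames/colnames set, or a data
#' frame / tibble whose first column (conventionally `entrez_id`) holds the
#' gene IDs and whose remaining columns are one numeric column per sample.
#'
#' @param x A matrix or data frame as described above.
#' @return A numeric matrix, genes x samples, with unique integer-valued
#'   rownames and unique colnames.
#' @examples
#' df <- tibble::tibble(entrez_id = c(7157L, 1956L), s1 = c(5, 2), s2 = c(6, 1))
#' as_expr_matrix(df)
#' @export
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!is.numeric(x)) stop("expression matrix must be numeric", call. = FALSE)
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
    }
    m <- x
  } else if (is.data.frame(x)) {
    ids <- x[[1L]]
    m <- as.matrix(x[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("all sample columns must be numeric", call. = FALSE)
    rownames(m) <- as.character(as.integer(ids))
  } else {
    stop("cannot interpret object of class '", class(x)[1L],
         "' as an expression matrix", call. = FALSE)
  }
  validate_expr_matrix(m)
  m
}

validate_expr_matrix <- function(m) {
  if (anyDuplicated(rownames(m)) > 0L) {
    stop("duplicate gene IDs in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(m)) > 0L) {
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(rownames(m)))
  if (anyNA(ids)) stop("gene IDs must be integers (Entrez IDs)", call. = FALSE)
  invisible(m)
}

#' Gene IDs of an expression matrix
#'
#' @param x An expression matrix (see [as_expr_matrix()]).
#' @return Integer vector of Entrez gene IDs, in row order.
#' @export
gene_ids <- function(x) as.integer(rownames(as_expr_matrix(x)))

#' Read a tab-separated expression matrix
#'
#' Reads a TSV with one header line: the first column holds Entrez gene IDs
#' (`genes_in = "rows"`, the layout of GEO series matrices) or sample IDs
#' (`genes_in = "columns"`, in which case the table is transposed on load).
#' Duplicate gene rows are collapsed by their arithmetic mean, consistent with
#' the probe-collapsing rule, and a warning reports the count. Rows containing
#' missing values are dropped (`missing = "drop"`, with a warning) or rejected
#' (`missing = "error"`).
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   treated as comments.
#' @param genes_in Orientation of the file, `"rows"` (default) or `"columns"`.
#' @param missing Policy for rows with missing values: `"drop"` or `"error"`.
#' @return A gene-by-sample numeric matrix (see [as_expr_matrix()]).
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, genes_in = c("rows", "columns"),
                                   missing = c("drop", "error")) {
  genes_in <- match.arg(genes_in)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read.table uniquifies duplicate column names, so check the raw header
  first <- readLines(path, n = 100L)
  first <- first[!startsWith(first, "#")][1L]
  header_ids <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(header_ids) > 0L) {
    stop("duplicate ", if (genes_in == "rows") "sample" else "gene",
         " IDs in header of ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs an ID column and >=1 value column",
                          call. = FALSE)
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(NULL, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !(vals[[j]] %in% c("NA", "", "NaN")) & !is.na(vals[[j]]))
    if (length(bad) > 0L) {
      stop(sprintf("unparseable numeric value %s at row '%s', column '%s' of %s",
                   dQuote(vals[[j]][bad[1L]]), ids[bad[1L]], colnames(vals)[j], path),
           call. = FALSE)
    }
    num[, j] <- v
  }
  if (genes_in == "columns") {
    samples <- ids
    genes <- colnames(vals)
    num <- t(num)
    dimnames(num) <- list(genes, samples)
  } else {
    rownames(num) <- ids
  }
  if (anyDuplicated(colnames(num)) > 0L) {
    stop("duplicate sample IDs in ", path, call. = FALSE)
  }
  na_row <- rowSums(is.na(num)) > 0L
  if (any(na_row)) {
    if (missing == "error") {
      stop(sum(na_row), " gene rows contain missing values in ", path, call. = FALSE)
    }
    warning(sum(na_row), " gene rows with missing values dropped", call. = FALSE)
    num <- num[!na_row, , drop = FALSE]
  }
  num <- collapse_duplicate_genes(num)
  validate_expr_matrix(num)
  num
}

# duplicate gene rows -> arithmetic mean per sample (same rule as probe collapse)
collapse_duplicate_genes <- function(m) {
  ids <- as.character(as.integer(rownames(m)))
  if (anyDuplicated(ids) == 0L) {
    rownames(m) <- ids
    return(m)
  }
  n_dup <- length(ids) - length(unique(ids))
  warning(n_dup, " duplicate gene rows collapsed by arithmetic mean", call. = FALSE)
  g <- factor(ids, levels = unique(ids))
  out <- rowsum(m, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] at `genes_in = "rows"`: first column
#' `entrez_id`, one column per sample, full-precision values so that a
#' write/read round trip is value-exact.
#'
#' @param x An expression matrix (see [as_expr_matrix()]).
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines written before the table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, header_lines = NULL) {
  m <- as_expr_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("entrez_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 2L, format_full_precision)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  writeLines(paste(rownames(m), apply(body, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

format_full_precision <- function(v) {
  sprintf("%.17g", v)
}

#' Collapse a probe-level matrix to gene level
#'
#' Applies the standard microarray annotation rule: probes mapping to zero or
#' to multiple Entrez genes are deleted; the remaining probes are grouped by
#' gene and the gene's expression is the arithmetic mean of its probes, per
#' sample.
#'
#' @param probe_matrix Numeric matrix with probe IDs in rownames, samples in
#'   columns.
#' @param map A probe map as returned by [read_probe_map()]: a tibble with
#'   columns `probe_id` (character) and `entrez_ids` (list of integer
#'   vectors; length 0 = unmapped, length > 1 = ambiguous).
#' @return A gene-by-sample expression matrix.
#' @export
collapse_probes <- function(probe_matrix, map) {
  if (!is.matrix(probe_matrix) || is.null(rownames(probe_matrix))) {
    stop("probe_matrix must be a matrix with probe IDs in rownames", call. = FALSE)
  }
  stopifnot(is.data.frame(map), all(c("probe_id", "entrez_ids") %in% names(map)))
  if (anyDuplicated(map$probe_id) > 0L) {
    stop("duplicate probe IDs in map", call. = FALSE)
  }
  n_target <- lengths(map$entrez_ids)
  keep_map <- map[n_target == 1L, ]
  dropped <- sum(n_target != 1L)
  if (dropped > 0L) {
    message(dropped, " probes mapping to zero or multiple genes deleted")
  }
  idx <- match(rownames(probe_matrix), keep_map$probe_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no probe maps uniquely to a gene", call. = FALSE)
  m <- probe_matrix[keep, , drop = FALSE]
  genes <- vapply(keep_map$entrez_ids[idx[keep]], `[[`, integer(1L), 1L)
  g <- factor(genes)
  out <- rowsum(m, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  validate_expr_matrix(out)
  out
}

#' Read a probe-to-gene annotation table
#'
#' Two-column TSV `probe_id <tab> entrez_ids`, where `entrez_ids` is a
#' comma-separated list of Entrez IDs (empty = unmapped probe).
#'
#' @param path Path to the TSV (a header line `probe_id` is accepted and
#'   skipped).
#' @return Tibble with columns `probe_id` and `entrez_ids` (list column of
#'   integer vectors), suitable for [collapse_probes()].
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) > 0L && startsWith(lines[1L], "probe_id")) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  probe <- vapply(parts, `[[`, character(1L), 1L)
  ids <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) return(integer(0L))
    out <- suppressWarnings(as.integer(strsplit(p[2L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(out)) stop("non-integer Entrez ID for probe ", p[1L], call. = FALSE)
    out
  })
  if (anyDuplicated(probe) > 0L) stop("duplicate probe IDs in ", path, call. = FALSE)
  tibble::tibble(probe_id = probe, entrez_ids = ids)
}

#' Remove genes at or below a noise floor
#'
#' For RNA-seq matrices on a normalized-count scale: a gene is removed when
#' its measurement is at or below `noise_threshold` in at least
#' `sample_fraction` of the samples. Both boundaries are inclusive.
#'
#' @param x Expression matrix (normalized counts).
#' @param noise_threshold Noise floor; default 0.2 normalized counts.
#' @param sample_fraction Fraction of samples at/below the floor that triggers
#'   removal; default 0.75. Must lie in (0, 1].
#' @return The filtered expression matrix.
#' @export
filter_low_expression <- function(x, noise_threshold = 0.2, sample_fraction = 0.75) {
  m <- as_expr_matrix(x)
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]", call. = FALSE)
  }
  frac_low <- rowMeans(m <= noise_threshold)
  drop <- frac_low >= sample_fraction
  if (any(drop)) message(sum(drop), " genes at/below the noise floor removed")
  m[!drop, , drop = FALSE]
}

#' Genes measured by every dataset
#'
#' @param matrices A list of two or more expression matrices.
#' @return Sorted integer vector: the intersection of the gene IDs.
#' @export
common_gene_universe <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  ids <- lapply(matrices, gene_ids)
  out <- sort(Reduce(intersect, ids))
  if (length(out) == 0L) stop("no genes are common to all matrices", call. = FALSE)
  out
}
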