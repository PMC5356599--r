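#' Stable-pair (REO) set objects
#'
#' A `reo_set` is a tibble of canonical gene pairs, one row per pair, with
#' `gene_low < gene_high` (integer Entrez IDs) and a `direction` column:
#' `+1` means the lower-ID gene has the higher expression in the stable
#' ordering, `-1` the opposite. Sets produced by [significant_stable_pairs()]
#' also carry the majority support count `k`, the effective cohort size `n`,
#' the one-sided binomial `p` and the BH-adjusted `fdr`. The tissue/platform
#' label and the gene universe travel as attributes.
#'
#' @param pairs A data frame with at least `gene_low`, `gene_high`,
#'   `direction`.
#' @param label Character label for the cohort/platform the set came from.
#' @param universe Integer vector of all gene IDs evaluated (defaults to the
#'   genes appearing in `pairs`).
#' @return A tibble of class `reo_set`.
#' @export
new_reo_set <- function(pairs, label = NA_character_, universe = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_low", "gene_high", "direction") %in% names(pairs)))
  out <- tibble::as_tibble(pairs)
  out$gene_low <- as.integer(out$gene_low)
  out$gene_high <- as.integer(out$gene_high)
  out$direction <- as.integer(out$direction)
  if (any(out$gene_low >= out$gene_high)) {
    stop("pair keys must be canonical: gene_low < gene_high", call. = FALSE)
  }
  if (!all(out$direction %in% c(-1L, 1L))) {
    stop("direction must be +1 or -1", call. = FALSE)
  }
  if (anyDuplicated(out[c("gene_low", "gene_high")]) > 0L) {
    stop("a pair may appear at most once in a set", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(unique(c(out$gene_low, out$gene_high)))
  }
  structure(out,
            class = c("reo_set", class(tibble::tibble())),
            reo_label = label,
            reo_universe = sort(as.integer(universe)))
}

#' @rdname new_reo_set
#' @param x Object to query.
#' @export
reo_label <- function(x) attr(x, "reo_label", exact = TRUE)

#' @rdname new_reo_set
#' @export
reo_universe <- function(x) attr(x, "reo_universe", exact = TRUE)

#' @export
print.reo_set <- function(x, ...) {
  lbl <- reo_label(x)
  cat("<reo_set", if (!is.na(lbl)) paste0(" '", lbl, "'"), "> ",
      nrow(x), " stable pairs over ", length(reo_universe(x)), " genes\n",
      sep = "")
  NextMethod()
}

#' Read / write stable-pair sets as TSV
#'
#' The interchange format is a tab-separated table with header
#' `gene_low gene_high direction k n p fdr` (`#`-prefixed provenance lines
#' allowed before the header). Write/read round trips are value-exact.
#'
#' @param path File path.
#' @param label,universe Passed to [new_reo_set()] on read; the universe
#'   defaults to the genes present in the file.
#' @return `read_pair_set()` returns a `reo_set`; `write_pair_set()` returns
#'   `path` invisibly.
#' @export
read_pair_set <- function(path, label = NA_character_, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  new_reo_set(df, label = label, universe = universe)
}

#' @rdname read_pair_set
#' @param x A `reo_set`.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @export
write_pair_set <- function(x, path, header_lines = NULL) {
  stopifnot(inherits(x, "reo_set"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  cols <- intersect(c("gene_low", "gene_high", "direction", "k", "n", "p", "fdr"),
                    names(x))
  df <- as.data.frame(x)[cols]
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], format_full_precision)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}

pair_key <- function(x) paste(x$gene_low, x$gene_high, sep = ":")
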