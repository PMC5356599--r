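#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name, description,
#' member...`. Members are parsed as Entrez integers and deduplicated within
#' each set.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of integer
#'   vectors), `names` (named character vector of descriptions) and
#'   `universe` (the union of all members).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path, call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  descs <- vapply(parts, `[[`, character(1L), 2L)
  members <- lapply(parts, function(p) {
    tok <- p[-(1:2)]
    tok <- tok[nzchar(tok)]
    out <- suppressWarnings(as.integer(tok))
    if (anyNA(out)) {
      stop("non-integer gene member '", tok[which(is.na(out))[1L]],
           "' in set ", p[1L], call. = FALSE)
    }
    unique(out)
  })
  if (any(lengths(members) == 0L)) {
    stop("empty member list in set ", ids[which(lengths(members) == 0L)[1L]],
         call. = FALSE)
  }
  new_gene_set_collection(stats::setNames(members, ids), stats::setNames(descs, ids))
}

#' Construct a gene-set collection from named member lists
#'
#' @param sets Named list of integer vectors (Entrez IDs), one per set.
#' @param names Optional named character vector of set descriptions.
#' @return A `gene_set_collection`; its universe is the union of all
#'   members.
#' @export
new_gene_set_collection <- function(sets, names = NULL) {
  if (is.null(names)) names <- stats::setNames(names(sets), names(sets))
  stopifnot(!is.null(names(sets)), anyDuplicated(names(sets)) == 0L)
  structure(
    list(sets = sets, names = names,
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets covering ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection as GMT
#'
#' @param x A `gene_set_collection` (see [read_gene_sets()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$names[[id]], x$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
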