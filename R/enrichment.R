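#' Per-sample pathway enrichment of up- and down-regulated genes
#'
#' For one sample's up- and down-regulated DEG lists, each pathway is tested
#' for over-representation with the hypergeometric upper tail: with `N`
#' universe genes of which `K` belong to the pathway and a DEG list of size
#' `nd` (both restricted to the universe), the p-value is `P(X >= x)` for
#' the observed overlap `x`. P-values are BH-adjusted across pathways
#' separately within each direction.
#'
#' By default the universe is the intersection of the measured genes with
#' the union of all pathway members (`restrict_to_sets = TRUE`), the common
#' convention when testing against a pathway catalogue; set it to `FALSE`
#' to use all measured genes. DEG-list members outside the universe are
#' dropped (and counted in a message).
#'
#' @param deg_up,deg_down Integer vectors of Entrez IDs called up- and
#'   down-regulated in the sample (either may be empty).
#' @param sets A `gene_set_collection` (see [read_gene_sets()]).
#' @param universe Integer vector of the genes measured in the sample.
#' @param restrict_to_sets Restrict the universe to pathway-covered genes
#'   (default `TRUE`).
#' @return Tibble with one row per pathway and direction: `pathway_id`,
#'   `pathway_name`, `direction`, `x`, `K`, `nd`, `N`, `p`, `fdr`.
#' @export
enrich_sample <- function(deg_up, deg_down, sets, universe,
                          restrict_to_sets = TRUE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.integer(universe))
  if (restrict_to_sets) universe <- intersect(universe, sets$universe)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  one_direction <- function(degs, direction) {
    degs <- unique(as.integer(degs))
    outside <- setdiff(degs, universe)
    if (length(outside) > 0L) {
      message(length(outside), " ", direction,
              "-regulated genes outside the universe dropped")
      degs <- intersect(degs, universe)
    }
    K <- unname(vapply(sets$sets, function(s) length(intersect(s, universe)),
                       integer(1L)))
    x <- unname(vapply(sets$sets, function(s) length(intersect(s, degs)),
                       integer(1L)))
    nd <- length(degs)
    N <- length(universe)
    p <- stats::phyper(x - 1L, K, N - K, nd, lower.tail = FALSE)
    tibble::tibble(
      pathway_id = names(sets$sets),
      pathway_name = unname(sets$names[names(sets$sets)]),
      direction = direction, x = x, K = K, nd = nd, N = N,
      p = p, fdr = bh_adjust(p)
    )
  }
  dplyr::bind_rows(one_direction(deg_up, "up"), one_direction(deg_down, "down"))
}

#' Cohort coverage of per-sample pathway enrichment
#'
#' Summarises a cohort of per-sample enrichment tables: for each pathway and
#' direction, the fraction of samples significant at `fdr < fdr_cut` and at
#' `p < p_cut`. Pathways can be filtered to those significant in at least
#' `min_fraction` of the samples by either rule.
#'
#' @param per_sample_rows A list of [enrich_sample()] tibbles, one per
#'   sample (optionally named by sample ID).
#' @param fdr_cut FDR significance threshold; default 0.1.
#' @param p_cut Looser raw-p threshold; default 0.05.
#' @param min_fraction Report filter: keep pathways whose best coverage
#'   fraction reaches this value (default 0 = keep everything).
#' @return Tibble with columns `pathway_id`, `pathway_name`, `direction`,
#'   `n_samples`, `frac_fdr`, `frac_p`.
#' @export
cohort_coverage <- function(per_sample_rows, fdr_cut = 0.1, p_cut = 0.05,
                            min_fraction = 0) {
  stopifnot(is.list(per_sample_rows), length(per_sample_rows) >= 1L)
  all_rows <- dplyr::bind_rows(per_sample_rows, .id = "sample")
  out <- all_rows |>
    dplyr::group_by(.data$pathway_id, .data$pathway_name, .data$direction) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      frac_fdr = mean(.data$fdr < fdr_cut),
      frac_p = mean(.data$p < p_cut),
      .groups = "drop"
    )
  out[pmax(out$frac_fdr, out$frac_p) >= min_fraction, ]
}
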