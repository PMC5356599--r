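#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an overlap-statistics object
#'
#' @param x A `reo_overlap` from [overlap_stats()].
#' @param ... Unused.
#' @return One-row tibble with all overlap fields.
#' @export
tidy.reo_overlap <- function(x, ...) {
  tibble::tibble(
    label1 = x$label1, label2 = x$label2, L1 = x$L1, L2 = x$L2,
    n_overlap = x$n_overlap, k_same = x$k_same,
    pog12 = x$pog12, pog21 = x$pog21,
    consistency = x$consistency, p = x$p
  )
}

#' @rdname tidy.reo_overlap
#' @export
glance.reo_overlap <- function(x, ...) tidy(x, ...)

#' Tidy a rank-difference comparison
#'
#' @param x A `rank_diff_test` from [rank_difference_comparison()].
#' @param ... Unused.
#' @return `tidy()`: the per-pair rank differences (`group`, `rank_diff`);
#'   `glance()`: a one-row summary with the medians and the Wilcoxon p.
#' @export
tidy.rank_diff_test <- function(x, ...) x$rank_diffs

#' @rdname tidy.rank_diff_test
#' @export
glance.rank_diff_test <- function(x, ...) {
  tibble::tibble(
    median_consistent = x$median_consistent,
    median_inconsistent = x$median_inconsistent,
    n_consistent = x$n_consistent, n_inconsistent = x$n_inconsistent,
    statistic = x$statistic, p = x$p
  )
}

#' Summaries of per-sample DEG results and population DEG sets
#'
#' @param x A `sample_deg_result` or `population_deg_set`.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @export
glance.sample_deg_result <- function(x, ...) {
  calls <- deg_calls(x)
  tibble::tibble(
    n_tested = nrow(x),
    n_candidates = sum(x$stage != "not-candidate"),
    n_degs = nrow(calls),
    n_up = sum(calls$direction == "up"),
    n_down = sum(calls$direction == "down"),
    fdr_threshold = attr(x, "fdr_threshold"),
    filter = attr(x, "filter")
  )
}

#' @rdname glance.sample_deg_result
#' @export
glance.population_deg_set <- function(x, ...) {
  tibble::tibble(
    n_deg_1 = attr(x, "n_deg_1"), n_deg_2 = attr(x, "n_deg_2"),
    n_overlap = attr(x, "n_overlap"), k_same = attr(x, "k_same"),
    concordance = attr(x, "concordance"),
    concordance_p = attr(x, "concordance_p"),
    n_population = nrow(x)
  )
}
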