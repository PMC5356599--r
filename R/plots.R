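#' Plot the stability profile of a stable-pair set
#'
#' Histogram of the per-pair support fraction `k / n` — how uniformly the
#' majority ordering is seen across the cohort.
#'
#' @param object A `reo_set` with `k` and `n` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_set <- function(object, ...) {
  stopifnot(all(c("k", "n") %in% names(object)))
  df <- tibble::tibble(support = object$k / object$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "majority-ordering support (k / n)", y = "gene pairs",
                  title = reo_label(object)) +
    ggplot2::theme_minimal()
}

#' Plot a subsampling saturation curve
#'
#' Mean (and replicate spread of the) fraction of the full-cohort stable
#' set recovered at each subsample size.
#'
#' @param object A `reo_saturation` tibble from
#'   [stability_saturation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_saturation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$recovery)) +
    ggplot2::geom_jitter(width = 0.3, height = 0, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "firebrick") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "firebrick") +
    ggplot2::labs(x = "subsample size (samples)",
                  y = "fraction of full-cohort stable pairs recovered") +
    ggplot2::theme_minimal()
}

#' Plot per-pair rank differences by cross-platform consistency
#'
#' @param object A `rank_diff_test` from [rank_difference_comparison()].
#' @param ... Unused.
#' @return A ggplot object (boxplot on a log10 scale).
#' @export
autoplot.rank_diff_test <- function(object, ...) {
  ggplot2::ggplot(object$rank_diffs,
                  ggplot2::aes(x = .data$group, y = .data$rank_diff)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "within-sample rank difference") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of one sample's DEG calls
#'
#' Reversal-proportion difference (up-supporting minus down-supporting)
#' against -log10 Fisher p, coloured by call stage.
#'
#' @param object A `sample_deg_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_deg_result <- function(object, ...) {
  df <- tibble::tibble(
    delta = ifelse(object$n_greater > 0, object$a / object$n_greater, 0) -
      ifelse(object$n_lesser > 0, object$c / object$n_lesser, 0),
    logp = -log10(pmax(object$p, .Machine$double.xmin)),
    stage = object$stage
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$logp,
                                   colour = .data$stage)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::labs(x = "reversal-proportion difference (up - down support)",
                  y = expression(-log[10] ~ "Fisher p")) +
    ggplot2::theme_minimal()
}

#' Tile plot of cohort pathway coverage
#'
#' @param object A [cohort_coverage()] tibble.
#' @param ... Unused.
#' @return A ggplot object: pathways x direction, fill = fraction of
#'   samples significant at the FDR threshold.
#' @export
plot_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$direction,
                                       y = .data$pathway_id,
                                       fill = .data$frac_fdr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "DEG direction", y = NULL,
                  fill = "fraction of\nsamples (FDR)") +
    ggplot2::theme_minimal()
}
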