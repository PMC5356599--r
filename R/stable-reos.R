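#' Count the ordering of every gene pair across samples
#'
#' For every canonical gene pair (gene_low < gene_high by Entrez ID) counts,
#' over the samples of a cohort, how often the lower-ID gene is strictly
#' above the higher-ID gene, how often strictly below, and how often the two
#' values tie. The three counts always sum to the number of samples.
#'
#' Counting is done in gene-index tiles so that working memory stays bounded
#' at roughly `block_size^2` doubles regardless of the total number of pairs.
#'
#' @param x Expression matrix (see [as_expr_matrix()]), >= 2 genes.
#' @param block_size Tile width for the blocked pair scan.
#' @return Tibble with columns `gene_low`, `gene_high`,
#'   `n_low_gt_high`, `n_high_gt_low`, `n_ties`, ordered by key.
#' @export
pair_direction_counts <- function(x, block_size = 512L) {
  m <- as_expr_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  ids <- as.integer(rownames(m))
  ord <- order(ids)
  m <- m[ord, , drop = FALSE]
  ids <- ids[ord]
  G <- nrow(m)
  n_samp <- ncol(m)
  starts <- seq(1L, G, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1L, G))
  acc <- vector("list", length(blocks) * (length(blocks) + 1L) / 2L)
  slot <- 0L
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      I <- blocks[[bi]]; J <- blocks[[bj]]
      gt <- matrix(0L, length(I), length(J))
      lt <- matrix(0L, length(I), length(J))
      for (s in seq_len(n_samp)) {
        d <- outer(m[I, s], m[J, s], "-")
        gt <- gt + (d > 0)
        lt <- lt + (d < 0)
      }
      if (bi == bj) {
        keep <- which(upper.tri(gt), arr.ind = TRUE)
      } else {
        keep <- as.matrix(expand.grid(row = seq_along(I), col = seq_along(J),
                                      KEEP.OUT.ATTRS = FALSE))
      }
      slot <- slot + 1L
      acc[[slot]] <- tibble::tibble(
        gene_low = ids[I[keep[, 1L]]],
        gene_high = ids[J[keep[, 2L]]],
        n_low_gt_high = gt[keep],
        n_high_gt_low = lt[keep]
      )
    }
  }
  out <- dplyr::bind_rows(acc)
  out$n_ties <- n_samp - out$n_low_gt_high - out$n_high_gt_low
  dplyr::arrange(out, .data$gene_low, .data$gene_high)
}

#' One-sided binomial stability p-value
#'
#' Probability of observing at least `k` of `n` cohort samples with a given
#' ordering when each sample shows it independently with probability `p0`:
#' `P(X >= k)` for `X ~ Binomial(n, p0)`. Computed with the upper-tail
#' binomial CDF, which is numerically stable for large `n` (no subtraction of
#' near-unity terms).
#'
#' @param k Number of samples showing the ordering (vectorised).
#' @param n Effective cohort size (vectorised).
#' @param p0 Chance probability of the ordering in one sample; default 0.5.
#' @return Numeric vector of p-values in (0, 1].
#' @export
binomial_stability_pvalue <- function(k, n, p0 = 0.5) {
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input
#' and clipped to 1.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# shared: counts table -> majority direction/k/n under a tie policy
majority_stats <- function(counts, n_samples, tie_policy = c("exclude", "denominator")) {
  tie_policy <- match.arg(tie_policy)
  direction <- ifelse(counts$n_low_gt_high >= counts$n_high_gt_low, 1L, -1L)
  k <- pmax(counts$n_low_gt_high, counts$n_high_gt_low)
  n <- if (tie_policy == "exclude") n_samples - counts$n_ties
       else rep.int(n_samples, nrow(counts))
  tibble::tibble(gene_low = counts$gene_low, gene_high = counts$gene_high,
                 direction = direction, k = k, n = n)
}

#' Significantly stable gene-pair orderings in a normal cohort
#'
#' For every canonical gene pair the majority ordering across the cohort is
#' tested one-sidedly against chance (`p0 = 0.5`) with
#' [binomial_stability_pvalue()]; p-values are BH-adjusted over *all*
#' evaluated pairs and pairs with `fdr < fdr_threshold` are retained.
#'
#' Within-sample ties support no ordering: under the default
#' `tie_policy = "exclude"` a tied sample is removed from that pair's
#' binomial denominator; `"denominator"` keeps the total sample count as `n`.
#' Pairs tied in every sample (`n = 0`) are skipped.
#'
#' @param x Expression matrix of the normal cohort.
#' @param fdr_threshold Retention threshold on the BH-adjusted p; default 0.01.
#' @param p0 Chance probability of one ordering per sample; default 0.5.
#' @param tie_policy `"exclude"` (default) or `"denominator"`; see Details.
#' @param label Optional cohort/platform label stored on the result.
#' @param block_size Passed to [pair_direction_counts()].
#' @return A [new_reo_set()] tibble with columns `gene_low`, `gene_high`,
#'   `direction`, `k`, `n`, `p`, `fdr`; the universe attribute holds every
#'   gene of `x`.
#' @examples
#' cohort <- generate_normal_cohort(G = 30, n = 25, seed = 1)
#' significant_stable_pairs(cohort$matrix, label = "demo")
#' @export
significant_stable_pairs <- function(x, fdr_threshold = 0.01, p0 = 0.5,
                                     tie_policy = c("exclude", "denominator"),
                                     label = NA_character_, block_size = 512L) {
  m <- as_expr_matrix(x)
  counts <- pair_direction_counts(m, block_size = block_size)
  stats_tbl <- majority_stats(counts, ncol(m), tie_policy)
  skip <- stats_tbl$n == 0L
  if (any(skip)) {
    message(sum(skip), " all-tie pairs skipped")
    stats_tbl <- stats_tbl[!skip, ]
  }
  stats_tbl$p <- binomial_stability_pvalue(stats_tbl$k, stats_tbl$n, p0)
  stats_tbl$fdr <- bh_adjust(stats_tbl$p)
  keep <- stats_tbl$fdr < fdr_threshold
  new_reo_set(stats_tbl[keep, ], label = label, universe = gene_ids(m))
}

#' Highly stable pairs by fixed cohort fraction
#'
#' The legacy selection mode: a pair is kept when its majority ordering is
#' seen in at least `min_fraction` of *all* cohort samples (ties count
#' against stability because the denominator is the total sample count).
#' Binomial `p`/`fdr` columns are still populated for reference.
#'
#' @inheritParams significant_stable_pairs
#' @param min_fraction Minimum fraction of samples showing the majority
#'   ordering; default 0.99.
#' @return A [new_reo_set()] tibble, as for [significant_stable_pairs()].
#' @export
highly_stable_pairs <- function(x, min_fraction = 0.99, p0 = 0.5,
                                tie_policy = c("exclude", "denominator"),
                                label = NA_character_, block_size = 512L) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  }
  m <- as_expr_matrix(x)
  counts <- pair_direction_counts(m, block_size = block_size)
  stats_tbl <- majority_stats(counts, ncol(m), tie_policy)
  stats_tbl <- stats_tbl[stats_tbl$n > 0L, ]
  stats_tbl$p <- binomial_stability_pvalue(stats_tbl$k, stats_tbl$n, p0)
  stats_tbl$fdr <- bh_adjust(stats_tbl$p)
  keep <- stats_tbl$k / ncol(m) >= min_fraction
  new_reo_set(stats_tbl[keep, ], label = label, universe = gene_ids(m))
}

#' Recovery of the full-cohort stable set from subsamples
#'
#' Measures how quickly the stable-pair catalogue saturates with cohort
#' size: for each requested size, samples are drawn without replacement
#' `n_reps` times, the stable set is recomputed on the subset, and the
#' fraction of the full-cohort set recovered (same pair key *and* same
#' direction) is recorded. Deterministic for a fixed `seed`.
#'
#' @inheritParams significant_stable_pairs
#' @param subsample_sizes Integer vector of cohort sizes to probe (each >= 2,
#'   <= the cohort size).
#' @param n_reps Subsample replicates per size; default 20.
#' @param seed Integer seed controlling all subsampling.
#' @return Tibble with one row per (size, replicate): columns `size`, `rep`,
#'   `recovery`, plus the full-set size as attribute `n_full_pairs`.
#' @export
stability_saturation_curve <- function(x, subsample_sizes, n_reps = 20L, seed,
                                       fdr_threshold = 0.01, p0 = 0.5,
                                       tie_policy = c("exclude", "denominator")) {
  m <- as_expr_matrix(x)
  tie_policy <- match.arg(tie_policy)
  if (any(subsample_sizes < 2L)) stop("subsample sizes must be >= 2", call. = FALSE)
  if (max(subsample_sizes) > ncol(m)) {
    stop("subsample size exceeds cohort size", call. = FALSE)
  }
  full <- suppressMessages(
    significant_stable_pairs(m, fdr_threshold = fdr_threshold, p0 = p0,
                             tie_policy = tie_policy)
  )
  full_keys <- paste(pair_key(full), full$direction)
  grid <- tidyr::expand_grid(size = as.integer(subsample_sizes),
                             rep = seq_len(n_reps))
  withr::with_seed(seed, {
    grid$recovery <- purrr::pmap_dbl(grid, function(size, rep) {
      cols <- sample.int(ncol(m), size)
      sub <- suppressMessages(
        significant_stable_pairs(m[, cols, drop = FALSE],
                                 fdr_threshold = fdr_threshold, p0 = p0,
                                 tie_policy = tie_policy)
      )
      if (length(full_keys) == 0L) return(NA_real_)
      mean(full_keys %in% paste(pair_key(sub), sub$direction))
    })
  })
  structure(
    dplyr::as_tibble(grid),
    n_full_pairs = nrow(full),
    class = c("reo_saturation", class(tibble::tibble()))
  )
}
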