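#' Overlap and concordance of two stable-pair sets
#'
#' Before comparison both sets are restricted to pairs whose genes lie in
#' the intersection of the two gene universes, so that the POG denominators
#' refer to pairs both platforms could have detected. Reported quantities:
#' list sizes `L1`/`L2` (post-restriction), the number of overlapping pair
#' keys `n_overlap`, the number `k_same` agreeing in direction, the POG
#' scores `pog12 = k_same / L1` and `pog21 = k_same / L2`, the consistency
#' `k_same / n_overlap`, and a one-sided binomial p-value for the
#' consistency under a 0.5 chance model of direction agreement.
#'
#' @param set1,set2 `reo_set` objects (see [new_reo_set()]).
#' @return An object of class `reo_overlap` (a list with the fields above
#'   plus the two labels). Use [generics::tidy()] for a one-row tibble.
#' @examples
#' a <- new_reo_set(data.frame(gene_low = 1:3, gene_high = 4:6,
#'                             direction = c(1L, 1L, -1L)), label = "a")
#' b <- new_reo_set(data.frame(gene_low = 1:2, gene_high = 4:5,
#'                             direction = c(1L, -1L)), label = "b",
#'                  universe = 1:6)
#' overlap_stats(a, b)
#' @export
overlap_stats <- function(set1, set2) {
  stopifnot(inherits(set1, "reo_set"), inherits(set2, "reo_set"))
  shared <- intersect(reo_universe(set1), reo_universe(set2))
  r1 <- restrict_to_universe(set1, shared)
  r2 <- restrict_to_universe(set2, shared)
  ov <- dplyr::inner_join(
    r1[c("gene_low", "gene_high", "direction")],
    r2[c("gene_low", "gene_high", "direction")],
    by = c("gene_low", "gene_high"), suffix = c("_1", "_2")
  )
  n_overlap <- nrow(ov)
  k_same <- sum(ov$direction_1 == ov$direction_2)
  if (n_overlap == 0L) {
    message("no overlapping pairs; consistency undefined")
    consistency <- NA_real_
    p <- 1
  } else {
    consistency <- k_same / n_overlap
    p <- binomial_stability_pvalue(k_same, n_overlap, 0.5)
  }
  structure(
    list(label1 = reo_label(set1), label2 = reo_label(set2),
         L1 = nrow(r1), L2 = nrow(r2),
         n_overlap = n_overlap, k_same = k_same,
         pog12 = if (nrow(r1) > 0L) k_same / nrow(r1) else NA_real_,
         pog21 = if (nrow(r2) > 0L) k_same / nrow(r2) else NA_real_,
         consistency = consistency, p = p),
    class = "reo_overlap"
  )
}

restrict_to_universe <- function(set, universe) {
  keep <- set$gene_low %in% universe & set$gene_high %in% universe
  out <- set[keep, ]
  attr(out, "reo_universe") <- as.integer(sort(universe))
  out
}

#' @export
print.reo_overlap <- function(x, ...) {
  cat("<reo_overlap> ", x$label1, " vs ", x$label2, "\n", sep = "")
  cat(sprintf("  L1 = %d, L2 = %d, overlap = %d, same direction = %d\n",
              x$L1, x$L2, x$n_overlap, x$k_same))
  cat(sprintf("  POG12 = %.4f, POG21 = %.4f, consistency = %.4f, p = %.3g\n",
              x$pog12, x$pog21, x$consistency, x$p))
  invisible(x)
}

#' Binomial significance of a concordance score
#'
#' Probability of at least `k` of `n` overlapping pairs agreeing in
#' direction when agreement is a fair coin per pair.
#'
#' @param k Number of direction-concordant pairs.
#' @param n Number of overlapping pairs.
#' @return One-sided binomial p-value.
#' @export
concordance_significance <- function(k, n) {
  binomial_stability_pvalue(k, n, p0 = 0.5)
}

#' Pairs stably ordered the same way in every input set
#'
#' Restricts all sets to the shared gene universe, then keeps the pairs
#' present in *every* set with an identical direction. Per-source support is
#' carried along as columns suffixed with each source label
#' (`k_<label>`, `n_<label>`, `p_<label>`, `fdr_<label>` where available).
#'
#' @param sets List of two or more `reo_set` objects.
#' @param label Label for the resulting set; defaults to the source labels
#'   joined by `"+"`.
#' @return A `reo_set` on the intersected universe (possibly empty).
#' @export
intersect_consistent <- function(sets, label = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2L,
            all(vapply(sets, inherits, logical(1L), "reo_set")))
  labels <- vapply(seq_along(sets), function(i) {
    l <- reo_label(sets[[i]])
    if (is.na(l)) paste0("set", i) else l
  }, character(1L))
  if (anyDuplicated(labels) > 0L) labels <- make.unique(labels, sep = "_")
  shared <- sort(Reduce(intersect, lapply(sets, reo_universe)))
  tbls <- purrr::map2(sets, labels, function(s, lbl) {
    s <- restrict_to_universe(s, shared)
    keep <- intersect(c("gene_low", "gene_high", "direction", "k", "n", "p", "fdr"),
                      names(s))
    out <- tibble::as_tibble(s)[keep]
    extra <- setdiff(keep, c("gene_low", "gene_high", "direction"))
    names(out)[match(extra, names(out))] <- paste(extra, lbl, sep = "_")
    out
  })
  core <- purrr::reduce(tbls, function(a, b) {
    dplyr::inner_join(a, b, by = c("gene_low", "gene_high", "direction"))
  })
  if (nrow(core) == 0L) message("no consistently stable pairs across the sets")
  new_reo_set(core, label = label %||% paste(labels, collapse = "+"),
              universe = shared)
}

#' Rank differences of consistent vs inconsistent pairs
#'
#' Computes, for each gene pair, the within-sample rank difference in a
#' reference expression matrix — ranks ascending over genes within each
#' sample, average rank for ties — summarised over samples by the mean
#' (default) or the median. The two collections of per-pair rank differences
#' (cross-platform consistent vs inconsistent pairs) are compared with a
#' two-sided Wilcoxon rank-sum test: exact when the combined size is <= 30,
#' otherwise the normal approximation with continuity correction.
#'
#' @param consistent A `reo_set` (or data frame of pair keys) of pairs whose
#'   orderings agree across platforms.
#' @param inconsistent A data frame of pair keys (`gene_low`, `gene_high`)
#'   whose orderings disagree.
#' @param reference Expression matrix containing every involved gene.
#' @param per_pair Summary of the per-sample rank differences: `"mean"`
#'   (default) or `"median"`.
#' @return Object of class `rank_diff_test`: medians of both groups, group
#'   sizes, and the Wilcoxon p-value. [generics::tidy()] gives the per-pair
#'   rank differences; [generics::glance()] the one-row summary.
#' @export
rank_difference_comparison <- function(consistent, inconsistent, reference,
                                       per_pair = c("mean", "median")) {
  per_pair <- match.arg(per_pair)
  if (nrow(consistent) == 0L || nrow(inconsistent) == 0L) {
    stop("both pair collections must be non-empty", call. = FALSE)
  }
  m <- as_expr_matrix(reference)
  ranks <- apply(m, 2L, rank)
  rd <- function(pairs) {
    i <- match(as.character(pairs$gene_low), rownames(m))
    j <- match(as.character(pairs$gene_high), rownames(m))
    if (anyNA(i) || anyNA(j)) {
      stop("reference matrix does not contain all pair genes", call. = FALSE)
    }
    diffs <- abs(ranks[i, , drop = FALSE] - ranks[j, , drop = FALSE])
    if (per_pair == "mean") rowMeans(diffs)
    else apply(diffs, 1L, stats::median)
  }
  d_cons <- rd(consistent)
  d_incons <- rd(inconsistent)
  n_tot <- length(d_cons) + length(d_incons)
  r_all <- rank(c(d_cons, d_incons))
  w <- sum(r_all[seq_along(d_cons)])
  if (diff(range(c(d_cons, d_incons))) == 0) {
    p <- 1
  } else if (n_tot <= 30L) {
    # ties-safe exact two-sided p by dynamic programming over rank sums
    p <- rank_sum_exact_p(r_all, length(d_cons))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d_cons, d_incons, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value
    )
  }
  structure(
    list(median_consistent = stats::median(d_cons),
         median_inconsistent = stats::median(d_incons),
         n_consistent = length(d_cons), n_inconsistent = length(d_incons),
         statistic = w - length(d_cons) * (length(d_cons) + 1) / 2, p = p,
         rank_diffs = tibble::tibble(
           group = rep(c("consistent", "inconsistent"),
                       c(length(d_cons), length(d_incons))),
           rank_diff = c(d_cons, d_incons))),
    class = "rank_diff_test"
  )
}

# Exact permutation null of the rank sum of the first group, with average
# ranks for ties. Doubled ranks keep sums integral; the distribution of
# (group-1 rank sum) over all C(n, nx) assignments is built by DP, and the
# two-sided p is min(1, 2 * min(lower tail, upper tail)).
rank_sum_exact_p <- function(r_all, nx) {
  r2 <- as.integer(round(2 * r_all))
  n <- length(r2)
  max_s <- sum(r2)
  # f[j+1, s+1] = number of j-subsets seen so far with doubled-rank sum s
  f <- matrix(0, nx + 1L, max_s + 1L)
  f[1L, 1L] <- 1
  for (ri in r2) {
    jmax <- min(nx, n)
    for (j in rev(seq_len(jmax))) {
      nz <- which(f[j, ] > 0)
      if (length(nz) > 0L) {
        f[j + 1L, nz + ri] <- f[j + 1L, nz + ri] + f[j, nz]
      }
    }
  }
  dist <- f[nx + 1L, ]
  total <- sum(dist)
  w2 <- sum(r2[seq_len(nx)])
  lower <- sum(dist[seq_len(w2 + 1L)]) / total
  upper <- sum(dist[(w2 + 1L):(max_s + 1L)]) / total
  min(1, 2 * min(lower, upper))
}

#' @export
print.rank_diff_test <- function(x, ...) {
  cat("<rank_diff_test> Wilcoxon rank-sum, two-sided\n")
  cat(sprintf("  median rank difference: consistent = %.1f (n=%d), inconsistent = %.1f (n=%d)\n",
              x$median_consistent, x$n_consistent,
              x$median_inconsistent, x$n_inconsistent))
  cat(sprintf("  p = %.3g\n", x$p))
  invisible(x)
}
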