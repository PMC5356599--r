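#' Index stable pairs by gene
#'
#' Reshapes a stable-pair set into a per-gene partner index: for each gene A
#' the partners that sit *above* it in the stable normal ordering
#' (greater-in-normal, G_A) and those that sit *below* it (lesser-in-normal,
#' L_A). Every pair is indexed under both of its genes with mirrored
#' orientation.
#'
#' @param stable A `reo_set` with canonical keys and directions.
#' @return Object of class `gene_pair_index`: a directed edge table
#'   (`gene`, `partner`, `partner_greater`) plus the gene list.
#' @export
build_pair_index <- function(stable) {
  stopifnot(inherits(stable, "reo_set"))
  lo <- stable$gene_low; hi <- stable$gene_high; dir <- stable$direction
  # direction +1: gene_low above gene_high in the normal ordering
  edges <- tibble::tibble(
    gene = c(lo, hi),
    partner = c(hi, lo),
    partner_greater = c(dir == -1L, dir == 1L)
  )
  structure(
    list(edges = edges, genes = sort(unique(edges$gene))),
    class = "gene_pair_index"
  )
}

#' @export
print.gene_pair_index <- function(x, ...) {
  cat("<gene_pair_index> ", nrow(x$edges) / 2L, " pairs over ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher's exact p for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule (the mass of all tables
#' with fixed margins whose probability does not exceed the observed
#' table's). Vectorised over the four counts. A table with a zero row or
#' column margin carries no information and returns 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- cbind(a, b, c, d)
  key <- paste(a, b, c, d)
  uniq <- !duplicated(key)
  pu <- apply(tab[uniq, , drop = FALSE], 1L, function(r) {
    if ((r[1] + r[2]) == 0 || (r[3] + r[4]) == 0 ||
        (r[1] + r[3]) == 0 || (r[2] + r[4]) == 0) return(1)
    # fisher.test can exceed 1 by rounding error; p is a probability
    min(1, stats::fisher.test(matrix(r, 2L, 2L, byrow = TRUE))$p.value)
  })
  unname(pu[match(key, key[uniq])])
}

as_profile <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 1L) stop("profile must be a single sample column", call. = FALSE)
    x <- stats::setNames(x[, 1L], rownames(x))
  }
  if (is.data.frame(x)) {
    stopifnot(ncol(x) == 2L)
    x <- stats::setNames(as.numeric(x[[2L]]), as.character(as.integer(x[[1L]])))
  }
  if (!is.numeric(x) || is.null(names(x))) {
    stop("profile must be a named numeric vector (names = Entrez IDs)",
         call. = FALSE)
  }
  x
}

#' Call differentially expressed genes in one disease sample
#'
#' The RankComp procedure. Each stable pair whose within-sample ordering in
#' the test sample strictly contradicts its stable normal direction is a
#' *reversal* (ties are not reversals). For every gene A with at least one
#' indexed partner, the 2x2 table
#' \preformatted{
#'                      reversed   not reversed
#'   greater-in-normal      a           b
#'   lesser-in-normal       c           d
#' }
#' is tested with a two-sided Fisher's exact test against the null that the
#' reversal proportion is the same in both partner groups. A reversal
#' against a greater-in-normal partner supports up-regulation of A; against
#' a lesser-in-normal partner, down-regulation. P-values are BH-adjusted
#' across tested genes; candidates have `fdr < fdr_threshold` and a
#' direction (genes whose two reversal proportions are equal, including
#' both zero, are never called).
#'
#' The filtering stage then recomputes each candidate's table after
#' excluding partners that are themselves candidates and keeps only genes
#' still significant (BH over the filtered p-values at the same threshold)
#' with an unchanged direction. `filter = "fixpoint"` repeats this until the
#' retained set stops changing (at most `max_iter` rounds);
#' `"single-pass"` (default) does it once; `"none"` skips it.
#'
#' @param sample A named numeric vector (names = Entrez IDs), single-column
#'   matrix, or two-column data frame (id, value) with the disease sample's
#'   expression. Genes missing from the sample have their pairs skipped.
#' @param index A [build_pair_index()] object.
#' @param fdr_threshold Per-sample BH threshold; default 0.05.
#' @param filter `"single-pass"` (default), `"none"` or `"fixpoint"`.
#' @param max_iter Round cap for `filter = "fixpoint"`.
#' @return A tibble of class `sample_deg_result`, one row per tested gene:
#'   `gene`, partner-group sizes `n_greater`/`n_lesser`, table cells
#'   `a`,`b`,`c`,`d`, `p`, `fdr`, `direction` (`"up"`/`"down"`/`NA`),
#'   `p_filtered`, `fdr_filtered` (candidates only) and `stage`
#'   (`"not-candidate"`, `"candidate"`, `"filtered-retained"`,
#'   `"filtered-removed"`). Use [deg_calls()] to extract the final calls.
#' @export
call_sample_degs <- function(sample, index, fdr_threshold = 0.05,
                             filter = c("single-pass", "none", "fixpoint"),
                             max_iter = 100L) {
  filter <- match.arg(filter)
  stopifnot(inherits(index, "gene_pair_index"))
  xs <- as_profile(sample)
  edges <- index$edges
  known <- edges$gene %in% names(xs) & edges$partner %in% names(xs)
  if (!all(known)) {
    message(sum(!known) / 2L, " pairs skipped: gene absent from the sample")
    edges <- edges[known, ]
  }
  if (nrow(edges) == 0L) stop("no stable pairs overlap the sample", call. = FALSE)
  xg <- unname(xs[as.character(edges$gene)])
  xp <- unname(xs[as.character(edges$partner)])
  reversed <- ifelse(edges$partner_greater, xg > xp, xg < xp)

  g <- factor(edges$gene)
  agg <- rowsum(cbind(nG = edges$partner_greater,
                      a = edges$partner_greater & reversed,
                      nL = !edges$partner_greater,
                      c = !edges$partner_greater & reversed) + 0L,
                g)
  res <- tibble::tibble(
    gene = as.integer(levels(g)),
    n_greater = as.integer(agg[, "nG"]),
    n_lesser = as.integer(agg[, "nL"]),
    a = as.integer(agg[, "a"]),
    c = as.integer(agg[, "c"])
  )
  res$b <- res$n_greater - res$a
  res$d <- res$n_lesser - res$c
  res <- res[c("gene", "n_greater", "n_lesser", "a", "b", "c", "d")]
  res$p <- fisher_exact_2x2(res$a, res$b, res$c, res$d)
  res$fdr <- bh_adjust(res$p)
  res$direction <- deg_direction(res$a, res$n_greater, res$c, res$n_lesser)
  candidate <- res$fdr < fdr_threshold & !is.na(res$direction)
  res$p_filtered <- NA_real_
  res$fdr_filtered <- NA_real_
  res$stage <- ifelse(candidate, "candidate", "not-candidate")

  if (filter != "none" && any(candidate)) {
    current <- res$gene[candidate]
    rounds <- if (filter == "single-pass") 1L else max_iter
    for (it in seq_len(rounds)) {
      ft <- filtered_tables(edges, reversed, current)
      idx <- match(ft$gene, res$gene)
      p_f <- fisher_exact_2x2(ft$a, ft$b, ft$c, ft$d)
      fdr_f <- bh_adjust(p_f)
      dir_f <- deg_direction(ft$a, ft$nG, ft$c, ft$nL)
      keep <- fdr_f < fdr_threshold & !is.na(dir_f) &
        dir_f == res$direction[idx]
      res$p_filtered[idx] <- p_f
      res$fdr_filtered[idx] <- fdr_f
      retained <- ft$gene[keep]
      if (filter == "single-pass" || setequal(retained, current)) {
        current <- retained
        break
      }
      current <- retained
      if (length(current) == 0L) break
    }
    res$stage[candidate] <- ifelse(res$gene[candidate] %in% current,
                                   "filtered-retained", "filtered-removed")
  }
  structure(res,
            class = c("sample_deg_result", class(tibble::tibble())),
            fdr_threshold = fdr_threshold, filter = filter)
}

# direction of differential expression from the two reversal proportions;
# empty partner group contributes proportion 0, equal proportions -> NA
deg_direction <- function(a, nG, c, nL) {
  pG <- ifelse(nG > 0L, a / nG, 0)
  pL <- ifelse(nL > 0L, c / nL, 0)
  ifelse(pG > pL, "up", ifelse(pL > pG, "down", NA_character_))
}

# recompute per-gene tables for genes in `genes`, dropping edges whose
# partner is itself in the current candidate set
filtered_tables <- function(edges, reversed, genes) {
  sel <- edges$gene %in% genes & !(edges$partner %in% genes)
  e <- edges[sel, ]
  r <- reversed[sel]
  g <- factor(e$gene, levels = sort(unique(genes)))
  agg <- rowsum(cbind(nG = e$partner_greater,
                      a = e$partner_greater & r,
                      nL = !e$partner_greater,
                      c = !e$partner_greater & r) + 0L,
                g)
  out <- tibble::tibble(
    gene = as.integer(rownames(agg)),
    nG = as.integer(agg[, "nG"]), a = as.integer(agg[, "a"]),
    nL = as.integer(agg[, "nL"]), c = as.integer(agg[, "c"])
  )
  # candidates all of whose partners are candidates lose every pair: p = 1
  missing <- setdiff(genes, out$gene)
  if (length(missing) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      gene = as.integer(missing), nG = 0L, a = 0L, nL = 0L, c = 0L))
  }
  out$b <- out$nG - out$a
  out$d <- out$nL - out$c
  out
}

#' Final DEG calls of a sample result
#'
#' @param x A `sample_deg_result`.
#' @return The rows called differentially expressed after whatever filtering
#'   mode produced `x` (`stage` of `"candidate"` when no filtering ran, else
#'   `"filtered-retained"`).
#' @export
deg_calls <- function(x) {
  stopifnot(inherits(x, "sample_deg_result"))
  stage_final <- if (attr(x, "filter") == "none") "candidate" else "filtered-retained"
  x[x$stage == stage_final, ]
}

#' Population-level DEGs reproducible in two case-control datasets
#'
#' Per dataset and gene, a two-sample t-test (equal-variance Student by
#' default, Welch with `var_equal = FALSE`) compares cases against controls;
#' p-values are BH-adjusted per dataset. The population-level set contains
#' the genes significant in *both* datasets with the *same* deregulation
#' direction (sign of mean case minus mean control). The direction
#' concordance of the two significant lists and its binomial significance
#' (chance agreement 0.5) are attached; see [generics::glance()].
#'
#' @param x1,x2 Expression matrices of the two datasets.
#' @param case1,case2 Logical vectors (one per sample column): `TRUE` for
#'   case/disease samples, `FALSE` for controls. Each group needs >= 2
#'   samples.
#' @param fdr_threshold Per-dataset BH threshold; default 0.01.
#' @param var_equal Equal-variance t-test (default `TRUE`).
#' @return Tibble of class `population_deg_set`: `gene`, `direction`,
#'   `p_1`, `fdr_1`, `p_2`, `fdr_2` for the reproducible genes, with the
#'   concordance summary in attributes.
#' @export
population_degs <- function(x1, case1, x2, case2, fdr_threshold = 0.01,
                            var_equal = TRUE) {
  d1 <- dataset_degs(x1, case1, var_equal)
  d2 <- dataset_degs(x2, case2, var_equal)
  d1$fdr <- bh_adjust(d1$p)
  d2$fdr <- bh_adjust(d2$p)
  sig1 <- d1[d1$fdr < fdr_threshold & !is.na(d1$direction), ]
  sig2 <- d2[d2$fdr < fdr_threshold & !is.na(d2$direction), ]
  ov <- dplyr::inner_join(sig1, sig2, by = "gene", suffix = c("_1", "_2"))
  k_same <- sum(ov$direction_1 == ov$direction_2)
  members <- ov[ov$direction_1 == ov$direction_2, ]
  out <- tibble::tibble(gene = members$gene, direction = members$direction_1,
                        p_1 = members$p_1, fdr_1 = members$fdr_1,
                        p_2 = members$p_2, fdr_2 = members$fdr_2)
  structure(out,
            class = c("population_deg_set", class(tibble::tibble())),
            n_deg_1 = nrow(sig1), n_deg_2 = nrow(sig2),
            n_overlap = nrow(ov), k_same = k_same,
            concordance = if (nrow(ov) > 0L) k_same / nrow(ov) else NA_real_,
            concordance_p = if (nrow(ov) > 0L)
              concordance_significance(k_same, nrow(ov)) else 1)
}

dataset_degs <- function(x, case, var_equal) {
  m <- as_expr_matrix(x)
  stopifnot(is.logical(case), length(case) == ncol(m))
  if (sum(case) < 2L || sum(!case) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(
      stats::t.test(m[i, case], m[i, !case], var.equal = var_equal)$p.value,
      error = function(e) 1  # constant data in both groups
    )
  }, numeric(1L))
  delta <- unname(rowMeans(m[, case, drop = FALSE]) -
                    rowMeans(m[, !case, drop = FALSE]))
  tibble::tibble(
    gene = gene_ids(m), p = p,
    direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", NA_character_))
  )
}

#' Keep only calls on population-level DEGs
#'
#' Restricts a per-sample result to genes in a predetermined
#' population-level DEG set (the call's own direction is kept).
#'
#' @param calls A `sample_deg_result`.
#' @param population A `population_deg_set`, or anything with a `gene`
#'   column, or an integer vector of Entrez IDs.
#' @return The filtered `sample_deg_result`.
#' @export
restrict_to_population <- function(calls, population) {
  stopifnot(inherits(calls, "sample_deg_result"))
  genes <- if (is.data.frame(population)) population$gene else as.integer(population)
  out <- calls[calls$gene %in% genes, ]
  attributes(out)[c("fdr_threshold", "filter")] <-
    attributes(calls)[c("fdr_threshold", "filter")]
  class(out) <- class(calls)
  out
}

#' Precision of per-sample DEG calls against a paired normal
#'
#' The benchmark deregulation direction of each called gene is the sign of
#' (cancer expression minus paired adjacent-normal expression). Calls
#' agreeing with the benchmark are true positives, disagreeing calls false
#' positives; genes with exactly equal benchmark values are unevaluable and
#' excluded from both counts. Precision is TP / (TP + FP).
#'
#' @param calls A `sample_deg_result` (its final calls are evaluated; see
#'   [deg_calls()]) or any data frame with `gene` and `direction` columns.
#' @param cancer_profile,normal_profile Named numeric vectors (or
#'   single-column matrices) covering all called genes.
#' @return One-row tibble of class `precision_report`: `tp`, `fp`,
#'   `precision`, `n_evaluated`, `n_unevaluable`.
#' @export
evaluate_precision <- function(calls, cancer_profile, normal_profile) {
  if (inherits(calls, "sample_deg_result")) calls <- deg_calls(calls)
  stopifnot(all(c("gene", "direction") %in% names(calls)))
  xc <- as_profile(cancer_profile)
  xn <- as_profile(normal_profile)
  g <- as.character(calls$gene)
  if (!all(g %in% names(xc)) || !all(g %in% names(xn))) {
    stop("profiles must cover all called genes", call. = FALSE)
  }
  delta <- xc[g] - xn[g]
  evaluable <- delta != 0
  bench <- ifelse(delta > 0, "up", "down")
  tp <- sum(evaluable & calls$direction == bench)
  fp <- sum(evaluable & calls$direction != bench)
  tibble::new_tibble(
    tibble::tibble(
      tp = tp, fp = fp,
      precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
      n_evaluated = tp + fp,
      n_unevaluable = sum(!evaluable)
    ),
    class = "precision_report"
  )
}
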