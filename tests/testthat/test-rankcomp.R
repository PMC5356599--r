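test_that("the pair index mirrors every pair under both genes", {
  # direction +1: the lower-ID gene is the high expresser
  s <- new_reo_set(tibble::tibble(gene_low = 3L, gene_high = 8L, direction = 1L))
  idx <- build_pair_index(s)
  e <- idx$edges
  expect_identical(e$partner_greater[e$gene == 3L], FALSE)  # 8 sits below 3
  expect_identical(e$partner_greater[e$gene == 8L], TRUE)   # 3 sits above 8

  empty <- build_pair_index(new_reo_set(tibble::tibble(
    gene_low = integer(0), gene_high = integer(0), direction = integer(0))))
  expect_identical(nrow(empty$edges), 0L)

  withr::with_seed(53, {
    keys <- t(combn(1:12, 2))
    pick <- sample.int(nrow(keys), 30)
    s2 <- new_reo_set(tibble::tibble(
      gene_low = keys[pick, 1], gene_high = keys[pick, 2],
      direction = sample(c(-1L, 1L), 30, replace = TRUE)))
    e2 <- build_pair_index(s2)$edges
    expect_identical(nrow(e2), 60L)
    # mirrored orientation for every directed edge
    merged <- dplyr::inner_join(e2, e2,
                                by = c(gene = "partner", partner = "gene"))
    expect_identical(nrow(merged), 60L)
    expect_true(all(merged$partner_greater.x != merged$partner_greater.y))
  })
})

test_that("two-sided Fisher p equals full table enumeration for moderate margins", {
  expect_identical(fisher_exact_2x2(0, 10, 0, 10), 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  withr::with_seed(59, {
    for (i in 1:200) {
      tab <- sample(0:8, 4, replace = TRUE)
      expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                   oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("a sample matching every stable ordering yields zero DEGs", {
  cohort <- generate_normal_cohort(G = 80, n = 30, noise_sd = 0.1,
                                   template_spacing = 0.4, seed = 61)
  s <- significant_stable_pairs(cohort$matrix)
  idx <- build_pair_index(s)
  res <- call_sample_degs(cohort$truth$template, idx)
  expect_identical(nrow(deg_calls(res)), 0L)
  expect_true(all(res$a == 0L & res$c == 0L))
})

test_that("a constructed full reversal gives the closed-form Fisher p and an up call", {
  # gene 500 sits below partners 1..30 (G_A) and above partners 101..130 (L_A)
  g_a <- 1:30; l_a <- 101:130
  s <- new_reo_set(tibble::tibble(
    gene_low = c(g_a, l_a), gene_high = 500L,
    direction = c(rep(1L, 30), rep(-1L, 30))))
  idx <- build_pair_index(s)
  # sample: gene 500 leaps above all its greater-in-normal partners
  x <- c(stats::setNames(seq(2, 3, length.out = 30), g_a),
         stats::setNames(seq(0, 1, length.out = 30), l_a),
         "500" = 10)
  res <- call_sample_degs(x, idx, filter = "none")
  row <- res[res$gene == 500L, ]
  expect_identical(c(row$a, row$b, row$c, row$d), c(30L, 0L, 0L, 30L))
  expect_identical(row$direction, "up")
  expect_equal(row$p, 2 / choose(60, 30), tolerance = 1e-9)
  expect_identical(deg_calls(res)$gene[1], 500L)
})

test_that("ties are never reversals and fully tied samples give no DEGs", {
  s <- new_reo_set(tibble::tibble(gene_low = 1L, gene_high = 2L, direction = 1L))
  idx <- build_pair_index(s)
  res <- call_sample_degs(c("1" = 5, "2" = 5), idx, filter = "none")
  expect_true(all(res$a == 0L & res$c == 0L))
  expect_identical(nrow(deg_calls(res)), 0L)
})

test_that("DEG calls are invariant to gene and pair order", {
  withr::with_seed(67, {
    cohort <- generate_normal_cohort(G = 60, n = 30, seed = 3)
    s <- significant_stable_pairs(cohort$matrix)
    idx1 <- build_pair_index(s)
    shuffled <- s[sample.int(nrow(s)), ]
    idx2 <- build_pair_index(new_reo_set(shuffled, universe = reo_universe(s)))
    pt <- generate_paired_tumor(cohort$truth, n_degs = 5, seed = 4)
    r1 <- call_sample_degs(pt$tumor, idx1)
    r2 <- call_sample_degs(pt$tumor[sample(names(pt$tumor))], idx2)
    expect_identical(as.data.frame(r1), as.data.frame(r2))
  })
})

test_that("more one-sided reversals never weaken the up-call on small instances", {
  # |G_A| = |L_A| = 6; reversals in G_A support up
  p_at <- function(a) fisher_exact_2x2(a, 6 - a, 0, 6)
  ps <- vapply(0:6, p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the coupled-pair filter removes genes whose evidence is other DEGs", {
  # construction: 20 "crasher" genes (21..40) sit above gene 50 and above ten
  # bottom genes (61..70) in the normal ordering, and below a top block
  # (1..10); gene 50 additionally sits above bottom genes 61..80. In the test
  # sample the crashers fall to the very bottom. Gene 50 then shows 20
  # reversals, every one against a crasher, so its up-call must vanish once
  # coupled pairs containing other DEGs are excluded.
  crash <- 21:40
  pairs <- dplyr::bind_rows(
    tidyr::expand_grid(gene_low = 1:10, gene_high = crash) |>
      dplyr::mutate(direction = 1L),               # top block above crashers
    tibble::tibble(gene_low = crash, gene_high = 50L, direction = 1L),
    tidyr::expand_grid(gene_low = crash, gene_high = 61:70) |>
      dplyr::mutate(direction = 1L),               # crashers above bottom
    tibble::tibble(gene_low = 50L, gene_high = 61:80, direction = 1L)
  )
  idx <- build_pair_index(new_reo_set(pairs))
  x <- c(stats::setNames(100 - 1:10, 1:10),        # top block unchanged
         stats::setNames(seq(0.01, 0.2, length.out = 20), crash),  # crashed
         "50" = 50,
         stats::setNames(30 - 1:20, 61:80))        # bottom unchanged
  res <- call_sample_degs(x, idx, filter = "single-pass")
  expect_setequal(res$gene[res$stage != "not-candidate"], c(crash, 50L))
  expect_setequal(deg_calls(res)$gene, crash)      # the real DEGs survive
  expect_identical(res$stage[res$gene == 50L], "filtered-removed")
  expect_true(all(res$direction[res$gene %in% crash] == "down"))
  # without filtering, gene 50 is a (spurious) up candidate
  res_nf <- call_sample_degs(x, idx, filter = "none")
  expect_identical(res_nf$direction[res_nf$gene == 50L], "up")
  expect_true(50L %in% deg_calls(res_nf)$gene)
})

test_that("fixpoint filtering reaches a stable retained set", {
  withr::with_seed(71, {
    cohort <- generate_normal_cohort(G = 120, n = 40, seed = 5)
    s <- significant_stable_pairs(cohort$matrix)
    idx <- build_pair_index(s)
    pt <- generate_paired_tumor(cohort$truth, n_degs = 8, seed = 6)
    r_fix <- call_sample_degs(pt$tumor, idx, filter = "fixpoint")
    retained <- deg_calls(r_fix)$gene
    # re-applying the exclusion to the fixpoint set changes nothing
    r_again <- call_sample_degs(pt$tumor, idx, filter = "fixpoint")
    expect_identical(deg_calls(r_again)$gene, retained)
    expect_true(all(r_fix$stage %in% c("not-candidate", "filtered-retained",
                                       "filtered-removed")))
  })
})

test_that("population-level DEGs need significance and direction agreement in both datasets", {
  withr::with_seed(73, {
    truth <- generate_normal_cohort(G = 120, n = 2, seed = 7)$truth
    planted <- plant_deg_set(truth, 10, effect_log2 = 2, seed = 8)
    cc1 <- generate_case_control(truth, 12, 12, planted, seed = 9)
    cc2 <- generate_case_control(truth, 12, 12, planted, seed = 10)
    pop <- population_degs(cc1$matrix, cc1$case, cc2$matrix, cc2$case)
    expect_setequal(pop$gene, planted$gene)
    expect_identical(pop$direction[match(planted$gene, pop$gene)],
                     planted$direction)

    # brute-force reimplementation: classic equal-variance t + BH + overlap
    oracle_members <- local({
      one <- function(m, case) {
        t_p <- apply(m, 1, function(v) {
          x <- v[case]; y <- v[!case]
          sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                       (length(x) + length(y) - 2))
          tt <- (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
          2 * pt(-abs(tt), length(x) + length(y) - 2)
        })
        data.frame(gene = as.integer(rownames(m)), p = t_p,
                   dir = sign(rowMeans(m[, case]) - rowMeans(m[, !case])))
      }
      a <- one(cc1$matrix, cc1$case); b <- one(cc2$matrix, cc2$case)
      a$fdr <- oracle_bh(a$p); b$fdr <- oracle_bh(b$p)
      sig <- merge(a[a$fdr < 0.01, ], b[b$fdr < 0.01, ], by = "gene")
      sig$gene[sig$dir.x == sig$dir.y]
    })
    expect_setequal(pop$gene, oracle_members)
  })

  # a gene moving opposite ways in the two datasets is excluded
  m <- tiny_matrix(c(1, 1, 1, 1, 5, 5, 5, 5,
                     2, 2, 2, 2, 2, 2, 2, 2), genes = 1:2)
  up <- population_degs(m, rep(c(TRUE, FALSE), each = 4),
                        m[, c(5:8, 1:4)], rep(c(TRUE, FALSE), each = 4),
                        fdr_threshold = 0.05)
  expect_identical(nrow(up), 0L)
  expect_identical(attr(up, "k_same"), 0L)
})

test_that("restriction to a population set is a plain key filter", {
  withr::with_seed(79, {
    cohort <- generate_normal_cohort(G = 50, n = 25, seed = 11)
    s <- significant_stable_pairs(cohort$matrix)
    idx <- build_pair_index(s)
    pt <- generate_paired_tumor(cohort$truth, n_degs = 6, seed = 12)
    res <- call_sample_degs(pt$tumor, idx)
    keep <- sample(res$gene, 20)
    r2 <- restrict_to_population(res, keep)
    expect_identical(r2$gene, intersect(res$gene, keep))
    expect_identical(nrow(restrict_to_population(res, integer(0))), 0L)
    full <- restrict_to_population(res, res$gene)
    expect_identical(as.data.frame(full), as.data.frame(res))
  })
})

test_that("precision against a paired normal counts sign agreement, ties unevaluable", {
  calls <- tibble::tibble(gene = 1:4, direction = c("up", "up", "down", "down"))
  cancer <- c("1" = 5, "2" = 3, "3" = 1, "4" = 2)
  normal <- c("1" = 4, "2" = 4, "3" = 2, "4" = 2)  # gene2 contradicts, gene4 ties
  pr <- evaluate_precision(calls, cancer, normal)
  expect_identical(pr$tp, 2L)
  expect_identical(pr$fp, 1L)
  expect_equal(pr$precision, 2 / 3)
  expect_identical(pr$n_unevaluable, 1L)

  all_match <- evaluate_precision(calls[c(1, 3), ], cancer, normal)
  expect_equal(all_match$precision, 1)

  none <- evaluate_precision(calls[4, ], cancer, normal)
  expect_true(is.na(none$precision))

  # random instance equals a brute-force sign comparison
  withr::with_seed(83, {
    g <- 1:30
    xc <- stats::setNames(rnorm(30), g)
    xn <- stats::setNames(rnorm(30), g)
    cl <- tibble::tibble(gene = sample(g, 12),
                         direction = sample(c("up", "down"), 12, replace = TRUE))
    pr2 <- evaluate_precision(cl, xc, xn)
    bench <- ifelse(xc[as.character(cl$gene)] > xn[as.character(cl$gene)],
                    "up", "down")
    expect_identical(pr2$tp, sum(cl$direction == bench))
    expect_equal(pr2$precision, mean(cl$direction == bench))
  })
})
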