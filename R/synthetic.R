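#' Simulate a template-ordered normal cohort
#'
#' Emulates the data-generating situation the rank-based method assumes: all
#' normal samples of a tissue share one latent expression template, and each
#' measured sample is the template plus independent Gaussian measurement
#' noise on a log-intensity-like scale. Pair stability is then controlled by
#' the ratio of the template spacing between two genes to the noise level.
#'
#' The template is an evenly spaced ascending grid: gene `g` (Entrez IDs are
#' simply `1..G`) has baseline `baseline + g * template_spacing`. The default
#' spacing (0.02) with `G` around a thousand spans a realistic log2 dynamic
#' range of ~20, and the default noise (0.2) is a typical replicate-level
#' log2 standard deviation; under these defaults close template neighbours
#' are rank-unstable while distant pairs are essentially always ordered the
#' same way.
#'
#' @param G Number of genes (>= 2).
#' @param n Number of samples (>= 1).
#' @param noise_sd Per-measurement Gaussian noise SD (> 0 unless
#'   `template_spacing` is used with zero noise for a degenerate cohort);
#'   default 0.2.
#' @param template_spacing Template increment between consecutive genes
#'   (> 0); default 0.02.
#' @param baseline Additive offset of the template; default 4.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with `matrix` (gene-by-sample expression matrix) and
#'   `truth` (a `synthetic_truth` object holding the template and the
#'   generator parameters).
#' @examples
#' cohort <- generate_normal_cohort(G = 50, n = 10, seed = 7)
#' dim(cohort$matrix)
#' @export
generate_normal_cohort <- function(G, n, noise_sd = 0.2, template_spacing = 0.02,
                                   baseline = 4, seed) {
  stopifnot(G >= 2L, n >= 1L)
  if (template_spacing <= 0) stop("template_spacing must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  template <- baseline + seq_len(G) * template_spacing
  names(template) <- as.character(seq_len(G))
  m <- withr::with_seed(seed, {
    template + matrix(stats::rnorm(G * n, sd = noise_sd), G, n)
  })
  dimnames(m) <- list(names(template), sprintf("N%03d", seq_len(n)))
  truth <- structure(
    list(template = template, planted_degs = empty_planted(),
         platform_bias = NULL, noise_sd = noise_sd,
         template_spacing = template_spacing, seed = seed),
    class = "synthetic_truth"
  )
  list(matrix = m, truth = truth)
}

empty_planted <- function() {
  tibble::tibble(gene = integer(0L), direction = character(0L),
                 effect_log2 = numeric(0L))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$template), " genes, noise_sd = ",
      x$noise_sd, ", spacing = ", x$template_spacing,
      ", planted DEGs = ", nrow(x$planted_degs), "\n", sep = "")
  invisible(x)
}

#' Simulate a platform variant of a cohort
#'
#' Emulates platform-specific probe effects: a fixed per-gene additive
#' offset, drawn once and applied identically to every sample (a probe
#' bias, not noise), on a random fraction of the genes. Gene pairs whose
#' template difference is smaller than the bias can flip their stable
#' ordering on the variant platform, so cross-platform inconsistencies
#' concentrate among pairs with small rank differences.
#'
#' @param matrix Gene-by-sample expression matrix of the source cohort.
#' @param bias_sd SD of the per-gene offsets; default 0.1.
#' @param bias_fraction Fraction of genes receiving an offset, in \[0, 1\];
#'   default 0.3.
#' @param seed Integer seed.
#' @return List with `matrix` (the biased matrix, same dimensions) and
#'   `bias` (tibble `gene`, `offset` for affected genes).
#' @export
generate_platform_variant <- function(matrix, bias_sd = 0.1, bias_fraction = 0.3,
                                      seed) {
  m <- as_expr_matrix(matrix)
  if (bias_fraction < 0 || bias_fraction > 1) {
    stop("bias_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (bias_sd < 0) stop("bias_sd must be non-negative", call. = FALSE)
  G <- nrow(m)
  withr::with_seed(seed, {
    n_bias <- round(G * bias_fraction)
    hit <- sample.int(G, n_bias)
    offset <- stats::rnorm(n_bias, sd = bias_sd)
  })
  m[hit, ] <- m[hit, ] + offset
  list(matrix = m,
       bias = tibble::tibble(gene = gene_ids(m)[hit], offset = offset))
}

#' Simulate a paired tumor / adjacent-normal profile
#'
#' The adjacent normal is a fresh noisy draw from the cohort template (the
#' patient's pre-disease state); the tumor is that same draw with `n_degs`
#' genes shifted by `effect_log2` log2 units, a fraction `frac_up` upward
#' and the rest downward. The planted genes and directions are recorded as
#' ground truth.
#'
#' @param truth A `synthetic_truth` from [generate_normal_cohort()].
#' @param n_degs Number of planted DEGs (<= number of genes); ignored when
#'   `planted` is supplied.
#' @param effect_log2 Absolute planted effect in log2 units (>= 0);
#'   default 3.
#' @param frac_up Fraction of planted DEGs shifted up; default 0.5.
#' @param noise_sd Noise SD for the fresh draws; defaults to the cohort's.
#' @param planted Optional fixed DEG repertoire (tibble `gene`,
#'   `direction`, optionally `effect_log2`), e.g. from [plant_deg_set()],
#'   so that several tumors of one disease share the same truth; when
#'   `NULL` a fresh random repertoire is drawn.
#' @param seed Integer seed.
#' @return List with `tumor` and `adjacent_normal` (named numeric vectors)
#'   and `planted` (tibble `gene`, `direction`, `effect_log2`).
#' @export
generate_paired_tumor <- function(truth, n_degs, effect_log2 = 3, frac_up = 0.5,
                                  noise_sd = NULL, planted = NULL, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (effect_log2 < 0) stop("effect_log2 must be non-negative", call. = FALSE)
  G <- length(truth$template)
  noise_sd <- noise_sd %||% truth$noise_sd
  if (is.null(planted)) {
    planted <- plant_deg_set(truth, n_degs, effect_log2 = effect_log2,
                             frac_up = frac_up, seed = seed)
  }
  if (!"effect_log2" %in% names(planted)) planted$effect_log2 <- effect_log2
  adjacent <- withr::with_seed(seed, truth$template + stats::rnorm(G, sd = noise_sd))
  names(adjacent) <- names(truth$template)
  tumor <- adjacent
  i <- match(as.character(planted$gene), names(tumor))
  stopifnot(!anyNA(i))
  tumor[i] <- tumor[i] +
    ifelse(planted$direction == "up", 1, -1) * planted$effect_log2
  list(tumor = tumor, adjacent_normal = adjacent,
       planted = tibble::as_tibble(planted))
}

#' Draw a fixed planted-DEG repertoire for a synthetic disease
#'
#' Samples the genes and directions once, so that several simulated disease
#' samples (or case-control training datasets) of the same tissue share one
#' ground-truth DEG set, the way a real cancer's population-level DEGs are
#' common across patients.
#'
#' @inheritParams generate_paired_tumor
#' @return Tibble `gene`, `direction`, `effect_log2`.
#' @export
plant_deg_set <- function(truth, n_degs, effect_log2 = 3, frac_up = 0.5, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  G <- length(truth$template)
  if (n_degs > G) stop("n_degs exceeds the number of genes", call. = FALSE)
  withr::with_seed(seed, {
    deg_genes <- sort(sample.int(G, n_degs))
    dir_up <- seq_along(deg_genes) %in% sample.int(n_degs, round(n_degs * frac_up))
  })
  tibble::tibble(
    gene = as.integer(names(truth$template))[deg_genes],
    direction = ifelse(dir_up, "up", "down"),
    effect_log2 = effect_log2
  )
}

#' Simulate a case-control expression dataset
#'
#' Controls are fresh noisy draws from the cohort template; cases carry the
#' planted DEG shifts on top of their own fresh draws. Used to
#' pre-determine population-level DEGs on synthetic data.
#'
#' @inheritParams generate_paired_tumor
#' @param n_case,n_control Sample counts for the two groups.
#' @param planted The disease's DEG repertoire (see [plant_deg_set()]).
#' @return List with `matrix` (gene-by-sample, cases then controls) and
#'   `case` (logical vector per column).
#' @export
generate_case_control <- function(truth, n_case, n_control, planted,
                                  noise_sd = NULL, seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(c("gene", "direction") %in% names(planted)))
  if (!"effect_log2" %in% names(planted)) planted$effect_log2 <- 3
  noise_sd <- noise_sd %||% truth$noise_sd
  G <- length(truth$template)
  m <- withr::with_seed(seed, {
    truth$template +
      matrix(stats::rnorm(G * (n_case + n_control), sd = noise_sd),
             G, n_case + n_control)
  })
  dimnames(m) <- list(names(truth$template),
                      c(sprintf("C%03d", seq_len(n_case)),
                        sprintf("H%03d", seq_len(n_control))))
  i <- match(as.character(planted$gene), rownames(m))
  shift <- ifelse(planted$direction == "up", 1, -1) * planted$effect_log2
  m[i, seq_len(n_case)] <- m[i, seq_len(n_case)] + shift
  list(matrix = m, case = rep(c(TRUE, FALSE), c(n_case, n_control)))
}

#' Simulate a gene-set collection with one planted-enriched set
#'
#' Random gene sets drawn from a universe, plus (when `enriched_in` is
#' non-empty) one set deliberately packed with planted DEGs so that
#' enrichment machinery has a known positive control.
#'
#' @param universe Integer vector of gene IDs to draw from.
#' @param n_sets Number of random sets.
#' @param set_size_range Length-2 integer vector, inclusive size range;
#'   default `c(10, 50)`.
#' @param enriched_in Integer vector of planted DEG IDs for the packed set
#'   (may be empty).
#' @param packed_fraction Fraction of the packed set drawn from
#'   `enriched_in`; default 0.8.
#' @param seed Integer seed.
#' @return A `gene_set_collection`; the packed set (when present) is named
#'   `"PLANTED"`.
#' @export
generate_gene_sets <- function(universe, n_sets, set_size_range = c(10L, 50L),
                               enriched_in = integer(0L), packed_fraction = 0.8,
                               seed) {
  universe <- unique(as.integer(universe))
  stopifnot(length(set_size_range) == 2L, set_size_range[1L] >= 1L,
            set_size_range[2L] >= set_size_range[1L])
  if (set_size_range[1L] > length(universe)) {
    stop("set sizes exceed the universe size", call. = FALSE)
  }
  set_size_range <- pmin(set_size_range, length(universe))
  enriched_in <- intersect(as.integer(enriched_in), universe)
  withr::with_seed(seed, {
    sizes <- sample(seq(set_size_range[1L], set_size_range[2L]), n_sets,
                    replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(i) {
      sort(sample(universe, sizes[i]))
    })
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    if (length(enriched_in) > 0L) {
      sz <- min(max(sizes), max(2L, length(enriched_in)))
      n_planted <- min(length(enriched_in), max(1L, round(sz * packed_fraction)))
      planted <- sample(enriched_in, n_planted)
      filler <- sample(setdiff(universe, planted), sz - n_planted)
      sets$PLANTED <- sort(c(planted, filler))
    }
  })
  new_gene_set_collection(
    sets, stats::setNames(rep("synthetic gene set", length(sets)), names(sets))
  )
}
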