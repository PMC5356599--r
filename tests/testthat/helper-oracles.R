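# Independent oracles used across the suite. None of these call the package
# functions they are used to check.

# upper binomial tail by direct pmf summation in log space
oracle_binom_upper <- function(k, n, p0 = 0.5) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

# two-sided Fisher p by full enumeration of tables with the observed margins,
# minimum-likelihood rule (tolerance mirrors the conventional 1 + 1e-7 slack)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p_obs <- logp[x == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# hypergeometric upper tail by closed-form summation
oracle_hyper_upper <- function(x, K, N, nd) {
  if (x <= 0) return(1)
  i <- x:min(K, nd)
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, nd - i)) / choose(N, nd)
}

# pair ordering counts by brute-force double loop
oracle_pair_counts <- function(m) {
  ids <- as.integer(rownames(m))
  out <- list()
  idx <- order(ids)
  for (ii in seq_along(idx)) {
    for (jj in seq_along(idx)) {
      if (jj <= ii) next
      i <- idx[ii]; j <- idx[jj]
      gt <- sum(m[i, ] > m[j, ]); lt <- sum(m[i, ] < m[j, ])
      out[[length(out) + 1L]] <- data.frame(
        gene_low = ids[i], gene_high = ids[j],
        n_low_gt_high = gt, n_high_gt_low = lt,
        n_ties = ncol(m) - gt - lt
      )
    }
  }
  do.call(rbind, out)
}

# BH step-up computed by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# exact two-sided rank-sum p by enumerating every group assignment
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  w_all <- apply(splits, 2L, function(id) sum(r[id]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
}

# tiny deterministic expression matrix builder
tiny_matrix <- function(values, genes, samples = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(as.character(genes), samples)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
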