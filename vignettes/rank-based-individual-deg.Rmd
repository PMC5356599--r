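---
title: "Individualized differential expression from stable gene-pair orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized differential expression from stable gene-pair orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reotools)
```

## The model

Within a single expression profile, every pair of genes $(a, b)$ has a
*relative expression ordering* (REO): either $a > b$ or $a < b$ on the
measured scale (or a tie). Because the ordering is computed within one
sample, it is untouched by between-sample normalization, batch effects and
monotone scale changes — the properties that make cross-dataset work on
absolute expression values so fragile.

In a particular type of normal tissue, most orderings recur across
individuals. reotools quantifies this with a one-sided binomial test: if a
pair shows the same ordering in $k$ of $n$ informative cohort samples, and a
single sample would show that ordering by chance with probability
$p_0 = 0.5$, then

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n,\ p_0),$$

computed with the upper-tail CDF (numerically safe for large $n$; no
$1 - \sum$ cancellation). P-values are Benjamini–Hochberg adjusted over
*all* evaluated pairs — all $\binom{G}{2}$ keys with at least one untied
sample — and pairs with FDR below a threshold (default 0.01) form the
tissue's stable-REO catalogue. A legacy mode instead keeps pairs whose
majority ordering covers at least a fixed fraction (default 99%) of all
samples.

**Ties.** A tied pair in a sample supports neither ordering. By default a
tied sample is removed from that pair's binomial denominator
(`tie_policy = "exclude"`); the alternative `"denominator"` keeps the full
sample count, which is the more conservative reading when ties are common
(e.g. zero-inflated RNA-seq counts). In the fixed-fraction mode ties always
count against stability because the denominator is the total cohort size.

**Direction testing.** Only the majority ordering is tested, one-sidedly,
exactly as the formula above is written. When the two orderings split the
cohort evenly the p-value is at least 0.5 and the pair can never be called
stable; no two-sided correction is applied.

## Calling DEGs in one disease sample (RankComp)

Given a stable catalogue and a *single* disease profile, every stable pair
whose ordering in the profile strictly contradicts its normal direction is
a *reversal* (a tie is not a reversal). For a gene $A$, partners split into
those greater-in-normal ($G_A$) and lesser-in-normal ($L_A$), giving the
2×2 table

|                     | reversed | not reversed |
|---------------------|----------|--------------|
| greater-in-normal   | $a$      | $b$          |
| lesser-in-normal    | $c$      | $d$          |

A reversal against a greater-in-normal partner means $A$ now sits above a
gene it used to sit below — evidence of up-regulation; a reversal in $L_A$
supports down-regulation. If $A$ itself is unchanged, shifts caused by
*other* genes' changes hit both partner groups at random, so the null
hypothesis — equal reversal proportions in the two rows — is tested with a
two-sided Fisher's exact test (minimum-likelihood rule). Per-sample BH
adjustment across tested genes at `fdr_threshold` (default 0.05; the
original description fixes no value) defines candidates. Genes with equal
reversal proportions on both sides (including $a = c = 0$) are never
called: there is no directional evidence, whatever the p-value. A table
with a zero row or column margin is uninformative and scores $p = 1$; one
consequence worth knowing is that a gene at the very extreme of the
ordering (empty $G_A$ or empty $L_A$) that reverses *all* of its pairs has
a zero "not reversed" column and cannot be called.

**Coupled-pair filtering.** A strongly shifted gene drags its partners'
tables along: each partner sees one reversal it did not cause. The filter
recomputes each candidate's table after removing pairs whose partner is
itself a candidate, re-tests, re-adjusts (BH over the filtered p-values at
the same threshold) and keeps only genes still significant with an
unchanged direction. `filter = "single-pass"` (default) does this once;
`"fixpoint"` iterates until the retained set stabilizes (guard: 100
rounds); `"none"` skips it.

**Population-level restriction.** A single profile deviates from the
cohort template for many reasons unrelated to disease — individual-specific
expression is real signal to the reversal test. To keep calls
disease-associated, population-level DEGs are pre-determined from two
independent case-control datasets (per-gene Student's t-test, equal
variances by default, Welch optional; BH per dataset; membership requires
significance in both with the same direction), and per-sample calls are
restricted to that set with `restrict_to_population()`. The per-sample
precision benchmark follows the paired-design convention: the sign of
(cancer − paired adjacent normal) per called gene, ties unevaluable,
precision = TP/(TP+FP).

## Comparing catalogues across datasets and platforms

Two catalogues are compared after harmonizing universes (pairs whose genes
both platforms measured): `overlap_stats()` reports the list sizes, the
overlap, the same-direction count $k$, POG scores $k/L_1$ and $k/L_2$, the
consistency $k/n_{\text{overlap}}$ and its binomial significance under a
0.5 chance model of direction agreement. `intersect_consistent()` keeps
pairs present in every catalogue with identical direction — the
cross-platform core on which individualized calling is most robust,
because orderings that survive differing probe designs tend to involve
genes far apart in rank. `rank_difference_comparison()` makes that
diagnosis explicit: per pair, the within-sample rank difference in a
reference dataset (ranks ascending per sample, average rank at ties;
summarised over samples by the mean, or the median via `per_pair`),
compared between cross-platform-consistent and -inconsistent pairs with a
two-sided Wilcoxon rank-sum test. For 30 or fewer pairs the null is
enumerated exactly by a tie-safe dynamic program over rank sums; above
that, the normal approximation with continuity correction is used.

## Pathway enrichment per sample

Up- and down-regulated calls are tested separately against a GMT
collection with the hypergeometric upper tail $P(X \ge x)$ and BH
adjustment across pathways within each direction. The universe defaults to
the intersection of the measured genes with the union of pathway members:
restricting to catalogue-covered genes is the conservative choice, since
padding the universe with genes that can never overlap a pathway only
shrinks the tail probability and inflates apparent enrichment. The
permissive alternative (`restrict_to_sets = FALSE`) is one flag away and
its effect on p-values is exactly that monotone shift. Cohort-level
summaries report, per pathway and direction, the fraction of samples
significant at FDR < 0.1 and at p < 0.05 (both thresholds configurable).

## What the synthetic cohorts emulate

`generate_normal_cohort()` draws every sample as a shared, strictly
increasing expression template plus i.i.d. Gaussian noise on a
log-intensity-like scale. This captures the one property the method rests
on — a common within-tissue ordering perturbed by per-sample variation —
and deliberately nothing else. Defaults were fixed once as the package's
study conditions:

* `template_spacing = 0.02`: with ~1000 genes the template spans a
  realistic log2 dynamic range (~20 units);
* `noise_sd = 0.2`: a typical replicate-level log2 SD. Under these
  defaults close template neighbours are rank-unstable while distant pairs
  are essentially deterministic, so the catalogue contains the realistic
  mix of weak and strong pairs;
* `generate_platform_variant()` adds a *fixed* per-gene offset
  (`bias_sd = 0.1` on 30% of genes) identical across samples — a probe
  effect, not noise. Only pairs whose template gap is smaller than the
  bias can flip their stable direction, which is why cross-platform
  inconsistencies concentrate at small rank differences;
* `generate_paired_tumor()` models the adjacent normal as a fresh draw
  from the template (the patient's pre-disease state) and the tumor as
  that same draw with planted ±`effect_log2` shifts (default 3 log2
  units — a strong but common cancer effect size, far above both the
  spacing and the noise). A fixed repertoire from `plant_deg_set()` lets
  many tumors share one disease truth, mirroring population-level DEGs.

Saturation-style analyses use a cohort with `template_spacing = 0.6`
(spacing/noise ratio 3), where orderings are near-deterministic and close
to all pairs should be detected as stable; that ratio is the regime those
checks are defined for, not a package default.

What the generator does *not* emulate: count-type mean–variance coupling
(negative-binomial RNA-seq noise), correlated gene modules, missing
values, and platform-specific dynamic-range compression. Passing tests
therefore demonstrate the statistical machinery is correct under the
method's own assumptions, not that those assumptions hold for any given
real dataset.

## Numerical and design choices

* Binomial tails via the upper-tail CDF; Fisher p-values clamped to 1
  (the underlying routine can exceed 1 by an ulp); hypergeometric tails
  via `phyper(x − 1, …, lower.tail = FALSE)`.
* Pair counting runs in gene-index tiles (`block_size`, default 512) so
  working memory stays bounded while the pair space grows quadratically;
  results for the package's intended scale (up to a few thousand genes)
  are materialized as tibbles and stream to TSV through
  `write_pair_set()`. Full-transcriptome catalogues (~2×10⁸ pairs) are
  beyond desk scale and out of scope.
* Problem sizes in the shipped checks — cohorts of 300–1000 genes and
  60 samples, 20 simulated tumors, 20 subsample replicates — were chosen
  as the smallest sizes at which the studied proportions are stable to a
  few percent.
* All generators are pure functions of their parameters and an explicit
  `seed` (RNG state is isolated and restored), so every pipeline,
  including the shell interface, is reproducible byte-for-byte from its
  recorded configuration.
* Degenerate inputs: all-tie pairs are skipped with a message; an all-tie
  sample yields zero DEGs; empty DEG lists give p = 1 everywhere; an
  empty overlap reports consistency as missing with p = 1.

## Worked example

```{r example, eval = FALSE}
cohort <- generate_normal_cohort(G = 300, n = 60, seed = 1)
stable <- significant_stable_pairs(cohort$matrix, label = "lung-demo")

planted <- plant_deg_set(cohort$truth, n_degs = 20, seed = 2)
tumor <- generate_paired_tumor(cohort$truth, planted = planted, seed = 3)

idx <- build_pair_index(stable)
calls <- call_sample_degs(tumor$tumor, idx)
glance(calls)
evaluate_precision(calls, tumor$tumor, tumor$adjacent_normal)
```

## Known limitations

* Genes at the extremes of the template ordering have one-sided partner
  sets; their calls rely on a single Fisher row and are conservative (see
  the margin rule above).
* The per-sample FDR threshold inside RankComp is a modelling choice, not
  a calibrated error rate: reversals of one gene's pairs are correlated,
  so the BH guarantee is approximate at the per-sample level.
* Without population-level restriction, individual-specific deviations
  are (correctly) called and counted against precision benchmarks defined
  by planted disease truth; restriction is therefore part of the standard
  pipeline, not an optional refinement.
* The exact rank-sum enumeration is used only up to 30 values; beyond
  that the normal approximation is standard but approximate at extreme
  tails.
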