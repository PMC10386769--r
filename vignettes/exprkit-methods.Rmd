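---
title: "exprkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exprkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprkit)
```

This vignette explains what each stage of the toolkit computes, the
assumptions behind it, the defaults and why they were chosen, and the
numerical conventions that make outputs byte-reproducible. It is the
package's own account of its methods; every number shown is computed by the
code in this document or by the test suite.

## Data model

An `expr_matrix` is a gene × sample grid of finite values with unique
identifiers on both axes and a declared unit (`counts`, `CPM`, `RPKM`,
`FPKM`, `TPM`, `log2`). The unit is load-bearing: normalization refuses
anything but `counts` (so already-normalized data are never silently
renormalized — a classic silent error), differential expression and
biomarker discovery refuse raw `counts` (normalize first), and negative
values are rejected except under `log2`. Identifier matching is exact and
case-sensitive throughout; symbol aliasing or ortholog mapping belongs in
upstream curation, not in an analysis engine where a silent fuzzy match can
change results. Delimiters are explicit parameters (default tab), never
auto-detected.

## Normalization

Library size is defined as the column sum of the supplied count matrix.
Quantifier logs with "total mapped reads" are not part of the input
contract, and column sums make every result reproducible from the matrix
alone. FPKM is accepted as an input label and treated as synonymous with
RPKM; outputs are labelled RPKM. TPM is computed from per-length read rates
and renormalized per column, which guarantees column sums of 10⁶ (checked in
the tests to 10⁻⁶ relative) and makes TPM equal to column-rescaled RPKM — a
cross-check the acceptance layer exercises on random matrices. Counts are
parsed as decimal reals because expectation-based quantifiers emit
fractional counts; a `strict_integer` flag restores integrality checking.

The log2 transform uses a pseudocount (default 1.0, in the matrix's
expression units). One unit is the conventional choice at bulk sequencing
depth: it maps zeros to zero and is small against typical CPM values while
damping the ratio explosion of near-zero genes.

## Differential expression

Two tests are offered per gene, chosen for being assumption-light at the
group sizes typical of public bulk datasets:

* **Welch's t** on per-sample values, with sample variances (n−1),
  Satterthwaite degrees of freedom, and two-sided p from the t distribution.
  Degenerate inputs get documented conventions rather than NaNs: both
  variances zero with equal means gives t = 0, p = 1; both zero with
  different means gives p = 0 with a warning (the data admit no
  within-group noise model).
* **Wilcoxon rank-sum**, exact via the null rank-sum distribution when both
  groups have ≤ 25 observations and no ties (the exact-p floor at e.g.
  n = 4 vs 8 is 2/495 ≈ 0.004 — visible in q-value ties on small designs);
  otherwise a normal approximation with mid-ranks, tie-corrected variance
  and continuity correction. Ties always force the corrected approximation.
  The two-sided rule is min(1, 2·min(lower, upper)). All-tied data return
  p = 1.

The fold change is `log2((mean_A + c)/(mean_B + c))` with shared pseudocount
`c` on linear-scale units; for `log2`-unit input it is the difference of
group means, since the values are already log ratios and the linear formula
would be dimensionally wrong there. Genes with zero expression in every
sample of both groups carry no information and are dropped with a count.
Benjamini–Hochberg adjustment runs across all genes tested, via
`stats::p.adjust` behind a validating wrapper. Volcano thresholds
(|log2FC| ≥ 1, q < 0.05) are recorded as output metadata only and never
applied as filters.

## Biomarker discovery

The discovery tool ranks genes for one target group against the union of
the others. The verbal recipe — maximize fold change, minimize coefficient
of variation — is formalized as an additive rank combination because it is
scale-free (no tuning constant trades off log2FC units against CV units)
and exactly testable:

* `rank_fc`: 1 = largest log2FC toward the target;
* `rank_cv`: 1 = smallest `max(CV_target, max over non-target groups of
  within-group CV)`;
* `cv_fc` score = `rank_fc + rank_cv`, ascending.

CV uses the sample standard deviation over the mean on the linear
(non-log) normalized scale — CV is a ratio statistic and its familiar
benchmarks (0.2 tight, 0.5 noisy) are linear-scale quantities; all-zero
vectors get CV 0 by convention. Taking the **max** CV over *all* groups,
target included, encodes that a usable marker must be uniformly high in its
group and uniformly low in each other group; a gene wildly variable in any
one group is a poor marker even if its rest-pooled CV looks fine. Genes
must be up-regulated toward the target (`log2FC > 0`) to be eligible —
down-markers are not selected, matching the high-in-one/low-in-others
profile the tool is meant to surface — but ineligible genes are retained
and flagged rather than hidden. Welch/Wilcoxon orderings (ascending p, then
descending |log2FC|) and a `combined` ordering (`rank_fc + rank_cv +
rank_p`) are available. Every rank ties-break on ascending gene identifier,
making output tables deterministic to the byte.

## Gene-set analysis

**Pre-ranked GSEA.** The ranked list is sorted by descending log2 fold
change (ties by identifier; non-finite statistics dropped with a count).
The enrichment score is the standard weighted running sum: members at
rank r step up by |stat_r|^w normalized over members, non-members step down
by 1/(N − n_set); ES is the extremum of largest absolute deviation. Weight
defaults to 1.0; weight 0 recovers the classical unweighted KS statistic
(verified against an independent oracle in the tests, alongside agreement
with the fgsea reference statistic). Two numerical conventions matter:

* If the positive and negative extrema tie in magnitude (within 10⁻⁹,
  absorbing float jitter between equivalent summation orders) the score is
  0, which preserves exact antisymmetry under statistic negation.
* If all member statistics are zero, hit increments fall back to equal
  weights.

The null is a gene-sampling permutation: n draws of set-size positions from
the ranked list, shared across sets of equal size (the null depends only on
the size, and sharing makes 200-set runs cheap) from a single seeded RNG
stream. The p-value conditions on the observed sign,
`p = (1 + #{same-sign nulls with |ES'| ≥ |ES|}) / (1 + #{same-sign nulls})`,
with resolution floor 1/(n_perm + 1); NES divides ES by the mean |ES'| of
same-sign nulls. The multilevel speedups of production GSEA engines are
deliberately out of scope: at desk scale (hundreds of sets, thousands of
permutations) plain sampling is exact enough and far simpler. Set-size
bounds default to 5–500, conventional practice for GMT collections. BH runs
once across all tested sets, positive and negative ES together.

**Over-representation.** Upper-tail hypergeometric via `stats::phyper`
(P(X ≥ k)), with the set intersected with the universe first and the query
required to lie inside it. The tests compare against direct
`choose()`-summation across all small universes.

**Set-level comparison.** Each member gene is reduced to its within-group
mean expression; the two per-gene mean vectors are compared with the
*unpaired* rank-sum test. The per-gene pairing would also admit a
signed-rank alternative, but the workflow this engine implements names the
rank-sum test, and the unpaired form asks the intended population question
— are the term's genes, as a set, expressed higher in one group? A minimum
of 3 matrix-resident members is enforced; below that the test is
meaningless and refused.

## Dimensionality reduction

Libraries (samples) are the observations; a flag transposes for gene-space
embedding. Log2 input is recommended (and warned about if absent) since
heavy-tailed linear expression lets a handful of genes dominate distances —
but it is not forced. PCA centers features, optionally unit-scales, drops
constant features with a count, and decomposes via `stats::prcomp`
(singular values). The sign of each component is fixed by making its
largest-magnitude loading positive, so golden files are stable across
platforms and BLAS builds. Classical MDS double-centers the squared
distance matrix (`stats::cmdscale`) and reports the negative-eigenvalue
mass as a distortion fraction — on exact Euclidean input it is ≤ 10⁻⁸, and
embedding distances reproduce the input (both checked in the acceptance
layer). t-SNE and UMAP are delegated to Rtsne and uwot, single-threaded
under a set seed; their contract here is shape, determinism-given-seed and
cluster preservation, not optimizer internals — re-implementing them would
dwarf everything else in the package. Hierarchical heatmap ordering uses
`stats::hclust` on Euclidean or correlation distance (1 − Pearson r;
constant rows get distance 1 to everything since their correlation is
undefined), with the linkage's natural leaf order.

## Synthetic data

The generator emulates grouped bulk RNA-seq libraries: per-gene baseline
means are log-normal (location log 200, scale 1 — a realistic spread of
moderately to highly expressed genes at desk-scale depth), counts are
negative binomial with a single shared size parameter (default 4, i.e.
biological CV ≈ 0.5, the overdispersion regime of real bulk data), and gene
lengths are uniform on 200–10,000 bp. Default design: 500 genes, three
groups of four libraries. Planted structure, all recorded in truth tables:

* **markers** — 10 per group at 8-fold enrichment; within-group counts are
  rejection-resampled (500 attempts, then keep the lowest-CV draw with a
  warning) until the sample CV is ≤ 0.2 in *every* group, mirroring the
  uniformly-stable profile the ranking rewards;
* **DE genes** — 50 between the first two groups at |log2 effect| 2, half
  up and half down;
* **gene sets** — 10 sets of 20 drawing 80% of members from the
  up-regulated DE genes, plus 10 random background sets.

Everything is drawn from one seeded RNG stream, so a bundle is a pure
function of its spec — the determinism every downstream byte-identity test
relies on. The generator does **not** emulate batch effects, library-prep
artifacts, gene–gene correlation, length-dependent counting bias or
zero-inflation; passing tests therefore demonstrate correctness of the
statistics and plumbing under a clean overdispersed-count model, not
robustness to the full messiness of archived public data.

Test and acceptance problem sizes are chosen at desk scale: 2,000 null
genes at 10 vs 10 for type-I calibration, 1,000-gene ranked lists with 200
null sets and 1,000 permutations for GSEA calibration, and 50 simulation
seeds for marker recovery — small enough to run in seconds-to-minutes,
large enough that binomial error on the measured rates is a few per mille
to a few percent.

## Worked check

```{r calibration}
b <- generate_dataset(synthetic_spec(seed = 1))
m <- cpm(b$matrix)
res <- discover_biomarkers(m, b$groups, "A", method = "cv_fc", top_k = 10)
mean(res$gene[res$selected] %in% b$truth$markers$A)
```

```{r gsea}
de <- run_differential_expression(log_transform(m), b$groups, "B", "A",
                                  test = "welch")
gs <- preranked_gsea(make_ranked_list(de), b$sets,
                     n_permutations = 500, seed = 1)
head(as.data.frame(gs)[, c("set", "size", "es", "nes", "p_value", "q_value")])
```

With B as the first group, the planted sets (built from genes up-regulated
in B) rank at the top with positive enrichment scores and permutation-floor
p-values, while the background sets spread across the null.

## Known limitations

* The DE layer has no dispersion sharing across genes — at n = 2–3 per
  group, negative-binomial engines with moderated dispersion (edgeR,
  DESeq2) are more powerful; this package intentionally implements the
  assumption-light tests of its workflow instead of re-implementing those
  engines.
* The permutation GSEA p-value cannot go below 1/(n_perm + 1); very strong
  enrichments saturate at the floor rather than separating further.
* No paired designs, covariates or batch correction anywhere.
* GO collections are consumed as flat GMT sets; no is_a/part_of graph
  propagation.
* The biomarker rank combination weights fold change and CV equally; that
  is a documented formalization of a verbal criterion, not an optimum.
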