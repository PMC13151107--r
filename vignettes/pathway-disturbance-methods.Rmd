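---
title: "Scoring pathway disturbance from germline and somatic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pathway disturbance from germline and somatic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdisturb)
```

## The model

`pathdisturb` quantifies, for a single cancer sample, how strongly each
biological pathway is disturbed by the sample's DNA alterations, separately
for germline variants and somatic mutations. The method rests on a gene-level
impact score that combines two orthogonal quantities:

* **Variant deleteriousness.** Each variant carries a Phred-scaled CADD score
  (0–99, higher = more damaging). For a gene $g$ with $N$ qualifying variants,
  $$\mathrm{geneCADD}_g = \frac{\sum_{n=1}^{N} \mathrm{CADD}_n}{100\,N},$$
  the scaled mean, bounded by 0.99.
* **Gene essentiality.** A DepMap CRISPR gene-dependency probability in
  $[0,1]$ (1 = knockout kills the cell line), averaged over the cell lines of
  the sample's cancer-type lineage. A `pan-cancer` average over all cell
  lines is the fallback for cancer types without a DepMap lineage — that
  fallback is this package's choice, not something the upstream method
  specifies.

The gene-level impact is the product
$\mathrm{impact}_g = \mathrm{geneCADD}_g \cdot \mathrm{geneDepMap}_g$, set to
0 for genes called not expressed (below). A damaging variant in a gene whose
loss the cell tolerates scores low, as does a benign variant in an essential
gene.

### Variant filters

Variants are taken from standard VCFs (GRCh38), multi-allelic records split
one row per alternate allele, and VAF recomputed as AD/DP of the named allele
(any caller-provided AF field is ignored so the semantics are uniform).
Defaults:

| origin   | AD      | VAF      | gnomAD AF   | CADD   |
|----------|---------|----------|-------------|--------|
| somatic  | ≥ 5     | > 5%     | —           | ≥ 15   |
| germline | ≥ 5     | > 20%    | ≤ 0.001     | ≥ 15   |

The CADD cutoff is configurable (`run_config(cadd_cutoff = …)`). Two
missing-annotation rules are deliberate package decisions: a variant absent
from the gnomAD table is treated as rare (absence from a population database
is itself evidence of rarity; such passes are tallied), while a variant
absent from the CADD table is dropped whenever the CADD cutoff is positive,
because its deleteriousness is unknowable. Indel lookup keys are
parsimony-trimmed (shared suffix, then shared prefix with position advance)
so dialect differences between callers and lookup tables do not break joins;
full left-alignment would need the reference sequence and is out of scope.

### The expression gate

When a raw-count expression table is supplied, genes are called expressed or
not from a $KS = 5$ component univariate Gaussian mixture fitted to
$\log_2(\mathrm{count}+1)$ values. The EM fit is k-means-initialised with 10
restarts keeping the best log-likelihood (the reference implementation's
exact initialisation is not reproduced; only the post-fit cutoff procedure is
constrained). The five components are split into a low and a high group by
k-means ($k = 2$) on the $KS \times 3$ matrix of per-component (weight, mean,
sd), clustered on its raw scale; with the rows sorted by mean, the two
extreme components seed the clustering, which makes the split deterministic.
An earlier design standardised the three columns so that no single parameter
would dominate the Euclidean distance, but that proved wrong in testing:
whenever EM fits a narrow spike component (common with the zero atom of
count data), the spike's extreme weight/sd coordinates hijack the split —
one seed left the largest-mean component in the *low* group and the gate
silenced 80% of genuinely expressed genes. On the raw scale the mean axis
dominates, which is exactly what a low/high expression split is about.
The decision boundary follows the maximum a
posteriori rule: the summed weighted densities of the two groups are
evaluated on a 10,001-point grid between the extreme component means, and
every sign change of their difference is a cutoff. The smallest cutoff is the
gate; a gene is expressed iff its value is **at or above** it ("lower than
the smallest cutoff" means not expressed, so equality passes). Without
expression data the gate is the identity — results equal a cutoff of
$-\infty$. Genes present in the variant data but absent from the expression
table are treated as expressed (no evidence of silence) and tallied.

An earlier implementation scanned for the boundary only between adjacent
components of opposite groups; when the density crossing fell outside that
bracket the scan degenerated to the bracket edge. The global grid avoids
this edge case and is what the package uses.

### The enrichment statistic

Genes of the annotation space (the union of all gene-set members) that pass
the expression gate form the universe of size $N$; genes without qualifying
variants occupy ranks with impact 0. Unexpressed genes are *excluded from the
universe entirely* (changing the miss denominator), matching a universe
defined as expressed genes; this is one reading of an ambiguous point and is
fixed here. Genes are ranked by impact descending, ties broken by symbol
ascending, so the ranking is reproducible across platforms.

For a pathway $S$ with $N_S$ members in the universe, walking the ranking
accumulates
$$P_{hit}(S,i) = \sum_{j \le i,\, g_j \in S} \frac{\mathrm{impact}_j}{\mathrm{impact}_{total}},
\qquad
P_{miss}(S,i) = \frac{\#\{j \le i : g_j \notin S\}}{N - N_S},$$
where $\mathrm{impact}_{total}$ sums over **all** universe genes — a
deliberate deviation from classical GSEA's within-ranking normalisation that
is preserved exactly. The enrichment score is the maximum of the signed
deviation $P_{hit} - P_{miss}$, floored at 0 (positive scoring): impact
scores are non-negative and only enrichment, never depletion, is meaningful
disturbance. The absolute-deviation variant is available
(`score_type = "abs"`) but is not the default.

Because the deviation can only peak immediately after a hit, the permutation
engine evaluates it at the $N_S$ hit positions in $O(N_S)$ per permutation;
the tests verify this fast path against a naive full walk exactly.

### Significance, NES and the disturbance score

The null draws `nperm` uniform random $N_S$-subsets of the universe
(6000 permutations for somatic, 1000 for germline by default) and reports the
plus-one empirical p-value $(1 + \#\{ES_{perm} \ge ES_{obs}\})/(nperm+1)$.
Each pathway derives its RNG stream from the master seed plus a hash of the
pathway id, so results do not depend on scoring order. NES is the observed ES
divided by the mean permuted ES (0/0 defined as 0; a positive ES over a zero
null mean is flagged `NA`). p-values are BH-adjusted within one (sample,
origin, annotation source) family, with disturbance called at adjusted
p < 0.25. The per-pathway disturbance score is
$$\mathrm{dscore}(S) = NES(S) \cdot \frac{\sum_{g \in S} \mathrm{impact}_g}{N_S},$$
comparable across samples because the mean member impact re-anchors the
within-sample NES. Pathways with fewer than 2 members in the universe are
skipped: a singleton "pathway" is a gene test, not a set test.

A calibration subtlety: under the positive convention a random gene set
scored against diffuse iid impacts has ES exactly 0 most of the time, so the
plus-one p-value carries a large atom at 1. It is *valid* (conservative),
but not uniform; the acceptance test therefore checks uniformity of the
randomized tie-broken p-value — exactly $U(0,1)$ under exchangeability — and
sub-uniformity of the reported p. `permutation_test()` returns the tie
decomposition (`n_gt`, `n_eq`) to make that check possible.

## Phenotypic convergence

Across a cohort, a pathway converges phenotypically when different members
are altered in different individuals. With $k_g$ the number of samples in
which member $g$ is altered (≥ 1 variant passing the origin's policy),
$$C(S) = \sum_{g \in S} \binom{k_g}{2}$$
counts sample pairs sharing an altered member. The normalisation — stated
upstream only in words — is implemented as division by
$N_S \cdot \binom{M}{2}$ (set size times possible sample pairs).
Significance comes from 1000 random gene sets of size $N_S$ drawn from the
genes assessable in the cohort (the alteration matrix's columns, not the full
annotation space: sampling unassessable genes would deflate the null),
yielding a Z-score and a plus-one empirical p. The Z is identical whether
computed on the raw or the normalised score, since the normalisation is a
positive constant for fixed $(N_S, M)$.

## Pathway graphs

GO biological-process terms parse from OBO into a directed child→parent graph
with the five relation types (`is_a`, `part_of`, `regulates`,
`positively_regulates`, `negatively_regulates`), rooted at `GO:0008150`;
obsolete terms are dropped. KEGG relations form an undirected "related"
graph with duplicates and self-loops removed. The significant subgraph for GO
keeps the significant nodes plus every non-significant node on a parent-edge
path from a significant node to the root — implemented as the BFS ancestors
from which the root is reachable, over **all five** relation types (a flag
restricts this; whether the original traverses only `is_a`/`part_of` is not
stated). A significant node disconnected from the root is kept as an
isolated component with a warning; the empty significant set yields the root
alone. KEGG has no root, so its subgraph is the significant nodes plus
one-hop neighbours. Exports are plain text — a sorted TSV edge list and a
JSON node table carrying id, name, disturbance score, significance class and
$\ln(\text{gene count})$ size — and round-trip through `import_subgraph()`.

## What the synthetic data emulate

`fixture_spec()` states the testing world once:

* signal variants carry CADD $\sim U(15, 40)$ (bracketing the ≥ 15
  deleteriousness threshold, which upstream motivates as the median of
  canonical splice-site changes); background noise variants $U(0, 10)$;
* germline variants meant to pass carry gnomAD AF ≤ 0.001;
* expression follows the two-component $\log_2$ mixture
  $\mathcal N(0.5, 0.3)$ / $\mathcal N(8, 1)$ also used by the gate tests;
  genes engineered to carry signal are drawn from the high component so the
  gate cannot erase the constructed truth;
* designated disturbed pathways hold 90% of the sample's impact mass, made
  exact by rescaling background gene dependencies after the draw;
* convergent cohorts alter each member of the designated pathway with
  probability 0.35 per sample against 0.05 for background genes, so samples
  share the pathway through different genes.

The generator does **not** mimic real mutation spectra, trinucleotide
context, linkage, or pathway-size distributions of GO/KEGG. A green
end-to-end test therefore establishes that the machinery recovers planted
signal at realistic magnitudes — not that the biological conclusions of any
cohort analysis would replicate.

## Numerical choices and edge cases

* EM: sd floor at $10^{-4} \cdot \mathrm{sd}(x)$, relative log-likelihood
  tolerance $10^{-6}$, 2000-iteration cap (count data put a point mass at
  zero, which slows convergence); collapse of a component invalidates the
  restart. Constant input is an error.
* Permutation subsets are drawn with replacement and duplicate columns
  redrawn (fast for $N_S \ll N$), falling back to exact per-column sampling
  for dense sets; a single radix sort orders all draws at once.
* `impact_total = 0` (no scored gene) yields an all-zero record per pathway
  rather than an error; a sample with no passing variants returns an empty
  table and a clean exit.
* BH uses `stats::p.adjust`; ranking ties break by gene symbol; every
  emitted record satisfies `dscore == nes * mean_impact` to $10^{-12}$.

## Known limitations

Copy-number and structural variants, epigenetics, and directional
(activating vs inactivating) effects are out of scope, as are multi-gene
variant annotation, leading-edge reporting, and cross-sample NES
normalisation. DepMap essentiality reflects in-vitro survival only. The
gnomAD-missing-passes and CADD-missing-drops rules above are judgment calls
on points the upstream description leaves open.
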