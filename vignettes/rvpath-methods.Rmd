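---
title: "Pathway-level rare-variant association testing with rvpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level rare-variant association testing with rvpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvpath)
```

## The problem

Individually, rare variants (minor allele frequency well below 5%) carry too
little information for SNP-by-SNP association testing: a variant carried by a
handful of individuals cannot, on its own, produce a stable test statistic.
Burden methods answer this by combining the rare variants of a *gene* into one
statistic. Pathway (gene-set) analysis goes one level higher and asks whether
a predefined *set* of genes — typically a biological pathway — is associated
with a dichotomous phenotype.

With rare variants there are two competing ways to get from variants to a
set-level p-value, and this package implements both so they can be compared
on equal terms:

1. **Direct pooling** — treat all SNPs of all genes in the set as one big
   "gene" and apply a rare-variant burden statistic to the pool
   (`direct_set_test()`).
2. **Gene-level aggregation** — compute a burden p-value per gene, then
   aggregate the per-gene p-values over the set with a classical pathway
   statistic (`set_test()` with a `_Fisher`, `_KS` or `_GSEA` method).

Crossing the two burden statistics (WS, CMC) with the two strategies (direct;
Fisher / KS / GSEA aggregation) gives the eight methods the evaluation
harness compares: `WS`, `CMC`, `WS_Fisher`, `CMC_Fisher`, `WS_KS`, `CMC_KS`,
`WS_GSEA`, `CMC_GSEA`.

## The statistics

### Weighted-sum (WS) burden test

For variant $i$, let $m_i^U$ be the number of minor alleles among unaffected
individuals and $n_i^U$ the number of genotyped unaffected individuals. The
control-anchored, add-one smoothed frequency and the resulting weight are

$$q_i = \frac{m_i^U + 1}{2 n_i^U + 2}, \qquad
  w_i = \sqrt{n_i\, q_i (1 - q_i)},$$

with $n_i$ the total number of genotyped individuals. Each individual gets a
genetic score $\gamma_j = \sum_i g_{ij} / w_i$ over the group's variants
(dosage $g_{ij} \in \{0,1,2\}$; missing dosages contribute 0 but are excluded
from the frequency denominators). The statistic is the rank sum
$x = \sum_{j\,\text{affected}} \operatorname{rank}(\gamma_j)$, with midranks
for ties. Because the weights depend on who is unaffected, a phenotype
permutation must recompute $q$, $w$, $\gamma$ and $x$ from scratch; the
one-sided p-value is $(1 + \#\{x^* \ge x_{\text{obs}}\})/(B + 1)$. The
add-one estimator keeps p-values strictly positive, which the Fisher
aggregator downstream requires. On samples small enough to enumerate,
`ws_test(..., exhaustive = TRUE)` replaces sampling with the exact
relabeling distribution.

### Combined multivariate collapsing (CMC)

Variants below the `rare_threshold` MAF cutoff (default 0.05, the common
convention; configurable everywhere it appears) are collapsed per collapsing
unit into a 0/1 carrier indicator; common variants stay as dosage columns.
The case and control mean vectors of the resulting design are compared with
Hotelling's statistic

$$T^2 = \frac{n_1 n_2}{n_1 + n_2}\, \mathbf d' S^{-1} \mathbf d, \qquad
  F = T^2\,\frac{n_1 + n_2 - p - 1}{p\,(n_1 + n_2 - 2)}
  \sim F(p,\; n_1 + n_2 - p - 1),$$

read against the asymptotic F distribution (upper tail). A singular pooled
covariance falls back to the Moore–Penrose pseudo-inverse with degrees of
freedom from the matrix rank, under a warning. For set-level tests the
default collapsing unit is the gene (one indicator per gene plus the common
variants); `grouping = "set"` collapses the whole set into one indicator.

### Aggregation statistics

Gene scores are $s_g = -\log p_g$ from one burden method over all genes.

* **Fisher**: $X^2 = -2 \sum_{g \in S} \ln p_g$ against $\chi^2_{2|S|}$.
  Asymptotic p-values are floored at $10^{-300}$ before the log so the
  transform never overflows; permutation p-values are already bounded away
  from 0 by the add-one estimator.
* **KS**: two-sample Kolmogorov–Smirnov statistic between in-set and
  out-of-set scores, with the asymptotic Kolmogorov distribution at
  effective size $n_1 n_2/(n_1+n_2)$. Two-sided by default
  (`ks_alternative` switches to the one-sided "in-set larger" variant);
  the paper family of methods does not fix a sidedness, and two-sided is
  the safer default when the direction of deviation is unknown.
* **GSEA** (weighted KS): genes ranked by score (descending; ties broken by
  gene id so results are platform-independent), a running sum gains
  $s_g^{\,\tau} / \sum_{h \in S} s_h^{\,\tau}$ at in-set genes and loses
  $1/(N - |S|)$ at out-of-set genes; the enrichment score is the signed
  extremum. The weight exponent $\tau$ defaults to 1 (the standard weighted
  statistic); $\tau = 0$ recovers the classic unweighted KS running
  statistic. If every in-set weighted score is zero, hits are weighted
  uniformly ($1/|S|$) under a warning.

GSEA significance uses phenotype permutation: each outer permutation
re-shuffles the labels and recomputes the *entire* gene score profile before
recomputing the enrichment score. For WS scores this nests one permutation
test inside another. Two design choices tame the multiplicative cost:

* The inner WS null for a gene is drawn once per (gene, replicate) and
  reused across the outer permutations (`nested = FALSE`, the default).
  This is statistically faithful because permutations of a permuted label
  vector are exactly the permutations of the original vector — the inner
  reference distribution is identical either way; only the independence of
  inner draws across outer permutations is given up. `nested = TRUE`
  restores fully independent inner draws at multiplicative cost.
* The per-gene WS p-values inside GSEA use `inner_permutations` (default
  100), coarser than a standalone gene test; the enrichment score depends
  on the profile's ranking, which is robust to this granularity.

## Benchmark set construction and the spurious-gene filter

`build_sets()` reproduces the four-category benchmark collection: (1)
`causal_mix` sets holding $C$ causal genes (by default
$C \in \{5,10,15,20,25\}$, 100 sets each) topped up with noncausal genes;
(2) `null` sets of noncausal genes only; (3) `null_nonspurious` sets drawn
from noncausal genes that also pass the spurious filter; (4) the category-1
sets with their noncausal members redrawn from the nonspurious pool —
category 4 deliberately reuses the category-1 causal draws (they are
"modified" copies, not fresh draws), so power comparisons between the two
isolate the effect of spurious noncausal members.

A noncausal gene is *spurious* when both burden methods flag it repeatedly
across replicates: the count of replicates with WS **and** CMC p-values
below 0.05 in the same replicate exceeds 15 of 200. The joint-count reading
is the default (`mode = "joint"`); a marginal reading (each method's own
count exceeds the threshold) is available as `mode = "marginal"` since the
rule's phrasing admits both. Thresholds scale with the replicate count
(e.g. "more than 3.75", i.e. at least 4, of 50).

`set_features()` computes the five per-set covariates used to explain which
method wins: causal-gene count, causal-SNP count, total SNP count, average
causal-gene MAF (causal-SNP MAFs summed within each causal gene, then
averaged over the set's causal genes), and the weighted risk score
$\sum_{\text{causal SNPs} \in S} \text{MAF} \times \beta$.
`best_method_regression()` fits the logistic model of "WS was (co-)best" on
those five features; ties for best are counted as WS-best when WS is in the
argmax set.

## The synthetic mini-exome

The generator emulates the structure of the GAW17-style benchmark without
its access-restricted data:

* **Genotypes.** Per-variant MAFs from a scaled Beta(0.2, 2) on
  $(7.17\times10^{-4}, 0.5]$ — a rare-dominated spectrum matching the
  printed MAF range; the shape itself is this package's choice since only
  the range is published. Dosages are two independent allele draws
  (Hardy–Weinberg), variants independent — so no background linkage
  disequilibrium, no population structure.
* **Disease model.** Additive logistic on minor-allele dosage:
  $\operatorname{logit} P(\text{case}) = \beta_0 + \sum_i \beta_i g_{ij}$,
  the minimal model consistent with a per-SNP log-odds "true risk"
  $\beta_i$. The benchmark's own generative model is undisclosed, so this
  is a stand-in, not a reconstruction. $\beta_0$ is calibrated by monotone
  root bracketing so the mean case probability hits `target_prevalence`
  (default 0.3) to within $10^{-6}$.
* **Effects.** Causal $\beta$ defaults to Uniform(0.5, 2.0) on the log-odds
  scale (odds ratios ≈ 1.6–7.4), in line with the effect sizes rare-variant
  burden simulations conventionally plant; 160 causal SNPs in 36 causal
  genes at full scale, every causal gene hosting at least one.
* **Phenotype replicates.** Many independent Bernoulli draws on the *same*
  fixed genotypes (200 at full scale), mirroring the replicate design.
* **Spurious association.** `ld_spurious_genes` noncausal genes get their
  columns replaced by copies of causal-SNP columns with per-allele flip
  probability `1 - ld_fidelity`. Source SNPs are sampled with probability
  proportional to their risk contribution (MAF × β): a copied column only
  creates spurious association if it carries association, so the mechanism
  deliberately mirrors signal-bearing causal variants rather than, say, a
  causal SNP with a single carrier. This is a minimal stand-in for
  gametic-phase disequilibrium — it produces noncausal genes correlated
  with causal ones (hence repeatedly, spuriously significant) without
  haplotype machinery, and does not emulate graded LD decay or population
  stratification.

What passing tests on this generator do **not** show: behaviour under real
LD structure, stratified populations, missingness patterns of real
sequencing, or the benchmark's actual (interaction-bearing, partly
unmeasured) disease model. The harness results are qualitative twins of the
published design — calibration on nonspurious nulls, inflation from
LD-copied genes, power growing with the causal-gene count, WS-direct
winning under many weak effects and Fisher aggregation under few strong
ones — not numeric reproductions.

## Problem sizes and numerical choices

The package-level defaults are full GAW17 scale (697 individuals, 3,205
genes, 200 replicates, 1,000 WS permutations). All shipped analyses,
tests and the acceptance script run the desk-scale profile
(`desk_profile()`: 500 individuals, 300 genes, mean 3 SNPs/gene, 72 causal
SNPs in 36 causal genes, 50 replicates) with 200 WS permutations and 100
GSEA outer permutations — sizes chosen so a full eight-method evaluation
completes in minutes on one CPU while keeping every qualitative contrast
measurable. 72 causal SNPs (not a scaled 160) because 36 causal genes at a
mean of 3 SNPs per gene cannot host 160; the generator treats that as an
infeasible configuration and says so.

Numerical conventions, in one place:

* Permutation p-values use the add-one estimator $(1+b)/(1+B)$; they can
  never be 0 and never exceed 1.
* Rank ties use midranks; GSEA ranking ties break by gene id; permutation
  count comparisons use a $10^{-12}$ slack so floating-point equality of
  rank sums is treated as a tie, conservatively.
* Asymptotic p-values are floored at $10^{-300}$ before $-\log$.
* Degenerate units (a gene or design with no genotype variation) are
  dropped from testing and scored 0 in profiles, under a warning; an
  entirely constant design is an error for a single test.
* All randomness flows from one master seed; per-unit streams are derived
  by hashing `(seed, purpose, unit, replicate)`, so results are identical
  whatever the processing order, and the same evaluation run can be
  reproduced piecewise by standalone calls (`ws_test` on a set with the
  same label, seed and replicate gives the byte-identical p-value the
  harness recorded). One exception: inside `evaluate_methods()` the GSEA
  outer phenotype permutations are drawn once per replicate and shared by
  every set (and both score bases), because the permuted gene profiles do
  not depend on the set — each set's test remains a valid permutation
  test, and the full gene-profile recomputation is paid once instead of
  once per set. A standalone `gsea_test()` draws its own per-set stream.

A note on type-I-error experiments with this replicate design: with a
causal phenotype on one fixed genotype draw, set-level rejections are
correlated across replicates — individuals with persistently high case
propensity may, by chance of the single draw, also carry high rare-allele
load in particular null sets. Rejection rates estimated on one draw then
scatter around the nominal level more than binomial theory suggests, even
for an exactly valid test. Calibration checks in this package therefore use
signal-free (all-$\beta$-zero) phenotypes, under which the permutation
tests are conditionally exact; the causal model is reserved for power and
best-method experiments, where that correlation is part of the design being
emulated.

## Known limitations

* One gene per SNP: real exomes have overlapping genes; the benchmark's
  "at least one gene" membership is simplified to exactly one.
* Multi-allelic VCF records are rejected, not split; the methods are
  defined on biallelic minor-allele counts.
* No covariates, no quantitative phenotypes, no population-stratification
  correction, no variance-component (SKAT-family) tests.
* GSEA reports per-set p-values only — no normalized enrichment score or
  cross-set FDR.
* The LD-copy mechanism produces block-copy correlation, not graded LD.
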