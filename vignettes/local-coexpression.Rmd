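---
title: "Identifying and characterising local gene co-expression with locop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterising local gene co-expression with locop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locop)
```

## The problem and the statistic

Genes located near each other in the genome are frequently transcribed as
a group: their expression levels co-vary across individuals. `locop`
detects such *co-expressed gene pairs* (COPs) from a genes × individuals
expression matrix and then asks what distinguishes them — chromatin
insulation, enhancer wiring, transcription-factor load, shared genetic
regulation — and what their shared regulatory variants imply for complex
traits.

The core difficulty is that a gene's chance of showing a high correlation
with *some* neighbour grows with the number of neighbours in its cis
window. The discovery statistic handles this with a per-gene permutation
null:

1. For gene $g$ with cis set $C_g$ (genes with TSS within 1 Mb), compute
   the observed Pearson correlations $r_{gh}$, $h \in C_g$, on
   inverse-normal-transformed expression.
2. Shuffle $g$'s values across individuals $R$ times, leaving every other
   gene untouched, and record per shuffle the maximum $|r|$ over $C_g$.
   Keeping the cis genes intact preserves their correlation structure, so
   the null max accounts for both the size and the internal redundancy of
   the cis set.
3. The *adjusted p-value* of pair $(g,h)$ is $(k + 1)/(R + 1)$ where $k$
   counts null maxima at or above $|r_{gh}|$.
4. Benjamini–Hochberg is applied to the per-gene best adjusted p-values;
   the largest adjusted p passing at FDR 1% becomes the global threshold,
   and a pair is called when its adjusted p is at or below the threshold
   *from both genes' nulls*.

Pairs with $|r| \ge 0.99$ are treated as technical artifacts (e.g.
mis-mapped duplicated loci) and removed before the BH step.

### Conventions chosen where the procedure is underdetermined

Several details of this scheme admit more than one reading; the package
fixes them as follows and exposes switches where both readings are useful.

* **Two-sided statistic.** The null compares $|r|$ against null maxima of
  $|r|$, so negative co-expression is discoverable (a `signed` mode is
  available). Negative pairs are subsequently removed by
  `apply_pair_filters()` for feature analysis, where positive and
  negative co-expression are not expected to share mechanisms.
* **Empirical p estimator.** $(k+1)/(R+1)$ never returns zero and makes
  the null p-value exactly uniform on its discrete grid. Ties between an
  observed value and a null maximum count toward the null (conservative).
* **Threshold comparison.** Calling uses $\le$ the largest BH-passing
  adjusted p. On the discrete $(k+1)/(R+1)$ grid a strict inequality
  would silently drop the boundary value, making results depend on $R$ in
  a brittle way.
* **Artifact removal order.** Artifacts are removed before BH so that a
  gene whose best pair is an artifact is represented by its best genuine
  pair.
* **Reproducible permutation streams.** Every stochastic stage draws its
  seed as `derive_seed(seed, key)` — a stable rolling hash of the global
  seed and a stage key (e.g. `"copnull:GENE7"`). Discovery output is
  therefore independent of gene iteration order, and any per-gene null
  can be regenerated in isolation; the test suite exploits this to check
  the fast implementation permutation-for-permutation against a plain
  double-loop oracle.

Note the interplay of $R$, the number of genes $m$ and the FDR level: the
smallest achievable adjusted p is $1/(R+1)$, so BH at level $q$ can only
call genes when $1/(R+1) \cdot m/k \le q$ for the number $k$ of truly
co-expressed genes. $R = 1000$ (the default) is comfortable for
genome-scale runs; reduced-$R$ runs in tests and scripts are sized so
this constraint is satisfied (e.g. $R = 500$ when ~40% of 2,000 genes
carry signal).

## Preprocessing

`preprocess_expression()` applies, in order: gene filtering (biotype
whitelist, excluded regions such as an MHC-like locus keyed on TSS
membership, excluded chromosomes, a ≥50% zero-fraction ceiling, optional
minimum-expression rules), OLS residualization on known covariates plus
optional expression PCs, and a rank-based inverse-normal transform (INT).

* Hidden-factor correction uses plain PCA scores of the gene-standardized
  matrix: deterministic, dependency-light, and the established analogue
  of factor-model residualization in eQTL practice. Removing many PCs
  also strips broad trans co-expression, which concentrates power on
  local effects.
* INT maps ranks to normal quantiles with the $\mathrm{rank}/(n+1)$
  convention and average ranks for ties; it is idempotent, and after it
  Pearson correlations are rank correlations, robust to the raw scale.
* Default order is residualize → INT, so the values entering discovery
  are exactly N(0,1) per gene; the reverse order is available by calling
  the steps directly.

## Matched controls

Feature comparisons between COPs and non-COPs are confounded by distance
(most COPs are close pairs, and most annotations scale with distance).
`match_noncops()` samples, per COP, one tested pair that is not called,
has both adjusted p-values > 0.5 (so it is confidently null, not a
near-miss), and differs in TSS distance by at most 100 bp — without
replacement, visiting COPs in a seed-shuffled order so scarce candidates
are not systematically awarded to early COPs. `match_transcops()` is the
correlation-matched analogue for distant/cross-chromosome pairs, with
"at most 5% different" read as *relative* to the COP's correlation.

With matched controls a distance-only classifier should be uninformative.
At small control-set sizes (tens of pairs) the repeated-split AUC shows a
downward finite-sample bias — the fitted slope anti-correlates with the
test-set composition when feature values are pairwise tied — so the
calibrated ≈0.5 check is asserted at full scale (~750 matched pairs),
where the bias is within ±0.03.

## Feature metrics and the AUC harness

All interval work uses 0-based half-open coordinates; "between the TSSs"
is the open interval between the two TSS positions, and overlap means any
intersection. The inverted-CTCF metric is $n_+ \times n_-$ over
oppositely oriented motifs between the TSSs — every opposite-orientation
pairing is a candidate loop anchor. TF-motif totals sum occurrences per
±50 kb window, so an instance overlapping both windows counts once per
window. Missing annotation data is zero-filled (absence of evidence is
scored as absence of signal, keeping the feature table complete).

`evaluate_model()` mirrors standard practice: stratified 80/20 split, the
features standardized with training-fold statistics, unregularized
logistic regression with intercept, ROC AUC on the held-out pairs, 50
repetitions with per-repetition derived seeds, mean AUC reported.
Standardization only stabilizes the optimizer — AUC is invariant to
monotone feature maps, which the tests assert.

## cis-eQTL mapping and sharing

The association test is simple OLS of INT expression on genotype dosage
(two-sided t-test), equivalent to correlation. The permutation pass
shuffles the phenotype, keeps the best association p per shuffle, and
reports either the empirical $(k+1)/(R+1)$ (default) or a Beta CDF fitted
to the null minima by the method of moments — the approximation used by
standard eQTL mappers to sharpen small-$R$ adjusted p-values; on null
genes the two agree within 0.02 at $R = 1000$. eGenes are the BH-passing
genes at FDR 5%.

eQTL *sharing* asks whether the lead eQTL of each eGene in a pair also
associates with the partner gene (nominal p < 0.05) with the same effect
sign; the pair score is 0, 1 or 2. If the lead-partner association was
not retained by the nominal pass it is recomputed directly rather than
treated as missing. Only eGene leads are considered, and any tested
partner gene qualifies.

## Enrichment tests

Pair-level functional relatedness (same GO term, pathway, complex,
paralogy) uses one-sided Fisher tests of COP status against relatedness
over all tested pairs. Reported odds ratios are the sample cross-product
(with a 0.5 continuity correction on zero cells), matching how 2×2
effects are usually quoted; p-values come from the exact test.

The annotation-overlap enrichment preserves the layout of annotations
around genes: each gene's neighbourhood — its annotation intervals as
TSS-relative offsets, mirrored for minus-strand genes — is randomly
reassigned among the genes in each of (by default) 10,000 permutations.
The expected overlap is the permutation mean; the p-value is the
two-sided empirical probability with floor $1/(n_{perm}+1)$; and the odds
ratio compares observed vs *rounded* expected counts in a 2×2 layout
(expected counts are not integers; rounding is the documented and tested
choice). Granularity is gene–eQTL pairs: a variant leading two genes
counts twice.

## GWAS pleiotropy

A variant's pleiotropy is the number of traits with association p
strictly below 5e-8. Shared vs other lead eQTLs are compared by Fisher
tests on the ≥1-trait and >1-trait proportions (over all variants) and
by a two-sided Wilcoxon rank-sum test on the counts, by default
restricted to variants associated with at least one trait (an
`include_zeros` switch inverts this). The genomic inflation factor is
$\lambda = \mathrm{median}(\chi^2_1\ \text{statistics})/0.45494$, with
the constant documented to the precision used; p-values of zero are
clipped to the smallest representable double. QQ backgrounds can be
subsampled (seed-controlled) to 10,000 variants.

Deduplication for pleiotropy is per unique variant, with "shared in at
least one tissue" dominating.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces a gene catalog (exponential TSS gaps,
random strands/biotypes over several chromosomes), expression in which
block members load on a shared latent factor (pairwise correlation =
loading², recovered after residualizing the generated confounders),
Binomial(2, MAF) genotypes with one planted cis variant per true pair
(affecting one gene, or both with equal sign for a `shared_fraction` of
pairs), annotation tracks whose density is thinned between or around
true-pair TSSs, enhancer–gene links with a boosted common enhancer per
true pair, power-law Hi-C contacts with a true-pair boost, GO-like terms
with a privately shared term per true pair, and GWAS p-values that are
Uniform(0,1) except for designated shared/other eQTL variants made
genome-wide significant in a focal trait (plus extras for shared ones).

Defaults are fixed at study-like conditions: 300 individuals, 2,000
genes over 5 chromosomes at 100 kb mean spacing, 260 blocks of 3 genes at
loading 0.85 (~780 true cis pairs), 5 confounders at strength 0.3, MAF
U(0.05, 0.5), standardized eQTL effect 0.5, shared fraction 0.5, 35 GWAS
traits. Track densities (20 CTCF sites, 10 CTCF motifs, 80 TF motifs, 40
enhancers per Mb) and depletion factors (0.5/0.6/0.6) are set so the
configured depletions dominate link-count noise at these scales — with
very sparse tracks the per-pair counts are nearly all zero and carry no
direction.

The generator deliberately omits: linkage disequilibrium beyond
independent variants, read-level sequencing noise, tissue-specific
expression programs, population structure, and any relationship between
annotation classes. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated on data satisfying their
assumptions — not that real tissues will show any particular effect size.

## Problem sizes used by the bundled checks

The test suite exercises discovery at 300–2,000 genes with 150–300
individuals and 80–500 permutations; the calibration script uses the
full default conditions (20 null datasets of 2,000 genes for the FDR
check; one 2,000-gene planted dataset with R = 500 for the
distance-neutrality check). These sizes give stable estimates of the
quantities asserted (fractions over 2,000 genes, AUC means over 50
splits) while remaining single-CPU friendly.

## Known limitations

* The permutation null is exchangeable across individuals; strong sample
  structure not captured by covariates would require a restricted
  permutation scheme.
* Lead-eQTL sharing is a pragmatic screen, not colocalization: allelic
  heterogeneity or LD contamination can produce sharing without a common
  causal variant. A posterior-probability colocalization step is outside
  the package's scope.
* The beta approximation to permutation p-values is fitted by moments,
  adequate for calling at FDR 5% but not for extreme tail precision.
* Cross-tissue sharing assumes COP calls are comparable across tissues
  (same FDR machinery per tissue), as in the discovery-replication
  design it implements.
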