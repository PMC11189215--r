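---
title: "Scanning for regulators of TE subfamily expression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for regulators of TE subfamily expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Transposable elements (TEs) — dominated in humans by the LINE-1 (L1)
retrotransposon family — are present in hundreds of thousands of mostly
immobile copies. Their aggregate RNA output varies across individuals and is
implicated in inflammation and aging phenotypes, but because individual
copies are fixed and poorly mappable, conventional per-locus eQTL mapping is
a weak instrument for finding *regulators of global TE activity*. The scan
implemented here inverts the unit of analysis: locus counts are aggregated
to the subfamily level, and every genotyped SNV is tested against each
subfamily's aggregate RNA level genome-wide — a trans-eQTL design in which a
hit means "this locus tracks the output of an entire TE subfamily".

The association model at every stage is bivariate ordinary least squares on
prepared expression:

$$y_{f} = \beta_0 + \beta \, d + \varepsilon,$$

where $d$ is the additive ALT-allele dosage (0/1/2) and $y_f$ the
inverse-normal-transformed expression of feature $f$; the slope is tested
two-sided with $n-2$ degrees of freedom. Covariates (lab batch, population,
sex, genotype PCs 1–2, net L1/Alu structural-variant copy number, viral
(EBV-like) expression) do not enter the scan model: they are removed
beforehand by per-feature least-squares residualization, after which the
inverse normal transform (Blom offset $c = 3/8$, average ranks on ties)
makes every feature exactly normally scored. This preparation makes the
bivariate scan equivalent to a covariate-adjusted scan while letting the
same matrix algebra drive millions of tests and their permutation
replicates.

Candidate regulators are **SNV–gene–TE trios**: an SNV significant in the
cis scan (gene within 1 Mb of the SNV, nearest-boundary distance), the
trans scan, and whose gene–TE expression regression survives BH adjustment,
all three gates strict at FDR < 0.05. Trans-significant SNVs with no
cis-significant gene are kept as *orphans*. Trio SNVs are greedily clumped
(500 kb, r² > 0.10, seeded by trans-eQTL p-value); genes linked to a clump's
index SNV are tier-1 candidates, genes linked only to non-index members
tier-2.

### Two significance thresholds

Each scan is thresholded by the stricter of:

* the largest p with Benjamini–Hochberg FDR < 0.05, and
* the largest p with **permutation-averaged empirical FDR** < 0.05, where
  the scan is repeated on expression matrices whose sample labels are
  scrambled (one shared permutation per round, preserving feature–feature
  correlation; 20 rounds by default) and
  $\mathrm{eFDR}(p) = \frac{\tfrac{1}{B}\sum_b \#\{p^{(b)}_{null} \le p\}}{\#\{p_{real} \le p\}}$,
  capped at 1.

The empirical threshold is taken at the largest *observed real* p with
eFDR < 0.05 (not a grid value); with no qualifying p it is 0 and nothing is
called.

### Mediation

For each trio the SNV→TE effect is decomposed by the standard three
regressions: $a$ (gene ~ SNV), $b$ and direct $c'$ (TE ~ gene + SNV), total
$c$ (TE ~ SNV); indirect $= ab$ and $c = c' + ab$ exactly for OLS (the
package asserts this identity to 1e-10). Significance comes from a
permutation p-value with the add-one convention. The permutation replaces
the mediator with $\hat a \, d + \text{permuted residual}$: the observed
SNV→gene association is preserved while the gene→TE path is broken. We
chose this over permuting the raw mediator vector because the raw scheme
tests the compound null ($a = 0$ and $b = 0$) and substantially over-calls
when the SNV→gene path is real but the gene plays no role in TE expression —
the situation that matters when screening trios that are cis-significant by
construction. Under the complete null the residual scheme is mildly
conservative, which we accept. Classification: *significant* (BH-adjusted
empirical p < 0.05 over the full trio family), *consistent*
(sign(indirect) = sign(total)), *partial* (consistent, with proportion
mediated strictly inside (0, 1) — the term is used without a numeric rule in
common practice; this operationalization is ours).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| MAF minimum | 0.01 | allele fraction | standard common-variant QC |
| HWE exact p minimum | 1e-6 | probability | tail-sensitive, hence an exact (Wigginton-style) test rather than chi-square |
| low-expression rule | CPM of 10 reads in the median library, exceeded (strictly) in ≥ 90% of samples | CPM | keeps ubiquitously expressed features; preserves power |
| cis window | 1e6 | bp | conventional cis-eQTL reach, nearest gene boundary |
| LD pruning | window 50 / step 10 / r² 0.1 | variants, r² | ancestry PCs from a near-independent panel |
| clumping | 500 kb, r² > 0.10 | bp, r² | one index SNV per association peak |
| scan permutations | 20 | rounds | empirical FDR averaging |
| mediation permutations | 1,000 (pipeline default; 30,000 for a final analysis) | draws | add-one p resolution 1/(B+1) |
| GSEA | weight 1, min set size 3, 1,000+ permutations | — | classic weighted-KS form |
| L1 flank for density tests | 5,000 | bp | "near the SNV" window, two-sided |

## What the synthetic cohort emulates — and what it does not

`sim_config()` defaults define the reference cohort used throughout the
tests and the acceptance script: 200 samples from 2 populations
(Balding–Nichols, $F_{st} = 0.1$), 2,000 SNVs on 2 autosomes with block-copy
LD (blocks of 10, copy probability 0.8), 200 genes, 400 TE loci placed to
realize 100 loci in each genomic stratum (exonic / intronic /
nearby-intergenic ≤ 5 kb / distal-intergenic > 5 kb), 20 TE subfamilies in 7
families with age-informative L1 names, negative-binomial counts
(dispersion 0.05, library sizes 1–2 M), one viral expression feature, 40
structural variants for the copy-number covariate, and 3 planted mediated
trios with $a = b = 0.6$ on the latent log scale and no direct path. These
values were fixed once as a realistic desk-scale miniature of a
lymphoblastoid-cohort eQTL design; effect sizes correspond to a strong but
not implausible common-variant regulator.

Features of real data deliberately *not* emulated: mappability and GC
artifacts in TE quantification, multi-mapping ambiguity between close
subfamilies, realistic recombination maps (LD here is blockwise by
construction), relatedness/kinship, and trans effects acting through more
than one gene. Passing tests therefore demonstrate correctness of the
statistics and the integration logic under a known truth — not robustness
to quantification artifacts.

One generator consequence worth knowing when reading mediation output: TE
counts are generated from the *latent* (noise-free) gene value, so the
gene's measurement noise is not transmitted to the TE. After covariate
residualization, the realized-gene term conditional on the SNV can carry
little of the transmitted signal, and the fitted decomposition then
allocates part of the planted $ab$ path to the direct term. Trio recovery
and the decomposition identity are unaffected; module-level tests validate
the mediation estimator on chains built from realized values.

## Numerical choices

* **HWE**: exact conditional enumeration with a $1+10^{-9}$ relative guard
  so probability-tied heterozygote configurations are always included.
* **Pruning victim rule**: within a window, the lower-MAF member of an
  offending pair is removed (tie → later position), pairs examined in
  position order; deterministic. The external tool's exact within-window
  rule is not published; this greedy rule is our documented stand-in.
* **GSEA tie-break**: the signed extremum of the running sum; when the
  positive and negative excursions tie in magnitude (this happens with
  rational increments), the positive one is taken, with a 1e-9 relative
  tolerance so the choice cannot depend on floating-point accumulation
  order. Ranking ties are broken by feature ID.
* **Normalization**: median-of-ratios size factors with
  $\log_2(\text{count}/s_j + 1)$; this package's variance stabilization is
  intentionally simple since every downstream statistic is rank- or
  permutation-based. The transform name is recorded in output provenance.
* **PCA**: per-variant standardization, zero-variance columns dropped with a
  warning; component signs fixed by making the largest-magnitude loading
  positive.
* **p-values** are never reported as exactly 0 (floored at the smallest
  positive double); stored tables carry 17 significant digits so thresholds
  re-derive exactly from disk.
* **Empirical-FDR threshold**: largest observed real p with eFDR < α
  (documented choice; a grid variant would differ only between observed
  p-values).
* **PheWAS-style enrichment**: the literal $1 - \mathrm{ecdf}$ p-value can
  be exactly 0; a conservative add-one alternative is always computed
  alongside and is the basis of the BH adjustment, while the literal value
  is reported for comparability.
* **Random SNV combinations** match the observed set size exactly and are
  drawn from the full scan universe (including the observed SNVs — whether
  the original analysis excluded them is unstated; including them is the
  conservative choice).

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` run at desk scale, chosen so
the whole suite completes in minutes on one core: oracle equivalences on
enumerable instances (HWE ≤ 50 genotypes, 1,000 random GSEA instances,
2ⁿ sign enumeration ≤ 10); calibration and recovery on the reference
cohort (20 end-to-end replicates for tier-1 trio recovery, 50 replicates
for cis power at $a$ = 0.6, 200 null trios for mediation calibration);
mediation permutations 200–1,000 in tests versus 30,000 for a final
analysis. Sizes are stated in the tests themselves.

## Known limitations

* The trans scan assumes aggregate subfamily counts are a meaningful
  phenotype; pervasive intronic TE read-through is only partially handled by
  the genomic-region stratification.
* Single-mediator decomposition: no multi-gene or chained mediation.
* The GSEA null permutes feature labels (set membership), not samples — the
  sample-permutation variant is impossible once only a ranked list is
  retained; normalized scores are comparable within an analysis, not across
  tools.
* No kinship or mixed-model correction: population structure is handled by
  PC covariates only.
* The empirical-FDR machinery stores all permutation p-values; at very
  large scan sizes this is memory-heavy and would need streaming
  summaries.
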