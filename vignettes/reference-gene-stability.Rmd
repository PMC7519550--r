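---
title: "Selecting and validating RT-qPCR reference genes with cqstab"
author: "cqstab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating RT-qPCR reference genes with cqstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqstab)
```

## The problem

RT-qPCR reports transcript abundance as the quantification cycle Cq: the
amplification cycle at which fluorescence crosses a threshold. Under perfect
doubling, one cycle corresponds to a two-fold difference in starting
template, so linear-scale relative expression is $2^{-Cq}$ and Cq itself is
a log-scale quantity. Comparing a gene of interest (GOI) across samples or
conditions requires dividing out sample-to-sample differences in input
material, which is done by normalizing against reference (housekeeping)
genes. A reference gene that itself drifts -- across passages of a cell
culture, between sub-clones, or under stress conditions -- silently distorts
every downstream fold change. `cqstab` implements the standard battery of
stability estimators used to choose reference genes from a candidate panel,
a consensus over them, and a statistical validation step that turns
"the normalization looked fine" into a reproducible verdict.

All estimators consume a `CqSet`: long-format Cq observations indexed by
gene, culture (biological replicate / sub-clone), passage, lysate within
passage, and technical replicate. By default, technical replicates are
averaged to lysate means *on the Cq scale* before any $2^{-Cq}$ transform
(`collapse = TRUE` everywhere); averaging on the log scale first matches how
plates are routinely summarised and avoids giving the linear-scale mean a
bias towards the lowest replicate. Replicate-level analysis is available via
`collapse = FALSE`. Incomplete gene-by-sample matrices are never imputed:
estimators that need a complete matrix fail with the explicit list of
missing cells, because any imputation changes every score.

## The stability estimators

**CV% (`cvStability`).** Each Cq is transformed to $2^{-Cq}$ and a gene is
scored by the coefficient of variation $100\,\mathrm{SD}/\mathrm{mean}$ of
those linear-scale values. CV% is invariant to a constant Cq offset (a pure
abundance difference), so it ranks variability, not expression level.

**geNorm (`geNorm`, `geNormV`).** With relative quantities
$Q_{gs} = 2^{\min_s Cq_{gs} - Cq_{gs}}$, the M value of gene $g$ is the mean
over other genes $h$ of $\mathrm{SD}_s(\log_2 Q_{gs}/Q_{hs})$. Because the
log-ratio differs from $-(Cq_{gs} - Cq_{hs})$ only by a constant, M is
independent of the anchor; the minimum-Cq anchor is used for numeric range.
The least stable (highest M) gene is removed iteratively, recording M at
each round, until two genes remain; those two cannot be separated by a
pairwise measure and are reported jointly at rank 1 (the next gene takes
rank 3). Ranks therefore follow the exclusion order. An M below 1 is
conventionally acceptable. `geNormV` then builds normalization factors from
the $n$ most stable genes and reports
$V_{n/n+1} = \mathrm{SD}_s(\log_2 NF_n/NF_{n+1})$; `optimalGeneCount`
applies the conventional rule that the smallest $n$ with $V < 0.15$ genes
suffice, and when no $V$ passes the cutoff it recommends nothing and flags
the minimising $n$ for user judgement.

**NormFinder (`normFinder`).** A model-based decomposition on the Cq scale:
$y_{gs} = \alpha_g + \beta_s + \varepsilon_{gs}$ with gene-specific
residual variance $\sigma^2_g$. With double-centred residuals
$r_{gs} = y_{gs} - \bar y_{g\cdot} - \bar y_{\cdot s} + \bar y_{\cdot\cdot}$
and $u_g = \sum_s r_{gs}^2/(n-1)$, the expectation
$E[u_g] = (1 - 2/k)\sigma_g^2 + \bar\sigma^2/k$ yields the unbiased
estimator $\hat\sigma_g^2 = (u_g - \bar u/(k-1))\cdot k/(k-2)$, truncated at
zero. The $k/(k-2)$ factor is the small-panel bias correction, which is why
at least three genes are required. In single-group mode the stability value
is $\hat\sigma_g$. In grouped mode (sub-clones analysed jointly) the
gene-by-group interaction $d_{gG}$ -- a systematic expression difference of
a gene between groups -- is estimated from the double-centred group-mean
profile, shrunk towards zero by the empirical-Bayes factor
$\gamma^2/(\gamma^2 + \hat\sigma^2_{gG}/n_G)$ with $\gamma^2$ the
across-gene interaction variance (method-of-moments, truncated at zero),
and a gene's stability averages $|\tilde d_{gG}| + \sqrt{\hat\sigma^2_{gG}/n_G}$
over groups, so both bias and noise count against a candidate. The best
pair minimises the same quantity for the average of two genes: in
single-group mode $\sqrt{(\hat\sigma^2_i + \hat\sigma^2_j)/4}$, in grouped
mode the shrunk pair bias plus the pair sampling SD. This pair definition is
this package's formulation; it reduces to the intuitive "two genes halve the
variance" rule and is documented here because published tools differ in
detail.

**BestKeeper (`bestKeeper`).** Descriptive statistics of each gene's
crossing points: geometric and arithmetic mean, range, a dispersion
"SD (± CP)" and its fold-change expression $2^{SD}$ (x-fold), plus the
BestKeeper index (per-sample geometric mean over all candidates) and
Pearson correlations of every pair and of each gene with the index. The
dispersion is by default the mean absolute deviation around the arithmetic
mean CP -- the original spreadsheet tool's convention -- with the sample SD
available via `dispersion = "sd"`; both are labelled in the output since
published descriptions are ambiguous about which is meant. Genes are ranked
smaller-dispersion-first and genes with dispersion above one cycle (more
than two-fold) are flagged inconsistent. Some sources instead describe the
criterion as "SD as close to 1 as possible but not above"; the
implementation keeps smaller-is-better and only flags values above 1, which
is the reading consistent with the dispersion being a noise measure.

**Comparative ΔCt (`comparativeDeltaCt`).** For each gene pair the SD over
samples of the Cq difference; a gene's score is the mean over all pairs it
participates in. Like geNorm's M (whose per-pair term is the same SD), it is
invariant to per-gene constant offsets.

All five estimators return a `StabilityTable` (lower score = more stable,
competition ranks). `consensusRanking` aggregates them by the geometric
mean of ranks -- the aggregation popularised by the RefFinder web tool. The
web tool internally re-runs the four algorithms with its own settings, so
its printed geomeans are generally not the geometric means of any published
rank columns; this package deliberately implements only the transparent
aggregation of the ranks you supply. `integratedSelection` codifies the
working-geneset choice: count top-$k$ appearances per estimator (default
$k = 3$), require no significant passage trend (default $\alpha = 0.05$),
and emit the best pair plus a cross-dataset "experimental candidate" as a
triplet, with a full audit log and lexicographic tie-breaks.

## Validation by normalization

`normalizationFactor` computes the per-sample geometric mean of the
reference genes' $2^{-Cq}$. `normalizeGoi` divides a target by it, rescales
so the calibrator passage (or condition) averages 1, and tests every other
group against the calibrator. The statistical gate (`chooseTest`) follows
standard practice: Shapiro-Wilk on the residuals at $\alpha = 0.05$ decides
between one-way ANOVA and Kruskal-Wallis, and per-group comparisons against
the calibrator use the matching two-sample test with Holm adjustment.
"Successful normalization" is codified as *no Holm-adjusted comparison
significant at $\alpha$*; `screenReferenceSets` tabulates that verdict over
a grid of GOIs and candidate sets. Groups whose values are constant (no
residual distribution to test) go to the rank-based branch, and fully
degenerate data return $P = 1$.

For stress conditions, `stressFoldChange` applies the conventional two-fold
rule to each reference gene: the linear fold change of mean expression
stress/control flags a gene when it leaves $(0.5, 2)$; the boundary is
inclusive up to floating-point round-off so a planted one-cycle shift flags
deterministically. Fold changes are reported as positive linear ratios with
their log2 alongside -- a linear ratio cannot be negative, and negative
"fold changes" in the literature are read here as log2 values.
`stressGoiTest` normalizes a target within each condition and compares
conditions with a two-sided Mann-Whitney test.

## The synthetic generator

The raw Cq data this kind of study produces are rarely deposited, so the
package ships a seeded generator whose defaults emulate a two-sub-clone
passage study of the MCF-7 breast-cancer cell line: 12 candidate reference
genes with baseline mean Cq and technical dispersion matching published
descriptive statistics for such a panel (e.g. ACTB 15.98 ± 0.26, GAPDH
17.13 ± 0.17, ribosomal RNAs near Cq 8, CCSER2 26.58 ± 0.21), culture A1
over passages 28-32 and culture A2 over passages 25-30 (set
`n_passages = 6`), 3 lysates per passage and 3 technical replicates per
lysate, with per-gene culture offsets reproducing the published sub-clone
differences. The model is additive on the Cq scale,

$$Cq_{gplr} = b_g + s_{g,c} + d_g(p-1) + P_p + L_{pl} + \varepsilon_{gplr},$$

because Cq is proportional to log template quantity and every estimator
above assumes log-scale additivity. $P_p \sim N(0, 0.15^2)$ and
$L_{pl} \sim N(0, 0.10^2)$ are gene-shared passage and lysate effects
modelling shared input-material variation; their defaults were chosen once
so that total per-gene SDs fall in the 0.2-0.6 cycle range typical of such
panels, and are documented as tunable rather than measured. $d_g$ is a
planted linear drift (cycles/passage) used to create known-unstable genes.
Random streams are named per (component, culture) so cultures are mutually
independent and regenerating a panel never perturbs a GOI stream.

`generateGoi` plants targets with exact passage-mean deviations (technical
noise is centred within passage): `stable` keeps all planted deviations
within ±0.5 cycles, `variable` forces at least one passage beyond ±0.5, and
`trend` plants a monotone trend of a given total amplitude; the half-cycle
boundary mirrors the convention that deviations beyond ±0.5 Cq are no
longer "stable". By default a GOI also inherits the panel's shared per-well
effect (the average gene-centred deviation of each well), because a real
target measured on the same lysates shares the material-level variation
that normalization exists to remove; without inheritance, passage-level
shared effects would register as genuine expression changes of the target
and the validation verdict would conflate the two.

What passing tests on these panels does *not* show about real data: the
generator has no amplification-efficiency differences between genes
(efficiency is fixed at 2 wherever $2^{-Cq}$ appears, with a per-call
`efficiency` hook), no plate or batch effects beyond the lysate level, no
missingness, and Gaussian noise throughout; heavy-tailed wells, primer
artefacts and inter-run calibration are out of scope.

## Numerical choices and edge cases

- Ties in ranks use competition ("1224") ranking; the geNorm final pair
  shares rank 1 by construction. Tied selection candidates break
  lexicographically, logged in the audit trail.
- Negative variance estimates (NormFinder) truncate at zero before square
  roots; degenerate noise-free inputs therefore give exactly zero
  stability values.
- `chooseTest` treats data whose total range is within $10^{-10}$ relative
  tolerance as constant ($P = 1$), and constant-within-group data go to the
  rank-based branch; this keeps exact self-normalization ($\mathrm{rel}
  \equiv 1$ up to round-off) from producing spurious significance.
- Passages are ordinal labels, not assumed consecutive; sample ordering in
  matrices is deterministic (culture, passage, lysate, replicate), and all
  scores are invariant to observation order and gene order.
- Cq validity is bounded by `maxCycles` (default 40, the usual cycle count
  of the instrument protocol); out-of-range or non-numeric values are
  rejected with the offending rows listed.

## Problem sizes used in the test battery

The bundled checks run on sizes chosen to finish in seconds while leaving
the statistics meaningful: 50 random 5-gene × 10-sample matrices for the
oracle-equivalence checks (every estimator against naive loops over its
defining formula, agreement to $10^{-10}$), 100 seeded runs for the
planted-truth recovery studies (a 0.3 cycles/passage drift gene must rank
last under geNorm, NormFinder and comparative ΔCt), and 200 seeded
all-stable runs for the type-I behaviour of the validation verdict
(observed false-failure rate well under 10% at $\alpha = 0.05$ with Holm
adjustment). `scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

- Efficiency-corrected quantification from dilution series (Pfaffl-style)
  is not implemented; efficiency enters only as a constant base.
- Grouped NormFinder follows the variance-decomposition model described
  above; other implementations differ in their exact shrinkage and pair
  formulas, so numeric values (not rankings) may differ across tools.
- The consensus is exactly the geometric mean of supplied ranks; no attempt
  is made to reproduce the RefFinder server's internal re-runs.
- Instrument raw formats (RDML, EDS) are not parsed; input is delimited
  text.
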