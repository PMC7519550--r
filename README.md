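# cqstab

Reference-gene stability and normalization validation for RT-qPCR Cq data.

RT-qPCR reports transcript abundance as the quantification cycle (Cq): the
amplification cycle at which fluorescence crosses a threshold, with one cycle
corresponding to a two-fold difference in template under perfect doubling
(linear-scale expression `2^-Cq`). Measuring a gene of interest across
conditions requires dividing by reference (housekeeping) genes, and an
unstable reference silently distorts every downstream fold change. `cqstab`
is for anyone who has a candidate reference panel measured over a structured
design — cultures/sub-clones × passages × lysates × technical replicates —
and needs to decide, reproducibly, which genes to normalize with and how
many.

The package implements:

- **Five stability estimators**, each returning per-gene scores and ranks
  (lower = more stable):
  - `cvStability()` — CV% of linear-scale expression `2^-Cq`;
  - `geNorm()` — M values, the mean SD of pairwise log2 expression ratios,
    with iterative exclusion of the least stable gene; `geNormV()` computes
    the pairwise variation `V(n/n+1) = SD(log2 NF_n/NF_{n+1})` and
    `optimalGeneCount()` applies the `V < 0.15` rule for how many reference
    genes suffice;
  - `normFinder()` — the variance-decomposition model on the Cq scale
    (additive gene + sample model, residual-based gene variances with the
    small-panel bias correction, inter-group bias shrinkage in grouped
    mode, best-pair search);
  - `bestKeeper()` — crossing-point descriptives, SD±CP dispersion and
    x-fold, the per-sample geometric-mean index, and all Pearson
    correlations;
  - `comparativeDeltaCt()` — mean SD of pairwise Cq differences.
- **Consensus and selection**: `consensusRanking()` (geometric mean of
  ranks) and `integratedSelection()` (top-k support across estimators and
  datasets, passage-trend criterion, audited pair + triplet choice).
- **Validation**: `normalizationFactor()` (geometric mean of reference
  `2^-Cq`), `normalizeGoi()` (calibrator-relative expression with a
  Shapiro-Wilk-gated ANOVA/Kruskal-Wallis test and Holm-adjusted
  comparisons, yielding a successful/failed verdict),
  `screenReferenceSets()`, and the nutrient-stress tools
  `stressFoldChange()` (two-fold rule) and `stressGoiTest()`
  (Mann-Whitney).
- **A seeded synthetic generator** (`defaultProfile()`,
  `generateReferencePanel()`, `generateGoi()`, `generateStressPanel()`)
  emulating a two-sub-clone MCF-7-like passage study with passage/lysate/
  technical variance components and planted instabilities, for benchmarking
  the estimators against known ground truth.

Data live in a `CqSet` (long-format Cq observations; see `readCqTable()` /
`writeCqTable()` for the CSV/TSV dialects). A thin command-line front end
over the same functions is in `inst/scripts/qstab.R`.

## Worked example

Using the bundled synthetic fixtures (generated by the package itself, see
`inst/extdata/`):

```r
library(cqstab)
panel <- readCqTable(system.file("extdata", "synthetic_panel_A1.csv",
                                 package = "cqstab"))
panel
#> CqSet with 540 observations (unit: tech_rep )
#>   genes   : 12 -- ACTB, CCSER2, GAPDH, HNRNPL, HSPCB, PCBP1 ...
#>   cultures: A1
#>   passages: 28, 29, 30, 31, 32

g <- geNorm(panel)
head(as.data.frame(g), 3)
#>      gene algorithm     score rank
#> 7    PGK1    genorm 0.1350253    1
#> 10 RNA28S    genorm 0.1350253    1
#> 1    ACTB    genorm 0.1470323    3
```

The geNorm final pair (PGK1, RNA28S here) shares rank 1 with the M value of
the two-gene set; every M is far below the conventional acceptability bound
of 1. The pairwise-variation series answers "how many reference genes do I
need":

```r
v <- geNormV(panel, g)
round(v[1:4], 4)
#>   V2/3   V3/4   V4/5   V5/6
#> 0.0436 0.0355 0.0269 0.0253
optimalGeneCount(v)$count
#> [1] 2
```

`V2/3 = 0.044 < 0.15`, so two reference genes already suffice for this
panel. Consensus across all five estimators (geometric mean of ranks,
smaller is better):

```r
cons <- consensusRanking(list(cvStability(panel), g, normFinder(panel),
                              bestKeeper(panel), comparativeDeltaCt(panel)))
head(sort(round(cons$geomean, 2)), 4)
#>  GAPDH RNA28S   ACTB   PGK1
#>   1.97   2.24   3.90   4.44
```

Finally, validate a candidate reference triplet against a gene of interest:
the target is divided by the per-sample normalization factor, rescaled so
the calibrator passage (p28) averages 1, and every later passage is
compared against the calibrator with Holm-adjusted tests. No significant
comparison means the reference set absorbed the sample-to-sample variation:

```r
goi <- readCqTable(system.file("extdata", "synthetic_goi1_A1.csv",
                               package = "cqstab"))
nf  <- normalizationFactor(panel, c("GAPDH", "CCSER2", "PCBP1"))
res <- normalizeGoi(goi, nf, calibrator = 28)
res$verdict
#> [1] "successful"
round(res$comparisons$p_adj, 3)
#> [1] 0.715 0.216 0.715 0.717
```

## Documentation

The methods vignette (`vignettes/reference-gene-stability.Rmd`) describes
the models and their assumptions, every tunable default (collapse level,
efficiency, dispersion convention, α, the V cutoff, top-k), what the
synthetic generator does and does not emulate, and known limitations.
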