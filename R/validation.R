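#' @include describe.R
NULL

#' Normality-gated group comparison
#'
#' The statistical gate used throughout the validation workflow: residuals
#' (values minus their group mean) are tested for normality with
#' Shapiro-Wilk at level \code{alpha}; normal data go to one-way ANOVA,
#' non-normal data to Kruskal-Wallis. Post-hoc comparisons of every group
#' against the calibrator group (Dunnett-style contrast set) use the
#' matching two-sample test (t / Wilcoxon rank-sum) with Holm adjustment.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length, >= 2 levels,
#'   >= 2 values per group (>= 3 recommended for the normality gate).
#' @param calibrator optional group level to compare the others against;
#'   defaults to the first level.
#' @param alpha level of the Shapiro-Wilk gate.
#' @return list with \code{test} ("anova" or "kruskal"), \code{p_global},
#'   \code{shapiro_p}, and \code{comparisons} (data.frame: group, p_raw,
#'   p_adj vs the calibrator, Holm-adjusted).
#' @export
chooseTest <- function(values, groups, calibrator = NULL, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("every group needs at least 2 values: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (is.null(calibrator)) calibrator <- levels(groups)[1L]
  calibrator <- as.character(calibrator)
  if (!calibrator %in% levels(groups))
    stop("unknown calibrator group: ", calibrator)

  resid <- values - ave(values, groups)
  tol <- 1e-10 * max(abs(values), 1)
  if (diff(range(values)) <= tol) {
    # degenerate: no variation at all (up to numerical noise)
    comparisons <- data.frame(group = setdiff(levels(groups), calibrator),
                              p_raw = 1, p_adj = 1, stringsAsFactors = FALSE)
    return(list(test = "anova", p_global = 1, shapiro_p = NA_real_,
                comparisons = comparisons))
  }
  # constant-within-group data have no residual distribution to test;
  # fall through to the rank-based branch, which needs no normality
  shapiro_p <- if (sd(resid) <= tol || length(resid) < 3L) NA_real_
               else shapiro.test(resid)$p.value
  normal <- !is.na(shapiro_p) && shapiro_p >= alpha
  if (normal) {
    fit <- aov(values ~ groups)
    p_global <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    cmp <- function(g) t.test(values[groups == g],
                              values[groups == calibrator])$p.value
  } else {
    p_global <- suppressWarnings(kruskal.test(values, groups)$p.value)
    cmp <- function(g) suppressWarnings(
      wilcox.test(values[groups == g],
                  values[groups == calibrator])$p.value)
  }
  others <- setdiff(levels(groups), calibrator)
  p_raw <- vapply(others, cmp, 0)
  comparisons <- data.frame(group = others, p_raw = unname(p_raw),
                            p_adj = unname(p.adjust(p_raw, "holm")),
                            stringsAsFactors = FALSE)
  list(test = if (normal) "anova" else "kruskal",
       p_global = p_global, shapiro_p = shapiro_p,
       comparisons = comparisons)
}

#' Multi-reference normalization factor
#'
#' The per-sample normalization factor is the geometric mean, over the
#' chosen reference genes, of their relative linear-scale expressions
#' \eqn{2^{-Cq}}. It is invariant to the order of the reference genes; a
#' single reference gives NF = \eqn{2^{-Cq}}.
#'
#' @param ds a \linkS4class{CqSet} containing the reference genes.
#' @param refs character vector of reference gene names (non-empty, all
#'   present in \code{ds}).
#' @param collapse average technical replicates to lysate means first.
#' @param efficiency amplification factor per cycle (default 2).
#' @return Named numeric vector (one positive value per sample) with
#'   attributes \code{refs} and \code{sampleInfo}.
#' @export
normalizationFactor <- function(ds, refs, collapse = TRUE, efficiency = 2) {
  if (!length(refs)) stop("empty reference gene set")
  missing_refs <- setdiff(refs, geneNames(ds))
  if (length(missing_refs))
    stop("reference gene(s) not in dataset: ",
         paste(missing_refs, collapse = ", "))
  m <- analysisMatrix(ds, collapse)
  lin <- efficiency^(-m[refs, , drop = FALSE])
  nf <- apply(lin, 2L, geoMean)
  attr(nf, "refs") <- sort(refs)
  attr(nf, "sampleInfo") <- sampleInfo(m)
  nf
}

#' Normalize a gene of interest and validate the reference set
#'
#' Divides the target's linear-scale expression \eqn{2^{-Cq}} by the
#' normalization factor sample-by-sample, rescales so the calibrator group
#' mean is 1, and tests every other group against the calibrator with the
#' normality-gated procedure of \code{\link{chooseTest}}. Normalization is
#' judged \code{"successful"} when no Holm-adjusted comparison is
#' significant at \code{alpha} -- i.e. the reference set absorbs the
#' sample-to-sample variation without leaving spurious fold changes.
#'
#' @param goi single-gene \linkS4class{CqSet} on the same sample grid as the
#'   normalization factor.
#' @param nf result of \code{\link{normalizationFactor}}.
#' @param calibrator calibrator group label (a passage, by default).
#' @param groupBy sample-info column defining the comparison groups
#'   (default "passage").
#' @param collapse,efficiency as in \code{\link{normalizationFactor}}.
#' @param alpha significance level (default 0.05).
#' @return list with \code{relative} (per-sample relative expression,
#'   calibrator mean 1), \code{groups}, \code{test}, \code{p_global},
#'   \code{comparisons} (Holm-adjusted P per group), and \code{verdict}
#'   ("successful"/"failed").
#' @export
normalizeGoi <- function(goi, nf, calibrator, groupBy = "passage",
                         collapse = TRUE, efficiency = 2, alpha = 0.05) {
  m <- analysisMatrix(goi, collapse)
  if (nrow(m) != 1L) stop("goi must contain exactly one gene")
  if (!identical(colnames(m), names(nf)))
    stop("sample grid mismatch between GOI and normalization factor")
  info <- sampleInfo(m)
  groups <- factor(info[[groupBy]])
  if (!calibrator %in% levels(groups))
    stop("unknown calibrator group: ", calibrator)
  rel <- as.vector(efficiency^(-m[1L, ])) / as.vector(nf)
  rel <- rel / mean(rel[groups == as.character(calibrator)])
  names(rel) <- colnames(m)
  ct <- chooseTest(rel, groups, calibrator = calibrator, alpha = alpha)
  verdict <- if (all(ct$comparisons$p_adj > alpha)) "successful" else "failed"
  list(relative = rel, groups = groups, test = ct$test,
       p_global = ct$p_global, comparisons = ct$comparisons,
       verdict = verdict, calibrator = as.character(calibrator),
       refs = attr(nf, "refs"), alpha = alpha)
}

#' Screen candidate reference sets against genes of interest
#'
#' Runs \code{\link{normalizeGoi}} for every combination of gene of
#' interest and candidate reference set and tabulates the verdicts -- the
#' reproducible analogue of a normalization-screening verdict grid.
#'
#' @param gois a named list of single-gene \linkS4class{CqSet}s (or one
#'   CqSet).
#' @param panel \linkS4class{CqSet} containing the candidate reference
#'   genes.
#' @param sets list of character vectors (candidate reference sets).
#' @param calibrator calibrator group label.
#' @param groupBy,collapse,efficiency,alpha as in \code{\link{normalizeGoi}}.
#' @return data.frame with columns goi, set, verdict, min_p_adj, n_signif;
#'   zero rows when \code{sets} is empty.
#' @export
screenReferenceSets <- function(gois, panel, sets, calibrator,
                                groupBy = "passage", collapse = TRUE,
                                efficiency = 2, alpha = 0.05) {
  if (is(gois, "CqSet")) gois <- setNames(list(gois), geneNames(gois)[1L])
  if (is.null(names(gois)))
    names(gois) <- vapply(gois, function(g) geneNames(g)[1L], "")
  out <- list()
  for (gname in names(gois)) for (s in sets) {
    nf <- normalizationFactor(panel, s, collapse = collapse,
                              efficiency = efficiency)
    res <- normalizeGoi(gois[[gname]], nf, calibrator = calibrator,
                        groupBy = groupBy, collapse = collapse,
                        efficiency = efficiency, alpha = alpha)
    out[[length(out) + 1L]] <- data.frame(
      goi = gname, set = paste(sort(s), collapse = "+"),
      verdict = res$verdict, min_p_adj = min(res$comparisons$p_adj),
      n_signif = sum(res$comparisons$p_adj <= alpha),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(goi = character(), set = character(),
                      verdict = character(), min_p_adj = numeric(),
                      n_signif = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reference-gene fold changes under a stress condition
#'
#' For each gene shared by the two panels, computes the linear fold change
#' of mean expression under stress versus control,
#' \eqn{mean(2^{-Cq}_{stress}) / mean(2^{-Cq}_{control})}, its log2, a
#' two-sided Wilcoxon rank-sum P value on the per-sample linear expressions,
#' and flags genes whose fold change leaves the (0.5, 2) band -- the
#' conventional "at least two-fold" rule for disqualifying a reference gene
#' under the condition.
#'
#' @param control,stress \linkS4class{CqSet}s sharing at least one gene.
#' @param collapse,efficiency as elsewhere.
#' @return data.frame with columns gene, fold, log2_fold, flag_2x, p.
#' @export
stressFoldChange <- function(control, stress, collapse = TRUE,
                             efficiency = 2) {
  shared <- intersect(geneNames(control), geneNames(stress))
  if (!length(shared)) stop("no shared genes between control and stress")
  mc <- analysisMatrix(control, collapse)
  ms <- analysisMatrix(stress, collapse)
  out <- do.call(rbind, lapply(shared, function(g) {
    xc <- efficiency^(-mc[g, ])
    xs <- efficiency^(-ms[g, ])
    fold <- mean(xs) / mean(xc)
    p <- suppressWarnings(wilcox.test(xs, xc)$p.value)
    data.frame(gene = g, fold = fold, log2_fold = log2(fold),
               flag_2x = twoFoldFlag(fold), p = p,
               stringsAsFactors = FALSE)
  }))
  out[order(out$gene), , drop = FALSE]
}

#' Normalized fold change of a gene of interest under stress
#'
#' Normalizes the target by the reference-set normalization factor within
#' each condition, then compares the per-sample relative expressions
#' between conditions with a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test and reports the fold change of condition means with its log2.
#' A fold change within (0.5, 2) and a non-significant P indicate the
#' reference set absorbed the condition effect.
#'
#' @param control,stress \linkS4class{CqSet}s each containing the target
#'   gene and all reference genes, >= 3 samples per condition.
#' @param goi target gene name.
#' @param refs character vector of reference genes.
#' @param collapse,efficiency as elsewhere.
#' @return list with \code{fold}, \code{log2_fold}, \code{p},
#'   \code{flag_2x}, and the per-sample normalized expressions
#'   \code{rel_control}, \code{rel_stress}.
#' @export
stressGoiTest <- function(control, stress, goi, refs, collapse = TRUE,
                          efficiency = 2) {
  rel <- function(ds) {
    nf <- normalizationFactor(ds, refs, collapse = collapse,
                              efficiency = efficiency)
    m <- analysisMatrix(ds, collapse)
    if (!goi %in% rownames(m)) stop("gene of interest '", goi,
                                    "' not in dataset")
    as.vector(efficiency^(-m[goi, ])) / as.vector(nf)
  }
  rc <- rel(control); rs <- rel(stress)
  if (length(rc) < 3L || length(rs) < 3L)
    stop("need at least 3 samples per condition")
  fold <- mean(rs) / mean(rc)
  p <- suppressWarnings(wilcox.test(rs, rc)$p.value)
  list(fold = fold, log2_fold = log2(fold), p = p,
       flag_2x = twoFoldFlag(fold),
       rel_control = rc, rel_stress = rs)
}

#' Correlate per-gene Cq with log2 expression from sequencing
#'
#' Pearson correlation (with two-sided P) and ordinary least-squares fit of
#' mean Cq on log2 expression across genes, used to relate qPCR abundances
#' to RNA-seq abundances of the same panel.
#'
#' @param cq named numeric vector of per-gene mean Cq.
#' @param log2expr named numeric vector of per-gene log2 expression; names
#'   are matched to \code{cq}, >= 3 shared genes required.
#' @return list with \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{n}.
#' @export
correlateCqExpression <- function(cq, log2expr) {
  shared <- intersect(names(cq), names(log2expr))
  if (length(shared) < 3L) stop("need >= 3 paired genes")
  x <- log2expr[shared]; y <- cq[shared]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance on one axis; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r2, n = length(shared))
}
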