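#' @include cq-io.R StabilityTable-class.R
NULL

# Matrix used by the stability estimators: technical replicates are averaged
# to lysate means first (Cq averaging on the log scale, before any 2^-Cq
# transform) unless collapse = FALSE asks for replicate-level analysis.
analysisMatrix <- function(ds, collapse = TRUE) {
  if (collapse && sampleUnit(ds) == "tech_rep")
    ds <- collapseReplicates(ds)
  cqMatrix(ds, requireComplete = TRUE)
}

#' Descriptive per-gene Cq statistics
#'
#' Arithmetic mean, sample standard deviation (n - 1), minimum, maximum and
#' geometric mean of the Cq values of each gene, computed at the dataset's
#' current sample unit.
#'
#' @param ds a \linkS4class{CqSet}.
#' @return data.frame with columns gene, n, mean_cq, sd_cq, min_cq, max_cq,
#'   geo_mean_cq.
#' @examples
#' panel <- generateReferencePanel(defaultProfile(seed = 1), "A1")
#' head(describeGenes(panel))
#' @export
describeGenes <- function(ds) {
  obs <- cqObservations(ds)
  out <- do.call(rbind, lapply(split(obs$cq, obs$gene), function(x) {
    if (length(x) < 2L)
      stop("descriptive statistics need >= 2 observations per gene")
    data.frame(n = length(x), mean_cq = mean(x), sd_cq = sd(x),
               min_cq = min(x), max_cq = max(x), geo_mean_cq = geoMean(x))
  }))
  out <- cbind(gene = rownames(out), out)
  rownames(out) <- NULL
  out$gene <- as.character(out$gene)
  out
}

#' Coefficient of variation of linear-scale expression
#'
#' Transforms each Cq to relative linear-scale expression \eqn{2^{-Cq}}
#' (perfect doubling per cycle) and scores each gene by the coefficient of
#' variation CV = SD/mean of those values, reported as a percentage. CV\% is
#' invariant to adding a constant to a gene's Cq (a pure abundance shift).
#'
#' @param ds a \linkS4class{CqSet}.
#' @param collapse average technical replicates to lysate means first
#'   (default), mirroring how plates are summarised before analysis.
#' @param efficiency amplification factor per cycle (default 2, perfect
#'   doubling).
#' @return A \linkS4class{StabilityTable} (algorithm "cv"); details hold the
#'   per-gene mean and SD of \eqn{2^{-Cq}}.
#' @export
cvStability <- function(ds, collapse = TRUE, efficiency = 2) {
  m <- analysisMatrix(ds, collapse)
  lin <- efficiency^(-m)
  mu <- rowMeans(lin)
  sdev <- apply(lin, 1L, sd)
  cv <- 100 * sdev / mu
  stabilityTable("cv", cv,
                 details = list(linearStats = data.frame(
                   gene = rownames(m), mean_linear = unname(mu),
                   sd_linear = unname(sdev), cv_pct = unname(cv),
                   stringsAsFactors = FALSE)))
}

#' Calibrator-relative fold changes across passages
#'
#' Expresses each sample of each gene as a linear fold change
#' \eqn{2^{-Cq}} relative to the mean \eqn{2^{-Cq}} of the calibrator
#' passage of that gene (so the calibrator passage averages 1), then tests
#' each gene for expression changes across passages: a Shapiro-Wilk test on
#' the residuals gates one-way ANOVA versus Kruskal-Wallis (see
#' \code{\link{chooseTest}}), with Holm-adjusted comparisons of every other
#' passage against the calibrator.
#'
#' @param ds a \linkS4class{CqSet} (a single culture, typically).
#' @param calibrator passage label whose mean expression defines 1.
#' @param collapse average technical replicates to lysate means first.
#' @param scale run the tests on linear \eqn{2^{-Cq}} fold changes
#'   (\code{"linear"}, default) or directly on Cq values (\code{"cq"}).
#' @param alpha significance level for the normality gate.
#' @return list with \code{fold} (long data.frame: gene, culture, passage,
#'   lysate, fold), \code{tests} (per gene: chosen test, global P,
#'   Shapiro-Wilk P) and \code{comparisons} (per gene and non-calibrator
#'   passage: Holm-adjusted P versus the calibrator).
#' @export
passageFoldChange <- function(ds, calibrator, collapse = TRUE,
                              scale = c("linear", "cq"), alpha = 0.05) {
  scale <- match.arg(scale)
  if (collapse && sampleUnit(ds) == "tech_rep") ds <- collapseReplicates(ds)
  obs <- cqObservations(ds)
  if (!calibrator %in% obs$passage)
    stop("calibrator passage ", calibrator, " not present in dataset")
  parts <- split(obs, obs$gene)
  fold <- do.call(rbind, lapply(parts, function(d) {
    cal <- mean(2^(-d$cq[d$passage == calibrator]))
    data.frame(gene = d$gene, culture = d$culture, passage = d$passage,
               lysate = d$lysate, fold = 2^(-d$cq) / cal,
               stringsAsFactors = FALSE)
  }))
  rownames(fold) <- NULL
  tests <- list(); comps <- list()
  for (g in names(parts)) {
    d <- parts[[g]]
    y <- if (scale == "linear") {
      cal <- mean(2^(-d$cq[d$passage == calibrator]))
      2^(-d$cq) / cal
    } else d$cq
    ct <- chooseTest(y, factor(d$passage), calibrator = calibrator,
                     alpha = alpha)
    tests[[g]] <- data.frame(gene = g, test = ct$test,
                             p_global = ct$p_global,
                             shapiro_p = ct$shapiro_p,
                             stringsAsFactors = FALSE)
    comps[[g]] <- cbind(gene = g, ct$comparisons)
  }
  list(fold = fold,
       tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       comparisons = do.call(rbind, c(comps, list(make.row.names = FALSE))))
}

#' Expression stability from an RNA-seq expression matrix
#'
#' Log-transforms a linear-scale gene-by-sample expression matrix
#' (\code{log2(x + 1)} for normalized counts, \code{log2(x)} for TPM; zeros
#' are rejected in TPM mode) and reports the per-gene mean, SD and CV\% on
#' the log2 scale, with the screening labels used for cross-platform
#' comparison of candidate reference genes: mean log2 TPM > 5 =
#' "medium-to-high expression", SD < 1 = "low variance".
#'
#' @param m numeric matrix, genes x samples, linear scale, finite and
#'   non-negative.
#' @param mode \code{"counts"} (log2(x+1)) or \code{"tpm"} (log2(x)).
#' @return data.frame with columns gene, mean_log2, sd_log2, cv_pct,
#'   medium_high_expression, low_variance.
#' @export
expressionStability <- function(m, mode = c("counts", "tpm")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (!all(is.finite(m)) || any(m < 0))
    stop("expression matrix must be finite and non-negative on linear scale")
  if (mode == "tpm" && any(m == 0))
    stop("TPM mode cannot log-transform zeros; use counts mode (log2(x+1))")
  lg <- if (mode == "counts") log2(m + 1) else log2(m)
  mu <- rowMeans(lg)
  sdev <- apply(lg, 1L, sd)
  data.frame(gene = rownames(m), mean_log2 = unname(mu),
             sd_log2 = unname(sdev), cv_pct = unname(100 * sdev / mu),
             medium_high_expression = unname(mu > 5),
             low_variance = unname(sdev < 1),
             stringsAsFactors = FALSE)
}
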