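#' @include describe.R
NULL

#' BestKeeper descriptive stability analysis
#'
#' Computes the BestKeeper descriptives for each candidate gene's crossing
#' points (CP, synonymous with Cq): geometric and arithmetic mean, min, max,
#' the dispersion "SD (+/- CP)", and its fold-change expression x-fold =
#' \eqn{2^{SD}}; the BestKeeper index (per-sample geometric mean of all
#' genes' CP); and Pearson correlations of every gene pair and of each gene
#' against the index. Genes are ranked ascending by dispersion and genes
#' with SD > 1 are flagged inconsistent (a CP spread of more than one cycle,
#' i.e. more than two-fold).
#'
#' The dispersion is, by default, the mean absolute deviation of the CP
#' values around their arithmetic mean (the convention of the original
#' BestKeeper spreadsheet tool); \code{dispersion = "sd"} uses the sample
#' standard deviation instead.
#'
#' @param ds a \linkS4class{CqSet}.
#' @param collapse average technical replicates to lysate means first.
#' @param dispersion \code{"mad"} (mean absolute deviation, default) or
#'   \code{"sd"}.
#' @return A \linkS4class{StabilityTable} (algorithm "bestkeeper"). Details:
#'   \code{descriptives} (per-gene table with geo_mean, mean, min, max,
#'   sd_cp, x_fold, inconsistent), \code{index} (per-sample BestKeeper
#'   index), \code{geneCor}/\code{geneCorP} (pairwise Pearson r and P),
#'   \code{indexCor} (per-gene r, P against the index).
#' @references Pfaffl et al. (2004) Biotechnology Letters 26:509.
#' @export
bestKeeper <- function(ds, collapse = TRUE, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  m <- analysisMatrix(ds, collapse)
  k <- nrow(m)
  disp <- apply(m, 1L, function(x)
    if (dispersion == "mad") mean(abs(x - mean(x))) else sd(x))
  desc <- data.frame(
    gene = rownames(m),
    geo_mean = apply(m, 1L, geoMean),
    mean = rowMeans(m),
    min = apply(m, 1L, min),
    max = apply(m, 1L, max),
    sd_cp = unname(disp),
    x_fold = unname(2^disp),
    inconsistent = unname(disp > 1),
    stringsAsFactors = FALSE)
  rownames(desc) <- NULL
  index <- apply(m, 2L, geoMean)
  geneCor <- matrix(1, k, k, dimnames = list(rownames(m), rownames(m)))
  geneCorP <- matrix(NA_real_, k, k, dimnames = dimnames(geneCor))
  if (k >= 2L) for (g in seq_len(k - 1L)) for (h in seq(g + 1L, k)) {
    ct <- suppressWarnings(cor.test(m[g, ], m[h, ], method = "pearson"))
    geneCor[g, h] <- geneCor[h, g] <- unname(ct$estimate)
    geneCorP[g, h] <- geneCorP[h, g] <- ct$p.value
  }
  indexCor <- do.call(rbind, lapply(seq_len(k), function(g) {
    ct <- suppressWarnings(cor.test(m[g, ], index, method = "pearson"))
    data.frame(gene = rownames(m)[g], r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
  stabilityTable("bestkeeper", setNames(disp, rownames(m)),
                 details = list(descriptives = desc, index = index,
                                geneCor = geneCor, geneCorP = geneCorP,
                                indexCor = indexCor,
                                dispersion = dispersion))
}
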