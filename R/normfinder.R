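#' @include describe.R
NULL

# Bias-corrected residual-based variance estimates for one group.
# Model: y_gs = gene_g + sample_s + e_gs with Var(e_gs) = sigma_g^2.
# With r the double-centred residuals and u_g = sum_s r_gs^2 / (n-1),
# E[u_g] = (1 - 2/k) sigma_g^2 + mean(sigma^2)/k, giving the unbiased
# estimator sigma_g^2 = (u_g - mean(u)/(k-1)) * k/(k-2), truncated at 0.
# The k/(k-2) factor is the small-panel bias correction; undefined at k <= 2.
groupVariances <- function(m) {
  k <- nrow(m); n <- ncol(m)
  if (k < 3L) stop("NormFinder variance estimation needs at least 3 genes")
  if (n < 2L) stop("NormFinder needs at least 2 samples per group")
  r <- m - rowMeans(m) - rep(colMeans(m), each = k) + mean(m)
  u <- rowSums(r^2) / (n - 1L)
  pmax(0, (u - mean(u) / (k - 1L)) * k / (k - 2L))
}

#' NormFinder model-based stability analysis
#'
#' Fits the additive two-way model of the NormFinder approach on the Cq (log)
#' scale: expression of gene g in sample s is gene level + sample level +
#' noise with gene-specific variance. Per-gene intragroup variances are
#' estimated from the double-centred residuals with the small-panel bias
#' correction (see Andersen et al. 2004); negative estimates are truncated
#' at zero. In single-group mode the stability value is the intragroup SD.
#' In grouped mode (e.g. the two sub-clone cultures analysed jointly) the
#' gene-by-group interaction d_gg' -- systematic expression differences of a
#' gene between groups -- is estimated, shrunk towards zero with an
#' empirical-Bayes factor \eqn{\gamma^2 / (\gamma^2 + \sigma^2_g/n)} where
#' \eqn{\gamma^2} is the across-gene variance of the interactions, and each
#' gene's stability value combines the absolute shrunk bias with the
#' sampling SD of its group means, averaged over groups. The best pair of
#' genes is the pair whose average expression has the lowest combined
#' stability value.
#'
#' @param ds a \linkS4class{CqSet} with >= 3 genes.
#' @param groups \code{NULL} for single-group mode, \code{TRUE} to group by
#'   culture label, or a character vector naming a sample-info column.
#' @param collapse average technical replicates to lysate means first.
#' @return A \linkS4class{StabilityTable} (algorithm "normfinder"). Details:
#'   \code{variances} (per-gene, per-group intragroup variance estimates),
#'   \code{bestPair} and \code{pairStability} (all pairs, ascending).
#' @references Andersen, Jensen & Orntoft (2004) Cancer Research 64:5245.
#' @export
normFinder <- function(ds, groups = NULL, collapse = TRUE) {
  m <- analysisMatrix(ds, collapse)
  info <- sampleInfo(m)
  if (isTRUE(groups)) groups <- "culture"
  grouping <- if (is.null(groups)) factor(rep("all", ncol(m)))
              else factor(info[[groups]])
  if (nlevels(grouping) < 1L || any(table(grouping) < 2L))
    stop("every group needs at least 2 samples")
  k <- nrow(m)
  glev <- levels(grouping)
  sig2 <- sapply(glev, function(g)
    groupVariances(m[, grouping == g, drop = FALSE]))
  sig2 <- matrix(sig2, nrow = k, dimnames = list(rownames(m), glev))
  ng <- as.vector(table(grouping)[glev])

  if (length(glev) == 1L) {
    stab <- sqrt(sig2[, 1L])
    pairScore <- function(i, j) sqrt((sig2[i, 1L] + sig2[j, 1L]) / 4)
    dtilde <- NULL
  } else {
    # gene-by-group interaction: group mean profile, double-centred
    gm <- sapply(glev, function(g) rowMeans(m[, grouping == g, drop = FALSE]))
    d <- gm - rowMeans(gm) - rep(colMeans(gm), each = k) + mean(gm)
    vard <- sweep(sig2, 2L, ng, `/`)  # sampling variance of group means
    gamma2 <- max(0, mean(d^2) - mean(vard))
    dtilde <- d * gamma2 / (gamma2 + vard)
    stab <- rowMeans(abs(dtilde) + sqrt(vard))
    pairScore <- function(i, j)
      mean(abs(dtilde[i, ] + dtilde[j, ]) / 2 +
             sqrt((vard[i, ] + vard[j, ]) / 4))
  }
  names(stab) <- rownames(m)

  pairs <- combn(rownames(m), 2L)
  pstab <- apply(pairs, 2L, function(p) pairScore(p[1L], p[2L]))
  pairTab <- data.frame(gene1 = pairs[1L, ], gene2 = pairs[2L, ],
                        stability = pstab, stringsAsFactors = FALSE)
  pairTab <- pairTab[order(pairTab$stability, pairTab$gene1, pairTab$gene2), ]
  rownames(pairTab) <- NULL
  stabilityTable("normfinder", stab,
                 details = list(variances = sig2,
                                groupBias = dtilde,
                                bestPair = unlist(pairTab[1L, c("gene1", "gene2")],
                                                  use.names = FALSE),
                                pairStability = pairTab))
}
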