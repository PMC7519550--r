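#' @include describe.R
NULL

# Pairwise log2-ratio SD matrix of relative quantities. With relative
# quantity Q_gs = eff^(minCq_g - Cq_gs), log2(Q_g/Q_h) differs from
# -(Cq_g - Cq_h)*log2(eff) by a constant, so its SD over samples is the SD
# of the Cq difference (scaled); the Q form is kept for fidelity to the
# published definition and is anchor-invariant.
pairwiseLogRatioSD <- function(m, efficiency = 2) {
  q <- log2(efficiency) * (apply(m, 1L, min) - m)  # log2 Q
  k <- nrow(m)
  v <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (g in seq_len(k - 1L)) for (h in seq(g + 1L, k)) {
    s <- sd(q[g, ] - q[h, ])
    v[g, h] <- v[h, g] <- s
  }
  v
}

#' geNorm expression-stability analysis
#'
#' Computes the geNorm M value of every candidate gene -- the mean standard
#' deviation of its pairwise log2 expression ratios against all other
#' candidates, on relative quantities \eqn{Q_{gs} = 2^{minCq_g - Cq_{gs}}}
#' -- then iteratively removes the least stable (highest M) gene, recording
#' M values at every round, until two genes remain. Those final two genes
#' cannot be distinguished by the method and are reported jointly at rank 1;
#' ranks of the remaining genes follow the exclusion order. An M value below
#' 1 is conventionally considered acceptable for a reference gene.
#'
#' @param ds a \linkS4class{CqSet} with at least 3 genes.
#' @param collapse average technical replicates to lysate means first.
#' @param efficiency amplification factor per cycle (default 2).
#' @return A \linkS4class{StabilityTable} (algorithm "genorm"): scores are
#'   each gene's M at the round of its removal (final-pair M for the last
#'   two), ranks follow the exclusion order. Details: \code{exclusionOrder}
#'   (first removed first), \code{inclusionOrder} (most stable first),
#'   \code{rounds} (per round: genes, their M values, average M).
#' @references Vandesompele et al. (2002) Genome Biology 3:research0034.
#' @export
geNorm <- function(ds, collapse = TRUE, efficiency = 2) {
  m <- analysisMatrix(ds, collapse)
  if (nrow(m) < 3L) stop("geNorm needs at least 3 genes")
  v <- pairwiseLogRatioSD(m, efficiency)
  remaining <- rownames(m)
  score <- setNames(numeric(length(remaining)), remaining)
  excluded <- character()
  rounds <- list()
  while (length(remaining) > 2L) {
    M <- rowSums(v[remaining, remaining, drop = FALSE]) /
      (length(remaining) - 1L)
    rounds[[length(rounds) + 1L]] <- list(genes = remaining, M = M,
                                          meanM = mean(M))
    worst <- names(M)[which.max(M)]  # which.max: first index on ties
    score[worst] <- M[[worst]]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  finalM <- v[remaining[1L], remaining[2L]]
  score[remaining] <- finalM
  rounds[[length(rounds) + 1L]] <- list(
    genes = remaining, M = setNames(rep(finalM, 2L), remaining),
    meanM = finalM)
  k <- length(score)
  rank <- setNames(numeric(k), c(excluded, remaining))
  rank[excluded] <- seq(k, 3L)
  rank[remaining] <- 1
  stabilityTable("genorm", score, rank = rank,
                 details = list(exclusionOrder = excluded,
                                inclusionOrder = c(remaining, rev(excluded)),
                                rounds = rounds,
                                pairSD = v))
}

#' geNorm pairwise variation series V(n/n+1)
#'
#' For n = 2 .. k-1, builds normalization factors NF_n(s) as the geometric
#' mean of the relative quantities of the n most stable genes (geNorm
#' inclusion order) and computes \eqn{V_{n/n+1} = SD_s(log2(NF_n /
#' NF_{n+1}))}: how much adding the (n+1)-th gene still changes the
#' normalization. Small V means the extra gene is unnecessary.
#'
#' @param ds a \linkS4class{CqSet}.
#' @param genormResult result of \code{\link{geNorm}} on the same data; run
#'   internally when \code{NULL}.
#' @param collapse,efficiency as in \code{\link{geNorm}}.
#' @return Named numeric vector ("V2/3", "V3/4", ...), each value >= 0.
#' @seealso \code{\link{optimalGeneCount}}
#' @export
geNormV <- function(ds, genormResult = NULL, collapse = TRUE,
                    efficiency = 2) {
  m <- analysisMatrix(ds, collapse)
  if (is.null(genormResult))
    genormResult <- geNorm(ds, collapse = collapse, efficiency = efficiency)
  inc <- genormResult@details$inclusionOrder
  if (!setequal(inc, rownames(m)))
    stop("geNorm result does not match the dataset's gene set")
  k <- length(inc)
  if (k < 3L) stop("pairwise variation needs at least 3 genes")
  lq <- log2(efficiency) * (apply(m, 1L, min) - m)  # log2 Q
  logNF <- function(n) colMeans(lq[inc[seq_len(n)], , drop = FALSE])
  V <- vapply(2:(k - 1L), function(n) sd(logNF(n) - logNF(n + 1L)), 0)
  names(V) <- paste0("V", 2:(k - 1L), "/", 3:k)
  V
}
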