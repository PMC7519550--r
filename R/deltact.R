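#' @include describe.R
NULL

#' Comparative delta-Ct stability analysis
#'
#' For every gene pair (g, h) computes the per-sample Cq difference
#' \eqn{\Delta Ct_s = Cq_{gs} - Cq_{hs}} and its standard deviation over
#' samples; a stable pair keeps a constant difference. Each gene is scored
#' by the mean pairwise SD over all pairs it participates in, and genes are
#' ranked ascending. Scores are invariant to adding a constant to any
#' gene's Cq.
#'
#' @param ds a \linkS4class{CqSet} with >= 2 genes.
#' @param collapse average technical replicates to lysate means first.
#' @return A \linkS4class{StabilityTable} (algorithm "deltact"); details
#'   hold the full pairwise SD matrix.
#' @references Silver et al. (2006) BMC Molecular Biology 7:33.
#' @export
comparativeDeltaCt <- function(ds, collapse = TRUE) {
  m <- analysisMatrix(ds, collapse)
  k <- nrow(m)
  if (k < 2L) stop("comparative delta-Ct needs at least 2 genes")
  v <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (g in seq_len(k - 1L)) for (h in seq(g + 1L, k)) {
    s <- sd(m[g, ] - m[h, ])
    v[g, h] <- v[h, g] <- s
  }
  score <- rowSums(v) / (k - 1L)
  stabilityTable("deltact", score, details = list(pairSD = v))
}
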