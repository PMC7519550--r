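#' @include StabilityTable-class.R
NULL

#' Competition ranks from stability scores
#'
#' @param scores named numeric vector of stability scores (lower = more
#'   stable) or a \linkS4class{StabilityTable}.
#' @return Named numeric vector of ascending competition ranks (ties share
#'   the minimum rank).
#' @export
rankGenes <- function(scores) {
  if (is(scores, "StabilityTable")) return(stabilityRanks(scores))
  competitionRank(scores)
}

#' Geometric-mean consensus ranking across stability estimators
#'
#' Aggregates the per-estimator rankings of a candidate panel into a single
#' consensus by the geometric mean of each gene's ranks (the aggregation
#' popularised by the RefFinder tool), then ranks ascending by that
#' geometric mean. A gene's geomean rank always lies between its best and
#' worst single-estimator rank.
#'
#' @param tables a list of \linkS4class{StabilityTable}s over the same gene
#'   set, or a numeric gene-by-estimator rank matrix.
#' @return list with \code{rankMatrix} (gene x estimator), \code{geomean}
#'   (named, per gene) and \code{rank} (final competition ranks).
#' @export
consensusRanking <- function(tables) {
  if (is.matrix(tables)) {
    rm <- tables
  } else {
    if (length(tables) < 2L)
      stop("consensus needs at least 2 estimator rankings")
    genes <- sort(names(stabilityScores(tables[[1L]])))
    for (t in tables)
      if (!setequal(names(stabilityScores(t)), genes))
        stop("estimator tables cover different gene sets")
    rm <- sapply(tables, function(t) stabilityRanks(t)[genes])
    rownames(rm) <- genes
    colnames(rm) <- vapply(tables, function(t) t@algorithm, "")
  }
  if (ncol(rm) < 2L) stop("consensus needs at least 2 estimator rankings")
  gm <- apply(rm, 1L, geoMean)
  list(rankMatrix = rm, geomean = gm, rank = competitionRank(gm))
}

#' Optimal number of reference genes from the geNorm V series
#'
#' Applies the geNorm rule: use the smallest n for which
#' \eqn{V_{n/n+1}} falls below the cutoff (0.15 by convention) -- adding an
#' (n+1)-th reference gene would no longer meaningfully change the
#' normalization factor. When no V value is below the cutoff, no count is
#' recommended and the minimizing n is flagged for user judgement.
#'
#' @param v named V series from \code{\link{geNormV}}.
#' @param cutoff threshold on V (default 0.15).
#' @return list with \code{count} (integer, or NA when no V is below the
#'   cutoff), \code{recommended} (logical), \code{bestN} (minimizing n) and
#'   \code{trace} (data.frame n, V, below_cutoff).
#' @export
optimalGeneCount <- function(v, cutoff = 0.15) {
  if (!length(v)) stop("empty V series")
  n <- 2:(length(v) + 1L)
  below <- v < cutoff
  trace <- data.frame(n = n, V = unname(v), below_cutoff = unname(below))
  if (any(below))
    list(count = n[which(below)[1L]], recommended = TRUE,
         bestN = n[which.min(v)], trace = trace)
  else
    list(count = NA_integer_, recommended = FALSE,
         bestN = n[which.min(v)], trace = trace)
}

#' Integrated reference-gene selection
#'
#' Codifies the integrated selection procedure used to pick working
#' reference genes from the full battery of estimators: (i) each gene is
#' scored by how many estimators place it in the top \code{topK}; (ii) genes
#' with a significant expression trend across passages (P <= alpha) are
#' flagged as violating the trend criterion; (iii) the selected pair is the
#' two best-supported trend-clean genes of the primary dataset, and -- to
#' avoid discarding a strong candidate merely because only two genes are
#' kept -- an "experimental candidate" with the highest top-K support
#' aggregated across all provided datasets completes a triplet. Ties are
#' broken lexicographically and every rule evaluation is recorded in an
#' audit log.
#'
#' @param tables a named list of \linkS4class{StabilityTable}s for the
#'   primary dataset, or a named list of such lists (one per dataset; the
#'   first is primary).
#' @param trendP optional named numeric vector of per-gene passage-trend P
#'   values (e.g. from \code{\link{passageFoldChange}}'s global tests).
#' @param topK top-rank threshold (default 3).
#' @param alpha significance level for the trend criterion (default 0.05).
#' @return list with \code{pair}, \code{experimental}, \code{triplet},
#'   \code{support} (per-gene top-K counts per dataset) and \code{audit}
#'   (data.frame: dataset, algorithm, gene, rank, in_top_k, plus trend
#'   rows).
#' @export
integratedSelection <- function(tables, trendP = NULL, topK = 3,
                                alpha = 0.05) {
  if (length(tables) && is(tables[[1L]], "StabilityTable"))
    tables <- list(primary = tables)
  if (is.null(names(tables)))
    names(tables) <- paste0("dataset", seq_along(tables))
  genes <- sort(names(stabilityScores(tables[[1L]][[1L]])))
  if (length(genes) < 3L) stop("integrated selection needs >= 3 genes")
  audit <- list()
  support <- matrix(0L, nrow = length(genes), ncol = length(tables),
                    dimnames = list(genes, names(tables)))
  for (dsName in names(tables)) {
    for (t in tables[[dsName]]) {
      r <- stabilityRanks(t)[genes]
      support[, dsName] <- support[, dsName] + as.integer(r <= topK)
      audit[[length(audit) + 1L]] <- data.frame(
        dataset = dsName, algorithm = t@algorithm, gene = genes,
        rank = unname(r), in_top_k = unname(r <= topK),
        criterion = sprintf("rank <= %d", topK), stringsAsFactors = FALSE)
    }
  }
  trendOK <- setNames(rep(NA, length(genes)), genes)
  if (!is.null(trendP)) {
    trendOK[names(trendP)] <- trendP > alpha
    audit[[length(audit) + 1L]] <- data.frame(
      dataset = names(tables)[1L], algorithm = "passage_trend",
      gene = names(trendP), rank = NA_real_,
      in_top_k = unname(trendP > alpha),
      criterion = sprintf("trend P > %g", alpha), stringsAsFactors = FALSE)
  }
  primary <- support[, 1L]
  # pair: best-supported trend-clean genes of the primary dataset
  eligible <- genes[is.na(trendOK[genes]) | trendOK[genes]]
  if (length(eligible) < 2L) eligible <- genes  # trend rule noted, not fatal
  ord <- eligible[order(-primary[eligible], eligible)]
  pair <- ord[1:2]
  total <- rowSums(support)
  rest <- setdiff(genes[order(-total, genes)], pair)
  experimental <- rest[1L]
  list(pair = pair, experimental = experimental,
       triplet = c(pair, experimental),
       support = support, trendOK = trendOK,
       audit = do.call(rbind, audit))
}
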