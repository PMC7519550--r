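#' @include AllGenerics.R utils.R
NULL

#' StabilityTable: per-gene stability scores from one estimator
#'
#' Result container shared by all stability estimators. Scores are on the
#' estimator's own scale (CV\%, geNorm M, NormFinder stability value,
#' BestKeeper dispersion, mean pairwise-SD); in every case lower means more
#' stable. Ranks are ascending competition ranks over the scores, except
#' where an estimator defines its own tie structure (the geNorm final pair
#' shares rank 1).
#'
#' @slot algorithm label of the estimator ("cv", "genorm", "normfinder",
#'   "bestkeeper", "deltact", ...).
#' @slot score named numeric vector of per-gene scores.
#' @slot rank named numeric vector of per-gene ranks over the same genes.
#' @slot direction only \code{"lower_is_stable"} is defined.
#' @slot details estimator-specific extras (exclusion order, correlation
#'   matrices, best pair, ...).
#' @export
setClass("StabilityTable",
  representation(algorithm = "character", score = "numeric", rank = "numeric",
                 direction = "character", details = "list"),
  prototype(direction = "lower_is_stable", details = list()))

setValidity("StabilityTable", function(object) {
  msg <- character()
  if (!identical(object@direction, "lower_is_stable"))
    msg <- c(msg, "direction must be 'lower_is_stable'")
  if (is.null(names(object@score)) || is.null(names(object@rank)) ||
      !setequal(names(object@score), names(object@rank)))
    msg <- c(msg, "score and rank must be named over the same gene set")
  else {
    r <- object@rank[names(object@score)]
    if (any(r < 1 | r > length(r)))
      msg <- c(msg, "ranks must lie in [1, number of genes]")
    # valid competition ("1224") ranking: each tie block starts at
    # 1 + number of strictly better genes
    tab <- table(r)
    expected <- cumsum(c(0, head(as.vector(tab), -1L))) + 1
    if (!isTRUE(all.equal(as.numeric(names(tab)), expected)))
      msg <- c(msg, "ranks are not a valid competition ranking")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# Internal constructor: competition ranks unless explicit ranks are given.
stabilityTable <- function(algorithm, score, rank = NULL, details = list()) {
  if (is.null(rank)) rank <- competitionRank(score)
  new("StabilityTable", algorithm = algorithm, score = score,
      rank = rank[names(score)], direction = "lower_is_stable",
      details = details)
}

#' @describeIn StabilityTable genes scored, in score order (most stable
#'   first).
#' @param x a \code{StabilityTable}.
#' @export
setMethod("geneNames", "StabilityTable",
          function(x) names(sort(x@score)))

#' @describeIn StabilityTable named score vector.
#' @export
setMethod("stabilityScores", "StabilityTable", function(x) x@score)

#' @describeIn StabilityTable named rank vector.
#' @export
setMethod("stabilityRanks", "StabilityTable", function(x) x@rank)

setMethod("show", "StabilityTable", function(object) {
  cat("StabilityTable [", object@algorithm, "] over",
      length(object@score), "genes (lower = more stable)\n")
  df <- as.data.frame(object)
  print(head(df, 12L), row.names = FALSE)
  if (nrow(df) > 12L) cat("  ...", nrow(df) - 12L, "more\n")
})

#' Coerce a StabilityTable to a data.frame
#'
#' @param x a \linkS4class{StabilityTable}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns gene, algorithm, score, rank, sorted by
#'   rank.
#' @exportS3Method base::as.data.frame
#' @export as.data.frame.StabilityTable
as.data.frame.StabilityTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  df <- data.frame(gene = names(x@score), algorithm = x@algorithm,
                   score = unname(x@score), rank = unname(x@rank),
                   stringsAsFactors = FALSE)
  df[order(df$rank, df$gene), , drop = FALSE]
}
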