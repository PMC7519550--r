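#' @include cqstab-package.R
NULL

#' Gene identifiers of an object
#'
#' @param x a \linkS4class{CqSet} or \linkS4class{StabilityTable}.
#' @return Character vector of gene names.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Culture (group) labels present in a Cq dataset
#'
#' @param x a \linkS4class{CqSet}.
#' @return Character vector of culture labels.
#' @export
setGeneric("cultureNames", function(x) standardGeneric("cultureNames"))

#' Sample unit of a Cq dataset
#'
#' The unit of one observation: individual technical replicates
#' (\code{"tech_rep"}) or lysates after averaging technical replicates
#' (\code{"lysate_mean"}).
#'
#' @param x a \linkS4class{CqSet}.
#' @return Single character string.
#' @export
setGeneric("sampleUnit", function(x) standardGeneric("sampleUnit"))

#' Provenance label of a Cq dataset
#'
#' @param x a \linkS4class{CqSet}.
#' @return Single character string.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Long-format observations of a Cq dataset
#'
#' @param x a \linkS4class{CqSet}.
#' @return A data.frame with columns \code{gene}, \code{culture},
#'   \code{passage}, \code{lysate}, \code{tech_rep}, \code{cq}.
#' @export
setGeneric("cqObservations", function(x) standardGeneric("cqObservations"))

#' Average technical replicates to lysate means
#'
#' @param x a \linkS4class{CqSet} at technical-replicate level.
#' @param level target level; only \code{"lysate_mean"} is defined.
#' @return A \linkS4class{CqSet} with one observation per
#'   (gene, culture, passage, lysate).
#' @export
setGeneric("collapseReplicates",
           function(x, level = "lysate_mean") standardGeneric("collapseReplicates"))

#' Stability scores of a StabilityTable
#'
#' @param x a \linkS4class{StabilityTable}.
#' @return Named numeric vector of per-gene scores (lower = more stable).
#' @export
setGeneric("stabilityScores", function(x) standardGeneric("stabilityScores"))

#' Stability ranks of a StabilityTable
#'
#' @param x a \linkS4class{StabilityTable}.
#' @return Named numeric vector of per-gene competition ranks.
#' @export
setGeneric("stabilityRanks", function(x) standardGeneric("stabilityRanks"))
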