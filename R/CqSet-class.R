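#' @include AllGenerics.R utils.R
NULL

#' CqSet: long-format quantification-cycle observations
#'
#' A \code{CqSet} stores RT-qPCR quantification-cycle (Cq) values in long
#' format, one row per measured well, together with the nested sample
#' structure of a cell-culture study: culture (biological replicate or
#' sub-clone), passage, lysate within passage, and technical replicate within
#' lysate. It is the single input currency of all stability estimators in
#' this package.
#'
#' Validity requires: all Cq values finite with \code{0 < cq <= maxCycles};
#' the key (gene, culture, passage, lysate, tech_rep) unique; and every gene
#' observed in at least two distinct samples, since every stability estimator
#' needs a variance.
#'
#' @slot observations data.frame with columns \code{gene}, \code{culture},
#'   \code{passage} (ordinal integer), \code{lysate}, \code{tech_rep},
#'   \code{cq} (cycles).
#' @slot sampleUnit \code{"tech_rep"} (raw wells) or \code{"lysate_mean"}
#'   (technical replicates averaged).
#' @slot maxCycles number of amplification cycles the instrument ran; the
#'   upper bound for a valid Cq (default 40).
#' @slot provenance free-text label describing where the data came from.
#'
#' @seealso \code{\link{readCqTable}}, \code{\link{cqMatrix}},
#'   \code{\link{generateReferencePanel}}
#' @export
setClass("CqSet",
  representation(observations = "data.frame",
                 sampleUnit = "character",
                 maxCycles = "numeric",
                 provenance = "character"),
  prototype(observations = data.frame(gene = character(), culture = character(),
                                      passage = integer(), lysate = integer(),
                                      tech_rep = integer(), cq = numeric()),
            sampleUnit = "tech_rep", maxCycles = 40, provenance = ""))

.CQ_COLUMNS <- c("gene", "culture", "passage", "lysate", "tech_rep", "cq")

setValidity("CqSet", function(object) {
  obs <- object@observations
  msg <- character()
  missing_cols <- setdiff(.CQ_COLUMNS, names(obs))
  if (length(missing_cols))
    return(paste("missing observation column(s):",
                 paste(missing_cols, collapse = ", ")))
  if (!object@sampleUnit %in% c("tech_rep", "lysate_mean"))
    msg <- c(msg, "sampleUnit must be 'tech_rep' or 'lysate_mean'")
  if (length(object@maxCycles) != 1L || !is.finite(object@maxCycles) ||
      object@maxCycles <= 0)
    msg <- c(msg, "maxCycles must be a single positive number")
  if (nrow(obs)) {
    bad <- which(!is.finite(obs$cq) | obs$cq <= 0 | obs$cq > object@maxCycles)
    if (length(bad))
      msg <- c(msg, sprintf(
        "cq out of range (0, %g] in row(s): %s", object@maxCycles,
        paste(head(bad, 10L), collapse = ", ")))
    key <- do.call(paste, c(obs[c("gene", "culture", "passage", "lysate",
                                  "tech_rep")], sep = "\r"))
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicated (gene, culture, passage, lysate, tech_rep) key in row(s): %s",
                            paste(head(which(duplicated(key)), 10L), collapse = ", ")))
    sid <- sampleId(obs, object@sampleUnit)
    nsamp <- vapply(split(sid, obs$gene), function(s) length(unique(s)), 0L)
    if (any(nsamp < 2L))
      msg <- c(msg, sprintf("gene(s) observed in < 2 distinct samples: %s",
                            paste(names(nsamp)[nsamp < 2L], collapse = ", ")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a CqSet
#'
#' @param observations data.frame with columns \code{gene}, \code{culture},
#'   \code{passage}, \code{lysate}, \code{tech_rep}, \code{cq}.
#' @param sampleUnit observation unit, \code{"tech_rep"} or
#'   \code{"lysate_mean"}.
#' @param maxCycles number of PCR cycles run; Cq must lie in (0, maxCycles].
#' @param provenance free-text label.
#' @return A validated \linkS4class{CqSet}.
#' @examples
#' obs <- expand.grid(gene = c("ACTB", "GAPDH"), culture = "A1", passage = 28,
#'                    lysate = 1:2, tech_rep = 1L, stringsAsFactors = FALSE)
#' obs$cq <- c(16.0, 17.1, 16.1, 17.2)
#' cs <- CqSet(obs)
#' geneNames(cs)
#' @export
CqSet <- function(observations, sampleUnit = "tech_rep", maxCycles = 40,
                  provenance = "") {
  observations <- as.data.frame(observations)
  missing_cols <- setdiff(.CQ_COLUMNS, names(observations))
  if (length(missing_cols))
    stop("missing observation column(s): ", paste(missing_cols, collapse = ", "))
  observations <- observations[.CQ_COLUMNS]
  observations$gene <- as.character(observations$gene)
  observations$culture <- as.character(observations$culture)
  observations$passage <- as.integer(observations$passage)
  observations$lysate <- as.integer(observations$lysate)
  observations$tech_rep <- as.integer(observations$tech_rep)
  if (!is.numeric(observations$cq))
    stop("cq column must be numeric")
  rownames(observations) <- NULL
  new("CqSet", observations = observations, sampleUnit = sampleUnit,
      maxCycles = maxCycles, provenance = as.character(provenance))
}

#' @describeIn CqSet gene identifiers present.
#' @param x a \code{CqSet}.
#' @export
setMethod("geneNames", "CqSet", function(x) sort(unique(x@observations$gene)))

#' @describeIn CqSet culture labels present.
#' @export
setMethod("cultureNames", "CqSet", function(x) sort(unique(x@observations$culture)))

#' @describeIn CqSet observation unit.
#' @export
setMethod("sampleUnit", "CqSet", function(x) x@sampleUnit)

#' @describeIn CqSet provenance label.
#' @export
setMethod("provenance", "CqSet", function(x) x@provenance)

#' @describeIn CqSet long-format observation table.
#' @export
setMethod("cqObservations", "CqSet", function(x) x@observations)

setMethod("show", "CqSet", function(object) {
  obs <- object@observations
  cat("CqSet with", nrow(obs), "observations (unit:", object@sampleUnit, ")\n")
  cat("  genes   :", length(unique(obs$gene)), "--",
      paste(head(sort(unique(obs$gene)), 6L), collapse = ", "),
      if (length(unique(obs$gene)) > 6L) "..." else "", "\n")
  cat("  cultures:", paste(sort(unique(obs$culture)), collapse = ", "), "\n")
  if (nrow(obs))
    cat("  passages:", paste(sort(unique(obs$passage)), collapse = ", "), "\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' Number of observations in a CqSet
#' @param x a CqSet.
#' @return Integer row count.
#' @export
setMethod("length", "CqSet", function(x) nrow(x@observations))
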