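#' @include CqSet-class.R
NULL

#' Read a Cq table from delimited text
#'
#' Reads either a long-format table (columns \code{gene}, \code{culture},
#' \code{passage}, \code{lysate}, \code{tech_rep}, \code{cq}) or a wide
#' gene-by-sample table whose first column is \code{gene} and whose remaining
#' column names encode the sample as \code{"culture.passage.lysate.rep"}
#' (or \code{"culture.passage.lysate"} for lysate-mean data). The delimiter
#' is taken from the file extension (\code{.tsv}/\code{.txt} = tab, otherwise
#' comma); row order never affects downstream results.
#'
#' @param path file to read.
#' @param layout \code{"long"} or \code{"wide"}.
#' @param maxCycles upper bound of a valid Cq (cycles the instrument ran).
#' @param sampleUnit unit recorded in the file; for wide files it is inferred
#'   from the number of fields in the column names when \code{NULL}.
#' @param provenance free-text label; defaults to the file name.
#' @return A validated \linkS4class{CqSet}.
#' @seealso \code{\link{writeCqTable}}
#' @export
readCqTable <- function(path, layout = c("long", "wide"), maxCycles = 40,
                        sampleUnit = NULL, provenance = basename(path)) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (layout == "long") {
    missing_cols <- setdiff(.CQ_COLUMNS, names(raw))
    if (length(missing_cols))
      stop("schema error: missing column(s): ",
           paste(missing_cols, collapse = ", "))
    cq <- suppressWarnings(as.numeric(raw$cq))
    bad <- which(is.na(cq) & !is.na(raw$cq) | !is.na(cq) &
                   (cq <= 0 | cq > maxCycles))
    if (length(bad))
      stop("validation error: non-numeric or out-of-range cq in row(s): ",
           paste(bad, collapse = ", "))
    raw$cq <- cq
    if (is.null(sampleUnit)) sampleUnit <- "tech_rep"
    obs <- raw[.CQ_COLUMNS]
  } else {
    if (!identical(tolower(names(raw)[1L]), "gene"))
      stop("schema error: wide layout requires first column 'gene'")
    ids <- names(raw)[-1L]
    parts <- strsplit(ids, ".", fixed = TRUE)
    nparts <- lengths(parts)
    if (!all(nparts %in% c(3L, 4L)) || length(unique(nparts)) != 1L)
      stop("schema error: wide column names must be 'culture.passage.lysate[.rep]'")
    if (is.null(sampleUnit))
      sampleUnit <- if (nparts[1L] == 4L) "tech_rep" else "lysate_mean"
    meta <- do.call(rbind, lapply(parts, function(p)
      data.frame(culture = p[1L], passage = as.integer(p[2L]),
                 lysate = as.integer(p[3L]),
                 tech_rep = if (length(p) == 4L) as.integer(p[4L]) else 1L,
                 stringsAsFactors = FALSE)))
    obs <- do.call(rbind, lapply(seq_along(ids), function(j) {
      cq <- suppressWarnings(as.numeric(raw[[j + 1L]]))
      bad <- which(is.na(cq) & !is.na(raw[[j + 1L]]) |
                     !is.na(cq) & (cq <= 0 | cq > maxCycles))
      if (length(bad))
        stop("validation error: non-numeric or out-of-range cq for sample ",
             ids[j], " row(s): ", paste(bad, collapse = ", "))
      cbind(data.frame(gene = as.character(raw$gene),
                       stringsAsFactors = FALSE),
            meta[rep(j, nrow(raw)), , drop = FALSE], cq = cq)
    }))
    obs <- obs[!is.na(obs$cq), , drop = FALSE]
  }
  CqSet(obs, sampleUnit = sampleUnit, maxCycles = maxCycles,
        provenance = provenance)
}

#' Write a CqSet to delimited text
#'
#' Inverse of \code{\link{readCqTable}}: the written file reads back to an
#' identical observation multiset.
#'
#' @param x a \linkS4class{CqSet}.
#' @param path output file; extension selects the delimiter as in
#'   \code{\link{readCqTable}}.
#' @param layout \code{"long"} or \code{"wide"}.
#' @return \code{path}, invisibly.
#' @export
writeCqTable <- function(x, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  if (layout == "long") {
    tab <- cqObservations(x)
  } else {
    m <- cqMatrix(x, requireComplete = TRUE)
    tab <- data.frame(gene = rownames(m), as.data.frame(m),
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  write.table(tab, path, sep = sep, quote = TRUE, row.names = FALSE,
              qmethod = "double")
  invisible(path)
}

#' @describeIn collapseReplicates average technical replicates of a CqSet to
#'   one observation per (gene, culture, passage, lysate); Cq values are
#'   averaged on the Cq (log) scale before any linear-scale transform.
#' @export
setMethod("collapseReplicates", "CqSet", function(x, level = "lysate_mean") {
  level <- match.arg(level, "lysate_mean")
  if (sampleUnit(x) == "lysate_mean") return(x)
  obs <- cqObservations(x)
  agg <- aggregate(cq ~ gene + culture + passage + lysate, data = obs,
                   FUN = mean)
  agg$tech_rep <- 1L
  CqSet(agg[.CQ_COLUMNS], sampleUnit = "lysate_mean",
        maxCycles = x@maxCycles, provenance = provenance(x))
})

#' Merge two Cq datasets over their shared genes
#'
#' Pools the observations of two datasets (for example the two sub-clone
#' cultures of one cell line) restricted to genes present in both, keeping
#' culture labels so grouped analyses can still separate them.
#'
#' @param a,b \linkS4class{CqSet}s at the same sample unit.
#' @return A \linkS4class{CqSet} with the union of observations over shared
#'   genes.
#' @export
mergeCqSets <- function(a, b) {
  stopifnot(is(a, "CqSet"), is(b, "CqSet"))
  if (!identical(sampleUnit(a), sampleUnit(b)))
    stop("cannot merge datasets with different sample units")
  shared <- intersect(geneNames(a), geneNames(b))
  if (!length(shared))
    stop("gene sets are disjoint; nothing to merge")
  obs <- rbind(cqObservations(a), cqObservations(b))
  obs <- obs[obs$gene %in% shared, , drop = FALSE]
  CqSet(obs, sampleUnit = sampleUnit(a),
        maxCycles = max(a@maxCycles, b@maxCycles),
        provenance = paste(provenance(a), provenance(b), sep = " + "))
}

#' Gene-by-sample Cq matrix of a CqSet
#'
#' Pivots the long observations to a genes-by-samples matrix with a
#' deterministic sample ordering (culture, then passage, then lysate, then
#' technical replicate). Column names are \code{"culture.passage.lysate[.rep]"}
#' and the per-sample metadata travel in the \code{"sampleInfo"} attribute.
#' No imputation is ever performed: with \code{requireComplete = TRUE}
#' (the default for all stability estimators) missing cells are an error that
#' lists every (gene, sample) hole; otherwise they are returned as \code{NA}
#' alongside a \code{"missingCells"} attribute.
#'
#' @param x a \linkS4class{CqSet}.
#' @param requireComplete error on missing cells?
#' @return Numeric matrix, genes in rows (sorted), samples in columns, with
#'   attributes \code{sampleInfo} (data.frame) and, if incomplete and
#'   allowed, \code{missingCells}.
#' @export
cqMatrix <- function(x, requireComplete = TRUE) {
  obs <- cqObservations(x)
  unit <- sampleUnit(x)
  sid <- sampleId(obs, unit)
  ord <- order(obs$culture, obs$passage, obs$lysate, obs$tech_rep)
  sids <- unique(sid[ord])
  genes <- sort(unique(obs$gene))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(sids),
              dimnames = list(genes, sids))
  m[cbind(match(obs$gene, genes), match(sid, sids))] <- obs$cq
  info <- unique(obs[ord, c("culture", "passage", "lysate",
                            if (unit == "tech_rep") "tech_rep")])
  rownames(info) <- sids
  holes <- which(is.na(m), arr.ind = TRUE)
  if (nrow(holes)) {
    report <- data.frame(gene = genes[holes[, 1L]], sample = sids[holes[, 2L]],
                         stringsAsFactors = FALSE)
    if (requireComplete)
      stop("incomplete Cq matrix; missing cells: ",
           paste(sprintf("(%s, %s)", report$gene, report$sample),
                 collapse = ", "))
    attr(m, "missingCells") <- report
  }
  attr(m, "sampleInfo") <- info
  m
}

#' Per-sample metadata of a Cq matrix
#'
#' @param m a matrix returned by \code{\link{cqMatrix}}.
#' @return data.frame with one row per column of \code{m}.
#' @export
sampleInfo <- function(m) attr(m, "sampleInfo")
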