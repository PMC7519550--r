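#' @include consensus.R validation.R synthetic.R
NULL

#' Run the full reference-gene selection workflow
#'
#' Orchestrates the whole pipeline on one or more Cq datasets: per-culture
#' stability tables from every enabled estimator, the combined-culture
#' analysis, the geNorm V series and optimal-gene-count rule, consensus
#' ranking, the integrated selection of a working pair plus experimental
#' candidate, and (optionally) verdict screening of candidate reference
#' sets against genes of interest. With no input datasets, seeded synthetic
#' panels for cultures A1 and A2 are generated from
#' \code{\link{defaultProfile}}. The run is fully deterministic for a fixed
#' config: the same config and seed give byte-identical JSON summaries.
#'
#' @param config list of options; recognised entries (with defaults):
#'   \code{datasets} (named list of \linkS4class{CqSet}s; default synthetic
#'   A1/A2), \code{gois} (named list of single-gene CqSets, optional),
#'   \code{sets} (list of candidate reference sets for screening, optional),
#'   \code{algorithms} (subset of c("cv","genorm","normfinder","bestkeeper",
#'   "deltact")), \code{alpha} (0.05), \code{cutoff} (0.15), \code{topK}
#'   (3), \code{efficiency} (2), \code{dispersion} ("mad"), \code{seed} (1),
#'   \code{calibrators} (named per-dataset passage labels; default first
#'   passage), \code{outDir} (optional: write CSVs and a JSON summary
#'   there).
#' @return A report bundle: list with per-dataset \code{stability} tables,
#'   \code{vSeries}, \code{geneCount}, \code{consensus}, \code{trend},
#'   \code{combined} analogues, \code{selection}, optional \code{verdicts},
#'   the effective \code{config}, and a \code{log} of every default in
#'   effect.
#' @export
runFullAnalysis <- function(config = list()) {
  cfg <- list(algorithms = c("cv", "genorm", "normfinder", "bestkeeper",
                             "deltact"),
              alpha = 0.05, cutoff = 0.15, topK = 3, efficiency = 2,
              dispersion = "mad", seed = 1L, collapse = TRUE)
  cfg[names(config)] <- config
  log <- c(sprintf("alpha = %g", cfg$alpha),
           sprintf("geNorm V cutoff = %g", cfg$cutoff),
           sprintf("topK = %d", as.integer(cfg$topK)),
           sprintf("PCR efficiency = %g (2^-Cq transforms)", cfg$efficiency),
           sprintf("BestKeeper dispersion = %s", cfg$dispersion),
           sprintf("technical replicates collapsed to lysate means = %s",
                   cfg$collapse),
           sprintf("seed = %d", as.integer(cfg$seed)))
  if (is.null(cfg$datasets)) {
    spec <- defaultProfile(seed = cfg$seed)
    cfg$datasets <- list(A1 = generateReferencePanel(spec, "A1"),
                         A2 = generateReferencePanel(spec, "A2"))
    log <- c(log, "datasets: synthetic A1/A2 panels from defaultProfile()")
  }
  runTables <- function(ds, grouped = FALSE) {
    tabs <- list()
    if ("cv" %in% cfg$algorithms)
      tabs$cv <- cvStability(ds, collapse = cfg$collapse,
                             efficiency = cfg$efficiency)
    if ("genorm" %in% cfg$algorithms)
      tabs$genorm <- geNorm(ds, collapse = cfg$collapse,
                            efficiency = cfg$efficiency)
    if ("normfinder" %in% cfg$algorithms)
      tabs$normfinder <- normFinder(ds, groups = if (grouped) TRUE else NULL,
                                    collapse = cfg$collapse)
    if ("bestkeeper" %in% cfg$algorithms)
      tabs$bestkeeper <- bestKeeper(ds, collapse = cfg$collapse,
                                    dispersion = cfg$dispersion)
    if ("deltact" %in% cfg$algorithms)
      tabs$deltact <- comparativeDeltaCt(ds, collapse = cfg$collapse)
    tabs
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  bundle <- list(config = cfg, log = log, datasets = list())
  for (dsName in names(cfg$datasets)) {
    ds <- cfg$datasets[[dsName]]
    cal <- if (!is.null(cfg$calibrators[[dsName]])) cfg$calibrators[[dsName]]
           else min(cqObservations(ds)$passage)
    tabs <- stage(paste0("stability:", dsName), runTables(ds))
    vs <- if ("genorm" %in% cfg$algorithms)
      stage(paste0("genormV:", dsName),
            geNormV(ds, tabs$genorm, collapse = cfg$collapse,
                    efficiency = cfg$efficiency)) else NULL
    trend <- stage(paste0("trend:", dsName),
                   passageFoldChange(ds, calibrator = cal,
                                     collapse = cfg$collapse,
                                     alpha = cfg$alpha))
    cons <- if (length(tabs) >= 2L)
      stage(paste0("consensus:", dsName), consensusRanking(tabs)) else NULL
    bundle$datasets[[dsName]] <- list(
      stability = tabs, vSeries = vs,
      geneCount = if (!is.null(vs)) optimalGeneCount(vs, cfg$cutoff),
      trend = trend, consensus = cons, calibrator = cal)
  }
  if (length(cfg$datasets) >= 2L) {
    combined <- stage("merge", Reduce(mergeCqSets, cfg$datasets))
    tabs <- stage("stability:combined", runTables(combined, grouped = TRUE))
    vs <- if ("genorm" %in% cfg$algorithms)
      stage("genormV:combined", geNormV(combined, tabs$genorm,
                                        collapse = cfg$collapse,
                                        efficiency = cfg$efficiency))
    bundle$combined <- list(
      stability = tabs, vSeries = vs,
      geneCount = if (!is.null(vs)) optimalGeneCount(vs, cfg$cutoff),
      consensus = if (length(tabs) >= 2L) consensusRanking(tabs))
  }
  trendP <- local({
    t1 <- bundle$datasets[[1L]]$trend$tests
    setNames(t1$p_global, t1$gene)
  })
  allTabs <- c(lapply(bundle$datasets, `[[`, "stability"),
               if (!is.null(bundle$combined))
                 list(combined = bundle$combined$stability))
  bundle$selection <- stage("selection",
    integratedSelection(allTabs, trendP = trendP, topK = cfg$topK,
                        alpha = cfg$alpha))
  if (!is.null(cfg$gois) && !is.null(cfg$sets)) {
    primary <- cfg$datasets[[1L]]
    bundle$verdicts <- stage("screen",
      screenReferenceSets(cfg$gois, primary, cfg$sets,
                          calibrator = bundle$datasets[[1L]]$calibrator,
                          collapse = cfg$collapse,
                          efficiency = cfg$efficiency, alpha = cfg$alpha))
  }
  if (!is.null(cfg$outDir)) writeBundle(bundle, cfg$outDir)
  bundle
}

# Serialize the bundle: tidy CSV of all stability tables plus a JSON summary.
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tidy <- do.call(rbind, unlist(lapply(
    c(bundle$datasets, list(combined = bundle$combined)),
    function(d) lapply(d$stability, as.data.frame)), recursive = FALSE))
  if (!is.null(tidy)) {
    tidy <- cbind(dataset = sub("\\..*$", "", rownames(tidy)), tidy)
    rownames(tidy) <- NULL
    write.csv(tidy, file.path(outDir, "scores.csv"), row.names = FALSE)
  }
  summary <- list(
    selection = bundle$selection[c("pair", "experimental", "triplet")],
    geneCount = lapply(c(bundle$datasets, list(combined = bundle$combined)),
                       function(d) d$geneCount$count),
    log = bundle$log)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(bundle$verdicts))
    write.csv(bundle$verdicts, file.path(outDir, "verdicts.csv"),
              row.names = FALSE)
  invisible(outDir)
}

#' Render a report bundle as markdown
#'
#' Formats the tables of a \code{\link{runFullAnalysis}} bundle as a
#' human-readable markdown summary: per-dataset stability rankings (tied
#' ranks share a numeral), the V-series decision, the consensus table, the
#' selection audit and, when present, the verdict grid of the reference-set
#' screening.
#'
#' @param bundle result of \code{\link{runFullAnalysis}}.
#' @return Character vector of markdown lines, invisibly printable with
#'   \code{cat(..., sep = "\n")}.
#' @export
renderReport <- function(bundle) {
  fmtTable <- function(df) {
    cells <- rbind(names(df), vapply(df, function(col)
      format(col, digits = 4, trim = TRUE), character(nrow(df))))
    widths <- apply(nchar(cells), 2L, max)
    row <- function(i) paste0("| ", paste(mapply(formatC, cells[i, ],
                                                 width = widths,
                                                 MoreArgs = list(flag = "-")),
                                          collapse = " | "), " |")
    sepr <- paste0("|", paste(strrep("-", widths + 2L), collapse = "|"), "|")
    c(row(1L), sepr, vapply(seq_len(nrow(df)) + 1L, row, ""))
  }
  out <- c("# Reference-gene stability report", "")
  for (dsName in names(bundle$datasets)) {
    d <- bundle$datasets[[dsName]]
    out <- c(out, sprintf("## Dataset %s", dsName), "")
    for (t in d$stability)
      out <- c(out, sprintf("### %s", t@algorithm), "",
               fmtTable(as.data.frame(t)), "")
    if (!is.null(d$geneCount)) {
      gc <- d$geneCount
      out <- c(out, if (gc$recommended)
        sprintf("Optimal number of reference genes: %d (first V below cutoff).",
                gc$count)
        else sprintf("No V value below the cutoff; minimizing n = %d flagged for user judgement.",
                     gc$bestN), "")
    }
  }
  if (!is.null(bundle$combined)) {
    out <- c(out, "## Combined dataset", "")
    cons <- bundle$combined$consensus
    if (!is.null(cons)) {
      df <- data.frame(gene = names(cons$geomean),
                       geomean_rank = unname(cons$geomean),
                       rank = unname(cons$rank))
      out <- c(out, "### Consensus (geometric mean of ranks)", "",
               fmtTable(df[order(df$rank), ]), "")
    }
  }
  sel <- bundle$selection
  out <- c(out, "## Integrated selection", "",
           sprintf("Selected pair: %s", paste(sel$pair, collapse = " + ")),
           sprintf("Experimental candidate: %s", sel$experimental),
           sprintf("Recommended triplet: %s",
                   paste(sel$triplet, collapse = " + ")), "")
  if (!is.null(bundle$verdicts)) {
    out <- c(out, "## Reference-set screening", "")
    out <- c(out, if (nrow(bundle$verdicts)) fmtTable(bundle$verdicts)
             else "No candidate sets screened.", "")
  }
  out <- c(out, "## Defaults in effect", "", paste("-", bundle$log))
  out
}
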