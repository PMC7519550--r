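#' @include CqSet-class.R cq-io.R
NULL

# Reference-panel baselines: per-gene mean Cq and technical dispersion for
# the 12-gene MCF-7 candidate panel, sub-clone culture A1 (A2 offsets below).
.PANEL_A1 <- data.frame(
  gene = c("ACTB", "GAPDH", "RPL13A", "PGK1", "HSPCB", "RNA28S", "RNA18S",
           "PUM1", "CCSER2", "HNRNPL", "PCBP1", "SF3A1"),
  baseline_cq = c(15.98, 17.13, 21.03, 21.08, 20.40, 8.27, 7.93,
                  23.14, 26.58, 22.73, 22.13, 23.39),
  tech_sd = c(0.26, 0.17, 0.29, 0.22, 0.29, 0.23, 0.27,
              0.21, 0.21, 0.35, 0.22, 0.34),
  stringsAsFactors = FALSE)

# Sub-clone divergence: culture A2 mean Cq minus culture A1 mean Cq.
.A2_SHIFT <- c(ACTB = 16.11 - 15.98, GAPDH = 17.07 - 17.13,
               RPL13A = 20.74 - 21.03, PGK1 = 21.09 - 21.08,
               HSPCB = 20.42 - 20.40, RNA28S = 8.35 - 8.27,
               RNA18S = 8.26 - 7.93, PUM1 = 23.08 - 23.14,
               CCSER2 = 26.56 - 26.58, HNRNPL = 22.91 - 22.73,
               PCBP1 = 22.17 - 22.13, SF3A1 = 23.51 - 23.39)

#' Default synthetic profile: a 12-gene MCF-7-like reference panel
#'
#' Returns the generator specification emulating a two-sub-clone passage
#' study: 12 candidate reference genes with per-gene baseline Cq and
#' technical-replicate dispersion (culture A1 values; ACTB 15.98 +- 0.26,
#' GAPDH 17.13 +- 0.17, RNA18S 7.93 +- 0.27, CCSER2 26.58 +- 0.21, ...),
#' 5 passages x 3 lysates x 3 technical replicates, a gene-shared passage
#' effect (SD 0.15 cycles) and lysate effect (SD 0.10 cycles), per-gene
#' sub-clone offsets for culture A2, and zero planted drift.
#'
#' @param seed integer seed for the generator.
#' @return A \code{SyntheticSpec}: a list with elements \code{genes}
#'   (data.frame gene/baseline_cq/tech_sd), \code{n_passages},
#'   \code{n_lysates}, \code{n_tech}, \code{passage_sd}, \code{lysate_sd},
#'   \code{drift} (named cycles/passage), \code{group_shift} (named list per
#'   culture of named per-gene offsets), \code{seed}.
#' @examples
#' spec <- defaultProfile()
#' spec$genes[spec$genes$gene == "ACTB", ]
#' @export
defaultProfile <- function(seed = 1L) {
  spec <- list(
    genes = .PANEL_A1,
    n_passages = 5L,
    n_lysates = 3L,
    n_tech = 3L,
    passage_sd = 0.15,
    lysate_sd = 0.10,
    drift = setNames(rep(0, nrow(.PANEL_A1)), .PANEL_A1$gene),
    group_shift = list(A1 = setNames(rep(0, nrow(.PANEL_A1)), .PANEL_A1$gene),
                       A2 = .A2_SHIFT),
    seed = as.integer(seed))
  validateSyntheticSpec(spec)
  spec
}

validateSyntheticSpec <- function(spec) {
  stopifnot(is.data.frame(spec$genes),
            all(c("gene", "baseline_cq", "tech_sd") %in% names(spec$genes)),
            all(spec$genes$tech_sd >= 0),
            spec$passage_sd >= 0, spec$lysate_sd >= 0,
            spec$n_passages >= 1L, spec$n_lysates >= 1L, spec$n_tech >= 1L)
  invisible(spec)
}

#' Generate a synthetic reference-gene Cq panel
#'
#' Simulates technical-replicate-level Cq values under the additive
#' variance-component model
#' \deqn{Cq_{gplr} = b_g + s_{g,c} + d_g (p - 1) + P_p + L_{pl} +
#'   \epsilon_{gplr}}
#' with \eqn{b_g} the gene baseline, \eqn{s_{g,c}} the per-culture offset,
#' \eqn{d_g} a planted linear drift (cycles/passage), \eqn{P_p} a
#' gene-shared passage effect \eqn{N(0, passage\_sd^2)}, \eqn{L_{pl}} a
#' gene-shared lysate effect \eqn{N(0, lysate\_sd^2)} (both model shared
#' sample-level variation: amount and quality of input material), and
#' \eqn{\epsilon} per-well technical noise \eqn{N(0, tech\_sd_g^2)}.
#' Identical spec and seed give a bit-for-bit identical dataset; the random
#' streams are named per (component, culture) so panels for different
#' cultures, and gene-of-interest streams, are mutually independent.
#'
#' @param spec a \code{SyntheticSpec}, see \code{\link{defaultProfile}}.
#' @param culture culture label; "A1" and "A2" select the bundled sub-clone
#'   offsets and passage numbering (A1: p28-p32, A2: p25-p30 with
#'   \code{n_passages = 6}), any other label uses passages 1..n and zero
#'   offset unless present in \code{spec$group_shift}.
#' @param passages optional explicit passage labels (ordinal integers),
#'   length \code{spec$n_passages}.
#' @return A \linkS4class{CqSet} at technical-replicate level.
#' @examples
#' panel <- generateReferencePanel(defaultProfile(seed = 7), "A1")
#' panel
#' @export
generateReferencePanel <- function(spec, culture = "A1", passages = NULL) {
  validateSyntheticSpec(spec)
  if (is.null(passages)) {
    passages <- switch(culture,
      A1 = seq(28L, length.out = spec$n_passages),
      A2 = seq(25L, length.out = spec$n_passages),
      seq_len(spec$n_passages))
  }
  stopifnot(length(passages) == spec$n_passages)
  genes <- spec$genes$gene
  drift <- if (is.null(spec$drift)) setNames(rep(0, length(genes)), genes)
           else spec$drift[genes]
  drift[is.na(drift)] <- 0
  shift <- spec$group_shift[[culture]]
  shift <- if (is.null(shift)) setNames(rep(0, length(genes)), genes)
           else ifelse(is.na(shift[genes]), 0, shift[genes])
  np <- spec$n_passages; nl <- spec$n_lysates; nt <- spec$n_tech
  P <- withStream(spec$seed, "passage", culture,
                  fn = function() rnorm(np, 0, spec$passage_sd))
  L <- withStream(spec$seed, "lysate", culture,
                  fn = function() matrix(rnorm(np * nl, 0, spec$lysate_sd),
                                         nrow = np))
  eps <- withStream(spec$seed, "tech", culture, fn = function() {
    arr <- array(rnorm(length(genes) * np * nl * nt), c(length(genes), np, nl, nt))
    sweep(arr, 1L, spec$genes$tech_sd, `*`)
  })
  grid <- expand.grid(tech_rep = seq_len(nt), lysate = seq_len(nl),
                      p_idx = seq_len(np), g_idx = seq_along(genes),
                      KEEP.OUT.ATTRS = FALSE)
  cq <- spec$genes$baseline_cq[grid$g_idx] +
    unname(shift[grid$g_idx]) +
    unname(drift[grid$g_idx]) * (grid$p_idx - 1L) +
    P[grid$p_idx] +
    L[cbind(grid$p_idx, grid$lysate)] +
    eps[cbind(grid$g_idx, grid$p_idx, grid$lysate, grid$tech_rep)]
  obs <- data.frame(gene = genes[grid$g_idx], culture = culture,
                    passage = passages[grid$p_idx], lysate = grid$lysate,
                    tech_rep = grid$tech_rep, cq = cq,
                    stringsAsFactors = FALSE)
  CqSet(obs, sampleUnit = "tech_rep",
        maxCycles = max(40, ceiling(max(cq))),
        provenance = sprintf("synthetic panel, culture %s, seed %d",
                             culture, spec$seed))
}

#' Generate a synthetic gene of interest on an existing sample grid
#'
#' Adds one simulated target gene on the same (culture, passage, lysate,
#' tech rep) grid as an existing panel. Three modes mirror how validation
#' targets are constructed: \code{"stable"} keeps every passage mean within
#' +-0.5 Cq of the baseline (passage-level deviations drawn uniformly within
#' +-amplitude, capped at 0.5); \code{"variable"} forces at least one passage
#' mean more than 0.5 Cq away (one passage receives a deviation of
#' +-amplitude, which must exceed 0.5); \code{"trend"} plants a monotone
#' passage trend with total range \code{amplitude}.
#'
#' Planted passage-mean deviations are exact: technical noise is centred
#' within each passage, so the passage means equal baseline + deviation.
#' With \code{inheritSampleEffects = TRUE} (default) the target additionally
#' carries the panel's shared per-well effect (the average gene-centred Cq
#' deviation of each well), emulating that a real target is measured on the
#' same lysates as the references and shares their material-level variation
#' -- which is exactly the component a normalization factor removes. The
#' planted deviations, not the inherited effects, are what the
#' stable/variable bounds refer to.
#'
#' @param gspec list with \code{name} (default "GOI"), \code{baseline_cq},
#'   \code{mode} ("stable", "variable" or "trend"), \code{amplitude}
#'   (cycles, >= 0), \code{tech_sd} (per-well noise, default 0.15) and
#'   \code{seed}. The GOI stream is independent of the panel stream.
#' @param panel \linkS4class{CqSet} defining the sample grid.
#' @param inheritSampleEffects add the panel's shared per-well effects to
#'   the target (default TRUE).
#' @return A single-gene \linkS4class{CqSet} on the panel's grid.
#' @export
generateGoi <- function(gspec, panel, inheritSampleEffects = TRUE) {
  mode <- match.arg(gspec$mode, c("stable", "variable", "trend"))
  amplitude <- gspec$amplitude
  stopifnot(amplitude >= 0)
  if (mode == "stable" && amplitude > 0.5)
    stop("stable mode requires amplitude <= 0.5")
  if (mode == "variable" && amplitude <= 0.5)
    stop("variable mode requires amplitude > 0.5")
  name <- if (is.null(gspec$name)) "GOI" else gspec$name
  tech_sd <- if (is.null(gspec$tech_sd)) 0.15 else gspec$tech_sd
  grid <- unique(cqObservations(panel)[c("culture", "passage", "lysate",
                                         "tech_rep")])
  passages <- sort(unique(grid$passage))
  np <- length(passages)
  dev <- withStream(gspec$seed, "goi", name, fn = function() {
    switch(mode,
      stable = runif(np, -amplitude, amplitude),
      variable = {
        d <- runif(np, -0.25, 0.25)
        d[sample.int(np, 1L)] <- sample(c(-1, 1), 1L) * amplitude
        d
      },
      trend = seq(0, amplitude, length.out = np) *
        sample(c(-1, 1), 1L))
  })
  # passage-mean deviations are planted exactly: technical noise is centred
  # within each passage so the passage mean equals baseline + dev
  obs <- grid
  obs$gene <- name
  eps <- withStream(gspec$seed, "goi-noise", name,
                    fn = function() rnorm(nrow(grid), 0, tech_sd))
  for (p in passages) {
    idx <- obs$passage == p
    eps[idx] <- eps[idx] - mean(eps[idx])
  }
  shared <- 0
  if (inheritSampleEffects) {
    pobs <- cqObservations(panel)
    centred <- pobs$cq - ave(pobs$cq, pobs$gene)
    key <- do.call(paste, c(pobs[c("culture", "passage", "lysate",
                                   "tech_rep")], sep = "\r"))
    well <- vapply(split(centred, key), mean, 0)
    shared <- unname(well[do.call(paste, c(grid[c("culture", "passage",
                                                  "lysate", "tech_rep")],
                                           sep = "\r"))])
  }
  obs$cq <- gspec$baseline_cq + dev[match(obs$passage, passages)] + eps +
    shared
  CqSet(obs[c("gene", "culture", "passage", "lysate", "tech_rep", "cq")],
        sampleUnit = sampleUnit(panel), maxCycles = panel@maxCycles,
        provenance = sprintf("synthetic GOI '%s', mode %s, seed %d",
                             name, mode, gspec$seed))
}

#' Generate a stress-condition panel with planted per-gene shifts
#'
#' Produces a reference panel under a stress condition by adding a constant
#' per-gene Cq offset on top of a freshly generated panel: an offset of
#' -1 Cq corresponds to a 2x linear-scale up-regulation (one PCR cycle =
#' one doubling).
#'
#' @param spec a \code{SyntheticSpec}.
#' @param shifts named numeric vector of per-gene Cq offsets (genes absent
#'   from the panel are ignored; panel genes absent here get 0).
#' @param culture label for the stress culture (e.g. "B5").
#' @return A \linkS4class{CqSet}.
#' @export
generateStressPanel <- function(spec, shifts = numeric(), culture = "B5") {
  panel <- generateReferencePanel(spec, culture = culture)
  obs <- cqObservations(panel)
  sh <- shifts[obs$gene]
  sh[is.na(sh)] <- 0
  obs$cq <- obs$cq + unname(sh)
  CqSet(obs, sampleUnit = "tech_rep",
        maxCycles = max(panel@maxCycles, ceiling(max(obs$cq))),
        provenance = sprintf("synthetic stress panel, culture %s, seed %d",
                             culture, spec$seed))
}
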