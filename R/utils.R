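# Internal helpers shared across the estimators.

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return The geometric mean exp(mean(log(x))).
#' @export
geoMean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Competition ("1224") ranks, ascending: ties share the minimum rank.
competitionRank <- function(score) {
  r <- rank(score, ties.method = "min")
  names(r) <- names(score)
  r
}

# Deterministic 31-bit stream seed derived from a base seed and labels, so
# that e.g. the technical-noise stream of culture A2 never collides with the
# passage-effect stream of culture A1 and GOI streams are isolated from the
# panel streams.
streamSeed <- function(seed, ...) {
  labels <- paste(c("cqstab", ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(labels)) h <- (h * 131 + cp) %% 2147483629L
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

# Run fn() under a local RNG state seeded from streamSeed(seed, ...).
withStream <- function(seed, ..., fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(streamSeed(seed, ...))
  fn()
}

# Boundary-inclusive two-fold rule: a fold change of exactly 2 (a planted
# one-cycle shift) must flag, so allow for floating-point round-off in the
# ratio of means.
twoFoldFlag <- function(fold) {
  fold >= 2 * (1 - 1e-9) | fold <= 0.5 * (1 + 1e-9)
}

# Sample id string used for matrix column names, "culture.passage.lysate[.rep]".
sampleId <- function(obs, unit) {
  id <- paste(obs$culture, obs$passage, obs$lysate, sep = ".")
  if (identical(unit, "tech_rep")) id <- paste(id, obs$tech_rep, sep = ".")
  id
}
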