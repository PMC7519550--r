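# Brute-force oracle implementations of the stability estimators, written as
# naive loops over the defining formulas. They stay deliberately independent
# of the package code paths they check.

# Build a CqSet from a genes-by-samples Cq matrix (one culture, one lysate,
# each column its own passage).
matrixCqSet <- function(m, culture = "X") {
  obs <- do.call(rbind, lapply(seq_len(nrow(m)), function(g)
    data.frame(gene = rownames(m)[g], culture = culture,
               passage = seq_len(ncol(m)), lysate = 1L, tech_rep = 1L,
               cq = m[g, ], stringsAsFactors = FALSE)))
  CqSet(obs, sampleUnit = "lysate_mean",
        maxCycles = max(40, ceiling(max(m))))
}

randomCqMatrix <- function(k, n, lo = 15, hi = 30) {
  m <- matrix(runif(k * n, lo, hi), nrow = k,
              dimnames = list(paste0("G", seq_len(k)),
                              paste0("S", seq_len(n))))
  m
}

# geNorm M values of the full panel: mean over other genes of the SD of the
# pairwise log2 ratio of relative quantities Q = 2^(minCq - Cq).
oracleGenormM <- function(m) {
  k <- nrow(m)
  q <- matrix(0, k, ncol(m))
  for (g in 1:k) for (s in 1:ncol(m)) q[g, s] <- 2^(min(m[g, ]) - m[g, s])
  M <- numeric(k)
  for (g in 1:k) {
    sds <- c()
    for (h in 1:k) if (h != g) {
      ratio <- log2(q[g, ] / q[h, ])
      sds <- c(sds, sd(ratio))
    }
    M[g] <- mean(sds)
  }
  names(M) <- rownames(m)
  M
}

# Full iterative geNorm: per-gene M at the round of removal plus orders.
oracleGenormFull <- function(m) {
  remaining <- rownames(m)
  score <- setNames(numeric(nrow(m)), rownames(m))
  excluded <- character()
  while (length(remaining) > 2L) {
    M <- oracleGenormM(m[remaining, , drop = FALSE])
    worst <- names(M)[which.max(M)]
    score[worst] <- M[[worst]]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  ratio <- log2((2^(min(m[remaining[1], ]) - m[remaining[1], ])) /
                  (2^(min(m[remaining[2], ]) - m[remaining[2], ])))
  score[remaining] <- sd(ratio)
  list(score = score, exclusionOrder = excluded,
       inclusionOrder = c(remaining, rev(excluded)))
}

# geNorm pairwise variation series for a given inclusion order.
oracleVSeries <- function(m, inc) {
  q <- m
  for (g in 1:nrow(m)) q[g, ] <- 2^(min(m[g, ]) - m[g, ])
  nf <- function(n) {
    out <- numeric(ncol(m))
    for (s in 1:ncol(m)) out[s] <- prod(q[inc[1:n], s])^(1 / n)
    out
  }
  k <- nrow(m)
  v <- numeric(k - 2L)
  for (n in 2:(k - 1L)) v[n - 1L] <- sd(log2(nf(n) / nf(n + 1L)))
  v
}

# Comparative delta-Ct gene scores by explicit pair enumeration.
oracleDeltaCt <- function(m) {
  k <- nrow(m)
  score <- setNames(numeric(k), rownames(m))
  for (g in 1:k) {
    sds <- c()
    for (h in 1:k) if (h != g) sds <- c(sds, sd(m[g, ] - m[h, ]))
    score[g] <- mean(sds)
  }
  score
}

# CV% of 2^-Cq by explicit loops.
oracleCV <- function(m) {
  out <- setNames(numeric(nrow(m)), rownames(m))
  for (g in 1:nrow(m)) {
    x <- 2^(-m[g, ])
    out[g] <- 100 * sd(x) / mean(x)
  }
  out
}

# BestKeeper descriptives, index and correlations by explicit loops.
oracleBestKeeper <- function(m, dispersion = "mad") {
  k <- nrow(m); n <- ncol(m)
  desc <- data.frame(gene = rownames(m), geo_mean = NA_real_, mean = NA_real_,
                     min = NA_real_, max = NA_real_, sd_cp = NA_real_,
                     x_fold = NA_real_, stringsAsFactors = FALSE)
  for (g in 1:k) {
    x <- m[g, ]
    desc$geo_mean[g] <- prod(x)^(1 / n)
    desc$mean[g] <- mean(x)
    desc$min[g] <- min(x)
    desc$max[g] <- max(x)
    desc$sd_cp[g] <- if (dispersion == "mad") mean(abs(x - mean(x))) else sd(x)
    desc$x_fold[g] <- 2^desc$sd_cp[g]
  }
  index <- numeric(n)
  for (s in 1:n) index[s] <- prod(m[, s])^(1 / k)
  r <- matrix(1, k, k, dimnames = list(rownames(m), rownames(m)))
  for (g in 1:k) for (h in 1:k) if (g != h) r[g, h] <- cor(m[g, ], m[h, ])
  list(descriptives = desc, index = index, geneCor = r)
}

# NormFinder single-group per-gene variance estimates from the published
# residual formula r_gs = y_gs - mean_g - mean_s + grand, with the
# small-panel bias correction, truncated at zero.
oracleNormfinderVar <- function(m) {
  k <- nrow(m); n <- ncol(m)
  r <- m
  for (g in 1:k) for (s in 1:n)
    r[g, s] <- m[g, s] - mean(m[g, ]) - mean(m[, s]) + mean(m)
  u <- numeric(k)
  for (g in 1:k) u[g] <- sum(r[g, ]^2) / (n - 1)
  est <- (u - mean(u) / (k - 1)) * k / (k - 2)
  setNames(pmax(0, est), rownames(m))
}

# Shared fixtures for the planted-truth checks.
driftedProfile <- function(seed, gene = "HNRNPL", rate = 0.3) {
  spec <- defaultProfile(seed = seed)
  spec$drift[gene] <- rate
  spec
}
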