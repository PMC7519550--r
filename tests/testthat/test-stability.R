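test_that("descriptive statistics match closed forms", {
  obs <- data.frame(gene = rep(c("A", "B"), each = 2),
                    culture = "X", passage = 1:2, lysate = 1L, tech_rep = 1L,
                    cq = c(20, 20, 20, 22))
  d <- describeGenes(CqSet(obs))
  a <- d[d$gene == "A", ]
  expect_equal(c(a$mean_cq, a$sd_cq, a$min_cq, a$max_cq, a$geo_mean_cq),
               c(20, 0, 20, 20, 20))
  b <- d[d$gene == "B", ]
  expect_equal(b$mean_cq, 21)
  expect_equal(b$sd_cq, sqrt(2))
  expect_equal(b$geo_mean_cq, sqrt(20 * 22))
})

test_that("CV% matches the two-point closed form and is shift-invariant", {
  m <- rbind(A = c(20, 21), B = c(25, 25.5))
  ds <- matrixCqSet(m)
  cv <- stabilityScores(cvStability(ds))
  # explicit: 2^-20 = 9.5367e-7, 2^-21 = 4.7684e-7
  x <- c(9.5367431640625e-07, 4.76837158203125e-07)
  expect_equal(unname(cv["A"]), 100 * sd(x) / mean(x))
  expect_equal(unname(round(cv["A"], 2)), 47.14)

  # adding a constant Cq offset to one gene leaves its CV unchanged
  m2 <- m; m2["A", ] <- m2["A", ] + 3
  cv2 <- stabilityScores(cvStability(matrixCqSet(m2)))
  expect_equal(cv2["A"], cv["A"])

  # constant gene
  m3 <- rbind(A = c(20, 20, 20), B = c(19, 20, 21))
  expect_equal(unname(stabilityScores(cvStability(matrixCqSet(m3)))["A"]), 0)
})

test_that("geNorm matches the brute-force oracle on random matrices", {
  set.seed(400)
  for (i in 1:5) {
    m <- randomCqMatrix(5, 8)
    full <- oracleGenormFull(m)
    g <- geNorm(matrixCqSet(m))
    expect_equal(stabilityScores(g)[names(full$score)], full$score,
                 tolerance = 1e-12)
    expect_identical(g@details$exclusionOrder, full$exclusionOrder)
    expect_identical(g@details$inclusionOrder, full$inclusionOrder)
    # first-round M values against the direct double loop
    expect_equal(g@details$rounds[[1]]$M[rownames(m)], oracleGenormM(m),
                 tolerance = 1e-12)
  }
})

test_that("geNorm degenerate and invariance cases", {
  # genes identical up to constants: all M = 0, all V = 0
  m <- outer(c(0, 1, 2, 5), runif(6, 18, 25), `+`)
  rownames(m) <- paste0("G", 1:4); colnames(m) <- paste0("S", 1:6)
  ds <- matrixCqSet(m)
  g <- geNorm(ds)
  expect_equal(unname(stabilityScores(g)), rep(0, 4))
  expect_equal(unname(geNormV(ds, g)), rep(0, 2))
  # final pair tie policy: ranks 1,1,3,4
  expect_equal(sort(unname(stabilityRanks(g))), c(1, 1, 3, 4))

  # per-gene constant offset leaves M unchanged
  set.seed(401)
  m <- randomCqMatrix(4, 6)
  m2 <- m; m2["G2", ] <- m2["G2", ] + 4
  expect_equal(stabilityScores(geNorm(matrixCqSet(m2))),
               stabilityScores(geNorm(matrixCqSet(m))))

  expect_error(geNorm(matrixCqSet(randomCqMatrix(2, 5))), "3 genes")
})

test_that("geNorm exclusion order always removes the round's maximal M", {
  set.seed(402)
  for (i in 1:10) {
    m <- randomCqMatrix(6, 7)
    g <- geNorm(matrixCqSet(m))
    # removed gene at round t is the max-M gene of round t
    for (t in seq_along(g@details$exclusionOrder)) {
      M <- g@details$rounds[[t]]$M
      expect_identical(g@details$exclusionOrder[t], names(M)[which.max(M)])
    }
  }
})

test_that("pairwise variation matches brute-force recomputation", {
  set.seed(403)
  for (i in 1:5) {
    m <- randomCqMatrix(5, 9)
    ds <- matrixCqSet(m)
    g <- geNorm(ds)
    v <- geNormV(ds, g)
    expect_equal(unname(v), oracleVSeries(m, g@details$inclusionOrder),
                 tolerance = 1e-12)
    expect_true(all(v >= 0))
  }
  # a gene proportional to the 3-gene normalization factor contributes
  # nothing at the step where it joins: V3/4 = 0
  set.seed(404)
  m <- randomCqMatrix(3, 6)
  q <- 2^(apply(m, 1, min) - m)
  nf3 <- apply(q, 2, function(z) prod(z)^(1 / 3))
  extra <- -log2(nf3) + 20  # Cq whose relative quantity is proportional to NF3
  m4 <- rbind(m, G4 = extra)
  ds4 <- matrixCqSet(m4)
  g4 <- geNorm(ds4)
  g4@details$inclusionOrder <- c(rownames(m), "G4")  # force the join order
  v <- geNormV(ds4, g4)
  expect_lt(v[["V3/4"]], 1e-12)
})

test_that("NormFinder matches the published single-group estimator", {
  set.seed(405)
  for (i in 1:5) {
    m <- randomCqMatrix(5, 10)
    nf <- normFinder(matrixCqSet(m))
    expect_equal(stabilityScores(nf), sqrt(oracleNormfinderVar(m)),
                 tolerance = 1e-12)
  }
  expect_error(normFinder(matrixCqSet(randomCqMatrix(2, 5))), "3 genes")
})

test_that("NormFinder is exactly zero for noise-free additive data", {
  gene <- c(A = 16, B = 20, C = 24, D = 27)
  sample_eff <- seq(-0.5, 0.5, length.out = 6)
  m <- outer(gene, sample_eff, `+`)
  colnames(m) <- paste0("S", 1:6)
  nf <- normFinder(matrixCqSet(m))
  expect_equal(unname(stabilityScores(nf)), rep(0, 4))
})

test_that("NormFinder recovers a high-variance gene (spot check)", {
  set.seed(406)
  gene <- c(G1 = 18, G2 = 20, G3 = 22, G4 = 24)
  sample_eff <- rnorm(8, 0, 0.5)
  noise <- matrix(rnorm(32, 0, 0.2), 4, 8)
  noise[4, ] <- rnorm(8, 0, 0.4)          # 4x the residual variance
  m <- outer(gene, sample_eff, `+`) + noise
  colnames(m) <- paste0("S", 1:8)
  nf <- normFinder(matrixCqSet(m))
  expect_equal(unname(stabilityRanks(nf)["G4"]), 4)
})

test_that("grouped NormFinder penalises between-group bias", {
  set.seed(407)
  gene <- c(G1 = 18, G2 = 20, G3 = 22, G4 = 24, G5 = 26)
  mkGroup <- function(culture, bias) {
    m <- outer(gene, rnorm(8, 0, 0.3), `+`) +
      matrix(rnorm(40, 0, 0.15), 5, 8)
    m["G5", ] <- m["G5", ] + bias     # systematic sub-clone difference
    colnames(m) <- paste0(culture, 1:8)
    obs <- do.call(rbind, lapply(rownames(m), function(g)
      data.frame(gene = g, culture = culture, passage = 1:8, lysate = 1L,
                 tech_rep = 1L, cq = m[g, ], stringsAsFactors = FALSE)))
    obs
  }
  ds <- CqSet(rbind(mkGroup("A1", -0.6), mkGroup("A2", 0.6)),
              sampleUnit = "lysate_mean")
  grouped <- normFinder(ds, groups = TRUE)
  expect_equal(unname(stabilityRanks(grouped)["G5"]), 5)
  expect_false(is.null(grouped@details$groupBias))
  # best pair excludes the biased gene
  expect_false("G5" %in% grouped@details$bestPair)
})

test_that("BestKeeper matches hand-rolled descriptives and correlations", {
  set.seed(408)
  for (i in 1:5) {
    m <- randomCqMatrix(4, 6)
    bk <- bestKeeper(matrixCqSet(m))
    oracle <- oracleBestKeeper(m)
    got <- bk@details$descriptives
    expect_equal(got$geo_mean, oracle$descriptives$geo_mean, tolerance = 1e-10)
    expect_equal(got$sd_cp, oracle$descriptives$sd_cp, tolerance = 1e-12)
    expect_equal(got$x_fold, oracle$descriptives$x_fold, tolerance = 1e-10)
    expect_equal(unname(bk@details$index), oracle$index, tolerance = 1e-10)
    expect_equal(bk@details$geneCor, oracle$geneCor, tolerance = 1e-12)
  }
  # constant gene; perfectly covarying pair
  m <- rbind(A = c(20, 20, 20, 20), B = c(19, 20, 21, 20.5),
             C = c(22, 23, 24, 23.5))
  colnames(m) <- paste0("S", 1:4)
  bk <- bestKeeper(matrixCqSet(m))
  d <- bk@details$descriptives
  expect_equal(d$sd_cp[d$gene == "A"], 0)
  expect_equal(d$x_fold[d$gene == "A"], 1)
  expect_equal(bk@details$geneCor["B", "C"], 1)
  # the sd variant is the sample SD
  bk2 <- bestKeeper(matrixCqSet(m), dispersion = "sd")
  expect_equal(stabilityScores(bk2)[["B"]], sd(m["B", ]))
})

test_that("comparative delta-Ct matches pair enumeration", {
  set.seed(409)
  for (i in 1:5) {
    m <- randomCqMatrix(5, 8)
    dc <- comparativeDeltaCt(matrixCqSet(m))
    expect_equal(stabilityScores(dc), oracleDeltaCt(m), tolerance = 1e-12)
  }
  # constant offsets: all scores 0; 2-gene symmetry
  base <- runif(5, 18, 22)
  m <- rbind(A = base, B = base + 2, C = base - 1)
  colnames(m) <- paste0("S", 1:5)
  expect_equal(unname(stabilityScores(comparativeDeltaCt(matrixCqSet(m)))),
               rep(0, 3))
  m2 <- randomCqMatrix(2, 6)
  sc <- stabilityScores(comparativeDeltaCt(matrixCqSet(m2)))
  expect_equal(sc[[1]], sc[[2]])
  expect_equal(sc[[1]], sd(m2[1, ] - m2[2, ]))
})

test_that("log-scale expression screens use the documented transforms", {
  m <- rbind(A = c(32, 32, 32), B = c(0, 1, 3), C = c(100, 120, 80))
  colnames(m) <- paste0("S", 1:3)
  tpm <- expressionStability(m[c("A", "C"), ], mode = "tpm")
  expect_equal(tpm$mean_log2[tpm$gene == "A"], 5)
  expect_equal(tpm$sd_log2[tpm$gene == "A"], 0)
  expect_true(tpm$low_variance[tpm$gene == "A"])
  expect_false(tpm$medium_high_expression[tpm$gene == "A"])  # mean not > 5

  counts <- expressionStability(m, mode = "counts")
  expect_equal(unname(counts[counts$gene == "B",
                             c("mean_log2", "sd_log2")][[1]]), 1)
  expect_error(expressionStability(m, mode = "tpm"), "zero")
})
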