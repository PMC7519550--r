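test_that("the normality gate chooses the right branch", {
  # identical groups: nothing to detect
  res <- chooseTest(rep(5, 12), rep(1:3, each = 4))
  expect_equal(res$p_global, 1)
  expect_true(all(res$comparisons$p_adj == 1))

  # clearly separated normal groups -> ANOVA branch, significant
  set.seed(600)
  y <- c(rnorm(10, 0, 1), rnorm(10, 3, 1))
  res <- chooseTest(y, rep(c("a", "b"), each = 10), calibrator = "a")
  expect_equal(res$test, "anova")
  expect_lt(res$p_global, 0.01)

  # heavy-tailed data fall back to Kruskal-Wallis in most seeds
  branches <- vapply(1:20, function(s) {
    set.seed(600 + s)
    y <- exp(rnorm(24, 0, 1.5))
    chooseTest(y, rep(1:3, each = 8))$test
  }, "")
  expect_gt(mean(branches == "kruskal"), 0.5)

  expect_error(chooseTest(1:5, c(1, 1, 1, 1, 2)), "at least 2 values")
  expect_error(chooseTest(1:6, rep(1:3, 2), calibrator = "9"), "calibrator")
})

test_that("normalization factors are geometric means of linear quantities", {
  obs <- expand.grid(gene = c("R1", "R2", "G"), culture = "X", passage = 1:2,
                     lysate = 1L, tech_rep = 1L, stringsAsFactors = FALSE)
  obs$cq <- c(20, 22, 24, 21, 23, 25)
  ds <- CqSet(obs, sampleUnit = "lysate_mean")
  nf <- normalizationFactor(ds, c("R1", "R2"))
  expect_equal(as.vector(nf), c(2^-21, 2^-22))        # geomean closed form
  expect_equal(as.vector(normalizationFactor(ds, "R1")), c(2^-20, 2^-21))
  expect_equal(as.vector(normalizationFactor(ds, c("R2", "R1"))),
               as.vector(nf))
  expect_error(normalizationFactor(ds, character()), "empty")
  expect_error(normalizationFactor(ds, c("R1", "NOPE")), "NOPE")
})

test_that("self-normalization is exactly flat and judged successful", {
  spec <- defaultProfile(seed = 61)
  panel <- generateReferencePanel(spec, "A1")
  gapdh <- CqSet(subset(cqObservations(panel), gene == "GAPDH"))
  nf <- normalizationFactor(panel, "GAPDH")
  res <- normalizeGoi(gapdh, nf, calibrator = 28)
  expect_equal(unname(res$relative), rep(1, 15))
  expect_equal(res$verdict, "successful")
})

test_that("stable GOI with stable references validates; planted trends fail", {
  spec <- defaultProfile(seed = 62)
  panel <- generateReferencePanel(spec, "A1")
  refs <- c("GAPDH", "CCSER2", "PCBP1")
  nf <- normalizationFactor(panel, refs)
  stable <- generateGoi(list(baseline_cq = 24, mode = "stable",
                             amplitude = 0.05, seed = 7), panel)
  expect_equal(normalizeGoi(stable, nf, calibrator = 28)$verdict,
               "successful")

  trended <- generateGoi(list(baseline_cq = 24, mode = "trend",
                              amplitude = 1.0, seed = 8), panel)
  expect_equal(normalizeGoi(trended, nf, calibrator = 28)$verdict, "failed")

  # a trend-planted reference breaks normalization of a stable target
  specBad <- driftedProfile(seed = 63, gene = "PCBP1", rate = 0.5)
  panelBad <- generateReferencePanel(specBad, "A1")
  stable2 <- generateGoi(list(baseline_cq = 24, mode = "stable",
                              amplitude = 0.05, seed = 9), panelBad)
  nfBad <- normalizationFactor(panelBad, refs)
  expect_equal(normalizeGoi(stable2, nfBad, calibrator = 28)$verdict,
               "failed")
})

test_that("verdicts are invariant to sample order and lysate relabeling", {
  spec <- defaultProfile(seed = 64)
  panel <- generateReferencePanel(spec, "A1")
  goi <- generateGoi(list(baseline_cq = 24, mode = "stable",
                          amplitude = 0.2, seed = 10), panel)
  refs <- c("GAPDH", "CCSER2")
  run <- function(p, g) {
    normalizeGoi(g, normalizationFactor(p, refs), calibrator = 28)
  }
  base <- run(panel, goi)
  # shuffle observation rows
  shufP <- CqSet(cqObservations(panel)[sample.int(length(panel)), ])
  shufG <- CqSet(cqObservations(goi)[sample.int(length(goi)), ])
  expect_equal(run(shufP, shufG)$verdict, base$verdict)
  expect_equal(run(shufP, shufG)$p_global, base$p_global)
  # relabel lysates consistently (1->3, 2->1, 3->2)
  relab <- function(ds) {
    obs <- cqObservations(ds)
    obs$lysate <- c(3L, 1L, 2L)[obs$lysate]
    CqSet(obs)
  }
  expect_equal(run(relab(panel), relab(goi))$verdict, base$verdict)
})

test_that("screening tabulates one verdict per GOI and candidate set", {
  spec <- defaultProfile(seed = 65)
  panel <- generateReferencePanel(spec, "A1")
  gois <- list(
    GOI1 = generateGoi(list(name = "GOI1", baseline_cq = 24, mode = "stable",
                            amplitude = 0.05, seed = 11), panel),
    GOI2 = generateGoi(list(name = "GOI2", baseline_cq = 27, mode = "trend",
                            amplitude = 1.2, seed = 12), panel))
  sets <- list("GAPDH", c("GAPDH", "CCSER2"), c("GAPDH", "CCSER2", "PCBP1"))
  grid <- screenReferenceSets(gois, panel, sets, calibrator = 28)
  expect_equal(nrow(grid), 6L)
  expect_true(all(grid$verdict[grid$goi == "GOI1"] == "successful"))
  expect_true(all(grid$verdict[grid$goi == "GOI2"] == "failed"))
  empty <- screenReferenceSets(gois, panel, list(), calibrator = 28)
  expect_equal(nrow(empty), 0L)
})

test_that("stress fold changes follow the two-fold rule", {
  spec <- defaultProfile(seed = 66)
  control <- generateReferencePanel(spec, "B5")
  same <- generateStressPanel(spec, shifts = numeric(), culture = "B5")
  res0 <- stressFoldChange(control, same)
  expect_equal(res0$fold, rep(1, 12), tolerance = 1e-12)
  expect_false(any(res0$flag_2x))

  shifted <- generateStressPanel(spec, shifts = c(ACTB = -1, GAPDH = 0.8),
                                 culture = "B5")
  res <- stressFoldChange(control, shifted)
  expect_equal(res$fold[res$gene == "ACTB"], 2)
  expect_true(res$flag_2x[res$gene == "ACTB"])
  expect_equal(res$fold[res$gene == "GAPDH"], 2^-0.8, tolerance = 1e-12)
  expect_false(res$flag_2x[res$gene == "GAPDH"])     # 0.574 inside (0.5, 2)
  expect_equal(res$log2_fold[res$gene == "GAPDH"], -0.8, tolerance = 1e-9)
})

test_that("normalized stress tests absorb global shifts but keep GOI shifts", {
  spec <- defaultProfile(seed = 67)
  refs <- c("GAPDH", "CCSER2", "PCBP1")
  mkCondition <- function(culture, goiShift = 0, globalShift = 0) {
    p <- generateReferencePanel(spec, culture)
    g <- generateGoi(list(baseline_cq = 24, mode = "stable", amplitude = 0.1,
                          seed = 13), p)
    obs <- rbind(cqObservations(p), cqObservations(g))
    obs$cq <- obs$cq + globalShift + ifelse(obs$gene == "GOI", goiShift, 0)
    CqSet(obs)
  }
  ctrl <- mkCondition("B5")
  ident <- mkCondition("B5")
  res <- stressGoiTest(ctrl, ident, "GOI", refs)
  expect_equal(res$fold, 1, tolerance = 1e-12)
  expect_gt(res$p, 0.9)

  # planted 2x GOI up-regulation (-1 Cq) is detected
  up <- mkCondition("B5", goiShift = -1)
  res2 <- stressGoiTest(ctrl, up, "GOI", refs)
  expect_equal(res2$fold, 2, tolerance = 1e-12)
  expect_lt(res2$p, 0.05)
  expect_true(res2$flag_2x)

  # a global shift hitting GOI and references equally is absorbed
  glob <- mkCondition("B5", globalShift = -1.5)
  res3 <- stressGoiTest(ctrl, glob, "GOI", refs)
  expect_equal(res3$fold, 1, tolerance = 1e-12)
  expect_false(res3$flag_2x)

  firstPassage <- min(cqObservations(ctrl)$passage)
  tiny <- CqSet(cqObservations(ctrl)[cqObservations(ctrl)$lysate <= 2 &
                                       cqObservations(ctrl)$passage ==
                                         firstPassage, ])
  expect_error(stressGoiTest(tiny, tiny, "GOI", refs), "3 samples")
})

test_that("Cq / log2-expression correlation matches least squares", {
  cq <- c(A = 25, B = 20, C = 15, D = 10)
  expr <- c(A = 2, B = 4.5, C = 7, D = 9.5)
  res <- correlateCqExpression(cq, expr)
  expect_equal(res$r, -1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, -2)
  expect_equal(res$intercept, 29)

  set.seed(601)
  x <- setNames(rnorm(10, 5, 1), paste0("g", 1:10))
  y <- setNames(30 - 2 * x + rnorm(10, 0, 0.5), names(x))
  res2 <- correlateCqExpression(y, x)
  fit <- lm(y ~ x)
  expect_equal(res2$slope, unname(coef(fit)[2]))
  expect_equal(res2$r, unname(cor(x, y)))
  expect_equal(res2$p, cor.test(x, y)$p.value)

  expect_error(correlateCqExpression(cq[1:2], expr[1:2]), "3 paired")
  expect_error(correlateCqExpression(cq, setNames(rep(3, 4), names(cq))),
               "variance")
})
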