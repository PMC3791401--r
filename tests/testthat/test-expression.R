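# Misregulation calling and the binding-vs-regulation statistics.

test_that("fold change and t-test follow the signed convention", {
  # identical groups: t = 0, p = 1
  r <- foldChangeTest(c(2, 4, 8), c(2, 4, 8))
  expect_equal(r$ratio, 1)
  expect_equal(r$p, 1)
  # no within-group variance at all: p = 1 by convention
  expect_equal(foldChangeTest(c(4, 4), c(4, 4))$p, 1)

  # exact doubling with tiny noise: signed fold ~ +2, small p
  set.seed(2)
  ctrl <- 2^(rnorm(4, 5, 0.01))
  up <- ctrl * 2
  r2 <- foldChangeTest(ctrl, up)
  expect_equal(r2$fold, 2, tolerance = 0.02)
  expect_lt(r2$p, 1e-4)

  # halving is reported as -2 (downregulation)
  r3 <- foldChangeTest(ctrl, ctrl / 2)
  expect_equal(r3$fold, -2, tolerance = 0.02)

  expect_error(foldChangeTest(c(1, 2), c(3)), "replicates")
  expect_error(foldChangeTest(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("t-test p matches the closed-form pooled-t oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- 2^rnorm(3, 6, 0.5)  # linear-scale replicates
    y <- 2^rnorm(3, 6.5, 0.5)
    got <- foldChangeTest(x, y)
    lx <- log2(x)
    ly <- log2(y)
    n1 <- 3; n2 <- 3
    sp2 <- ((n1 - 1) * var(lx) + (n2 - 1) * var(ly)) / (n1 + n2 - 2)
    tstat <- (mean(ly) - mean(lx)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
    expect_equal(got$p, p, tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  # monotone in rank order and bounded
  set.seed(4)
  p <- runif(50)
  f <- bhAdjust(p)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f[order(p)]) >= -1e-12))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("misregulation calls require both fold and FDR cuts", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    fold_change = c(-1.6, -1.4, 2.0, 1.8),
    fdr = c(0.05, 0.001, 0.2, 0.09))
  calls <- callMisregulated(rec)
  expect_equal(as.character(calls$direction),
               c("down", "unaffected", "unaffected", "up"))
})

test_that("Fisher overlap reports expected counts and hypergeometric tail", {
  # N=10, |A|=5, |B|=4, all of B inside A: p = C(5,4) C(5,0) / C(10,4)
  res <- fisherOverlap(letters[1:5], letters[2:5], 10)
  expect_equal(res$expected_overlap, 2)
  expect_equal(res$p_value, 5 / 210)

  # oracle: direct hypergeometric summation of the upper tail
  set.seed(8)
  uni <- sprintf("g%03d", 1:60)
  A <- sample(uni, 20)
  B <- sample(uni, 15)
  res2 <- fisherOverlap(A, B, 60)
  obs <- res2$observed_overlap
  oracle <- sum(vapply(obs:15, function(k) {
    choose(20, k) * choose(40, 15 - k) / choose(60, 15)
  }, numeric(1)))
  expect_equal(res2$p_value, oracle, tolerance = 1e-12)

  expect_equal(fisherOverlap(character(0), letters[1:3], 10)$p_value, 1)
  expect_error(fisherOverlap(letters[1:5], letters[1:3], 4), "universe")
})

test_that("Mann-Whitney exact branch matches the worked example", {
  res <- mannWhitneyBinding(c(3, 4, 5), c(1, 2))
  expect_equal(res$u_statistic, 6)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")

  # identical multisets carry no evidence of superiority
  same <- mannWhitneyBinding(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.5)
})

test_that("exact branch equals full permutation enumeration with ties", {
  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(2:6, 1)
    n2 <- sample(2:4, 1)
    # coarse values force ties
    s1 <- sample(0:3, n1, replace = TRUE)
    s2 <- sample(0:3, n2, replace = TRUE)
    got <- mannWhitneyBinding(s1, s2)
    # oracle: enumerate every assignment and count pairwise wins directly
    comb <- c(s1, s2)
    uObs <- sum(outer(s1, s2, ">")) + 0.5 * sum(outer(s1, s2, "=="))
    idx <- utils::combn(length(comb), n1)
    uAll <- apply(idx, 2, function(ii) {
      a <- comb[ii]
      b <- comb[-ii]
      sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    })
    expect_equal(got$u_statistic, uObs)
    expect_equal(got$p_value, mean(uAll >= uObs - 1e-9))
  }
})

test_that("approximate branch tracks wilcox.test without ties", {
  set.seed(3)
  s1 <- rexp(15) + 0.5
  s2 <- rexp(18)
  got <- mannWhitneyBinding(s1, s2)
  expect_equal(got$method, "normal")
  ref <- wilcox.test(s1, s2, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("zero handling drops zeros from both sets and errors when empty", {
  withZeros <- mannWhitneyBinding(c(0, 0, 5), c(0, 1))
  expect_equal(withZeros$n1, 3)
  expect_equal(withZeros$n2, 2)
  without <- mannWhitneyBinding(c(0, 0, 5), c(0, 1), includeZeros = FALSE)
  expect_equal(without$n1, 1)
  expect_equal(without$n2, 1)
  expect_error(mannWhitneyBinding(c(0, 0), c(1, 2), includeZeros = FALSE),
               "set1")
})

test_that("standard-curve quantification inverts the fitted line", {
  curve <- data.frame(log10_quantity = c(0, 1, 2),
                      ct = 20 + -3.32 * c(0, 1, 2))
  expect_equal(quantifyFromStandardCurve(16.68, curve), 10)
  expect_equal(quantifyFromStandardCurve(20, curve), 1)
  bad <- data.frame(log10_quantity = c(1, 1, 1), ct = c(20, 19, 18))
  expect_error(quantifyFromStandardCurve(15, bad), "degenerate")
  rising <- data.frame(log10_quantity = c(0, 1, 2), ct = c(10, 12, 14))
  expect_error(quantifyFromStandardCurve(12, rising), "slope")
})

test_that("ChIP enrichment ratios follow the percent-input formula", {
  expect_equal(chipEnrichment(3, 3, "vs_igg"), 1)
  # 5% input aliquot measuring 40 units: 100 * 2 / (40 / 0.05) = 0.25%
  expect_equal(chipEnrichment(2, 40, "percent_input", inputFraction = 0.05),
               0.25)
  expect_equal(chipEnrichment(7, 7, "percent_input", inputFraction = 1), 100)
  expect_error(chipEnrichment(2, 0, "vs_igg"), "control")
})

test_that("strongly shifted planted genes are called with high power", {
  # a 5-noise-sd knockdown shift should be all but unmissable
  cfg <- SimConfig(seed = 42, nGenes = 120L, nScaffolds = 3L,
                   scaffoldLength = 400000L, targetFraction = 0.5,
                   deEffectSize = 2.5, nReplicates = 4L)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  expr <- simulateExpression(sim$genes, plantedPromoterScores(pk, sim$genes),
                             cfg)
  rec <- callMisregulated(expressionRecords(expr))
  planted <- expr$gene_id[expr$truth == "down"]
  called <- rec$gene_id[rec$direction == "down"]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.9)
})

test_that("planted binding-to-downregulation linkage is detected", {
  # default (study-condition) effect size and replication
  cfg <- SimConfig(seed = 42, nGenes = 120L, nScaffolds = 3L,
                   scaffoldLength = 400000L, targetFraction = 0.5,
                   nBackgroundPeaks = 60L)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  expr <- simulateExpression(sim$genes, plantedPromoterScores(pk, sim$genes),
                             cfg)
  rec <- callMisregulated(expressionRecords(expr))
  called <- rec$gene_id[rec$direction == "down"]
  unaff <- rec$gene_id[rec$direction == "unaffected"]
  expect_gte(length(called), 5)

  # called-down genes show higher proximal occupancy than unaffected ones
  a <- assignNearestGene(pk, sim$genes)
  occ <- binOccupancy(a, sim$genes)
  prox <- windowSum(occ, "proximal", "up") + windowSum(occ, "proximal", "down")
  mw <- mannWhitneyBinding(prox[called], prox[unaff])
  expect_lt(mw$p_value, 0.05)
})
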