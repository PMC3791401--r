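# Nearest-gene assignment, region classification, binned occupancy,
# windowed sums, distance histograms and the heat-map transform.

test_that("TSS and TES follow the strand convention", {
  gs <- makeGenes("s1", c(101, 101), c(500, 500), c("+", "-"))
  expect_equal(unname(tssOf(gs)), c(101L, 500L))
  expect_equal(unname(tesOf(gs)), c(500L, 101L))
  # single-bp-exon degenerate gene still has its TSS inside the body
  tiny <- makeGenes("s1", 1000, 1001, "+")
  expect_true(tssOf(tiny) >= 1000 && tssOf(tiny) <= 1001)
})

test_that("nearest-gene assignment picks minimal summit-to-TSS distance", {
  gs <- makeGenes("s1", c(900, 1200), c(1100, 1500), "+",
                  gene_id = c("gA", "gB"))
  pk <- makePeaks("s1", 1000L)
  a <- assignNearestGene(pk, gs)
  expect_equal(S4Vectors::mcols(a)$gene_id, "gA")
  # 100 bp downstream of gA's TSS on a + gene
  expect_equal(S4Vectors::mcols(a)$signed_distance, 100L)

  # summit exactly at a TSS
  a0 <- assignNearestGene(makePeaks("s1", 1200L), gs)
  expect_equal(S4Vectors::mcols(a0)$gene_id, "gB")
  expect_equal(S4Vectors::mcols(a0)$signed_distance, 0L)
})

test_that("equidistant TSSs resolve to the lexicographically smaller gene id", {
  gs <- makeGenes("s1", c(950, 1050), c(1000, 1500), "+",
                  gene_id = c("gZ", "gA"))
  a <- assignNearestGene(makePeaks("s1", 1000L), gs)
  expect_equal(S4Vectors::mcols(a)$gene_id, "gA")
})

test_that("peaks on gene-free scaffolds stay unassigned", {
  gs <- makeGenes("s1", 900, 1100, "+")
  pk <- makePeaks(c("s1", "s2"), c(1000L, 1000L))
  a <- assignNearestGene(pk, gs)
  expect_equal(is.na(S4Vectors::mcols(a)$gene_id), c(FALSE, TRUE))
})

test_that("assignment agrees with the all-pairs brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    nG <- sample(5:50, 1)
    nP <- sample(50:200, 1)
    scafG <- sample(c("s1", "s2", "s3"), nG, replace = TRUE)
    start <- sample(1000:200000, nG)
    gs <- GeneModelSet(GenomicRanges::GRanges(
      scafG, IRanges::IRanges(start, start + sample(500:5000, nG, TRUE)),
      strand = sample(c("+", "-"), nG, TRUE),
      gene_id = sprintf("g%03d", sample(nG)),
      symbol = "s"))
    pk <- makePeaks(sample(c("s1", "s2", "s3"), nP, replace = TRUE),
                    sample(1:210000, nP))
    got <- S4Vectors::mcols(assignNearestGene(pk, gs))$gene_id
    expect_identical(got, bruteNearestGene(pk, gs))
  }
})

test_that("region classification bands by distance from the body edge", {
  gs <- makeGenes("s1", 10000, 20000, "+", gene_id = "gA")
  summits <- c(9500L,   # 500 bp upstream of the body
               8500L,   # 1.5 kb upstream
               3000L,   # 7 kb upstream
               26000L,  # 6 kb downstream
               15000L,  # inside the body
               20500L)  # 500 bp downstream
  a <- classifyRegions(assignNearestGene(makePeaks("s1", summits), gs), gs)
  expect_equal(as.character(S4Vectors::mcols(a)$region_class),
               c("proximal_up", "intermediate_up", "distal_up",
                 "distal_down", "gene_body", "proximal_down"))
  # no exon annotation: gene-body summits are introns by subtraction
  expect_equal(as.character(S4Vectors::mcols(a)$subclass[5]), "intron")

  # same positions on a minus-strand gene flip orientation
  gsm <- makeGenes("s1", 10000, 20000, "-", gene_id = "gA")
  am <- classifyRegions(assignNearestGene(makePeaks("s1", summits), gsm), gsm)
  expect_equal(as.character(S4Vectors::mcols(am)$region_class),
               c("proximal_down", "intermediate_down", "distal_down",
                 "distal_up", "gene_body", "proximal_up"))
})

test_that("gene-body subclasses honour UTR-over-exon precedence", {
  body <- GenomicRanges::GRanges("s1", IRanges::IRanges(1000, 5000),
                                 strand = "+", gene_id = "gA", symbol = "gA")
  exons <- GenomicRanges::GRangesList(gA = GenomicRanges::GRanges(
    "s1", IRanges::IRanges(c(1000, 3000), c(1500, 3500)), strand = "+"))
  utr5 <- GenomicRanges::GRangesList(gA = GenomicRanges::GRanges(
    "s1", IRanges::IRanges(1000, 1100), strand = "+"))
  gs <- GeneModelSet(body, exons = exons, utr5 = utr5)
  summits <- c(1050L,  # in utr5 (inside exon 1 too)
               1300L,  # exon
               2000L,  # intron
               3200L)  # exon
  a <- classifyRegions(assignNearestGene(makePeaks("s1", summits), gs), gs)
  expect_equal(as.character(S4Vectors::mcols(a)$subclass),
               c("utr5", "exon", "intron", "exon"))
})

test_that("region counts partition the assigned peaks", {
  cfg <- SimConfig(seed = 7, nGenes = 60L, nScaffolds = 2L,
                   scaffoldLength = 400000L, nBackgroundPeaks = 80L)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  a <- classifyRegions(assignNearestGene(pk, sim$genes), sim$genes)
  dist <- regionDistribution(a)
  expect_equal(sum(dist$region), dist$n_assigned)
  expect_equal(dist$n_assigned + dist$n_unassigned, length(pk))
  # gene-body count decomposes into its subclasses (subtraction rule)
  expect_equal(sum(dist$subclass), unname(dist$region["gene_body"]))
  # empty input gives all-zero counts
  empty <- regionDistribution(a[0])
  expect_equal(sum(empty$region), 0L)
})

test_that("occupancy binning conserves scores and routes overflow", {
  gs <- makeGenes("s1", 50000, 60000, "+", gene_id = "gA")
  pk <- makePeaks("s1",
                  c(49999L,  # signed -1: upstream bin adjacent to the TSS
                    38000L,  # signed -12000: upstream overflow
                    50100L, 50300L),  # same downstream bin
                  score = c(30, 7, 10, 20))
  a <- assignNearestGene(pk, gs)
  occ <- binOccupancy(a, gs)
  bins <- occupancyBins(occ)
  expect_equal(unname(bins["gA", "bin_-400"]), 30)
  expect_equal(unname(bins["gA", "overflow_up"]), 7)
  expect_equal(unname(bins["gA", "bin_0"]), 30)  # 10 + 20 additive
  expect_equal(unname(occupancyTotals(occ)["gA"]), 67)
  expect_equal(unname(occupancyTotals(occ)["gA"]), sum(bins["gA", ]))
})

test_that("window sums come from raw distances, not re-summed bins", {
  gs <- makeGenes("s1", 50000, 60000, "+", gene_id = "gA")
  pk <- makePeaks("s1", c(49200L, 47000L), score = c(12, 5))
  a <- assignNearestGene(pk, gs)  # signed distances -800 and -3000
  occ <- binOccupancy(a, gs)
  expect_equal(unname(windowSum(occ, "proximal", "up")["gA"]), 12)
  expect_equal(unname(windowSum(occ, "intermediate", "up")["gA"]), 5)
  expect_equal(unname(windowSum(occ, "proximal", "down")["gA"]), 0)
  expect_error(windowSum(occ, "promoter", "up"))
})

test_that("binning conservation holds on simulated data", {
  cfg <- SimConfig(seed = 21, nGenes = 80L, nScaffolds = 2L,
                   scaffoldLength = 500000L)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  a <- assignNearestGene(pk, sim$genes)
  occ <- binOccupancy(a, sim$genes)
  assignedScores <- S4Vectors::mcols(a)$score[!is.na(S4Vectors::mcols(a)$gene_id)]
  expect_equal(sum(occupancyTotals(occ)), sum(assignedScores))
  expect_true(all(occupancyBins(occ) >= 0))
})

test_that("TSS-planted peaks make the TSS-adjacent bins modal", {
  cfg <- SimConfig(seed = 5, nGenes = 150L, nScaffolds = 3L,
                   scaffoldLength = 500000L, targetFraction = 1,
                   tssPeakSd = 100, nBackgroundPeaks = 0L)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  a <- assignNearestGene(pk, sim$genes)
  occ <- binOccupancy(a, sim$genes)
  colTotals <- colSums(occupancyBins(occ))
  modal <- names(which.max(colTotals))
  expect_true(modal %in% c("bin_-400", "bin_0"))
})

test_that("distance histograms count all assignments exactly once", {
  gs <- makeGenes("s1", 50000, 60000, "+", gene_id = "gA")
  pk <- makePeaks("s1", rep(50000L, 5))
  a <- assignNearestGene(pk, gs)
  h <- distanceHistogram(a, gs)
  expect_equal(sum(h$counts), 5)
  expect_equal(h$counts[h$mids == 100], 5)  # distance 0 in bin [0, 200)
  expect_equal(h$n_out_of_range, 0)

  far <- assignNearestGene(makePeaks("s1", 95000L), gs)
  hf <- distanceHistogram(far, gs)
  expect_equal(sum(hf$counts), 0)
  expect_equal(hf$n_out_of_range, 1)

  # TES anchor: a summit at the gene end has TES-distance 0
  hTes <- distanceHistogram(assignNearestGene(makePeaks("s1", 60000L), gs),
                            gs, anchor = "tes")
  expect_equal(hTes$counts[hTes$mids == 100], 1)
})

test_that("heat-map transform is ln(score + 1)", {
  expect_equal(heatmapValue(0), 0)
  expect_equal(heatmapValue(exp(1) - 1), 1)
  expect_equal(heatmapValue(30), log(31))
  expect_error(heatmapValue(-1), ">= 0")
})
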