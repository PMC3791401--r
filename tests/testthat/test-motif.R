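# PWM construction, both-strand scanning, score scaling, coverage and
# positional statistics.

test_that("PWM construction from counts follows the log-odds formula", {
  # uniform counts: every weight 0, every window scores 0
  uni <- buildPWM(matrix(5, nrow = 4, ncol = 4), pseudocount = 0.01)
  expect_true(all(abs(pwmWeights(uni)) < 1e-12))
  hits <- scanPWM(uni, "ACGTACGT", threshold = 0)
  expect_true(all(hits$raw_score == 0))

  # a near-one-hot matrix is maximised by its consensus
  pwm <- consensusPWM("TTTCACACC")
  best <- scanPWM(pwm, "TTTCACACC", threshold = 0)
  expect_equal(max(best$raw_score), pwmMaxScore(pwm))

  # hand-computed toy: 2 positions, counts (3,1,0,0) and (0,0,1,1)
  counts <- rbind(c(3, 1, 0, 0), c(0, 0, 1, 1))
  pc <- 0.5
  pwm2 <- buildPWM(counts, pseudocount = pc)
  wAC <- log10(((3 + pc) / (4 + 4 * pc)) / 0.25) +
    log10(((0 + pc) / (2 + 4 * pc)) / 0.25)
  got <- scanPWM(pwm2, "AC", threshold = -Inf)
  expect_equal(got$raw_score[got$strand == "+"], wAC)

  expect_error(buildPWM(rbind(c(0, 0, 0, 0), c(1, 1, 1, 1))), "all-zero")
})

test_that("scanning equals the brute-force window-enumeration oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    pwm <- randomPWM(sample(4:10, 1))
    seqs <- randomDNA(sample(200:2000, 1))
    all <- bruteScan(pwmWeights(pwm), seqs, -Inf)
    thr <- unname(quantile(all$raw_score, 0.9))
    got <- scanPWM(pwm, seqs, threshold = thr)
    want <- bruteScan(pwmWeights(pwm), seqs, thr)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$raw_score, want$raw_score, tolerance = 1e-12)
  }
})

test_that("the SPR oligo contains exactly one v1-core match", {
  oligo <- "AAAAAAAATTTCACACCTTA"
  pwm <- consensusPWM("TTTCACACC")
  hits <- scanPWM(pwm, oligo, threshold = 3)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 9L)  # 0-based window start 8

  # strand symmetry: the reverse complement carries the same single hit
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(oligo)))
  rcHits <- scanPWM(pwm, rc, threshold = 3)
  expect_equal(nrow(rcHits), 1L)
  expect_equal(rcHits$strand, "-")
  expect_equal(rcHits$raw_score, hits$raw_score)

  # a threshold above the matrix maximum yields nothing
  expect_equal(nrow(scanPWM(pwm, oligo, threshold = pwmMaxScore(pwm) + 1)), 0L)
  # sequences shorter than the motif yield nothing
  expect_equal(nrow(scanPWM(pwm, "ACGT")), 0L)
})

test_that("masked bases (N) can never produce a hit", {
  pwm <- consensusPWM("TTTCACACC")  # length 9
  # N at position 13: every window whose span covers it scores -Inf
  hitsN <- scanPWM(pwm, "AAAAAAAATTTCNCACCTTA", threshold = -100)
  expect_false(any(hitsN$start %in% 5:13))
  masked <- scanPWM(pwm, "NNNNNNNNNNNN", threshold = -1e6)
  expect_equal(nrow(masked), 0L)
})

test_that("BED score scaling is the clamped linear 1.5-5 -> 0-1000 map", {
  expect_equal(bedScore(1.5), 0L)
  expect_equal(bedScore(5), 1000L)
  expect_equal(bedScore(0), 0L)     # below range clamps to 0
  expect_equal(bedScore(9), 1000L)  # above range clamps to 1000
  expect_equal(bedScore(3.25), 500L)
  s <- seq(1, 6, by = 0.1)
  expect_true(all(diff(bedScore(s)) >= 0))  # monotone
})

test_that("summit flanks are centred, truncated and trackable", {
  seqs <- Biostrings::DNAStringSet(c(s1 = randomDNA(1000)))
  pk <- makePeaks("s1", c(501L, 51L), halfw = 20L)
  fl <- extractSummitFlanks(pk, seqs, width = 200)
  fm <- S4Vectors::mcols(fl)
  # 0-based summit 500, width 200 -> window [400, 600) = 1-based 401..600
  expect_equal(fm$flank_start[1], 401L)
  expect_equal(Biostrings::width(fl)[1], 200L)
  expect_false(fm$truncated[1])
  # near the scaffold edge the window truncates and is flagged
  expect_equal(fm$flank_start[2], 1L)
  expect_equal(Biostrings::width(fl)[2], 150L)
  expect_true(fm$truncated[2])
  # round-trip bookkeeping: flank offset + flank start = genomic position
  expect_equal(as.character(Biostrings::subseq(seqs[["s1"]], 451, 460)),
               as.character(Biostrings::subseq(fl[[1]], 451 - fm$flank_start[1] + 1,
                                               460 - fm$flank_start[1] + 1)))
})

test_that("planted motifs are recovered with full coverage at plant_prob 1", {
  cfg <- SimConfig(seed = 9, nGenes = 60L, nScaffolds = 2L,
                   scaffoldLength = 300000L, targetFraction = 1,
                   nBackgroundPeaks = 40L, motifPlantProb = 1)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  planted <- suppressWarnings(plantMotifs(sim$sequences, pk, "TTTCACACC", cfg))
  # overlap-protected planting may skip a handful of crowded peaks
  expect_gte(nrow(planted$truth), length(pk) - 10L)
  pwm <- consensusPWM("TTTCACACC")
  hits <- scanPeakFlanks(pwm, pk, planted$sequences, width = 400,
                         threshold = 5)
  # every peak that received an instance is covered ...
  covered <- unique(hits$peak_id[abs(hits$offset_from_summit) <= 100])
  expect_true(all(planted$truth$peak_id %in% covered))
  # ... and every planted instance is found at its position and strand
  key <- paste(hits$scaffold, hits$start, hits$strand)
  truthKey <- paste(planted$truth$scaffold, planted$truth$start,
                    planted$truth$strand)
  expect_true(all(truthKey %in% key))
})

test_that("coverage estimates the planting probability", {
  cfg <- SimConfig(seed = 13, nGenes = 350L, nScaffolds = 5L,
                   scaffoldLength = 900000L, targetFraction = 1,
                   nBackgroundPeaks = 650L, motifPlantProb = 0.8)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(sim$genes, cfg)
  expect_gte(length(pk), 1000)
  planted <- suppressWarnings(plantMotifs(sim$sequences, pk, "TTTCACACC", cfg))
  pwm <- consensusPWM("TTTCACACC")
  hits <- scanPeakFlanks(pwm, pk, planted$sequences, width = 400,
                         threshold = 5)
  cov <- motifCoverage(pk, hits, window = 100)
  # binomial 99% CI around 0.8 at n >= 1000 is about +/- 0.033, plus a
  # small surplus from chance background matches
  expect_gt(cov, 0.8 - 0.04)
  expect_lt(cov, 0.8 + 0.06)
  # plant_prob 0 leaves an empty truth list
  cfg0 <- SimConfig(seed = 13, motifPlantProb = 0)
  p0 <- plantMotifs(sim$sequences, pk, "TTTCACACC", cfg0)
  expect_equal(nrow(p0$truth), 0L)
})

test_that("positional histograms localise hits around summits", {
  hits <- data.frame(offset_from_summit = rep(0L, 10))
  h <- motifPositionHistogram(hits)
  expect_equal(sum(h$counts), 10)
  expect_equal(h$counts[h$mids == 10], 10)  # central bin [0, 20)

  unif <- data.frame(offset_from_summit = seq(-100L, 99L))
  hu <- motifPositionHistogram(unif, binwidth = 20)
  inside <- hu$mids > -100 & hu$mids < 100
  expect_true(all(hu$counts[inside] == 20))
  expect_true(all(hu$counts[!inside] == 0))

  expect_equal(sum(motifPositionHistogram(
    data.frame(offset_from_summit = integer(0)))$counts), 0)
})
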