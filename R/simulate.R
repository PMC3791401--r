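# Synthetic-data generators.  Every generator is deterministic for a fixed
# SimConfig seed and draws from its own substream (see subSeed()), so a
# pipeline's fixtures do not change when an unrelated generator is added.
# Each generator returns its planted truth alongside the data, so
# downstream modules can be checked for parameter recovery.

#' Simulate a genome: gene models and scaffold sequences
#'
#' Tiles `nGenes` genes across `nScaffolds` scaffolds of
#' `scaffoldLength` bp with exponential intergenic gaps, uniform gene
#' lengths, random strands and 1-8 exons per gene (the first and last exon
#' anchored at the body edges, short UTRs at the TSS/TES ends).  Scaffold
#' sequence is i.i.d. uniform over A/C/G/T.
#'
#' @param cfg a [SimConfig-class].
#' @return A list with `genes` (a [GeneModelSet-class]) and `sequences`
#'   (a named `DNAStringSet` with one element per scaffold).
#' @export
simulateGenome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withSubstream(cfg@seed, 1L, {
    scafNames <- sprintf("scaffold_%d", seq_len(cfg@nScaffolds))
    perScaffold <- rep(cfg@nGenes %/% cfg@nScaffolds, cfg@nScaffolds)
    extra <- cfg@nGenes %% cfg@nScaffolds
    if (extra > 0) perScaffold[seq_len(extra)] <- perScaffold[seq_len(extra)] + 1L

    rows <- list()
    exons <- list()
    u5 <- list()
    u3 <- list()
    geneNum <- 0L
    for (s in seq_len(cfg@nScaffolds)) {
      pos <- 1L
      for (k in seq_len(perScaffold[s])) {
        geneNum <- geneNum + 1L
        gap <- as.integer(round(rexp(1, 1 / cfg@intergenicMean))) + 200L
        len <- sample(cfg@geneLengthRange[1]:cfg@geneLengthRange[2], 1L)
        start <- pos + gap
        end <- start + len - 1L
        if (end > cfg@scaffoldLength - 200L) {
          stop(sprintf(
            "requested genes do not fit: scaffold %d full after %d gene(s)",
            s, k - 1L), call. = FALSE)
        }
        strand <- sample(c("+", "-"), 1L)
        id <- sprintf("gene%05d", geneNum)
        rows[[geneNum]] <- data.frame(
          scaffold = scafNames[s], start = start, end = end,
          strand = strand, gene_id = id)
        # exon structure: split the body into nEx blocks, one exon per
        # block; first exon starts at the body start, last ends at the end
        nEx <- sample(1:8, 1L)
        edges <- unique(as.integer(round(seq(start, end + 1L,
                                             length.out = nEx + 1L))))
        nEx <- length(edges) - 1L
        exStart <- integer(nEx)
        exEnd <- integer(nEx)
        for (e in seq_len(nEx)) {
          lo <- edges[e]
          hi <- edges[e + 1L] - 1L
          blockLen <- hi - lo + 1L
          w <- max(1L, as.integer(round(runif(1, 0.2, 0.8) * blockLen)))
          if (e == 1L) {
            exStart[e] <- lo
            exEnd[e] <- min(hi, lo + w - 1L)
          } else if (e == nEx) {
            exEnd[e] <- hi
            exStart[e] <- max(lo, hi - w + 1L)
          } else {
            off <- if (blockLen > w) sample.int(blockLen - w + 1L, 1L) - 1L else 0L
            exStart[e] <- lo + off
            exEnd[e] <- min(hi, exStart[e] + w - 1L)
          }
        }
        exons[[id]] <- GenomicRanges::GRanges(
          scafNames[s], IRanges::IRanges(exStart, exEnd), strand = strand)
        # UTRs: up to 100 bp of the TSS-side and TES-side terminal exons
        firstLen <- min(100L, exEnd[1L] - exStart[1L] + 1L)
        lastLen <- min(100L, exEnd[nEx] - exStart[nEx] + 1L)
        startSide <- GenomicRanges::GRanges(
          scafNames[s],
          IRanges::IRanges(exStart[1L], exStart[1L] + firstLen - 1L),
          strand = strand)
        endSide <- GenomicRanges::GRanges(
          scafNames[s],
          IRanges::IRanges(exEnd[nEx] - lastLen + 1L, exEnd[nEx]),
          strand = strand)
        if (strand == "+") {
          u5[[id]] <- startSide
          u3[[id]] <- endSide
        } else {
          u5[[id]] <- endSide
          u3[[id]] <- startSide
        }
        pos <- end + 1L
      }
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      genesGr <- GenomicRanges::GRanges(
        seqnames = factor(df$scaffold, levels = scafNames),
        ranges = IRanges::IRanges(df$start, df$end),
        strand = df$strand,
        gene_id = df$gene_id,
        symbol = paste0("sym_", df$gene_id))
    } else {
      genesGr <- GenomicRanges::GRanges(gene_id = character(0),
                                        symbol = character(0))
      GenomeInfoDb::seqlevels(genesGr) <- scafNames
    }
    GenomeInfoDb::seqlengths(genesGr) <-
      setNames(rep(cfg@scaffoldLength, cfg@nScaffolds), scafNames)
    sequences <- Biostrings::DNAStringSet(vapply(scafNames, function(nm) {
      paste(sample(c("A", "C", "G", "T"), cfg@scaffoldLength,
                   replace = TRUE), collapse = "")
    }, character(1)))
    names(sequences) <- scafNames
    list(genes = GeneModelSet(
           genesGr,
           exons = GenomicRanges::GRangesList(exons),
           utr5 = GenomicRanges::GRangesList(u5),
           utr3 = GenomicRanges::GRangesList(u3)),
         sequences = sequences)
  })
}

# Draw -log10(p) scores from the long-tailed shifted-exponential model.
drawScores <- function(n, cfg) {
  cfg@scoreMin + rexp(n, 1 / (cfg@scoreMean - cfg@scoreMin))
}

#' Simulate a ChIP-seq peak track with TSS-planted structure
#'
#' A `targetFraction` of genes receives one planted peak whose summit is
#' Normal(TSS, `tssPeakSd`); `nBackgroundPeaks` further peaks are placed
#' uniformly across the scaffolds.  Scores are drawn from the long-tailed
#' shifted-exponential -log10(p) model, giving the characteristic
#' many-genes-bound-at-low-level score distribution.  The planted
#' assignment is recorded in the metadata for truth checking.
#'
#' @param genes a [GeneModelSet-class] (from [simulateGenome()]).
#' @param cfg a [SimConfig-class].
#' @param label track label (factor name and stage).
#' @return A `GRanges` with metadata `summit`, `score`, `label`, `planted`
#'   (logical) and `planted_gene` (gene id or `NA`).
#' @export
simulatePeaks <- function(genes, cfg, label = "TF_stage12") {
  stopifnot(is(cfg, "SimConfig"))
  g <- geneBodies(genes)
  if (!length(g)) stop("gene set is empty", call. = FALSE)
  withSubstream(cfg@seed, 2L, {
    ids <- geneIds(genes)
    tss <- tssOf(genes)
    gsc <- as.character(GenomicRanges::seqnames(g))
    slen <- GenomeInfoDb::seqlengths(g)
    nTarget <- round(cfg@targetFraction * length(ids))
    targetIdx <- if (nTarget > 0) sort(sample(length(ids), nTarget)) else integer(0)

    mkPeaks <- function(scaffold, summit, planted, plantedGene) {
      n <- length(summit)
      if (!n) return(NULL)
      halfw <- sample(100:200, n, replace = TRUE)
      start <- pmax(summit - halfw, 1L)
      end <- pmin(summit + halfw, slen[scaffold])
      data.frame(scaffold = scaffold, start = start, end = end,
                 summit = summit, score = drawScores(n, cfg),
                 planted = planted, planted_gene = plantedGene,
                 stringsAsFactors = FALSE)
    }

    planted <- NULL
    if (length(targetIdx)) {
      summit <- as.integer(round(rnorm(length(targetIdx),
                                       mean = tss[targetIdx],
                                       sd = cfg@tssPeakSd)))
      summit <- pmax(1L, pmin(summit, slen[gsc[targetIdx]] - 1L))
      planted <- mkPeaks(gsc[targetIdx], summit, TRUE, ids[targetIdx])
    }
    background <- NULL
    if (cfg@nBackgroundPeaks > 0) {
      bsc <- sample(names(slen), cfg@nBackgroundPeaks, replace = TRUE)
      bsum <- as.integer(floor(runif(cfg@nBackgroundPeaks, 1,
                                     slen[bsc] + 1)))
      background <- mkPeaks(bsc, bsum, FALSE, NA_character_)
    }
    df <- rbind(planted, background)
    gr <- GenomicRanges::GRanges(
      seqnames = factor(df$scaffold, levels = names(slen)),
      ranges = IRanges::IRanges(df$start, df$end),
      summit = as.integer(df$summit),
      score = df$score,
      label = label,
      planted = df$planted,
      planted_gene = df$planted_gene)
    GenomeInfoDb::seqlengths(gr) <- slen
    sort(gr)
  })
}

#' Simulate a cofactor peak track sharing sites with a primary track
#'
#' A `cofactorSharedFraction` of the primary peaks is duplicated with
#' summit jitter Normal(0, `cofactorJitterSd`) and independently resampled
#' scores; the remaining fraction of the track is placed uniformly.  The
#' provenance of every cofactor peak (`source_peak`: index into the
#' primary track, or `NA` for background) is the truth table for
#' co-localisation recovery.
#'
#' @param peaks primary `GRanges` peak track (with seqlengths).
#' @param cfg a [SimConfig-class].
#' @param label track label for the cofactor.
#' @return A `GRanges` like `peaks` with metadata `summit`, `score`,
#'   `label`, `source_peak`.
#' @export
simulateCofactorTrack <- function(peaks, cfg, label = "cofactor_stage12") {
  assertPeaks(peaks)
  if (!length(peaks)) stop("primary track is empty", call. = FALSE)
  withSubstream(cfg@seed, 3L, {
    slen <- GenomeInfoDb::seqlengths(peaks)
    if (any(is.na(slen))) {
      stop("peaks must carry seqlengths for background placement",
           call. = FALSE)
    }
    n <- length(peaks)
    nShared <- round(cfg@cofactorSharedFraction * n)
    sharedIdx <- if (nShared > 0) sort(sample(n, nShared)) else integer(0)
    psc <- as.character(GenomicRanges::seqnames(peaks))
    summit <- S4Vectors::mcols(peaks)$summit

    shared <- NULL
    if (length(sharedIdx)) {
      jit <- as.integer(round(rnorm(length(sharedIdx), 0,
                                    cfg@cofactorJitterSd)))
      s <- pmax(1L, pmin(summit[sharedIdx] + jit,
                         slen[psc[sharedIdx]] - 1L))
      shared <- data.frame(scaffold = psc[sharedIdx], summit = s,
                           source_peak = sharedIdx)
    }
    nBg <- n - nShared
    bg <- NULL
    if (nBg > 0) {
      bsc <- sample(names(slen), nBg, replace = TRUE)
      bg <- data.frame(scaffold = bsc,
                       summit = as.integer(floor(runif(nBg, 1,
                                                       slen[bsc] + 1))),
                       source_peak = NA_integer_)
    }
    df <- rbind(shared, bg)
    halfw <- sample(100:200, nrow(df), replace = TRUE)
    gr <- GenomicRanges::GRanges(
      seqnames = factor(df$scaffold, levels = names(slen)),
      ranges = IRanges::IRanges(pmax(df$summit - halfw, 1L),
                                pmin(df$summit + halfw, slen[df$scaffold])),
      summit = as.integer(df$summit),
      score = drawScores(nrow(df), cfg),
      label = label,
      source_peak = df$source_peak)
    GenomeInfoDb::seqlengths(gr) <- slen
    sort(gr)
  })
}

#' Plant motif instances into scaffold sequence near peak summits
#'
#' With probability `motifPlantProb` per peak, writes the consensus (or
#' its reverse complement, with probability 1/2) at a position uniform
#' within +/-100 bp of the summit.  Instances that would overrun the
#' scaffold are skipped with a warning.  Returns the mutated sequences and
#' the truth list of planted positions.
#'
#' @param sequences named `DNAStringSet` of scaffold sequences.
#' @param peaks `GRanges` peak track.
#' @param consensus character motif consensus (A/C/G/T only).
#' @param cfg a [SimConfig-class].
#' @param maxOffset maximal |planting offset| from the summit (default 100).
#' @return A list with `sequences` (mutated `DNAStringSet`) and `truth`
#'   (`data.frame` with `peak_id`, `scaffold`, `start`, `strand`).
#' @export
plantMotifs <- function(sequences, peaks, consensus, cfg,
                        maxOffset = 100L) {
  assertPeaks(peaks)
  stopifnot(is(cfg, "SimConfig"))
  consensus <- toupper(consensus)
  if (!grepl("^[ACGT]+$", consensus)) {
    stop("consensus must contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(consensus)
  if (any(L >= Biostrings::width(sequences))) {
    stop("consensus is not shorter than every scaffold", call. = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  withSubstream(cfg@seed, 4L, {
    chars <- as.character(sequences)
    psc <- as.character(GenomicRanges::seqnames(peaks))
    summit <- S4Vectors::mcols(peaks)$summit
    plant <- runif(length(peaks)) < cfg@motifPlantProb
    offs <- sample(seq(-maxOffset, maxOffset), length(peaks),
                   replace = TRUE)
    minus <- runif(length(peaks)) < 0.5
    truth <- list()
    nSkipped <- 0L
    # previously planted spans per scaffold; a planting that would
    # overwrite an earlier instance is skipped so truth stays intact
    occupied <- lapply(setNames(nm = names(sequences)),
                       function(nm) matrix(integer(0), ncol = 2))
    for (i in which(plant)) {
      start <- summit[i] + offs[i]
      end <- start + L - 1L
      if (start < 1L || end > nchar(chars[[psc[i]]])) {
        nSkipped <- nSkipped + 1L
        next
      }
      occ <- occupied[[psc[i]]]
      if (nrow(occ) && any(start <= occ[, 2] & end >= occ[, 1])) {
        nSkipped <- nSkipped + 1L
        next
      }
      occupied[[psc[i]]] <- rbind(occ, c(start, end))
      substr(chars[[psc[i]]], start, end) <-
        if (minus[i]) rc else consensus
      truth[[length(truth) + 1L]] <- data.frame(
        peak_id = i, scaffold = psc[i], start = start,
        strand = if (minus[i]) "-" else "+")
    }
    if (nSkipped > 0L) {
      warning(nSkipped, " motif instance(s) skipped (scaffold edge or ",
              "overlap with an earlier planting)")
    }
    mutated <- Biostrings::DNAStringSet(unlist(chars))
    names(mutated) <- names(sequences)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(peak_id = integer(0), scaffold = character(0),
                 start = integer(0), strand = character(0))
    list(sequences = mutated, truth = truth)
  })
}

#' Per-gene promoter-proximal planted binding scores
#'
#' Sums the scores of planted peaks per planted gene, the truth signal
#' that [simulateExpression()] couples to downregulation.
#'
#' @param peaks output of [simulatePeaks()].
#' @param genes the [GeneModelSet-class] the peaks were planted on.
#' @return Named numeric vector over all genes (0 where nothing planted).
#' @export
plantedPromoterScores <- function(peaks, genes) {
  mc <- S4Vectors::mcols(peaks)
  if (is.null(mc$planted_gene)) {
    stop("peaks carry no planted truth", call. = FALSE)
  }
  out <- setNames(numeric(length(geneIds(genes))), geneIds(genes))
  keep <- !is.na(mc$planted_gene)
  if (any(keep)) {
    s <- tapply(mc$score[keep], mc$planted_gene[keep], sum)
    out[names(s)] <- as.numeric(s)
  }
  out
}

#' Simulate replicate expression with a planted binding-to-downregulation link
#'
#' Control replicates are Normal(mu_g, `deNoiseSd`) on the log2 scale
#' (mu_g ~ Normal(8, 1)); knockdown replicates are shifted by
#' `-deEffectSize` for genes whose promoter-proximal planted binding is at
#' or above the `boundQuantile` quantile of the positive planted scores,
#' and unshifted otherwise.  This plants the relationship in which genes
#' downregulated upon knockdown carry higher promoter-proximal occupancy
#' than unaffected genes.  Values are returned on the linear scale
#' (2^log2), ready for [foldChangeTest()].
#'
#' @param genes a [GeneModelSet-class].
#' @param promoterScores named per-gene planted binding scores (see
#'   [plantedPromoterScores()]).
#' @param cfg a [SimConfig-class].
#' @param boundQuantile quantile of positive planted scores above which a
#'   gene is treated as functionally bound (default 0.5).
#' @return A `data.frame` with `gene_id`, `truth` (factor down/up/
#'   unaffected), `ctrl_1..k` and `kd_1..k` linear-scale replicate values.
#' @export
simulateExpression <- function(genes, promoterScores, cfg,
                               boundQuantile = 0.5) {
  stopifnot(is(cfg, "SimConfig"))
  ids <- geneIds(genes)
  if (!all(ids %in% names(promoterScores))) {
    stop("promoterScores must cover every gene", call. = FALSE)
  }
  withSubstream(cfg@seed, 5L, {
    sc <- promoterScores[ids]
    pos <- sc[sc > 0]
    bound <- if (length(pos)) {
      sc >= quantile(pos, boundQuantile)
    } else {
      rep(FALSE, length(sc))
    }
    n <- length(ids)
    k <- cfg@nReplicates
    mu <- rnorm(n, 8, 1)
    ctrl <- matrix(rnorm(n * k, mu, cfg@deNoiseSd), nrow = n)
    kd <- matrix(rnorm(n * k, mu - cfg@deEffectSize * bound,
                       cfg@deNoiseSd), nrow = n)
    out <- data.frame(
      gene_id = ids,
      truth = factor(ifelse(bound, "down", "unaffected"),
                     levels = c("down", "up", "unaffected")))
    for (j in seq_len(k)) out[[paste0("ctrl_", j)]] <- 2^ctrl[, j]
    for (j in seq_len(k)) out[[paste0("kd_", j)]] <- 2^kd[, j]
    out
  })
}

#' Simulate a noisy 1:1 binding-isotherm curve
#'
#' `response_i = rmax c_i / (kd + c_i) + Normal(0, noiseSd)`.
#'
#' @param kd dissociation constant (molar).
#' @param rmax saturating response.
#' @param concentrations molar concentrations (positive; for well-posed
#'   fits they should span at least `[kd/10, 10 kd]`).
#' @param noiseSd response noise SD.
#' @param seed integer seed.
#' @return A `data.frame` with `concentration_molar` and `response`.
#' @export
simulateBindingCurve <- function(kd, rmax,
                                 concentrations =
                                   10^seq(log10(3e-9), log10(3.8e-6),
                                          length.out = 8),
                                 noiseSd = 0, seed = 1L) {
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (kd <= 0 || rmax <= 0) stop("kd and rmax must be > 0", call. = FALSE)
  withSubstream(seed, 6L, {
    resp <- rmax * concentrations / (kd + concentrations) +
      rnorm(length(concentrations), 0, noiseSd)
    data.frame(concentration_molar = concentrations, response = resp)
  })
}
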