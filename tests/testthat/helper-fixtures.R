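# Fixtures built in code: small peak tracks, gene sets and oracles shared
# across test files.

makePeaks <- function(scaffold, summit, score = 30,
                      label = "TF", halfw = 100L,
                      seqlen = NULL) {
  n <- length(summit)
  score <- rep_len(score, n)
  scaffold <- rep_len(scaffold, n)
  gr <- GenomicRanges::GRanges(
    seqnames = scaffold,
    ranges = IRanges::IRanges(pmax(summit - halfw, 1L), summit + halfw),
    summit = as.integer(summit),
    score = score,
    label = rep_len(label, n))
  if (!is.null(seqlen)) GenomeInfoDb::seqlengths(gr) <- seqlen
  gr
}

makeGenes <- function(scaffold, start, end, strand, gene_id = NULL) {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_len(n))
  GeneModelSet(GenomicRanges::GRanges(
    seqnames = rep_len(scaffold, n),
    ranges = IRanges::IRanges(start, end),
    strand = rep_len(strand, n),
    gene_id = gene_id,
    symbol = gene_id))
}

# Brute-force all-pairs oracle for nearest-gene assignment: loops over
# every gene for every peak, independent of the package's per-scaffold
# search.
bruteNearestGene <- function(peaks, genes) {
  g <- geneBodies(genes)
  ids <- S4Vectors::mcols(g)$gene_id
  tss <- tssOf(genes)
  gsc <- as.character(GenomicRanges::seqnames(g))
  psc <- as.character(GenomicRanges::seqnames(peaks))
  summit <- S4Vectors::mcols(peaks)$summit
  vapply(seq_along(peaks), function(j) {
    best_d <- Inf
    best_id <- NA_character_
    for (i in seq_along(g)) {
      if (gsc[i] != psc[j]) next
      d <- abs(tss[i] - summit[j])
      if (d < best_d || (d == best_d && ids[i] < best_id)) {
        best_d <- d
        best_id <- ids[i]
      }
    }
    best_id
  }, character(1))
}

# Brute-force PWM scan oracle: enumerate every window on both strands by
# explicit per-position weight lookup on character vectors.
bruteScan <- function(weights, sequence, threshold) {
  seqChars <- strsplit(toupper(sequence), "")[[1]]
  L <- nrow(weights)
  n <- length(seqChars) - L + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  if (n < 1L) {
    return(data.frame(start = integer(0), strand = character(0),
                      raw_score = numeric(0)))
  }
  for (i in seq_len(n)) {
    win <- seqChars[i:(i + L - 1L)]
    sPlus <- 0
    for (k in seq_len(L)) {
      b <- win[k]
      sPlus <- sPlus + if (b %in% colnames(weights)) weights[k, b] else -Inf
    }
    # minus strand: the reverse complement of the window read 5'->3'
    rcWin <- rev(unname(comp[win]))
    sMinus <- 0
    for (k in seq_len(L)) {
      b <- rcWin[k]
      sMinus <- sMinus +
        if (!is.na(b) && b %in% colnames(weights)) weights[k, b] else -Inf
    }
    if (sPlus >= threshold) {
      out[[length(out) + 1L]] <- data.frame(start = i, strand = "+",
                                            raw_score = sPlus)
    }
    if (sMinus >= threshold) {
      out[[length(out) + 1L]] <- data.frame(start = i, strand = "-",
                                            raw_score = sMinus)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), strand = character(0),
                      raw_score = numeric(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

randomPWM <- function(L) {
  counts <- matrix(stats::runif(L * 4, 0.1, 10), nrow = L)
  buildPWM(counts, pseudocount = 0.01)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
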