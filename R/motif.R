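# PWM construction and scanning of summit-flanking sequence on both
# strands, with the 1.5-5 -> 0-1000 BED score scaling used for browser
# display, motif coverage of peak sets, and summit-relative positional
# histograms.  De novo motif discovery is out of scope: matrices come from
# aligned site counts or a consensus.

DNA_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Build a PWM from aligned site counts
#'
#' Weights are log10 likelihood ratios against the background:
#' `weights[k, b] = log10(((count + pc) / (rowsum + 4 pc)) / background_b)`.
#' With uniform counts every window scores 0; the consensus sequence of a
#' near-one-hot matrix attains the matrix maximum.
#'
#' @param counts L x 4 matrix of aligned base counts, columns A, C, G, T.
#' @param pseudocount added to every cell (default 0.01).
#' @param background numeric(4) base probabilities (default uniform).
#' @param motifId motif identifier.
#' @param scoreRange reportable raw-score range, default `c(1.5, 5)`.
#' @return A [PWMatrix-class].
#' @export
buildPWM <- function(counts, pseudocount = 0.01,
                     background = rep(0.25, 4), motifId = "motif",
                     scoreRange = c(1.5, 5)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns", call. = FALSE)
  colnames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("all-zero count row at position ", which(rs == 0)[1], call. = FALSE)
  }
  prob <- (counts + pseudocount) / (rs + 4 * pseudocount)
  w <- log10(sweep(prob, 2L, background, "/"))
  new("PWMatrix", motifId = motifId, weights = w,
      background = background, scoreRange = as.numeric(scoreRange))
}

#' Build a PWM from a consensus sequence
#'
#' One count per consensus base at each position (IUPAC codes spread their
#' count over the matching bases), then [buildPWM()].
#'
#' @param consensus character consensus, e.g. `"TTTCACACC"`.
#' @inheritParams buildPWM
#' @return A [PWMatrix-class].
#' @export
consensusPWM <- function(consensus, pseudocount = 0.01,
                         background = rep(0.25, 4),
                         motifId = consensus, scoreRange = c(1.5, 5)) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(consensus), "")[[1]]
  counts <- t(vapply(chars, function(ch) {
    bases <- iupac[[ch]]
    if (is.null(bases)) stop("invalid consensus base '", ch, "'",
                             call. = FALSE)
    out <- setNames(numeric(4), c("A", "C", "G", "T"))
    out[bases] <- 1 / length(bases)
    out
  }, numeric(4)))
  buildPWM(counts, pseudocount = pseudocount, background = background,
           motifId = motifId, scoreRange = scoreRange)
}

#' Scale a raw PWM score to the BED 0-1000 range
#'
#' Raw scores are clamped to the reportable range (default 1.5 to 5) and
#' mapped linearly to 0-1000 for browser display, so `bedScore(1.5) == 0`
#' and `bedScore(5) == 1000`.
#'
#' @param rawScore numeric raw score(s).
#' @param scoreRange numeric(2) clamp range.
#' @return Integer score(s) in [0, 1000].
#' @export
bedScore <- function(rawScore, scoreRange = c(1.5, 5)) {
  as.integer(round(1000 * (clamp(rawScore, scoreRange[1], scoreRange[2]) -
                           scoreRange[1]) /
                   (scoreRange[2] - scoreRange[1])))
}

# Integer-encode a DNA string; unknown bases (incl. N) -> code 5, which
# scores -Inf so masked sequence can never produce a hit.
encodeDNA <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  codes <- DNA_CODES[chars]
  codes[is.na(codes)] <- 5L
  unname(codes)
}

# Reverse-complement a PWM: reverse the positions and swap A<->T, C<->G.
reversePWMWeights <- function(w) {
  w[rev(seq_len(nrow(w))), c("T", "G", "C", "A"), drop = FALSE]
}

scoreWindows <- function(codes, w) {
  L <- nrow(w)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  waug <- cbind(w, `N` = rep(-Inf, nrow(w)))
  total <- numeric(n)
  for (k in seq_len(L)) {
    total <- total + waug[k, codes[k:(k + n - 1L)]]
  }
  total
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of the motif length is scored on the forward strand and
#' against the reverse complement; windows reaching `threshold` are
#' reported.  Minus-strand hits are reported at the forward-strand window
#' start, so all positions share one coordinate system (1-based window
#' starts).  Windows containing `N` (or any non-ACGT base) score `-Inf`.
#'
#' @param pwm a [PWMatrix-class].
#' @param sequence a `DNAString`, `DNAStringSet` element or character
#'   scalar.
#' @param threshold minimal raw score to report (default: lower end of the
#'   PWM's reportable range).
#' @return A `data.frame` with `start` (1-based window start), `strand`
#'   (`"+"`/`"-"`), `raw_score` and `bed_score`, ordered by `start`.
#' @examples
#' pwm <- consensusPWM("TTTCACACC")
#' scanPWM(pwm, "AAAAAAAATTTCACACCTTA", threshold = 3)
#' @export
scanPWM <- function(pwm, sequence, threshold = pwm@scoreRange[1]) {
  codes <- encodeDNA(sequence)
  L <- nrow(pwm@weights)
  fwd <- scoreWindows(codes, pwm@weights)
  rev_ <- scoreWindows(codes, reversePWMWeights(pwm@weights))
  strandHits <- function(scores, strand) {
    keep <- which(scores >= threshold)
    if (!length(keep)) return(NULL)
    data.frame(start = keep, strand = rep(strand, length(keep)),
               raw_score = scores[keep])
  }
  hits <- rbind(strandHits(fwd, "+"), strandHits(rev_, "-"))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      raw_score = numeric(0), bed_score = integer(0)))
  }
  hits$bed_score <- bedScore(hits$raw_score, pwm@scoreRange)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract fixed-width sequence flanks centred on peak summits
#'
#' For each peak, the `width`-bp window centred on the summit (the standard
#' 200-bp and 400-bp summit-flank regions used for motif analysis).
#' Windows running over a scaffold edge are truncated and flagged.
#'
#' @param peaks `GRanges` with `summit` metadata.
#' @param sequences named `DNAStringSet` of scaffold sequences.
#' @param width flank width in bp (200 or 400 typically; must be even).
#' @return A `DNAStringSet` with metadata columns `scaffold`,
#'   `flank_start` (1-based genomic start of the window), `summit`,
#'   `peak_id` and `truncated`.
#' @export
extractSummitFlanks <- function(peaks, sequences, width = 200L) {
  assertPeaks(peaks)
  if (width %% 2L != 0L) stop("width must be even", call. = FALSE)
  half <- width %/% 2L
  psc <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(psc), names(sequences))
  if (length(missing)) {
    stop("scaffold(s) missing from sequences: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  summit <- S4Vectors::mcols(peaks)$summit
  slen <- setNames(Biostrings::width(sequences), names(sequences))[psc]
  # window covering 0-based [summit0 - half, summit0 + half)
  from <- pmax(summit - half, 1L)
  to <- pmin(summit + half - 1L, slen)
  flanks <- Biostrings::DNAStringSet(vapply(seq_along(peaks), function(i) {
    as.character(Biostrings::subseq(sequences[[psc[i]]], from[i], to[i]))
  }, character(1)))
  names(flanks) <- paste0(psc, ":", from, "-", to)
  S4Vectors::mcols(flanks) <- S4Vectors::DataFrame(
    scaffold = psc,
    flank_start = as.integer(from),
    summit = as.integer(summit),
    peak_id = seq_along(peaks),
    truncated = (summit - half < 1L) | (summit + half - 1L > slen))
  flanks
}

#' Scan peak summit flanks with a PWM in genomic coordinates
#'
#' Convenience wrapper: extracts `width`-bp summit flanks, scans each on
#' both strands, and reports hits in genomic coordinates together with the
#' offset of the hit start from the peak summit.
#'
#' @inheritParams extractSummitFlanks
#' @param pwm a [PWMatrix-class].
#' @param threshold minimal raw score (see [scanPWM()]).
#' @return A `data.frame` with `scaffold`, `start` (1-based genomic),
#'   `strand`, `raw_score`, `bed_score`, `peak_id` and
#'   `offset_from_summit`.
#' @export
scanPeakFlanks <- function(pwm, peaks, sequences, width = 400L,
                           threshold = pwm@scoreRange[1]) {
  flanks <- extractSummitFlanks(peaks, sequences, width = width)
  fm <- S4Vectors::mcols(flanks)
  out <- lapply(seq_along(flanks), function(i) {
    h <- scanPWM(pwm, flanks[[i]], threshold = threshold)
    if (!nrow(h)) return(NULL)
    gstart <- fm$flank_start[i] + h$start - 1L
    data.frame(scaffold = fm$scaffold[i], start = gstart,
               strand = h$strand, raw_score = h$raw_score,
               bed_score = h$bed_score, peak_id = fm$peak_id[i],
               offset_from_summit = gstart - fm$summit[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(0), start = integer(0),
                      strand = character(0), raw_score = numeric(0),
                      bed_score = integer(0), peak_id = integer(0),
                      offset_from_summit = integer(0))
  }
  out
}

#' Fraction of peaks covered by at least one motif hit
#'
#' A peak counts as covered when at least one hit starts within `window`
#' bp of its summit.  Several hit tables (one per motif variant) can be
#' supplied; coverage is then the union over variants, matching how a
#' small set of motif variants jointly accounts for a peak set.
#'
#' @param peaks `GRanges` peak track.
#' @param hits a hit `data.frame` from [scanPeakFlanks()], or a list of
#'   them.
#' @param window maximal |offset from summit| in bp (default 100).
#' @return Fraction in [0, 1].
#' @export
motifCoverage <- function(peaks, hits, window = 100) {
  if (!length(peaks)) stop("empty peak set", call. = FALSE)
  if (is.data.frame(hits)) hits <- list(hits)
  covered <- unique(unlist(lapply(hits, function(h) {
    h$peak_id[abs(h$offset_from_summit) <= window]
  })))
  length(intersect(covered, seq_along(peaks))) / length(peaks)
}

#' Positional histogram of motif hits around peak summits
#'
#' Counts of hit-start offsets from the summit over [-limit, +limit] in
#' `binwidth`-bp bins.  For motifs genuinely bound by the precipitated
#' factor the mode is expected at the summit.
#'
#' @param hits hit `data.frame` from [scanPeakFlanks()].
#' @param binwidth bin width in bp (default 20).
#' @param limit half-range in bp (default 200).
#' @return A list with `mids`, `counts`, `n_out_of_range`.
#' @export
motifPositionHistogram <- function(hits, binwidth = 20L, limit = 200L) {
  d <- hits$offset_from_summit
  edges <- seq(-limit, limit, by = binwidth)
  inside <- d >= -limit & d < limit
  idx <- floor((d[inside] + limit) / binwidth) + 1L
  list(mids = edges[-length(edges)] + binwidth / 2,
       counts = tabulate(idx, nbins = length(edges) - 1L),
       n_out_of_range = sum(!inside))
}
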