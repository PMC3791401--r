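#' Gene models: bodies, exons and UTRs
#'
#' Container for a set of gene models.  Gene bodies are a [GenomicRanges::GRanges]
#' (1-based, inclusive, stranded `+`/`-`) with metadata columns `gene_id` and
#' `symbol`; exon and UTR structure is carried as [GenomicRanges::GRangesList]s
#' named by `gene_id`.  The transcription start site (TSS) of each gene is a
#' deterministic function of the body and strand: `start` for `+` genes,
#' `end` for `-` genes (see [tssOf()]).
#'
#' @slot genes `GRanges` of gene bodies with `gene_id`, `symbol` metadata.
#' @slot exons `GRangesList` of exons per gene (possibly empty per gene).
#' @slot utr5,utr3 `GRangesList` of untranslated regions per gene.
#'
#' @aliases GeneModelSet-class
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  slots = c(
    genes = "GRanges",
    exons = "GRangesList",
    utr5 = "GRangesList",
    utr3 = "GRangesList"
  )
)

setValidity("GeneModelSet", function(object) {
  g <- object@genes
  msgs <- character()
  mc <- S4Vectors::mcols(g)
  if (!"gene_id" %in% colnames(mc)) {
    return("gene bodies must carry a 'gene_id' metadata column")
  }
  ids <- mc$gene_id
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate gene_id")
  if (length(g) && any(!as.character(GenomicRanges::strand(g)) %in% c("+", "-"))) {
    msgs <- c(msgs, "gene strand must be '+' or '-'")
  }
  for (nm in c("exons", "utr5", "utr3")) {
    grl <- slot(object, nm)
    if (length(grl) && !all(names(grl) %in% ids)) {
      msgs <- c(msgs, sprintf("'%s' names must be gene ids", nm))
    }
  }
  ex <- object@exons
  if (length(ex)) {
    bodies <- g[match(names(ex), ids)]
    for (i in seq_along(ex)) {
      e <- ex[[i]]
      if (!length(e)) next
      b <- bodies[i]
      if (any(as.character(GenomicRanges::seqnames(e)) !=
              as.character(GenomicRanges::seqnames(b))) ||
          any(GenomicRanges::start(e) < GenomicRanges::start(b)) ||
          any(GenomicRanges::end(e) > GenomicRanges::end(b))) {
        msgs <- c(msgs, sprintf("exons of '%s' extend beyond the gene body",
                                names(ex)[i]))
        break
      }
      e <- sort(e)
      if (length(e) > 1L &&
          any(GenomicRanges::start(e)[-1L] <=
              GenomicRanges::end(e)[-length(e)])) {
        msgs <- c(msgs, sprintf("exons of '%s' overlap", names(ex)[i]))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModelSet
#'
#' @param genes `GRanges` of gene bodies with `gene_id` (and optionally
#'   `symbol`) metadata columns; strand must be `+` or `-`.
#' @param exons,utr5,utr3 optional `GRangesList`s named by `gene_id`.
#' @return A [GeneModelSet-class] object.
#' @examples
#' g <- GenomicRanges::GRanges("scaffold_1",
#'   IRanges::IRanges(101, 500), strand = "+", gene_id = "geneA", symbol = "a")
#' GeneModelSet(g)
#' @export
GeneModelSet <- function(genes,
                         exons = GenomicRanges::GRangesList(),
                         utr5 = GenomicRanges::GRangesList(),
                         utr3 = GenomicRanges::GRangesList()) {
  if (!"symbol" %in% colnames(S4Vectors::mcols(genes))) {
    S4Vectors::mcols(genes)$symbol <- S4Vectors::mcols(genes)$gene_id
  }
  new("GeneModelSet", genes = genes, exons = exons, utr5 = utr5, utr3 = utr3)
}

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet with %d gene(s) on %d scaffold(s)\n",
              length(object@genes),
              length(unique(as.character(GenomicRanges::seqnames(object@genes))))))
  cat(sprintf("  genes with exon annotation: %d\n", length(object@exons)))
})

#' Gene-level binding occupancy
#'
#' Per-gene summary of ChIP-seq binding: peak -log10(p) scores binned into
#' 400-bp intervals relative to the TSS (25 upstream bins, 25 downstream
#' bins covering +/-10 kb, plus one overflow bin per side for peaks beyond
#' 10 kb), windowed sums over the proximal (<=1 kb), intermediate (1-5 kb)
#' and distal (>5 kb) bands on each side, and the total sum of scores.
#' The total always equals the row sum of the bins (overflow included), so
#' the binning conserves the summed peak scores exactly.
#'
#' @slot bins numeric matrix, genes x 52 bins; rownames are gene ids.
#' @slot windowSums numeric matrix, genes x 6 window sums.
#' @slot totals numeric vector of per-gene total sum of -log10(p).
#'
#' @aliases GeneOccupancy-class
#' @exportClass GeneOccupancy
setClass("GeneOccupancy",
  slots = c(
    bins = "matrix",
    windowSums = "matrix",
    totals = "numeric"
  )
)

setValidity("GeneOccupancy", function(object) {
  msgs <- character()
  if (ncol(object@bins) != 52L) msgs <- c(msgs, "bins must have 52 columns")
  if (any(object@bins < 0)) msgs <- c(msgs, "bin values must be >= 0")
  if (ncol(object@windowSums) != 6L) {
    msgs <- c(msgs, "windowSums must have 6 columns")
  }
  if (length(object@totals) != nrow(object@bins)) {
    msgs <- c(msgs, "totals length must match bins rows")
  }
  if (nrow(object@bins) &&
      any(abs(object@totals - rowSums(object@bins)) > 1e-8)) {
    msgs <- c(msgs, "totals must equal rowSums(bins)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneOccupancy", function(object) {
  cat(sprintf("GeneOccupancy for %d gene(s)\n", nrow(object@bins)))
  cat(sprintf("  genes with any binding: %d\n", sum(object@totals > 0)))
  cat(sprintf("  grand total sum[-log10 p]: %.1f\n", sum(object@totals)))
})

#' Position weight matrix for motif scanning
#'
#' A log-likelihood-ratio position weight matrix over the DNA alphabet.
#' `weights[k, b]` is log10 of the probability of base `b` at motif position
#' `k` over the background probability of `b`; the score of a sequence
#' window is the sum of its per-position weights.  `scoreRange` is the
#' display range used when scaling raw scores to the BED 0-1000 range
#' (scores are clamped to the range, then mapped linearly).
#'
#' @slot motifId character motif identifier.
#' @slot weights L x 4 numeric matrix, columns A, C, G, T.
#' @slot background numeric(4) background base probabilities.
#' @slot scoreRange numeric(2) reportable score range, default c(1.5, 5).
#'
#' @aliases PWMatrix-class
#' @exportClass PWMatrix
setClass("PWMatrix",
  slots = c(
    motifId = "character",
    weights = "matrix",
    background = "numeric",
    scoreRange = "numeric"
  )
)

setValidity("PWMatrix", function(object) {
  msgs <- character()
  w <- object@weights
  if (ncol(w) != 4L || !identical(colnames(w), c("A", "C", "G", "T"))) {
    msgs <- c(msgs, "weights must have columns A, C, G, T")
  }
  if (nrow(w) < 1L) msgs <- c(msgs, "motif length must be >= 1")
  if (any(!is.finite(w))) msgs <- c(msgs, "weights must be finite")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6) {
    msgs <- c(msgs, "background must be 4 probabilities summing to 1")
  }
  if (length(object@scoreRange) != 2L ||
      object@scoreRange[1] >= object@scoreRange[2]) {
    msgs <- c(msgs, "scoreRange must be an increasing pair")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PWMatrix", function(object) {
  cat(sprintf("PWMatrix '%s': %d positions, max score %.3f\n",
              object@motifId, nrow(object@weights), pwmMaxScore(object)))
})

#' Equilibrium binding curve with fitted parameters
#'
#' A set of (concentration, response) measurements together with the 1:1
#' Langmuir-isotherm fit R = Rmax * c / (Kd + c).  `kd` is the equilibrium
#' dissociation constant (molar): the ligand concentration at which half of
#' the available sites are occupied.
#'
#' @slot concentrations numeric vector of molar concentrations.
#' @slot responses numeric vector of equilibrium responses.
#' @slot kd fitted dissociation constant (molar).
#' @slot rmax fitted saturating response.
#' @slot residualNorm Euclidean norm of the fit residuals.
#'
#' @aliases BindingCurve-class
#' @exportClass BindingCurve
setClass("BindingCurve",
  slots = c(
    concentrations = "numeric",
    responses = "numeric",
    kd = "numeric",
    rmax = "numeric",
    residualNorm = "numeric"
  )
)

setValidity("BindingCurve", function(object) {
  msgs <- character()
  if (length(object@concentrations) != length(object@responses)) {
    msgs <- c(msgs, "concentrations and responses must have equal length")
  }
  if (length(object@concentrations) < 3L) {
    msgs <- c(msgs, "a binding curve needs >= 3 points")
  }
  if (object@kd <= 0) msgs <- c(msgs, "kd must be > 0")
  if (object@rmax <= 0) msgs <- c(msgs, "rmax must be > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BindingCurve", function(object) {
  cat(sprintf("BindingCurve: %d points, Kd = %.3g M, Rmax = %.3g (resid %.3g)\n",
              length(object@concentrations), object@kd, object@rmax,
              object@residualNorm))
})

#' Configuration for the synthetic-data generators
#'
#' Holds every tunable of the simulation: genome layout, peak placement
#' around transcription start sites, the long-tailed -log10(p) score
#' distribution, cofactor-track sharing and positional jitter, motif
#' planting, and the planted binding-to-downregulation expression effect.
#' All generators derive their RNG stream from the single `seed`, each from
#' its own substream, so outputs are byte-identical for a fixed seed and
#' independent of which other generators run.
#'
#' @slot seed integer root seed.
#' @slot nScaffolds,scaffoldLength genome layout.
#' @slot nGenes number of genes, tiled across scaffolds.
#' @slot geneLengthRange integer pair, uniform gene body length (bp).
#' @slot intergenicMean mean of the exponential intergenic gap (bp).
#' @slot targetFraction fraction of genes given a promoter-proximal peak.
#' @slot tssPeakSd SD (bp) of planted summit positions around the TSS.
#' @slot scoreMin,scoreMean parameters of the shifted-exponential
#'   -log10(p) score distribution (scores = scoreMin + Exp(scoreMean - scoreMin)).
#' @slot nBackgroundPeaks uniformly placed background peaks per track.
#' @slot cofactorJitterSd SD (bp) of shared-summit jitter in cofactor tracks.
#' @slot cofactorSharedFraction fraction of peaks shared with a cofactor.
#' @slot motifPlantProb per-peak probability of planting a motif instance.
#' @slot deEffectSize knockdown expression shift (log2 units) for bound genes.
#' @slot deNoiseSd replicate noise SD (log2 units).
#' @slot nReplicates replicates per condition (>= 2).
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    seed = "integer",
    nScaffolds = "integer",
    scaffoldLength = "integer",
    nGenes = "integer",
    geneLengthRange = "integer",
    intergenicMean = "numeric",
    targetFraction = "numeric",
    tssPeakSd = "numeric",
    scoreMin = "numeric",
    scoreMean = "numeric",
    nBackgroundPeaks = "integer",
    cofactorJitterSd = "numeric",
    cofactorSharedFraction = "numeric",
    motifPlantProb = "numeric",
    deEffectSize = "numeric",
    deNoiseSd = "numeric",
    nReplicates = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  fr <- c(targetFraction = object@targetFraction,
          cofactorSharedFraction = object@cofactorSharedFraction,
          motifPlantProb = object@motifPlantProb)
  bad <- fr < 0 | fr > 1
  if (any(bad)) {
    msgs <- c(msgs, sprintf("fraction(s) outside [0,1]: %s",
                            paste(names(fr)[bad], collapse = ", ")))
  }
  sds <- c(tssPeakSd = object@tssPeakSd, cofactorJitterSd = object@cofactorJitterSd,
           deNoiseSd = object@deNoiseSd)
  if (any(sds < 0)) msgs <- c(msgs, "standard deviations must be >= 0")
  if (object@nReplicates < 2L) msgs <- c(msgs, "nReplicates must be >= 2")
  if (length(object@geneLengthRange) != 2L ||
      object@geneLengthRange[1] > object@geneLengthRange[2] ||
      object@geneLengthRange[1] < 1L) {
    msgs <- c(msgs, "geneLengthRange must be an increasing positive pair")
  }
  if (object@scoreMean <= object@scoreMin || object@scoreMin < 0) {
    msgs <- c(msgs, "need 0 <= scoreMin < scoreMean")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig (seed %d)\n",
    "  genome: %d scaffold(s) x %d bp, %d genes\n",
    "  peaks: target fraction %.2f, TSS sd %.0f bp, %d background\n",
    "  cofactor: shared %.2f, jitter sd %.0f bp; motif plant prob %.2f\n",
    "  expression: effect %.2f log2, noise sd %.2f, %d replicates\n"),
    object@seed, object@nScaffolds, object@scaffoldLength, object@nGenes,
    object@targetFraction, object@tssPeakSd, object@nBackgroundPeaks,
    object@cofactorSharedFraction, object@cofactorJitterSd,
    object@motifPlantProb, object@deEffectSize, object@deNoiseSd,
    object@nReplicates))
})

#' @rdname SimConfig-class
#' @param seed,nScaffolds,scaffoldLength,nGenes,geneLengthRange,intergenicMean
#'   see slots.
#' @param targetFraction,tssPeakSd,scoreMin,scoreMean,nBackgroundPeaks see slots.
#' @param cofactorJitterSd,cofactorSharedFraction,motifPlantProb see slots.
#' @param deEffectSize,deNoiseSd,nReplicates see slots.
#' @return `SimConfig()` returns a validated [SimConfig-class] object.
#' @examples
#' SimConfig(seed = 1, nGenes = 50L)
#' @export
SimConfig <- function(seed = 1L,
                      nScaffolds = 5L,
                      scaffoldLength = 600000L,
                      nGenes = 300L,
                      geneLengthRange = c(2000L, 8000L),
                      intergenicMean = 3000,
                      targetFraction = 0.5,
                      tssPeakSd = 100,
                      scoreMin = 2,
                      scoreMean = 20,
                      nBackgroundPeaks = 100L,
                      cofactorJitterSd = 10,
                      cofactorSharedFraction = 0.9,
                      motifPlantProb = 0.82,
                      deEffectSize = 1.5,
                      deNoiseSd = 0.5,
                      nReplicates = 3L) {
  new("SimConfig",
      seed = as.integer(seed), nScaffolds = as.integer(nScaffolds),
      scaffoldLength = as.integer(scaffoldLength), nGenes = as.integer(nGenes),
      geneLengthRange = as.integer(geneLengthRange),
      intergenicMean = intergenicMean, targetFraction = targetFraction,
      tssPeakSd = tssPeakSd, scoreMin = scoreMin, scoreMean = scoreMean,
      nBackgroundPeaks = as.integer(nBackgroundPeaks),
      cofactorJitterSd = cofactorJitterSd,
      cofactorSharedFraction = cofactorSharedFraction,
      motifPlantProb = motifPlantProb, deEffectSize = deEffectSize,
      deNoiseSd = deNoiseSd, nReplicates = as.integer(nReplicates))
}
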