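# Generics and accessors for the package's S4 classes.

#' Gene bodies of a GeneModelSet
#' @param x a [GeneModelSet-class].
#' @return A `GRanges` of gene bodies.
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))

#' @rdname geneBodies
#' @export
setMethod("geneBodies", "GeneModelSet", function(x) x@genes)

#' Gene identifiers
#' @param x a [GeneModelSet-class] or [GeneOccupancy-class].
#' @return Character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneModelSet", function(x) {
  S4Vectors::mcols(x@genes)$gene_id
})

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneOccupancy", function(x) rownames(x@bins))

#' Exon ranges per gene
#' @param x a [GeneModelSet-class].
#' @return A `GRangesList` named by gene id.
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname exonRanges
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' UTR ranges per gene
#' @param x a [GeneModelSet-class].
#' @param which `"utr5"` or `"utr3"`.
#' @return A `GRangesList` named by gene id.
#' @export
setGeneric("utrRanges", function(x, which = "utr5") standardGeneric("utrRanges"))

#' @rdname utrRanges
#' @export
setMethod("utrRanges", "GeneModelSet", function(x, which = "utr5") {
  which <- match.arg(which, c("utr5", "utr3"))
  slot(x, which)
})

#' Binned occupancy matrix
#' @param x a [GeneOccupancy-class].
#' @return Numeric matrix, genes x 52 bins (400-bp TSS-relative bins plus
#'   upstream/downstream overflow).
#' @export
setGeneric("occupancyBins", function(x) standardGeneric("occupancyBins"))

#' @rdname occupancyBins
#' @export
setMethod("occupancyBins", "GeneOccupancy", function(x) x@bins)

#' Per-gene total occupancy (sum of -log10 p)
#' @param x a [GeneOccupancy-class].
#' @return Named numeric vector.
#' @export
setGeneric("occupancyTotals", function(x) standardGeneric("occupancyTotals"))

#' @rdname occupancyTotals
#' @export
setMethod("occupancyTotals", "GeneOccupancy", function(x) {
  setNames(x@totals, rownames(x@bins))
})

#' Fitted dissociation constant
#' @param x a [BindingCurve-class].
#' @return The fitted Kd (molar).
#' @export
setGeneric("kdValue", function(x) standardGeneric("kdValue"))

#' @rdname kdValue
#' @export
setMethod("kdValue", "BindingCurve", function(x) x@kd)

#' Fitted saturating response
#' @param x a [BindingCurve-class].
#' @return The fitted Rmax.
#' @export
setGeneric("rmaxValue", function(x) standardGeneric("rmaxValue"))

#' @rdname rmaxValue
#' @export
setMethod("rmaxValue", "BindingCurve", function(x) x@rmax)

#' PWM weight matrix
#' @param x a [PWMatrix-class].
#' @return L x 4 numeric matrix of log10 likelihood-ratio weights.
#' @export
setGeneric("pwmWeights", function(x) standardGeneric("pwmWeights"))

#' @rdname pwmWeights
#' @export
setMethod("pwmWeights", "PWMatrix", function(x) x@weights)

#' Maximum attainable PWM score
#' @param x a [PWMatrix-class].
#' @return The score of the best-matching window.
#' @export
setGeneric("pwmMaxScore", function(x) standardGeneric("pwmMaxScore"))

#' @rdname pwmMaxScore
#' @export
setMethod("pwmMaxScore", "PWMatrix", function(x) {
  sum(apply(x@weights, 1L, max))
})
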