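# Co-occupancy between peak tracks (factor x factor or stage x stage) and
# two-tier shared-target calling at the gene level.  Peak-level sharing
# (summit distance) and gene-level sharing (occupancy tiers) are distinct
# operations and never mixed silently.

#' Nearest reference-summit distance for every query peak
#'
#' For each query summit, the minimal absolute distance to any reference
#' summit on the same scaffold.  Query peaks on scaffolds with no reference
#' peak have no distance (`Inf`) and are counted in `n_excluded`.
#'
#' @param query,reference `GRanges` peak tracks with `summit` metadata.
#' @return A list with `distances` (numeric, one per query peak, `Inf`
#'   where no same-scaffold reference exists) and `n_excluded`.
#' @export
nearestSummitDistances <- function(query, reference) {
  assertPeaks(query, "query")
  assertPeaks(reference, "reference")
  if (!length(query) || !length(reference)) {
    stop("both peak tracks must be non-empty", call. = FALSE)
  }
  qsc <- as.character(GenomicRanges::seqnames(query))
  rsc <- as.character(GenomicRanges::seqnames(reference))
  qs <- S4Vectors::mcols(query)$summit
  rs <- S4Vectors::mcols(reference)$summit
  d <- rep(Inf, length(query))
  for (sc in unique(qsc)) {
    ref <- sort(rs[rsc == sc])
    qi <- which(qsc == sc)
    if (!length(ref)) next
    idx <- findInterval(qs[qi], ref)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(ref))
    d[qi] <- pmin(abs(qs[qi] - ref[lo]), abs(qs[qi] - ref[hi]))
  }
  list(distances = d, n_excluded = sum(is.infinite(d)))
}

#' Fraction of query peaks co-localised with a reference track
#'
#' The fraction of query peaks whose nearest reference summit lies within
#' `threshold` bp (default 100 bp, the summit-distance criterion for peak
#' maintenance between stages and recruitment to shared sites).  The
#' denominator is the full query track, so query peaks on reference-free
#' scaffolds count as non-co-localised.  Note the measure is not symmetric
#' in its arguments.
#'
#' @inheritParams nearestSummitDistances
#' @param threshold maximal summit distance in bp (default 100).
#' @return Fraction in [0, 1].
#' @examples
#' \dontrun{colocalizationFraction(xbra_st12, xbra_st20)}
#' @export
colocalizationFraction <- function(query, reference, threshold = 100) {
  if (!length(query)) stop("query track is empty", call. = FALSE)
  d <- nearestSummitDistances(query, reference)$distances
  sum(d <= threshold) / length(query)
}

#' Tier gene-level occupancy under the two-tier stringency rule
#'
#' A gene is a `strong` target of a factor when its summed -log10(p)
#' occupancy reaches `strong` (default 25, i.e. p <= 1e-25), `relaxed`
#' when it reaches `relaxed` (default 1, i.e. p <= 0.1), and `absent`
#' otherwise.
#'
#' @param occupancy numeric matrix of gene x factor total occupancies
#'   (sum of -log10 p), or a named list of per-gene vectors.
#' @param strong,relaxed tier thresholds in -log10(p) units.
#' @return Character matrix of tiers with the same dimnames.
#' @export
targetTiers <- function(occupancy, strong = 25, relaxed = 1) {
  occ <- asOccupancyMatrix(occupancy)
  tiers <- matrix("absent", nrow = nrow(occ), ncol = ncol(occ),
                  dimnames = dimnames(occ))
  tiers[occ >= relaxed] <- "relaxed"
  tiers[occ >= strong] <- "strong"
  tiers
}

asOccupancyMatrix <- function(occupancy) {
  if (is.list(occupancy) && !is.data.frame(occupancy)) {
    genes <- sort(unique(unlist(lapply(occupancy, names))))
    occ <- sapply(occupancy, function(v) {
      out <- setNames(numeric(length(genes)), genes)
      out[names(v)] <- v
      out
    })
    if (is.null(dim(occ))) occ <- matrix(occ, ncol = length(occupancy),
                                         dimnames = list(genes,
                                                         names(occupancy)))
    occ
  } else {
    as.matrix(occupancy)
  }
}

#' Shared-target Venn regions under strong-anchored relaxed rescue
#'
#' Genes enter a factor's target universe when their occupancy is strong
#' (p <= 1e-25 equivalent).  When comparing factors, stringency is relaxed
#' down to p <= 0.1 for a factor provided the gene is a strong target of at
#' least one other factor ("relaxed rescue"); a gene that is merely relaxed
#' for every factor belongs to no set.  Venn region membership follows from
#' these per-factor memberships.  Per-factor totals are reported as strong
#' + rescued, mirroring the "a + b = total" bookkeeping of shared-target
#' counts.
#'
#' @param occupancy gene x factor occupancy matrix (or named list of
#'   per-gene vectors), in summed -log10(p) units.
#' @param strong,relaxed tier thresholds (see [targetTiers()]).
#' @return A list with `regions` (named list, one character vector of gene
#'   ids per non-empty Venn region, names like `"A&B"`), `perFactor`
#'   (data.frame with `n_strong`, `n_rescued`, `total`), `membership`
#'   (logical gene x factor matrix) and `tiers`.
#' @export
sharedTargetVenn <- function(occupancy, strong = 25, relaxed = 1) {
  occ <- asOccupancyMatrix(occupancy)
  if (ncol(occ) < 2L) stop("need >= 2 factors", call. = FALSE)
  if (is.null(colnames(occ))) {
    stop("occupancy must name its factors", call. = FALSE)
  }
  if (any(is.na(occ))) {
    stop("occupancy missing for some gene/factor pairs", call. = FALSE)
  }
  tiers <- targetTiers(occ, strong = strong, relaxed = relaxed)
  isStrong <- tiers == "strong"
  atLeastRelaxed <- tiers != "absent"
  strongElsewhere <- rowSums(isStrong) - isStrong > 0
  membership <- isStrong | (atLeastRelaxed & strongElsewhere)

  keys <- apply(membership, 1L, function(m) {
    paste(colnames(occ)[m], collapse = "&")
  })
  keep <- keys != ""
  regions <- split(rownames(occ)[keep], keys[keep])
  perFactor <- data.frame(
    factor = colnames(occ),
    n_strong = colSums(isStrong),
    n_rescued = colSums(membership & !isStrong),
    total = colSums(membership),
    row.names = NULL)
  list(regions = regions, perFactor = perFactor,
       membership = membership, tiers = tiers)
}

#' Pearson correlation of gene occupancy levels between two tracks
#'
#' @param levelsA,levelsB named numeric vectors of per-gene occupancy;
#'   the correlation is computed on the intersection of gene sets.
#' @return Pearson r.
#' @export
occupancyCorrelation <- function(levelsA, levelsB) {
  common <- intersect(names(levelsA), names(levelsB))
  if (length(common) < 3L) {
    stop("need >= 3 genes in common", call. = FALSE)
  }
  a <- levelsA[common]
  b <- levelsB[common]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance in occupancy levels", call. = FALSE)
  }
  cor(a, b)
}
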