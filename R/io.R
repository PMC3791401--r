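# Readers and writers for the tabular and genomic formats the pipeline
# touches.  Internal coordinates follow the GRanges convention (1-based,
# inclusive); BED files (0-based, half-open) and Ensembl-style gene tables
# (1-based, inclusive) are converted at this boundary and nowhere else.

#' Read an Ensembl-style tab-separated gene table
#'
#' Expects six headerless tab-separated columns: gene id, scaffold, start,
#' end, strand (1/-1) and description, with 1-based inclusive coordinates
#' (as exported from BioMart).  Rows with start >= end are rejected with a
#' warning; a malformed strand value or a duplicated gene id is an error.
#'
#' @param path path to the gene table.
#' @return A [GeneModelSet-class] (without exon/UTR annotation).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("esr5\tscaffold_1051\t54853\t55447\t1\tLOC100135364", tf)
#' gs <- readGeneTable(tf)
#' geneIds(gs)
#' @export
readGeneTable <- function(path) {
  raw <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("gene_id", "scaffold", "start", "end",
                             "strand", "description"),
               colClasses = c("character", "character", "numeric",
                              "numeric", "character", "character")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        NULL
      } else {
        stop("failed to parse gene table: ", conditionMessage(e),
             call. = FALSE)
      }
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("gene table '", path, "' is empty")
    return(GeneModelSet(GenomicRanges::GRanges(gene_id = character(0),
                                               symbol = character(0))))
  }
  strand_chr <- trimws(raw$strand)
  # tolerate a unicode minus sign in hand-edited tables
  strand_chr <- gsub("−", "-", strand_chr)
  ok <- strand_chr %in% c("1", "+1", "-1")
  if (any(!ok)) {
    stop(sprintf("malformed strand value '%s' at line %d",
                 raw$strand[which(!ok)[1]], which(!ok)[1]), call. = FALSE)
  }
  dup <- duplicated(raw$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in gene table: ",
         paste(unique(raw$gene_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad <- raw$start >= raw$end
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with start >= end", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
    strand_chr <- strand_chr[!bad]
  }
  if (nrow(raw) == 0L) {
    return(GeneModelSet(GenomicRanges::GRanges(gene_id = character(0),
                                               symbol = character(0))))
  }
  g <- GenomicRanges::GRanges(
    seqnames = raw$scaffold,
    ranges = IRanges::IRanges(start = raw$start, end = raw$end),
    strand = ifelse(strand_chr == "-1", "-", "+"),
    gene_id = raw$gene_id,
    symbol = raw$description)
  GeneModelSet(g)
}

#' Write a GeneModelSet as an Ensembl-style gene table
#'
#' Inverse of [readGeneTable()]: six tab-separated columns, 1-based
#' inclusive coordinates, strand as 1/-1.
#'
#' @param genes a [GeneModelSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGeneTable <- function(genes, path) {
  g <- geneBodies(genes)
  df <- data.frame(
    gene_id = S4Vectors::mcols(g)$gene_id,
    scaffold = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = ifelse(as.character(GenomicRanges::strand(g)) == "-", "-1", "1"),
    description = S4Vectors::mcols(g)$symbol)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED/narrowPeak-style peak table
#'
#' Expects whitespace-separated columns scaffold, start, end, name, score
#' and optionally a summit offset (BED convention: 0-based, half-open
#' intervals; the summit offset is relative to the interval start).  The
#' score is interpreted as -log10 of the peak p-value.  When no summit
#' column is present the floor midpoint of the interval is used.  Records
#' whose summit falls outside the interval are rejected with a warning; a
#' negative start is a parse error.
#'
#' Returned summits are 1-based genomic positions (GRanges convention), so
#' a BED record `chr1 100 300` with summit offset 50 has `summit == 151`
#' (0-based position 150).
#'
#' @param path path to the peak file.
#' @return A `GRanges` with metadata columns `summit`, `score`, `label`.
#' @export
readPeaks <- function(path) {
  raw <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE, sep = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL
      else stop("failed to parse peak file: ", conditionMessage(e),
                call. = FALSE)
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("peak file '", path, "' is empty")
    return(GenomicRanges::GRanges(summit = integer(0), score = numeric(0),
                                  label = character(0)))
  }
  if (ncol(raw) < 5L) {
    stop("peak file needs >= 5 columns (scaffold, start, end, name, score)",
         call. = FALSE)
  }
  if (!is.numeric(raw[[2]]) || !is.numeric(raw[[3]])) {
    stop("peak file start/end columns are not numeric", call. = FALSE)
  }
  if (any(raw[[2]] < 0)) {
    stop(sprintf("negative start at line %d", which(raw[[2]] < 0)[1]),
         call. = FALSE)
  }
  start0 <- raw[[2]]
  end0 <- raw[[3]]
  mid0 <- floor((start0 + end0) / 2)
  if (ncol(raw) >= 6L && is.numeric(raw[[6]])) {
    # records without a summit offset (NA after ragged parse) fall back
    # to the interval midpoint
    summit0 <- ifelse(is.na(raw[[6]]), mid0, start0 + raw[[6]])
  } else {
    summit0 <- mid0
  }
  ok <- summit0 >= start0 & summit0 < end0
  if (any(!ok)) {
    warning(sprintf("rejected %d record(s) with summit outside the interval",
                    sum(!ok)))
  }
  raw <- raw[ok, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = raw[[1]],
    ranges = IRanges::IRanges(start = raw[[2]] + 1L, end = raw[[3]]),
    summit = as.integer(summit0[ok] + 1L),
    score = as.numeric(raw[[5]]),
    label = as.character(raw[[4]]))
}

#' Write scored intervals as BED
#'
#' Writes six columns: scaffold, 0-based start, end, name, score, summit
#' offset.  Coordinates round-trip exactly through [readPeaks()].  With
#' `extend = TRUE` both interval edges are pushed out by 40 bp (clamped at
#' the scaffold start), the convention used to build browser tracks of
#' motif matches.  An optional `scale` function maps raw scores to the BED
#' score column; results outside [0, 1000] are clamped with a warning.
#'
#' @param peaks a `GRanges` with `summit`, `score` (and optionally `label`)
#'   metadata columns.
#' @param path output path.
#' @param extend logical; extend both edges by `extendBy` bp.
#' @param extendBy extension width in bp (default 40).
#' @param scale optional function applied to the score column.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(peaks, path, extend = FALSE, extendBy = 40L,
                     scale = NULL) {
  assertPeaks(peaks)
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  if (extend) {
    start0 <- pmax(start0 - as.integer(extendBy), 0L)
    end0 <- end0 + as.integer(extendBy)
  }
  sc <- S4Vectors::mcols(peaks)$score
  if (!is.null(scale)) {
    sc <- scale(sc)
    if (length(sc) && any(sc < 0 | sc > 1000)) {
      warning("scaled score(s) outside [0, 1000] clamped")
      sc <- clamp(sc, 0, 1000)
    }
  }
  label <- S4Vectors::mcols(peaks)$label
  if (is.null(label)) label <- paste0("peak_", seq_along(peaks))
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(peaks)),
    start = start0,
    end = end0,
    name = label,
    score = sc,
    # summit offset is relative to the written (possibly extended) start
    summit_offset = S4Vectors::mcols(peaks)$summit - 1L - start0)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression table (CSV)
#'
#' @param path CSV with at least `gene_id` plus replicate or summary columns.
#' @return A `data.frame`.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% colnames(df)) {
    stop("expression table must have a 'gene_id' column", call. = FALSE)
  }
  df
}

#' Read an SPR-style binding-curve table (CSV)
#'
#' @param path CSV with columns `concentration_molar` and `response`.
#' @return A `data.frame` with positive, sorted concentrations.
#' @export
readBindingCurveTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_molar", "response")
  if (!all(need %in% colnames(df))) {
    stop("binding-curve table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$concentration_molar <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  df[order(df$concentration_molar), , drop = FALSE]
}
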