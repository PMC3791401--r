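# Internal helpers shared across modules.

AVOGADRO <- 6.02214076e23

#' Derive a reproducible sub-seed from a root seed
#'
#' Each stochastic generator draws from its own substream so that adding a
#' generator to a pipeline does not perturb the output of the others.  The
#' sub-seed is a deterministic hash of (root seed, stream offset), kept
#' within the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed integer root seed.
#' @param offset integer stream offset (one per generator).
#' @return An integer seed.
#' @keywords internal
subSeed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 100003) * 10007 + abs(as.numeric(offset)) * 7919 + 13
  as.integer(s %% 2147483647)
}

# Evaluate expr with the RNG seeded from a substream, restoring the caller's
# RNG state afterwards.
withSubstream <- function(seed, offset, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(subSeed(seed, offset))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Validate that a GRanges carries the metadata columns of a peak track.
assertPeaks <- function(peaks, arg = "peaks") {
  if (!is(peaks, "GRanges")) {
    stop(sprintf("'%s' must be a GRanges of peaks", arg), call. = FALSE)
  }
  mc <- S4Vectors::mcols(peaks)
  for (col in c("summit", "score")) {
    if (!col %in% colnames(mc)) {
      stop(sprintf("'%s' lacks required metadata column '%s'", arg, col),
           call. = FALSE)
    }
  }
  if (length(peaks)) {
    bad <- mc$summit < GenomicRanges::start(peaks) |
      mc$summit > GenomicRanges::end(peaks)
    if (any(bad)) {
      stop(sprintf("'%s' has %d summit(s) outside the peak interval",
                   arg, sum(bad)), call. = FALSE)
    }
    if (any(mc$score < 0)) {
      stop(sprintf("'%s' has negative -log10(p) scores", arg), call. = FALSE)
    }
  }
  invisible(peaks)
}
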