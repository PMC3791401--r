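# Misregulation calling from replicate expression data and the statistics
# linking binding to regulation: Fisher's exact set overlap with expected
# counts, and the one-tailed two-group Mann-Whitney U test on gene-level
# DNA occupancies (exact, tie-aware enumeration for small samples).

#' Fold change and t-test from replicate expression values
#'
#' The fold change is the ratio of group means, reported in the signed
#' convention: magnitude >= 1, with a minus sign marking downregulation in
#' the knockdown (so a ratio of 0.5 is reported as -2).  The p-value comes
#' from a two-tailed pooled two-sample Student's t-test on log2-transformed
#' replicate values, where fold effects are additive and symmetric.
#'
#' @param controlReps,kdReps positive replicate values (linear scale), >= 2
#'   each.
#' @return A list with `fold` (signed), `ratio` (kd/control), `log2fold`,
#'   `t` and `p`.
#' @export
foldChangeTest <- function(controlReps, kdReps) {
  if (length(controlReps) < 2L || length(kdReps) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  if (any(c(controlReps, kdReps) <= 0)) {
    stop("replicate values must be positive (linear scale)", call. = FALSE)
  }
  mc <- mean(controlReps)
  if (mc == 0) stop("zero mean control", call. = FALSE)
  ratio <- mean(kdReps) / mc
  fold <- if (ratio >= 1) ratio else -1 / ratio
  x <- log2(controlReps)
  y <- log2(kdReps)
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: no within-group variance
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(fold = fold, ratio = ratio, log2fold = log2(ratio),
                  t = 0, p = 1))
    }
    warning("zero within-group variance with unequal means; p set to 0")
    return(list(fold = fold, ratio = ratio, log2fold = log2(ratio),
                t = Inf, p = 0))
  }
  tt <- t.test(y, x, var.equal = TRUE)
  list(fold = fold, ratio = ratio, log2fold = log2(ratio),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving.
#'
#' @param pValues numeric p-values in [0, 1].
#' @return FDR values in [0, 1], same order as input.
#' @export
bhAdjust <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pValues, method = "BH")
}

#' Call misregulated genes from fold changes and FDRs
#'
#' A gene is `down` when its signed fold change is <= -foldCut with FDR
#' below `fdrCut`, `up` when >= +foldCut with FDR below `fdrCut`, and
#' `unaffected` otherwise (defaults: >= 1.5-fold, FDR < 10%).
#'
#' @param records `data.frame` with columns `gene_id`, `fold_change`
#'   (signed convention) and `fdr`.
#' @param foldCut minimal fold-change magnitude (default 1.5).
#' @param fdrCut FDR threshold (default 0.10, exclusive).
#' @return `records` with an added factor column `direction`.
#' @export
callMisregulated <- function(records, foldCut = 1.5, fdrCut = 0.10) {
  need <- c("gene_id", "fold_change", "fdr")
  if (!all(need %in% colnames(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sig <- records$fdr < fdrCut
  dir <- ifelse(sig & records$fold_change <= -foldCut, "down",
         ifelse(sig & records$fold_change >= foldCut, "up", "unaffected"))
  records$direction <- factor(dir, levels = c("down", "up", "unaffected"))
  records
}

#' Fisher's exact overlap of two gene sets with expected overlap
#'
#' Given two gene sets drawn from a universe of `universeN` genes, reports
#' the expected overlap under independent random draws, `|A| |B| / N`, and
#' the one-sided enrichment p-value `P(X >= observed)` from the
#' hypergeometric distribution.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universeN size of the gene universe.
#' @return A list with `n_universe`, `set_a_size`, `set_b_size`,
#'   `observed_overlap`, `expected_overlap` and `p_value`.
#' @export
fisherOverlap <- function(setA, setB, universeN) {
  setA <- unique(setA)
  setB <- unique(setB)
  nA <- length(setA)
  nB <- length(setB)
  if (nA > universeN || nB > universeN) {
    stop("set sizes exceed the universe", call. = FALSE)
  }
  obs <- length(intersect(setA, setB))
  if (obs > min(nA, nB)) {
    stop("overlap exceeds the smaller set", call. = FALSE)
  }
  p <- phyper(obs - 1L, nA, universeN - nA, nB, lower.tail = FALSE)
  list(n_universe = universeN, set_a_size = nA, set_b_size = nB,
       observed_overlap = obs, expected_overlap = nA * nB / universeN,
       p_value = p)
}

# U statistic for "set1 greater": #{x > y} + 0.5 #{x == y},
# computed from midranks.
uStatistic <- function(set1, set2) {
  r <- rank(c(set1, set2))
  sum(r[seq_along(set1)]) - length(set1) * (length(set1) + 1) / 2
}

#' One-tailed two-group Mann-Whitney U test on DNA occupancy levels
#'
#' Tests whether `set1` shows stochastically higher occupancy than `set2`
#' (one-tailed, alternative "set1 greater").  For combined sample sizes up
#' to `exactMax` the p-value is exact: the observed U is compared against
#' every possible assignment of the combined (tie-aware, mid-ranked)
#' values into the two groups.  Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' Zero occupancies can be excluded from both sets (`includeZeros =
#' FALSE`), mirroring how occupancy comparisons are run with and without
#' unbound genes.
#'
#' @param set1,set2 numeric vectors of non-negative gene-level occupancy.
#' @param includeZeros keep zero occupancies (default TRUE).
#' @param exactMax maximal combined n for the exact branch (default 20).
#' @return A list with `u_statistic`, `p_value`, `n1`, `n2`, `method`
#'   (`"exact"` or `"normal"`) and `include_zeros`.
#' @export
mannWhitneyBinding <- function(set1, set2, includeZeros = TRUE,
                               exactMax = 20L) {
  if (any(c(set1, set2) < 0)) {
    stop("occupancy levels must be >= 0", call. = FALSE)
  }
  if (!includeZeros) {
    set1 <- set1[set1 != 0]
    set2 <- set2[set2 != 0]
  }
  if (!length(set1)) stop("set1 is empty after zero removal", call. = FALSE)
  if (!length(set2)) stop("set2 is empty after zero removal", call. = FALSE)
  n1 <- length(set1)
  n2 <- length(set2)
  U <- uStatistic(set1, set2)
  if (n1 + n2 <= exactMax) {
    r <- rank(c(set1, set2))
    N <- n1 + n2
    idx <- combn(N, n1)
    uPerm <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(uPerm >= U - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    r <- rank(c(set1, set2))
    tieTab <- table(r)
    tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tieCorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2 - 0.5) / sqrt(sigma2)
      p <- pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(u_statistic = U, p_value = p, n1 = n1, n2 = n2,
       method = method, include_zeros = includeZeros)
}

#' Quantify a qPCR measurement against a standard curve
#'
#' Fits the least-squares line `ct = a log10(q) + b` through the standard
#' curve and inverts it at the observed ct.  A non-negative slope (ct not
#' decreasing with quantity) invalidates the curve.
#'
#' @param ct observed cycle-threshold value.
#' @param curvePoints `data.frame` with columns `log10_quantity` and `ct`,
#'   >= 3 rows.
#' @return The interpolated quantity (same units as the curve standards).
#' @export
quantifyFromStandardCurve <- function(ct, curvePoints) {
  need <- c("log10_quantity", "ct")
  if (!all(need %in% colnames(curvePoints))) {
    stop("curvePoints must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(curvePoints) < 3L) {
    stop("need >= 3 standard-curve points", call. = FALSE)
  }
  if (length(unique(curvePoints$log10_quantity)) < 2L) {
    stop("standard-curve quantities are degenerate", call. = FALSE)
  }
  fit <- lm(ct ~ log10_quantity, data = curvePoints)
  a <- coef(fit)[["log10_quantity"]]
  b <- coef(fit)[["(Intercept)"]]
  if (!is.finite(a) || a >= 0) {
    stop("invalid standard curve: slope must be negative", call. = FALSE)
  }
  10^((ct - b) / a)
}

#' ChIP-qPCR enrichment ratios
#'
#' `vs_igg` reports the antibody-to-IgG quantity ratio; `percent_input`
#' reports the immunoprecipitated quantity as a percentage of the input
#' chromatin, where the input was measured from an `inputFraction` aliquot
#' (e.g. 0.05 for a 5% input): `100 q_ab / (q_input / inputFraction)`.
#'
#' @param qAb antibody-ChIP quantity (> 0).
#' @param qControl IgG quantity (`vs_igg`) or input-aliquot quantity
#'   (`percent_input`); must be > 0.
#' @param mode `"vs_igg"` or `"percent_input"`.
#' @param inputFraction fraction of input chromatin the aliquot represents.
#' @return Enrichment ratio or percent of input.
#' @export
chipEnrichment <- function(qAb, qControl,
                           mode = c("vs_igg", "percent_input"),
                           inputFraction = 1) {
  mode <- match.arg(mode)
  if (qControl <= 0) stop("zero or negative control quantity", call. = FALSE)
  if (qAb < 0) stop("negative antibody quantity", call. = FALSE)
  if (mode == "vs_igg") {
    qAb / qControl
  } else {
    if (inputFraction <= 0 || inputFraction > 1) {
      stop("inputFraction must be in (0, 1]", call. = FALSE)
    }
    100 * qAb / (qControl / inputFraction)
  }
}

#' Build expression records from a simulated replicate table
#'
#' Applies [foldChangeTest()] per gene to the control/knockdown replicate
#' columns of a table (as produced by [simulateExpression()]), then
#' [bhAdjust()] across genes, returning records in the signed fold-change
#' convention ready for [callMisregulated()].
#'
#' @param replicateTable `data.frame` with `gene_id`, `ctrl_*` and `kd_*`
#'   columns holding linear-scale replicate values.
#' @return A `data.frame` with `gene_id`, `fold_change`, `p_value`, `fdr`.
#' @export
expressionRecords <- function(replicateTable) {
  ctrlCols <- grep("^ctrl_", colnames(replicateTable))
  kdCols <- grep("^kd_", colnames(replicateTable))
  if (!length(ctrlCols) || !length(kdCols)) {
    stop("table must have ctrl_* and kd_* replicate columns", call. = FALSE)
  }
  res <- lapply(seq_len(nrow(replicateTable)), function(i) {
    foldChangeTest(as.numeric(replicateTable[i, ctrlCols]),
                   as.numeric(replicateTable[i, kdCols]))
  })
  data.frame(
    gene_id = replicateTable$gene_id,
    fold_change = vapply(res, `[[`, numeric(1), "fold"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    fdr = bhAdjust(vapply(res, `[[`, numeric(1), "p")))
}
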