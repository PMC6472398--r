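## Transcriptome-level aggregation of per-gene offsets, with bootstrap
## confidence intervals, the high-coverage trend test, threshold-robustness
## and cross-dataset consistency scans.

#' Percentile bootstrap confidence interval for a fraction
#'
#' @param indicator 0/1 (or logical) vector, one element per gene.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional RNG seed; the caller's RNG state is untouched.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
bootstrapFractionCI <- function(indicator, B = 1000L, seed = NULL,
                                level = 0.95) {
  if (B < 1) stop("B must be at least 1")
  x <- as.numeric(indicator)
  n <- length(x)
  if (n < 1) stop("need at least one observation")
  a <- (1 - level) / 2
  withSeed(seed, {
    means <- colMeans(matrix(x[sample.int(n, n * B, replace = TRUE)], nrow = n))
    unname(stats::quantile(means, c(a, 1 - a)))
  })
}

aggregateOneCombo <- function(deltas, thresholds, B = 1000L, seed = NULL) {
  n <- length(deltas)
  if (n == 0L)
    return(list(status = "insufficient", primary = NA_real_,
                secondary = NA_real_, fraction = NA_real_, n_genes = 0L,
                ci_lo = NA_real_, ci_hi = NA_real_))
  top2 <- topTwoValues(deltas)
  frac <- mean(deltas == top2[1])
  ## sorted indicator: the CI depends only on (n, k), so aggregation is
  ## invariant to gene order
  ci <- bootstrapFractionCI(sort(deltas == top2[1]), B = B, seed = seed)
  if (n < thresholds$minGenes)
    return(list(status = "insufficient", primary = top2[1],
                secondary = top2[2], fraction = frac, n_genes = n,
                ci_lo = ci[1], ci_hi = ci[2]))
  status <- if (frac >= thresholds$uniqueFraction) "unique" else "ambiguous"
  secondary <- if (status == "unique") NA_real_ else top2[2]
  if (status == "ambiguous" && is.na(secondary)) {
    ## single observed offset but below the unique fraction cannot happen
    ## (fraction would be 1); guard for completeness
    secondary <- top2[1]
  }
  list(status = status, primary = top2[1], secondary = secondary,
       fraction = frac, n_genes = n, ci_lo = ci[1], ci_hi = ci[2])
}

#' Aggregate per-gene offsets into an offset table
#'
#' For each (size, frame) combination, the modal per-gene offset is called
#' `unique` when it accounts for at least `uniqueFraction` of informative
#' genes and at least `minGenes` genes contributed; with fewer genes the
#' combination is `insufficient`, otherwise `ambiguous` with the top two
#' offsets reported.  A 95% percentile bootstrap interval for the modal
#' fraction accompanies every call.
#'
#' @param results data.frame from [detectOffsets()] (rows with status other
#'   than `"informative"` are ignored).
#' @param thresholds a [selectionThresholds()] list.
#' @param sizeRange combinations to report (default 20:35, all frames).
#' @param B bootstrap resamples per combination.
#' @param seed seed for the bootstrap (combination-specific streams are
#'   derived from it).
#' @return An [OffsetTable-class] with one row per (size, frame).
#' @export
aggregateOffsets <- function(results, thresholds = selectionThresholds(),
                             sizeRange = 20:35, B = 1000L, seed = NULL) {
  thresholds <- asThresholds(thresholds)
  inf <- results[results$status == "informative", , drop = FALSE]
  grid <- expand.grid(size = as.integer(sizeRange), frame = 0:2)
  grid <- grid[order(grid$size, grid$frame), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    S <- grid$size[i]; F <- grid$frame[i]
    d <- inf$delta_prime[inf$size == S & inf$frame == F]
    s <- if (is.null(seed)) NULL else deriveSeed(seed, i)
    c(list(size = S, frame = F),
      aggregateOneCombo(d, thresholds, B = B, seed = s))
  })
  OffsetTable(do.call(rbind.data.frame, rows), strict = TRUE)
}

#' Coverage-trend test for an ambiguous (size, frame) combination
#'
#' Restricts the gene set to increasingly high coverage (average reads per
#' codon at least each cutoff), tracks the percentage of genes whose
#' per-gene offset equals the modal offset of the full set, drops cutoffs
#' retaining fewer than `minGenes` genes, and regresses percentage on
#' cutoff by ordinary least squares.  The combination is `resolved` when
#' the slope is positive and significant and the final retained percentage
#' reaches the unique-fraction threshold.
#'
#' @param coverage numeric per-gene average reads per codon (the filter
#'   statistic).
#' @param delta per-gene offsets, parallel to `coverage`.
#' @param thresholdGrid increasing coverage cutoffs (default 1,2,5,10,...,50).
#' @param thresholds a [selectionThresholds()] list.
#' @param alpha significance level for the slope (default 0.05).
#' @param modalOffset optionally force the reference offset; defaults to
#'   the modal offset of the full gene set.
#' @return list with `thresholds` (cutoffs used), `fractions` (percent),
#'   `nGenes`, `slope`, `p_value`, `resolved`, `resolved_offset`.
#' @export
coverageTrend <- function(coverage, delta,
                          thresholdGrid = c(1, 2, 5, 10, 15, 20, 25,
                                            30, 35, 40, 45, 50),
                          thresholds = selectionThresholds(),
                          alpha = 0.05, modalOffset = NULL) {
  stopifnot(length(coverage) == length(delta))
  thresholds <- asThresholds(thresholds)
  thresholdGrid <- sort(thresholdGrid)
  if (is.null(modalOffset)) modalOffset <- modalValue(delta)
  keepCut <- numeric(0); frac <- numeric(0); ns <- integer(0)
  for (cut in thresholdGrid) {
    idx <- coverage >= cut
    if (sum(idx) < thresholds$minGenes) next
    keepCut <- c(keepCut, cut)
    ns <- c(ns, sum(idx))
    frac <- c(frac, 100 * mean(delta[idx] == modalOffset))
  }
  if (length(keepCut) < 2L)
    return(list(thresholds = keepCut, fractions = frac, nGenes = ns,
                slope = NA_real_, p_value = NA_real_, resolved = FALSE,
                resolved_offset = NA_real_))
  fit <- stats::lm(frac ~ keepCut)
  slope <- unname(coef(fit)[2])
  p <- if (!is.na(slope) && sd(frac) > 0) {
    ## degenerate exact-linear series trigger a "perfect fit" caveat from
    ## summary.lm; the p-value is still the right object to report
    sm <- suppressWarnings(summary(fit))$coefficients
    if (nrow(sm) >= 2) sm[2, 4] else NA_real_
  } else NA_real_
  if (is.na(slope)) slope <- 0
  resolved <- !is.na(p) && slope > 0 && p < alpha &&
    tail(frac, 1) >= 100 * thresholds$uniqueFraction
  list(thresholds = keepCut, fractions = frac, nGenes = ns, slope = slope,
       p_value = p, resolved = resolved,
       resolved_offset = if (resolved) modalOffset else NA_real_)
}

#' Robustness of unique offset calls to threshold variation
#'
#' Re-runs detection under each start-codon ratio and re-aggregates under
#' each unique-fraction threshold; a (size, frame) combination whose call
#' is unique at the baseline thresholds is labeled `"R"` (robust) when the
#' unique call and its offset are identical under every variation, `"S"`
#' (sensitive) otherwise.  Combinations not unique at baseline are labeled
#' NA.
#'
#' @param profiles a [RiboProfileSet-class].
#' @param thresholds baseline [selectionThresholds()].
#' @param uniqueFractions unique-fraction variations (default 0.6, 0.7, 0.8).
#' @param startRatios start-codon ratio variations (default 1/10, 1/5, 1).
#' @param sizeRange fragment sizes to scan.
#' @return data.frame with `size`, `frame`, `label`.
#' @export
robustnessScan <- function(profiles, thresholds = selectionThresholds(),
                           uniqueFractions = c(0.6, 0.7, 0.8),
                           startRatios = c(1/10, 1/5, 1),
                           sizeRange = 20:35) {
  thresholds <- asThresholds(thresholds)
  detRuns <- lapply(startRatios, function(sr) {
    th <- thresholds; th$startRatio <- sr
    detectOffsets(profiles, th, sizeRange)
  })
  base <- aggregateOffsets(detectOffsets(profiles, thresholds, sizeRange),
                           thresholds, sizeRange, B = 200L, seed = 1L)
  baseRows <- offsetRows(base)
  calls <- list()
  for (det in detRuns) for (uf in uniqueFractions) {
    th <- thresholds; th$uniqueFraction <- uf
    calls[[length(calls) + 1L]] <-
      offsetRows(aggregateOffsets(det, th, sizeRange, B = 200L, seed = 1L))
  }
  label <- rep(NA_character_, nrow(baseRows))
  for (i in seq_len(nrow(baseRows))) {
    if (baseRows$status[i] != "unique") next
    same <- vapply(calls, function(cr) {
      cr$status[i] == "unique" &&
        identical(cr$primary[i], baseRows$primary[i])
    }, logical(1))
    label[i] <- if (all(same)) "R" else "S"
  }
  data.frame(size = baseRows$size, frame = baseRows$frame, label = label,
             stringsAsFactors = FALSE)
}

#' Cross-dataset consistency of unique offsets
#'
#' A unique offset in the reference table is consistent with an individual
#' dataset when that dataset's most probable offset for the same (size,
#' frame) - regardless of whether it reaches the unique threshold - is the
#' same.  Combinations consistent in fewer than `cutoff` of the datasets
#' are flagged for discard.
#'
#' @param reference an [OffsetTable-class] (typically from pooled data).
#' @param tables list of [OffsetTable-class] from individual datasets.
#' @param cutoff minimum consistent-dataset fraction (default 0.75).
#' @return data.frame with `size`, `frame`, `consistency` (fraction, NA for
#'   non-unique reference rows) and `discard` flag.
#' @export
consistencyCheck <- function(reference, tables, cutoff = 0.75) {
  ref <- offsetRows(reference)
  cons <- rep(NA_real_, nrow(ref))
  for (i in seq_len(nrow(ref))) {
    if (ref$status[i] != "unique") next
    match1 <- vapply(tables, function(tb) {
      r <- offsetRows(tb)
      j <- which(r$size == ref$size[i] & r$frame == ref$frame[i])
      if (!length(j)) return(NA)
      !is.na(r$primary[j]) && r$primary[j] == ref$primary[i]
    }, logical(1))
    match1 <- match1[!is.na(match1)]
    if (length(match1)) cons[i] <- mean(match1)
  }
  data.frame(size = ref$size, frame = ref$frame, consistency = cons,
             discard = !is.na(cons) & cons < cutoff,
             stringsAsFactors = FALSE)
}
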