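## Per-gene integer-programming optimization of the A-site offset.
##
## For one gene and one (fragment size S, frame F) track the objective is
## T(Delta) = number of reads whose anchor position, shifted by Delta toward
## the CDS interior, lands between nucleotide 4 (first nt of the second
## codon) and N_C (last nt of the stop codon).  Delta is scanned over
## {0, 3, 6, ...} up to S: shifting in codon steps preserves the frame of
## the anchor nucleotide, and the A-site must lie within the fragment.

feasibleDeltas <- function(size) seq.int(0L, as.integer(size), by = 3L)

checkDelta <- function(delta, size) {
  if (length(delta) != 1L || is.na(delta) || delta %% 3 != 0 ||
      delta < 0 || delta > size)
    stop("delta must be a multiple of 3 in [0, ", size, "], got ", delta)
  as.integer(delta)
}

shiftDirection <- function(anchor) {
  switch(anchor, five_prime = 1L, three_prime = -1L,
         stop("anchor must be 'five_prime' or 'three_prime'"))
}

#' Per-codon counts after shifting a track by an offset
#'
#' Shifts every anchor position by `delta` (toward the 3' end for 5'-anchored
#' reads, toward the 5' end for 3'-anchored reads) and sums counts into the
#' codon containing the shifted nucleotide.  Shifted positions outside
#' the interval 1..N_C are not assigned to any codon.
#'
#' @param track list with `pos` and `count` (see [trackCounts()]).
#' @param ncCds CDS length N_C in nucleotides (multiple of 3).
#' @param delta offset in nt; multiple of 3 between 0 and `size`.
#' @param size fragment size (used only to validate `delta`).
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @return numeric vector of length `ncCds / 3`.
#' @export
shiftedCodonCounts <- function(track, ncCds, delta, size = ncCds,
                               anchor = "five_prime") {
  delta <- checkDelta(delta, size)
  nCod <- ncCds %/% 3L
  out <- numeric(nCod)
  if (!length(track$pos)) return(out)
  shifted <- track$pos + shiftDirection(anchor) * delta
  keep <- shifted >= 1L & shifted <= ncCds
  if (any(keep)) {
    cod <- (shifted[keep] + 2L) %/% 3L
    agg <- rowsum(track$count[keep], cod)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Objective score of one candidate offset
#'
#' T(Delta) = total reads whose shifted anchor position lies in the window 4..N_C:
#' from the second codon through the last nucleotide of the stop codon.
#'
#' @inheritParams shiftedCodonCounts
#' @return list with `delta` and the integer score `T`.
#' @export
objectiveScore <- function(track, ncCds, delta, size = ncCds,
                           anchor = "five_prime") {
  delta <- checkDelta(delta, size)
  if (!length(track$pos)) return(list(delta = delta, T = 0))
  shifted <- track$pos + shiftDirection(anchor) * delta
  list(delta = delta, T = sum(track$count[shifted >= 4L & shifted <= ncCds]))
}

secondaryPass <- function(codonCounts, startRatio) {
  if (length(codonCounts) < 4L)
    stop("secondary criteria need at least 4 codons")
  codonCounts[1] < startRatio * mean(codonCounts[2:4]) &&
    codonCounts[2] > codonCounts[3]
}

#' Secondary selection criteria between two candidate offsets
#'
#' When the top two objective scores are too close, the candidate whose
#' shifted profile looks biologically plausible is preferred: its start-codon
#' count must be below `startRatio` times the mean count of codons 2-4 (the
#' A-site cannot sit on the start codon) and its second-codon count must
#' exceed its third-codon count (initiation enriches the second codon).  If
#' exactly one candidate passes both sub-criteria it is chosen; when both or
#' neither pass, the maximum-score candidate `deltaPrime` is kept.
#'
#' @param codonCountsPrime,codonCountsSecond per-codon counts of the two
#'   candidates after shifting (see [shiftedCodonCounts()]).
#' @param deltaPrime,deltaSecond the two candidate offsets (prime = higher
#'   score).
#' @param thresholds a [selectionThresholds()] list.
#' @return list with `delta` (the chosen offset), `passPrime`, `passSecond`.
#' @export
applySecondaryCriteria <- function(codonCountsPrime, codonCountsSecond,
                                   deltaPrime, deltaSecond,
                                   thresholds = selectionThresholds()) {
  thresholds <- asThresholds(thresholds)
  if (length(codonCountsPrime) != length(codonCountsSecond))
    stop("candidate codon-count vectors differ in length")
  p1 <- secondaryPass(codonCountsPrime, thresholds$startRatio)
  p2 <- secondaryPass(codonCountsSecond, thresholds$startRatio)
  delta <- if (p1 && !p2) deltaPrime
           else if (p2 && !p1) deltaSecond
           else deltaPrime
  list(delta = delta, passPrime = p1, passSecond = p2)
}

#' Choose between the top two offsets given their scores
#'
#' Implements the decision rule downstream of the exhaustive scan: when the
#' difference between the top two scores is at least the average number of
#' reads per codon the maximum-score offset stands; otherwise the secondary
#' criteria of [applySecondaryCriteria()] arbitrate.
#'
#' @param deltaPrime,deltaSecond top two offsets by score.
#' @param tPrime,tSecond their objective scores (tPrime >= tSecond).
#' @param avgReadsPerCodon average reads per codon of the gene's track,
#'   computed over the CDS plus one fragment length upstream.
#' @param codonCountsPrime,codonCountsSecond shifted per-codon counts of the
#'   two candidates; only consulted when the closeness test fires.
#' @param thresholds a [selectionThresholds()] list.
#' @return list with chosen `delta` and logical `secondaryApplied`.
#' @export
selectOffset <- function(deltaPrime, deltaSecond, tPrime, tSecond,
                         avgReadsPerCodon, codonCountsPrime = NULL,
                         codonCountsSecond = NULL,
                         thresholds = selectionThresholds()) {
  if (is.na(deltaSecond) || (tPrime - tSecond) >= avgReadsPerCodon)
    return(list(delta = deltaPrime, secondaryApplied = FALSE))
  sel <- applySecondaryCriteria(codonCountsPrime, codonCountsSecond,
                                deltaPrime, deltaSecond, thresholds)
  list(delta = sel$delta, secondaryApplied = TRUE)
}

## Average reads per codon: window is the CDS plus one fragment length
## upstream, divided by the number of codons.
avgReadsPerCodon <- function(track, ncCds, size) {
  if (!length(track$pos)) return(0)
  sum(track$count[track$pos >= 1L - size & track$pos <= ncCds]) / (ncCds / 3)
}

#' Gene coverage filter for one (size, frame) track
#'
#' A gene enters the per-(S,F) optimization only when its track holds more
#' than `minAvgReadsPerCodon` reads per codon on average - counted over the
#' CDS and an upstream region of one fragment length - and no more than
#' `maxMultimapFraction` of its mapped reads are multimapped.
#'
#' @param track list with `pos`, `count`.
#' @param ncCds CDS length in nt.
#' @param size fragment size.
#' @param multimapFraction the gene's multimapped-read fraction.
#' @param thresholds a [selectionThresholds()] list.
#' @return logical.
#' @export
passesGeneFilter <- function(track, ncCds, size, multimapFraction = 0,
                             thresholds = selectionThresholds()) {
  thresholds <- asThresholds(thresholds)
  if (multimapFraction > thresholds$maxMultimapFraction) return(FALSE)
  avgReadsPerCodon(track, ncCds, size) > thresholds$minAvgReadsPerCodon
}

#' Optimize the A-site offset for one gene and one (size, frame) track
#'
#' Exhaustively scans Delta in {0, 3, ..., <= S}, records the objective
#' score at each candidate, and reports the optimum Delta' with the best
#' distinct runner-up Delta''.  When the top two scores differ by less than
#' the gene's average reads per codon the secondary criteria arbitrate.
#' When all candidate scores are equal (including an all-zero track) the
#' gene is uninformative for this combination and is excluded from
#' aggregation rather than contributing an arbitrary offset.
#'
#' Exact score ties at the maximum are resolved by entering the two
#' largest-offset tied candidates into the secondary criteria; a remaining
#' tie keeps the smaller offset.
#'
#' @param track list with `pos`, `count`.
#' @param ncCds CDS length N_C in nt.
#' @param size fragment size S.
#' @param frame frame F (recorded in the result).
#' @param thresholds a [selectionThresholds()] list.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @return list with `delta_prime`, `delta_second`, `T_prime`, `T_second`,
#'   `secondary_applied`, `status` ("informative"/"uninformative").
#' @export
optimizeGeneOffset <- function(track, ncCds, size, frame,
                               thresholds = selectionThresholds(),
                               anchor = "five_prime") {
  thresholds <- asThresholds(thresholds)
  deltas <- feasibleDeltas(size)
  dir <- shiftDirection(anchor)
  if (length(track$pos)) {
    ts <- vapply(deltas, function(d) {
      shifted <- track$pos + dir * d
      sum(track$count[shifted >= 4L & shifted <= ncCds])
    }, numeric(1))
  } else ts <- numeric(length(deltas))

  if (length(unique(ts)) == 1L) {
    return(list(delta_prime = NA_integer_, delta_second = NA_integer_,
                T_prime = ts[1], T_second = ts[1],
                secondary_applied = FALSE, status = "uninformative"))
  }
  avg <- avgReadsPerCodon(track, ncCds, size)
  maxT <- max(ts)
  tied <- deltas[ts == maxT]
  if (length(tied) >= 2L) {
    ## top-score tie: the two largest tied offsets enter the secondary
    ## criteria; if they do not decide, keep the smaller of the two
    cand <- sort(tied, decreasing = TRUE)[1:2]
    dp <- cand[1]; ds <- cand[2]
    tp <- maxT; tsnd <- maxT
    cp <- shiftedCodonCounts(track, ncCds, dp, size, anchor)
    cs <- shiftedCodonCounts(track, ncCds, ds, size, anchor)
    sel <- applySecondaryCriteria(cp, cs, dp, ds, thresholds)
    delta <- if (xor(sel$passPrime, sel$passSecond)) sel$delta else min(dp, ds)
    applied <- TRUE
  } else {
    dp <- tied
    rest <- ts[deltas != dp]
    restD <- deltas[deltas != dp]
    tsnd <- max(rest)
    ds <- min(restD[rest == tsnd])   # runner-up ties -> smaller offset
    tp <- maxT
    if ((tp - tsnd) < avg) {
      cp <- shiftedCodonCounts(track, ncCds, dp, size, anchor)
      cs <- shiftedCodonCounts(track, ncCds, ds, size, anchor)
      sel <- selectOffset(dp, ds, tp, tsnd, avg, cp, cs, thresholds)
      delta <- sel$delta
      applied <- sel$secondaryApplied
    } else {
      delta <- dp
      applied <- FALSE
    }
  }
  ## report the chosen offset as Delta', the other candidate as Delta''
  if (delta != dp) { ds2 <- dp; tp2 <- tsnd; ts2 <- tp }
  else { ds2 <- ds; tp2 <- tp; ts2 <- tsnd }
  list(delta_prime = as.integer(delta), delta_second = as.integer(ds2),
       T_prime = tp2, T_second = ts2,
       secondary_applied = applied, status = "informative")
}

#' Detect per-gene offsets across the full (size, frame) grid
#'
#' Runs the gene filter and per-gene optimization for every gene and every
#' (S, F) combination in `sizeRange` x frames 0-2, yielding exactly
#' `3 * length(sizeRange)` optimization slots per gene (48 for the default
#' 20-35 nt range).  Genes failing the coverage filter for a combination
#' are reported with status `"filtered"`; genes whose candidate scores are
#' all equal with status `"uninformative"`.  Only `"informative"` rows
#' carry offsets and enter aggregation.
#'
#' @param profiles a [RiboProfileSet-class].
#' @param thresholds a [selectionThresholds()] list.
#' @param sizeRange integer vector of fragment sizes (default 20:35).
#' @return data.frame with columns `gene_id`, `size`, `frame`,
#'   `delta_prime`, `delta_second`, `T_prime`, `T_second`, `coverage`
#'   (average reads per codon in the filter window), `secondary_applied`,
#'   `status`.
#' @export
detectOffsets <- function(profiles, thresholds = selectionThresholds(),
                          sizeRange = 20:35) {
  stopifnot(is(profiles, "RiboProfileSet"))
  thresholds <- asThresholds(thresholds)
  info <- geneInfo(profiles)
  anchor <- anchorType(profiles)
  mm <- profiles@multimapFraction
  dt <- profiles@counts
  ## split tracks once: named list "gene|size|frame" -> list(pos, count)
  sub <- dt[size %in% sizeRange]
  trk <- if (nrow(sub)) {
    split(sub, by = c("gene_id", "size", "frame"), sep = "|")
  } else list()
  frames <- 0:2
  nGenes <- nrow(info)
  out <- vector("list", nGenes * length(sizeRange) * 3L)
  k <- 0L
  for (gi in seq_len(nGenes)) {
    g <- info$gene_id[gi]
    ncCds <- info$cds_length[gi]
    for (S in sizeRange) for (F in frames) {
      k <- k + 1L
      key <- paste(g, S, F, sep = "|")
      tr <- trk[[key]]
      track <- if (is.null(tr)) list(pos = integer(), count = numeric())
               else list(pos = tr$pos, count = tr$count)
      cov <- avgReadsPerCodon(track, ncCds, S)
      if (!passesGeneFilter(track, ncCds, S, mm[[g]], thresholds)) {
        out[[k]] <- list(g, S, F, NA_integer_, NA_integer_, NA_real_,
                         NA_real_, cov, FALSE, "filtered")
        next
      }
      r <- optimizeGeneOffset(track, ncCds, S, F, thresholds, anchor)
      out[[k]] <- list(g, S, F, r$delta_prime, r$delta_second, r$T_prime,
                       r$T_second, cov, r$secondary_applied, r$status)
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setnames(res, c("gene_id", "size", "frame", "delta_prime",
                              "delta_second", "T_prime", "T_second",
                              "coverage", "secondary_applied", "status"))
  as.data.frame(res)
}
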