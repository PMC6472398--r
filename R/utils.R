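## Small shared helpers.

#' Event index of an (S, F) combination
#'
#' Fragment size / frame pairs are ordered (20,0), (20,1), (20,2), (21,0),
#' ..., (35,2); the index is 0-based so (28,0) is event 24.
#'
#' @param size fragment size, 20-35 nt.
#' @param frame frame 0-2.
#' @return integer 0-based event index.
#' @export
sfEventIndex <- function(size, frame) {
  size <- as.integer(size); frame <- as.integer(frame)
  stopifnot(all(size >= 20L & size <= 35L), all(frame %in% 0:2))
  (size - 20L) * 3L + frame
}

#' The 48-event (size, frame) grid in event order
#' @return data.frame with columns `size` (20-35) and `frame` (0-2).
#' @export
sfEventGrid <- function() {
  data.frame(size = rep(20:35, each = 3L), frame = rep(0:2, 16L))
}

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
## state afterwards.  seed = NULL uses (and advances) the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Pipeline stages draw their own seeds from one master seed by a fixed
#' hash so that each stage is individually reproducible.
#'
#' @param master integer master seed.
#' @param stage integer or character stage label.
#' @return integer seed below 2^31.
#' @export
deriveSeed <- function(master, stage) {
  s <- if (is.character(stage)) sum(utf8ToInt(stage)) else as.integer(stage)
  as.integer((as.numeric(master) * 7919 + s * 104729) %% 2147483647)
}

## Most frequent value; ties broken toward the smallest.
modalValue <- function(x) {
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  vals <- as.numeric(names(tab))
  vals[order(-as.numeric(tab), vals)][1]
}

## Top two most frequent values (ties toward smaller), padded with NA.
topTwoValues <- function(x) {
  if (!length(x)) return(c(NA_real_, NA_real_))
  tab <- table(x)
  vals <- as.numeric(names(tab))
  ord <- order(-as.numeric(tab), vals)
  out <- vals[ord]
  c(out[1], if (length(out) >= 2) out[2] else NA_real_)
}

#' Selection thresholds for offset detection and aggregation
#'
#' Bundles the tunable thresholds of the method: the gene-coverage filter
#' (average reads per codon per fragment size per frame), the start-codon
#' ratio of the secondary selection criteria, the unique-call gene fraction,
#' and the minimum number of contributing genes.
#'
#' @param minAvgReadsPerCodon genes enter the per-(S,F) optimization only
#'   when their track holds more than this many reads per codon on average,
#'   counted over the CDS plus an upstream region of one fragment length
#'   (default 1).
#' @param startRatio a candidate offset passes the secondary criteria only
#'   if its start-codon count is below `startRatio` times the mean count of
#'   codons 2-4 (default 1/5).
#' @param uniqueFraction minimum fraction of genes sharing the modal offset
#'   for a unique call (default 0.70).
#' @param minGenes minimum number of contributing genes (default 10).
#' @param maxMultimapFraction genes with a larger multimapped-read fraction
#'   are discarded (default 0.01).
#' @return A named list of class `SelectionThresholds`.
#' @export
selectionThresholds <- function(minAvgReadsPerCodon = 1, startRatio = 1/5,
                                uniqueFraction = 0.70, minGenes = 10L,
                                maxMultimapFraction = 0.01) {
  stopifnot(minAvgReadsPerCodon > 0, startRatio > 0,
            uniqueFraction > 0, uniqueFraction <= 1, minGenes >= 1)
  structure(list(minAvgReadsPerCodon = minAvgReadsPerCodon,
                 startRatio = startRatio,
                 uniqueFraction = uniqueFraction,
                 minGenes = as.integer(minGenes),
                 maxMultimapFraction = maxMultimapFraction),
            class = "SelectionThresholds")
}

asThresholds <- function(x) {
  if (inherits(x, "SelectionThresholds")) return(x)
  do.call(selectionThresholds, as.list(x))
}
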