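## Central S4 containers.
##
## Coordinate convention used everywhere: CDS-anchored, 1-based.  x = 1 is the
## first nucleotide of the start codon, upstream positions are 0, -1, -2, ...,
## and the CDS length N_C includes the stop codon.  The frame of a position is
## (x - 1) mod 3 with the mathematical (always non-negative) modulus, so frames
## are continuous across the start boundary.

#' Collection of gene (transcript) models
#'
#' Holds per-gene CDS geometry - CDS length in nucleotides (stop codon
#' included), number of codons, upstream/downstream pads - plus, optionally,
#' the CDS nucleotide sequences and the genomic CDS ranges used to project
#' aligned reads into transcript coordinates.
#'
#' @slot info data.frame with columns `gene_id`, `cds_length`, `n_codons`,
#'   `upstream_pad`, `downstream_pad`, `is_monocistronic`.
#' @slot sequences A [Biostrings::DNAStringSet] of CDS sequences (possibly
#'   empty) named by gene id; each sequence has length `cds_length`.
#' @slot ranges A [GenomicRanges::GRangesList] of CDS parts per gene
#'   (possibly empty), used only when reads are imported from genomic
#'   alignments.
#' @exportClass GeneModelSet
setClass("GeneModelSet",
         representation(info = "data.frame", sequences = "ANY", ranges = "ANY"))

setValidity("GeneModelSet", function(object) {
  info <- object@info
  need <- c("gene_id", "cds_length", "n_codons", "upstream_pad",
            "downstream_pad", "is_monocistronic")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(info$gene_id)) return("duplicated gene ids")
  if (any(info$cds_length %% 3L != 0L))
    return("all CDS lengths must be divisible by 3")
  if (any(info$cds_length < 9L))
    return("CDS length must be at least 9 nt (3 codons)")
  if (any(info$n_codons * 3L != info$cds_length))
    return("n_codons inconsistent with cds_length")
  if (any(info$upstream_pad < 0L) || any(info$downstream_pad < 0L))
    return("pads must be non-negative")
  if (length(object@sequences)) {
    if (!all(names(object@sequences) %in% info$gene_id))
      return("sequence names not among gene ids")
    w <- Biostrings::width(object@sequences)
    exp <- info$cds_length[match(names(object@sequences), info$gene_id)]
    if (any(w != exp)) return("sequence widths differ from cds_length")
  }
  TRUE
})

#' Construct a GeneModelSet
#'
#' @param gene_id character vector of gene identifiers.
#' @param cds_length integer CDS lengths in nucleotides (multiples of 3,
#'   stop codon included).
#' @param upstream_pad,downstream_pad non-negative pad sizes in nucleotides;
#'   recycled across genes.
#' @param is_monocistronic logical, recycled.
#' @param sequences optional [Biostrings::DNAStringSet] (or named character
#'   vector) of CDS sequences.
#' @param ranges optional [GenomicRanges::GRangesList] of genomic CDS parts.
#' @return A [GeneModelSet-class] object.
#' @export
GeneModelSet <- function(gene_id, cds_length, upstream_pad = 40L,
                         downstream_pad = 0L, is_monocistronic = TRUE,
                         sequences = NULL, ranges = NULL) {
  n <- length(gene_id)
  info <- data.frame(
    gene_id = as.character(gene_id),
    cds_length = as.integer(cds_length),
    n_codons = as.integer(cds_length) %/% 3L,
    upstream_pad = rep_len(as.integer(upstream_pad), n),
    downstream_pad = rep_len(as.integer(downstream_pad), n),
    is_monocistronic = rep_len(as.logical(is_monocistronic), n),
    stringsAsFactors = FALSE
  )
  if (is.null(sequences)) {
    sequences <- Biostrings::DNAStringSet()
  } else if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(ranges)) ranges <- GenomicRanges::GRangesList()
  new("GeneModelSet", info = info, sequences = sequences, ranges = ranges)
}

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", nrow(object@info), "genes\n")
  cat("  CDS length range:", paste(range(object@info$cds_length),
                                   collapse = "-"), "nt\n")
  cat("  sequences:", length(object@sequences), "| genomic ranges:",
      length(object@ranges), "\n")
})

#' 5'-anchored footprint count profiles for a set of genes
#'
#' The canonical container for Ribo-Seq read positions.  Counts are stored
#' sparsely as a table keyed by (gene_id, size, frame, pos), where `pos` is
#' the CDS-anchored coordinate of the anchor nucleotide (5' end by default)
#' and `frame = (pos - 1) mod 3` for the five-prime anchor.
#'
#' @slot counts data.table with columns `gene_id`, `size`, `frame`, `pos`,
#'   `count` (positive integer counts).
#' @slot genes A [GeneModelSet-class].
#' @slot anchor `"five_prime"` or `"three_prime"`.
#' @slot multimapFraction named numeric, per-gene fraction of multimapped
#'   reads between 0 and 1.
#' @slot totalMappedReads named numeric, per-gene total mapped read count.
#' @exportClass RiboProfileSet
setClass("RiboProfileSet",
         representation(counts = "ANY", genes = "GeneModelSet",
                        anchor = "character", multimapFraction = "numeric",
                        totalMappedReads = "numeric"))

setValidity("RiboProfileSet", function(object) {
  dt <- object@counts
  if (!data.table::is.data.table(dt) ||
      !all(c("gene_id", "size", "frame", "pos", "count") %in% names(dt)))
    return("counts must be a data.table with gene_id, size, frame, pos, count")
  if (!object@anchor %in% c("five_prime", "three_prime"))
    return("anchor must be 'five_prime' or 'three_prime'")
  if (nrow(dt)) {
    if (any(dt$count < 0)) return("negative counts")
    if (any(dt$count != floor(dt$count))) return("non-integer counts")
    bad <- dt$frame != (dt$pos - 1L) %% 3L
    if (any(bad))
      return(sprintf("%d rows violate frame = (pos - 1) mod 3", sum(bad)))
    if (!all(unique(dt$gene_id) %in% object@genes@info$gene_id))
      return("counts reference unknown gene ids")
  }
  TRUE
})

#' Construct a RiboProfileSet
#'
#' @param counts data.frame/data.table with columns `gene_id`, `size`,
#'   `frame`, `pos`, `count`; rows with zero count are dropped and duplicate
#'   keys are summed.
#' @param genes A [GeneModelSet-class] covering every gene in `counts`.
#' @param anchor `"five_prime"` (default) or `"three_prime"`.
#' @param multimapFraction optional named per-gene multimapped-read fraction;
#'   genes not named default to 0.
#' @param totalMappedReads optional named per-gene totals; defaults to the
#'   sum of track counts per gene.
#' @return A [RiboProfileSet-class].
#' @export
RiboProfileSet <- function(counts, genes, anchor = "five_prime",
                           multimapFraction = NULL, totalMappedReads = NULL) {
  dt <- data.table::as.data.table(counts)
  dt <- dt[, .(gene_id = as.character(gene_id), size = as.integer(size),
               frame = as.integer(frame), pos = as.integer(pos),
               count = as.numeric(count))]
  dt <- dt[count != 0]
  if (nrow(dt)) {
    dt <- dt[, .(count = sum(count)), by = .(gene_id, size, frame, pos)]
  }
  data.table::setkeyv(dt, c("gene_id", "size", "frame", "pos"))
  ids <- genes@info$gene_id
  mm <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(multimapFraction)) {
    mm[names(multimapFraction)] <- as.numeric(multimapFraction)
  }
  if (is.null(totalMappedReads)) {
    tot <- stats::setNames(rep(0, length(ids)), ids)
    if (nrow(dt)) {
      agg <- dt[, .(n = sum(count)), by = gene_id]
      tot[agg$gene_id] <- agg$n
    }
  } else {
    tot <- stats::setNames(rep(0, length(ids)), ids)
    tot[names(totalMappedReads)] <- as.numeric(totalMappedReads)
  }
  new("RiboProfileSet", counts = dt, genes = genes, anchor = anchor,
      multimapFraction = mm, totalMappedReads = tot)
}

setMethod("show", "RiboProfileSet", function(object) {
  dt <- object@counts
  cat("RiboProfileSet:", length(unique(dt$gene_id)), "genes with reads /",
      nrow(object@genes@info), "genes;",
      format(sum(dt$count), big.mark = ","), "reads;",
      "anchor:", object@anchor, "\n")
  if (nrow(dt))
    cat("  fragment sizes:", paste(range(dt$size), collapse = "-"),
        "nt; frames:", paste(sort(unique(dt$frame)), collapse = ","), "\n")
})

#' Transcriptome-level offset table
#'
#' One row per (fragment size, frame) combination with the aggregated A-site
#' offset call: `unique` (one offset explains at least the unique-fraction
#' threshold of per-gene optima over at least the minimum number of genes),
#' `ambiguous` (top two offsets reported), or `insufficient` (too few genes).
#'
#' @slot rows data.frame with columns `size`, `frame`, `status`, `primary`,
#'   `secondary`, `fraction`, `n_genes`, `ci_lo`, `ci_hi`.
#' @slot strict logical; when TRUE every stored offset must be a non-negative
#'   multiple of 3 no larger than the fragment size (the integer-programming
#'   constraints).  Baseline literature methods with nucleotide-resolution
#'   offsets unset it.
#' @exportClass OffsetTable
setClass("OffsetTable", representation(rows = "data.frame", strict = "logical"))

setValidity("OffsetTable", function(object) {
  df <- object@rows
  need <- c("size", "frame", "status", "primary", "secondary", "fraction",
            "n_genes", "ci_lo", "ci_hi")
  if (!all(need %in% names(df)))
    return(paste("rows must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df[, c("size", "frame")])) return("duplicated (size, frame)")
  if (!all(df$status %in% c("unique", "ambiguous", "insufficient")))
    return("status must be unique/ambiguous/insufficient")
  off <- c(df$primary, df$secondary)
  s2 <- c(df$size, df$size)
  ok <- is.na(off) | (off >= 0 & off <= s2)
  if (!all(ok)) return("offsets must lie in [0, size]")
  if (isTRUE(object@strict)) {
    ok3 <- is.na(off) | off %% 3 == 0
    if (!all(ok3)) return("offsets must be multiples of 3")
  }
  amb <- df$status == "ambiguous"
  if (any(amb & (is.na(df$primary) | is.na(df$secondary))))
    return("ambiguous rows need both primary and secondary offsets")
  if (any(df$status == "unique" & is.na(df$primary)))
    return("unique rows need a primary offset")
  TRUE
})

#' Construct an OffsetTable
#'
#' @param rows data.frame as described in [OffsetTable-class]; missing
#'   diagnostic columns (`fraction`, `n_genes`, `ci_lo`, `ci_hi`,
#'   `secondary`) are filled with NA.
#' @param strict enforce the multiple-of-3 offset constraint (default TRUE).
#' @return An [OffsetTable-class].
#' @export
OffsetTable <- function(rows, strict = TRUE) {
  rows <- as.data.frame(rows)
  for (col in c("secondary", "fraction", "ci_lo", "ci_hi"))
    if (is.null(rows[[col]])) rows[[col]] <- NA_real_
  if (is.null(rows$n_genes)) rows$n_genes <- NA_integer_
  rows$size <- as.integer(rows$size)
  rows$frame <- as.integer(rows$frame)
  rows$primary <- as.numeric(rows$primary)
  rows$secondary <- as.numeric(rows$secondary)
  rows <- rows[order(rows$size, rows$frame),
               c("size", "frame", "status", "primary", "secondary",
                 "fraction", "n_genes", "ci_lo", "ci_hi")]
  rownames(rows) <- NULL
  new("OffsetTable", rows = rows, strict = strict)
}

setMethod("show", "OffsetTable", function(object) {
  df <- object@rows
  cat("OffsetTable:", nrow(df), "(size, frame) combinations;",
      sum(df$status == "unique"), "unique,",
      sum(df$status == "ambiguous"), "ambiguous,",
      sum(df$status == "insufficient"), "insufficient\n")
  wide <- offsetTableWide(object)
  print(wide, row.names = FALSE)
})

#' Probability distribution over the 48 ordered (size, frame) events
#'
#' Footprint (S, F) classes are treated as 48 ordered events (20,0), (20,1),
#' (20,2), ..., (35,2).  A Poisson pmf with parameter `lam` is index-shifted
#' so that its mode lands on a chosen event (default (28,0), event index 24),
#' truncated to the 48 events and renormalized.
#'
#' @slot lam Poisson parameter.
#' @slot pmf numeric length 48, sums to 1, named "S_F".
#' @slot events data.frame with `size`, `frame` in event order.
#' @slot modeEvent integer c(size, frame) of the intended mode.
#' @exportClass SFDistribution
setClass("SFDistribution",
         representation(lam = "numeric", pmf = "numeric",
                        events = "data.frame", modeEvent = "integer"))

setValidity("SFDistribution", function(object) {
  if (length(object@pmf) != 48L) return("pmf must have length 48")
  if (abs(sum(object@pmf) - 1) > 1e-9) return("pmf must sum to 1")
  if (any(object@pmf < 0)) return("negative pmf")
  idx <- sfEventIndex(object@modeEvent[1], object@modeEvent[2])
  if (object@pmf[idx + 1L] < max(object@pmf) - 1e-12)
    return("pmf is not maximal at the mode event")
  TRUE
})

setMethod("show", "SFDistribution", function(object) {
  cat("SFDistribution over 48 (size, frame) events; lambda =", object@lam,
      "; mode at (", object@modeEvent[1], ",", object@modeEvent[2], ")\n")
  top <- order(object@pmf, decreasing = TRUE)[1:3]
  cat("  top events:", paste(sprintf("%s=%.3f", names(object@pmf)[top],
                                     object@pmf[top]), collapse = ", "), "\n")
})

#' Per-codon A-site profiles for a set of genes
#'
#' @slot values named list, one numeric vector per gene of length
#'   `n_codons`; non-negative, integer except for the center-weighted method.
#' @slot method name of the A-site assignment method that produced it.
#' @slot genes the [GeneModelSet-class] the profiles refer to.
#' @exportClass AsiteProfileSet
setClass("AsiteProfileSet",
         representation(values = "list", method = "character",
                        genes = "GeneModelSet"))

setValidity("AsiteProfileSet", function(object) {
  info <- object@genes@info
  nc <- stats::setNames(info$n_codons, info$gene_id)
  for (g in names(object@values)) {
    v <- object@values[[g]]
    if (is.na(nc[g])) return(paste("unknown gene", g))
    if (length(v) != nc[g]) return(paste("wrong profile length for", g))
    if (any(v < 0)) return(paste("negative A-site values for", g))
  }
  TRUE
})

setMethod("show", "AsiteProfileSet", function(object) {
  cat("AsiteProfileSet:", length(object@values), "genes; method:",
      object@method, ";", format(round(sum(unlist(object@values))),
                                 big.mark = ","), "assigned reads\n")
})
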