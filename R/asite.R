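## A-site profile construction: apply an offset table (ours or a baseline
## method's) to 5'-anchored profiles, normalize densities, and summarize
## metagene-wise.

#' Build per-codon A-site profiles from 5' profiles and an offset table
#'
#' Each read at anchor position x in track (S, F) is moved to the codon
#' containing nucleotide x + Delta(S, F) (x - Delta for 3'-anchored
#' profiles); shifted positions outside the CDS are discarded.  Ambiguous
#' and insufficient combinations contribute nothing when `dropAmbiguous`,
#' and combinations listed in `dropFlagged` - by default (27,1) and (27,2),
#' the combinations most often inconsistent across datasets - are always
#' excluded.  The P-site profile is obtained with `site = "P"`, which
#' applies Delta - 3 (one codon toward the 5' end).
#'
#' @param profiles a [RiboProfileSet-class].
#' @param table an [OffsetTable-class].
#' @param dropAmbiguous drop non-unique combinations (default TRUE).
#' @param dropFlagged list of c(size, frame) pairs to exclude; default
#'   `list(c(27,1), c(27,2))`.  Use `list()` to keep everything.
#' @param site `"A"` (default) or `"P"`.
#' @param method label recorded on the result.
#' @return An [AsiteProfileSet-class] covering every gene of the profile
#'   set (genes without retained reads get all-zero vectors).
#' @export
buildAsiteProfile <- function(profiles, table, dropAmbiguous = TRUE,
                              dropFlagged = list(c(27L, 1L), c(27L, 2L)),
                              site = c("A", "P"), method = "ip") {
  stopifnot(is(profiles, "RiboProfileSet"), is(table, "OffsetTable"))
  site <- match.arg(site)
  rows <- offsetRows(table)
  map <- data.table::as.data.table(rows[, c("size", "frame", "status",
                                            "primary")])
  if (dropAmbiguous) map <- map[status == "unique"]
  map <- map[!is.na(primary)]
  if (length(dropFlagged)) {
    fl <- data.table::rbindlist(lapply(dropFlagged, function(p)
      data.table::data.table(size = as.integer(p[1]),
                             frame = as.integer(p[2]))))
    map <- map[!fl, on = c("size", "frame")]
  }
  if (site == "P") map[, primary := primary - 3]
  info <- geneInfo(profiles)
  dir <- shiftDirection(anchorType(profiles))
  dt <- profiles@counts[map[, .(size, frame, primary)],
                        on = c("size", "frame"), nomatch = NULL]
  vals <- lapply(stats::setNames(info$gene_id, info$gene_id),
                 function(g) numeric(info$n_codons[match(g, info$gene_id)]))
  if (nrow(dt)) {
    dt[, pos := pos + dir * as.integer(primary)]
    dt <- dt[pos >= 1L]
    lens <- data.table::as.data.table(info[, c("gene_id", "cds_length")])
    dt <- dt[lens, on = "gene_id", nomatch = NULL][pos <= cds_length]
    if (nrow(dt)) {
      dt[, codon := (pos + 2L) %/% 3L]
      agg <- dt[, .(value = sum(count)), by = .(gene_id, codon)]
      for (g in unique(agg$gene_id)) {
        sub <- agg[gene_id == g]
        vals[[g]][sub$codon] <- sub$value
      }
    }
  }
  new("AsiteProfileSet", values = vals, method = method,
      genes = profiles@genes)
}

#' Offset tables of baseline A-site assignment rules
#'
#' Literature heuristics used for comparison: a constant 15 nt (or 18 nt)
#' offset applied to fragments of 27-30 nt; the frame-specific
#' near-neighbor offsets (15/14/16 for sizes 28-29 and 15/17/16 for size
#' 30, frames 0/1/2); the mESC length-specific offsets (15 nt for 29-30,
#' 16 nt for 31-33, 17 nt for 34-35); and a constant 15 nt over 25-35 nt
#' as used in mESC studies.  Combinations outside each rule's size range
#' are marked insufficient, so their reads are dropped.
#'
#' @param method one of `"const15"`, `"const18"`, `"hussmann_frame"`,
#'   `"ingolia_mesc"`, `"const15_wide"`.
#' @param sizeRange optional override of the rule's size range (constant
#'   rules only).
#' @return An [OffsetTable-class] (non-strict: some rules use offsets that
#'   are not multiples of 3).
#' @export
baselineOffsetTable <- function(method = c("const15", "const18",
                                           "hussmann_frame", "ingolia_mesc",
                                           "const15_wide"),
                                sizeRange = NULL) {
  method <- match.arg(method)
  cell <- function(size, frame, off)
    data.frame(size = size, frame = frame, status = "unique", primary = off)
  rows <- switch(method,
    const15 = {
      r <- if (is.null(sizeRange)) 27:30 else sizeRange
      do.call(rbind, lapply(r, function(s)
        do.call(rbind, lapply(0:2, function(f) cell(s, f, 15)))))
    },
    const18 = {
      r <- if (is.null(sizeRange)) 27:30 else sizeRange
      do.call(rbind, lapply(r, function(s)
        do.call(rbind, lapply(0:2, function(f) cell(s, f, 18)))))
    },
    const15_wide = {
      r <- if (is.null(sizeRange)) 25:35 else sizeRange
      do.call(rbind, lapply(r, function(s)
        do.call(rbind, lapply(0:2, function(f) cell(s, f, 15)))))
    },
    hussmann_frame = rbind(
      cell(28L, 0L, 15), cell(28L, 1L, 14), cell(28L, 2L, 16),
      cell(29L, 0L, 15), cell(29L, 1L, 14), cell(29L, 2L, 16),
      cell(30L, 0L, 15), cell(30L, 1L, 17), cell(30L, 2L, 16)),
    ingolia_mesc = do.call(rbind, lapply(29:35, function(s) {
      off <- if (s <= 30L) 15 else if (s <= 33L) 16 else 17
      do.call(rbind, lapply(0:2, function(f) cell(s, f, off)))
    })))
  grid <- expand.grid(size = 20:35, frame = 0:2)
  miss <- !paste(grid$size, grid$frame) %in% paste(rows$size, rows$frame)
  if (any(miss))
    rows <- rbind(rows, data.frame(size = grid$size[miss],
                                   frame = grid$frame[miss],
                                   status = "insufficient",
                                   primary = NA_real_))
  OffsetTable(rows, strict = FALSE)
}

#' Center-weighted A-site profiles
#'
#' For reads longer than 23 nt, 11 nt are trimmed from both ends and one
#' read-unit of density is spread uniformly over the remaining
#' S - 22 central nucleotides; nucleotide densities are then summed into
#' codons.  Reads of 23 nt or shorter contribute nothing.
#'
#' @param profiles a [RiboProfileSet-class] (5'-anchored).
#' @return An [AsiteProfileSet-class] (fractional values); attribute
#'   `outside_mass` holds the density falling outside the CDS.
#' @export
centerWeightedProfile <- function(profiles) {
  stopifnot(is(profiles, "RiboProfileSet"),
            anchorType(profiles) == "five_prime")
  info <- geneInfo(profiles)
  dt <- profiles@counts[size > 23L]
  vals <- lapply(stats::setNames(info$gene_id, info$gene_id),
                 function(g) numeric(info$n_codons[match(g, info$gene_id)]))
  outside <- 0
  if (nrow(dt)) {
    span <- dt$size - 22L
    expanded <- data.table::data.table(
      gene_id = rep(dt$gene_id, span),
      nt = unlist(lapply(seq_len(nrow(dt)), function(i)
        (dt$pos[i] + 11L):(dt$pos[i] + dt$size[i] - 12L))),
      w = rep(dt$count / span, span))
    lens <- data.table::as.data.table(info[, c("gene_id", "cds_length")])
    expanded <- expanded[lens, on = "gene_id", nomatch = NULL]
    inCds <- expanded$nt >= 1L & expanded$nt <= expanded$cds_length
    outside <- sum(expanded$w[!inCds])
    expanded <- expanded[inCds]
    if (nrow(expanded)) {
      expanded[, codon := (nt + 2L) %/% 3L]
      agg <- expanded[, .(value = sum(w)), by = .(gene_id, codon)]
      for (g in unique(agg$gene_id)) {
        sub <- agg[gene_id == g]
        vals[[g]][sub$codon] <- sub$value
      }
    }
  }
  out <- new("AsiteProfileSet", values = vals, method = "center_weighted",
             genes = profiles@genes)
  attr(out, "outside_mass") <- outside
  out
}

#' Normalized per-codon ribosome density
#'
#' Divides each codon's value by the mean over all CDS codons, so the
#' output averages 1 over the gene.  All-zero profiles are a hard error:
#' callers must filter unexpressed genes first.
#'
#' @param x a numeric per-codon vector or an [AsiteProfileSet-class].
#' @param ... unused.
#' @return A numeric vector, or (for a profile set) a named list of
#'   normalized vectors in which all-zero genes are dropped.
#' @export
setGeneric("normalizedDensity", function(x, ...)
  standardGeneric("normalizedDensity"))

#' @rdname normalizedDensity
setMethod("normalizedDensity", "numeric", function(x, ...) {
  m <- mean(x)
  if (m == 0) stop("cannot normalize an all-zero profile")
  x / m
})

#' @rdname normalizedDensity
setMethod("normalizedDensity", "AsiteProfileSet", function(x, ...) {
  vals <- asiteValues(x)
  keep <- vapply(vals, function(v) sum(v) > 0, logical(1))
  lapply(vals[keep], function(v) v / mean(v))
})

#' Metagene density profile
#'
#' Positional mean of normalized per-codon densities across genes, aligned
#' at the start codon (position 1 = start codon) or at the stop codon
#' (position 0 = stop codon, negative positions inside the CDS).  Genes
#' shorter than the window contribute only their available positions.
#'
#' @param asites an [AsiteProfileSet-class] or a named list of normalized
#'   density vectors.
#' @param alignAt `"start"` or `"stop"`.
#' @param windowCodons window width in codons (default 50).
#' @return data.frame with `position`, `mean_density`, `n_genes`.
#' @export
metageneDensity <- function(asites, alignAt = c("start", "stop"),
                            windowCodons = 50L) {
  alignAt <- match.arg(alignAt)
  dens <- if (is(asites, "AsiteProfileSet")) normalizedDensity(asites)
          else asites
  if (!length(dens)) stop("no genes with reads to average")
  w <- as.integer(windowCodons)
  sums <- numeric(w); ns <- integer(w)
  for (v in dens) {
    L <- length(v)
    k <- min(w, L)
    piece <- if (alignAt == "start") v[seq_len(k)] else v[(L - k + 1L):L]
    idx <- if (alignAt == "start") seq_len(k) else (w - k + 1L):w
    sums[idx] <- sums[idx] + piece
    ns[idx] <- ns[idx] + 1L
  }
  position <- if (alignAt == "start") seq_len(w) else -(w - 1L):0L
  keep <- ns > 0L
  data.frame(position = position[keep], mean_density = sums[keep] / ns[keep],
             n_genes = ns[keep])
}
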