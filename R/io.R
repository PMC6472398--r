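## Readers and writers: gene annotations (GFF3/GTF/BED + FASTA), alignments
## (SAM/BAM), and the two canonical TSV formats - the long profile table
## (gene_id, fragment_size, frame, position, count) and the wide offset
## table (one row per fragment size, one column per frame, "a/b" for
## ambiguous calls, NA for insufficient ones).

#' Load gene models from an annotation file
#'
#' Imports a GFF3/GTF/BED annotation with `rtracklayer::import()`, joins
#' CDS features per transcript, keeps the longest-CDS isoform per gene,
#' excludes transcripts whose joined CDS length is not a multiple of 3
#' (counted in the `excluded` attribute), and, when a FASTA file is given,
#' attaches CDS sequences.  The FASTA may contain either the CDS sequences
#' themselves (named by gene id) or the genome (names matching annotation
#' seqnames), in which case CDS parts are extracted, spliced and
#' reverse-complemented as needed.
#'
#' @param annotationPath GFF3/GTF/BED file.
#' @param fastaPath optional FASTA file.
#' @param upstreamPad,downstreamPad pads in nt (defaults 40, 0).
#' @return A [GeneModelSet-class]; attribute `excluded` counts transcripts
#'   dropped for CDS length not divisible by 3.
#' @export
loadGeneModels <- function(annotationPath, fastaPath = NULL,
                           upstreamPad = 40L, downstreamPad = 0L) {
  ext <- tolower(tools::file_ext(annotationPath))
  gr <- rtracklayer::import(annotationPath)
  md <- S4Vectors::mcols(gr)
  if (ext == "bed") {
    tx <- as.character(md$name)
    gene <- tx
    cds <- gr
  } else {
    isCds <- !is.na(md$type) & toupper(as.character(md$type)) == "CDS"
    cds <- gr[isCds]
    md <- S4Vectors::mcols(cds)
    tx <- if (!is.null(md$transcript_id)) as.character(md$transcript_id)
          else if (!is.null(md$Parent)) as.character(S4Vectors::unstrsplit(md$Parent, ","))
          else as.character(md$ID)
    gene <- if (!is.null(md$gene_id)) as.character(md$gene_id) else tx
    bad <- is.na(tx) | tx == ""
    if (any(bad)) {
      warning(sum(bad), " CDS feature(s) without a transcript grouping skipped")
      cds <- cds[!bad]; tx <- tx[!bad]; gene <- gene[!bad]
    }
  }
  if (!length(cds)) stop("no CDS features found in ", annotationPath)
  parts <- GenomicRanges::split(cds, tx)
  parts <- GenomicRanges::reduce(parts)
  lens <- sum(GenomicRanges::width(parts))
  txGene <- tapply(gene, tx, function(g) g[1])[names(parts)]
  ## longest CDS per gene
  ord <- order(unname(txGene), -lens[names(parts)])
  keepTx <- names(parts)[ord][!duplicated(unname(txGene)[ord])]
  parts <- parts[keepTx]
  lens <- lens[keepTx]
  divOk <- lens %% 3L == 0L & lens >= 9L
  excluded <- sum(!divOk)
  if (excluded)
    warning(excluded, " transcript(s) excluded: CDS length not a positive ",
            "multiple of 3 (>= 9 nt)")
  parts <- parts[divOk]
  lens <- lens[divOk]
  ids <- unname(txGene[names(parts)])
  ## order CDS parts 5'->3' along the transcript
  parts <- S4Vectors::endoapply(parts, function(p) {
    p <- GenomicRanges::sort(p)
    if (length(p) && as.character(GenomicRanges::strand(p))[1] == "-")
      p <- rev(p)
    p
  })
  seqs <- NULL
  if (!is.null(fastaPath)) {
    fa <- Biostrings::readDNAStringSet(fastaPath)
    names(fa) <- sub("\\s.*$", "", names(fa))
    if (all(ids %in% names(fa))) {
      seqs <- fa[ids]
      names(seqs) <- ids
    } else {
      seqs <- Biostrings::DNAStringSet(vapply(seq_along(parts), function(i) {
        p <- parts[[i]]
        chunks <- vapply(seq_along(p), function(j) {
          chr <- as.character(GenomicRanges::seqnames(p))[j]
          s <- as.character(Biostrings::subseq(
            fa[[chr]], GenomicRanges::start(p)[j], GenomicRanges::end(p)[j]))
          if (as.character(GenomicRanges::strand(p))[j] == "-")
            s <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(s)))
          s
        }, character(1))
        paste(chunks, collapse = "")
      }, character(1)))
      names(seqs) <- ids
    }
  }
  names(parts) <- ids
  GeneModelSet(ids, lens, upstreamPad, downstreamPad,
               sequences = seqs, ranges = parts) -> gm
  attr(gm, "excluded") <- excluded
  gm
}

#' Read/write a plain gene table
#'
#' TSV with columns `gene_id`, `cds_length` and optionally `upstream_pad`,
#' `downstream_pad`, `cds_sequence` - the annotation-free way to supply
#' gene geometry alongside a profile table.
#'
#' @param path TSV file.
#' @return [readGeneTable()] returns a [GeneModelSet-class];
#'   [writeGeneTable()] returns `path` invisibly.
#' @export
readGeneTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "cds_length") %in% names(df)))
  seqs <- if (!is.null(df$cds_sequence) && !all(is.na(df$cds_sequence)))
    stats::setNames(df$cds_sequence, df$gene_id) else NULL
  GeneModelSet(df$gene_id, df$cds_length,
               upstream_pad = if (is.null(df$upstream_pad)) 40L else df$upstream_pad,
               downstream_pad = if (is.null(df$downstream_pad)) 0L else df$downstream_pad,
               sequences = seqs)
}

#' @rdname readGeneTable
#' @param genes a [GeneModelSet-class].
#' @export
writeGeneTable <- function(genes, path) {
  info <- geneInfo(genes)
  df <- info[, c("gene_id", "cds_length", "upstream_pad", "downstream_pad")]
  seqs <- cdsSequences(genes)
  if (length(seqs))
    df$cds_sequence <- as.character(seqs)[match(df$gene_id, names(seqs))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import anchor-nucleotide profiles from a SAM/BAM file
#'
#' Counts the anchor nucleotide (5' end by default, 3' end optionally) of
#' every aligned footprint in CDS-anchored transcript coordinates.  Two
#' reference spaces are supported: transcriptomic (reference names are gene
#' ids; position 1 is the first nt of the upstream pad) and genomic
#' (references match the annotation; reads are projected through the CDS
#' parts stored in the gene models).  Reads with lengths outside
#' `sizeRange` or mapping to no gene are ignored.  Reads with an NH tag
#' greater than 1 are tallied separately per gene into the multimapped
#' fraction and excluded from the tracks; when the NH tag is absent the
#' fraction is 0 with a caveat message.
#'
#' @param file SAM or BAM file (SAM files are converted on the fly).
#' @param genes a [GeneModelSet-class].
#' @param sizeRange inclusive fragment-size bounds (default c(20, 35)).
#' @param anchor `"five_prime"` (default) or `"three_prime"`.
#' @return A [RiboProfileSet-class].
#' @export
profilesFromAlignments <- function(file, genes, sizeRange = c(20L, 35L),
                                   anchor = "five_prime") {
  stopifnot(is(genes, "GeneModelSet"))
  if (tolower(tools::file_ext(file)) == "sam") {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  rname <- as.character(b$rname)
  len <- b$qwidth
  keepLen <- !is.na(len) & len >= sizeRange[1] & len <= sizeRange[2]
  nh <- b$tag$NH
  if (is.null(nh)) {
    message("NH tag absent: multimapped fraction reported as 0")
    nh <- rep(1L, length(rname))
  }
  nh[is.na(nh)] <- 1L
  info <- geneInfo(genes)
  transcriptomic <- all(unique(rname) %in% info$gene_id)
  if (transcriptomic) {
    g <- rname
    pad <- info$upstream_pad[match(g, info$gene_id)]
    x5 <- b$pos - pad          # x = refpos - pad; refpos 1 = pad start
    x <- if (anchor == "five_prime") x5 else x5 + len - 1L
  } else {
    if (!length(genes@ranges))
      stop("genomic alignments need gene models with CDS ranges ",
           "(use loadGeneModels)")
    proj <- projectGenomic(b, len, genes)
    g <- proj$gene
    x <- if (anchor == "five_prime") proj$x5 else proj$x3
  }
  ok <- keepLen & !is.na(g) & !is.na(x)
  g <- g[ok]; x <- x[ok]; len <- len[ok]; nh <- nh[ok]
  multi <- nh > 1L
  tot <- tapply(rep(1L, length(g)), g, sum)
  mTot <- tapply(as.integer(multi), g, sum)
  mm <- stats::setNames(rep(0, nrow(info)), info$gene_id)
  mm[names(tot)] <- ifelse(tot > 0, mTot / tot, 0)
  totAll <- stats::setNames(rep(0, nrow(info)), info$gene_id)
  totAll[names(tot)] <- tot
  u <- !multi
  counts <- data.table::data.table(gene_id = g[u], size = as.integer(len[u]),
                                   pos = as.integer(x[u]))
  counts <- counts[, .(count = as.numeric(.N)), by = .(gene_id, size, pos)]
  counts[, frame := (pos - 1L) %% 3L]
  RiboProfileSet(counts[, .(gene_id, size, frame, pos, count)], genes,
                 anchor = anchor, multimapFraction = mm,
                 totalMappedReads = totAll)
}

## Project genomic anchor coordinates onto CDS-anchored transcript
## coordinates through the CDS parts of each gene.
projectGenomic <- function(b, len, genes) {
  info <- geneInfo(genes)
  ranges <- genes@ranges
  spans <- unlist(range(ranges))
  pads <- info$upstream_pad[match(names(spans), info$gene_id)] +
    max(info$downstream_pad, 40L)
  padded <- GenomicRanges::resize(spans,
                                  GenomicRanges::width(spans) + 2L * pads,
                                  fix = "center")
  n <- length(b$pos)
  g5 <- ifelse(as.character(b$strand) == "-", b$pos + len - 1L, b$pos)
  g3 <- ifelse(as.character(b$strand) == "-", b$pos, b$pos + len - 1L)
  q <- GenomicRanges::GRanges(b$rname, IRanges::IRanges(g5, width = 1L))
  hit <- GenomicRanges::findOverlaps(q, padded, select = "first",
                                     ignore.strand = TRUE)
  gene <- names(spans)[hit]
  x5 <- rep(NA_integer_, n); x3 <- rep(NA_integer_, n)
  for (i in which(!is.na(gene))) {
    gi <- gene[i]
    x5[i] <- genomicToCds(g5[i], ranges[[gi]])
    x3[i] <- genomicToCds(g3[i], ranges[[gi]])
  }
  list(gene = gene, x5 = x5, x3 = x3)
}

genomicToCds <- function(gpos, parts) {
  minus <- as.character(GenomicRanges::strand(parts))[1] == "-"
  st <- GenomicRanges::start(parts); en <- GenomicRanges::end(parts)
  w <- en - st + 1L
  cum <- c(0L, cumsum(w))[seq_along(w)]
  for (j in seq_along(w)) {
    if (gpos >= st[j] && gpos <= en[j]) {
      return(if (minus) cum[j] + (en[j] - gpos) + 1L
             else cum[j] + (gpos - st[j]) + 1L)
    }
  }
  ## upstream of the CDS start (within the pad): contiguous genomic offset
  if (minus) {
    first <- en[1]
    if (gpos > first) return(1L - (gpos - first))
  } else {
    first <- st[1]
    if (gpos < first) return(1L - (first - gpos))
  }
  NA_integer_
}

#' Read/write the long profile table
#'
#' TSV columns: `gene_id`, `fragment_size`, `frame`, `position`, `count`,
#' optional `multimap_fraction` (per gene, default 0).  Rows whose frame is
#' inconsistent with `(position - 1) mod 3` raise an error naming the
#' offending rows; negative counts are a hard error.  Writing then reading
#' reproduces counts exactly.
#'
#' @param path TSV file.
#' @param genes a [GeneModelSet-class] covering the genes in the table.
#' @param anchor anchor of the stored positions.
#' @return [readProfileTable()] returns a [RiboProfileSet-class].
#' @export
readProfileTable <- function(path, genes, anchor = "five_prime") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "fragment_size", "frame", "position", "count")
  if (!all(need %in% names(df)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0))
    stop("negative count in profile table: row(s) ",
         paste(head(which(df$count < 0), 10), collapse = ", "))
  if (anchor == "five_prime") {
    bad <- which(df$frame != (df$position - 1L) %% 3L)
    if (length(bad))
      stop("frame inconsistent with position in row(s): ",
           paste(head(bad, 20), collapse = ", "))
  }
  mm <- NULL
  if (!is.null(df$multimap_fraction)) {
    per <- tapply(df$multimap_fraction, df$gene_id, function(v) v[1])
    mm <- stats::setNames(as.numeric(per), names(per))
  }
  RiboProfileSet(data.frame(gene_id = df$gene_id, size = df$fragment_size,
                            frame = df$frame, pos = df$position,
                            count = df$count),
                 genes, anchor = anchor, multimapFraction = mm)
}

#' @rdname readProfileTable
#' @param profiles a [RiboProfileSet-class].
#' @export
writeProfileTable <- function(profiles, path) {
  dt <- profileCounts(profiles)
  mm <- multimapFraction(profiles)
  out <- data.frame(gene_id = dt$gene_id, fragment_size = dt$size,
                    frame = dt$frame, position = dt$pos, count = dt$count)
  if (any(mm > 0)) out$multimap_fraction <- unname(mm[out$gene_id])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

formatOffsetCell <- function(status, primary, secondary) {
  if (status == "unique") as.character(as.integer(primary))
  else if (status == "ambiguous")
    paste0(as.integer(primary), "/", as.integer(secondary))
  else "NA"
}

## wide data.frame used for serialization and show()
offsetTableWide <- function(x) {
  rows <- offsetRows(x)
  sizes <- sort(unique(rows$size))
  wide <- data.frame(fragment_size = sizes)
  for (f in 0:2) {
    wide[[paste0("frame", f)]] <- vapply(sizes, function(s) {
      i <- which(rows$size == s & rows$frame == f)
      if (!length(i)) return("NA")
      formatOffsetCell(rows$status[i], rows$primary[i], rows$secondary[i])
    }, character(1))
  }
  wide
}

#' Read/write the wide offset-table format
#'
#' One row per fragment size, columns `fragment_size`, `frame0`, `frame1`,
#' `frame2`.  Unique calls are a single integer, ambiguous calls
#' "primary/secondary", insufficient calls NA.  Offsets that are not
#' non-negative multiples of 3, or exceed the fragment size, raise an error
#' naming the offending cell.  An optional diagnostics TSV carries the
#' modal fraction, gene count and bootstrap CI per combination.
#'
#' @param path TSV file.
#' @return [readOffsetTable()] returns an [OffsetTable-class].
#' @export
readOffsetTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("fragment_size", "frame0", "frame1", "frame2") %in% names(df)))
  rows <- list()
  for (i in seq_len(nrow(df))) {
    s <- as.integer(df$fragment_size[i])
    for (f in 0:2) {
      cell <- df[[paste0("frame", f)]][i]
      cellName <- sprintf("size %d frame %d", s, f)
      if (is.na(cell) || cell == "NA" || cell == "") {
        rows[[length(rows) + 1L]] <-
          data.frame(size = s, frame = f, status = "insufficient",
                     primary = NA_real_, secondary = NA_real_)
        next
      }
      parts <- as.numeric(strsplit(cell, "/", fixed = TRUE)[[1]])
      if (any(is.na(parts)) || any(parts %% 3 != 0) || any(parts > s) ||
          any(parts < 0))
        stop("invalid offset cell at ", cellName, ": '", cell,
             "' (offsets must be non-negative multiples of 3 and <= size)")
      rows[[length(rows) + 1L]] <-
        data.frame(size = s, frame = f,
                   status = if (length(parts) > 1) "ambiguous" else "unique",
                   primary = parts[1],
                   secondary = if (length(parts) > 1) parts[2] else NA_real_)
    }
  }
  OffsetTable(do.call(rbind, rows), strict = TRUE)
}

#' @rdname readOffsetTable
#' @param x an [OffsetTable-class].
#' @param diagnosticsPath optional TSV for per-combination diagnostics.
#' @export
writeOffsetTable <- function(x, path, diagnosticsPath = NULL) {
  stopifnot(is(x, "OffsetTable"))
  utils::write.table(offsetTableWide(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(diagnosticsPath)) {
    utils::write.table(offsetRows(x), diagnosticsPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
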