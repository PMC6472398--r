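# Fixture builders shared across test files.  Everything is generated in
# code; no binary data.

# A gene whose (S, frame) track is engineered so the per-gene optimum is
# `delta`: `perCodon` reads are placed at x = a + frame - delta for every
# A-site codon a = 3k - 2, k = 2..L.  All emitted positions are in frame
# `frame` by construction.
plantedTrackRows <- function(geneId, nCodons, size, frame, delta,
                             perCodon = 3) {
  k <- 2:nCodons
  a <- 3L * k - 2L
  x <- a + frame - delta
  data.frame(gene_id = geneId, size = size, frame = frame, pos = x,
             count = perCodon)
}

# profile set of `n` genes on a single (size, frame) combination whose
# per-gene optima follow `deltas` (recycled)
plantedProfileSet <- function(n, deltas, nCodons = 40L, size = 28L,
                              frame = 0L, perCodon = 3) {
  deltas <- rep_len(deltas, n)
  ids <- sprintf("pg%03d", seq_len(n))
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    plantedTrackRows(ids[i], nCodons, size, frame, deltas[i], perCodon)))
  genes <- GeneModelSet(ids, 3L * nCodons)
  RiboProfileSet(rows, genes)
}

# tiny gene set with explicit CDS sequences
seqGeneSet <- function(seqs, upstreamPad = 40L) {
  GeneModelSet(names(seqs), nchar(unname(seqs)), upstreamPad,
               sequences = seqs)
}

# codon string helpers
codons <- function(...) paste0(c(...), collapse = "")
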