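## Synthetic Ribo-Seq generator with known ground-truth offsets.
##
## Pipeline: Gillespie translation kinetics -> per-codon A-site occupancy
## histograms -> normalization to a per-gene read budget -> per-read (S, F)
## assignment from a truncated, mode-shifted Poisson distribution over the
## 48 ordered (size, frame) events -> 5'-end positions emitted so that the
## ground-truth offset points back at the occupied A-site codon.

SENSE_CODONS <- c(
  "TTT","TTC","TTA","TTG","CTT","CTC","CTA","CTG","ATT","ATC","ATA","ATG",
  "GTT","GTC","GTA","GTG","TCT","TCC","TCA","TCG","CCT","CCC","CCA","CCG",
  "ACT","ACC","ACA","ACG","GCT","GCC","GCA","GCG","TAT","TAC","CAT","CAC",
  "CAA","CAG","AAT","AAC","AAA","AAG","GAT","GAC","GAA","GAG","TGT","TGC",
  "TGG","CGT","CGC","CGA","CGG","AGT","AGC","AGA","AGG","GGT","GGC","GGA",
  "GGG")

aaCodon <- function(aa) {
  ## one representative codon per amino acid (used to plant motifs)
  map <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
           E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
           M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
           Y = "TAT", V = "GTT")
  unname(map[strsplit(aa, "")[[1]]])
}

#' Generate a synthetic gene set
#'
#' Gene lengths are drawn uniformly from `lengthRange` (codons, stop codon
#' included).  When `withSequences` is TRUE a random CDS is built per gene:
#' ATG start, random sense codons, TAA stop.  A tripeptide motif (e.g.
#' "PPG") can be planted at random internal positions to emulate stalling
#' sites; planted third-codon indices are returned as an attribute.
#'
#' @param nGenes number of genes.
#' @param lengthRange codon count range, inclusive (default 150-500).
#' @param upstreamPad,downstreamPad pads in nt (default 40, 0).
#' @param withSequences build random CDS sequences.
#' @param motif optional tripeptide to plant (implies sequences).
#' @param motifPerGene how many copies to plant per gene (default 2).
#' @param seed RNG seed.
#' @return A [GeneModelSet-class]; when a motif is planted, attribute
#'   `motif_sites` holds a data.frame (`gene_id`, `third_codon_index`).
#' @export
simulateGeneSet <- function(nGenes = 300L, lengthRange = c(150L, 500L),
                            upstreamPad = 40L, downstreamPad = 0L,
                            withSequences = FALSE, motif = NULL,
                            motifPerGene = 2L, seed = NULL) {
  withSeed(seed, {
    lens <- sample(seq.int(lengthRange[1], lengthRange[2]), nGenes,
                   replace = TRUE)
    ids <- sprintf("g%04d", seq_len(nGenes))
    seqs <- NULL
    sites <- NULL
    if (withSequences || !is.null(motif)) {
      seqs <- character(nGenes)
      siteList <- vector("list", nGenes)
      for (i in seq_len(nGenes)) {
        L <- lens[i]
        codons <- c("ATG", sample(SENSE_CODONS, L - 2L, replace = TRUE), "TAA")
        if (!is.null(motif)) {
          stopifnot(nchar(motif) == 3L)
          mot <- aaCodon(motif)
          ## third residue must sit strictly inside codons [4, L-1] so the
          ## planted site never touches start, stop or each other
          cand <- seq.int(5L, L - 2L)
          picks <- integer(0)
          for (p in sample(cand)) {
            if (length(picks) >= motifPerGene) break
            if (all(abs(p - picks) > 3L)) picks <- c(picks, p)
          }
          picks <- sort(picks)
          for (p in picks) codons[(p - 2L):p] <- mot
          siteList[[i]] <- data.frame(gene_id = ids[i],
                                      third_codon_index = picks)
        }
        seqs[i] <- paste(codons, collapse = "")
      }
      names(seqs) <- ids
      if (!is.null(motif)) sites <- do.call(rbind, siteList)
    }
    gm <- GeneModelSet(ids, 3L * lens, upstreamPad, downstreamPad,
                       sequences = seqs)
    if (!is.null(sites)) attr(gm, "motif_sites") <- sites
    gm
  })
}

#' Simulate per-codon A-site occupancies by Gillespie kinetics
#'
#' Each gene is simulated as an ensemble of `nCopies` independent
#' single-ribosome transcript copies: initiation (A-site placed on codon 2),
#' codon-by-codon elongation, termination after the stop codon is decoded.
#' Every `snapshotInterval` reactions the A-site codon of every occupied
#' copy is recorded.  Per-codon dwell time - and hence expected occupancy -
#' is inversely proportional to the codon's elongation rate.
#'
#' @param genes a [GeneModelSet-class].
#' @param initiationRate initiation rate (default 1, the elongation scale).
#' @param elongationRates either a single rate applied to every codon, or a
#'   named list of per-codon rate vectors keyed by gene id.
#' @param nCopies transcript copies per gene (default 10).
#' @param stepsPerCodon Gillespie reactions simulated per codon of gene
#'   length (default 200; total steps = `stepsPerCodon * n_codons`).
#' @param snapshotInterval reactions between snapshots (default 100).
#' @param seed RNG seed.
#' @return named list of integer per-codon occupancy vectors.
#' @export
simulateOccupancies <- function(genes, initiationRate = 1,
                                elongationRates = 1, nCopies = 10L,
                                stepsPerCodon = 200L,
                                snapshotInterval = 100L, seed = NULL) {
  stopifnot(is(genes, "GeneModelSet"))
  info <- geneInfo(genes)
  withSeed(seed, {
    occ <- vector("list", nrow(info))
    names(occ) <- info$gene_id
    for (i in seq_len(nrow(info))) {
      L <- info$n_codons[i]
      rates <- if (is.list(elongationRates)) {
        r <- elongationRates[[info$gene_id[i]]]
        if (is.null(r)) rep(1, L) else rep_len(r, L)
      } else rep_len(elongationRates, L)
      occ[[i]] <- gillespie_occupancy(L, rates, initiationRate,
                                      as.integer(stepsPerCodon) * L,
                                      as.integer(snapshotInterval),
                                      as.integer(nCopies))
    }
    occ
  })
}

#' Normalize an occupancy histogram to an exact integer read total
#'
#' Largest-remainder rounding: proportions are scaled to `target`, floored,
#' and the remaining reads handed to the codons with the largest fractional
#' parts, so the integer counts sum to `target` exactly.
#'
#' @param occ non-negative occupancy vector.
#' @param target integer read total.
#' @return integer vector summing to `target`.
#' @export
normalizeOccupancy <- function(occ, target) {
  target <- as.integer(target)
  if (target < 0) stop("target must be non-negative")
  s <- sum(occ)
  if (s == 0) {
    if (target == 0) return(integer(length(occ)))
    stop("cannot normalize an all-zero occupancy to a positive total")
  }
  raw <- occ / s * target
  base <- floor(raw)
  rem <- target - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Build the (size, frame) event distribution
#'
#' A Poisson pmf with parameter `lam` over k = 0, 1, 2, ... is index-shifted
#' so that its mode lands on the event index of `modeSF` (24 for (28,0)),
#' truncated to the 48 events and renormalized to sum to 1.  For integer
#' `lam` the Poisson pmf ties exactly at k = lam-1 and k = lam, so the event
#' immediately left of the mode carries equal probability.
#'
#' @param lam Poisson parameter (> 0); the paper-style presets are
#'   4, 8, 16, 24, 48 and 80.
#' @param modeSF target mode as c(size, frame) (default c(28, 0); presets
#'   with modes at (24,0) and (32,0) are obtained by changing this).
#' @return An [SFDistribution-class].
#' @export
buildSFDistribution <- function(lam, modeSF = c(28L, 0L)) {
  stopifnot(lam > 0)
  grid <- sfEventGrid()
  modeIdx <- sfEventIndex(modeSF[1], modeSF[2])
  shift <- modeIdx - floor(lam)
  k <- 0:47 - shift
  pmf <- ifelse(k >= 0, stats::dpois(k, lam), 0)
  if (sum(pmf) <= 0) stop("no probability mass on the 48-event grid")
  pmf <- pmf / sum(pmf)
  names(pmf) <- paste(grid$size, grid$frame, sep = "_")
  new("SFDistribution", lam = lam, pmf = pmf, events = grid,
      modeEvent = as.integer(modeSF))
}

#' Ground-truth offset schemes
#'
#' The four reference schemes used to validate offset recovery: constant 15
#' nt for every (S, F); constant 18 nt; 12 nt for sizes 20-27 with 18 nt
#' for sizes 28-35; or an arbitrary user table with a unique offset per
#' combination.
#'
#' @param kind `"const15"`, `"const18"`, `"split12_18"` or `"table"`.
#' @param table an [OffsetTable-class], required for `kind = "table"`.
#' @param sizeRange fragment sizes covered (default 20:35).
#' @return An [OffsetTable-class] with every combination unique.
#' @export
offsetScheme <- function(kind = c("const15", "const18", "split12_18", "table"),
                         table = NULL, sizeRange = 20:35) {
  kind <- match.arg(kind)
  if (kind == "table") {
    stopifnot(is(table, "OffsetTable"))
    return(table)
  }
  grid <- expand.grid(size = as.integer(sizeRange), frame = 0:2)
  off <- switch(kind,
    const15 = rep(15, nrow(grid)),
    const18 = rep(18, nrow(grid)),
    split12_18 = ifelse(grid$size <= 27L, 12, 18))
  OffsetTable(data.frame(size = grid$size, frame = grid$frame,
                         status = "unique", primary = off),
              strict = TRUE)
}

offsetLookup <- function(table) {
  rows <- offsetRows(table)
  stats::setNames(rows$primary, paste(rows$size, rows$frame, sep = "_"))
}

#' Emit artificial 5'-anchored profiles from occupancies
#'
#' Every occupancy read sitting on A-site codon k (first nucleotide
#' a = 3k - 2) is assigned an (S, F) event by a multinomial draw from
#' `sfDist` and emitted at 5'-end position x = a + F - offset(S, F), the
#' unique frame-F position from which the ground-truth offset points back
#' into the A-site codon.  Reads whose position falls below the available
#' upstream pad are dropped and counted as spill.
#'
#' @param occupancies named list of integer per-codon read counts (already
#'   normalized, see [normalizeOccupancy()]).
#' @param genes the [GeneModelSet-class] the occupancies belong to.
#' @param sfDist an [SFDistribution-class].
#' @param scheme ground-truth [OffsetTable-class] (see [offsetScheme()]).
#' @param seed RNG seed for the multinomial draws.
#' @return list with `profiles` (a [RiboProfileSet-class]) and `spilled`
#'   (reads dropped at the upstream boundary).
#' @export
generateProfiles <- function(occupancies, genes, sfDist, scheme,
                             seed = NULL) {
  stopifnot(is(genes, "GeneModelSet"), is(sfDist, "SFDistribution"))
  info <- geneInfo(genes)
  pmf <- sfPmf(sfDist)
  grid <- sfEventGrid()
  offs <- offsetLookup(scheme)
  delta <- offs[paste(grid$size, grid$frame, sep = "_")]
  if (any(is.na(delta) & pmf > 0))
    stop("scheme does not define offsets for every event with positive pmf")
  spilled <- 0
  withSeed(seed, {
    pieces <- vector("list", nrow(info))
    for (i in seq_len(nrow(info))) {
      g <- info$gene_id[i]
      occ <- occupancies[[g]]
      if (is.null(occ) || sum(occ) == 0) next
      L <- info$n_codons[i]
      pad <- info$upstream_pad[i]
      hot <- which(occ > 0)
      ## 48 x length(hot) matrix of event counts per occupied codon
      cnt <- matrix(vapply(hot, function(k) rmultinom(1L, occ[k], pmf)[, 1],
                           integer(48L)), nrow = 48L)
      a <- 3L * hot - 2L
      nz <- which(cnt > 0, arr.ind = TRUE)
      if (!nrow(nz)) next
      ev <- nz[, 1]; ci <- nz[, 2]
      x <- a[ci] + grid$frame[ev] - as.integer(delta[ev])
      keep <- x >= 1L - pad
      spilled <- spilled + sum(cnt[nz][!keep])
      if (any(keep)) {
        pieces[[i]] <- data.table::data.table(
          gene_id = g, size = grid$size[ev[keep]],
          frame = grid$frame[ev[keep]], pos = x[keep],
          count = as.numeric(cnt[nz][keep]))
      }
    }
    counts <- data.table::rbindlist(pieces)
    if (!nrow(counts))
      counts <- data.table::data.table(gene_id = character(),
                                       size = integer(), frame = integer(),
                                       pos = integer(), count = numeric())
    list(profiles = RiboProfileSet(counts, genes), spilled = spilled)
  })
}

#' Compare a recovered offset table with the ground truth
#'
#' A combination matches when the recovered status is `unique` and the
#' primary offset equals the truth; ambiguous and insufficient calls count
#' as non-matches.  The fraction is reported over all 48 combinations and,
#' separately, over combinations with at least `minGenes` contributing
#' genes (the covered combinations; tail events of the (S, F) distribution
#' can carry too little read mass for any gene to qualify).
#'
#' @param truth ground-truth [OffsetTable-class].
#' @param recovered recovered [OffsetTable-class] (from
#'   [aggregateOffsets()]).
#' @param minGenes coverage cutoff for the covered denominator (default 10).
#' @return list with `fraction_all`, `fraction_covered`, `n_covered` and a
#'   per-combination `report` data.frame.
#' @export
compareOffsetTables <- function(truth, recovered, minGenes = 10L) {
  tr <- offsetRows(truth); rr <- offsetRows(recovered)
  m <- merge(tr[, c("size", "frame", "primary")],
             rr[, c("size", "frame", "status", "primary", "n_genes")],
             by = c("size", "frame"), suffixes = c("_truth", "_rec"))
  m$covered <- !is.na(m$n_genes) & m$n_genes >= minGenes
  m$match <- m$status == "unique" & !is.na(m$primary_rec) &
    m$primary_rec == m$primary_truth
  list(fraction_all = mean(m$match),
       fraction_covered = if (any(m$covered)) mean(m$match[m$covered])
                          else NA_real_,
       n_covered = sum(m$covered),
       report = m[order(m$size, m$frame), ])
}

#' One-stop synthetic Ribo-Seq dataset
#'
#' Chains [simulateGeneSet()], [simulateOccupancies()],
#' [normalizeOccupancy()] and [generateProfiles()] under one master seed.
#' Per-gene read depth (reads per codon) is drawn from a truncated
#' log-normal emulating the heavy-tailed coverage of pooled experimental
#' datasets: median `medianReadsPerCodon`, log-sd `sdlogReadsPerCodon`,
#' truncated to `[minReadsPerCodon, maxReadsPerCodon]`.
#'
#' @param nGenes,lengthRange passed to [simulateGeneSet()].
#' @param lam,modeSF passed to [buildSFDistribution()].
#' @param scheme an [OffsetTable-class] or a kind string for
#'   [offsetScheme()] (default "const15").
#' @param medianReadsPerCodon,sdlogReadsPerCodon,minReadsPerCodon,maxReadsPerCodon
#'   read-depth distribution parameters (defaults 50, 1.5, 2, 5000).
#' @param genes optionally reuse an existing [GeneModelSet-class].
#' @param elongationRates passed to [simulateOccupancies()].
#' @param seed master seed; stage seeds are derived with [deriveSeed()].
#' @return list with `profiles`, `truth`, `genes`, `occupancies`, `spilled`.
#' @export
simulateRiboseq <- function(nGenes = 300L, lengthRange = c(150L, 500L),
                            lam = 8, modeSF = c(28L, 0L),
                            scheme = "const15",
                            medianReadsPerCodon = 50,
                            sdlogReadsPerCodon = 1.5,
                            minReadsPerCodon = 2,
                            maxReadsPerCodon = 5000,
                            genes = NULL, elongationRates = 1,
                            seed = 1L) {
  if (is.character(scheme)) scheme <- offsetScheme(scheme)
  if (is.null(genes))
    genes <- simulateGeneSet(nGenes, lengthRange, seed = deriveSeed(seed, "genes"))
  info <- geneInfo(genes)
  occ <- simulateOccupancies(genes, elongationRates = elongationRates,
                             seed = deriveSeed(seed, "gillespie"))
  norm <- withSeed(deriveSeed(seed, "budget"), {
    rpc <- stats::rlnorm(nrow(info), meanlog = log(medianReadsPerCodon),
                         sdlog = sdlogReadsPerCodon)
    rpc <- pmin(pmax(rpc, minReadsPerCodon), maxReadsPerCodon)
    targets <- round(rpc * info$n_codons)
    out <- vector("list", nrow(info))
    names(out) <- info$gene_id
    for (i in seq_len(nrow(info)))
      out[[i]] <- normalizeOccupancy(occ[[info$gene_id[i]]], targets[i])
    out
  })
  sfd <- buildSFDistribution(lam, modeSF)
  gen <- generateProfiles(norm, genes, sfd, scheme,
                          seed = deriveSeed(seed, "emit"))
  list(profiles = gen$profiles, truth = scheme, genes = genes,
       occupancies = norm, spilled = gen$spilled)
}
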