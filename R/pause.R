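## PPX/XPP pause-motif statistics: motif discovery on CDS translations,
## median normalized density at the stall codon (the motif's third residue,
## which sits in the A-site during the stall), permutation-test p-values,
## and paired comparison of A-site assignment methods.

#' Find tripeptide motif instances on translated CDS sequences
#'
#' Translates each CDS with the standard genetic code and scans for
#' polyproline motifs: for `"PPX"` every position i whose two preceding
#' residues are P-P (motif = "PP" + residue i), for `"XPP"` every position
#' i where residues i-1 and i are P-P (motif = residue(i-2) + "PP"), or a
#' literal tripeptide such as `"PPG"`.  The reported `third_codon_index` is
#' the codon of the motif's third residue - the A-site codon at a stall.
#' Overlapping instances are allowed; the start and stop codons are never
#' indexed.  Genes whose translation contains an internal stop are scanned
#' anyway and flagged in the `internal_stops` attribute.
#'
#' @param genes a [GeneModelSet-class] with CDS sequences.
#' @param pattern `"PPX"`, `"XPP"` or a literal 3-letter motif.
#' @return data.frame with `gene_id`, `motif`, `third_codon_index`.
#' @export
findMotifInstances <- function(genes, pattern = "PPX") {
  stopifnot(is(genes, "GeneModelSet"))
  seqs <- cdsSequences(genes)
  if (!length(seqs)) stop("gene models carry no CDS sequences")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    seqs, if.fuzzy.codon = "X")))
  internalStops <- character(0)
  out <- vector("list", length(aa))
  for (i in seq_along(aa)) {
    a <- strsplit(aa[i], "")[[1]]
    L <- length(a)
    if (any(a[-L] == "*")) internalStops <- c(internalStops, names(aa)[i])
    ## third residue index range: cannot be the start codon (needs i >= 3
    ## anyway) nor the stop codon
    idx <- seq.int(3L, L - 1L)
    hit <- if (pattern == "PPX") {
      idx[a[idx - 2L] == "P" & a[idx - 1L] == "P" & a[idx] != "*"]
    } else if (pattern == "XPP") {
      idx[a[idx - 1L] == "P" & a[idx] == "P"]
    } else {
      stopifnot(nchar(pattern) == 3L)
      p <- strsplit(pattern, "")[[1]]
      idx[a[idx - 2L] == p[1] & a[idx - 1L] == p[2] & a[idx] == p[3]]
    }
    if (length(hit))
      out[[i]] <- data.frame(gene_id = names(aa)[i],
                             motif = paste0(a[hit - 2L], a[hit - 1L], a[hit]),
                             third_codon_index = hit,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), motif = character(),
                      third_codon_index = integer())
  attr(res, "internal_stops") <- unique(internalStops)
  res
}

## density of each instance's third codon, NA when the gene has no
## normalized profile
instanceDensities <- function(instances, densities) {
  vapply(seq_len(nrow(instances)), function(i) {
    v <- densities[[instances$gene_id[i]]]
    if (is.null(v)) return(NA_real_)
    k <- instances$third_codon_index[i]
    if (k < 1 || k > length(v)) return(NA_real_)
    v[k]
  }, numeric(1))
}

## coverage filter: fraction of codons with any signal
coveredFraction <- function(v) mean(v > 0)

#' Median pause score of a motif with bootstrap CI
#'
#' Keeps instances on genes whose normalized A-site profile has signal on
#' at least `minCoveredFraction` of codon positions, takes the normalized
#' density at each instance's third codon, and reports the median with a
#' percentile bootstrap confidence interval over instances.
#'
#' @param instances data.frame from [findMotifInstances()] (typically one
#'   motif).
#' @param densities named list of normalized density vectors (see
#'   [normalizedDensity()]).
#' @param minCoveredFraction gene coverage filter (default 0.5).
#' @param B bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `motif`, `n_instances`, `median_density`, `ci95`,
#'   and the retained per-instance `densities`.
#' @export
motifPauseScores <- function(instances, densities, minCoveredFraction = 0.5,
                             B = 1000L, seed = NULL) {
  okGene <- names(densities)[vapply(densities, coveredFraction,
                                    numeric(1)) >= minCoveredFraction]
  inst <- instances[instances$gene_id %in% okGene, , drop = FALSE]
  d <- instanceDensities(inst, densities)
  d <- d[!is.na(d)]
  motif <- if (nrow(instances)) unique(instances$motif)[1] else NA_character_
  if (!length(d))
    return(list(motif = motif, n_instances = 0L, median_density = NA_real_,
                ci95 = c(NA_real_, NA_real_), densities = numeric(0)))
  ci <- withSeed(seed, {
    meds <- vapply(seq_len(B), function(b)
      stats::median(sample(d, length(d), replace = TRUE)), numeric(1))
    unname(stats::quantile(meds, c(0.025, 0.975)))
  })
  list(motif = motif, n_instances = length(d),
       median_density = stats::median(d), ci95 = ci, densities = d)
}

#' Permutation-test p-value for a motif's median pause score
#'
#' Repeatedly draws, without replacement, `n` densities from the background
#' pool (instances of all other tripeptide motifs) and records the median;
#' the p-value is the fraction of permutation medians greater than or equal
#' to the observed median.  A p-value of 0 means below 1/`nPerm`.
#'
#' @param observedMedian observed median density of the motif.
#' @param n number of instances of the motif.
#' @param background densities of background motif instances (length >= n).
#' @param nPerm permutation iterations (default 10000).
#' @param seed RNG seed.
#' @return numeric p-value between 0 and 1.
#' @export
permutationTest <- function(observedMedian, n, background, nPerm = 10000L,
                            seed = NULL) {
  background <- background[!is.na(background)]
  if (length(background) < n)
    stop("background pool (", length(background),
         ") smaller than the number of instances (", n, ")")
  withSeed(seed, {
    meds <- vapply(seq_len(nPerm), function(b)
      stats::median(background[sample.int(length(background), n)]),
      numeric(1))
    mean(meds >= observedMedian)
  })
}

#' Pause-score table for all motifs of a pattern
#'
#' Runs [motifPauseScores()] for every distinct motif matching `pattern`
#' and attaches permutation p-values against the pool of all other
#' tripeptide instances.
#'
#' @param genes a [GeneModelSet-class] with sequences.
#' @param densities named list of normalized density vectors.
#' @param pattern `"PPX"` or `"XPP"`.
#' @param minCoveredFraction gene coverage filter (default 0.5).
#' @param nPerm permutation iterations (default 10000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with one row per motif: `motif`, `n_instances`,
#'   `median_density`, `ci_lo`, `ci_hi`, `p_value`, `significant`.
#' @export
pauseScoreTable <- function(genes, densities, pattern = "PPX",
                            minCoveredFraction = 0.5, nPerm = 10000L,
                            alpha = 0.05, seed = NULL) {
  inst <- findMotifInstances(genes, pattern)
  ## background pool: every consecutive tripeptide position
  bg <- allTripeptideInstances(genes)
  okGene <- names(densities)[vapply(densities, coveredFraction,
                                    numeric(1)) >= minCoveredFraction]
  bg <- bg[bg$gene_id %in% okGene, , drop = FALSE]
  bgDens <- instanceDensities(bg, densities)
  motifs <- sort(unique(inst$motif))
  rows <- lapply(seq_along(motifs), function(mi) {
    m <- motifs[mi]
    sc <- motifPauseScores(inst[inst$motif == m, , drop = FALSE], densities,
                           minCoveredFraction, seed = if (is.null(seed)) NULL
                           else deriveSeed(seed, mi))
    if (sc$n_instances == 0L)
      return(data.frame(motif = m, n_instances = 0L,
                        median_density = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p_value = NA_real_,
                        significant = FALSE))
    pool <- bgDens[bg$motif != m]
    p <- permutationTest(sc$median_density, sc$n_instances,
                         pool, nPerm,
                         seed = if (is.null(seed)) NULL
                                else deriveSeed(seed, 1000L + mi))
    data.frame(motif = m, n_instances = sc$n_instances,
               median_density = sc$median_density, ci_lo = sc$ci95[1],
               ci_hi = sc$ci95[2], p_value = p, significant = p < alpha)
  })
  do.call(rbind, rows)
}

## every consecutive tripeptide (third-codon index 3 .. L-1)
allTripeptideInstances <- function(genes) {
  seqs <- cdsSequences(genes)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    seqs, if.fuzzy.codon = "X")))
  out <- lapply(seq_along(aa), function(i) {
    a <- strsplit(aa[i], "")[[1]]
    L <- length(a)
    idx <- seq.int(3L, L - 1L)
    idx <- idx[a[idx] != "*" & a[idx - 1L] != "*" & a[idx - 2L] != "*"]
    data.frame(gene_id = names(aa)[i],
               motif = paste0(a[idx - 2L], a[idx - 1L], a[idx]),
               third_codon_index = idx, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Paired comparison of A-site assignment methods at stall motifs
#'
#' Retains motif instances on genes whose pooled 5' profile covers at
#' least `minCovered` of codon positions over the CDS plus 18 nt upstream,
#' and whose normalized density at the third codon exceeds `enrichment` in
#' at least one compared method.  For each retained instance the normalized
#' density of every method is recorded; the headline statistic is the
#' fraction of instances at which method A assigns strictly greater density
#' than method B, with a two-sided Wilcoxon signed-rank p-value on the
#' paired differences (reported as NA below 6 instances).
#'
#' @param instances data.frame from [findMotifInstances()] (one motif).
#' @param asitesA,asitesB [AsiteProfileSet-class] objects for the two
#'   methods.
#' @param profiles the underlying [RiboProfileSet-class] (for the coverage
#'   filter).
#' @param minCovered coverage fraction (default 0.9).
#' @param enrichment density cutoff (default 1.5).
#' @return list with `n_instances`, `fraction_a_greater`, `wilcoxon_p`,
#'   and the per-instance density matrix.
#' @export
compareMethods <- function(instances, asitesA, asitesB, profiles,
                           minCovered = 0.9, enrichment = 1.5) {
  info <- geneInfo(profiles)
  dt <- profiles@counts
  ## pooled coverage over CDS + 18 nt upstream, in codon bins
  covOk <- vapply(unique(instances$gene_id), function(g) {
    L <- info$cds_length[match(g, info$gene_id)]
    sub <- dt[gene_id == g & pos >= -17L & pos <= L]
    if (!nrow(sub)) return(FALSE)
    bins <- unique((sub$pos + 20L) %/% 3L)  # codon bins incl 6 upstream
    nBins <- (L + 18L) %/% 3L
    length(bins) / nBins >= minCovered
  }, logical(1))
  inst <- instances[covOk[instances$gene_id], , drop = FALSE]
  dA <- normalizedDensity(asitesA)
  dB <- normalizedDensity(asitesB)
  a <- instanceDensities(inst, dA)
  b <- instanceDensities(inst, dB)
  ok <- !is.na(a) & !is.na(b) & (pmax(a, b) > enrichment)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  frac <- if (n) mean(a > b) else NA_real_
  p <- if (n >= 6 && any(a != b))
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  else if (n >= 6) 1
  else NA_real_
  list(n_instances = n, fraction_a_greater = frac, wilcoxon_p = p,
       densities = cbind(a = a, b = b))
}
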