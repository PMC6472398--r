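---
title: "Calibrating A-site offsets from ribosome footprints: methods and design notes"
author: "riboAsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating A-site offsets from ribosome footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ribo-Seq reports each ribosome-protected mRNA fragment (footprint) by the
position of its 5' end. The codon being decoded — the one in the ribosomal
A-site — lies a fixed number of nucleotides Delta downstream of that end,
but Delta is not directly observable: nuclease digestion is stochastic and
trims fragments asymmetrically, so footprints of different sizes S
(20–35 nt) and different 5'-end reading frames F (0, 1, 2, measured
relative to the start codon) carry different offsets. Getting Delta wrong
by even one codon smears every downstream codon-level quantity
(pause sites, dwell times, density correlations).

`riboAsite` estimates Delta per (S, F) class by an integer-constrained
optimization rooted in one biological fact: during normal elongation the
A-site of a translating ribosome must sit between the second codon and the
stop codon of the CDS. For each gene `i`, fragment size `S` and frame `F`,
the 5'-aligned read profile is shifted 3 nt at a time — the shift must keep
the frame, hence the two integer constraints `Delta mod 3 = 0` and
`0 <= Delta <= S` — and the objective

    T(Delta | i, S, F) = sum over j in [4, N_C] of R(j, Delta | i, S, F)

counts the reads whose shifted 5' position lands between nucleotide 4 (the
first nucleotide of codon 2) and `N_C` (the last nucleotide of the stop
codon; the CDS length `N_C` includes the stop codon). The maximizing shift
Delta' is the per-gene A-site offset; the P-site offset is always
Delta' − 3.

## Coordinates and containers

All positions are CDS-anchored and 1-based: x = 1 is the first nucleotide
of the start codon, upstream positions are 0, −1, −2, …, and the frame of
any position is the mathematical modulus `(x − 1) mod 3`, which makes
frames continuous across the start boundary. Profiles are held sparsely in
a `RiboProfileSet` (gene, size, frame, position, count); gene geometry in
a `GeneModelSet`; aggregated calls in an `OffsetTable`.

For nucleases that digest the 5' side preferentially (e.g. MNase
protocols in bacteria), profiles can be anchored at the 3' end instead
(`anchor = "three_prime"`); offsets then shift toward the 5' direction
and F is defined from the 3'-end nucleotide. Everything downstream is
symmetric.

## The decision rule

Per gene, all feasible shifts {0, 3, 6, …, ≤ S} are scanned exhaustively
(there are at most 12 of them; no numerical optimizer is involved, so the
optimum is exact and deterministic). Two situations need care:

* **Close scores.** When the top two scores differ by less than the
  gene's average reads per codon, sampling noise could have swapped them.
  Two secondary criteria then arbitrate between the candidates: the
  start-codon count must be below one fifth (configurable `startRatio`)
  of the mean count of codons 2–4 (the A-site can never sit on the start
  codon), and the second codon must hold more reads than the third
  (initiation enriches codon 2, where the A-site sits while the start
  codon occupies the P-site). If exactly one candidate passes both, it
  wins; otherwise the max-score candidate stands.
* **Exact ties.** If several shifts tie for the maximum, the two largest
  tied offsets enter the secondary criteria and a remaining tie keeps the
  smaller offset. Genes whose scores are equal at *every* shift
  (typically genes with no reads near either CDS boundary) carry no
  positional information at all; they are marked `uninformative` and
  excluded from aggregation. Assigning such genes an arbitrary offset of
  0 would seed a spurious mode in the offset distribution, which is why
  exclusion was chosen.

"Average reads per codon" — used both by the closeness test and by the
gene coverage filter — is computed over the CDS plus an upstream region
one fragment length wide, divided by the number of codons. The same
window serves both purposes for consistency; the filter itself demands
more than `minAvgReadsPerCodon = 1` read per codon per (S, F) and a
multimapped-read fraction of at most 1%.

## Aggregation and diagnostics

Per-gene optima for one (S, F) are aggregated across the transcriptome:
the modal offset is called **unique** when it covers at least 70% of
informative genes (`uniqueFraction`) with at least 10 genes (`minGenes`);
with fewer genes the combination is **insufficient**; otherwise it is
**ambiguous** and the top two offsets are reported. Every call carries a
95% percentile bootstrap CI (B = 1000 by default, seeded; the indicator
vector is sorted first so the CI depends only on the gene count and the
modal count, keeping aggregation invariant to gene order).

Three diagnostics probe the stability of the table:

* `coverageTrend` re-filters genes at increasing coverage cutoffs
  (default grid 1, 2, 5, …, 50 reads/codon — the range is prescribed, the
  intermediate grid is this package's choice) and regresses the modal
  fraction (in %) on the cutoff by OLS. A combination is *resolved* when
  the slope is positive and significant at alpha = 0.05 and the final
  fraction clears the unique threshold. Cutoffs retaining fewer than 10
  genes are dropped. The reference (modal) offset is fixed from the full
  gene set rather than re-derived per cutoff; re-deriving it would let a
  drifting mode masquerade as a trend.
* `robustnessScan` re-runs detection under start ratios 1/10, 1/5, 1 and
  re-aggregates under unique fractions 0.6, 0.7, 0.8; a unique call that
  survives all nine combinations identically is labeled R (robust),
  otherwise S (sensitive).
* `consistencyCheck` compares a pooled reference table against
  per-dataset tables: a unique reference offset is consistent with a
  dataset when that dataset's modal offset matches, even below the unique
  threshold; combinations consistent in fewer than 75% of datasets are
  flagged for discard. The package ships the pooled budding-yeast offset
  table (`inst/extdata/scerevisiae_offsets.tsv`) whose two habitual
  offenders, (27,1) and (27,2), are the default `dropFlagged` set when
  building A-site profiles.

## The synthetic-data generator

Because no experiment reveals the true offset directly, validation uses
artificial Ribo-Seq data with known ground truth:

1. **Occupancies.** Translation on each gene is simulated with the
   Gillespie algorithm on an ensemble of 10 independent single-ribosome
   transcript copies: initiation (rate 1) places the A-site on codon 2
   with the start codon in the P-site, elongation steps codon by codon at
   per-codon rates (uniform by default; a slow codon emulates a pause
   site), and termination follows decoding of the stop codon. Every 100
   reactions the A-site codon of every occupied copy is recorded, so a
   codon's expected occupancy is proportional to its dwell time (1/rate).
   The kernel is ~20 lines of C++ (Rcpp) and simulates 200 reactions per
   codon of gene length by default. The model deliberately omits
   excluded-volume interactions between ribosomes, re-initiation queueing
   and collision-induced pausing: downstream tests consume occupancy
   *statistics*, not kinetics, and a single-ribosome ensemble gives the
   exact stationary dwell distribution with no extra parameters.
2. **Read budget.** Occupancy histograms are normalized to an integer
   per-gene read total by largest-remainder rounding (the integer sum is
   exact). Per-gene depth is drawn log-normally — median 50 reads/codon,
   sdlog 1.5, truncated to [2, 5000] — emulating the heavy right tail of
   pooled experimental datasets, in which a minority of deeply covered
   genes allows rarer (S, F) classes to pass the coverage filter. A flat
   depth would leave every class below the per-(S,F) filter, because each
   class receives only a pmf-share of the gene's reads.
3. **(S, F) assignment.** Each read is assigned one of the 48 ordered
   events (20,0), (20,1), …, (35,2) by a multinomial draw from a Poisson
   pmf (lambda presets 4, 8, 16, 24, 48, 80) index-shifted so its mode
   lands on (28,0) (event 24), truncated to the grid and renormalized.
   For integer lambda the Poisson pmf ties exactly at k = lambda−1 and
   k = lambda, so the event one step left of (28,0) carries equal
   probability — the documented shift is kept and the mode check accepts
   the tie. Events shifted below the grid have zero probability; with
   lambda = 8 the sizes 20–25 in frame 0 receive no reads at all, which
   is why recovery is scored both over all 48 combinations and over the
   *covered* ones (those with at least `minGenes` qualifying genes).
   Alternative presets with modes at (24,0) and (32,0) are available via
   `modeSF`.
4. **Emission.** A read for A-site codon k (first nucleotide a = 3k − 2)
   with event (S, F) and scheme offset Delta is emitted at
   x = a + F − Delta: the unique frame-F position from which Delta points
   back into the A-site codon. Reads falling below the upstream pad are
   dropped and counted (`spilled`), so read totals are conserved
   end-to-end. Ground-truth schemes: constant 15, constant 18, 12-below-
   28/18-from-28, or any user table.

What the generator does **not** emulate: nuclease sequence bias, ligation
bias, CHX-induced profile distortion, uORF/IRES contamination and
polysome collisions. Passing the recovery test therefore shows that the
optimizer inverts the generative model it was given at realistic depths —
not that real libraries are free of those artifacts; the robustness,
consistency and coverage-trend diagnostics exist precisely because real
data violate these idealizations.

## A-site profiles, baselines and pause statistics

Applying a table moves each read to the codon *containing* the shifted
nucleotide (`ceil((x + Delta)/3)`). For frame 1/2 tracks the shifted
position sits mid-codon by construction and the containing codon is
reported — codon-level assignment is the contract; sub-codon resolution
is explicitly out of scope. Baseline literature rules are available for
comparison (constant 15/18 over 27–30 nt, frame-specific 15/14/16 and
15/17/16 offsets, mESC length-specific 15/16/17, constant 15 over
25–35 nt, and center-weighting, which trims 11 nt from both ends and
spreads each read uniformly over the remainder). Normalized density
divides by the mean over **all** CDS codons (not just covered ones;
configurable by filtering beforehand), so a uniform gene sits at 1.

Pause statistics target PPX/XPP polyproline motifs, which stall the
ribosome with the third residue's codon in the A-site. The median
normalized density over motif instances (genes with at least 50% of
codons covered) is tested against 10,000 permutation draws of equal-size
instance sets from all *other* tripeptide motifs, sampled without
replacement within each draw; p is the fraction of permutation medians at
or above the observed one. Method comparisons retain instances on genes
with ≥ 90% codon coverage (pooled 5' profile over the CDS + 18 nt
upstream) and density > 1.5 in at least one method, count strict wins
only (ties are not wins), and attach a two-sided Wilcoxon signed-rank p
(withheld below 6 instances). Instances within the first five codons are
kept by default (filter the instance table beforehand to exclude them),
since the post-initiation pause is a separate, sequence-independent
phenomenon visible in `metageneDensity`.

## Numerical and design choices, in one place

* Exhaustive scan, no solver: the feasible set has ≤ 12 points.
* Window upper bound includes the stop codon (j ≤ N_C), literal to the
  objective; reads shifted beyond N_C fall out of the window (no
  wrapping, no clipping).
* Runner-up ties resolve toward the smaller offset; max-score ties are
  arbitrated as described above.
* Offsets in tables must be non-negative multiples of 3 bounded by the
  fragment size; baseline methods with nucleotide-resolution offsets are
  held in non-strict tables so the same machinery applies.
* Multimapped fraction is tracked per gene (from the NH tag, or an
  optional TSV column) and gates the filter at 1%.
* All randomness (bootstrap, emission, permutations, pipelines) is
  seeded; pipeline stages derive per-stage seeds from one master seed by
  a fixed integer hash, so stages are individually reproducible and the
  whole run is byte-identical under the same seed.
* Problem sizes used by the shipped validation: 300 genes of 150–500
  codons for offset recovery (the scale at which every covered (S, F)
  class resolves), 1,000 random tracks for the brute-force equivalence
  check, and 40 pause-site genes for the positional-specificity check.

## Limitations

The method assumes reads near the start codon arise from the annotated
CDS; uORF-rich transcriptomes need pre-filtering to single-initiation
genes, and Shine–Dalgarno-protected fragments in bacteria can defeat the
objective entirely (3' anchoring mitigates but does not remove this).
Combinations that remain ambiguous at any depth — e.g. when two offsets
are genuinely equiprobable products of digestion — should be discarded
rather than forced. Frameshifting, novel ORFs and sub-codon positioning
are out of scope by design: the method preserves the 3 nt periodicity of
the input profile.
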