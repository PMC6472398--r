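# riboAsite

Codon-level analysis of ribosome profiling (Ribo-Seq) data starts with a
deceptively simple question: given a ribosome-protected mRNA fragment
reported by its 5′ end, **which codon was in the ribosome's A-site?**
The answer is an offset Δ (in nucleotides) that depends on the fragment's
size *S* (20–35 nt) and the reading frame *F* of its 5′ end — both products
of stochastic nuclease digestion. Heuristic constants (e.g. "+15 for
28-mers") discard most fragment sizes and misplace reads for others,
diluting every downstream signal: pause sites, dwell times, density–tRNA
correlations.

`riboAsite` determines Δ(S, F) by integer programming. For each gene *i*
the 5′-aligned read profile is shifted 3 nt at a time, subject to

* 0 ≤ Δ ≤ S (the A-site lies within the fragment), and
* Δ mod 3 = 0 (shifting preserves the 5′-end frame),

and the objective

> T(Δ | i, S, F) = Σ<sub>j = 4</sub><sup>N<sub>C,i</sub></sup> R(j, Δ | i, S, F)

counts the reads that land between the second codon and the stop codon —
the only region where an elongating ribosome's A-site can be. The
maximizing Δ′ per gene is aggregated across genes; an (S, F) class gets a
**unique** offset when ≥ 70 % of genes (≥ 10 genes) agree, with bootstrap
CIs, coverage-trend, threshold-robustness and cross-dataset consistency
diagnostics. The P-site is always Δ − 3. A Gillespie-based simulator
generates artificial Ribo-Seq data with known ground-truth offsets to
validate recovery, and permutation tests quantify ribosome pausing at
PPX/XPP polyproline motifs on the resulting A-site profiles.

For whom: anyone turning Ribo-Seq libraries (yeast, mammalian, or — with
3′ anchoring — bacterial) into per-codon A-site densities, and anyone
benchmarking A-site assignment rules.

## Worked example

Simulate a dataset whose true offset is 15 nt for every (S, F), with the
experimentally typical fragment-size/frame distribution (Poisson λ = 8,
mode at (28, 0)), then recover the offset table:

```r
library(riboAsite)

sim <- simulateRiboseq(nGenes = 50, lengthRange = c(150, 300), lam = 8,
                       scheme = "const15", seed = 42)
res <- detectOffsets(sim$profiles)          # per-gene Δ′ for all 48 (S, F)
tab <- aggregateOffsets(res, B = 500, seed = 7)
subset(offsetRows(tab), size %in% 27:30,
       select = c(size, frame, status, primary, fraction, n_genes))
```

```
 size frame    status primary  fraction n_genes
   27     0    unique      15 1.0000000      44
   27     1    unique      15 0.9361702      47
   27     2    unique      15 0.9787234      47
   28     0    unique      15 0.9787234      47
   28     1    unique      15 0.9787234      47
   28     2    unique      15 0.9565217      46
   29     0    unique      15 0.9318182      44
   29     1    unique      15 0.9285714      42
   29     2    unique      15 0.9375000      32
   30     0    unique      15 0.7241379      29
   30     1    unique      15 0.8888889      18
   30     2 ambiguous      15 0.6428571      14
```

Each row is one (fragment size, frame) class: `primary` is the recovered
A-site offset, `fraction` the share of genes whose per-gene optimum agrees
(0.98 at (28,0) means near-unanimity), `n_genes` how many genes passed the
coverage filter. Well-covered classes recover the planted 15 nt uniquely;
(30, 2) sits at the coverage margin and is honestly called ambiguous
rather than forced. Comparing with the ground truth:

```r
cmp <- compareOffsetTables(sim$truth, tab)
# recovered 93% of covered combinations (15 of 48 covered)
```

Classes in the far tail of the (S, F) distribution receive too few reads
to qualify and are flagged `insufficient` — never guessed. From here,
`buildAsiteProfile()` turns profiles + table into per-codon A-site
densities, `pauseScoreTable()` scores PPX/XPP stalling with permutation
p-values, and `runDetect()` / `runValidateSynthetic()` / `runPause()`
drive the same steps from a config file (a thin CLI lives in
`inst/cli/asite-ip.R`). Real data enter via `profilesFromAlignments()`
(SAM/BAM + GFF3/GTF/BED/FASTA) or the plain TSV profile format.

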