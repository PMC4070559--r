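# vdjwin — window-based multiclonal analysis of V(D)J recombination reads

`vdjwin` analyses immune repertoire sequencing (Rep-Seq) reads for
clonality studies, e.g. minimal residual disease follow-up in leukemia. It
is built on the observation that full V(D)J alignment of every read is
unnecessary for *counting clones*: it is enough to locate, in each read, a
short fixed-length window overlapping the CDR3 junction, and to use that
window as the clone identifier.

The analysis runs in two stages:

1. **Ultrafast window prediction.** Germline V and J genes are indexed by
   their spaced-seed k-words (default TRG seed `#####-#####`, weight 10).
   Scanning a read's k-words against this index — no alignment — gives the
   strand, the end of the V evidence ($e$), and the start of the J
   evidence ($s$); reads with conflicting or insufficient evidence are
   discarded with a reason. The **w-window** (w = 40 bp for VJ loci,
   60 bp for VDJ) is extracted centered on $\lfloor(e+s)/2\rfloor$, in
   V→J orientation.
2. **Clone clustering and designation.** Windows are sorted and counted —
   identical windows define a clone, with optional bounded edit-distance
   merging (substitutions / indels / homopolymer indels, all 0 by
   default). For each of the top clones (default: 20 most abundant with
   ≥ 10 reads, plus any user-followed window) a representative sequence is
   built from k-mers supported by ≥ 50% of the clone's reads, and a
   semi-global dynamic-programming segmenter designates it against the
   germline, e.g. `TRGV5*01 -5/CC/0 TRGJ1*02` (V gene TRGV5*01 with 5
   bases deleted, two inserted Cs, undeleted J gene TRGJ1*02).

A built-in simulator generates ground-truthed germlines (TRG-like gene
lengths), recombinations (junction deletions, random N insertions) and
reads (amplicon or fragment, substitutions, homopolymer indels, random
strand), so every stage is testable against a known truth without any
external dataset. Real germline FASTA files (IMGT/GENE-DB headers are
understood) work unchanged.

## Worked example

```r
library(vdjwin)

db     <- make_synthetic_germline(n_v = 5, n_j = 3, rng_seed = 42)   # TRG-like
clones <- simulate_clones(db, 3, rng_seed = 7)
sim    <- generate_reads(clones, 2000, abundances = c(0.9, 0.09, 0.01),
                         p_sub = 0.01, p_homo = 0.005, rng_seed = 11)

report <- run_pipeline(sim$reads, db, clustering = cluster_params(min_reads = 5))
report
#> run_report: 2000 reads, 99.1% segmented, 20 clones selected
#>             SEGMENTED         UNSEG_TOO_FEW UNSEG_STRAND_CONFLICT
#>                  1982                     0                     2
#>           UNSEG_ORDER      UNSEG_WINDOW_OOB       UNSEG_TOO_SHORT
#>                    16                     0                     0

report$clones[1:3, c("seed_window", "read_count", "designation")]
#>                                seed_window read_count                        designation
#> 1 CGGGCAGCTCATGACGCTTGTTCGTTGTCTATTCCAGGTC       1178 TRGV2*01 -6/CTTGTTCGT/-1 TRGJ3*01
#> 2 TATGGACGGCTTCACCTCGGCTCGCCGCACCTGTATACAC        107   TRGV3*01 -2/CGGCTCG/-3 TRGJ2*01
#> 3 GCCGCTGATGTCCAAAAACTGTATTCCAGGTC...               18          TRGV5*01 -5//-5 TRGJ3*01
```

Reading the output: 1982 of 2000 reads got a window (the rest were
discarded with a reason, mostly chance k-word order conflicts at 1%
error). The three simulated clones are recovered as the three most
abundant window clusters — 1178/107/18 reads, matching the 0.9/0.09/0.01
abundances — and their designations equal the simulated truth
(`clone01` was generated as `TRGV2*01 -6/CTTGTTCGT/-1 TRGJ3*01`; clone 3's
printed `-5//-5` reconstructs to the identical sequence as the generated
`-5/T/-6`, the inserted T coinciding with the deleted J end). The smaller
clusters below rank 3 are sequencing-error satellites of the main clone,
each one edit from its window — exactly what the optional
`cluster_params(max_subst = 1, ...)` merging is for. Accuracy against the
simulator truth:

```r
center_accuracy(report$hits, sim$truth, tolerance = 10)$fraction
#> [1] 1
```

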