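---
title: "Window-based multiclonal analysis of V(D)J recombination reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based multiclonal analysis of V(D)J recombination reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjwin)
```

## The problem

V(D)J recombination assembles lymphocyte receptor genes from germline V,
(optionally D,) and J segments, with nucleotide deletions at the joined ends
and random, non-templated N-diversity insertions between them. The junction
(spanning the CDR3) is therefore an essentially unique fingerprint of a
lymphocyte clone, which is what clonality studies and minimal residual
disease (MRD) follow-up in leukemia rely on. High-throughput repertoire
sequencing (Rep-Seq) produces millions of reads that standard mappers cannot
place — the junction does not exist in any reference — and that full V(D)J
aligners process too slowly when the goal is merely to *count clones*.

`vdjwin` implements a two-stage strategy. Stage one is an ultrafast
heuristic that, for each read, predicts a fixed-length **w-window** centered
on the junction, using only k-word lookups in a germline index — no
alignment. Stage two groups reads into clones by exact (or bounded
edit-distance) window identity, computes one representative sequence per
selected clone, and runs a dynamic-programming V(D)J designation on that
single representative per clone rather than on every read.

## Stage one: the k-word heuristic

**Index.** Every masked k-word (under a spaced seed) occurring in a germline
V gene is labeled `V`; likewise `J`; words present in both sets are
`AMBIGUOUS` and never used as evidence. D genes are not indexed (they are
too short and too heavily trimmed to be reliable anchors). For seed weight
$k$ the index is a flat table of $4^k$ labels (build cost $O(r + 4^k)$ for
total germline size $r$), or a sorted key table above weight 12. Both modes
answer identically; this is tested exhaustively at small $k$.

**Spaced seeds.** The default TRG seed is `#####-#####` (weight 10,
span 11): the middle base of an 11 bp subsequence is a don't-care. A
substitution then destroys at most 10 consecutive masked words instead of
11, and words are recognised again as soon as substitutions are about
$k/2$ apart — this is what keeps the heuristic usable at hypermutation-like
substitution rates. TRB/IGH default to a weight-12 and TRA to a weight-13
seed; for those loci only the weight is canonical, and the single central
don't-care is chosen by analogy with the TRG seed.

**Per-read decision.** Each read position contributes the label of its
k-word on the forward strand and of its reverse complement. Reads are
discarded when: they are shorter than the seed span; both strands carry
more than `strand_tolerance` informative (unambiguous V/J) hits (default 1,
so a single stray opposite-strand hit is forgiven); after choosing the
majority strand there is no V or no J evidence; or the first J word starts
before the last V word begins. Otherwise, with $e$ the last base covered by
the last V k-word and $s$ the first base of the first J k-word, the
predicted center is $\lfloor (e+s)/2 \rfloor$ and the window is the $w$
bases centered there, always reported in V→J orientation. Overlapping
V/J words ($e \ge s$) are allowed — junction deletions can legitimately
bring them together.

Numerical conventions decided here (the method description leaves them
open): the center tie is broken by `floor`; windows that would overrun a
read end are discarded (`UNSEG_WINDOW_OOB`) rather than clipped, because a
clipped window could never equal a full window and would break exact-match
clustering. On clean data the predicted center equals the floored midpoint
of the N region up to a 1 bp parity shift: a flanking k-word stretches one
base into the junction whenever the adjacent junction base coincides with
the germline continuation (probability about 1/4 per side).

**Window length.** `w = 40` for VJ loci and `w = 60` for VDJ loci (whose
insert is N1+D+N2 and can be much longer), so that a centering error of
10–15 bp still leaves the complete insert plus germline flanks inside the
window. `w` must be even, which makes the centering arithmetic exact.

## Stage two: clones, representatives, designations

**Clone definition.** Clones are sets of reads with *identical* windows —
sorted, counted, and ordered by count (descending) then window
(lexicographic), so every output is deterministic. This definition is
deliberately stringent: sequences differing only in N bases belong to
different clones, and merging them by default would destroy exactly the
signal MRD tracking needs. Bounded-distance merging (substitutions, plain
indels, homopolymer indels counted separately — the homopolymer class
matches the characteristic error of flow-based sequencers such as Ion
Torrent) is available but defaults to zero tolerance. The merge algorithm
is a greedy pass in table order comparing each window to the seed windows
of already-formed clusters; the method description prescribes only the
pairwise bounded-distance criterion, and greedy-to-seed is the
deterministic, near-linear choice. User-specified window pairs merge
unconditionally before the automatic pass. Edit triples are computed on a
lexicographically canonicalised pair, which makes the reported triple
symmetric by construction.

**Selection.** The `top_n = 20` most abundant clones with at least
`min_reads = 10` reads are processed further; user-followed windows are
always reported, flagged, regardless of rank. Unselected clones still count
toward the segmented total, so abundance ratios are unaffected.

**Representative.** All k-mers of a clone's reads are counted as
presence-per-read (the support threshold, default 50%, is expressed in
*reads*, so occurrences within one read must not inflate counts). A
representative region is a maximal run of read positions whose every k-mer
reaches the support threshold; the longest such region across the clone's
reads is returned, preferring regions that fully contain the clone window
over regions that merely overlap it (the downstream designation needs
germline flanks on *both* sides of the junction), with the window string
itself as a final fallback. Ties go to the earliest read, then leftmost
region. `k_rep` defaults to the locus seed weight.

**Designation.** The representative is aligned against all germline genes
by semi-global dynamic programming (linear gaps; match +2, mismatch −1,
gap −2 — the method description specifies no scheme, and these simple
unit-style costs are easy to verify against brute force). For every split
point the best V alignment ending at or before it and the best J alignment
starting after it are combined, and the split maximising the summed score
wins; equal-score splits prefer the longer V, then the longer J. The score
DP fixes the genes and the approximate split. The *reported boundaries*,
however, come from a refinement: the longest exactly germline-matching run
on each side. A pure score maximiser will happily absorb random N bases
that only partly resemble a deleted germline end (a few chance matches
outweigh one mismatch), which would make the designation imply bases the
sequence does not contain; with exact-run boundaries, a designation always
reconstructs — germline-prefix + N + germline-suffix — to the very sequence
it was derived from, so designations can be compared as equivalence
classes by their reconstruction. Junction bases that genuinely coincide
with a deleted gene end may still be attributed to the gene; that
attribution wobble is unresolvable in principle and harmless under
reconstruction equality. D genes are assigned as the longest exact D run
inside the N region when it reaches `d_min_score` (default 8, i.e. 4
matched bases at default scoring); V or J scores below `min_score`
(default 10) flag the clone as window-only. Designations print in the
compact field notation, e.g. `TRGV5*01 -5/CC/0 TRGJ1*02` (five bases
deleted from the V 3' end, two inserted Cs, no J deletion).

## The simulator

The simulator is first-class, tested code: it is the ground truth every
stage is evaluated against. It emulates a TRG-like locus by default —
uniform-ACGT V genes of 250–310 bp, J genes of 40–70 bp (D genes
10–35 bp when requested), the typical segment lengths for these loci —
and regenerates the germline until the locus seed yields zero ambiguous
index words, the property the real TRG germline has under the weight-10
seed. Recombinations draw genes uniformly, end deletions uniformly from
[0, 8] bp and N lengths uniformly from [0, 10] bp: plausible ranges for
TRγ junctions (observed deletions of 0–5 and inserts of 0–4 nt fall well
inside them), configurable because the true distributions are biological
unknowns, not claims of this package. Reads are full amplicons or uniform
random fragments; substitutions are i.i.d. per base (never resampling the
original base) and homopolymer ±1 bp indels occur per run of length ≥ 2,
Ion Torrent-style. The truth sidecar carries each read's clone, strand,
and junction center *after* all coordinate transformations — indels
upstream of the junction shift the truth coordinate; the strand flip does
not, because truth is kept in V→J orientation.

What the simulator does **not** model: PCR amplification bias, chimeras,
primer and concatenation artifacts, clustered (as opposed to uniform)
hypermutation, quality-value structure, and real germline homology
(synthetic genes are i.i.d., so they are *easier* to tell apart than real
V alleles of one family). Passing tests therefore demonstrate the
algorithmic contracts — window identity, conservation, recovery within
binomial error — on idealised reads, not sequencer-grade performance on a
real repertoire.

## Evaluation and problem sizes

`center_accuracy` compares predicted window centers with the simulator
truth over reads that were both window-predicted and junction-covered,
reporting the fraction strictly within a tolerance plus the full distance
histogram; `abundance_recovery` maps each simulated clone to its window by
running the heuristic on the clone's own sequence and compares read
fractions. The package's evaluation runs use a 5 V / 3 J synthetic TRG
germline, 10 equally abundant clones (the clone count is the study
condition; the abundance split is this package's choice, stated here
because the condition leaves it open), and 10,000 amplicon reads per
condition: a low-error condition (1% substitutions, 0.5% homopolymer-run
indels) and a hypermutation-like condition (6% substitutions). Typical
results: ~99.9% of evaluated reads within 10 bp at low error, and ~99.5%
within 15 bp at 6% substitutions — the heuristic's accuracy degrades only
marginally under hypermutation-scale noise, which is the property that
makes window-based clustering safe. Abundance recovery is exercised with
fractions 0.9/0.09/0.009/0.001 at 100,000 reads and recovered within four
binomial standard deviations. Property suites run at deliberately tiny
sizes (germlines of ≤ 5 genes of ≤ 60 bp, windows ≤ 12 bp, designation
instances of ≤ 15 bp against ≤ 9 bp genes) where brute-force oracles are
exact and cheap.

## Known limitations

* The heuristic needs at least one clean k-word in each of V and J; very
  short J segments (or J ends eroded beyond `span` bases) make reads
  undetectable rather than wrong — they are counted in the discard
  statistics.
* Clone definition by window is locus-local: the same biological clone
  sequenced over two loci is two clones.
* The designation is a first hint, not an IMGT-grade junction analysis:
  no allele-level mutation profiling, no productivity/frame call, and the
  exact-run boundary convention deliberately sacrifices mutated flanking
  bases (they end up in N) for reconstruction faithfulness. On a clone
  representative — which is majority-supported and therefore nearly
  error-free — this costs little.
* Automatic clustering compares candidates to cluster *seeds* only
  (greedy): two windows each within bounds of a middle window but not of
  each other may end up split or merged depending on abundance order.
  This is the documented, deterministic behaviour.
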