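Package: vdjwin
Title: Window-Based Multiclonal Analysis of V(D)J Recombination Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage analysis of immune repertoire sequencing (Rep-Seq)
    reads. A spaced-seed k-word heuristic locates, for each read and
    without any germline alignment, a fixed-length window overlapping the
    CDR3 junction of a V(D)J recombination. Reads are then grouped into
    clones by exact (or bounded-edit-distance) window identity, each clone
    receives a representative sequence built from clone-wide k-mer
    support, and the representative is given a refined V(D)J designation
    by semi-global dynamic programming against germline genes. A built-in
    simulator generates ground-truthed germlines, recombinations and
    error-bearing reads so that every stage can be evaluated against a
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
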