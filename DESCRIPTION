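Package: knotscan
Title: Descriptor-Based Search for RNA Structural Motifs with Pseudoknots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finds occurrences of RNA structural motifs in nucleotide
    sequences.  A motif is written as a descriptor: an ordered map of
    single-stranded and helical elements with IUPAC sequence constraints,
    wildcards, and per-element budgets for mismatches, mispairs and
    single-base bulge insertions.  Helices may interleave arbitrarily, so
    pseudoknotted topologies are fully supported.  Sequences are scanned in
    overlapping windows by a backtracking search whose per-element matching
    is exact dynamic programming; the element search order is chosen
    automatically by information-content and flexibility heuristics combined
    with online statistical elimination of candidate orders (timed races
    decided by one-sided Welch t-tests).  Includes a synthetic-data
    generator that plants motif occurrences at known coordinates and an
    exhaustive brute-force oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
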