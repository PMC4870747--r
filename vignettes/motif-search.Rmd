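---
title: "Descriptor-based RNA motif search: model, heuristics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based RNA motif search: model, heuristics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotscan)
```

## The problem

Functional RNAs — ribozymes, riboswitches, aptamers — are conserved far
more strongly in secondary structure than in sequence.  A practical way to
find new family members in genomic DNA is a hand-written *descriptor*: an
ordered list of structural elements, each with sequence constraints in
IUPAC notation, and small budgets for deviations.  knotscan implements a
complete descriptor language, an exact windowed backtracking search over
DNA/RNA sequences, and an automatic choice of the element search order.

Two element kinds exist:

* **single-stranded elements** (`s1 m:i PATTERN`) — a run of IUPAC classes
  and wildcards `*`.  A wildcard matches one arbitrary nucleotide or the
  empty string, so a block of $k$ wildcards gives up to $k$ bases of length
  flexibility.  Up to $m$ mismatches (a base outside its class, chargeable
  only at non-wildcard tokens) and $i$ internal single-base insertions are
  tolerated.
* **helical elements** (`h1 m:r:i PAT5:PAT3 [PAIRS]`) — two column-aligned
  strand patterns; `PAT3` is written 3'→5' so column $j$ of both strands
  forms one base pair, checked against an allowed-pair set (Watson–Crick
  by default, wobble pairs by adding `GT,TG`).  Budgets: $m$ sequence
  mismatches summed over both strands, $r$ mispaired columns, and $i$
  single-base bulges on either strand, no two adjacent.

Each helix appears twice in the motif map (`h1` for its 5' strand, `h1'`
for its 3' strand) and the map imposes **no restriction on interleaving**,
so arbitrary pseudoknots — e.g. `h1 h2 h1' h2'` — are expressible.
Occurrences tile a contiguous region: consecutive map occurrences are
adjacent on the sequence.

## Matching and the windowed backtracking search

Element matchers are exact dynamic programs (implemented in C++).  For a
single strand the state is (pattern position, text chars consumed,
mismatches, insertions, trailing-insertion flag); for a helix the match is
grown **outside-in** from the candidate pair (first 5' base, last 3' base)
with state (columns processed, columns consumed, bulges per strand,
mismatches, mispairs, adjacency flag).  The adjacency flag is set by a
bulge and cleared by a column consumption, which enforces "no two
insertions adjacent" — at most one bulge between consecutive paired
columns.  Each distinct interval (or interval pair) is reported once with
the lexicographically minimal distortion counts over all alignments that
produce it.

Semantics worth spelling out, since they interact:

* a column of a helix may be skipped only when **both** tokens are
  wildcards; a wildcard opposite a concrete class consumes a free base that
  must still satisfy the pair constraint;
* every consumed column is pair-checked (a helix is a helix); wildcard
  columns contribute all 16 base combinations to the information-content
  bound below, which therefore stays an upper bound;
* an `N` in the *text* (assembly gap, masked base) matches only the fully
  degenerate class and never forms a valid pair — conservative, so gaps do
  not fabricate hits;
* insertions are internal: a bulge or single-strand insertion must sit
  between two consumed positions.  Flanking insertions would be
  indistinguishable from slack belonging to the neighbouring element;
* a helix must pair at least one column, so degenerate all-wildcard
  helices cannot match emptily.

Sequences are scanned in windows of $\max\{20L, 3000\}$ bases, where $L$
is the maximum occurrence length, with consecutive windows overlapping by
exactly $L$ — every occurrence is complete in at least one window, and
duplicates from the overlap are removed by their full interval tuple.
Within a window the elements are matched in some order; after fixing a
match, the next element's *search domain* (allowed start interval, end
interval, and a mandatory-cover interval) follows from the nearest fixed
occurrence on each side plus the min/max total length of the unfixed
elements in between.  For a helix both strands get a domain, plus a joint
bound on the gap between them when nothing in between is fixed yet.
Domains are deliberately *relaxations*: they never exclude a placement
that completes to a full occurrence, which is why the result set is
provably independent of the search order (a property the test suite
checks against a brute-force oracle on hundreds of random instances).

Reverse-strand hits come from scanning the reverse complement; they are
reported with strand `-` and forward-axis coordinates.  Coordinates are
internally 0/1-mixed but all user-facing coordinates are 1-based inclusive;
an empty match at position $s$ is the interval $[s, s-1]$.

## Choosing the search order

The search order changes the running time by orders of magnitude but never
the results.  Two per-element heuristics feed the automatic choice:

**Information content** $h_1$: starting from the background entropy of a
random sequence of the element's maximum length $N$ ($2N$ bits single, $4N$
bits for a helix's column pairs), we subtract $\log_2 X_U$, where $X_U$
upper-bounds the number of sequences that match.  $X_U$ is a product of

* per-position class sizes $C[i]$ (per-column valid-pair counts $P[j]$ for
  helices);
* per wildcard block of length $k$: $4^k(k+1)$ (helices: $16^k(k+1)$) —
  the block's bases are free and may be split between used and unused;
* a mismatch/mispair factor: the exact sum over at most $m$ (resp. $r$)
  violated positions, each contributing $4-C[i]$ (resp. $16-P[j]$) instead
  of $C[i]$ ($P[j]$), computed by a small polynomial DP;
* an insertion factor $4^i\sum_{j\le i}\binom{N+1}{j}$ for single strands
  and $4^{2i}\sum_{j\le i}\binom{2N+2}{j}$ for helices.  The $4^i$ (and
  $4^{2i}$) terms matter: an unused insertion-budget unit leaves a free
  tail position beyond the anchored match (one per strand for helices).
  Without them the factor is *not* an upper bound — enumeration of the
  helix `GG:CC` with one allowed bulge gives 40 matching sequence pairs
  against a purported bound of 17.  With them, exhaustive enumeration over
  the test grid (single strands to $N=8$; helices to $N=4$, where the
  $4^{2N}$ pair enumeration is still affordable) confirms
  $X_U \ge X$ whenever the mismatch budget is zero.  The mismatch factor
  is exempted by design: it is an accurate estimate rather than a
  guaranteed bound.

A fully specified element of length $N$ scores exactly $2N$ bits, an
all-`N` element 0 bits.  High $h_1$ = specific = few matches = good early
filter (the classic fail-first rule).  $X_U$ can reach $0$ only for an
element whose mandatory columns need more mispairs than budgeted; it is
floored at 1 so $h_1$ stays finite.

**Flexibility** $h_2$: for a candidate element, sum the length
flexibilities (max − min) of the map occurrences separating it from the
nearest already-ordered element on each side; take the minimum over sides
that have one, the single available side's value otherwise, and 0 for the
very first element (a constant offset cannot change the ranking at
position 1).  For a helix, compute per strand with the other strand
treated as fixed and take the maximum.  $h_2$ proxies the expected search
domain size.

An ordered $k$-tuple ($k = 3$ by default) scores
$$h(e_1,\dots,e_k) = \sum_{i=1}^{k} 2^{k-i}\,\bigl(c_1(e_i)\,h_1(e_i) + c_2\,h_2(e_1,\dots,e_i)\bigr)$$
with $c_1 = 3$ for single strands, $1$ for helices (single-strand matching
is much cheaper), and $c_2 = -0.2$.  Tuples scoring at least 85 % of the
maximum (at most 50) are completed to full orders by decreasing $h_1$ and
form the candidate set.

**Online elimination.**  Heuristics mispredict, so the candidates are
raced on the actual input: each window is searched with a uniformly drawn
surviving candidate and its process CPU time, normalized by window length,
is recorded.  After each new sample the sampled candidate is tested
pairwise against every survivor with a one-sided Welch $t$-test (unequal
variances, Welch–Satterthwaite degrees of freedom); the slower of a
significantly different pair is eliminated at $\alpha = 0.01$.  If both
members of a pair reach 75 samples without significance, the higher sample
mean is dropped (ties: the later candidate in proposal order).  When one
candidate survives, its leading $k$-tuple is frozen and the *next*
$k$-tuple is raced over the remaining elements (with $h_2$ evaluated
against the frozen prefix), until the order is fully fixed; fewer than $k$
remaining elements are trained as one shorter tuple.  If the input runs
out first, the current lowest-mean candidate finishes the scan.  Because
results are order-invariant, every window processed during the race
already contributes its occurrences; timing only affects speed.

The timing source is injectable (`timer` argument), which makes the
controller deterministic under a stubbed clock — that is how the test
suite verifies that a candidate with stub mean 1.0 (sd 0.1) eliminates one
with mean 10.0 (sd 1.0) in at least 95 of 100 seeded runs, and that the
occurrence set equals a fixed-order run's.

## Synthetic data and the oracle

`sample_occurrence()` realizes a descriptor as a concrete string (classes
sampled from their base sets, helix columns from the allowed pairs
intersected with the classes, wildcard usage sampled);
`generate_planted_sequence()` plants non-overlapping realizations in an
i.i.d. background (uniform bases by default, GC configurable).  The
generator emulates motif occurrences at known coordinates in random
background; it does **not** emulate genome composition (repeats,
isochores, biased dinucleotides) or distorted occurrences beyond what the
budgets allow, so passing recovery tests demonstrates correctness of the
search, not sensitivity on real genomes.

`brute_force_search()` is the independent oracle: it enumerates every
contiguous tiling of intervals over the map and validates each element by
plain recursive alignment enumeration — no DP tables, no domains, no
windows — and refuses instances beyond ~250 nt or 6 elements.  The
equivalence suite compares engine and oracle on 200 seeded random
instances (3–6 elements including pseudoknotted topologies, strand
lengths ≤ 6, budgets ≤ 2, texts of 100–200 nt with one planted
occurrence so instances are not vacuously empty).

Two bundled descriptors, both clearly labelled synthetic, mirror
classical topologies: an aptamer-like motif (two nested helices, three
single strands) and an HDV-ribozyme-like motif whose four helices form a
double pseudoknot.  Their sequence content is invented; only topology and
element counts are meaningful.  The planted-recovery suite plants the
HDV-like motif in 10 kb sequences (20 sequences × 3 plants) and requires
all 60 spans back on `+`, and again on `-` after reverse-complementing
the input; the bundled descriptor carries ≈ 85 bits of information
(summed per-element $h_1$), so chance background hits are expected at
rates below $10^{-20}$ per 10 kb sequence and do not occur at test
scale.

## Numerical and design choices

* **Problem sizes in the checks** were chosen to keep the full suite
  around two minutes on one core: 200 oracle instances, 50 × (5 orders + 3
  window sizes) invariance runs, 20 planted 10-kb sequences, an
  enumeration grid of 108 elements, 100 stubbed DDEO races and 100 Welch
  comparisons.
* **Degenerate Welch inputs** (fewer than two samples or two zero-variance
  samples) return the neutral p = 0.5, so nothing is eliminated on
  garbage.
* **Score threshold with negative maxima**: "at least 85 % of the
  maximum" is read multiplicatively for positive maxima and as
  $\max - 0.15\,|\max|$ otherwise, so the retained set is never empty.
* **Tie-breaks** are lexicographic everywhere (candidate proposal, h1
  completion, match sorting) for reproducibility; a seed fixes the DDEO
  draws.
* **Helix mismatch accounting**: one shared mismatch budget over both
  strands (symmetric and strictly more expressive than exempting one
  strand).
* **Occurrence identity** is the full per-element interval tuple; the
  oracle uses the same definition, so equivalence is testable.
  `collapse_spans = TRUE` gives the one-representative-per-span view.
* The optional shift-and prefilter is exact only for fully specified
  patterns without budgets; for anything else it returns all domain
  positions, which trivially satisfies its superset contract.

## Known limitations

* No scoring or energy model: a hit either satisfies the budgets or does
  not; no E-values.
* The backtracking search is exponential in the number of elements in the
  worst case; descriptors whose early elements are unspecific (low $h_1$)
  can be slow, which is precisely what the ordering machinery mitigates
  but cannot always overcome.
* Pure-R brute-force oracle and enumeration counters are test
  infrastructure; they blow up quickly and are guarded accordingly
  (helix enumeration stops at strand length 4 because it scales as
  $4^{2N}$).
* The descriptor dialect is semantically equivalent to, but not
  byte-compatible with, the file formats of other descriptor-based tools.
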