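---
title: "Mining piggyBac transposons: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining piggyBac transposons: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

piggyBac (PB) elements are Class II (cut-and-paste) DNA transposons.  A
complete copy is 2.2-3.5 kb long and carries short terminal inverted
repeats (TIRs, typically ~14 bp, occasionally 200-500 bp), a strict TTAA
target-site duplication (TSD) on both flanks, and a single ORF encoding a
transposase of roughly 580 aa with five recognisable regions: NTD, DDBD1,
the catalytic (DDD) domain with its three aspartates and an insertion
motif between the second and third, DDBD2 (opening with a conserved
tryptophan), and a cysteine-rich domain (CRD) with seven regularly spaced
cysteines.  Annotating these elements in an assembly means (i) finding
loci that encode PB-like transposases, (ii) resolving element boundaries
from TIR/TSD geometry, (iii) classifying copies, (iv) counting genomic
copies per family, and (v) summarising each family's age structure and
clade membership.  pbmine implements that workflow end to end, plus a
simulator that plants elements with known structure so every stage can be
scored against a truth table.

## Pipeline model, stage by stage

**Translated seeding.**  `protein_search()` re-implements a TBLASTN-style
search as exact 5-mer protein seeding over the six translation frames,
followed by Smith-Waterman extension (BLOSUM62, affine gaps, gap open 11 /
extend 1) of each seed cluster against the reference protein.  The
original protocol filtered at a tool-specific e-value (1e-100); a raw
score threshold is the desk-scale, dependency-free analogue.  The default
`min_score = 150` was calibrated once on dinucleotide-shuffled genomes:
the largest noise score observed on shuffles of a few hundred kb was ~53
(extrapolating extreme-value growth to 2 Mb adds roughly +6), while true
hits score ~370 (a 100-aa fragment) to ~2900 (a full-length match).  The
threshold is therefore far from both distributions and is not tuned per
dataset.  Candidate loci are hit intervals extended by 2000 bp flanks and
merged when they overlap (`build_loci()`).

**TIR/TSD boundary resolution.**  `find_tir_pairs()` enumerates *maximal*
inverted-repeat arm pairs under a mismatch budget (default 2; arms 10-500
bp), using an anti-diagonal scan implemented in C++ and checked in the
test suite against an exhaustive enumeration oracle.  Two non-obvious
choices:

* *Search window.*  Arms must start within `search_window` bp of the
  locus edges.  The window defaults to 45% of the locus length rather
  than a bare first/last quartile: loci are anchored on the transposase
  CDS, so with 2 kb flanks plus the element's internal UTR margins the
  true arms sit just outside the first 25% of the locus.  45% keeps the
  window tight enough to exclude deep-interior palindromes while always
  covering the flank-plus-margin region.

* *TSD-anchored trimming.*  TTAA is its own reverse complement, so for a
  canonical insertion the inverted repeat does not stop at the element
  edge: it continues through both TSDs and often a few chance bases of
  flank.  A maximal pair therefore overshoots the element boundary, and
  ranking raw pairs by their flanking 4-mers would essentially never see
  TTAA/TTAA.  `select_element()` evaluates each maximal pair at outer
  trims of 0-10 bp and ranks all variants: canonical TSD first, then
  equal (mutated) TSDs, then longer arm, fewer mismatches, leftmost
  start.  The reported element interval is the trimmed one.

* *Reported TIR length.*  The tabulated TIR length is the perfect
  (0-mismatch) inverted-repeat arm anchored at the selected element
  edges.  The budgeted maximal arm absorbs up to `max_mismatch`
  mismatches and a geometric tail of chance matches (~4 bp expected at
  budget 2), which would systematically overstate the TIR; the budgeted
  arm's length and mismatch count are still reported as
  `pair_arm_length` / `pair_mismatches`.  For elements whose planted arms
  themselves contain mismatches (the generator's `arm_mismatch` option),
  the measured length stops at the first mismatch and thus underestimates
  the planted arm; this is a documented limitation of the 0-mismatch
  convention, not of the pair search.

**Annotation.**  PB transposases are single-ORF, so gene prediction
reduces to `find_longest_orf()` (ATG-initiated, stop-terminated, both
strands, 100 aa floor -- the same floor the comparative stage uses).
`scan_domains()` aligns the protein globally to the bundled clade
consensus and maps the consensus triad positions through the alignment,
reporting residues verbatim so D-to-N or D-to-H losses stay visible; the
CRD check walks the seven-cysteine ladder allowing each rung +/-2 of the
consensus spacing (and tolerating extra chance cysteines).  Classification
follows the published definitions exactly: detectable TIR+TSD = *full*;
full and >= 500 aa transposase = *intact*; otherwise *truncated*.  An
intact label deliberately does not require an intact triad -- the
published counts are length-based -- so the triad flag is carried
separately.

**Census.**  `search_copies()` is a seed-and-extend nucleotide search
(11-mer words, local alignment at +1/-2 with affine gaps).  Identity is
matches over all alignment columns including gaps (the stricter
convention; the source protocol never defines "similarity"), coverage is
aligned query bases over query length, and a hit is counted iff coverage
> 40 AND identity > 80, both strict, mirroring the published
inequalities.  Hits overlapping a better hit by more than half their
length are suppressed (one copy, one count).  A cluster must also seed at
least 60 distinct query bp before extension; scattered chance 11-mers
rarely exceed ~30-50 bp, while genuine copies seed hundreds even at 25%
divergence, so this filter buys a large constant-factor speedup without a
sensitivity cost in the censused identity range.  When a family has more
than 10 counted copies, a majority-rule consensus over a star alignment
to the representative replaces the representative as the query
(`build_consensus()`); ties go to the representative's base and
gap-majority columns are dropped.  Insertions relative to the
representative are ignored -- adequate below ~20% divergence, where this
pipeline operates.

**Divergence dynamics.**  `count_substitutions()` aligns copy and
consensus globally and tallies transitions/transversions over gap-free
columns; `kimura_distance()` is the K2P closed form
K = -50 ln[(1-2P-Q) sqrt(1-2Q)].  Copies outside the estimator's domain
raise a typed saturation condition and are excluded from landscapes (with
a count).  `divergence_landscape()` bins each copy's aligned bp by its K
(1% bins), expressing bin mass as percent genome coverage -- the standard
repeat-landscape picture.  `call_age()` formalises the narrative reading:
*recent* when the majority of copy bp lies in bins entirely below 2% K,
*old* when the majority lies in bins entirely above 15% K.  "Entirely"
matters at the boundary: a copy at exactly K = 15 sits in bin [15,16),
which contains the cutoff, so it does not count as old -- matching the
strict "K > 15" phrasing.  Multi-wave calls require two local maxima at
least 3 bins apart, each holding at least 10% of copy bp.

**Comparative stage.**  Pairwise identity is global-alignment matches
over all columns.  The tree is a from-scratch neighbor-joining
implementation (`nj_tree()`) on distances (100 - identity)/100 --
deliberately an uncorrected distance, documented as such.  Maximum
likelihood inference with model selection was out of scope; NJ recovers
additive trees exactly and the downstream consumer is clade membership,
not branch-length inference.  The test suite checks NJ against both
random additive trees and an established implementation.
`assign_clades()` roots on the bundled outgroup and gives each query the
clade of the smallest rooted cluster containing it and references of a
single clade; mixed clusters yield "unassigned", and the number of clades
is whatever the references support -- three is a property of the bundled
set, not a constant in the code.  TIR logos are left-anchored (the TIR
start is the element edge), right-padded, with information content
2 + sum f log2 f per column.

## The synthetic genome: what it emulates, what it does not

`generate_genome()` plants elements with the structural statistics of
complete PB copies: configurable element length (default 2.5 kb), TIR
length (default 14 bp, CACTA/TACCG-prefixed, matching the conserved
terminal motifs), TTAA TSDs duplicated at both flanks, and a transposase
CDS obtained by reverse-translating a bundled clade consensus with
synonymous-site randomisation -- guaranteeing that the DDD triad and CRD
ladder exist for the annotation stage to find.  Copies are assigned to
divergence waves and mutated under an exact K2P site model: for target
divergence k and transition/transversion rate ratio kappa, per-site
substitution probabilities are the closed-form P(t), Q(t) with t chosen
so the expected K2P estimate equals k; this makes measured divergence an
unbiased estimator of the planted value (verified at n = 30 x 2.5 kb to
within +/-1.5 percentage points).  Truncated copies lose a uniform-random
20-50% prefix or suffix, including one TIR and its TSD.  Background is
i.i.d. at 38% GC -- roughly a bee genome's composition.

Deliberate idealisation, and hence what a green test does *not*
establish: no host genes, no nested or fragmented insertions beyond
simple end-truncation, no indel divergence (K2P is substitution-only; an
indel mode is left as an extension), no CpG-adjusted rates, and spacers
are scrubbed of ATGs so the planted ORF length is exact.  Two small
stated-world conventions keep the truth table well defined: planted
elements keep a minimum spacing (default 5 kb) so the 2 kb-flank loci of
distinct elements never merge, and one base just inside each TIR is
forced non-complementary so the planted TIR length is exactly
recoverable.  Real data violate all of these; the simulator validates the
machinery, not the field performance.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED outputs;
  human-readable tables add 1-based columns.
* `mutate_copy()` rejects targets above 150% K: the model's expected P
  and Q never saturate at finite divergence, but finite-sequence
  estimates far beyond that range are meaningless.
* NJ branch lengths that come out negative on non-additive input are
  clamped to zero and counted in an attribute.
* Ties in `select_element()` resolve canonical > equal-flank > longer arm
  > fewer mismatches > leftmost -- a total order, so results are
  deterministic.
* A non-monophyletic outgroup (possible on real trees) falls back to
  rooting on a single outgroup leaf.
* All randomness flows through explicit seeds; the same configuration and
  seed reproduce byte-identical artifacts, which the test suite asserts.

## Bundled reference set

The 3 clade consensuses, 13 clade references and 10 IS1380-like outgroup
proteins under `inst/extdata/` are **synthetic stand-ins** (the original
reference collection is not redistributable from a desk build): random
proteins structured so that the catalytic domain is the most conserved
between clades, the NTD the least, landmarks (triad, tryptophan, CRD
ladder) sit at fixed consensus coordinates recorded in
`pb_domain_annotation.json`, and the outgroup forms a coherent distant
family so it can root the tree.  They reproduce the *relationships* the
pipeline depends on, not any real sequence.

## Known limitations

Sub-terminal repeats (STIRs) and MITE derivatives are not searched;
e-values are not computed (raw scores only); the census assumes the query
family is known from the seeding stage rather than performing de novo
repeat discovery; and long-TIR elements with internal arm mismatches have
their tabulated TIR length measured only to the first mismatch.
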