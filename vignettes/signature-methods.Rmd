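---
title: "PSSM-based species signatures: model, parameters and design choices"
author: "barcodesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSSM-based species signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodesig)
```

## The model

`barcodesig` treats a DNA-barcode alignment as a stack of independent
multinomial columns. For an alignment `X` of `N` sequences and `c`
columns, the position probability matrix (PPM) is

$$M_{k,j} = \frac{1}{N}\sum_{i=1}^{N} I(X_{i,j} = k),
\qquad k \in \{A, C, G, T\},$$

the per-column relative frequency of each base. The assumptions are the
usual PSSM ones: columns are treated independently, and the alignment
is taken as given (the package consumes aligned FASTA; any upstream
aligner may be used). On gap-free columns each PPM column sums to 1.

Each sequence is summarized by its probability vector,
$v_i[j] = M_{X_{i,j},\,j}$ (zero at gap positions), and species
resolvability is judged by Euclidean distances between these vectors:
a species pair is *discriminated* when its minimum between-species
distance strictly exceeds the maximum within-species distance of both
species **and** is nonzero. This is the barcoding-gap concept
operationalized with the most conservative summaries (min versus max);
the per-species tally then requires success in *all* of a species'
pairs. Both choices are deliberate strictest readings — the underlying
rule is stated only as "inter higher than intra and nonzero", so we
default to the reading that cannot overstate discrimination and expose
`pair_policy = "all" | "any" | "majority"` for the tally.

A known degeneracy of the probability-vector representation: two
sequences carrying *different* bases in a column with equal base
frequencies (e.g. C/T at 50/50) receive identical vector entries and
can collapse to distance zero. The rule's "nonzero" clause then
correctly refuses to count such pairs as discriminated; the pair table
makes the zero visible rather than hiding it.

## Site discovery and signatures

Diagnostic sites are discovered twice:

* **Genus level** — per-genus majority consensus sequences are
  compared column-wise; any column where at least two consensuses
  disagree is a genus-level site. No frequency threshold is applied at
  this level because consensus disagreement is already a
  majority-level signal.
* **Species level** — within one genus, a column is a species-level
  site when every species is fixed (no within-species polymorphism,
  no gaps) and at least two species carry different bases. Fixation is
  required because a signature must match *all* conspecific sequences;
  a polymorphic column would cap recall below 1 by construction.

Sites from both levels are pooled per species and deduplicated by
column. Each site maps through the alignment-to-ungapped coordinate
map onto a chosen exemplar sequence (the species' first record) and
expands to a window of `flank` conserved bases per side. The default
`flank = 6` yields 13-mer patterns around isolated sites — long enough
that a pattern rarely occurs by chance in a ~700 bp locus
(expected ≈ 700/4^13 ≈ 10⁻⁵ random hits), short enough to keep
signatures compact; it is a plain parameter for other trade-offs.
Overlapping or adjacent windows merge. The signature is the ordered
pattern series joined by **exact** inter-pattern distances,
`lit1.{g1}lit2...`; distances are exact rather than ranged because an
indel between patterns is real biological signal against the target
species, and exactness is what gives signatures their specificity. A
`tolerance` parameter (`.{d-t,d+t}`) exists for noisy amplicons and
defaults to 0.

Candidate signatures for a species are the refinement trajectory
seeded from its species-level sites (falling back to genus-level sites
when a genus holds a single species) plus the all-sites signature.
Greedy refinement adds, while false positives remain, the unused site
whose addition removes the most FP without losing TP; the selected
candidate maximizes F-measure with deterministic tie-breaks (higher
recall, fewer patterns, shorter span, lexicographic regex). Species
whose target set cannot be matched by any candidate are reported with
a per-sequence diagnosis (`diagnose_miss()`): which pattern is absent,
or which inter-pattern distance was broken and by how much — the
practically important failure mode for fixed-distance signatures.

## Evaluation

Recall `TP/(TP+FN)`, precision `TP/(TP+FP)` (defined as 0 when
`TP+FP = 0`) and the balanced F1 are computed per signature; sequences
count at most once however many times a signature occurs. F bins into
categories A `[0.75, 1]`, B `[0.50, 0.75)`, C `[0.25, 0.50)`,
D `[0, 0.25)`; intervals are closed on the left and the boundaries are
applied to exact values, not rounded displays, so 0.7499… is B and
0.75 is A. Classification of queries is forward-strand only by default
(barcode amplicons are deposited in a canonical orientation);
`both_strands = TRUE` reverse-complements unmatched queries. `N` in a
query can never satisfy a literal (literals are pure A/C/G/T) but may
sit inside an inter-pattern run, mirroring how ambiguous bases behave
in regex search.

## Gap handling and coordinates

Gap-rich columns are removed before PSSM computation; the default
threshold `max_gap_frac = 0` drops any column containing a gap,
producing the equal-length gap-free matrix the column-multinomial
model expects. Residual gaps (with a laxer threshold) contribute no
counts and probabilities are *not* renormalized — a column mass below
1 stays visible instead of being silently rescaled. Trimming returns
an explicit old-to-new column map; sites are discovered in trimmed
coordinates and reported/built in the exemplar's raw ungapped
coordinates, so published pattern positions refer to the deposited
sequence, not to an alignment artifact. Consensus ties are broken by
the fixed order A < C < G < T and recorded per column, keeping the
consensus within the 4-letter alphabet (so pattern literals stay plain
regex strings) while leaving ties auditable.

## The synthetic generator

`generate_barcodes()` plants known structure so every stage is
testable without external data: one random backbone per genus
(uniform base composition), sibling backbones mutated at a
`genus_divergence` fraction of sites (default 0.05, an inter-genus
scale typical of plastid barcodes), each species defined by
`planted_sites_per_species` fixed substitutions at positions unique
within its genus, and each sequence drawn from the species template
with iid substitution noise and gap-coded single-base deletions. The
defaults — 3 genera × 2 species × 3 sequences × 700 bp, 2 planted
sites per species, no noise, seed 42 — are the package's reference
conditions: small enough to run in seconds, rich enough to exercise
genus and species site discovery, merging, refinement and
classification.

What the generator does **not** emulate: phylogenetic correlation
among sites, codon structure, realistic indel processes, rate
heterogeneity along the locus, or shared polymorphism between
species. Passing the recovery tests therefore shows the machinery is
correct (planted sites are recovered exactly; noise-free species get
recall = precision = 1), not that real *matK* data will behave as
cleanly — on real data, within-species variation and alignment error
reduce the usable site pool, and some species fail signature
generation precisely through the distance-mismatch mode the
diagnostics report. `corrupt_barcodes()` adds truncations, Ns and
single-base indels under common-random-numbers coupling across rates,
so recall degradation is monotone in the corruption rate by
construction of the experiment, not by luck of the draws.

## The QR codec

Signatures serialize to a two-line text record (species / exemplar /
span header, then the regex) and that exact byte string is the QR
payload, so a printed code is self-describing. The package implements
the QR model-2 symbology itself in R: byte mode, error-correction
level M, versions 1–20 (669-byte capacity, ample for barcode
signatures), all eight masks with standard penalty scoring, BCH-coded
format bits, and Reed–Solomon block codes over GF(256) with
Berlekamp–Massey error location on decode. Encoding is deterministic
for a fixed payload. The decoder expects a clean, upright,
axis-aligned rendering (as produced by the encoder or any standard
renderer) — perspective correction and photographic capture are out of
scope. Block-structure constants are guarded by a geometric
consistency test: the total codeword count derived from the symbol's
module layout must equal the data+EC split for every supported
version, so a transcription error in the tables cannot pass the suite.

## Numerical and degenerate-input choices

* Column stochasticity is asserted to 1e-12; distances use
  `stats::dist` (exact to double precision).
* The paired Wilcoxon locus comparison returns p = 1 with a warning
  when all paired differences are zero (the test is undefined there);
  otherwise it defers to `stats::wilcox.test`, which uses the exact
  distribution for small tie-free samples.
* Dataset filters run in a fixed order: locus, then N-containing
  sequences, then the ≥2-sequences-per-species rule — so a species
  left with one clean sequence is excluded.
* Singleton species (no intra-species pair) take `max_intra = 0`,
  reducing the discrimination rule to `min_inter > 0`.
* Sequences are upper-cased on read; characters outside
  `{A, C, G, T, N, -}` are rejected (IUPAC degeneracy codes are
  intentionally unsupported — diagnostic literals must stay exact).
* An all-gap column makes consensus computation fail with advice to
  trim first, rather than emitting an arbitrary base.

## Problem sizes

The test suite and the acceptance script run the reference synthetic
conditions above, 1000-fixture matcher-versus-oracle comparisons, and
100 QR round trips; these sizes give exhaustive coverage of the
discrete behaviours (merging, tie-breaks, boundary categories) while
keeping a full run in well under a minute per component.

## Known limitations

* Signatures are exact-match instruments: a single indel between two
  patterns breaks a match at `tolerance = 0`. This is by design but
  means partial or low-quality queries are reported as unidentified
  rather than fuzzily assigned.
* The discrimination rule depends on the sequence sample: adding
  sequences can only tighten it (more intra variation, smaller
  barcoding gap), and per-species results are not comparable across
  datasets with very different sampling depths.
* Reverse-strand queries are not searched unless requested.
* The QR decoder handles one symbol per image and no geometric
  distortion.
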