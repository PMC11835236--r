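---
title: "Methods: building a group I intron database with intronforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a group I intron database with intronforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronforge)
```

## The problem and the model

Covariance-model searches locate group I introns with high sensitivity,
but the hit coordinates reflect where the model aligned, not where
splicing occurs. Group I intron function constrains the true boundaries
tightly: the intron begins immediately after the conserved U that forms
the catalytic U–G pair, and both flanking exons must exist for splicing
to be assessable at all. `intronforge` therefore treats a covariance
model hit as a *rough locator* and the GenBank feature table as the
*boundary authority*: an annotated `intron` feature, or the gap between
consecutive parts of a compound location (exons of a spliced gene),
supplies candidate boundaries; the hit merely selects among them.

The procedure per hit is:

1. **Candidate extraction.** Every `intron` feature and every
   between-part gap of a compound-location feature that shares at least
   `min_overlap` positions with the hit range becomes a candidate.
   Overlap is counted on closed 1-based ranges; adjacency counts zero.
2. **Selection.** The candidate with the largest overlap wins; ties go
   to the earliest feature in file order, making the pipeline
   deterministic on any input.
3. **Validation**, in fixed order, first failure reported: the
   candidate must not start at the entry's first position, must not end
   at its last (otherwise the exonic context is unknown), and its
   initial base must be T (U in RNA).
4. **Context extraction.** Up to `max_context` nucleotides on each
   side, truncated at record edges; on the minus strand both intron and
   contexts are reverse-complemented so all reported sequences are in
   biological (intron) orientation.

Every hit is accounted for: it either yields an accepted intron or a
rejection record with one reason (`no_candidate`, `missing_record`,
`at_entry_start`, `at_entry_end`, `no_initial_U`, or
`duplicate_boundary`). Accepted introns are numbered
`<entry>_<ordinal>` in ascending start order within each entry.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_overlap` | 50 | alignment positions | minimum hit/candidate overlap; below it a candidate is not considered |
| `max_context` | 150 | nt | exonic context cap per side |
| `min_aa` | 120 | amino acids | ORF length floor for HEG candidates (typical homing endonucleases are 150–300 aa; 120 keeps single-motif LAGLIDADG enzymes) |
| `u_check_position` | `first_of_range` | — | where the conserved U is tested (see below) |
| `keywords` | `endonuc`, `homing`, `nuclease` | — | case-insensitive stems matched against domain annotations |
| `min_residues` | 1 | residues | occupancy threshold for calling a structural element present |
| `dedupe_identical_boundaries` | on | — | collapse several hits resolving to one boundary pair |

Defaults are deliberate scientific choices, not free dials: 50 positions
is large enough that a spurious feature cannot capture a hit by chance
while still tolerating model/annotation disagreement at the ends; 150 nt
of context is ample for assessing P1/P10 pairing with the exons; 120 aa
excludes the fragments that keyword matching would otherwise flood in.

### The two readings of the U rule

The conserved U is the *last nucleotide of the preceding exon*; by the
usual convention the annotated intron range begins with it, so the
default checks the first base of the candidate range
(`first_of_range`). Annotation pipelines that end the exon *on* the U
instead need `before_range`, which tests the base immediately before
the candidate. Both are implemented; the default matches how intron
features are written in practice. On the minus strand the check applies
to the first base of the reverse-complemented intron.

### Ambiguity codes

IUPAC ambiguity characters are allowed everywhere. The U check is a
strict equality with T — an N at the initial position fails, because a
conserved position should be observed, not presumed. In translation a
codon containing ambiguity translates to the consensus amino acid of
all its resolutions, else `X`, and never acts as a start or stop.

## Coordinates

All coordinates are 1-based inclusive throughout — the GenBank and
Infernal native convention, and R's. Because inputs, internals and the
`start_1based`/`end_1based` output columns share one convention, no
conversion ever occurs and no off-by-one class of bugs can arise at a
boundary. Overlap arithmetic on closed ranges is
`max(0, min(e1,e2) - max(s1,s2) + 1)`, verified in tests against
brute-force set intersection.

## Subtypes and structural elements

Subtype assignment is the argmax of per-subtype covariance-model bit
scores from a `cmscan` of each intron against the subtype CM library;
ties break lexicographically so permuting the scan file cannot change
the call. No score floor is applied before the argmax — an intron with
any hit is classified, one with none stays unclassified.

Element annotation reads the subtype's Stockholm alignment: a `#=GC`
label line assigns each column to a named element (`P1`…`P9`,
`P5a`–`P5d`, …; an element may own several column ranges, one per
strand of a paired region). An element is present in an intron when at
least `min_residues` of the intron's aligned residues fall in its
columns (default 1: the figure-level statistic of interest is
occupancy, and any stricter threshold would need a per-element length
model that the alignments do not provide). Present elements are
reported with intron-local residue spans.

## HEG detection and genetic-code provenance

ORFs are enumerated under **every** NCBI translation table (sourced
from the curated `Biostrings` tables, ids 1–26), not just the host's,
because homing endonucleases move between compartments and organisms.
An ORF runs from a valid start codon (ATG plus the table's alternative
initiators) to the first in-frame stop; an ORF still open at the
sequence end is reported, since a HEG can straddle the annotated
boundary. Within a frame, starts sharing a stop collapse to the
earliest. ORFs identical in interval and peptide under several tables
are merged, preferring the table expected for the intron's compartment,
then the organism's other compartments, then the lowest id. "Nested"
pruning removes ORFs whose interval is contained in a larger same-strand
ORF regardless of frame — partial overlaps survive, which is essential:
genuine overlapping endonuclease pairs in different frames exist and
must be retained.

Evidence is consulted in two tiers: InterProScan annotations first;
DELTA-BLAST subject titles only for introns with candidate ORFs but no
InterProScan-based call. Matching is case-insensitive substring search
for the keyword stems. Provenance classification is total: every
(table, context) pair maps to exactly one of `expected`,
`other_location`, `foreign`; an unknown own-compartment code yields
`foreign` with a warning rather than a guess.

## What the synthetic fixtures emulate — and what they do not

`generate_fixtures()` plants one intron per record in an
exon–intron–exon gene, annotated either as an `intron` feature or as a
compound-location gap, with the hit jittered up to ±30 nt around the
planted boundaries (so the 50-position rule is always comfortably met
for valid records, and deliberately failed for the planted
sub-threshold edge case). Planted HEG cassettes are stop-scrubbed under
their code and fenced by an in-frame stop so detection at the exact
planted start is guaranteed *under that code*. A truth manifest records
spans, strands, U-status and the expected per-hit outcome; everything
is reproducible byte-for-byte from the seed.

Two properties of real data are *not* emulated. First, intron bodies
are uniform random DNA, which has far more stop codons than real intron
sequence in most tables — but far fewer under permissive tables with
one or two stop codons (e.g. the flatworm-mitochondrial table). On
random sequence those tables regularly produce long ORFs that contain
the planted cassette; nested pruning then keeps the container, and the
HEG is reported on the covering ORF with honest `foreign` provenance.
The truth manifest therefore asserts *coverage* of the planted ORF, not
identity, and provenance semantics are verified separately on
constructed sequences where no incidental ORF can occur. Real introns,
with codon usage shaped by their resident HEGs, do not behave this way
— which is precisely why provenance is informative there. Second,
fixtures carry no realistic secondary structure, so passing tests say
nothing about covariance-model search sensitivity; the pipeline starts
*after* `cmsearch`, and that is the boundary of what the fixtures can
certify.

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 200 records for
boundary recovery (both pathways, 25% minus-strand), 60 records at 50%
U-start plus the three planted edge cases for rejection bookkeeping,
100 random sequences of 360–2000 nt per genetic code (tables 1, 4, 11)
for ORF-oracle equivalence, and 12-record HEG cohorts built twice for
determinism — sizes at which every property is exercised on both
strands and through both boundary pathways while a full run stays in
the tens of seconds. All randomness flows from a single seed;
`build_db()` writes no timestamps, so identical inputs give
byte-identical databases.

## Known limitations

* Boundary refinement is only as good as the GenBank annotation: a hit
  in an entry with neither intron features nor compound locations is
  rejected (`no_candidate`), never guessed at — de novo boundary
  inference is out of scope by design.
* The compound-gap rule accepts gaps of *any* compound feature, without
  requiring the parts to belong to one gene; entries with unusual
  multi-gene joins could contribute spurious candidates, though the
  overlap rule and U check filter most.
* Keyword matching inherits the vocabulary of the annotation databases;
  a domain description that avoids all three stems will be missed, and
  `nuclease` also matches non-homing nucleases — the evidence
  annotation is retained in the output so such calls can be audited.
* Secondary-structure prediction, base-pairing probability matrices and
  HEG family classification are outside this package's scope.
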