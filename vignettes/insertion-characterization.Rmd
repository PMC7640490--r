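---
title: "Characterizing insertion variants: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing insertion variants: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(inschar)
```

## The problem

A sequence-resolved insertion callset spells out, for every variant, the
anchor position on the reference and the full inserted sequence. That
resolution makes three questions answerable that symbolic callsets cannot
address: *what* was inserted (its relationship to sequence already present in
the genome), *where* (the repeat and genic context of the site), and *how
clean the junction is* (homology between the flanks and the insertion
extremities). All three strongly affect whether a short-read SV caller can
recover the variant, so the package treats them as first-class measurements
and provides a simulator that varies them one at a time.

## Insertion sub-types and the decision tree

An inserted sequence is classified by the evidence classes that cover it:

* **tandem repeat** — the sequence is an array of tandem copies of a short
  seed motif;
* **mobile element** — it aligns to a consensus element library;
* **tandem duplication** — a copy of it lies immediately adjacent to the
  insertion site;
* **dispersed duplication** — copies lie elsewhere in the genome, with a
  genomic copy count below `dispersed_copy_max` (default 50) so that highly
  repeated mobile elements (copy numbers typically far above that) are not
  mislabeled as duplications;
* **novel sequence** — nothing in the genome or the library accounts for it.

To be assigned, a type's evidence must cover at least `min_cov` (default
0.80) of the insertion as one contiguous segment; novel sequence is the one
exception, where the *total* unannotated fraction is used, contiguity not
required. When several types qualify, a fixed priority order decides:
tandem repeat, mobile element, tandem duplication, dispersed duplication,
novel sequence. The order encodes specificity — a tandem repeat trivially
also matches its own flank (every tandem repeat is in that sense a tandem
duplication), and a mobile element aligns at many dispersed loci, so the
more specific interpretation must be tested first. The order is a package
design choice, exposed in `classifier_config(priority =)`, and results
should be read with it in mind. Records meeting no threshold are
`unassigned`, with partial coverages reported in decreasing order, since
partially annotated or mixed-type insertions are informative even when no
single label fits. Mixture types and segmental-duplication/CNV sub-labels
are deliberately out of scope.

"Contiguous" tolerates gaps of up to `segment_gap` (10 bp) between merged
same-type alignment blocks, absorbing residual sequencing errors in
long-read-derived inserted sequences. Flank windows for tandem-duplication
evidence have the same length as the insertion, capped at `max_flank`
(10 kb) to bound cost on very large insertions.

## The alignment engine

The package implements its own desk-scale local aligner rather than calling
an external program: exact k-mer seeds (k = 11) located through a cached
integer-encoded k-mer index of the target, seed clustering by implied query
placement, and Smith-Waterman refinement (via `Biostrings`) of each
candidate locus. Identity is defined as matches / alignment columns, gaps
counted as columns, `N` matching nothing; alignments are trimmed to their
shortest maximal-scoring form so that equal-scoring extensions never inflate
a reported interval. Two thresholds control emission: `min_identity` (0.90
everywhere in the package) and `min_score` (default 30, i.e. net +30 under
match +1 / mismatch −1), plus a minimum of two seeds per cluster; the last
two suppress the chance ~11–20 bp perfect matches that a single random seed
hit would otherwise contribute to coverage. The junctional-homology search
relaxes both floors (one seed, score 11) because genuine homologies start at
11 bp and its own two distance constraints already control false positives.

Tandem structure is detected by shift-comparison rather than an external
repeat finder: for each candidate period p (proposed from the distance
histogram of repeated 6-mers, plus all periods ≤ 30), the longest run of
positions with `seq[i] == seq[i+p]` at mean mismatch ≤ 10% is found in
linear time; a verified array must contain at least two full copies, and the
smallest verified period wins ties. This reproduces the coverage-based
contract downstream consumers need (seed size, copy number, covered span)
without replicating any particular repeat-finder scoring model.

Copy counting reports disjoint genomic loci with an alignment of identity
≥ `min_identity` covering ≥ `min_query_cov` of the query, merging loci that
overlap by more than half of the shorter; it is monotone non-increasing in
both thresholds.

## Junctional homology

Small homologies (< 10 bp per side) are measured strictly: identical bases
counted outward from the insertion site until the first mismatch, left side
against the insertion's end, right side against its beginning. When a side
saturates the 10 bp cap the alignment tier takes over: local alignments
between the junction window (same length as the insertion, capped at 10 kb)
and the insertion, kept only if ≥ 90% identity and within 10 bp of both the
site and the corresponding insertion extremity; among several candidates
the one closest to the extremities wins, ties going to the larger homology
(a deliberate conservative-upper-estimate choice). The two sides are summed
after removing their overlap on the inserted sequence, and the reported
total is the maximum of the strict and alignment totals — the max rule is
this package's resolution of an ambiguity in how the two tiers combine;
since the strict scan is a special case of the alignment criteria, the
alignment tier can only refine a saturated scan upward.

Records are assumed left-normalized as in VCF; homology is measured at the
coordinates as given. Positions at contig edges use the available flank and
are flagged.

The null model places `n` insertions of i.i.d. uniform A/C/G/T bases at
uniform positions and scores them with the same detector. Per side the
strict-scan homology is geometric with success probability 3/4, so the total
T has P(T = t) = (t+1)(9/16)4^−t and the maximum over 2,000 draws
concentrates on 6–7 bp — the chance ceiling that makes observed homologies
of tens to hundreds of bp on real callsets interpretable.

## Simulation suite

The default suite enumerates 22 datasets of 200 homozygous insertions each:
1 baseline + 3 sizes + 5 types + 5 homology sizes + 5 contexts + 3
real-callset replays. The non-repeated context dataset is identified with
the baseline itself — baseline sites are exonic, hence non-repeated — which
is what keeps the count at 22 rather than 23. Scenario families change one
factor at a time relative to the baseline:

* **baseline** — 250 bp donor sequences (novel in the genome) at exonic
  sites, zero junctional homology;
* **size** — the same locations, fresh donors of 50/500/1000 bp (fresh
  donors per size, rather than truncations of the baseline donors, is the
  package's reading of an underdetermined protocol);
* **type** — tandem repeats tiled from a 6 or 25 bp seed taken at the left
  breakpoint junction, tandem duplications copying the 250 bp right
  breakpoint sequence, mobile elements of 200–300 bp drawn from annotated
  elements, dispersed duplications drawn from exons of the same chromosome;
* **homology** — the first X ∈ {10, 20, 50, 100, 150} bases of each baseline
  insertion replaced by the right breakpoint sequence;
* **context** — baseline-style insertions placed inside SINEs, LINEs, small
  (< 300 bp) or large (> 300 bp) simple repeats, or proximal pairs with a
  gap drawn uniformly from 5–150 bp (pairs reuse baseline donors; `n` counts
  total insertions, so `n/2` pairs);
* **real** — a supplied truth table replayed as-is, its sites with novel
  donors, or its sequences at exonic sites.

Two generator-hygiene rules make the designed labels exact rather than
approximate. First, junction-adjacent mismatches are forced wherever the
design asks for zero homology on a side. Second, designed homologies are
verified with the package's own detector and the insertion tail resampled
on the rare occasions the 90%-identity alignment rule would legitimately
extend a few bases past the planted copy (a net-positive score extension
across the forced mismatch); without this, a scenario labeled X = 50
occasionally measures 53–61. Verification uses the same public API as any
caller of the module, so the labels remain honest measurements.

Read simulation (short or long) is out of scope: the module emits the
mutated FASTA and truth VCF that read simulators and SV callers consume.

## Evaluation

Calls are filtered to PASS (`.` counts as PASS) and size > 50 bp, then
matched one-to-one to truths: candidate pairs within the 10 bp site margin
are assigned in order of increasing distance, ties broken by leftmost truth
then leftmost call, so no call validates two truths (which matters for the
proximal scenario) and results are independent of input order. Sequence
resolution additionally requires ≥ 90% end-to-end identity
(Needleman-Wunsch; the package fixes the alignment style since insertion
sequences must match over their whole length) and ±10% size. Symbolic
duplication calls can be resolved from reference coordinates carried in
INFO (`DUPCOORDS=chr:start-end`) before matching. False positives are
retained calls matching no truth, reported as absolute counts — precision
and FDR depend on the truth-set size and are deliberately not reported.
Long-read-style evaluation (80% identity) is expressible through
`match_config()`.

## Synthetic data: what it emulates and what it does not

`generate_genome()` plants, on a uniform-random background at configurable
GC, two-exon genes (annotation only), genuine tandem arrays with 2–25 bp
seeds in two size regimes (below and above 300 bp), and SINE-scale (~300 bp)
and LINE-scale (6 kb consensus, 5′-truncated instances of 0.5–3 kb) elements
as mutated copies of a synthetic consensus library at 5% divergence — within
the 10% that the 90%-identity rules tolerate, so those rules bind
realistically. The library is synthetic (not actual Alu/L1 sequences); the
genome has no polymorphism other than the planted insertions, no sequencing
error, and none of the long-range repeat structure of a real genome.
Passing parameter-recovery tests on this material therefore demonstrates
that the algorithms implement their definitions correctly — not that real
callsets are free of the sequencing-error, normalization and polymorphism
effects that real inserted sequences carry; on real data the measured
homologies are best read as lower bounds.

## Problem sizes and numerical choices

The test suite works on a 300 kb annotated genome with callsets of 10–40
records, which exercises every rule at the same thresholds used at
chromosome scale; the null-model check runs at its full stated conditions
(10 Mb, 2,000 insertions of 250 bp). Coordinates are 1-based and closed
throughout, matching the VCF anchor convention and the IRanges ecosystem;
conversion happens only at BED import. Determinism: every generator takes
an explicit seed and identical (spec, seed) pairs produce byte-identical
truth VCFs. Known degenerate inputs: insertions shorter than 20 bp cannot
be aligned by the seeded engine and fall back to the tandem scan with a
warning; insertions at contig edges use the available flank and are
flagged; `N` bases never match anything.

## Known limitations

The classifier assigns one label per record; genuine biological mixtures are
reported only through the partial coverages of unassigned records. The
dispersed-duplication copy-count rule uses a fixed threshold (50) rather
than the empirical copy-number distribution of element families. The
multiway sharing estimate is single-linkage clustering within a 1 kb
window and is as rough as such estimates inherently are. The discovery
technology parser exposes its token rules (`discovery_config()`) because
published callsets do not share a tag grammar; records without tags are
conservatively counted as non-short-read and tallied.
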