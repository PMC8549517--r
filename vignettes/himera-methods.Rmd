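---
title: "Methods: detecting HIM-mediated bracovirus integrations from chimeric reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting HIM-mediated bracovirus integrations from chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(himera)
```

This vignette is the package's own account of what it computes, which
conventions it adopts at points where more than one reasonable choice
exists, and what its synthetic validation does and does not demonstrate
about real data.

## The biological model

A bracovirus-bearing wasp genome carries proviral segments, each flanked by
two identical direct repeat junctions (DRJs). Excision recombines the DRJs,
so the circularised segment retains a single DRJ copy; `excise_circle()`
therefore returns a circle of length (segment length − one DRJ), linearised
from the retained DRJ. Circles that carry a host integration motif (HIM —
J2 motif, spacer, J1 motif, in that order when the circle is oriented
5'DRJ→3'DRJ) can integrate into host chromosomes: the circle is cut inside
J2 and inside J1, the spacer between the cuts is lost, and the linearised
circle is joined to host DNA with J1 at one extremity and J2 at the other.
Every integration therefore produces two wasp–host junctions, and a
sequencing read crossing either junction is a chimeric read.

Assumptions inherited from this model: integrations are mediated by a
site-specific machinery, so the canonical cut positions are fixed per
segment (junctions without microhomology all fall at the same base);
apparent variation in junction position comes from junction microhomology,
which makes the alignment end ambiguous by exactly the homology length.

## The chimera classifier

`classify_chimeras()` takes one best alignment per read per genome
(`select_best_hit()`: bit score, then identity, then subject id, then
subject start — fully deterministic) and computes, from the two
read-coordinate intervals, five disjoint base classes whose sum is always
the read length: wasp-exclusive, host-exclusive, doubly-aligned (`overlap_len`,
the junction microhomology), inserted (`insert_len`, bases between the two
alignments), and unaligned (bases outside both alignments). Four filters
gate acceptance, with defaults of 16 exclusive bases per genome, a strict
10% bound on bases mapping to neither genome (unaligned + inserted), 20 bp
of overlap and 5 inserted bases. When several filters fail, the reported
rejection reason follows the filter order (exclusive sides, then
neither-genome fraction, then overlap, then insert).

Junction coordinates follow the alignment-end convention: the junction
position on each genome is the subject coordinate of the alignment
endpoint nearest the junction, *regardless of any overlap*. Because that
endpoint is read directly off the alignment record (never interpolated),
the convention is exact even for gapped alignments.

Two chimeras are PCR duplicates (`dedupe_pcr()`) when they agree in the
subject intervals on both genomes, the junction coordinates, and the
relative orientation. The underlying assumption — independent fragments
essentially never share both fragment boundaries — is stated rather than
derived; with it, deduplication is idempotent and conservative (fragments
differing in any boundary are retained as independent evidence).

## Event calling

An integration event is a unique junction: (segment, host contig, host
position, orientation, host flank). The *host flank* — which side of the
host coordinate the wasp sequence attaches to — distinguishes the J1-side
and J2-side junctions of a single insertion even when, through homology at
the target site, both realise the same host coordinate. Support is the
number of deduplicated chimeras in the group; the reported wasp-side
coordinate is the modal one.

By default only junctions falling in the J1/J2 regions are counted
(`scope = "j"`), the parsimonious choice for quantification; `scope = "him"`
admits any junction inside a HIM, which is what the synthetic round-trip
uses, since target-site homology can shift a J2-side junction coordinate
legitimately outside the annotated motif.

`call_ies()` also clusters breakpoints: an event is absorbed into a
better-supported event of the same (segment, contig, orientation, flank)
within `merge_tolerance = 5` bp. A substitution error adjacent to a
junction truncates the local alignment by a base or two and would
otherwise surface as a spurious singleton event beside the true one; on
error-free data the clustering is a no-op because independent integrations
are never that close. Support is summed into the representative, so the
total support across events is conserved. Setting `merge_tolerance = 0`
recovers plain unique-position counting.

Normalisations are `ipmh()` (events per million host-mapped reads) and
`ies_per_genome()` = (IPMH / read length) × genome size in Mbp; genome
size is expressed in Mbp to keep that formula literal.

## J-region delineation

`delineate_j_regions()` implements the empirical rule: take the position
inside the HIM supported by the most chimeric reads, extend to adjacent
positions while each is supported by at least `min_support = 2` reads
(the mode itself is always kept, so a single read still anchors a
width-zero region), then repeat for a second mode outside the first
region. Two refinements make the rule well-behaved on sparse histograms:
the second region may not extend into the first, and the second mode must
itself reach `min_support` (a stray singleton elsewhere in the HIM is not
a hotspot; with only one genuine mode the result is a soft one-region
answer). The two regions are reported ordered (J2, J1) along the circle,
with their separating gap.

## The microhomology null

`simulate_null_chimeras()` draws artificial reads as a random circle
substring joined to a random host substring, each side at least 28 bp,
lengths summing to the read length (150 bp). Each read's two maximal local
alignments back to its sources are reconstructed by deterministic
exact-match extension of the known planted intervals — exact for these
error-free substrings — and the hit table is passed through the *same*
`select_best_hit()` + `classify_chimeras()` code path as real data, so the
null's overlap is measured by the production classifier, not by a
reimplementation. Under uniform base composition the one-sided
junction-base match probability is 1/4 and the two-base extension
probability 1/16; the classifier's two-sided overlap follows the sum of
two independent geometric tails, P(overlap = k) = (k+1)(1/4)^k(3/4)^2.
These identities are asserted by the test suite at n = 10^5.

`compare_mh_distributions()` rescales the expected counts to the observed
total (the alternative — rescaling to the number of simulated reads — is
arbitrary to within a constant and does not change the ratios), reports
per-length observed/expected ratios, and computes a chi-square statistic
after pooling upper-tail bins until every expected count reaches 5.

## The spatial-randomness test

`make_windows()` tiles each contig from position 1 with fixed-width
windows (100 kb by default); the sub-window remainder at each contig end
is excluded but accounted for, so no window mixes contigs. Events are
assigned half-open (position `window_size + 1` falls in window 2). Under
the null, per-window counts are Poisson with the observed mean; the
occupancy spectrum (windows with k events) is compared to its expectation
by chi-square with upper-tail classes pooled to expected ≥ 5 and one
degree of freedom charged for the estimated rate. The test also reports
the largest occupancy the null makes plausible (the largest k with at
least half a window expected). Calibration is checked by simulation in the
test suite: across 1,000 null replicates at 5,000 windows and rate 0.7 the
type-I error at α = 0.05 falls within [3%, 7%], and concentrating 10% of
events into 10 windows is detected essentially always. Note the test is
two-sided about dispersion: regularly spaced events (as the synthetic
generator produces, see below) are rejected just like clustered ones.

## The synthetic-data generator

`simulate_dataset()` builds both genomes and all reads from a single seed
(`sim_config()`), with every downstream stream seeded from it, so a run is
byte-reproducible. It emulates:

* proviral segments flanked by identical per-segment DRJs (default 100 bp),
  with a HIM (J2 + spacer + J1) near the 3' DRJ; spacers are drawn
  uniformly from 41–73 bp; J motifs (30 bp) share a canonical sequence
  across segments mutated at `j_divergence = 25%` of positions per
  segment, conserved enough to be recognisable motifs yet divergent enough
  that a 16-bp junction-spanning alignment identifies its segment;
* circle excision with DRJ collapse, and HIM-mediated integration with the
  spacer removed and J1/J2 at the insert extremities, in either
  orientation;
* junction microhomology as a *property of the host target site*: the
  requested tract (drawn from `microhomology_probs`, default concentrated
  on 0–5 bp) is written into the host reference flanking the J1-side
  junction, the next base is forced to mismatch, and chance first-base
  homology at the J2-side junction is scrubbed where the bases are not
  already dictated by the tract. Cuts never move — matching the
  site-specific-recombinase assumption;
* background reads from both genomes at configurable fold-coverages,
  abundance-weighted reads from the excised circles
  (`segment_copy_number`), junction-spanning reads around every
  integration junction, uniform substitution errors, and exact PCR
  duplicates at a configurable rate.

Two implementation conventions deserve justification:

*The host reference stays fixed.* Insertions are not materialised in the
returned host sequence; junction reads are generated from per-event
integrated-allele fragments. This mirrors reality — somatic integrations
live in single cells while alignment runs against one fixed reference —
and keeps all truth coordinates on that reference.

*Truth records the aligner's view.* The truth table stores, per junction,
the coordinates an aligner reporting maximal-score local alignments will
produce: extensions past each cut are computed with the same scoring the
pipeline's aligner uses (+2 match, −3 mismatch, 5 + 2k affine gaps), read-
side extension feeding the realized overlap and subject-side extension the
realized coordinate. Recovery can therefore be asserted *exactly*, with no
tolerance window hiding defects.

One generator constraint exists purely to keep the planted geometry
identifiable: each spacer's first two bases are forced to differ from the
J1 prefix. Without it, a planted J1-side microhomology tract whose bases
happen to match the spacer prefix silently extends the J2-side junction
alignment, so the requested and realized geometries diverge for reasons
unrelated to the pipeline under test.

What the generator does **not** emulate: indels and structural sequencing
errors, paired-end structure (the analysis treats reads as independent
single ends), non-uniform base composition by default (uniform composition
makes the (1/4)^k null analytic; GC is configurable), non-HIM integration
mechanisms, and genome-scale repeat content. Integration sites are placed
on a jittered grid with a minimum spacing of about two read lengths so
junction windows never overlap — hence simulated sites are *under*-
dispersed and the spatial-randomness test correctly rejects on simulated
data. Passing the synthetic round-trip demonstrates the pipeline's
bookkeeping (coordinates, filters, deduplication, delineation, and
normalisation) is exact under controlled conditions; it does not
demonstrate robustness to repeats, indels, or alignment ambiguity in real
gigabase genomes.

## Duplication annotation

`search_motifs()` wraps a BLASTN search (e-value 1e−6, both strands,
forward-strand coordinates) of motif libraries against a genome.
`call_him_duplications()` reproduces the duplication signatures: an **Hdp**
(HIM-mediated duplication, an integrated circle copy in the wasp genome)
is a region bounded by a J1-covering half-HIM hit at one extremity and a
J2-covering half-HIM hit at the other, on the same strand and in the
orientation the insertion product dictates, with no DRJ at either
extremity — the single internal DRJ retained from circularisation is
expressly permitted, since an integrated circle contains one. A "half-HIM"
hit covers ≥ 80% of the J motif on one side of the spacer and ≤ 20% of the
other. An **Rdp** (rearranged duplication) is a chained segment-homologous
region (co-linear hits joined across ≤ 500-bp gaps, covering ≥ 80% of the
query) containing exactly one internal DRJ hit, with no DRJs and no J
motifs at its extremities. All intersections tolerate ±10 bp of
alignment-end fuzziness. Intact proviral segments — DRJs at both
extremities, intact HIM inside — can match neither signature, which the
test suite asserts, along with invariance of the calls under
reverse-complementing the genome.

## Pipeline and problem sizes

`run_pipeline()` chains the stages. In simulation mode reads are aligned
to the wasp genome first and only wasp-hitting reads are re-aligned to the
host (the paper-style two-pass strategy; host background, the bulk of the
data, is screened once); `blastn -task blastn -word_size 11 -dust no` is
used because chimera sides as short as 16 bp are below the default
megablast word size. Host-mapped totals in simulation mode come from the
read-truth table. Deterministic given seed and inputs; the report bundle
(TSV/GFF3/BED plus a text summary) records seed, thresholds and package
version.

The validation suite runs at deliberately desk-sized scales: a 200-kb
host, a 100-kb wasp genome with 16 HIM segments (~2 kb each), 13
integrations per segment (~208 events, ~416 junctions), 30× coverage,
~75,000 reads; the abundance–correlation study uses 5 segments with copy
numbers 1–16; the null model runs at 10^5 reads; window-test calibration
uses 1,000 replicates of 5,000 windows. These sizes keep a full run in
tens of seconds while leaving every per-junction quantity well supported.

## Known limitations

* The PCR-duplicate criterion and the breakpoint-clustering radius are
  stated conventions, not estimated from data.
* Reads whose best wasp hits tie across segments resolve
  deterministically (lexicographic subject), which can mis-assign a read
  whose wasp side lies entirely within a J motif if segments' motifs were
  identical; the generator's `j_divergence` keeps this rare, but real
  multi-copy segments would need a dedicated ambiguity policy.
* The chi-square occupancy test relies on large-sample theory; with very
  few windows (or rates near zero) it degrades and the implementation
  flags the degenerate cases rather than testing them.
* Absolute circle copy number is not estimated; depth ratios and rank
  correlations are as far as the data support.
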