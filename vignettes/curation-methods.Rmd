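---
title: "Methods: assembly curation for a diploid, high-GC protist genome"
author: "crcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly curation for a diploid, high-GC protist genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

crcurate packages the curation computations that turn a raw long-read
assembly of a small diploid eukaryote into a publishable draft: estimating
the haploid genome size from the k-mer spectrum of the reads, breaking
contigs at unsupported coverage drops, removing bacterial contaminant
contigs by fragment-wise taxonomic vote, circularising and re-anchoring the
mitochondrial contig, estimating the rDNA operon copy number from depth
ratios, and summarising assemblies (N50, GC, fragment-based ANI). The
organism it was built around is a marine bacterivorous flagellate with a
~70% GC nuclear genome, clear diploid structure, and a culture that is
necessarily non-axenic — its food is bacteria, so its read sets and
assemblies always contain bacterial sequence. Every method here is equally
applicable to other assemblies with those properties.

This vignette documents the models and decision rules, the tunable
parameters with their defaults and units, what the synthetic-data generator
does and does not emulate, and the numerical corner cases.

## Genome size from the diploid k-mer spectrum

Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
complement, default k = 19) are counted exactly in memory from the reads.
The multiplicity histogram of a diploid genome shows two peaks: homozygous
(2n) k-mers occur on both haplotypes and pile up at twice the per-haplotype
k-mer coverage; heterozygous (1n) k-mers occur on one haplotype and peak at
half the 2n multiplicity. Sequencing errors produce a spike at multiplicity
1–2.

The estimator takes

* the **error cutoff** as the first valley of the histogram: the smallest
  multiplicity m >= 2 whose (smoothed) count is below that of m + 1;
* the **2n peak** as the argmax of the smoothed histogram at or above the
  cutoff;
* the **haploid size** as (total k-mers above the cutoff) / (2n peak
  multiplicity);
* an optional **1n peak** as a local maximum between the cutoff and 0.75x
  the 2n peak.

Smoothing is a centred moving average with window 3: raw histograms from
moderate-coverage data are noisy at single-bin resolution, and peak/valley
rules on raw counts are brittle. When several smoothed bins tie for the
maximum, the bin with the highest raw count wins — this makes the estimator
exact on a degenerate single-spike histogram (all k-mers at multiplicity
m0 gives haploid size = number of distinct k-mers). Multiplicities above a
cap (default 10,000) are pooled, so organelle and rDNA k-mers cannot blow
up memory; the conservation identity (sum of m x count[m] equals k-mers
ingested) is asserted on every run whenever the cap bin is empty.

Two caveats are inherent to the method and deliberately not corrected:
k-mers from abundant contaminants above the error cutoff inflate the
estimate, and the ratio estimator assumes the 2n peak location is exactly
twice the per-haplotype coverage, which discretisation can shift by one
multiplicity unit (about 1% at 100x). On the package's validation scenario
(5 Mbp diploid, heterozygosity 0.005, GC 0.70, 60x error-free 300 bp
reads) the estimate lands within a few percent of truth and the 1n peak
sits at half the 2n peak; the test suite asserts 5% and a 1n/2n ratio in
[0.4, 0.6].

## Coverage-drop junctions

Chimeric contigs (misjoins) are not supported by reads spanning the join,
so per-base depth dips toward zero there, while the flanks keep normal
coverage. Depth is computed from SAM/BAM/PAF alignments: primary,
non-supplementary mapped records only; CIGAR M/=/X consume reference and
add depth; D/N consume reference without depth; clips and insertions add
nothing. This matches the common pileup convention and is pinned by tests.

Junction calls are maximal runs of positions with depth < c that

1. lie wholly inside `[e, L - f)` (the `e`/`f` end-exclusion zones absorb
   the natural coverage ramp at contig ends);
2. have mean depth >= d*c over the `a` bases to the left and `b` bases to
   the right of the run (flanks truncated at the exclusion zones);
3. runs closer than `d` bases are merged before flank evaluation.

Defaults are a = b = 200, c = 5, d = 2, e = f = 30, the parameter values
the original curation was run with; the semantics attached to each letter
are this package's own, chosen so that only well-supported internal drops
are broken. Breaking removes the low-coverage run itself rather than
cutting at a point — bases with sub-threshold support are unreliable —
and pieces shorter than `min_piece` (default 1000 bp) are dropped and
logged. The identity (kept bases) + (removed run bases) + (dropped piece
bases) = (input bases) holds exactly and is asserted.

The width of the coverage valley at a misjoin scales with the read
length (reads starting within one read length of the join either span it
or stop short), so the flank windows `a`/`b` should be of at least
read-length order for the flank means to clear d*c comfortably; the
package's validation scenario pairs 150 bp reads with the default 200 bp
flanks for this reason.

The flank condition is what keeps the false-positive rate at zero on
uniform-coverage data: an interior position at 30x is below c = 5 with
probability ~1e-9, and the V-shaped ramps at real contig ends either touch
the exclusion zones (condition 1) or fail the flank means (condition 2).

## Fragment-wise decontamination

Contigs are split into consecutive 500 bp windows (a final remainder is
kept when >= 250 bp — half a window of classifiable signal — and dropped
otherwise). An external protein-level classifier assigns a taxon id to
each fragment; crcurate consumes that table (Kaiju's three-column format)
and resolves each taxid to its superkingdom by walking the taxonomy tree's
parent links until a node of rank `superkingdom` is found. Assignments
above superkingdom (e.g. "cellular organisms"), below an absent
superkingdom, or unknown taxids resolve to `unclassified`.

The decision rule is taxonomy-only and strict: a contig is dropped iff
**strictly more than 50%** of its *classified* fragments resolve to
Bacteria. Three choices deserve explanation:

* **Denominator = classified fragments.** Unclassified fragments carry no
  evidence either way; letting them dilute the bacterial fraction would
  make heavily diverged contaminants unkillable. Both counts are reported
  per contig so the all-fragments variant is recomputable.
* **Viral assignments never count toward exclusion.** Viral signatures in
  this genus are expected endogenous viral elements, i.e. genuine host
  sequence. Viral fragments count as classified (denominator) but not as
  bacterial (numerator).
* **Strict inequality.** A 50:50 contig is kept; the boundary is tested.

Three corroborative criteria are computed and reported but never drive the
verdict: GC content over unambiguous bases, median read coverage, and a
tetranucleotide z-score — the Euclidean distance of a contig's canonical
4-mer profile (136 classes, 4-mer pooled with its reverse complement) from
the length-weighted mean profile of the set, standardised robustly by
median/MAD so a minority of contaminant profiles cannot inflate the scale
they are judged against. In the original analysis all four criteria agreed
and the taxonomic rule was adopted as the single decision rule; this
package mirrors that.

## Mitochondrial contig curation

The mitochondrial contig is identified by canonical 21-mer containment
against a mitochondrial reference: the fraction of the reference's
distinct 21-mers present in each contig, argmax wins, with a 0.5 floor
(random nuclear sequence shares essentially no 21-mers with an organelle
genome, so scores are near 0 or near 1). Containment rather than identity
means flanking junk on the contig does not depress the score, and no
external mapper is needed.

Assemblers emit circular replicons as linear contigs whose ends duplicate
each other. `circ_trim` finds the longest suffix that aligns to a prefix
with >= 95% ungapped identity (15-mer seeds taken at several prefix
offsets anchor candidate overlaps, so a mismatch inside the first seed
cannot hide a true overlap; candidates >= 50 bp are verified over their
full length) and removes the suffix copy. Ties in length break toward
higher identity; the operation is idempotent. The identity threshold
tolerates residual consensus errors near contig ends in long-read
assemblies; both threshold and minimum length are exposed.

`circ_restart` then rotates the (now circular) sequence so it starts at a
reference anchor — conventionally the large subunit rRNA gene. The anchor
is located in the doubled sequence (so matches spanning the linearisation
origin are found) on both strands, allowing up to 10% mismatches; the
sequence is reverse-complemented if needed and rotated so the anchor
starts at position 0. Any rotation or strand presentation of the same
circle therefore normalises to byte-identical output (assuming the anchor
occurs once, which the error on ambiguous anchors makes explicit).

## rDNA operon copy number and substitutions

Assemblies collapse a tandem rDNA array into roughly one unit, so reads
from all copies pile onto it. The haploid copy number is estimated as

    median per-base depth across the operon
    ---------------------------------------
    median per-base depth across the 50 longest contigs

with depths pooled per base (not per contig) in the denominator. Both
numerator and denominator scale with ploidy and with sequencing effort, so
the ratio is the per-haploid-genome copy count and is scale-invariant
under depth multiplication — both properties are tested. With fewer than
50 contigs all are used and the estimate is annotated. Medians use the
lower-median convention throughout so results on integer depth arrays are
integers, not interpolations.

Per-strain substitutions over an operon alignment use the unique-variant
rule: in a gap-free column, a strain scores a substitution when its base
differs from the base shared unanimously by all other strains. Columns
with gaps, or with any other pattern (two variants among four strains,
say), are skipped and surfaced as counts rather than silently resolved.
Allele fractions at externally supplied SNP sites are summarised from the
alignment pileup (primary records, M/=/X bases); variant *calling* is out
of scope — the sites come from a caller, the package only counts bases.

## Assembly statistics and ANI

N50 is the contig length at which the descending cumulative length first
reaches half the total; GC excludes ambiguity codes from numerator and
denominator. ANI cuts the query into non-overlapping 1000 bp fragments
(the last partial fragment is not scored), seeds each fragment against the
reference by shared 15-mers voting over (contig, strand, diagonal), and
scores the best candidate window by gapped alignment (unit match/mismatch,
affine gaps), identity = matches / alignment length. Fragments reaching
80% identity count as orthologous; ANI is their mean identity, reported
per direction (the CLI prints both and their mean). Self-ANI is exactly
100 by construction. The 1000 bp fragment length (rather than fastANI's
3000) keeps enough fragments for stable means on desk-scale genomes;
the 80% orthology floor follows common ANI practice. Agreement with
fastANI on real assemblies is expected to a few tenths of a percent, not
bit-exact.

## The synthetic-data generator

`generate_genome()` emulates exactly the statistical structure the
curation stages key on, with defaults set to the study system: a diploid
nuclear genome at GC 0.70 split into `n_chromosomes` contigs, haplotype B
differing from A by i.i.d. substitutions at `het_rate` (default 0.005 — a
value in the typical range for protist isolates; the true heterozygosity
of the organism is not published), a tandem array of identical rDNA units
shared by both haplotypes, an AT-rich (GC 0.35) mitochondrial circle
emitted linearised at a random rotation with `mito_end_overlap` duplicated
bases, and bacterial contaminants at GC 0.45. Sequence is i.i.d. per base
given the GC target — sufficient for composition screening, k-mer spectra
and coverage statistics, which are the quantities under test.

`simulate_reads()` places reads uniformly (length-weighted over contigs,
uniform within), on random strands, with i.i.d. substitution errors and
constant Q40 qualities; `emit_alignments()` converts the true placements
into all-match SAM records through a block liftover, so no external mapper
is ever run. Chimeras are built by concatenating two whole source contigs
while reads are simulated from the *sources*: no read spans the join, so
the planted misjoin produces exactly the V-shaped coverage gap a real one
does. The same liftover mechanism collapses a planted tandem array onto a
single-unit assembly for the copy-number scenario. `emit_classifier_table()`
fabricates Kaiju-style output at a configurable accuracy and unclassified
rate, with wrong labels drawn uniformly from the other superkingdoms.

What the generator does **not** emulate — and what passing tests therefore
do not certify: indel-dominant long-read error profiles, quality-score
structure, GC-dependent coverage bias, repeat families beyond the single
rDNA array, structural variation other than the planted chimeras, and
classifier errors that correlate along a contig. The pipeline's behaviour
under those realities must be judged on real data.

A fixed generator seed yields byte-identical FASTA/FASTQ/SAM/TSV outputs;
one extra knob beyond the core genome properties (`n_chromosomes`, default
8) controls how the haploid genome is split into contigs, because chimera
planting needs at least two sources and decontamination scenarios need a
population of host contigs.

## Problem sizes and numerical choices

The validation scenarios (`benchmark_*`, also run by
`scripts/acceptance.R`) use a 5 Mbp diploid at 60x for genome size, 140 x
10 kb sources / 20 chimeras at 30x for junctions, a 30-contig host with 20
contaminants for decontamination, 15 kb circles with 50–2000 bp overlaps
for the mitochondrion, 5/20/80-copy arrays at 100x for copy number, and
2 x 100 kb assemblies for ANI — sizes chosen so each scenario exercises
the statistical regime of the real analysis while remaining comfortable to
run on a laptop.

Degenerate inputs are defined rather than accidental: histograms without a
valley are an error ("no error/signal separation"); contigs shorter than
the junction windows yield no calls; a contig with no classified fragment
is kept and flagged `unclassified`; a zero-depth backbone is an error; an
anchor absent at 90% identity is an error; zero-depth SNP sites report
`NA` fractions. Ties are specified: lower medians, longest-then-highest-
identity overlaps, first-then-raw-count histogram peaks.

## Limitations

The junction caller reconstructs a procedure whose original implementation
is only documented by its flag values; the semantics here are declared and
tested but not guaranteed identical to the original script. The k-mer
counter is exact and in-memory, sized for desk-scale read sets, not for
streaming billions of reads. ANI is a reconstruction that agrees with
fragment-mapping tools to tenths of a percent, not a drop-in replacement.
Decontamination trusts the upstream classifier's calibration; with heavily
biased classifiers the 50% rule inherits that bias.
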