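---
title: "Methods: quantifying ZF-CBE editing and off-target activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ZF-CBE editing and off-target activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbepipe)
```

# The measurement problem

A zinc-finger cytosine base editor (ZF-CBE) carries a split
double-stranded-DNA cytidine deaminase on two zinc-finger arrays that bind
either side of a target. Deamination converts C to U; repair (or
replication) fixes the change as C•G→T•A. Three questions follow every
experiment, and each gets its own pipeline stage:

* *How much editing happened at the target?* — amplicon sequencing over
  the site, quantified per position and as stop-codon conversion.
* *Where else did the editor act?* — genome-wide discovery of
  deamination sites from purified genomic DNA treated with the editor and
  then with USER (uracil DNA glycosylase + endonuclease VIII), which
  converts every uracil into a single-strand break. After shearing and
  sequencing, real edits appear as many reads sharing one exact 5′ start
  position against a background of random shear points.
* *How much cellular editing occurs at those candidate sites?* — a
  multiplexed amplicon panel over all candidates, quantified with
  retention and masking rules that keep germline variation and assay
  artefacts out of the statistic.

A fourth, design-time stage asks *where could an editor create a
premature stop codon* in a protein of interest, and whether the required
cytosines sit in a 5′ context the deaminase accepts.

# Editing window and amplicon quantification

The editing window is defined structurally, not empirically: with binding
arms `[l0, l1)` and `[r0, r1)` (0-based half-open, top strand), the
window is `[l1 − 1, r0 + 1)` — the inter-arm gap widened by exactly one
base on each side. Window positions are labelled `<refbase><k>` with
1-based offset `k` from the window start (C10, C11 style). The labelling
origin is a package convention: the field's figures use C-number labels
without defining a shared origin, so positions are always reported with
explicit 0-based coordinates alongside the labels.

Reads are pairwise-aligned to the amplicon (affine gaps, match 2,
mismatch −3, gap open 10, gap extend 1), global in the reference and
semi-global in the read so residual adapter never drags the alignment.
Both orientations are tried and the better kept, which makes every
reported number invariant under reverse-complementing the input.
Alignments below a configurable identity floor (default 0.6) are
discarded and counted — they are mispriming products, not evidence.
Identical reads are aligned once and weighted, so deeply sequenced
amplicons cost unique-read, not total-read, time.

Per position, a read contributes a base call only where its alignment
covers the position without an indel; deletions are tallied in their own
channel and insertions anchor after the preceding reference position.
Consequently base + deletion frequencies sum to ≤ 1 per position. The
stop-codon fraction is computed over reads that span the annotated codon
*without* an indel inside it; indel-in-codon reads are excluded from the
denominator and reported separately. This keeps the substitution and
indel channels separable: an experiment with 10% stop conversion and 5%
indels reports both numbers without either contaminating the other. The
window indel fraction counts reads with any indel overlapping the window
(scope configurable to the whole amplicon).

Reporting thresholds follow the field's listing conventions: substitution
events outside the window are flagged at frequency ≥ 3%, and
non-reference bases other than the intended deamination product (T at a
reference C, A at a reference G) at ≥ 2%. Whether the unintended-base
rule should apply only inside the window is genuinely ambiguous in
practice, so both scopes are computed and flagged separately
(`flagged_unintended_bases` for the window, `flagged_unintended_anywhere`
for the full amplicon). Comparisons are `>=` on frequencies derived as
exact count ratios, so 30/1000 flags at a 3% threshold and 29/1000 does
not.

# Break discovery from 5′ read-start pileups

Filters run in a fixed order with first-failure attribution, so the
filter tally in the run summary is an audit trail: mean base quality
≥ 14, MAPQ ≥ 50, 5′ soft-clip ≤ 5 bp (measured at the read's sequencing
start — the right-hand CIGAR end for reverse-strand reads), duplicate
flag, mapped. Two choices deserve explanation:

* *Duplicate flags are consumed, not derived.* At a true break site many
  legitimate reads share the same 5′ coordinate by construction;
  coordinate-based deduplication would erase exactly the signal being
  measured. Upstream optical-duplicate marking (which uses flow-cell
  geometry, not coordinates alone) is the right tool, and this module
  trusts its flags.
* *"Q-score 14" is read as mean base quality per read.* Minimum-base and
  trimming interpretations exist; mean-per-read is the least destructive
  and is configurable.

Start counting is per exact position and strand-separated (a nick
produces same-orientation pileups); the depth denominator is
strand-agnostic coverage at the position. A position is a candidate when
start count ≥ 10 *and* start fraction ≥ 0.2, both configurable, both
compared with `>=`. Counting is implemented per position rather than with
any smoothing kernel: candidates are defined at identical 5′ start
positions, so a sliding accumulation is an implementation detail, not a
statistic.

Finalization removes candidates inside repeat-mask intervals (half-open,
single-position containment), subtracts the unedited control by exact
position match on either strand (a distance-tolerant variant is available
via `control_distance`), and merges survivors within 50 bp by single
linkage. Cluster representatives are the member with maximal start count,
leftmost on ties. Both pre-merge and post-merge counts are reported,
since published per-construct counts can be read either way. Set
comparison between constructs pairs clusters greedily by nearest distance
within 50 bp, each cluster used at most once, and reports Venn-style
counts.

# Panel quantification and masking

Demultiplexing uses the first 23 nt of each read against the panel's
23-nt prefixes (exact by default; with mismatches allowed, ambiguous
matches are unassigned). Assignment is a partition — assigned +
unassigned + too-short = total — which the tests assert.

Retention mirrors replicated assay practice: an amplicon is kept if at
least 2 of 4 replicates carry ≥ 1000 assigned reads, and if ≥ 15% of
unedited-sample reads "resemble" the expected reference. Resemblance is
undefined in prose descriptions of such filters; here it is global
alignment identity ≥ 0.85 (configurable, audit-logged). This separates
mispriming products (low identity) from genuinely edited amplicons (high
identity with a few mismatches), which is the distinction the filter
exists to draw.

Positions whose unedited non-reference allele frequency lies strictly
inside (0.04, 0.96) are masked: intermediate frequencies are
germline-like heterozygosity or systematic artefacts, not editing. The
boundaries are strict inequalities, so an allele at exactly 0.04 stays
in. The per-amplicon statistic is the maximum over unmasked positions of
the treated-minus-unedited frequency increase of A or of T — cytosine
editing on the bottom strand surfaces as an A gain on the top strand, so
both bases indicate editing, one per strand. Negative changes are floored
at zero (the statistic indicates editing, not depletion), deletion
alleles never contribute, and an amplicon whose positions are all masked
reports "not evaluable" rather than zero. Loci count as edited when the
statistic exceeds 1% strictly.

Replicate aggregation is an open choice in published screens; the default
computes the statistic per replicate and reports the mean, with all
per-replicate values retained so maxima or pooled variants can be
recomputed from the same object.

# Stop-target scanning

Exactly four codons are convertible to a stop by single-strand C→T
editing: CAG→TAG, CAA→TAA, CGA→TGA via a sense-strand C at codon position
1, and TGG→TGA/TAG (one antisense C each) or TAA (both) via the Cs
opposite its two Gs. TGG counts once per codon in summaries even though
it offers multiple routes; per-route detail stays in the target table.
The 5′ context of each target C is read on its edited strand: for a sense
C the preceding sense base; for an antisense C the complement of the
sense base immediately 3′ of the paired G. Classes are 5′-TC; 5′-TCC
(neighbour C whose own 5′ neighbour is T); else 5′-AC / 5′-GC / 5′-CC. A
codon qualifies under a deaminase profile (e.g. `{5'-TC, 5'-TCC}` for
DddA-like enzymes) if *any* stop-achieving target C qualifies —
consistent with how per-residue candidate lists are drawn up in practice.
Missing flanks at terminal codons give "undetermined", never a guess.
The scanner is validated against an exhaustive oracle that applies every
single sense C→T and G→A substitution and checks for stop membership.

# What the simulators emulate — and what they do not

`simulate_break_library` draws fragment lengths from a truncated normal
(mean `frag_mean`, sd `frag_mean`/5) — shearing is physical and any
unimodal model suffices for testing a caller that only consumes 5′ start
positions. Background fragments start uniformly on both strands; at each
truth site a stated fraction of overlapping fragments has its 5′ end
moved exactly to the site on the stated strand, which is the defining
signature USER leaves. Records carry MAPQ, 5′ soft-clips, constant
per-base qualities (with injectable low-quality or clipped reads for
filter tests) and duplicate flags. Single-end records are the fixture
default. Not modelled: instrument-specific error profiles, optical
duplicate tile geometry, PCR chimeras, or local coverage bias — so
passing tests demonstrate threshold logic and recovery under the assay's
idealized signal model, not robustness to every real-data artefact.

`simulate_amplicon_reads` applies per-position substitution rules
independently per read, whole-codon conversions as mutually exclusive
alternatives (so 40% TGG→TGA plus 10% TGG→TAA partitions reads), one
optional indel channel, then uniform per-base error. `simulate_rhamp_run`
adds replicate structure, germline-like intermediate-frequency alleles in
both conditions, treated-only edits, and off-panel contaminants. Every
generator is byte-deterministic given its seed and emits exactly the
requested read count.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally everywhere; SAM's 1-based
  convention is converted at the IO boundary, and BED is native.
* Threshold comparisons are `>=` for listing/calling rules and strict
  `>` / open intervals where the rule is worded that way (edited-locus
  counting, AF masking). Frequencies are exact count ratios, so printed
  boundary cases (10/50 = 0.2, 30/1000 = 0.03) behave exactly.
* Alignment gap placement is ambiguous when an indel abuts a repeated or
  edited base; fixtures therefore place measured substitutions a few
  bases away from simulated indels, and the aligner's scoring (gap open
  10, extend 1) keeps gaps compact. This is a property of all
  alignment-based quantification, not of this implementation.
* Cluster-representative ties break leftmost; greedy set-pairing breaks
  distance ties by position order — both deterministic.
* Empty inputs return empty, typed results (empty profile, empty
  candidate table); malformed inputs (mask with `end <= start`, bad
  CIGAR, missing SAM header) fail fast naming the offending record or
  line.

# Problem sizes in the test suite

The suite validates recovery at the scales the methods operate at, scaled
to what a laptop runs in seconds-to-minutes: break discovery on a 200-kb
single-contig genome at 30× with 20 implanted sites across edit fractions
0.25–1.0 (with a matched null library), amplicon profiles at 10,000 reads,
panels of 3–4 amplicons × 4 replicates × 1500 reads. Production settings
(multi-Gb genomes, 550-bp inserts, 60,000× amplicon coverage) differ only
in volume, not in logic; the per-position counting paths are linear in
reads. The statistical bar throughout is recovery within three binomial
standard deviations of simulated truth, plus exact behaviour at every
documented threshold boundary.

# Known limitations

* The amplicon aligner quantifies substitutions and short indels; it is
  not a structural-variant or translocation caller, and UMI handling and
  paired-end merging are upstream concerns.
* Break discovery consumes aligned records; alignment itself, repeat
  track generation and duplicate detection are out of scope.
* The stop scanner takes the CDS as input and does not resolve
  transcript isoforms; residue numbering follows the supplied offset.
* The panel statistic measures net A/T gain; complex alleles (MNVs,
  editing plus indel on one read) contribute through their aligned base
  calls, not as haplotypes.
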