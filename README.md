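# cbepipe

Analysis pipeline for zinc-finger cytosine base editor (ZF-CBE)
experiments. A ZF-CBE fuses a double-stranded-DNA cytidine deaminase
(DddA-like, or a toxin-derived homolog) to engineered zinc-finger arrays,
producing targeted C•G→T•A changes in the gap between the two binding
sites. `cbepipe` covers the four computational stages such experiments
need, plus a truth-known simulator so every stage can be validated without
touching real sequencing data:

1. **Amplicon quantification** (`quantify_amplicon`) — per-position editing,
   premature stop-codon conversion and indel rates from amplicon reads.
   The editing window is derived from the zinc-finger binding arms: with
   arms `[l0, l1)` and `[r0, r1)` on the top strand, the window is
   `[l1 − 1, r0 + 1)` — the inter-arm gap plus one flanking base on each
   side. Substitutions outside the window are listed at ≥ 3%, unintended
   (non-C→T-product) bases at ≥ 2%.
2. **Genome-wide break discovery** (`discover_breaks`) — off-target
   candidates from whole-genome sequencing of USER-treated DNA, where
   uracil excision leaves single-strand breaks that appear as stacks of
   identical strand-aware 5′ read-start positions. Reads are filtered
   (mean base quality ≥ 14, MAPQ ≥ 50, 5′ soft-clip ≤ 5 bp, duplicates
   removed); a position with start count *s* and local depth *d* is a
   candidate when *s* ≥ 10 and *s*/*d* ≥ 0.2; candidates are control-
   subtracted, repeat-masked, and merged within 50 bp.
3. **Multiplexed panel quantification** (`rhamp_quantify`) — off-target
   editing across an rhAmpSeq-style amplicon panel: reads are
   demultiplexed by their first 23 nt; amplicons are retained if present
   in ≥ 2 of 4 replicates with ≥ 1000 reads and ≥ 15% of unedited reads
   resemble the expected reference; positions with unedited allele
   frequencies strictly inside (0.04, 0.96) are masked as germline-like;
   the per-amplicon statistic is max over unmasked positions of the
   treated-minus-unedited increase in A or T frequency (editing on either
   strand), and loci count as edited above 1%.
4. **Stop-target scanning** (`scan_stop_codons`) — codons convertible to
   TGA/TAG/TAA by a single-strand C→T event (CAG, CAA, CGA via a sense C;
   TGG via antisense Cs opposite its Gs), with the 5′ sequence context of
   each target cytosine (5′-TC, 5′-TCC, 5′-AC, 5′-GC, 5′-CC) classified on
   the edited strand — the context that determines whether a given
   deaminase can act there.

The simulators (`make_genome`, `simulate_break_library`,
`simulate_amplicon_reads`, `simulate_rhamp_run`) emit FASTA/FASTQ/SAM/BED
with known truth, and all analysis functions accept either in-memory
objects or files in those formats. A thin command-line front end lives at
`inst/cli/cbepipe`.

## Worked example

Implant two single-strand break sites in a 50-kb genome and recover them:

```r
library(cbepipe)
g <- make_genome(50000, 0.45, seed = 7)
truth <- break_truth("chrS", c(12000, 31000), c("+", "-"), c(0.9, 0.5))
treated <- simulate_break_library(g, truth, mean_depth = 40, seed = 8)
control <- simulate_break_library(g, mean_depth = 40, seed = 9)
res <- discover_breaks(treated, control)
res
#> break_discovery: 2 candidate position(s), 2 cluster(s) after control subtraction/masking/merging
res$clusters[, c("contig", "position", "strand", "start_count")]
#>   contig position strand start_count
#> 1   chrS    12000      +          83
#> 2   chrS    31000      -          37
```

Both implanted sites come back at their exact coordinates; the start
counts reflect the implanted edit fractions (0.9 and 0.5) times the local
fragment depth. The matched control contributes no candidates.

Quantify a simulated amplicon library carrying 30% C→T at one window
cytosine, 10% TGG→TAA stop conversion and 5% indels:

```r
ref <- amplicon_reference("site1", seq70, left_arm = c(5, 17),
                          right_arm = c(33, 45), target_codon_start = 18)
sim <- simulate_amplicon_reads(ref, amplicon_sim_profile(
  sub_rates = data.frame(pos = 22, alt = "T", rate = 0.30),
  codon_edits = data.frame(start = 18, to = "TAA", rate = 0.10),
  indel_rate = 0.05, indel_pos = 28, indel_len = 2,
  n_reads = 5000, seed = 99))
rep <- quantify_amplicon(sim$reads, ref)
rep
#> editing_report
#>   stop fraction: 0.1016
#>   indel fraction (window): 0.0518
#>   flagged outside window (>= 3%): 0
#>   flagged unintended bases in window (>= 2%): 0
rep$frequencies["T", 23]
#> [1] 0.2898
```

The stop fraction (0.1016), window indel fraction (0.0518) and the T
frequency at the edited cytosine (0.2898) each land within binomial noise
of the simulated truth (0.10 / 0.05 / 0.30).

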