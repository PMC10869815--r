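# Fixture builders shared across test files. Everything is generated in
# code; no binary data on disk.

# A 70-bp amplicon with arms [5,17) and [33,45) (window [16,34)), a TGG
# target codon at 18-20 (sense) inside the window, a C at 22 (window) and
# a C at 2 (outside the window) for flagging tests. The window is wide
# enough that an indel channel at 28-29 stays clear of the measured codon
# and cytosine even when gap placement shifts by a base or two.
make_test_amplicon <- function() {
  set.seed(4242)
  ch <- sample(c("A", "C", "G", "T"), 70, replace = TRUE)
  ch[19:21] <- c("T", "G", "G")   # target codon, 0-based 18
  ch[23] <- "C"                   # window cytosine, 0-based 22
  ch[3] <- "C"                    # outside-window cytosine, 0-based 2
  amplicon_reference("amp_test", paste(ch, collapse = ""),
                     left_arm = c(5L, 17L), right_arm = c(33L, 45L),
                     target_codon_start = 18L, codon_strand = "sense")
}

# Minimal alignment-record rows in the package's internal form, for
# boundary tests that need exact control over every filter attribute.
make_record <- function(pos, strand = "+", contig = "chr1", width = 150L,
                        mapq = 60L, clip5 = 0L, mean_qual = 30,
                        duplicate = FALSE, unmapped = FALSE,
                        qname = "r") {
  ref_end <- pos + width
  data.frame(qname = qname,
             flag = ifelse(strand == "-", 16L, 0L) +
                    ifelse(duplicate, 1024L, 0L) +
                    ifelse(unmapped, 4L, 0L),
             contig = contig, pos = as.integer(pos),
             mapq = as.integer(mapq), cigar = paste0(width, "M"),
             seq = strrep("A", width),
             qual = strrep(rawToChar(as.raw(33L + round(mean_qual))), width),
             unmapped = unmapped, strand = strand, duplicate = duplicate,
             ref_end = as.integer(ref_end), clip5 = as.integer(clip5),
             start5 = as.integer(ifelse(strand == "+", pos, ref_end - 1L)),
             mean_qual = mean_qual,
             stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# n reads whose strand-aware 5' ends start at `at`, plus `covering` reads
# that span `at` but start elsewhere.
make_start_stack <- function(at, n_start, n_cover, width = 150L) {
  rows <- lapply(seq_len(n_start), function(i) {
    make_record(at, qname = sprintf("s%d", i), width = width)
  })
  cov <- lapply(seq_len(n_cover), function(i) {
    make_record(at - i, qname = sprintf("c%d", i), width = width)
  })
  do.call(rbind, c(rows, cov))
}

# Random in-frame CDS with no leading/trailing constraints, for scanner
# oracle tests.
make_random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}
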