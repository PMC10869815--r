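test_that("editing window is the inter-arm gap plus one flanking base each side", {
  r <- amplicon_reference("a", strrep("ACGT", 8), c(0, 12), c(20, 32))
  expect_equal(r$window, c(11L, 21L))

  # abutting arms leave only the two flanking bases
  r2 <- amplicon_reference("b", strrep("ACGT", 6), c(0, 12), c(12, 24))
  expect_equal(r2$window, c(11L, 13L))

  # window length = gap + 2 for random arm placements
  set.seed(99)
  for (i in 1:25) {
    l0 <- sample(0:5, 1); l1 <- l0 + sample(4:10, 1)
    r0 <- l1 + sample(0:12, 1); r1 <- r0 + sample(4:10, 1)
    rr <- amplicon_reference("c", strrep("A", r1 + 3),
                             c(l0, l1), c(r0, r1))
    expect_equal(rr$window[2] - rr$window[1], (r0 - l1) + 2L)
  }

  expect_error(amplicon_reference("d", strrep("A", 40), c(0, 20), c(15, 30)),
               "arms")
})

test_that("aligner reports substitutions, indels and orientation correctly", {
  ref <- make_test_amplicon()
  s <- ref$sequence

  a0 <- align_amplicon_reads(s, ref)
  expect_equal(length(a0$alignments), 1L)
  expect_identical(a0$alignments[[1]]$read_base,
                   strsplit(s, "")[[1]])
  expect_equal(nrow(a0$alignments[[1]]$del), 0L)

  r1 <- s; substr(r1, 23, 23) <- "T"   # C->T at 0-based 22
  a1 <- align_amplicon_reads(r1, ref)
  mism <- which(a1$alignments[[1]]$read_base != strsplit(s, "")[[1]])
  expect_equal(a1$alignments[[1]]$ref_pos[mism], 22L)

  r2 <- paste0(substr(s, 1, 40), substr(s, 44, 70))  # 3-bp del at 0-based 40
  a2 <- align_amplicon_reads(r2, ref)
  expect_equal(a2$alignments[[1]]$del,
               data.frame(start = 40L, len = 3L))

  # reverse-complement reads land in the "-" orientation with the same calls
  a3 <- align_amplicon_reads(revcomp(r1), ref)
  expect_equal(a3$alignments[[1]]$orientation, "-")
  mism3 <- which(a3$alignments[[1]]$read_base != strsplit(s, "")[[1]])
  expect_equal(a3$alignments[[1]]$ref_pos[mism3], 22L)

  # junk reads fall below the identity floor and are counted
  junk <- strrep("A", 70)
  aj <- align_amplicon_reads(c(s, junk), ref)
  expect_equal(aj$n_discarded, 1L)

  expect_error(align_amplicon_reads(character(0), ref), "non-empty")
  expect_error(align_amplicon_reads("", ref), "non-empty")
})

test_that("position tabulation recovers simulated per-position rates", {
  ref <- make_test_amplicon()
  prof <- amplicon_sim_profile(
    sub_rates = data.frame(pos = 22L, alt = "T", rate = 0.30),
    n_reads = 10000L, seed = 50)
  sim <- simulate_amplicon_reads(ref, prof)
  alns <- align_amplicon_reads(sim, ref)
  pp <- tabulate_positions(alns)

  expect_true(all(pp$total <= 10000))
  freq <- position_frequencies(pp)
  expect_lt(abs(freq["T", 23] - 0.30), 3 * sqrt(0.3 * 0.7 / 10000))
  # untouched positions are pure reference
  expect_equal(unname(freq[cbind(match(pp$ref_chars[1:10],
                                       rownames(freq)), 1:10)]),
               rep(1, 10))
  # frequencies are a sub-probability vector everywhere
  expect_true(all(colSums(freq) <= 1 + 1e-12))
})

test_that("100 unedited reads give reference frequency 1 at every position", {
  ref <- make_test_amplicon()
  alns <- align_amplicon_reads(rep(ref$sequence, 100), ref)
  freq <- position_frequencies(tabulate_positions(alns))
  expect_equal(unname(freq[cbind(match(strsplit(ref$sequence, "")[[1]],
                                       rownames(freq)), 1:70)]),
               rep(1, 70))
})

test_that("stop-codon calling counts the three stops and excludes indel reads", {
  ref <- make_test_amplicon()
  s <- ref$sequence
  # TGG at 18-20: G->A at second codon base gives TAG
  r_tag <- s; substr(r_tag, 20, 20) <- "A"
  expect_equal(substr(r_tag, 19, 21), "TAG")
  # deletion through the codon
  r_del <- paste0(substr(s, 1, 18), substr(s, 22, 70))

  alns <- align_amplicon_reads(c(rep(s, 6), rep(r_tag, 3), r_del), ref)
  stop_call <- call_stop_codon_fraction(alns, ref)
  expect_equal(stop_call$n_spanning, 9)
  expect_equal(stop_call$n_indel_in_codon, 1)
  expect_equal(stop_call$stop_fraction, 3 / 9)
  expect_equal(unname(stop_call$by_codon["TAG"]), 3)

  # all-unedited reads give stop fraction 0
  a0 <- align_amplicon_reads(rep(s, 20), ref)
  expect_equal(call_stop_codon_fraction(a0, ref)$stop_fraction, 0)

  noc <- amplicon_reference("x", s, c(5, 17), c(25, 37))
  expect_error(call_stop_codon_fraction(a0, noc), "codon")
})

test_that("simulated per-variant stop split is recovered", {
  ref <- make_test_amplicon()
  prof <- amplicon_sim_profile(
    codon_edits = data.frame(start = c(18L, 18L), to = c("TGA", "TAA"),
                             rate = c(0.40, 0.10)),
    n_reads = 6000L, seed = 51)
  alns <- align_amplicon_reads(simulate_amplicon_reads(ref, prof), ref)
  sc <- call_stop_codon_fraction(alns, ref)
  expect_lt(abs(sc$stop_fraction - 0.50), 3 * sqrt(0.5 * 0.5 / 6000))
  expect_lt(abs(sc$by_codon["TGA"] / sc$n_spanning - 0.40),
            3 * sqrt(0.4 * 0.6 / 6000))
  expect_lt(abs(sc$by_codon["TAA"] / sc$n_spanning - 0.10),
            3 * sqrt(0.1 * 0.9 / 6000))
})

test_that("flagging thresholds behave exactly at the 3% and 2% boundaries", {
  ref <- make_test_amplicon()
  s <- ref$sequence
  edit_out <- s; substr(edit_out, 3, 3) <- "T"   # outside window (0-based 2)

  reads29 <- c(rep(edit_out, 29), rep(s, 971))   # 2.9%
  rep29 <- quantify_amplicon(reads29, ref)
  expect_equal(nrow(rep29$flagged_outside_window), 0L)

  reads30 <- c(rep(edit_out, 30), rep(s, 970))   # 3.0%
  rep30 <- quantify_amplicon(reads30, ref)
  expect_equal(nrow(rep30$flagged_outside_window), 1L)
  expect_equal(rep30$flagged_outside_window$position, 2L)
  expect_equal(rep30$flagged_outside_window$frequency, 0.03)

  # C->G at the window cytosine is an unintended product; 2.0% flags it
  edit_g <- s; substr(edit_g, 23, 23) <- "G"
  rep_g <- quantify_amplicon(c(rep(edit_g, 20), rep(s, 980)), ref)
  expect_true(any(rep_g$flagged_unintended_bases$position == 22L &
                  rep_g$flagged_unintended_bases$base == "G"))
  # while the intended C->T product at the same level is not
  edit_t <- s; substr(edit_t, 23, 23) <- "T"
  rep_t <- quantify_amplicon(c(rep(edit_t, 20), rep(s, 980)), ref)
  expect_false(any(rep_t$flagged_unintended_bases$base == "T" &
                   rep_t$flagged_unintended_bases$position == 22L))

  # zero-edit fixture: empty flags, zero indels
  rep0 <- quantify_amplicon(rep(s, 200), ref)
  expect_equal(nrow(rep0$flagged_outside_window), 0L)
  expect_equal(nrow(rep0$flagged_unintended_bases), 0L)
  expect_equal(rep0$indel_fraction, 0)
})

test_that("raising flag thresholds never increases flagged events", {
  ref <- make_test_amplicon()
  prof <- amplicon_sim_profile(
    sub_rates = data.frame(pos = c(2L, 22L, 30L), alt = c("T", "G", "A"),
                           rate = c(0.05, 0.04, 0.025)),
    n_reads = 4000L, seed = 52)
  alns <- align_amplicon_reads(simulate_amplicon_reads(ref, prof), ref)
  pp <- tabulate_positions(alns)
  lo <- build_editing_report(pp, ref, outside_threshold = 0.02,
                             unintended_threshold = 0.01)
  hi <- build_editing_report(pp, ref, outside_threshold = 0.06,
                             unintended_threshold = 0.05)
  expect_lte(nrow(hi$flagged_outside_window),
             nrow(lo$flagged_outside_window))
  expect_lte(nrow(hi$flagged_unintended_bases),
             nrow(lo$flagged_unintended_bases))
})

test_that("reports are invariant under reverse-complementing all reads", {
  ref <- make_test_amplicon()
  prof <- amplicon_sim_profile(
    sub_rates = data.frame(pos = 22L, alt = "T", rate = 0.25),
    codon_edits = data.frame(start = 18L, to = "TGA", rate = 0.2),
    indel_rate = 0.04, indel_pos = 40L, indel_len = 2L,
    n_reads = 2000L, seed = 53)
  sim <- simulate_amplicon_reads(ref, prof)
  fwd <- quantify_amplicon(sim$reads, ref)
  rev <- quantify_amplicon(revcomp(sim$reads), ref)
  expect_equal(rev$stop_fraction, fwd$stop_fraction)
  expect_equal(rev$indel_fraction, fwd$indel_fraction)
  expect_equal(rev$frequencies, fwd$frequencies)
})

test_that("window indel fraction counts only window-overlapping indels by default", {
  ref <- make_test_amplicon()  # window [16, 26)
  s <- ref$sequence
  in_del <- paste0(substr(s, 1, 22), substr(s, 25, 70))   # del at 22-23
  out_del <- paste0(substr(s, 1, 45), substr(s, 48, 70))  # del at 45-46
  alns <- align_amplicon_reads(c(rep(s, 6), rep(in_del, 2), out_del), ref)
  st <- amplicon_indel_stats(alns)
  expect_equal(st$indel_fraction, 2 / 9)
  st_all <- amplicon_indel_stats(alns, scope = "amplicon")
  expect_equal(st_all$indel_fraction, 3 / 9)
})
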