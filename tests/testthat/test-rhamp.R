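make_panel_fix <- function(n = 3, len = 60, seed = 77) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                             collapse = ""))
  panel_def(paste0("amp", seq_len(n)), seqs)
}

test_that("prefix demultiplexing is an exact partition with mismatch control", {
  panel <- make_panel_fix()
  reads <- c(panel$sequence, strrep("A", 60), "ACGT")
  dm <- demultiplex_by_prefix(reads, panel)
  expect_equal(lengths(dm$bins), setNames(rep(1L, 3), panel$name))
  expect_equal(dm$unassigned, 1L)
  expect_equal(dm$too_short, 1L)
  expect_equal(sum(lengths(dm$bins)) + dm$unassigned + dm$too_short,
               dm$n_total)

  # one prefix mismatch: rejected at 0, accepted at 1
  mut <- panel$sequence[1]
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  expect_equal(demultiplex_by_prefix(mut, panel)$unassigned, 1L)
  dm1 <- demultiplex_by_prefix(mut, panel, max_mismatches = 1)
  expect_equal(length(dm1$bins$amp1), 1L)

  expect_error(panel_def(c("a", "b"), rep(panel$sequence[1], 2)),
               "distinct")
})

test_that("replicate retention boundaries follow the 2-of-4 / 1000-read rule", {
  panel <- make_panel_fix()
  cfg <- retention_config()
  counts <- rbind(amp1 = c(1000, 1000, 0, 0),
                  amp2 = c(1000, 999, 0, 0),
                  amp3 = c(5000, 5000, 5000, 5000))
  audit <- apply_amplicon_filters(counts, NULL, panel, cfg)
  expect_equal(audit$retained, c(TRUE, FALSE, TRUE))
  expect_match(audit$reason[2], "replicates")

  expect_error(apply_amplicon_filters(
    rbind(ampX = c(1000, 1000, 1000, 1000)), NULL, panel, cfg),
    "absent from panel")
})

test_that("reference-similarity retention excludes amplicons below 15%", {
  panel <- make_panel_fix()
  cfg <- retention_config()
  counts <- rbind(amp1 = c(2000, 2000, 2000, 2000),
                  amp2 = c(2000, 2000, 2000, 2000),
                  amp3 = c(2000, 2000, 2000, 2000))
  set.seed(78)
  garbage <- function(n) replicate(n, paste(
    sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
  bins <- list(
    amp1 = c(rep(panel$sequence[1], 15), garbage(85)),  # exactly 15%
    amp2 = c(rep(panel$sequence[2], 14), garbage(86)),  # 14%
    amp3 = rep(panel$sequence[3], 50))
  audit <- apply_amplicon_filters(counts, bins, panel, cfg)
  expect_equal(audit$retained, c(TRUE, FALSE, TRUE))
  expect_match(audit$reason[2], "similarity")
  # an all-pass fixture carries no exclusion reasons
  expect_true(all(is.na(audit$reason[audit$retained])))
})

test_that("background masking uses strict open-interval boundaries", {
  panel <- make_panel_fix()
  expected <- panel$sequence[1]
  mkprof <- function(alt_count, total = 1000L, pos0 = 10L) {
    refb <- substr(expected, pos0 + 1, pos0 + 1)
    altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
    reads <- rep(expected, total)
    if (alt_count > 0) {
      mut <- expected
      substr(mut, pos0 + 1, pos0 + 1) <- altb
      reads[seq_len(alt_count)] <- mut
    }
    position_allele_frequencies(reads, expected)
  }
  cfg <- retention_config()
  expect_equal(mask_background(mkprof(0), cfg), integer(0))
  # AF exactly 0.04: not masked (strict); 0.041: masked
  expect_equal(mask_background(mkprof(40), cfg), integer(0))
  expect_equal(mask_background(mkprof(41), cfg), 10L)
  # AF 0.5 (germline-like): masked; 0.96: not masked
  expect_equal(mask_background(mkprof(500), cfg), 10L)
  expect_equal(mask_background(mkprof(960), cfg), integer(0))
})

test_that("max A/T change recovers simulated editing and respects the mask", {
  panel <- make_panel_fix()
  expected <- panel$sequence[1]
  # choose a position whose reference base is C so the edit raises T
  cpos <- regexpr("C", expected)[1] - 1L
  n <- 4000L
  edited <- expected
  substr(edited, cpos + 1, cpos + 1) <- "T"
  treated <- c(rep(edited, round(0.10 * n)), rep(expected, n - round(0.10 * n)))
  unedited <- rep(expected, n)
  aft <- position_allele_frequencies(treated, expected)
  afu <- position_allele_frequencies(unedited, expected)

  st <- max_at_change(aft, afu, integer(0), "amp1")
  expect_lt(abs(st$max_at_change - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  expect_equal(st$argmax_position, cpos)
  expect_equal(st$argmax_base, "T")

  # identical profiles give exactly zero
  st0 <- max_at_change(afu, afu, integer(0))
  expect_equal(st0$max_at_change, 0)

  # masking the edited position suppresses the signal
  stm <- max_at_change(aft, afu, masked = cpos)
  expect_lt(stm$max_at_change, 0.02)
  expect_false(identical(stm$argmax_position, cpos))

  # all positions masked: not evaluable rather than zero
  stall <- max_at_change(aft, afu, masked = seq_len(nchar(expected)) - 1L)
  expect_true(is.na(stall$max_at_change))
  expect_false(stall$evaluable)
})

test_that("edited-locus counting is strictly greater than the threshold", {
  expect_equal(count_edited_loci(list(0.009, 0.010, 0.011)), 1)
  expect_equal(count_edited_loci(list()), 0)
  expect_equal(count_edited_loci(list(0.05, 0.05, 0.002), threshold = 0.01),
               2)
})

test_that("full panel quantification recovers edits and returns zero on the null", {
  panel <- make_panel_fix(n = 4, seed = 80)
  amps <- data.frame(name = panel$name, sequence = panel$sequence)
  # edited positions must sit clear of the 23-nt demultiplexing prefix
  cpos <- 23L + regexpr("C", substr(panel$sequence[2], 25, 60))[1] - 1L
  gpos <- 23L + regexpr("G", substr(panel$sequence[3], 25, 60))[1] - 1L
  spec <- panel_sim_spec(amps, replicates = 4, reads_per_replicate = 1500,
    editing = data.frame(amplicon = c("amp2", "amp3"),
                         pos = c(cpos, gpos), strand = c("+", "-"),
                         fraction = c(0.10, 0.05)))
  sim <- simulate_rhamp_run(spec, seed = 81)
  res <- rhamp_quantify(sim, panel = panel)
  expect_true(all(res$audit$retained))
  s <- setNames(res$stats$mean_stat, res$stats$amplicon)
  n <- 1500
  expect_lt(abs(s["amp2"] - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(s["amp3"] - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # at error rate 0 un-edited amplicons give exactly 0
  expect_equal(unname(s["amp1"]), 0)
  expect_equal(unname(s["amp4"]), 0)
  expect_equal(res$edited_loci, 2)

  # replicate mean lies between the per-replicate extremes
  rs <- res$replicate_stats["amp2", ]
  expect_gte(s[["amp2"]], min(rs))
  expect_lte(s[["amp2"]], max(rs))

  # an edit confined to a masked germline position is suppressed
  alt2 <- "T"
  spec_m <- panel_sim_spec(amps, replicates = 2, reads_per_replicate = 1500,
    germline = data.frame(amplicon = "amp2", pos = cpos, alt = alt2,
                          af = 0.5),
    editing = data.frame(amplicon = "amp2", pos = cpos, strand = "+",
                         fraction = 0.10))
  res_m <- rhamp_quantify(simulate_rhamp_run(spec_m, seed = 82),
                          panel = panel)
  expect_lt(res_m$stats$mean_stat[res_m$stats$amplicon == "amp2"], 0.02)
  masked_pos <- res_m$stats$n_masked[res_m$stats$amplicon == "amp2"]
  expect_gte(masked_pos, 1)
})

test_that("retention monotonicity: stricter settings never retain more", {
  panel <- make_panel_fix()
  counts <- rbind(amp1 = c(1200, 1100, 900, 0),
                  amp2 = c(1000, 1000, 1000, 1000),
                  amp3 = c(999, 2000, 0, 0))
  for (cfgs in list(list(base = retention_config(),
                         strict = retention_config(min_reads = 1100L)),
                    list(base = retention_config(),
                         strict = retention_config(min_replicates = 3L)))) {
    a_base <- apply_amplicon_filters(counts, NULL, panel, cfgs$base)
    a_strict <- apply_amplicon_filters(counts, NULL, panel, cfgs$strict)
    expect_true(all(a_strict$retained <= a_base$retained))
  }
  expect_error(retention_config(min_replicates = 5L, n_replicates = 4L),
               "min_replicates")
  expect_error(retention_config(af_low = 0.5, af_high = 0.4), "af_low")
})
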