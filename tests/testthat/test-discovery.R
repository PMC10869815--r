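test_that("alignment filters hit their documented boundaries", {
  cfg <- discovery_config()
  recs <- make_records(
    make_record(100, mapq = 49, qname = "mapq49"),
    make_record(100, mapq = 50, qname = "mapq50"),
    make_record(200, clip5 = 6, qname = "clip6"),
    make_record(200, clip5 = 5, qname = "clip5"),
    make_record(300, duplicate = TRUE, qname = "dup"),
    make_record(400, mean_qual = 13.5, qname = "lowq"),
    make_record(400, mean_qual = 14, qname = "q14"),
    make_record(500, unmapped = TRUE, qname = "unmapped"))
  out <- filter_alignments(recs, cfg)
  kept <- out$alignments$qname
  expect_setequal(kept, c("mapq50", "clip5", "q14"))
  expect_equal(unname(out$tally["mapq"]), 1)
  expect_equal(unname(out$tally["clip5"]), 1)
  expect_equal(unname(out$tally["duplicate"]), 1)
  expect_equal(unname(out$tally["mean_quality"]), 1)
  expect_equal(unname(out$tally["unmapped"]), 1)
  expect_equal(sum(out$tally), nrow(recs))

  # duplicates retained when removal is off
  cfg2 <- discovery_config(remove_duplicates = FALSE)
  out2 <- filter_alignments(recs, cfg2)
  expect_true("dup" %in% out2$alignments$qname)

  # a record failing several filters is attributed to the first in order
  both <- make_record(1, mapq = 10, mean_qual = 5, qname = "both")
  t3 <- filter_alignments(both, cfg)$tally
  expect_equal(unname(t3["mean_quality"]), 1)
  expect_equal(unname(t3["mapq"]), 0)

  # unmapped-only input: empty output with tally, no failure
  t4 <- filter_alignments(make_record(1, unmapped = TRUE), cfg)
  expect_equal(nrow(t4$alignments), 0L)
  expect_equal(unname(t4$tally["unmapped"]), 1)
})

test_that("pileup counts strand-aware 5' starts and strand-agnostic depth", {
  fwd <- make_record(100, "+", width = 150)
  pu <- pileup_read_starts(fwd)
  expect_equal(pu$starts$position, 100L)
  expect_equal(pu$starts$strand, "+")
  expect_equal(depth_at(pu, "chr1", c(99L, 100L, 249L, 250L)),
               c(0L, 1L, 1L, 0L))

  rev <- make_record(100, "-", width = 150)
  pur <- pileup_read_starts(rev)
  expect_equal(pur$starts$position, 249L)
  expect_equal(pur$starts$strand, "-")

  # oracle equivalence of start counts on a simulated fixture
  g <- make_genome(5000, 0.5, seed = 60)
  lib <- simulate_break_library(g, mean_depth = 10, seed = 61)
  pu2 <- pileup_read_starts(lib$alignments)
  ora <- oracle_start_counts(lib$alignments)
  got <- setNames(pu2$starts$start_count,
                  paste(pu2$starts$contig, pu2$starts$strand,
                        pu2$starts$position))
  expect_equal(sort(names(got)), sort(names(ora)))
  expect_true(all(got[names(ora)] == unlist(ora)))
})

test_that("candidate calling enforces both thresholds at their exact boundaries", {
  cfg <- discovery_config()
  # start_count 10, depth 50 -> fraction 0.20 exactly: candidate
  pu <- pileup_read_starts(make_start_stack(1000, 10, 40))
  cand <- call_break_candidates(pu, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start_count, 10L)
  expect_equal(cand$depth, 50L)
  expect_equal(cand$start_fraction, 0.2)

  # 9 starts never qualify regardless of depth
  expect_equal(nrow(call_break_candidates(
    pileup_read_starts(make_start_stack(1000, 9, 0)), cfg)), 0L)

  # start_count 10, depth 51 -> fraction just below 0.2: no candidate
  expect_equal(nrow(call_break_candidates(
    pileup_read_starts(make_start_stack(1000, 10, 41)), cfg)), 0L)
})

test_that("raising caller thresholds never adds candidates", {
  g <- make_genome(30000, 0.5, seed = 62)
  truth <- break_truth("chrS", c(8000, 21000), c("+", "-"), c(0.6, 0.3))
  lib <- simulate_break_library(g, truth, mean_depth = 40, seed = 63)
  pu <- pileup_read_starts(filter_alignments(lib$alignments))
  base <- call_break_candidates(pu, discovery_config())
  stricter_n <- call_break_candidates(pu,
    discovery_config(min_start_reads = 15))
  stricter_f <- call_break_candidates(pu,
    discovery_config(min_start_fraction = 0.4))
  key <- function(x) paste(x$contig, x$strand, x$position)
  expect_true(all(key(stricter_n) %in% key(base)))
  expect_true(all(key(stricter_f) %in% key(base)))
})

test_that("finalization subtracts control, masks repeats and merges by single linkage", {
  mk <- function(pos, count = 20L) {
    data.frame(contig = "chr1", strand = "+", position = pos,
               start_count = count, depth = count * 2L,
               start_fraction = 0.5, stringsAsFactors = FALSE)
  }
  # full subtraction
  a <- mk(c(100L, 500L))
  expect_equal(nrow(finalize_candidates(a, a)), 0L)

  # half-open mask semantics: inside removed, 1 bp outside retained
  mask <- data.frame(contig = "chr1", start = 90L, end = 101L)
  fin <- finalize_candidates(mk(c(100L, 101L)), NULL, mask)
  expect_equal(fin$position, 101L)
  expect_error(finalize_candidates(mk(100L), NULL,
               data.frame(contig = "chr1", start = 10L, end = 10L)),
               "mask")

  # chained merging: p, p+40, p+90 -> one cluster
  fin2 <- finalize_candidates(mk(c(1000L, 1040L, 1090L),
                                 count = c(12L, 30L, 11L)), NULL, NULL)
  expect_equal(nrow(fin2), 1L)
  expect_equal(fin2$n_members, 3L)
  expect_equal(fin2$position, 1040L)  # max start_count member
  expect_equal(fin2$summed_start_count, 53L)

  # representative ties break to the leftmost member
  fin3 <- finalize_candidates(mk(c(2000L, 2030L), count = c(15L, 15L)),
                              NULL, NULL)
  expect_equal(fin3$position, 2000L)

  # clustering agrees with a brute-force single-linkage oracle
  set.seed(64)
  pos <- sort(sample(1:5000, 40))
  fin4 <- finalize_candidates(mk(pos), NULL, NULL)
  expect_equal(nrow(fin4), length(unique(
    oracle_cluster_positions(pos, 50))))

  # idempotence: re-finalizing the representatives changes nothing
  again <- finalize_candidates(mk(fin4$position), NULL, NULL)
  expect_equal(again$position, fin4$position)
})

test_that("candidate-set comparison pairs greedily within the distance bound", {
  cl <- function(pos) {
    data.frame(contig = "chr1", position = pos, strand = "+",
               start_count = 10L, summed_start_count = 10L,
               n_members = 1L, member_positions = as.character(pos),
               stringsAsFactors = FALSE)
  }
  ab <- compare_candidate_sets(cl(c(100L, 300L)), cl(c(100L, 300L)))
  expect_equal(unname(ab$counts["shared"]), 2)
  expect_equal(unname(ab$counts["a_only"]), 0)

  # 51 bp apart with shared_distance 50: not shared
  far <- compare_candidate_sets(cl(100L), cl(151L), shared_distance = 50)
  expect_equal(unname(far$counts["shared"]), 0)
  near <- compare_candidate_sets(cl(100L), cl(150L), shared_distance = 50)
  expect_equal(unname(near$counts["shared"]), 1)

  # each cluster matched at most once
  multi <- compare_candidate_sets(cl(c(100L, 120L)), cl(110L))
  expect_equal(unname(multi$counts["shared"]), 1)
  expect_equal(unname(multi$counts["a_only"]), 1)

  # constructed overlap is recovered exactly
  shared_pos <- c(1000L, 2000L, 3000L)
  a <- cl(c(shared_pos, 5000L, 6000L))
  b <- cl(c(shared_pos + 10L, 9000L))
  cmp <- compare_candidate_sets(a, b)
  expect_equal(unname(cmp$counts["shared"]), 3)
  expect_equal(unname(cmp$counts["a_only"]), 2)
  expect_equal(unname(cmp$counts["b_only"]), 1)
})

test_that("null libraries are symmetric: swapping treated and control stays empty", {
  g <- make_genome(30000, 0.5, seed = 65)
  lib1 <- simulate_break_library(g, mean_depth = 30, seed = 66)
  lib2 <- simulate_break_library(g, mean_depth = 30, seed = 67)
  r12 <- discover_breaks(lib1, lib2)
  r21 <- discover_breaks(lib2, lib1)
  expect_equal(nrow(r12$clusters), 0L)
  expect_equal(nrow(r21$clusters), 0L)
})

test_that("implanted sites are recovered and attributed to the right positions", {
  g <- make_genome(60000, 0.5, seed = 68)
  sites <- seq(5000, 55000, by = 10000)
  truth <- break_truth("chrS", sites,
                       rep(c("+", "-"), length.out = length(sites)),
                       rep(0.8, length(sites)))
  lib <- simulate_break_library(g, truth, mean_depth = 50, seed = 69)
  ctl <- simulate_break_library(g, mean_depth = 50, seed = 70)
  res <- discover_breaks(lib, ctl)
  hit <- vapply(sites, function(p) {
    any(abs(res$clusters$position - p) <= 1)
  }, logical(1))
  expect_true(all(hit))
})
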