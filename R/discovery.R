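#' Discovery-stage configuration
#'
#' Thresholds for genome-wide break discovery from USER-nicked WGS
#' alignments. Defaults follow the assay's published settings: reads kept
#' at mean base quality >= 14, MAPQ >= 50, 5' soft-clip <= 5 bp, duplicates
#' removed; candidate positions need at least 10 identical 5' read starts
#' making up at least 20% of the local depth; candidates within 50 bp are
#' merged.
#'
#' @param min_read_quality minimum mean base quality per read.
#' @param min_mapq minimum mapping quality.
#' @param max_clip5 maximum 5' soft-clip length in bases.
#' @param min_start_reads minimum identical 5' read starts.
#' @param min_start_fraction minimum start_count / depth.
#' @param merge_distance single-linkage merge distance in bases.
#' @param remove_duplicates drop duplicate-flagged records.
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(min_read_quality = 14, min_mapq = 50,
                             max_clip5 = 5, min_start_reads = 10,
                             min_start_fraction = 0.2, merge_distance = 50,
                             remove_duplicates = TRUE) {
  for (nm in c("min_read_quality", "min_mapq", "max_clip5",
               "min_start_reads", "merge_distance")) {
    stopifnot_scalar_number(get(nm), nm, lo = 0)
  }
  if (min_start_fraction <= 0 || min_start_fraction > 1) {
    stop("min_start_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(min_read_quality = min_read_quality, min_mapq = min_mapq,
                 max_clip5 = max_clip5, min_start_reads = min_start_reads,
                 min_start_fraction = min_start_fraction,
                 merge_distance = merge_distance,
                 remove_duplicates = remove_duplicates),
            class = "discovery_config")
}

#' Filter WGS alignments before read-start pileup
#'
#' Retains mapped records with mean base quality, mapping quality, 5'
#' soft-clip and duplicate status within the configured limits. Removal is
#' attributed to the first failing filter, in the order: mean base quality,
#' MAPQ, 5' soft-clip, duplicate flag, unmapped.
#'
#' @param records alignment-record data.frame ([read_alignments()] or the
#'   `alignments` element of a [simulate_break_library()] result).
#' @param cfg a [discovery_config()].
#' @return list: `alignments` (retained records), `tally` (named removal
#'   counts incl. `retained`).
#' @export
filter_alignments <- function(records, cfg = discovery_config()) {
  if (inherits(records, "break_library")) records <- records$alignments
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  fail_q <- !is.na(records$mean_qual) &
            records$mean_qual < cfg$min_read_quality
  fail_q[is.na(records$mean_qual)] <- FALSE
  fail_mapq <- records$mapq < cfg$min_mapq
  fail_clip <- records$clip5 > cfg$max_clip5
  fail_dup <- cfg$remove_duplicates & records$duplicate
  fail_unmap <- records$unmapped
  reason[fail_unmap] <- "unmapped"
  reason[fail_dup] <- "duplicate"
  reason[fail_clip] <- "clip5"
  reason[fail_mapq] <- "mapq"
  reason[fail_q] <- "mean_quality"  # first in attribution order wins (last set)
  keep <- is.na(reason)
  tally <- c(mean_quality = sum(reason == "mean_quality", na.rm = TRUE),
             mapq = sum(reason == "mapq", na.rm = TRUE),
             clip5 = sum(reason == "clip5", na.rm = TRUE),
             duplicate = sum(reason == "duplicate", na.rm = TRUE),
             unmapped = sum(reason == "unmapped", na.rm = TRUE),
             retained = sum(keep))
  list(alignments = records[keep, , drop = FALSE], tally = tally)
}

#' Pile up strand-aware 5' read-start positions and local depth
#'
#' `start_count` tallies reads whose 5' end (leftmost aligned coordinate
#' for forward reads, rightmost for reverse reads) falls exactly at a
#' position, separately per strand; `depth` tallies reads whose aligned
#' span covers the position, on either strand.
#'
#' @param filtered retained records from [filter_alignments()] (the list or
#'   the data.frame).
#' @return object of class `start_pileup`: `starts` data.frame (contig,
#'   strand, position, start_count) and a per-contig depth Rle list.
#' @export
pileup_read_starts <- function(filtered) {
  if (is.list(filtered) && !is.data.frame(filtered) &&
      !is.null(filtered$alignments)) {
    filtered <- filtered$alignments
  }
  if (nrow(filtered) == 0L) {
    return(structure(list(starts = data.frame(contig = character(),
                                              strand = character(),
                                              position = integer(),
                                              start_count = integer()),
                          depth = list()),
                     class = "start_pileup"))
  }
  key <- paste(filtered$contig, filtered$strand, filtered$start5)
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  starts <- data.frame(contig = parts[, 1], strand = parts[, 2],
                       position = as.integer(parts[, 3]),
                       start_count = as.integer(agg),
                       stringsAsFactors = FALSE)
  starts <- starts[order(starts$contig, starts$position, starts$strand), ]
  rownames(starts) <- NULL

  depth <- lapply(split(filtered, filtered$contig), function(d) {
    IRanges::coverage(IRanges::IRanges(start = d$pos + 1L,
                                       end = d$ref_end))
  })
  structure(list(starts = starts, depth = depth), class = "start_pileup")
}

depth_at <- function(pileup, contig, position) {
  cov <- pileup$depth[[contig]]
  if (is.null(cov)) return(0L)
  p1 <- position + 1L
  out <- integer(length(p1))
  inb <- p1 >= 1L & p1 <= length(cov)
  if (any(inb)) out[inb] <- as.integer(cov[p1[inb]])
  out
}

#' Call candidate break sites from a start pileup
#'
#' Emits every (contig, strand, position) whose identical-5'-start count
#' meets `min_start_reads` and whose start fraction (start_count / depth at
#' that position) meets `min_start_fraction`.
#'
#' @param pileup a [pileup_read_starts()] result.
#' @param cfg a [discovery_config()].
#' @return data.frame of class `break_candidates`: contig, position,
#'   strand, start_count, depth, start_fraction.
#' @export
call_break_candidates <- function(pileup, cfg = discovery_config()) {
  st <- pileup$starts
  if (nrow(st) == 0L) return(empty_candidates())
  st <- st[st$start_count >= cfg$min_start_reads, , drop = FALSE]
  if (nrow(st) == 0L) return(empty_candidates())
  st$depth <- unlist(lapply(seq_len(nrow(st)), function(i) {
    depth_at(pileup, st$contig[i], st$position[i])
  }))
  st$start_fraction <- st$start_count / pmax(st$depth, 1L)
  st <- st[st$start_fraction >= cfg$min_start_fraction, , drop = FALSE]
  rownames(st) <- NULL
  class(st) <- c("break_candidates", "data.frame")
  st
}

empty_candidates <- function() {
  out <- data.frame(contig = character(), strand = character(),
                    position = integer(), start_count = integer(),
                    depth = integer(), start_fraction = numeric())
  class(out) <- c("break_candidates", "data.frame")
  out
}

#' Subtract the control, mask repeats and merge nearby candidates
#'
#' Removes treated candidates located inside any repeat-mask interval or
#' present (same contig and position, either strand) in the unedited
#' control's candidate list, then merges survivors within `merge_distance`
#' of one another by single linkage into clusters. Each cluster's
#' representative is the member with the highest start count (leftmost on
#' ties).
#'
#' @param treated candidates from the treated library.
#' @param unedited candidates from the matched unedited library (called
#'   with identical configuration).
#' @param repeat_mask data.frame(contig, start, end), 0-based half-open
#'   (e.g. from [read_intervals()]); may be NULL.
#' @param cfg a [discovery_config()].
#' @param control_distance if > 0, also remove treated candidates within
#'   this distance of a control candidate (distance-tolerant variant;
#'   default 0 = exact-position subtraction).
#' @return data.frame of class `candidate_clusters`: contig, position
#'   (representative), start_count (representative's), summed_start_count,
#'   n_members, member_positions (comma-separated).
#' @export
finalize_candidates <- function(treated, unedited = NULL, repeat_mask = NULL,
                                cfg = discovery_config(),
                                control_distance = 0) {
  x <- as.data.frame(treated)
  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0 && nrow(x) > 0) {
    if (any(repeat_mask$end <= repeat_mask$start)) {
      stop("malformed mask interval (end <= start)", call. = FALSE)
    }
    gr_mask <- GenomicRanges::GRanges(
      repeat_mask$contig,
      IRanges::IRanges(start = repeat_mask$start + 1L, end = repeat_mask$end))
    gr_pos <- GenomicRanges::GRanges(
      x$contig, IRanges::IRanges(start = x$position + 1L, width = 1L))
    hit <- IRanges::overlapsAny(gr_pos, gr_mask)
    x <- x[!hit, , drop = FALSE]
  }
  if (!is.null(unedited) && nrow(unedited) > 0 && nrow(x) > 0) {
    if (control_distance > 0) {
      drop <- vapply(seq_len(nrow(x)), function(i) {
        u <- unedited[unedited$contig == x$contig[i], "position"]
        length(u) > 0 && min(abs(u - x$position[i])) <= control_distance
      }, logical(1))
    } else {
      drop <- paste(x$contig, x$position) %in%
              paste(unedited$contig, unedited$position)
    }
    x <- x[!drop, , drop = FALSE]
  }
  merge_candidates(x, cfg$merge_distance)
}

# Single-linkage 1D clustering: chain candidates whose successive gaps are
# <= merge_distance within each contig.
merge_candidates <- function(x, merge_distance) {
  out <- data.frame(contig = character(), position = integer(),
                    strand = character(), start_count = integer(),
                    summed_start_count = integer(), n_members = integer(),
                    member_positions = character(),
                    stringsAsFactors = FALSE)
  if (nrow(x) > 0) {
    for (ctg in unique(x$contig)) {
      d <- x[x$contig == ctg, , drop = FALSE]
      # candidates at the same position on both strands are one site
      d <- d[order(d$position), , drop = FALSE]
      gaps <- diff(d$position)
      grp <- cumsum(c(1L, as.integer(gaps > merge_distance)))
      for (g in unique(grp)) {
        m <- d[grp == g, , drop = FALSE]
        rep_i <- which(m$start_count == max(m$start_count))
        rep_i <- rep_i[which.min(m$position[rep_i])]
        out <- rbind(out, data.frame(
          contig = ctg, position = m$position[rep_i],
          strand = m$strand[rep_i], start_count = m$start_count[rep_i],
          summed_start_count = sum(m$start_count),
          n_members = nrow(m),
          member_positions = paste(unique(m$position), collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
    out <- out[order(out$contig, out$position), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("candidate_clusters", "data.frame")
  out
}

#' Compare two finalized candidate-cluster sets
#'
#' A cluster in `a` is shared if some cluster in `b` lies within
#' `shared_distance` on the same contig; pairing is greedy by nearest
#' distance and each cluster is matched at most once. Counts are reported
#' Venn-style.
#'
#' @param a,b `candidate_clusters` from [finalize_candidates()].
#' @param shared_distance maximum pairing distance in bases (default 50).
#' @return list: `shared` (data.frame of paired positions and distance),
#'   `a_only`, `b_only`, and `counts` (shared, a_only, b_only, a_total,
#'   b_total, union).
#' @export
compare_candidate_sets <- function(a, b, shared_distance = 50) {
  pairs <- data.frame(contig = character(), a_position = integer(),
                      b_position = integer(), distance = integer())
  a_used <- rep(FALSE, nrow(a)); b_used <- rep(FALSE, nrow(b))
  if (nrow(a) > 0 && nrow(b) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
      j <- which(b$contig == a$contig[i] & !is.na(b$position))
      if (length(j) == 0L) return(NULL)
      d <- abs(b$position[j] - a$position[i])
      ok <- d <= shared_distance
      if (!any(ok)) return(NULL)
      data.frame(i = i, j = j[ok], d = d[ok])
    }))
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (a_used[i] || b_used[j]) next
        a_used[i] <- TRUE; b_used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          contig = a$contig[i], a_position = a$position[i],
          b_position = b$position[j], distance = cand$d[r]))
      }
    }
  }
  counts <- c(shared = nrow(pairs), a_only = sum(!a_used),
              b_only = sum(!b_used), a_total = nrow(a), b_total = nrow(b),
              union = nrow(pairs) + sum(!a_used) + sum(!b_used))
  list(shared = pairs, a_only = a[!a_used, , drop = FALSE],
       b_only = b[!b_used, , drop = FALSE], counts = counts)
}

#' Run break discovery end to end
#'
#' Filters treated and control alignments, piles up 5' read starts, calls
#' candidates in both libraries with the same configuration, subtracts the
#' control, masks repeats and merges nearby candidates.
#'
#' @param treated,control alignment records (data.frame,
#'   `break_library`, or SAM path).
#' @param repeat_mask data.frame(contig, start, end) or BED path or NULL.
#' @param cfg a [discovery_config()].
#' @return list of class `break_discovery`: `clusters`,
#'   `treated_candidates`, `control_candidates`, `pre_merge_count`,
#'   `post_merge_count`, `filter_tally` (treated and control).
#' @export
discover_breaks <- function(treated, control = NULL, repeat_mask = NULL,
                            cfg = discovery_config()) {
  load_records <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "break_library")) return(x$alignments)
    if (is.character(x) && length(x) == 1L) return(read_alignments(x))
    x
  }
  if (is.character(repeat_mask) && length(repeat_mask) == 1L) {
    repeat_mask <- read_intervals(repeat_mask)
  }
  tr <- filter_alignments(load_records(treated), cfg)
  tr_cand <- call_break_candidates(pileup_read_starts(tr), cfg)
  ctl_cand <- NULL; ctl_tally <- NULL
  if (!is.null(control)) {
    ct <- filter_alignments(load_records(control), cfg)
    ctl_cand <- call_break_candidates(pileup_read_starts(ct), cfg)
    ctl_tally <- ct$tally
  }
  clusters <- finalize_candidates(tr_cand, ctl_cand, repeat_mask, cfg)
  structure(list(clusters = clusters, treated_candidates = tr_cand,
                 control_candidates = ctl_cand,
                 pre_merge_count = nrow(tr_cand),
                 post_merge_count = nrow(clusters),
                 filter_tally = list(treated = tr$tally,
                                     control = ctl_tally),
                 config = cfg),
            class = "break_discovery")
}

#' @export
print.break_discovery <- function(x, ...) {
  cat(sprintf("break_discovery: %d candidate position(s), %d cluster(s) after control subtraction/masking/merging\n",
              x$pre_merge_count, x$post_merge_count))
  invisible(x)
}
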