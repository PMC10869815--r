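#' Multiplexed amplicon panel definition
#'
#' @param name amplicon names.
#' @param sequence expected reference sequence per amplicon (>= 23 nt); the
#'   first 23 nt form the demultiplexing prefix and must be pairwise
#'   distinct.
#' @return data.frame of class `panel_def` with a `prefix` column.
#' @export
panel_def <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) < 23)) {
    stop("panel sequences must be at least 23 nt", call. = FALSE)
  }
  prefix <- substr(sequence, 1, 23)
  if (anyDuplicated(prefix)) {
    stop("23-nt panel prefixes must be pairwise distinct", call. = FALSE)
  }
  out <- data.frame(name = as.character(name), sequence = sequence,
                    prefix = prefix, stringsAsFactors = FALSE)
  class(out) <- c("panel_def", "data.frame")
  out
}

#' Retention and masking configuration for panel quantification
#'
#' Defaults follow the published analysis: an amplicon is retained if
#' present in >= 2 of 4 replicates with >= 1000 reads each and, in the
#' unedited sample, at least 15% of its reads resemble the expected
#' reference; positions with unedited allele frequencies strictly inside
#' (0.04, 0.96) are masked; loci count as edited above 1%.
#'
#' @param min_replicates,n_replicates replicate retention rule.
#' @param min_reads minimum assigned reads per qualifying replicate.
#' @param min_reference_fraction minimum fraction of unedited reads
#'   resembling the expected reference.
#' @param similarity_floor alignment identity at or above which a read
#'   "resembles" the expected reference (default 0.85).
#' @param af_low,af_high open masking interval for unedited non-reference
#'   allele frequencies.
#' @param edited_threshold strict threshold for counting edited loci.
#' @return list of class `retention_config`.
#' @export
retention_config <- function(min_replicates = 2L, n_replicates = 4L,
                             min_reads = 1000L,
                             min_reference_fraction = 0.15,
                             similarity_floor = 0.85,
                             af_low = 0.04, af_high = 0.96,
                             edited_threshold = 0.01) {
  if (min_replicates < 1 || min_replicates > n_replicates) {
    stop("need 0 < min_replicates <= n_replicates", call. = FALSE)
  }
  if (!(af_low >= 0 && af_low < af_high && af_high <= 1)) {
    stop("need 0 <= af_low < af_high <= 1", call. = FALSE)
  }
  structure(list(min_replicates = as.integer(min_replicates),
                 n_replicates = as.integer(n_replicates),
                 min_reads = as.integer(min_reads),
                 min_reference_fraction = min_reference_fraction,
                 similarity_floor = similarity_floor,
                 af_low = af_low, af_high = af_high,
                 edited_threshold = edited_threshold),
            class = "retention_config")
}

#' Demultiplex panel reads by their first 23 nucleotides
#'
#' Assigns each read to the amplicon whose 23-nt prefix matches the read's
#' first 23 nt within `max_mismatches`. With mismatches allowed, a read
#' matching more than one prefix equally well is left unassigned. Reads
#' shorter than 23 nt are counted separately. Assignment is a partition:
#' assigned + unassigned + too-short = total.
#'
#' @param reads character vector of read sequences.
#' @param panel a [panel_def()].
#' @param max_mismatches allowed prefix mismatches (default 0).
#' @return list: `bins` (named list of read vectors), `unassigned` count,
#'   `too_short` count, `n_total`.
#' @export
demultiplex_by_prefix <- function(reads, panel, max_mismatches = 0L) {
  stopifnot(inherits(panel, "panel_def"))
  n <- length(reads)
  too_short <- nchar(reads) < 23L
  pre <- substr(reads, 1, 23)
  assign <- rep(NA_integer_, n)
  if (max_mismatches == 0L) {
    assign[!too_short] <- match(pre[!too_short], panel$prefix)
  } else {
    pm <- do.call(cbind, lapply(panel$prefix, function(p) {
      prefix_mismatches(pre, p)
    }))
    for (i in which(!too_short)) {
      d <- pm[i, ]
      best <- min(d)
      if (best <= max_mismatches && sum(d == best) == 1L) {
        assign[i] <- which.min(d)
      }
    }
  }
  bins <- lapply(seq_len(nrow(panel)), function(a) reads[which(assign == a)])
  names(bins) <- panel$name
  list(bins = bins,
       unassigned = sum(is.na(assign) & !too_short),
       too_short = sum(too_short),
       n_total = n)
}

prefix_mismatches <- function(x, p) {
  pc <- strsplit(p, "")[[1]]
  xm <- matrix(unlist(strsplit(substr(x, 1, 23), "")), nrow = 23L)
  colSums(xm != pc)
}

#' Fraction of reads resembling the expected reference
#'
#' A read "resembles" the reference if its pairwise-alignment identity is
#' at or above the similarity floor. Unique reads are aligned once.
#'
#' @param reads character vector.
#' @param expected expected reference sequence.
#' @param similarity_floor identity threshold (default 0.85).
#' @return fraction in [0, 1] (NA for an empty bin).
#' @export
reference_similarity_fraction <- function(reads, expected,
                                          similarity_floor = 0.85) {
  if (length(reads) == 0L) return(NA_real_)
  uniq <- unique(reads)
  w <- tabulate(match(reads, uniq), nbins = length(uniq))
  alns <- align_amplicon_reads(uniq, expected, min_identity = 0)
  ident <- vapply(alns$alignments, function(a) a$identity, numeric(1))
  sum(w[ident >= similarity_floor]) / length(reads)
}

#' Apply replicate and reference-similarity retention filters
#'
#' An amplicon is retained iff (a) at least `min_replicates` replicates
#' carry at least `min_reads` assigned reads, and (b) the fraction of
#' unedited-sample reads resembling the expected reference is at least
#' `min_reference_fraction`. Every exclusion carries its reason.
#'
#' @param replicate_counts matrix or data.frame of assigned read counts,
#'   one row per amplicon (rownames = amplicon names), one column per
#'   replicate, for the sample being filtered.
#' @param unedited_bins named list (per amplicon) of unedited-sample read
#'   vectors (pooled over replicates), used for the similarity rule; NULL
#'   skips rule (b).
#' @param panel a [panel_def()].
#' @param cfg a [retention_config()].
#' @return data.frame audit: amplicon, replicates_passing, similarity
#'   fraction, retained, reason.
#' @export
apply_amplicon_filters <- function(replicate_counts, unedited_bins = NULL,
                                   panel, cfg = retention_config()) {
  stopifnot(inherits(panel, "panel_def"))
  amps <- rownames(replicate_counts)
  if (is.null(amps)) stop("replicate_counts needs amplicon rownames",
                          call. = FALSE)
  if (!all(amps %in% panel$name)) {
    stop("amplicon absent from panel: ",
         paste(setdiff(amps, panel$name), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(amplicon = amps,
                    replicates_passing = NA_integer_,
                    reference_fraction = NA_real_,
                    retained = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(amps)) {
    rc <- as.numeric(replicate_counts[i, ])
    np <- sum(rc >= cfg$min_reads)
    out$replicates_passing[i] <- np
    if (np < cfg$min_replicates) {
      out$reason[i] <- sprintf("replicates: %d of %d with >= %d reads",
                               np, length(rc), cfg$min_reads)
      next
    }
    if (!is.null(unedited_bins)) {
      frac <- reference_similarity_fraction(
        unedited_bins[[amps[i]]],
        panel$sequence[panel$name == amps[i]],
        cfg$similarity_floor)
      out$reference_fraction[i] <- frac
      if (is.na(frac) || frac < cfg$min_reference_fraction) {
        out$reason[i] <- sprintf(
          "reference similarity: %.3f < %.2f in unedited sample",
          ifelse(is.na(frac), 0, frac), cfg$min_reference_fraction)
        next
      }
    }
    out$retained[i] <- TRUE
  }
  out
}

#' Per-position allele frequencies for one amplicon bin
#'
#' Aligns a bin's reads to the expected reference (same aligner contract as
#' the amplicon quantification stage) and returns per-position A/C/G/T and
#' deletion frequencies over informative reads.
#'
#' @param reads character vector of reads assigned to the amplicon.
#' @param expected expected reference sequence.
#' @return a `position_profile` (zero counts for an empty bin).
#' @export
position_allele_frequencies <- function(reads, expected) {
  expected <- toupper(as.character(expected))
  if (length(reads) == 0L) {
    L <- nchar(expected)
    return(structure(list(counts = matrix(0, 5, L,
                            dimnames = list(c("A", "C", "G", "T", "del"),
                                            NULL)),
                          ins = numeric(L), total = numeric(L),
                          ref_chars = strsplit(expected, "")[[1]]),
                     class = "position_profile"))
  }
  tabulate_positions(align_amplicon_reads(reads, expected), expected)
}

#' Mask germline-like background positions
#'
#' A position is masked iff any non-reference allele frequency in the
#' unedited sample lies strictly inside (`af_low`, `af_high`): intermediate
#' frequencies indicate germline variation or systematic artefacts, not
#' editing.
#'
#' @param unedited_af a `position_profile` from the unedited sample.
#' @param cfg a [retention_config()].
#' @return integer vector of masked positions (0-based).
#' @export
mask_background <- function(unedited_af, cfg = retention_config()) {
  freq <- position_frequencies(unedited_af)
  L <- ncol(freq)
  masked <- integer(0)
  for (pos in seq_len(L)) {
    refb <- unedited_af$ref_chars[pos]
    alt <- setdiff(rownames(freq), refb)
    f <- freq[alt, pos]
    if (any(f > cfg$af_low & f < cfg$af_high)) {
      masked <- c(masked, pos - 1L)
    }
  }
  masked
}

#' Maximum A/T frequency-change statistic for one amplicon
#'
#' Over unmasked positions, computes the treated-minus-unedited frequency
#' increase of A and of T and returns the maximum, floored at zero (the
#' statistic indicates cytosine base editing on either strand: C-to-T on
#' the top strand raises T, on the bottom strand raises A). Deletion
#' alleles never contribute.
#'
#' @param treated_af,unedited_af `position_profile`s on the same expected
#'   reference.
#' @param masked 0-based masked positions from [mask_background()].
#' @param amplicon amplicon name carried into the result.
#' @return list of class `offtarget_stat`: `amplicon`, `max_at_change`
#'   (NA if no position is evaluable), `argmax_position` (0-based),
#'   `argmax_base`, `masked`, `evaluable`.
#' @export
max_at_change <- function(treated_af, unedited_af, masked = integer(0),
                          amplicon = NA_character_) {
  ft <- position_frequencies(treated_af)
  fu <- position_frequencies(unedited_af)
  stopifnot(ncol(ft) == ncol(fu))
  L <- ncol(ft)
  open <- setdiff(seq_len(L) - 1L, masked)
  open <- open[treated_af$total[open + 1L] > 0 &
               unedited_af$total[open + 1L] > 0]
  if (length(open) == 0L) {
    return(structure(list(amplicon = amplicon, max_at_change = NA_real_,
                          argmax_position = NA_integer_,
                          argmax_base = NA_character_, masked = masked,
                          evaluable = FALSE),
                     class = "offtarget_stat"))
  }
  dA <- ft["A", open + 1L] - fu["A", open + 1L]
  dT <- ft["T", open + 1L] - fu["T", open + 1L]
  deltas <- rbind(A = dA, T = dT)
  best <- which(deltas == max(deltas), arr.ind = TRUE)[1, ]
  structure(list(amplicon = amplicon,
                 max_at_change = max(0, max(deltas)),
                 argmax_position = open[best["col"]],
                 argmax_base = rownames(deltas)[best["row"]],
                 masked = masked, evaluable = TRUE),
            class = "offtarget_stat")
}

#' Count edited loci above a strict threshold
#'
#' @param stats list of `offtarget_stat` (or numeric statistics).
#' @param threshold strict lower bound (default 0.01: "above 1%").
#' @return number of loci with statistic strictly greater than `threshold`.
#' @export
count_edited_loci <- function(stats, threshold = 0.01) {
  vals <- vapply(stats, function(s) {
    if (inherits(s, "offtarget_stat")) s$max_at_change else as.numeric(s)
  }, numeric(1))
  sum(vals > threshold, na.rm = TRUE)
}

#' Quantify off-target editing across a panel end to end
#'
#' Demultiplexes every replicate of both conditions, applies retention
#' filters, computes unedited allele frequencies and the background mask
#' per amplicon, then the max A/T-change statistic per replicate and its
#' replicate mean.
#'
#' @param treated,unedited lists of replicates, each a character vector of
#'   reads (a [simulate_rhamp_run()] result supplies both).
#' @param panel a [panel_def()].
#' @param cfg a [retention_config()].
#' @param max_mismatches demultiplexing mismatches allowed.
#' @return list of class `rhamp_result`: `stats` (per-amplicon data.frame
#'   with mean and per-replicate statistics), `audit` (retention audit),
#'   `edited_loci`, `demux` (per-replicate assignment summaries).
#' @export
rhamp_quantify <- function(treated, unedited, panel,
                           cfg = retention_config(), max_mismatches = 0L) {
  if (inherits(treated, "panel_sim")) {
    sim <- treated
    treated <- sim$treated
    unedited <- sim$unedited
  }
  demux_cond <- function(reps) {
    lapply(reps, demultiplex_by_prefix, panel = panel,
           max_mismatches = max_mismatches)
  }
  dt <- demux_cond(treated)
  du <- demux_cond(unedited)
  counts <- function(dx) {
    m <- vapply(dx, function(d) lengths(d$bins), integer(nrow(panel)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(panel))
    rownames(m) <- panel$name
    m
  }
  ct <- counts(dt)
  pooled_unedited <- lapply(panel$name, function(a) {
    unlist(lapply(du, function(d) d$bins[[a]]), use.names = FALSE)
  })
  names(pooled_unedited) <- panel$name
  audit <- apply_amplicon_filters(ct, pooled_unedited, panel, cfg)

  stats <- data.frame(amplicon = panel$name, retained = audit$retained,
                      mean_stat = NA_real_, argmax_position = NA_integer_,
                      argmax_base = NA_character_,
                      n_masked = NA_integer_, stringsAsFactors = FALSE)
  rep_stats <- matrix(NA_real_, nrow(panel), length(dt),
                      dimnames = list(panel$name, names(dt)))
  per_amp <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    if (!audit$retained[i]) next
    a <- panel$name[i]
    expected <- panel$sequence[i]
    afu <- position_allele_frequencies(pooled_unedited[[a]], expected)
    masked <- mask_background(afu, cfg)
    stats$n_masked[i] <- length(masked)
    reps <- lapply(seq_along(dt), function(r) {
      aft <- position_allele_frequencies(dt[[r]]$bins[[a]], expected)
      max_at_change(aft, afu, masked, amplicon = a)
    })
    per_amp[[i]] <- reps
    vals <- vapply(reps, function(s) s$max_at_change, numeric(1))
    rep_stats[i, ] <- vals
    stats$mean_stat[i] <- mean(vals, na.rm = TRUE)
    ev <- which(!vapply(reps, function(s) is.na(s$max_at_change),
                        logical(1)))
    if (length(ev)) {
      top <- ev[which.max(vals[ev])]
      stats$argmax_position[i] <- reps[[top]]$argmax_position
      stats$argmax_base[i] <- reps[[top]]$argmax_base
    }
  }
  structure(list(stats = stats, replicate_stats = rep_stats,
                 audit = audit,
                 edited_loci = count_edited_loci(
                   as.list(stats$mean_stat[stats$retained]),
                   cfg$edited_threshold),
                 demux = list(treated = dt, unedited = du),
                 per_amplicon = per_amp, config = cfg),
            class = "rhamp_result")
}

#' @export
print.rhamp_result <- function(x, ...) {
  cat(sprintf("rhamp_result: %d/%d amplicons retained; %d edited locus/loci above %.0f%%\n",
              sum(x$audit$retained), nrow(x$audit), x$edited_loci,
              100 * x$config$edited_threshold))
  invisible(x)
}
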