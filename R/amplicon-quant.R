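#' Tabulate per-position base calls across aligned amplicon reads
#'
#' Builds the per-position substrate for editing quantification: counts of
#' A/C/G/T and deletion at every reference position, insertion counts
#' anchored after each position, and the number of informative reads per
#' position. A read contributes a base call at a position only if its
#' alignment covers the position without an indel there; a deletion
#' spanning the position is tallied in the deletion channel instead.
#'
#' @param alns an [align_amplicon_reads()] result.
#' @param ref optional `amplicon_reference` (defaults to the one stored in
#'   `alns`).
#' @return object of class `position_profile`: `counts` (5 x L matrix, rows
#'   A/C/G/T/del), `ins` (insertion counts anchored after each position),
#'   `total` (informative reads per position), and `ref_chars`.
#' @export
tabulate_positions <- function(alns, ref = NULL) {
  stopifnot(inherits(alns, "amplicon_alignments"))
  if (is.null(ref)) ref <- alns$ref
  refseq <- if (inherits(ref, "amplicon_reference")) ref$sequence
            else as.character(ref)
  L <- nchar(refseq)
  counts <- matrix(0, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "del"), NULL))
  ins <- numeric(L)
  for (i in seq_along(alns$alignments)) {
    a <- alns$alignments[[i]]
    w <- alns$counts[i]
    ok <- a$ref_pos >= 0 & a$ref_pos < L
    bidx <- match(a$read_base[ok], BASES)
    pos1 <- a$ref_pos[ok] + 1L
    known <- !is.na(bidx)
    if (any(known)) {
      flat <- cbind(bidx[known], pos1[known])
      for (r in seq_len(nrow(flat))) {
        counts[flat[r, 1], flat[r, 2]] <- counts[flat[r, 1], flat[r, 2]] + w
      }
    }
    if (nrow(a$del) > 0) {
      for (k in seq_len(nrow(a$del))) {
        span <- a$del$start[k]:(a$del$start[k] + a$del$len[k] - 1L)
        span <- span[span >= 0 & span < L] + 1L
        counts["del", span] <- counts["del", span] + w
      }
    }
    if (nrow(a$ins) > 0) {
      anch <- a$ins$after
      anch <- anch[anch >= 0 & anch < L] + 1L
      ins[anch] <- ins[anch] + w
    }
  }
  structure(list(counts = counts, ins = ins,
                 total = colSums(counts),
                 ref_chars = strsplit(refseq, "")[[1]]),
            class = "position_profile")
}

#' Per-position frequencies from a position profile
#' @param profile a `position_profile`.
#' @return 5 x L matrix of frequencies (0 where no informative reads).
#' @export
position_frequencies <- function(profile) {
  tot <- pmax(profile$total, 1)
  sweep(profile$counts, 2, tot, "/") * rep(as.numeric(profile$total > 0),
                                           each = 5)
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("position_profile over %d positions; median informative reads %d\n",
              length(x$total), as.integer(stats::median(x$total))))
  invisible(x)
}

#' Fraction of reads whose target codon was converted to a stop
#'
#' Among reads that span the annotated target codon without an indel inside
#' it, computes the fraction whose codon — read on the annotated strand —
#' is one of the three stop codons TGA, TAG, TAA, with a per-variant
#' breakdown. Reads with an indel inside the codon are excluded from the
#' denominator and reported separately.
#'
#' @param alns an [align_amplicon_reads()] result.
#' @param ref optional `amplicon_reference` with `target_codon_start` set.
#' @return list: `stop_fraction`, `by_codon` (named counts for TGA/TAG/TAA),
#'   `n_spanning` (denominator), `n_indel_in_codon`, `n_total`.
#' @export
call_stop_codon_fraction <- function(alns, ref = NULL) {
  stopifnot(inherits(alns, "amplicon_alignments"))
  if (is.null(ref)) ref <- alns$ref
  if (!inherits(ref, "amplicon_reference") ||
      is.null(ref$target_codon_start)) {
    stop("no target codon annotated on this amplicon", call. = FALSE)
  }
  cs <- ref$target_codon_start
  stops <- c(TGA = 0, TAG = 0, TAA = 0)
  n_span <- 0; n_indel <- 0; n_stop <- 0
  for (i in seq_along(alns$alignments)) {
    a <- alns$alignments[[i]]
    w <- alns$counts[i]
    hit <- match(cs:(cs + 2L), a$ref_pos)
    covered <- a$span[1] <= cs && a$span[2] >= cs + 3L
    if (!covered) next
    has_del <- nrow(a$del) > 0 &&
      any(a$del$start < cs + 3L & a$del$start + a$del$len > cs)
    has_ins <- nrow(a$ins) > 0 && any(a$ins$after %in% c(cs, cs + 1L))
    if (has_del || has_ins || anyNA(hit)) {
      n_indel <- n_indel + w
      next
    }
    codon <- paste(a$read_base[hit], collapse = "")
    if (ref$codon_strand == "antisense") codon <- revcomp(codon)
    n_span <- n_span + w
    if (codon %in% names(stops)) {
      stops[codon] <- stops[codon] + w
      n_stop <- n_stop + w
    }
  }
  list(stop_fraction = if (n_span > 0) n_stop / n_span else NA_real_,
       by_codon = stops, n_spanning = n_span,
       n_indel_in_codon = n_indel, n_total = alns$n_total)
}

#' Indel statistics relative to the editing window
#'
#' @param alns an [align_amplicon_reads()] result.
#' @param window integer `c(start, end)` 0-based half-open; defaults to the
#'   reference's derived editing window.
#' @param scope "window" (an indel counts if it overlaps the window) or
#'   "amplicon" (anywhere in the aligned span).
#' @return list: `indel_fraction`, `n_indel_reads`, `n_reads`.
#' @export
amplicon_indel_stats <- function(alns, window = NULL, scope = "window") {
  stopifnot(inherits(alns, "amplicon_alignments"))
  if (is.null(window)) {
    if (!inherits(alns$ref, "amplicon_reference")) {
      stop("window required when the reference carries no arm annotation",
           call. = FALSE)
    }
    window <- alns$ref$window
  }
  n_indel <- 0; n_reads <- 0
  for (i in seq_along(alns$alignments)) {
    a <- alns$alignments[[i]]
    w <- alns$counts[i]
    n_reads <- n_reads + w
    has <- FALSE
    if (scope == "amplicon") {
      has <- nrow(a$del) > 0 || nrow(a$ins) > 0
    } else {
      if (nrow(a$del) > 0) {
        has <- any(a$del$start < window[2] & a$del$start + a$del$len > window[1])
      }
      if (!has && nrow(a$ins) > 0) {
        # an insertion after position p interrupts the window if it falls
        # strictly inside [start, end): p in [start, end-1)
        has <- any(a$ins$after >= window[1] & a$ins$after < window[2] - 1L)
      }
    }
    if (has) n_indel <- n_indel + w
  }
  list(indel_fraction = if (n_reads > 0) n_indel / n_reads else NA_real_,
       n_indel_reads = n_indel, n_reads = n_reads)
}

#' Assemble an editing report with flagging thresholds
#'
#' Applies the reporting rules used for amplicon base-editing tables:
#' substitutions at positions outside the editing window are flagged at or
#' above `outside_threshold` (default 3%), and non-reference bases other
#' than the intended deamination product (T at a reference C, A at a
#' reference G) are flagged at or above `unintended_threshold` (default
#' 2%). The unintended-base rule is evaluated both inside the window and
#' over the whole amplicon, flagged separately. Window positions are
#' labelled `<refbase><k>` by 1-based offset `k` from the window start on
#' the top strand (C10, C11 style).
#'
#' @param profile a [tabulate_positions()] result.
#' @param ref the `amplicon_reference`.
#' @param stop result of [call_stop_codon_fraction()] (optional).
#' @param indel_stats result of [amplicon_indel_stats()] (optional).
#' @param outside_threshold flag level for outside-window substitutions.
#' @param unintended_threshold flag level for unintended product bases.
#' @return object of class `editing_report`.
#' @export
build_editing_report <- function(profile, ref, stop = NULL,
                                 indel_stats = NULL,
                                 outside_threshold = 0.03,
                                 unintended_threshold = 0.02) {
  stopifnot(inherits(profile, "position_profile"))
  window <- if (inherits(ref, "amplicon_reference")) ref$window
            else c(0L, length(profile$total))
  freq <- position_frequencies(profile)
  L <- ncol(freq)
  rc <- profile$ref_chars
  in_window <- seq_len(L) > window[1] & seq_len(L) <= window[2]

  intended <- function(pos) {
    if (rc[pos] == "C") "T" else if (rc[pos] == "G") "A" else NA_character_
  }
  flags_outside <- list(); flags_unint_window <- list()
  flags_unint_all <- list()
  for (pos in seq_len(L)) {
    if (profile$total[pos] == 0) next
    for (b in BASES) {
      if (b == rc[pos]) next
      f <- freq[b, pos]
      if (!in_window[pos] && f >= outside_threshold) {
        flags_outside[[length(flags_outside) + 1L]] <-
          data.frame(position = pos - 1L, base = b, frequency = f,
                     threshold = outside_threshold)
      }
      unint <- is.na(intended(pos)) || b != intended(pos)
      if (unint && f >= unintended_threshold) {
        rec <- data.frame(position = pos - 1L, base = b, frequency = f,
                          threshold = unintended_threshold)
        flags_unint_all[[length(flags_unint_all) + 1L]] <- rec
        if (in_window[pos]) {
          flags_unint_window[[length(flags_unint_window) + 1L]] <- rec
        }
      }
    }
  }
  bindf <- function(lst) if (length(lst)) do.call(rbind, lst) else
    data.frame(position = integer(), base = character(),
               frequency = numeric(), threshold = numeric())

  labels <- rep(NA_character_, L)
  wpos <- which(in_window)
  labels[wpos] <- sprintf("%s%d", rc[wpos], seq_along(wpos))

  structure(list(
    stop_fraction = if (is.null(stop)) NA_real_ else stop$stop_fraction,
    stop_by_codon = if (is.null(stop)) NULL else stop$by_codon,
    indel_fraction = if (is.null(indel_stats)) NA_real_
                     else indel_stats$indel_fraction,
    frequencies = freq,
    window = window,
    window_labels = labels,
    flagged_outside_window = bindf(flags_outside),
    flagged_unintended_bases = bindf(flags_unint_window),
    flagged_unintended_anywhere = bindf(flags_unint_all),
    thresholds = c(outside = outside_threshold,
                   unintended = unintended_threshold)),
    class = "editing_report")
}

#' @export
print.editing_report <- function(x, ...) {
  cat("editing_report\n")
  cat(sprintf("  stop fraction: %s\n",
              ifelse(is.na(x$stop_fraction), "n/a",
                     sprintf("%.4f", x$stop_fraction))))
  cat(sprintf("  indel fraction (window): %s\n",
              ifelse(is.na(x$indel_fraction), "n/a",
                     sprintf("%.4f", x$indel_fraction))))
  cat(sprintf("  flagged outside window (>= %.0f%%): %d\n",
              100 * x$thresholds["outside"], nrow(x$flagged_outside_window)))
  cat(sprintf("  flagged unintended bases in window (>= %.0f%%): %d\n",
              100 * x$thresholds["unintended"],
              nrow(x$flagged_unintended_bases)))
  invisible(x)
}

#' Quantify base editing for one amplicon end to end
#'
#' Convenience driver: aligns reads, tabulates positions, calls the stop
#' fraction (if a codon is annotated), computes window indel statistics and
#' assembles the editing report.
#'
#' @param reads character vector of reads, an `amplicon_sim`, or a FASTQ
#'   path.
#' @param ref an [amplicon_reference()].
#' @param ... passed to [align_amplicon_reads()] and
#'   [build_editing_report()].
#' @return an `editing_report`; the alignments, profile and stop call are
#'   attached as attributes `alignments`, `profile`, `stop`.
#' @export
quantify_amplicon <- function(reads, ref, ...) {
  dots <- list(...)
  aln_args <- dots[names(dots) %in% c("quals", "min_identity",
                                      "gap_opening", "gap_extension")]
  rep_args <- dots[names(dots) %in% c("outside_threshold",
                                      "unintended_threshold")]
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- read_fastq(reads)
    reads <- fq$seq
    if (is.null(aln_args$quals)) aln_args$quals <- fq$qual
  }
  alns <- do.call(align_amplicon_reads, c(list(reads = reads, ref = ref),
                                          aln_args))
  profile <- tabulate_positions(alns)
  stop_call <- if (!is.null(ref$target_codon_start)) {
    call_stop_codon_fraction(alns, ref)
  } else NULL
  indels <- amplicon_indel_stats(alns)
  rep <- do.call(build_editing_report,
                 c(list(profile = profile, ref = ref, stop = stop_call,
                        indel_stats = indels), rep_args))
  attr(rep, "alignments") <- alns
  attr(rep, "profile") <- profile
  attr(rep, "stop") <- stop_call
  rep
}
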