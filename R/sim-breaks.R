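#' Break-site truth table
#'
#' Declares single-strand break sites to implant in a simulated
#' whole-genome-sequencing library. At each site, a stated fraction of
#' fragments overlapping the position has its 5' end forced exactly onto the
#' site on the stated strand, mimicking the common breakpoints that
#' USER-excised uracils leave at base-edited positions.
#'
#' @param contig contig name (recycled).
#' @param position 0-based reference coordinate of each break.
#' @param strand "+" or "-" per site.
#' @param edit_fraction fraction in [0, 1] of overlapping fragments redirected
#'   to start at the site.
#' @return a data.frame of class `break_truth`.
#' @export
break_truth <- function(contig, position, strand, edit_fraction) {
  if (length(position) == 0L) {
    out <- data.frame(contig = character(), position = integer(),
                      strand = character(), edit_fraction = numeric())
    class(out) <- c("break_truth", "data.frame")
    return(out)
  }
  if (any(!strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(edit_fraction < 0 | edit_fraction > 1)) {
    stop("edit_fraction must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(contig = as.character(contig),
                    position = as.integer(position),
                    strand = as.character(strand),
                    edit_fraction = as.numeric(edit_fraction),
                    stringsAsFactors = FALSE)
  class(out) <- c("break_truth", "data.frame")
  out
}

#' Simulate a USER-nicked whole-genome sequencing library
#'
#' Generates single-end aligned reads over a reference: background fragments
#' with uniformly distributed 5' starts (random shearing), plus implanted
#' break sites where a stated fraction of overlapping fragments has its 5'
#' end placed exactly at the site on the stated strand. Every record carries
#' a mapping quality, a 5' soft-clip length, per-base qualities and a
#' duplicate flag, so the discovery-stage filters are exercisable. The
#' matched unedited control is the same call with an empty truth table and a
#' different seed.
#'
#' Fragment lengths are drawn from a normal around `frag_mean`
#' (sd = `frag_mean`/5), truncated at `read_length`; any unimodal model
#' suffices since only 5'-start positions matter downstream. Break-site reads
#' are generated on the truth strand only; background reads fall on both
#' strands with equal probability.
#'
#' @param genome a `reference_sequence` (single contig).
#' @param truth a `break_truth` table (possibly empty).
#' @param mean_depth target fold coverage (> 0).
#' @param read_length read length in bases.
#' @param frag_mean mean fragment length.
#' @param error_rate per-base miscall probability in read sequences.
#' @param clip5_inject named integer vector: read index -> 5' soft-clip
#'   length to inject (default none).
#' @param mapq_profile list(values=, probs=) to draw mapping qualities from;
#'   default point mass at 60.
#' @param mapq_inject named integer vector: read index -> mapping quality.
#' @param qual_inject named integer vector: read index -> constant per-base
#'   Phred quality for that read (e.g. 10 to fail the mean-quality filter).
#' @param base_quality constant per-base Phred quality otherwise.
#' @param dup_fraction fraction of records flagged as duplicates.
#' @param seed integer seed.
#' @return a list of class `break_library`: `alignments` (alignment-record
#'   data.frame as returned by [read_alignments()]), `truth` (the truth
#'   table), and `genome`.
#' @seealso [discover_breaks()], [write_sam()]
#' @export
simulate_break_library <- function(genome, truth = break_truth(character(0),
                                   integer(0), character(0), numeric(0)),
                                   mean_depth = 30, read_length = 150,
                                   frag_mean = 300, error_rate = 0,
                                   clip5_inject = NULL,
                                   mapq_profile = list(values = 60, probs = 1),
                                   mapq_inject = NULL,
                                   qual_inject = NULL,
                                   base_quality = 30L,
                                   dup_fraction = 0, seed) {
  gseq <- genome_sequence(genome)
  glen <- nchar(gseq)
  contig <- genome_name(genome)
  stopifnot_scalar_number(mean_depth, "mean_depth", lo = 1e-9)
  stopifnot_scalar_number(error_rate, "error_rate", 0, 1)
  stopifnot_scalar_number(dup_fraction, "dup_fraction", 0, 1)
  if (nrow(truth) > 0 && any(truth$position < 0 | truth$position >= glen)) {
    stop("truth site outside contig bounds", call. = FALSE)
  }

  n_reads <- max(1L, round(glen * mean_depth / read_length))
  rec <- with_seed(seed, {
    frag_len <- pmax(read_length,
                     round(rnorm(n_reads, frag_mean, frag_mean / 5)))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    fstart <- floor(runif(n_reads, 0, pmax(1, glen - frag_len + 1)))
    fend <- pmin(glen, fstart + frag_len)  # 0-based half-open

    # redirect fragments overlapping a truth site
    if (nrow(truth) > 0) {
      for (k in seq_len(nrow(truth))) {
        p <- truth$position[k]
        hit <- which(fstart <= p & fend > p)
        if (length(hit) == 0L) next
        take <- hit[runif(length(hit)) < truth$edit_fraction[k]]
        if (length(take) == 0L) next
        strand[take] <- truth$strand[k]
        if (truth$strand[k] == "+") {
          fstart[take] <- p
          fend[take] <- pmin(glen, p + frag_len[take])
        } else {
          fend[take] <- p + 1L
          fstart[take] <- pmax(0L, p + 1L - frag_len[take])
        }
      }
    }

    # the sequenced read covers the fragment's 5' end
    aln_start <- ifelse(strand == "+", fstart,
                        pmax(0L, fend - read_length))
    aln_end <- ifelse(strand == "+", pmin(glen, fstart + read_length), fend)
    m_len <- as.integer(aln_end - aln_start)

    mapq <- sample(rep(as.integer(mapq_profile$values),
                       length.out = max(2L, length(mapq_profile$values))),
                   n_reads, replace = TRUE,
                   prob = rep(mapq_profile$probs,
                              length.out = max(2L, length(mapq_profile$probs))))
    if (!is.null(mapq_inject)) {
      idx <- as.integer(names(mapq_inject))
      mapq[idx] <- as.integer(mapq_inject)
    }
    clip5 <- integer(n_reads)
    if (!is.null(clip5_inject)) {
      idx <- as.integer(names(clip5_inject))
      clip5[idx] <- as.integer(clip5_inject)
    }
    dup <- runif(n_reads) < dup_fraction

    seqs <- substring(gseq, aln_start + 1L, aln_end)
    if (error_rate > 0) {
      seqs <- inject_errors(seqs, error_rate)
    }
    # injected clip bases hang off the 5' end of the read, outside the
    # aligned span (alignment coordinates unchanged)
    if (any(clip5 > 0)) {
      for (i in which(clip5 > 0)) {
        pad <- paste(sample(BASES, clip5[i], replace = TRUE), collapse = "")
        seqs[i] <- if (strand[i] == "+") paste0(pad, seqs[i])
                   else paste0(seqs[i], pad)
      }
    }
    qual_phred <- rep(as.integer(base_quality), n_reads)
    if (!is.null(qual_inject)) {
      idx <- as.integer(names(qual_inject))
      qual_phred[idx] <- as.integer(qual_inject)
    }
    # qualities are constant per read: build one string per (phred, length)
    qlen <- nchar(seqs)
    key <- paste(qual_phred, qlen)
    uk <- !duplicated(key)
    qmap <- setNames(vapply(which(uk), function(i) {
      phred_to_qual(rep(qual_phred[i], qlen[i]))
    }, character(1)), key[uk])
    quals <- unname(qmap[key])

    cigar <- ifelse(clip5 > 0,
                    ifelse(strand == "+",
                           paste0(clip5, "S", m_len, "M"),
                           paste0(m_len, "M", clip5, "S")),
                    paste0(m_len, "M"))
    flag <- ifelse(strand == "-", 16L, 0L) + ifelse(dup, 1024L, 0L)

    data.frame(
      qname = sprintf("sim%06d", seq_len(n_reads)),
      flag = flag,
      contig = contig,
      pos = as.integer(aln_start),
      mapq = as.integer(mapq),
      cigar = cigar,
      seq = seqs,
      qual = quals,
      stringsAsFactors = FALSE
    )
  })

  aln <- annotate_alignments(rec)
  structure(list(alignments = aln, truth = truth, genome = genome),
            class = "break_library")
}

inject_errors <- function(seqs, error_rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < error_rate)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (j in hit) ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.break_library <- function(x, ...) {
  cat(sprintf("break_library: %d records on '%s', %d implanted site(s)\n",
              nrow(x$alignments), genome_name(x$genome), nrow(x$truth)))
  invisible(x)
}
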