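#' Align amplicon reads to their reference
#'
#' Pairwise-aligns each read to the amplicon reference with affine gap
#' penalties: global in the reference, semi-global in the read (read
#' overhangs such as residual adapter are not penalized). Each read is
#' tried as given and reverse-complemented and the better-scoring
#' orientation kept. Alignments whose identity (matches / alignment
#' columns) falls below `min_identity` are discarded and counted.
#' Identical reads are aligned once and carried with a weight, so deeply
#' sequenced amplicons stay fast.
#'
#' @param reads character vector of read sequences (or an `amplicon_sim`).
#' @param ref an [amplicon_reference()] or plain DNA string.
#' @param quals optional Phred+33 quality strings parallel to `reads`.
#' @param min_identity identity floor below which alignments are discarded
#'   (default 0.6).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return object of class `amplicon_alignments`: a list with `alignments`
#'   (one record per unique read: 0-based `ref_pos`/`read_base` call pairs,
#'   `del` and `ins` gap tables, covered span, mean base quality,
#'   orientation), parallel `counts`, the reference, `n_total` and
#'   `n_discarded`.
#' @export
align_amplicon_reads <- function(reads, ref, quals = NULL,
                                 min_identity = 0.6,
                                 gap_opening = 10, gap_extension = 1) {
  if (inherits(reads, "amplicon_sim")) {
    if (is.null(quals)) quals <- reads$quals
    reads <- reads$reads
  }
  refseq <- if (inherits(ref, "amplicon_reference")) ref$sequence
            else toupper(as.character(ref))
  if (length(reads) == 0L || any(!nzchar(reads))) {
    stop("reads must be non-empty sequences", call. = FALSE)
  }
  reads <- toupper(reads)

  uniq <- unique(reads)
  idx <- match(reads, uniq)
  counts <- tabulate(idx, nbins = length(uniq))
  mean_quals <- if (is.null(quals)) rep(NA_real_, length(uniq)) else {
    mq <- vapply(quals, mean_read_quality, numeric(1), USE.NAMES = FALSE)
    as.numeric(tapply(mq, idx, mean))
  }

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3,
                                                     baseOnly = FALSE)
  align_set <- function(x) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(x), subject = refseq,
      type = "local-global", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
  }
  fwd <- align_set(uniq)
  rev <- align_set(revcomp(uniq))
  use_rev <- BiocGenerics::score(rev) > BiocGenerics::score(fwd)

  alns <- vector("list", length(uniq))
  keep <- logical(length(uniq))
  for (i in seq_along(uniq)) {
    pa <- if (use_rev[i]) rev[i] else fwd[i]
    alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- Biostrings::nmatch(pa) / alen
    if (ident < min_identity) next
    keep[i] <- TRUE
    walk <- walk_alignment(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)),
      ref_offset = BiocGenerics::start(Biostrings::subject(pa)) - 1L)
    walk$mean_qual <- mean_quals[i]
    walk$orientation <- if (use_rev[i]) "-" else "+"
    walk$identity <- ident
    alns[[i]] <- walk
  }

  structure(list(ref = ref, alignments = alns[keep], counts = counts[keep],
                 n_total = length(reads),
                 n_discarded = sum(counts[!keep])),
            class = "amplicon_alignments")
}

# Convert a gapped (pattern, subject) string pair into 0-based reference
# coordinates: per-position base calls, deletion and insertion records.
walk_alignment <- function(pat, sub, ref_offset = 0L) {
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  is_ins <- sc == "-"
  is_del <- pc == "-"
  # reference position of each column (0-based); insertions anchor after
  # the preceding reference position
  rpos <- cumsum(!is_ins) - 1L + ref_offset
  call_cols <- !is_ins & !is_del
  ref_pos <- rpos[call_cols]
  read_base <- pc[call_cols]

  runs <- function(mask) {
    if (!any(mask)) return(data.frame(start = integer(), len = integer()))
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    data.frame(start = rpos[starts[w]], len = r$lengths[w])
  }
  del <- runs(is_del)
  ins <- runs(is_ins)
  if (nrow(ins) > 0) ins$start <- ins$start  # anchor: ref pos preceding gap
  names(ins) <- c("after", "len")

  list(ref_pos = ref_pos, read_base = read_base, del = del, ins = ins,
       span = c(min(rpos[!is_ins]), max(rpos[!is_ins]) + 1L))
}

#' @export
print.amplicon_alignments <- function(x, ...) {
  cat(sprintf("amplicon_alignments: %d reads (%d unique kept, %d discarded below identity floor)\n",
              x$n_total, length(x$alignments), x$n_discarded))
  invisible(x)
}
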