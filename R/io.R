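## Readers and writers for the standard formats the pipeline consumes and
## emits. Internal coordinates are 0-based half-open everywhere; SAM's
## 1-based convention is converted at this boundary.

CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

cigar_ref_span <- function(cigar) {
  if (cigar == "*") return(0L)
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
}

cigar_clip5 <- function(cigar, strand) {
  if (cigar == "*") return(0L)
  p <- parse_cigar(cigar)
  n <- length(p$op)
  # the read's sequencing start is the left CIGAR end for forward reads
  # and the right end for reverse reads
  if (strand == "+") {
    if (p$op[1] == "S") p$len[1] else 0L
  } else {
    if (p$op[n] == "S") p$len[n] else 0L
  }
}

# Derive the columns the discovery filters need from raw SAM fields.
annotate_alignments <- function(rec) {
  n <- nrow(rec)
  rec$unmapped <- bitwAnd(rec$flag, 4L) > 0L | rec$contig == "*"
  rec$strand <- ifelse(bitwAnd(rec$flag, 16L) > 0L, "-", "+")
  rec$duplicate <- bitwAnd(rec$flag, 1024L) > 0L
  span <- vapply(rec$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  rec$ref_end <- rec$pos + span
  rec$clip5 <- vapply(seq_len(n), function(i) {
    cigar_clip5(rec$cigar[i], rec$strand[i])
  }, integer(1))
  rec$start5 <- ifelse(rec$strand == "+", rec$pos, rec$ref_end - 1L)
  rec$start5[rec$unmapped] <- NA_integer_
  rec$mean_qual <- vapply(rec$qual, mean_read_quality, numeric(1),
                          USE.NAMES = FALSE)
  rec
}

#' Read aligned records from a SAM file
#'
#' Parses a SAM file into the package's alignment-record data.frame: raw
#' fields (qname, flag, contig, 0-based pos, mapq, cigar, seq, qual) plus
#' the derived columns the discovery filters use (strand, strand-aware 5'
#' start, reference end, 5' soft-clip length, mean base quality, duplicate
#' and unmapped flags). BAM files are accepted when the Rsamtools package
#' is installed.
#'
#' @param path SAM (or BAM) file path.
#' @return alignment-record data.frame.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_alignments_bam(path))
  }
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "@")) {
    stop(sprintf("format error in '%s': missing SAM header at line 1", path),
         call. = FALSE)
  }
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(annotate_alignments(data.frame(
      qname = character(), flag = integer(), contig = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      seq = character(), qual = character(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(body, "\t")
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0) {
    stop(sprintf("format error in '%s': truncated record '%s'",
                 path, fields[[short[1]]][1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  cigar <- m[, 6]
  bad <- which(cigar != "*" & !grepl(CIGAR_RE, cigar))
  if (length(bad) > 0) {
    stop(sprintf("format error in '%s': malformed CIGAR in record '%s'",
                 path, m[bad[1], 1]), call. = FALSE)
  }
  rec <- data.frame(qname = m[, 1], flag = as.integer(m[, 2]),
                    contig = m[, 3], pos = as.integer(m[, 4]) - 1L,
                    mapq = as.integer(m[, 5]), cigar = cigar,
                    seq = m[, 10], qual = m[, 11],
                    stringsAsFactors = FALSE)
  annotate_alignments(rec)
}

read_alignments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package", call. = FALSE)
  }
  b <- Rsamtools::scanBam(path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
               "qual")))[[1]]
  rec <- data.frame(qname = b$qname, flag = as.integer(b$flag),
                    contig = as.character(b$rname),
                    pos = as.integer(b$pos) - 1L,
                    mapq = as.integer(b$mapq),
                    cigar = as.character(b$cigar),
                    seq = as.character(b$seq),
                    qual = as.character(b$qual),
                    stringsAsFactors = FALSE)
  rec$contig[is.na(rec$contig)] <- "*"
  rec$cigar[is.na(rec$cigar)] <- "*"
  rec$mapq[is.na(rec$mapq)] <- 0L
  rec$pos[is.na(rec$pos)] <- 0L
  annotate_alignments(rec)
}

#' Write alignment records to a SAM file
#'
#' @param records alignment-record data.frame (or a `break_library`).
#' @param path output path.
#' @param contig_lengths named integer vector for the `@SQ` header lines;
#'   inferred from the records' maximum reference end if omitted.
#' @return the path, invisibly.
#' @export
write_sam <- function(records, path, contig_lengths = NULL) {
  if (inherits(records, "break_library")) {
    lib <- records
    records <- lib$alignments
    if (is.null(contig_lengths)) {
      contig_lengths <- setNames(nchar(genome_sequence(lib$genome)),
                                 genome_name(lib$genome))
    }
  }
  if (is.null(contig_lengths)) {
    mapped <- records[!records$unmapped, , drop = FALSE]
    contig_lengths <- tapply(mapped$ref_end, mapped$contig, max)
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  ord <- order(records$contig, records$pos)
  r <- records[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  r$qname, r$flag, r$contig, r$pos + 1L, r$mapq, r$cigar,
                  r$seq, r$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; intervals are validated (end > start, with
#' the offending line number reported) and returned per-contig sorted.
#'
#' @param path BED file path.
#' @return data.frame of class `interval_set`: contig, start, end (plus
#'   name if present).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer())
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 3L)) {
    stop(sprintf("format error in '%s': fewer than 3 columns at line %d",
                 path, lineno[which(lengths(fields) < 3L)[1]]),
         call. = FALSE)
  }
  out <- data.frame(contig = vapply(fields, `[`, "", 1),
                    start = as.integer(vapply(fields, `[`, "", 2)),
                    end = as.integer(vapply(fields, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  if (any(lengths(fields) >= 4L)) {
    out$name <- vapply(fields, function(f) {
      if (length(f) >= 4) f[4] else NA_character_
    }, "")
  }
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    stop(sprintf("format error in '%s': end <= start at line %d",
                 path, lineno[bad[1]]), call. = FALSE)
  }
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Write intervals (or candidate clusters) to a BED file
#'
#' Clusters are written with the summed start count in the BED score
#' column.
#'
#' @param x data.frame with contig/start/end, or `candidate_clusters`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "candidate_clusters")) {
    lines <- sprintf("%s\t%d\t%d\tcluster%d\t%d\t%s",
                     x$contig, x$position, x$position + 1L,
                     seq_len(nrow(x)), x$summed_start_count, x$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", x$contig, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return list: `id`, `seq`, `qual` character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x), seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write reads to a FASTQ file
#' @param seqs character vector of sequences (or an `amplicon_sim`).
#' @param path output path.
#' @param quals Phred+33 strings (constant Q30 if omitted).
#' @param ids read names.
#' @return the path, invisibly.
#' @export
write_fastq <- function(seqs, path, quals = NULL, ids = NULL) {
  if (inherits(seqs, "amplicon_sim")) {
    if (is.null(quals)) quals <- seqs$quals
    seqs <- seqs$reads
  }
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(L) phred_to_qual(rep(30L, L)),
                    character(1))
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector or a `reference_sequence`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "reference_sequence")) {
    seqs <- setNames(seqs$sequence, seqs$name)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
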