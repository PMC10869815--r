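#' Amplicon read simulation profile
#'
#' Describes the edit structure of a simulated amplicon library:
#' per-position substitution rates, optional whole-codon conversions
#' (mutually exclusive when they share a codon start, so e.g. 40% TGG->TGA
#' plus 10% TGG->TAA partitions reads), an indel channel, and independent
#' per-base sequencing error.
#'
#' @param sub_rates data.frame with columns `pos` (0-based), `alt`
#'   (substituted base) and `rate` in [0, 1]; at most one rule per
#'   (position, alternate base).
#' @param codon_edits data.frame with columns `start` (0-based codon offset),
#'   `to` (3-base replacement) and `rate`; rules sharing a `start` are
#'   mutually exclusive alternatives.
#' @param indel_rate fraction of reads carrying the indel.
#' @param indel_pos 0-based position of the indel.
#' @param indel_len indel length in bases (1-10).
#' @param indel_type "del" or "ins".
#' @param error_rate per-base independent miscall probability.
#' @param n_reads number of reads to emit.
#' @param seed integer seed.
#' @return a list of class `amplicon_sim_profile`.
#' @export
amplicon_sim_profile <- function(sub_rates = NULL, codon_edits = NULL,
                                 indel_rate = 0, indel_pos = 0L,
                                 indel_len = 3L, indel_type = "del",
                                 error_rate = 0, n_reads = 1000L, seed) {
  if (!is.null(sub_rates)) {
    stopifnot(all(c("pos", "alt", "rate") %in% names(sub_rates)))
    if (any(sub_rates$rate < 0 | sub_rates$rate > 1)) {
      stop("substitution rates must lie in [0, 1]", call. = FALSE)
    }
    if (anyDuplicated(sub_rates[c("pos", "alt")])) {
      stop("at most one substitution rule per position per alternate base",
           call. = FALSE)
    }
  }
  if (!is.null(codon_edits)) {
    stopifnot(all(c("start", "to", "rate") %in% names(codon_edits)))
    if (any(codon_edits$rate < 0 | codon_edits$rate > 1)) {
      stop("codon edit rates must lie in [0, 1]", call. = FALSE)
    }
    tot <- tapply(codon_edits$rate, codon_edits$start, sum)
    if (any(tot > 1 + 1e-12)) {
      stop("codon edit rates at one codon must sum to <= 1", call. = FALSE)
    }
  }
  stopifnot_scalar_number(indel_rate, "indel_rate", 0, 1)
  stopifnot_scalar_number(error_rate, "error_rate", 0, 1)
  if (indel_rate > 0 && (indel_len < 1 || indel_len > 10)) {
    stop("indel_len must be 1-10 bases", call. = FALSE)
  }
  if (!indel_type %in% c("del", "ins")) {
    stop("indel_type must be 'del' or 'ins'", call. = FALSE)
  }
  structure(list(sub_rates = sub_rates, codon_edits = codon_edits,
                 indel_rate = indel_rate, indel_pos = as.integer(indel_pos),
                 indel_len = as.integer(indel_len), indel_type = indel_type,
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 seed = as.integer(seed)),
            class = "amplicon_sim_profile")
}

#' Simulate amplicon sequencing reads with a known edit profile
#'
#' Each read starts from the reference sequence; substitution and codon
#' rules fire independently per read, then the indel, then per-base error.
#' Deterministic for a given profile seed.
#'
#' @param ref an `amplicon_reference` or a plain DNA string.
#' @param profile an [amplicon_sim_profile()].
#' @return list of class `amplicon_sim`: `reads` (character vector),
#'   `quals` (Phred+33 strings), and `profile` (the truth).
#' @export
simulate_amplicon_reads <- function(ref, profile) {
  stopifnot(inherits(profile, "amplicon_sim_profile"))
  refseq <- if (inherits(ref, "amplicon_reference")) ref$sequence
            else as.character(ref)
  rlen <- nchar(refseq)
  sub <- profile$sub_rates
  if (!is.null(sub) && any(sub$pos < 0 | sub$pos >= rlen)) {
    stop("substitution position outside amplicon bounds", call. = FALSE)
  }
  if (!is.null(profile$codon_edits) &&
      any(profile$codon_edits$start < 0 |
          profile$codon_edits$start + 2 >= rlen)) {
    stop("codon edit outside amplicon bounds", call. = FALSE)
  }
  if (profile$indel_rate > 0 &&
      (profile$indel_pos < 0 || profile$indel_pos >= rlen)) {
    stop("indel position outside amplicon bounds", call. = FALSE)
  }

  n <- profile$n_reads
  ref_chars <- strsplit(refseq, "")[[1]]
  reads <- with_seed(profile$seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      ch <- ref_chars
      if (!is.null(sub)) {
        fire <- runif(nrow(sub)) < sub$rate
        for (j in which(fire)) ch[sub$pos[j] + 1L] <- sub$alt[j]
      }
      ce <- profile$codon_edits
      if (!is.null(ce)) {
        for (s in unique(ce$start)) {
          rules <- ce[ce$start == s, , drop = FALSE]
          u <- runif(1)
          cum <- cumsum(rules$rate)
          pick <- which(u < cum)[1]
          if (!is.na(pick)) {
            ch[(s + 1L):(s + 3L)] <- strsplit(rules$to[pick], "")[[1]]
          }
        }
      }
      if (profile$indel_rate > 0 && runif(1) < profile$indel_rate) {
        p <- profile$indel_pos + 1L
        if (profile$indel_type == "del") {
          drop <- p:min(length(ch), p + profile$indel_len - 1L)
          ch <- ch[-drop]
        } else {
          ins <- sample(BASES, profile$indel_len, replace = TRUE)
          ch <- append(ch, ins, after = p)
        }
      }
      if (profile$error_rate > 0) {
        hit <- which(runif(length(ch)) < profile$error_rate)
        for (j in hit) ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
      }
      out[i] <- paste(ch, collapse = "")
    }
    out
  })
  quals <- vapply(nchar(reads),
                  function(L) phred_to_qual(rep(30L, L)), character(1))
  structure(list(reads = reads, quals = quals, profile = profile),
            class = "amplicon_sim")
}
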