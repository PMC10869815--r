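STOP_CODONS <- c("TGA", "TAG", "TAA")

#' Coding region for stop-codon target scanning
#'
#' @param id region identifier.
#' @param cds in-frame sense-strand DNA string (length divisible by 3).
#' @param flank5,flank3 optional flanking sense-strand context, used for 5'
#'   context classification at terminal codons.
#' @param offset residue number of the first codon (default 1), so the
#'   scan can be addressed in protein coordinates.
#' @return list of class `coding_region`. Warns (does not fail) if the CDS
#'   contains internal stop codons.
#' @export
coding_region <- function(id, cds, flank5 = "", flank3 = "", offset = 1L) {
  cds <- toupper(gsub("\\s", "", as.character(cds)))
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  n_codon <- nchar(cds) / 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  internal <- which(codons %in% STOP_CODONS)
  internal <- internal[internal < n_codon]
  if (length(internal) > 0) {
    warning(sprintf("CDS '%s' contains internal stop codon(s) at codon %s",
                    id, paste(internal, collapse = ",")))
  }
  structure(list(id = id, cds = cds,
                 flank5 = toupper(flank5), flank3 = toupper(flank3),
                 offset = as.integer(offset), n_codon = n_codon),
            class = "coding_region")
}

# sense base at 0-based CDS coordinate, reaching into the flanks;
# NA outside the available context
region_base <- function(region, pos) {
  vapply(pos, function(p) {
    if (p >= 0 && p < nchar(region$cds)) {
      substr(region$cds, p + 1, p + 1)
    } else if (p < 0 && nchar(region$flank5) >= -p) {
      f <- region$flank5
      substr(f, nchar(f) + p + 1, nchar(f) + p + 1)
    } else if (p >= nchar(region$cds) &&
               nchar(region$flank3) >= p - nchar(region$cds) + 1) {
      substr(region$flank3, p - nchar(region$cds) + 1,
             p - nchar(region$cds) + 1)
    } else NA_character_
  }, character(1))
}

#' Classify the 5' deaminase context of a target cytosine
#'
#' For a sense-strand target C at 0-based CDS coordinate `cds_pos`, the 5'
#' neighbour is the preceding sense base. For an antisense target C
#' (opposite a sense G at `cds_pos`), the 5' neighbour on the edited strand
#' is the complement of the sense base immediately 3' of that G. The class
#' is 5'-TC if the neighbour is T; 5'-TCC if the neighbour is C and the
#' base 5' of that C (still on the edited strand) is T; otherwise 5'-AC,
#' 5'-GC or 5'-CC by the neighbour base. Missing flanking context yields
#' "undetermined".
#'
#' @param region a [coding_region()].
#' @param cds_pos 0-based coordinate of the target C (sense) or of the
#'   sense G it sits opposite (antisense).
#' @param strand "sense" or "antisense".
#' @return character class: "5'-TC", "5'-TCC", "5'-AC", "5'-GC", "5'-CC",
#'   or "undetermined".
#' @export
classify_deaminase_context <- function(region, cds_pos, strand = "sense") {
  if (strand == "sense") {
    nb <- region_base(region, cds_pos - 1L)
    nb2 <- region_base(region, cds_pos - 2L)
  } else {
    nb <- complement_base(region_base(region, cds_pos + 1L))
    nb2 <- complement_base(region_base(region, cds_pos + 2L))
  }
  if (is.na(nb)) return("undetermined")
  if (nb == "T") return("5'-TC")
  if (nb == "C") {
    if (is.na(nb2)) return("undetermined")
    return(if (nb2 == "T") "5'-TCC" else "5'-CC")
  }
  if (nb == "A") return("5'-AC")
  if (nb == "G") return("5'-GC")
  "undetermined"
}

#' Scan a coding region for stop-convertible codons
#'
#' Enumerates every codon convertible to a premature stop codon by
#' single-strand C-to-T editing: CAG to TAG, CAA to TAA and CGA to TGA via
#' a sense-strand C at the first codon position, and TGG to TGA / TAG /
#' TAA via antisense Cs opposite the two sense Gs (one G-to-A change each,
#' or both for TAA). Each target cytosine's 5' deaminase context is
#' classified on its edited strand.
#'
#' @param region a [coding_region()].
#' @param residue_range inclusive residue interval `c(from, to)` in the
#'   region's residue numbering; defaults to the whole CDS.
#' @return object of class `stop_scan`: `codons` (one row per convertible
#'   codon: residue, codon, achievable stops, edited strand), `targets`
#'   (one row per target cytosine: residue, codon, strand, position within
#'   codon, 0-based CDS coordinate of the edited sense base, stop achieved
#'   by that single edit, context class), and the region.
#' @export
scan_stop_codons <- function(region, residue_range = NULL) {
  stopifnot(inherits(region, "coding_region"))
  if (is.null(residue_range)) {
    residue_range <- c(region$offset, region$offset + region$n_codon - 1L)
  }
  first <- residue_range[1] - region$offset + 1L
  last <- residue_range[2] - region$offset + 1L
  if (first < 1 || last > region$n_codon || first > last) {
    stop("residue_range outside the CDS", call. = FALSE)
  }
  codon_rows <- list(); target_rows <- list()
  for (ci in first:last) {
    cstart <- 3L * (ci - 1L)
    codon <- substr(region$cds, cstart + 1L, cstart + 3L)
    residue <- ci + region$offset - 1L
    rec <- switch(codon,
      CAG = list(stops = "TAG", strand = "sense",
                 targets = data.frame(codon_pos = 0L, stop = "TAG")),
      CAA = list(stops = "TAA", strand = "sense",
                 targets = data.frame(codon_pos = 0L, stop = "TAA")),
      CGA = list(stops = "TGA", strand = "sense",
                 targets = data.frame(codon_pos = 0L, stop = "TGA")),
      TGG = list(stops = c("TAG", "TGA", "TAA"), strand = "antisense",
                 targets = data.frame(codon_pos = c(1L, 2L),
                                      stop = c("TAG", "TGA"))),
      NULL)
    if (is.null(rec)) next
    codon_rows[[length(codon_rows) + 1L]] <- data.frame(
      residue = residue, codon = codon,
      stops = paste(rec$stops, collapse = ","),
      strand = rec$strand, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(rec$targets))) {
      cds_pos <- cstart + rec$targets$codon_pos[k]
      ctx <- classify_deaminase_context(region, cds_pos, rec$strand)
      target_rows[[length(target_rows) + 1L]] <- data.frame(
        residue = residue, codon = codon, strand = rec$strand,
        codon_pos = rec$targets$codon_pos[k], cds_pos = cds_pos,
        stop = rec$targets$stop[k], context = ctx,
        stringsAsFactors = FALSE)
    }
  }
  bindf <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  structure(list(
    codons = bindf(codon_rows,
                   data.frame(residue = integer(), codon = character(),
                              stops = character(), strand = character())),
    targets = bindf(target_rows,
                    data.frame(residue = integer(), codon = character(),
                               strand = character(), codon_pos = integer(),
                               cds_pos = integer(), stop = character(),
                               context = character())),
    region = region, residue_range = residue_range),
    class = "stop_scan")
}

#' Summarize a stop-codon scan under a deaminase context profile
#'
#' @param scan a [scan_stop_codons()] result.
#' @param profile character vector of context classes the deaminase
#'   accepts, e.g. `c("5'-TC", "5'-TCC")` for a DddA-like enzyme; NULL
#'   accepts all classes.
#' @return list: `total` convertible codons, `by_codon` named counts,
#'   `qualifying` (codon table subset where at least one stop-achieving
#'   target C has an accepted context), `n_qualifying`.
#' @export
summarize_scan <- function(scan, profile = NULL) {
  stopifnot(inherits(scan, "stop_scan"))
  by_codon <- table(factor(scan$codons$codon,
                           levels = c("CAG", "TGG", "CAA", "CGA")))
  if (is.null(profile)) {
    qual <- scan$codons
  } else {
    ok_res <- unique(scan$targets$residue[scan$targets$context %in% profile])
    qual <- scan$codons[scan$codons$residue %in% ok_res, , drop = FALSE]
  }
  list(total = nrow(scan$codons),
       by_codon = setNames(as.integer(by_codon), names(by_codon)),
       qualifying = qual, n_qualifying = nrow(qual))
}

#' @export
print.stop_scan <- function(x, ...) {
  s <- summarize_scan(x)
  cat(sprintf("stop_scan of '%s' residues %d-%d: %d convertible codon(s) (%s)\n",
              x$region$id, x$residue_range[1], x$residue_range[2], s$total,
              paste(sprintf("%dx %s", s$by_codon, names(s$by_codon)),
                    collapse = ", ")))
  invisible(x)
}
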