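#' Annotated amplicon reference
#'
#' An amplicon sequence (top strand) annotated with the left and right
#' zinc-finger binding-arm intervals, the target codon assayed for stop
#' conversion, and the derived editing window. All intervals are 0-based
#' half-open on the top strand.
#'
#' @param id amplicon identifier.
#' @param sequence top-strand DNA string.
#' @param left_arm integer length-2 vector `c(start, end)` of the left ZF
#'   binding site (0-based half-open).
#' @param right_arm same for the right ZF binding site; must start after the
#'   left arm ends.
#' @param target_codon_start 0-based offset of the codon assayed for stop
#'   conversion, or NULL if none.
#' @param codon_strand "sense" or "antisense": strand on which the codon is
#'   read relative to the top strand.
#' @return list of class `amplicon_reference` with a derived `window`
#'   element (see [derive_editing_window()]).
#' @export
amplicon_reference <- function(id, sequence, left_arm, right_arm,
                               target_codon_start = NULL,
                               codon_strand = "sense") {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  stopifnot(length(left_arm) == 2L, length(right_arm) == 2L)
  if (left_arm[1] < 0 || right_arm[2] > L) {
    stop("arm intervals must lie within the amplicon", call. = FALSE)
  }
  if (!is.null(target_codon_start)) {
    if (target_codon_start < 0 || target_codon_start + 3 > L) {
      stop("target codon must lie fully inside the amplicon", call. = FALSE)
    }
    if (!codon_strand %in% c("sense", "antisense")) {
      stop("codon_strand must be 'sense' or 'antisense'", call. = FALSE)
    }
  }
  ref <- structure(list(id = id, sequence = sequence,
                        left_arm = as.integer(left_arm),
                        right_arm = as.integer(right_arm),
                        target_codon_start =
                          if (is.null(target_codon_start)) NULL
                          else as.integer(target_codon_start),
                        codon_strand = codon_strand),
                   class = "amplicon_reference")
  ref$window <- derive_editing_window(ref)
  ref
}

#' Derive the base-editing window from the ZF binding arms
#'
#' The editing window is the gap between the two zinc-finger array binding
#' sites widened by exactly one base on each side (the first 5' and 3'
#' flanking base): with arms `[l0, l1)` and `[r0, r1)`, the window is
#' `[l1 - 1, r0 + 1)` on the top strand.
#'
#' @param ref an `amplicon_reference` (window element ignored).
#' @return integer length-2 vector `c(start, end)`, 0-based half-open.
#' @examples
#' r <- amplicon_reference("a", strrep("ACGT", 8), c(0, 12), c(20, 32))
#' derive_editing_window(r)  # 11 21
#' @export
derive_editing_window <- function(ref) {
  la <- ref$left_arm; ra <- ref$right_arm
  if (la[2] > la[1] && ra[2] > ra[1] && la[2] <= ra[1]) {
    return(c(la[2] - 1L, ra[1] + 1L))
  }
  stop("binding arms must be non-empty, non-overlapping and ordered left-right",
       call. = FALSE)
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("amplicon_reference '%s': %d bp; arms [%d,%d) [%d,%d); window [%d,%d)\n",
              x$id, nchar(x$sequence), x$left_arm[1], x$left_arm[2],
              x$right_arm[1], x$right_arm[2], x$window[1], x$window[2]))
  if (!is.null(x$target_codon_start)) {
    cat(sprintf("  target codon at %d (%s strand): %s\n",
                x$target_codon_start, x$codon_strand,
                substr(x$sequence, x$target_codon_start + 1,
                       x$target_codon_start + 3)))
  }
  invisible(x)
}
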