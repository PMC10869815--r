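#' Generate a random reference sequence
#'
#' Draws a random DNA sequence with a specified expected GC content. Used as
#' a stand-in genome (or amplicon backbone) for truth-known simulations: the
#' same (length, gc_fraction, seed) triple always reproduces the identical
#' sequence.
#'
#' @param length number of bases (>= 1).
#' @param gc_fraction expected GC content in [0, 1].
#' @param seed integer seed; part of the sequence's identity.
#' @param name contig name recorded with the sequence.
#' @return an object of class `reference_sequence`: a list with elements
#'   `name`, `sequence` (character string over A/C/G/T), and `seed`.
#' @examples
#' g <- make_genome(1000, gc_fraction = 0.4, seed = 1)
#' substr(g$sequence, 1, 20)
#' @export
make_genome <- function(length, gc_fraction = 0.5, seed, name = "chrS") {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1) {
    stop("'length' must be a positive integer", call. = FALSE)
  }
  stopifnot_scalar_number(gc_fraction, "gc_fraction", 0, 1)
  seq <- with_seed(seed, {
    probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    paste(sample(BASES, as.integer(length), replace = TRUE, prob = probs),
          collapse = "")
  })
  structure(list(name = name, sequence = seq, seed = as.integer(seed)),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  n <- nchar(x$sequence)
  gc <- sum(strsplit(x$sequence, "")[[1]] %in% c("C", "G")) / n
  cat(sprintf("reference_sequence '%s': %d bp, GC %.3f (seed %d)\n",
              x$name, n, gc, x$seed))
  invisible(x)
}

genome_sequence <- function(genome) {
  if (inherits(genome, "reference_sequence")) genome$sequence
  else as.character(genome)
}

genome_name <- function(genome) {
  if (inherits(genome, "reference_sequence")) genome$name else "ref"
}
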