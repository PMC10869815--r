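#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.table write.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state, so generators are deterministic
#' for a given seed without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse-complement a DNA string
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) unname(COMPLEMENT[b])

## Phred+33 helpers -----------------------------------------------------------

qual_to_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

phred_to_qual <- function(phred) {
  intToUtf8(as.integer(phred) + 33L)
}

mean_read_quality <- function(qual) {
  if (is.na(qual) || qual == "*" || nchar(qual) == 0L) return(NA_real_)
  mean(qual_to_phred(qual))
}
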