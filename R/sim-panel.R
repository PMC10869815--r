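#' Multiplexed amplicon panel simulation specification
#'
#' Describes a simulated rhAmpSeq-style run: a panel of amplicons whose
#' first 23 nt are unique (the demultiplexing key), a replicate structure
#' per condition, germline-like positions carrying an intermediate allele
#' frequency in both conditions, base-editing events present only in the
#' treated condition, and a fraction of off-panel contaminant reads.
#'
#' @param amplicons data.frame with columns `name` and `sequence`; the
#'   first 23 nt of each sequence must be pairwise distinct.
#' @param replicates replicates per condition.
#' @param reads_per_replicate reads per amplicon per replicate.
#' @param germline data.frame(amplicon, pos, alt, af): positions carrying an
#'   intermediate allele frequency in both conditions (0-based `pos`).
#' @param editing data.frame(amplicon, pos, strand, fraction): C-to-T edits
#'   on the sense ("+", read base becomes T) or antisense ("-", read base
#'   becomes A) strand, applied only in the treated condition.
#' @param contaminant_fraction fraction of reads with no panel prefix.
#' @param error_rate per-base miscall probability (default 0).
#' @return list of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(amplicons, replicates = 4L,
                           reads_per_replicate = 2000L,
                           germline = NULL, editing = NULL,
                           contaminant_fraction = 0, error_rate = 0) {
  stopifnot(all(c("name", "sequence") %in% names(amplicons)))
  if (any(nchar(amplicons$sequence) < 23)) {
    stop("panel sequences must be at least 23 nt", call. = FALSE)
  }
  prefixes <- substr(amplicons$sequence, 1, 23)
  if (anyDuplicated(prefixes)) {
    stop("23-nt panel prefixes must be pairwise distinct", call. = FALSE)
  }
  stopifnot_scalar_number(contaminant_fraction, "contaminant_fraction", 0, 1)
  stopifnot_scalar_number(error_rate, "error_rate", 0, 1)
  structure(list(amplicons = amplicons, prefixes = prefixes,
                 replicates = as.integer(replicates),
                 reads_per_replicate = as.integer(reads_per_replicate),
                 germline = germline, editing = editing,
                 contaminant_fraction = contaminant_fraction,
                 error_rate = error_rate),
            class = "panel_sim_spec")
}

#' Simulate a multiplexed amplicon (rhAmpSeq-style) run
#'
#' Emits per-condition, per-replicate read sets. Reads begin with their
#' amplicon's exact 23-nt prefix except for the stated contaminant fraction;
#' germline positions carry their allele frequency in both conditions;
#' edited positions carry the extra A or T fraction only in the treated
#' condition.
#'
#' @param spec a [panel_sim_spec()].
#' @param seed integer seed.
#' @return list of class `panel_sim`: `treated` and `unedited`, each a list
#'   of replicates, each replicate a character vector of reads; plus `spec`.
#' @export
simulate_rhamp_run <- function(spec, seed) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  with_seed(seed, {
    conds <- list()
    for (cond in c("treated", "unedited")) {
      reps <- vector("list", spec$replicates)
      for (r in seq_len(spec$replicates)) {
        reads <- character(0)
        for (a in seq_len(nrow(spec$amplicons))) {
          nm <- spec$amplicons$name[a]
          aseq <- spec$amplicons$sequence[a]
          n <- spec$reads_per_replicate
          mat <- matrix(rep(strsplit(aseq, "")[[1]], n),
                        nrow = n, byrow = TRUE)
          gl <- spec$germline
          if (!is.null(gl)) {
            gl_a <- gl[gl$amplicon == nm, , drop = FALSE]
            for (k in seq_len(nrow(gl_a))) {
              hit <- runif(n) < gl_a$af[k]
              mat[hit, gl_a$pos[k] + 1L] <- gl_a$alt[k]
            }
          }
          ed <- spec$editing
          if (cond == "treated" && !is.null(ed)) {
            ed_a <- ed[ed$amplicon == nm, , drop = FALSE]
            for (k in seq_len(nrow(ed_a))) {
              hit <- runif(n) < ed_a$fraction[k]
              newb <- if (ed_a$strand[k] == "+") "T" else "A"
              mat[hit, ed_a$pos[k] + 1L] <- newb
            }
          }
          if (spec$error_rate > 0) {
            err <- which(matrix(runif(length(mat)) < spec$error_rate,
                                nrow = n))
            for (j in err) mat[j] <- sample(setdiff(BASES, mat[j]), 1L)
          }
          reads <- c(reads, apply(mat, 1, paste, collapse = ""))
        }
        if (spec$contaminant_fraction > 0) {
          swap <- which(runif(length(reads)) < spec$contaminant_fraction)
          L <- nchar(spec$amplicons$sequence[1])
          for (j in swap) {
            repeat {
              cont <- paste(sample(BASES, L, replace = TRUE), collapse = "")
              if (!substr(cont, 1, 23) %in% spec$prefixes) break
            }
            reads[j] <- cont
          }
        }
        reps[[r]] <- reads
      }
      names(reps) <- paste0("rep", seq_len(spec$replicates))
      conds[[cond]] <- reps
    }
    structure(c(conds, list(spec = spec)), class = "panel_sim")
  })
}
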