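# Independent oracles, deliberately naive: they share no code with the
# pipeline paths they check.

# Brute-force break caller: per-read tallies, no coverage Rle, no
# vectorized pileup. Depth is only evaluated at positions that already
# meet the start-count floor (the fraction rule cannot rescue a position
# below it).
oracle_break_candidates <- function(records, min_start_reads = 10,
                                    min_start_fraction = 0.2) {
  out <- data.frame(contig = character(), strand = character(),
                    position = integer(), start_count = integer(),
                    depth = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(out)
  key <- paste(records$contig, records$strand, records$start5)
  tab <- table(key)
  tab <- tab[tab >= min_start_reads]
  for (k in names(tab)) {
    parts <- strsplit(k, " ")[[1]]
    ctg <- parts[1]; strand <- parts[2]; p <- as.integer(parts[3])
    depth <- sum(records$contig == ctg & records$pos <= p &
                 records$ref_end > p)
    if (as.integer(tab[k]) / depth >= min_start_fraction) {
      out <- rbind(out, data.frame(contig = ctg, strand = strand,
                                   position = p,
                                   start_count = as.integer(tab[k]),
                                   depth = depth,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$contig, out$position, out$strand), , drop = FALSE]
}

# Brute-force single-linkage clustering by pairwise distance chaining.
oracle_cluster_positions <- function(positions, merge_distance) {
  n <- length(positions)
  if (n == 0L) return(integer(0))
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] &&
          abs(positions[i] - positions[j]) <= merge_distance) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# Exhaustive single-substitution stop oracle: applies every sense C->T
# and every sense G->A over the scanned residues and records codons that
# become one of TGA/TAG/TAA, with the stop each single edit achieves.
oracle_stop_targets <- function(cds, first_codon, last_codon) {
  stops <- c("TGA", "TAG", "TAA")
  hits <- list()
  for (ci in first_codon:last_codon) {
    cstart <- 3 * (ci - 1)
    codon <- substr(cds, cstart + 1, cstart + 3)
    for (k in 1:3) {
      b <- substr(codon, k, k)
      sub <- if (b == "C") "T" else if (b == "G") "A" else next
      mut <- codon
      substr(mut, k, k) <- sub
      if (mut %in% stops) {
        hits[[length(hits) + 1L]] <- data.frame(
          codon_index = ci, codon = codon, codon_pos = k - 1L,
          edit = paste0(b, ">", sub), stop = mut,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(codon_index = integer(), codon = character(),
               codon_pos = integer(), edit = character(),
               stop = character())
}

# Per-position base tally straight from simulator truth-free reads, used
# as the pileup oracle on small fixtures: counts 5' starts by walking
# reads one by one.
oracle_start_counts <- function(records) {
  counts <- list()
  for (i in seq_len(nrow(records))) {
    k <- paste(records$contig[i], records$strand[i], records$start5[i])
    counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  counts
}
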