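#' Pipeline run configuration
#'
#' Collects stage selection, per-stage inputs and thresholds. Threshold
#' blocks are validated eagerly (a bad field is rejected by name before
#' any computation) and the full configuration is echoed into the run
#' summary for provenance.
#'
#' @param stages character subset of "discovery", "amplicon", "rhamp",
#'   "scan".
#' @param discovery list: `treated`, `control`, `mask` (paths or objects)
#'   plus any [discovery_config()] fields.
#' @param amplicon list: `reads` (FASTQ path or vector), `reference` (an
#'   [amplicon_reference()] or a JSON annotation path) plus report
#'   thresholds.
#' @param rhamp list: `treated`, `unedited` (lists of FASTQ paths or read
#'   vectors, one per replicate), `panel` (a [panel_def()] or TSV path)
#'   plus [retention_config()] fields.
#' @param scan list: `cds` (FASTA path or string), `id`, `offset`,
#'   `from`, `to`, `profile` (context classes).
#' @param out_dir output directory (NULL: no files written).
#' @param seed integer seed recorded in the summary.
#' @return list of class `run_config`.
#' @export
run_config <- function(stages, discovery = NULL, amplicon = NULL,
                       rhamp = NULL, scan = NULL, out_dir = NULL,
                       seed = NA_integer_) {
  known <- c("discovery", "amplicon", "rhamp", "scan")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ","),
         call. = FALSE)
  }
  take <- function(block, builder) {
    if (is.null(block)) return(NULL)
    fields <- intersect(names(block), names(formals(builder)))
    do.call(builder, block[fields])  # validates thresholds by field name
  }
  structure(list(stages = stages, discovery = discovery,
                 amplicon = amplicon, rhamp = rhamp, scan = scan,
                 discovery_cfg = take(discovery, discovery_config),
                 retention_cfg = take(rhamp, retention_config),
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run selected pipeline stages
#'
#' Executes the configured stages in dependency order, writes stage
#' outputs (TSV/BED/JSON) plus a JSON run summary holding the
#' configuration snapshot and per-stage record counts in and out, and
#' returns results in memory.
#'
#' @param config a [run_config()] (or a YAML file path with the same
#'   structure, requiring the yaml package).
#' @return list of class `run_summary`: `results` per stage, `counts` per
#'   stage, `config`, `warnings`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package", call. = FALSE)
    }
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "run_config"))
  # fail on missing input files before any computation
  for (st in config$stages) {
    blk <- config[[st]]
    for (f in blk) {
      if (is.character(f)) {
        for (p in f) {
          if (grepl("[/\\.]", p) && !file.exists(p) && nchar(p) < 300 &&
              grepl("\\.(sam|bam|bed|fastq|fq|fasta|fa|tsv|json|yaml)$", p)) {
            stop(sprintf("missing input file for stage '%s': %s", st, p),
                 call. = FALSE)
          }
        }
      }
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list(); counts <- list(); warns <- character(0)

  if ("discovery" %in% config$stages) {
    blk <- config$discovery
    cfg <- if (is.null(config$discovery_cfg)) discovery_config()
           else config$discovery_cfg
    res <- discover_breaks(blk$treated, blk$control, blk$mask, cfg)
    results$discovery <- res
    counts$discovery <- c(
      treated_in = unname(sum(res$filter_tally$treated)),
      treated_retained = unname(res$filter_tally$treated["retained"]),
      candidates_pre_merge = res$pre_merge_count,
      clusters = res$post_merge_count)
    if (!is.null(out_dir)) {
      write_bed(res$clusters, file.path(out_dir, "clusters.bed"))
      write.table(as.data.frame(res$treated_candidates),
                  file.path(out_dir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if ("amplicon" %in% config$stages) {
    blk <- config$amplicon
    ref <- blk$reference
    if (is.character(ref) && file.exists(ref)) ref <- read_amplicon_json(ref)
    rep <- quantify_amplicon(blk$reads, ref)
    results$amplicon <- rep
    alns <- attr(rep, "alignments")
    counts$amplicon <- c(reads_in = alns$n_total,
                         reads_discarded = alns$n_discarded)
    if (!is.null(out_dir)) {
      prof <- attr(rep, "profile")
      freq <- position_frequencies(prof)
      write.table(data.frame(position = seq_len(ncol(freq)) - 1L,
                             ref = prof$ref_chars, t(freq),
                             informative = prof$total),
                  file.path(out_dir, "amplicon_profile.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(jsonlite::toJSON(editing_report_json(rep),
                                  auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE),
                 file.path(out_dir, "editing_report.json"))
    }
  }
  if ("rhamp" %in% config$stages) {
    blk <- config$rhamp
    panel <- blk$panel
    if (is.character(panel) && file.exists(panel)) {
      tab <- read.table(panel, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      panel <- panel_def(tab$name, tab$sequence)
    }
    load_reps <- function(x) {
      lapply(x, function(r) if (is.character(r) && length(r) == 1L &&
                                file.exists(r)) read_fastq(r)$seq else r)
    }
    cfg <- if (is.null(config$retention_cfg)) retention_config()
           else config$retention_cfg
    res <- rhamp_quantify(load_reps(blk$treated), load_reps(blk$unedited),
                          panel, cfg)
    results$rhamp <- res
    counts$rhamp <- c(
      amplicons = nrow(res$audit),
      retained = sum(res$audit$retained),
      edited_loci = res$edited_loci)
    if (!is.null(out_dir)) {
      write.table(cbind(res$stats,
                        reason = res$audit$reason[match(res$stats$amplicon,
                                                        res$audit$amplicon)]),
                  file.path(out_dir, "rhamp_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if ("scan" %in% config$stages) {
    blk <- config$scan
    cds <- blk$cds
    if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
      cds <- unname(read_fasta(cds)[1])
    }
    region <- coding_region(if (is.null(blk$id)) "cds" else blk$id, cds,
                            offset = if (is.null(blk$offset)) 1L
                                     else blk$offset)
    rng <- if (!is.null(blk$from)) c(blk$from, blk$to) else NULL
    scan <- scan_stop_codons(region, rng)
    summ <- summarize_scan(scan, blk$profile)
    results$scan <- list(scan = scan, summary = summ)
    counts$scan <- c(codons = summ$total, qualifying = summ$n_qualifying)
    if (!is.null(out_dir)) {
      write.table(scan$targets, file.path(out_dir, "stop_targets.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary <- structure(list(tool_version =
                              as.character(utils::packageVersion("cbepipe")),
                            config = config, counts = counts,
                            results = results, warnings = warns),
                       class = "run_summary")
  if (!is.null(out_dir)) {
    snap <- list(tool_version = summary$tool_version,
                 stages = config$stages, seed = config$seed,
                 discovery = unclass(config$discovery_cfg),
                 retention = unclass(config$retention_cfg),
                 counts = counts, warnings = warns)
    writeLines(jsonlite::toJSON(snap, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(out_dir, "run_summary.json"))
  }
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary (cbepipe", x$tool_version, ")\n")
  for (st in names(x$counts)) {
    cat(sprintf("  %s: %s\n", st,
                paste(names(x$counts[[st]]), x$counts[[st]], sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}

#' Read an amplicon annotation from JSON
#'
#' Expected keys: id, sequence, left_arm, right_arm (0-based half-open
#' pairs), optional target_codon_start, codon_strand.
#'
#' @param path JSON path.
#' @return an [amplicon_reference()].
#' @export
read_amplicon_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  amplicon_reference(j$id, j$sequence, j$left_arm, j$right_arm,
                     j$target_codon_start,
                     if (is.null(j$codon_strand)) "sense" else j$codon_strand)
}

editing_report_json <- function(rep) {
  list(stop_fraction = rep$stop_fraction,
       stop_by_codon = as.list(rep$stop_by_codon),
       indel_fraction = rep$indel_fraction,
       window = rep$window,
       thresholds = as.list(rep$thresholds),
       flagged_outside_window = rep$flagged_outside_window,
       flagged_unintended_bases = rep$flagged_unintended_bases,
       flagged_unintended_anywhere = rep$flagged_unintended_anywhere)
}
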