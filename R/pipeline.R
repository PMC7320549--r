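# End-to-end pipeline: simulate (optional) -> screen -> phylogeny ->
# long-read dot plots -> in silico PCR, with TSV/GFF3/FASTA/Newick outputs
# and a structured run log.

#' Pipeline configuration
#'
#' @param plan Generator plan (see [simulate_sample()]), or `NULL` to read
#'   `input_fasta` instead.
#' @param input_fasta Path to an input FASTA (used when `plan` is `NULL`).
#' @param cfg A [generator_config()].
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created if missing).
#' @param sample_id Sample label.
#' @param dotplot_min_read_length Only sequences longer than this (bp) get a
#'   self-dot-plot analysis (ultralong-read selection).
#' @param target_product Intended junction PCR product length (bp).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(plan = NULL, input_fasta = NULL,
                            cfg = generator_config(), seed = cfg$seed,
                            out_dir = "satjunction_out",
                            sample_id = "sample",
                            dotplot_min_read_length = 30000L,
                            target_product = 400L) {
  structure(list(plan = plan, input_fasta = input_fasta, cfg = cfg,
                 seed = as.integer(seed), out_dir = out_dir,
                 sample_id = sample_id,
                 dotplot_min_read_length = as.integer(dotplot_min_read_length),
                 target_product = as.integer(target_product)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config=", hash), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

stamp_gff <- function(path, hash) {
  lines <- readLines(path)
  writeLines(c(lines[1], paste0("#config=", hash),
               lines[-1]), path)
}

#' Run the full screening pipeline
#'
#' Executes, in order: sample simulation (when a plan is given), the
#' junction screen on every sequence, anchored phylogeny of the detected
#' array consensuses and parental fragments, self-dot-plot tandem analysis
#' of sequences above the ultralong-read threshold, and in silico PCR with
#' the outward-facing forward primer plus a designed array-specific reverse
#' primer per junction. All outputs are deterministic given the seed; TSV
#' and GFF3 outputs carry the configuration hash in a comment header.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths plus the in-memory
#'   `screen` result.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(config$out_dir, "run_log.txt")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  logline <- function(...) {
    msg <- paste0(...)
    writeLines(msg, logcon)
    message(msg)
  }
  logline("# satjunction run, config=", hash, ", seed=", config$seed)
  paths <- list(log = logf)
  out <- function(name) file.path(config$out_dir, name)

  # stage: input
  if (!is.null(config$plan)) {
    logline("stage simulate: planting features")
    sim <- simulate_sample(config$plan, config$cfg, config$seed)
    seqs <- sim$sequences
    paths$fasta <- out("sample.fasta")
    write_fasta(seqs, paths$fasta)
    paths$truth <- out("truth.gff3")
    write_gff3(sim$truth, paths$truth)
    stamp_gff(paths$truth, hash)
  } else {
    if (is.null(config$input_fasta)) stop("stage input: no plan and no FASTA")
    logline("stage input: reading ", config$input_fasta)
    seqs <- read_fasta(config$input_fasta)
    set.seed(config$seed)
  }
  logline("stage input: ", length(seqs), " sequence(s)")

  # stage: screen
  logline("stage screen: motif scan, arrays, classification, junctions")
  screen <- screen_genome(seqs, sample_id = config$sample_id)
  paths$report <- write_tsv(screen$report, out("screen_report.tsv"), hash)
  paths$junctions <- out("junctions.gff3")
  write_gff3(junctions_to_features(screen), paths$junctions)
  stamp_gff(paths$junctions, hash)
  cons <- consensus_records(screen)
  paths$consensus <- out("consensus.fasta")
  write_fasta(cons, paths$consensus)
  logline("stage screen: ", length(screen$junctions), " junction(s), ",
          length(screen$arrays), " array(s)")

  # stage: phylogeny of consensuses + parental fragments
  logline("stage phylo: anchored alignment, p-distances, NJ")
  aln <- anchor_align(cons)
  paths$pfm <- write_tsv(
    if (length(aln) > 0) pfm(aln) else pfm("A")[0, ],
    out("pfm.tsv"), hash)
  paths$newick <- out("monomers.nwk")
  if (length(aln) >= 3L) {
    tree <- nj_tree(p_distance_matrix(aln))
    ape::write.tree(tree, paths$newick)
  } else {
    writeLines(character(0), paths$newick)
    logline("stage phylo: fewer than 3 anchored sequences, no tree")
  }

  # stage: long-read dot plots
  long <- Filter(function(s) nchar(s$residues) > config$dotplot_min_read_length,
                 seqs)
  logline("stage dotplot: ", length(long), " sequence(s) above ",
          config$dotplot_min_read_length, " bp")
  regions <- do.call(rbind, c(
    list(regions_to_df(list())),
    lapply(long, function(s)
      regions_to_df(detect_tandem_regions(self_match_map(s))))))
  paths$dotplot <- write_tsv(regions, out("dotplot.tsv"), hash)

  # stage: in silico PCR per junction
  logline("stage pcr: ", length(screen$junctions), " junction template(s)")
  fwd <- tnp2b_forward_primer()
  seq_by_id <- stats::setNames(seqs, vapply(seqs, function(s) s$id, ""))
  amps <- do.call(rbind, c(
    list(find_amplicons("A", primer("x", strrep("A", 15)),
                        primer("y", strrep("A", 15)))[0, ]),
    lapply(screen$junctions, function(j) {
      template <- seq_by_id[[j$seq_id]]
      rev <- try(design_reverse_primer(template, fwd,
                                       target_product = config$target_product),
                 silent = TRUE)
      if (inherits(rev, "try-error")) return(NULL)
      find_amplicons(template, fwd, rev)
    })))
  paths$pcr <- write_tsv(amps, out("pcr.tsv"), hash)

  logline("stage done: all outputs in ", config$out_dir)
  invisible(c(paths, list(screen = screen)))
}

# GFF-style features for junction calls and their children.
junctions_to_features <- function(screen) {
  rows <- list()
  for (j in screen$junctions) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = j$seq_id, type = "junction",
      start = min(j$tpase$start, j$array_start),
      end = max(j$tpase$end, j$array_end), strand = j$strand,
      identity_pct = j$fragment_consensus_identity_pct,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = j$seq_id, type = "tpase", start = j$tpase$start,
      end = j$tpase$end, strand = j$strand,
      identity_pct = NA_real_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = j$seq_id, type = "parental_fragment",
      start = j$fragment_start, end = j$fragment_end, strand = j$strand,
      identity_pct = NA_real_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = j$seq_id, type = "sat_array", start = j$array_start,
      end = j$array_end, strand = j$strand,
      identity_pct = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(seqid = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity_pct = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Array consensuses and junction parental fragments as dna_seq records.
consensus_records <- function(screen) {
  recs <- list()
  for (i in seq_along(screen$arrays)) {
    a <- screen$arrays[[i]]
    recs[[length(recs) + 1L]] <- dna_seq(
      sprintf("%s_array%d_consensus", a$seq_id, i), a$consensus,
      sprintf("period=%d copies=%.1f", a$period, a$copy_number))
  }
  for (i in seq_along(screen$junctions)) {
    j <- screen$junctions[[i]]
    recs[[length(recs) + 1L]] <- dna_seq(
      sprintf("%s_junction%d_fragment", j$seq_id, i), j$fragment_residues,
      sprintf("identity=%.1f", j$fragment_consensus_identity_pct))
  }
  recs
}
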