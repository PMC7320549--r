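# Sequence types, FASTA/GFF3 I/O and the global-alignment identity primitive.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a DNA sequence record
#'
#' The universal carrier for contigs, reads, motifs, monomers and primers.
#' Residues are normalized to upper case and restricted to the alphabet
#' `A, C, G, T, N`.
#'
#' @param id Sequence identifier (single string).
#' @param residues Nucleotide string (case-insensitive).
#' @param description Optional free-text description.
#' @return An object of class `dna_seq` with fields `id`, `residues`,
#'   `description`.
#' @export
#' @examples
#' dna_seq("chr1", "acgtn")
dna_seq <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0)
    stop("non-nucleotide character(s) in sequence '", id, "': ",
         paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues, description = description),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("dna_seq '%s' (%d bp) %s\n", x$id, n, preview))
  invisible(x)
}

# Accept either a dna_seq or a bare string; return the residue string.
as_residues <- function(x) {
  if (inherits(x, "dna_seq")) return(x$residues)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a dna_seq or a single character string")
}

seq_id_of <- function(x, default = "seq") {
  if (inherits(x, "dna_seq")) x$id else default
}

# Residues as a character vector of single bases.
seq_chars <- function(x) strsplit(as_residues(x), "", fixed = TRUE)[[1]]

#' Round half away from zero
#'
#' Fixed-rule decimal rounding (0.05 at one decimal always rounds up), used
#' for all printed percent identities and fractional copy numbers so results
#' match their reported one-decimal scale deterministically.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Reverse complement
#'
#' Watson-Crick reverse complement; `N` maps to `N`.
#'
#' @param seq A `dna_seq` or nucleotide string.
#' @return Same type as the input (a `dna_seq` keeps its id with an `_rc`
#'   suffix).
#' @export
#' @examples
#' revcomp("TTTCATTTGA")
revcomp <- function(seq) {
  res <- as_residues(seq)
  rc <- chartr("ACGTN", "TGCAN", res)
  rc <- paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  if (inherits(seq, "dna_seq"))
    dna_seq(paste0(seq$id, "_rc"), rc, seq$description)
  else rc
}

#' Global alignment percent identity
#'
#' Needleman-Wunsch optimal global alignment under the scoring
#' match = +1, mismatch = -1, gap = -2, with a deterministic traceback
#' preference of diagonal, then up, then left. Identity is
#' `100 * matches / columns` where the denominator counts every alignment
#' column (gap columns count as non-matches) and `N` never matches,
#' rounded half-up to one decimal.
#'
#' @param a,b Sequences (`dna_seq` or strings); both non-empty.
#' @param match,mismatch,gap Scoring parameters.
#' @return A list of class `alignment_result`: `aligned_a`, `aligned_b`,
#'   `score`, `matches`, `columns`, `identity_pct`.
#' @export
#' @examples
#' global_align_identity("ACGT", "ACG")$identity_pct  # 75.0
global_align_identity <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  ra <- as_residues(a); rb <- as_residues(b)
  if (nchar(ra) == 0L || nchar(rb) == 0L)
    stop("global_align_identity: sequences must be non-empty")
  out <- .nw_align_cpp(ra, rb, as.integer(match), as.integer(mismatch),
                       as.integer(gap))
  out$identity_pct <- round_half_up(100 * out$matches / out$columns, 1)
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("global alignment: %d/%d identical columns (%.1f%%), score %d\n",
              x$matches, x$columns, x$identity_pct, x$score))
  invisible(x)
}

# Hamming identity of two equal-length gap-free strings, percent (not
# rounded). N counts as a mismatch.
hamming_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  100 * sum(ca == cb & ca != "N") / length(ca)
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a list of
#' [dna_seq()] records with residues normalized to upper case. A light
#' pre-check reports the line number of a malformed first record header.
#'
#' @param path Path to a FASTA file.
#' @return List of `dna_seq`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, n = 50L)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first_content) && !startsWith(trimws(lines[first_content]), ">"))
    stop("malformed FASTA: expected '>' header at line ", first_content,
         " of ", path)
  set <- Biostrings::readDNAStringSet(path)
  nm <- names(set)
  lapply(seq_along(set), function(i) {
    full <- nm[i]
    id <- sub("\\s.*$", "", full)
    desc <- if (grepl("\\s", full)) sub("^\\S+\\s+", "", full) else ""
    dna_seq(id, as.character(set[[i]]), desc)
  })
}

#' Write sequences to FASTA
#'
#' Writes a list of [dna_seq()] records, wrapped at 60 columns.
#'
#' @param seqs A `dna_seq` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(set) <- vapply(seqs, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write features to GFF3
#'
#' Features use 1-based inclusive coordinates. Input is a data frame with
#' columns `seqid, type, start, end, strand` plus any additional attribute
#' columns, which are serialized into column 9. Export goes through
#' [rtracklayer::export()].
#'
#' @param features Data frame of features.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path, source = "satjunction") {
  required <- c("seqid", "type", "start", "end", "strand")
  stopifnot(all(required %in% names(features)))
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- features$type
  extra <- setdiff(names(features), c(required, "source"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- features[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a feature data frame
#'
#' Inverse of [write_gff3()] for the columns the screen uses.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with `seqid, type, start, end, strand` and any
#'   attribute columns.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  for (col in setdiff(names(mc), c("type", "source", "score", "phase")))
    df[[col]] <- as.vector(mc[[col]])
  df
}
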