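# Mismatch-tolerant (Hamming) motif search on both strands.

#' Create a motif
#'
#' A named nucleotide pattern with a Hamming mismatch tolerance. Matching is
#' substitution-only (no indels), mirroring "maximum mismatch" motif searches.
#'
#' @param name Motif name.
#' @param pattern Pattern (`dna_seq` or string), length >= 4.
#' @param max_mismatch Maximum number of mismatches, `< nchar(pattern)`.
#' @return An object of class `motif`.
#' @export
#' @examples
#' motif("anchor", "TTTCATTTGA", 0)
motif <- function(name, pattern, max_mismatch = 0L) {
  pat <- as_residues(pattern)
  stopifnot(nchar(pat) >= 4L, max_mismatch < nchar(pat), max_mismatch >= 0L)
  structure(list(name = name, pattern = pat,
                 max_mismatch = as.integer(max_mismatch)),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif '%s': %s (<= %d mismatch)\n", x$name, x$pattern,
              x$max_mismatch))
  invisible(x)
}

# Mismatch count of pattern against every window of the text, vectorized over
# windows. N (in text or pattern) never matches. Returns integer vector of
# length n - m + 1 (or empty).
window_mismatches <- function(text_chars, pat_chars) {
  n <- length(text_chars); m <- length(pat_chars)
  nw <- n - m + 1L
  if (nw < 1L) return(integer(0))
  mis <- integer(nw)
  for (k in seq_len(m)) {
    tk <- text_chars[k:(k + nw - 1L)]
    mis <- mis + (tk != pat_chars[k] | tk == "N" | pat_chars[k] == "N")
  }
  mis
}

#' Scan a sequence for a motif
#'
#' Reports every window whose Hamming distance to the pattern (plus strand)
#' or to its reverse complement (minus strand) is at most `max_mismatch`.
#' Minus-strand hits are reported in plus-strand coordinates. Hits are sorted
#' by ascending start, plus strand before minus at equal start. A pattern
#' longer than the sequence yields an empty result.
#'
#' @param seq Sequence (`dna_seq` or string).
#' @param mot A [motif()].
#' @param strands One of `"+"`, `"-"`, `"both"`.
#' @return Data frame with columns `motif_name, seq_id, start, end, strand,
#'   mismatches` (1-based inclusive coordinates).
#' @export
#' @examples
#' scan_motif("GGTTTCATTTGACC", motif("anchor", "TTTCATTTGA", 0))
scan_motif <- function(seq, mot, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(mot, "motif"))
  chars <- seq_chars(seq)
  m <- nchar(mot$pattern)
  sid <- seq_id_of(seq)

  one_strand <- function(pattern, strand) {
    mis <- window_mismatches(chars, strsplit(pattern, "", fixed = TRUE)[[1]])
    keep <- which(mis <= mot$max_mismatch)
    if (length(keep) == 0L)
      return(data.frame(motif_name = character(0), seq_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0),
                        stringsAsFactors = FALSE))
    data.frame(motif_name = mot$name, seq_id = sid, start = keep,
               end = keep + m - 1L, strand = strand,
               mismatches = mis[keep], stringsAsFactors = FALSE)
  }

  out <- list()
  if (strands %in% c("both", "+")) out$plus <- one_strand(mot$pattern, "+")
  if (strands %in% c("both", "-")) out$minus <- one_strand(revcomp(mot$pattern), "-")
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Scan several sequences for several motifs
#'
#' @param seqs List of `dna_seq`.
#' @param motifs List of [motif()] objects.
#' @param strands Passed to [scan_motif()].
#' @return Combined hit data frame.
#' @export
scan_motifs <- function(seqs, motifs, strands = "both") {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  res <- do.call(rbind, unlist(lapply(seqs, function(s) {
    lapply(motifs, function(m) scan_motif(s, m, strands))
  }), recursive = FALSE))
  rownames(res) <- NULL
  res
}
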