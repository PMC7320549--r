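# Native tandem-array detector: finds arrays of short monomers, phases them,
# computes fractional copy number and a majority-rule consensus.
#
# Detection outline:
#   1. candidate periods are seeded from the recurrence spacing of exact
#      k-mers (default k = 10): a monomer of 20-60 bp retaining >= 80%
#      identity between neighbours shares exact 10-mers with high probability;
#   2. each seeded region is extended base-by-base in both directions with a
#      periodicity changepoint score (match at lag `period` scores +1,
#      mismatch -2, X-drop stop, argmax boundary) -- random background
#      drifts down at -1.25/bp while array interior climbs at ~+0.9/bp,
#      so the score maximum sits at the array boundary;
#   3. monomers are phased from the refined array start and a per-column
#      majority consensus is called.

#' Majority-rule consensus of phased monomers
#'
#' Per-column majority base over `A,C,G,T`; ties broken lexicographically
#' (`A < C < G < T`); `N` casts no vote. Deterministic.
#'
#' @param monomers Character vector or list of equal-length sequences.
#' @return Consensus string of the common monomer length.
#' @export
#' @examples
#' build_consensus(c("AAAC", "AAAG"))  # tie -> "AAAC"
build_consensus <- function(monomers) {
  if (is.list(monomers)) monomers <- vapply(monomers, as_residues, "")
  monomers <- toupper(monomers)
  stopifnot(length(monomers) >= 1L)
  lens <- nchar(monomers)
  if (length(unique(lens)) != 1L)
    stop("build_consensus: monomers must all have equal length (phased)")
  p <- lens[1]
  mat <- matrix(unlist(strsplit(monomers, "", fixed = TRUE)),
                nrow = length(monomers), ncol = p, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(p), function(j) {
    counts <- tabulate(match(mat[, j], bases), nbins = 4L)
    if (all(counts == 0L)) return("N")
    bases[which.max(counts)]
  }, "") |> paste(collapse = "")
}

# Exact k-mer recurrence spacings: for each position, the distance to the
# next occurrence of the same k-mer, restricted to `range`. Returns a data
# frame (pos, spacing).
kmer_spacings <- function(chars, k, range) {
  n <- length(chars)
  if (n < 2L * k) return(data.frame(pos = integer(0), spacing = integer(0)))
  s <- paste(chars, collapse = "")
  words <- substring(s, 1:(n - k + 1L), k:n)
  groups <- split(seq_along(words), words)
  groups <- groups[lengths(groups) > 1L]
  if (length(groups) == 0L)
    return(data.frame(pos = integer(0), spacing = integer(0)))
  pos <- unlist(lapply(groups, function(g) g[-length(g)]), use.names = FALSE)
  spc <- unlist(lapply(groups, function(g) diff(g)), use.names = FALSE)
  keep <- spc >= range[1] & spc <= range[2]
  data.frame(pos = pos[keep], spacing = spc[keep])
}

# X-drop argmax over a +1/-2 match score profile: walk the profile until the
# score drops `xdrop` below its running maximum, return the argmax position
# (0 if no positive prefix exists). Shared by the array-boundary and
# domain-extent estimators.
xdrop_run <- function(g, xdrop) {
  if (length(g) == 0L) return(0L)
  cum <- cumsum(g)
  drop <- cum - cummax(cum)
  stop_at <- which(drop <= -xdrop)[1]
  upto <- if (is.na(stop_at)) length(g) else stop_at
  best <- which.max(cum[seq_len(upto)])
  if (cum[best] <= 0) 0L else best
}

# Boundary extension over the lag-p match profile. `idx` is the ordered
# vector of positions to walk (away from the seed); g(i) = +1 if
# chars[i] == chars[i + p] else -2.
xdrop_steps <- function(chars, idx, p, xdrop) {
  if (length(idx) == 0L) return(0L)
  g <- ifelse(chars[idx] == chars[idx + p] & chars[idx] != "N", 1, -2)
  xdrop_run(g, xdrop)
}

#' Detect tandem arrays of short monomers
#'
#' Finds maximal non-overlapping arrays whose period lies in `period_range`,
#' phases full monomers from the array start, and reports a fractional copy
#' number `round(array_length / period, 1)` (the trailing partial monomer is
#' included through the length) together with a majority-rule consensus.
#'
#' @param seq Sequence (`dna_seq` or string).
#' @param period_range Numeric length-2: allowed monomer length in bp.
#' @param min_copies Minimum (fractional) copies for a reportable array.
#' @param max_monomer_divergence Maximum mean monomer-to-consensus divergence.
#' @param k Seed word size for period detection.
#' @param xdrop X-drop threshold of the boundary extension.
#' @return List of `tandem_array` objects with fields `seq_id, start, end,
#'   period, copy_number, monomers, partial_tail, consensus, strand`.
#' @export
detect_arrays <- function(seq, period_range = c(20, 60), min_copies = 3,
                          max_monomer_divergence = 0.25, k = 10L, xdrop = 12) {
  chars <- seq_chars(seq)
  n <- length(chars)
  sid <- seq_id_of(seq)
  empty <- list()
  if (n < min_copies * period_range[1]) return(empty)

  sp <- kmer_spacings(chars, k, period_range)
  if (nrow(sp) == 0L) return(empty)

  support <- table(sp$spacing)
  periods <- as.integer(names(support[support >= 3L]))
  candidates <- list()
  for (p in periods) {
    pos <- sort(sp$pos[sp$spacing == p])
    cluster_id <- cumsum(c(1L, diff(pos) > 2L * p))
    for (cl in split(pos, cluster_id)) {
      if (length(cl) < 3L || (max(cl) - min(cl)) < p) next
      i0 <- min(cl)
      # right boundary: walk i = i0 .. n - p, array end = last good i + p
      right_idx <- if (i0 <= n - p) i0:(n - p) else integer(0)
      nr <- xdrop_steps(chars, right_idx, p, xdrop)
      end <- if (nr > 0L) i0 + nr - 1L + p else min(i0 + p, n)
      # left boundary: walk i = i0 - 1 .. 1
      left_idx <- if (i0 > 1L) (i0 - 1L):1L else integer(0)
      nl <- xdrop_steps(chars, left_idx, p, xdrop)
      start <- i0 - nl
      start <- snap_start_to_anchor(chars, start, end, p)
      len <- end - start + 1L
      copies <- len / p
      if (copies < min_copies) next
      nfull <- floor(len / p)
      mono_starts <- start + (seq_len(nfull) - 1L) * p
      monomers <- vapply(mono_starts, function(s0)
        paste(chars[s0:(s0 + p - 1L)], collapse = ""), "")
      consensus <- build_consensus(monomers)
      mean_div <- mean(vapply(monomers, function(m)
        1 - hamming_identity(m, consensus) / 100, 0))
      if (mean_div > max_monomer_divergence) next
      arr <- structure(list(
        seq_id = sid, start = start, end = end, period = p,
        copy_number = round_half_up(len / p, 1),
        monomers = monomers, partial_tail = len - nfull * p,
        consensus = consensus,
        strand = consensus_strand(consensus)
      ), class = "tandem_array")
      candidates[[length(candidates) + 1L]] <- arr
    }
  }
  if (length(candidates) == 0L) return(empty)

  # overlap resolution: keep the longer array; at equal length the shorter
  # period (harmonics of a true period produce same-extent duplicates)
  lens <- vapply(candidates, function(a) a$end - a$start + 1L, 0L)
  pers <- vapply(candidates, function(a) a$period, 0L)
  ord <- order(-lens, pers)
  kept <- list()
  for (i in ord) {
    a <- candidates[[i]]
    clash <- any(vapply(kept, function(b)
      a$start <= b$end & b$start <= a$end, TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, function(a) a$start, 0L))]
}

# Phase correction: a one-base boundary slop (a background base that happens
# to extend the periodic pattern) would rotate the whole monomer frame. When
# the consensus carries the anchor motif, its rotation pins the true frame:
# shift the array start by the smallest (centred) rotation that puts the
# anchor at monomer position 1.
snap_start_to_anchor <- function(chars, start, end, p) {
  nfull <- (end - start + 1L) %/% p
  if (nfull < 1L) return(start)
  mono_starts <- start + (seq_len(nfull) - 1L) * p
  monomers <- vapply(mono_starts, function(s0)
    paste(chars[s0:(s0 + p - 1L)], collapse = ""), "")
  cons <- build_consensus(monomers)
  doubled <- paste0(cons, substr(cons, 1L, min(nchar(SAT_ANCHOR) - 1L, p)))
  hits <- scan_motif(doubled, motif("anchor", SAT_ANCHOR, 0L), "+")
  if (nrow(hits) == 0L)
    hits <- scan_motif(doubled, motif("anchor", SAT_ANCHOR, 1L), "+")
  if (nrow(hits) == 0L) return(start)
  r <- hits$start[1]
  shift <- ((r - 1L + p %/% 2L) %% p) - p %/% 2L
  max(1L, start + shift)
}

# Strand of an array from the orientation of the anchor motif within the
# (circularly doubled) consensus: plus if the anchor occurs forward, minus if
# only its reverse complement occurs, '+' otherwise.
consensus_strand <- function(consensus) {
  doubled <- paste0(consensus, substr(consensus, 1, min(9, nchar(consensus))))
  anchor <- screen_motifs()$anchor
  hits <- scan_motif(doubled, anchor, "both")
  if (nrow(hits) == 0L) return("+")
  if (any(hits$strand == "+")) "+" else "-"
}

#' @export
print.tandem_array <- function(x, ...) {
  cat(sprintf(
    "tandem array %s:%d-%d (%s): period %d bp, %.1f copies, tail %d bp\n",
    x$seq_id, x$start, x$end, x$strand, x$period, x$copy_number,
    x$partial_tail))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Tabulate detected arrays
#'
#' @param arrays List of `tandem_array` from [detect_arrays()].
#' @return Data frame: `seq_id, start, end, strand, period, copy_number,
#'   partial_tail, consensus`.
#' @export
arrays_to_df <- function(arrays) {
  if (length(arrays) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      period = integer(0), copy_number = numeric(0),
                      partial_tail = integer(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(arrays, function(a)
    data.frame(seq_id = a$seq_id, start = a$start, end = a$end,
               strand = a$strand, period = a$period,
               copy_number = a$copy_number, partial_tail = a$partial_tail,
               consensus = a$consensus, stringsAsFactors = FALSE)))
}
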