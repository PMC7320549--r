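# Classification of transposase fragments (tnp2A complete domains vs tnp2B
# deletion derivatives), derivative-array junction calls, and the
# per-sample screen report.

# X-drop extension of a contig region against the reference domain along a
# fixed diagonal `delta` (contig position = reference position + delta).
# Returns c(start, end) of the maximal contig extent, or NULL.
diagonal_extent <- function(chars, ref_chars, seed_pos, delta, xdrop = 40) {
  n <- length(chars); rl <- length(ref_chars)
  lo <- max(1L, delta + 1L)          # contig pos of ref position 1
  hi <- min(n, delta + rl)           # contig pos of ref position rl
  if (seed_pos < lo || seed_pos > hi) return(NULL)
  g_of <- function(idx) ifelse(chars[idx] == ref_chars[idx - delta] &
                                 chars[idx] != "N", 1, -2)
  right_idx <- seed_pos:hi
  nr <- xdrop_run(g_of(right_idx), xdrop)
  left_idx <- if (seed_pos > lo) (seed_pos - 1L):lo else integer(0)
  nl <- xdrop_run(g_of(left_idx), xdrop)
  if (nr == 0L && nl == 0L) return(NULL)
  c(seed_pos - nl, seed_pos + nr - 1L)
}

# Modal diagonal between a contig window and the reference from shared exact
# k-mers; returns list(delta, seed_pos) or NULL.
shared_kmer_diagonal <- function(chars, ref_chars, win_start, win_end,
                                 near = NULL, k = 12L) {
  win <- chars[win_start:win_end]
  if (length(win) < k || length(ref_chars) < k) return(NULL)
  wstr <- paste(win, collapse = "")
  rstr <- paste(ref_chars, collapse = "")
  wwords <- substring(wstr, 1:(nchar(wstr) - k + 1L), k:nchar(wstr))
  rwords <- substring(rstr, 1:(nchar(rstr) - k + 1L), k:nchar(rstr))
  ridx <- split(seq_along(rwords), rwords)
  shared <- which(wwords %in% names(ridx))
  if (length(shared) == 0L) return(NULL)
  pairs <- do.call(rbind, lapply(shared, function(i)
    cbind(cpos = win_start + i - 1L, rpos = ridx[[wwords[i]]])))
  deltas <- pairs[, "cpos"] - pairs[, "rpos"]
  modal <- as.integer(names(sort(table(deltas), decreasing = TRUE))[1])
  on_diag <- pairs[deltas == modal, , drop = FALSE]
  anchor <- if (is.null(near)) win_start else near
  seed_pos <- on_diag[which.min(abs(on_diag[, "cpos"] - anchor)), "cpos"]
  list(delta = modal, seed_pos = as.integer(seed_pos),
       seed_lo = as.integer(min(on_diag[, "cpos"])),
       seed_hi = as.integer(max(on_diag[, "cpos"])))
}

#' Classify transposase fragments as complete domains or deletion derivatives
#'
#' Anchors candidate regions on diagnostic motif hits and extends them
#' against the packaged reference domain. A `tnp2A` call requires a
#' `TATAACTTGCCTCCTT` hit (<= 1 mismatch) and no `GGCTGGGTTACC` hit
#' (<= 2 mismatches) within its extent; a `tnp2B` call is anchored on a
#' `GGCTGGGTTACC` hit with a maximal region aligning to the reference
#' domain's internal segment. Candidate regions shorter than `min_extent`
#' are discarded (this rejects chance motif hits in non-homologous
#' sequence).
#'
#' @param seq Sequence (`dna_seq` or string).
#' @param motif_hits Optional precomputed hit table from [scan_motifs()]
#'   with the packaged motifs on both strands; computed when `NULL`.
#' @param reference_domain Reference domain (`dna_seq`); defaults to the
#'   packaged one.
#' @param min_extent Minimum aligned extent (bp) for a reportable call.
#' @param fragment_length Nominal parental fragment length (bp), used to
#'   delimit a derivative's 3' end when the anchor motif follows its
#'   diagnostic motif.
#' @param xdrop X-drop threshold of the diagonal extension; the default
#'   tolerates the ~30 bp non-homologous block (diagnostic motif, spacer and
#'   anchor) characteristic of derivatives, whose worst-case crossing
#'   penalty is 60.
#' @return Data frame of calls: `kind, seq_id, start, end, strand, length,
#'   motif_start, motif_end, domain_identity_pct`.
#' @export
classify_tpase <- function(seq, motif_hits = NULL,
                           reference_domain = ref_tnp2_domain(),
                           min_extent = 60L, xdrop = 80,
                           fragment_length = 41L) {
  if (is.null(reference_domain))
    stop("configuration error: reference domain is required")
  motifs <- screen_motifs()
  if (is.null(motif_hits))
    motif_hits <- scan_motifs(seq, motifs[c("tnp2a", "tnp2b")], "both")
  chars_fwd <- seq_chars(seq)
  n <- length(chars_fwd)
  chars_rev <- rev(chartr("ACGTN", "TGCAN", chars_fwd))
  ref_chars <- seq_chars(reference_domain)
  motif_ref_start <- 159L
  sid <- seq_id_of(seq)

  empty <- data.frame(kind = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      motif_start = integer(0), motif_end = integer(0),
                      domain_identity_pct = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(motif_hits) || nrow(motif_hits) == 0L) return(empty)
  motif_hits <- motif_hits[motif_hits$seq_id == sid, , drop = FALSE]
  if (nrow(motif_hits) == 0L) return(empty)

  calls <- list()
  add_call <- function(kind, ws, we, strand, ms, me, ident) {
    # map working (strand-oriented) coords back to plus-strand coords
    if (strand == "-") {
      tmp <- ws; ws <- n - we + 1L; we <- n - tmp + 1L
      tmp <- ms; ms <- n - me + 1L; me <- n - tmp + 1L
    }
    calls[[length(calls) + 1L]] <<- data.frame(
      kind = kind, seq_id = sid, start = ws, end = we, strand = strand,
      length = we - ws + 1L, motif_start = ms, motif_end = me,
      domain_identity_pct = ident, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(motif_hits))) {
    hit <- motif_hits[i, ]
    strand <- hit$strand
    chars <- if (strand == "+") chars_fwd else chars_rev
    # hit position in the working (strand-oriented) frame
    hs <- if (strand == "+") hit$start else n - hit$end + 1L
    he <- if (strand == "+") hit$end else n - hit$start + 1L

    if (hit$motif_name == "tnp2A") {
      delta <- hs - motif_ref_start
      ext <- diagonal_extent(chars, ref_chars, hs, delta, xdrop)
      if (is.null(ext) || ext[2] - ext[1] + 1L < min_extent) next
      # a derivative motif inside the extent vetoes the complete-domain call
      ps <- if (strand == "+") ext else c(n - ext[2] + 1L, n - ext[1] + 1L)
      veto <- any(motif_hits$motif_name == "tnp2B" &
                    motif_hits$strand == strand &
                    motif_hits$start <= ps[2] & motif_hits$end >= ps[1])
      if (veto) next
      ident <- domain_identity(chars, ref_chars, ext, delta)
      add_call("tnp2A", ext[1], ext[2], strand, hs, he, ident)
    } else if (hit$motif_name == "tnp2B") {
      ws <- max(1L, hs - 650L); we <- min(n, he + 650L)
      diag <- shared_kmer_diagonal(chars, ref_chars, ws, we, near = hs)
      if (is.null(diag)) next
      # the derivative's homologous segments can be separated by planted or
      # diverged blocks: extend from the outermost seeds on the modal
      # diagonal and take the union
      ext_lo <- diagonal_extent(chars, ref_chars, diag$seed_lo, diag$delta,
                                xdrop)
      ext_hi <- diagonal_extent(chars, ref_chars, diag$seed_hi, diag$delta,
                                xdrop)
      exts <- Filter(Negate(is.null), list(ext_lo, ext_hi))
      if (length(exts) == 0L) next
      ext <- c(min(vapply(exts, `[`, 0L, 1L)),
               max(vapply(exts, `[`, 0L, 2L)))
      # a derivative ends with its parental fragment: when the anchor motif
      # follows the diagnostic motif, the 3' end of the call is the
      # fragment end (the alignment extent alone cannot see past the
      # non-homologous diagnostic block when no seed lands in the short
      # fragment tail)
      look_end <- min(n, he + 80L)
      if (he + 1L <= look_end) {
        region <- paste(chars[(he + 1L):look_end], collapse = "")
        ah <- scan_motif(region, motif("anchor", SAT_ANCHOR, 1L), "+")
        if (nrow(ah) > 0L) {
          fs <- he + ah$start[1]
          ext[2] <- min(n, fs + fragment_length - 1L)
        }
      }
      if (ext[2] - ext[1] + 1L < min_extent) next
      # the anchoring motif must sit in or immediately before the extent
      if (he < ext[1] - 30L || hs > ext[2] + 30L) next
      ext[1] <- min(ext[1], hs)
      ident <- domain_identity(chars, ref_chars, ext, diag$delta)
      add_call("tnp2B", ext[1], ext[2], strand, hs, he, ident)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- out[!duplicated(out[, c("kind", "start", "end", "strand")]), ,
             drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

domain_identity <- function(chars, ref_chars, ext, delta) {
  rs <- max(1L, ext[1] - delta); re <- min(length(ref_chars), ext[2] - delta)
  if (ext[2] - ext[1] + 1L < 60L || re <= rs) return(NA_real_)
  a <- paste(chars[ext[1]:ext[2]], collapse = "")
  b <- paste(ref_chars[rs:re], collapse = "")
  global_align_identity(a, b)$identity_pct
}

# Re-derive an array's monomers/consensus in the reverse-complement frame:
# phase from the (rc-frame) array start.
rephase_array_rc <- function(chars_fwd, arr) {
  n <- length(chars_fwd)
  chars_rc <- rev(chartr("ACGTN", "TGCAN", chars_fwd))
  p <- arr$period
  start <- n - arr$end + 1L
  end <- n - arr$start + 1L
  start <- snap_start_to_anchor(chars_rc, start, end, p)
  len <- end - start + 1L
  nfull <- floor(len / p)
  mono_starts <- start + (seq_len(nfull) - 1L) * p
  monomers <- vapply(mono_starts, function(s0)
    paste(chars_rc[s0:(s0 + p - 1L)], collapse = ""), "")
  list(start = start, end = end,
       monomers = monomers, consensus = build_consensus(monomers),
       period = p, copy_number = round_half_up(len / p, 1))
}

#' Find derivative-array junctions
#'
#' For every `tnp2B` call, locates the anchor motif marking the parental
#' fragment start (downstream of the diagnostic motif, within the call's
#' extent), then emits a junction call iff an array of the same orientation
#' starts within `[fragment_end - period, fragment_end + max_gap]` and the
#' array's first monomer aligns to the parental fragment at >=
#' `min_start_monomer_identity_pct` percent identity. The reported
#' fragment-to-consensus identity compares the fragment's first
#' period bp (the part that is simultaneously the start monomer) with the
#' array consensus by global alignment.
#'
#' @param seqs List of `dna_seq` (or a single one).
#' @param tpase_hits Call table from [classify_tpase()].
#' @param arrays List of arrays from [detect_arrays()].
#' @param max_gap Maximum gap (bp) between fragment end and array start.
#' @param min_start_monomer_identity_pct Minimum identity between the
#'   array's first monomer and the parental fragment.
#' @param fragment_length Nominal parental fragment length (bp).
#' @param anchor_max_mismatch Mismatch tolerance when locating the anchor.
#' @return List of `junction_call` objects with fields `seq_id, tpase,
#'   fragment_start, fragment_end, strand, array_start, array_end, period,
#'   copy_number, consensus, same_orientation,
#'   fragment_consensus_identity_pct, start_monomer_identity_pct,
#'   start_monomer_is_fragment`.
#' @export
find_junctions <- function(seqs, tpase_hits, arrays, max_gap = 10L,
                           min_start_monomer_identity_pct = 80,
                           fragment_length = 41L, anchor_max_mismatch = 1L) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  names(seqs) <- vapply(seqs, function(s) s$id, "")
  anchor <- motif("anchor", SAT_ANCHOR, anchor_max_mismatch)
  out <- list()
  if (is.null(tpase_hits) || nrow(tpase_hits) == 0L) return(out)
  tb <- tpase_hits[tpase_hits$kind == "tnp2B", , drop = FALSE]
  for (i in seq_len(nrow(tb))) {
    hit <- tb[i, ]
    seq <- seqs[[hit$seq_id]]
    if (is.null(seq)) next
    chars_fwd <- seq_chars(seq)
    n <- length(chars_fwd)
    minus <- hit$strand == "-"
    # working frame: the strand the derivative is encoded on
    chars <- if (minus) rev(chartr("ACGTN", "TGCAN", chars_fwd)) else chars_fwd
    hs <- if (minus) n - hit$end + 1L else hit$start
    he <- if (minus) n - hit$start + 1L else hit$end
    ms <- if (minus) n - hit$motif_end + 1L else hit$motif_start
    me <- if (minus) n - hit$motif_start + 1L else hit$motif_end

    # anchor marking the fragment start, downstream of the diagnostic motif
    region_end <- min(n, he + 2L)
    if (me + 1L > region_end) next
    region <- paste(chars[(me + 1L):region_end], collapse = "")
    ahits <- scan_motif(region, anchor, "+")
    if (nrow(ahits) == 0L) next
    fs <- me + ahits$start[nrow(ahits)]

    # candidate arrays in the working frame, same orientation
    want_strand <- if (minus) "-" else "+"
    cands <- list()
    for (arr in arrays) {
      if (arr$seq_id != hit$seq_id || arr$strand != want_strand) next
      a <- if (minus) rephase_array_rc(chars_fwd, arr)
      else arr[c("start", "end", "monomers", "consensus", "period",
                 "copy_number")]
      fe <- min(fs + fragment_length - 1L, max(he, a$start - 1L))
      if (a$start >= fe - a$period && a$start <= fe + max_gap)
        cands[[length(cands) + 1L]] <- c(a, list(fragment_end = fe))
    }
    if (length(cands) == 0L) next
    dist <- vapply(cands, function(a) abs(a$start - a$fragment_end - 1L), 0)
    len <- vapply(cands, function(a) a$end - a$start + 1L, 0)
    best <- cands[[order(dist, -len)[1]]]
    fe <- best$fragment_end
    # the junction pins the derivative's 3' end at the fragment end, which
    # is more precise than the alignment-extent estimate
    if (minus) hit$start <- n - fe + 1L else hit$end <- fe
    hit$length <- hit$end - hit$start + 1L
    frag_seq <- paste(chars[fs:fe], collapse = "")
    mono1 <- best$monomers[1]
    sm_ident <- global_align_identity(mono1, frag_seq)$identity_pct
    if (sm_ident < min_start_monomer_identity_pct) next
    frag_prefix <- substr(frag_seq, 1L, min(nchar(frag_seq), best$period))
    fc_ident <- global_align_identity(frag_prefix, best$consensus)$identity_pct

    # report fragment coordinates in the plus-strand frame
    pfs <- if (minus) n - fe + 1L else fs
    pfe <- if (minus) n - fs + 1L else fe
    out[[length(out) + 1L]] <- structure(list(
      seq_id = hit$seq_id, tpase = hit,
      fragment_start = pfs, fragment_end = pfe,
      fragment_length = fe - fs + 1L, strand = want_strand,
      array_start = if (minus) n - best$end + 1L else best$start,
      array_end = if (minus) n - best$start + 1L else best$end,
      period = best$period, copy_number = best$copy_number,
      consensus = best$consensus, fragment_residues = frag_seq,
      same_orientation = TRUE,
      fragment_consensus_identity_pct = fc_ident,
      start_monomer_identity_pct = sm_ident,
      start_monomer_is_fragment =
        sm_ident >= min_start_monomer_identity_pct
    ), class = "junction_call")
  }
  out
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf(
    "junction %s:%d-%d (%s): tnp2B %d bp + array %.1f x %d bp, identity %.1f%%\n",
    x$seq_id, x$fragment_start, x$array_end, x$strand, x$tpase$length,
    x$copy_number, x$period, x$fragment_consensus_identity_pct))
  invisible(x)
}

#' Screen a set of contigs for derivative-array junctions
#'
#' Runs motif scanning, array detection, transposase classification and
#' junction finding per contig, and aggregates a per-sample report (one row
#' per junction; a presence-only row when derivatives occur without a
#' junction; a negative row otherwise).
#'
#' @param contigs List of `dna_seq` (or a single one).
#' @param sample_id Sample label for the report.
#' @param period_range,min_copies,max_monomer_divergence Passed to
#'   [detect_arrays()].
#' @param max_gap,min_start_monomer_identity_pct,fragment_length Passed to
#'   [find_junctions()].
#' @return List of class `screen_result`: `report` (data frame with columns
#'   `sample, tnp2b_present, tnp2b_with_array, contig, tnp2b_length,
#'   array_copy_number, identity_pct`), `tpase_hits`, `arrays`, `junctions`.
#' @export
screen_genome <- function(contigs, sample_id = "sample",
                          period_range = c(20, 60), min_copies = 3,
                          max_monomer_divergence = 0.25, max_gap = 10L,
                          min_start_monomer_identity_pct = 80,
                          fragment_length = 41L) {
  if (inherits(contigs, "dna_seq")) contigs <- list(contigs)
  all_hits <- list(); all_arrays <- list(); all_junctions <- list()
  for (contig in contigs) {
    hits <- classify_tpase(contig)
    arrays <- detect_arrays(contig, period_range = period_range,
                            min_copies = min_copies,
                            max_monomer_divergence = max_monomer_divergence)
    junctions <- find_junctions(contig, hits, arrays, max_gap = max_gap,
                                min_start_monomer_identity_pct =
                                  min_start_monomer_identity_pct,
                                fragment_length = fragment_length)
    all_hits[[length(all_hits) + 1L]] <- hits
    all_arrays <- c(all_arrays, arrays)
    all_junctions <- c(all_junctions, junctions)
  }
  tpase_hits <- do.call(rbind, all_hits)
  if (is.null(tpase_hits)) tpase_hits <- classify_tpase("ACGTACGT")[0, ]

  rows <- list()
  for (j in all_junctions) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample_id, tnp2b_present = TRUE, tnp2b_with_array = TRUE,
      contig = j$seq_id, tnp2b_length = j$tpase$length,
      array_copy_number = j$copy_number,
      identity_pct = j$fragment_consensus_identity_pct,
      stringsAsFactors = FALSE)
  }
  tb <- tpase_hits[tpase_hits$kind == "tnp2B", , drop = FALSE]
  if (length(rows) == 0L && nrow(tb) > 0L) {
    rows[[1L]] <- data.frame(
      sample = sample_id, tnp2b_present = TRUE, tnp2b_with_array = FALSE,
      contig = tb$seq_id[1], tnp2b_length = tb$length[1],
      array_copy_number = NA_real_, identity_pct = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    rows[[1L]] <- data.frame(
      sample = sample_id, tnp2b_present = FALSE, tnp2b_with_array = FALSE,
      contig = NA_character_, tnp2b_length = NA_integer_,
      array_copy_number = NA_real_, identity_pct = NA_real_,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, tpase_hits = tpase_hits,
                 arrays = all_arrays, junctions = all_junctions),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen result:", nrow(x$report), "report row(s),",
      length(x$junctions), "junction(s),", length(x$arrays), "array(s)\n")
  print(x$report)
  invisible(x)
}
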