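# Anchored monomer alignment, p-distance matrix, neighbor-joining tree and
# position frequency matrix (sequence-logo data).

#' Anchor-align monomers and parental fragments
#'
#' Aligns near-equal-length sequences by the conserved anchor motif: each
#' sequence is left-padded with gaps so the anchor starts fall in the same
#' column, then right-padded to uniform length. No internal gaps are
#' introduced. Sequences lacking the anchor (at the motif's mismatch
#' tolerance) are excluded and listed in the `rejects` attribute.
#'
#' @param seqs List of `dna_seq` (or character vector, optionally named).
#' @param anchor A [motif()]; defaults to the satellite anchor at <= 1
#'   mismatch.
#' @return Named character vector of equal-length gapped strings, with
#'   attribute `rejects` (names of excluded inputs).
#' @export
anchor_align <- function(seqs, anchor = motif("anchor", SAT_ANCHOR, 1L)) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  if (is.character(seqs)) seqs <- as.list(seqs)
  nms <- names(seqs)
  if (is.null(nms)) nms <- rep("", length(seqs))
  ids <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (inherits(s, "dna_seq")) s$id
    else if (nzchar(nms[i])) nms[i]
    else paste0("seq", i)
  }, "")
  res <- vapply(seqs, as_residues, "")
  offsets <- vapply(res, function(r) {
    hits <- scan_motif(r, anchor, "+")
    if (nrow(hits) == 0L) NA_integer_ else hits$start[1]
  }, 0L)
  rejects <- ids[is.na(offsets)]
  keep <- !is.na(offsets)
  res <- res[keep]; ids <- ids[keep]; offsets <- offsets[keep]
  if (length(res) == 0L) {
    out <- character(0)
    attr(out, "rejects") <- rejects
    return(out)
  }
  lead <- max(offsets) - offsets
  padded <- paste0(strrep("-", lead), res)
  width <- max(nchar(padded))
  padded <- paste0(padded, strrep("-", width - nchar(padded)))
  names(padded) <- ids
  attr(padded, "rejects") <- rejects
  padded
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d[i, j]` is the proportion of differing sites over columns where neither
#' sequence has a gap. Columns with a gap in either sequence are ignored for
#' that pair. p-distances may violate the triangle inequality; none is
#' asserted.
#'
#' @param alignment Named character vector of equal-length gapped strings.
#' @return Symmetric numeric matrix with zero diagonal, labelled by the
#'   alignment names.
#' @export
p_distance_matrix <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2L, length(unique(nchar(alignment))) == 1L)
  labels <- names(alignment)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  mat <- matrix(unlist(strsplit(alignment, "", fixed = TRUE)),
                nrow = n, byrow = TRUE)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok))
      stop("undefined distance: no comparable columns for pair ",
           labels[i], " / ", labels[j])
    d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Q-matrix criterion, standard branch-length
#' formulas), the greedy heuristic for the minimum-evolution criterion.
#' Ties in the Q matrix are broken deterministically by the
#' lexicographically smallest label pair. Negative branch lengths are
#' clamped to zero.
#'
#' @param d Symmetric distance matrix with labels (n >= 3).
#' @return An [ape] `phylo` object (unrooted); its Newick serialization is
#'   available via `ape::write.tree`.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (max(abs(d - t(d))) > 1e-8)
    stop("nj_tree: distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  # node bookkeeping: each active cluster holds its Newick fragment
  frags <- labels
  active <- seq_len(nrow(d))
  D <- d
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (length(active) > 3L) {
    r <- length(active)
    Dr <- D[active, active]
    R <- rowSums(Dr)
    Q <- (r - 2) * Dr - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_labels <- apply(cand, 1, function(ij)
      paste(sort(c(frags[active[ij[1]]], frags[active[ij[2]]])),
            collapse = "\r"))
    pick <- cand[order(pair_labels)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dr[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[ai], fmt(li),
                        frags[aj], fmt(lj))
    # distances of the new node to the remaining clusters
    rest <- active[-c(i, j)]
    dnew <- (D[ai, rest] + D[aj, rest] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    newidx <- nrow(D)
    D[newidx, rest] <- dnew
    D[rest, newidx] <- dnew
    frags <- c(frags, new_frag)
    active <- c(rest, newidx)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[a], fmt(la),
                    frags[b], fmt(lb), frags[c3], fmt(lc))
  ape::read.tree(text = newick)
}

#' Position frequency matrix of an alignment
#'
#' Column-wise base frequencies among non-gap symbols, the gap fraction per
#' column, and the information content `2 - H` (Shannon entropy in bits)
#' used for sequence-logo rendering.
#'
#' @param alignment Character vector of equal-length gapped strings.
#' @return Data frame with columns `column, A, C, G, T, gap_fraction,
#'   ic_bits`.
#' @export
pfm <- function(alignment) {
  stopifnot(length(alignment) >= 1L,
            length(unique(nchar(alignment))) == 1L)
  n <- length(alignment)
  width <- nchar(alignment[1])
  mat <- matrix(unlist(strsplit(alignment, "", fixed = TRUE)),
                nrow = n, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(width), function(j) {
    col <- mat[, j]
    counts <- tabulate(match(col, bases), nbins = 4L)
    nongap <- sum(counts)
    freqs <- if (nongap > 0) counts / nongap else rep(0, 4)
    pos <- freqs[freqs > 0]
    ic <- if (nongap > 0) 2 + sum(pos * log2(pos)) else 0
    data.frame(column = j, A = freqs[1], C = freqs[2], G = freqs[3],
               T = freqs[4], gap_fraction = mean(col == "-"),
               ic_bits = ic)
  })
  do.call(rbind, rows)
}
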