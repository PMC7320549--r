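# Self-comparison of ultralong reads: exact word-match map and detection of
# tandem regions as stacks of parallel diagonals, with period and copy
# estimation.

#' Self word-match map of a read
#'
#' All pairs of positions `(i, j)`, `i < j`, carrying identical exact words
#' of `word_size` bp (the trivial `i = j` diagonal is excluded). Built via a
#' word-position index.
#'
#' @param read Sequence (`dna_seq` or string), at least `2 * word_size` bp.
#' @param word_size Word length in bp.
#' @param step Sampling step between word start positions.
#' @return List of class `self_match_map`: `read_id`, `word_size`,
#'   `matches` (data frame `i`, `j`), `read_length`.
#' @export
self_match_map <- function(read, word_size = 12L, step = 1L) {
  res <- as_residues(read)
  n <- nchar(res)
  stopifnot(n >= 2L * word_size)
  starts <- seq.int(1L, n - word_size + 1L, by = step)
  words <- substring(res, starts, starts + word_size - 1L)
  groups <- split(starts, words)
  groups <- groups[lengths(groups) > 1L]
  if (length(groups) == 0L) {
    matches <- data.frame(i = integer(0), j = integer(0))
  } else {
    pairs <- lapply(groups, function(g) {
      cmb <- combn(sort(g), 2L)
      data.frame(i = cmb[1, ], j = cmb[2, ])
    })
    matches <- do.call(rbind, pairs)
    matches <- matches[order(matches$i, matches$j), , drop = FALSE]
    rownames(matches) <- NULL
  }
  structure(list(read_id = seq_id_of(read, "read"), word_size = word_size,
                 matches = matches, read_length = n),
            class = "self_match_map")
}

#' @export
print.self_match_map <- function(x, ...) {
  cat(sprintf("self match map of %s (%d bp): %d word pairs (word %d)\n",
              x$read_id, x$read_length, nrow(x$matches), x$word_size))
  invisible(x)
}

#' Detect tandem regions from a self-match map
#'
#' Clusters word matches by offset `j - i`; offsets whose collinear matches
#' span at least `min_span` bp form diagonals. Overlapping stacks of at
#' least `min_diagonals` diagonals at near-multiples (within 10%) of a base
#' spacing define a tandem region; the period estimate is the modal spacing
#' between neighbouring diagonals and the copy estimate is the region
#' length divided by the period.
#'
#' @param map A [self_match_map()].
#' @param min_diagonals Minimum number of parallel diagonals.
#' @param min_span Minimum i-span (bp) for a diagonal to count.
#' @return List of `dotplot_tandem_region` objects: `read_id, start, end,
#'   period_estimate, copy_estimate, diagonal_count`.
#' @export
detect_tandem_regions <- function(map, min_diagonals = 3L, min_span = 200L) {
  stopifnot(inherits(map, "self_match_map"))
  m <- map$matches
  if (nrow(m) == 0L) return(list())
  w <- map$word_size
  offs <- m$j - m$i
  diag_stats <- lapply(split(seq_len(nrow(m)), offs), function(idx) {
    ii <- sort(m$i[idx])
    # collinear run extraction: an isolated chance word pair far from the
    # dense core must not stretch the diagonal, so keep the longest run of
    # matches separated by at most min_span
    run_id <- cumsum(c(1L, diff(ii) > min_span))
    runs <- split(ii, run_id)
    spans <- vapply(runs, function(r) max(r) - min(r), 0)
    core <- runs[[which.max(spans)]]
    list(offset = m$j[idx][1] - m$i[idx][1], imin = min(core),
         imax = max(core), count = length(core))
  })
  spans <- vapply(diag_stats, function(d) d$imax - d$imin + w, 0)
  counts <- vapply(diag_stats, function(d) d$count, 0)
  # a real diagonal is densely supported along its span; chance word pairs
  # are isolated, so a sparse far-apart pair must not count as a diagonal
  good <- diag_stats[spans >= min_span & counts >= pmax(10, 0.1 * spans)]
  if (length(good) < min_diagonals) return(list())

  # cluster diagonals whose i-ranges overlap (merged intervals)
  ord <- order(vapply(good, function(d) d$imin, 0))
  good <- good[ord]
  clusters <- list(); current <- list(good[[1]])
  cur_end <- good[[1]]$imax
  for (d in good[-1]) {
    if (d$imin <= cur_end + w) {
      current[[length(current) + 1L]] <- d
      cur_end <- max(cur_end, d$imax)
    } else {
      clusters[[length(clusters) + 1L]] <- current
      current <- list(d); cur_end <- d$imax
    }
  }
  clusters[[length(clusters) + 1L]] <- current

  regions <- list()
  for (cl in clusters) {
    if (length(cl) < min_diagonals) next
    offsets <- sort(vapply(cl, function(d) d$offset, 0))
    base <- min(offsets)
    gaps <- diff(offsets)
    if (length(gaps) > 0) {
      tb <- table(gaps[gaps > 0])
      if (length(tb) > 0) base <- as.numeric(names(sort(tb, decreasing = TRUE))[1])
    }
    # diagonals must sit at near-multiples of the base spacing
    mult_ok <- abs(offsets / base - round(offsets / base)) <= 0.1
    if (sum(mult_ok) < min_diagonals) next
    keep <- cl[mult_ok]
    start <- min(vapply(keep, function(d) d$imin, 0))
    end <- max(vapply(keep, function(d) d$imax + d$offset + w - 1L, 0))
    len <- end - start + 1
    regions[[length(regions) + 1L]] <- structure(list(
      read_id = map$read_id, start = as.integer(start), end = as.integer(end),
      period_estimate = as.integer(round(base)),
      copy_estimate = round_half_up(len / base, 1),
      diagonal_count = length(keep)
    ), class = "dotplot_tandem_region")
  }
  regions[order(vapply(regions, function(r) r$start, 0L))]
}

#' @export
print.dotplot_tandem_region <- function(x, ...) {
  cat(sprintf(
    "tandem region %s:%d-%d: period ~%d bp, ~%.1f copies (%d diagonals)\n",
    x$read_id, x$start, x$end, x$period_estimate, x$copy_estimate,
    x$diagonal_count))
  invisible(x)
}

#' Tabulate dot-plot tandem regions
#'
#' @param regions List from [detect_tandem_regions()].
#' @return Data frame.
#' @export
regions_to_df <- function(regions) {
  if (length(regions) == 0L)
    return(data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), period_estimate = integer(0),
                      copy_estimate = numeric(0), diagonal_count = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(regions, function(r)
    data.frame(read_id = r$read_id, start = r$start, end = r$end,
               period_estimate = r$period_estimate,
               copy_estimate = r$copy_estimate,
               diagonal_count = r$diagonal_count, stringsAsFactors = FALSE)))
}
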