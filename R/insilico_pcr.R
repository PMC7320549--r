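# Amplicon prediction for outward-facing primer pairs, plus array-specific
# reverse-primer design with a specificity check.

#' Create a primer
#'
#' A primer anneals if it matches its template site with at most
#' `max_mismatch` mismatches and no mismatch within the 3'-terminal
#' `three_prime_exact` bases (an approximation of the primer-extension
#' requirement).
#'
#' @param name Primer name.
#' @param residues Primer sequence (5' to 3'), length >= 15.
#' @param max_mismatch Maximum total mismatches.
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly.
#' @return An object of class `primer`.
#' @export
primer <- function(name, residues, max_mismatch = 1L, three_prime_exact = 5L) {
  res <- as_residues(residues)
  stopifnot(nchar(res) >= 15L, three_prime_exact <= nchar(res))
  structure(list(name = name, residues = res,
                 max_mismatch = as.integer(max_mismatch),
                 three_prime_exact = as.integer(three_prime_exact)),
            class = "primer")
}

# Annealing sites of a primer on the plus strand of the template.
# For `orientation = "fwd"` the primer sequence itself is matched and its 3'
# end is the rightmost site base; for "rev" the reverse complement of the
# primer is matched and the 3' end corresponds to the leftmost site base.
# Returns data frame (start, end, mismatches).
primer_sites <- function(template_chars, pr, orientation = c("fwd", "rev")) {
  orientation <- match.arg(orientation)
  pat <- if (orientation == "fwd") pr$residues else revcomp(pr$residues)
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  m <- length(pc)
  n <- length(template_chars)
  nw <- n - m + 1L
  if (nw < 1L)
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  total <- integer(nw); three <- integer(nw)
  tp_cols <- if (orientation == "fwd") (m - pr$three_prime_exact + 1L):m
  else seq_len(pr$three_prime_exact)
  for (k in seq_len(m)) {
    tk <- template_chars[k:(k + nw - 1L)]
    mis <- (tk != pc[k] | tk == "N" | pc[k] == "N")
    total <- total + mis
    if (k %in% tp_cols) three <- three + mis
  }
  keep <- which(total <= pr$max_mismatch & three == 0L)
  data.frame(start = keep, end = keep + m - 1L, mismatches = total[keep])
}

#' Predict amplicons for a primer pair
#'
#' The forward primer is matched on the plus strand; the reverse primer is
#' matched as its reverse complement downstream. All products up to
#' `max_product` bp are reported, sorted by length ascending; the shortest
#' is the headline value for a satellite template, which typically yields a
#' ladder.
#'
#' @param template Sequence (`dna_seq` or string).
#' @param fwd,rev [primer()] objects.
#' @param max_product Maximum product length (bp).
#' @return Data frame: `template_id, fwd_start, fwd_end, rev_start,
#'   rev_end, product_length, fwd_mismatches, rev_mismatches`.
#' @export
find_amplicons <- function(template, fwd, rev, max_product = 5000L) {
  stopifnot(inherits(fwd, "primer"), inherits(rev, "primer"))
  chars <- seq_chars(template)
  tid <- seq_id_of(template, "template")
  f <- primer_sites(chars, fwd, "fwd")
  r <- primer_sites(chars, rev, "rev")
  empty <- data.frame(template_id = character(0), fwd_start = integer(0),
                      fwd_end = integer(0), rev_start = integer(0),
                      rev_end = integer(0), product_length = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(f) == 0L || nrow(r) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    if (f$end[i] >= r$start[j]) next
    len <- r$end[j] - f$start[i] + 1L
    if (len > max_product) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = tid, fwd_start = f$start[i], fwd_end = f$end[i],
      rev_start = r$start[j], rev_end = r$end[j], product_length = len,
      fwd_mismatches = f$mismatches[i], rev_mismatches = r$mismatches[j],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$product_length, res$fwd_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Design an array-specific reverse primer for junction validation
#'
#' Emulates the design of the outward-facing validation pair: given the
#' forward (derivative-specific) primer site, chooses a reverse primer from
#' the template so the amplified junction fragment is approximately
#' `target_product` bp. On a near-homogeneous satellite template a primer
#' drawn from the consensus would anneal to every monomer, so candidates
#' are verified for specificity by running [find_amplicons()] and accepted
#' only if the shortest predicted product is the intended one (candidates
#' whose 3' terminus sits on a monomer-variant position pass this check,
#' as in allele-specific primer placement).
#'
#' @param template Sequence (`dna_seq` or string).
#' @param fwd Forward [primer()] (must have a site on the template).
#' @param target_product Intended product length (bp).
#' @param primer_length Reverse primer length (bp).
#' @param search Maximum deviation (bp) from the target length explored.
#' @param max_mismatch,three_prime_exact Passed to the designed [primer()].
#' @return A [primer()] named `"rev_designed"`, with attribute
#'   `intended_product`.
#' @export
design_reverse_primer <- function(template, fwd, target_product = 400L,
                                  primer_length = 21L, search = 50L,
                                  max_mismatch = 1L, three_prime_exact = 5L) {
  chars <- seq_chars(template)
  n <- length(chars)
  fsites <- primer_sites(chars, fwd, "fwd")
  if (nrow(fsites) == 0L)
    stop("design error: forward primer has no site on the template")
  f0 <- fsites$start[1]
  make_candidate <- function(delta) {
    end_pos <- f0 + target_product + delta - 1L
    start_pos <- end_pos - primer_length + 1L
    if (start_pos <= fsites$end[1] || end_pos > n) return(NULL)
    site <- paste(chars[start_pos:end_pos], collapse = "")
    pr <- primer("rev_designed", revcomp(site), max_mismatch = max_mismatch,
                 three_prime_exact = three_prime_exact)
    attr(pr, "intended_product") <- end_pos - f0 + 1L
    pr
  }
  deltas <- order(abs(seq(-search, search)))  # 0, -1, 1, -2, 2, ...
  deltas <- seq(-search, search)[deltas]
  fallback <- NULL
  for (delta in deltas) {
    pr <- make_candidate(delta)
    if (is.null(pr)) next
    if (is.null(fallback)) fallback <- pr
    amps <- find_amplicons(template, fwd, pr)
    if (nrow(amps) > 0L &&
        amps$product_length[1] == attr(pr, "intended_product"))
      return(pr)
  }
  if (is.null(fallback))
    stop("design error: no reverse primer site available near the target")
  fallback
}

#' The published outward-facing forward primer
#'
#' The derivative-specific forward primer: the diagnostic 12-mer followed by
#' the 8 bp immediately upstream of the parental fragment.
#'
#' @param ... Overrides passed to [primer()].
#' @return A [primer()].
#' @export
tnp2b_forward_primer <- function(...) {
  primer("tnp2B_fwd", paste0(TNP2B_MOTIF, "GACTTACA"), ...)
}
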