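# Independent oracles and small fixture builders used across the suite.

# Uniform random DNA string (no GC skew; tests control the RNG).
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Brute-force all-windows Hamming scanner (per-window loop; independent of
# the package's vectorized implementation).
brute_hamming_scan <- function(seq, pattern, max_mm, strands = "both") {
  sc <- strsplit(toupper(seq), "")[[1]]
  one <- function(pat, strand) {
    pc <- strsplit(pat, "")[[1]]
    m <- length(pc)
    hits <- NULL
    if (length(sc) >= m) {
      for (i in 1:(length(sc) - m + 1)) {
        win <- sc[i:(i + m - 1)]
        mm <- sum(win != pc | win == "N" | pc == "N")
        if (mm <= max_mm)
          hits <- rbind(hits, data.frame(start = i, end = i + m - 1,
                                         strand = strand, mismatches = mm))
      }
    }
    hits
  }
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                          collapse = "")
  out <- NULL
  if (strands %in% c("both", "+")) out <- rbind(out, one(toupper(pattern), "+"))
  if (strands %in% c("both", "-")) out <- rbind(out, one(rc(toupper(pattern)), "-"))
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  out[order(out$start, out$strand), , drop = FALSE]
}

# Mutate a string at exactly the given positions (deterministic base cycle,
# independent of the generator's RNG-based mutator).
mutate_at <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  ch[positions] <- nxt[ch[positions]]
  paste(ch, collapse = "")
}

# A planted tandem array string: n full copies of `monomer` plus a prefix
# tail of `tail_len` bases.
planted_array <- function(monomer, n, tail_len = 0) {
  paste0(strrep(monomer, n), substr(monomer, 1, tail_len))
}
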