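# Ground-truth generator: CACTA-like elements, tnp2B deletion derivatives,
# seeded satellite arrays, contigs and ultralong reads, with GFF-style truth.
# This is the test substrate for every other module: its defaults are the
# study conditions (8300 bp element, 630 bp domain with the diagnostic
# 16-mer at 159, 41 bp parental fragment whose first 10 bp are the anchor,
# diagnostic 12-mer starting 20 bp upstream of the fragment, 39 bp monomers
# at 94.4 copies, consensus divergence 0.103, 2% per-monomer noise).

the_cache <- new.env(parent = emptyenv())

#' Packaged reference tnp2 domain
#'
#' Loads the packaged synthetic 630 bp tnp2 transposase domain reference
#' (a stand-in for the pfam02992 domain consensus) carrying the diagnostic
#' `TATAACTTGCCTCCTT` motif at positions 159-174 and free of the anchor and
#' tnp2B motifs at their scan tolerances on both strands.
#'
#' @return A [dna_seq()].
#' @export
ref_tnp2_domain <- function() {
  if (is.null(the_cache$ref)) {
    path <- system.file("extdata", "tnp2_domain_reference.fasta",
                        package = "satjunction")
    the_cache$ref <- read_fasta(path)[[1]]
  }
  the_cache$ref
}

#' Generator configuration
#'
#' Parameters of the synthetic-genome generator. All coordinates are 1-based
#' inclusive; fractions lie in `[0, 1)`.
#'
#' @param seed Integer seed recorded in outputs.
#' @param background_gc GC content of random background.
#' @param jozin_length Total length of the complete CACTA-like element (bp).
#' @param domain_length Length of the complete tnp2 domain (bp); must match
#'   the packaged reference.
#' @param tnp2a_motif_start Start of the 16 nt diagnostic motif within the
#'   domain.
#' @param domain_offset Offset of the domain within the element (bp).
#' @param domain_divergence Expected pairwise divergence between the domains
#'   of two independently generated element copies; each copy receives
#'   `round(domain_divergence / 2 * domain_length)` substitutions from the
#'   reference, never inside the diagnostic motif.
#' @param tnp2b_length Length of the deletion derivative (100-600 bp).
#' @param fragment_length Length of the parental fragment at the derivative's
#'   3' end (first 10 bp are the anchor motif).
#' @param diagnostic_offset Distance from the 12 nt diagnostic motif start to
#'   the fragment start (bp).
#' @param monomer_period Satellite monomer length (bp).
#' @param copy_number Fractional monomer copy number of generated arrays.
#' @param consensus_divergence Fraction of monomer positions at which the
#'   array consensus differs from the parental fragment (realized as an exact
#'   substitution count `round(consensus_divergence * monomer_period)`, never
#'   inside the 10 bp anchor, so planted identities are deterministic).
#' @param per_monomer_noise Per-site Bernoulli substitution probability of
#'   monomers 2..n relative to the consensus.
#' @param read_error_rate Uniform substitution rate applied to simulated
#'   reads.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, background_gc = 0.37,
                             jozin_length = 8300L, domain_length = 630L,
                             tnp2a_motif_start = 159L, domain_offset = 1500L,
                             domain_divergence = 0.071,
                             tnp2b_length = 295L, fragment_length = 41L,
                             diagnostic_offset = 20L, monomer_period = 39L,
                             copy_number = 94.4, consensus_divergence = 0.103,
                             per_monomer_noise = 0.02, read_error_rate = 0) {
  cfg <- list(seed = as.integer(seed), background_gc = background_gc,
              jozin_length = as.integer(jozin_length),
              domain_length = as.integer(domain_length),
              tnp2a_motif_start = as.integer(tnp2a_motif_start),
              domain_offset = as.integer(domain_offset),
              domain_divergence = domain_divergence,
              tnp2b_length = as.integer(tnp2b_length),
              fragment_length = as.integer(fragment_length),
              diagnostic_offset = as.integer(diagnostic_offset),
              monomer_period = as.integer(monomer_period),
              copy_number = copy_number,
              consensus_divergence = consensus_divergence,
              per_monomer_noise = per_monomer_noise,
              read_error_rate = read_error_rate)
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      background_gc >= 0, background_gc < 1,
      domain_divergence >= 0, domain_divergence < 1,
      consensus_divergence >= 0, consensus_divergence < 1,
      per_monomer_noise >= 0, per_monomer_noise < 1,
      read_error_rate >= 0, read_error_rate < 1,
      copy_number >= 1,
      fragment_length >= nchar(SAT_ANCHOR),
      monomer_period >= nchar(SAT_ANCHOR)
    )
    if (tnp2b_length < 100L || tnp2b_length > 600L)
      stop("configuration error: tnp2b_length must lie in 100-600 bp")
    if (tnp2b_length < diagnostic_offset + fragment_length)
      stop("configuration error: tnp2b_length too short to host the ",
           "diagnostic motif, offset and parental fragment")
    if (domain_offset + domain_length > jozin_length)
      stop("configuration error: domain does not fit inside the element")
  })
  invisible(cfg)
}

# Random background with the configured GC.
random_dna <- function(n, gc = 0.37) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Substitute each given position with a uniformly drawn different base.
substitute_at <- function(chars, positions) {
  for (i in positions)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  chars
}

# Any occurrence (either strand) of the banned motifs at scan tolerance?
# Returns a data frame of offending windows (start, width).
banned_windows <- function(chars, allow_tnp2a_at = integer(0),
                           allow_tnp2b_at = integer(0),
                           allow_anchor_at = integer(0)) {
  specs <- list(
    list(p = SAT_ANCHOR, mm = 0L, allow = allow_anchor_at),
    list(p = TNP2A_MOTIF, mm = 1L, allow = allow_tnp2a_at),
    list(p = TNP2B_MOTIF, mm = 2L, allow = allow_tnp2b_at)
  )
  out <- list()
  for (sp in specs) {
    for (pat in unique(c(sp$p, revcomp(sp$p)))) {
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      mis <- window_mismatches(chars, pc)
      hits <- setdiff(which(mis <= sp$mm), sp$allow)
      if (length(hits) > 0)
        out[[length(out) + 1L]] <-
          data.frame(start = hits, width = length(pc))
    }
  }
  if (length(out) == 0L) data.frame(start = integer(0), width = integer(0))
  else do.call(rbind, out)
}

# A diverged copy of the packaged reference domain:
# round(domain_divergence/2 * L) substitutions, never inside the diagnostic
# motif; resampled (<=100 times) until free of banned motif occurrences.
domain_instance <- function(cfg) {
  ref <- seq_chars(ref_tnp2_domain())
  L <- length(ref)
  if (cfg$domain_length != L)
    stop("configuration error: domain_length must equal the packaged ",
         "reference length (", L, " bp)")
  motif_pos <- cfg$tnp2a_motif_start:(cfg$tnp2a_motif_start + nchar(TNP2A_MOTIF) - 1L)
  mutable <- setdiff(seq_len(L), motif_pos)
  k <- round(cfg$domain_divergence / 2 * L)
  for (attempt in 1:100) {
    chars <- substitute_at(ref, sample(mutable, k))
    if (nrow(banned_windows(chars, allow_tnp2a_at = cfg$tnp2a_motif_start)) == 0L)
      return(chars)
  }
  stop("generation error: could not produce a motif-clean domain copy")
}

#' Build a complete CACTA-like element
#'
#' Generates one element of `cfg$jozin_length` bp: 5'/3' terminal
#' `CACTA`/`TAGTG` inverted-repeat stubs, one complete tnp2 domain (a
#' diverged copy of the packaged reference carrying the diagnostic 16-mer at
#' `cfg$tnp2a_motif_start`), and random placeholder sequence for the
#' downstream DUF4216/DUF4218/TPase-associated segments. The element is
#' resampled (up to 100 times) until it contains no occurrence of the
#' satellite anchor or the tnp2B motif at their scan tolerances on either
#' strand, and exactly one occurrence of the tnp2A motif.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   consumed).
#' @return List with `seq` (a `dna_seq`), `truth` (feature data frame) and
#'   `domain` (the planted domain as a `dna_seq`).
#' @export
build_jozin <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$jozin_length
  off <- cfg$domain_offset
  for (attempt in 1:100) {
    domain <- domain_instance(cfg)
    chars <- strsplit(random_dna(n, cfg$background_gc), "", fixed = TRUE)[[1]]
    chars[1:5] <- c("C", "A", "C", "T", "A")
    chars[(n - 4):n] <- c("T", "A", "G", "T", "G")
    chars[off:(off + cfg$domain_length - 1L)] <- domain
    motif_abs <- off + cfg$tnp2a_motif_start - 1L
    if (nrow(banned_windows(chars, allow_tnp2a_at = motif_abs)) > 0L) next
    seqstr <- paste(chars, collapse = "")
    dom_end <- off + cfg$domain_length - 1L
    truth <- rbind(
      truth_row("jozin", 1L, n, "+",
                list(domain_divergence = cfg$domain_divergence)),
      truth_row("tnp2A_domain", off, dom_end, "+",
                list(motif_start = motif_abs)),
      truth_row("duf_placeholder", dom_end + 100L, dom_end + 700L, "+",
                list(note = "DUF4216/DUF4218/TPase-associated placeholder"))
    )
    return(list(seq = dna_seq("jozin", seqstr),
                truth = truth,
                domain = dna_seq("tnp2A_domain", paste(domain, collapse = ""))))
  }
  stop("generation error: motif exclusion unreachable after 100 resamples")
}

truth_row <- function(type, start, end, strand, attrs = list()) {
  data.frame(seqid = "", type = type, start = as.integer(start),
             end = as.integer(end), strand = strand,
             attributes = paste(names(attrs), unlist(lapply(attrs, format)),
                                sep = "=", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Build a tnp2B deletion derivative
#'
#' Copies `cfg$tnp2b_length` bp from the internal region of a complete
#' domain (source window anchored at domain position 63 where it fits),
#' plants the diagnostic 12-mer plus the 8 bp `GACTTACA` spacer so the motif
#' starts `cfg$diagnostic_offset` bp upstream of the parental fragment, and
#' overwrites the first 10 bp of the terminal `cfg$fragment_length` bp
#' fragment with the anchor `TTTCATTTGA`. Any residual occurrence of the
#' complete-domain 16-mer (at scan tolerance) is disrupted so the derivative
#' never classifies as a complete domain.
#'
#' @param cfg A [generator_config()].
#' @param jozin_domain Domain copy (`dna_seq` or string) from [build_jozin()].
#' @param seed Optional integer seed.
#' @return List with `seq`, `truth` and `fragment` (the parental fragment as
#'   a `dna_seq`).
#' @export
build_tnp2b <- function(cfg = generator_config(), jozin_domain, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_config(cfg)
  dom <- seq_chars(jozin_domain)
  L <- cfg$tnp2b_length
  src_start <- max(1L, min(63L, length(dom) - L + 1L))
  chars <- dom[src_start:(src_start + L - 1L)]
  f <- L - cfg$fragment_length + 1L
  chars[f:(f + 9L)] <- strsplit(SAT_ANCHOR, "", fixed = TRUE)[[1]]
  block <- paste0(TNP2B_MOTIF, "GACTTACA")
  motif_start <- f - cfg$diagnostic_offset
  chars[motif_start:(f - 1L)] <- strsplit(block, "", fixed = TRUE)[[1]]

  # disrupt residual banned occurrences outside the planted blocks
  planted <- c(motif_start:(motif_start + nchar(TNP2B_MOTIF) - 1L), f:(f + 9L))
  for (iter in 1:25) {
    bad <- banned_windows(chars, allow_tnp2b_at = motif_start,
                          allow_anchor_at = f)
    if (nrow(bad) == 0L) break
    w <- bad[1, ]
    win <- setdiff(w$start:(w$start + w$width - 1L), planted)
    if (length(win) == 0L)
      stop("generation error: banned motif inside planted block")
    chars <- substitute_at(chars, sample(win, min(2L, length(win))))
  }
  if (nrow(banned_windows(chars, allow_tnp2b_at = motif_start,
                          allow_anchor_at = f)) > 0L)
    stop("generation error: could not sanitize derivative")

  frag <- paste(chars[f:L], collapse = "")
  truth <- rbind(
    truth_row("tnp2B", 1L, L, "+",
              list(source_start = src_start, motif_start = motif_start)),
    truth_row("parental_fragment", f, L, "+",
              list(length = cfg$fragment_length))
  )
  list(seq = dna_seq("tnp2B", paste(chars, collapse = "")),
       truth = truth,
       fragment = dna_seq("parental_fragment", frag))
}

#' Build a satellite array seeded from a parental fragment
#'
#' The array consensus is the first `monomer_period` bp of the fragment
#' mutated at exactly `round(consensus_divergence * period)` positions
#' (drawn without replacement, never inside the 10 bp anchor). Monomer 1 is
#' the fragment's first period bp verbatim; monomers 2..floor(copies) are
#' the consensus with per-site substitution probability `per_monomer_noise`;
#' a trailing partial monomer contributes the first
#' `floor(frac(copies) * period)` bp of the consensus. Total length is
#' `floor(copy_number * period)`.
#'
#' @param parent_fragment Fragment (`dna_seq` or string), at least one
#'   period long.
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed.
#' @return List with `seq`, `truth`, `consensus` (string) and
#'   `planted_identity_pct` (fragment-prefix vs consensus, exact by
#'   construction).
#' @export
build_array <- function(parent_fragment, cfg = generator_config(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- cfg$monomer_period
  frag <- seq_chars(parent_fragment)
  stopifnot(length(frag) >= p)
  m <- round(cfg$consensus_divergence * p)
  consensus <- frag[1:p]
  if (m > 0) {
    anchor_len <- nchar(SAT_ANCHOR)
    consensus <- substitute_at(consensus,
                               sample((anchor_len + 1L):p, m))
  }
  nfull <- floor(cfg$copy_number)
  noise_monomer <- function() {
    mono <- consensus
    flips <- which(stats::runif(p) < cfg$per_monomer_noise)
    if (length(flips) > 0) mono <- substitute_at(mono, flips)
    paste(mono, collapse = "")
  }
  monomers <- c(paste(frag[1:p], collapse = ""),
                if (nfull > 1) vapply(seq_len(nfull - 1L), function(i)
                  noise_monomer(), ""))
  tail_len <- floor((cfg$copy_number - nfull) * p + 1e-9)
  tail_seq <- if (tail_len > 0) paste(consensus[1:tail_len], collapse = "") else ""
  seqstr <- paste0(paste(monomers, collapse = ""), tail_seq)
  total <- nchar(seqstr)
  planted_identity <- round_half_up(100 * (p - m) / p, 1)
  truth <- rbind(
    truth_row("sat_array", 1L, total, "+",
              list(period = p, copies = cfg$copy_number,
                   divergence = cfg$consensus_divergence,
                   planted_identity_pct = planted_identity,
                   consensus = paste(consensus, collapse = ""))),
    do.call(rbind, lapply(seq_len(nfull), function(i)
      truth_row("monomer", (i - 1L) * p + 1L, i * p, "+", list(index = i))))
  )
  list(seq = dna_seq("sat_array", seqstr), truth = truth,
       consensus = paste(consensus, collapse = ""),
       planted_identity_pct = planted_identity)
}

#' Simulate a sample of contigs or reads with ground truth
#'
#' Builds random-background contigs with planted features at planned
#' offsets and emits a ground-truth feature table. Fully reproducible from
#' the seed: identical plan + config + seed give byte-identical output.
#'
#' @param plan List of contig plans; each is a list with `id`, `length`, an
#'   optional logical `read` (apply `read_error_rate`), and `elements`, a
#'   list of plantings: `list(type = c("junction","jozin","tnp2b","array"),
#'   at = <offset>, ...config overrides...)`.
#' @param cfg A [generator_config()]; per-element overrides are merged onto
#'   it.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return List with `sequences` (list of `dna_seq`), `truth` (feature data
#'   frame in 1-based inclusive coordinates), `cfg` and `seed`.
#' @export
simulate_sample <- function(plan, cfg = generator_config(), seed = cfg$seed) {
  set.seed(seed)
  sequences <- list()
  truth_all <- list()
  for (contig in plan) {
    stopifnot(!is.null(contig$id), !is.null(contig$length))
    chars <- strsplit(random_dna(contig$length, cfg$background_gc),
                      "", fixed = TRUE)[[1]]
    occupied <- integer(0)
    elements <- contig$elements %||% list()
    if (length(elements) > 1) {
      ord <- order(vapply(elements, function(e) e$at, 0))
      elements <- elements[ord]
    }
    for (el in elements) {
      ecfg <- merge_config(cfg, el)
      piece <- build_element(el$type, ecfg)
      at <- as.integer(el$at)
      len <- nchar(piece$seq$residues)
      span <- at:(at + len - 1L)
      if (at < 1L || max(span) > contig$length)
        stop("plan error: element '", el$type, "' does not fit in contig '",
             contig$id, "'")
      if (length(intersect(span, occupied)) > 0L)
        stop("plan error: overlapping planted features in contig '",
             contig$id, "'")
      occupied <- c(occupied, span)
      chars[span] <- strsplit(piece$seq$residues, "", fixed = TRUE)[[1]]
      tr <- piece$truth
      tr$seqid <- contig$id
      tr$start <- tr$start + at - 1L
      tr$end <- tr$end + at - 1L
      truth_all[[length(truth_all) + 1L]] <- tr
    }
    if (isTRUE(contig$read) && cfg$read_error_rate > 0) {
      flips <- which(stats::runif(contig$length) < cfg$read_error_rate)
      if (length(flips) > 0) chars <- substitute_at(chars, flips)
    }
    sequences[[length(sequences) + 1L]] <-
      dna_seq(contig$id, paste(chars, collapse = ""),
              paste0("seed=", seed))
  }
  truth <- if (length(truth_all) > 0) do.call(rbind, truth_all)
  else truth_row("none", 1L, 1L, "+")[0, ]
  rownames(truth) <- NULL
  list(sequences = sequences, truth = truth, cfg = cfg, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_config <- function(cfg, overrides) {
  keep <- intersect(names(overrides), names(cfg))
  if (length(keep) > 0) cfg[keep] <- overrides[keep]
  validate_config(cfg)
  cfg
}

# Assemble one plantable element; junctions are a derivative followed
# immediately by the array it seeds (the array's first monomer repeats the
# fragment's first period bp, so the start monomer is simultaneously a tnp2
# fragment).
build_element <- function(type, cfg) {
  switch(type,
    jozin = {
      jz <- build_jozin(cfg)
      list(seq = jz$seq, truth = jz$truth)
    },
    tnp2b = {
      dom <- paste(domain_instance(cfg), collapse = "")
      build_tnp2b(cfg, dom)
    },
    junction = {
      dom <- paste(domain_instance(cfg), collapse = "")
      tb <- build_tnp2b(cfg, dom)
      ar <- build_array(tb$fragment, cfg)
      artruth <- ar$truth
      artruth$start <- artruth$start + cfg$tnp2b_length
      artruth$end <- artruth$end + cfg$tnp2b_length
      list(seq = dna_seq("junction",
                         paste0(tb$seq$residues, ar$seq$residues)),
           truth = rbind(tb$truth, artruth))
    },
    array = {
      frag <- paste0(SAT_ANCHOR,
                     random_dna(cfg$fragment_length - nchar(SAT_ANCHOR),
                                cfg$background_gc))
      build_array(frag, cfg)
    },
    stop("plan error: unknown element type '", type, "'")
  )
}

#' Plan: a junction locus on one contig
#'
#' Convenience plan for a single contig carrying one derivative-array
#' junction, defaulting to the reported D-genome junction locus (39 bp
#' monomer, 94.4 copies, 115 bp derivative, 41 bp fragment).
#'
#' @param contig_length Contig length (bp).
#' @param at Junction offset within the contig.
#' @param tnp2b_length,copy_number,monomer_period Config overrides.
#' @param ... Further config overrides for the element.
#' @return A plan list for [simulate_sample()].
#' @export
junction_locus_plan <- function(contig_length = 4500L, at = 300L,
                                tnp2b_length = 115L, copy_number = 94.4,
                                monomer_period = 39L, ...) {
  list(list(id = "contig_1", length = as.integer(contig_length),
            elements = list(c(list(type = "junction", at = as.integer(at),
                                   tnp2b_length = tnp2b_length,
                                   copy_number = copy_number,
                                   monomer_period = monomer_period),
                              list(...)))))
}

#' Plan: an ultralong read with one junction
#'
#' Convenience plan mirroring an ultralong nanopore read carrying a
#' derivative followed by a long satellite array (defaults: 49,142 bp read,
#' 125 copies of a 40 bp monomer, i.e. a 5.0 kb array).
#'
#' @param read_length Read length (bp).
#' @param at Junction offset within the read.
#' @param copy_number,monomer_period Config overrides.
#' @param ... Further config overrides.
#' @return A plan list for [simulate_sample()].
#' @export
longread_plan <- function(read_length = 49142L, at = 20000L,
                          copy_number = 125, monomer_period = 40L, ...) {
  list(list(id = "read_1", length = as.integer(read_length), read = TRUE,
            elements = list(c(list(type = "junction", at = as.integer(at),
                                   copy_number = copy_number,
                                   monomer_period = monomer_period),
                              list(...)))))
}
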