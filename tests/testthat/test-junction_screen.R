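# Fixtures: one simulated contig carrying a derivative-array junction is
# reused by several blocks (generation is the expensive step).
local_junction_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_sample(junction_locus_plan(), seed = 42)
    cache
  }
})

test_that("a complete domain classifies as tnp2A with ~630 bp extent", {
  set.seed(51)
  jz <- build_jozin(seed = 51)
  contig <- dna_seq("c1", paste0(rand_dna(300), jz$seq$residues,
                                 rand_dna(300)))
  hits <- classify_tpase(contig)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kind, "tnp2A")
  expect_lte(abs(hits$length - 630L), 2L)
  expect_gt(hits$domain_identity_pct, 90)
})

test_that("a planted derivative classifies as tnp2B, never as tnp2A", {
  set.seed(53)
  cfg <- generator_config(tnp2b_length = 295L)
  dom <- paste(satjunction:::domain_instance(cfg), collapse = "")
  tb <- build_tnp2b(cfg, dom)
  contig <- dna_seq("c1", paste0(rand_dna(400), tb$seq$residues,
                                 rand_dna(400)))
  hits <- classify_tpase(contig)
  expect_equal(hits$kind, "tnp2B")
  expect_lte(abs(hits$start - 401L), 10L)
  expect_lte(abs(hits$end - (400L + 295L)), 10L)
  # classification partition: no call is both kinds
  expect_equal(anyDuplicated(hits[, c("start", "end")]), 0L)
})

test_that("random background yields no transposase calls", {
  set.seed(7)
  expect_equal(nrow(classify_tpase(rand_dna(5000))), 0L)
})

test_that("the junction replica recovers fragment, lengths and identity", {
  sim <- local_junction_sim()
  contig <- sim$sequences[[1]]
  res <- screen_genome(contig, "replica")
  expect_equal(length(res$junctions), 1L)
  j <- res$junctions[[1]]
  expect_equal(j$fragment_length, 41L)
  expect_equal(j$tpase$length, 115L)
  expect_true(j$start_monomer_is_fragment)
  expect_true(j$same_orientation)
  expect_equal(j$period, 39L)
  expect_equal(j$copy_number, 94.4)
  expect_equal(j$fragment_consensus_identity_pct, 89.7)
  # internal consistency: the reported identity is reproducible by an
  # independent call to the alignment primitive
  redo <- global_align_identity(substr(j$fragment_residues, 1, j$period),
                                j$consensus)$identity_pct
  expect_equal(redo, j$fragment_consensus_identity_pct)
  expect_equal(res$report$tnp2b_with_array, TRUE)
})

test_that("orientation and gap rules suppress junction calls", {
  sim <- local_junction_sim()
  contig <- sim$sequences[[1]]
  truth <- sim$truth
  arr_row <- truth[truth$type == "sat_array", ]
  chars <- strsplit(contig$residues, "")[[1]]

  # reverse-complement only the array segment: orientations now differ
  seg <- paste(chars[arr_row$start:arr_row$end], collapse = "")
  flipped <- chars
  flipped[arr_row$start:arr_row$end] <- strsplit(revcomp(seg), "")[[1]]
  res <- screen_genome(dna_seq("flip", paste(flipped, collapse = "")), "flip")
  expect_equal(length(res$junctions), 0L)
  expect_true(res$report$tnp2b_present)
  expect_false(res$report$tnp2b_with_array)

  # insert a 500 bp spacer between derivative and array: gap rule fails
  tb_row <- truth[truth$type == "tnp2B", ]
  set.seed(61)
  spaced <- paste0(substr(contig$residues, 1, tb_row$end), rand_dna(500),
                   substr(contig$residues, tb_row$end + 1,
                          nchar(contig$residues)))
  res <- screen_genome(dna_seq("spaced", spaced), "spaced")
  expect_equal(length(res$junctions), 0L)
  expect_true(res$report$tnp2b_present)
})

test_that("a sample with only a complete element reports no derivative", {
  jz <- build_jozin(seed = 63)
  res <- screen_genome(jz$seq, "element_only")
  expect_false(res$report$tnp2b_present)
  expect_false(res$report$tnp2b_with_array)
})

test_that("screen recovers planted junctions across 20 seeded samples", {
  n_exact_len <- 0L
  for (s in 1:20) {
    sim <- simulate_sample(
      junction_locus_plan(contig_length = 2500L, copy_number = 11.4,
                          tnp2b_length = 200L, consensus_divergence = 0.13,
                          per_monomer_noise = 0.03),
      seed = 7000 + s)
    res <- screen_genome(sim$sequences[[1]], paste0("s", s))
    # 100% recall and precision: exactly the one planted junction
    expect_equal(length(res$junctions), 1L)
    j <- res$junctions[[1]]
    expect_lte(abs(j$copy_number - 11.4) / 11.4, 0.02)
    truth_ident <- as.numeric(sub(".*planted_identity_pct=([0-9.]+).*", "\\1",
                                  sim$truth$attributes[
                                    sim$truth$type == "sat_array"]))
    expect_lte(abs(j$fragment_consensus_identity_pct - truth_ident), 1.5)
    expect_lte(abs(j$tpase$length - 200L), 10L)
    if (j$tpase$length == 200L) n_exact_len <- n_exact_len + 1L
  }
  # the 5' boundary abuts random background, where a coincidentally
  # homologous base is indistinguishable from the element (~25% per base),
  # so exact lengths occur in roughly half the samples
  expect_gte(n_exact_len, 5L)
})
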