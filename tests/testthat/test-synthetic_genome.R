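test_that("the generated element meets its structural contract", {
  jz <- build_jozin(seed = 1)
  expect_equal(nchar(jz$seq$residues), 8300L)
  expect_equal(substr(jz$seq$residues, 1, 5), "CACTA")
  expect_equal(substr(jz$seq$residues, 8296, 8300), "TAGTG")
  dom_row <- jz$truth[jz$truth$type == "tnp2A_domain", ]
  expect_equal(dom_row$end - dom_row$start + 1L, 630L)
  # no satellite anchor and no derivative motif anywhere, either strand
  mots <- screen_motifs()
  expect_equal(nrow(scan_motif(jz$seq, mots$anchor, "both")), 0L)
  expect_equal(nrow(scan_motif(jz$seq, mots$tnp2b, "both")), 0L)
  # exactly one complete-domain motif, at the configured domain position
  h <- scan_motif(jz$seq, mots$tnp2a, "both")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, dom_row$start + 159L - 1L)
})

test_that("derivatives carry the motif architecture of the parental fragment", {
  cfg <- generator_config(tnp2b_length = 115L)
  set.seed(3)
  dom <- paste(satjunction:::domain_instance(cfg), collapse = "")
  tb <- build_tnp2b(cfg, dom)
  expect_equal(nchar(tb$seq$residues), 115L)
  frag_row <- tb$truth[tb$truth$type == "parental_fragment", ]
  expect_equal(frag_row$end - frag_row$start + 1L, 41L)
  expect_equal(frag_row$end, 115L)
  # fragment begins with the anchor, exactly
  expect_equal(substr(tb$seq$residues, frag_row$start, frag_row$start + 9),
               "TTTCATTTGA")
  # diagnostic motif starts 20 bp upstream of the fragment start
  h <- scan_motif(tb$seq, screen_motifs()$tnp2b, "+")
  expect_equal(h$start, frag_row$start - 20L)
  # the 8 bp spacer completes the published forward primer
  expect_equal(substr(tb$seq$residues, h$start, h$start + 19),
               "GGCTGGGTTACCGACTTACA")
  # no complete-domain motif survives in the derivative
  expect_equal(nrow(scan_motif(tb$seq, screen_motifs()$tnp2a, "both")), 0L)
  expect_error(generator_config(tnp2b_length = 50L), "configuration error")
})

test_that("array arithmetic and planted identity are deterministic", {
  cfg <- generator_config(copy_number = 5, consensus_divergence = 0,
                          per_monomer_noise = 0)
  set.seed(5)
  frag <- paste0("TTTCATTTGA", rand_dna(31))
  ar <- build_array(frag, cfg)
  expect_equal(nchar(ar$seq$residues), 5L * 39L)
  expect_equal(ar$consensus, substr(frag, 1, 39))
  expect_equal(ar$planted_identity_pct, 100)

  # 10.3% divergence on 39 bp: exactly 4 substitutions, 35/39 = 89.7
  cfg <- generator_config(copy_number = 6, consensus_divergence = 0.103)
  ar <- build_array(frag, cfg)
  ham <- sum(strsplit(ar$consensus, "")[[1]] !=
               strsplit(substr(frag, 1, 39), "")[[1]])
  expect_equal(ham, 4L)
  expect_equal(ar$planted_identity_pct, 89.7)
  expect_equal(global_align_identity(substr(frag, 1, 39),
                                     ar$consensus)$identity_pct, 89.7)
  # anchor exempt from consensus mutation
  expect_equal(substr(ar$consensus, 1, 10), "TTTCATTTGA")

  # fractional copies: floor(5.5 * 39) = 214 bp
  cfg <- generator_config(copy_number = 5.5)
  ar <- build_array(frag, cfg)
  expect_equal(nchar(ar$seq$residues), 214L)
})

test_that("identical plan, config and seed give byte-identical samples", {
  plan <- junction_locus_plan(contig_length = 2000L, copy_number = 8.4)
  a <- simulate_sample(plan, seed = 42)
  b <- simulate_sample(plan, seed = 42)
  expect_identical(a$sequences[[1]]$residues, b$sequences[[1]]$residues)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_sample(plan, seed = 43)
  expect_false(identical(a$sequences[[1]]$residues,
                         c2$sequences[[1]]$residues))
})

test_that("plan errors are raised for unbuildable layouts", {
  bad <- list(list(id = "c", length = 500L,
                   elements = list(list(type = "junction", at = 100L))))
  expect_error(simulate_sample(bad, seed = 1), "plan error")
  overlap <- list(list(id = "c", length = 20000L,
                       elements = list(
                         list(type = "jozin", at = 100L),
                         list(type = "tnp2b", at = 150L))))
  expect_error(simulate_sample(overlap, seed = 1), "plan error")
})

test_that("generated pieces pass their own classifier (cross-module truth)", {
  for (s in 1:5) {
    sim <- simulate_sample(junction_locus_plan(contig_length = 2200L,
                                               copy_number = 9.4,
                                               tnp2b_length = 150L),
                           seed = 900 + s)
    hits <- classify_tpase(sim$sequences[[1]])
    expect_equal(hits$kind, "tnp2B")
  }
  jz <- build_jozin(seed = 77)
  hits <- classify_tpase(jz$seq)
  expect_equal(hits$kind, "tnp2A")
})

test_that("empty plans give pure background where the screen finds nothing", {
  plan <- list(list(id = "bg", length = 6000L, elements = list()))
  sim <- simulate_sample(plan, seed = 11)
  res <- screen_genome(sim$sequences[[1]], "bg")
  expect_equal(length(res$junctions), 0L)
  expect_equal(length(res$arrays), 0L)
  expect_false(res$report$tnp2b_present)
})
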