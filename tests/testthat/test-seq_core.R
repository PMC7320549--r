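test_that("reverse complement obeys Watson-Crick pairing and involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("TTTCATTTGA"), "TCAAATGAAA")
  expect_equal(revcomp("N"), "N")
  set.seed(1)
  for (i in 1:20) {
    s <- rand_dna(sample(1:80, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
  expect_error(dna_seq("x", "ACGU"), "non-nucleotide")
})

test_that("global alignment identity matches hand-derived values", {
  expect_equal(global_align_identity("ACGTACGT", "ACGTACGT")$identity_pct, 100)
  # enumerated optimum under match +1 / mismatch -1 / gap -2:
  # align ACGT over ACG- (3 matches / 4 columns)
  r <- global_align_identity("ACGT", "ACG")
  expect_equal(r$matches, 3L)
  expect_equal(r$columns, 4L)
  expect_equal(r$identity_pct, 75)
  # a 39-mer against itself with 4 substitutions: 35/39 columns
  set.seed(7)
  a <- rand_dna(39)
  b <- mutate_at(a, c(12, 20, 28, 36))
  r <- global_align_identity(a, b)
  expect_equal(r$matches, 35L)
  expect_equal(r$columns, 39L)
  expect_equal(r$identity_pct, 89.7)
  expect_error(global_align_identity("", "ACG"), "non-empty")
})

test_that("alignment identity is symmetric and bounded, 100 iff identical", {
  set.seed(11)
  for (i in 1:25) {
    a <- rand_dna(sample(5:50, 1))
    b <- if (i %% 5 == 0) a else rand_dna(sample(5:50, 1))
    ra <- global_align_identity(a, b)
    rb <- global_align_identity(b, a)
    expect_equal(ra$identity_pct, rb$identity_pct)
    expect_gte(ra$identity_pct, 0)
    expect_lte(ra$identity_pct, 100)
    expect_equal(ra$identity_pct == 100, identical(a, b))
  }
})

test_that("traceback alignment reproduces the DP corner score and the
           Hamming oracle on gap-free optima", {
  set.seed(23)
  gap_free_seen <- 0
  for (i in 1:40) {
    n <- sample(10:50, 1)
    a <- rand_dna(n)
    # low divergence keeps most optima gap-free
    b <- mutate_at(a, sample(n, max(1, rbinom(1, n, 0.08))))
    r <- global_align_identity(a, b)
    # score recomputed independently from the aligned strings
    ca <- strsplit(r$aligned_a, "")[[1]]
    cb <- strsplit(r$aligned_b, "")[[1]]
    col_score <- ifelse(ca == "-" | cb == "-", -2, ifelse(ca == cb, 1, -1))
    expect_equal(sum(col_score), r$score)
    if (!grepl("-", r$aligned_a, fixed = TRUE) &&
        !grepl("-", r$aligned_b, fixed = TRUE)) {
      gap_free_seen <- gap_free_seen + 1
      hd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_equal(r$identity_pct, round_half_up(100 * (1 - hd / n), 1))
    }
  }
  expect_gt(gap_free_seen, 20)
})

test_that("alignment agrees with an independent aligner on scores", {
  set.seed(31)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- rand_dna(sample(10:40, 1))
    b <- rand_dna(sample(10:40, 1))
    mine <- global_align_identity(a, b)$score
    # linear gap penalty -2 == opening 0 / extension 2 in pwalign terms
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("FASTA writing and reading round-trip with normalization", {
  path <- withr::local_tempfile(fileext = ".fasta")
  recs <- list(dna_seq("chr1", "ACGT"),
               dna_seq("chr2", strrep("ACGTN", 30), "a long record"),
               dna_seq("chr3", "acgt"))
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(length(back), 3L)
  expect_equal(vapply(back, function(s) s$id, ""), c("chr1", "chr2", "chr3"))
  expect_equal(back[[1]]$residues, "ACGT")
  expect_equal(back[[2]]$residues, strrep("ACGTN", 30))
  expect_equal(back[[2]]$description, "a long record")
  expect_equal(back[[3]]$residues, "ACGT")  # lowercase normalized

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("chr1 no header marker", "ACGT"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("GFF3 features round-trip with 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".gff3")
  feats <- data.frame(seqid = "contig_1", type = c("tnp2B", "sat_array"),
                      start = c(300L, 415L), end = c(414L, 4095L),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  write_gff3(feats, path)
  back <- read_gff3(path)
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(as.character(back$type), feats$type)
})
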