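test_that("majority consensus follows the vote and the lexicographic tie rule", {
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(build_consensus(c("AAAA", "AAAA", "AAAT")), "AAAA")
  expect_equal(build_consensus(c("AAAC", "AAAG")), "AAAC")  # C/G tie -> C
  expect_error(build_consensus(c("AAA", "AAAA")), "equal length")
})

test_that("exact planted arrays are recovered with period, copies and consensus", {
  set.seed(101)
  monomer <- rand_dna(40)
  seq <- paste0(rand_dna(500), planted_array(monomer, 10), rand_dna(500))
  arrs <- detect_arrays(seq)
  expect_equal(length(arrs), 1L)
  a <- arrs[[1]]
  expect_equal(a$period, 40L)
  expect_equal(a$copy_number, 10.0)
  expect_equal(a$consensus, monomer)
  # noise-free boundaries: within one base of truth (a background base that
  # happens to extend the periodic pattern is indistinguishable)
  expect_lte(abs(a$start - 501L), 1L)
  expect_lte(abs(a$end - 900L), 1L)
})

test_that("fractional copy number includes the trailing partial monomer", {
  set.seed(103)
  monomer <- rand_dna(39)
  # 94 copies plus a 16 bp prefix: 3682/39 = 94.41 -> 94.4
  seq <- paste0(rand_dna(300), planted_array(monomer, 94, 16), rand_dna(300))
  arrs <- detect_arrays(seq)
  expect_equal(length(arrs), 1L)
  expect_equal(arrs[[1]]$period, 39L)
  expect_equal(arrs[[1]]$copy_number, 94.4)
  expect_equal(length(arrs[[1]]$monomers), 94L)
})

test_that("uniform random sequence contains no reportable array", {
  set.seed(1)
  expect_equal(detect_arrays(rand_dna(10000)), list())
})

test_that("consensus recovery holds for noisy arrays across seeds", {
  n_exact_phase <- 0L
  rotations <- function(s) {
    n <- nchar(s)
    vapply(0:(n - 1), function(k)
      paste0(substr(s, k + 1, n), substr(s, 1, k)), "")
  }
  for (s in 1:20) {
    set.seed(300 + s)
    monomer <- rand_dna(40)
    copies <- vapply(1:12, function(i) {
      if (i == 1) monomer
      else mutate_at(monomer, which(runif(40) < 0.05))
    }, "")
    seq <- paste0(rand_dna(200), paste(copies, collapse = ""), rand_dna(200))
    arrs <- detect_arrays(seq)
    expect_equal(length(arrs), 1L)
    expect_equal(arrs[[1]]$period, 40L)
    # majority voting across >= 10 copies at <= 5% noise recovers the
    # planted consensus; without an anchor motif the monomer frame is
    # determined only up to the boundary ambiguity (flanking bases that
    # happen to extend the period are indistinguishable), so the consensus
    # must be the rotation consistent with the detected start, and the
    # boundary must sit within a few bases of truth
    shift <- arrs[[1]]$start - 201L
    expect_lte(abs(shift), 5L)
    expect_equal(arrs[[1]]$consensus, rotations(monomer)[(shift %% 40) + 1L])
    if (shift == 0L) n_exact_phase <- n_exact_phase + 1L
  }
  expect_gte(n_exact_phase, 10L)
})

test_that("copy number times period tracks the detected array length", {
  set.seed(107)
  for (p in c(20, 39, 55)) {
    monomer <- rand_dna(p)
    seq <- paste0(rand_dna(150), planted_array(monomer, 8, floor(p / 3)),
                  rand_dna(150))
    arrs <- detect_arrays(seq)
    expect_equal(length(arrs), 1L)
    a <- arrs[[1]]
    expect_lte(abs(a$copy_number * a$period - (a$end - a$start + 1)),
               a$period)
  }
})

test_that("anchored consensus pins the monomer phase to the anchor", {
  set.seed(109)
  monomer <- paste0("TTTCATTTGA", rand_dna(29))
  seq <- paste0(rand_dna(400), planted_array(monomer, 12, 10), rand_dna(400))
  arrs <- detect_arrays(seq)
  expect_equal(length(arrs), 1L)
  expect_equal(arrs[[1]]$start, 401L)
  expect_equal(substr(arrs[[1]]$consensus, 1, 10), "TTTCATTTGA")
  expect_equal(arrs[[1]]$strand, "+")
  # reverse-complemented array reports minus strand in plus coordinates
  rcseq <- revcomp(seq)
  arrs_rc <- detect_arrays(rcseq)
  expect_equal(length(arrs_rc), 1L)
  expect_equal(arrs_rc[[1]]$strand, "-")
})
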