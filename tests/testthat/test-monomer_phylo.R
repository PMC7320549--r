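test_that("anchor alignment lines up anchors and rejects anchorless input", {
  aln <- anchor_align(c(a = "CCTTTCATTTGAAC", b = "TTTCATTTGAACGG"))
  expect_equal(unname(nchar(aln)), c(16L, 16L))
  # anchors share a column: positions of the anchor must coincide
  expect_equal(regexpr("TTTCATTTGA", aln[["a"]]),
               regexpr("TTTCATTTGA", aln[["b"]]))
  expect_equal(attr(aln, "rejects"), character(0))

  with_reject <- anchor_align(c(a = "CCTTTCATTTGAAC", b = "AAAAAAAAAAAAAA"))
  expect_equal(attr(with_reject, "rejects"), "b")
  expect_equal(names(with_reject), "a")

  # identical monomers: no gap columns at all
  two <- anchor_align(c(x = "TTTCATTTGACCGG", y = "TTTCATTTGACCGG"))
  expect_false(any(grepl("-", two, fixed = TRUE)))
})

test_that("p-distances match hand counts and matrix invariants", {
  set.seed(71)
  a <- paste0("TTTCATTTGA", rand_dna(29))
  b <- mutate_at(a, c(15, 22, 30, 38))
  d <- p_distance_matrix(anchor_align(c(a = a, b = b)))
  expect_equal(d["a", "b"], 4 / 39)
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))

  # gap columns are excluded from the comparison
  aln <- c(x = "--ACGT", y = "AAACGA")
  d <- p_distance_matrix(aln)
  expect_equal(d["x", "y"], 1 / 4)

  expect_error(p_distance_matrix(c(a = "A-", b = "-A")),
               "no comparable columns")
})

test_that("neighbor joining reproduces the three-taxon closed form", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  el <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(el[["A"]], 0.05)
  expect_equal(el[["B"]], 0.15)
  expect_equal(el[["C"]], 0.25)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3")
})

test_that("NJ recovers additive trees and agrees with the reference NJ", {
  for (s in 1:10) {
    set.seed(400 + s)
    n <- sample(4:8, 1)
    truth <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(truth)
    ord <- order(rownames(dm))
    dm <- dm[ord, ord]
    mine <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(truth), mine), 0)
    expect_equal(phangorn::RF.dist(ape::nj(stats::as.dist(dm)), mine), 0)
    # additive distances are reproduced by the tree's path lengths
    back <- ape::cophenetic.phylo(mine)
    expect_equal(back[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)
  }
})

test_that("degenerate distance matrices give star trees with zero lengths", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(d)
  expect_equal(sort(tree$tip.label), letters[1:4])
  expect_true(all(tree$edge.length == 0))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0, 0, 1, 1, 2, 0), 3, 3)),
               "symmetric")
})

test_that("position frequencies and information content follow the entropy
           arithmetic", {
  one <- pfm("ACGT")
  expect_equal(one$A, c(1, 0, 0, 0))
  expect_equal(one$ic_bits, rep(2, 4))

  four <- pfm(c("A", "A", "C", "G"))
  expect_equal(four$A, 0.5)
  expect_equal(four$C, 0.25)
  expect_equal(four$G, 0.25)
  expect_equal(four$ic_bits, 0.5)

  # frequencies sum to one over non-gap symbols; gaps tracked separately
  mixed <- pfm(c("A-", "AC", "AG"))
  expect_equal(mixed$A + mixed$C + mixed$G + mixed$T, c(1, 1))
  expect_equal(mixed$gap_fraction, c(0, 1 / 3))
})

test_that("generator monomers show full conservation at the anchor columns", {
  sim <- simulate_sample(junction_locus_plan(contig_length = 1500L,
                                             copy_number = 10.4),
                         seed = 81)
  arr <- detect_arrays(sim$sequences[[1]])[[1]]
  aln <- anchor_align(arr$monomers)
  freq <- pfm(aln)
  # anchor is exempt from consensus mutation and nearly noise-free
  expect_true(all(freq$ic_bits[1:10] > 1.5))
})
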