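test_that("progressive alignment handles identical, gapped and reordered input", {
  a <- progressive_align(c(x = "MKTAYIAK", y = "MKTAYIAK"))
  expect_equal(ncol(a), 8L)
  expect_false(any(a == "-"))

  # single deletion placed against the unmatched residue
  b <- progressive_align(c(x = "ACDE", y = "ACE"))
  expect_equal(paste(b["y", ], collapse = ""), "AC-E")

  seqs <- c(s1 = "MKTAYIAKQR", s2 = "MKTAYIQR", s3 = "MKTAYIAKQR",
            s4 = "MKTWYIAKQR")
  a1 <- progressive_align(seqs)
  a2 <- progressive_align(seqs[c(3, 1, 4, 2)])
  expect_setequal(rownames(a1), rownames(a2))
  # ungapping always recovers the inputs
  expect_equal(ungap_alignment(a1)[names(seqs)], seqs)
  expect_equal(ungap_alignment(a2)[names(seqs)], seqs)

  expect_error(progressive_align(c(only = "ACDE")), "at least 2")
})

test_that("p-distance counts mismatches over compared sites", {
  aln <- progressive_align(setNames(c("AAAA", "AAAA"), c("a", "b")),
                           prealigned = TRUE)
  expect_equal(p_distance(aln)["a", "b"], 0)

  aln2 <- progressive_align(setNames(c("AAAA", "AATT"), c("a", "b")),
                            prealigned = TRUE)
  expect_equal(p_distance(aln2)["a", "b"], 0.5)

  aln3 <- progressive_align(setNames(c("AA--", "AATT"), c("a", "b")),
                            prealigned = TRUE)
  expect_equal(p_distance(aln3)["a", "b"], 0)      # pairwise deletion

  aln4 <- progressive_align(setNames(c("AA--", "--TT"), c("a", "b")),
                            prealigned = TRUE)
  expect_error(p_distance(aln4), "no comparable sites")

  # complete deletion drops any gapped column for all pairs
  aln5 <- progressive_align(setNames(c("AAC-", "AATT", "GATT"),
                                     c("a", "b", "c")), prealigned = TRUE)
  d5 <- p_distance(aln5, deletion_mode = "complete")
  expect_equal(d5["b", "c"], 1 / 3)
})

test_that("p-distance is bounded, symmetric and zero iff identical sites", {
  set.seed(23)
  for (i in 1:10) {
    aln <- random_alignment(5, 30)
    d <- p_distance(aln)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    for (p in which(d == 0, arr.ind = TRUE)[, 1]) break
  }
})

test_that("Fitch scoring matches hand counts and is rooting-invariant", {
  m <- matrix(c("A", "A", "C", "C"), ncol = 1,
              dimnames = list(paste0("t", 1:4), NULL))
  aln <- structure(m, class = c("cnido_alignment", "matrix", "array"))
  t12 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  t13 <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(parsimony_score(t12, aln), 1L)
  expect_equal(parsimony_score(t13, aln), 2L)

  # all-identical columns cost nothing
  same <- structure(matrix("A", 4, 6, dimnames = list(paste0("t", 1:4),
                                                      NULL)),
                    class = c("cnido_alignment", "matrix", "array"))
  expect_equal(parsimony_score(t12, same), 0L)

  # re-rooting does not change the score
  set.seed(31)
  aln6 <- random_alignment(6, 20)
  tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
  s0 <- parsimony_score(tr, aln6)
  for (og in tr$tip.label) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(parsimony_score(rr, aln6), s0)
  }

  expect_error(parsimony_score(ape::rtree(4), aln6), "differ")
})

test_that("gap handling switches between 21st state and missing", {
  m <- matrix(c("A", "A", "-", "-"), ncol = 1,
              dimnames = list(paste0("t", 1:4), NULL))
  aln <- structure(m, class = c("cnido_alignment", "matrix", "array"))
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(parsimony_score(tr, aln, gap_mode = "state"), 1L)
  expect_equal(parsimony_score(tr, aln, gap_mode = "missing"), 0L)
})

test_that("Fitch equals brute-force state enumeration on 6-leaf trees", {
  set.seed(41)
  for (i in 1:12) {
    aln <- random_alignment(6, 8)
    tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
    expect_equal(parsimony_score(tr, aln), oracle_parsimony(tr, aln))
  }
})

test_that("Fitch agrees with an established parsimony implementation", {
  set.seed(43)
  for (i in 1:8) {
    aln <- random_alignment(7, 25, states = c("A", "C", "G", "T"))
    tr <- ape::rtree(7, tip.label = paste0("t", 1:7))
    pd <- phangorn::phyDat(unclass(aln), type = "DNA")
    expect_equal(parsimony_score(tr, aln),
                 as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("hill-climbing search attains the exhaustive optimum", {
  set.seed(47)
  for (i in 1:10) {
    aln <- random_alignment(7, 25)
    ex <- best_tree(aln, "parsimony", search = "exhaustive")
    hc <- best_tree(aln, "parsimony", search = "hillclimb", seed = i)
    expect_equal(hc$score, ex$score)
  }
})

test_that("neighbor joining recovers the topology behind an additive matrix", {
  set.seed(53)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    d <- stats::cophenetic(tr)
    nj <- ape::nj(as.dist(d))
    expect_equal(rf_dist(nj, tr), 0)
  }
})

test_that("canonical Newick is byte-stable and label-rotation invariant", {
  tr <- ape::read.tree(text = "((b,(d,c)),(a,e));")
  s1 <- canonical_newick(tr)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(canonical_newick(back), s1)
  set.seed(59)
  rot <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_equal(canonical_newick(rot), s1)
  expect_match(s1, ";$")
})

test_that("degenerate tree inputs raise errors", {
  aln <- random_alignment(2, 10)
  expect_error(best_tree(aln), "at least 3")
})
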