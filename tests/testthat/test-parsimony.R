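tree4 <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Fitch length on elementary cases matches labeling enumeration", {
  # constant character: zero steps
  M0 <- characterMatrix(matrix("1", 4, 1, dimnames = list(c("A","B","C","D"), NULL)))
  expect_equal(fitchLength(tree4, M0), 0)
  # one clean split: one step (verified by enumerating internal labelings)
  M1 <- characterMatrix(matrix(c("1","1","0","0"), 4, 1,
                               dimnames = list(c("A","B","C","D"), NULL)))
  expect_equal(fitchLength(tree4, M1), 1)
  expect_equal(fitchLength(tree4, M1), oracle_fitch(tree4, M1))
})

test_that("Fitch length equals the labeling-enumeration oracle on random matrices", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    mat <- matrix(sample(c("A", "C", "G", "T", "?"), n * 6, TRUE,
                         prob = c(.22, .22, .22, .22, .12)), n, 6,
                  dimnames = list(tr$tip.label, NULL))
    M <- characterMatrix(mat)
    expect_equal(fitchLength(tr, M), oracle_fitch(tr, M))
  }
})

test_that("Fitch length is invariant to rooting and taxon order", {
  set.seed(103)
  tr <- ape::rtree(7, rooted = FALSE)
  mat <- matrix(sample(c("0", "1"), 7 * 25, TRUE), 7, 25,
                dimnames = list(tr$tip.label, NULL))
  M <- characterMatrix(mat)
  s <- fitchLength(tr, M)
  for (og in tr$tip.label[1:3])
    expect_equal(fitchLength(ape::root(tr, og, resolve.root = TRUE), M), s)
  perm <- sample(nrow(mat))
  expect_equal(fitchLength(tr, characterMatrix(mat[perm, , drop = FALSE])), s)
})

test_that("m <= s <= g on random matrices and topologies", {
  set.seed(107)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    mat <- matrix(sample(c("0", "1", "?"), n * 15, TRUE,
                         prob = c(.45, .45, .1)), n, 15,
                  dimnames = list(tr$tip.label, NULL))
    M <- characterMatrix(mat)
    b <- plastomeR:::.char_bounds(M)
    steps <- fitchLength(tr, M, perCharacter = TRUE)
    expect_true(all(b$m <= steps + 1e-9))
    expect_true(all(steps <= b$g + 1e-9))
  }
})

test_that("per-character maximum steps g matches brute force over all topologies", {
  # binary character with 3 ones and 3 zeros over 6 taxa: g = 3
  labs <- LETTERS[1:6]
  st <- stats::setNames(c("1", "1", "1", "0", "0", "0"), labs)
  M <- characterMatrix(matrix(st, ncol = 1, dimnames = list(labs, NULL)))
  trees <- oracle_all_topologies(labs)
  expect_length(trees, 105L)
  worst <- max(vapply(trees, function(t) fitchLength(t, M), numeric(1)))
  expect_equal(plastomeR:::.char_bounds(M)$g, 3)
  expect_equal(worst, 3)
})

test_that("exhaustive search equals the independent topology enumeration", {
  set.seed(109)
  for (i in 1:6) {
    n <- sample(5:6, 1)
    labs <- paste0("t", seq_len(n))
    mat <- matrix(sample(c("0", "1"), n * 20, TRUE), n, 20,
                  dimnames = list(labs, NULL))
    M <- characterMatrix(mat)
    res <- exhaustiveSearch(M)
    trees <- oracle_all_topologies(labs)
    lens <- vapply(trees, function(t) fitchLength(t, M), numeric(1))
    expect_equal(res$score@steps, min(lens))
    # every reported optimum scores the optimum; each optimal topology in
    # the oracle enumeration matches one reported tree
    opt_oracle <- trees[lens == min(lens)]
    expect_equal(length(res$trees), length(opt_oracle))
    for (t in opt_oracle)
      expect_true(any(vapply(res$trees, function(x)
        ape::dist.topo(ape::unroot(x), ape::unroot(t)) == 0, logical(1))))
  }
  expect_error(exhaustiveSearch(characterMatrix(
    matrix("1", 3, 1, dimnames = list(c("a", "b", "c"), NULL)))), "4-9")
})

test_that("all-constant matrices tie every topology at zero steps", {
  labs <- LETTERS[1:6]
  M <- characterMatrix(matrix("0", 6, 5, dimnames = list(labs, NULL)))
  res <- exhaustiveSearch(M)
  expect_equal(res$score@steps, 0)
  expect_length(res$trees, 105L)
  expect_true(all(res$lengths == 0))
})

test_that("CI and RI match the reference implementation and a homoplasy-free case", {
  # homoplasy-free: CI = 1
  labs <- LETTERS[1:6]
  tr <- ape::read.tree(text = "(A,(B,(C,(D,(E,F)))));")
  mat <- cbind(c("1","1","0","0","0","0"), c("0","0","0","0","1","1"),
               c("1","1","1","0","0","0"))
  dimnames(mat) <- list(labs, NULL)
  M <- characterMatrix(mat)
  sc <- scoreStats(tr, M)
  expect_equal(sc@ci, 1)
  # against phangorn on random binary data at the search optimum
  set.seed(113)
  mat <- matrix(sample(c("0", "1"), 6 * 40, TRUE, prob = c(.6, .4)), 6, 40,
                dimnames = list(labs, NULL))
  M <- characterMatrix(mat)
  res <- exhaustiveSearch(M)
  pd <- phangorn::phyDat(mat, type = "USER", levels = c("0", "1"))
  best <- res$trees[[1]]
  expect_equal(res$score@steps, phangorn::parsimony(best, pd))
  expect_equal(res$score@ci, phangorn::CI(best, pd))
  expect_equal(res$score@ri, phangorn::RI(best, pd))
})

test_that("bootstrap support: single-signal matrix, determinism, range", {
  labs <- LETTERS[1:6]
  # one variable character: its induced bipartition gets 100%, nothing else
  mat <- matrix(c("1", "1", "0", "0", "0", "0"), ncol = 1,
                dimnames = list(labs, NULL))
  M <- characterMatrix(mat)
  bs <- bootstrapSupport(M, reps = 40, seed = 7)
  expect_identical(names(bs), "C|D|E|F")   # {A,B} vs rest, canonical side
  expect_equal(unname(bs[["C|D|E|F"]]), 100)
  # fixed seed: bit-identical support on re-run
  set.seed(131)
  mat2 <- matrix(sample(c("0", "1"), 6 * 30, TRUE), 6, 30,
                 dimnames = list(labs, NULL))
  M2 <- characterMatrix(mat2)
  b1 <- bootstrapSupport(M2, reps = 25, seed = 99)
  b2 <- bootstrapSupport(M2, reps = 25, seed = 99)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 100))
  expect_error(bootstrapSupport(M2, reps = 5), "seed")
})

test_that("character mapping classifies synapomorphy vs homoplasy and polarity", {
  tr <- ape::read.tree(text = "(OG,(A,(B,(C,(D,E)))));")
  # derived state confined to the cherry (D,E): single origin
  st <- stats::setNames(c("0", "0", "0", "0", "1", "1"),
                        c("OG", "A", "B", "C", "D", "E"))
  f <- mapCharacter(tr, st, "OG")
  expect_equal(f$origins, 1)
  expect_equal(f$classification, "synapomorphic")
  expect_setequal(f$derived_taxa, c("D", "E"))
  expect_equal(f$polarity, "-")  # gap (1) is derived => deletion
  # derived state in two clades separated by ancestral taxa: two origins
  st2 <- stats::setNames(c("0", "1", "0", "1", "1", "0"),
                         c("OG", "A", "B", "C", "D", "E"))
  f2 <- mapCharacter(tr, st2, "OG")
  expect_equal(f2$origins, oracle_fitch(tr, characterMatrix(
    matrix(st2, ncol = 1, dimnames = list(names(st2), NULL)))))
  expect_equal(f2$classification, "homoplasious")
  # polarity flips with the outgroup state
  st3 <- st; st3[["OG"]] <- "1"
  expect_equal(mapCharacter(tr, st3, "OG")$polarity, "+")
  # missing outgroup state: polarity undetermined
  st4 <- st; st4[["OG"]] <- "?"
  expect_true(is.na(mapCharacter(tr, st4, "OG")$polarity))
})

test_that("heuristic search finds the planted topology beyond the exhaustive cap", {
  set.seed(137)
  tr0 <- ape::rtree(12, rooted = FALSE)
  h <- simulateRepeatHistory(tr0, nChar = 90, homoplasyProb = 0, seed = 3)
  res <- heuristicSearch(h$matrix, seed = 1)
  # characters are compatible (one gain each), so the global optimum has
  # CI = 1; reaching it means the tree displays every character's split
  expect_equal(res$score@steps, res$score@minSteps)
  expect_equal(res$score@ci, 1)
  # the true tree scores the same optimum
  expect_equal(fitchLength(tr0, h$matrix), res$score@steps)
})

test_that("NEXUS and PHYLIP matrix writers round-trip", {
  labs <- paste0("tax", 1:5)
  mat <- matrix(sample(c("0", "1", "?"), 5 * 12, TRUE), 5, 12,
                dimnames = list(labs, NULL))
  M <- characterMatrix(mat)
  nex <- withr::local_tempfile(fileext = ".nex")
  writeNexusMatrix(M, nex)
  M2 <- readNexusMatrix(nex)
  expect_equal(unname(characterStates(M2)), unname(mat))
  expect_equal(taxa(M2), labs)
  phy <- withr::local_tempfile(fileext = ".phy")
  writePhylipMatrix(M, phy)
  M3 <- readPhylipMatrix(phy)
  expect_equal(unname(characterStates(M3)), unname(mat))
  expect_equal(taxa(M3), labs)
  # DNA matrices survive too
  dmat <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 9, TRUE), 4, 9,
                 dimnames = list(labs[1:4], NULL))
  Md <- characterMatrix(dmat)
  writeNexusMatrix(Md, nex)
  expect_equal(unname(characterStates(readNexusMatrix(nex))), unname(dmat))
})

test_that("strict consensus keeps only shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  cons <- strictConsensus(c(t1, t2))
  bp <- plastomeR:::.bipartitions(ape::unroot(cons))
  expect_true(all(vapply(bp, function(b)
    b %in% intersect(plastomeR:::.bipartitions(ape::unroot(t1)),
                     plastomeR:::.bipartitions(ape::unroot(t2))), logical(1))))
})
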