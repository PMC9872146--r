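abc_distance <- function() {
  matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

test_that("dice matches hand counts and validates input", {
  expect_equal(dice(c(1, 1, 0, 1), c(1, 0, 1, 1)), 2 / 3)
  expect_equal(dice(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(dice(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(dice(c(0, 0), c(0, 0)), "undefined")
  expect_error(dice(c(1, 2), c(1, 0)), "0/1")
})

test_that("one minus dice can violate the triangle inequality", {
  # the pipeline documents this and never assumes metricity
  a <- c(1, 0)
  b <- c(1, 1)
  cc <- c(0, 1)
  d_ab <- 1 - dice(a, b)
  d_bc <- 1 - dice(b, cc)
  d_ac <- 1 - dice(a, cc)
  expect_gt(d_ac, d_ab + d_bc)
})

test_that("similarity_matrix equals brute-force pairwise dice", {
  m <- random_allele_matrix(8, 3, seed = 21)
  s <- similarity_matrix(m)
  mat <- as_matrix(m)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_equal(s[i, j], dice(mat[i, ], mat[j, ]))
    }
  }
  expect_identical(diag(s), setNames(rep(1, 8), rownames(mat)))
  expect_equal(s, t(s))
  # cross-check against an independent implementation: binary Bray-Curtis
  # dissimilarity equals 1 - Dice
  vd <- as.matrix(vegan::vegdist(mat, method = "bray"))
  expect_equal(unname(1 - s), unname(vd), tolerance = 1e-12)
})

test_that("missing-amplification policies agree on complete data and differ sensibly", {
  panel <- toy_panel()
  complete <- binarize(toy_genotypes(list(
    A = list(L1 = 100, L2 = 200), B = list(L1 = 105, L2 = 210),
    C = list(L1 = 100, L2 = 210)
  )), panel)
  expect_equal(similarity_matrix(complete, "zeros"),
               similarity_matrix(complete, "pairwise-complete"))

  # with one missing locus, pairwise-complete ignores it for that pair
  with_miss <- binarize(toy_genotypes(list(
    A = list(L1 = 100, L2 = 200), B = list(L1 = 100, L2 = numeric(0))
  )), panel)
  sz <- similarity_matrix(with_miss, "zeros")
  sp <- similarity_matrix(with_miss, "pairwise-complete")
  expect_equal(sz["A", "B"], 2 * 1 / (2 + 1))
  expect_equal(sp["A", "B"], 1)

  zero_row <- binarize(toy_genotypes(list(
    A = list(L1 = 100), B = list(L1 = numeric(0))
  )), panel)
  expect_error(similarity_matrix(zero_row), "no scored band")
})

test_that("upgma reproduces the hand-worked three-leaf merge", {
  tree <- upgma(abc_distance())
  td <- tidy(tree)
  expect_equal(td$height, c(1, 4))
  coph <- cophenetic_matrix(tree)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 8)
  expect_equal(coph["B", "C"], 8)

  # two leaves: single node at d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(tidy(upgma(d2))$height, 1.5)

  # all distances equal: every internal merge at the same height
  de <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  expect_equal(unique(tidy(upgma(de))$distance), 1)

  dn <- abc_distance()
  dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(upgma(dn), "NA")
})

test_that("upgma agrees exactly with the naive from-scratch reference", {
  for (seed in 1:20) {
    n <- sample(5:7, 1)
    d <- random_distance(n, seed)
    expect_equal(cophenetic_matrix(upgma(d)), oracle_upgma_coph(d),
                 tolerance = 1e-12)
  }
})

test_that("upgma agrees with hclust average linkage on tie-free input", {
  for (seed in 31:35) {
    d <- random_distance(12, seed)
    ours <- cophenetic_matrix(upgma(d))
    ref <- as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(d), "average")))
    expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-12)
  }
})

test_that("upgma trees are ultrametric (three-point condition)", {
  d <- random_distance(20, seed = 8)
  coph <- cophenetic_matrix(upgma(d))
  set.seed(9)
  for (r in 1:200) {
    trip <- sample(20, 3)
    dd <- sort(c(coph[trip[1], trip[2]], coph[trip[1], trip[3]],
                 coph[trip[2], trip[3]]))
    expect_lte(dd[2], dd[3] + 1e-12)
    expect_equal(dd[2], dd[3], tolerance = 1e-9)
  }
  # heights non-decreasing from leaves to root
  expect_true(!is.unsorted(upgma(d)$height))
})

test_that("cophenetic correlation is 1 on ultrametric input and permutation-invariant", {
  d <- random_distance(10, seed = 12)
  tree <- upgma(d)
  coph <- cophenetic_matrix(tree)
  # the cophenetic matrix is itself ultrametric: refitting is exact
  expect_equal(cophenetic_correlation(coph, cophenetic_matrix(upgma(coph))), 1)

  r0 <- cophenetic_correlation(d, coph)
  perm <- sample(rownames(d))
  expect_equal(cophenetic_correlation(d[perm, perm], coph[perm, perm]), r0)

  const <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(const) <- 0
  expect_error(cophenetic_correlation(const, const), "constant")
})

test_that("the fitted tree outscores random alternative ultrametric trees", {
  d <- random_distance(12, seed = 14)
  fit <- cophenetic_correlation(d, cophenetic_matrix(upgma(d)))
  for (seed in 15:19) {
    alt <- cophenetic_matrix(upgma(random_distance(12, seed)))
    expect_gte(fit, cophenetic_correlation(d, alt))
  }
})

test_that("cut_k extracts subtree clusters labelled by layout order", {
  tree <- upgma(abc_distance())
  cl2 <- cut_k(tree, 2)
  grp <- split(cl2$accession, cl2$cluster)
  expect_setequal(grp[[which(lengths(grp) == 2)]], c("A", "B"))
  expect_setequal(grp[[which(lengths(grp) == 1)]], "C")

  cl1 <- cut_k(tree, 1)
  expect_identical(unique(cl1$cluster), "A")
  cln <- cut_k(tree, 3)
  expect_identical(sort(cln$cluster), c("A", "B", "C"))
  expect_error(cut_k(tree, 0), "k must be")
  expect_error(cut_k(tree, 4), "k must be")

  # labels follow leftmost-leaf layout positions
  d <- random_distance(9, seed = 23)
  tree9 <- upgma(d)
  cl <- cut_k(tree9, 4)
  layout <- tree9$labels[tree9$order]
  first_seen <- cl$cluster[match(layout, cl$accession)]
  expect_identical(unique(first_seen), LETTERS[1:4])
})

test_that("newick export encodes branch lengths and round-trips via ape", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(to_newick(upgma(d2)), "(A:1,B:1);")
  expect_identical(to_newick(upgma(abc_distance())), "((A:1,B:1):3,C:4);")

  d <- random_distance(10, seed = 30)
  tree <- upgma(d)
  phy <- ape::read.tree(text = to_newick(tree))
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
  back <- ape::cophenetic.phylo(phy)
  coph <- cophenetic_matrix(tree)
  expect_equal(back[rownames(coph), colnames(coph)], coph, tolerance = 1e-8)
})
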