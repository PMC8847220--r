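test_that("UPGMA reproduces the hand-agglomerated ultrametric example", {
  m <- four_taxon_ultrametric()
  tr <- upgma_tree(m)
  expect_true(ape::is.ultrametric(tr))
  # topology (((A,B),C),D)
  expected <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  expect_equal(robinson_foulds(tr, expected), 0)
  # merge heights 1, 2, 3 <=> path distances reproduce the input exactly
  expect_equal(unclass(tree_distances(tr)), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  # root equidistant from every leaf
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-12)
})

test_that("UPGMA on two taxa halves the distance onto each branch", {
  m <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma_tree(m)
  expect_equal(sort(tr$edge.length), c(2, 2))
})

test_that("UPGMA reconstructs random ultrametric matrices exactly", {
  withr::with_seed(53, {
    for (rep in 1:8) {
      m <- ultrametric_matrix(sample(4:10, 1))
      expect_equal(unclass(tree_distances(upgma_tree(m))), m,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  })
})

test_that("NJ recovers the additive 4-taxon example with exact lengths", {
  m <- four_taxon_additive()
  tr <- nj_tree(m)
  # split AB|CD present
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(robinson_foulds(tr, gen), 0)
  # additivity: induced path distances equal the input exactly
  expect_equal(unclass(tree_distances(tr)), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  # terminal branch lengths recovered
  tips <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(tips[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("NJ on three taxa uses the closed-form three-point lengths", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  tips <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  # a = (dAB + dAC - dBC)/2 etc.
  expect_equal(tips[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ reconstructs random additive matrices on <= 8 taxa", {
  withr::with_seed(59, {
    for (rep in 1:8) {
      tr0 <- random_tree(sample(4:8, 1))
      m <- additive_matrix(tr0)
      tr <- nj_tree(m)
      expect_equal(robinson_foulds(tr, tr0), 0)
      expect_equal(unclass(tree_distances(tr)), m, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("BIONJ agrees with NJ on additive input and three taxa", {
  m <- four_taxon_additive()
  expect_equal(robinson_foulds(bionj_tree(m), nj_tree(m)), 0)
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unclass(tree_distances(bionj_tree(m3))),
               unclass(tree_distances(nj_tree(m3))), tolerance = 1e-9)
})

test_that("BIONJ recovers the generating topology under small noise", {
  withr::with_seed(61, {
    hits <- 0L
    n_rep <- 100L
    for (rep in seq_len(n_rep)) {
      tr0 <- random_tree(8, min_edge = 1, max_edge = 3)
      m <- additive_matrix(tr0)
      noise <- matrix(rnorm(64, sd = 0.05), 8)
      noise <- (noise + t(noise)) / 2
      diag(noise) <- 0
      mp <- pmax(m + noise, 0)
      dimnames(mp) <- dimnames(m)
      if (robinson_foulds(bionj_tree(mp), tr0) == 0) hits <- hits + 1L
    }
    expect_gte(hits / n_rep, 0.9)
  })
})

test_that("clamped trees never carry negative branch lengths", {
  withr::with_seed(67, {
    for (rep in 1:10) {
      k <- 6
      m <- matrix(runif(k * k, 1, 5), k)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      dimnames(m) <- list(sprintf("X%d", 1:k), sprintf("X%d", 1:k))
      suppressMessages({
        expect_true(all(nj_tree(m)$edge.length >= 0))
        expect_true(all(bionj_tree(m)$edge.length >= 0))
      })
    }
  })
})

test_that("scaling a matrix preserves topology and scales branch lengths", {
  withr::with_seed(71, tr0 <- random_tree(7))
  m <- additive_matrix(tr0)
  for (builder in list(nj_tree, bionj_tree, upgma_tree)) {
    t1 <- builder(m)
    t5 <- builder(5 * m)
    expect_equal(robinson_foulds(t1, t5), 0)
    expect_equal(sort(t5$edge.length), sort(5 * t1$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("tree output is invariant to input row order", {
  withr::with_seed(73, tr0 <- random_tree(6))
  m <- additive_matrix(tr0)
  perm <- sample(nrow(m))
  t1 <- bionj_tree(m)
  t2 <- bionj_tree(m[perm, perm])
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("outgroup rooting keeps ingroup splits and is idempotent", {
  withr::with_seed(79, tr <- random_tree(6))
  rooted <- root_with_outgroup(tr, "T01")
  expect_true(ape::is.rooted(rooted))
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 ape::Ntip(rooted) + 1, 2]
  expect_true(which(rooted$tip.label == "T01") %in% root_children)
  expect_equal(robinson_foulds(rooted, tr), 0)
  twice <- root_with_outgroup(rooted, "T01")
  expect_equal(robinson_foulds(twice, rooted), 0)
  expect_error(root_with_outgroup(tr, "NOPE"), "not a leaf")
})

test_that("Robinson-Foulds counts symmetric split differences", {
  t_ab <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t_ac <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(t_ab, t_ab), 0)
  expect_equal(robinson_foulds(t_ab, t_ac), 2)
  withr::with_seed(83, {
    for (rep in 1:5) {
      a <- random_tree(8); b <- random_tree(8); c <- random_tree(8)
      expect_equal(robinson_foulds(a, b), robinson_foulds(b, a))
      expect_gte(robinson_foulds(a, b), 0)
      # metric triangle inequality on tree space
      expect_lte(robinson_foulds(a, c),
                 robinson_foulds(a, b) + robinson_foulds(b, c))
    }
  })
  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(robinson_foulds(t_ab, t3), "leaf label sets")
})
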