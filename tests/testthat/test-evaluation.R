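# Metrics: AUCs against a concordance oracle (and pROC), complete-linkage
# dendrograms against a naive farthest-point oracle, purity metrics against
# an enumeration oracle, and the cross-validation split contracts.

test_that("ROCAUC/PRAUC behave at the extremes", {
  lab <- c(rep(1, 5), rep(-1, 5))
  expect_equal(binaryAucs(lab, 10:1)[["rocauc"]], 1)
  expect_equal(binaryAucs(lab, 10:1)[["prauc"]], 1)
  set.seed(50)
  lab2 <- sample(c(0, 1), 4000, TRUE)
  scr <- runif(4000)
  expect_equal(binaryAucs(lab2, scr)[["rocauc"]], 0.5, tolerance = 0.03)
  expect_error(binaryAucs(rep(1, 5), runif(5)), "both classes")
})

test_that("ROCAUC equals the all-pairs concordance count, ties included", {
  set.seed(51)
  for (rep in 1:20) {
    lab <- sample(c(-1, 1), 20, TRUE)
    if (length(unique(lab)) < 2) next
    scr <- sample(seq(0, 1, by = 0.1), 20, TRUE) # plenty of ties
    expect_equal(
      binaryAucs(lab, scr)[["rocauc"]],
      oracleRocAuc(lab, scr),
      tolerance = 1e-12
    )
  }
})

test_that("ROCAUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  lab <- sample(c(0, 1), 200, TRUE)
  scr <- runif(200) + 0.3 * lab
  ref <- as.numeric(pROC::auc(pROC::roc(lab, scr, quiet = TRUE)))
  expect_equal(binaryAucs(lab, scr)[["rocauc"]], ref, tolerance = 1e-12)
})

test_that("dendrograms follow the farthest-point criterion", {
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc <- buildDendrogram(D2)
  expect_equal(hc$height, 3)
  # two tight pairs merge before anything else
  D4 <- matrix(10, 4, 4)
  D4[1, 2] <- D4[2, 1] <- 1
  D4[3, 4] <- D4[4, 3] <- 2
  diag(D4) <- 0
  dimnames(D4) <- list(letters[1:4], letters[1:4])
  hc4 <- buildDendrogram(D4)
  sets <- hclustLeafSets(hc4)
  expect_identical(sets[[1]], c(1L, 2L))
  expect_identical(sets[[2]], c(3L, 4L))
  expect_true(all(diff(hc4$height) >= 0))
  expect_error(buildDendrogram(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  bad <- D4
  bad[1, 2] <- bad[2, 1] <- -1
  expect_error(buildDendrogram(bad), "nonnegative")
})

test_that("dendrograms match a naive complete-linkage oracle", {
  set.seed(53)
  for (rep in 1:8) {
    n <- sample(5:15, 1)
    P <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(dist(P))
    hc <- buildDendrogram(D)
    orc <- oracleCompleteLinkage(D)
    expect_equal(hclustLeafSets(hc), orc$leafSets)
    expect_equal(hc$height, orc$heights, tolerance = 1e-12)
  }
})

test_that("exact dendrogram purity matches hand-worked and oracle values", {
  # tree ((a1,b1),(a2,b2)) with classes A,A,B,B: every pair meets at the
  # root, half of whose leaves share the class
  hc <- structure(
    list(
      merge = rbind(c(-1L, -3L), c(-2L, -4L), c(1L, 2L)),
      height = c(1, 1.5, 2), order = c(1L, 3L, 2L, 4L),
      labels = c("a1", "a2", "b1", "b2"), method = "complete"
    ),
    class = "hclust"
  )
  labs <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(dendrogramPurityExact(hc, labs), 0.5)
  # invariant under class renaming
  relab <- c(a1 = "Z", a2 = "Z", b1 = "Q", b2 = "Q")
  expect_equal(dendrogramPurityExact(hc, relab), 0.5)
  # pure subtrees score exactly 1
  hcPure <- structure(
    list(
      merge = rbind(c(-1L, -2L), c(-3L, -4L), c(1L, 2L)),
      height = c(1, 1.5, 2), order = 1:4,
      labels = c("a1", "a2", "b1", "b2"), method = "complete"
    ),
    class = "hclust"
  )
  expect_equal(dendrogramPurityExact(hcPure, labs), 1)
  set.seed(54)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    hcR <- randomDendrogram(n)
    labsR <- sample(LETTERS[1:3], n, TRUE)
    if (!any(duplicated(labsR))) next
    expect_equal(
      dendrogramPurityExact(hcR, labsR),
      oracleExactPurity(hcR, labsR),
      tolerance = 1e-12
    )
  }
  expect_error(
    dendrogramPurityExact(hcPure, c(a1 = "A", a2 = "B", b1 = "C", b2 = "D")),
    "no same-class"
  )
})

test_that("sampled EDP reduces to the exact purity under exhaustive k", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    hc <- randomDendrogram(n)
    labs <- sample(LETTERS[1:2], n, TRUE)
    if (!any(duplicated(labs))) next
    expect_equal(
      expectedDendrogramPurity(hc, labs, k = 1000),
      dendrogramPurityExact(hc, labs),
      tolerance = 1e-12
    )
  }
})

test_that("sampled EDP converges to the exact value as k grows", {
  set.seed(56)
  hc <- randomDendrogram(20)
  labs <- sample(LETTERS[1:3], 20, TRUE)
  exact <- dendrogramPurityExact(hc, labs)
  set.seed(57)
  expect_lt(abs(expectedDendrogramPurity(hc, labs, k = 200) - exact), 0.05)
  # seeded sampling is reproducible
  set.seed(58)
  e1 <- expectedDendrogramPurity(hc, labs, k = 3)
  set.seed(58)
  e2 <- expectedDendrogramPurity(hc, labs, k = 3)
  expect_identical(e1, e2)
})

test_that("EDP averages over levels and skips pairless levels", {
  set.seed(59)
  hc <- randomDendrogram(8, labels = sprintf("e%d", 1:8))
  l1 <- setNames(rep(c("A", "B"), each = 4), sprintf("e%d", 1:8))
  l2 <- setNames(rep(c("A/x", "A/y", "B/x", "B/y"), each = 2), sprintf("e%d", 1:8))
  set.seed(60)
  edp <- expectedDendrogramPurity(hc, list(l1, l2), k = 1000)
  expect_equal(
    edp,
    mean(c(dendrogramPurityExact(hc, l1), dendrogramPurityExact(hc, l2))),
    tolerance = 1e-12
  )
  # a leaf level of singletons is skipped with a warning
  leafLevel <- setNames(sprintf("s%d", 1:8), sprintf("e%d", 1:8))
  expect_warning(
    withLeaf <- expectedDendrogramPurity(hc, list(l1, leafLevel), k = 1000),
    "skipped"
  )
  expect_equal(withLeaf, dendrogramPurityExact(hc, l1))
})

test_that("EDP is 1 exactly when every class forms a pure subtree", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    hc <- randomDendrogram(n)
    labs <- sample(LETTERS[1:sample(2:3, 1)], n, TRUE)
    if (!any(duplicated(labs))) next
    edp <- expectedDendrogramPurity(hc, labs, k = 1000)
    expect_gte(edp, 0)
    expect_lte(edp, 1)
    expect_equal(edp == 1, allClassesPure(hc, labs))
  }
})

test_that("level labels keep identically named children of different parents apart", {
  paths <- list(
    e1 = c("A", "x", "e1"), e2 = c("A", "x", "e2"),
    e3 = c("B", "x", "e3"), e4 = c("B", "y", "e4")
  )
  tree <- hierarchyTree(paths, "nr3")
  lv <- levelLabels(tree)
  expect_equal(length(lv), 2L)
  expect_equal(unname(lv$level1), c("A", "A", "B", "B"))
  # 'x' under A and 'x' under B are different classes
  expect_false(lv$level2[["e1"]] == lv$level2[["e3"]])
  expect_true(lv$level2[["e1"]] == lv$level2[["e2"]])
})

test_that("cross-validation folds partition the interactions", {
  data <- tinyDataset(nd = 10, nt = 5, fd = 4, seed = 62)
  set.seed(63)
  folds <- crossvalSplit(data, 5)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), seq_len(nrow(interactions(data))))
  expect_lte(diff(range(lengths(folds))), 1L)
  # 10 interactions over 5 folds -> folds of 2
  small <- interactions(data)[1:10, ]
  set.seed(64)
  f10 <- crossvalSplit(small, 5)
  expect_true(all(lengths(f10) == 2L))
  set.seed(65)
  a <- crossvalSplit(data, 4)
  set.seed(65)
  b <- crossvalSplit(data, 4)
  expect_identical(a, b)
  expect_error(crossvalSplit(small[1:3, ], 5), "fewer interactions")
  expect_error(crossvalSplit(small, 1), "at least 2")
})

test_that("dendrograms export to Newick with merge heights", {
  D <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  rownames(D) <- colnames(D) <- sprintf("e%d", 1:6)
  hc <- buildDendrogram(D)
  f <- tempfile(fileext = ".nwk")
  writeNewick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, sprintf("e%d", 1:6))
  expect_equal(max(ape::node.depth.edgelength(tr)), max(hc$height) / 2,
    tolerance = 1e-6
  )
})
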