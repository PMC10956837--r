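# Hierarchy parsing, LCA/hop distance matrices (against brute-force
# oracles), and the anchor/positive/negative sampler contracts.

test_that("leveled hierarchy files parse, keeping duplicate paths", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "d1\tA\tA1\tA1a\tA1a1\td1.1",
    "d1\tB\tB1\tB1a\tB1a1\td1.2",
    "d2\tA\tA1\tA1a\tA1a2\td2.1",
    "d3\tB\tB2\tB2a\tB2a1\td3.1"
  ), f)
  tree <- parseHierarchy(f, "atc5")
  expect_s4_class(tree, "HierarchyTree")
  expect_equal(length(tree), 3L)
  expect_equal(nrow(tree@paths[["d1"]]), 2L) # both ATC codes retained
  expect_equal(tree@depth, 5L)
  # wrong path length
  g <- tempfile(fileext = ".tsv")
  writeLines("d1\tA\tA1\tA1a\tA1a1", g)
  expect_error(parseHierarchy(g, "atc5"), "columns")
  suppressWarnings(expect_error(parseHierarchy(tempfile(), "atc5"), "parse|cannot"))
})

test_that("hierarchy TSV round-trips through write/parse", {
  set.seed(20)
  tree <- randomToyTree(8, "kinase4")
  f <- tempfile(fileext = ".tsv")
  writeHierarchy(tree, f)
  back <- parseHierarchy(f, "kinase4")
  expect_setequal(entities(back), entities(tree))
  expect_equal(
    distanceMatrix(lcaDistanceMatrix(back))[entities(tree), entities(tree)],
    distanceMatrix(lcaDistanceMatrix(tree))
  )
})

test_that("LCA distances follow the level rules", {
  # share ATC1..ATC4, differ at the leaf -> 1; different ATC1 -> 5
  paths <- list(
    d1 = c("A", "A1", "A1a", "A1a1", "d1"),
    d2 = c("A", "A1", "A1a", "A1a1", "d2"),
    d3 = c("B", "B1", "B1a", "B1a1", "d3")
  )
  D <- distanceMatrix(lcaDistanceMatrix(hierarchyTree(paths, "atc5")))
  expect_equal(D["d1", "d2"], 1)
  expect_equal(D["d1", "d3"], 5)
  expect_equal(diag(D), c(d1 = 0, d2 = 0, d3 = 0))
})

test_that("the other/atypical override raises group-level kinase distances", {
  paths <- list(
    k1 = c("other", "f1", "s1", "k1"),
    k2 = c("other", "f2", "s1", "k2"),
    k3 = c("other", "f1", "s2", "k3"),
    k4 = c("TK", "f1", "s1", "k4"),
    k5 = c("TK", "f2", "s1", "k5")
  )
  D <- distanceMatrix(lcaDistanceMatrix(hierarchyTree(paths, "kinase4")))
  expect_equal(D["k1", "k2"], 4) # LCA is the 'other' group node: 4 not 3
  expect_equal(D["k1", "k3"], 2) # shared family inside 'other': no override
  expect_equal(D["k4", "k5"], 3) # ordinary group keeps distance 3
})

test_that("duplicate-leaf entities take the minimum over path pairs", {
  paths <- list(
    d1 = rbind(
      c("A", "A1", "A1a", "A1a1", "d1.1"),
      c("B", "B1", "B1a", "B1a1", "d1.2")
    ),
    d2 = c("B", "B1", "B1a", "B1a2", "d2"),
    d3 = c("A", "A2", "A2a", "A2a1", "d3")
  )
  D <- distanceMatrix(lcaDistanceMatrix(hierarchyTree(paths, "atc5")))
  expect_equal(D["d1", "d2"], 2) # via d1's second code, not 5 via the first
  expect_equal(D["d1", "d3"], 4)
})

test_that("LCA matrix equals the brute-force all-path-pairs oracle", {
  set.seed(21)
  for (rep in 1:12) {
    kind <- sample(c("atc5", "kinase4", "nr3"), 1)
    tree <- randomToyTree(sample(5:30, 1), kind)
    dm <- lcaDistanceMatrix(tree)
    expect_equal(distanceMatrix(dm), oracleLcaMatrix(tree))
    expect_error(hopDistanceMatrix(tree), "graph")
  }
})

test_that("LCA distances are invariant to entity reordering", {
  set.seed(22)
  tree <- randomToyTree(10, "atc5")
  perm <- sample(entities(tree))
  tree2 <- hierarchyTree(tree@paths[perm], "atc5")
  D1 <- distanceMatrix(lcaDistanceMatrix(tree))
  D2 <- distanceMatrix(lcaDistanceMatrix(tree2))
  expect_equal(D2[rownames(D1), colnames(D1)], D1)
})

test_that("hop distances equal shortest-path counts on graphs", {
  # path graph a-b-c-d plus a star e-f, e-g
  g <- hierarchyGraph(data.frame(
    from = c("a", "b", "c", "e", "e"),
    to = c("b", "c", "d", "f", "g")
  ))
  dm <- hopDistanceMatrix(g)
  D <- distanceMatrix(dm)
  expect_equal(D["a", "b"], 1)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "d"], 3)
  expect_equal(D["f", "g"], 2)
  expect_true(is.infinite(D["a", "e"])) # different components
  expect_error(hopDistanceMatrix(g, disconnected = "error"), "disconnected")
})

test_that("regularization batches respect the farther-negative contract", {
  set.seed(23)
  for (rep in 1:10) {
    tree <- randomToyTree(sample(8:25, 1), sample(c("atc5", "nr3"), 1))
    dm <- lcaDistanceMatrix(tree)
    batch <- sampleRegularizationBatch(dm, n = 5, m = 6)
    D <- distanceMatrix(dm)
    for (i in seq_along(batch$anchors)) {
      a <- batch$anchors[i]
      dpos <- D[a, batch$positives[i]]
      expect_lt(dpos, tree@depth) # positives share a non-root ancestor
      expect_gt(dpos, 0)
      expect_false(batch$positives[i] == a)
      for (k in batch$negatives[[i]]) expect_gt(D[a, k], dpos)
      expect_lte(length(batch$negatives[[i]]), 6)
    }
  }
})

test_that("anchors whose neighbors all sit at maximal distance are excluded", {
  # d3 only relates to the others through the root
  paths <- list(
    d1 = c("A", "A1", "d1"),
    d2 = c("A", "A2", "d2"),
    d3 = c("B", "B1", "d3")
  )
  dm <- lcaDistanceMatrix(hierarchyTree(paths, "nr3"))
  set.seed(24)
  for (rep in 1:20) {
    batch <- sampleRegularizationBatch(dm, n = 3, m = 2)
    expect_false("d3" %in% batch$anchors)
    expect_false("d3" %in% batch$positives)
  }
  # a hierarchy where nobody has a non-root ancestor cannot be sampled
  lonely <- hierarchyTree(
    list(a = c("A", "A1", "a"), b = c("B", "B1", "b")), "nr3"
  )
  expect_error(
    sampleRegularizationBatch(lcaDistanceMatrix(lonely), 1, 1),
    "positive candidate"
  )
})

test_that("negatives are exactly the leaves farther than the drawn positive", {
  paths <- list(
    d1 = c("A", "A1", "d1"),
    d2 = c("A", "A1", "d2"), # distance 1 from d1
    d3 = c("A", "A2", "d3"), # distance 2 from d1
    d4 = c("B", "B1", "d4") # distance 3 from d1
  )
  dm <- lcaDistanceMatrix(hierarchyTree(paths, "nr3"))
  set.seed(25)
  seen <- character(0)
  for (rep in 1:50) {
    batch <- sampleRegularizationBatch(dm, n = 4, m = 10)
    i <- match("d1", batch$anchors)
    if (is.na(i)) next
    seen <- c(seen, batch$positives[i])
    if (batch$positives[i] == "d2") {
      expect_setequal(batch$negatives[[i]], c("d3", "d4"))
    } else if (batch$positives[i] == "d3") {
      expect_setequal(batch$negatives[[i]], "d4")
    }
  }
  # distance-uniform sampling realizes both candidate distances
  expect_setequal(unique(seen), c("d2", "d3"))
})

test_that("batch sampling is reproducible under a fixed seed", {
  set.seed(26)
  tree <- randomToyTree(15, "atc5")
  dm <- lcaDistanceMatrix(tree)
  set.seed(99)
  b1 <- sampleRegularizationBatch(dm, 5, 4)
  set.seed(99)
  b2 <- sampleRegularizationBatch(dm, 5, 4)
  expect_identical(b1, b2)
})
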