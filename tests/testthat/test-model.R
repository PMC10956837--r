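# Objective closed forms, analytic-vs-numeric gradients, prediction heads,
# batch assembly, and training behavior on tiny data.

test_that("weighted BCE matches hand-computed values", {
  # near-perfect predictions vanish
  expect_lt(weightedBce(c(1 - 1e-9, 1e-9), c(1, -1)), 1e-6)
  # one positive at p = 0.5 with 2:1 weights
  expect_equal(weightedBce(0.5, 1, posWeight = 2, negWeight = 1), 2 * log(2),
    tolerance = 1e-9
  )
  # one negative at p = 0.5 with 1:2 weights
  expect_equal(weightedBce(0.5, -1, posWeight = 1, negWeight = 2), 2 * log(2),
    tolerance = 1e-9
  )
  # mean over samples, clamped extremes stay finite
  expect_true(is.finite(weightedBce(c(0, 1), c(1, -1))))
  expect_error(weightedBce(c(0.5), c(1, -1)), "length")
})

test_that("ranking regularizer matches closed forms and ignores negative order", {
  Z <- rbind(
    a = c(0, 0), p1 = c(1, 0), n1 = c(0, 1), # pos and neg at equal distance
    p2 = c(1, 0), n2 = c(2, 0) # d+ = 1, d- = 2
  )
  b1 <- structure(list(
    anchors = "a", positives = "p1", negatives = list("n1"),
    positiveDistance = 1
  ), class = "RegularizationBatch")
  expect_equal(hierarchyRegLoss(Z, b1, "euclidean"), 0, tolerance = 1e-9)
  b2 <- structure(list(
    anchors = "a", positives = "p2", negatives = list("n2"),
    positiveDistance = 1
  ), class = "RegularizationBatch")
  expect_equal(hierarchyRegLoss(Z, b2, "euclidean"), -1, tolerance = 1e-9)
  # permutation of negatives leaves the loss unchanged
  Z3 <- rbind(Z, n3 = c(0, 2), n4 = c(-2, 0))
  b3 <- structure(list(
    anchors = "a", positives = "p2",
    negatives = list(c("n2", "n3", "n4")), positiveDistance = 1
  ), class = "RegularizationBatch")
  b3r <- b3
  b3r$negatives <- list(c("n4", "n2", "n3"))
  expect_equal(
    hierarchyRegLoss(Z3, b3, "euclidean"),
    hierarchyRegLoss(Z3, b3r, "euclidean")
  )
  # empty negative set: anchor skipped with a warning
  b4 <- b2
  b4$negatives <- list(character(0))
  expect_warning(v <- hierarchyRegLoss(Z, b4, "euclidean"), "empty negative")
  expect_equal(v, 0)
})

test_that("composite loss is linear in the regularization weights", {
  expect_equal(totalLoss(1, 2, 3, 0.1, 0.1), 1.5)
  expect_equal(totalLoss(1, 2, 3, 0, 0), 1)
  expect_equal(
    totalLoss(0.5, 4, 7, 0.3, 0.2) - totalLoss(0.5, 4, 7, 0.1, 0.2),
    0.2 * 4,
    tolerance = 1e-12
  )
})

test_that("analytic gradients agree with finite differences for both heads", {
  set.seed(30)
  nd <- 6L
  nt <- 5L
  fd <- 4L
  Fd <- matrix(rnorm(nd * fd), nd, fd, dimnames = list(sprintf("D%03d", 1:nd), NULL))
  Ft <- matrix(rnorm(nt * fd), nt, fd, dimnames = list(sprintf("T%03d", 1:nt), NULL))
  it <- expand.grid(drug = rownames(Fd), target = rownames(Ft), stringsAsFactors = FALSE)
  it$label <- sample(c(-1, 1), nrow(it), TRUE)
  y <- ifelse(it$label > 0, 1, 0)
  dmT <- lcaDistanceMatrix(genHierarchy(c(2, 2, 2), "nr3", nt, prefix = "T"))
  dmD <- lcaDistanceMatrix(genHierarchy(c(2, 3, 1, 1, 1), "atc5", nd, prefix = "D"))
  for (head in c("lorentz", "euclidean")) {
    for (incP in c(FALSE, TRUE)) {
      set.seed(31)
      regT <- sampleRegularizationBatch(dmT, 3, 4)
      regD <- sampleRegularizationBatch(dmD, 2, 3)
      ctrl <- trainingConfig(
        posWeight = 2, negWeight = 1,
        lambdaDrug = 0.2, lambdaTarget = 0.3, includePositive = incP
      )
      netD <- hierDTI:::mlpInit(fd, 3L, 2L)
      netT <- hierDTI:::mlpInit(fd, 3L, 2L)
      # scale one layer so some latents cross the clip threshold
      netT$W[[2]] <- netT$W[[2]] * 1.6
      lg <- hierDTI:::.lossAndGrads(
        netD, netT, Fd, Ft, it$drug, it$target, y,
        regD, regT, head, 1, 1, 0, ctrl
      )
      f <- function(a, b) {
        hierDTI:::.lossAndGrads(
          a, b, Fd, Ft, it$drug, it$target, y,
          regD, regT, head, 1, 1, 0, ctrl
        )$loss
      }
      eps <- 1e-6
      for (probe in 1:8) {
        side <- sample(c("d", "t"), 1)
        base <- if (side == "d") netD else netT
        l <- sample(2L, 1)
        i <- sample(nrow(base$W[[l]]), 1)
        j <- sample(ncol(base$W[[l]]), 1)
        up <- base
        up$W[[l]][i, j] <- up$W[[l]][i, j] + eps
        dn <- base
        dn$W[[l]][i, j] <- dn$W[[l]][i, j] - eps
        num <- if (side == "d") {
          (f(up, netT) - f(dn, netT)) / (2 * eps)
        } else {
          (f(netD, up) - f(netD, dn)) / (2 * eps)
        }
        ana <- if (side == "d") lg$gradsD$dW[[l]][i, j] else lg$gradsT$dW[[l]][i, j]
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  }
})

test_that("prediction heads have the stated functional forms", {
  set.seed(32)
  fd <- 6L
  net <- hierDTI:::mlpInit(fd, 4L, 3L)
  # identical encoders + identical features -> identical latents -> p = 1
  model <- new("DTIModel",
    drugNet = net, targetNet = net, head = "lorentz",
    alpha = 1, beta = 1, latentDim = 3L,
    lossTrace = data.frame(), config = list()
  )
  x <- rnorm(fd)
  expect_equal(predictInteraction(model, x, x), 1, tolerance = 1e-12)
  # monotone decreasing in the squared Lorentzian distance
  X <- matrix(rnorm(20 * fd), 20, fd)
  Y <- matrix(rnorm(20 * fd), 20, fd)
  p <- predictInteraction(model, X, Y)
  Zd <- encodeEntities(model, X, "drug")
  Zt <- encodeEntities(model, Y, "target")
  d2 <- vapply(
    1:20, function(i) squaredLorentzDistance(Zd[i, ], Zt[i, ]),
    numeric(1)
  )
  expect_identical(order(p), order(-d2))
  expect_true(all(p > 0 & p <= 1))
  # euclidean head with all-zero encoders -> logistic(0) = 0.5
  zero <- net
  zero$W <- lapply(zero$W, function(w) w * 0)
  modelE <- new("DTIModel",
    drugNet = zero, targetNet = zero, head = "euclidean",
    alpha = 1, beta = 1, latentDim = 3L,
    lossTrace = data.frame(), config = list()
  )
  expect_equal(predictInteraction(modelE, x, rnorm(fd)), 0.5)
  expect_error(predictInteraction(model, rnorm(3), x), "dimension")
})

test_that("training batches have the configured shape and entity coverage", {
  data <- tinyDataset()
  dTree <- genHierarchy(c(2, 2, 1, 1, 2), "atc5", 8, prefix = "D")
  tTree <- genHierarchy(c(2, 3, 1), "nr3", 6, prefix = "T")
  dmD <- lcaDistanceMatrix(dTree)
  dmT <- lcaDistanceMatrix(tTree)
  set.seed(33)
  batch <- sampleTrainingBatch(data, dmD, dmT, b = 3, n = 1, m = 2)
  expect_equal(nrow(batch$interactions), 3L)
  expect_equal(length(batch$drugReg$anchors), 1L)
  expect_lte(length(batch$drugReg$negatives[[1]]), 2L)
  # entities outside the hierarchy never enter regularization batches
  dmPart <- lcaDistanceMatrix(subsetTree(dTree, sprintf("D%03d", 1:5)))
  set.seed(34)
  for (rep in 1:10) {
    b <- sampleTrainingBatch(data, dmPart, NULL, b = 4, n = 3, m = 4)
    ids <- c(b$drugReg$anchors, b$drugReg$positives, unlist(b$drugReg$negatives))
    expect_true(all(ids %in% sprintf("D%03d", 1:5)))
    expect_null(b$targetReg)
  }
  set.seed(35)
  b1 <- sampleTrainingBatch(data, dmD, dmT, b = 5, n = 2, m = 3)
  set.seed(35)
  b2 <- sampleTrainingBatch(data, dmD, dmT, b = 5, n = 2, m = 3)
  expect_identical(b1, b2)
})

test_that("training reduces the loss and keeps lorentz latents on-manifold", {
  data <- tinyDataset(nd = 12, nt = 8, fd = 10, seed = 36)
  dTree <- genHierarchy(c(3, 2, 1, 1, 2), "atc5", 12, prefix = "D")
  tTree <- genHierarchy(c(2, 2, 2), "nr3", 8, prefix = "T")
  m <- trainModel(data, lcaDistanceMatrix(dTree), lcaDistanceMatrix(tTree),
    head = "lorentz", latentDim = 3, hidden = c(16, 16), dropout = 0.1,
    control = trainingConfig(
      epochs = 6, batchSize = 32, learningRate = 1e-3,
      lambdaDrug = 0.1, lambdaTarget = 0.1, nAnchors = 3, mNegatives = 4,
      seed = 37
    )
  )
  tr <- lossTrace(m)
  expect_equal(nrow(tr), 6L)
  expect_lt(tr$total[6], tr$total[1])
  Z <- encodeEntities(m, drugFeatures(data), "drug")
  selfIp <- -Z[, 1]^2 + rowSums(Z[, -1, drop = FALSE]^2)
  expect_equal(selfIp, rep(-1, nrow(Z)),
    ignore_attr = TRUE, tolerance = 1e-6
  )
  tang <- encodeEntities(m, drugFeatures(data), "drug", "tangent")
  expect_true(all(sqrt(rowSums(tang^2)) <= 1 + 1e-12))
})

test_that("unregularized runs never touch the hierarchy sampler", {
  data <- tinyDataset(nd = 6, nt = 5, fd = 8, seed = 38)
  # no distance matrices at all: must train fine with lambda = 0
  m <- trainModel(data,
    head = "euclidean", latentDim = 2, hidden = 8,
    control = trainingConfig(epochs = 2, batchSize = 16, learningRate = 1e-3, seed = 39)
  )
  tr <- lossTrace(m)
  expect_true(all(tr$regDrug == 0) && all(tr$regTarget == 0))
  # lambda > 0 without the matching distances is a configuration error
  expect_error(
    trainModel(data,
      head = "euclidean",
      control = trainingConfig(lambdaDrug = 0.1)
    ),
    "drugDistances"
  )
})

test_that("training is reproducible from its seed", {
  data <- tinyDataset(nd = 6, nt = 5, fd = 8, seed = 40)
  tTree <- genHierarchy(c(2, 2, 2), "nr3", 5, prefix = "T")
  run <- function() {
    trainModel(data,
      targetDistances = lcaDistanceMatrix(tTree),
      head = "lorentz", latentDim = 2, hidden = 8,
      control = trainingConfig(
        epochs = 3, batchSize = 16, learningRate = 1e-3,
        lambdaTarget = 0.2, nAnchors = 2, mNegatives = 3, seed = 41
      )
    )
  }
  expect_equal(lossTrace(run()), lossTrace(run()), tolerance = 1e-12)
})

test_that("model checkpoints round-trip through save/load", {
  data <- tinyDataset(nd = 5, nt = 4, fd = 6, seed = 42)
  m <- trainModel(data,
    head = "lorentz", latentDim = 2, hidden = 4,
    control = trainingConfig(epochs = 1, batchSize = 8, seed = 43)
  )
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_equal(
    predictDataset(m2, data), predictDataset(m, data),
    tolerance = 1e-12
  )
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), bad)
  expect_error(loadModel(bad), "checkpoint")
})
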