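# Pairwise DTI model: drug and target feed-forward encoders into a shared
# latent space, a Euclidean dot-product or squared-Lorentzian-distance head,
# the weighted BCE + ranking-regularizer objective, and the Adam training
# loop. Gradients through clip -> exponential map -> Lorentzian distance are
# analytic; tests/test-model.R checks them against finite differences.

#' Training configuration
#'
#' Defaults follow the reference setup: 16 epochs, interaction batch size
#' 1024, Adam with learning rate 5e-5, `n = 10` hierarchy anchors with at
#' most `m = 256` negatives each, and class weights 1:1 (set the
#' positive/negative weights to e.g. 2:1 or 1:2 to offset label imbalance).
#'
#' @param epochs number of passes over the labeled interactions.
#' @param batchSize interactions per gradient step (`b`).
#' @param learningRate Adam step size.
#' @param posWeight,negWeight class weights of the weighted BCE.
#' @param lambdaDrug,lambdaTarget weights of the drug/target hierarchy
#'   regularization terms (0 disables the corresponding sampler entirely).
#' @param nAnchors,mNegatives ranking-batch shape (`n`, `m`).
#' @param includePositive if `TRUE` the regularizer's softmax denominator
#'   also contains the positive term (the printed form excludes it).
#' @param seed optional integer; seeds R's RNG at the start of training.
#' @return a list of class `TrainingConfig`.
#' @export
trainingConfig <- function(epochs = 16L, batchSize = 1024L, learningRate = 5e-5,
                           posWeight = 1, negWeight = 1,
                           lambdaDrug = 0, lambdaTarget = 0,
                           nAnchors = 10L, mNegatives = 256L,
                           includePositive = FALSE, seed = NULL) {
  stopifnot(
    epochs >= 1L, batchSize >= 1L, learningRate > 0,
    posWeight > 0, negWeight > 0, lambdaDrug >= 0, lambdaTarget >= 0,
    nAnchors >= 1L, mNegatives >= 1L
  )
  structure(
    list(
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, posWeight = posWeight,
      negWeight = negWeight, lambdaDrug = lambdaDrug,
      lambdaTarget = lambdaTarget, nAnchors = as.integer(nAnchors),
      mNegatives = as.integer(mNegatives),
      includePositive = isTRUE(includePositive), seed = seed
    ),
    class = "TrainingConfig"
  )
}

#' Weighted binary cross-entropy
#'
#' Mean over samples of `-w_y * (y log p + (1 - y) log(1 - p))`, with the
#' class weight `w_y` equal to `posWeight` for positives and `negWeight`
#' for negatives. Predictions are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param predictions probabilities.
#' @param labels binary labels; `0/1` or signed `-1/+1`.
#' @param posWeight,negWeight class weights.
#' @return a nonnegative number.
#' @examples
#' weightedBce(0.5, 1, posWeight = 2, negWeight = 1) # 2 * log(2)
#' @export
weightedBce <- function(predictions, labels, posWeight = 1, negWeight = 1) {
  if (length(predictions) != length(labels)) stop("length mismatch")
  y <- ifelse(labels > 0, 1, 0)
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  w <- ifelse(y == 1, posWeight, negWeight)
  mean(-w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Ranking-based hierarchy regularization loss
#'
#' For each anchor `x_i` with positive `x_{i+}` and negative set `K_i`,
#' the (minimized) term is
#' `d(x_i, x_{i+}) + log sum_{k in K_i} exp(-d(x_i, x_k))`,
#' i.e. the negative log of `exp(-d+) / sum_k exp(-d_k)`; the total is the
#' sum over anchors. Decreasing negative distances raise the loss,
#' increasing the positive distance raises it. Anchors with an empty
#' negative set are skipped with a warning.
#'
#' @param latents numeric matrix of latent points, row names covering every
#'   anchor/positive/negative id; hyperboloid ambient coordinates for
#'   `distance = "sqlorentz"`, plain latent vectors for `"euclidean"`.
#' @param batch a `RegularizationBatch` from [sampleRegularizationBatch()].
#' @param distance `"sqlorentz"` (squared Lorentzian) or `"euclidean"`.
#' @param beta curvature parameter for the Lorentzian distance.
#' @param includePositive include the positive in the denominator sum.
#' @return a number (can be negative).
#' @export
hierarchyRegLoss <- function(latents, batch, distance = c("sqlorentz", "euclidean"),
                             beta = 1, includePositive = FALSE) {
  distance <- match.arg(distance)
  ids <- rownames(latents)
  need <- unique(c(batch$anchors, batch$positives, unlist(batch$negatives)))
  if (!all(need %in% ids)) stop("latents missing for some batch entities")
  dfun <- function(a, others) {
    A <- latents[a, , drop = FALSE]
    B <- latents[others, , drop = FALSE]
    if (distance == "sqlorentz") {
      as.vector(rowsSquaredLorentz(A, B, beta))
    } else {
      sqrt(rowSums(sweep(B, 2L, latents[a, ])^2))
    }
  }
  total <- 0
  skipped <- 0L
  for (i in seq_along(batch$anchors)) {
    negs <- batch$negatives[[i]]
    if (length(negs) == 0L) {
      skipped <- skipped + 1L
      next
    }
    dpos <- dfun(batch$anchors[i], batch$positives[i])
    dneg <- dfun(batch$anchors[i], negs)
    den <- if (includePositive) c(dpos, dneg) else dneg
    total <- total + dpos + .logSumExp(-den)
  }
  if (skipped > 0L) {
    warning(sprintf("%d anchor(s) skipped: empty negative set", skipped))
  }
  unname(total)
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Composite training objective
#'
#' `L = L_wBCE + lambdaDrug * L_REG^drug + lambdaTarget * L_REG^target`.
#'
#' @param bce weighted BCE value.
#' @param regDrug,regTarget hierarchy regularization values.
#' @param lambdaDrug,lambdaTarget regularization weights.
#' @export
totalLoss <- function(bce, regDrug = 0, regTarget = 0,
                      lambdaDrug = 0, lambdaTarget = 0) {
  bce + lambdaDrug * regDrug + lambdaTarget * regTarget
}

#' Sample one training batch
#'
#' Draws `b` labeled interactions uniformly without replacement, plus one
#' regularization batch per modality when a hierarchy distance matrix is
#' supplied. Only entities that carry feature vectors (and appear in the
#' distance matrix) can be sampled as anchors, positives or negatives.
#'
#' @param data a [DTIDataset-class].
#' @param drugDistances,targetDistances optional
#'   [HierarchyDistanceMatrix-class] objects.
#' @param b,n,m batch shape: interactions, anchors, max negatives.
#' @return a list with `interactions` (a row subset of the interaction
#'   table), `drugReg` and `targetReg` (possibly `NULL`).
#' @export
sampleTrainingBatch <- function(data, drugDistances = NULL, targetDistances = NULL,
                                b = 1024L, n = 10L, m = 256L) {
  stopifnot(is(data, "DTIDataset"))
  it <- data@interactions
  if (nrow(it) == 0L) stop("no labeled interactions")
  idx <- sample(nrow(it), min(b, nrow(it)))
  drugReg <- if (!is.null(drugDistances)) {
    sampleRegularizationBatch(drugDistances, n, m,
      restrictTo = rownames(data@drugFeatures)
    )
  }
  targetReg <- if (!is.null(targetDistances)) {
    sampleRegularizationBatch(targetDistances, n, m,
      restrictTo = rownames(data@targetFeatures)
    )
  }
  list(interactions = it[idx, , drop = FALSE], drugReg = drugReg, targetReg = targetReg)
}

# ---- gradient plumbing -----------------------------------------------------

# chain a gradient w.r.t. hyperboloid ambient coordinates back to the
# (clipped) tangent output, then through the norm clip.
# U: raw encoder outputs (k x d); G: gradient w.r.t. manifold points
# (k x (d+1)); returns gradient w.r.t. U (k x d).
.chainExpClip <- function(U, G, alpha, beta) {
  sb <- sqrt(beta)
  Uc <- rowsClipNorm(U, alpha)
  r <- sqrt(rowSums(Uc^2))
  small <- r < 1e-6
  cshr <- cosh(r / sb)
  snhr <- sinh(r / sb)
  sBeta <- ifelse(small, 1, sb * snhr / r) # d(x_sp)/du diagonal factor
  dx0 <- ifelse(small, 1 / sb, snhr / r) # d(x0)/du = this * u
  dsdr_r <- ifelse(small, 1 / (3 * beta), (cshr * r - sb * snhr) / r^3)
  g0 <- G[, 1L]
  Gsp <- G[, -1L, drop = FALSE]
  ug <- rowSums(Uc * Gsp)
  Gu <- Gsp * sBeta + Uc * (dx0 * g0 + dsdr_r * ug)
  # clip Jacobian: identity inside the ball, tangential projection outside
  n0 <- sqrt(rowSums(U^2))
  out <- which(n0 > alpha)
  if (length(out)) {
    Uhat <- U[out, , drop = FALSE] / n0[out]
    proj <- Gu[out, , drop = FALSE] -
      Uhat * rowSums(Uhat * Gu[out, , drop = FALSE])
    Gu[out, ] <- (alpha / n0[out]) * proj
  }
  Gu
}

# negate the time coordinate: gradient of <x, y>_L w.r.t. x is flip(y)
.lorentzFlip <- function(X) {
  X[, 1L] <- -X[, 1L]
  X
}

# regularizer value + gradient w.r.t. the latent matrix rows.
# Z: k x q latent matrix (manifold ambient or plain latents) with rownames;
# returns list(loss, grad) with grad the same shape as Z.
.regLossGrad <- function(Z, batch, distance, beta, includePositive) {
  G <- matrix(0, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  total <- 0
  for (i in seq_along(batch$anchors)) {
    negs <- batch$negatives[[i]]
    if (length(negs) == 0L) next
    a <- batch$anchors[i]
    p <- batch$positives[i]
    za <- Z[a, ]
    others <- c(p, negs)
    Zo <- Z[others, , drop = FALSE]
    if (distance == "sqlorentz") {
      d <- as.vector(-2 * beta - 2 * (Zo %*% .lorentzFlipVec(za)))
    } else {
      d <- sqrt(rowSums(sweep(Zo, 2L, za)^2))
    }
    dpos <- d[1L]
    dneg <- d[-1L]
    denIdx <- if (includePositive) seq_along(d) else seq_along(d)[-1L]
    lse <- .logSumExp(-d[denIdx])
    total <- total + dpos + lse
    # dLoss/dd: +1 on the positive, -softmax weight on denominator members
    w <- exp(-d[denIdx] - lse)
    dd <- numeric(length(d))
    dd[1L] <- 1
    dd[denIdx] <- dd[denIdx] - w
    if (distance == "sqlorentz") {
      # d d2(x,y)/dx = -2 * flip(y)
      G[a, ] <- G[a, ] - 2 * as.vector(t(.lorentzFlip(Zo)) %*% dd)
      G[others, ] <- G[others, , drop = FALSE] +
        (-2 * dd) * matrix(.lorentzFlipVec(za), length(d), ncol(Z), byrow = TRUE)
    } else {
      diff <- sweep(Zo, 2L, za) # y - x (rows)
      dd_over_d <- dd / pmax(d, 1e-12)
      G[a, ] <- G[a, ] - colSums(diff * dd_over_d)
      G[others, ] <- G[others, , drop = FALSE] + diff * dd_over_d
    }
  }
  list(loss = unname(total), grad = G)
}

.lorentzFlipVec <- function(x) {
  x[1L] <- -x[1L]
  x
}

# ---- training --------------------------------------------------------------

#' Train a pairwise DTI model
#'
#' Xavier-initialized encoders are trained with Adam on the composite
#' objective: weighted BCE over interaction batches plus, when hierarchy
#' distance matrices and positive `lambda` weights are supplied, a ranking
#' regularization term per modality. With the `"lorentz"` head the distance
#' inside the regularizer is the squared Lorentzian distance between the
#' on-manifold latents; with the `"euclidean"` head it is the Euclidean
#' distance between latents.
#'
#' @param data a [DTIDataset-class].
#' @param drugDistances,targetDistances optional
#'   [HierarchyDistanceMatrix-class] priors; required when the
#'   corresponding `lambda` is positive.
#' @param head `"lorentz"` (exp-map + `exp(-d_L^2)` activation) or
#'   `"euclidean"` (logistic dot product).
#' @param latentDim latent dimension `d`.
#' @param hidden hidden-layer widths of both encoders.
#' @param dropout dropout fraction applied after each hidden ReLU
#'   (training only; evaluation is deterministic).
#' @param alpha clip threshold applied to lorentz-head latents before the
#'   exponential map.
#' @param beta curvature parameter (space curvature `-1/beta`).
#' @param control a [trainingConfig()].
#' @return a trained [DTIModel-class]; `lossTrace(model)` holds per-epoch
#'   mean weighted BCE, regularization sums, and the total.
#' @export
trainModel <- function(data, drugDistances = NULL, targetDistances = NULL,
                       head = c("lorentz", "euclidean"), latentDim = 8L,
                       hidden = c(1024L, 1024L), dropout = 0.1,
                       alpha = 1, beta = 1, control = trainingConfig()) {
  stopifnot(is(data, "DTIDataset"), latentDim >= 2L, dropout >= 0, dropout < 1)
  head <- match.arg(head)
  if (control$lambdaDrug > 0 && is.null(drugDistances)) {
    stop("lambdaDrug > 0 requires drugDistances")
  }
  if (control$lambdaTarget > 0 && is.null(targetDistances)) {
    stop("lambdaTarget > 0 requires targetDistances")
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  Fd <- data@drugFeatures
  Ft <- data@targetFeatures
  it <- data@interactions
  y <- ifelse(it$label > 0, 1, 0)
  drugNet <- mlpInit(ncol(Fd), hidden, latentDim)
  targetNet <- mlpInit(ncol(Ft), hidden, latentDim)
  stateD <- adamInit(drugNet)
  stateT <- adamInit(targetNet)
  useDrugReg <- control$lambdaDrug > 0 && !is.null(drugDistances)
  useTargetReg <- control$lambdaTarget > 0 && !is.null(targetDistances)
  trace <- data.frame(
    epoch = integer(), bce = numeric(), regDrug = numeric(),
    regTarget = numeric(), total = numeric()
  )
  for (epoch in seq_len(control$epochs)) {
    perm <- sample(nrow(it))
    starts <- seq(1L, nrow(it), by = control$batchSize)
    eBce <- eRd <- eRt <- 0
    for (s in starts) {
      idx <- perm[s:min(s + control$batchSize - 1L, nrow(it))]
      regD <- if (useDrugReg) {
        sampleRegularizationBatch(drugDistances,
          control$nAnchors, control$mNegatives,
          restrictTo = rownames(Fd)
        )
      }
      regT <- if (useTargetReg) {
        sampleRegularizationBatch(targetDistances,
          control$nAnchors, control$mNegatives,
          restrictTo = rownames(Ft)
        )
      }
      step <- .trainStep(
        drugNet, targetNet, stateD, stateT,
        Fd, Ft, it$drug[idx], it$target[idx], y[idx],
        regD, regT, head, alpha, beta, dropout, control
      )
      drugNet <- step$drugNet
      targetNet <- step$targetNet
      stateD <- step$stateD
      stateT <- step$stateT
      eBce <- eBce + step$bce
      eRd <- eRd + step$regDrug
      eRt <- eRt + step$regTarget
    }
    nb <- length(starts)
    tot <- totalLoss(
      eBce / nb, eRd / nb, eRt / nb,
      control$lambdaDrug, control$lambdaTarget
    )
    if (!is.finite(tot)) {
      stop(sprintf(
        "non-finite loss at epoch %d (bce %.4g, regDrug %.4g, regTarget %.4g)",
        epoch, eBce / nb, eRd / nb, eRt / nb
      ))
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, bce = eBce / nb, regDrug = eRd / nb,
      regTarget = eRt / nb, total = tot
    ))
  }
  new("DTIModel",
    drugNet = drugNet, targetNet = targetNet, head = head,
    alpha = alpha, beta = beta, latentDim = as.integer(latentDim),
    lossTrace = trace,
    config = list(
      hidden = hidden, dropout = dropout, control = control,
      inputDimDrug = ncol(Fd), inputDimTarget = ncol(Ft)
    )
  )
}

# one Adam step over an interaction batch plus optional reg batches
.trainStep <- function(drugNet, targetNet, stateD, stateT, Fd, Ft,
                       bDrugs, bTargets, y, regD, regT,
                       head, alpha, beta, dropout, control) {
  lg <- .lossAndGrads(
    drugNet, targetNet, Fd, Ft, bDrugs, bTargets, y,
    regD, regT, head, alpha, beta, dropout, control
  )
  upD <- adamStep(drugNet, lg$gradsD, stateD, control$learningRate)
  upT <- adamStep(targetNet, lg$gradsT, stateT, control$learningRate)
  list(
    drugNet = upD$net, targetNet = upT$net,
    stateD = upD$state, stateT = upT$state,
    bce = lg$bce, regDrug = lg$regDrug, regTarget = lg$regTarget
  )
}

# composite loss and weight gradients for one batch (no parameter update);
# the unit tests check these gradients against finite differences.
.lossAndGrads <- function(drugNet, targetNet, Fd, Ft,
                          bDrugs, bTargets, y, regD, regT,
                          head, alpha, beta, dropout, control) {
  B <- length(y)
  regIdsD <- if (!is.null(regD)) {
    unique(c(regD$anchors, regD$positives, unlist(regD$negatives)))
  } else {
    character()
  }
  regIdsT <- if (!is.null(regT)) {
    unique(c(regT$anchors, regT$positives, unlist(regT$negatives)))
  } else {
    character()
  }
  idsD <- unique(c(bDrugs, regIdsD))
  idsT <- unique(c(bTargets, regIdsT))
  di <- match(bDrugs, idsD)
  ti <- match(bTargets, idsT)
  cacheD <- mlpForward(drugNet, Fd[idsD, , drop = FALSE], dropout, training = TRUE)
  cacheT <- mlpForward(targetNet, Ft[idsT, , drop = FALSE], dropout, training = TRUE)
  Ud <- cacheD$out
  Ut <- cacheT$out
  w <- ifelse(y == 1, control$posWeight, control$negWeight)
  if (head == "lorentz") {
    Xd <- rowsExpMapOrigin(rowsClipNorm(Ud, alpha), beta)
    Xt <- rowsExpMapOrigin(rowsClipNorm(Ut, alpha), beta)
    rownames(Xd) <- idsD
    rownames(Xt) <- idsT
    xd <- Xd[di, , drop = FALSE]
    xt <- Xt[ti, , drop = FALSE]
    inner <- -xd[, 1L] * xt[, 1L] + rowSums(xd[, -1L, drop = FALSE] * xt[, -1L, drop = FALSE])
    d2 <- pmax(-2 * beta - 2 * inner, 0)
    praw <- exp(-d2)
    p <- pmin(pmax(praw, 1e-7), 1 - 1e-7)
    bce <- mean(-w * (y * log(p) + (1 - y) * log(1 - p)))
    dLdp <- -w * (y / p - (1 - y) / (1 - p)) / B
    dLdd2 <- dLdp * (-praw)
    dLdInner <- dLdd2 * (-2)
    # gradient w.r.t. manifold points, accumulated over repeated entities
    Gxd <- .accumRows(dLdInner * .lorentzFlip(xt), di, nrow(Xd))
    Gxt <- .accumRows(dLdInner * .lorentzFlip(xd), ti, nrow(Xt))
    rownames(Gxd) <- idsD
    rownames(Gxt) <- idsT
    regDrugLoss <- regTargetLoss <- 0
    if (!is.null(regD)) {
      rg <- .regLossGrad(Xd, regD, "sqlorentz", beta, control$includePositive)
      regDrugLoss <- rg$loss
      Gxd <- Gxd + control$lambdaDrug * rg$grad
    }
    if (!is.null(regT)) {
      rg <- .regLossGrad(Xt, regT, "sqlorentz", beta, control$includePositive)
      regTargetLoss <- rg$loss
      Gxt <- Gxt + control$lambdaTarget * rg$grad
    }
    Gud <- .chainExpClip(Ud, Gxd, alpha, beta)
    Gut <- .chainExpClip(Ut, Gxt, alpha, beta)
  } else {
    rownames(Ud) <- idsD
    rownames(Ut) <- idsT
    zd <- Ud[di, , drop = FALSE]
    zt <- Ut[ti, , drop = FALSE]
    logit <- rowSums(zd * zt)
    p <- 1 / (1 + exp(-logit))
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- mean(-w * (y * log(pc) + (1 - y) * log(1 - pc)))
    dLdLogit <- w * (p - y) / B
    Gud <- .accumRows(dLdLogit * zt, di, nrow(Ud))
    Gut <- .accumRows(dLdLogit * zd, ti, nrow(Ut))
    rownames(Gud) <- idsD
    rownames(Gut) <- idsT
    regDrugLoss <- regTargetLoss <- 0
    if (!is.null(regD)) {
      rg <- .regLossGrad(Ud, regD, "euclidean", beta, control$includePositive)
      regDrugLoss <- rg$loss
      Gud <- Gud + control$lambdaDrug * rg$grad
    }
    if (!is.null(regT)) {
      rg <- .regLossGrad(Ut, regT, "euclidean", beta, control$includePositive)
      regTargetLoss <- rg$loss
      Gut <- Gut + control$lambdaTarget * rg$grad
    }
  }
  gradsD <- mlpBackward(drugNet, cacheD, Gud)
  gradsT <- mlpBackward(targetNet, cacheT, Gut)
  list(
    bce = bce, regDrug = regDrugLoss, regTarget = regTargetLoss,
    loss = totalLoss(
      bce, regDrugLoss, regTargetLoss,
      control$lambdaDrug, control$lambdaTarget
    ),
    gradsD = gradsD, gradsT = gradsT
  )
}

# sum rows of `contrib` into an nOut-row matrix grouped by index `idx`
.accumRows <- function(contrib, idx, nOut) {
  out <- matrix(0, nOut, ncol(contrib))
  agg <- rowsum(contrib, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# ---- inference -------------------------------------------------------------

#' Encode entities into the model's latent space
#'
#' @param model a [DTIModel-class].
#' @param features numeric matrix (rows = entities) or a single feature
#'   vector.
#' @param type `"drug"` or `"target"` (selects the encoder).
#' @param space `"manifold"` returns hyperboloid ambient coordinates
#'   (`d + 1` columns) for the lorentz head and the plain latents for the
#'   euclidean head; `"tangent"` returns the clipped encoder output;
#'   `"poincare"` additionally maps lorentz-head points into the unit ball.
#' @return a numeric matrix, one row per entity.
#' @export
encodeEntities <- function(model, features, type = c("drug", "target"),
                           space = c("manifold", "tangent", "poincare")) {
  stopifnot(is(model, "DTIModel"))
  type <- match.arg(type)
  space <- match.arg(space)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  net <- if (type == "drug") model@drugNet else model@targetNet
  if (ncol(features) != net$dims[1L]) {
    stop(sprintf(
      "feature dimension %d does not match the %s encoder (%d)",
      ncol(features), type, net$dims[1L]
    ))
  }
  U <- mlpForward(net, features)$out
  rownames(U) <- rownames(features)
  if (model@head == "euclidean") {
    if (space == "poincare") stop("poincare coordinates are defined for the lorentz head")
    return(U)
  }
  Uc <- rowsClipNorm(U, model@alpha)
  if (space == "tangent") {
    return(Uc)
  }
  X <- rowsExpMapOrigin(Uc, model@beta)
  rownames(X) <- rownames(features)
  if (space == "poincare") {
    P <- rowsLorentzToPoincare(X)
    rownames(P) <- rownames(features)
    return(P)
  }
  X
}

#' Predict interaction probabilities
#'
#' Euclidean head: `sigmoid(<d, t>)`; lorentz head: `exp(-d_L^2(d, t))`
#' with both latents clipped and lifted onto the hyperboloid. Feature
#' matrices are paired row by row.
#'
#' @param model a [DTIModel-class].
#' @param drugFeatures,targetFeatures feature vectors or matrices with
#'   matching row counts.
#' @return a numeric vector of probabilities in `(0, 1]`.
#' @export
predictInteraction <- function(model, drugFeatures, targetFeatures) {
  if (!is.matrix(drugFeatures)) drugFeatures <- matrix(drugFeatures, nrow = 1L)
  if (!is.matrix(targetFeatures)) targetFeatures <- matrix(targetFeatures, nrow = 1L)
  if (nrow(drugFeatures) != nrow(targetFeatures)) stop("row counts must match")
  Zd <- encodeEntities(model, drugFeatures, "drug")
  Zt <- encodeEntities(model, targetFeatures, "target")
  if (model@head == "euclidean") {
    1 / (1 + exp(-rowSums(Zd * Zt)))
  } else {
    inner <- -Zd[, 1L] * Zt[, 1L] +
      rowSums(Zd[, -1L, drop = FALSE] * Zt[, -1L, drop = FALSE])
    exp(-pmax(-2 * model@beta - 2 * inner, 0))
  }
}

#' Score a dataset's interaction pairs
#'
#' @param model a [DTIModel-class].
#' @param data a [DTIDataset-class].
#' @param idx optional row indices of the interaction table.
#' @return a numeric vector of probabilities, one per (selected) row.
#' @export
predictDataset <- function(model, data, idx = NULL) {
  it <- data@interactions
  if (!is.null(idx)) it <- it[idx, , drop = FALSE]
  Zd <- encodeEntities(model, data@drugFeatures, "drug")
  Zt <- encodeEntities(model, data@targetFeatures, "target")
  zd <- Zd[it$drug, , drop = FALSE]
  zt <- Zt[it$target, , drop = FALSE]
  if (model@head == "euclidean") {
    1 / (1 + exp(-rowSums(zd * zt)))
  } else {
    inner <- -zd[, 1L] * zt[, 1L] +
      rowSums(zd[, -1L, drop = FALSE] * zt[, -1L, drop = FALSE])
    exp(-pmax(-2 * model@beta - 2 * inner, 0))
  }
}

#' Pairwise latent distance matrix of one modality
#'
#' The distance the model itself is organized by: squared Lorentzian for the
#' lorentz head, Euclidean for the euclidean head. This is the matrix fed to
#' [buildDendrogram()] for hierarchy-preservation analysis.
#'
#' @param model a [DTIModel-class].
#' @param features feature matrix of the modality's entities.
#' @param type `"drug"` or `"target"`.
#' @return a symmetric matrix with the feature row names.
#' @export
latentDistanceMatrix <- function(model, features, type = c("drug", "target")) {
  type <- match.arg(type)
  Z <- encodeEntities(model, features, type)
  D <- if (model@head == "lorentz") {
    rowsSquaredLorentz(Z, Z, model@beta)
  } else {
    as.matrix(stats::dist(Z))
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(features), rownames(features))
  D
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing RDS containers holding the weights, the
#' head and geometry settings, the training configuration and a format
#' version.
#'
#' @param model a [DTIModel-class].
#' @param path file path (`.rds`).
#' @name modelCheckpoint
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "DTIModel"))
  saveRDS(list(format = "hierDTI-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname modelCheckpoint
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hierDTI-checkpoint-1")) {
    stop("not a hierDTI checkpoint")
  }
  validObject(obj$model)
  obj$model
}
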