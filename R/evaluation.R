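# Predictive metrics, farthest-point dendrograms, exact and sampled
# dendrogram purity, and the interaction-based cross-validation split.

#' ROC and precision-recall areas under the curve
#'
#' ROCAUC is computed with the rank (Mann-Whitney) statistic, handling score
#' ties through midranks; PRAUC is the step integral of the precision-recall
#' curve (average precision).
#'
#' @param labels binary labels (`0/1` or signed `-1/+1`); both classes must
#'   be present.
#' @param scores predicted scores or probabilities.
#' @return a named numeric vector `c(rocauc =, prauc =)`.
#' @export
binaryAucs <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  y <- ifelse(labels > 0, 1L, 0L)
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)
  rocauc <- (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  tp <- cumsum(ys)
  precision <- tp / seq_along(ys)
  recall <- tp / np
  prauc <- sum(diff(c(0, recall)) * precision)
  c(rocauc = rocauc, prauc = prauc)
}

#' Farthest-point (complete-linkage) dendrogram
#'
#' Agglomerative hierarchical clustering of a distance matrix with the
#' farthest-point (complete linkage) criterion; the learned hierarchy tree
#' the purity metrics are evaluated on.
#'
#' @param D a symmetric, nonnegative, zero-diagonal distance matrix with
#'   row names.
#' @return an object of class `hclust` (merge heights are non-decreasing).
#' @export
buildDendrogram <- function(D) {
  if (is(D, "HierarchyDistanceMatrix")) D <- D@D
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("D must be a symmetric matrix")
  }
  if (any(D < 0) || any(!is.finite(D))) stop("D must be finite and nonnegative")
  stats::hclust(stats::as.dist(D), method = "complete")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths encode the merge heights.
#'
#' @param hc an `hclust` object.
#' @param file output path.
#' @export
writeNewick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file)
  invisible(file)
}

# For one class labeling, the purity of every leaf pair: the same-class leaf
# fraction of the smallest subtree containing the pair. Computed with one
# sweep over the merges: a pair's smallest containing subtree is the merge
# that first joins their clusters.
.pairPurityMatrix <- function(hc, labels) {
  n <- length(hc$order)
  if (length(labels) != n) stop("labels must cover every leaf")
  if (!is.null(hc$labels)) labels <- labels[hc$labels]
  P <- matrix(NA_real_, n, n)
  members <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(k) if (k < 0) -k else members[[k]]
    A <- pick(hc$merge[s, 1L])
    B <- pick(hc$merge[s, 2L])
    m <- c(A, B)
    members[[s]] <- m
    tab <- table(labels[m])
    frac <- as.numeric(tab[as.character(labels[A])]) / length(m) # class fraction per A leaf
    sameAB <- outer(labels[A], labels[B], "==")
    vals <- matrix(frac, length(A), length(B))
    vals[!sameAB] <- NA_real_
    P[cbind(rep(A, times = length(B)), rep(B, each = length(A)))] <- as.vector(vals)
    P[cbind(rep(B, each = length(A)), rep(A, times = length(B)))] <- as.vector(vals)
  }
  P
}

#' Exact dendrogram purity
#'
#' For every pair of leaves with the same class, the smallest subtree
#' containing both is found and the fraction of its leaves sharing the
#' pair's class recorded; dendrogram purity is the average of these
#' fractions pooled over all same-class pairs. It reaches 1 exactly when
#' every class forms a pure subtree.
#'
#' @param hc an `hclust` dendrogram (see [buildDendrogram()]).
#' @param labels a vector of class labels, named by leaf id (or in leaf
#'   order when the dendrogram carries no labels).
#' @return a number in `[0, 1]`.
#' @export
dendrogramPurityExact <- function(hc, labels) {
  P <- .pairPurityMatrix(hc, labels)
  vals <- P[upper.tri(P)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no same-class leaf pair exists")
  mean(vals)
}

#' Expected (sampled) dendrogram purity
#'
#' The sampled estimator of dendrogram purity, averaged over hierarchy
#' levels: for each level's class labeling, `k` same-class pairs per class
#' are drawn without replacement (all pairs when a class has fewer), their
#' purities pooled across classes, and the per-level scores averaged.
#' Classes with fewer than two leaves cannot form a pair and are skipped;
#' a level with no pair at all is dropped with a warning.
#'
#' Uses R's global RNG; call `set.seed()` for reproducible sampling.
#'
#' @param hc an `hclust` dendrogram.
#' @param levels a list of per-level label vectors (each named by leaf id),
#'   e.g. from [levelLabels()]; a single vector is treated as one level.
#' @param k pairs sampled per class per level.
#' @return a number in `[0, 1]`.
#' @export
expectedDendrogramPurity <- function(hc, levels, k = 10L) {
  stopifnot(k >= 1L)
  if (!is.list(levels)) levels <- list(levels)
  perLevel <- numeric(0)
  for (li in seq_along(levels)) {
    labels <- levels[[li]]
    P <- .pairPurityMatrix(hc, labels)
    if (!is.null(hc$labels)) labels <- labels[hc$labels]
    vals <- numeric(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) next
      pairs <- utils::combn(idx, 2L)
      npair <- ncol(pairs)
      take <- if (npair <= k) seq_len(npair) else sample(npair, k)
      vals <- c(vals, P[cbind(pairs[1L, take], pairs[2L, take])])
    }
    if (length(vals) == 0L) {
      warning(sprintf("level %d has no same-class pair; skipped", li))
      next
    }
    perLevel <- c(perLevel, mean(vals))
  }
  if (length(perLevel) == 0L) stop("no level produced a same-class pair")
  mean(perLevel)
}

#' Per-level class labelings of a leveled hierarchy
#'
#' For level `i` the class of an entity is its full label path down to level
#' `i` (prefixes are concatenated, so identically named children of
#' different parents stay distinct). Entities with several paths use their
#' first path. By default the leaf level is excluded, since leaf classes
#' are singletons.
#'
#' @param tree a leveled [HierarchyTree-class].
#' @param levels which levels to return; default `1:(depth - 1)`.
#' @return a named list of named character vectors, one per level.
#' @export
levelLabels <- function(tree, levels = NULL) {
  stopifnot(is(tree, "HierarchyTree"))
  if (tree@kind == "graph") stop("level labels are defined for leveled hierarchies")
  if (is.null(levels)) levels <- seq_len(tree@depth - 1L)
  first <- t(vapply(
    tree@paths, function(p) p[1L, ],
    character(tree@depth)
  ))
  out <- lapply(levels, function(l) {
    lab <- apply(first[, seq_len(l), drop = FALSE], 1L, paste, collapse = "/")
    names(lab) <- tree@entities
    lab
  })
  names(out) <- paste0("level", levels)
  out
}

#' Interaction-based cross-validation split
#'
#' Shuffles the labeled interaction rows and partitions them into `k`
#' near-equal folds. The split is over interactions, not entities: every
#' drug and target can occur in both the training and the test side, which
#' is why hierarchy preservation (EDP) is evaluated in-sample while the AUC
#' metrics use the held-out fold.
#'
#' Uses R's global RNG; call `set.seed()` for a reproducible split.
#'
#' @param data a [DTIDataset-class] (or an interaction data.frame).
#' @param k number of folds (>= 2).
#' @return a list of `k` integer index vectors partitioning the rows.
#' @export
crossvalSplit <- function(data, k = 5L) {
  it <- if (is(data, "DTIDataset")) data@interactions else data
  n <- nrow(it)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("fewer interactions than folds")
  perm <- sample(n)
  unname(split(perm, rep_len(seq_len(k), n)))
}

#' Evaluate a model configuration by cross-validation
#'
#' Runs `k`-fold interaction-based cross-validation: for each fold a fresh
#' model is trained on the remaining folds and scored on the held-out
#' interactions (ROCAUC/PRAUC); expected dendrogram purity is computed
#' in-sample over the hierarchy-labeled entities of each modality.
#'
#' @param data a [DTIDataset-class].
#' @param drugTree,targetTree optional leveled [HierarchyTree-class] priors
#'   (needed for regularization and for EDP).
#' @param k number of folds.
#' @param edpK EDP pairs sampled per class per level.
#' @param ... passed to [trainModel()] (head, latentDim, hidden, control, ...).
#' @return a list with `folds` (a data.frame of per-fold metrics) and
#'   `summary` (mean and sd per metric).
#' @export
crossValidate <- function(data, drugTree = NULL, targetTree = NULL,
                          k = 5L, edpK = 10L, ...) {
  folds <- crossvalSplit(data, k)
  drugDist <- if (!is.null(drugTree)) lcaDistanceMatrix(drugTree)
  targetDist <- if (!is.null(targetTree)) lcaDistanceMatrix(targetTree)
  rows <- lapply(seq_along(folds), function(f) {
    test <- folds[[f]]
    trainData <- new("DTIDataset",
      interactions = data@interactions[-test, , drop = FALSE],
      drugFeatures = data@drugFeatures, targetFeatures = data@targetFeatures
    )
    model <- trainModel(trainData, drugDist, targetDist, ...)
    scores <- predictDataset(model, data, idx = test)
    aucs <- binaryAucs(data@interactions$label[test], scores)
    edpD <- if (!is.null(drugTree)) {
      modelEdp(model, data, drugTree, type = "drug", k = edpK)
    } else {
      NA_real_
    }
    edpT <- if (!is.null(targetTree)) {
      modelEdp(model, data, targetTree, type = "target", k = edpK)
    } else {
      NA_real_
    }
    data.frame(
      fold = f, rocauc = aucs[["rocauc"]], prauc = aucs[["prauc"]],
      edpDrug = edpD, edpTarget = edpT
    )
  })
  folds_df <- do.call(rbind, rows)
  metrics <- c("rocauc", "prauc", "edpDrug", "edpTarget")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_df[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds_df[[m]]), numeric(1))
  )
  list(folds = folds_df, summary = summary)
}

#' Expected dendrogram purity of a trained model's latent space
#'
#' Builds the farthest-point dendrogram over the latent distance matrix of
#' the hierarchy-labeled entities of one modality and evaluates the sampled
#' EDP against the prior hierarchy's per-level class labels.
#'
#' @param model a [DTIModel-class].
#' @param data a [DTIDataset-class].
#' @param tree the modality's leveled [HierarchyTree-class].
#' @param type `"drug"` or `"target"`.
#' @param k EDP pairs per class per level.
#' @return a number in `[0, 1]`.
#' @export
modelEdp <- function(model, data, tree, type = c("drug", "target"), k = 10L) {
  type <- match.arg(type)
  feats <- if (type == "drug") data@drugFeatures else data@targetFeatures
  ids <- intersect(rownames(feats), tree@entities)
  if (length(ids) < 2L) stop("need at least two hierarchy-labeled entities")
  D <- latentDistanceMatrix(model, feats[ids, , drop = FALSE], type)
  hc <- buildDendrogram(D)
  labs <- lapply(levelLabels(tree), function(v) v[ids])
  expectedDendrogramPurity(hc, labs, k = k)
}
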