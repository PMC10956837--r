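# Synthetic benchmark generator: leveled hierarchies, hierarchy-correlated
# Gaussian features, and block-structured sparse signed interactions. This
# is what makes the whole pipeline testable without external data; the
# defaults define the package's standard desk-scale benchmark (see the
# methods vignette for the rationale behind each value).

#' Generate a balanced leveled hierarchy
#'
#' Builds a balanced tree with `branching[l]` children per node at level
#' `l` and assigns entities to its first `nEntities` leaves. For the
#' `"kinase4"` kind the first top-level group is labeled `"other"`, so the
#' catch-all dissimilarity override is exercised.
#'
#' Uses R's global RNG only through downstream calls; the tree itself is
#' deterministic given its arguments.
#'
#' @param branching integer vector of per-level child counts; its length is
#'   the depth of `kind`.
#' @param kind leveled hierarchy kind (see [hierarchyTree()]).
#' @param nEntities number of entities (at most `prod(branching)` leaves);
#'   default all leaves.
#' @param prefix entity id prefix (e.g. `"D"` or `"T"`).
#' @return a [HierarchyTree-class].
#' @export
genHierarchy <- function(branching, kind = c("atc5", "kinase4", "nr3"),
                         nEntities = prod(branching), prefix = "E") {
  kind <- match.arg(kind)
  depth <- .HIER_DEPTH[[kind]]
  if (length(branching) != depth) {
    stop(sprintf("branching must have length %d for kind '%s'", depth, kind))
  }
  if (any(branching < 1L)) stop("branching counts must be positive")
  nLeaves <- prod(branching)
  if (nEntities > nLeaves) stop("more entities than leaves")
  # leaf paths in lexicographic order of per-level child indices
  grid <- expand.grid(rev(lapply(branching, seq_len)))[, length(branching):1, drop = FALSE]
  labels <- lapply(seq_len(depth), function(l) {
    lab <- paste0("L", l, ".", grid[[l]])
    if (kind == "kinase4" && l == 1L) lab[grid[[l]] == 1L] <- "other"
    lab
  })
  pathMat <- do.call(cbind, labels)
  ids <- sprintf("%s%03d", prefix, seq_len(nEntities))
  paths <- stats::setNames(
    lapply(seq_len(nEntities), function(i) pathMat[i, , drop = FALSE]),
    ids
  )
  # make the leaf level entity-specific so leaves are unique
  for (i in seq_len(nEntities)) paths[[i]][, depth] <- ids[i]
  hierarchyTree(paths, kind = kind)
}

#' Generate hierarchy-correlated features
#'
#' Hierarchical Gaussian model standing in for Mol2vec/ProtVec-style
#' inputs: every internal tree node inherits its parent's mean plus an
#' independent Gaussian offset whose per-coordinate standard deviation
#' halves with each level (`2^(1 - l)` at level `l`), and each leaf's
#' feature vector is its deepest cluster's mean plus `N(0, noiseSd^2)`
#' noise (so `noiseSd = 0` makes leaves of the same deepest cluster
#' identical). Entities in the same subtree are therefore closer in feature
#' space the deeper their common ancestor — and the deepest splits are weak
#' relative to the leaf noise, so fine hierarchy levels are not trivially
#' readable from the features alone.
#'
#' Uses R's global RNG; call `set.seed()` first.
#'
#' @param tree a leveled [HierarchyTree-class].
#' @param featureDim feature dimension (default 300, matching the
#'   pre-trained chemical/protein embeddings the model normally consumes).
#' @param noiseSd per-coordinate leaf noise standard deviation (default 0.5).
#' @return a numeric matrix, one row per entity (row names = entity ids).
#' @export
genFeatures <- function(tree, featureDim = 300L, noiseSd = 0.5) {
  stopifnot(is(tree, "HierarchyTree"), tree@kind != "graph")
  depth <- tree@depth
  ids <- tree@entities
  first <- t(vapply(tree@paths, function(p) p[1L, ], character(depth)))
  means <- matrix(0, length(ids), featureDim)
  prefix <- rep("", length(ids))
  for (l in seq_len(depth - 1L)) {
    prefix <- paste(prefix, first[, l], sep = "/")
    uniq <- unique(prefix)
    offs <- matrix(
      stats::rnorm(length(uniq) * featureDim, sd = 2^(1 - l)),
      length(uniq), featureDim
    )
    means <- means + offs[match(prefix, uniq), , drop = FALSE]
  }
  X <- means + matrix(stats::rnorm(length(ids) * featureDim, sd = noiseSd),
    length(ids), featureDim
  )
  rownames(X) <- ids
  X
}

#' Generate block-structured sparse signed interactions
#'
#' Every (drug, target) pair is observed independently with probability
#' `1 - sparsity`; an observed pair is positive with the probability given
#' by `blockAffinity[drug top-level cluster, target top-level cluster]` and
#' negative otherwise. Tying interaction probability to the top-level
#' hierarchy clusters makes the BCE signal learnable from features while
#' leaving the deeper hierarchy levels to the regularizer.
#'
#' Uses R's global RNG; call `set.seed()` first.
#'
#' @param drugTree,targetTree leveled [HierarchyTree-class] objects.
#' @param blockAffinity matrix of positive-label probabilities, one row per
#'   drug top-level cluster, one column per target top-level cluster.
#' @param sparsity fraction of pairs left unobserved, in `[0, 1)`.
#' @return a data.frame with columns `drug`, `target`, `label` (+1/-1).
#' @export
genInteractions <- function(drugTree, targetTree, blockAffinity, sparsity = 0.7) {
  stopifnot(sparsity >= 0, sparsity < 1)
  if (any(blockAffinity < 0 | blockAffinity > 1)) {
    stop("blockAffinity entries must be probabilities")
  }
  topOf <- function(tree) {
    lab <- vapply(tree@paths, function(p) p[1L, 1L], character(1))
    match(lab, unique(lab))
  }
  dTop <- topOf(drugTree)
  tTop <- topOf(targetTree)
  if (max(dTop) > nrow(blockAffinity) || max(tTop) > ncol(blockAffinity)) {
    stop("blockAffinity is smaller than the number of top-level clusters")
  }
  grid <- expand.grid(
    drug = seq_along(drugTree@entities),
    target = seq_along(targetTree@entities)
  )
  observed <- stats::runif(nrow(grid)) >= sparsity
  grid <- grid[observed, , drop = FALSE]
  pPos <- blockAffinity[cbind(dTop[grid$drug], tTop[grid$target])]
  label <- ifelse(stats::runif(nrow(grid)) < pPos, 1, -1)
  data.frame(
    drug = drugTree@entities[grid$drug],
    target = targetTree@entities[grid$target],
    label = label,
    stringsAsFactors = FALSE
  )
}

#' The default synthetic DTI benchmark
#'
#' Generates the package's standard desk-scale benchmark: 200 drugs on a
#' balanced 5-level hierarchy (branching 5-2-5-2-2) and 22 targets on a
#' 3-level hierarchy (branching 4-3-2, truncated to 22 leaves, echoing a
#' nuclear-receptor-sized panel), 300-dimensional hierarchy-correlated
#' features, and block-structured interactions with 70% of pairs
#' unobserved. `hierarchyCoverage < 1` drops hierarchy information for a
#' random fraction of entities per modality (they still carry features and
#' interactions, but never enter regularization batches or EDP).
#'
#' @param seed integer seed driving all randomness.
#' @param nDrugs,nTargets entity counts.
#' @param drugBranching,targetBranching per-level child counts.
#' @param featureDim,noiseSd feature generator settings.
#' @param blockAffinity positive-probability matrix (drug top cluster x
#'   target top cluster); the default gives each drug cluster one
#'   high-affinity (0.95) target cluster and 0.02 elsewhere, keeping the
#'   Bayes-optimal ROCAUC of the block structure above 0.95 so a
#'   well-trained model can separate held-out interactions.
#' @param sparsity fraction of unobserved pairs.
#' @param hierarchyCoverage fraction of entities keeping hierarchy labels.
#' @return a list with `data` (a [DTIDataset-class]), `drugTree`,
#'   `targetTree`, `drugDistances`, `targetDistances`.
#' @export
synthBenchmark <- function(seed = 1L, nDrugs = 200L, nTargets = 22L,
                           drugBranching = c(5L, 2L, 5L, 2L, 2L),
                           targetBranching = c(4L, 3L, 2L),
                           featureDim = 300L, noiseSd = 0.5,
                           blockAffinity = NULL, sparsity = 0.7,
                           hierarchyCoverage = 1) {
  stopifnot(hierarchyCoverage > 0, hierarchyCoverage <= 1)
  set.seed(seed)
  drugTree <- genHierarchy(drugBranching, "atc5", nDrugs, prefix = "D")
  targetTree <- genHierarchy(targetBranching, "nr3", nTargets, prefix = "T")
  if (is.null(blockAffinity)) {
    kd <- drugBranching[1L]
    kt <- targetBranching[1L]
    blockAffinity <- matrix(0.02, kd, kt)
    blockAffinity[cbind(seq_len(kd), ((seq_len(kd) - 1L) %% kt) + 1L)] <- 0.95
  }
  Fd <- genFeatures(drugTree, featureDim, noiseSd)
  Ft <- genFeatures(targetTree, featureDim, noiseSd)
  it <- genInteractions(drugTree, targetTree, blockAffinity, sparsity)
  dropHier <- function(tree, keepFrac) {
    if (keepFrac >= 1) {
      return(tree)
    }
    keep <- sort(sample(
      length(tree@entities),
      max(2L, round(keepFrac * length(tree@entities)))
    ))
    hierarchyTree(tree@paths[keep], kind = tree@kind, specialGroups = tree@specialGroups)
  }
  drugTree <- dropHier(drugTree, hierarchyCoverage)
  targetTree <- dropHier(targetTree, hierarchyCoverage)
  data <- new("DTIDataset",
    interactions = it, drugFeatures = Fd, targetFeatures = Ft
  )
  list(
    data = data, drugTree = drugTree, targetTree = targetTree,
    drugDistances = lcaDistanceMatrix(drugTree),
    targetDistances = lcaDistanceMatrix(targetTree)
  )
}
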