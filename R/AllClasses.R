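#' @import methods
NULL

#' HierarchyTree: a leveled rooted tree (or graph) over drugs or targets
#'
#' Container for a priori biological hierarchies. Leveled kinds (`"atc5"`,
#' `"kinase4"`, `"nr3"`) store one or more root-to-leaf label paths per
#' entity; entities may carry several paths (an ATC-style drug can hold
#' multiple codes). The `"graph"` kind (MeSH-style) stores an undirected edge
#' list in which entities may be internal nodes as well as leaves.
#'
#' @slot kind character, one of `"atc5"`, `"kinase4"`, `"nr3"`, `"graph"`.
#' @slot depth integer; number of levels (5/4/3) for leveled kinds, `NA` for
#'   graphs.
#' @slot paths named list; one character matrix per entity, each row a
#'   root-to-leaf path of length `depth` (leveled kinds only).
#' @slot specialGroups character; top-level labels treated as dissimilarity
#'   overrides (e.g. the kinome `"other"` and `"atypical"` groups).
#' @slot edges data.frame with columns `from`, `to` (graph kind only).
#' @slot entities character; entity identifiers, in matrix order.
#'
#' @seealso [parseHierarchy()], [lcaDistanceMatrix()], [hopDistanceMatrix()]
#' @export
setClass("HierarchyTree",
  representation(
    kind = "character",
    depth = "integer",
    paths = "list",
    specialGroups = "character",
    edges = "data.frame",
    entities = "character"
  ),
  prototype(
    kind = "atc5", depth = 5L, paths = list(),
    specialGroups = character(), edges = data.frame(), entities = character()
  )
)

setValidity("HierarchyTree", function(object) {
  msg <- character()
  if (!object@kind %in% c("atc5", "kinase4", "nr3", "graph")) {
    msg <- c(msg, sprintf("unknown hierarchy kind '%s'", object@kind))
  }
  if (object@kind != "graph") {
    if (length(object@paths) == 0L) msg <- c(msg, "leveled hierarchy has no paths")
    bad <- vapply(object@paths, function(p) ncol(p) != object@depth, logical(1))
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "paths of wrong length for: %s",
        paste(names(object@paths)[bad], collapse = ", ")
      ))
    }
    npaths <- vapply(object@paths, nrow, integer(1))
    if (any(npaths < 1L)) msg <- c(msg, "every entity needs at least one path")
    if (!identical(sort(names(object@paths)), sort(object@entities))) {
      msg <- c(msg, "entities and path names disagree")
    }
    lvl1 <- unique(unlist(lapply(object@paths, function(p) p[, 1L])))
    if (!all(object@specialGroups %in% c(lvl1, character()))) {
      # special groups that never occur are tolerated (defaults cover both
      # kinome catch-alls even when a dataset only contains one of them)
    }
  } else {
    if (nrow(object@edges) == 0L) msg <- c(msg, "graph hierarchy has no edges")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HierarchyTree number of entities
#' @param x,object a `HierarchyTree`
#' @export
setMethod("length", "HierarchyTree", function(x) length(x@entities))

#' @export
setMethod("show", "HierarchyTree", function(object) {
  if (object@kind == "graph") {
    cat(sprintf(
      "HierarchyTree (graph): %d entities, %d edges\n",
      length(object@entities), nrow(object@edges)
    ))
  } else {
    cat(sprintf(
      "HierarchyTree (%s, depth %d): %d entities, %d paths%s\n",
      object@kind, object@depth, length(object@entities),
      sum(vapply(object@paths, nrow, integer(1))),
      if (length(object@specialGroups)) {
        paste0(", special groups: ", paste(object@specialGroups, collapse = ", "))
      } else ""
    ))
  }
  invisible(object)
})

#' @describeIn HierarchyTree entity identifiers
#' @export
setGeneric("entities", function(object) standardGeneric("entities"))

#' @export
setMethod("entities", "HierarchyTree", function(object) object@entities)

#' HierarchyDistanceMatrix: pairwise hierarchy dissimilarities
#'
#' Symmetric integer-valued dissimilarities between entities, derived from a
#' [HierarchyTree-class] either as lowest-common-ancestor level distances
#' (leveled kinds; values in `1..depth` off the diagonal) or unweighted
#' shortest-path hop counts (graph kind; `Inf` marks disconnected pairs).
#'
#' @slot entities character; entity ids, row/column order of `D`.
#' @slot D numeric matrix of dissimilarities.
#' @slot kind character; the originating hierarchy kind.
#' @slot depth integer; tree depth (`NA` for graphs).
#' @export
setClass("HierarchyDistanceMatrix",
  representation(
    entities = "character", D = "matrix",
    kind = "character", depth = "integer"
  )
)

setValidity("HierarchyDistanceMatrix", function(object) {
  msg <- character()
  D <- object@D
  if (nrow(D) != ncol(D)) msg <- c(msg, "D must be square")
  if (nrow(D) != length(object@entities)) msg <- c(msg, "entities/D size mismatch")
  if (!isTRUE(all.equal(D, t(D)))) msg <- c(msg, "D must be symmetric")
  if (any(diag(D) != 0)) msg <- c(msg, "diagonal must be zero")
  off <- D[row(D) != col(D)]
  if (object@kind != "graph" && length(off) && any(off < 1 | off > object@depth)) {
    msg <- c(msg, "leveled distances must lie in 1..depth off the diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "HierarchyDistanceMatrix", function(object) {
  cat(sprintf(
    "HierarchyDistanceMatrix (%s): %d entities, distances in [%s, %s]\n",
    object@kind, length(object@entities),
    format(min(object@D)), format(max(object@D[is.finite(object@D)]))
  ))
  invisible(object)
})

#' @export
setMethod("entities", "HierarchyDistanceMatrix", function(object) object@entities)

#' @describeIn HierarchyDistanceMatrix extract the plain distance matrix
#' @param object a `HierarchyDistanceMatrix`
#' @export
setGeneric("distanceMatrix", function(object) standardGeneric("distanceMatrix"))

#' @export
setMethod("distanceMatrix", "HierarchyDistanceMatrix", function(object) object@D)

#' DTIDataset: sparse signed interactions plus per-entity features
#'
#' Holds the observed part of a drug x target interaction matrix as a long
#' table of signed labels (+1 interacting / -1 non-interacting; unobserved
#' pairs are simply absent) together with fixed, precomputed feature vectors
#' for every referenced entity (e.g. 300-dimensional Mol2vec/ProtVec-style
#' embeddings).
#'
#' @slot interactions data.frame with columns `drug`, `target`, `label`
#'   (`+1`/`-1`) and optionally `value` (the raw affinity before
#'   binarization).
#' @slot drugFeatures,targetFeatures numeric matrices, one row per entity,
#'   row names are entity ids.
#' @export
setClass("DTIDataset",
  representation(
    interactions = "data.frame",
    drugFeatures = "matrix",
    targetFeatures = "matrix"
  )
)

setValidity("DTIDataset", function(object) {
  msg <- character()
  it <- object@interactions
  if (!all(c("drug", "target", "label") %in% names(it))) {
    msg <- c(msg, "interactions need columns drug, target, label")
  } else {
    if (anyDuplicated(paste(it$drug, it$target, sep = "\r"))) {
      msg <- c(msg, "duplicate (drug, target) pairs")
    }
    if (!all(it$label %in% c(-1, 1))) msg <- c(msg, "labels must be +1/-1")
    if (!all(it$drug %in% rownames(object@drugFeatures))) {
      msg <- c(msg, "interaction references drugs without features")
    }
    if (!all(it$target %in% rownames(object@targetFeatures))) {
      msg <- c(msg, "interaction references targets without features")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "DTIDataset", function(object) {
  it <- object@interactions
  cat(sprintf(
    "DTIDataset: %d drugs x %d targets, %d labeled interactions (%d+/%d-)\n",
    nrow(object@drugFeatures), nrow(object@targetFeatures), nrow(it),
    sum(it$label == 1), sum(it$label == -1)
  ))
  cat(sprintf(
    "  features: drugs %dd, targets %dd; sparsity %.4f\n",
    ncol(object@drugFeatures), ncol(object@targetFeatures),
    1 - nrow(it) / (nrow(object@drugFeatures) * nrow(object@targetFeatures))
  ))
  invisible(object)
})

#' @describeIn DTIDataset the signed interaction table
#' @param object a `DTIDataset`
#' @export
setGeneric("interactions", function(object) standardGeneric("interactions"))

#' @export
setMethod("interactions", "DTIDataset", function(object) object@interactions)

#' @describeIn DTIDataset drug feature matrix
#' @export
setGeneric("drugFeatures", function(object) standardGeneric("drugFeatures"))

#' @export
setMethod("drugFeatures", "DTIDataset", function(object) object@drugFeatures)

#' @describeIn DTIDataset target feature matrix
#' @export
setGeneric("targetFeatures", function(object) standardGeneric("targetFeatures"))

#' @export
setMethod("targetFeatures", "DTIDataset", function(object) object@targetFeatures)

#' DTIModel: pairwise encoders plus a prediction head
#'
#' A trained (or freshly initialized) pairwise DTI predictor: two
#' feed-forward encoders mapping drug and target feature vectors into a
#' shared latent space, and a head turning a latent pair into an interaction
#' probability. The `"euclidean"` head scores with a logistic-transformed dot
#' product; the `"lorentz"` head clips the encoder output to norm `alpha`,
#' lifts it onto the hyperboloid of curvature `-1/beta` with the origin
#' exponential map, and scores with `exp(-d_L^2)`.
#'
#' @slot drugNet,targetNet internal weight lists (see `hierDTI:::mlpInit`).
#' @slot head character, `"euclidean"` or `"lorentz"`.
#' @slot alpha numeric clip threshold for the lorentz head.
#' @slot beta numeric curvature parameter (space curvature is `-1/beta`).
#' @slot latentDim integer latent dimension `d` (the hyperboloid lives in
#'   ambient dimension `d + 1`).
#' @slot lossTrace data.frame of per-epoch loss components.
#' @slot config list of the encoder/training configuration used.
#' @export
setClass("DTIModel",
  representation(
    drugNet = "list", targetNet = "list",
    head = "character", alpha = "numeric", beta = "numeric",
    latentDim = "integer", lossTrace = "data.frame", config = "list"
  )
)

setValidity("DTIModel", function(object) {
  msg <- character()
  if (!object@head %in% c("euclidean", "lorentz")) {
    msg <- c(msg, "head must be 'euclidean' or 'lorentz'")
  }
  if (object@latentDim < 2L) msg <- c(msg, "latentDim must be >= 2")
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "DTIModel", function(object) {
  cat(sprintf(
    "DTIModel (%s head): latent dim %d, beta = %g%s\n",
    object@head, object@latentDim, object@beta,
    if (object@head == "lorentz") sprintf(", clip alpha = %g", object@alpha) else ""
  ))
  if (nrow(object@lossTrace)) {
    cat(sprintf(
      "  trained %d epochs; final total loss %.4f\n",
      nrow(object@lossTrace), object@lossTrace$total[nrow(object@lossTrace)]
    ))
  } else {
    cat("  untrained\n")
  }
  invisible(object)
})

#' @describeIn DTIModel per-epoch loss components recorded during training
#' @param object a `DTIModel`
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @export
setMethod("lossTrace", "DTIModel", function(object) object@lossTrace)

#' DiskEmbedding: a two-dimensional Poincare-disk embedding
#'
#' Positions of drugs, targets and (optionally) internal hierarchy-tree
#' nodes inside the open unit disk, as produced by [poincareMapsReduce()] and
#' augmented by [embedTree()].
#'
#' @slot coords numeric matrix (n x 2), row names are node ids; all row
#'   norms are strictly below 1.
#' @slot kind character vector parallel to `coords` rows: `"drug"`,
#'   `"target"` or `"internal"`.
#' @slot edges data.frame with columns `parent`, `child` (tree edges; may be
#'   empty).
#' @slot lossTrace numeric vector of the reducer's recorded KL losses.
#' @export
setClass("DiskEmbedding",
  representation(
    coords = "matrix", kind = "character",
    edges = "data.frame", lossTrace = "numeric"
  ),
  prototype(edges = data.frame(), lossTrace = numeric())
)

setValidity("DiskEmbedding", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must be n x 2")
  if (length(object@kind) != nrow(object@coords)) {
    msg <- c(msg, "kind must parallel coords rows")
  }
  if (nrow(object@coords) && any(sqrt(rowSums(object@coords^2)) >= 1)) {
    msg <- c(msg, "all points must lie strictly inside the unit disk")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "DiskEmbedding", function(object) {
  cat(sprintf(
    "DiskEmbedding: %d nodes (%s)%s\n",
    nrow(object@coords),
    paste(sprintf("%d %s", table(object@kind), names(table(object@kind))),
      collapse = ", "
    ),
    if (nrow(object@edges)) sprintf(", %d tree edges", nrow(object@edges)) else ""
  ))
  invisible(object)
})

#' @describeIn DiskEmbedding disk coordinates (n x 2 matrix)
#' @param object a `DiskEmbedding`
#' @export
setGeneric("diskCoords", function(object) standardGeneric("diskCoords"))

#' @export
setMethod("diskCoords", "DiskEmbedding", function(object) object@coords)
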