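# Hierarchy parsing, lowest-common-ancestor and hop distance matrices, and
# the anchor/positive/negative sampler feeding the ranking regularizer.

.HIER_DEPTH <- c(atc5 = 5L, kinase4 = 4L, nr3 = 3L, graph = NA_integer_)

#' Construct a leveled hierarchy tree from entity paths
#'
#' @param paths a named list (one element per entity) of character matrices
#'   or vectors; each row/vector is a root-to-leaf label path whose length
#'   must equal the depth of `kind`. Entities may carry several paths
#'   (ATC-style drugs can hold multiple codes).
#' @param kind `"atc5"` (depth 5), `"kinase4"` (depth 4) or `"nr3"`
#'   (depth 3).
#' @param specialGroups top-level labels whose members are treated as less
#'   similar: when the lowest common ancestor of two entities is such a
#'   group node itself, their distance is raised from `depth - 1` to
#'   `depth`. Defaults to the kinome catch-alls for `"kinase4"`.
#' @return a [HierarchyTree-class].
#' @export
hierarchyTree <- function(paths, kind = c("atc5", "kinase4", "nr3"),
                          specialGroups = NULL) {
  kind <- match.arg(kind)
  depth <- .HIER_DEPTH[[kind]]
  if (is.null(specialGroups)) {
    specialGroups <- if (kind == "kinase4") c("other", "atypical") else character()
  }
  paths <- lapply(paths, function(p) {
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    if (ncol(p) != depth) {
      stop(sprintf("path of length %d in a depth-%d (%s) hierarchy", ncol(p), depth, kind))
    }
    p
  })
  new("HierarchyTree",
    kind = kind, depth = depth, paths = paths,
    specialGroups = as.character(specialGroups),
    edges = data.frame(), entities = names(paths)
  )
}

#' Construct a graph (MeSH-style) hierarchy from an edge list
#'
#' Entities may occupy internal nodes as well as leaves; dissimilarity is
#' the unweighted shortest-path hop count (see [hopDistanceMatrix()]).
#'
#' @param edges a two-column data.frame (`from`, `to`) of undirected edges.
#' @return a [HierarchyTree-class] of kind `"graph"`.
#' @export
hierarchyGraph <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L || nrow(edges) == 0L) stop("edge list needs rows with two columns")
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  new("HierarchyTree",
    kind = "graph", depth = NA_integer_, paths = list(),
    specialGroups = character(), edges = edges[, 1:2],
    entities = sort(unique(c(edges$from, edges$to)))
  )
}

#' Read a hierarchy file
#'
#' Leveled kinds expect a header-less TSV with an entity id followed by
#' `depth` tab-separated path labels per row; an entity appearing on several
#' rows keeps all its paths. The graph kind expects a two-column `from<TAB>to`
#' edge list.
#'
#' @param file path to a TSV file.
#' @param kind hierarchy kind (see [hierarchyTree()]), or `"graph"`.
#' @param specialGroups see [hierarchyTree()].
#' @return a [HierarchyTree-class].
#' @export
parseHierarchy <- function(file, kind = c("atc5", "kinase4", "nr3", "graph"),
                           specialGroups = NULL) {
  kind <- match.arg(kind)
  tab <- tryCatch(
    utils::read.delim(file,
      header = FALSE, colClasses = "character",
      blank.lines.skip = TRUE
    ),
    error = function(e) stop(sprintf("cannot parse '%s': %s", file, conditionMessage(e)))
  )
  if (nrow(tab) == 0L) stop(sprintf("empty hierarchy file '%s'", file))
  if (kind == "graph") {
    if (ncol(tab) != 2L) stop("graph hierarchy files need exactly two columns")
    return(hierarchyGraph(tab))
  }
  depth <- .HIER_DEPTH[[kind]]
  if (ncol(tab) != depth + 1L) {
    stop(sprintf(
      "expected %d path columns for kind '%s', found %d",
      depth, kind, ncol(tab) - 1L
    ))
  }
  ids <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  paths <- lapply(split(seq_len(nrow(mat)), ids), function(i) {
    mat[i, , drop = FALSE]
  })
  paths <- paths[unique(ids)] # keep first-seen entity order
  hierarchyTree(paths, kind = kind, specialGroups = specialGroups)
}

#' Write a leveled hierarchy to TSV
#'
#' The dialect read back by [parseHierarchy()]: one row per path, entity id
#' first.
#'
#' @param tree a leveled [HierarchyTree-class].
#' @param file output path.
#' @export
writeHierarchy <- function(tree, file) {
  stopifnot(is(tree, "HierarchyTree"))
  if (tree@kind == "graph") {
    utils::write.table(tree@edges, file,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
    return(invisible(file))
  }
  rows <- do.call(rbind, lapply(tree@entities, function(e) {
    cbind(e, tree@paths[[e]], deparse.level = 0)
  }))
  utils::write.table(rows, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(file)
}

#' Lowest-common-ancestor distance matrix of a leveled hierarchy
#'
#' For two entities the distance is `depth - L`, where `L` is the level
#' (root = 0) of the deepest common ancestor over some pair of their paths:
#' 1 when only the leaf level differs, up to `depth` when the top level
#' differs. Entities with several paths take the minimum over all path
#' pairs. When the deepest common ancestor is a top-level node in
#' `specialGroups` (the kinome "other"/"atypical" rule) the distance
#' `depth - 1` is overridden to `depth`, reflecting that members of those
#' catch-all groups are not expected to be similar unless they share a
#' family or subfamily.
#'
#' @param tree a leveled [HierarchyTree-class].
#' @return a [HierarchyDistanceMatrix-class].
#' @export
lcaDistanceMatrix <- function(tree) {
  stopifnot(is(tree, "HierarchyTree"))
  if (tree@kind == "graph") stop("LCA distances are defined for leveled hierarchies; use hopDistanceMatrix()")
  depth <- tree@depth
  ids <- tree@entities
  # flatten paths; prefix codes nest, so the common-prefix length is the
  # number of levels at which the cumulative prefixes agree
  owner <- rep(seq_along(ids), vapply(tree@paths, nrow, integer(1)))
  flat <- do.call(rbind, tree@paths)
  np <- nrow(flat)
  pref <- matrix(0L, np, depth)
  acc <- rep("", np)
  for (l in seq_len(depth)) {
    acc <- paste(acc, flat[, l], sep = "\x1f")
    pref[, l] <- match(acc, unique(acc))
  }
  common <- matrix(0L, np, np)
  for (l in seq_len(depth)) {
    common <- common + outer(pref[, l], pref[, l], "==")
  }
  Dp <- depth - common
  if (length(tree@specialGroups)) {
    special <- flat[, 1L] %in% tree@specialGroups
    hit <- outer(special, special, "&") & common == 1L
    Dp[hit] <- depth
  }
  # entity-level minimum over path pairs (duplicate-leaf rule)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ri <- Dp[owner == i, , drop = FALSE]
    mi <- apply(ri, 2L, min)
    D[i, ] <- vapply(seq_len(n), function(j) min(mi[owner == j]), numeric(1))
  }
  D <- pmin(D, t(D)) # min over ordered path pairs is symmetric already; belt and braces
  diag(D) <- 0
  new("HierarchyDistanceMatrix",
    entities = ids, D = D, kind = tree@kind, depth = depth
  )
}

#' Hop-count distance matrix of a graph hierarchy
#'
#' Unweighted shortest-path length between entity nodes, suiting MeSH-style
#' hierarchies where entities occupy internal nodes too (one entity can be a
#' descendant of another).
#'
#' @param tree a [HierarchyTree-class] of kind `"graph"`.
#' @param disconnected `"inf"` keeps `Inf` for pairs in different components
#'   (such pairs are excluded from regularization sampling); `"error"`
#'   aborts instead.
#' @return a [HierarchyDistanceMatrix-class].
#' @export
hopDistanceMatrix <- function(tree, disconnected = c("inf", "error")) {
  stopifnot(is(tree, "HierarchyTree"))
  disconnected <- match.arg(disconnected)
  if (tree@kind != "graph") stop("hop distances are defined for graph hierarchies; use lcaDistanceMatrix()")
  g <- igraph::graph_from_data_frame(tree@edges, directed = FALSE)
  D <- igraph::distances(g, algorithm = "unweighted")
  D <- D[tree@entities, tree@entities]
  if (disconnected == "error" && any(!is.finite(D))) {
    stop("graph hierarchy has disconnected entity pairs")
  }
  new("HierarchyDistanceMatrix",
    entities = tree@entities, D = D,
    kind = "graph", depth = NA_integer_
  )
}

# positive-candidate mask: leaves sharing a non-root ancestor with the
# anchor (leveled: 0 < D < depth); graph kind: any finite positive distance
.positiveCandidates <- function(dm) {
  D <- dm@D
  if (dm@kind == "graph") {
    ok <- is.finite(D) & D > 0
  } else {
    ok <- D > 0 & D < dm@depth
  }
  diag(ok) <- FALSE
  ok
}

#' Sample an anchor/positive/negative batch from a hierarchy
#'
#' Draws `n` anchors uniformly without replacement from entities that have
#' at least one positive candidate (a leaf sharing a non-root ancestor; for
#' graph hierarchies, any finite-distance entity). For each anchor the
#' positive is drawn uniformly over the hierarchy distances realized among
#' its candidates, then uniformly among candidates at the drawn distance.
#' Up to `m` negatives are then drawn uniformly without replacement from the
#' entities strictly farther from the anchor than its positive.
#'
#' Sampling uses R's global random number generator; call `set.seed()` first
#' for reproducible batches.
#'
#' @param dm a [HierarchyDistanceMatrix-class].
#' @param n number of anchors.
#' @param m maximum number of negatives per anchor.
#' @param restrictTo optional character vector; sampling is restricted to
#'   these entities (e.g. those that actually carry feature vectors).
#' @return a list of class `RegularizationBatch` with elements `anchors`,
#'   `positives`, `negatives` (a list of character vectors, possibly empty)
#'   and `positiveDistance`.
#' @export
sampleRegularizationBatch <- function(dm, n = 10L, m = 256L, restrictTo = NULL) {
  stopifnot(is(dm, "HierarchyDistanceMatrix"), n >= 1L, m >= 1L)
  ids <- dm@entities
  keep <- if (is.null(restrictTo)) ids else intersect(ids, restrictTo)
  if (length(keep) < 2L) stop("need at least two entities to sample from")
  D <- dm@D[keep, keep, drop = FALSE]
  sub <- dm
  sub@entities <- keep
  sub@D <- D
  cand <- .positiveCandidates(sub)
  pool <- keep[rowSums(cand) > 0L]
  if (length(pool) == 0L) stop("no entity has a positive candidate under the hierarchy")
  anchors <- sample(pool, min(n, length(pool)))
  positives <- character(length(anchors))
  posDist <- numeric(length(anchors))
  negatives <- vector("list", length(anchors))
  for (i in seq_along(anchors)) {
    a <- anchors[i]
    cset <- keep[cand[a, ]]
    dvals <- unique(D[a, cset])
    dpick <- if (length(dvals) == 1L) dvals else sample(dvals, 1L)
    atd <- cset[D[a, cset] == dpick]
    positives[i] <- if (length(atd) == 1L) atd else sample(atd, 1L)
    posDist[i] <- dpick
    far <- keep[is.finite(D[a, ]) & D[a, ] > dpick]
    far <- setdiff(far, a)
    negatives[[i]] <- if (length(far) <= m) {
      if (length(far) > 1L) sample(far) else far
    } else {
      sample(far, m)
    }
  }
  structure(
    list(
      anchors = anchors, positives = positives,
      negatives = negatives, positiveDistance = posDist
    ),
    class = "RegularizationBatch"
  )
}

#' @export
print.RegularizationBatch <- function(x, ...) {
  cat(sprintf(
    "RegularizationBatch: %d anchors, %s negatives per anchor\n",
    length(x$anchors),
    paste(range(lengths(x$negatives)), collapse = "-")
  ))
  invisible(x)
}
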