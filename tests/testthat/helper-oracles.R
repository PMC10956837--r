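# Brute-force oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (loops, enumeration) and independent of
# the implementation paths they check.

# random point in the open unit ball
rBall <- function(d, rmax = 0.9) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2)) * stats::runif(1, 0, rmax)
}

# random on-manifold point (beta = 1) via the exponential map oracle-free
# construction x = (sqrt(1 + |u|^2), u)
rLorentz <- function(d, scale = 1) {
  u <- stats::rnorm(d, sd = scale)
  c(sqrt(1 + sum(u^2)), u)
}

# random leveled hierarchy with optional multi-path entities; leaf labels
# are entity-unique so off-diagonal LCA distances are >= 1
randomToyTree <- function(nEntities, kind = c("atc5", "kinase4", "nr3"),
                          pMultiPath = 0.25) {
  kind <- match.arg(kind)
  depth <- c(atc5 = 5L, kinase4 = 4L, nr3 = 3L)[[kind]]
  topLabels <- if (kind == "kinase4") {
    c("other", "atypical", "TK", "CAMK")
  } else {
    c("A", "B", "C")
  }
  ids <- sprintf("E%02d", seq_len(nEntities))
  makePath <- function(id, j) {
    path <- character(depth)
    path[1L] <- sample(topLabels, 1L)
    if (depth > 2L) {
      for (l in 2L:(depth - 1L)) path[l] <- sample(paste0("n", 1:3), 1L)
    }
    path[depth] <- paste0(id, ".", j)
    path
  }
  paths <- lapply(ids, function(id) {
    np <- 1L + stats::rbinom(1L, 1L, pMultiPath)
    do.call(rbind, lapply(seq_len(np), function(j) makePath(id, j)))
  })
  names(paths) <- ids
  hierarchyTree(paths, kind = kind)
}

# all-path-pairs LCA distance oracle, including the special-group override
# and the duplicate-leaf minimum rule
oracleLcaMatrix <- function(tree) {
  depth <- tree@depth
  ids <- tree@entities
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      best <- Inf
      for (pi in seq_len(nrow(tree@paths[[i]]))) {
        for (pj in seq_len(nrow(tree@paths[[j]]))) {
          a <- tree@paths[[i]][pi, ]
          b <- tree@paths[[j]][pj, ]
          l <- 0L
          while (l < depth && a[l + 1L] == b[l + 1L]) l <- l + 1L
          d <- depth - l
          if (l == 1L && a[1L] %in% tree@specialGroups) d <- depth
          best <- min(best, d)
        }
      }
      D[i, j] <- best
    }
  }
  D
}

# naive farthest-point agglomeration: returns the sorted leaf set and the
# height of every merge, in merge order
oracleCompleteLinkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  leafSets <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    bh <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < bh) {
          bh <- h
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    leafSets[[length(leafSets) + 1L]] <- sort(merged)
    heights <- c(heights, bh)
    clusters[[best[1L]]] <- merged
    clusters <- clusters[-best[2L]]
  }
  list(leafSets = leafSets, heights = heights)
}

# leaf sets per internal node of an hclust object, by recursion
hclustLeafSets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(k) if (k < 0) -k else sets[[k]]
    sets[[s]] <- sort(c(pick(hc$merge[s, 1L]), pick(hc$merge[s, 2L])))
  }
  sets
}

# O(n^2)-search purity oracle: for a same-class pair, the smallest subtree
# containing both, then the same-class leaf fraction of its leaves
oracleExactPurity <- function(hc, labels) {
  n <- length(hc$order)
  if (!is.null(hc$labels)) labels <- labels[hc$labels]
  sets <- hclustLeafSets(hc)
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (labels[i] != labels[j]) next
      containing <- Filter(function(s) i %in% s && j %in% s, sets)
      sizes <- vapply(containing, length, integer(1))
      leaves <- containing[[which.min(sizes)]]
      vals <- c(vals, mean(labels[leaves] == labels[i]))
    }
  }
  mean(vals)
}

# TRUE iff every class's leaves form a pure subtree (a leaf counts as one)
allClassesPure <- function(hc, labels) {
  if (!is.null(hc$labels)) labels <- labels[hc$labels]
  sets <- c(as.list(seq_along(labels)), hclustLeafSets(hc))
  all(vapply(unique(labels), function(cl) {
    members <- sort(which(labels == cl))
    any(vapply(sets, function(s) identical(s, members), logical(1)))
  }, logical(1)))
}

# random binary dendrogram over n leaves (uniform random merge order,
# strictly increasing heights), as an hclust object
randomDendrogram <- function(n, labels = NULL) {
  avail <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  for (s in seq_len(n - 1L)) {
    pick <- sample(length(avail), 2L)
    merge[s, ] <- sort(avail[pick])
    avail <- c(avail[-pick], s)
  }
  heights <- cumsum(stats::runif(n - 1L, 0.1, 1))
  ord <- integer(0)
  walk <- function(k) {
    if (k < 0) {
      ord <<- c(ord, -k)
    } else {
      walk(merge[k, 1L])
      walk(merge[k, 2L])
    }
  }
  walk(n - 1L)
  structure(
    list(
      merge = merge, height = heights, order = ord,
      labels = labels, method = "complete"
    ),
    class = "hclust"
  )
}

# O(n^2) concordance oracle for the ROC area
oracleRocAuc <- function(labels, scores) {
  y <- ifelse(labels > 0, 1L, 0L)
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# a tiny dense DTIDataset for model tests
tinyDataset <- function(nd = 8L, nt = 6L, fd = 10L, seed = 42L) {
  set.seed(seed)
  Fd <- matrix(stats::rnorm(nd * fd), nd, fd,
    dimnames = list(sprintf("D%03d", seq_len(nd)), NULL)
  )
  Ft <- matrix(stats::rnorm(nt * fd), nt, fd,
    dimnames = list(sprintf("T%03d", seq_len(nt)), NULL)
  )
  it <- expand.grid(
    drug = rownames(Fd), target = rownames(Ft),
    stringsAsFactors = FALSE
  )
  it$label <- sample(c(-1, 1), nrow(it), replace = TRUE)
  dtiDataset(it, Fd, Ft)
}
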