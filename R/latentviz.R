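# Two-dimensional Poincare-disk view of the latent space: a simplified
# hyperbolic dimensionality reduction in the style of Poincare maps
# (kNN graph -> self-tuning Gaussian kernel -> relative forest accessibility
# similarity -> KL embedding on the disk), bottom-up hierarchy-tree
# embedding via Einstein midpoints, and translation-based navigation.

#' Reducer configuration
#'
#' Defaults follow the reference setup: 2000 epochs, batch size 64,
#' learning rate 0.05, 5 neighbors, output dimension 2.
#'
#' @param epochs optimization epochs.
#' @param batch rows updated per gradient step.
#' @param learningRate Riemannian SGD step size.
#' @param neighbors kNN graph degree (also sets the self-tuning kernel
#'   bandwidth: each point's bandwidth is its distance to the
#'   `neighbors`-th neighbor).
#' @param seed optional integer seed.
#' @return a list of class `ReducerConfig`.
#' @export
reducerConfig <- function(epochs = 2000L, batch = 64L, learningRate = 0.05,
                          neighbors = 5L, seed = NULL) {
  stopifnot(epochs >= 1L, batch >= 1L, learningRate > 0, neighbors >= 1L)
  structure(
    list(
      epochs = as.integer(epochs), batch = as.integer(batch),
      learningRate = learningRate, neighbors = as.integer(neighbors),
      outDim = 2L, seed = seed
    ),
    class = "ReducerConfig"
  )
}

.DISK_MAX <- 1 - 1e-5 # projection radius for the reducer

# row-normalized relative-forest-accessibility targets from a distance matrix
.rfaTargets <- function(D, neighbors) {
  n <- nrow(D)
  k <- min(neighbors, n - 1L)
  # self-tuning bandwidth: distance to the k-th neighbor
  sigma <- vapply(seq_len(n), function(i) sort(D[i, -i])[k], numeric(1))
  sigma <- pmax(sigma, 1e-12)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    W[i, nb] <- exp(-D[i, nb]^2 / (sigma[i] * sigma[nb]))
  }
  W <- pmax(W, t(W)) # union symmetrization
  L <- diag(rowSums(W)) - W
  R <- solve(diag(n) + L)
  R <- pmax(R, 0)
  diag(R) <- 0
  P <- R / rowSums(R)
  P
}

#' Poincare-disk dimensionality reduction
#'
#' A simplified re-implementation of the Poincare-maps style reducer. From
#' a precomputed hyperbolic distance matrix it builds a union-symmetrized
#' kNN graph with self-tuning Gaussian weights, converts it to
#' relative-forest-accessibility similarities `(I + L)^{-1}` (L the graph
#' Laplacian), row-normalizes them into targets `p_ij`, and fits 2-D disk
#' coordinates minimizing `KL(p || q)` with `q_ij` proportional to
#' `exp(-d_P(z_i, z_j))` by mini-batch gradient descent (conformally scaled
#' steps, projection back into the open disk).
#'
#' @param D symmetric distance matrix with zero diagonal (typically the
#'   Poincare distances between model latents, see
#'   [latentPoincareDistances()]).
#' @param cfg a [reducerConfig()].
#' @param kind optional character vector labeling each row (`"drug"` /
#'   `"target"`); stored in the result.
#' @return a [DiskEmbedding-class]; its `lossTrace` records the KL loss at
#'   the start and every 50 epochs.
#' @export
poincareMapsReduce <- function(D, cfg = reducerConfig(), kind = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-6))) {
    stop("D must be a symmetric matrix")
  }
  if (n < 3L) stop("need at least 3 points")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  P <- .rfaTargets(D, cfg$neighbors)
  Z <- matrix(stats::rnorm(n * 2L, sd = 1e-3), n, 2L)
  klLoss <- function(Z) {
    dp <- poincareDistanceMatrix(Z)
    Q <- exp(-dp)
    diag(Q) <- 0
    Q <- Q / rowSums(Q)
    sum(P[P > 0] * log(P[P > 0] / pmax(Q[P > 0], 1e-300)))
  }
  trace <- klLoss(Z)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(n)
    for (s in seq(1L, n, by = cfg$batch)) {
      rows <- perm[s:min(s + cfg$batch - 1L, n)]
      norms2 <- rowSums(Z^2)
      for (i in rows) {
        zi <- Z[i, ]
        a <- max(1 - sum(zi^2), 1e-12)
        diffs <- sweep(-Z, 2L, -zi) # zi - zj rows
        b <- pmax(1 - norms2, 1e-12)
        c2 <- rowSums(diffs^2)
        gamma <- 1 + 2 * c2 / (a * b)
        d <- acosh(pmax(gamma, 1))
        d[i] <- Inf
        q <- exp(-d)
        q <- q / sum(q)
        coef <- P[i, ] - q # dKL_i / dd_ij
        coef[i] <- 0
        # grad of d_P(z_i, z_j) w.r.t. z_i
        root <- sqrt(pmax(gamma^2 - 1, 1e-12))
        gfac <- (4 / (a * b * root)) * coef
        gfac[i] <- 0
        grad <- colSums(gfac * (diffs + (c2 / a) * matrix(zi, n, 2L, byrow = TRUE)))
        grad <- (a^2 / 4) * grad # conformal (Riemannian) scaling
        zi <- zi - cfg$learningRate * grad
        nz <- sqrt(sum(zi^2))
        if (nz > .DISK_MAX) zi <- zi * (.DISK_MAX / nz)
        Z[i, ] <- zi
      }
    }
    if (epoch %% 50L == 0L) {
      l <- klLoss(Z)
      if (!is.finite(l)) stop("reducer loss diverged")
      trace <- c(trace, l)
    }
  }
  trace <- c(trace, klLoss(Z))
  rownames(Z) <- ids
  if (is.null(kind)) kind <- rep("drug", n)
  new("DiskEmbedding",
    coords = Z, kind = kind,
    edges = data.frame(), lossTrace = trace
  )
}

#' Poincare distance matrix of a model's latent embeddings
#'
#' Maps lorentz-head latents through the hyperboloid-to-ball
#' diffeomorphism and returns all pairwise Poincare distances — the input
#' expected by [poincareMapsReduce()].
#'
#' @param model a lorentz-head [DTIModel-class].
#' @param drugFeatures,targetFeatures feature matrices of the entities to
#'   embed (either may be `NULL`).
#' @return a list with the symmetric distance matrix `D` and the `kind`
#'   vector of its rows.
#' @export
latentPoincareDistances <- function(model, drugFeatures = NULL, targetFeatures = NULL) {
  stopifnot(is(model, "DTIModel"))
  if (model@head != "lorentz") stop("Poincare coordinates require the lorentz head")
  Ps <- list()
  kinds <- character()
  if (!is.null(drugFeatures)) {
    Ps$drug <- encodeEntities(model, drugFeatures, "drug", space = "poincare")
    kinds <- c(kinds, rep("drug", nrow(drugFeatures)))
  }
  if (!is.null(targetFeatures)) {
    Ps$target <- encodeEntities(model, targetFeatures, "target", space = "poincare")
    kinds <- c(kinds, rep("target", nrow(targetFeatures)))
  }
  if (length(Ps) == 0L) stop("no features supplied")
  P <- do.call(rbind, Ps)
  rownames(P) <- unlist(lapply(Ps, rownames), use.names = FALSE)
  list(D = poincareDistanceMatrix(P), kind = kinds)
}

#' Embed a hierarchy tree over an existing disk embedding
#'
#' Internal tree nodes are positioned bottom-up: each parent is the
#' Einstein midpoint (hyperbolic average) of its children's disk positions,
#' computed leaves-upward; an edge list connects every node to its parent.
#' For well-spread leaves the root lands near the disk center.
#'
#' @param disk a [DiskEmbedding-class] containing every leaf of `tree`.
#' @param tree a leveled [HierarchyTree-class]; leaves are the entities.
#' @return a [DiskEmbedding-class] with internal nodes appended (kind
#'   `"internal"`) and the tree `edges` filled in. Internal node ids are the
#'   `/`-joined label prefixes; the root is `"<root>"`.
#' @export
embedTree <- function(disk, tree) {
  stopifnot(is(disk, "DiskEmbedding"), is(tree, "HierarchyTree"))
  if (tree@kind == "graph") stop("tree embedding needs a leveled hierarchy")
  leaves <- tree@entities
  missing <- setdiff(leaves, rownames(disk@coords))
  if (length(missing)) {
    stop(sprintf("leaves missing from the disk embedding: %s", paste(missing, collapse = ", ")))
  }
  allInternal <- .collectInternal(disk, tree)
  coordsOut <- rbind(disk@coords, allInternal$coords)
  kindOut <- c(disk@kind, rep("internal", nrow(allInternal$coords)))
  new("DiskEmbedding",
    coords = coordsOut, kind = kindOut,
    edges = allInternal$edges, lossTrace = disk@lossTrace
  )
}

# bottom-up Einstein-midpoint positions for every internal prefix node
.collectInternal <- function(disk, tree) {
  depth <- tree@depth
  leaves <- tree@entities
  first <- t(vapply(tree@paths, function(p) p[1L, ], character(depth)))
  pos <- stats::setNames(
    lapply(leaves, function(e) disk@coords[e, ]), leaves
  )
  edges <- data.frame(parent = character(), child = character())
  # prefix of each leaf at each internal level
  prefixes <- lapply(seq_len(depth - 1L), function(l) {
    apply(first[, seq_len(l), drop = FALSE], 1L, paste, collapse = "/")
  })
  current <- leaves
  for (l in rev(seq_len(depth - 1L))) {
    parentOf <- if (identical(current, leaves)) {
      stats::setNames(prefixes[[l]], leaves)
    } else {
      stats::setNames(
        vapply(current, function(id) {
          parts <- strsplit(id, "/", fixed = TRUE)[[1L]]
          paste(parts[seq_len(l)], collapse = "/")
        }, character(1)), current
      )
    }
    for (pid in unique(parentOf)) {
      kids <- current[parentOf[current] == pid]
      pos[[pid]] <- einsteinMidpoint(do.call(rbind, pos[kids]))
      edges <- rbind(edges, data.frame(parent = pid, child = kids))
    }
    current <- unique(parentOf)
  }
  pos[["<root>"]] <- einsteinMidpoint(do.call(rbind, pos[current]))
  edges <- rbind(edges, data.frame(parent = "<root>", child = current))
  internal <- setdiff(names(pos), leaves)
  coords <- do.call(rbind, pos[internal])
  rownames(coords) <- internal
  list(coords = coords, edges = edges)
}

#' Translate a disk embedding so a chosen node sits at the origin
#'
#' Applies the distance-preserving Mobius translation to every point,
#' moving `focus` to the disk center — the "zoom-in" navigation operator:
#' translating an internal hierarchy node to the origin, where spatial
#' resolution is amplified, exposes the fine structure of its neighborhood.
#'
#' @param disk a [DiskEmbedding-class].
#' @param focus a node id present in the embedding.
#' @return a [DiskEmbedding-class] with translated coordinates.
#' @export
translateView <- function(disk, focus) {
  stopifnot(is(disk, "DiskEmbedding"))
  if (!focus %in% rownames(disk@coords)) stop(sprintf("unknown focus node '%s'", focus))
  Z <- mobiusTranslate(disk@coords, disk@coords[focus, ])
  # numerical guard: keep everything strictly inside the disk
  nz <- sqrt(rowSums(Z^2))
  over <- nz >= 1
  if (any(over)) Z[over, ] <- Z[over, , drop = FALSE] * (.DISK_MAX / nz[over])
  new("DiskEmbedding",
    coords = Z, kind = disk@kind,
    edges = disk@edges, lossTrace = disk@lossTrace
  )
}

#' Plot a disk embedding
#'
#' Draws the unit-circle boundary, the points colored by kind (or by a
#' supplied labeling), and any tree edges.
#'
#' @param disk a [DiskEmbedding-class].
#' @param color optional named vector of class labels used for coloring.
#' @param main plot title.
#' @export
plotDisk <- function(disk, color = NULL, main = "Poincaré disk") {
  Z <- disk@coords
  graphics::plot(NA,
    xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05), asp = 1,
    xlab = "", ylab = "", main = main, axes = FALSE
  )
  th <- seq(0, 2 * pi, length.out = 256L)
  graphics::lines(cos(th), sin(th), col = "grey60")
  if (nrow(disk@edges)) {
    for (r in seq_len(nrow(disk@edges))) {
      p <- Z[disk@edges$parent[r], ]
      c <- Z[disk@edges$child[r], ]
      graphics::segments(p[1L], p[2L], c[1L], c[2L], col = "grey80")
    }
  }
  lab <- if (is.null(color)) disk@kind else as.character(color[rownames(Z)])
  cols <- grDevices::rainbow(length(unique(lab)))[match(lab, unique(lab))]
  graphics::points(Z[, 1L], Z[, 2L], pch = 19, cex = 0.6, col = cols)
  invisible(disk)
}
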