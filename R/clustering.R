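#' Embed single-cell profiles in two dimensions by UMAP
#'
#' Projects the z-scored log-intensity matrix to 2-D. When phenotype labels
#' are supplied the supervised variant of the projection is used, pulling
#' cells of the same predefined phenotype together.
#'
#' @param table a log-state [SingleCellTable-class].
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @param phenotype_labels optional per-cell labels enabling the supervised
#'   projection.
#' @param seed RNG seed (single-threaded, reproducible).
#' @return list: \code{coords} (cells x 2 matrix), \code{params},
#'   \code{supervised}.
#' @export
embedCells <- function(table, n_neighbors = 15, min_dist = 0.1,
                       metric = "euclidean", phenotype_labels = NULL,
                       seed = 1L) {
  z <- zscoreMatrix(table)
  if (nrow(z) <= n_neighbors)
    stop("need more cells than n_neighbors (", n_neighbors, ")")
  set.seed(seed)
  y <- if (!is.null(phenotype_labels)) factor(phenotype_labels) else NULL
  coords <- uwot::umap(z, n_neighbors = n_neighbors, min_dist = min_dist,
                       metric = metric, y = y, n_threads = 1,
                       n_sgd_threads = 0, batch = FALSE)
  rownames(coords) <- rownames(z)
  list(coords = coords,
       params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                     metric = metric, seed = seed),
       supervised = !is.null(y))
}

#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Density-based clusters of arbitrary shape with an explicit noise label:
#' core distances at \code{min_samples} neighbors define the mutual
#' reachability distance, whose single-linkage hierarchy is condensed at
#' \code{min_cluster_size} and cut by excess-of-mass cluster selection.
#' Points falling out of every selected cluster are labeled \code{-1}
#' (noise). When the condensed tree has no true split (one dense blob), the
#' root is returned as a single cluster.
#'
#' @param X numeric matrix (points x features), e.g. an embedding.
#' @param min_cluster_size smallest cluster size; default
#'   \code{max(10, 1\% of points)}.
#' @param min_samples neighbor count for core distances (defaults to
#'   \code{min_cluster_size}).
#' @return list: \code{cluster} (integer per point, -1 = noise),
#'   \code{n_clusters}.
#' @export
hdbscan <- function(X, min_cluster_size = NULL, min_samples = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(min_cluster_size))
    min_cluster_size <- max(10L, ceiling(0.01 * n))
  if (is.null(min_samples)) min_samples <- min_cluster_size
  if (min_cluster_size > n)
    return(list(cluster = rep(-1L, n), n_clusters = 0L))
  d <- as.matrix(dist(X))
  k <- min(min_samples, n - 1L)
  core <- apply(d, 1, function(r) sort(r)[k + 1L]) # k-th neighbor (excl self)
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- hclust(stats::as.dist(mreach), method = "single")

  # --- condensed tree ------------------------------------------------
  # Walk the single-linkage dendrogram top-down. A condensed node is born
  # at lambda = 1/height of its parent split; children smaller than
  # min_cluster_size fall out as points at the split's lambda.
  merge <- hc$merge; height <- hc$height
  nm <- nrow(merge)
  members <- vector("list", nm)   # leaves under each internal node
  for (i in seq_len(nm)) {
    left <- if (merge[i, 1] < 0) -merge[i, 1] else NULL
    if (is.null(left)) left <- members[[merge[i, 1]]]
    right <- if (merge[i, 2] < 0) -merge[i, 2] else NULL
    if (is.null(right)) right <- members[[merge[i, 2]]]
    members[[i]] <- c(left, right)
  }
  sizeOf <- function(node) if (node < 0) 1L else length(members[[node]])
  pointsOf <- function(node) if (node < 0) -node else members[[node]]

  nodes <- list()  # condensed nodes: birth_lambda, stability, points info
  newNode <- function(birth) {
    nodes[[length(nodes) + 1L]] <<- list(birth = birth, stability = 0,
                                         children = integer(0),
                                         pts = integer(0), ptl = numeric(0))
    length(nodes)
  }
  addPoints <- function(id, pts, lambda) {
    nd <- nodes[[id]]
    nd$pts <- c(nd$pts, pts)
    nd$ptl <- c(nd$ptl, rep(lambda, length(pts)))
    nd$stability <- nd$stability + sum(rep(lambda, length(pts)) - nd$birth)
    nodes[[id]] <<- nd
  }
  # iterative descent: stack of (dendrogram node, condensed node id)
  root <- newNode(0)
  stack <- list(list(node = nm, cid = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cid <- fr$cid
    if (node < 0) { # singleton leaf: point leaves at infinite density
      addPoints(cid, -node, 1 / max(.Machine$double.eps, 0)) # not reached
      next
    }
    lambda <- 1 / max(height[node], .Machine$double.eps)
    kids <- merge[node, ]
    sz <- c(sizeOf(kids[1]), sizeOf(kids[2]))
    big <- sz >= min_cluster_size
    if (all(big)) { # true split: two new condensed clusters
      for (j in 1:2) {
        ch <- newNode(lambda)
        nodes[[cid]]$children <- c(nodes[[cid]]$children, ch)
        stack[[length(stack) + 1L]] <- list(node = kids[j], cid = ch)
      }
    } else if (any(big)) { # small side falls out; cluster continues
      small <- which(!big); large <- which(big)
      addPoints(cid, pointsOf(kids[small]), lambda)
      stack[[length(stack) + 1L]] <- list(node = kids[large], cid = cid)
    } else { # cluster dissolves entirely
      addPoints(cid, c(pointsOf(kids[1]), pointsOf(kids[2])), lambda)
    }
  }

  # --- excess-of-mass selection --------------------------------------
  selected <- logical(length(nodes))
  scoreOf <- numeric(length(nodes))
  ids <- seq_along(nodes)
  # process children before parents (children have larger ids by construction)
  for (id in rev(ids)) {
    nd <- nodes[[id]]
    if (!length(nd$children)) {
      scoreOf[id] <- nd$stability
      selected[id] <- TRUE
      next
    }
    childScore <- sum(scoreOf[nd$children])
    if (nd$stability > childScore && id != root) {
      scoreOf[id] <- nd$stability
      selected[id] <- TRUE
      # unselect all descendants
      desc <- nd$children
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(lapply(desc, function(i) nodes[[i]]$children))
      }
    } else {
      scoreOf[id] <- max(nd$stability, childScore)
    }
  }
  selected[root] <- FALSE
  if (!any(selected) && length(nodes) == 1L) {
    # no true split anywhere: the whole dataset is one dense cluster
    selected[root] <- TRUE
  }

  cluster <- rep(-1L, n)
  cl <- 0L
  collectPts <- function(id) {
    # points of a selected cluster = its own points + all descendants'
    out <- list(pts = nodes[[id]]$pts)
    for (ch in nodes[[id]]$children) {
      sub <- collectPts(ch)
      out$pts <- c(out$pts, sub$pts)
    }
    out
  }
  for (id in ids[selected]) {
    cl <- cl + 1L
    cluster[collectPts(id)$pts] <- cl
  }
  list(cluster = cluster, n_clusters = cl)
}

#' Cluster an embedding
#'
#' Runs [hdbscan()] on the 2-D embedding coordinates.
#'
#' @param embedding output of [embedCells()] (or any points x 2 matrix).
#' @param min_cluster_size see [hdbscan()].
#' @return list: \code{cluster} (integer vector, -1 = noise),
#'   \code{n_clusters}.
#' @export
clusterCells <- function(embedding, min_cluster_size = NULL) {
  coords <- if (is.list(embedding)) embedding$coords else embedding
  hdbscan(coords, min_cluster_size = min_cluster_size)
}

#' Per-cluster mean marker profiles
#'
#' Mean log intensity of each marker within each cluster (noise cells
#' excluded), z-scored per marker across clusters for relative comparison.
#'
#' @param table a log-state [SingleCellTable-class].
#' @param assignment output of [clusterCells()] (or an integer vector).
#' @return clusters x markers matrix (attribute \code{"raw_means"} holds the
#'   un-scaled cluster means).
#' @export
clusterProfiles <- function(table, assignment) {
  cl <- if (is.list(assignment)) assignment$cluster else assignment
  stopifnot(length(cl) == ncol(table))
  keep <- cl >= 0
  if (!any(keep)) stop("no clustered cells (all noise)")
  x <- t(intensityMatrix(table))[keep, , drop = FALSE]
  g <- cl[keep]
  means <- apply(x, 2, function(v) tapply(v, g, mean))
  means <- matrix(means, nrow = length(unique(g)),
                  dimnames = list(sort(unique(g)), markerNames(table)))
  z <- apply(means, 2, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  z <- matrix(z, nrow = nrow(means), dimnames = dimnames(means))
  attr(z, "raw_means") <- means
  z
}

#' Phenotype-by-cluster composition
#'
#' Cross-tabulates manual phenotype labels against unsupervised cluster ids;
#' row-normalized fractions show how each phenotype distributes over
#' clusters. Noise cells (cluster -1) are tabulated in their own column.
#'
#' @param assignment cluster ids (list or integer vector).
#' @param phenotypes per-cell phenotype labels, same length.
#' @return list: \code{counts}, \code{fractions} (row-normalized).
#' @export
composition <- function(assignment, phenotypes) {
  cl <- if (is.list(assignment)) assignment$cluster else assignment
  stopifnot(length(cl) == length(phenotypes))
  counts <- table(phenotype = phenotypes, cluster = cl)
  fractions <- counts / pmax(rowSums(counts), 1)
  list(counts = unclass(counts), fractions = unclass(fractions))
}
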