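#' HDBSCAN density clustering
#'
#' Hierarchical density-based clustering of points (typically a 2-D
#' embedding). The algorithm follows the standard formulation: per-point core
#' distances at `min_samples` neighbours, mutual-reachability distances, a
#' minimum spanning tree, a condensed cluster tree at `min_cluster_size`, and
#' excess-of-mass cluster selection. `cluster_selection_epsilon` merges
#' selected clusters born below the given distance threshold into their first
#' ancestor born at or above it, which suppresses over-splitting of dense
#' regions.
#'
#' Intended for the moderate sample counts of patient cohorts (distances are
#' computed densely, O(n^2) memory). Exact duplicate points merge at distance
#' zero; their density is treated as finite by capping the inverse distance,
#' and a dataset whose points are all coincident yields all-noise (no density
#' gradient to define a cluster).
#'
#' @param x numeric matrix, points in rows.
#' @param min_cluster_size smallest size a grouping must have to be a cluster
#'   (>= 2).
#' @param min_samples neighbourhood size for core-distance (density)
#'   estimation; defaults to `min_cluster_size`.
#' @param cluster_selection_epsilon distance threshold below which selected
#'   clusters are merged upward (0 disables).
#' @return integer vector of cluster labels, `1..k` with `0` for noise.
#'   Labels are numbered by first member occurrence.
#' @export
hdbscan_cluster <- function(x, min_cluster_size = 5L,
                            min_samples = min_cluster_size,
                            cluster_selection_epsilon = 0) {
  x <- as.matrix(x)
  n <- nrow(x)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  min_samples <- max(1L, as.integer(min_samples))
  if (n < 2L) return(rep(0L, n))
  D <- as.matrix(stats::dist(x))

  k <- min(min_samples, n - 1L)
  core <- vapply(seq_len(n), function(i) sort(D[i, -i], partial = k)[k], 0)
  cm <- pmax(matrix(core, n, n), matrix(core, n, n, byrow = TRUE))
  MR <- pmax(D, cm)

  # Prim's MST on the mutual-reachability graph
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  best <- MR[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)  # from, to, weight
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[e, ] <- c(best_from[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & MR[j, ] < best
    best[upd] <- MR[j, upd]; best_from[upd] <- j
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage dendrogram over the MST (union-find)
  parent <- seq_len(2L * n - 1L)       # union-find forest
  node_of <- seq_len(n)                # current dendro node of each root
  child <- matrix(0L, n - 1L, 2L)      # children of internal node n+m
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (m in seq_len(n - 1L)) {
    a <- find(edges[m, 1]); b <- find(edges[m, 2])
    new <- n + m
    child[m, ] <- c(node_of[a], node_of[b])
    height[m] <- edges[m, 3]
    size[new] <- size[node_of[a]] + size[node_of[b]]
    parent[a] <- new; parent[b] <- new; parent[new] <- new
    node_of[new] <- new
  }
  root <- 2L * n - 1L
  lam_of <- function(h) if (h <= 0) 1e9 else min(1 / h, 1e9)

  # condensed tree
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_death <- numeric(0)
  cl_children <- list(); cl_points <- list(); cl_plam <- list()
  new_cluster <- function(par, birth) {
    cid <- length(cl_parent) + 1L
    cl_parent[cid] <<- par; cl_birth[cid] <<- birth; cl_death[cid] <<- NA_real_
    cl_children[[cid]] <<- integer(0)
    cl_points[[cid]] <<- integer(0); cl_plam[[cid]] <<- numeric(0)
    if (par > 0L) cl_children[[par]] <<- c(cl_children[[par]], cid)
    cid
  }
  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v) else stack <- c(stack, child[v - n, ])
    }
    out
  }
  attach_points <- function(cid, pts, lam) {
    cl_points[[cid]] <<- c(cl_points[[cid]], pts)
    cl_plam[[cid]] <<- c(cl_plam[[cid]], rep(lam, length(pts)))
  }
  root_cid <- new_cluster(0L, 0)
  stack <- list(c(root, root_cid))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr[1]; cid <- fr[2]
    repeat {
      m <- node - n
      lam <- lam_of(height[m])
      ch <- child[m, ]
      sz <- size[ch]
      big <- sz >= min_cluster_size
      if (all(big)) {
        cl_death[cid] <- lam
        for (c2 in ch) stack[[length(stack) + 1L]] <- c(c2, new_cluster(cid, lam))
        break
      }
      for (c2 in ch[!big]) attach_points(cid, leaves_under(c2), lam)
      if (!any(big)) { cl_death[cid] <- lam; break }
      node <- ch[big][1]
    }
  }
  ncl <- length(cl_parent)
  if (ncl == 1L) return(rep(0L, n))

  # stability: points that fall out contribute (lambda_fall - lambda_birth);
  # points passing into child clusters leave at the parent's death lambda
  stability <- vapply(seq_len(ncl), function(cid)
    sum(cl_plam[[cid]] - cl_birth[cid]), 0)
  n_desc_points <- vapply(seq_len(ncl), function(cid)
    length(unlist(cl_points[subtree_ids(cl_children, cid)])), 0L)
  for (cid in seq_len(ncl)) {
    kids <- cl_children[[cid]]
    if (length(kids))
      stability[cid] <- stability[cid] +
        sum(n_desc_points[kids]) * (cl_death[cid] - cl_birth[cid])
  }
  selected <- rep(FALSE, ncl); score <- numeric(ncl)
  for (cid in rev(seq_len(ncl))) {   # children have larger ids than parents
    kids <- cl_children[[cid]]
    if (!length(kids)) { selected[cid] <- TRUE; score[cid] <- stability[cid]; next }
    child_sum <- sum(score[kids])
    if (cid != root_cid && stability[cid] >= child_sum) {
      selected[cid] <- TRUE; score[cid] <- stability[cid]
      for (d in setdiff(subtree_ids(cl_children, cid), cid)) selected[d] <- FALSE
    } else score[cid] <- child_sum
  }

  if (cluster_selection_epsilon > 0) {
    chosen <- which(selected)
    for (cid in chosen) {
      cur <- cid
      while (cl_parent[cur] > 0L && cl_parent[cur] != root_cid &&
             1 / cl_birth[cur] < cluster_selection_epsilon)
        cur <- cl_parent[cur]
      if (cur != cid) { selected[cid] <- FALSE; selected[cur] <- TRUE }
    }
    # drop selections nested inside another selected cluster
    for (cid in which(selected)) {
      anc <- cl_parent[cid]
      while (anc > 0L) {
        if (selected[anc]) { selected[cid] <- FALSE; break }
        anc <- cl_parent[anc]
      }
    }
  }

  labels <- rep(0L, n)
  sel <- which(selected)
  for (i in seq_along(sel)) {
    pts <- unlist(cl_points[subtree_ids(cl_children, sel[i])])
    labels[pts] <- i
  }
  # renumber by first member occurrence for determinism
  seen <- unique(labels[labels > 0L])
  labels[labels > 0L] <- match(labels[labels > 0L], seen)
  labels
}

# ids of a condensed subtree rooted at cid (including cid)
subtree_ids <- function(children, cid) {
  out <- integer(0); stack <- cid
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    if (length(children[[v]])) stack <- c(stack, children[[v]])
  }
  out
}
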