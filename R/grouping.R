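# --- per-frame clustering primitives -------------------------------------

# classic DBSCAN on a tiny point set; returns integer labels (0 = outlier)
.dbscan_frame <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbr, length, 0L) >= min_pts          # self counts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (v in nbr[[q]]) {
        if (labels[v] == 0L) {
          labels[v] <- cl
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
  }
  labels
}

# simplified hierarchical density clustering: single linkage on mutual
# reachability distances (core distance = distance to the (min_pts-1)-th
# nearest other point), dendrogram cut at eps, clusters below min_pts
# dissolved to outliers. Membership confidence = (smallest core distance in
# the cluster) / (member's core distance), capped at 1 — a surrogate for
# "how distant the member is compared with the density of the cluster".
.hclust_density_frame <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  corek <- vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i])
    if (length(d) < min_pts - 1) Inf else d[min_pts - 1]
  }, 0)
  MR <- pmax(D, outer(corek, rep(1, n)), outer(rep(1, n), corek))
  diag(MR) <- 0
  if (n < 2) return(list(labels = integer(n), confidence = rep(NA_real_, n)))
  hc <- stats::hclust(stats::as.dist(MR), method = "single")
  labels <- stats::cutree(hc, h = eps)
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < min_pts])] <- 0L
  labels <- match(labels, sort(unique(labels[labels > 0L])), nomatch = 0L)
  conf <- rep(NA_real_, n)
  for (cl in setdiff(unique(labels), 0L)) {
    idx <- which(labels == cl)
    cmin <- min(corek[idx])
    conf[idx] <- if (cmin == 0) 1 else pmin(1, cmin / corek[idx])
    conf[idx][corek[idx] == 0] <- 1
  }
  list(labels = as.integer(labels), confidence = conf)
}

#' Density-based clustering of member positions over a movement period
#'
#' Per-frame clustering with either plain DBSCAN or a hierarchical
#' density-based method (single linkage on mutual-reachability distances;
#' provides a per-member membership confidence). Members above the distance
#' threshold from every cluster are outliers (label 0).
#'
#' @param period a `movement_period`.
#' @param method `"dbscan"` or `"hdbscan"`.
#' @param min_cluster_size minimum members forming a cluster (>= 2).
#' @param distance_threshold meters (> 0).
#' @return a `cluster_frames`: list with `t`, integer `labels`
#'   `[time, member]` (0 = outlier), `confidence` matrix (hierarchical
#'   method only, else `NULL`), `method`, `params`, `dt`.
#' @export
cluster_frames <- function(period, method = c("dbscan", "hdbscan"),
                           min_cluster_size = 2, distance_threshold = 5) {
  method <- match.arg(method)
  stopifnot(min_cluster_size >= 2, distance_threshold > 0)
  traj <- period$traj
  nT <- length(traj$t); m <- length(traj$member_ids)
  if (m < min_cluster_size)
    warning("fewer members than min_cluster_size: everyone is an outlier")
  labels <- matrix(0L, nT, m, dimnames = list(NULL, traj$member_ids))
  confidence <- if (method == "hdbscan")
    matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids)) else NULL
  for (ti in seq_len(nT)) {
    pts <- traj$pos[ti, , , drop = TRUE]
    if (m < min_cluster_size) next
    if (method == "dbscan") {
      labels[ti, ] <- .dbscan_frame(pts, distance_threshold, min_cluster_size)
    } else {
      r <- .hclust_density_frame(pts, distance_threshold, min_cluster_size)
      labels[ti, ] <- r$labels
      confidence[ti, ] <- r$confidence
    }
  }
  structure(list(t = traj$t, labels = labels, confidence = confidence,
                 method = method,
                 params = c(min_cluster_size = min_cluster_size,
                            distance_threshold = distance_threshold),
                 dt = traj$dt),
            class = "cluster_frames")
}

#' Outlier time and distinct outlier count
#'
#' @param frames a `cluster_frames`.
#' @return list with `outlier_time` (seconds per member), `n_outliers`
#'   (distinct members ever labeled outlier).
#' @export
outlier_metrics <- function(frames) {
  stopifnot(nrow(frames$labels) >= 1)
  ot <- colSums(frames$labels == 0L) * frames$dt
  list(outlier_time = ot, n_outliers = sum(ot > 0))
}

# adjusted Rand index of two integer labelings; identical partitions
# (including the trivial ones) score 1
.adjusted_rand <- function(a, b) {
  if (all(tapply(seq_along(a), a, function(i) length(unique(b[i]))) == 1) &&
      all(tapply(seq_along(b), b, function(i) length(unique(a[i]))) == 1))
    return(1)
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_idx <- si * sj / choose(n, 2)
  max_idx <- (si + sj) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}

#' Cluster-membership consistency over a movement period
#'
#' Mean adjusted partition agreement (adjusted Rand index) between
#' consecutive frames, with outliers treated as singleton clusters;
#' 1 means the partition never changes.
#'
#' @param frames a `cluster_frames`.
#' @return a number in `[-1, 1]`, typically `[0, 1]`.
#' @export
cluster_consistency <- function(frames) {
  L <- frames$labels
  nT <- nrow(L)
  stopifnot(nT >= 2)
  singletonize <- function(v) {
    out <- as.integer(v)
    k <- max(out, 0L)
    idx <- which(out == 0L)
    out[idx] <- k + seq_along(idx)
    out
  }
  ari <- vapply(seq_len(nT - 1), function(ti)
    .adjusted_rand(singletonize(L[ti, ]), singletonize(L[ti + 1, ])), 0)
  mean(ari)
}

#' Nearest-neighbor distances in raw and PACS coordinates
#'
#' Per frame, each member's minimum Euclidean distance to any other member
#' (raw planar coordinates) and the per-axis minima of |dx| and |dy| in
#' PACS coordinates.
#'
#' @param period a `movement_period` with >= 2 members.
#' @param pacs optional `pacs_frames` for the per-axis variants.
#' @return list with matrices `nn_dist`, `nn_dx`, `nn_dy` `[time, member]`
#'   and a `features` vector (means and entropies).
#' @export
nearest_neighbor_features <- function(period, pacs = NULL) {
  traj <- period$traj
  m <- length(traj$member_ids)
  stopifnot(m >= 2)
  nT <- length(traj$t)
  nn_dist <- matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids))
  for (ti in seq_len(nT)) {
    D <- as.matrix(dist(traj$pos[ti, , ]))
    diag(D) <- Inf
    nn_dist[ti, ] <- apply(D, 1, min)
  }
  nn_dx <- nn_dy <- NULL
  if (!is.null(pacs)) {
    axis_nn <- function(M) {
      out <- matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids))
      for (ti in seq_len(nT)) {
        D <- abs(outer(M[ti, ], M[ti, ], "-"))
        diag(D) <- Inf
        out[ti, ] <- apply(D, 1, min)
      }
      out
    }
    nn_dx <- axis_nn(pacs$x)
    nn_dy <- axis_nn(pacs$y)
  }
  feats <- c(nn.dist.mean = mean(nn_dist),
             nn.dist.entropy = mean(apply(nn_dist, 2, series_entropy)))
  if (!is.null(nn_dx)) {
    feats <- c(feats,
               nn.dx.mean = mean(nn_dx, na.rm = TRUE),
               nn.dy.mean = mean(nn_dy, na.rm = TRUE),
               nn.dx.entropy = mean(apply(nn_dx, 2, series_entropy)),
               nn.dy.entropy = mean(apply(nn_dy, 2, series_entropy)))
  }
  list(nn_dist = nn_dist, nn_dx = nn_dx, nn_dy = nn_dy, features = feats)
}
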