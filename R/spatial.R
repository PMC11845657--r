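#' Stretch index: mean member distance to the centroid
#'
#' @param period a `movement_period` with at least 2 members.
#' @return list with `t`, `si` (time series), `mean`, and `entropy`
#'   (Shannon entropy of the series histogram via [series_entropy()]).
#' @export
stretch_index <- function(period) {
  traj <- period$traj
  stopifnot(length(traj$member_ids) >= 2)
  ctr <- .centroid(traj)
  d <- sqrt((traj$pos[, , 1] - ctr[, 1])^2 + (traj$pos[, , 2] - ctr[, 2])^2)
  si <- rowMeans(d)
  list(t = traj$t, si = si, mean = mean(si), entropy = series_entropy(si))
}

# signed shoelace area of polygon given as [k, 2] matrix (vertices in order)
.poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# clip convex polygon by half-plane a*x + b*y <= c (Sutherland-Hodgman)
.clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(poly)
  val <- a * poly[, 1] + b * poly[, 2] - cc
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 1e-12) out <- rbind(out, poly[i, ])
    if ((vi < -1e-12 && vj > 1e-12) || (vi > 1e-12 && vj < -1e-12)) {
      tt <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + tt * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Convex hull and hull-clipped Voronoi areas for one frame
#'
#' Voronoi cells of the member points clipped to their convex hull, so each
#' member gets the part of the group's covered area they dominate; the cell
#' areas partition the hull exactly. Degenerate frames (fewer than 3
#' distinct non-collinear members) get zero hull area and `NA` cells.
#'
#' @param pts matrix `[member, 2]` of planar positions.
#' @return list `hull_area`, `voronoi_area` (vector per member).
#' @export
hull_and_voronoi <- function(pts) {
  pts <- as.matrix(pts)
  m <- nrow(pts)
  hull_idx <- grDevices::chull(pts)
  hull <- pts[hull_idx, , drop = FALSE]
  area <- .poly_area(hull)
  if (area < 1e-12)
    return(list(hull_area = 0, voronoi_area = rep(NA_real_, m)))
  va <- numeric(m)
  for (i in seq_len(m)) {
    cell <- hull
    for (j in seq_len(m)) {
      if (i == j) next
      nrm <- pts[j, ] - pts[i, ]
      if (sum(nrm^2) < 1e-18) next           # coincident members share a cell
      mid <- (pts[i, ] + pts[j, ]) / 2
      cell <- .clip_halfplane(cell, nrm[1], nrm[2], sum(nrm * mid))
      if (nrow(cell) < 3) break
    }
    va[i] <- .poly_area(cell)
  }
  list(hull_area = area, voronoi_area = va)
}

#' Hull and Voronoi summaries over a movement period
#'
#' @param period a `movement_period`.
#' @return list with `t`, `hull_area` series, `voronoi` matrix
#'   `[time, member]`, and `features` (hull max/min/mean/var/entropy,
#'   Voronoi mean and mean per-member coefficient of variation over time).
#' @export
hull_voronoi_features <- function(period) {
  traj <- period$traj
  nT <- length(traj$t); m <- length(traj$member_ids)
  ha <- numeric(nT)
  va <- matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids))
  for (ti in seq_len(nT)) {
    hv <- hull_and_voronoi(traj$pos[ti, , ])
    ha[ti] <- hv$hull_area
    va[ti, ] <- hv$voronoi_area
  }
  cv <- apply(va, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  })
  feats <- c(spat.hull.max = max(ha), spat.hull.min = min(ha),
             spat.hull.mean = mean(ha), spat.hull.var = .pop_var(ha),
             spat.hull.entropy = series_entropy(ha),
             spat.voronoi.mean = mean(va, na.rm = TRUE),
             spat.voronoi.cv = mean(cv, na.rm = TRUE))
  list(t = traj$t, hull_area = ha, voronoi = va, features = feats)
}

#' Length/width ratio of the group in PACS coordinates
#'
#' Length is the PACS-y range, width the PACS-x range; frames with zero
#' width are masked (`NA`).
#'
#' @param pacs a `pacs_frames` object.
#' @return list with `t`, `ratio` series, `mean`, `entropy`.
#' @export
length_width_ratio <- function(pacs) {
  len <- apply(pacs$y, 1, function(v)
    if (all(is.na(v))) NA_real_ else diff(range(v, na.rm = TRUE)))
  wid <- apply(pacs$x, 1, function(v)
    if (all(is.na(v))) NA_real_ else diff(range(v, na.rm = TRUE)))
  ratio <- ifelse(!is.na(wid) & wid > 1e-12, len / wid, NA_real_)
  list(t = pacs$t, ratio = ratio, mean = mean(ratio, na.rm = TRUE),
       entropy = series_entropy(ratio[!is.na(ratio)]))
}

#' Spatial Exploration Index per member
#'
#' Mean distance of each member from their own average PACS location.
#'
#' @param pacs a `pacs_frames` object with at least 2 frames.
#' @return named numeric vector, one SEI (meters) per member.
#' @export
spatial_exploration_index <- function(pacs) {
  stopifnot(length(pacs$t) >= 2)
  vapply(seq_along(pacs$member_ids), function(k) {
    x <- pacs$x[, k]; y <- pacs$y[, k]
    ok <- !is.na(x) & !is.na(y)
    mean(sqrt((x[ok] - mean(x[ok]))^2 + (y[ok] - mean(y[ok]))^2))
  }, 0) |> stats::setNames(pacs$member_ids)
}

# exact 1-D Wasserstein-1 distance between two empirical distributions
.wasserstein1 <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  x <- sort(unique(c(a, b)))
  if (length(x) < 2) return(0)
  Fa <- stats::ecdf(a)(x); Fb <- stats::ecdf(b)(x)
  n <- length(x)
  sum(abs(Fa[-n] - Fb[-n]) * diff(x))
}

#' Cross-period consistency of member PACS distributions
#'
#' For every pair of movement periods and each PACS axis: the variance-ratio
#' F statistic (larger over smaller, orientation-free) and the 1-D
#' Wasserstein distance between the member's coordinate distributions,
#' averaged over period pairs.
#'
#' @param pacs_list list of `pacs_frames`, one per movement period (>= 2).
#' @return data.frame with one row per member: `f_x`, `f_y`, `w_x`, `w_y`.
#' @export
distribution_consistency <- function(pacs_list) {
  if (length(pacs_list) < 2) {
    message("distribution consistency requires >= 2 movement periods; absent")
    return(NULL)
  }
  ids <- pacs_list[[1]]$member_ids
  pairs <- utils::combn(length(pacs_list), 2)
  res <- lapply(seq_along(ids), function(k) {
    acc <- matrix(0, ncol(pairs), 4)
    for (pi in seq_len(ncol(pairs))) {
      A <- pacs_list[[pairs[1, pi]]]; B <- pacs_list[[pairs[2, pi]]]
      fr <- function(a, b) {
        va <- .pop_var(a); vb <- .pop_var(b)
        if (is.na(va) || is.na(vb) || min(va, vb) < 1e-15) return(NA_real_)
        max(va, vb) / min(va, vb)
      }
      acc[pi, ] <- c(fr(A$x[, k], B$x[, k]), fr(A$y[, k], B$y[, k]),
                     .wasserstein1(A$x[, k], B$x[, k]),
                     .wasserstein1(A$y[, k], B$y[, k]))
    }
    colMeans(acc, na.rm = TRUE)
  })
  res <- do.call(rbind, res)
  data.frame(member_id = ids, f_x = res[, 1], f_y = res[, 2],
             w_x = res[, 3], w_y = res[, 4])
}
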