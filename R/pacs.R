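#' Fit the smoothed group path for one movement period
#'
#' The group's path is the smoothing-spline fit (easting and northing
#' against time) to the centroid positions, densely pre-sampled so that the
#' cumulative arc-length table is accurate and nearest-point queries can be
#' answered by segment projection. A pre-determined route (e.g. a road or a
#' racing line) can be supplied instead of the centroid path as a matrix of
#' waypoints; it is parameterized by cumulative chord length.
#'
#' @param period a `movement_period` with at least 4 timepoints (ignored if
#'   `route` is given except for error checking).
#' @param smoothing spline penalty as in [smooth_track()] (`NULL` = GCV).
#' @param route optional matrix `[k, 2]` of waypoints overriding the
#'   centroid path.
#' @param spacing dense pre-sampling spacing along the curve, meters
#'   (default 0.1).
#' @return a `path_spline`: list with `xy` (dense vertices), `s` (cumulative
#'   arc length), `tangent` (unit tangents per vertex), `total_length`.
#' @export
fit_centroid_path <- function(period, smoothing = NULL, route = NULL,
                              spacing = 0.1) {
  if (is.null(route)) {
    stopifnot(inherits(period, "movement_period"))
    tt <- period$traj$t
    if (length(tt) < 4) stop("period has fewer than 4 timepoints")
    ctr <- .centroid(period$traj)
    if (max(dist(ctr)) < 1e-9)
      stop("degenerate path: all centroid positions coincide")
    if (is.null(smoothing) || smoothing > 0) {
      fe <- .fit_ss(tt, ctr[, 1], smoothing)
      fn <- .fit_ss(tt, ctr[, 2], smoothing)
      chord <- sum(sqrt(rowSums(diff(ctr)^2)))
      ndense <- max(ceiling(chord / spacing) + 1, 4 * length(tt))
      ud <- seq(min(tt), max(tt), length.out = ndense)
      xy <- cbind(stats::predict(fe, ud)$y, stats::predict(fn, ud)$y)
    } else {
      fe <- stats::splinefun(tt, ctr[, 1], method = "natural")
      fn <- stats::splinefun(tt, ctr[, 2], method = "natural")
      chord <- sum(sqrt(rowSums(diff(ctr)^2)))
      ndense <- max(ceiling(chord / spacing) + 1, 4 * length(tt))
      ud <- seq(min(tt), max(tt), length.out = ndense)
      xy <- cbind(fe(ud), fn(ud))
    }
  } else {
    route <- as.matrix(route)
    stopifnot(ncol(route) == 2, nrow(route) >= 2)
    u <- c(0, cumsum(sqrt(rowSums(diff(route)^2))))
    if (max(u) < 1e-9) stop("degenerate route: waypoints coincide")
    keep <- !duplicated(u)
    u <- u[keep]; route <- route[keep, , drop = FALSE]
    ndense <- max(ceiling(max(u) / spacing) + 1, 4 * nrow(route))
    ud <- seq(0, max(u), length.out = ndense)
    if (nrow(route) >= 4) {
      fx <- stats::splinefun(u, route[, 1], method = "natural")
      fy <- stats::splinefun(u, route[, 2], method = "natural")
      xy <- cbind(fx(ud), fy(ud))
    } else {
      xy <- cbind(stats::approx(u, route[, 1], ud)$y,
                  stats::approx(u, route[, 2], ud)$y)
    }
  }
  # drop consecutive duplicate vertices (stationary stretches)
  seglen <- sqrt(rowSums(diff(xy)^2))
  keep <- c(TRUE, seglen > 1e-12)
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 2) stop("degenerate path after de-duplication")
  seglen <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seglen))
  segdir <- diff(xy) / seglen
  tangent <- rbind(segdir[1, , drop = FALSE],
                   (segdir[-nrow(segdir), , drop = FALSE] +
                      segdir[-1, , drop = FALSE]) / 2,
                   segdir[nrow(segdir), , drop = FALSE])
  tangent <- tangent / sqrt(rowSums(tangent^2))
  structure(list(xy = xy, s = s, tangent = tangent,
                 total_length = s[length(s)], spacing = spacing),
            class = "path_spline")
}

#' @export
print.path_spline <- function(x, ...) {
  cat(sprintf("<path_spline> length %.2f m, %d dense vertices\n",
              x$total_length, nrow(x$xy)))
  invisible(x)
}

# foot point of one point on the dense polyline, restricted to vertex index
# range [lo, hi]; returns list(s, dist, sign_x, idx)
.foot_point <- function(path, p, lo = 1L, hi = nrow(path$xy), s_prev = NA) {
  xy <- path$xy
  lo <- max(1L, lo); hi <- min(nrow(xy), hi)
  i0 <- lo:(max(lo, hi - 1L))                       # segment start indices
  ax <- xy[i0, 1]; ay <- xy[i0, 2]
  bx <- xy[i0 + 1L, 1]; by <- xy[i0 + 1L, 2]
  vx <- bx - ax; vy <- by - ay
  L2 <- vx * vx + vy * vy
  tt <- pmin(1, pmax(0, ((p[1] - ax) * vx + (p[2] - ay) * vy) / L2))
  fx <- ax + tt * vx; fy <- ay + tt * vy
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  dmin <- min(d2)
  cand <- which(d2 <= dmin + 1e-12)
  if (length(cand) > 1 && !is.na(s_prev)) {
    scand <- path$s[i0[cand]] + tt[cand] * sqrt(L2[cand])
    cand <- cand[which.min(abs(scand - s_prev))]
  } else cand <- cand[1]
  k <- i0[cand]
  sfoot <- path$s[k] + tt[cand] * sqrt(L2[cand])
  tanv <- c(vx[cand], vy[cand]) / sqrt(L2[cand])
  offx <- p[1] - fx[cand]; offy <- p[2] - fy[cand]
  cross <- tanv[1] * offy - tanv[2] * offx       # >0: point left of travel
  list(s = sfoot, dist = sqrt(d2[cand]), sign = if (cross > 0) -1 else 1,
       idx = k)
}

#' Transform a movement period into the Path-Adapted Coordinate System
#'
#' For every member and timepoint, finds the globally nearest point on the
#' group path (the foot point), with ties on self-approaching paths broken
#' by temporal continuity (the foot point whose arc length is closest to
#' the member's previous one). PACS-x is the lateral distance to the path,
#' negative when the member is to the left of the travel direction; PACS-y
#' is the signed arc length from the centroid's foot point to the member's
#' foot point, positive ahead of the centroid.
#'
#' @param period a `movement_period`.
#' @param path a `path_spline` from [fit_centroid_path()].
#' @param max_offset members farther than this from the path are flagged
#'   (not dropped); meters, default 500.
#' @param search_window local nearest-point search half-width around the
#'   previous foot point, meters (default 50 plus the frame-to-frame
#'   displacement bound).
#' @return a `pacs_frames` object: list with `t`, matrices `x`, `y`
#'   `[time, member]`, `s_centroid`, logical `flagged` matrix, `member_ids`.
#' @export
pacs_transform <- function(period, path = NULL, max_offset = 500,
                           search_window = 50) {
  stopifnot(inherits(period, "movement_period"))
  if (is.null(path)) path <- fit_centroid_path(period)
  traj <- period$traj
  nT <- length(traj$t); m <- length(traj$member_ids)
  win_idx <- ceiling(search_window / mean(diff(path$s))) + 2L
  x <- y <- matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids))
  flagged <- matrix(FALSE, nT, m)
  s_ctr <- numeric(nT)
  ctr <- .centroid(traj)
  prev_idx_c <- NA_integer_; prev_s_c <- NA_real_
  prev_idx <- rep(NA_integer_, m); prev_s <- rep(NA_real_, m)
  for (ti in seq_len(nT)) {
    fp <- if (is.na(prev_idx_c)) .foot_point(path, ctr[ti, ]) else
      .foot_point(path, ctr[ti, ], prev_idx_c - win_idx,
                  prev_idx_c + win_idx, prev_s_c)
    s_ctr[ti] <- fp$s; prev_idx_c <- fp$idx; prev_s_c <- fp$s
    for (k in seq_len(m)) {
      p <- traj$pos[ti, k, ]
      fpk <- if (is.na(prev_idx[k])) .foot_point(path, p, s_prev = NA) else
        .foot_point(path, p, prev_idx[k] - win_idx, prev_idx[k] + win_idx,
                    prev_s[k])
      x[ti, k] <- fpk$sign * fpk$dist
      y[ti, k] <- fpk$s - s_ctr[ti]
      flagged[ti, k] <- fpk$dist > max_offset
      prev_idx[k] <- fpk$idx; prev_s[k] <- fpk$s
    }
  }
  structure(list(t = traj$t, x = x, y = y, s_centroid = s_ctr,
                 flagged = flagged, member_ids = traj$member_ids,
                 dt = traj$dt),
            class = "pacs_frames")
}

#' @export
print.pacs_frames <- function(x, ...) {
  cat(sprintf("<pacs_frames> %d members x %d timepoints (%d flagged)\n",
              length(x$member_ids), length(x$t), sum(x$flagged)))
  invisible(x)
}

#' Centroid-heading baseline transform
#'
#' Expresses each member's position in the frame centered on the centroid
#' and rotated by the centroid's *instantaneous* heading — the conventional
#' transform that PACS improves upon. Frames where the centroid is (nearly)
#' stationary have no defined heading and are masked (`NA`). Kept as the
#' baseline for artifact comparisons: a member trailing the group at a turn
#' sweeps sideways in this frame while staying put in PACS.
#'
#' @param period a `movement_period`.
#' @param min_speed centroid speed below which the heading is undefined,
#'   m/s (default 0.3).
#' @return a `pacs_frames`-shaped object (x lateral, +right; y along
#'   heading, +ahead) with stationary frames `NA`.
#' @export
centroid_heading_transform <- function(period, min_speed = 0.3) {
  traj <- period$traj
  ctr <- .centroid(traj)
  v <- .central_diff(ctr, traj$dt)
  spd <- sqrt(rowSums(v^2))
  ok <- spd >= min_speed
  h <- v / spd
  nT <- length(traj$t); m <- length(traj$member_ids)
  x <- y <- matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids))
  for (k in seq_len(m)) {
    dx <- traj$pos[, k, 1] - ctr[, 1]
    dy <- traj$pos[, k, 2] - ctr[, 2]
    # right vector = heading rotated -90deg = (hy, -hx)
    x[, k] <- ifelse(ok, dx * h[, 2] - dy * h[, 1], NA_real_)
    y[, k] <- ifelse(ok, dx * h[, 1] + dy * h[, 2], NA_real_)
  }
  structure(list(t = traj$t, x = x, y = y, s_centroid = rep(NA_real_, nT),
                 flagged = matrix(FALSE, nT, m), member_ids = traj$member_ids,
                 dt = traj$dt),
            class = "pacs_frames")
}

# central differences along rows of an [n, 2] matrix; one-sided at ends
.central_diff <- function(xy, dt) {
  n <- nrow(xy)
  if (n < 2) return(matrix(NA_real_, n, ncol(xy)))
  d <- rbind(xy[2, ] - xy[1, ],
             (xy[3:n, , drop = FALSE] - xy[1:(n - 2), , drop = FALSE]) / 2,
             xy[n, ] - xy[n - 1, ])
  if (n == 2) d <- rbind(xy[2, ] - xy[1, ], xy[2, ] - xy[1, ])
  d / dt
}
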