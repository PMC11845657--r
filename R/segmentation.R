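#' Detect rest periods for one member
#'
#' A member is resting while their positions stay within a disc of the given
#' area (100 m2 corresponds to a diameter of about 11.28 m) for at least
#' `min_duration_s`. Matches the stop-detection semantics of diameter-based
#' detectors: a timepoint is part of a rest if it lies in any time window of
#' length `>= min_duration_s` whose points have maximum pairwise distance no
#' larger than the disc diameter; maximal runs of such timepoints form the
#' reported intervals. The implied speed rationale: staying inside 11.28 m
#' for 120 s means an average speed below about 0.833 m/s — the bound that
#' separates a very slow stroll from marching.
#'
#' @param t regular time grid (seconds).
#' @param pos matrix `[time, 2]` of planar positions for one member.
#' @param area_m2 disc area, square meters (default 100).
#' @param min_duration_s minimum rest duration, seconds (default 120).
#' @return `data.frame(start, end)`; zero rows if the member never rests.
#' @export
detect_individual_rests <- function(t, pos, area_m2 = 100,
                                    min_duration_s = 120) {
  stopifnot(nrow(pos) == length(t))
  n <- length(t)
  if (n < 2) return(data.frame(start = numeric(0), end = numeric(0)))
  diam <- 2 * sqrt(area_m2 / pi)
  covered <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    # window [i, j] always satisfies the diameter bound; try to extend
    repeat {
      if (j >= n) break
      cand <- pos[j + 1L, ]
      dx <- pos[i:j, 1] - cand[1]
      dy <- pos[i:j, 2] - cand[2]
      if (max(dx * dx + dy * dy) <= diam^2) j <- j + 1L else break
    }
    if (t[j] - t[i] >= min_duration_s) covered[i:j] <- TRUE
  }
  .runs_to_intervals(covered, t)
}

.runs_to_intervals <- function(flag, t) {
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = t[starts[keep]], end = t[ends[keep]])
}

#' Merge individual rests into group rest periods
#'
#' A group rest requires a time interval during which *every* member is
#' inside one of their individual rests (a nonempty common core). For each
#' maximal common core, the group interval spans from the earliest start to
#' the latest end of the member intervals involved: the first individual
#' arriving at the break area opens the break and the last one leaving
#' closes it. Overlapping group envelopes are merged.
#'
#' @param individual_rests named list (one entry per member) of
#'   `data.frame(start, end)` as returned by [detect_individual_rests()].
#' @return `data.frame(start, end)` of group-scope rests, sorted,
#'   non-overlapping.
#' @export
merge_group_rests <- function(individual_rests) {
  m <- length(individual_rests)
  stopifnot(m >= 1)
  if (any(vapply(individual_rests, nrow, 0L) == 0))
    return(data.frame(start = numeric(0), end = numeric(0)))
  bounds <- sort(unique(unlist(lapply(individual_rests, function(d)
    c(d$start, d$end)))))
  if (length(bounds) < 2)
    return(data.frame(start = numeric(0), end = numeric(0)))
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  all_cov <- vapply(mids, function(tm)
    all(vapply(individual_rests, function(d)
      any(d$start <= tm & d$end >= tm), TRUE)), TRUE)
  if (!any(all_cov)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(all_cov)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  cores <- data.frame(start = bounds[starts_i[r$values]],
                      end = bounds[ends_i[r$values] + 1L])
  env <- lapply(seq_len(nrow(cores)), function(k) {
    cs <- cores$start[k]; ce <- cores$end[k]
    memb <- lapply(individual_rests, function(d)
      d[d$start < ce & d$end > cs, , drop = FALSE])
    c(min(vapply(memb, function(d) min(d$start), 0)),
      max(vapply(memb, function(d) max(d$end), 0)))
  })
  env <- do.call(rbind, env)
  out <- data.frame(start = env[, 1], end = env[, 2])
  out <- out[order(out$start), , drop = FALSE]
  # merge envelopes that grew into each other
  if (nrow(out) > 1) {
    merged <- out[1, ]
    for (k in 2:nrow(out)) {
      if (out$start[k] <= merged$end[nrow(merged)]) {
        merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], out$end[k])
      } else merged <- rbind(merged, out[k, ])
    }
    out <- merged
  }
  rownames(out) <- NULL
  out
}

#' Detect group rests directly from a trajectory
#'
#' Convenience wrapper: individual rest detection per member followed by
#' [merge_group_rests()].
#'
#' @param traj a `group_trajectory`.
#' @inheritParams detect_individual_rests
#' @return `data.frame(start, end)` of group rests.
#' @export
detect_group_rests <- function(traj, area_m2 = 100, min_duration_s = 120) {
  ind <- lapply(seq_along(traj$member_ids), function(k)
    detect_individual_rests(traj$t, traj$pos[, k, ], area_m2 = area_m2,
                            min_duration_s = min_duration_s))
  names(ind) <- traj$member_ids
  merge_group_rests(ind)
}

#' Extract trimmed movement periods between group rests
#'
#' The complement of the group rests within the trajectory span, each side
#' trimmed by `trim_s` to exclude the transitions into and out of rest. When
#' no group rest exists the span is split into two equal halves (so features
#' that compare movement periods remain computable), each half then trimmed.
#' Periods shorter than `min_period_s` after trimming are dropped.
#'
#' @param traj a `group_trajectory`.
#' @param group_rests `data.frame(start, end)`, sorted, non-overlapping
#'   (e.g. from [detect_group_rests()]).
#' @param trim_s seconds trimmed from each raw boundary (default 30).
#' @param min_period_s minimum kept period length (default 120).
#' @return list of `movement_period` objects (`index`, `start`, `end`,
#'   `traj` slice).
#' @export
extract_movement_periods <- function(traj, group_rests, trim_s = 30,
                                     min_period_s = 120) {
  t0 <- min(traj$t); t1 <- max(traj$t)
  if (nrow(group_rests) == 0) {
    half <- t0 + (t1 - t0) / 2
    raw <- data.frame(start = c(t0, half), end = c(half, t1))
  } else {
    gr <- group_rests[order(group_rests$start), , drop = FALSE]
    starts <- c(t0, gr$end)
    ends <- c(gr$start, t1)
    raw <- data.frame(start = starts, end = ends)
    raw <- raw[raw$end > raw$start, , drop = FALSE]
  }
  raw$start <- raw$start + trim_s
  raw$end <- raw$end - trim_s
  raw <- raw[raw$end - raw$start >= min_period_s, , drop = FALSE]
  out <- vector("list", nrow(raw))
  for (k in seq_len(nrow(raw))) {
    out[[k]] <- structure(
      list(index = k, start = raw$start[k], end = raw$end[k],
           traj = .slice_trajectory(traj, raw$start[k], raw$end[k])),
      class = "movement_period")
  }
  out
}

#' @export
print.movement_period <- function(x, ...) {
  cat(sprintf("<movement_period #%d> [%g, %g] s (%d timepoints)\n",
              x$index, x$start, x$end, length(x$traj$t)))
  invisible(x)
}
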