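# Small programmatic fixtures shared across test files.

# wrap a [time, member, 2] position array as a group_trajectory
mk_traj <- function(pos, dt = 1) {
  ids <- sprintf("m%02d", seq_len(dim(pos)[2]))
  dimnames(pos) <- list(NULL, ids, c("easting", "northing"))
  group_trajectory(ids, (seq_len(dim(pos)[1]) - 1) * dt, pos)
}

# movement period spanning a whole trajectory
mk_period <- function(traj, index = 1L) {
  structure(list(index = index, start = min(traj$t), end = max(traj$t),
                 traj = traj),
            class = "movement_period")
}

# group marching east at `speed`, members at fixed (dx, dy) offsets
straight_traj <- function(n_t = 200, offsets = cbind(c(0, 0), c(0, 3)),
                          speed = 1.3, dt = 1) {
  m <- nrow(offsets)
  pos <- array(NA_real_, c(n_t, m, 2))
  tt <- (seq_len(n_t) - 1) * dt
  for (k in seq_len(m)) {
    pos[, k, 1] <- speed * tt + offsets[k, 1]
    pos[, k, 2] <- offsets[k, 2]
  }
  mk_traj(pos, dt)
}

# write a tiny CSV track file, returning its path
write_csv_fixture <- function(df, name = "tracks.csv") {
  p <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

# a minimal GPX 1.1 document with one <trk> per member
write_gpx_fixture <- function(members, name = "track.gpx") {
  trks <- vapply(names(members), function(nm) {
    segs <- vapply(members[[nm]], function(seg) {
      pts <- paste(sprintf(
        '      <trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
        seg$lat, seg$lon, seg$time), collapse = "\n")
      paste0("    <trkseg>\n", pts, "\n    </trkseg>")
    }, "")
    paste0("  <trk>\n    <name>", nm, "</name>\n",
           paste(segs, collapse = "\n"), "\n  </trk>")
  }, "")
  doc <- paste0('<?xml version="1.0"?>\n',
                '<gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1">\n',
                paste(trks, collapse = "\n"), "\n</gpx>\n")
  p <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(doc, p)
  p
}

# march configuration for a 4-member heading-copy chain with delays 1,2,3 s
chain_config <- function(seed, heading_noise_sd = 0.1, gps_noise_sd = 0,
                         n_t_target = 500) {
  uu <- seq(0, 1, length.out = 15)
  wp <- cbind(600 * uu, 80 * sin(2 * pi * uu * 1.5))
  sim_config(
    n_members = 4, waypoints = wp, base_speed = 1.1,
    formation = data.frame(along = c(0, -4, -8, -12),
                           lateral = c(0, 1.5, -1.5, 1.5)),
    leader_graph = data.frame(influencer = c(1, 2, 3), follower = c(2, 3, 4),
                              delay = c(1, 2, 3)),
    heading_noise_sd = heading_noise_sd, gps_noise_sd = gps_noise_sd,
    rest_schedule = data.frame(onset = numeric(0), duration = numeric(0)),
    seed = seed)
}

# Fig-2-style turn scenario: a tight knot of members rounds a right turn
# while one member trails ~60 m behind on the path. Path: east, then a
# quarter-turn (radius 25 m) to the south, then south.
turn_scenario <- function(n_t = 140, speed = 1.3, trail_gap = 60) {
  r <- 25
  turn_start <- 120
  path_point <- function(s) {
    # s: arc length along east -> quarter circle right -> south
    t(vapply(s, function(si) {
      if (si <= turn_start) c(si, 0)
      else if (si <= turn_start + pi * r / 2) {
        a <- (si - turn_start) / r
        c(turn_start + r * sin(a), -r * (1 - cos(a)))
      } else c(turn_start + r, -r - (si - turn_start - pi * r / 2))
    }, c(0, 0)))
  }
  offs <- data.frame(along = c(0, -2, -4, -6, -trail_gap),
                     lateral = c(0, 1, -1, 0.5, 0))
  tt <- (seq_len(n_t) - 1)
  pos <- array(NA_real_, c(n_t, nrow(offs), 2))
  for (k in seq_len(nrow(offs))) {
    s <- speed * tt + 40 + offs$along[k]
    p <- path_point(pmax(s, 0))
    # lateral offset along the local normal (right of travel positive)
    tn <- path_point(pmax(s, 0) + 0.5) - path_point(pmax(s - 0.5, 0))
    tn <- tn / sqrt(rowSums(tn^2))
    pos[, k, 1] <- p[, 1] + offs$lateral[k] * tn[, 2]
    pos[, k, 2] <- p[, 2] - offs$lateral[k] * tn[, 1]
  }
  # analysis window: from just before the knot enters the turn until the
  # trailing member has cleared it (all foot points inside the path span)
  t_enter <- (turn_start - 40) / speed
  window <- which(tt >= t_enter - 10 & tt <= t_enter + 65)
  list(period = mk_period(mk_traj(pos)), trailing = nrow(offs),
       window = window)
}

# ratio of the trailing member's lateral sweep amplitude in the
# centroid-heading baseline vs PACS, over the turn window
sweep_amplitude_ratio <- function(sc) {
  per <- sc$period
  pacs <- pacs_transform(per, fit_centroid_path(per))
  base <- centroid_heading_transform(per)
  k <- sc$trailing
  w <- sc$window
  w <- w[!is.na(base$x[w, k])]
  diff(range(base$x[w, k])) / diff(range(pacs$x[w, k]))
}

# mean per-member location entropy under a transform, over the turn window.
# The histogram window must accommodate the baseline transform's ~30 m
# artifact sweep (clipping it into a 10 m window would saturate the border
# bins); bin size stays 1 m and the window is identical for both transforms,
# which is what makes the entropies comparable.
turn_window_entropy <- function(frames, window, window_area = 900) {
  mean(vapply(seq_along(frames$member_ids), function(k) {
    ok <- window[!is.na(frames$x[window, k])]
    location_entropy(frames$x[ok, k], frames$y[ok, k],
                     window_area = window_area)
  }, 0))
}
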