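#' Configuration for a simulated group march
#'
#' The generator emulates the structure of a loaded foot march: a designated
#' leader follows a curvilinear waypoint route at doctrine pace, each other
#' member steers toward a formation offset expressed in path coordinates
#' (meters along / lateral to the route) while copying its influencer's
#' heading with a configured time delay, the whole group halts during
#' scheduled rests, and i.i.d. Gaussian GPS noise is added last. Every
#' source of randomness comes from one stream seeded by `seed`.
#'
#' Defaults state a realistic march: 8 members (units field 6-9), 1.1 m/s
#' (4 km/h doctrine pace), staggered column with 3 m along-path spacing and
#' alternating 1.5 m lateral offsets, the squad leader influencing every
#' follower with a 2 s heading delay, 0.1 rad heading noise and 1.5 m GPS
#' noise, and the doctrine break schedule (15 min after the first 45 min,
#' then 10 min every 50 min) truncated to the march duration.
#'
#' @param n_members group size (default 8).
#' @param waypoints matrix `[k, 2]` of route waypoints, meters. Default: a
#'   2 km S-shaped course.
#' @param base_speed marching speed, m/s (default 1.1).
#' @param formation data.frame(along, lateral) per member, meters; member 1
#'   is the leader at the head of the column. Duplicate offsets error.
#' @param leader_graph data.frame(influencer, follower, delay) of heading
#'   copying, delays in seconds (>= 0). Default: leader -> everyone, 2 s.
#' @param heading_noise_sd per-step heading noise, rad/sqrt(s) (default 0.1).
#' @param gps_noise_sd additive position noise, meters (default 1.5).
#' @param rest_schedule data.frame(onset, duration) in seconds of scheduled
#'   halts; `NULL` = doctrine schedule fitted to the march length;
#'   `data.frame()` = no rests.
#' @param dt simulation/grid step, seconds (default 1).
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_members = 8, waypoints = NULL, base_speed = 1.1,
                       formation = NULL, leader_graph = NULL,
                       heading_noise_sd = 0.1, gps_noise_sd = 1.5,
                       rest_schedule = NULL, dt = 1, seed = 1) {
  stopifnot(n_members >= 2, base_speed > 0, dt > 0,
            heading_noise_sd >= 0, gps_noise_sd >= 0)
  if (is.null(waypoints)) {
    uu <- seq(0, 1, length.out = 21)
    waypoints <- cbind(2000 * uu, 150 * sin(2 * pi * uu * 2))
  }
  if (is.null(formation)) {
    formation <- data.frame(
      along = -3 * (seq_len(n_members) - 1),
      lateral = ifelse(seq_len(n_members) %% 2 == 0, 1.5, -1.5))
    formation$lateral[1] <- 0
  }
  stopifnot(nrow(formation) == n_members)
  if (anyDuplicated(formation))
    stop("impossible formation: duplicate member offsets")
  if (is.null(leader_graph)) {
    leader_graph <- data.frame(influencer = rep(1L, n_members - 1),
                               follower = 2:n_members,
                               delay = rep(2, n_members - 1))
  }
  if (nrow(leader_graph) && any(leader_graph$delay < 0))
    stop("delays must be >= 0")
  structure(list(n_members = n_members, waypoints = as.matrix(waypoints),
                 base_speed = base_speed, formation = formation,
                 leader_graph = leader_graph,
                 heading_noise_sd = heading_noise_sd,
                 gps_noise_sd = gps_noise_sd,
                 rest_schedule = rest_schedule, dt = dt,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# doctrine break schedule: 15 min after 45 min, then 10 min every 50 min
.doctrine_rests <- function(total_move_s) {
  onset <- 2700; dur <- 900
  out <- data.frame(onset = numeric(0), duration = numeric(0))
  move <- 0
  while (onset - sum(out$duration) < total_move_s - 300) {
    out <- rbind(out, data.frame(onset = onset, duration = dur))
    onset <- onset + dur + 3000
    dur <- 600
  }
  out
}

#' Simulate a seeded group march with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `traj` (a `group_trajectory` on a planar grid),
#'   `clean` (the noise-free positions, same shape) and `truth` (list:
#'   `rests` data.frame(start,end), `formation`, `delays`, `route_length`).
#' @export
simulate_march <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dt <- cfg$dt
  m <- cfg$n_members
  # dense route with arc-length parameterization
  wp <- cfg$waypoints
  u <- c(0, cumsum(sqrt(rowSums(diff(wp)^2))))
  keep <- !duplicated(u); u <- u[keep]; wp <- wp[keep, , drop = FALSE]
  nd <- max(1000L, ceiling(max(u) / 0.5))
  ud <- seq(0, max(u), length.out = nd)
  rx <- if (nrow(wp) >= 4) stats::splinefun(u, wp[, 1], "natural") else
    function(s) stats::approx(u, wp[, 1], s, rule = 2)$y
  ry <- if (nrow(wp) >= 4) stats::splinefun(u, wp[, 2], "natural") else
    function(s) stats::approx(u, wp[, 2], s, rule = 2)$y
  dx <- cbind(rx(ud), ry(ud))
  seg <- sqrt(rowSums(diff(dx)^2))
  sarc <- c(0, cumsum(seg))
  L <- max(sarc)
  route_pos <- function(s) {
    s0 <- pmin(pmax(s, 0), L)
    cbind(stats::approx(sarc, dx[, 1], s0)$y,
          stats::approx(sarc, dx[, 2], s0)$y)
  }
  route_tan <- function(s) {
    s0 <- pmin(pmax(s, 1e-6), L - 1e-6)
    h <- min(1, L / 100)
    d <- route_pos(pmin(s0 + h, L)) - route_pos(pmax(s0 - h, 0))
    d / sqrt(rowSums(d^2))
  }
  point_at <- function(s, lateral) {
    # extrapolate linearly beyond the route ends
    p <- route_pos(s)
    tn <- route_tan(s)
    over <- s > L; under <- s < 0
    if (any(over)) p[over, ] <- p[over, ] + (s[over] - L) * tn[over, ]
    if (any(under)) p[under, ] <- p[under, ] + s[under] * tn[under, ]
    nrm <- cbind(tn[, 2], -tn[, 1])          # right of travel
    p + lateral * nrm
  }

  move_time <- L / cfg$base_speed
  rests <- cfg$rest_schedule
  if (is.null(rests)) rests <- .doctrine_rests(move_time)
  if (!nrow(rests)) rests <- data.frame(onset = numeric(0),
                                        duration = numeric(0))
  total_T <- move_time + sum(rests$duration)
  nT <- floor(total_T / dt) + 1L
  tt <- (seq_len(nT) - 1) * dt
  resting <- rep(FALSE, nT)
  for (r in seq_len(nrow(rests)))
    resting[tt >= rests$onset[r] &
              tt < rests$onset[r] + rests$duration[r]] <- TRUE

  # leader progress along the route
  s_lead <- cumsum(c(0, ifelse(resting[-nT], 0, cfg$base_speed * dt)))

  delays_steps <- rep(NA_integer_, m)
  influencer <- rep(NA_integer_, m)
  if (nrow(cfg$leader_graph)) {
    influencer[cfg$leader_graph$follower] <- cfg$leader_graph$influencer
    delays_steps[cfg$leader_graph$follower] <-
      as.integer(round(cfg$leader_graph$delay / dt))
  }

  theta <- matrix(NA_real_, nT, m)          # realized headings
  pos <- array(NA_real_, dim = c(nT, m, 2))
  tan0 <- route_tan(0)
  for (k in seq_len(m))
    pos[1, k, ] <- point_at(cfg$formation$along[k], cfg$formation$lateral[k])
  theta[1, ] <- atan2(tan0[2], tan0[1])
  k_form <- 0.08                            # formation-restoring gain (1/s)
  max_turn <- 1.5                           # bounded turn rate (rad/s)
  noise <- matrix(stats::rnorm(nT * m, 0, cfg$heading_noise_sd * sqrt(dt)),
                  nT, m)
  # precompute route lookups (targets per member, leader reference heading)
  tgt <- lapply(seq_len(m), function(k)
    point_at(s_lead + cfg$formation$along[k], cfg$formation$lateral[k]))
  lead_tan <- route_tan(pmin(s_lead + 5, L))      # small lookahead
  for (ti in 2:nT) {
    if (resting[ti - 1]) {
      pos[ti, , ] <- pos[ti - 1, , ]
      theta[ti, ] <- theta[ti - 1, ]
      next
    }
    for (k in seq_len(m)) {
      if (is.na(influencer[k])) {
        href <- lead_tan[ti - 1, ]
      } else {
        src <- max(1L, ti - max(delays_steps[k], 1L))
        a <- theta[src, influencer[k]]
        href <- c(cos(a), sin(a))
      }
      pull <- tgt[[k]][ti - 1, ] - pos[ti - 1, k, ]
      des <- cfg$base_speed * href + k_form * pull
      ades <- atan2(des[2], des[1])
      dth <- atan2(sin(ades - theta[ti - 1, k]),
                   cos(ades - theta[ti - 1, k]))
      dth <- sign(dth) * min(abs(dth), max_turn * dt)
      th <- theta[ti - 1, k] + dth + noise[ti, k]
      theta[ti, k] <- th
      pos[ti, k, ] <- pos[ti - 1, k, ] +
        cfg$base_speed * dt * c(cos(th), sin(th))
    }
  }
  clean <- pos
  pos <- pos + array(stats::rnorm(length(pos), 0, cfg$gps_noise_sd),
                     dim = dim(pos))
  ids <- sprintf("m%02d", seq_len(m))
  dimnames(pos) <- dimnames(clean) <- list(NULL, ids,
                                           c("easting", "northing"))
  traj <- group_trajectory(ids, tt, pos)
  truth <- list(rests = if (nrow(rests))
    data.frame(start = rests$onset, end = rests$onset + rests$duration)
    else data.frame(start = numeric(0), end = numeric(0)),
    formation = cfg$formation, delays = cfg$leader_graph,
    route_length = L)
  list(traj = traj,
       clean = group_trajectory(ids, tt, clean),
       truth = truth)
}

#' Simulate a feature-table / outcome dataset for the prediction harness
#'
#' Features are i.i.d. standard normal; the outcome is a linear combination
#' of the informative columns plus Gaussian noise. Mirrors the dimensions
#' of a small multi-group study (16 groups x 69 candidate features) for
#' stress tests.
#'
#' @param n_groups,k_features table dimensions (defaults 16, 69).
#' @param informative integer indices of informative features.
#' @param coefficients their linear coefficients (recycled).
#' @param noise_sd outcome noise standard deviation.
#' @param seed integer seed.
#' @return list with `X` (matrix, named columns `f01...`), `y`, `support`.
#' @export
simulate_feature_outcome_dataset <- function(n_groups = 16, k_features = 69,
                                             informative = 1:5,
                                             coefficients = 1,
                                             noise_sd = 0.5, seed = 1) {
  stopifnot(all(informative >= 1), all(informative <= k_features))
  set.seed(seed)
  X <- matrix(stats::rnorm(n_groups * k_features), n_groups, k_features,
              dimnames = list(sprintf("g%02d", seq_len(n_groups)),
                              sprintf("f%02d", seq_len(k_features))))
  beta <- rep_len(coefficients, length(informative))
  y <- as.vector(X[, informative, drop = FALSE] %*% beta) +
    stats::rnorm(n_groups, 0, noise_sd)
  names(y) <- rownames(X)
  list(X = X, y = y, support = informative)
}
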