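# unit heading vectors per member from smoothed velocities; samples slower
# than min_speed (heading undefined near rest) or gap-masked are NA
.headings <- function(period, min_speed = 0.3) {
  traj <- period$traj
  nT <- length(traj$t); m <- length(traj$member_ids)
  hx <- hy <- matrix(NA_real_, nT, m, dimnames = list(NULL, traj$member_ids))
  for (k in seq_len(m)) {
    v <- .central_diff(traj$pos[, k, ], traj$dt)
    spd <- sqrt(rowSums(v^2))
    ok <- spd >= min_speed & !traj$mask[, k]
    hx[ok, k] <- v[ok, 1] / spd[ok]
    hy[ok, k] <- v[ok, 2] / spd[ok]
  }
  list(hx = hx, hy = hy)
}

#' Directional correlation between two members across time lags
#'
#' `C_ij(tau)` is the mean dot product of member `i`'s unit heading at time
#' `t` with member `j`'s at time `t + tau`, over all valid samples. The lag
#' maximizing `C` is the directional correlation time delay: a positive
#' `tau*` means `j` copies `i`'s direction after `tau*` seconds, i.e. `i`
#' leads. Ties at multiple maxima resolve to the smallest `|tau|`.
#'
#' @param period a `movement_period`.
#' @param i,j member indices or ids.
#' @param max_lag largest lag examined, seconds (default 10).
#' @param min_speed heading speed floor, m/s (default 0.3).
#' @param min_overlap minimum valid paired samples per lag; lags with fewer
#'   are `NA` (default 10).
#' @param headings optional precomputed heading list (internal reuse).
#' @return list with `lags`, `C`, `tau_star`, `c_max`.
#' @export
directional_correlation <- function(period, i, j, max_lag = 10,
                                    min_speed = 0.3, min_overlap = 10,
                                    headings = NULL) {
  traj <- period$traj
  if (is.character(i)) i <- match(i, traj$member_ids)
  if (is.character(j)) j <- match(j, traj$member_ids)
  h <- if (is.null(headings)) .headings(period, min_speed) else headings
  dt <- traj$dt
  nlag <- floor(max_lag / dt)
  lags <- seq(-nlag, nlag) * dt
  nT <- nrow(h$hx)
  C <- rep(NA_real_, length(lags))
  for (li in seq_along(lags)) {
    s <- as.integer(round(lags[li] / dt))
    if (s >= 0) { ti <- seq_len(nT - s); tj <- ti + s }
    else { tj <- seq_len(nT + s); ti <- tj - s }
    d <- h$hx[ti, i] * h$hx[tj, j] + h$hy[ti, i] * h$hy[tj, j]
    ok <- !is.na(d)
    if (sum(ok) >= min_overlap) C[li] <- mean(d[ok])
  }
  tau_star <- c_max <- NA_real_
  if (any(!is.na(C))) {
    cm <- max(C, na.rm = TRUE)
    cand <- lags[!is.na(C) & C >= cm - 1e-12]
    tau_star <- cand[which.min(abs(cand))]
    c_max <- cm
  }
  list(lags = lags, C = C, tau_star = tau_star, c_max = c_max)
}

#' Build the leader-follower hierarchy graph for one movement period
#'
#' Pairwise directional-correlation delays define node leadership scores
#' (mean delay over partners; positive = leading) and directed edges from
#' the leading member of each pair to the follower, weighted by `|tau*|`.
#' Pairs with `tau* = 0` (or undefined) contribute no edge.
#'
#' @inheritParams directional_correlation
#' @return a `hierarchy_graph`: list with `members`, `scores`, `edges`
#'   (`data.frame(leader, follower, delay)`), `tau` (antisymmetric matrix).
#' @export
build_hierarchy <- function(period, max_lag = 10, min_speed = 0.3,
                            min_overlap = 10) {
  traj <- period$traj
  m <- length(traj$member_ids)
  h <- .headings(period, min_speed)
  tau <- matrix(NA_real_, m, m,
                dimnames = list(traj$member_ids, traj$member_ids))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      dc <- directional_correlation(period, i, j, max_lag = max_lag,
                                    min_speed = min_speed,
                                    min_overlap = min_overlap, headings = h)
      tau[i, j] <- dc$tau_star
      tau[j, i] <- if (is.na(dc$tau_star)) NA_real_ else -dc$tau_star
    }
  }
  scores <- vapply(seq_len(m), function(i) {
    v <- tau[i, -i]
    if (all(is.na(v))) 0 else mean(v[!is.na(v)])
  }, 0)
  names(scores) <- traj$member_ids
  edges <- data.frame(leader = character(0), follower = character(0),
                      delay = numeric(0))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      tv <- tau[i, j]
      if (is.na(tv) || tv == 0) next
      if (tv > 0)
        edges <- rbind(edges, data.frame(leader = traj$member_ids[i],
                                         follower = traj$member_ids[j],
                                         delay = tv))
      else
        edges <- rbind(edges, data.frame(leader = traj$member_ids[j],
                                         follower = traj$member_ids[i],
                                         delay = -tv))
    }
  }
  structure(list(members = traj$member_ids, scores = scores, edges = edges,
                 tau = tau),
            class = "hierarchy_graph")
}

#' @export
print.hierarchy_graph <- function(x, ...) {
  cat("<hierarchy_graph>", length(x$members), "members,",
      nrow(x$edges), "edges\n")
  ord <- order(-x$scores)
  cat("  scores:", paste(sprintf("%s=%.2f", x$members[ord], x$scores[ord]),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Highly-correlated-segment ratio for a member pair
#'
#' The period is cut into consecutive windows; windows where the pair's
#' mean separation is within `proximity_m` are "proximate". A proximate
#' window is an HCS when the maximum directional correlation over lags
#' exceeds `threshold`. The ratio is HCS time over proximate non-HCS time;
#' when all proximate time is highly correlated the ratio is `Inf` with a
#' `flag` attribute.
#'
#' @inheritParams directional_correlation
#' @param window_s window length, seconds (default 30).
#' @param proximity_m proximity bound, meters (default 10).
#' @param threshold HCS correlation floor (default 0.99).
#' @return ratio (>= 0, possibly `Inf`), with attributes `n_hcs`, `n_prox`.
#' @export
hcs_ratio <- function(period, i, j, window_s = 30, proximity_m = 10,
                      max_lag = 10, min_speed = 0.3, threshold = 0.99) {
  traj <- period$traj
  if (is.character(i)) i <- match(i, traj$member_ids)
  if (is.character(j)) j <- match(j, traj$member_ids)
  nper <- max(1L, floor(window_s / traj$dt))
  nT <- length(traj$t)
  starts <- seq(1L, nT - nper + 1L, by = nper)
  n_hcs <- 0L; n_prox <- 0L
  for (st in starts) {
    idx <- st:(st + nper - 1L)
    sub <- structure(list(
      index = period$index, start = traj$t[idx[1]], end = traj$t[idx[nper]],
      traj = .slice_trajectory(traj, traj$t[idx[1]], traj$t[idx[nper]])),
      class = "movement_period")
    d <- sqrt((traj$pos[idx, i, 1] - traj$pos[idx, j, 1])^2 +
                (traj$pos[idx, i, 2] - traj$pos[idx, j, 2])^2)
    if (mean(d) > proximity_m) next
    n_prox <- n_prox + 1L
    dc <- directional_correlation(sub, i, j, max_lag = max_lag,
                                  min_speed = min_speed,
                                  min_overlap = max(3L, nper %/% 3L))
    if (!is.na(dc$c_max) && dc$c_max > threshold) n_hcs <- n_hcs + 1L
  }
  ratio <- if (n_prox - n_hcs == 0) {
    if (n_hcs > 0) Inf else NA_real_
  } else n_hcs / (n_prox - n_hcs)
  attr(ratio, "n_hcs") <- n_hcs
  attr(ratio, "n_prox") <- n_prox
  ratio
}

#' Quality metrics of a hierarchy graph
#'
#' `downward_ratio` is the fraction of edges pointing from a higher-scored
#' node to a lower-scored one; the loop count is the number of strongly
#' connected components with more than one node (bounded, deterministic
#' surrogate for cycle enumeration).
#'
#' @param graph a `hierarchy_graph`.
#' @return list `downward_ratio` (`NA` with a flag if there are no edges)
#'   and `loop_count`.
#' @export
hierarchy_quality <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0)
    return(list(downward_ratio = NA_real_, loop_count = 0L,
                flag = "empty edge set"))
  down <- mean(graph$scores[e$leader] > graph$scores[e$follower])
  g <- igraph::graph_from_data_frame(e[c("leader", "follower")],
                                     vertices = graph$members)
  comp <- igraph::components(g, mode = "strong")
  list(downward_ratio = down,
       loop_count = sum(comp$csize > 1))
}

#' Leadership instability across movement periods
#'
#' For each pair of periods, the edit distance between hierarchy graphs is
#' the number of unordered member pairs whose edge state differs (absent /
#' i leads / j leads), normalized by the number of member pairs; the
#' feature is the mean over all period pairs.
#'
#' @param graphs list of `hierarchy_graph`s, one per movement period (>= 2).
#' @return mean normalized edit distance in `[0, 1]`, or `NULL` (with a
#'   message) for a single period.
#' @export
leadership_instability <- function(graphs) {
  if (length(graphs) < 2) {
    message("leadership instability requires >= 2 movement periods; absent")
    return(NULL)
  }
  members <- graphs[[1]]$members
  state <- function(g) {
    m <- length(members)
    s <- matrix(0L, m, m, dimnames = list(members, members))
    if (nrow(g$edges)) {
      for (r in seq_len(nrow(g$edges))) {
        s[g$edges$leader[r], g$edges$follower[r]] <- 1L
        s[g$edges$follower[r], g$edges$leader[r]] <- -1L
      }
    }
    s[upper.tri(s)]
  }
  states <- lapply(graphs, state)
  pairs <- utils::combn(length(graphs), 2)
  npairs <- length(states[[1]])
  mean(vapply(seq_len(ncol(pairs)), function(pi)
    sum(states[[pairs[1, pi]]] != states[[pairs[2, pi]]]) / npairs, 0))
}
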