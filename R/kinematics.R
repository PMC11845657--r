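#' Velocity-based series for one movement period
#'
#' Speeds and acceleration magnitudes per member (central differences on the
#' smoothed regular grid, one-sided at the ends), plus the two group-level
#' series: spread (fastest minus slowest member at each timepoint) and the
#' population variance of member speeds at each timepoint. Grid points
#' flagged by the resampling gap mask propagate as `NA`.
#'
#' @param period a `movement_period` with at least 3 samples.
#' @return a `kinematic_series`: list with `t`, matrices `speed`, `accel`
#'   `[time, member]`, vectors `spread`, `speed_var`.
#' @export
compute_kinematics <- function(period) {
  traj <- period$traj
  nT <- length(traj$t)
  if (nT < 3) stop("period has fewer than 3 samples")
  m <- length(traj$member_ids)
  speed <- accel <- matrix(NA_real_, nT, m,
                           dimnames = list(NULL, traj$member_ids))
  for (k in seq_len(m)) {
    v <- .central_diff(traj$pos[, k, ], traj$dt)
    a <- .central_diff(v, traj$dt)
    speed[, k] <- sqrt(rowSums(v^2))
    accel[, k] <- sqrt(rowSums(a^2))
    bad <- traj$mask[, k]
    speed[bad, k] <- NA; accel[bad, k] <- NA
  }
  spread <- apply(speed, 1, function(s)
    if (all(is.na(s))) NA_real_ else diff(range(s, na.rm = TRUE)))
  svar <- apply(speed, 1, .pop_var)
  structure(list(t = traj$t, speed = speed, accel = accel, spread = spread,
                 speed_var = svar, dt = traj$dt),
            class = "kinematic_series")
}

.pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Summarize velocity-based features
#'
#' Per-member max/mean/population-variance of speed and max/mean of
#' acceleration magnitude, averaged into group features; spread and
#' cross-member variance series means; entropies of the starred time series
#' through [series_entropy()]. Acceleration features are marked
#' low-confidence in the metadata: consumer GPS lacks the accuracy to
#' characterize acceleration precisely.
#'
#' @param series a `kinematic_series`.
#' @param entropy_bins histogram bin count handed to [series_entropy()]
#'   (shared edges can be imposed dataset-wide via `entropy_breaks`).
#' @param entropy_breaks optional named list of shared break vectors for
#'   the series `speed`, `spread`, `speed_var`.
#' @return named numeric vector of `kin.*` features, with attribute
#'   `low_confidence` naming the acceleration-derived entries.
#' @export
summarize_kinematics <- function(series, entropy_bins = 20,
                                 entropy_breaks = NULL) {
  stopifnot(inherits(series, "kinematic_series"))
  br <- function(nm) if (!is.null(entropy_breaks)) entropy_breaks[[nm]] else NULL
  per_max <- apply(series$speed, 2, max, na.rm = TRUE)
  per_mean <- apply(series$speed, 2, mean, na.rm = TRUE)
  per_var <- apply(series$speed, 2, .pop_var)
  acc_mean <- apply(series$accel, 2, mean, na.rm = TRUE)
  acc_max <- apply(series$accel, 2, max, na.rm = TRUE)
  sp_ent <- mean(apply(series$speed, 2, series_entropy,
                       bins = entropy_bins, breaks = br("speed")))
  out <- c(
    kin.speed.mean = mean(per_mean),
    kin.speed.max = mean(per_max),
    kin.speed.var = mean(per_var),
    kin.speed.entropy = sp_ent,
    kin.accel.mean = mean(acc_mean),
    kin.accel.max = mean(acc_max),
    kin.spread.mean = mean(series$spread, na.rm = TRUE),
    kin.spread.entropy = series_entropy(series$spread, bins = entropy_bins,
                                        breaks = br("spread")),
    kin.speedvar.mean = mean(series$speed_var, na.rm = TRUE),
    kin.speedvar.entropy = series_entropy(series$speed_var,
                                          bins = entropy_bins,
                                          breaks = br("speed_var")))
  attr(out, "low_confidence") <- c("kin.accel.mean", "kin.accel.max")
  out
}
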