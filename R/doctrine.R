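#' Doctrine-compliance metrics for foot marches
#'
#' Dismounted foot-march doctrine recommends members keep 2-5 m spacing in
#' daylight, march at roughly 4 km/h (~1.1 m/s), and take breaks on a
#' regular schedule. These helpers score how closely a group follows the
#' guidance.
#'
#' @name doctrine
NULL

#' @describeIn doctrine fraction of movement-period samples below the
#'   reasonable-pace limit (1.7 m/s, the outdoor "fast walk" boundary).
#' @param speeds numeric vector of movement-period speeds, m/s.
#' @param pace_limit m/s (default 1.7).
#' @export
reasonable_pace_ratio <- function(speeds, pace_limit = 1.7) {
  s <- speeds[!is.na(speeds)]
  stopifnot(length(s) > 0, pace_limit > 0)
  mean(s < pace_limit)
}

#' @describeIn doctrine fraction of time the nearest-neighbor distance is
#'   inside the recommended interval (closed on both ends).
#' @param nn_dist numeric vector (or matrix) of nearest-neighbor distances,
#'   meters.
#' @param spacing length-2 interval, meters (default `c(2, 5)`).
#' @export
spacing_compliance <- function(nn_dist, spacing = c(2, 5)) {
  stopifnot(spacing[1] < spacing[2])
  d <- nn_dist[!is.na(nn_dist)]
  mean(d >= spacing[1] & d <= spacing[2])
}

#' @describeIn doctrine population standard deviations of successive
#'   rest-onset gaps and of rest durations; `NULL` (with a message) when
#'   fewer than 2 group rests exist.
#' @param group_rests `data.frame(start, end)` of group rests.
#' @export
break_regularity <- function(group_rests) {
  if (nrow(group_rests) < 2) {
    message("break regularity requires >= 2 group rests; absent")
    return(NULL)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(sd_onset_interval = if (nrow(group_rests) >= 3)
    pop_sd(diff(group_rests$start)) else 0,
    sd_duration = pop_sd(group_rests$end - group_rests$start))
}

#' @describeIn doctrine per-frame column length: the largest difference in
#'   PACS-y among members; returns the series plus mean and max.
#' @param pacs a `pacs_frames` object.
#' @export
column_length <- function(pacs) {
  cl <- apply(pacs$y, 1, function(v)
    if (all(is.na(v))) NA_real_ else diff(range(v, na.rm = TRUE)))
  list(t = pacs$t, series = cl, mean = mean(cl, na.rm = TRUE),
       max = max(cl, na.rm = TRUE))
}
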