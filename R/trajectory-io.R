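#' Read raw GPS tracks from GPX or CSV
#'
#' Reads per-individual GPS samples from a file or a directory of files.
#' CSV files must carry a header `time,id,lat,lon` (geographic) or
#' `time,id,easting,northing,zone` (already projected); times are ISO-8601
#' strings or epoch seconds. GPX 1.1 track files contribute one member per
#' `<trk>` (named by `<name>`, falling back to the file name); multiple track
#' segments are concatenated. Samples are grouped by member and time-sorted;
#' duplicate timestamps within a member keep the first occurrence.
#'
#' @param path a file or a directory containing `.gpx`/`.csv` files.
#' @param format `"auto"` (by extension), `"gpx"` or `"csv"`.
#' @return a `data.frame` of class `flock_samples` with columns `member_id`,
#'   `t` (seconds), and either `lat`,`lon` (degrees) or `easting`,`northing`
#'   (meters, with a `zone` attribute) depending on the source convention.
#' @export
read_tracks <- function(path, format = c("auto", "gpx", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(gpx|csv)$", ignore.case = TRUE,
               full.names = TRUE)
  } else path
  if (!length(files)) stop("no .gpx or .csv files under ", path)
  parts <- lapply(files, function(f) {
    fmt <- if (format == "auto") {
      if (grepl("\\.gpx$", f, ignore.case = TRUE)) "gpx" else "csv"
    } else format
    if (fmt == "gpx") .read_gpx(f) else .read_track_csv(f)
  })
  conv <- vapply(parts, function(p) attr(p, "convention"), "")
  if (length(unique(conv)) > 1)
    stop("mixed coordinate conventions (lat/lon vs easting/northing) across files")
  out <- do.call(rbind, parts)
  out <- out[order(out$member_id, out$t), , drop = FALSE]
  dup <- duplicated(out[c("member_id", "t")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (conv[1] == "geo") .check_geo(out)
  attr(out, "convention") <- conv[1]
  class(out) <- c("flock_samples", "data.frame")
  out
}

.check_geo <- function(df) {
  if (any(df$lat < -90 | df$lat > 90))
    stop("latitude out of [-90, 90] (row ",
         which(df$lat < -90 | df$lat > 90)[1], ")")
  if (any(df$lon < -180 | df$lon > 180))
    stop("longitude out of [-180, 180] (row ",
         which(df$lon < -180 | df$lon > 180)[1], ")")
  invisible(df)
}

.parse_time <- function(x, file, line) {
  if (is.numeric(x)) return(as.numeric(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  tt <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  bad <- which(is.na(tt))
  if (length(bad))
    stop(sprintf("%s: unparseable time on data line %d: '%s'",
                 file, line[bad[1]], x[bad[1]]))
  as.numeric(tt)
}

.read_track_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  names(df) <- nm
  geo <- all(c("time", "id", "lat", "lon") %in% nm)
  utm <- all(c("time", "id", "easting", "northing") %in% nm)
  if (!geo && !utm)
    stop(file, ": header must contain time,id,lat,lon or time,id,easting,northing")
  if (geo && utm)
    stop(file, ": mixed coordinate conventions in one file")
  lines <- seq_len(nrow(df)) + 1L
  cols <- if (geo) c("lat", "lon") else c("easting", "northing")
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad) || anyNA(v))
      stop(sprintf("%s: malformed numeric field '%s' on line %d", file, cl,
                   lines[if (length(bad)) bad[1] else which(is.na(v))[1]]))
    df[[cl]] <- v
  }
  out <- data.frame(member_id = as.character(df$id),
                    t = .parse_time(df$time, file, lines),
                    stringsAsFactors = FALSE)
  out[cols] <- df[cols]
  attr(out, "convention") <- if (geo) "geo" else "utm"
  if (utm && "zone" %in% nm) attr(out, "zone") <- df$zone[1]
  out
}

.read_gpx <- function(file) {
  doc <- xml2::read_xml(file)
  doc <- xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (!length(trks)) stop(file, ": no <trk> elements")
  base <- sub("\\.gpx$", "", basename(file), ignore.case = TRUE)
  parts <- lapply(seq_along(trks), function(i) {
    trk <- trks[[i]]
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || !nzchar(nm))
      nm <- if (length(trks) > 1) paste0(base, "_", i) else base
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (!length(pts)) return(NULL)
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    if (anyNA(lat) || anyNA(lon))
      stop(file, ": trkpt missing lat/lon attribute")
    data.frame(member_id = nm, t = .parse_time(tim, file, seq_along(tim)),
               lat = lat, lon = lon, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  attr(out, "convention") <- "geo"
  out
}

#' Project geographic samples to UTM planar coordinates
#'
#' Chooses the UTM zone from the mean position of all samples and projects
#' every member into that single zone, so that within-group distances are
#' planar meters. Samples already in planar coordinates pass through.
#'
#' @param samples a `flock_samples` data.frame from [read_tracks()].
#' @param zone optional manual zone override.
#' @return an object of class `utm_tracks`: a list with `tracks` (named list
#'   of per-member `data.frame(t, easting, northing)`), `zone`, `hemisphere`.
#' @export
to_utm <- function(samples, zone = NULL) {
  conv <- attr(samples, "convention")
  if (identical(conv, "utm")) {
    tracks <- split(samples[c("t", "easting", "northing")], samples$member_id)
    z <- attr(samples, "zone"); if (is.null(z)) z <- NA_integer_
    return(structure(list(tracks = tracks, zone = z, hemisphere = "N"),
                     class = "utm_tracks"))
  }
  .check_geo(samples)
  zones <- utm_zone_of(samples$lon)
  if (is.null(zone)) {
    if (length(unique(zones)) > 2)
      stop("samples span more than 2 UTM zones; supply `zone` manually")
    zone <- utm_zone_of(mean(samples$lon))
  }
  hemisphere <- if (mean(samples$lat) < 0) "S" else "N"
  prj <- utm_project(samples$lat, samples$lon, zone = zone,
                     hemisphere = hemisphere)
  df <- data.frame(t = samples$t, easting = prj$easting,
                   northing = prj$northing)
  tracks <- split(df, samples$member_id)
  structure(list(tracks = tracks, zone = zone, hemisphere = hemisphere),
            class = "utm_tracks")
}

#' Smooth one planar track with a smoothing spline
#'
#' Fits an independent cubic smoothing spline to easting and northing as
#' functions of time. With `smoothing = NULL` the penalty is chosen per track
#' by generalized cross-validation; `smoothing = 0` returns the input
#' unchanged (interpolating limit); any positive value is passed through as
#' the spline `lambda`.
#'
#' @param track `data.frame(t, easting, northing)` with at least 4 points.
#' @param smoothing `NULL` (GCV), `0`, or a positive penalty.
#' @return a track of the same shape, evaluated at the input times.
#' @export
smooth_track <- function(track, smoothing = NULL) {
  if (nrow(track) < 4) stop("need at least 4 points to smooth a track")
  if (!is.null(smoothing) && smoothing == 0) return(track)
  fit1 <- .fit_ss(track$t, track$easting, smoothing)
  fit2 <- .fit_ss(track$t, track$northing, smoothing)
  data.frame(t = track$t,
             easting = stats::predict(fit1, track$t)$y,
             northing = stats::predict(fit2, track$t)$y)
}

.fit_ss <- function(x, y, smoothing = NULL) {
  if (is.null(smoothing)) {
    stats::smooth.spline(x, y, cv = FALSE, keep.data = FALSE)
  } else {
    stats::smooth.spline(x, y, lambda = smoothing, keep.data = FALSE)
  }
}

#' Resample member tracks onto a common regular time grid
#'
#' Builds the common grid spanning the intersection of all members' time
#' ranges and evaluates each member's natural interpolating spline on it.
#' Grid points that fall inside a raw sampling gap longer than `max_gap`
#' are still filled but flagged in the mask so downstream features can
#' exclude them.
#'
#' @param tracks a `utm_tracks` object (typically smoothed per member with
#'   [smooth_track()] first).
#' @param dt grid step in seconds (default 1).
#' @param max_gap maximum unflagged raw gap, seconds (default 60).
#' @return a `group_trajectory`: list with `member_ids`, `t`, `dt`,
#'   `pos` (array `[time, member, c("easting","northing")]`), `mask`
#'   (logical `[time, member]`, `TRUE` = inside an over-long gap), `zone`,
#'   `hemisphere`.
#' @export
resample_group <- function(tracks, dt = 1, max_gap = 60) {
  stopifnot(inherits(tracks, "utm_tracks"), dt > 0)
  trs <- tracks$tracks
  t0 <- max(vapply(trs, function(d) min(d$t), 0))
  t1 <- min(vapply(trs, function(d) max(d$t), 0))
  if (t1 <= t0) stop("member time ranges have empty intersection")
  grid <- seq(t0, t1, by = dt)
  m <- length(trs)
  pos <- array(NA_real_, dim = c(length(grid), m, 2),
               dimnames = list(NULL, names(trs), c("easting", "northing")))
  mask <- matrix(FALSE, length(grid), m, dimnames = list(NULL, names(trs)))
  for (k in seq_len(m)) {
    d <- trs[[k]]
    fe <- stats::splinefun(d$t, d$easting, method = "natural")
    fn <- stats::splinefun(d$t, d$northing, method = "natural")
    pos[, k, 1] <- fe(grid)
    pos[, k, 2] <- fn(grid)
    gaps <- diff(d$t)
    long <- which(gaps > max_gap)
    for (g in long)
      mask[grid > d$t[g] & grid < d$t[g + 1], k] <- TRUE
  }
  group_trajectory(member_ids = names(trs), t = grid, pos = pos, mask = mask,
                   zone = tracks$zone, hemisphere = tracks$hemisphere)
}

#' Smooth an already-gridded group trajectory
#'
#' Applies the per-member smoothing spline of [smooth_track()] to every
#' member of a `group_trajectory` (e.g. simulator output, or data ingested
#' with `smooth = FALSE`). GPS position noise otherwise dominates all
#' velocity- and heading-derived features.
#'
#' @param traj a `group_trajectory`.
#' @param smoothing as in [smooth_track()] (`NULL` = per-track GCV).
#' @return a smoothed `group_trajectory` on the same grid.
#' @export
smooth_trajectory <- function(traj, smoothing = NULL) {
  out <- traj
  for (k in seq_along(traj$member_ids)) {
    d <- data.frame(t = traj$t, easting = traj$pos[, k, 1],
                    northing = traj$pos[, k, 2])
    sm <- smooth_track(d, smoothing = smoothing)
    out$pos[, k, 1] <- sm$easting
    out$pos[, k, 2] <- sm$northing
  }
  out
}

#' Construct a group trajectory container
#'
#' Regular-grid planar positions for all members of one group. Mostly
#' produced by [resample_group()] or [simulate_march()], but exposed so other
#' front ends can build one directly.
#'
#' @param member_ids character vector of member ids.
#' @param t numeric time grid, uniform step.
#' @param pos numeric array `[time, member, 2]` (easting, northing meters).
#' @param mask logical `[time, member]` gap flags (default all `FALSE`).
#' @param zone,hemisphere UTM bookkeeping (may be `NA` for synthetic planar
#'   data).
#' @return an object of class `group_trajectory`.
#' @export
group_trajectory <- function(member_ids, t, pos, mask = NULL,
                             zone = NA_integer_, hemisphere = "N") {
  stopifnot(length(dim(pos)) == 3, dim(pos)[1] == length(t),
            dim(pos)[2] == length(member_ids), dim(pos)[3] == 2)
  dts <- diff(t)
  if (length(dts) && max(abs(dts - dts[1])) > 1e-8 * max(1, abs(dts[1])))
    stop("time grid is not uniform")
  if (anyNA(pos)) stop("positions must be complete after interpolation")
  if (is.null(mask)) mask <- matrix(FALSE, length(t), length(member_ids))
  structure(list(member_ids = as.character(member_ids), t = as.numeric(t),
                 dt = if (length(dts)) dts[1] else NA_real_,
                 pos = pos, mask = mask, zone = zone,
                 hemisphere = hemisphere),
            class = "group_trajectory")
}

#' @export
print.group_trajectory <- function(x, ...) {
  cat(sprintf("<group_trajectory> %d members x %d timepoints, dt = %gs\n",
              length(x$member_ids), length(x$t), x$dt))
  cat("  members:", paste(x$member_ids, collapse = ", "), "\n")
  cat(sprintf("  span: [%g, %g] s; zone %s%s; %d flagged gap points\n",
              min(x$t), max(x$t), x$zone, x$hemisphere, sum(x$mask)))
  invisible(x)
}

# slice a trajectory to t in [start, end] (closed)
.slice_trajectory <- function(traj, start, end) {
  idx <- which(traj$t >= start - 1e-9 & traj$t <= end + 1e-9)
  group_trajectory(traj$member_ids, traj$t[idx],
                   traj$pos[idx, , , drop = FALSE],
                   traj$mask[idx, , drop = FALSE],
                   zone = traj$zone, hemisphere = traj$hemisphere)
}

# centroid path over time: matrix [time, 2]
.centroid <- function(traj) {
  cbind(rowMeans(traj$pos[, , 1, drop = FALSE]),
        rowMeans(traj$pos[, , 2, drop = FALSE]))
}

#' Write / read the tidy trajectory CSV dialect
#'
#' Long-format CSV with columns `time,id,easting,northing,zone`, the same
#' dialect [read_tracks()] accepts, so simulator output can round-trip
#' through the ingest path.
#'
#' @param traj a `group_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  m <- length(traj$member_ids)
  df <- data.frame(
    time = rep(traj$t, m),
    id = rep(traj$member_ids, each = length(traj$t)),
    easting = as.vector(traj$pos[, , 1]),
    northing = as.vector(traj$pos[, , 2]),
    zone = if (is.na(traj$zone)) "" else traj$zone)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param dt,max_gap passed to [resample_group()] when the file is irregular.
#' @param smooth smooth each member's track ([smooth_track()], GCV penalty)
#'   before resampling; default `TRUE` — raw consumer GPS noise otherwise
#'   dominates all velocity-derived features.
#' @param smoothing optional explicit spline penalty (see [smooth_track()]).
#' @export
read_trajectory_csv <- function(path, dt = 1, max_gap = 60, smooth = TRUE,
                                smoothing = NULL) {
  s <- read_tracks(path, format = "csv")
  u <- to_utm(s)
  if (smooth)
    u$tracks <- lapply(u$tracks, smooth_track, smoothing = smoothing)
  resample_group(u, dt = dt, max_gap = max_gap)
}
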