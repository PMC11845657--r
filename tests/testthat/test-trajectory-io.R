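test_that("CSV tracks read, sort, de-duplicate, and validate", {
  p <- write_csv_fixture(data.frame(
    time = c(2, 0, 1, 1), id = "a",
    lat = c(42.02, 42.00, 42.01, 99), lon = -71.4))
  s <- read_tracks(p, format = "csv")
  expect_s3_class(s, "flock_samples")
  expect_equal(nrow(s), 3)                     # duplicate t=1 keeps first
  expect_equal(s$t, c(0, 1, 2))
  expect_equal(s$lat, c(42.00, 42.01, 42.02))

  bad <- write_csv_fixture(data.frame(time = 0, id = "a", lat = 200,
                                      lon = 0), "bad.csv")
  expect_error(read_tracks(bad, format = "csv"), "latitude")

  malformed <- write_csv_fixture(data.frame(time = 0:1, id = "a",
                                            lat = c("42.0", "oops"),
                                            lon = 0), "mal.csv")
  expect_error(read_tracks(malformed, format = "csv"), "line 3")
})

test_that("GPX segments concatenate and time-sort per member", {
  p <- write_gpx_fixture(list(alpha = list(
    list(lat = 42.001, lon = -71.4, time = "2024-05-01T12:00:10Z"),
    list(lat = c(42.000, 42.0005), lon = c(-71.4, -71.4),
         time = c("2024-05-01T12:00:00Z", "2024-05-01T12:00:05Z")))))
  s <- read_tracks(p, format = "gpx")
  expect_equal(s$member_id, rep("alpha", 3))
  expect_equal(diff(s$t), c(5, 5))
  expect_equal(s$lat, c(42.000, 42.0005, 42.001))
})

test_that("UTM projection matches an independent implementation", {
  # central meridian of zone 31 at the equator: exact by construction
  p <- utm_project(0, 3)
  expect_equal(p$zone, 31L)
  expect_equal(p$easting, 500000, tolerance = 1e-9)
  expect_equal(p$northing, 0, tolerance = 1e-9)

  # cross-check against the Snyder-series oracle at scattered points
  set.seed(7)
  lat <- runif(25, -60, 60)
  lon <- runif(25, -1.5, 1.5) + 3          # stay inside zone 31
  mine <- utm_project(lat, lon, zone = 31, hemisphere = "N")
  ref <- snyder_utm(lat, lon, zone = 31)
  expect_lt(max(abs(mine$easting - ref$easting)), 0.01)
  expect_lt(max(abs(mine$northing - ref$northing)), 0.01)

  # small equatorial longitude offsets map to ~111.32 m per 0.001 degree
  a <- utm_project(0, 3.000, zone = 31)
  b <- utm_project(0, 3.001, zone = 31)
  d <- sqrt((a$easting - b$easting)^2 + (a$northing - b$northing)^2)
  expect_equal(d, 111.32, tolerance = 1e-3)
})

test_that("projection round-trips below 1e-6 degrees", {
  set.seed(11)
  lat <- runif(100, -75, 75)
  lon <- runif(100, -2.9, 2.9) + 3
  p <- utm_project(lat, lon, zone = 31, hemisphere = "N")
  inv <- utm_unproject(p$easting, p$northing, 31, "N")
  expect_lt(max(abs(inv$lat - lat)), 1e-6)
  expect_lt(max(abs(inv$lon - lon)), 1e-6)
})

test_that("to_utm picks one zone and rejects wide spans", {
  s <- data.frame(member_id = "a", t = 0:2, lat = c(42, 42.001, 42.002),
                  lon = c(-71.4, -71.4, -71.4))
  attr(s, "convention") <- "geo"
  u <- to_utm(s)
  expect_s3_class(u, "utm_tracks")
  expect_equal(u$zone, utm_zone_of(-71.4))

  wide <- data.frame(member_id = "a", t = 0:2, lat = 42,
                     lon = c(-71, -60, -49))
  attr(wide, "convention") <- "geo"
  expect_error(to_utm(wide), "zone")
})

test_that("smoothing reproduces lines, damps spikes, is equivariant", {
  tt <- 0:19
  line <- data.frame(t = tt, easting = 1.5 * tt, northing = 0.4 * tt + 2)
  sm <- smooth_track(line, smoothing = 1e-4)
  expect_lt(max(abs(sm$easting - line$easting)), 1e-9)
  expect_lt(max(abs(sm$northing - line$northing)), 1e-9)

  spiky <- line
  spiky$northing[10] <- spiky$northing[10] + 10
  sm2 <- smooth_track(spiky, smoothing = 1e-3)
  # deviation from the underlying line at the spike reduced by > 50%
  expect_lt(abs(sm2$northing[10] - line$northing[10]), 0.5 * 10)

  expect_identical(smooth_track(line, smoothing = 0), line)
  expect_error(smooth_track(line[1:3, ]), "4 points")

  # translation equivariance
  shifted <- line
  shifted$easting <- shifted$easting + 1000
  a <- smooth_track(line)
  b <- smooth_track(shifted)
  expect_equal(b$easting, a$easting + 1000, tolerance = 1e-8)
})

test_that("resampling fills gaps, intersects ranges, flags long gaps", {
  trk <- function(t, e, n = 0) data.frame(t = t, easting = e,
                                          northing = rep(n, length(t)))
  u <- structure(list(tracks = list(a = trk(c(0, 2, 3, 4), c(0, 2, 3, 4))),
                      zone = 31L, hemisphere = "N"), class = "utm_tracks")
  g <- resample_group(u, dt = 1)
  expect_equal(g$pos[2, 1, 1], 1, tolerance = 1e-9)   # linear gap at t=1

  u2 <- structure(list(tracks = list(
    a = trk(seq(0, 100, 5), seq(0, 100, 5)),
    b = trk(seq(10, 90, 5), seq(10, 90, 5))),
    zone = 31L, hemisphere = "N"), class = "utm_tracks")
  g2 <- resample_group(u2, dt = 1)
  expect_equal(range(g2$t), c(10, 90))

  # 600 s hole with max_gap 60: filled but flagged
  tt <- c(seq(0, 100, 5), seq(700, 800, 5))
  u3 <- structure(list(tracks = list(a = trk(tt, tt)),
                       zone = 31L, hemisphere = "N"), class = "utm_tracks")
  g3 <- resample_group(u3, dt = 1, max_gap = 60)
  inside <- g3$t > 100 & g3$t < 700
  expect_true(all(g3$mask[inside, 1]))
  expect_false(any(g3$mask[!inside, 1]))
  expect_false(anyNA(g3$pos))

  # identity on an already-gridded track
  u4 <- structure(list(tracks = list(a = trk(0:10, (0:10) * 2))),
                  class = "utm_tracks")
  u4$zone <- 31L; u4$hemisphere <- "N"
  g4 <- resample_group(u4, dt = 1)
  expect_equal(g4$pos[, 1, 1], (0:10) * 2, tolerance = 1e-10)

  expect_error(resample_group(structure(list(tracks = list(
    a = trk(0:10, 0:10), b = trk(20:30, 20:30)),
    zone = 31L, hemisphere = "N"), class = "utm_tracks"), dt = 1),
    "empty intersection")
})

test_that("trajectory CSV round-trips through the ingest path", {
  traj <- straight_traj(n_t = 20)
  p <- file.path(withr::local_tempdir(), "traj.csv")
  write_trajectory_csv(traj, p)
  back <- read_trajectory_csv(p, dt = 1)
  expect_equal(back$pos, traj$pos, tolerance = 1e-6)
  expect_equal(back$member_ids, traj$member_ids)
})
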