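# static frame repeated over time from a [member, 2] layout
static_period <- function(pts, n_t = 20) {
  pos <- array(NA_real_, c(n_t, nrow(pts), 2))
  for (k in seq_len(nrow(pts))) {
    pos[, k, 1] <- pts[k, 1]
    pos[, k, 2] <- pts[k, 2]
  }
  mk_period(mk_traj(pos))
}

test_that("well-separated knots cluster identically under both methods", {
  knots <- rbind(cbind(rnorm(4, 0, 1), rnorm(4, 0, 1)),
                 cbind(rnorm(4, 100, 1), rnorm(4, 0, 1)))
  per <- static_period(knots)
  for (meth in c("dbscan", "hdbscan")) {
    cf <- cluster_frames(per, meth, min_cluster_size = 2,
                         distance_threshold = 10)
    expect_true(all(cf$labels > 0))
    expect_equal(length(unique(cf$labels[1, ])), 2)
    expect_equal(unname(cf$labels[1, 1:4]), rep(unname(cf$labels[1, 1]), 4))
    expect_equal(unname(cf$labels[1, 5:8]), rep(unname(cf$labels[1, 5]), 4))
  }
})

test_that("stragglers are outliers; chains stay density-connected", {
  set.seed(4)
  pts <- rbind(cbind(rnorm(7, 0, 2), rnorm(7, 0, 2)), c(50, 0))
  per <- static_period(pts)
  cf <- cluster_frames(per, "dbscan", 2, 10)
  expect_true(all(cf$labels[, 8] == 0))
  expect_true(all(cf$labels[, 1:7] > 0))

  # chain spaced 4 m with threshold 5: one cluster by density reachability
  chain <- cbind(seq(0, 28, by = 4), 0)
  cfc <- cluster_frames(static_period(chain), "dbscan", 2, 5)
  expect_true(all(cfc$labels == 1))
  # brute-force reachability oracle: adjacency within eps, transitive closure
  D <- as.matrix(dist(chain)) <= 5
  reach <- D
  for (i in seq_len(nrow(D))) reach <- reach | (reach %*% reach > 0)
  expect_true(all(reach))
})

test_that("outlier metrics account time and distinct members", {
  pts <- rbind(cbind(rnorm(5, 0, 1), rnorm(5, 0, 1)), c(60, 0))
  per <- static_period(pts, n_t = 200)
  cf <- cluster_frames(per, "dbscan", 2, 10)
  om <- outlier_metrics(cf)
  expect_equal(unname(om$outlier_time[6]), 200)
  expect_equal(om$n_outliers, 1)

  noout <- static_period(cbind(rnorm(5), rnorm(5)))
  om0 <- outlier_metrics(cluster_frames(noout, "dbscan", 2, 10))
  expect_equal(sum(om0$outlier_time), 0)
  expect_equal(om0$n_outliers, 0)

  # relabeling invariance
  cf2 <- cf
  cf2$labels <- cf$labels[, c(2, 1, 3:6)]
  expect_equal(sum(outlier_metrics(cf2)$outlier_time),
               sum(om$outlier_time))
})

test_that("cluster consistency: static, flipping, single-cluster cases", {
  pts <- rbind(cbind(rnorm(4, 0, 1), rnorm(4)), cbind(rnorm(4, 50, 1),
                                                      rnorm(4)))
  expect_equal(cluster_consistency(cluster_frames(static_period(pts),
                                                  "dbscan", 2, 10)), 1)

  one <- static_period(cbind(rnorm(6, 0, 1), rnorm(6, 0, 1)))
  expect_equal(cluster_consistency(cluster_frames(one, "dbscan", 2, 10)), 1)

  # alternating partitions: agreement equals the ARI of the two labelings
  fr <- list(t = 1:4, dt = 1,
             labels = rbind(c(1, 1, 2, 2), c(1, 2, 1, 2),
                            c(1, 1, 2, 2), c(1, 2, 1, 2)))
  class(fr) <- "cluster_frames"
  # direct ARI of the two labelings via the contingency formula
  ari_direct <- flockr:::.adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(cluster_consistency(fr), ari_direct)
})

test_that("hdbscan-style confidence is defined only when clustered", {
  pts <- rbind(cbind(rnorm(6, 0, 2), rnorm(6, 0, 2)), c(80, 0))
  cf <- cluster_frames(static_period(pts), "hdbscan", 2, 10)
  expect_false(is.null(cf$confidence))
  expect_true(all(is.na(cf$confidence[cf$labels == 0])))
  expect_true(all(cf$confidence[cf$labels > 0] > 0 &
                    cf$confidence[cf$labels > 0] <= 1))
  cfd <- cluster_frames(static_period(pts), "dbscan", 2, 10)
  expect_null(cfd$confidence)
})

test_that("nearest neighbors match the all-pairs oracle", {
  # two members 7 m apart
  two <- static_period(cbind(c(0, 7), c(0, 0)))
  nn2 <- nearest_neighbor_features(two)
  expect_equal(unname(nn2$nn_dist[1, ]), c(7, 7))

  # single file spaced 3 m in PACS: NN_y 3, NN_x 0
  nT <- 10
  pc <- list(t = 1:nT, x = matrix(0.5, nT, 4),
             y = matrix(rep(c(0, 3, 6, 9), each = nT), nT, 4),
             member_ids = sprintf("m%02d", 1:4))
  per4 <- static_period(cbind(c(0, 3, 6, 9), 0.5), n_t = nT)
  nn4 <- nearest_neighbor_features(per4, pc)
  expect_equal(unname(nn4$nn_dy[1, ]), c(3, 3, 3, 3))
  expect_equal(unname(nn4$nn_dx[1, ]), c(0, 0, 0, 0))

  # random frame vs brute force
  set.seed(14)
  pts <- matrix(rnorm(12, 0, 10), 6, 2)
  nn6 <- nearest_neighbor_features(static_period(pts))
  D <- as.matrix(dist(pts)); diag(D) <- Inf
  expect_equal(unname(nn6$nn_dist[1, ]), unname(apply(D, 1, min)))
  # NN bounded by max pairwise distance
  expect_true(all(nn6$nn_dist <= max(D[is.finite(D)])))
})
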