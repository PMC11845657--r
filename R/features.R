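#' Extract the full group-level feature vector from one trajectory
#'
#' Runs the whole pipeline for one group: rest segmentation, movement
#' periods, PACS transform per period, then every feature family —
#' velocity-based, spatiotemporal, clustering (over a small parameter
#' grid), leadership, movement regularity, and doctrine compliance —
#' averaged over members and movement periods into one named numeric
#' vector suitable for [build_feature_table()].
#'
#' Features that need several movement periods (distribution consistency,
#' leadership instability, break regularity) come back `NA` when the
#' trajectory yields fewer; the VAR/VARX predictability features need
#' periods of at least `var_window` samples.
#'
#' @param traj a `group_trajectory`.
#' @param area_m2,min_duration_s rest-detection parameters.
#' @param trim_s,min_period_s movement-period parameters.
#' @param clustering_grid data.frame(min_cluster_size, distance_threshold)
#'   parameter grid (default sizes {2,3} x thresholds {5,10} m).
#' @param max_lag leadership lag bound, seconds.
#' @param var_window rolling predictability window (samples).
#' @return named numeric feature vector.
#' @export
extract_group_features <- function(traj, area_m2 = 100,
                                   min_duration_s = 120, trim_s = 30,
                                   min_period_s = 120,
                                   clustering_grid = expand.grid(
                                     min_cluster_size = c(2, 3),
                                     distance_threshold = c(5, 10)),
                                   max_lag = 10, var_window = 100) {
  rests <- detect_group_rests(traj, area_m2, min_duration_s)
  periods <- extract_movement_periods(traj, rests, trim_s, min_period_s)
  if (!length(periods)) stop("no usable movement periods")
  pacs_list <- lapply(periods, function(p) pacs_transform(p))

  per_period <- lapply(seq_along(periods), function(pi) {
    p <- periods[[pi]]; pc <- pacs_list[[pi]]
    kin <- summarize_kinematics(compute_kinematics(p))
    si <- stretch_index(p)
    hv <- hull_voronoi_features(p)
    lw <- length_width_ratio(pc)
    sei <- spatial_exploration_index(pc)
    nn <- nearest_neighbor_features(p, pc)
    clu <- unlist(lapply(seq_len(nrow(clustering_grid)), function(g) {
      k <- clustering_grid$min_cluster_size[g]
      e <- clustering_grid$distance_threshold[g]
      fr <- cluster_frames(p, "hdbscan", k, e)
      om <- outlier_metrics(fr)
      cons <- cluster_consistency(fr)
      conf <- mean(fr$confidence[fr$labels > 0])
      stats::setNames(
        c(mean(om$outlier_time), om$n_outliers, cons, conf),
        sprintf("clu.k%d.e%d.%s", k, e,
                c("outlier_time", "n_outliers", "consistency",
                  "confidence")))
    }))
    hier <- build_hierarchy(p, max_lag = max_lag)
    hq <- hierarchy_quality(hier)
    spd <- compute_kinematics(p)$speed
    cl <- column_length(pc)
    loc_ent <- mean(vapply(seq_along(pc$member_ids), function(k)
      location_entropy(pc$x[, k], pc$y[, k]), 0))
    nT <- length(p$traj$t)
    ve <- vxe <- NA_real_
    if (nT >= var_window) {
      pos_list <- lapply(seq_along(p$traj$member_ids), function(k)
        p$traj$pos[, k, ])
      ve <- mean(vapply(pos_list, function(pp)
        as.numeric(var_error(pp, window = var_window,
                             train = var_window - 5)), 0))
      vxe <- mean(vapply(seq_along(pos_list), function(k) {
        ex <- do.call(cbind, pos_list[-k])
        as.numeric(varx_error(pos_list[[k]], ex, window = var_window,
                              train = var_window - 5))
      }, 0))
    }
    c(kin,
      spat.stretch.mean = si$mean, spat.stretch.entropy = si$entropy,
      hv$features,
      spat.lw_ratio.mean = lw$mean, spat.lw_ratio.entropy = lw$entropy,
      spat.sei.mean = mean(sei),
      nn$features,
      clu,
      lead.score.sd = stats::sd(hier$scores),
      lead.delay.mean_abs = mean(abs(hier$edges$delay), na.rm = TRUE),
      lead.downward_ratio = hq$downward_ratio,
      lead.loops = hq$loop_count,
      reg.loc_entropy = loc_ent,
      reg.var_error = ve,
      reg.varx_error = vxe,
      doc.pace_ratio = reasonable_pace_ratio(spd),
      doc.spacing_ratio = spacing_compliance(nn$nn_dist),
      doc.column_len.mean = cl$mean,
      doc.column_len.max = cl$max)
  })
  feats <- colMeans(do.call(rbind, per_period), na.rm = FALSE)
  # cross-period features
  dc <- if (length(pacs_list) >= 2) distribution_consistency(pacs_list)
  else NULL
  feats <- c(feats,
             spat.consistency.f_x = if (is.null(dc)) NA_real_ else
               mean(dc$f_x, na.rm = TRUE),
             spat.consistency.f_y = if (is.null(dc)) NA_real_ else
               mean(dc$f_y, na.rm = TRUE),
             spat.consistency.w_x = if (is.null(dc)) NA_real_ else
               mean(dc$w_x, na.rm = TRUE),
             spat.consistency.w_y = if (is.null(dc)) NA_real_ else
               mean(dc$w_y, na.rm = TRUE))
  graphs <- if (length(periods) >= 2)
    lapply(periods, build_hierarchy, max_lag = max_lag) else NULL
  li <- if (is.null(graphs)) NULL else
    suppressMessages(leadership_instability(graphs))
  feats <- c(feats, lead.instability = if (is.null(li)) NA_real_ else li)
  br <- suppressMessages(break_regularity(rests))
  feats <- c(feats,
             doc.break_onset_sd = if (is.null(br)) NA_real_ else
               br$sd_onset_interval,
             doc.break_dur_sd = if (is.null(br)) NA_real_ else
               br$sd_duration)
  feats
}
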