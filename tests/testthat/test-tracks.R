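mk_track <- function(xy, dt = 1, id = "c1") {
  data.frame(track_id = id, t_min = (seq_len(nrow(xy)) - 1) * dt,
             x_um = xy[, 1], y_um = xy[, 2])
}

test_that("speeds follow the displacement/interval definition", {
  tr <- mk_track(rbind(c(0, 0), c(3, 4), c(3, 4)))
  sp <- track_speeds(tr)
  expect_equal(sp$v_inst, c(5, 0))
  expect_equal(sp$v_av, 2.5)
  # average speed equals the mean instantaneous speed at uniform dt
  set.seed(2)
  tr2 <- mk_track(matrix(cumsum(rnorm(40)), ncol = 2), dt = 2)
  sp2 <- track_speeds(tr2)
  expect_equal(sp2$v_av, mean(sp2$v_inst))
  expect_error(track_speeds(tr[1, , drop = FALSE]), "2 points")
})

test_that("duration filter keeps 'at least' boundary tracks", {
  recs <- do.call(rbind, lapply(1:3, function(i) {
    n <- c(10, 11, 13)[i]   # durations 90, 100, 120 at dt = 10
    data.frame(track_id = paste0("c", i), t_min = (0:(n - 1)) * 10,
               x_um = 0, y_um = 0)
  }))
  ts <- track_set(recs, dt = 10)
  kept <- filter_tracks(ts, min_duration = 100)
  expect_setequal(unique(kept$track_id), c("c2", "c3"))
  expect_equal(unname(attr(kept, "filter_counts")["kept"]), 2L)
  # identity at 0; empty set stays empty
  expect_equal(nrow(filter_tracks(ts, 0)), nrow(ts))
  expect_equal(nrow(filter_tracks(kept[0, ], 100)), 0L)
})

test_that("tracks with temporal gaps are split, not interpolated", {
  df <- data.frame(track_id = "g", t_min = c(0, 1, 2, 5, 6),
                   x_um = c(0, 1, 2, 10, 11), y_um = 0)
  ts <- track_set(df, dt = 1)
  expect_equal(length(unique(ts$track_id)), 2L)
  sp <- lapply(split(as.data.frame(ts), ts$track_id), track_speeds)
  expect_true(all(unlist(lapply(sp, `[[`, "v_inst")) == 1))
})

test_that("MSD matches the ballistic closed form and the brute-force
           oracle", {
  # straight track at 2 um/min
  tr <- mk_track(cbind(2 * (0:10), 0))
  m <- msd_curve(tr, dt = 1)
  expect_equal(m$msd_um2[m$lag_min == 3], 36)
  expect_equal(m$msd_um2, (2 * m$lag_min)^2)
  # stationary
  m0 <- msd_curve(mk_track(cbind(rep(1, 6), rep(2, 6))), dt = 1)
  expect_true(all(m0$msd_um2 == 0))
  # oracle equality on random tracks
  set.seed(31)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    pos <- matrix(cumsum(rnorm(2 * n)), ncol = 2)
    tr <- mk_track(pos, dt = 2)
    m <- msd_curve(tr, max_lag = n - 1, dt = 2)
    expect_equal(m$msd_um2, msd_oracle(pos, 2, n - 1))
  }
})

test_that("pooled MSD recovers the diffusion coefficient of Brownian
           tracks", {
  set.seed(7)
  sigma <- 1.2; dt <- 1
  recs <- do.call(rbind, lapply(1:200, function(i)
    mk_track(matrix(cumsum(rnorm(200, sd = sigma)), ncol = 2),
             dt = dt, id = paste0("c", i))))
  ts <- track_set(recs, dt = dt)
  m <- msd_curve(ts, max_lag = 8)
  slope <- coef(lm(msd_um2 ~ 0 + lag_min, data = m))[[1]]
  expect_lt(abs(slope - 2 * sigma^2 / dt) / (2 * sigma^2 / dt), 0.15)
})

test_that("idling decomposition partitions intervals and respects the
           strict threshold", {
  tr <- mk_track(rbind(c(0, 0), c(0.5, 0), c(1, 0), c(4, 0), c(7, 0)))
  dec <- idling_decomposition(tr, threshold = 1.5)
  expect_equal(dec$rel_idling, 50)
  expect_equal(dec$v_inst_idle_mean, 0.5)
  expect_equal(dec$v_inst_act_mean, 3)
  expect_equal(dec$n_idle + dec$n_active, length(dec$v_inst))
  # weighted phase means recompose the overall mean
  overall <- (dec$n_idle * dec$v_inst_idle_mean +
                dec$n_active * dec$v_inst_act_mean) /
    (dec$n_idle + dec$n_active)
  expect_equal(overall, mean(dec$v_inst))
  # boundary: speed exactly at threshold is active (strictly-less idles)
  trb <- mk_track(rbind(c(0, 0), c(1.5, 0), c(3, 0)))
  expect_equal(idling_decomposition(trb, 1.5)$rel_idling, 0)
  # all-idle: active mean absent
  still <- mk_track(cbind(rep(0, 5), 0))
  ds <- idling_decomposition(still, 1.5)
  expect_equal(ds$rel_idling, 100)
  expect_true(is.na(ds$v_inst_act_mean))
  expect_error(idling_decomposition(tr, threshold = 0), "threshold")
})

test_that("relative idling is monotone in the threshold with limits 0 and
           100", {
  set.seed(11)
  tr <- mk_track(matrix(cumsum(rnorm(60)), ncol = 2))
  thetas <- c(1e-6, 0.5, 1, 2, 5, 1e6)
  ri <- vapply(thetas, function(th)
    idling_decomposition(tr, th)$rel_idling, numeric(1))
  expect_equal(ri[1], 0)
  expect_equal(ri[length(ri)], 100)
  expect_true(all(diff(ri) >= 0))
})

test_that("saltatory cohort parameters are recovered from truth-labelled
           tracks", {
  g <- gen_saltatory_tracks(n_tracks = 50, n_frames = 36, dt = 10,
                            v_active = 3, v_idle = 0.3, p_idle = 0.6,
                            seed = 1)
  mot <- motility_metrics(g$tracks, threshold = 1.5)
  pooled <- attr(mot, "pooled_rel_idling")
  expect_equal(pooled, 100 * mean(g$truth$idle))   # exact: no noise
  expect_lt(abs(pooled - 60), 5)
  expect_lt(abs(mean(mot$v_inst_act_mean, na.rm = TRUE) - 3) / 3, 0.10)
  expect_lt(abs(mean(mot$v_inst_idle_mean, na.rm = TRUE) - 0.3) / 0.3, 0.15)
})

test_that("high-active classification uses a strict cutoff and feeds
           Fisher's test", {
  tab <- classify_high_active(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                              cutoff = 2.5)
  expect_equal(sum(tab[, "high"]), 2L)
  expect_equal(unname(tab["a", ]), c(0L, 2L))
  # boundary value 2.5 itself is not "high"
  tab2 <- classify_high_active(c(2.5, 3), c("a", "b"))
  expect_equal(unname(tab2["a", "high"]), 0L)
  all_low <- classify_high_active(c(1, 2), c("a", "b"))
  expect_true(all(all_low[, "high"] == 0))
  p <- fisher_exact(tab)
  expect_equal(p$p, fisher_oracle(tab))
  expect_error(classify_high_active(1:3, c("a", "b", "c")), "two groups")
})

test_that("lesion extension speeds: uniform motion, per-cell averaging,
           post-arrival decay", {
  lt <- gen_lesion_tracks(n_tips = 9, start_radius = 40, v_ext = 2, dt = 1,
                          n_frames = 16, tips_per_cell = 3, seed = 2)
  res <- lesion_extension_speed(lt, duration = 15)
  expect_equal(res$per_cell$v_av, rep(2, 3), tolerance = 1e-9)
  expect_equal(res$per_cell$n_tips, rep(3L, 3))
  expect_equal(res$v_inst_curve$mean, rep(2, 15), tolerance = 1e-9)

  # tips reach the boundary and hold: late instantaneous speeds drop to 0
  lt2 <- gen_lesion_tracks(n_tips = 4, start_radius = 12, v_ext = 2, dt = 1,
                           n_frames = 16, lesion_radius = 5, seed = 3)
  res2 <- lesion_extension_speed(lt2, duration = 15)
  curve <- res2$v_inst_curve
  expect_equal(curve$mean[curve$t_min > 4], rep(0, sum(curve$t_min > 4)),
               tolerance = 1e-9)
  # mean over tips: construct one cell with tips at speeds 1 and 3
  t_min <- 0:5
  df <- rbind(
    data.frame(track_id = "t1", cell_id = "c", t_min = t_min,
               x_um = 20 - 1 * t_min, y_um = 0),
    data.frame(track_id = "t2", cell_id = "c", t_min = t_min,
               x_um = 0, y_um = 25 - 3 * t_min))
  ts <- track_set(df, dt = 1, lesion_center = c(0, 0), kind = "process-tip")
  r <- lesion_extension_speed(ts, duration = 5)
  expect_equal(r$per_cell$v_av, 2)
  ts_nc <- track_set(df, dt = 1, kind = "process-tip")
  expect_error(lesion_extension_speed(ts_nc), "lesion_center")
})

test_that("MSD-derived idling threshold is advisory and flags ballistic
           sets", {
  # pure-idle cohort: estimate near the idle speed, below the default
  g <- gen_saltatory_tracks(n_tracks = 20, n_frames = 30, dt = 10,
                            v_active = 3, v_idle = 0.3, p_idle = 0.999,
                            p_switch = 0, seed = 5)
  est <- estimate_idling_threshold(g$tracks)
  expect_lt(abs(est$estimate - 0.3), 0.1)
  expect_lt(est$estimate, 1.5)
  expect_false(est$flagged)
  expect_equal(est$threshold, 1.5)

  # ballistic cohort: flagged
  recs <- do.call(rbind, lapply(1:12, function(i) {
    th <- i
    mk_track(cbind(2 * (0:20) * cos(th), 2 * (0:20) * sin(th)),
             dt = 1, id = paste0("b", i))
  }))
  bal <- estimate_idling_threshold(track_set(recs, dt = 1))
  expect_true(bal$flagged)
  expect_error(estimate_idling_threshold(track_set(recs[recs$track_id %in%
    paste0("b", 1:3), ], dt = 1)), "10 tracks")
})
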