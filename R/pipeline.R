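#' Run the full synthetic demonstration pipeline
#'
#' Generates one dataset with every synthetic generator (ramified
#' skeletons, a motility movie, saltatory soma tracks, lesion-response
#' tip tracks, and a two-group phagocytosis time course), writes the raw
#' inputs in their standard formats (SWC, TIFF, CSV), reads them back,
#' runs every analysis stage, and writes the metric tables and a
#' statistics report as CSV. This is the programmatic core of the
#' `morphodyn pipeline` command-line entry point.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_cells skeletons to generate for the morphology table.
#' @param quiet suppress progress messages.
#' @return (invisibly) a named list of the output file paths and the
#'   in-memory result tables.
#' @export
run_demo_pipeline <- function(out_dir, seed = 1, n_cells = 20,
                              quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()

  ## morphology: skeletons per genotype-like group ------------------------
  say("generating skeletons + morphometrics ...")
  swc_dir <- file.path(out_dir, "swc")
  dir.create(swc_dir, showWarnings = FALSE)
  morph_rows <- list()
  for (i in seq_len(n_cells)) {
    grp <- if (i <= n_cells / 2) "WT" else "KO"
    # knockout-like cells: fewer, shorter processes
    bp <- if (grp == "WT") 0.35 else 0.15
    depth <- if (grp == "WT") 6 else 4
    gt <- gen_random_tree(n_primary = 4, branch_prob = bp,
                          seg_length_range = c(2, 6), max_depth = depth,
                          seed = seed * 1000 + i)
    f <- file.path(swc_dir, sprintf("cell_%02d_%s.swc", i, grp))
    write_swc(gt$skeleton, f)
    sk <- read_swc(f)
    m <- morphometrics(sk)
    morph_rows[[i]] <- data.frame(cell = basename(f), group = grp,
                                  total_length = m$total_length,
                                  n_tips = m$n_tips,
                                  n_branch_points = m$n_branch_points,
                                  max_intersections = m$max_intersections,
                                  max_radius = m$max_radius)
  }
  morph <- do.call(rbind, morph_rows)
  paths$morphometrics <- file.path(out_dir, "morphometrics.csv")
  utils::write.csv(morph, paths$morphometrics, row.names = FALSE)

  ## surveillance ---------------------------------------------------------
  say("generating motility movie + surveillance ...")
  mm <- gen_motility_movie(canvas = c(64, 64), pixel_size = 0.5,
                           n_frames = 11, dt = 1, growth_px_per_frame = 10,
                           seed = seed + 1)
  paths$movie <- file.path(out_dir, "motility_movie.tif")
  write_movie_tiff(mm$movie, paths$movie)
  bm <- read_movie_tiff(paths$movie, pixel_size = 0.5, frame_interval = 1)
  surv <- surveillance_area(bm, window = 10)
  surv_df <- data.frame(pair = seq_along(surv$per_pair_um2),
                        changed_area_um2 = surv$per_pair_um2)
  paths$surveillance <- file.path(out_dir, "surveillance.csv")
  utils::write.csv(surv_df, paths$surveillance, row.names = FALSE)

  ## saltatory migration --------------------------------------------------
  say("generating migration tracks + idling decomposition ...")
  wt <- gen_saltatory_tracks(n_tracks = 25, n_frames = 36, dt = 10,
                             v_active = 3, v_idle = 0.3, p_idle = 0.6,
                             seed = seed + 2)
  ko <- gen_saltatory_tracks(n_tracks = 25, n_frames = 36, dt = 10,
                             v_active = 2.4, v_idle = 0.5, p_idle = 0.6,
                             seed = seed + 3)
  wt_df <- as.data.frame(wt$tracks); ko_df <- as.data.frame(ko$tracks)
  wt_df$group <- "WT"; ko_df$group <- "cKO"
  wt_df$track_id <- paste0("WT_", wt_df$track_id)
  ko_df$track_id <- paste0("cKO_", ko_df$track_id)
  ts <- track_set(rbind(wt_df, ko_df), dt = 10)
  paths$tracks <- file.path(out_dir, "tracks.csv")
  write_tracks_csv(ts, paths$tracks)
  ts <- read_tracks_csv(paths$tracks, dt = 10)
  ts <- filter_tracks(ts, min_duration = 100)
  mot <- motility_metrics(ts, threshold = 1.5)
  paths$motility <- file.path(out_dir, "motility_metrics.csv")
  utils::write.csv(mot, paths$motility, row.names = FALSE)
  tab <- classify_high_active(mot$v_inst_act_mean, mot$group, cutoff = 2.5)
  fish <- fisher_exact(tab)

  ## lesion response ------------------------------------------------------
  say("generating lesion-response tracks + extension speeds ...")
  lt <- gen_lesion_tracks(n_tips = 12, start_radius = 40, v_ext = 2,
                          dt = 1, n_frames = 16, seed = seed + 4)
  les <- lesion_extension_speed(lt, duration = 15)
  paths$lesion <- file.path(out_dir, "lesion_extension.csv")
  utils::write.csv(les$per_cell, paths$lesion, row.names = FALSE)
  paths$lesion_curve <- file.path(out_dir, "lesion_vinst_curve.csv")
  utils::write.csv(les$v_inst_curve, paths$lesion_curve, row.names = FALSE)

  ## phagocytosis time course --------------------------------------------
  say("generating phagocytosis events + time course ...")
  tps <- c(10, 30, 120)
  ev <- list()
  sid <- 0
  for (tp in tps) {
    sid <- sid + 1
    ev[[length(ev) + 1]] <- gen_cytometry_events(
      n_events = 2000, pos_fraction = 0, sample = paste0("ctrl_t", tp),
      pos_log_mu = 6, group = "control", timepoint_min = tp,
      is_control = TRUE, seed = seed * 100 + sid)$events
    for (g in c("WT", "KO")) for (r in 1:5) {
      sid <- sid + 1
      pf <- switch(g, WT = 0.15 + 0.1 * match(tp, tps),
                   KO = 0.2 + 0.13 * match(tp, tps))
      ev[[length(ev) + 1]] <- gen_cytometry_events(
        n_events = 2000, pos_fraction = pf,
        sample = sprintf("%s_t%d_r%d", g, tp, r), group = g,
        timepoint_min = tp, is_control = FALSE,
        seed = seed * 100 + sid)$events
    }
  }
  events <- do.call(rbind, ev)
  paths$events <- file.path(out_dir, "events.csv")
  utils::write.csv(events, paths$events, row.names = FALSE)
  events <- utils::read.csv(paths$events, stringsAsFactors = FALSE)
  phago <- phagocytosis_timecourse(events)
  paths$phago <- file.path(out_dir, "phagocytosis_timecourse.csv")
  utils::write.csv(phago$summary, paths$phago, row.names = FALSE)

  ## statistics report ----------------------------------------------------
  say("writing statistics report ...")
  rep <- rbind(
    stats_report(morph, "total_length"),
    stats_report(morph, "n_tips"),
    stats_report(mot, "v_av"),
    stats_report(mot, "rel_idling"),
    stats_report(mot, "v_inst_act_mean"))
  rep$p_adjusted <- NA
  if (!is.null(phago$tests)) {
    pt <- data.frame(metric = paste0("pct_positive_t", phago$tests$timepoint_min),
                     group1 = phago$tests$group1, group2 = phago$tests$group2,
                     n1 = NA, n2 = NA, test = "mann-whitney",
                     statistic = phago$tests$U, p = phago$tests$p,
                     p_adjusted = phago$tests$p_adjusted)
    rep <- rbind(rep, pt)
  }
  rep <- rbind(rep, data.frame(metric = "high_active_fraction",
                               group1 = rownames(tab)[1],
                               group2 = rownames(tab)[2],
                               n1 = sum(tab[1, ]), n2 = sum(tab[2, ]),
                               test = "fisher", statistic = fish$odds_ratio,
                               p = fish$p, p_adjusted = NA))
  paths$stats <- file.path(out_dir, "stats_report.csv")
  utils::write.csv(rep, paths$stats, row.names = FALSE)
  say("done: ", out_dir)
  invisible(list(paths = paths, morphometrics = morph, surveillance = surv,
                 motility = mot, high_active_table = tab, lesion = les,
                 phagocytosis = phago, stats = rep))
}

#' Read a binary-mask TIFF movie
#'
#' Convenience reader for 0/255 mask movies written by
#' [write_movie_tiff()].
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval calibration (um/px, min).
#' @return a [binary_movie()].
#' @export
read_movie_tiff <- function(path, pixel_size, frame_interval) {
  st <- read_stack_tiff(path, pixel_size, frame_interval, axes = "tyx")
  masks <- st$data[, 1, , , drop = FALSE]
  dim(masks) <- dim(masks)[c(1, 3, 4)]
  binary_movie(masks > 0, pixel_size, frame_interval)
}
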