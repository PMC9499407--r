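#' Track sets
#'
#' A `track_set` is a long-format table of time-stamped positions in
#' micrometres, one row per (track, frame): columns `track_id`, `t_min`,
#' `x_um`, `y_um` and optionally `z_um`, `group`, `cell_id`, `frame`.
#' All tracks share one frame interval `dt`; tracks with missing frames
#' are split into gap-free segments on construction (speed between
#' non-consecutive time points is not an instantaneous speed). Positions
#' are used in 3D whenever a `z_um` column is present.
#'
#' @param df data frame of track points (see above; MTrackJ-style
#'   exports with columns `track_id`, `t`/`t_min`, `x`/`x_um`, ... are
#'   normalized).
#' @param dt frame interval in minutes; inferred from the data when
#'   omitted.
#' @param lesion_center optional (x, y) um position of a lesion centre.
#' @param kind "soma" or "process-tip".
#' @return an object of class `track_set` (a data frame with attributes
#'   `dt`, `lesion_center`, `kind`).
#' @export
track_set <- function(df, dt = NULL, lesion_center = NULL,
                      kind = c("soma", "process-tip")) {
  kind <- match.arg(kind)
  df <- as.data.frame(df)
  alias <- c(t = "t_min", x = "x_um", y = "y_um", z = "z_um", id = "track_id")
  for (a in names(alias))
    if (a %in% names(df) && !(alias[[a]] %in% names(df)))
      names(df)[names(df) == a] <- alias[[a]]
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track table needs columns ", paste(need, collapse = ", "))
  df <- df[order(df$track_id, df$t_min), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(dt)) {
    steps <- unlist(tapply(df$t_min, df$track_id, diff, simplify = FALSE))
    if (!length(steps)) stop("cannot infer dt from single-point tracks")
    dt <- min(steps)
  }
  if (dt <= 0) stop("'dt' must be > 0")
  # split tracks at temporal gaps into gap-free segments
  seg_of <- function(t) cumsum(c(0, abs(diff(t) - dt) > 1e-6 * max(dt, 1)))
  segs <- unlist(tapply(df$t_min, df$track_id, seg_of, simplify = FALSE))
  df$.segment <- segs
  nseg <- tapply(df$.segment, df$track_id, max)
  if (any(nseg > 0)) {
    split_ids <- names(nseg)[nseg > 0]
    sel <- df$track_id %in% split_ids
    df$track_id[sel] <- paste0(df$track_id[sel], ".seg", df$.segment[sel] + 1)
  }
  df$.segment <- NULL
  structure(df, class = c("track_set", "data.frame"),
            dt = dt, lesion_center = lesion_center, kind = kind)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set (%s): %d tracks, %d points, dt %.3g min%s\n",
              attr(x, "kind"), length(unique(x$track_id)), nrow(x),
              attr(x, "dt"),
              if (!is.null(attr(x, "lesion_center"))) ", lesion at (" %+%
                paste(attr(x, "lesion_center"), collapse = ", ") %+% ") um"
              else ""))
  invisible(x)
}

`%+%` <- function(a, b) paste0(a, b)

#' Read track tables from CSV
#'
#' @param path CSV with MTrackJ-convention columns (track_id, t/t_min,
#'   x/x_um, y/y_um[, z_um, group, cell_id]).
#' @param ... passed to [track_set()].
#' @return a [track_set()].
#' @export
read_tracks_csv <- function(path, ...) {
  track_set(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @rdname read_tracks_csv
#' @param ts a [track_set()].
#' @export
write_tracks_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

track_list <- function(ts) split(as.data.frame(ts), ts$track_id)

track_positions <- function(track) {
  cols <- c("x_um", "y_um", if ("z_um" %in% names(track)) "z_um")
  as.matrix(track[order(track$t_min), cols, drop = FALSE])
}

#' Duration filter for tracks
#'
#' Keeps tracks observed for at least `min_duration` minutes
#' (inclusive: a track spanning exactly the minimum is kept). Cells
#' leaving the field of view early are thereby excluded.
#'
#' @param ts a [track_set()].
#' @param min_duration minimum track duration in minutes (default 100).
#' @return the filtered [track_set()]; attribute `filter_counts` holds
#'   kept/dropped counts.
#' @export
filter_tracks <- function(ts, min_duration = 100) {
  stopifnot(inherits(ts, "track_set"))
  dur <- tapply(ts$t_min, ts$track_id, function(t) max(t) - min(t))
  keep_ids <- names(dur)[dur >= min_duration]
  out <- ts[ts$track_id %in% keep_ids, , drop = FALSE]
  res <- structure(out, class = class(ts), dt = attr(ts, "dt"),
                   lesion_center = attr(ts, "lesion_center"),
                   kind = attr(ts, "kind"))
  attr(res, "filter_counts") <- c(kept = length(keep_ids),
                                  dropped = length(dur) - length(keep_ids))
  res
}

#' Average and instantaneous speeds of one track
#'
#' Instantaneous speed is the Euclidean displacement between consecutive
#' time points divided by the frame interval; average speed is the total
#' path length divided by the track duration (equal to the mean
#' instantaneous speed for uniformly sampled tracks).
#'
#' @param track data frame of one track's points (as in [track_set()]).
#' @return list with `v_av` (um/min), `v_inst` (um/min per interval),
#'   `t_mid` (interval mid-times, min).
#' @export
track_speeds <- function(track) {
  track <- track[order(track$t_min), , drop = FALSE]
  if (nrow(track) < 2) stop("track needs at least 2 points")
  p <- track_positions(track)
  d <- unname(sqrt(rowSums(diff(p)^2)))
  dtv <- diff(track$t_min)
  list(v_av = sum(d) / (max(track$t_min) - min(track$t_min)),
       v_inst = d / dtv,
       t_mid = (track$t_min[-1] + track$t_min[-nrow(track)]) / 2)
}

#' Time-averaged mean squared displacement
#'
#' MSD(k dt) is the mean over all overlapping origins t of
#' squared displacement between t and t + k dt. For a `track_set`,
#' displacement pairs are pooled across tracks (each lag's mean is
#' weighted by its pair count).
#'
#' @param x one track (data frame) or a [track_set()].
#' @param max_lag maximum lag in frames; default `n_frames - 1` (per
#'   track).
#' @param dt frame interval in minutes (taken from the `track_set`
#'   attribute when available).
#' @return object of class `msd_curve`: data frame with `lag_min`,
#'   `msd_um2`, `n_pairs`.
#' @export
msd_curve <- function(x, max_lag = NULL, dt = attr(x, "dt")) {
  tracks <- if (inherits(x, "track_set")) track_list(x) else list(x)
  if (is.null(dt)) dt <- min(diff(sort(unique(tracks[[1]]$t_min))))
  acc <- new.env()
  for (tr in tracks) {
    p <- track_positions(tr[order(tr$t_min), , drop = FALSE])
    n <- nrow(p)
    ml <- if (is.null(max_lag)) n - 1 else min(max_lag, n - 1)
    for (k in seq_len(ml)) {
      disp2 <- rowSums((p[(1 + k):n, , drop = FALSE] -
                          p[1:(n - k), , drop = FALSE])^2)
      key <- as.character(k)
      prev <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0)
      acc[[key]] <- prev + c(sum(disp2), length(disp2))
    }
  }
  lags <- sort(as.integer(ls(acc)))
  msd <- vapply(lags, function(k) {
    v <- acc[[as.character(k)]]; v[1] / v[2]
  }, numeric(1))
  npairs <- vapply(lags, function(k) acc[[as.character(k)]][2], numeric(1))
  structure(data.frame(lag_min = lags * dt, msd_um2 = msd, n_pairs = npairs),
            class = c("msd_curve", "data.frame"))
}

#' Idling / active phase decomposition of a track
#'
#' Intervals whose instantaneous speed falls strictly below the idling
#' threshold are idling; the rest are active migration. Relative idling
#' time is the percentage of intervals spent idling. Phase-specific mean
#' instantaneous speeds are reported; a phase that never occurs yields
#' `NA` (absent), not zero. The default threshold of 1.5 um/min (the
#' same quantity as 15 um per 10 min) is the MSD-derived idling cut-off
#' used for embryonic cortical microglia.
#'
#' @param track one track's points (data frame).
#' @param threshold idling threshold in um/min (> 0), default 1.5.
#' @return list with `v_av`, `v_inst`, `rel_idling` (%), `v_inst_idle_mean`,
#'   `v_inst_act_mean`, `n_idle`, `n_active`, `threshold_used`.
#' @export
idling_decomposition <- function(track, threshold = 1.5) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be > 0")
  sp <- track_speeds(track)
  idle <- sp$v_inst < threshold
  list(v_av = sp$v_av,
       v_inst = sp$v_inst,
       rel_idling = 100 * mean(idle),
       v_inst_idle_mean = if (any(idle)) mean(sp$v_inst[idle]) else NA_real_,
       v_inst_act_mean = if (any(!idle)) mean(sp$v_inst[!idle]) else NA_real_,
       n_idle = sum(idle), n_active = sum(!idle),
       threshold_used = threshold)
}

#' Per-cell motility metrics for a track set
#'
#' Applies [idling_decomposition()] to every track and returns one row
#' per cell -- the unit of downstream statistical analysis -- plus the
#' pooled idling fraction over all intervals as an attribute.
#'
#' @param ts a [track_set()].
#' @param threshold idling threshold in um/min.
#' @return data frame (track_id, group, n_intervals, v_av, rel_idling,
#'   v_inst_idle_mean, v_inst_act_mean); attribute `pooled_rel_idling`.
#' @export
motility_metrics <- function(ts, threshold = 1.5) {
  stopifnot(inherits(ts, "track_set"))
  rows <- lapply(track_list(ts), function(tr) {
    dec <- idling_decomposition(tr, threshold)
    data.frame(track_id = tr$track_id[1],
               group = if ("group" %in% names(tr)) tr$group[1] else NA,
               n_intervals = dec$n_idle + dec$n_active,
               v_av = dec$v_av, rel_idling = dec$rel_idling,
               v_inst_idle_mean = dec$v_inst_idle_mean,
               v_inst_act_mean = dec$v_inst_act_mean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pooled_rel_idling") <-
    sum(out$rel_idling / 100 * out$n_intervals) / sum(out$n_intervals) * 100
  attr(out, "threshold_used") <- threshold
  out
}

#' Classify cells by high active-migration speed
#'
#' Splits cells of two groups at a cutoff on their mean active-phase
#' instantaneous speed (strictly greater counts as "high"), yielding the
#' 2x2 contingency table for Fisher's exact test.
#'
#' @param active_means numeric vector of per-cell active-phase mean
#'   speeds (um/min); `NA` (no active phase) counts as not-high.
#' @param groups factor/character of the same length with exactly 2
#'   levels.
#' @param cutoff um/min, default 2.5.
#' @return 2x2 integer matrix (rows = groups, cols = c("high", "not_high")).
#' @export
classify_high_active <- function(active_means, groups, cutoff = 2.5) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (length(active_means) != length(groups))
    stop("'active_means' and 'groups' lengths differ")
  high <- !is.na(active_means) & active_means > cutoff
  tab <- table(groups, factor(ifelse(high, "high", "not_high"),
                              levels = c("high", "not_high")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(levels(groups), c("high", "not_high")))
  m
}

#' Lesion-directed process-extension speeds
#'
#' For a set of process-tip tracks converging on a lesion, computes per
#' tip the average and instantaneous extension speed over the first
#' `duration` minutes, averages tips within each parent cell, and
#' reports the population instantaneous-speed time course (mean +- SEM
#' across cells at each time point).
#'
#' @param ts a [track_set()] of kind "process-tip" with a `cell_id`
#'   column.
#' @param duration analysis window in minutes from each track's start
#'   (default 15).
#' @param require_center error when no lesion centre is attached
#'   (directional interpretation requested).
#' @return list with `per_cell` (cell_id, n_tips, v_av), `per_tip`,
#'   and `v_inst_curve` (t_min, mean, sem, n_cells).
#' @export
lesion_extension_speed <- function(ts, duration = 15, require_center = TRUE) {
  stopifnot(inherits(ts, "track_set"))
  if (require_center && is.null(attr(ts, "lesion_center")))
    stop("track set has no lesion_center")
  if (!"cell_id" %in% names(ts)) stop("'cell_id' column required")
  per_tip <- list(); inst <- list()
  for (tr in track_list(ts)) {
    t0 <- min(tr$t_min)
    sub <- tr[tr$t_min <= t0 + duration + 1e-9, , drop = FALSE]
    if (nrow(sub) < 2) next
    sp <- track_speeds(sub)
    per_tip[[length(per_tip) + 1]] <-
      data.frame(track_id = tr$track_id[1], cell_id = tr$cell_id[1],
                 v_av = sp$v_av)
    inst[[length(inst) + 1]] <-
      data.frame(cell_id = tr$cell_id[1], t_min = sp$t_mid - t0,
                 v_inst = sp$v_inst)
  }
  per_tip <- do.call(rbind, per_tip)
  per_cell <- do.call(rbind, lapply(split(per_tip, per_tip$cell_id),
    function(d) data.frame(cell_id = d$cell_id[1], n_tips = nrow(d),
                           v_av = mean(d$v_av))))
  rownames(per_cell) <- NULL
  inst <- do.call(rbind, inst)
  # mean per cell per time point first, then mean +- SEM across cells
  cellmean <- stats::aggregate(v_inst ~ cell_id + t_min, inst, mean)
  curve <- do.call(rbind, lapply(split(cellmean, cellmean$t_min), function(d)
    data.frame(t_min = d$t_min[1], mean = mean(d$v_inst),
               sem = stats::sd(d$v_inst) / sqrt(nrow(d)),
               n_cells = nrow(d))))
  rownames(curve) <- NULL
  list(per_cell = per_cell, per_tip = per_tip, v_inst_curve = curve)
}

#' Advisory MSD-based idling threshold
#'
#' Fits the pooled short-lag MSD to the diffusive form
#' MSD(tau) = 4 D tau + c and converts the fitted one-frame displacement
#' scale sqrt(MSD_fit(dt)) / dt into a candidate idling threshold. The
#' estimate is advisory: it is reported alongside, and never silently
#' replaces, the configured default of 1.5 um/min. Ballistic curvature
#' (MSD(2 dt) / MSD(dt) well above the diffusive ratio of 2) flags the
#' estimate as unreliable.
#'
#' @param ts a [track_set()] with >= 10 tracks.
#' @param n_lags number of short lags used in the linear fit.
#' @param default configured threshold returned as `threshold` (um/min).
#' @return list with `estimate` (um/min or NA), `flagged` (ballistic
#'   curvature), `threshold` (the configured default), `msd_fit`
#'   (coefficients).
#' @export
estimate_idling_threshold <- function(ts, n_lags = 4, default = 1.5) {
  stopifnot(inherits(ts, "track_set"))
  if (length(unique(ts$track_id)) < 10)
    stop("at least 10 tracks required")
  dt <- attr(ts, "dt")
  est <- tryCatch({
    m <- msd_curve(ts, max_lag = n_lags)
    fit <- stats::lm(msd_um2 ~ lag_min, data = m)
    msd_dt <- max(sum(stats::coef(fit) * c(1, dt)), 0)
    ratio <- if (nrow(m) >= 2 && m$msd_um2[1] > 0)
      m$msd_um2[2] / m$msd_um2[1] else NA_real_
    list(estimate = sqrt(msd_dt) / dt,
         flagged = is.finite(ratio) && ratio > 3,
         coefs = stats::coef(fit))
  }, error = function(e) NULL)
  if (is.null(est))
    return(list(estimate = NA_real_, flagged = FALSE, threshold = default,
                msd_fit = NULL))
  list(estimate = est$estimate, flagged = est$flagged, threshold = default,
       msd_fit = est$coefs)
}
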