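#' Synthetic ramified-cell and motility data with ground truth
#'
#' The `gen_*` family produces every input the pipeline consumes --
#' skeletons, binary motility movies, saltatory migration tracks,
#' lesion-response tip tracks and cytometry event mixtures -- together
#' with the generator-side ground truth (`truth` component) needed to
#' test the downstream statistics. All stochastic generators are
#' deterministic for a fixed `seed`.
#'
#' @name synthgen
NULL

# isolated RNG: restore the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Star skeleton: analytic Sholl fixture
#'
#' Builds a soma at the origin with `n_branches` straight, unbranched,
#' evenly angled processes of exactly `branch_length` um in the xy plane.
#' Deterministic; every sphere of radius between `soma_radius` and
#' `branch_length` crosses each branch exactly once, so the Sholl
#' profile is known in closed form.
#'
#' @param n_branches number of processes (>= 1).
#' @param branch_length process length in um (> 0).
#' @param soma_radius soma radius in um.
#' @param nodes_per_branch polyline nodes per process (>= 1).
#' @return a [skeleton()].
#' @export
gen_star_skeleton <- function(n_branches, branch_length, soma_radius = 2,
                              nodes_per_branch = 5) {
  if (n_branches < 1 || branch_length <= 0 || soma_radius <= 0 ||
      nodes_per_branch < 1)
    stop("arguments must be positive (n_branches >= 1)")
  angles <- 2 * pi * (seq_len(n_branches) - 1) / n_branches
  ids <- 1L
  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = soma_radius, parent = NA_integer_))
  nid <- 1L
  for (b in seq_len(n_branches)) {
    parent <- 1L
    for (k in seq_len(nodes_per_branch)) {
      nid <- nid + 1L
      d <- branch_length * k / nodes_per_branch
      rows[[length(rows) + 1L]] <- data.frame(
        id = nid, type = 3L,
        x = d * cos(angles[b]), y = d * sin(angles[b]), z = 0,
        radius = 0.5, parent = parent)
      parent <- nid
    }
  }
  skeleton(do.call(rbind, rows))
}

#' Random outward-growing tree skeleton
#'
#' Grows `n_primary` processes from the soma; at every segment tip the
#' process bifurcates with probability `branch_prob`, otherwise it
#' continues, up to `max_depth` segments deep. Segment directions are
#' jittered but constrained to increase the distance from the soma, so
#' every parent-child segment crosses any Sholl sphere at most once.
#' The construction totals (length, tips, branch points) are recorded in
#' the `truth` component.
#'
#' @param n_primary number of primary processes.
#' @param branch_prob bifurcation probability per segment in [0, 1].
#' @param seg_length_range um interval segment lengths are drawn from.
#' @param max_depth maximum segments from soma to tip (>= 1).
#' @param seed RNG seed.
#' @return list with `skeleton` and `truth` (list with `total_length`,
#'   `n_tips`, `n_branch_points`).
#' @export
gen_random_tree <- function(n_primary = 4, branch_prob = 0.3,
                            seg_length_range = c(2, 6), max_depth = 6,
                            seed = 1) {
  if (max_depth < 1) stop("'max_depth' must be >= 1")
  if (branch_prob < 0 || branch_prob > 1)
    stop("'branch_prob' must be in [0, 1]")
  with_seed(seed, {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = 2, parent = NA_integer_)
    total_length <- 0
    n_tips <- 0L
    n_branch <- 0L
    nid <- 1L
    grow <- function(pid, p, depth) {
      # one new segment from point p; guaranteed outward
      len <- runif(1, seg_length_range[1], seg_length_range[2])
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      r_hat <- if (sum(p^2) < 1e-12) u else p / sqrt(sum(p^2))
      dirv <- r_hat + 0.8 * u
      dirv <- dirv / sqrt(sum(dirv^2))
      if (sum(dirv * r_hat) <= 0) dirv <- r_hat   # cannot occur; safety
      q <- p + len * dirv
      nid <<- nid + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(nid, 3L, q[1], q[2], q[3], 0.5, pid)
      total_length <<- total_length + len
      myid <- nid
      if (depth >= max_depth) {
        n_tips <<- n_tips + 1L
        return(invisible(NULL))
      }
      if (runif(1) < branch_prob) {
        n_branch <<- n_branch + 1L
        grow(myid, q, depth + 1L)
        grow(myid, q, depth + 1L)
      } else {
        grow(myid, q, depth + 1L)
      }
    }
    for (b in seq_len(n_primary)) grow(1L, c(0, 0, 0), 1L)
    list(skeleton = skeleton(nodes),
         truth = list(total_length = total_length, n_tips = n_tips,
                      n_branch_points = n_branch))
  })
}

#' Saltatory two-state migration tracks
#'
#' Simulates soma tracks alternating between idling (small steps of
#' `v_idle * dt`) and active migration (steps of `v_active * dt`) with
#' isotropic random directions. The phase sequence is a stationary
#' two-state chain: at each interval the state is redrawn from
#' Bernoulli(`p_idle`) with probability `p_switch`, otherwise kept, so
#' the long-run idle fraction is `p_idle`. Per-interval state labels are
#' returned as ground truth.
#'
#' @param n_tracks number of cells.
#' @param n_frames positions per track.
#' @param dt frame interval in minutes.
#' @param v_active,v_idle speeds in um/min (`v_idle < v_active`).
#' @param p_idle stationary idling probability, strictly in (0, 1) unless
#'   `p_switch` is 0.
#' @param p_switch per-interval probability of redrawing the state.
#' @param dim 2 or 3 spatial dimensions.
#' @param seed RNG seed.
#' @return list with `tracks` (a [track_set()]) and `truth`: data frame
#'   (track_id, interval, idle) with one row per track interval.
#' @export
gen_saltatory_tracks <- function(n_tracks = 50, n_frames = 36, dt = 10,
                                 v_active = 3, v_idle = 0.3, p_idle = 0.6,
                                 p_switch = 0.3, dim = 2, seed = 1) {
  if (dt <= 0) stop("'dt' must be > 0")
  if (v_idle >= v_active) stop("'v_idle' must be < 'v_active'")
  if (p_idle < 0 || p_idle > 1) stop("'p_idle' must be in [0, 1]")
  stopifnot(dim %in% c(2, 3), n_frames >= 2)
  with_seed(seed, {
    recs <- vector("list", n_tracks)
    truth <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      n_int <- n_frames - 1L
      state <- logical(n_int)        # TRUE = idle
      state[1] <- runif(1) < p_idle
      if (n_int > 1) for (k in 2:n_int)
        state[k] <- if (runif(1) < p_switch) runif(1) < p_idle else state[k - 1]
      step_len <- ifelse(state, v_idle, v_active) * dt
      if (dim == 2) {
        th <- runif(n_int, 0, 2 * pi)
        steps <- cbind(step_len * cos(th), step_len * sin(th))
      } else {
        u <- matrix(rnorm(3 * n_int), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        steps <- u * step_len
      }
      start <- runif(dim, 0, 500)
      pos <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, "+"))
      if (n_int == 1) pos <- rbind(start, start + steps[1, ])
      rec <- data.frame(track_id = paste0("cell", i),
                        frame = seq_len(n_frames),
                        t_min = (seq_len(n_frames) - 1) * dt,
                        x_um = pos[, 1], y_um = pos[, 2])
      if (dim == 3) rec$z_um <- pos[, 3]
      recs[[i]] <- rec
      truth[[i]] <- data.frame(track_id = paste0("cell", i),
                               interval = seq_len(n_int), idle = state)
    }
    list(tracks = track_set(do.call(rbind, recs), dt = dt),
         truth = do.call(rbind, truth))
  })
}

#' Binary process-motility movie with exact scanned-area truth
#'
#' Builds a movie of a growing binary cell mask: a soma disk whose
#' processes gain exactly `growth_px_per_frame` pixels per frame, chosen
#' from the current mask boundary. Growth is monotone, so the changed
#' pixel set of every consecutive frame pair is exactly the new pixels
#' and pairs are mutually disjoint; the per-pair changed-pixel counts
#' and their total area are exact ground truth for the surveillance
#' statistic.
#'
#' @param canvas integer (height, width) in pixels.
#' @param pixel_size um per pixel.
#' @param n_frames number of frames.
#' @param dt frame interval in minutes.
#' @param growth_px_per_frame pixels added per frame transition.
#' @param seed RNG seed.
#' @return list with `movie` (a [binary_movie()]) and `truth`: list with
#'   `changed_px` (per pair), `total_area_um2`.
#' @export
gen_motility_movie <- function(canvas = c(64, 64), pixel_size = 0.5,
                               n_frames = 11, dt = 1,
                               growth_px_per_frame = 10, seed = 1) {
  stopifnot(length(canvas) == 2, n_frames >= 2, pixel_size > 0, dt > 0,
            growth_px_per_frame >= 0)
  h <- canvas[1]; w <- canvas[2]
  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    cy <- ceiling(h / 2); cx <- ceiling(w / 2)
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask[(yy - cy)^2 + (xx - cx)^2 <= 9] <- TRUE   # soma disk, r = 3 px
    frames <- array(FALSE, dim = c(n_frames, h, w))
    frames[1, , ] <- mask
    changed <- integer(n_frames - 1L)
    for (f in 2:n_frames) {
      added <- 0L
      while (added < growth_px_per_frame) {
        # 4-neighbour frontier of the current mask
        nb <- matrix(FALSE, h, w)
        nb[-1, ] <- nb[-1, ] | mask[-h, ]
        nb[-h, ] <- nb[-h, ] | mask[-1, ]
        nb[, -1] <- nb[, -1] | mask[, -w]
        nb[, -w] <- nb[, -w] | mask[, -1]
        frontier <- which(nb & !mask)
        if (!length(frontier))
          stop("growth exceeds canvas: no room left at frame ", f)
        take <- min(growth_px_per_frame - added, length(frontier))
        mask[sample(frontier, take)] <- TRUE
        added <- added + take
      }
      frames[f, , ] <- mask
      changed[f - 1L] <- growth_px_per_frame
    }
    list(movie = binary_movie(frames, pixel_size = pixel_size,
                              frame_interval = dt),
         truth = list(changed_px = changed,
                      total_area_um2 = sum(changed) * pixel_size^2))
  })
}

#' Lesion-response process-tip tracks
#'
#' Places process tips on a circle of `start_radius` um around a lesion
#' centre and moves each radially inward at `v_ext` um/min until it
#' reaches the lesion boundary, where it holds. Tips are grouped into
#' parent cells (`tips_per_cell` consecutive tips per cell).
#'
#' @param n_tips number of tips.
#' @param start_radius starting distance from the lesion centre (um).
#' @param v_ext extension speed (um/min).
#' @param dt frame interval (min).
#' @param n_frames frames per track.
#' @param lesion_radius radius of the lesion core (um); tips stop here.
#' @param tips_per_cell tips assigned to each parent cell.
#' @param seed RNG seed (tip angles).
#' @return a [track_set()] of kind "process-tip" with attributes
#'   `lesion_center` and a `cell_id` column.
#' @export
gen_lesion_tracks <- function(n_tips = 12, start_radius = 40, v_ext = 2,
                              dt = 1, n_frames = 16, lesion_radius = 5,
                              tips_per_cell = 3, seed = 1) {
  stopifnot(n_tips >= 1, dt > 0, n_frames >= 2, v_ext >= 0,
            start_radius > lesion_radius, lesion_radius >= 0)
  with_seed(seed, {
    ang <- runif(n_tips, 0, 2 * pi)
    t_min <- (seq_len(n_frames) - 1) * dt
    recs <- vector("list", n_tips)
    for (i in seq_len(n_tips)) {
      r <- pmax(lesion_radius, start_radius - v_ext * t_min)
      recs[[i]] <- data.frame(
        track_id = paste0("tip", i),
        cell_id = paste0("cell", (i - 1) %/% tips_per_cell + 1),
        frame = seq_len(n_frames), t_min = t_min,
        x_um = r * cos(ang[i]), y_um = r * sin(ang[i]))
    }
    track_set(do.call(rbind, recs), dt = dt, lesion_center = c(0, 0),
              kind = "process-tip")
  })
}

#' Two-population cytometry event mixture
#'
#' Draws `n_events` single-channel fluorescence intensities from a
#' log-normal two-population mixture (negative bulk plus brighter
#' positives) with per-event truth labels, emulating a synaptosome-uptake
#' phagocytosis readout.
#'
#' @param n_events number of events.
#' @param pos_fraction probability an event is positive, in [0, 1].
#' @param neg_log_mu,neg_log_sigma log-scale location/scale of negatives.
#' @param pos_log_mu,pos_log_sigma log-scale location/scale of positives
#'   (`pos_log_mu > neg_log_mu`).
#' @param sample,group,timepoint_min,is_control event-table metadata.
#' @param seed RNG seed.
#' @return list with `events` (data frame: event_id, intensity, sample,
#'   timepoint_min, group, is_control) and `truth`: logical vector of
#'   positive labels.
#' @export
gen_cytometry_events <- function(n_events = 10000, pos_fraction = 0.3,
                                 neg_log_mu = 2, neg_log_sigma = 0.4,
                                 pos_log_mu = 6, pos_log_sigma = 0.5,
                                 sample = "S1", group = "WT",
                                 timepoint_min = 120, is_control = FALSE,
                                 seed = 1) {
  if (pos_fraction < 0 || pos_fraction > 1)
    stop("'pos_fraction' must be in [0, 1]")
  if (pos_log_mu <= neg_log_mu)
    stop("'pos_log_mu' must exceed 'neg_log_mu'")
  with_seed(seed, {
    pos <- runif(n_events) < pos_fraction
    intensity <- ifelse(pos,
                        rlnorm(n_events, pos_log_mu, pos_log_sigma),
                        rlnorm(n_events, neg_log_mu, neg_log_sigma))
    list(events = data.frame(event_id = seq_len(n_events),
                             intensity = intensity, sample = sample,
                             timepoint_min = timepoint_min, group = group,
                             is_control = is_control),
         truth = pos)
  })
}
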