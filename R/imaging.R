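#' Calibrated image stacks and binary movies
#'
#' An `image_stack` holds a non-negative intensity array ordered
#' (t, z, y, x) with physical calibration: `pixel_size` in um/pixel and
#' `frame_interval` in minutes. A `binary_movie` holds a logical
#' (t, y, x) mask array with the same calibration; it is the substrate
#' of the surveillance statistic.
#'
#' @param data numeric array, (t, z, y, x) or (t, y, x) (a singleton z
#'   axis is added).
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval minutes between frames (> 0).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, frame_interval) {
  if (!is.array(data) || !length(dim(data)) %in% c(3, 4))
    stop("'data' must be a (t, z, y, x) or (t, y, x) array")
  if (length(dim(data)) == 3)
    data <- array(data, dim = c(dim(data)[1], 1L, dim(data)[2], dim(data)[3]))
  if (any(data < 0)) stop("intensities must be non-negative")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("calibration must be strictly positive")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frame(s) x %d z x %d x %d px, %.3g um/px, dt %.3g min\n",
              d[1], d[2], d[3], d[4], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @rdname image_stack
#' @param masks logical (t, y, x) array.
#' @export
binary_movie <- function(masks, pixel_size, frame_interval) {
  if (!is.array(masks) || length(dim(masks)) != 3)
    stop("'masks' must be a (t, y, x) array")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("calibration must be strictly positive")
  structure(list(masks = masks > 0, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "binary_movie")
}

#' @export
print.binary_movie <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("binary_movie: %d frames x %d x %d px, %.3g um/px, dt %.3g min\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

# 2D median filter with square window of given radius (edge-replicated)
median_filter2d <- function(m, radius = 1) {
  if (radius < 1) return(m)
  h <- nrow(m); w <- ncol(m)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  stackm <- matrix(0, h * w, nrow(offs))
  ridx <- seq_len(h); cidx <- seq_len(w)
  for (k in seq_len(nrow(offs))) {
    rs <- pmin(pmax(ridx + offs$dy[k], 1L), h)
    cs <- pmin(pmax(cidx + offs$dx[k], 1L), w)
    stackm[, k] <- m[rs, cs]
  }
  # row-wise median: sort each row; window size is odd, take middle column
  mid <- (nrow(offs) + 1L) / 2L
  med <- apply(stackm, 1L, function(v) sort.int(v, partial = mid)[mid])
  matrix(med, h, w)
}

# modal grey level of a matrix (histogram peak over 256 bins)
modal_level <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(m, br, rightmost.closed = TRUE), 256)
  mids <- (br[-1] + br[-257]) / 2
  mids[which.max(h)]
}

# shift a matrix by integer (dy, dx), zero-filling exposed borders
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# best integer translation of `frame` onto `ref` by exhaustive search of
# the normalized cross-correlation over the overlap region, for shifts in
# [-max_shift, max_shift]^2; ties resolve to the smaller displacement
estimate_shift <- function(ref, frame, max_shift = 5) {
  h <- nrow(ref); w <- ncol(ref)
  best <- c(0L, 0L); best_score <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    a <- frame[ys, xs]
    b <- ref[ys - dy, xs - dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    score <- stats::cor(as.vector(a), as.vector(b))
    better <- score > best_score + 1e-12 ||
      (score > best_score - 1e-12 &&
         abs(dy) + abs(dx) < sum(abs(best)))
    if (better) { best_score <- score; best <- c(dy, dx) }
  }
  best
}

#' Preprocess an image stack
#'
#' Applies, per z-slice and frame: background subtraction (the modal
#' grey level, a supplied constant, or none) clamped at zero, then a
#' square median filter of the given radius. Finally each frame is
#' registered for translational drift against frame 1 by exhaustive
#' integer cross-correlation on the z-maximum projection; the estimated
#' per-frame displacements are returned in attribute `shifts`.
#'
#' @param stack an [image_stack()].
#' @param median_radius median-filter radius in pixels (0 disables).
#' @param background "modal", "none", or a numeric constant offset.
#' @param register estimate and undo per-frame translation?
#' @param max_shift registration search radius in pixels.
#' @return an [image_stack()]; attribute `shifts` is a (t x 2) matrix of
#'   estimated (dy, dx) displacements relative to frame 1.
#' @export
preprocess_stack <- function(stack, median_radius = 1, background = "modal",
                             register = TRUE, max_shift = 5) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (prod(d) == 0) stop("empty stack")
  out <- stack$data
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    sl <- out[t, z, , ]
    bg <- if (identical(background, "modal")) modal_level(sl)
          else if (identical(background, "none")) 0
          else as.numeric(background)
    sl <- pmax(sl - bg, 0)
    if (median_radius >= 1) sl <- median_filter2d(sl, median_radius)
    out[t, z, , ] <- sl
  }
  shifts <- matrix(0L, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  if (register && d[1] > 1) {
    proj <- function(t) apply(out[t, , , , drop = FALSE], c(3, 4), max)
    ref <- proj(1)
    for (t in 2:d[1]) {
      s <- estimate_shift(ref, proj(t), max_shift = max_shift)
      shifts[t, ] <- s
      if (any(s != 0)) for (z in seq_len(d[2]))
        out[t, z, , ] <- shift_matrix(out[t, z, , ], -s[1], -s[2])
    }
  }
  res <- image_stack(out, stack$pixel_size, stack$frame_interval)
  attr(res, "shifts") <- shifts
  res
}

#' Maximum-intensity projection over z
#'
#' @param stack an [image_stack()] with a z axis.
#' @return an [image_stack()] with singleton z: each (t, y, x) value is
#'   the maximum over z.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  proj <- array(apply(stack$data, c(1, 3, 4), max), dim = c(d[1], 1, d[3], d[4]))
  res <- image_stack(proj, stack$pixel_size, stack$frame_interval)
  attr(res, "shifts") <- attr(stack, "shifts")
  res
}

#' Huang minimal-fuzziness threshold
#'
#' Selects the grey level minimizing the Huang--Wang measure of
#' fuzziness of the thresholded image. For a candidate threshold t, each
#' grey level g gets membership u(g) = 1 / (1 + |g - m| / C), where m is
#' the mean level of g's class (background if g <= t, foreground
#' otherwise) and C the occupied grey-level range; the fuzziness is the
#' count-weighted sum of the Shannon entropies
#' S(u) = -u log u - (1-u) log(1-u). All candidate levels are searched
#' exhaustively; ties resolve to the lowest level. Foreground is
#' `level > threshold`.
#'
#' @param counts histogram counts, or a numeric matrix/array of
#'   intensities (a 256-bin histogram is built over its range).
#' @param levels grey values corresponding to `counts` (default 0-based
#'   bin index).
#' @return the threshold grey level.
#' @export
huang_threshold <- function(counts, levels = NULL) {
  if (is.matrix(counts) || (is.array(counts) && length(dim(counts)) > 1) ||
      (is.numeric(counts) && !is.null(dim(counts)))) {
    x <- as.numeric(counts)
    rng <- range(x)
    if (diff(rng) == 0) stop("degenerate histogram: constant image")
    br <- seq(rng[1], rng[2], length.out = 257)
    counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE), 256)
    levels <- (br[-1] + br[-257]) / 2
  }
  if (is.null(levels)) levels <- seq_along(counts) - 1
  keep <- counts > 0
  g <- levels[keep]; w <- counts[keep]
  if (length(g) < 2) stop("degenerate histogram: fewer than 2 occupied levels")
  C <- max(g) - min(g)
  cw <- cumsum(w); cwg <- cumsum(w * g)
  W <- sum(w); WG <- sum(w * g)
  ent <- function(u) {
    s <- -u * log(u) - (1 - u) * log(1 - u)
    s[!is.finite(s)] <- 0
    s
  }
  # candidates: all occupied levels with a non-empty foreground class
  n <- length(g)
  fuzz <- rep(NA_real_, n - 1)
  for (k in seq_len(n - 1)) {
    m0 <- cwg[k] / cw[k]
    m1 <- (WG - cwg[k]) / (W - cw[k])
    u <- numeric(n)
    u[1:k] <- 1 / (1 + abs(g[1:k] - m0) / C)
    u[(k + 1):n] <- 1 / (1 + abs(g[(k + 1):n] - m1) / C)
    fuzz[k] <- sum(w * ent(u))
  }
  g[which.min(fuzz)]
}

#' Binarize a movie by Huang thresholding
#'
#' Computes a Huang threshold per frame (on the z-projected stack) and
#' applies either each frame's own threshold (`mode = "per-frame"`) or,
#' by default, the minimum threshold across frames to every frame
#' (`mode = "global-min"`) -- the most inclusive choice, ensuring that
#' processes visible in any frame are retained in all frames. Pixels
#' outside `roi_mask` (e.g. a manually drawn single-cell region) are set
#' to background.
#'
#' @param stack an [image_stack()] (z is max-projected if present).
#' @param mode "global-min" (default) or "per-frame".
#' @param roi_mask optional logical (y, x) matrix.
#' @return a [binary_movie()].
#' @export
binarize_movie <- function(stack, mode = c("global-min", "per-frame"),
                           roi_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  d <- dim(stack$data)
  if (d[2] > 1) stack <- max_project(stack)
  mov <- stack$data[, 1, , , drop = FALSE]
  dim(mov) <- dim(mov)[c(1, 3, 4)]
  nt <- dim(mov)[1]
  thr <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- mov[t, , ]
    if (diff(range(fr)) == 0)
      stop("degenerate histogram in frame ", t)
    thr[t] <- huang_threshold(as.matrix(fr))
  }
  if (mode == "global-min") thr[] <- min(thr)
  masks <- array(FALSE, dim = dim(mov))
  for (t in seq_len(nt)) masks[t, , ] <- mov[t, , ] > thr[t]
  if (!is.null(roi_mask)) {
    stopifnot(identical(dim(roi_mask), dim(mov)[2:3]))
    for (t in seq_len(nt)) masks[t, , ] <- masks[t, , ] & roi_mask
  }
  bm <- binary_movie(masks, stack$pixel_size, stack$frame_interval)
  attr(bm, "thresholds") <- thr
  bm
}

#' Surveillance: scanned area from binarized frame pairs
#'
#' For every consecutive frame pair the changed pixels -- the symmetric
#' difference (XOR) of the two masks, capturing both process extension
#' and retraction -- are counted; the scanned area is the summed changed
#' pixels over all pairs falling inside the analysis window, converted
#' to um^2 with the pixel calibration.
#'
#' @param bm a [binary_movie()] with at least 2 frames.
#' @param window analysis window in minutes (default 10); the first
#'   `window / frame_interval` pairs starting at `start_offset` are
#'   summed.
#' @param start_offset index of the first pair used (default 1).
#' @return list with `scanned_area_um2` (total over the window),
#'   `per_pair_um2` (all consecutive pairs), `pairs_used`.
#' @export
surveillance_area <- function(bm, window = 10, start_offset = 1) {
  stopifnot(inherits(bm, "binary_movie"))
  nt <- dim(bm$masks)[1]
  if (nt < 2) stop("at least 2 frames required")
  if (window < bm$frame_interval)
    stop("'window' is shorter than one frame interval")
  n_pairs_window <- floor(window / bm$frame_interval + 1e-9)
  duration <- (nt - 1) * bm$frame_interval
  if (window > duration + 1e-9)
    stop("'window' exceeds the movie duration (", duration, " min)")
  px_area <- bm$pixel_size^2
  per_pair <- vapply(seq_len(nt - 1), function(t)
    sum(xor(bm$masks[t, , ], bm$masks[t + 1, , ])) * px_area, numeric(1))
  use <- seq(start_offset, length.out = n_pairs_window)
  if (max(use) > length(per_pair))
    stop("window does not fit at the requested start offset")
  list(scanned_area_um2 = sum(per_pair[use]),
       per_pair_um2 = per_pair, pairs_used = use)
}

#' Read / write calibrated TIFF movies
#'
#' `read_stack_tiff` reads a multi-page TIFF into an [image_stack()];
#' pages are interpreted with the axis layout given in `axes` ("tyx" for
#' a planar movie, "tzyx" with `nz` z-slices per time point).
#' `write_movie_tiff` writes an [image_stack()] or [binary_movie()] as a
#' multi-page TIFF (masks as 0/255 8-bit).
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration (um/px, min).
#' @param axes page layout, "tyx" or "tzyx".
#' @param nz z-slices per time point when `axes = "tzyx"`.
#' @return `read_stack_tiff`: an [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size, frame_interval,
                            axes = "tyx", nz = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  np <- length(pages)
  if (axes == "tyx") nz <- 1
  nt <- np / nz
  if (nt != round(nt)) stop("page count ", np, " not divisible by nz = ", nz)
  arr <- array(0, dim = c(nt, nz, h, w))
  k <- 1
  for (t in seq_len(nt)) for (z in seq_len(nz)) {
    arr[t, z, , ] <- pages[[k]]
    k <- k + 1
  }
  image_stack(arr, pixel_size, frame_interval)
}

#' @rdname read_stack_tiff
#' @param x an [image_stack()] or [binary_movie()].
#' @export
write_movie_tiff <- function(x, path) {
  if (inherits(x, "binary_movie")) {
    arr <- x$masks
    pages <- lapply(seq_len(dim(arr)[1]), function(t)
      matrix(ifelse(arr[t, , ], 255L, 0L) / 255, dim(arr)[2], dim(arr)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else if (inherits(x, "image_stack")) {
    d <- dim(x$data)
    mx <- max(x$data, 1)
    pages <- list()
    for (t in seq_len(d[1])) for (z in seq_len(d[2]))
      pages[[length(pages) + 1]] <- x$data[t, z, , ] / mx
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else stop("unsupported object")
  invisible(path)
}
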