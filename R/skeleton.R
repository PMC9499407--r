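#' Skeleton objects
#'
#' A `skeleton` is a rooted 3D tree of measured nodes with SWC semantics:
#' each node carries an integer id, an SWC type code, coordinates in
#' micrometres, a radius and a parent id (`NA` for the root). It is the
#' substrate for Sholl analysis and morphometrics.
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (parent `NA` or -1 for the root). Coordinates are
#'   in micrometres.
#' @return An object of class `skeleton`: the validated node table plus a
#'   `soma_id` attribute. The soma is the node with SWC type code 1 if
#'   exactly one such node exists, otherwise the root node.
#' @examples
#' nodes <- data.frame(id = 1:2, type = c(1, 3),
#'                     x = c(0, 5), y = 0, z = 0,
#'                     radius = c(2, 0.5), parent = c(NA, 1))
#' sk <- skeleton(nodes)
#' morphometrics(sk)$total_length  # 5
#' @export
skeleton <- function(nodes) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stop("'nodes' must be a data frame with columns ",
         paste(required, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$parent[!is.na(nodes$parent) & nodes$parent < 0] <- NA
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)

  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  num <- c("x", "y", "z", "radius")
  if (!all(vapply(nodes[num], function(v) all(is.finite(v)), logical(1))))
    stop("non-finite coordinate or radius")

  roots <- which(is.na(nodes$parent))
  if (length(roots) == 0L) stop("skeleton has no root node")
  if (length(roots) > 1L)
    stop("skeleton has multiple roots: nodes ",
         paste(nodes$id[roots], collapse = ", "))

  idx <- match(nodes$parent, nodes$id)
  dangling <- which(!is.na(nodes$parent) & is.na(idx))
  if (length(dangling))
    stop("node ", nodes$id[dangling[1]], " references missing parent ",
         nodes$parent[dangling[1]])

  # connectivity / acyclicity: walk each node to the root
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    steps <- 0L
    j <- i
    while (!is.na(nodes$parent[j])) {
      j <- idx[j]
      steps <- steps + 1L
      if (steps > n)
        stop("cycle detected at node ", nodes$id[i])
    }
  }

  soma <- nodes$id[roots]
  typed <- nodes$id[nodes$type == 1L]
  if (length(typed) == 1L) soma <- typed

  structure(nodes, class = c("skeleton", "data.frame"), soma_id = soma)
}

#' @export
print.skeleton <- function(x, ...) {
  m <- morphometrics(x)
  cat("skeleton:", nrow(x), "nodes, soma id", attr(x, "soma_id"), "\n")
  cat(sprintf("  total process length %.2f um, %d tips, %d branch points\n",
              m$total_length, m$n_tips, m$n_branch_points))
  invisible(x)
}

# parent->child straight segments, excluding the root's virtual parent.
# Returns a data frame with endpoint coordinates (one row per segment).
skeleton_segments <- function(sk) {
  idx <- match(sk$parent, sk$id)
  keep <- !is.na(idx)
  data.frame(
    x0 = sk$x[idx[keep]], y0 = sk$y[idx[keep]], z0 = sk$z[idx[keep]],
    x1 = sk$x[keep],      y1 = sk$y[keep],      z1 = sk$z[keep],
    child = sk$id[keep]
  )
}

#' Read a skeleton from an SWC file
#'
#' Parses the standard 7-column SWC text format (id, type, x, y, z,
#' radius, parent; `#` comment lines ignored). Node order in the file is
#' irrelevant. Structural defects -- duplicate ids, dangling parents,
#' cycles, zero or multiple roots -- raise an error naming the offending
#' node.
#'
#' @param path path to an SWC file.
#' @return A [skeleton()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no node records in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC record on line: ", lines[bad[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in SWC file ", path)
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  nodes$parent[nodes$parent < 0] <- NA
  skeleton(nodes)
}

#' Write a skeleton to an SWC file
#'
#' Emits standard 7-column SWC with every parent listed before its
#' children (topological order), so the file is readable by common
#' morphology tools.
#'
#' @param sk a [skeleton()].
#' @param path output path.
#' @export
write_swc <- function(sk, path) {
  sk <- skeleton(as.data.frame(sk))   # re-validate before writing
  ord <- integer(0)
  idx <- match(sk$parent, sk$id)
  remaining <- rep(TRUE, nrow(sk))
  placed <- rep(FALSE, nrow(sk))
  while (any(remaining)) {
    ready <- which(remaining & (is.na(idx) | placed[idx]))
    ord <- c(ord, ready)
    placed[ready] <- TRUE
    remaining[ready] <- FALSE
  }
  s <- sk[ord, ]
  par <- ifelse(is.na(s$parent), -1L, s$parent)
  rec <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                 s$id, s$type, s$x, s$y, s$z, s$radius, par)
  writeLines(c("# SWC written by morphodyn", rec), path)
  invisible(path)
}

#' Sholl profile of a skeleton
#'
#' Counts, for concentric spheres of radius `dr, 2*dr, ...` centred on
#' the soma, the number of parent-child segments crossing each sphere.
#' A segment crosses the sphere of radius r when one endpoint lies inside
#' and the other outside; an endpoint exactly at distance r counts as
#' inside (closed ball), so a branch tip ending exactly on a sphere does
#' not create a spurious intersection.
#'
#' @param sk a [skeleton()].
#' @param dr radius step in micrometres (default 1).
#' @param r_max largest radius; default (`NULL`) extends one step past the
#'   most distal node.
#' @return Object of class `sholl_profile`: data frame with columns
#'   `radius` (um) and `crossings`, with the soma position in attribute
#'   `center`.
#' @export
sholl_profile <- function(sk, dr = 1, r_max = NULL) {
  stopifnot(inherits(sk, "skeleton"))
  if (!is.numeric(dr) || dr <= 0) stop("'dr' must be > 0")
  soma <- which(sk$id == attr(sk, "soma_id"))
  c0 <- c(sk$x[soma], sk$y[soma], sk$z[soma])
  seg <- skeleton_segments(sk)
  d0 <- sqrt((seg$x0 - c0[1])^2 + (seg$y0 - c0[2])^2 + (seg$z0 - c0[3])^2)
  d1 <- sqrt((seg$x1 - c0[1])^2 + (seg$y1 - c0[2])^2 + (seg$z1 - c0[3])^2)
  if (is.null(r_max)) {
    dmax <- if (nrow(seg)) max(d0, d1) else 0
    r_max <- (floor(dmax / dr) + 1) * dr
  }
  radii <- seq(dr, r_max, by = dr)
  counts <- vapply(radii, function(r) sum((d0 <= r) != (d1 <= r)), integer(1))
  structure(data.frame(radius = radii, crossings = counts),
            class = c("sholl_profile", "data.frame"), center = c0)
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("Sholl profile:", nrow(x), "radii,",
      "max", max(x$crossings), "crossings at r =",
      x$radius[which.max(x$crossings)], "um\n")
  invisible(x)
}

#' Morphometric battery for a skeleton
#'
#' Computes the standard ramification metrics of a reconstructed cell:
#' total process length (sum of parent-child Euclidean segment lengths),
#' number of tips (non-soma nodes without children), number of branch
#' points (non-soma nodes with at least two children), and the peak of
#' the Sholl profile with the radius at which it occurs.
#'
#' @param sk a [skeleton()].
#' @param dr Sholl radius step used for the embedded profile (um).
#' @return list with `total_length` (um), `n_tips`, `n_branch_points`,
#'   `max_intersections`, `max_radius` (um).
#' @export
morphometrics <- function(sk, dr = 1) {
  stopifnot(inherits(sk, "skeleton"))
  seg <- skeleton_segments(sk)
  total <- if (nrow(seg))
    sum(sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 +
               (seg$z1 - seg$z0)^2)) else 0
  soma <- attr(sk, "soma_id")
  kids <- table(factor(sk$parent, levels = sk$id))
  nkids <- as.integer(kids)[match(sk$id, as.integer(names(kids)))]
  nkids[is.na(nkids)] <- 0L
  not_soma <- sk$id != soma
  n_tips <- sum(not_soma & nkids == 0L)
  n_branch <- sum(not_soma & nkids >= 2L)
  prof <- sholl_profile(sk, dr = dr)
  mi <- if (nrow(prof)) max(prof$crossings) else 0L
  mr <- if (mi > 0) prof$radius[which.max(prof$crossings)] else 0
  list(total_length = total, n_tips = n_tips, n_branch_points = n_branch,
       max_intersections = mi, max_radius = mr)
}

#' Cell density per square millimetre
#'
#' @param points matrix or data frame of cell positions (only the row
#'   count is used), or a single count.
#' @param region_area_mm2 area of the counted region in mm^2.
#' @return cells per mm^2.
#' @export
cell_density <- function(points, region_area_mm2) {
  if (!is.numeric(region_area_mm2) || length(region_area_mm2) != 1 ||
      region_area_mm2 <= 0)
    stop("'region_area_mm2' must be a single positive number")
  n <- if (is.matrix(points) || is.data.frame(points)) nrow(points)
       else if (length(points) == 1 && is.numeric(points)) points
       else length(points)
  n / region_area_mm2
}
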