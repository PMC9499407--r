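# Independent brute-force oracles and shared fixtures. Each oracle is a
# deliberately naive re-derivation of the quantity it checks, kept
# independent of the package's implementation path.

# Y-tree: 10 um trunk along +x bifurcating into two 10 um daughters.
make_y_tree <- function() {
  s2 <- 10 / sqrt(2)
  skeleton(data.frame(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(0, 10, 10 + s2, 10 + s2),
    y = c(0, 0, s2, -s2),
    z = 0, radius = c(2, .5, .5, .5),
    parent = c(NA, 1, 2, 2)))
}

# Sholl oracle: densely resample every parent-child segment and count,
# per radius, segments whose sampled distance-to-soma sequence changes
# classification (inside = distance <= r).
sholl_oracle <- function(sk, radii, step = 0.01) {
  soma <- which(sk$id == attr(sk, "soma_id"))
  c0 <- c(sk$x[soma], sk$y[soma], sk$z[soma])
  idx <- match(sk$parent, sk$id)
  counts <- integer(length(radii))
  for (i in which(!is.na(idx))) {
    p0 <- c(sk$x[idx[i]], sk$y[idx[i]], sk$z[idx[i]])
    p1 <- c(sk$x[i], sk$y[i], sk$z[i])
    L <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
    pts <- outer(ts, p1 - p0) + matrix(p0, length(ts), 3, byrow = TRUE)
    d <- sqrt(rowSums((pts - matrix(c0, length(ts), 3, byrow = TRUE))^2))
    for (k in seq_along(radii)) {
      inside <- d <= radii[k]
      counts[k] <- counts[k] + sum(abs(diff(inside)))
    }
  }
  counts
}

# Huang-Wang fuzziness oracle: plain re-evaluation of the criterion at
# one candidate threshold, scalar loops throughout.
huang_fuzziness_oracle <- function(counts, levels, t) {
  occ <- which(counts > 0)
  g <- levels[occ]; w <- counts[occ]
  C <- max(g) - min(g)
  lo <- g <= t
  if (!any(lo) || all(lo)) return(NA_real_)
  m0 <- sum(w[lo] * g[lo]) / sum(w[lo])
  m1 <- sum(w[!lo] * g[!lo]) / sum(w[!lo])
  f <- 0
  for (j in seq_along(g)) {
    m <- if (g[j] <= t) m0 else m1
    u <- 1 / (1 + abs(g[j] - m) / C)
    s <- 0
    if (u > 0 && u < 1) s <- -u * log(u) - (1 - u) * log(1 - u)
    f <- f + w[j] * s
  }
  f
}

huang_oracle <- function(counts, levels = seq_along(counts) - 1) {
  occ <- levels[counts > 0]
  cand <- occ[-length(occ)]
  fz <- vapply(cand, function(t) huang_fuzziness_oracle(counts, levels, t),
               numeric(1))
  cand[which.min(fz)]
}

# MSD oracle: explicit double loop over origin/lag pairs.
msd_oracle <- function(pos, dt, max_lag) {
  n <- nrow(pos)
  sapply(seq_len(max_lag), function(k) {
    tot <- 0; cnt <- 0
    for (i in seq_len(n - k)) {
      tot <- tot + sum((pos[i + k, ] - pos[i, ])^2)
      cnt <- cnt + 1
    }
    tot / cnt
  })
}

# Mann-Whitney oracle: U from direct pair counting (wins + half-ties),
# p from enumeration of every group-label assignment.
mw_oracle <- function(x, y) {
  u_pairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b)
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  U <- u_pairs(x, y)
  mu <- nx * ny / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) u_pairs(pool[i], pool[-i]))
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-9))
}

# Fisher oracle: hypergeometric enumeration over all tables with the
# observed margins; two-sided p sums tables no more probable than
# observed (with the customary 1e-7 relative tolerance for ties).
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# flat test image with gaussian blobs; registration fixture content
blob_image <- function(h = 48, w = 48, centers, amp = 5, sigma = 2,
                       offset = 10) {
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- matrix(offset, h, w)
  for (k in seq_len(nrow(centers)))
    img <- img + amp * exp(-((yy - centers[k, 1])^2 +
                               (xx - centers[k, 2])^2) / (2 * sigma^2))
  img
}
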