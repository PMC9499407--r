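test_that("huang threshold separates a two-level histogram", {
  counts <- integer(256)
  counts[10 + 1] <- 500; counts[200 + 1] <- 300
  t <- huang_threshold(counts)
  expect_gte(t, 10); expect_lt(t, 200)
  # both modes land on opposite sides of the threshold
  expect_true(10 <= t && 200 > t)
})

test_that("huang threshold equals the brute-force fuzziness oracle", {
  set.seed(21)
  for (i in 1:25) {
    counts <- rpois(256, lambda = rexp(256, 1 / 20))
    if (sum(counts > 0) < 2) next
    expect_equal(huang_threshold(counts), huang_oracle(counts))
  }
})

test_that("huang threshold is invariant under count scaling and rejects
           constant images", {
  counts <- integer(64); counts[c(5, 20, 50)] <- c(100, 30, 80)
  expect_equal(huang_threshold(counts * 7L), huang_threshold(counts))
  expect_error(huang_threshold(matrix(3, 4, 4)), "degenerate")
})

test_that("median filter removes salt noise and preserves flat fields", {
  img <- matrix(10, 16, 16)
  st <- image_stack(array(img, c(1, 1, 16, 16)), 0.5, 1)
  out <- preprocess_stack(st, median_radius = 1, background = "none",
                          register = FALSE)
  expect_equal(out$data[1, 1, , ], img)

  noisy <- img; noisy[8, 8] <- 200
  st2 <- image_stack(array(noisy, c(1, 1, 16, 16)), 0.5, 1)
  out2 <- preprocess_stack(st2, median_radius = 1, background = "none",
                           register = FALSE)
  expect_equal(out2$data[1, 1, , ], img)

  # constant background subtraction zeroes a constant image
  out3 <- preprocess_stack(st, median_radius = 0, background = 10,
                           register = FALSE)
  expect_true(all(out3$data == 0))
})

test_that("registration recovers known integer shifts exactly", {
  set.seed(5)
  centers <- cbind(runif(6, 12, 36), runif(6, 12, 36))
  ref <- blob_image(48, 48, centers)
  shifts <- rbind(c(0, 0), c(3, -2), c(-5, 5), c(1, 4))
  arr <- array(0, c(4, 1, 48, 48))
  for (t in 1:4)
    arr[t, 1, , ] <- morphodyn:::shift_matrix(ref, shifts[t, 1], shifts[t, 2])
  st <- image_stack(arr, 0.5, 1)
  out <- preprocess_stack(st, median_radius = 0, background = "none",
                          max_shift = 5)
  expect_equal(unname(attr(out, "shifts")), unname(shifts))
})

test_that("max projection takes the per-pixel maximum over z and commutes
           with frame selection", {
  arr <- array(runif(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  st <- image_stack(arr, 0.5, 1)
  pr <- max_project(st)
  expect_equal(pr$data[2, 1, 5, 5], max(arr[2, , 5, 5]))
  # z-constant stack projects to any slice
  cst <- image_stack(aperm(array(arr[, 1, , ], c(2, 8, 8, 3)),
                           c(1, 4, 2, 3)), 0.5, 1)
  prc <- max_project(cst)
  expect_equal(prc$data[, 1, , ], cst$data[, 2, , ])
  # commutes with selecting a frame
  one <- image_stack(arr[1, , , , drop = FALSE], 0.5, 1)
  expect_equal(max_project(one)$data[1, 1, , ], pr$data[1, 1, , ])
})

test_that("binarize_movie reproduces known supports; global-min captures
           dim frames", {
  cell <- matrix(0, 20, 20); cell[8:12, 8:12] <- 200
  dim_cell <- cell / 2
  arr <- array(0, c(2, 1, 20, 20))
  arr[1, 1, , ] <- cell; arr[2, 1, , ] <- dim_cell
  st <- image_stack(arr, 0.5, 1)
  bm <- binarize_movie(st, mode = "global-min")
  expect_equal(bm$masks[1, , ], cell > 0)
  expect_equal(bm$masks[2, , ], dim_cell > 0)   # dim frame fully captured
  # roi mask halves a symmetric cell
  roi <- matrix(FALSE, 20, 20); roi[, 1:10] <- TRUE
  bmr <- binarize_movie(st, roi_mask = roi)
  expect_equal(sum(bmr$masks[1, , ]), sum(bm$masks[1, , ] & roi))
  # degenerate frame errors, naming the frame
  arr2 <- arr; arr2[2, 1, , ] <- 7
  expect_error(binarize_movie(image_stack(arr2, 0.5, 1)), "frame 2")
})

test_that("surveillance area is exact on constructed movies", {
  mm <- gen_motility_movie(canvas = c(64, 64), pixel_size = 0.5,
                           n_frames = 11, growth_px_per_frame = 10, seed = 1)
  s <- surveillance_area(mm$movie, window = 10)
  expect_equal(s$scanned_area_um2, mm$truth$total_area_um2)
  expect_equal(s$scanned_area_um2, 25)

  # static movie
  masks <- array(FALSE, c(5, 8, 8)); masks[, 3, 3] <- TRUE
  bm <- binary_movie(masks, 0.5, 1)
  expect_equal(surveillance_area(bm, window = 4)$scanned_area_um2, 0)

  # a pixel toggling each frame counts extension and retraction
  tog <- array(FALSE, c(11, 4, 4)); tog[seq(1, 11, 2), 2, 2] <- TRUE
  bmt <- binary_movie(tog, 0.5, 1)
  expect_equal(surveillance_area(bmt, window = 10)$scanned_area_um2,
               10 * 0.25)
  expect_error(surveillance_area(bmt, window = 0.5), "frame interval")
})

test_that("surveillance is time-reversal symmetric and additive over
           disjoint cells", {
  mm <- gen_motility_movie(n_frames = 6, growth_px_per_frame = 8, seed = 4)
  fwd <- surveillance_area(mm$movie, window = 5)
  rev_masks <- mm$movie$masks[dim(mm$movie$masks)[1]:1, , ]
  rev <- surveillance_area(binary_movie(rev_masks, 0.5, 1), window = 5)
  expect_equal(fwd$scanned_area_um2, rev$scanned_area_um2)

  a <- gen_motility_movie(canvas = c(32, 32), n_frames = 6,
                          growth_px_per_frame = 5, seed = 1)$movie
  b <- gen_motility_movie(canvas = c(32, 32), n_frames = 6,
                          growth_px_per_frame = 7, seed = 2)$movie
  h <- dim(a$masks)[2]
  un <- array(FALSE, c(6, h, 64))
  un[, , 1:32] <- a$masks; un[, , 33:64] <- b$masks
  s_un <- surveillance_area(binary_movie(un, 0.5, 1), window = 5)
  s_a <- surveillance_area(a, window = 5); s_b <- surveillance_area(b, window = 5)
  expect_equal(s_un$scanned_area_um2,
               s_a$scanned_area_um2 + s_b$scanned_area_um2)
})
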