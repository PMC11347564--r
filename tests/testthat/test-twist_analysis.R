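test_that("Otsu threshold separates the classes", {
  # perfectly bimodal two-level image: any threshold in (100, 200] works
  # under the value >= threshold foreground convention
  img <- matrix(c(rep(100L, 60), rep(200L, 40)), 10, 10)
  th <- otsu_threshold(img)
  expect_true(th > 100 && th <= 200)
  expect_equal(sum(binarize(img, th)), 40)
  expect_error(otsu_threshold(matrix(7L, 4, 4)), "constant")
  expect_equal(otsu_threshold(img, manual = 150), 150)
})

test_that("Otsu equals the brute-force between-class argmax on 8-bit data", {
  set.seed(8)
  v <- as.integer(round(c(rnorm(4000, 70, 12), rnorm(2500, 180, 18))))
  v <- pmin(pmax(v, 0L), 255L)
  img <- matrix(v[1:6400], 80, 80)
  # independent oracle: exhaustive scan of all 256 candidate thresholds
  best <- -Inf; best_t <- NA
  for (t in 1:255) {
    lo <- img[img < t]; hi <- img[img >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(img)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  # thresholds are representatives of a partition: the oracle may return a
  # grey level absent from the image, so compare the partitions themselves
  expect_identical(binarize(img), img >= best_t)
  # inversion keeps the same partition (classes swap)
  inv <- 255L - img
  expect_identical(binarize(inv), !binarize(img))
})

test_that("Moore-Neighbor tracing with Jacob's stopping criterion", {
  b <- matrix(FALSE, 10, 10); b[3:5, 3:5] <- TRUE
  ch <- trace_boundaries(b)
  expect_length(ch, 1)
  expect_equal(nrow(unique(ch[[1]])), 8)   # perimeter of a 3x3 square
  b1 <- matrix(FALSE, 5, 5); b1[3, 3] <- TRUE
  expect_equal(nrow(trace_boundaries(b1)[[1]]), 1)
  b2 <- matrix(FALSE, 12, 12); b2[2:4, 2:4] <- TRUE; b2[8:10, 8:10] <- TRUE
  expect_length(trace_boundaries(b2), 2)
  expect_length(trace_boundaries(matrix(FALSE, 6, 6)), 0)
  # chains are closed 8-connected loops: consecutive pixels are adjacent
  steps <- abs(diff(ch[[1]]))
  expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))
})

test_that("petal filtering keeps the |ell| largest blobs and flags misses", {
  b <- matrix(FALSE, 64, 64)
  centers <- cbind(r = c(12, 12, 32, 52, 52), c = c(12, 52, 8, 12, 52))
  for (i in 1:5) b[centers[i, 1] + (-2:2), centers[i, 2] + (-2:2)] <- TRUE
  for (rc in list(c(30, 30), c(40, 40), c(20, 40))) b[rc[1], rc[2]] <- TRUE
  ps <- petal_filter(b, ell = 5)
  expect_equal(nrow(ps$centroids), 5)
  expect_false(ps$flagged)
  expect_true(petal_filter(matrix(FALSE, 16, 16), ell = 3)$flagged)
  # clean LG_0^3 interferogram: 3 centroids separated by 2*pi/3
  bp <- beam640(ell = 3)
  img <- interfere(lg_field(bp, default_beam_grid(bp, 256)),
                   reference_wave("plane"), camera_model())
  p3 <- petal_set(img, ell = 3)
  a <- sort(p3$centroids$angle)
  expect_equal(diff(a), rep(2 * pi / 3, 2), tolerance = 0.01)
})

test_that("relative twist: identity, rotation, seam crossing", {
  mk_ps <- function(angles) {
    structure(list(polygons = list(),
                   centroids = data.frame(radius_px = rep(20, length(angles)),
                                          angle = angles %% (2 * pi)),
                   areas = rep(100, length(angles)), flagged = FALSE,
                   center = c(32, 32), frame_id = NA),
              class = "petal_set")
  }
  base <- (0:2) * 2 * pi / 3
  ts0 <- relative_twist(list(mk_ps(base), mk_ps(base), mk_ps(base)))
  expect_equal(ts0$theta_rad, c(0, 0, 0))
  # +7 degrees about the center
  d7 <- 7 * pi / 180
  ts7 <- relative_twist(list(mk_ps(base), mk_ps(base + d7)))
  expect_equal(ts7$theta_rad[2], d7, tolerance = 1e-9)
  # crossing the 0/2pi seam: 359 deg -> 2 deg reads +3 deg, not -357
  a0 <- c(359, 119, 239) * pi / 180
  ts_seam <- relative_twist(list(mk_ps(a0), mk_ps(a0 + 3 * pi / 180)))
  expect_equal(ts_seam$theta_rad[2], 3 * pi / 180, tolerance = 1e-9)
  # rotation measured on rendered frames
  bp <- beam640(ell = 5)
  g <- default_beam_grid(bp, 256)
  f <- lg_field(bp, g)
  f2 <- f; f2$amplitude <- f$amplitude * exp(1i * 5 * d7)
  fs <- frame_stack(list(f, f2), reference_wave("plane"), camera_model())
  tm <- measure_twist(fs, ell = 5)
  expect_equal(tm$theta_deg[2], 7, tolerance = 0.1)
})

test_that("flagged frames are interpolated with a gap marker", {
  mk_ps <- function(angles, flagged = FALSE) {
    structure(list(polygons = list(),
                   centroids = data.frame(radius_px = rep(20, length(angles)),
                                          angle = angles %% (2 * pi)),
                   areas = rep(100, length(angles)), flagged = flagged,
                   center = c(32, 32), frame_id = NA),
              class = "petal_set")
  }
  base <- (0:2) * 2 * pi / 3
  sets <- list(mk_ps(base), mk_ps(base + 0.05, flagged = TRUE),
               mk_ps(base + 0.1))
  ts <- relative_twist(sets)
  expect_true(ts$flagged[2])
  expect_equal(ts$theta_rad[3], 0.1, tolerance = 1e-9)
  expect_equal(ts$theta_rad[2], 0.05, tolerance = 1e-9)  # interpolated
})

test_that("twist is insensitive to a 10% Otsu threshold perturbation", {
  bp <- beam640(ell = 3)
  g <- default_beam_grid(bp, 256)
  f <- lg_field(bp, g)
  f2 <- f; f2$amplitude <- f$amplitude * exp(1i * 3 * 5 * pi / 180)
  ref <- reference_wave("plane")
  cam <- camera_model()
  i1 <- interfere(f, ref, cam); i2 <- interfere(f2, ref, cam)
  th <- otsu_threshold(i1)
  rots <- sapply(c(1, 1.1), function(fac) {
    a <- petal_set(i1, 3, threshold = th * fac)
    b <- petal_set(i2, 3, threshold = th * fac)
    as.numeric(oamtwist:::.petal_rotation(a, b, 3)) * 180 / pi
  })
  expect_lt(abs(rots[2] - rots[1]), 0.05)
})

test_that("beam center defaults to the intensity centroid", {
  img <- matrix(0, 64, 64); img[40, 25] <- 100
  ctr <- find_beam_center(img)
  expect_equal(unname(ctr), c(25, 40))
})
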