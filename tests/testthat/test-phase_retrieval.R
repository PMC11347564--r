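mk_hologram <- function(field, carrier_cyc_px = 1 / 8) {
  g <- field$grid
  ref <- reference_wave("plane", tilt = c(2 * pi * carrier_cyc_px / g$pitch, 0))
  interfere(field, ref, camera_model())
}

test_that("retrieval of a tilted-plane-wave hologram is a pure piston", {
  g <- grid_spec(128, 128, pitch = 1e-5)
  flat <- structure(list(grid = g, z = 0,
                         amplitude = matrix(1 + 0i, 128, 128)),
                    class = "complex_field")
  pm <- retrieve_phase(mk_hologram(flat))
  sel <- pm$amplitude > 0.5 * max(pm$amplitude)
  piston <- Arg(sum(exp(1i * pm$phase[sel])))
  expect_lt(sqrt(mean(wrap_pi(pm$phase[sel] - piston)^2)), 0.01)
})

test_that("round trip recovers a known phase plate and the LG winding", {
  bp <- beam640(ell = 3)
  g <- default_beam_grid(bp, 256)
  f <- lg_field(bp, g)
  plate <- outer(seq(-1, 1, length.out = 256), seq(-1, 1, length.out = 256),
                 function(a, b) 0.8 * sin(2 * pi * a) * cos(2 * pi * b))
  fp <- f; fp$amplitude <- Mod(f$amplitude) * exp(1i * plate)
  pm <- retrieve_phase(mk_hologram(fp))
  expect_lt(phase_rms(pm$phase, plate, pm$amplitude), 0.05)
  # helical phase: winding -ell recovered exactly
  pml <- retrieve_phase(mk_hologram(f))
  fld <- structure(list(grid = g, z = 0,
                        amplitude = pml$amplitude * exp(1i * pml$phase)),
                   class = "complex_field")
  expect_equal(round(phase_winding(fld, doughnut_radius(bp))), -3)
})

test_that("retrieval linearity: a global piston shifts every pixel", {
  bp <- beam640(ell = 3)
  g <- default_beam_grid(bp, 128)
  f <- lg_field(bp, g)
  f2 <- f; f2$amplitude <- f$amplitude * exp(1i * 0.7)
  p1 <- retrieve_phase(mk_hologram(f))
  p2 <- retrieve_phase(mk_hologram(f2))
  sel <- p1$amplitude > 0.2 * max(p1$amplitude)
  d <- wrap_pi(p2$phase[sel] - p1$phase[sel])
  expect_equal(Arg(sum(exp(1i * d))), 0.7, tolerance = 1e-3)
  expect_lt(sd(d), 0.02)
})

test_that("a too-low carrier is rejected", {
  bp <- beam640(ell = 3)
  g <- default_beam_grid(bp, 128)
  img <- interfere(lg_field(bp, g),
                   reference_wave("plane", tilt = c(2 * pi / (40 * g$pitch), 0)),
                   camera_model())
  expect_error(retrieve_phase(img), "carrier too low")
})

test_that("annular mask brackets the ring and shrinks with the fraction", {
  bp <- beam640(ell = 3)
  g <- default_beam_grid(bp, 128)
  am <- annular_mask(bp, g)
  peak_px <- doughnut_radius(bp) / g$pitch
  expect_true(am$inner_px < peak_px && peak_px < am$outer_px)
  areas <- sapply(c(0.1, 0.3, 0.6, 0.9), function(fr)
    sum(annular_mask(bp, g, fraction = fr)$mask))
  expect_true(all(diff(areas) < 0))
  # intensity-image variant agrees roughly with the analytic one
  am2 <- annular_mask(Mod(lg_field(bp, g)$amplitude)^2, g)
  expect_equal(am2$inner_px, am$inner_px, tolerance = 0.25)
  expect_equal(am2$outer_px, am$outer_px, tolerance = 0.25)
  expect_error(annular_mask(beam640(ell = 0), g), "ell = 0")
})

test_that("memory map: identity, scrambled, and constructed contrast", {
  offs <- seq(-3 * pi / 10, 3 * pi / 10, length.out = 7)
  ny <- 40; nx <- 40
  # perfect memory: phase = delta everywhere -> slope 1, r^2 = 1
  ph_id <- lapply(offs, function(d) matrix(d, ny, nx))
  mm <- memory_map(ph_id, offs)
  expect_equal(max(abs(mm$slope - 1)), 0, tolerance = 1e-9)
  expect_equal(min(mm$r_squared), 1, tolerance = 1e-9)
  # fully scrambled: independent phases per offset -> the median slope over
  # 1e4 pixels vanishes (individual pixel fits are pure noise)
  set.seed(31)
  ph_sc <- lapply(offs, function(d) matrix(runif(1e4, -pi, pi), 100, 100))
  mm_sc <- memory_map(ph_sc, offs, r2_floor = 0)
  expect_lt(abs(median(mm_sc$slope)), 0.1)
  # constructed half-memory region
  m <- 0.9
  set.seed(32)
  S <- matrix(complex(real = rnorm(ny * nx), imaginary = rnorm(ny * nx)), ny, nx)
  region <- matrix(FALSE, ny, nx); region[, 1:20] <- TRUE
  ph_mix <- lapply(offs, function(d) {
    fld <- ifelse(region, NA, 1) # placeholder
    E <- m * exp(1i * d) + sqrt(1 - m^2) * S * 0.2
    Arg(ifelse(region, E, S))
  })
  mm_mix <- memory_map(ph_mix, offs, mask = region, r2_floor = 0)
  expect_gt(mm_mix$summary$inside$median_slope, 5 * abs(mm_mix$summary$outside$median_slope) - 0.05)
  expect_error(memory_map(ph_id[1:2], offs[1:2]), "length")
})

test_that("speckle grain segmentation labels every pixel near a seed", {
  set.seed(33)
  a <- Mod(speckle_field(64, 64, grain_px = 6, seed = 7))
  lab <- speckle_grains(a, min_distance = 4L)
  expect_true(all(lab > 0))
  expect_gt(max(lab), 10)
})
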