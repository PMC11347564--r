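test_that("beam parameter derivations are self-consistent", {
  bp <- beam640(ell = 3, w0 = 0.5e-3)
  expect_equal(bp$wavenumber_k, 2 * pi / 640e-9, tolerance = 1e-12)
  expect_equal(bp$rayleigh_zR, pi * (0.5e-3)^2 / 640e-9, tolerance = 1e-12)
  expect_error(beam_params(640e-9, 0.5e-3, ell = 2.5), "integer")
  expect_error(beam_params(640e-9, 0.5e-3, p = -1), "non-negative")
  # w(z) closed form
  expect_equal(beam_waist(bp, 0), 0.5e-3)
  expect_equal(beam_waist(bp, bp$rayleigh_zR), 0.5e-3 * sqrt(2))
  expect_equal(beam_waist(bp, 2 * bp$rayleigh_zR), 0.5e-3 * sqrt(5))
})

test_that("associated Laguerre recurrence matches the explicit series", {
  # independent oracle: the finite sum L_p^a(x) = sum_k (-1)^k C(p+a, p-k) x^k / k!
  lag_sum <- function(p, a, x) {
    ks <- 0:p
    sapply(x, function(xx)
      sum((-1)^ks * choose(p + a, p - ks) * xx^ks / factorial(ks)))
  }
  x <- c(0, 0.3, 1.7, 4.2, 9.5)
  for (p in c(0, 1, 2, 5)) for (a in c(0, 1, 4)) {
    expect_equal(laguerre_poly(p, a, x), lag_sum(p, a, x), tolerance = 1e-10)
  }
  # stays finite where factorial-ratio prefactors would overflow
  expect_true(all(is.finite(laguerre_poly(20, 5, seq(0, 50, by = 5)))))
})

test_that("lg_field special values match closed forms", {
  # on-axis amplitude vanishes for |ell| > 0
  bp3 <- beam640(ell = 3, w0 = 0.5e-3)
  g <- grid_spec(65, 65, pitch = 4e-5)  # odd grid: a pixel exactly on axis
  f <- lg_field(bp3, g)
  expect_identical(f$amplitude[33, 33], 0 + 0i)
  # fundamental mode peak: sqrt(2/(pi w0^2)), phase 0
  bp0 <- beam_params(640e-9, 0.5e-3, ell = 0)
  f0 <- lg_field(bp0, grid_spec(65, 65, pitch = 4e-5))
  expect_equal(Mod(f0$amplitude[33, 33]), sqrt(2 / (pi * (0.5e-3)^2)),
               tolerance = 1e-9)
  expect_equal(Arg(f0$amplitude[33, 33]), 0, tolerance = 1e-12)
  # ell = 5 ring peak at w0*sqrt(5/2): dense radial scan oracle
  bp5 <- beam640(ell = 5, w0 = 0.5e-3)
  rho <- seq(1e-6, 2e-3, length.out = 20000)
  prof <- rho^5 * exp(-rho^2 / (0.5e-3)^2)
  expect_equal(rho[which.max(prof)], 0.5e-3 * sqrt(5 / 2), tolerance = 1e-3)
  g5 <- default_beam_grid(bp5, 512)
  co <- grid_coords(g5)
  expect_equal(co$rho[which.max(Mod(lg_field(bp5, g5)$amplitude))],
               0.5e-3 * sqrt(5 / 2), tolerance = 5e-3)
  # too-small grid errors explicitly
  expect_error(lg_field(bp5, grid_spec(16, 16, pitch = 1e-5)), "underresolved")
})

test_that("energy is normalized and conserved along z", {
  bp <- beam640(ell = 4, w0 = 0.4e-3)
  for (z in c(0, 1.5, 3) * bp$rayleigh_zR) {
    g <- default_beam_grid(bp, 256, z = z)
    en <- sum(Mod(lg_field(bp, g, z)$amplitude)^2) * g$pitch^2
    expect_equal(en, 1, tolerance = 0.01)
  }
})

test_that("analytic phase agrees with arg(field) and winds by -ell", {
  bp <- beam640(ell = 3, w0 = 0.5e-3)
  z <- 0.37 * bp$rayleigh_zR
  g <- default_beam_grid(bp, 128, z = z)
  f <- lg_field(bp, g, z)
  co <- grid_coords(g)
  set.seed(4)
  idx <- sample(which(co$rho > 1e-5), 50)
  psi <- lg_phase(bp, co$rho[idx], co$phi[idx], z)
  d <- (psi - Arg(f$amplitude[idx])) %% (2 * pi)
  expect_true(all(pmin(d, 2 * pi - d) < 1e-9))
  # z = 0, p = 0: psi = -ell*phi exactly
  expect_equal(lg_phase(bp, 2e-4, 0.7, 0), -3 * 0.7, tolerance = 1e-12)
  # Gouy term at z = zR for p = 0, ell = 3: (0+3+1)*pi/4 = pi
  zR <- bp$rayleigh_zR
  # subtracting k*zR ~ 1e7 rad costs ~1e-10 absolute precision
  gouy <- lg_phase(bp, 0, 0, zR) + bp$wavenumber_k * zR
  expect_equal(gouy, pi, tolerance = 1e-8)
  # azimuthal winding: -ell, to high accuracy
  for (ell in c(-2, 1, 5)) {
    bpl <- beam640(ell = ell, w0 = 0.5e-3)
    gl <- default_beam_grid(bpl, 256)
    expect_equal(phase_winding(lg_field(bpl, gl), doughnut_radius(bpl)),
                 -ell, tolerance = 1e-6)
  }
})

test_that("waist fit recovers the generating waist", {
  bp <- beam640(ell = 3, w0 = 0.47e-3)
  g <- default_beam_grid(bp, 256)
  w_fit <- fit_beam_waist(Mod(lg_field(bp, g)$amplitude)^2, g, ell = 3)
  expect_equal(w_fit, 0.47e-3, tolerance = 0.03)
})
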