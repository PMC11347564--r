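test_that("spiral trajectory closed forms", {
  tp <- trajectory_point(0.8, 0.3, 0, ell = 3)
  expect_equal(tp$r, 0.8)
  expect_equal(tp$phi, 0.3)
  expect_equal(trajectory_point(0.8, 0, 0.5, 3)$r, 0.8 * sqrt(2))
  # zeta -> infinity: phi - phi0 -> ell*pi/(4 r0^2)
  expect_equal(trajectory_point(0.8, 0, 1e9, 3)$phi, 3 * pi / (4 * 0.8^2),
               tolerance = 1e-6)
  expect_error(trajectory_point(0, 0, 1, ell = 3), "singular")
})

test_that("trajectory arc length: limits, oracle, monotonicity", {
  # axial ray: with the longitudinal term the 3-D length is zeta_s
  expect_equal(trajectory_length(1e-9, 0, 2, ell = 0), 2, tolerance = 1e-9)
  # brute-force polyline oracle for the literal transverse-only integrand
  r0 <- 0.7; ell <- 3; zs <- 1.3
  z <- seq(0, zs, length.out = 1e6 + 1)
  r <- r0 * sqrt(1 + 4 * z^2)
  ph <- ell / (2 * r0^2) * atan(2 * z)
  x <- r * cos(ph); y <- r * sin(ph)
  polyline <- sum(sqrt(diff(x)^2 + diff(y)^2))
  lt <- trajectory_length(r0, 0, zs, ell, include_longitudinal = FALSE)
  expect_equal(lt, polyline, tolerance = 1e-6)
  # longitudinal variant is the 3-D chord sum
  poly3 <- sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
  expect_equal(trajectory_length(r0, 0, zs, ell), poly3, tolerance = 1e-6)
  # monotone in zeta_s
  expect_gt(trajectory_length(r0, 0, 2, ell), trajectory_length(r0, 0, 1, ell))
})

test_that("Poynting direction components", {
  bp <- beam640(ell = 3)
  p0 <- poynting_direction(bp, 3e-4, 0.2, 0)
  expect_equal(unname(p0["p_rho"]), 0)
  p <- poynting_direction(bp, 3e-4, 0.2, 0.1)
  # p_phi/p_z = ell/(k rho), independent of |LG|^2
  expect_equal(unname(p["p_phi"] / p["p_z"]),
               3 / (bp$wavenumber_k * 3e-4), tolerance = 1e-12)
  bp0 <- beam640(ell = 0)
  expect_equal(unname(poynting_direction(bp0, 3e-4, 0, 0.1)["p_phi"]), 0)
})

test_that("spiral matches a Runge-Kutta streamline of the direction field", {
  # dr/dz = p_rho/p_z = rho z/(zR^2+z^2); RK4 from the ring radius
  bp <- beam640(ell = 3, w0 = 0.5e-3)
  zR <- bp$rayleigh_zR
  k <- bp$wavenumber_k; w0 <- bp$waist_w0
  rho <- doughnut_radius(bp)
  zmax <- k * w0^2            # zeta = 1
  nstep <- 2000
  h <- zmax / nstep
  f <- function(rho, z) rho * z / (zR^2 + z^2)
  z <- 0
  for (i in seq_len(nstep)) {
    k1 <- f(rho, z); k2 <- f(rho + h / 2 * k1, z + h / 2)
    k3 <- f(rho + h / 2 * k2, z + h / 2); k4 <- f(rho + h * k3, z + h)
    rho <- rho + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    z <- z + h
  }
  r_closed <- (doughnut_radius(bp) / w0) * sqrt(1 + 4 * 1^2)
  expect_equal(rho / w0, r_closed, tolerance = 0.01)
})

test_that("Snell refraction through a layered stack", {
  # axial ray (ell = 0 at the waist): unchanged by any stack
  bp <- beam640(ell = 0)
  st <- cuvette_stack()
  rf <- refract_through_stack(bp, 0.5, 0, st)
  expect_equal(rf$delta_L, st$layers$d, tolerance = 1e-12)
  # 45-degree inclination into n = 1.5: refracted angle asin(sin(45)/1.5)
  bp45 <- beam_params(640e-9, 640e-9, ell = 3)  # k*w0 = 2*pi
  r0 <- 3 / (bp45$wavenumber_k * bp45$waist_w0)  # tan(theta) = 1 at zeta = 0
  glass <- medium_stack(d = 1e-3, n = 1.5)
  rf45 <- refract_through_stack(bp45, r0, 0, glass)
  expect_equal(rf45$theta_in[1], pi / 4, tolerance = 1e-9)
  expect_equal(rf45$theta_layer[1] * 180 / pi, 28.1255, tolerance = 1e-3)
  # oblique path is never shorter than the straight chord
  expect_gt(rf45$delta_L[1], 1e-3)
  # total internal reflection flagged when leaving a denser ambient
  expect_error(refract_through_stack(bp45, r0, 0, medium_stack(d = 1e-3, n = 1),
                                     n_ambient = 1.5), "internal reflection")
})

test_that("phase retardation formula is exact", {
  expect_equal(phase_retardation(640e-9, 1, 640e-9), 2 * pi)
  expect_equal(phase_retardation(0, 1.5, 640e-9), 0)
  # retardation difference for the reference thermal-run numbers
  d1 <- phase_retardation(3.6e-3, 1.3330 + 3.69e-4, 640e-9)
  d0 <- phase_retardation(3.6e-3, 1.3330, 640e-9)
  expect_equal(d1 - d0, 2 * pi * 3.69e-4 * 3.6e-3 / 640e-9, tolerance = 1e-9)
})

test_that("predicted twist: null case, monotonicity, linearity, ell-invariance", {
  cuv <- cuvette_stack()
  bp3 <- beam640(ell = 3)
  dn <- seq(0, 2e-5, length.out = 5)
  p3 <- predict_twist_series(bp3, cuv, dn, n_traj = 5000, seed = 11)
  # delta_n = 0 reference and strict monotonicity
  expect_equal(p3$theta_rad[1], 0)
  expect_true(all(diff(p3$theta_rad) > 0))
  # null series
  p0 <- predict_twist_series(bp3, cuv, c(0, 0, 0), n_traj = 5000, seed = 11)
  expect_equal(max(abs(p0$theta_rad)), 0, tolerance = 1e-6)
  # linear in delta_n within 2%
  fit <- lm(theta_rad ~ delta_n, data = p3)
  expect_lt(max(abs(residuals(fit))) / max(abs(p3$theta_rad)), 0.02)
  # the OAM phase twist psi = ell*theta is common to ell = 3 and 5 within 10%
  bp5 <- beam640(ell = 5)
  p5 <- predict_twist_series(bp5, cuv, dn, n_traj = 5000, seed = 11)
  expect_lt(max(abs(p3$psi_rad[-1] / p5$psi_rad[-1] - 1)), 0.10)
  # sensitivity floor: delta_n = 1e-6 is resolvable
  pf <- predict_twist_series(bp3, cuv, c(0, 1e-6), n_traj = 5000, seed = 12)
  expect_gt(abs(pf$theta_deg[2]), 0.2)
  # guards
  expect_error(predict_twist_series(bp3, cuv, dn, n_traj = 100), ">= 1e3")
  expect_error(predict_twist_series(bp3, cuv, c(0, 2e-5, 1e-5), n_traj = 5000),
               "monotone")
})
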