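test_that("optical depth and length scales", {
  expect_equal(optical_depth(1e-3, 10e3, 0.8), 2)
  expect_equal(optical_depth(8e-3, 6e3, 0.8), 9.6)
  expect_equal(optical_depth(2e-3, 5e3, 0), 2e-3 * 5e3)
  expect_error(optical_depth(1e-3, 10e3, 1), "undefined")
  # xi_L closed form (frozen from direct evaluation of the closed form)
  expect_equal(depolarization_length(1), 0.9667252716, tolerance = 1e-9)
  expect_equal(depolarization_length(2), 2 * depolarization_length(1))
  expect_equal(depolarization_length(1e-4), 9.667253e-5, tolerance = 1e-6)
  ss <- scatter_summary(8e-3, 6e3, 0.8)
  expect_equal(ss$l_s, ss$l_star * (1 - 0.8), tolerance = 1e-15)
  expect_equal(ss$optical_depth, 9.6)
})

test_that("degree of polarization follows the stated closed form", {
  expect_equal(degree_of_polarization(0, 1), 0)
  # frozen derived value: 2*sinh(1.034420)*exp(-1.034420)
  expect_equal(degree_of_polarization(1, 1), 0.8736678, tolerance = 1e-6)
  # strictly decreasing beyond the maximum at L = xi_L
  xi <- depolarization_length(1)
  L <- seq(1.5 * xi, 20 * xi, length.out = 50)
  expect_true(all(diff(degree_of_polarization(L, 1)) < 0))
  # clipped variant never exceeds 1
  expect_true(all(degree_of_polarization(seq(0, 5, by = 0.1), 1, clip = TRUE) <= 1))
})

test_that("regime labels follow the d/l* guideline", {
  expect_equal(regime_label(2), "low/intermediate")
  expect_equal(regime_label(12), "multiple/diffuse")
  expect_equal(regime_label(9.6), "low/intermediate")
  expect_equal(regime_label(9.6, refine = TRUE), "intermediate/near-diffuse")
  expect_equal(regime_label(10), "multiple/diffuse")
})

test_that("Henyey-Greenstein sampling reproduces g", {
  th <- sample_scatter(1e6, 0, seed = 21)
  expect_true(all(th >= 0 & th <= pi))
  expect_equal(mean(cos(th)), 0, tolerance = 0.003)
  th8 <- sample_scatter(1e6, 0.8, seed = 22)
  expect_equal(mean(cos(th8)), 0.8, tolerance = 0.002)
})

test_that("MC free paths, bookkeeping and event counts", {
  bp <- beam640(ell = 3)
  # optically thick slab: the first sampled free path is untruncated
  thick <- medium_stack(d = 10e-3, n = 1.4, mus = 3e3, mua = 0.05e3, g = 0.8)
  mc <- mc_propagate(bp, thick, detector_spec(nx = 32, ny = 32), n_ph = 4e5,
                     seed = 5)
  expect_equal(mc$mean_first_path * 3.05e3, 1, tolerance = 0.005)
  b <- mc$bookkeeping
  bal <- b$absorbed + b$escaped_front + b$escaped_back + b$capped +
    b$roulette_killed - b$roulette_boost
  expect_equal(bal, b$launched, tolerance = 1e-6)
  # transmitted photons scatter more at higher optical depth
  m2 <- mc_propagate(bp, phantom_low(), detector_spec(nx = 32, ny = 32),
                     n_ph = 5e4, seed = 6)
  m96 <- mc_propagate(bp, phantom_multi(), detector_spec(nx = 32, ny = 32),
                      n_ph = 5e4, seed = 6)
  expect_gt(m96$mean_events_transmitted, m2$mean_events_transmitted)
  b2 <- m2$bookkeeping
  expect_equal(b2$absorbed + b2$escaped_front + b2$escaped_back + b2$capped +
                 b2$roulette_killed - b2$roulette_boost, b2$launched,
               tolerance = 1e-6)
})

test_that("mus -> 0 reproduces the unscattered refraction/retardation field", {
  bp <- beam640(ell = 3)
  mk <- function(n_in) {
    st <- medium_stack(d = 3.6e-3, n = n_in, mus = 1e-6, mua = 0, g = 0)
    mc_field(mc_propagate(bp, st, detector_spec(), n_ph = 1e5, seed = 9), 0)
  }
  f0 <- mk(1.3616)
  expect_equal(phase_winding(f0, doughnut_radius(bp)), -3, tolerance = 1e-3)
  f1 <- mk(1.3616 + 1e-4)
  sel <- Mod(f0$amplitude) > 0.1 * max(Mod(f0$amplitude))
  piston <- Arg(sum(exp(1i * (Arg(f1$amplitude)[sel] - Arg(f0$amplitude)[sel]))))
  pred <- wrap_pi((2 * pi * 1e-4 * 3.6e-3 / 640e-9) %% (2 * pi))
  expect_equal(wrap_pi(piston - pred), 0, tolerance = 1e-3)
})

test_that("SLM offset composition is a pure coherent piston", {
  bp <- beam640(ell = 3)
  mc <- mc_propagate(bp, phantom_low(), detector_spec(nx = 64, ny = 64),
                     n_ph = 2e4, seed = 3)
  fa <- mc_field(mc, 0.4)
  fb <- mc_field(mc, 0)
  expect_equal(fa$amplitude, mc$coh * exp(0.4i) + mc$frozen, tolerance = 1e-12)
  expect_equal(fb$amplitude, mc$coh + mc$frozen, tolerance = 1e-12)
  # P(L) diagnostic map is within [0, 1] where defined
  pv <- mc$p_map[!is.na(mc$p_map)]
  expect_true(all(pv >= 0 & pv <= 1))
})
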