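#' Synthetic thermal run: temperature and refractive-index drift
#'
#' Emulates the cuvette protocol: a pre-cooled sample relaxes exponentially
#' from `T0` towards room temperature while frames are acquired at `fps`.
#' The refractive index follows a linear-in-temperature law
#' `n(t) = n_ref + c_nT (T(t) - T_ref)`; by default `c_nT` is chosen so the
#' run's total |Delta n| equals `target_delta_n` exactly (the tabulated
#' ethanol-water n(T) dependence is replaced by this configurable linear
#' coefficient). `c_nT` is negative by default (liquids rarefy on heating,
#' dn/dT < 0), so n decreases during the run; the magnitude is what the
#' sensing chain measures.
#'
#' @param duration_s run duration, seconds (default 25 min)
#' @param fps frame rate (default 10)
#' @param T0 starting temperature, deg C
#' @param T_room ambient temperature, deg C
#' @param tau_s thermal relaxation time constant, seconds
#' @param n_ref refractive index at `T_ref`
#' @param T_ref reference temperature for the linear law, deg C
#' @param c_nT dn/dT coefficient (1/deg C); NULL = derive from
#'   `target_delta_n`
#' @param target_delta_n total |Delta n| over the run when `c_nT` is derived
#' @return object of class `thermal_run`: data.frame(frame, t_s, T_C, n)
#'   with attributes `c_nT` and `total_delta_n`
#' @export
make_thermal_run <- function(duration_s = 1500, fps = 10, T0 = 7.8,
                             T_room = 21, tau_s = 480, n_ref = 1.3616,
                             T_ref = 21, c_nT = NULL,
                             target_delta_n = 3.69e-4) {
  stopifnot(duration_s > 0, fps > 0, tau_s > 0)
  t <- seq(0, by = 1 / fps, length.out = round(duration_s * fps))
  TC <- T_room - (T_room - T0) * exp(-t / tau_s)
  if (is.null(c_nT)) {
    dT <- TC[length(TC)] - TC[1]
    c_nT <- if (dT == 0) 0 else -target_delta_n / dT
  }
  n <- n_ref + c_nT * (TC - T_ref)
  out <- data.frame(frame = seq_along(t), t_s = t, T_C = TC, n = n)
  attr(out, "c_nT") <- c_nT
  attr(out, "total_delta_n") <- n[length(n)] - n[1]
  class(out) <- c("thermal_run", "data.frame")
  out
}

#' On-axis petal interferogram stack for a thermal run
#'
#' The forward generator for the sensing chain. Per frame, the
#' refractive-index change of the cuvette interior is converted to
#' per-trajectory phase retardations over a seeded |LG|^2 trajectory
#' ensemble; the resulting petal pattern is rendered against the reference
#' wave and quantized by the camera. The programmed twist ground truth
#' `Theta*(t) = mean(Delta Psi)/ell` is stored beside the stack.
#'
#' `method = "ensemble"` renders the azimuthally binned trajectory-ensemble
#' phase profile (the full forward model); `"linear"` applies the
#' ensemble-mean piston only (fast path, identical to first order).
#'
#' @param run a [make_thermal_run()] result
#' @param params a [beam_params()]
#' @param stack a [medium_stack()] (default [cuvette_stack()] at the run's
#'   initial n)
#' @param grid rendering grid (default [default_beam_grid()])
#' @param cam a [camera_model()]
#' @param ref a [reference_wave()]
#' @param n_frames frames in the rendered stack (evenly subsampled from the
#'   run; default 64 -- the full 15000-frame run is available by asking)
#' @param n_traj trajectory ensemble size
#' @param method "ensemble" or "linear"
#' @param interior_layer index of the probed layer (default thickest)
#' @param seed RNG seed
#' @return list(stack = frame_stack, truth = data.frame(frame, t_s, delta_n,
#'   theta_true_rad, theta_true_deg), mean_dL, seed)
#' @export
make_twist_stack <- function(run, params, stack = NULL, grid = NULL,
                             cam = camera_model(), ref = reference_wave(),
                             n_frames = 64L, n_traj = 20000L,
                             method = c("ensemble", "linear"),
                             interior_layer = NULL, seed = 1L) {
  stopifnot(inherits(run, "thermal_run"), inherits(params, "beam_params"))
  method <- match.arg(method)
  if (is.null(stack)) stack <- cuvette_stack(n_interior = run$n[1])
  if (is.null(grid)) grid <- default_beam_grid(params)
  if (is.null(interior_layer)) interior_layer <- which.max(stack$layers$d)
  idx <- unique(round(seq(1, nrow(run), length.out = n_frames)))
  delta_n <- run$n[idx] - run$n[idx[1]]
  set.seed(seed)
  starts <- sample_lg_starts(params, n_traj)
  dL <- .interior_paths(params, starts$r0, stack, interior_layer)
  k <- params$wavenumber_k; w0 <- params$waist_w0
  zeta_exit <- (stack$z_offset + sum(stack$layers$d)) / (k * w0^2)
  phi_exit <- .exit_phi(starts$r0, starts$phi0, zeta_exit, params$ell)
  theta_true <- 2 * pi * delta_n * mean(dL) / params$wavelength / params$ell
  base <- lg_field(params, grid)
  fields <- lapply(seq_along(idx), function(j) {
    fld <- base
    if (method == "linear") {
      fld$amplitude <- fld$amplitude * exp(1i * params$ell * theta_true[j])
    } else {
      dpsi <- 2 * pi * delta_n[j] * dL / params$wavelength
      u <- .azimuthal_profile(phi_exit, dpsi, 360L)
      fld$amplitude <- fld$amplitude * .profile_on_grid(u, grid, 360L)
    }
    fld
  })
  fs <- frame_stack(fields, ref, cam, times = run$t_s[idx])
  truth <- data.frame(frame = seq_along(idx), t_s = run$t_s[idx],
                      delta_n = delta_n,
                      theta_true_rad = theta_true,
                      theta_true_deg = theta_true * 180 / pi)
  list(stack = fs, truth = truth, mean_dL = mean(dL), seed = seed)
}

#' Band-limited complex speckle field
#'
#' Circular complex Gaussian white noise, optionally low-pass filtered in the
#' Fourier domain so the speckle grain size (amplitude correlation width) is
#' about `grain_px` pixels, then rescaled to unit mean power. `grain_px = 1`
#' returns i.i.d. pixels.
#'
#' @param ny,nx field dimensions
#' @param grain_px speckle grain size in pixels
#' @param seed RNG seed
#' @return complex matrix with unit mean |.|^2
#' @export
speckle_field <- function(ny, nx = ny, grain_px = 1, seed = 1L) {
  set.seed(seed)
  s <- matrix(complex(real = rnorm(ny * nx), imaginary = rnorm(ny * nx)),
              ny, nx) / sqrt(2)
  if (grain_px > 1) {
    fx <- ((seq_len(nx) - 1 + floor(nx / 2)) %% nx) - floor(nx / 2)
    fy <- ((seq_len(ny) - 1 + floor(ny / 2)) %% ny) - floor(ny / 2)
    f2 <- outer(fy^2, fx^2, `+`)
    sig_f <- nx / (2 * pi * grain_px) * 2   # cutoff sets the grain
    H <- exp(-f2 / (2 * sig_f^2))
    s <- stats::fft(stats::fft(s) * H, inverse = TRUE) / length(s)
  }
  s / sqrt(mean(Mod(s)^2))
}

#' Speckle stack specification
#'
#' @param grain_px speckle grain size, pixels
#' @param m_inside phase-memory fraction inside the annulus, in [0, 1]
#' @param m_outside phase-memory fraction outside the annulus
#' @param regime optional d/l* label this spec emulates
#' @return object of class `speckle_spec`
#' @export
speckle_spec <- function(grain_px = 8, m_inside = 1, m_outside = 0,
                         regime = NA_real_) {
  stopifnot(m_inside >= 0, m_inside <= 1, m_outside >= 0, m_outside <= 1)
  structure(list(grain_px = grain_px, m_inside = m_inside,
                 m_outside = m_outside, regime = regime),
            class = "speckle_spec")
}

#' Partially phase-preserving speckle fields over SLM offsets
#'
#' Emulates the phase-memory phenomenology without Monte Carlo cost. For
#' each offset delta the field is
#' `E = m (LG e^{i delta}) + sqrt(1 - m^2) env S`, with `m` the per-region
#' memory fraction (inside vs outside the annular mask), `S` a frozen
#' (delta-independent) speckle field, and `env` a smooth envelope (the LG
#' amplitude plus a diffuse halo at 35% of the peak) so there is light to
#' measure everywhere. Deterministic per seed.
#'
#' @param spec a [speckle_spec()]
#' @param params a [beam_params()]
#' @param offsets SLM phase offsets, radians (default 7 values spanning
#'   -3*pi/10 .. 3*pi/10)
#' @param grid a [grid_spec()] (default [default_beam_grid()])
#' @param seed RNG seed for the frozen speckle
#' @return list(fields = list of `complex_field` per offset, offsets, mask =
#'   [annular_mask()], spec, seed)
#' @export
make_speckle_stack <- function(spec, params,
                               offsets = seq(-3 * pi / 10, 3 * pi / 10,
                                             length.out = 7),
                               grid = NULL, seed = 1L) {
  stopifnot(inherits(spec, "speckle_spec"), inherits(params, "beam_params"))
  if (is.null(grid)) grid <- default_beam_grid(params)
  lg <- lg_field(params, grid)
  mask <- annular_mask(params, grid)
  m <- ifelse(mask$mask, spec$m_inside, spec$m_outside)
  S <- speckle_field(grid$ny, grid$nx, grain_px = spec$grain_px, seed = seed)
  peak <- max(Mod(lg$amplitude))
  env <- 0.35 * peak + 0.65 * Mod(lg$amplitude)
  fields <- lapply(offsets, function(d) {
    fld <- lg
    fld$amplitude <- m * lg$amplitude * exp(1i * d) +
      sqrt(1 - m^2) * env * S
    fld
  })
  list(fields = fields, offsets = offsets, mask = mask, spec = spec,
       seed = seed)
}
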