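#' Point on a spiral LG photon trajectory
#'
#' Closed forms in the dimensionless coordinates `r = rho/w0`,
#' `zeta = z/(k w0^2)`:
#' \deqn{r(\zeta) = r_0\sqrt{1+4\zeta^2},\qquad
#'   \varphi(\zeta) = \frac{\ell}{2 r_0^2}\arctan(2\zeta) + \varphi_0}
#'
#' @param r0 starting dimensionless radius (> 0 when ell != 0)
#' @param phi0 starting azimuth, radians
#' @param zeta dimensionless axial position (vectorised)
#' @param ell topological charge
#' @return list with numeric vectors `r` and `phi`
#' @export
trajectory_point <- function(r0, phi0, zeta, ell) {
  if (r0 <= 0 && ell != 0) stop("r0 = 0 with ell != 0: azimuthal term singular")
  if (r0 < 0) stop("r0 must be non-negative")
  list(r = r0 * sqrt(1 + 4 * zeta^2),
       phi = if (ell == 0) rep(phi0, length(zeta))
             else ell / (2 * r0^2) * atan(2 * zeta) + phi0)
}

# dimensionless transverse speed^2 of the spiral at zeta:
# (dr/dzeta)^2 + r^2 (dphi/dzeta)^2
.spiral_speed2_t <- function(r0, zeta, ell) {
  drdz <- 4 * r0 * zeta / sqrt(1 + 4 * zeta^2)
  if (ell == 0) return(drdz^2)
  r <- r0 * sqrt(1 + 4 * zeta^2)
  dphidz <- ell / (r0^2 * (1 + 4 * zeta^2))
  drdz^2 + (r * dphidz)^2
}

#' Arc length of a spiral LG trajectory
#'
#' Integrates the trajectory speed from 0 to `zeta_s` by adaptive quadrature
#' (relative tolerance 1e-10). With `include_longitudinal = FALSE` the
#' integrand is the transverse arc-length density
#' `sqrt((dr/dzeta)^2 + r^2 (dphi/dzeta)^2)` in its literal transverse-only
#' form; with the
#' default `TRUE` a `+1` is added under the radical so the result is the 3-D
#' geometric path in units of `k w0^2` -- required for the phase-retardation
#' bookkeeping to reduce to the ordinary `2 pi n d / lambda` for axial rays.
#'
#' @inheritParams trajectory_point
#' @param zeta_s end point of the integration (>= 0)
#' @param include_longitudinal include the axial term (default TRUE)
#' @return dimensionless arc length
#' @export
trajectory_length <- function(r0, phi0, zeta_s, ell, include_longitudinal = TRUE) {
  stopifnot(zeta_s >= 0)
  if (r0 <= 0 && ell != 0) stop("r0 = 0 with ell != 0: azimuthal term singular")
  if (zeta_s == 0) return(0)
  base <- if (include_longitudinal) 1 else 0
  f <- function(z) sqrt(base + .spiral_speed2_t(r0, z, ell))
  integrate(f, 0, zeta_s, rel.tol = 1e-10, abs.tol = 0)$value
}

#' Poynting vector direction of an LG beam
#'
#' Cylindrical components (up to the common constant prefactors of the mode):
#' \deqn{p_\rho = \frac{\omega k \rho z}{z_R^2+z^2}|LG|^2,\quad
#'   p_\phi = \frac{\omega\ell}{\rho}|LG|^2,\quad p_z = \omega k |LG|^2}
#'
#' @param params a [beam_params()]
#' @param rho radius in metres (> 0)
#' @param phi azimuth, radians
#' @param z propagation distance, metres
#' @return named numeric vector c(p_rho, p_phi, p_z)
#' @export
poynting_direction <- function(params, rho, phi, z) {
  stopifnot(inherits(params, "beam_params"), rho > 0)
  wz <- beam_waist(params, z)
  al <- abs(params$ell)
  inten <- (.lg_prefactor(params$p, al) / wz *
              (rho * sqrt(2) / wz)^al *
              laguerre_poly(params$p, al, 2 * rho^2 / wz^2) *
              exp(-rho^2 / wz^2))^2
  w <- params$angular_frequency
  k <- params$wavenumber_k
  zR <- params$rayleigh_zR
  c(p_rho = w * k * rho * z / (zR^2 + z^2) * inten,
    p_phi = w * params$ell / rho * inten,
    p_z = w * k * inten)
}

#' Layered medium (cuvette walls + interior, or phantom slab)
#'
#' Ordered planar layers, each with thickness `d` (m), refractive index `n`,
#' scattering coefficient `mus` (1/m), absorption coefficient `mua` (1/m) and
#' scattering anisotropy `g = <cos theta>`.
#'
#' @param d numeric vector of layer thicknesses, metres (> 0)
#' @param n refractive indices (>= 1)
#' @param mus scattering coefficients, 1/m (>= 0)
#' @param mua absorption coefficients, 1/m (>= 0)
#' @param g anisotropy factors in [0, 1)
#' @param z_offset axial position of the stack entrance, metres
#' @return object of class `medium_stack`
#' @export
medium_stack <- function(d, n, mus = 0, mua = 0, g = 0, z_offset = 0) {
  nl <- length(d)
  n <- rep_len(n, nl); mus <- rep_len(mus, nl)
  mua <- rep_len(mua, nl); g <- rep_len(g, nl)
  stopifnot(all(d > 0), all(n >= 1), all(mus >= 0), all(mua >= 0),
            all(g >= 0), all(g < 1))
  structure(list(layers = data.frame(d = d, n = n, mus = mus, mua = mua, g = g),
                 z_offset = z_offset),
            class = "medium_stack")
}

#' Ethanol-water cuvette stack
#'
#' Convenience constructor for the default sensing geometry: 5.6 mm total
#' thickness, two 1 mm glass walls (n = 1.5168) around a 3.6 mm liquid
#' interior.
#'
#' @param n_interior interior refractive index
#' @param n_glass wall refractive index
#' @param d_total,d_wall total / wall thicknesses in metres
#' @return a [medium_stack()]
#' @export
cuvette_stack <- function(n_interior = 1.3616, n_glass = 1.5168,
                          d_total = 5.6e-3, d_wall = 1e-3) {
  d_in <- d_total - 2 * d_wall
  stopifnot(d_in > 0)
  medium_stack(d = c(d_wall, d_in, d_wall),
               n = c(n_glass, n_interior, n_glass))
}

#' @export
print.medium_stack <- function(x, ...) {
  cat(sprintf("medium stack, %d layer(s), total %.3g mm (entrance at z = %.3g m)\n",
              nrow(x$layers), sum(x$layers$d) * 1e3, x$z_offset))
  print(x$layers)
  invisible(x)
}

#' Refract a spiral trajectory through a layered stack
#'
#' Bends the trajectory's local direction at each planar interface by Snell's
#' law, using the analytic tangent of the spiral (not a finite difference) for
#' the instantaneous inclination to the z-axis, and recomputes the geometric
#' pathlength per layer on the bent path. For the paraxial spirals involved
#' the inclination is milliradian-scale, so each in-layer segment is the layer
#' thickness divided by the cosine of the refracted inclination, plus the
#' spiral's own transverse arc contribution scaled into the layer.
#'
#' @param params a [beam_params()] (supplies `k` and `w0` for the
#'   dimensionless-to-physical conversion)
#' @param r0,phi0 trajectory start (dimensionless radius, azimuth)
#' @param stack a [medium_stack()]; its entrance is at `z_offset`
#' @param n_ambient refractive index before the first interface
#' @return data.frame, one row per layer: `n`, `d`, `theta_in`, `theta_layer`
#'   (radians), `delta_L` (m, geometric path within the layer),
#'   `delta_psi` (rad, `2 pi n delta_L / lambda`)
#' @export
refract_through_stack <- function(params, r0, phi0, stack, n_ambient = 1) {
  stopifnot(inherits(params, "beam_params"), inherits(stack, "medium_stack"))
  k <- params$wavenumber_k
  w0 <- params$waist_w0
  lay <- stack$layers
  zb <- stack$z_offset + cumsum(c(0, lay$d))  # interface z positions
  out <- lay
  out$theta_in <- NA_real_; out$theta_layer <- NA_real_
  out$delta_L <- NA_real_; out$delta_psi <- NA_real_
  n_prev <- n_ambient
  for (i in seq_len(nrow(lay))) {
    zeta_i <- zb[i] / (k * w0^2)
    # inclination of the spiral tangent to the z axis at the interface
    st2 <- .spiral_speed2_t(r0, zeta_i, params$ell)
    tan_th <- sqrt(st2) / (k * w0)          # physical transverse slope
    th_in <- atan(tan_th)
    s <- n_prev * sin(th_in) / lay$n[i]
    if (s >= 1) stop("total internal reflection at interface ", i,
                     ": check stack configuration")
    th_l <- asin(s)
    dL <- lay$d[i] / cos(th_l)
    out$theta_in[i] <- th_in
    out$theta_layer[i] <- th_l
    out$delta_L[i] <- dL
    out$delta_psi[i] <- phase_retardation(dL, lay$n[i], params$wavelength)
    n_prev <- lay$n[i]
  }
  out
}

#' Phase retardation from a geometric pathlength
#'
#' `delta_psi = 2 pi n delta_L / lambda` exactly.
#'
#' @param delta_L geometric pathlength in metres (>= 0, vectorised)
#' @param n refractive index
#' @param wavelength wavelength in metres
#' @return retardation in radians
#' @export
phase_retardation <- function(delta_L, n, wavelength) {
  stopifnot(all(delta_L >= 0), wavelength > 0)
  2 * pi * n * delta_L / wavelength
}

# vectorized per-trajectory geometric path in one layer of the stack
# (same physics as refract_through_stack, without per-trajectory overhead)
.interior_paths <- function(params, r0, stack, layer_index) {
  k <- params$wavenumber_k
  w0 <- params$waist_w0
  lay <- stack$layers
  zb <- stack$z_offset + cumsum(c(0, lay$d))
  zeta_i <- zb[layer_index] / (k * w0^2)
  st2 <- .spiral_speed2_t_vec(r0, zeta_i, params$ell)
  th <- atan(sqrt(st2) / (k * w0))
  # Snell chain from ambient through the preceding layers
  n_prev <- 1
  s <- sin(th)
  for (i in seq_len(layer_index)) {
    s <- n_prev * s / lay$n[i]
    n_prev <- lay$n[i]
  }
  if (any(s >= 1)) stop("total internal reflection in .interior_paths")
  lay$d[layer_index] / cos(asin(s))
}

.spiral_speed2_t_vec <- function(r0, zeta, ell) {
  drdz <- 4 * r0 * zeta / sqrt(1 + 4 * zeta^2)
  if (ell == 0) return(drdz^2)
  r <- r0 * sqrt(1 + 4 * zeta^2)
  dphidz <- ell / (r0^2 * (1 + 4 * zeta^2))
  drdz^2 + (r * dphidz)^2
}

# vectorized exit azimuth of the spiral
.exit_phi <- function(r0, phi0, zeta, ell) {
  if (ell == 0) return(phi0)
  ell / (2 * r0^2) * atan(2 * zeta) + phi0
}

#' Sample LG trajectory starting points
#'
#' Draws starts proportional to the |LG|^2 annular profile at z = 0: for
#' p = 0 the radial density of `rho^2` is Gamma(|ell| + 1, scale = w0^2/2),
#' so `r0 = sqrt(rgamma(.)) / w0`; azimuths are uniform.
#'
#' @param params a [beam_params()] (p = 0 assumed for the inverse-CDF draw)
#' @param n_traj number of trajectories
#' @return data.frame with columns `r0` (dimensionless), `phi0` (rad)
#' @export
sample_lg_starts <- function(params, n_traj) {
  stopifnot(n_traj >= 1)
  if (params$p != 0L)
    warning("start sampling uses the p = 0 radial profile")
  al <- abs(params$ell)
  rho2 <- rgamma(n_traj, shape = al + 1, scale = params$waist_w0^2 / 2)
  data.frame(r0 = sqrt(rho2) / params$waist_w0,
             phi0 = runif(n_traj, 0, 2 * pi))
}

#' Predict the petal-twist response to refractive-index change
#'
#' Launches `n_traj` spiral trajectory starts sampled from |LG|^2, computes
#' each trajectory's refracted geometric pathlength through the stack's
#' interior layer, accumulates the per-trajectory phase retardation for every
#' `delta_n` in the series relative to `delta_n = 0`, reconstructs the
#' transverse petal interference pattern, and measures its rotation with the
#' same petal algorithm used on experimental stacks (closed loop), so model
#' and measurement share one definition of "twist".
#'
#' @param params a [beam_params()]
#' @param stack a [medium_stack()]; `interior_layer` indexes the probed layer
#' @param delta_n_series monotone numeric vector of refractive-index changes
#'   applied to the interior layer (first entry should be 0 for a reference)
#' @param n_traj number of trajectories (>= 1e3)
#' @param interior_layer index of the probed layer (default: thickest)
#' @param grid rendering grid (default 256 x 256 sized to the beam)
#' @param n_phi_bins azimuthal bins for the trajectory-ensemble field
#' @param seed RNG seed recorded in the output
#' @return object of class `twist_prediction`: data.frame with `delta_n`,
#'   `theta_rad`, `theta_deg` (petal rotation), `psi_rad` (OAM phase twist
#'   `ell * theta`), plus attributes `n_traj`, `seed`, `flagged`
#' @export
predict_twist_series <- function(params, stack, delta_n_series, n_traj = 20000,
                                 interior_layer = NULL, grid = NULL,
                                 n_phi_bins = 360L, seed = 1L) {
  stopifnot(inherits(params, "beam_params"), inherits(stack, "medium_stack"))
  if (n_traj < 1000) stop("n_traj must be >= 1e3 for stable petals")
  if (is.unsorted(delta_n_series) && is.unsorted(rev(delta_n_series)))
    stop("delta_n_series must be monotone")
  if (is.null(interior_layer)) interior_layer <- which.max(stack$layers$d)
  set.seed(seed)
  starts <- sample_lg_starts(params, n_traj)

  # per-trajectory geometric path in the interior layer (refraction included)
  dL <- .interior_paths(params, starts$r0, stack, interior_layer)

  if (is.null(grid)) grid <- default_beam_grid(params)
  flagged <- n_traj < 5000

  # exit azimuth of each trajectory at the stack exit
  k <- params$wavenumber_k; w0 <- params$waist_w0
  zeta_exit <- (stack$z_offset + sum(stack$layers$d)) / (k * w0^2)
  phi_exit <- .exit_phi(starts$r0, starts$phi0, zeta_exit, params$ell)

  ref <- reference_wave(kind = "plane", amplitude_ratio = 1)
  cam <- camera_model(shot_noise = FALSE)
  base_field <- lg_field(params, grid)
  theta <- numeric(length(delta_n_series))
  prev_piston <- 0
  prev_theta <- 0
  for (j in seq_along(delta_n_series)) {
    dn <- delta_n_series[j]
    dpsi <- 2 * pi * dn * dL / params$wavelength  # retardation rel. to dn = 0
    u <- .azimuthal_profile(phi_exit, dpsi, n_phi_bins)
    fld <- base_field
    fld$amplitude <- fld$amplitude * .profile_on_grid(u, grid, n_phi_bins)
    img <- interfere(fld, ref, cam)
    ps <- petal_set(img, ell = params$ell, center = grid$origin)
    theta[j] <- if (j == 1) 0 else {
      # track rotation relative to the previous step to avoid petal aliasing
      prev_theta + .petal_rotation(prev_ps, ps, params$ell)
    }
    prev_ps <- ps
    prev_theta <- theta[j]
  }
  theta <- theta - theta[1]
  out <- data.frame(delta_n = delta_n_series,
                    theta_rad = theta,
                    theta_deg = theta * 180 / pi,
                    psi_rad = theta * params$ell)
  attr(out, "n_traj") <- n_traj
  attr(out, "seed") <- seed
  attr(out, "flagged") <- flagged
  class(out) <- c("twist_prediction", "data.frame")
  out
}

# weighted circular accumulation of exp(i dpsi) into azimuthal bins;
# returns complex unit-ish profile per bin
.azimuthal_profile <- function(phi, dpsi, n_bins) {
  b <- (floor(phi %% (2 * pi) / (2 * pi) * n_bins) %% n_bins) + 1L
  re <- as.vector(tapply(cos(dpsi), factor(b, levels = seq_len(n_bins)), sum))
  im <- as.vector(tapply(sin(dpsi), factor(b, levels = seq_len(n_bins)), sum))
  re[is.na(re)] <- 0; im[is.na(im)] <- 0
  u <- complex(real = re, imaginary = im)
  m <- Mod(u)
  # empty bins inherit the global mean phase; amplitude kept at unity so the
  # LG envelope is untouched (the ensemble modulates phase, not intensity)
  gl <- Arg(sum(u))
  ph <- ifelse(m > 0, Arg(u), gl)
  exp(1i * ph)
}

.profile_on_grid <- function(u, grid, n_bins) {
  co <- grid_coords(grid)
  b <- (floor(co$phi %% (2 * pi) / (2 * pi) * n_bins) %% n_bins) + 1L
  matrix(u[b], grid$ny, grid$nx)
}

#' Default rendering grid for a beam
#'
#' 256 x 256 with the pitch chosen so the doughnut diameter spans about one
#' third of the frame, mimicking the detector-plane framing of the reported
#' setup.
#'
#' @param params a [beam_params()]
#' @param n pixels per side
#' @param z propagation distance used for the doughnut size
#' @return a [grid_spec()]
#' @export
default_beam_grid <- function(params, n = 256L, z = 0) {
  dia <- 2 * doughnut_radius(params, z)
  grid_spec(n, n, pitch = 3 * dia / n)
}
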