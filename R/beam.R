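#' Laguerre-Gaussian beam parameters
#'
#' Bundles the quantities every LG-mode evaluation needs: wavelength, the
#' zero-order Gaussian waist `w(0)`, the topological charge `ell` (signed
#' integer winding number of the helical phase), and the radial index `p`.
#' Derived quantities (wavenumber `k = 2*pi/lambda`, Rayleigh range
#' `zR = pi*w0^2/lambda`, angular frequency `omega = 2*pi*c/lambda`) are
#' computed once and stored.
#'
#' @param wavelength wavelength in metres (> 0)
#' @param waist_w0 zero-order Gaussian beam waist in metres (> 0)
#' @param ell topological charge, signed integer
#' @param p radial index, non-negative integer
#' @return an object of class `beam_params`
#' @examples
#' bp <- beam_params(wavelength = 640e-9, waist_w0 = 0.5e-3, ell = 3)
#' bp$rayleigh_zR
#' @export
beam_params <- function(wavelength, waist_w0, ell = 0L, p = 0L) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(waist_w0), length(waist_w0) == 1L, waist_w0 > 0)
  if (abs(ell - round(ell)) > 1e-9) stop("topological charge `ell` must be an integer")
  if (p < 0 || abs(p - round(p)) > 1e-9) stop("radial index `p` must be a non-negative integer")
  structure(list(
    wavelength = wavelength,
    waist_w0 = waist_w0,
    ell = as.integer(round(ell)),
    p = as.integer(round(p)),
    wavenumber_k = 2 * pi / wavelength,
    angular_frequency = 2 * pi * .C_LIGHT / wavelength,
    rayleigh_zR = pi * waist_w0^2 / wavelength
  ), class = "beam_params")
}

#' @export
print.beam_params <- function(x, ...) {
  cat(sprintf("LG beam: lambda = %.4g nm, w0 = %.4g mm, ell = %d, p = %d\n",
              x$wavelength * 1e9, x$waist_w0 * 1e3, x$ell, x$p))
  cat(sprintf("  k = %.6g rad/m, zR = %.6g m, ring radius w0*sqrt(|ell|/2) = %.4g mm\n",
              x$wavenumber_k, x$rayleigh_zR,
              x$waist_w0 * sqrt(max(abs(x$ell), 1) / 2) * 1e3))
  invisible(x)
}

#' Transverse sampling grid
#'
#' A pixelated transverse plane: pixel counts, physical pixel pitch, and the
#' beam-axis origin in (fractional) pixel coordinates. Pixel centres are at
#' `(col - origin_x) * pitch`, `(row - origin_y) * pitch` with row/col
#' starting at 1; the default origin is the grid centre.
#'
#' @param nx,ny pixel counts (>= 8)
#' @param pitch physical size of one pixel in metres (> 0)
#' @param origin numeric length-2, beam-axis position in pixel coordinates
#'   (x = column, y = row); default grid centre
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(nx, ny = nx, pitch, origin = c((nx + 1) / 2, (ny + 1) / 2)) {
  stopifnot(nx >= 8, ny >= 8, pitch > 0, length(origin) == 2L)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pitch = pitch, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid a [grid_spec()]
#' @return list with matrices `x`, `y` (metres, ny x nx), `rho`, `phi`
#'   (cylindrical; `phi` counter-clockwise from +x in (-pi, pi])
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  xv <- (seq_len(grid$nx) - grid$origin[1]) * grid$pitch
  yv <- (seq_len(grid$ny) - grid$origin[2]) * grid$pitch
  x <- matrix(xv, grid$ny, grid$nx, byrow = TRUE)
  y <- matrix(yv, grid$ny, grid$nx)
  list(x = x, y = y, rho = sqrt(x^2 + y^2), phi = atan2(y, x))
}

#' Associated Laguerre polynomial by stable recurrence
#'
#' Evaluates L_p^alpha(x) with the three-term recurrence
#' `k L_k = (2k-1+alpha-x) L_{k-1} - (k-1+alpha) L_{k-2}`, which stays usable
#' up to p of a few tens where factorial-ratio formulas overflow.
#'
#' @param p non-negative integer degree
#' @param alpha order (here `|ell|`)
#' @param x numeric vector
#' @return numeric vector of L_p^alpha(x)
#' @export
laguerre_poly <- function(p, alpha, x) {
  p <- as.integer(p)
  stopifnot(p >= 0)
  if (p == 0L) return(rep(1, length(x)))
  lkm1 <- rep(1, length(x))        # L_0
  lk <- 1 + alpha - x              # L_1
  if (p == 1L) return(lk)
  for (k in 2:p) {
    lkp1 <- ((2 * k - 1 + alpha - x) * lk - (k - 1 + alpha) * lkm1) / k
    lkm1 <- lk
    lk <- lkp1
  }
  lk
}

#' Beam radius at propagation distance z
#'
#' `w(z) = w0 * sqrt(1 + (z/zR)^2)`.
#'
#' @param params a [beam_params()]
#' @param z propagation distance in metres (vectorised)
#' @return beam radius in metres
#' @export
beam_waist <- function(params, z) {
  stopifnot(inherits(params, "beam_params"))
  params$waist_w0 * sqrt(1 + (z / params$rayleigh_zR)^2)
}

#' Radius of peak LG ring intensity
#'
#' For p = 0 the doughnut peak sits at `w(z) * sqrt(|ell|/2)`; for ell = 0
#' the "ring" degenerates to the axis and `w(z)` is returned as the
#' characteristic transverse scale.
#'
#' @inheritParams beam_waist
#' @return radius in metres
#' @export
doughnut_radius <- function(params, z = 0) {
  w <- beam_waist(params, z)
  if (params$ell == 0L) w else w * sqrt(abs(params$ell) / 2)
}

# normalization prefactor sqrt(2 p! / (pi (|l|+p)!)) via log-gammas
.lg_prefactor <- function(p, al) {
  exp(0.5 * (log(2 / pi) + lgamma(p + 1) - lgamma(al + p + 1)))
}

#' Evaluate the LG complex field on a grid
#'
#' Samples the normalized paraxial LG mode
#' \deqn{LG_p^\ell(\rho,\phi,z) = \sqrt{\frac{2p!}{\pi(|\ell|+p)!\,w^2(z)}}
#'   \left[\frac{\rho\sqrt2}{w(z)}\right]^{|\ell|}
#'   L_p^{|\ell|}\!\left(\frac{2\rho^2}{w^2(z)}\right) e^{-\rho^2/w^2(z)}
#'   e^{iG(z)} e^{-ik\rho^2 z/2(z^2+z_R^2)} e^{-i\ell\phi} e^{-ikz}}
#' with Gouy phase \eqn{G(z) = (2p+|\ell|+1)\arctan(z/z_R)}. The phase
#' convention is `exp(-i*ell*phi)` with `phi` counter-clockwise from +x.
#' On-axis pixels (`rho = 0`) have amplitude exactly 0 for `|ell| > 0`.
#'
#' The discrete energy `sum(|E|^2) * pitch^2` of a well-resolved mode is 1.
#'
#' @param params a [beam_params()]
#' @param grid a [grid_spec()]; must span at least 3x the doughnut radius
#' @param z propagation distance in metres
#' @return an object of class `complex_field`: list(grid, z, amplitude) with
#'   `amplitude` a complex ny x nx matrix
#' @export
lg_field <- function(params, grid, z = 0) {
  stopifnot(inherits(params, "beam_params"), inherits(grid, "grid_spec"))
  wz <- beam_waist(params, z)
  span <- min(grid$nx, grid$ny) * grid$pitch
  need <- 3 * doughnut_radius(params, z)
  if (span < need) {
    stop(sprintf("underresolved beam: grid spans %.3g m but 3x doughnut radius is %.3g m",
                 span, need))
  }
  co <- grid_coords(grid)
  al <- abs(params$ell)
  k <- params$wavenumber_k
  zR <- params$rayleigh_zR
  x2 <- 2 * co$rho^2 / wz^2
  radial <- .lg_prefactor(params$p, al) / wz *
    (co$rho * sqrt(2) / wz)^al *
    laguerre_poly(params$p, al, x2) *
    exp(-co$rho^2 / wz^2)
  gouy <- (2 * params$p + al + 1) * atan(z / zR)
  sph <- -k * co$rho^2 * z / (2 * (z^2 + zR^2))
  phase <- gouy + sph - params$ell * co$phi - k * z
  amp <- radial * exp(1i * phase)
  if (al > 0) amp[co$rho == 0] <- 0 + 0i
  structure(list(grid = grid, z = z, amplitude = amp), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  en <- sum(Mod(x$amplitude)^2) * x$grid$pitch^2
  cat(sprintf("complex field %d x %d, pitch %.3g um, z = %.3g m, energy = %.4g\n",
              x$grid$ny, x$grid$nx, x$grid$pitch * 1e6, x$z, en))
  invisible(x)
}

#' Analytic LG phase (Gouy + spherical + helical + plane terms)
#'
#' \deqn{\Psi(\rho,\phi,z) = \frac{-k\rho^2 z}{2(z^2+z_R^2)} - \ell\phi - kz
#'   + (2p+|\ell|+1)\arctan(z/z_R)}
#' Agrees with `Arg(lg_field)` modulo 2*pi wherever the Laguerre polynomial is
#' positive (always, for p = 0). By convention returns 0 at rho = 0 when the
#' helical term would be undefined is not an issue since phi is still defined;
#' the field amplitude vanishes there for |ell| > 0.
#'
#' @param params a [beam_params()]
#' @param rho radial coordinate in metres (>= 0, vectorised)
#' @param phi azimuthal coordinate in radians (vectorised)
#' @param z propagation distance in metres
#' @return phase in radians (unwrapped analytic value, not reduced mod 2*pi)
#' @export
lg_phase <- function(params, rho, phi, z = 0) {
  stopifnot(inherits(params, "beam_params"), all(rho >= 0))
  k <- params$wavenumber_k
  zR <- params$rayleigh_zR
  gouy <- (2 * params$p + abs(params$ell) + 1) * atan(z / zR)
  -k * rho^2 * z / (2 * (z^2 + zR^2)) - params$ell * phi - k * z + gouy
}

#' Azimuthal winding of a phase map
#'
#' Line integral of the wrapped phase gradient around a circle, in units of
#' 2*pi: for an LG field this returns `-ell` (sign per the `exp(-i*ell*phi)`
#' convention).
#'
#' @param field a `complex_field` (or a phase matrix via `phase =`)
#' @param radius circle radius in metres (default: the doughnut radius is
#'   unknown here, so the caller supplies it)
#' @param n_samples number of samples around the circle
#' @param center beam-axis pixel coordinates; default the grid origin
#' @return winding number (numeric; integer up to floating point)
#' @export
phase_winding <- function(field, radius, n_samples = 4096, center = NULL) {
  stopifnot(inherits(field, "complex_field"))
  g <- field$grid
  if (is.null(center)) center <- g$origin
  th <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  cx <- center[1] + radius * cos(th) / g$pitch
  cy <- center[2] + radius * sin(th) / g$pitch
  ph <- .bilinear_arg(field$amplitude, cx, cy)
  d <- diff(c(ph, ph[1]))
  d <- (d + pi) %% (2 * pi) - pi
  sum(d) / (2 * pi)
}

# bilinear interpolation of a complex field's value, returning its argument
.bilinear_arg <- function(amp, cx, cy) {
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  nx <- ncol(amp); ny <- nrow(amp)
  x0 <- pmin(pmax(x0, 1L), nx - 1L); y0 <- pmin(pmax(y0, 1L), ny - 1L)
  idx <- function(r, c) (c - 1L) * ny + r
  v <- amp[idx(y0, x0)] * (1 - fx) * (1 - fy) +
    amp[idx(y0, x0 + 1L)] * fx * (1 - fy) +
    amp[idx(y0 + 1L, x0)] * (1 - fx) * fy +
    amp[idx(y0 + 1L, x0 + 1L)] * fx * fy
  Arg(v)
}

#' Fit the beam waist from a doughnut intensity image
#'
#' Least-squares fit of the p = 0 LG radial intensity profile
#' `I(rho) ~ rho^(2|ell|) exp(-2 rho^2 / w0^2)` to an observed image, over the
#' single free parameter w0. This operationalizes the "waist adjusted to fit
#' the experimental image" step; the fit minimizes the sum of squared
#' residuals between the normalized azimuthal-mean profile and the model.
#'
#' @param image intensity matrix
#' @param grid a [grid_spec()] describing the image
#' @param ell topological charge of the mode imaged
#' @return fitted waist w0 in metres
#' @export
fit_beam_waist <- function(image, grid, ell) {
  stopifnot(is.matrix(image), inherits(grid, "grid_spec"))
  co <- grid_coords(grid)
  rho <- as.vector(co$rho); inten <- as.vector(image)
  nb <- 200L
  rmax <- max(rho)
  bin <- pmin(floor(rho / rmax * nb) + 1L, nb)
  prof <- tapply(inten, bin, mean)
  rmid <- (as.numeric(names(prof)) - 0.5) * rmax / nb
  prof <- prof / max(prof)
  al <- abs(ell)
  obj <- function(w0) {
    m <- rmid^(2 * al) * exp(-2 * rmid^2 / w0^2)
    m <- m / max(m)
    sum((m - prof)^2)
  }
  optimize(obj, interval = c(rmax / 100, rmax))$minimum
}
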