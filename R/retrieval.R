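#' Off-axis holographic phase retrieval
#'
#' FFT of the interferogram, selection of a sideband (auto-located as the
#' strongest spectral peak outside a DC exclusion disk unless a `crop_spec`
#' is given), square crop with side equal to the peak's distance to DC,
#' raised-cosine edge apodization, recentring, and inverse FFT. The phase is
#' the argument and the amplitude the modulus of the result.
#'
#' For a real interferogram the two sidebands are exact conjugates; the
#' deterministic default picks the one in the `fx < 0` half-plane (ties on
#' `fx = 0` resolved towards `fy < 0`). With the package's reference-wave
#' convention (carrier phase `+i(kx x + ky y)`), the sample field's direct
#' (non-conjugated) sideband lies at minus the carrier frequency, so the
#' default returns `arg(E_sample)` up to a piston.
#'
#' @param image interferogram matrix (counts or intensity)
#' @param crop_spec optional list(center = c(fx, fy) integer frequency bins,
#'   halfwidth = bins) overriding the auto-location
#' @param dc_exclude DC exclusion disk radius in frequency bins (default
#'   max(3, n/32))
#' @return object of class `phase_map`: phase in (-pi, pi], amplitude,
#'   sideband record (center bins, halfwidth)
#' @export
retrieve_phase <- function(image, crop_spec = NULL, dc_exclude = NULL) {
  stopifnot(is.matrix(image))
  ny <- nrow(image); nx <- ncol(image)
  FT <- stats::fft(matrix(as.double(image), ny, nx))
  fx <- ((seq_len(nx) - 1 + floor(nx / 2)) %% nx) - floor(nx / 2)
  fy <- ((seq_len(ny) - 1 + floor(ny / 2)) %% ny) - floor(ny / 2)
  FX <- matrix(fx, ny, nx, byrow = TRUE)
  FY <- matrix(fy, ny, nx)
  if (is.null(dc_exclude)) dc_exclude <- max(3, round(min(nx, ny) / 32))
  if (is.null(crop_spec)) {
    mag <- Mod(FT)
    mag[sqrt(FX^2 + FY^2) <= dc_exclude] <- -Inf
    # deterministic half-plane: fx < 0, or fx == 0 and fy < 0
    mag[FX > 0 | (FX == 0 & FY >= 0)] <- -Inf
    pk <- which.max(mag)
    c0 <- c(FX[pk], FY[pk])
    # the raw peak can sit on the rim of a ring-shaped sideband (an LG
    # spectrum is itself a ring); refine to the |F|^2 centroid of the window
    hw0 <- max(3L, floor(sqrt(sum(c0^2)) / 2))
    offs <- seq(-hw0, hw0)
    wr <- ((c0[2] + offs) %% ny) + 1L
    wc <- ((c0[1] + offs) %% nx) + 1L
    m2 <- Mod(FT[wr, wc])^2
    c0 <- c(round(sum(t(m2) * (c0[1] + offs)) / sum(m2)),
            round(sum(m2 * (c0[2] + offs)) / sum(m2)))
    dist <- sqrt(sum(c0^2))
    hw <- floor(dist / 2)
  } else {
    c0 <- crop_spec$center
    dist <- sqrt(sum(c0^2))
    hw <- crop_spec$halfwidth
  }
  if (dist <= 2 * dc_exclude || hw < 2)
    stop("carrier too low: sideband overlaps the DC term")
  G <- matrix(0 + 0i, ny, nx)
  off <- seq(-hw, hw)
  # raised-cosine edge taper (flat inside 60% of the crop)
  r <- sqrt(outer(off^2, off^2, `+`)) / hw
  tap <- ifelse(r <= 0.6, 1,
                ifelse(r >= 1, 0, 0.5 * (1 + cos(pi * (r - 0.6) / 0.4))))
  src_r <- ((c0[2] + off) %% ny) + 1L
  src_c <- ((c0[1] + off) %% nx) + 1L
  dst_r <- (off %% ny) + 1L
  dst_c <- (off %% nx) + 1L
  G[dst_r, dst_c] <- FT[src_r, src_c] * t(tap)
  fld <- stats::fft(G, inverse = TRUE) / (nx * ny)
  structure(list(phase = Arg(fld), amplitude = Mod(fld),
                 sideband = list(center = c0, halfwidth = hw)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase map %d x %d, sideband at (%d, %d) bins, halfwidth %d\n",
              nrow(x$phase), ncol(x$phase),
              x$sideband$center[1], x$sideband$center[2], x$sideband$halfwidth))
  invisible(x)
}

#' Annular mask around the LG doughnut
#'
#' The ring bounded by the radii where the unscattered p = 0 |LG|^2 radial
#' profile falls to `fraction` (default 1/e^2) of its peak. Accepts either
#' beam parameters (analytic profile) or an intensity image (azimuthal-mean
#' profile).
#'
#' @param x a [beam_params()] or an intensity matrix
#' @param grid a [grid_spec()] for the mask raster
#' @param fraction intensity fraction defining the ring edges, in (0, 1)
#' @param z propagation distance for the analytic profile
#' @param center beam-axis pixel coordinates (default the grid origin)
#' @return object of class `annular_mask`: list(inner_px, outer_px, center,
#'   mask (logical matrix))
#' @export
annular_mask <- function(x, grid, fraction = exp(-2), z = 0, center = NULL) {
  stopifnot(inherits(grid, "grid_spec"), fraction > 0, fraction < 1)
  if (is.null(center)) center <- grid$origin
  if (inherits(x, "beam_params")) {
    if (x$ell == 0L) stop("annular mask undefined for ell = 0")
    al <- abs(x$ell)
    wz <- beam_waist(x, z)
    rp <- wz * sqrt(al / 2)
    prof <- function(rho) (rho / rp)^(2 * al) *
      exp(-2 * (rho^2 - rp^2) / wz^2) - fraction
    inner <- uniroot(prof, c(rp * 1e-6, rp), tol = 1e-12)$root
    outer_r <- uniroot(prof, c(rp, rp * 6), tol = 1e-12)$root
    inner_px <- inner / grid$pitch
    outer_px <- outer_r / grid$pitch
  } else {
    stopifnot(is.matrix(x))
    co <- grid_coords(grid)
    nb <- 128L
    rmax <- max(co$rho)
    bin <- pmin(floor(as.vector(co$rho) / rmax * nb) + 1L, nb)
    prof <- tapply(as.vector(x), bin, mean)
    rmid <- (as.numeric(names(prof)) - 0.5) * rmax / nb
    pk <- which.max(prof)
    thr <- fraction * prof[pk]
    lo <- which(prof[seq_len(pk)] < thr)
    hi <- which(prof[seq(pk, length(prof))] < thr)
    inner_px <- (if (length(lo)) rmid[max(lo)] else rmid[1]) / grid$pitch
    outer_px <- (if (length(hi)) rmid[pk + min(hi) - 1] else rmax) / grid$pitch
  }
  co <- grid_coords(grid)
  rpx <- co$rho / grid$pitch
  mask <- rpx >= inner_px & rpx <= outer_px
  if (!any(mask)) stop("annular mask is empty")
  structure(list(inner_px = inner_px, outer_px = outer_px, center = center,
                 fraction = fraction, mask = mask),
            class = "annular_mask")
}

#' @export
print.annular_mask <- function(x, ...) {
  cat(sprintf("annular mask: %.1f..%.1f px (%d pixels inside)\n",
              x$inner_px, x$outer_px, sum(x$mask)))
  invisible(x)
}

#' Phase-memory map: retrieved phase versus applied SLM offset
#'
#' Per pixel, regresses the change of the (retrieved) phase relative to the
#' frame nearest delta = 0 against the applied SLM phase offset delta. Phase
#' differences are taken on the unit circle (complex ratio) and then
#' unwrapped along the offset ordering, so no 2-D unwrapping is needed. A
#' slope of 1 means the speckle grain fully tracks the injected phase
#' (perfect memory); 0 means no memory.
#'
#' @param phases list of phase matrices (or `phase_map` / `complex_field`
#'   objects), one per offset
#' @param offsets numeric vector of SLM offsets, radians (>= 3 values)
#' @param mask optional [annular_mask()] (or logical matrix): summaries are
#'   reported inside vs outside it
#' @param r2_floor pixels with regression r^2 below this are excluded from
#'   the summaries (kept in the map)
#' @param amp_floor_frac pixels whose reference-frame intensity is below
#'   this fraction of the mean intensity are excluded from the summaries
#'   (phase is only measurable where there is light); ignored when the
#'   inputs carry no amplitude
#' @return object of class `memory_map`: slope, intercept, r_squared
#'   matrices and a `summary` list (median slope and IQR inside / outside /
#'   overall)
#' @export
memory_map <- function(phases, offsets, mask = NULL, r2_floor = 0.2,
                       amp_floor_frac = 0.05) {
  stopifnot(length(phases) == length(offsets), length(offsets) >= 3)
  getph <- function(p) {
    if (inherits(p, "phase_map")) p$phase
    else if (inherits(p, "complex_field")) Arg(p$amplitude)
    else p
  }
  getamp <- function(p) {
    if (inherits(p, "phase_map")) p$amplitude
    else if (inherits(p, "complex_field")) Mod(p$amplitude)
    else NULL
  }
  ord <- order(offsets)
  offsets <- offsets[ord]
  j0 <- which.min(abs(offsets))
  ref_amp <- getamp(phases[[ord[j0]]])
  phases <- lapply(phases[ord], getph)
  ref <- phases[[j0]]
  d <- lapply(phases, function(p) .wrap_pi(p - ref))
  # unwrap along the offset ordering (offset steps are < pi by construction)
  for (j in seq_along(d)[-1]) {
    d[[j]] <- d[[j - 1]] + .wrap_pi(d[[j]] - d[[j - 1]])
  }
  nyx <- dim(ref)
  n <- length(offsets)
  dmat <- vapply(d, as.vector, numeric(prod(nyx)))
  xb <- mean(offsets)
  xc <- offsets - xb
  sxx <- sum(xc^2)
  ybar <- rowMeans(dmat)
  sxy <- dmat %*% xc
  slope <- as.vector(sxy) / sxx
  intercept <- ybar - slope * xb
  fitted_ss <- slope^2 * sxx
  tot_ss <- rowSums((dmat - ybar)^2)
  r2 <- ifelse(tot_ss > 0, pmin(pmax(fitted_ss / tot_ss, 0), 1), 0)
  slope_m <- matrix(slope, nyx[1], nyx[2])
  r2_m <- matrix(r2, nyx[1], nyx[2])
  int_m <- matrix(intercept, nyx[1], nyx[2])
  lit <- if (!is.null(ref_amp))
    ref_amp^2 >= amp_floor_frac * mean(ref_amp^2)
  else matrix(TRUE, nyx[1], nyx[2])
  summ_of <- function(sel) {
    s <- slope_m[sel & lit & r2_m >= r2_floor]
    if (!length(s)) return(list(median_slope = NA_real_, iqr = NA_real_,
                                n = 0L))
    list(median_slope = median(s), iqr = stats::IQR(s), n = length(s))
  }
  msel <- if (is.null(mask)) NULL
          else if (inherits(mask, "annular_mask")) mask$mask else mask
  summary <- list(overall = summ_of(matrix(TRUE, nyx[1], nyx[2])))
  if (!is.null(msel)) {
    summary$inside <- summ_of(msel)
    summary$outside <- summ_of(!msel)
  }
  structure(list(slope = slope_m, intercept = int_m, r_squared = r2_m,
                 offsets = offsets, r2_floor = r2_floor, summary = summary),
            class = "memory_map")
}

#' @export
print.memory_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("memory map over %d offsets; overall median slope %.3f\n",
              length(x$offsets), s$overall$median_slope))
  if (!is.null(s$inside))
    cat(sprintf("  inside annulus: %.3f (n=%d)   outside: %.3f (n=%d)\n",
                s$inside$median_slope, s$inside$n,
                s$outside$median_slope, s$outside$n))
  invisible(x)
}

#' Speckle-grain segmentation of an amplitude map
#'
#' Assigns each pixel to the nearest local maximum of the (lightly smoothed)
#' amplitude within a given radius -- a cheap stand-in for watershed cells,
#' adequate for per-grain summary statistics.
#'
#' @param amplitude amplitude matrix
#' @param min_distance minimum separation of grain seeds, pixels
#' @return integer matrix of grain labels
#' @export
speckle_grains <- function(amplitude, min_distance = 4L) {
  a <- amplitude
  ny <- nrow(a); nx <- ncol(a)
  r <- as.integer(min_distance)
  # local maxima via dilation comparison
  dil <- a
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(-Inf, ny, nx)
    ri <- max(1, 1 + dr):min(ny, ny + dr)
    ci <- max(1, 1 + dc):min(nx, nx + dc)
    sh[ri, ci] <- a[ri - dr, ci - dc]
    dil <- pmax(dil, sh)
  }
  seeds <- which(a >= dil & a > 0)
  if (!length(seeds)) return(matrix(0L, ny, nx))
  sr <- ((seeds - 1L) %% ny) + 1L
  sc <- ((seeds - 1L) %/% ny) + 1L
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  lab <- matrix(0L, ny, nx)
  best <- matrix(Inf, ny, nx)
  for (s in seq_along(seeds)) {
    d2 <- (rows - sr[s])^2 + (cols - sc[s])^2
    upd <- d2 < best
    lab[upd] <- s
    best[upd] <- d2[upd]
  }
  lab
}
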