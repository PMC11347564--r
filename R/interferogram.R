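#' Reference wave for interferogram synthesis
#'
#' Either an ideal plane wave or an expanded Gaussian (waist >= 5x the LG
#' doughnut radius, so it approximates the plane wave it stands in for). A
#' transverse carrier tilt `(kx, ky)` in rad/m turns the interferogram
#' off-axis; `(0, 0)` is on-axis.
#'
#' @param kind "plane" or "expanded-gaussian"
#' @param tilt numeric length-2, transverse carrier (kx, ky) in rad/m
#' @param amplitude_ratio reference amplitude relative to the sample beam's
#'   peak amplitude (> 0)
#' @param phase_offset global reference phase, radians
#' @param waist Gaussian reference waist in metres (NULL: 5x doughnut radius,
#'   resolved at interfere() time)
#' @return object of class `reference_wave`
#' @export
reference_wave <- function(kind = c("plane", "expanded-gaussian"),
                           tilt = c(0, 0), amplitude_ratio = 1,
                           phase_offset = 0, waist = NULL) {
  kind <- match.arg(kind)
  stopifnot(amplitude_ratio > 0, length(tilt) == 2L)
  structure(list(kind = kind, tilt = as.numeric(tilt),
                 amplitude_ratio = amplitude_ratio,
                 phase_offset = phase_offset, waist = waist),
            class = "reference_wave")
}

#' Camera model
#'
#' Scaling, optional signal-proportional shot noise, dark offset and
#' quantization to `bit_depth` bits. With `exposure = NULL` the intensity is
#' auto-scaled so the brightest pixel sits at 60% of full scale (the reported
#' runs use short 1 ms exposures well below saturation).
#'
#' @param bit_depth bits per pixel (default 16)
#' @param exposure multiplicative counts-per-intensity factor, or NULL for
#'   auto-scaling
#' @param shot_noise logical, add Poisson shot noise (default FALSE so oracle
#'   tests stay exact)
#' @param dark_offset constant dark level in counts
#' @param seed RNG seed used when shot noise is on
#' @return object of class `camera_model`
#' @export
camera_model <- function(bit_depth = 16L, exposure = NULL, shot_noise = FALSE,
                         dark_offset = 0, seed = 1L) {
  structure(list(bit_depth = as.integer(bit_depth), exposure = exposure,
                 shot_noise = isTRUE(shot_noise), dark_offset = dark_offset,
                 seed = seed),
            class = "camera_model")
}

# evaluate the reference field on a grid (needs the sample field for the
# peak-amplitude normalization and default Gaussian waist)
.reference_field <- function(ref, sample) {
  g <- sample$grid
  co <- grid_coords(g)
  peak <- max(Mod(sample$amplitude))
  if (peak == 0) peak <- 1
  amp0 <- ref$amplitude_ratio * peak
  ph <- ref$tilt[1] * co$x + ref$tilt[2] * co$y + ref$phase_offset
  if (ref$kind == "plane") {
    amp0 * exp(1i * ph)
  } else {
    w <- ref$waist
    if (is.null(w)) {
      # 5x the ring radius of the brightest circle in the sample field
      rr <- co$rho[which.max(Mod(sample$amplitude))]
      w <- 5 * max(rr, g$pitch * g$nx / 6)
    }
    amp0 * exp(-co$rho^2 / w^2) * exp(1i * ph)
  }
}

#' Render a two-beam interferogram
#'
#' `I = |E_sample + E_reference|^2`, exposure-scaled, optionally
#' shot-noise-injected (Poisson, seeded) and quantized to the camera's bit
#' depth. Deterministic given the camera seed.
#'
#' @param sample a `complex_field`
#' @param ref a [reference_wave()]
#' @param cam a [camera_model()]
#' @return integer matrix of camera counts with attributes `saturated_frac`
#'   and `grid`; a saturation fraction above 1% triggers a warning recorded in
#'   the attribute
#' @export
interfere <- function(sample, ref, cam = camera_model()) {
  stopifnot(inherits(sample, "complex_field"), inherits(ref, "reference_wave"),
            inherits(cam, "camera_model"))
  er <- .reference_field(ref, sample)
  inten <- Mod(sample$amplitude + er)^2
  full <- 2^cam$bit_depth - 1
  sc <- if (is.null(cam$exposure)) {
    mx <- max(inten)
    if (mx > 0) 0.6 * full / mx else 1
  } else cam$exposure
  counts <- inten * sc + cam$dark_offset
  if (cam$shot_noise) {
    set.seed(cam$seed)
    counts <- rpois(length(counts), pmax(counts, 0))
    counts <- matrix(counts, nrow(inten), ncol(inten))
  }
  counts <- round(pmin(pmax(counts, 0), full))
  sat <- mean(counts >= full)
  if (sat > 0.01)
    warning(sprintf("saturation fraction %.1f%% exceeds 1%%", 100 * sat))
  structure(matrix(as.integer(counts), nrow(inten), ncol(inten)),
            saturated_frac = sat, grid = sample$grid)
}

#' Render a timed interferogram frame stack
#'
#' Applies [interfere()] to each field of a series and attaches timestamps on
#' the acquisition grid (default 10 frames per second).
#'
#' @param sample_series list of `complex_field` objects, or a function of the
#'   frame time returning one
#' @param ref a [reference_wave()]
#' @param cam a [camera_model()] (per-frame shot-noise seeds derive from its
#'   seed)
#' @param times frame times in seconds (default 0.1 s spacing)
#' @param fps frames per second used when `times` is NULL
#' @param n_frames number of frames when `sample_series` is a function
#' @return object of class `frame_stack`: list(frames = list of count
#'   matrices, times, grid)
#' @export
frame_stack <- function(sample_series, ref, cam = camera_model(),
                        times = NULL, fps = 10, n_frames = NULL) {
  if (is.function(sample_series)) {
    stopifnot(!is.null(n_frames))
    if (is.null(times)) times <- (seq_len(n_frames) - 1) / fps
    sample_series <- lapply(times, sample_series)
  }
  stopifnot(length(sample_series) >= 1L)
  if (is.null(times)) times <- (seq_along(sample_series) - 1) / fps
  frames <- vector("list", length(sample_series))
  for (i in seq_along(sample_series)) {
    cam_i <- cam
    cam_i$seed <- cam$seed + i - 1L
    frames[[i]] <- interfere(sample_series[[i]], ref, cam_i)
  }
  structure(list(frames = frames, times = times,
                 grid = sample_series[[1]]$grid),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame stack: %d frames, %d x %d px, t = %.3g..%.3g s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              min(x$times), max(x$times)))
  invisible(x)
}
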