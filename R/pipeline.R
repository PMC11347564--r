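#' Invert a predicted twist-vs-delta-n forward map
#'
#' Builds a monotone interpolant of Theta(delta_n) from a
#' [predict_twist_series()] table and inverts it for measured twist values
#' by bracketing. Errors if the forward map is not monotone over the
#' configured range.
#'
#' @param prediction a `twist_prediction` (columns delta_n, theta_rad)
#' @param theta measured twist values, radians
#' @return estimated delta_n values (clamped to the prediction range)
#' @export
invert_twist <- function(prediction, theta) {
  dn <- prediction$delta_n
  th <- prediction$theta_rad
  d <- diff(th)
  if (!(all(d >= 0) || all(d <= 0)))
    stop("forward map Theta(delta_n) is not monotone over the configured range")
  if (all(d <= 0)) { th <- rev(th); dn <- rev(dn) }
  f <- approxfun(th, dn, rule = 2)
  f(theta)
}

#' Default sensing-run configuration
#'
#' @param ell topological charge
#' @param n_frames rendered frames
#' @param n_traj trajectory ensemble size
#' @param seed RNG seed
#' @param shot_noise camera shot noise on/off
#' @param target_delta_n total |Delta n| of the thermal run
#' @return nested configuration list
#' @export
sensing_config <- function(ell = 5, n_frames = 64L, n_traj = 20000L,
                           seed = 1L, shot_noise = FALSE,
                           target_delta_n = 3.69e-4) {
  list(beam = list(wavelength_nm = 640, waist_mm = 0.45, ell = ell, p = 0),
       run = list(duration_s = 1500, fps = 10, T0 = 7.8, T_room = 21,
                  tau_s = 480, target_delta_n = target_delta_n),
       cuvette = list(d_total_mm = 5.6, d_wall_mm = 1, n_glass = 1.5168,
                      n_interior = 1.3616),
       render = list(n_frames = n_frames, n_traj = n_traj, nx = 256,
                     shot_noise = shot_noise),
       inversion = list(n_grid = 9),
       seed = seed)
}

.beam_from_config <- function(cfg) {
  beam_params(wavelength = cfg$wavelength_nm * 1e-9,
              waist_w0 = cfg$waist_mm * 1e-3,
              ell = cfg$ell, p = cfg$p %||% 0)
}

#' Refractive-index sensing run (thermal drift -> twist -> inversion)
#'
#' Headline analysis A: generates (or ingests) an on-axis petal stack for a
#' thermal refractive-index drift, measures the relative twist Theta(t) with
#' the petal algorithm, inverts the trajectory-model forward map
#' Theta(delta_n) by bracketing to estimate delta_n(t), and reports the
#' sensitivity (delta_n per degree of twist) at the operating point.
#'
#' @param config a [sensing_config()] list
#' @param stack optional pre-rendered list(stack, truth) from
#'   [make_twist_stack()] (bypasses generation; `truth` may be absent for
#'   real data)
#' @return object of class `sensing_report`: twist series, dn_hat, dn_true
#'   (if known), max_abs_error, sensitivity_dn_per_deg, forward map,
#'   manifest
#' @export
run_sensing <- function(config = sensing_config(), stack = NULL) {
  t0 <- Sys.time()
  params <- .beam_from_config(config$beam)
  run <- do.call(make_thermal_run, config$run)
  cuv <- cuvette_stack(n_interior = config$cuvette$n_interior,
                       n_glass = config$cuvette$n_glass,
                       d_total = config$cuvette$d_total_mm * 1e-3,
                       d_wall = config$cuvette$d_wall_mm * 1e-3)
  grid <- default_beam_grid(params, n = config$render$nx)
  if (is.null(stack)) {
    stack <- make_twist_stack(run, params, stack = cuv, grid = grid,
                              cam = camera_model(shot_noise = config$render$shot_noise,
                                                 seed = config$seed),
                              n_frames = config$render$n_frames,
                              n_traj = config$render$n_traj,
                              seed = config$seed)
  }
  ts <- measure_twist(stack$stack, ell = params$ell)
  # forward map from the reference state (delta_n = 0) to the run's total;
  # the grid starts at 0 so model and measurement share the same reference
  dn_end <- if (!is.null(stack$truth))
    stack$truth$delta_n[nrow(stack$truth)] else attr(run, "total_delta_n")
  # a degenerate ramp would make bracketing ill-posed: probe at least the
  # 2e-5 span over which the response is characterized
  if (abs(dn_end) < 2e-5) dn_end <- if (dn_end < 0 || dn_end == 0) -2e-5 else 2e-5
  dn_grid <- seq(0, dn_end, length.out = config$inversion$n_grid)
  pred <- predict_twist_series(params, cuv, dn_grid,
                               n_traj = max(5000, config$render$n_traj %/% 4),
                               grid = grid, seed = config$seed + 1L)
  dn_hat <- invert_twist(pred, ts$theta_rad)
  err <- NULL
  if (!is.null(stack$truth)) {
    err <- max(abs(dn_hat - stack$truth$delta_n))
  }
  # sensitivity: delta_n change per degree of twist at the operating point
  sl <- coef(lm(pred$delta_n ~ pred$theta_deg))[2]
  rep <- structure(list(
    twist = ts, dn_hat = dn_hat,
    dn_true = if (!is.null(stack$truth)) stack$truth$delta_n else NULL,
    max_abs_error = err,
    sensitivity_dn_per_deg = unname(sl),
    forward_map = pred,
    manifest = run_manifest(config, seeds = c(config$seed, config$seed + 1L),
                            t0 = t0)),
    class = "sensing_report")
  rep
}

#' @export
print.sensing_report <- function(x, ...) {
  cat(sprintf("sensing run: %d frames, twist span %.2f deg\n",
              nrow(x$twist), diff(range(x$twist$theta_deg))))
  cat(sprintf("  estimated total delta_n: %.4g", x$dn_hat[length(x$dn_hat)]))
  if (!is.null(x$dn_true))
    cat(sprintf("  (true %.4g, max |error| %.3g)", x$dn_true[length(x$dn_true)],
                x$max_abs_error))
  cat(sprintf("\n  sensitivity: %.3g delta_n per degree of twist\n",
              x$sensitivity_dn_per_deg))
  invisible(x)
}

#' Default phase-memory run configuration
#'
#' @param source "synthetic" (speckle generator) or "mc" (Monte Carlo)
#' @param d_mm,mus_per_mm,g phantom slab parameters
#' @param n_ph photon packets for the MC source
#' @param seed RNG seed
#' @param regime_override optional label overriding the guideline-based one
#' @return nested configuration list
#' @export
memory_config <- function(source = c("synthetic", "mc"), d_mm = 8,
                          mus_per_mm = 6, g = 0.8, n_ph = 1e5, seed = 1L,
                          regime_override = NULL) {
  source <- match.arg(source)
  list(beam = list(wavelength_nm = 640, waist_mm = 0.45, ell = 3, p = 0),
       phantom = list(d_mm = d_mm, n = 1.4, mus_per_mm = mus_per_mm,
                      mua_per_mm = 0.01, g = g),
       detector = list(nx = 128, ny = 128, pitch_um = 40, na = 0.25),
       offsets = seq(-3 * pi / 10, 3 * pi / 10, length.out = 7),
       source = source, n_ph = n_ph,
       speckle = list(grain_px = 8, m_inside = 0.9, m_outside = 0.05),
       regime_override = regime_override,
       seed = seed)
}

#' Phase-memory run (scattering -> speckle phase -> memory map)
#'
#' Headline analysis B: produces speckle fields per SLM phase offset (from
#' the Monte Carlo transport or from the synthetic speckle generator),
#' retrieves or takes their phase, computes the phase-memory map against the
#' offsets, and reports median slopes inside/outside the annular mask along
#' with the optical-depth regime label.
#'
#' @param config a [memory_config()] list
#' @param through_retrieval render off-axis interferograms and run
#'   [retrieve_phase()] (TRUE) or regress on the field phases directly
#' @return object of class `memory_report`: memory map, summary, optical
#'   depth, regime label, manifest
#' @export
run_memory <- function(config = memory_config(), through_retrieval = FALSE) {
  t0 <- Sys.time()
  params <- .beam_from_config(config$beam)
  ph <- config$phantom
  od <- optical_depth(ph$d_mm * 1e-3, ph$mus_per_mm * 1e3, ph$g)
  label <- config$regime_override %||% regime_label(od, refine = TRUE)
  offsets <- config$offsets
  if (config$source == "mc") {
    stack <- medium_stack(d = ph$d_mm * 1e-3, n = ph$n,
                          mus = ph$mus_per_mm * 1e3, mua = ph$mua_per_mm * 1e3,
                          g = ph$g)
    det <- detector_spec(nx = config$detector$nx, ny = config$detector$ny,
                         pitch = config$detector$pitch_um * 1e-6,
                         na = config$detector$na)
    mc <- mc_propagate(params, stack, det, n_ph = config$n_ph,
                       seed = config$seed)
    fields <- lapply(offsets, function(d) mc_field(mc, d))
    grid <- fields[[1]]$grid
    mask <- annular_mask(params, grid)
  } else {
    sp <- speckle_spec(grain_px = config$speckle$grain_px,
                       m_inside = config$speckle$m_inside,
                       m_outside = config$speckle$m_outside, regime = od)
    ss <- make_speckle_stack(sp, params, offsets = offsets,
                             seed = config$seed)
    fields <- ss$fields
    mask <- ss$mask
    grid <- fields[[1]]$grid
    mc <- NULL
  }
  phases <- if (through_retrieval) {
    carrier <- pi / (2 * grid$pitch)      # half Nyquist, resolves the grains
    ref <- reference_wave(kind = "plane", tilt = c(carrier, 0))
    cam <- camera_model(shot_noise = FALSE)
    lapply(fields, function(f) retrieve_phase(interfere(f, ref, cam)))
  } else fields
  mm <- memory_map(phases, offsets, mask = mask)
  structure(list(memory = mm, mask = mask, optical_depth = od,
                 regime = label, mc = if (config$source == "mc") mc else NULL,
                 manifest = run_manifest(config, seeds = config$seed,
                                         t0 = t0)),
            class = "memory_report")
}

#' @export
print.memory_report <- function(x, ...) {
  cat(sprintf("phase-memory run: d/l* = %.3g (%s)\n", x$optical_depth,
              x$regime))
  print(x$memory)
  invisible(x)
}

#' Run manifest
#'
#' Provenance record: configuration snapshot, seeds, package and R versions,
#' and timing. Written beside every CLI output so each result is traceable.
#'
#' @param config configuration list
#' @param seeds seeds used
#' @param t0 start time (POSIXct)
#' @param files named list of output files to digest (md5)
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(config, seeds, t0 = Sys.time(), files = NULL) {
  m <- list(config = config, seeds = seeds,
            package_version = as.character(utils::packageVersion("oamtwist")),
            r_version = R.version.string,
            started = format(t0, "%Y-%m-%dT%H:%M:%S"),
            elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(files)) {
    ex <- unlist(files)[file.exists(unlist(files))]
    m$digests <- as.list(tools::md5sum(ex))
  }
  class(m) <- "run_manifest"
  m
}
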