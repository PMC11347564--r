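# shared fixtures: small, fast beam/grid configurations built in code

beam640 <- function(ell = 3, w0 = 0.45e-3, p = 0) {
  beam_params(wavelength = 640e-9, waist_w0 = w0, ell = ell, p = p)
}

# the two reference phantom slabs (d in m, mus in 1/m)
phantom_low <- function() medium_stack(d = 1e-3, n = 1.4, mus = 10e3,
                                       mua = 0.01e3, g = 0.8)
phantom_multi <- function() medium_stack(d = 8e-3, n = 1.4, mus = 6e3,
                                         mua = 0.01e3, g = 0.8)

# circular difference in (-pi, pi]
wrap_pi <- function(d) {
  w <- (d + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# amplitude-weighted RMS of a wrapped phase difference after piston removal
phase_rms <- function(measured, truth, weight) {
  d <- wrap_pi(measured - truth)
  sel <- weight > 0.2 * max(weight)
  piston <- Arg(sum(exp(1i * d[sel])))
  sqrt(mean(wrap_pi(d[sel] - piston)^2))
}

# Rayleigh KS test on the off-annulus amplitude of a detector field, with
# radial envelope normalization and subsampling beyond the PSF correlation
rayleigh_ks_p <- function(field, r_in_px = 28, r_out_px = 46, stride = 24) {
  g <- field$grid
  co <- grid_coords(g)
  rpx <- as.vector(co$rho / g$pitch)
  amp <- as.vector(Mod(field$amplitude))
  sel <- which(rpx > r_in_px & rpx < r_out_px)
  bin <- floor(rpx[sel])
  env <- tapply(amp[sel]^2, bin, mean)
  an <- amp[sel] / sqrt(env[as.character(bin)])
  sub <- an[seq(1, length(an), by = stride)]
  sg <- sqrt(mean(sub^2) / 2)
  stats::ks.test(sub, function(q) 1 - exp(-q^2 / (2 * sg^2)))$p.value
}
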