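#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Henyey-Greenstein inverse-CDF sample of cos(theta)
static inline double hg_cos(double g) {
  double u = R::unif_rand();
  if (g < 1e-9) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// HG phase function per steradian
static inline double hg_pdf_sr(double g, double c) {
  double d = 1.0 + g * g - 2.0 * g * c;
  return (1.0 - g * g) / (4.0 * M_PI * d * std::sqrt(d));
}

// rotate unit vector (ux,uy,uz) by deflection cos(t)=ct, azimuth ph
static inline void rotate_dir(double &ux, double &uy, double &uz,
                              double ct, double ph) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(ph), sp = std::sin(ph);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// sinh-exponential degree of polarization, clipped to [0,1]
static inline double dop_clip(double L, double ls, double xi) {
  if (ls <= 0.0 || xi <= 0.0) return 1.0;
  double p = (2.0 * L / ls) * std::sinh(ls / xi) * std::exp(-L / xi);
  if (p > 1.0) p = 1.0;
  if (p < 0.0) p = 0.0;
  return p;
}

// deposit amplitude a*exp(i phase) at detector position (px,py) [m] with a
// Gaussian PSF stencil of width sigma_px pixels (L2-normalized)
static void deposit(NumericMatrix &re, NumericMatrix &im,
                    double px, double py, double a, double phase,
                    double pitch, double sigma_px, int stencil_r) {
  int nx = re.ncol(), ny = re.nrow();
  double cx = px / pitch + 0.5 * (nx + 1);   // fractional pixel coords (1-based)
  double cy = py / pitch + 0.5 * (ny + 1);
  int ic = (int)std::lround(cx), jc = (int)std::lround(cy);
  if (ic < 1 - stencil_r || ic > nx + stencil_r ||
      jc < 1 - stencil_r || jc > ny + stencil_r) return;
  double ca = a * std::cos(phase), sa = a * std::sin(phase);
  double s2 = 2.0 * sigma_px * sigma_px;
  // L2 normalization of the truncated kernel
  double norm2 = 0.0;
  for (int dj = -stencil_r; dj <= stencil_r; dj++)
    for (int di = -stencil_r; di <= stencil_r; di++) {
      double dx = ic + di - cx, dy = jc + dj - cy;
      double w = std::exp(-(dx * dx + dy * dy) / s2);
      norm2 += w * w;
    }
  double inv = 1.0 / std::sqrt(norm2);
  for (int dj = -stencil_r; dj <= stencil_r; dj++) {
    int j = jc + dj;
    if (j < 1 || j > ny) continue;
    for (int di = -stencil_r; di <= stencil_r; di++) {
      int i = ic + di;
      if (i < 1 || i > nx) continue;
      double dx = i - cx, dy = j - cy;
      double w = std::exp(-(dx * dx + dy * dy) / s2) * inv;
      re(j - 1, i - 1) += ca * w;
      im(j - 1, i - 1) += sa * w;
    }
  }
}

// [[Rcpp::export]]
List mc_propagate_cpp(NumericVector layer_d, NumericVector layer_n,
                      NumericVector layer_mus, NumericVector layer_mua,
                      NumericVector layer_g,
                      int det_nx, int det_ny, double det_pitch,
                      double det_gap, double det_na,
                      double w0, int ell, double k0,
                      int n_ph, double coh_sigma, double psf_sigma_px,
                      int max_events, double roulette_w, double roulette_boost) {
  RNGScope scope;
  int nl = layer_d.size();
  std::vector<double> zb(nl + 1);
  zb[0] = 0.0;
  for (int l = 0; l < nl; l++) zb[l + 1] = zb[l] + layer_d[l];
  double D = zb[nl];
  double z_det = D + det_gap;
  double sin_na = det_na;

  // scattering layer used for the depolarization metadata scales
  int sl = 0;
  for (int l = 0; l < nl; l++) if (layer_mus[l] > layer_mus[sl]) sl = l;
  double ls_meta = 0.0, xi_meta = 0.0;
  if (layer_mus[sl] > 0.0) {
    double lstar = 1.0 / (layer_mus[sl] * (1.0 - layer_g[sl]));
    ls_meta = lstar * (1.0 - layer_g[sl]);
    xi_meta = ls_meta / std::sqrt(3.0 * std::log(10.0 / 7.0));
  }

  NumericMatrix coh_re(det_ny, det_nx), coh_im(det_ny, det_nx);
  NumericMatrix inc_re(det_ny, det_nx), inc_im(det_ny, det_nx);
  NumericMatrix p_sum(det_ny, det_nx), w_sum(det_ny, det_nx);

  int stencil_r = (int)std::ceil(2.0 * psf_sigma_px);
  double launched = 0.0, absorbed = 0.0, escaped_front = 0.0,
    escaped_back = 0.0, capped = 0.0, rr_killed = 0.0, rr_boost = 0.0;
  double first_path_sum = 0.0;
  double trans_events_sum = 0.0; long trans_n = 0;
  long n_detected = 0, n_capped = 0;
  double al = std::abs((double)ell);
  double inv_kw0 = 1.0 / (k0 * w0);

  for (int ip = 0; ip < n_ph; ip++) {
    // launch from the |LG|^2 annulus: rho^2 ~ Gamma(|l|+1, w0^2/2)
    double rho2 = R::rgamma(al + 1.0, w0 * w0 / 2.0);
    double r0m = std::sqrt(rho2);
    double phi0 = R::unif_rand() * 2.0 * M_PI;
    double x = r0m * std::cos(phi0), y = r0m * std::sin(phi0), z = 0.0;
    // paraxial spiral tangent at the waist: azimuthal slope ell/(r0 k w0)
    double r0d = r0m / w0;
    double tslope = (ell != 0 && r0d > 1e-12) ? (double)ell / r0d * inv_kw0 : 0.0;
    double ux = -std::sin(phi0) * tslope, uy = std::cos(phi0) * tslope, uz = 1.0;
    double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= nrm; uy /= nrm; uz /= nrm;

    double w = 1.0;
    launched += 1.0;
    double psi = -(double)ell * phi0;   // launch azimuthal phase
    double Lpath = 0.0;
    int events = 0;
    int layer = 0;
    bool first_recorded = false;
    // refract from ambient (n=1) into layer 0
    {
      double n2 = layer_n[0];
      double s = std::sqrt(ux * ux + uy * uy) / n2;
      double sc = (std::sqrt(ux * ux + uy * uy) > 1e-15) ?
        s / std::sqrt(ux * ux + uy * uy) : 1.0;
      ux *= sc; uy *= sc;
      uz = std::sqrt(std::max(0.0, 1.0 - ux * ux - uy * uy));
    }

    bool alive = true;
    while (alive) {
      double tau = -std::log(R::unif_rand());
      if (!first_recorded) {
        double mt0 = layer_mus[layer] + layer_mua[layer];
        if (mt0 > 0.0) { first_path_sum += tau / mt0; first_recorded = true; }
      }
      // consume optical depth tau across layers
      while (true) {
        double mt = layer_mus[layer] + layer_mua[layer];
        double zlo = zb[layer], zhi = zb[layer + 1];
        double s_geo = (mt > 0.0) ? tau / mt : 1e30;
        double s_bound;
        int next;
        if (uz > 1e-12) { s_bound = (zhi - z) / uz; next = layer + 1; }
        else if (uz < -1e-12) { s_bound = (zlo - z) / uz; next = layer - 1; }
        else { s_bound = 1e30; next = layer; }
        if (mt <= 0.0 && s_bound >= 1e29) {
          // non-scattering layer and purely transverse flight: drop packet
          escaped_front += w; alive = false; break;
        }
        if (s_geo < s_bound) {
          // scattering/absorption vertex inside this layer
          x += ux * s_geo; y += uy * s_geo; z += uz * s_geo;
          Lpath += s_geo;
          psi += k0 * layer_n[layer] * s_geo;
          break;
        }
        // move to the boundary, spend its optical depth, cross
        x += ux * s_bound; y += uy * s_bound; z += uz * s_bound;
        Lpath += s_bound;
        psi += k0 * layer_n[layer] * s_bound;
        tau -= s_bound * mt;
        if (next < 0) { escaped_front += w; alive = false; break; }
        if (next >= nl) {
          // leaves through the back face into ambient n = 1
          double n1 = layer_n[nl - 1];
          double st2 = (ux * ux + uy * uy) * n1 * n1;
          if (st2 < 1.0) {
            double sc = n1;
            ux *= sc; uy *= sc;
            uz = std::sqrt(std::max(0.0, 1.0 - ux * ux - uy * uy));
            if (events == 0) {
              // unscattered beam: propagate to the detector plane, deposit
              double sdet = (z_det - z) / uz;
              double px = x + ux * sdet, py = y + uy * sdet;
              double sinth = std::sqrt(ux * ux + uy * uy);
              if (sinth <= sin_na) {
                double ph = psi + k0 * sdet;
                double a = std::sqrt(w);
                deposit(coh_re, coh_im, px, py, a, ph, det_pitch,
                        psf_sigma_px, stencil_r);
                int ic = (int)std::lround(px / det_pitch + 0.5 * (det_nx + 1));
                int jc = (int)std::lround(py / det_pitch + 0.5 * (det_ny + 1));
                if (ic >= 1 && ic <= det_nx && jc >= 1 && jc <= det_ny) {
                  p_sum(jc - 1, ic - 1) += w * dop_clip(Lpath + sdet, ls_meta, xi_meta);
                  w_sum(jc - 1, ic - 1) += w;
                }
                n_detected++;
              }
            } else {
              trans_events_sum += events; trans_n++;
            }
          }
          escaped_back += w;
          alive = false;
          break;
        }
        // internal interface refraction
        double n1 = layer_n[layer], n2 = layer_n[next];
        double st1 = std::sqrt(ux * ux + uy * uy);
        double st2 = st1 * n1 / n2;
        if (st2 >= 1.0) {
          uz = -uz;               // total internal reflection (rare, paraxial)
        } else {
          if (st1 > 1e-15) { ux *= st2 / st1; uy *= st2 / st1; }
          double uzs = std::sqrt(std::max(0.0, 1.0 - st2 * st2));
          uz = (uz >= 0.0) ? uzs : -uzs;
          layer = next;
        }
      }
      if (!alive) break;

      // scattering vertex
      events++;
      double mus = layer_mus[layer], mua = layer_mua[layer];
      double mt = mus + mua;
      absorbed += w * mua / mt;
      w *= mus / mt;

      // semi-analytic detection: one detector pixel per vertex, importance
      // sampled with density ~ 1/(r^2 + b^2) about the vertex to tame the
      // 1/s^2 solid-angle singularity of the local estimator
      {
        double zrel = z_det - z;
        double b2 = zrel * zrel + det_pitch * det_pitch;
        double halfW = 0.5 * det_nx * det_pitch, halfH = 0.5 * det_ny * det_pitch;
        double dxm = halfW + std::fabs(x), dym = halfH + std::fabs(y);
        double R2 = dxm * dxm + dym * dym;
        double lg1 = std::log(1.0 + R2 / b2);
        // vertices near the exit face dominate the detected field; split
        // them into several sub-samples to tame the estimator variance
        double tau_v = 0.0;
        {
          double zz = z;
          for (int l = layer; l < nl; l++) {
            double seg = zb[l + 1] - (zz > zb[l] ? zz : zb[l]);
            if (seg > 0.0) tau_v += seg * (layer_mus[l] + layer_mua[l]);
            zz = zb[l + 1];
          }
        }
        int K = 1 + (int)(11.0 * std::exp(-0.5 * tau_v));
        for (int ks = 0; ks < K; ks++) {
        double u = R::unif_rand();
        double r2 = b2 * (std::exp(u * lg1) - 1.0);
        double phr = R::unif_rand() * 2.0 * M_PI;
        double rr = std::sqrt(r2);
        double sxp = x + rr * std::cos(phr), syp = y + rr * std::sin(phr);
        int i = (int)std::lround(sxp / det_pitch + 0.5 * (det_nx + 1));
        int j = (int)std::lround(syp / det_pitch + 0.5 * (det_ny + 1));
        if (i < 1 || i > det_nx || j < 1 || j > det_ny) continue;
        {
        double px = (i - 0.5 * (det_nx + 1)) * det_pitch;
        double py = (j - 0.5 * (det_ny + 1)) * det_pitch;
        double rp2 = (px - x) * (px - x) + (py - y) * (py - y);
        // probability of having selected this pixel
        double q = det_pitch * det_pitch / (M_PI * lg1 * (rp2 + b2));
        double vx = px - x, vy = py - y, vz = z_det - z;
        double s = std::sqrt(vx * vx + vy * vy + vz * vz);
        vx /= s; vy /= s; vz /= s;
        double sinth = std::sqrt(vx * vx + vy * vy);
        if (vz > 0.0 && sinth <= sin_na) {
          double cgam = ux * vx + uy * vy + uz * vz;
          double f = hg_pdf_sr(layer_g[layer], cgam);
          // optical depth and optical path from the vertex to the back face
          double tau_exit = 0.0, opt_exit = 0.0, geo_exit = 0.0;
          double zz = z;
          for (int l = layer; l < nl; l++) {
            double seg = ((zb[l + 1] - std::max(zz, zb[l])) / vz);
            if (seg < 0.0) seg = 0.0;
            tau_exit += seg * (layer_mus[l] + layer_mua[l]);
            opt_exit += seg * layer_n[l];
            geo_exit += seg;
            zz = zb[l + 1];
          }
          double s_gap = s - geo_exit;           // free-space leg, 0 when imaging the exit face
          // pixel solid angle, regularized so vertices right under a pixel
          // cannot exceed the physical bound
          double domega = det_pitch * det_pitch * vz /
            (s * s + det_pitch * det_pitch);
          double inten = w * f * domega * std::exp(-tau_exit) / (q * K);
          if (inten > 0.0) {
            double a = std::sqrt(inten);
            double ph = psi + k0 * (opt_exit + s_gap);
            double Ltot = Lpath + geo_exit + s_gap;
            // transverse deviation of the exit-face arrival point from the
            // launch trajectory's unscattered exit point (rotational-symmetry
            // memory argument: small deviations preserve the helical phase)
            double bx = r0m * std::cos(phi0), by = r0m * std::sin(phi0);
            double dev2 = (px - bx) * (px - bx) + (py - by) * (py - by);
            double C = std::exp(-dev2 / (2.0 * coh_sigma * coh_sigma));
            double chi = R::unif_rand() * 2.0 * M_PI;
            if (C > 1e-8)
              deposit(coh_re, coh_im, px, py, a * C, ph, det_pitch,
                      psf_sigma_px, stencil_r);
            deposit(inc_re, inc_im, px, py, a * std::sqrt(1.0 - C * C), chi,
                    det_pitch, psf_sigma_px, stencil_r);
            p_sum(j - 1, i - 1) += inten * dop_clip(Ltot, ls_meta, xi_meta);
            w_sum(j - 1, i - 1) += inten;
            n_detected++;
          }
        }
        }
        }
      }

      // new direction
      double ct = hg_cos(layer_g[layer]);
      double phs = R::unif_rand() * 2.0 * M_PI;
      rotate_dir(ux, uy, uz, ct, phs);

      if (events >= max_events) {
        capped += w; n_capped++;
        alive = false;
        break;
      }
      if (w < roulette_w) {
        if (R::unif_rand() < 1.0 / roulette_boost) {
          rr_boost += w * (roulette_boost - 1.0);
          w *= roulette_boost;
        } else {
          rr_killed += w;
          alive = false;
        }
      }
    }
  }

  return List::create(
    _["coh_re"] = coh_re, _["coh_im"] = coh_im,
    _["inc_re"] = inc_re, _["inc_im"] = inc_im,
    _["p_sum"] = p_sum, _["w_sum"] = w_sum,
    _["launched"] = launched, _["absorbed"] = absorbed,
    _["escaped_front"] = escaped_front, _["escaped_back"] = escaped_back,
    _["capped"] = capped, _["rr_killed"] = rr_killed, _["rr_boost"] = rr_boost,
    _["mean_first_path"] = (n_ph > 0 ? first_path_sum / n_ph : NA_REAL),
    _["mean_events_transmitted"] = (trans_n > 0 ? trans_events_sum / trans_n : NA_REAL),
    _["n_detected"] = (double)n_detected,
    _["n_capped"] = (double)n_capped);
}

// [[Rcpp::export]]
NumericVector sample_hg_cpp(int n, double g) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = std::acos(hg_cos(g));
  return out;
}
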