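// Photon-packet Monte Carlo transport through a stack of planar turbid
// layers (MCML-style hop-drop-spin with weight packets and Russian
// roulette).  Geometry is laterally infinite: only z and the full 3-D
// direction are tracked, and all tallies are laterally integrated, which
// makes a normally incident pencil beam equivalent to an infinitely broad
// collimated beam.
//
// Randomness comes from R's own generator (unif_rand), so a set.seed()
// on the R side makes every run bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rnd01() {
  // open interval (0,1): -log(u) and inverse CDFs must not see 0 or 1
  double u;
  do {
    u = unif_rand();
  } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Unpolarized Fresnel reflectance at a planar interface; also returns the
// cosine of the refracted angle.  Returns 1 at/beyond the critical angle
// and at grazing incidence.
static double fresnel_cpp(double ni, double nt, double ci, double *ct_out) {
  if (ni == nt) { *ct_out = ci; return 0.0; }
  if (ci < 1e-12) { *ct_out = 0.0; return 1.0; }
  double si2 = 1.0 - ci * ci;
  if (si2 < 0.0) si2 = 0.0;
  double st = ni / nt * std::sqrt(si2);
  if (st >= 1.0) { *ct_out = 0.0; return 1.0; }
  double ct = std::sqrt(1.0 - st * st);
  *ct_out = ct;
  if (ci > 0.9999999) {
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine (inverse-CDF sampling; g = 0 is
// isotropic).
static inline double hg_cos(double g) {
  double u = rnd01();
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and uniform azimuth.
static void spin(double *ux, double *uy, double *uz, double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rnd01();
  double cp = std::cos(phi), sp = std::sin(phi);
  double x = *ux, y = *uy, z = *uz;
  if (std::fabs(z) > 0.99999) {
    *ux = st * cp;
    *uy = st * sp;
    *uz = (z >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - z * z);
    *ux = st * (x * z * cp - y * sp) / den + x * ct;
    *uy = st * (y * z * cp + x * sp) / den + y * ct;
    *uz = -st * cp * den + z * ct;
  }
  // renormalize against drift
  double nrm = std::sqrt(*ux * *ux + *uy * *uy + *uz * *uz);
  *ux /= nrm; *uy /= nrm; *uz /= nrm;
}

// Weighted track-length fluence tally: distribute path length s (weight w)
// travelled from depth z1 to z2 across depth bins of width dz (n_bins bins,
// depths beyond n_bins*dz ignored).
static void tally_path(NumericVector &path, double z1, double z2, double s,
                       double w, double dz, int n_bins) {
  double zmax_rec = n_bins * dz;
  double lo = std::min(z1, z2), hi = std::max(z1, z2);
  if (lo >= zmax_rec) return;
  double extent = hi - lo;
  if (extent < 1e-15) {
    int k = (int)std::floor(lo / dz);
    if (k >= 0 && k < n_bins) path[k] += w * s;
    return;
  }
  if (hi > zmax_rec) hi = zmax_rec;
  int k0 = (int)std::floor(lo / dz);
  int k1 = (int)std::floor((hi - 1e-15) / dz);
  if (k0 < 0) k0 = 0;
  if (k1 >= n_bins) k1 = n_bins - 1;
  for (int k = k0; k <= k1; ++k) {
    double a = std::max(lo, k * dz);
    double b = std::min(hi, (k + 1) * dz);
    if (b > a) path[k] += w * s * (b - a) / extent;
  }
}

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(NumericVector thickness, NumericVector mu_a, NumericVector mu_s,
               NumericVector g, NumericVector n_layer,
               double n_above, double n_below, bool mirror_top,
               int n_photons, double dz, int n_bins,
               double roulette_threshold, double roulette_survival,
               bool tally_fluence) {
  const int L = thickness.size();
  std::vector<double> zb(L + 1);
  zb[0] = 0.0;
  for (int i = 0; i < L; ++i) zb[i + 1] = zb[i] + thickness[i];

  // deterministic specular reflection at launch
  double ct_dummy;
  double rsp = fresnel_cpp(n_above, n_layer[0], 1.0, &ct_dummy);

  NumericVector dep(n_bins), path(n_bins);
  double sumR = 0, sumR2 = 0, sumT = 0, sumT2 = 0, sumA = 0, sumA2 = 0;
  double t_ball = 0;
  long n_refl = 0, n_trans = 0, n_dead = 0;
  const long max_events = 50000000L;  // internal-consistency guard

  for (int ip = 0; ip < n_photons; ++ip) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    int l = 0;
    double sleft = 0.0;
    bool alive = true, scattered = false;
    double rw = 0.0, tw = 0.0, aw = 0.0;
    long ev = 0;

    while (alive) {
      if (++ev > max_events)
        stop("photon exceeded the event budget: inconsistent stack or RNG state");
      double mt = mu_a[l] + mu_s[l];
      double db;  // distance to boundary along travel direction
      int hit;    // boundary index hit: l (upper) or l+1 (lower); -1 none
      if (uz > 0.0) {
        db = std::isinf(zb[l + 1]) ? R_PosInf : (zb[l + 1] - z) / uz;
        hit = l + 1;
      } else if (uz < 0.0) {
        db = (z - zb[l]) / (-uz);
        hit = l;
      } else {
        db = R_PosInf;
        hit = -1;
      }

      double step;
      bool at_boundary;
      if (mt <= 0.0) {
        // ballistic (clear) layer: jump straight to the boundary
        if (!std::isfinite(db)) {
          // clear semi-infinite layer (or trapped horizontal ray): the
          // packet leaves the recording region without further interaction
          tw += w;
          if (!scattered) t_ball += w;
          n_trans++;
          alive = false;
          break;
        }
        step = db;
        at_boundary = true;
      } else {
        if (sleft <= 0.0) sleft = -std::log(rnd01());
        double sfree = sleft / mt;
        if (db <= sfree) {
          step = db;
          sleft -= db * mt;
          at_boundary = true;
        } else {
          step = sfree;
          sleft = 0.0;
          at_boundary = false;
        }
      }

      double z_new = z + step * uz;
      if (tally_fluence) tally_path(path, z, z_new, step, w, dz, n_bins);
      z = z_new;

      if (at_boundary) {
        z = (uz > 0.0) ? zb[hit] : zb[hit];  // snap to the exact interface
        double ci = std::fabs(uz), ct;
        if (hit == 0) {
          // top surface
          if (mirror_top) {
            uz = -uz;  // deterministic specular return
          } else {
            double r = fresnel_cpp(n_layer[0], n_above, ci, &ct);
            if (rnd01() > r) {
              rw += w; n_refl++; alive = false;
            } else {
              uz = -uz;
            }
          }
        } else if (hit == L && uz > 0.0) {
          // bottom surface
          double r = fresnel_cpp(n_layer[L - 1], n_below, ci, &ct);
          if (rnd01() > r) {
            tw += w;
            if (!scattered) t_ball += w;
            n_trans++; alive = false;
          } else {
            uz = -uz;
          }
        } else {
          // internal interface between layer l and l2
          int l2 = (uz > 0.0) ? l + 1 : l - 1;
          double ni = n_layer[l], nt = n_layer[l2];
          double r = fresnel_cpp(ni, nt, ci, &ct);
          if (rnd01() > r) {
            double scale = ni / nt;
            ux *= scale; uy *= scale;
            uz = (uz > 0.0) ? ct : -ct;
            double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= nrm; uy /= nrm; uz /= nrm;
            l = l2;
          } else {
            uz = -uz;
          }
        }
      } else {
        // interaction site: drop then spin
        double dwgt = w * mu_a[l] / mt;
        if (dwgt > 0.0) {
          aw += dwgt;
          if (tally_fluence) {
            int k = (int)std::floor(z / dz);
            if (k >= 0 && k < n_bins) dep[k] += dwgt;
          }
          w -= dwgt;
        }
        scattered = true;
        spin(&ux, &uy, &uz, hg_cos(g[l]));
        if (w < roulette_threshold) {
          if (rnd01() <= roulette_survival) {
            w /= roulette_survival;
          } else {
            n_dead++; alive = false;
          }
        }
      }
    }

    sumR += rw; sumR2 += rw * rw;
    sumT += tw; sumT2 += tw * tw;
    sumA += aw; sumA2 += aw * aw;
  }

  double N = (double)n_photons;
  double Rd = sumR / N, Tt = sumT / N, At = sumA / N;
  double seR = std::sqrt(std::max(0.0, sumR2 / N - Rd * Rd) / N);
  double seT = std::sqrt(std::max(0.0, sumT2 / N - Tt * Tt) / N);
  double seA = std::sqrt(std::max(0.0, sumA2 / N - At * At) / N);

  return List::create(
      _["R_specular"] = rsp, _["R_diffuse"] = Rd, _["T_total"] = Tt,
      _["A_total"] = At, _["T_ballistic"] = t_ball / N,
      _["se_R"] = seR, _["se_T"] = seT, _["se_A"] = seA,
      _["n_reflected"] = (double)n_refl, _["n_transmitted"] = (double)n_trans,
      _["n_absorbed"] = (double)n_dead,
      _["dep"] = dep, _["path"] = path);
}
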