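// Core engine: occlusion-resolved ray-cast vision, perception-field attention,
// and Euler--Maruyama stepping of the speed/heading kinematics.  The exported
// entry points mirror the plain-R reference implementations in R/ so the two
// can be cross-checked in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double TWO_PI_ = 6.283185307179586476925287;

// wrap to [-pi, pi]; the atan2 form keeps the endpoint conventions
// (+pi stays +pi, -pi stays -pi) used throughout.
static inline double wrap_pi(double x) {
  return std::atan2(std::sin(x), std::cos(x));
}

// cheap wrap for values already within a few periods of zero
static inline double wrap_fast(double x) {
  while (x >  M_PI) x -= TWO_PI_;
  while (x < -M_PI) x += TWO_PI_;
  return x;
}

// ---------------------------------------------------------------------------
// fast atan2: polynomial minimax approximation, |error| < 1e-6 rad.
// Used only to locate the candidate bin range of a body segment; the range is
// padded by one bin on each side so the approximation can never drop a hit.
static inline double fast_atan(double z) {
  double z2 = z * z;
  return z * (0.99997726 + z2 * (-0.33262347 + z2 * (0.19354346 +
              z2 * (-0.11643287 + z2 * (0.05265332 + z2 * (-0.01172120))))));
}
static inline double fast_atan2(double y, double x) {
  double ay = std::fabs(y), ax = std::fabs(x);
  if (ax + ay < 1e-300) return 0.0;
  bool inv = ay > ax;
  double z = inv ? (ax / ay) : (ay / ax);
  double a = fast_atan(z);
  if (inv) a = M_PI_2 - a;
  if (x < 0) a = M_PI - a;
  return (y < 0) ? -a : a;
}

// fast exp: range reduction to 2^n * exp(r), degree-8 polynomial on the
// reduced interval; relative error ~1e-10, used in the perception math.
static inline double fexp(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) return std::numeric_limits<double>::infinity();
  const double LOG2E = 1.4426950408889634074;
  const double LN2 = 0.6931471805599453094;
  double t = x * LOG2E;
  double n = std::nearbyint(t);
  double r = (t - n) * LN2;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320))))))));
  union { double d; uint64_t u; } sc;
  sc.u = (uint64_t)((int64_t)n + 1023) << 52;
  return p * sc.d;
}

// ---------------------------------------------------------------------------
// counter-based per-agent noise: normals depend only on (seed, agent id, step)
// so that permuting the storage order of agents leaves trajectories invariant.
static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double u01(uint64_t h) {
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
static inline void agent_normals(uint64_t seed, uint64_t id, uint64_t step,
                                 double &z1, double &z2) {
  uint64_t k = sm64(seed ^ (id * 0x9E3779B97F4A7C15ULL)
                         ^ (step * 0xC2B2AE3D27D4EB4FULL));
  uint64_t k1 = sm64(k);
  uint64_t k2 = sm64(k1);
  double u1 = u01(k1), u2 = u01(k2);
  double rr = std::sqrt(-2.0 * std::log(u1));
  z1 = rr * std::cos(TWO_PI_ * u2);
  z2 = rr * std::sin(TWO_PI_ * u2);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_noise_pair(double seed, double id, double step) {
  double z1, z2;
  agent_normals((uint64_t)seed, (uint64_t)id, (uint64_t)step, z1, z2);
  return NumericVector::create(z1, z2);
}

// ---------------------------------------------------------------------------
struct Par {
  double lb, hb, le;
  int    nb;
  double kappa, chi, beta, amp, r0, ra, tau_phi;
  double v0, drag, fr, fa, re, rho_e, omega_r, omega_a, omega_o, ro, lo;
  double Dv, Dtheta, eps_r, dphi_max;
  int    phi_substeps;
  int    window_norm;   // 0: mean over occupied bins, 1: divide by |window|
  // derived
  double binw, delta0;
  int    att_bins;      // half-width (in bins) of the kernel support cutoff
  std::vector<double> cbin, cosc, sinc, dens;  // per-bin center tables
};

static Par make_par(const List &p) {
  Par q;
  q.lb = as<double>(p["lb"]);       q.hb = as<double>(p["hb"]);
  q.le = as<double>(p["le"]);       q.nb = as<int>(p["n_bins"]);
  q.kappa = as<double>(p["kappa"]); q.chi = as<double>(p["chi"]);
  q.beta = as<double>(p["beta"]);   q.amp = as<double>(p["amp"]);
  q.r0 = as<double>(p["r0"]);       q.ra = as<double>(p["ra"]);
  q.tau_phi = as<double>(p["tau_phi"]);
  q.v0 = as<double>(p["v0"]);       q.drag = as<double>(p["drag"]);
  q.fr = as<double>(p["fr"]);       q.fa = as<double>(p["fa"]);
  q.re = as<double>(p["re"]);       q.rho_e = as<double>(p["rho_e"]);
  q.omega_r = as<double>(p["omega_r"]); q.omega_a = as<double>(p["omega_a"]);
  q.omega_o = as<double>(p["omega_o"]);
  q.ro = as<double>(p["ro"]);       q.lo = as<double>(p["lo"]);
  q.Dv = as<double>(p["Dv"]);       q.Dtheta = as<double>(p["Dtheta"]);
  q.eps_r = as<double>(p["eps_r"]); q.dphi_max = as<double>(p["dphi_max"]);
  q.phi_substeps = as<int>(p["phi_substeps"]);
  q.window_norm = as<int>(p["window_norm"]);
  q.binw = TWO_PI_ / q.nb;
  q.delta0 = 2.0 * std::atan(q.lb / (2.0 * q.r0));
  // kernel support: G < ~1e-8 outside, i.e. kappa*(1-cos(dmax)) > 18.4
  double c = 1.0 - 18.4 / q.kappa;
  double dmax = (c <= -1.0) ? M_PI : std::acos(c);
  q.att_bins = (int)std::ceil(dmax / q.binw);
  if (2 * q.att_bins + 1 > q.nb) q.att_bins = (q.nb - 1) / 2;
  q.cbin.resize(q.nb); q.cosc.resize(q.nb); q.sinc.resize(q.nb);
  q.dens.resize(q.nb);
  for (int k = 0; k < q.nb; ++k) {
    double a = -M_PI + (k + 0.5) * q.binw;
    q.cbin[k] = a;
    q.cosc[k] = std::cos(a);
    q.sinc[k] = std::sin(a);
    q.dens[k] = (1.0 + q.chi * q.cosc[k]) / (1.0 + q.chi);
  }
  return q;
}

// piecewise speeding-force profile f(r)
static inline double f_prof(double r, const Par &P) {
  if (r < P.re) return -P.fr * (P.re - r) / P.re;
  if (r < P.ra) return  P.fa * (r - P.re) / (P.ra - P.re);
  return P.fa * P.ra / r;
}
// piecewise turning profile omega(r); first branch has denominator re
// (implemented as printed in the source model)
static inline double w_prof(double r, const Par &P) {
  if (r < P.rho_e) return -P.omega_r * (P.rho_e - r) / P.re;
  if (r < P.ra)    return  P.omega_a * (r - P.rho_e) / (P.ra - P.rho_e);
  return P.omega_a * P.ra / r;
}

// ---------------------------------------------------------------------------
// Occlusion-resolved visual field of agent i: one ray per bin center, the
// occupier of a bin is the neighbor whose body segment gives the nearest
// intersection.  occ is the 0-based neighbor index (-1 empty), rhit the
// distance to the visible intersection (clamped below by eps_r).
static void build_field(int i, int n,
                        const double *x, const double *y,
                        const double *ct, const double *st,
                        double theta_i, const Par &P,
                        std::vector<int> &occ, std::vector<double> &rhit,
                        std::vector<std::pair<double,int> > &ord) {
  const int nb = P.nb;
  const int BLK = 16, nblk = (nb + BLK - 1) / BLK;
  double blkmax[64];                   // upper bound of rhit per bin block
  bool blk_valid = false;
  const double hl = 0.5 * P.lb;
  std::fill(occ.begin(), occ.end(), -1);
  std::fill(rhit.begin(), rhit.end(), std::numeric_limits<double>::infinity());
  const double ex = x[i], ey = y[i];
  const double cth = std::cos(theta_i), sth = std::sin(theta_i);

  ord.clear();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double cx = x[j] - P.le * ct[j] - ex;
    double cy = y[j] - P.le * st[j] - ey;
    ord.push_back(std::make_pair(std::sqrt(cx * cx + cy * cy), j));
  }
  std::sort(ord.begin(), ord.end());   // near bodies first: better pruning

  for (size_t k = 0; k < ord.size(); ++k) {
    if (k == 12 && nblk <= 64) {
      // near bodies have filled most bins; freeze a per-block upper bound
      // of rhit (rhit only decreases, so the bound stays valid) to skip
      // whole blocks of occluded bins for the remaining, farther bodies
      for (int b = 0; b < nblk; ++b) {
        double m = 0.0;
        int hi2 = std::min(nb, (b + 1) * BLK);
        for (int q = b * BLK; q < hi2; ++q)
          if (rhit[q] > m) m = rhit[q];
        blkmax[b] = m;
      }
      blk_valid = true;
    }
    int j = ord[k].second;
    double dist = ord[k].first;
    double minpos = dist - hl;         // lower bound on eye-segment distance
    double cx = x[j] - P.le * ct[j] - ex;
    double cy = y[j] - P.le * st[j] - ey;
    double q1x = cx - hl * ct[j], q1y = cy - hl * st[j];
    double q2x = cx + hl * ct[j], q2y = cy + hl * st[j];
    double a1 = fast_atan2(q1y, q1x), a2 = fast_atan2(q2y, q2x);
    double span = wrap_fast(a2 - a1);
    double astart = (span >= 0) ? a1 : a2;
    span = std::fabs(span);
    double b1 = wrap_fast(astart - theta_i);
    double g1 = (b1 + M_PI) / P.binw + 0.5;
    // pad by the atan2 approximation error (1e-6 rad ~ 4e-5 bins)
    int mu_lo = (int)std::ceil(g1 - 6e-5);
    int mu_hi = (int)std::floor(g1 + span / P.binw + 6e-5);
    double egx = P.lb * ct[j], egy = P.lb * st[j];         // segment vector
    int idx = ((mu_lo - 1) % nb + nb) % nb;
    for (int mu = mu_lo; mu <= mu_hi; ++mu, (++idx == nb ? idx = 0 : 0)) {
      if (blk_valid && blkmax[idx / BLK] <= minpos) {
        // whole block occluded: jump to its last bin
        int skip = BLK - 1 - (idx % BLK);
        if (skip > mu_hi - mu) skip = mu_hi - mu;
        mu += skip;
        idx += skip;
        if (idx >= nb) idx -= nb;
        continue;
      }
      if (rhit[idx] <= minpos) continue;                   // already occluded
      // ray direction at world angle theta_i + cbin[idx]
      double dx = cth * P.cosc[idx] - sth * P.sinc[idx];
      double dy = sth * P.cosc[idx] + cth * P.sinc[idx];
      double den = dx * egy - dy * egx;                    // cross(d, e)
      double t;
      if (std::fabs(den) < 1e-12) {
        // ray nearly parallel to the body axis: nearest endpoint on the ray
        t = std::numeric_limits<double>::infinity();
        double c1 = dx * q1y - dy * q1x;
        double n1 = std::fabs(q1x) + std::fabs(q1y) + 1e-30;
        if (std::fabs(c1) < 1e-7 * n1) {
          double tp = dx * q1x + dy * q1y;
          if (tp > 0 && tp < t) t = tp;
        }
        double c2 = dx * q2y - dy * q2x;
        double n2 = std::fabs(q2x) + std::fabs(q2y) + 1e-30;
        if (std::fabs(c2) < 1e-7 * n2) {
          double tp = dx * q2x + dy * q2y;
          if (tp > 0 && tp < t) t = tp;
        }
        if (!std::isfinite(t)) continue;
      } else {
        double s = (q1x * dy - q1y * dx) / den;
        if (s < 0.0 || s > 1.0) continue;
        t = (q1x * egy - q1y * egx) / den;
        if (t <= 0.0) continue;
      }
      if (t < P.eps_r) t = P.eps_r;                        // overlap clamp
      if (t < rhit[idx]) { rhit[idx] = t; occ[idx] = j; }
    }
  }
}

// perception-field gradient dGamma/dphi at angle phi for agent i,
// summed over occupied bins within the kernel support cutoff
static double dgamma_at(int i, double phi,
                        const std::vector<int> &occ,
                        const std::vector<double> &rhit,
                        const double *v, const double *ct, const double *st,
                        const Par &P) {
  const int nb = P.nb;
  double phiw = wrap_fast(phi);
  int j0 = (int)std::floor((phiw + M_PI) / P.binw);
  if (j0 < 0) j0 = 0;
  if (j0 >= nb) j0 = nb - 1;
  double cp = std::cos(phiw), sp = std::sin(phiw);
  double vix = v[i] * ct[i], viy = v[i] * st[i];
  double acc = 0.0;
  for (int off = -P.att_bins; off <= P.att_bins; ++off) {
    int idx = ((j0 + off) % nb + nb) % nb;
    int j = occ[idx];
    if (j < 0) continue;
    double r = rhit[idx];
    // cos/sin of (phi - bin center) via the precomputed bin tables
    double cd = cp * P.cosc[idx] + sp * P.sinc[idx];
    double sd = sp * P.cosc[idx] - cp * P.sinc[idx];
    double G = fexp(P.kappa * (cd - 1.0));
    double dux = v[j] * ct[j] - vix, duy = v[j] * st[j] - viy;
    double u = std::sqrt(dux * dux + duy * duy);
    double era = fexp(-r / P.ra);
    double U = (1.0 - era) + era * fexp(P.beta * (u / P.v0 - 1.0));
    double A = P.amp * P.r0 / (P.r0 + r);
    acc += P.dens[idx] * U * A * P.kappa * sd * G;
  }
  return acc;
}

// mean speeding force and angular velocity over the occupied bins whose
// centers lie in the resolution window [phi - delta0/2, phi + delta0/2]
static void window_forces(int i, double phi,
                          const std::vector<int> &occ,
                          const std::vector<double> &rhit,
                          const double *ct, const double *st,
                          const Par &P, double &Fbar, double &Obar) {
  const int nb = P.nb;
  double h = 0.5 * P.delta0;
  double lo = wrap_fast(phi - h);
  double g1 = (lo + M_PI) / P.binw + 0.5;
  int mu_lo = (int)std::ceil(g1 - 1e-9);
  int mu_hi = (int)std::floor(g1 + P.delta0 / P.binw + 1e-9);
  double sf = 0.0, so = 0.0;
  int cnt = 0;
  for (int mu = mu_lo; mu <= mu_hi; ++mu) {
    int idx = ((mu - 1) % nb + nb) % nb;
    int j = occ[idx];
    if (j < 0) continue;
    double r = rhit[idx];
    double cpsi = ct[j] * ct[i] + st[j] * st[i];
    double spsi = st[j] * ct[i] - ct[j] * st[i];
    double era = fexp(-r / P.ra);
    double F = f_prof(r, P) * P.cosc[idx];
    double Ora = w_prof(r, P) * P.sinc[idx] *
                 (1.0 - era * (1.0 + cpsi) * 0.5);
    double dro = r - P.ro;
    double Oo = P.omega_o * fexp(-dro * dro / (2.0 * P.lo * P.lo)) *
                (1.0 + P.cosc[idx]) * 0.5 * spsi;
    sf += F;
    so += Ora + Oo;
    ++cnt;
  }
  int denom = P.window_norm ? (mu_hi - mu_lo + 1) : cnt;
  if (cnt > 0 && denom > 0) { Fbar = sf / denom; Obar = so / denom; }
  else                      { Fbar = 0.0;        Obar = 0.0; }
}

// ---------------------------------------------------------------------------
// One synchronous step of all agents from the pre-step state.  noise holds
// standard normals (n x 2); virtual agents keep (v, theta, phi) fixed.
// Returns false (and the index of the offender) on non-finite state.
static bool do_step(int n, double *x, double *y, double *v, double *th,
                    double *ph, const int *isv, const Par &P, double dt,
                    const double *z1, const double *z2, bool baseline,
                    std::vector<double> &x0, std::vector<double> &y0,
                    std::vector<double> &v0s, std::vector<double> &th0,
                    std::vector<double> &ph0, std::vector<double> &ct,
                    std::vector<double> &st, std::vector<int> &occ,
                    std::vector<double> &rhit,
                    std::vector<std::pair<double,int> > &ord, int &bad) {
  for (int i = 0; i < n; ++i) {
    x0[i] = x[i]; y0[i] = y[i]; v0s[i] = v[i]; th0[i] = th[i]; ph0[i] = ph[i];
    ct[i] = std::cos(th[i]); st[i] = std::sin(th[i]);
  }
  double sv = std::sqrt(2.0 * P.Dv * dt);
  double sth = std::sqrt(2.0 * P.Dtheta * dt);
  for (int i = 0; i < n; ++i) {
    // positions advance for everyone from the pre-step state
    x[i] = x0[i] + dt * v0s[i] * ct[i];
    y[i] = y0[i] + dt * v0s[i] * st[i];
    if (isv[i]) continue;
    double Fbar = 0.0, Obar = 0.0;
    if (!baseline) {
      build_field(i, n, &x0[0], &y0[0], &ct[0], &st[0], th0[i], P, occ, rhit,
                  ord);
      // the attention equation is the stiffest variable: integrate it
      // with sub-steps against the frozen field of this kinematic step
      int K = P.phi_substeps;
      double hs = dt / K, cap = P.dphi_max / K, phv = ph0[i];
      for (int ss = 0; ss < K; ++ss) {
        double dg = dgamma_at(i, phv, occ, rhit, &v0s[0], &ct[0], &st[0],
                              P);
        double dphi = -(hs / P.tau_phi) * dg;
        if (dphi >  cap) dphi =  cap;
        if (dphi < -cap) dphi = -cap;
        phv += dphi;
      }
      ph[i] = wrap_pi(phv);
      window_forces(i, ph0[i], occ, rhit, &ct[0], &st[0], P, Fbar, Obar);
    } else {
      // conventional control: arithmetic mean of the forces from all
      // scripted (virtual) agents, no vision, attention frozen
      double sf = 0.0, so = 0.0;
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i || !isv[j]) continue;
        double dx = x0[j] - x0[i], dy = y0[j] - y0[i];
        double r = std::sqrt(dx * dx + dy * dy);
        if (r < P.eps_r) r = P.eps_r;
        double bear = wrap_fast(std::atan2(dy, dx) - th0[i]);
        double cb = std::cos(bear), sb = std::sin(bear);
        double cpsi = ct[j] * ct[i] + st[j] * st[i];
        double spsi = st[j] * ct[i] - ct[j] * st[i];
        double era = std::exp(-r / P.ra);
        sf += f_prof(r, P) * cb;
        double dro = r - P.ro;
        so += w_prof(r, P) * sb * (1.0 - era * (1.0 + cpsi) * 0.5) +
              P.omega_o * std::exp(-dro * dro / (2.0 * P.lo * P.lo)) *
              (1.0 + cb) * 0.5 * spsi;
        ++cnt;
      }
      if (cnt > 0) { Fbar = sf / cnt; Obar = so / cnt; }
    }
    double vn = v0s[i] + dt * (P.drag * (P.v0 * P.v0 - v0s[i] * v0s[i]) + Fbar)
                + sv * z1[i];
    if (vn < 0.0) vn = 0.0;                       // fish do not swim backward
    v[i] = vn;
    th[i] = wrap_pi(th0[i] + dt * Obar + sth * z2[i]);
    if (!std::isfinite(v[i]) || !std::isfinite(th[i]) ||
        !std::isfinite(x[i]) || !std::isfinite(y[i]) ||
        !std::isfinite(ph[i])) {
      bad = i;
      return false;
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_project(NumericVector x, NumericVector y, NumericVector v,
                 NumericVector theta, int focal, List params) {
  Par P = make_par(params);
  int n = x.size();
  std::vector<double> ct(n), st(n);
  for (int j = 0; j < n; ++j) { ct[j] = std::cos(theta[j]); st[j] = std::sin(theta[j]); }
  std::vector<int> occ((size_t)P.nb);
  std::vector<double> rhit((size_t)P.nb);
  std::vector<std::pair<double,int> > ord;
  int i = focal - 1;
  build_field(i, n, &x[0], &y[0], &ct[0], &st[0], theta[i], P, occ, rhit, ord);
  IntegerVector occ_r(P.nb);
  NumericVector r_r(P.nb), phi_mu(P.nb);
  for (int k = 0; k < P.nb; ++k) {
    occ_r[k] = occ[k] + 1;          // 0 means empty
    r_r[k] = std::isfinite(rhit[k]) ? rhit[k] : NA_REAL;
    phi_mu[k] = P.cbin[k];
  }
  return List::create(_["occupier"] = occ_r, _["r"] = r_r,
                      _["phi_mu"] = phi_mu);
}

// [[Rcpp::export]]
List cpp_step(NumericVector x, NumericVector y, NumericVector v,
              NumericVector theta, NumericVector phi, IntegerVector virt,
              List params, double dt, NumericMatrix noise, bool baseline) {
  Par P = make_par(params);
  int n = x.size();
  std::vector<double> X(x.begin(), x.end()), Y(y.begin(), y.end()),
      V(v.begin(), v.end()), TH(theta.begin(), theta.end()),
      PH(phi.begin(), phi.end());
  std::vector<double> x0(n), y0(n), v0s(n), th0(n), ph0(n), ct(n), st(n);
  std::vector<int> occ((size_t)P.nb);
  std::vector<double> rhit((size_t)P.nb);
  std::vector<std::pair<double,int> > ord;
  std::vector<double> z1(n), z2(n);
  for (int i = 0; i < n; ++i) { z1[i] = noise(i, 0); z2[i] = noise(i, 1); }
  int bad = -1;
  bool ok = do_step(n, &X[0], &Y[0], &V[0], &TH[0], &PH[0], &virt[0], P, dt,
                    &z1[0], &z2[0], baseline, x0, y0, v0s, th0, ph0, ct, st,
                    occ, rhit, ord, bad);
  if (!ok)
    stop("non-finite state for agent %d after one step (dt too large?)",
         bad + 1);
  return List::create(_["x"] = NumericVector(X.begin(), X.end()),
                      _["y"] = NumericVector(Y.begin(), Y.end()),
                      _["v"] = NumericVector(V.begin(), V.end()),
                      _["theta"] = NumericVector(TH.begin(), TH.end()),
                      _["phi"] = NumericVector(PH.begin(), PH.end()));
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix init, IntegerVector virt, IntegerVector ids,
                  List params, int nsteps, double dt, double seed,
                  int record_every, bool baseline) {
  Par P = make_par(params);
  int n = init.nrow();
  std::vector<double> X(n), Y(n), V(n), TH(n), PH(n);
  for (int i = 0; i < n; ++i) {
    X[i] = init(i, 0); Y[i] = init(i, 1); V[i] = init(i, 2);
    TH[i] = init(i, 3); PH[i] = init(i, 4);
  }
  std::vector<double> x0(n), y0(n), v0s(n), th0(n), ph0(n), ct(n), st(n);
  std::vector<int> occ((size_t)P.nb);
  std::vector<double> rhit((size_t)P.nb);
  std::vector<std::pair<double,int> > ord;
  std::vector<double> z1(n, 0.0), z2(n, 0.0);
  bool noisy = (P.Dv > 0.0 || P.Dtheta > 0.0);
  uint64_t sd = (uint64_t)seed;

  int nrec = nsteps / record_every + 1;
  NumericMatrix RX(nrec, n), RY(nrec, n), RV(nrec, n), RTH(nrec, n),
      RPH(nrec, n);
  NumericVector RT(nrec);
  int rec = 0;
  for (int i = 0; i < n; ++i) {
    RX(0, i) = X[i]; RY(0, i) = Y[i]; RV(0, i) = V[i];
    RTH(0, i) = TH[i]; RPH(0, i) = PH[i];
  }
  RT[0] = 0.0;
  rec = 1;

  int status_step = -1, bad = -1;
  for (int s = 1; s <= nsteps; ++s) {
    if (noisy) {
      for (int i = 0; i < n; ++i) {
        if (virt[i]) { z1[i] = 0.0; z2[i] = 0.0; continue; }
        agent_normals(sd, (uint64_t)ids[i], (uint64_t)s, z1[i], z2[i]);
      }
    }
    bool ok = do_step(n, &X[0], &Y[0], &V[0], &TH[0], &PH[0], &virt[0], P, dt,
                      &z1[0], &z2[0], baseline, x0, y0, v0s, th0, ph0, ct, st,
                      occ, rhit, ord, bad);
    if (!ok) { status_step = s; break; }
    if (s % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        RX(rec, i) = X[i]; RY(rec, i) = Y[i]; RV(rec, i) = V[i];
        RTH(rec, i) = TH[i]; RPH(rec, i) = PH[i];
      }
      RT[rec] = s * dt;
      ++rec;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = RT, _["x"] = RX, _["y"] = RY, _["v"] = RV,
                      _["theta"] = RTH, _["phi"] = RPH, _["nrec"] = rec,
                      _["failed_step"] = status_step,
                      _["failed_agent"] = bad + 1);
}
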