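// Compiled core: counter-based RNG, BAOAB Langevin integrator, OPES-Explore
// kernel bias layers with grid-cached evaluation, multithermal expanded
// ensemble, and the synchronous replica-exchange ladder driver.
//
// Units: kJ/mol, nm, ps, K; kB = 0.0083144621 kJ/mol/K.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 keyed by (seed, replica, stream); every draw
// is a pure function of (key, counter), so replicas are reproducible
// independently of scheduling and R can replay the exact same noise.
// ---------------------------------------------------------------------------

static inline uint64_t sm64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t rng_key(uint64_t seed, uint64_t replica, uint64_t stream) {
  return sm64(sm64(seed + 0x243F6A8885A308D3ULL) ^
              sm64(replica * 0x9E3779B97F4A7C15ULL + 0xB7E151628AED2A6BULL) ^
              sm64(stream + 0x93C467E37DB0C7A4ULL));
}

static inline double rng_u01(uint64_t key, uint64_t ctr) {
  uint64_t r = sm64(key ^ sm64(ctr + 0x452821E638D01377ULL));
  // 53-bit mantissa, strictly inside (0, 1)
  return ((double)(r >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double rng_normal(uint64_t key, uint64_t ctr) {
  double u1 = rng_u01(key, 2ULL * ctr);
  double u2 = rng_u01(key, 2ULL * ctr + 1ULL);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// [[Rcpp::export]]
NumericVector cpp_rng_uniforms(double seed, double replica, double stream, int n) {
  uint64_t key = rng_key((uint64_t)seed, (uint64_t)replica, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng_u01(key, (uint64_t)i);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rng_normals(double seed, double replica, double stream, int n) {
  uint64_t key = rng_key((uint64_t)seed, (uint64_t)replica, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng_normal(key, (uint64_t)i);
  return out;
}

// ---------------------------------------------------------------------------
// Analytic flip model
//   U(x, y) = a (x^2 - 1)^2 + b x + ky/2 (y - y0(x))^2 + epsL * g(x)
//   y0(x)   = ymid + yamp * tanh(2 x)        (hydration-like mean)
//   g(x)    = (1 + tanh(gk * x)) / 2          (smooth bulged-basin selector)
// dim == 1 drops the y terms (plain double well).
// ---------------------------------------------------------------------------

struct Model {
  int dim;
  double a, b, ky, ymid, yamp, epsL, gk;
  double mass[2];

  double U(const double* x) const {
    double xx = x[0];
    double q = xx * xx - 1.0;
    double u = a * q * q + b * xx;
    if (epsL != 0.0) u += epsL * 0.5 * (1.0 + std::tanh(gk * xx));
    if (dim > 1) {
      double y0 = ymid + yamp * std::tanh(2.0 * xx);
      double d = x[1] - y0;
      u += 0.5 * ky * d * d;
    }
    return u;
  }

  void grad(const double* x, double* g) const {
    double xx = x[0];
    g[0] = 4.0 * a * xx * (xx * xx - 1.0) + b;
    if (epsL != 0.0) {
      double th = std::tanh(gk * xx);
      g[0] += epsL * 0.5 * gk * (1.0 - th * th);
    }
    if (dim > 1) {
      double t2 = std::tanh(2.0 * xx);
      double y0 = ymid + yamp * t2;
      double d = x[1] - y0;
      g[0] += -ky * d * yamp * 2.0 * (1.0 - t2 * t2);
      g[1] = ky * d;
    }
  }
};

static Model model_from_list(List m) {
  Model mod;
  mod.dim  = as<int>(m["dim"]);
  mod.a    = as<double>(m["a"]);
  mod.b    = as<double>(m["b"]);
  mod.ky   = mod.dim > 1 ? as<double>(m["ky"])   : 0.0;
  mod.ymid = mod.dim > 1 ? as<double>(m["ymid"]) : 0.0;
  mod.yamp = mod.dim > 1 ? as<double>(m["yamp"]) : 0.0;
  mod.epsL = as<double>(m["epsL"]);
  mod.gk   = as<double>(m["gk"]);
  NumericVector ms = m["mass"];
  mod.mass[0] = ms[0];
  mod.mass[1] = ms.size() > 1 ? ms[1] : 1.0;
  return mod;
}

// [[Rcpp::export]]
NumericVector cpp_model_energy(List model, NumericMatrix x) {
  Model mod = model_from_list(model);
  int n = x.nrow();
  NumericVector out(n);
  double p[2] = {0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    p[0] = x(i, 0);
    if (mod.dim > 1) p[1] = x(i, 1);
    out[i] = mod.U(p);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_model_gradient(List model, NumericMatrix x) {
  Model mod = model_from_list(model);
  int n = x.nrow();
  NumericMatrix out(n, mod.dim);
  double p[2] = {0.0, 0.0}, g[2] = {0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    p[0] = x(i, 0);
    if (mod.dim > 1) p[1] = x(i, 1);
    mod.grad(p, g);
    for (int d = 0; d < mod.dim; ++d) out(i, d) = g[d];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Collective variables on the toy model.
//   type 0 "hlda"    : s = p1 + p2 * tanh(2 x0)
//   type 1 "coord"   : s = x[j]           (j = p1, 0-based)
//   type 2 "torsion" : s = sin(p2 * x[j] + p3), j = p1 (bounded periodic proxy)
// ---------------------------------------------------------------------------

struct CvSpec {
  int type;
  double p1, p2, p3;

  double value(const double* x) const {
    switch (type) {
      case 0: return p1 + p2 * std::tanh(2.0 * x[0]);
      case 1: return x[(int)p1];
      case 2: return std::sin(p2 * x[(int)p1] + p3);
    }
    return 0.0;
  }
  // ds/dx into g (accumulated later with chain rule)
  void grad(const double* x, double* g, int dim) const {
    for (int d = 0; d < dim; ++d) g[d] = 0.0;
    switch (type) {
      case 0: {
        double t = std::tanh(2.0 * x[0]);
        g[0] = p2 * 2.0 * (1.0 - t * t);
        break;
      }
      case 1: g[(int)p1] = 1.0; break;
      case 2: g[(int)p1] = p2 * std::cos(p2 * x[(int)p1] + p3); break;
    }
  }
};

static CvSpec cv_from_vec(NumericVector v) {
  CvSpec cv;
  cv.type = (int)v[0];
  cv.p1 = v.size() > 1 ? v[1] : 0.0;
  cv.p2 = v.size() > 2 ? v[2] : 0.0;
  cv.p3 = v.size() > 3 ? v[3] : 0.0;
  return cv;
}

// [[Rcpp::export]]
NumericVector cpp_cv_value(NumericVector cv, NumericMatrix x) {
  CvSpec spec = cv_from_vec(cv);
  int n = x.nrow();
  NumericVector out(n);
  double p[2] = {0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    p[0] = x(i, 0);
    if (x.ncol() > 1) p[1] = x(i, 1);
    out[i] = spec.value(p);
  }
  return out;
}

// ---------------------------------------------------------------------------
// OPES-Explore layer. Kernel density of the *sampled* distribution with
// unit-weight Gaussian kernels; bias
//   V(s) = (gamma - 1) kT log( (1 - eps) p(s)/Z + eps ),  Z = sup_s p(s),
// which pins sup V = 0 and inf V = -DeltaE exactly (hard barrier cap).
// Evaluation between depositions uses a cached uniform grid with linear
// interpolation of V and dV/ds.
// ---------------------------------------------------------------------------

struct OpesLayer {
  CvSpec cv;
  double barrier, gamma, kT, eps;
  int pace;
  double merge_thr;
  double sigma0;          // <= 0 means adaptive: estimated before 1st deposit
  bool adaptive_sigma;
  // Welford accumulators for adaptive sigma0
  double w_n = 0.0, w_mean = 0.0, w_m2 = 0.0;
  // kernels
  std::vector<double> kc, ks, kh;
  double n_dep = 0.0;
  // grid cache (unnormalized kernel sum)
  int gn;
  double gmin, gmax, gdx;
  std::vector<double> pgrid, Vg, dVg;
  int rebuilds_since_full = 0;

  void init(double barrier_, double gamma_, double kT_, int pace_,
            double sigma0_, double merge_thr_, double gmin_, double gmax_, int gn_) {
    barrier = barrier_; kT = kT_; pace = pace_;
    gamma = gamma_ > 0 ? gamma_ : barrier_ / kT_;  // default beta * DeltaE
    if (gamma <= 1.0) gamma = 1.0 + 1e-8;
    eps = std::exp(-barrier / ((gamma - 1.0) * kT));
    sigma0 = sigma0_;
    adaptive_sigma = !(sigma0_ > 0.0);
    merge_thr = merge_thr_;
    gmin = gmin_; gmax = gmax_; gn = gn_;
    gdx = (gmax - gmin) / (gn - 1);
    pgrid.assign(gn, 0.0);
    Vg.assign(gn, 0.0);
    dVg.assign(gn, 0.0);
  }

  void welford(double s) {
    w_n += 1.0;
    double d = s - w_mean;
    w_mean += d / w_n;
    w_m2 += d * (s - w_mean);
  }

  void add_gauss(double c, double sig, double h, double sign) {
    double inv = 1.0 / sig;
    double norm = h * 0.3989422804014327 * inv; // 1/sqrt(2 pi)
    // only touch grid points within 8 sigma
    int i0 = (int)std::floor((c - 8.0 * sig - gmin) / gdx);
    int i1 = (int)std::ceil((c + 8.0 * sig - gmin) / gdx);
    if (i0 < 0) i0 = 0;
    if (i1 > gn - 1) i1 = gn - 1;
    for (int i = i0; i <= i1; ++i) {
      double z = (gmin + i * gdx - c) * inv;
      pgrid[i] += sign * norm * std::exp(-0.5 * z * z);
    }
  }

  void full_rebuild_p() {
    std::fill(pgrid.begin(), pgrid.end(), 0.0);
    for (size_t k = 0; k < kc.size(); ++k) add_gauss(kc[k], ks[k], kh[k], 1.0);
  }

  void refresh_V() {
    double Z = 0.0;
    for (int i = 0; i < gn; ++i) if (pgrid[i] > Z) Z = pgrid[i];
    double pref = (gamma - 1.0) * kT;
    if (Z <= 0.0) {
      std::fill(Vg.begin(), Vg.end(), 0.0);
      std::fill(dVg.begin(), dVg.end(), 0.0);
      return;
    }
    for (int i = 0; i < gn; ++i) {
      double p = pgrid[i] / Z;
      if (p < 0.0) p = 0.0;
      double v = pref * std::log((1.0 - eps) * p + eps);
      // analytic floor -DeltaE (guards eps underflow at gamma -> 1)
      Vg[i] = std::max(v, -barrier);
    }
    for (int i = 0; i < gn; ++i) {
      int il = i > 0 ? i - 1 : i;
      int ir = i < gn - 1 ? i + 1 : i;
      dVg[i] = (Vg[ir] - Vg[il]) / ((ir - il) * gdx);
    }
  }

  void deposit(double s) {
    if (adaptive_sigma) {
      double sd = w_n > 1.5 ? std::sqrt(w_m2 / (w_n - 1.0)) : 0.0;
      sigma0 = sd > 1e-12 ? sd : (gmax - gmin) / 200.0;
      adaptive_sigma = false;
    }
    n_dep += 1.0;
    double sig = sigma0 * std::pow(n_dep, -0.2); // 1D adaptive shrinkage
    // merge with nearest kernel if closer than merge_thr * its bandwidth
    int best = -1;
    double bestd = 1e300;
    for (size_t k = 0; k < kc.size(); ++k) {
      double d = std::fabs(s - kc[k]);
      if (d < bestd) { bestd = d; best = (int)k; }
    }
    if (best >= 0 && bestd < merge_thr * ks[best]) {
      double h1 = kh[best], c1 = kc[best], s1 = ks[best];
      double h = h1 + 1.0;
      double c = (h1 * c1 + s) / h;
      double m2 = (h1 * (s1 * s1 + c1 * c1) + (sig * sig + s * s)) / h - c * c;
      add_gauss(c1, s1, h1, -1.0);
      kc[best] = c; ks[best] = std::sqrt(std::max(m2, 1e-24)); kh[best] = h;
      add_gauss(kc[best], ks[best], kh[best], 1.0);
    } else {
      kc.push_back(s); ks.push_back(sig); kh.push_back(1.0);
      add_gauss(s, sig, 1.0, 1.0);
    }
    if (++rebuilds_since_full >= 500) { full_rebuild_p(); rebuilds_since_full = 0; }
    refresh_V();
  }

  double bias(double s, double* dVds) const {
    if (n_dep < 0.5) { if (dVds) *dVds = 0.0; return 0.0; }
    double t = (s - gmin) / gdx;
    if (t <= 0.0) { if (dVds) *dVds = 0.0; return Vg[0]; }
    if (t >= gn - 1) { if (dVds) *dVds = 0.0; return Vg[gn - 1]; }
    int i = (int)t;
    double f = t - i;
    if (dVds) *dVds = dVg[i] * (1.0 - f) + dVg[i + 1] * f;
    return Vg[i] * (1.0 - f) + Vg[i + 1] * f;
  }
};

// Exact (kernel-sum) OPES bias evaluation for tests and reweighting.
// Z is the supremum of the kernel density over a dense scan grid plus the
// kernel centers themselves.
// [[Rcpp::export]]
List cpp_opes_eval(NumericMatrix kernels, NumericVector s,
                   double barrier, double gamma, double kT,
                   double grid_min, double grid_max, int grid_n) {
  int nk = kernels.nrow();
  double eps = std::exp(-barrier / ((gamma - 1.0) * kT));
  double pref = (gamma - 1.0) * kT;
  int n = s.size();
  NumericVector V(n), dV(n);
  if (nk == 0) {
    return List::create(_["V"] = V, _["dV"] = dV, _["Z"] = 0.0, _["eps"] = eps);
  }
  auto pdens = [&](double x, double* dp) {
    double p = 0.0, d = 0.0;
    for (int k = 0; k < nk; ++k) {
      double c = kernels(k, 0), sig = kernels(k, 1), h = kernels(k, 2);
      double z = (x - c) / sig;
      double g = h * 0.3989422804014327 / sig * std::exp(-0.5 * z * z);
      p += g;
      d += -g * z / sig;
    }
    if (dp) *dp = d;
    return p;
  };
  double Z = 0.0, zbest = grid_min;
  double dx = (grid_max - grid_min) / (grid_n - 1);
  for (int i = 0; i < grid_n; ++i) {
    double x = grid_min + i * dx;
    double p = pdens(x, nullptr);
    if (p > Z) { Z = p; zbest = x; }
  }
  for (int k = 0; k < nk; ++k) {
    double p = pdens(kernels(k, 0), nullptr);
    if (p > Z) { Z = p; zbest = kernels(k, 0); }
  }
  // golden-section refinement of the supremum around the best scan point
  {
    double a = zbest - dx, b = zbest + dx;
    const double gr = 0.6180339887498949;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double fc = pdens(c, nullptr), fd = pdens(d, nullptr);
    for (int it = 0; it < 80 && (b - a) > 1e-13 * (1.0 + std::fabs(zbest)); ++it) {
      if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = pdens(c, nullptr); }
      else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = pdens(d, nullptr); }
    }
    double p = std::max(fc, fd);
    if (p > Z) Z = p;
  }
  for (int i = 0; i < n; ++i) {
    double p = pdens(s[i], nullptr);
    if (p > Z) Z = p;  // sup over the evaluation points too
  }
  for (int i = 0; i < n; ++i) {
    double dp;
    double p = pdens(s[i], &dp) / Z;
    dp /= Z;
    double arg = (1.0 - eps) * p + eps;
    double v = pref * std::log(arg);
    V[i] = std::max(v, -barrier);
    dV[i] = v > -barrier ? pref * (1.0 - eps) * dp / arg : 0.0;
  }
  return List::create(_["V"] = V, _["dV"] = dV, _["Z"] = Z, _["eps"] = eps);
}

// Deposit one kernel (with merging) into a kernel table; returns new table.
// [[Rcpp::export]]
NumericMatrix cpp_opes_deposit(NumericMatrix kernels, double s, double sigma,
                               double merge_thr) {
  int nk = kernels.nrow();
  int best = -1;
  double bestd = 1e300;
  for (int k = 0; k < nk; ++k) {
    double d = std::fabs(s - kernels(k, 0));
    if (d < bestd) { bestd = d; best = k; }
  }
  if (best >= 0 && bestd < merge_thr * kernels(best, 1)) {
    NumericMatrix out = clone(kernels);
    double h1 = out(best, 2), c1 = out(best, 0), s1 = out(best, 1);
    double h = h1 + 1.0;
    double c = (h1 * c1 + s) / h;
    double m2 = (h1 * (s1 * s1 + c1 * c1) + (sigma * sigma + s * s)) / h - c * c;
    out(best, 0) = c;
    out(best, 1) = std::sqrt(std::max(m2, 1e-24));
    out(best, 2) = h;
    return out;
  }
  NumericMatrix out(nk + 1, 3);
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < 3; ++j) out(k, j) = kernels(k, j);
  out(nk, 0) = s; out(nk, 1) = sigma; out(nk, 2) = 1.0;
  return out;
}

// ---------------------------------------------------------------------------
// Multithermal expanded ensemble over an inverse-temperature grid.
//   V(U) = -(1/beta0) log[ (1/J) sum_j exp(-(beta_j - beta0) U + beta0 lambda_j) ]
// ---------------------------------------------------------------------------

struct MultiT {
  std::vector<double> betas, lambdas;
  double beta0;
  int stride;
  // streaming logsumexp accumulators: A_j = lse_t( beta0 B_t - (beta_j-beta0) U_t )
  std::vector<double> Amax, Asum;
  double A0max = -1e300, A0sum = 0.0;
  std::vector<double> visit;

  void init(NumericVector b, double beta0_, int stride_) {
    betas.assign(b.begin(), b.end());
    beta0 = beta0_;
    stride = stride_;
    lambdas.assign(betas.size(), 0.0);
    Amax.assign(betas.size(), -1e300);
    Asum.assign(betas.size(), 0.0);
    visit.assign(betas.size(), 0.0);
  }

  double bias(double U, double* dVdU) const {
    int J = (int)betas.size();
    double amax = -1e300;
    std::vector<double> a(J);
    for (int j = 0; j < J; ++j) {
      a[j] = -(betas[j] - beta0) * U + beta0 * lambdas[j];
      if (a[j] > amax) amax = a[j];
    }
    double S = 0.0, Sd = 0.0;
    for (int j = 0; j < J; ++j) {
      double e = std::exp(a[j] - amax);
      S += e;
      Sd += e * (betas[j] - beta0);
    }
    if (dVdU) *dVdU = Sd / (S * beta0);
    return -(amax + std::log(S / J)) / beta0;
  }

  void accumulate(double U, double Btot) {
    int J = (int)betas.size();
    double a0 = beta0 * Btot;
    if (a0 > A0max) { A0sum = A0sum * std::exp(A0max - a0) + 1.0; A0max = a0; }
    else A0sum += std::exp(a0 - A0max);
    double amax = -1e300;
    std::vector<double> a(J);
    double S = 0.0;
    for (int j = 0; j < J; ++j) {
      a[j] = a0 - (betas[j] - beta0) * U;
      if (Asum[j] == 0.0 || a[j] > Amax[j]) {
        Asum[j] = Asum[j] * std::exp(Amax[j] - a[j]) + 1.0;
        Amax[j] = a[j];
      } else Asum[j] += std::exp(a[j] - Amax[j]);
      double av = -(betas[j] - beta0) * U + beta0 * lambdas[j];
      if (av > amax) amax = av;
    }
    // visitation weights under current shifts
    std::vector<double> w(J);
    for (int j = 0; j < J; ++j) {
      w[j] = std::exp(-(betas[j] - beta0) * U + beta0 * lambdas[j] - amax);
      S += w[j];
    }
    for (int j = 0; j < J; ++j) visit[j] += w[j] / S;
  }

  void update_lambdas() {
    if (A0sum <= 0.0) return;
    double A0 = A0max + std::log(A0sum);
    for (size_t j = 0; j < betas.size(); ++j) {
      if (Asum[j] <= 0.0) continue;
      double Aj = Amax[j] + std::log(Asum[j]);
      lambdas[j] = -(Aj - A0) / beta0;
    }
  }
};

// [[Rcpp::export]]
List cpp_mt_bias(NumericVector U, NumericVector betas, NumericVector lambdas,
                 double beta0) {
  MultiT mt;
  mt.betas.assign(betas.begin(), betas.end());
  mt.lambdas.assign(lambdas.begin(), lambdas.end());
  mt.beta0 = beta0;
  int n = U.size();
  NumericVector V(n), dV(n);
  for (int i = 0; i < n; ++i) {
    double d;
    V[i] = mt.bias(U[i], &d);
    dV[i] = d;
  }
  return List::create(_["V"] = V, _["dVdU"] = dV);
}

// ---------------------------------------------------------------------------
// Replica ladder driver: synchronous BAOAB stepping of n replicas with
// per-replica OPES layers + optional multithermal layer, even/odd alternating
// neighbor exchanges. Fully deterministic per seed.
// ---------------------------------------------------------------------------

struct Replica {
  double x[2], v[2], f[2];
  double U, Btot;
  std::vector<OpesLayer> layers;
  bool has_mt = false;
  MultiT mt;
  double wall_lo = -1e300, wall_hi = 1e300; // reflecting wall on x[0]
};

static void compute_forces(Replica& r, const Model& mod) {
  double g[2] = {0.0, 0.0};
  mod.grad(r.x, g);
  r.U = mod.U(r.x);
  double scale = 1.0;
  double B = 0.0;
  if (r.has_mt) {
    double dVdU;
    B += r.mt.bias(r.U, &dVdU);
    scale += dVdU;
  }
  for (int d = 0; d < mod.dim; ++d) r.f[d] = -scale * g[d];
  double cg[2];
  for (auto& L : r.layers) {
    double s = L.cv.value(r.x);
    double dVds;
    B += L.bias(s, &dVds);
    L.cv.grad(r.x, cg, mod.dim);
    for (int d = 0; d < mod.dim; ++d) r.f[d] -= dVds * cg[d];
  }
  r.Btot = B;
}

// total bias of replica r's current state evaluated at arbitrary position
static double bias_at(const Replica& r, const Model& mod, const double* x) {
  double B = 0.0;
  if (r.has_mt) B += r.mt.bias(mod.U(x), nullptr);
  for (const auto& L : r.layers) B += L.bias(L.cv.value(x), nullptr);
  return B;
}

// [[Rcpp::export]]
List cpp_run_ladder(List model, List replicas, double n_steps_d, double dt,
                    double friction, double temp, double seed,
                    int exchange_stride, int colvar_stride, NumericMatrix x0) {
  Model mod = model_from_list(model);
  int R = replicas.size();
  long long n_steps = (long long)n_steps_d;
  double kT = KB * temp;
  double beta0 = 1.0 / kT;

  std::vector<Replica> reps((size_t)R);
  int max_layers = 0;
  for (int r = 0; r < R; ++r) {
    List rc = replicas[r];
    Replica& rr = reps[r];
    List lls = rc["layers"];
    for (int l = 0; l < lls.size(); ++l) {
      List lc = lls[l];
      OpesLayer L;
      L.cv = cv_from_vec(lc["cv"]);
      NumericVector grid = lc["grid"];
      double sigma0 = lc.containsElementNamed("sigma0") ? as<double>(lc["sigma0"]) : -1.0;
      if (!R_finite(sigma0)) sigma0 = -1.0;
      double gamma = lc.containsElementNamed("gamma") ? as<double>(lc["gamma"]) : -1.0;
      if (!R_finite(gamma)) gamma = -1.0;
      L.init(as<double>(lc["barrier"]), gamma, kT, as<int>(lc["pace"]), sigma0,
             as<double>(lc["merge_threshold"]), grid[0], grid[1], (int)grid[2]);
      rr.layers.push_back(L);
    }
    if ((int)rr.layers.size() > max_layers) max_layers = (int)rr.layers.size();
    if (rc.containsElementNamed("mt") && !Rf_isNull(rc["mt"])) {
      List mc = rc["mt"];
      NumericVector temps = mc["temperatures"];
      NumericVector betas(temps.size());
      for (int j = 0; j < temps.size(); ++j) betas[j] = 1.0 / (KB * temps[j]);
      rr.has_mt = true;
      rr.mt.init(betas, beta0, as<int>(mc["stride"]));
    }
    if (rc.containsElementNamed("wall") && !Rf_isNull(rc["wall"])) {
      NumericVector w = rc["wall"];
      rr.wall_lo = w[0];
      rr.wall_hi = w[1];
    }
    for (int d = 0; d < mod.dim; ++d) rr.x[d] = x0(r, d);
    // Maxwell-Boltzmann velocities, stream 1
    uint64_t kv = rng_key((uint64_t)seed, (uint64_t)r, 1ULL);
    for (int d = 0; d < mod.dim; ++d)
      rr.v[d] = std::sqrt(kT / mod.mass[d]) * rng_normal(kv, (uint64_t)d);
    compute_forces(rr, mod);
  }

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  long long n_rec = n_steps / colvar_stride + 1;
  int ncol = 1 + mod.dim + max_layers + 2; // time, coords, cvs, U, bias
  std::vector<NumericMatrix> colvar;
  for (int r = 0; r < R; ++r) colvar.emplace_back((int)n_rec, ncol);
  std::vector<long long> irec((size_t)R, 0);

  auto record = [&](long long step) {
    for (int r = 0; r < R; ++r) {
      Replica& rr = reps[r];
      long long i = irec[r]++;
      if (i >= n_rec) continue;
      NumericMatrix& cm = colvar[r];
      int c = 0;
      cm(i, c++) = step * dt;
      for (int d = 0; d < mod.dim; ++d) cm(i, c++) = rr.x[d];
      for (int l = 0; l < max_layers; ++l)
        cm(i, c++) = l < (int)rr.layers.size() ? rr.layers[l].cv.value(rr.x) : NA_REAL;
      cm(i, c++) = rr.U;
      cm(i, c++) = rr.Btot;
    }
  };
  record(0);

  std::vector<long long> n_exch_rows;
  std::vector<double> ex_step, ex_i, ex_j, ex_delta, ex_acc;
  uint64_t kx = rng_key((uint64_t)seed, 1000003ULL, 2ULL);
  uint64_t ex_ctr = 0;

  std::vector<uint64_t> noise_keys((size_t)R);
  for (int r = 0; r < R; ++r) noise_keys[r] = rng_key((uint64_t)seed, (uint64_t)r, 0ULL);

  for (long long step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < R; ++r) {
      Replica& rr = reps[r];
      // BAOAB
      for (int d = 0; d < mod.dim; ++d) {
        rr.v[d] += 0.5 * dt * rr.f[d] / mod.mass[d];
        rr.x[d] += 0.5 * dt * rr.v[d];
      }
      if (temp > 0.0 && friction > 0.0) {
        uint64_t base = (uint64_t)(step - 1) * (uint64_t)mod.dim;
        for (int d = 0; d < mod.dim; ++d) {
          double xi = rng_normal(noise_keys[r], base + (uint64_t)d);
          rr.v[d] = c1 * rr.v[d] + c2 * std::sqrt(kT / mod.mass[d]) * xi;
        }
      } else if (friction > 0.0) {
        for (int d = 0; d < mod.dim; ++d) rr.v[d] = c1 * rr.v[d];
      }
      for (int d = 0; d < mod.dim; ++d) rr.x[d] += 0.5 * dt * rr.v[d];
      // reflecting wall on the flip coordinate
      if (rr.x[0] < rr.wall_lo) { rr.x[0] = 2.0 * rr.wall_lo - rr.x[0]; rr.v[0] = -rr.v[0]; }
      if (rr.x[0] > rr.wall_hi) { rr.x[0] = 2.0 * rr.wall_hi - rr.x[0]; rr.v[0] = -rr.v[0]; }
      compute_forces(rr, mod);
      if (!R_finite(rr.f[0]) || !R_finite(rr.x[0]))
        stop("non-finite force or coordinate at step %lld (replica %d)", step, r);
      for (int d = 0; d < mod.dim; ++d) rr.v[d] += 0.5 * dt * rr.f[d] / mod.mass[d];

      // OPES depositions
      for (auto& L : rr.layers) {
        double s = L.cv.value(rr.x);
        if (L.adaptive_sigma) L.welford(s);
        if (step % L.pace == 0) { L.deposit(s); }
      }
      // multithermal accumulation + shift updates
      if (rr.has_mt) {
        rr.mt.accumulate(rr.U, rr.Btot);
        if (step % rr.mt.stride == 0) {
          rr.mt.update_lambdas();
          compute_forces(rr, mod);
        }
      }
    }

    // neighbor exchanges, even/odd alternation
    if (exchange_stride > 0 && step % exchange_stride == 0 && R > 1) {
      int parity = (int)((step / exchange_stride) % 2);
      for (int i = parity; i + 1 < R; i += 2) {
        Replica& a = reps[i];
        Replica& b = reps[i + 1];
        double Bii = bias_at(a, mod, a.x), Bjj = bias_at(b, mod, b.x);
        double Bij = bias_at(a, mod, b.x), Bji = bias_at(b, mod, a.x);
        double delta = beta0 * ((Bij + Bji) - (Bii + Bjj));
        double u = rng_u01(kx, ex_ctr++);
        bool acc = delta <= 0.0 || u < std::exp(-delta);
        if (acc) {
          for (int d = 0; d < mod.dim; ++d) {
            std::swap(a.x[d], b.x[d]);
            std::swap(a.v[d], b.v[d]);
          }
          compute_forces(a, mod);
          compute_forces(b, mod);
        }
        ex_step.push_back((double)step);
        ex_i.push_back((double)i);
        ex_j.push_back((double)(i + 1));
        ex_delta.push_back(delta);
        ex_acc.push_back(acc ? 1.0 : 0.0);
      }
    }

    if (step % colvar_stride == 0) record(step);
  }

  // final-bias recomputation at every recorded frame (static-final-bias
  // estimator input for reweighting)
  List out_reps(R);
  for (int r = 0; r < R; ++r) {
    Replica& rr = reps[r];
    long long nr = irec[r];
    NumericMatrix& cm = colvar[r];
    NumericVector bias_final((int)nr);
    for (long long i = 0; i < nr; ++i) {
      double B = 0.0;
      for (int l = 0; l < (int)rr.layers.size(); ++l) {
        double s = cm(i, 1 + mod.dim + l);
        B += rr.layers[l].bias(s, nullptr);
      }
      if (rr.has_mt) B += rr.mt.bias(cm(i, 1 + mod.dim + max_layers), nullptr);
      bias_final[(int)i] = B;
    }
    List kl(rr.layers.size());
    NumericVector sig0s(rr.layers.size());
    for (size_t l = 0; l < rr.layers.size(); ++l) {
      OpesLayer& L = rr.layers[l];
      NumericMatrix km((int)L.kc.size(), 3);
      for (size_t k = 0; k < L.kc.size(); ++k) {
        km((int)k, 0) = L.kc[k];
        km((int)k, 1) = L.ks[k];
        km((int)k, 2) = L.kh[k];
      }
      kl[l] = km;
      sig0s[l] = L.sigma0;
    }
    List mtout = R_NilValue;
    if (rr.has_mt) {
      mtout = List::create(
        _["lambdas"] = NumericVector(rr.mt.lambdas.begin(), rr.mt.lambdas.end()),
        _["betas"] = NumericVector(rr.mt.betas.begin(), rr.mt.betas.end()),
        _["visitation"] = NumericVector(rr.mt.visit.begin(), rr.mt.visit.end()));
    }
    out_reps[r] = List::create(
      _["colvar"] = cm, _["n_rows"] = (double)nr, _["bias_final"] = bias_final,
      _["kernels"] = kl, _["sigma0"] = sig0s, _["mt"] = mtout,
      _["n_layers"] = (double)rr.layers.size());
  }

  int ne = (int)ex_step.size();
  NumericMatrix exlog(ne, 5);
  for (int i = 0; i < ne; ++i) {
    exlog(i, 0) = ex_step[i];
    exlog(i, 1) = ex_i[i];
    exlog(i, 2) = ex_j[i];
    exlog(i, 3) = ex_delta[i];
    exlog(i, 4) = ex_acc[i];
  }
  return List::create(_["replicas"] = out_reps, _["exchange_log"] = exlog,
                      _["max_layers"] = (double)max_layers, _["dim"] = (double)mod.dim);
}
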