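// Monte Carlo kernels: quadric CSG geometry, analog photon transport with
// track-length kerma scoring, condensed-history proton transport, and
// counter-based per-history RNG substreams (results independent of batching).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeded per history from (seed, history index)
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  double normal() {
    double u1 = unif_pos(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

static RNG history_rng(uint64_t seed, uint64_t hist) {
  uint64_t s = seed * 0x9E3779B97F4A7C15ULL + (hist + 1) * 0xD1B54A32D192ED03ULL;
  RNG r(s);
  r.next(); r.next();
  return r;
}

// ---------------------------------------------------------------------------
// Geometry
struct Prim {
  int kind;        // 1 ellipsoid, 2 elliptical cylinder (z axis), 3 box
  double p[8];
  bool inside(const double* x) const {
    switch (kind) {
      case 1: {
        double dx = (x[0] - p[0]) / p[3], dy = (x[1] - p[1]) / p[4],
               dz = (x[2] - p[2]) / p[5];
        return dx * dx + dy * dy + dz * dz <= 1.0;
      }
      case 2: {
        if (x[2] < p[4] || x[2] > p[5]) return false;
        double dx = (x[0] - p[0]) / p[2], dy = (x[1] - p[1]) / p[3];
        return dx * dx + dy * dy <= 1.0;
      }
      default: {
        return x[0] >= p[0] && x[0] <= p[3] && x[1] >= p[1] && x[1] <= p[4] &&
               x[2] >= p[2] && x[2] <= p[5];
      }
    }
  }
  // smallest crossing distance > tmin along the ray, or INFINITY
  double first_crossing(const double* o, const double* d, double tmin) const {
    double best = INFINITY;
    auto consider = [&](double t) { if (t > tmin && t < best) best = t; };
    if (kind == 1) {
      double A = 0, B = 0, C = -1;
      for (int i = 0; i < 3; ++i) {
        double di = d[i] / p[3 + i], oi = (o[i] - p[i]) / p[3 + i];
        A += di * di; B += 2 * oi * di; C += oi * oi;
      }
      double disc = B * B - 4 * A * C;
      if (disc >= 0 && A > 0) {
        double sq = std::sqrt(disc);
        consider((-B - sq) / (2 * A));
        consider((-B + sq) / (2 * A));
      }
    } else if (kind == 2) {
      double A = 0, B = 0, C = -1;
      for (int i = 0; i < 2; ++i) {
        double di = d[i] / p[2 + i], oi = (o[i] - p[i]) / p[2 + i];
        A += di * di; B += 2 * oi * di; C += oi * oi;
      }
      double disc = B * B - 4 * A * C;
      if (disc >= 0 && A > 0) {
        double sq = std::sqrt(disc);
        for (double t : { (-B - sq) / (2 * A), (-B + sq) / (2 * A) }) {
          double z = o[2] + t * d[2];
          if (z >= p[4] && z <= p[5]) consider(t);
        }
      }
      if (d[2] != 0) {
        for (double zp : { p[4], p[5] }) {
          double t = (zp - o[2]) / d[2];
          double dx = (o[0] + t * d[0] - p[0]) / p[2];
          double dy = (o[1] + t * d[1] - p[1]) / p[3];
          if (dx * dx + dy * dy <= 1.0) consider(t);
        }
      }
    } else {
      for (int i = 0; i < 3; ++i) {
        if (d[i] == 0) continue;
        for (double b : { p[i], p[3 + i] }) {
          double t = (b - o[i]) / d[i];
          bool ok = true;
          for (int j = 0; j < 3; ++j) {
            if (j == i) continue;
            double xj = o[j] + t * d[j];
            if (xj < p[j] - 1e-12 || xj > p[3 + j] + 1e-12) { ok = false; break; }
          }
          if (ok) consider(t);
        }
      }
    }
    return best;
  }
};

struct Geometry {
  std::vector<Prim> prims;
  // region -> terms -> signed 1-based prim refs (+inside / -outside)
  std::vector<std::vector<std::vector<int>>> regions;
  double lo[3], hi[3];
  int n_regions() const { return (int)regions.size(); }

  int locate(const double* x) const {
    for (size_t r = 0; r < regions.size(); ++r) {
      if (regions[r].empty()) return (int)r;  // exterior sentinel
      for (const auto& term : regions[r]) {
        bool ok = true;
        for (int ref : term) {
          bool in = prims[std::abs(ref) - 1].inside(x);
          if ((ref > 0) != in) { ok = false; break; }
        }
        if (ok) return (int)r;
      }
    }
    return (int)regions.size() - 1;
  }

  double next_surface(const double* o, const double* d) const {
    double best = INFINITY;
    for (const auto& pr : prims) {
      double t = pr.first_crossing(o, d, 1e-9);
      if (t < best) best = t;
    }
    for (int i = 0; i < 3; ++i) {
      if (d[i] == 0) continue;
      for (double b : { lo[i], hi[i] }) {
        double t = (b - o[i]) / d[i];
        if (t > 1e-9 && t < best) best = t;
      }
    }
    return best;
  }

  bool in_bbox(const double* x) const {
    for (int i = 0; i < 3; ++i)
      if (x[i] < lo[i] || x[i] > hi[i]) return false;
    return true;
  }
  // distance along d to enter the bbox, or -1 if the ray misses it
  double bbox_entry(const double* o, const double* d) const {
    double t0 = 0, t1 = INFINITY;
    for (int i = 0; i < 3; ++i) {
      if (d[i] == 0) {
        if (o[i] < lo[i] || o[i] > hi[i]) return -1;
      } else {
        double ta = (lo[i] - o[i]) / d[i], tb = (hi[i] - o[i]) / d[i];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
    }
    return (t0 <= t1) ? t0 : -1;
  }
};

static Geometry parse_geometry(const List& g) {
  Geometry geo;
  NumericMatrix pm = g["prims"];
  for (int i = 0; i < pm.nrow(); ++i) {
    Prim p;
    p.kind = (int)pm(i, 0);
    for (int j = 0; j < 7 && j + 1 < pm.ncol(); ++j) p.p[j] = pm(i, j + 1);
    geo.prims.push_back(p);
  }
  List regs = g["regions"];
  for (int r = 0; r < regs.size(); ++r) {
    List terms = regs[r];
    std::vector<std::vector<int>> rv;
    for (int t = 0; t < terms.size(); ++t) {
      IntegerVector iv = terms[t];
      rv.emplace_back(iv.begin(), iv.end());
    }
    geo.regions.push_back(rv);
  }
  NumericVector lo = g["bbox_lo"], hi = g["bbox_hi"];
  for (int i = 0; i < 3; ++i) { geo.lo[i] = lo[i]; geo.hi[i] = hi[i]; }
  return geo;
}

// [[Rcpp::export]]
int cpp_locate(List geom, NumericVector point) {
  Geometry g = parse_geometry(geom);
  double x[3] = { point[0], point[1], point[2] };
  return g.locate(x);
}

// [[Rcpp::export]]
List cpp_next_crossing(List geom, NumericVector point, NumericVector dir) {
  Geometry g = parse_geometry(geom);
  double o[3] = { point[0], point[1], point[2] };
  double d[3] = { dir[0], dir[1], dir[2] };
  double t = g.next_surface(o, d);
  if (!std::isfinite(t)) {
    return List::create(_["distance"] = R_PosInf,
                        _["region"] = g.n_regions() - 1);
  }
  double x[3] = { o[0] + (t + 1e-6) * d[0], o[1] + (t + 1e-6) * d[1],
                  o[2] + (t + 1e-6) * d[2] };
  return List::create(_["distance"] = t, _["region"] = g.locate(x));
}

// [[Rcpp::export]]
NumericVector cpp_region_fractions(List geom, int n, int seed) {
  Geometry g = parse_geometry(geom);
  NumericVector counts(g.n_regions());
  RNG rng = history_rng((uint64_t)seed, 0);
  double x[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k)
      x[k] = g.lo[k] + rng.unif() * (g.hi[k] - g.lo[k]);
    counts[g.locate(x)] += 1;
  }
  return counts;
}

// [[Rcpp::export]]
IntegerVector cpp_voxelize(List geom, NumericVector xs, NumericVector ys,
                           NumericVector zs) {
  Geometry g = parse_geometry(geom);
  IntegerVector out(xs.size() * ys.size() * zs.size());
  int idx = 0;
  for (int k = 0; k < zs.size(); ++k)
    for (int j = 0; j < ys.size(); ++j)
      for (int i = 0; i < xs.size(); ++i) {
        double x[3] = { xs[i], ys[j], zs[k] };
        out[i + xs.size() * (j + ys.size() * (size_t)k)] = g.locate(x) + 1;
        (void)idx;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Material tables (prepared on the R side)
struct MatTab {
  double rho, za, X0;
  std::vector<double> le, mu_c, mu_pe, mu_pair, mu_tr;  // photon, 1/cm
  std::vector<double> ple, S, R;                        // proton: MeV/cm, cm
};

static double interp_loglog(const std::vector<double>& lx,
                            const std::vector<double>& ly, double logx) {
  int n = (int)lx.size();
  if (logx <= lx[0]) return std::exp(ly[0]);
  if (logx >= lx[n - 1]) return std::exp(ly[n - 1]);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int m = (lo + hi) / 2; (lx[m] <= logx ? lo : hi) = m; }
  double w = (logx - lx[lo]) / (lx[lo + 1] - lx[lo]);
  return std::exp(ly[lo] + w * (ly[lo + 1] - ly[lo]));
}

static double interp_lin(const std::vector<double>& lx,
                         const std::vector<double>& y, double logx) {
  int n = (int)lx.size();
  if (logx <= lx[0]) return y[0];
  if (logx >= lx[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int m = (lo + hi) / 2; (lx[m] <= logx ? lo : hi) = m; }
  double w = (logx - lx[lo]) / (lx[lo + 1] - lx[lo]);
  return y[lo] + w * (y[lo + 1] - y[lo]);
}

struct Mats {
  std::vector<MatTab> tabs;            // one per material
  std::vector<int> region_mat;         // region -> material index
  // cached logs
  void prep() {
    for (auto& t : tabs) {
      for (auto v : { &t.mu_c, &t.mu_pe, &t.mu_tr, &t.S })
        for (auto& x : *v) x = std::log(std::max(x, 1e-300));
    }
  }
  double mu_compton(int m, double lE) const {
    return interp_loglog(tabs[m].le, tabs[m].mu_c, lE);
  }
  double mu_pe(int m, double lE) const {
    return interp_loglog(tabs[m].le, tabs[m].mu_pe, lE);
  }
  double mu_pair(int m, double E, double lE) const {
    if (E <= 1.02199790) return 0.0;
    return interp_lin(tabs[m].le, tabs[m].mu_pair, lE);
  }
  double mu_tr(int m, double lE) const {
    return interp_loglog(tabs[m].le, tabs[m].mu_tr, lE);
  }
  double S_at(int m, double lE) const {
    return interp_loglog(tabs[m].ple, tabs[m].S, lE);
  }
  double R_at(int m, double lE) const {
    return interp_lin(tabs[m].ple, tabs[m].R, lE);
  }
};

static Mats parse_mats(const List& ml) {
  Mats m;
  List tabs = ml["tabs"];
  for (int i = 0; i < tabs.size(); ++i) {
    List t = tabs[i];
    MatTab mt;
    mt.rho = as<double>(t["rho"]);
    mt.za = as<double>(t["za"]);
    mt.X0 = as<double>(t["X0"]);
    auto getv = [&](const char* nm) {
      NumericVector v = t[nm];
      return std::vector<double>(v.begin(), v.end());
    };
    mt.le = getv("logE"); mt.mu_c = getv("mu_c"); mt.mu_pe = getv("mu_pe");
    mt.mu_pair = getv("mu_pair"); mt.mu_tr = getv("mu_tr");
    mt.ple = getv("plogE"); mt.S = getv("S"); mt.R = getv("R");
    m.tabs.push_back(mt);
  }
  IntegerVector rm = ml["region_mat"];
  m.region_mat.assign(rm.begin(), rm.end());
  m.prep();
  return m;
}

// ---------------------------------------------------------------------------
// Klein-Nishina sampling (composition-rejection), exact in the KN
// differential cross section; returns eps = E'/E and cos(theta).
static const double MEC2 = 0.51099895;

static void sample_kn(double E, RNG& rng, double& eps, double& cost) {
  double k = E / MEC2;
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = std::log(1.0 / eps0), a2 = 0.5 * (1.0 - eps0 * eps0);
  double t, sin2;
  for (;;) {
    if (rng.unif() * (a1 + a2) < a1) {
      eps = std::exp(-a1 * rng.unif());
    } else {
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng.unif());
    }
    t = (1.0 - eps) / (k * eps);
    sin2 = t * (2.0 - t);
    double greject = 1.0 - eps * sin2 / (1.0 + eps * eps);
    if (rng.unif() <= greject) break;
  }
  cost = 1.0 - t;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_kn(double E, int n, int seed) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    RNG rng = history_rng((uint64_t)seed, (uint64_t)i);
    double eps, cost;
    sample_kn(E, rng, eps, cost);
    out(i, 0) = eps * E;
    out(i, 1) = cost;
  }
  return out;
}

// rotate unit vector u by polar angle (cost) about itself, azimuth uniform
static void rotate_direction(double* u, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double e1[3], e2[3];
  if (std::fabs(u[2]) < 0.99) {
    e1[0] = -u[1]; e1[1] = u[0]; e1[2] = 0;
  } else {
    e1[0] = 1; e1[1] = 0; e1[2] = 0;
  }
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  // orthogonalize e1 against u
  double dot = e1[0] * u[0] + e1[1] * u[1] + e1[2] * u[2];
  for (int i = 0; i < 3; ++i) e1[i] -= dot * u[i];
  n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  e2[0] = u[1] * e1[2] - u[2] * e1[1];
  e2[1] = u[2] * e1[0] - u[0] * e1[2];
  e2[2] = u[0] * e1[1] - u[1] * e1[0];
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    u[i] = cost * u[i] + sint * (cp * e1[i] + sp * e2[i]);
  double nn = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= nn;
}

// ---------------------------------------------------------------------------
// Beam sampling
struct Beam {
  int modality;  // 0 photon, 1 proton
  double src[3], aim[3], hx, hz;                     // photon
  std::vector<double> edges, cum;                    // photon spectrum
  double center[3], ax, az, E0, esigma;              // proton (elliptical aperture)
};

static Beam parse_beam(const List& b) {
  Beam bm;
  bm.modality = as<int>(b["modality"]);
  if (bm.modality == 0) {
    NumericVector s = b["src"], a = b["aim"];
    for (int i = 0; i < 3; ++i) { bm.src[i] = s[i]; bm.aim[i] = a[i]; }
    bm.hx = as<double>(b["hx"]); bm.hz = as<double>(b["hz"]);
    NumericVector e = b["edges"], p = b["probs"];
    bm.edges.assign(e.begin(), e.end());
    double c = 0;
    for (int i = 0; i < p.size(); ++i) { c += p[i]; bm.cum.push_back(c); }
    for (auto& x : bm.cum) x /= c;
  } else {
    NumericVector cc = b["center"];
    for (int i = 0; i < 3; ++i) bm.center[i] = cc[i];
    bm.ax = as<double>(b["ax"]);
    bm.az = as<double>(b["az"]);
    bm.E0 = as<double>(b["E0"]);
    bm.esigma = as<double>(b["esigma"]);
  }
  return bm;
}

struct Particle { double x[3], u[3], E, w; };

static Particle sample_primary(const Beam& b, RNG& rng) {
  Particle p;
  p.w = 1.0;
  if (b.modality == 0) {
    double u = rng.unif();
    size_t bin = std::lower_bound(b.cum.begin(), b.cum.end(), u) - b.cum.begin();
    if (bin >= b.cum.size()) bin = b.cum.size() - 1;
    double elo = b.edges[bin], ehi = b.edges[bin + 1];
    p.E = elo + rng.unif() * (ehi - elo);
    double q[3] = { b.aim[0] + b.hx * (2 * rng.unif() - 1), b.aim[1],
                    b.aim[2] + b.hz * (2 * rng.unif() - 1) };
    double d[3], n = 0;
    for (int i = 0; i < 3; ++i) { d[i] = q[i] - b.src[i]; n += d[i] * d[i]; }
    n = std::sqrt(n);
    for (int i = 0; i < 3; ++i) { p.x[i] = b.src[i]; p.u[i] = d[i] / n; }
  } else {
    double r = std::sqrt(rng.unif());
    double phi = 2 * M_PI * rng.unif();
    p.x[0] = b.center[0] + b.ax * r * std::cos(phi);
    p.x[1] = b.center[1];
    p.x[2] = b.center[2] + b.az * r * std::sin(phi);
    p.u[0] = 0; p.u[1] = -1; p.u[2] = 0;
    p.E = b.E0 + (b.esigma > 0 ? b.esigma * rng.normal() : 0.0);
    if (p.E < 2.0) p.E = 2.0;
    if (p.E > 249.9) p.E = 249.9;
  }
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_primaries(List beam, int n, int seed) {
  Beam b = parse_beam(beam);
  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    RNG rng = history_rng((uint64_t)seed, (uint64_t)i);
    Particle p = sample_primary(b, rng);
    out(i, 0) = p.x[0]; out(i, 1) = p.x[1]; out(i, 2) = p.x[2];
    out(i, 3) = p.u[0]; out(i, 4) = p.u[1]; out(i, 5) = p.u[2];
    out(i, 6) = p.E;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Transport
struct Config {
  double photon_cutoff, proton_cutoff, max_step, max_floss;
  bool straggle, scatter;
  int track_cap;
};

struct Tracks {
  std::vector<double> rows;  // hist, kind, region, x0,y0,z0, x1,y1,z1, E, event
  int cap;
  void add(int hist, int kind, int region, const double* a, const double* b,
           double E, int event) {
    if ((int)(rows.size() / 11) >= cap) return;
    double r[11] = { (double)hist, (double)kind, (double)region, a[0], a[1],
                     a[2], b[0], b[1], b[2], E, (double)event };
    rows.insert(rows.end(), r, r + 11);
  }
};

struct Ledger {
  double primary = 0, created = 0, transferred = 0, cutoff = 0, escaped = 0,
         deposited = 0;
  long collisions = 0, crossings = 0, lost = 0;
};

static const double NUDGE = 1e-6;

// returns false when the particle left the problem (escape handled inside)
static bool advance_to_bbox(const Geometry& g, Particle& p, Ledger& led) {
  if (g.in_bbox(p.x)) return true;
  double t = g.bbox_entry(p.x, p.u);
  if (t < 0) { led.escaped += p.w * p.E; return false; }
  for (int i = 0; i < 3; ++i) p.x[i] += (t + NUDGE) * p.u[i];
  if (!g.in_bbox(p.x)) { led.escaped += p.w * p.E; return false; }
  return true;
}

static void transport_photon_rng(Particle start, const Geometry& g,
                                 const Mats& M, const Config& cfg,
                                 std::vector<double>& h_track,
                                 std::vector<double>& h_coll, Ledger& led,
                                 Tracks* trk, int hist, RNG& rng) {
  std::vector<Particle> stack{ start };
  while (!stack.empty()) {
    Particle p = stack.back();
    stack.pop_back();
    bool alive = true;
    while (alive) {
      if (p.E < cfg.photon_cutoff) { led.cutoff += p.w * p.E; break; }
      if (!advance_to_bbox(g, p, led)) break;
      int reg = g.locate(p.x);
      int m = M.region_mat[reg];
      double lE = std::log(p.E);
      double muc = M.mu_compton(m, lE), mupe = M.mu_pe(m, lE),
             mupp = M.mu_pair(m, p.E, lE);
      double mut = muc + mupe + mupp;
      double dbound = g.next_surface(p.x, p.u);
      bool to_infinity = !std::isfinite(dbound);
      if (to_infinity) dbound = 1e9;
      double s = -std::log(rng.unif_pos()) / mut;
      double L = std::min(s, dbound);
      h_track[reg] += p.w * L * p.E * M.mu_tr(m, lE);
      double x1[3] = { p.x[0] + L * p.u[0], p.x[1] + L * p.u[1],
                       p.x[2] + L * p.u[2] };
      if (s < dbound) {
        // collision
        led.collisions++;
        if (trk) trk->add(hist, 0, reg, p.x, x1, p.E, 1);
        for (int i = 0; i < 3; ++i) p.x[i] = x1[i];
        double xi = rng.unif() * mut;
        if (xi < muc) {
          double eps, cost;
          sample_kn(p.E, rng, eps, cost);
          double etr = p.E * (1.0 - eps);
          h_coll[reg] += p.w * etr;
          led.transferred += p.w * etr;
          rotate_direction(p.u, cost, 2 * M_PI * rng.unif());
          p.E *= eps;
          if (p.E < cfg.photon_cutoff) {
            h_coll[reg] += p.w * p.E;
            led.cutoff += p.w * p.E;
            alive = false;
          }
        } else if (xi < muc + mupe) {
          h_coll[reg] += p.w * p.E;
          led.transferred += p.w * p.E;
          alive = false;
        } else {
          double etr = p.E - 2 * MEC2;
          h_coll[reg] += p.w * etr;
          led.transferred += p.w * etr;
          led.created += p.w * 2 * MEC2;
          // annihilation-in-place: two back-to-back 0.511 MeV photons
          double v[3] = { 0, 0, 1 };
          double cost = 2 * rng.unif() - 1;
          rotate_direction(v, cost, 2 * M_PI * rng.unif());
          Particle q1 = p, q2 = p;
          q1.E = q2.E = MEC2;
          for (int i = 0; i < 3; ++i) { q1.u[i] = v[i]; q2.u[i] = -v[i]; }
          stack.push_back(q1);
          stack.push_back(q2);
          alive = false;
        }
      } else {
        // boundary crossing (or flight to bbox edge)
        led.crossings++;
        if (trk) trk->add(hist, 0, reg, p.x, x1, p.E, 0);
        for (int i = 0; i < 3; ++i) p.x[i] = x1[i] + NUDGE * p.u[i];
        if (to_infinity || !g.in_bbox(p.x)) {
          // will re-enter through advance_to_bbox or escape there
          if (!g.in_bbox(p.x)) {
            double t = g.bbox_entry(p.x, p.u);
            if (t < 0) { led.escaped += p.w * p.E; alive = false; }
          }
        }
      }
    }
  }
}

static void transport_proton_rng(Particle p, const Geometry& g, const Mats& M,
                                 const Config& cfg, std::vector<double>& h_track,
                                 Ledger& led, Tracks* trk, int hist, RNG& rng) {
  const double mp = 938.27208816;
  int guard = 0;
  while (true) {
    if (++guard > 2000000) { led.lost++; break; }
    if (!advance_to_bbox(g, p, led)) break;
    int reg = g.locate(p.x);
    int m = M.region_mat[reg];
    if (p.E < cfg.proton_cutoff) {
      h_track[reg] += p.w * p.E;
      led.deposited += p.w * p.E;
      break;
    }
    double lE = std::log(p.E);
    double S = M.S_at(m, lE);
    double rho = M.tabs[m].rho;
    bool dense = rho >= 0.01;
    double dbound = g.next_surface(p.x, p.u);
    if (!std::isfinite(dbound)) dbound = 1e9;
    double step = dbound;
    if (dense) {
      step = std::min(step, cfg.max_step);
      step = std::min(step, cfg.max_floss * p.E / S);
      double range = M.R_at(m, lE);
      if (range <= step) {
        // stops inside this region
        double x1[3] = { p.x[0] + range * p.u[0], p.x[1] + range * p.u[1],
                         p.x[2] + range * p.u[2] };
        if (trk) trk->add(hist, 1, reg, p.x, x1, p.E, 4);
        h_track[reg] += p.w * p.E;
        led.deposited += p.w * p.E;
        break;
      }
    }
    double dE = S * step;
    if (cfg.straggle && dense) {
      double var = 0.1569 * M.tabs[m].za * rho * step;  // Bohr, MeV^2
      dE += std::sqrt(var) * rng.normal();
      if (dE < 0) dE = 0;
    }
    if (dE > p.E - cfg.proton_cutoff) {
      // would fall below cutoff: deposit everything here
      double x1[3] = { p.x[0] + step * p.u[0], p.x[1] + step * p.u[1],
                       p.x[2] + step * p.u[2] };
      if (trk) trk->add(hist, 1, reg, p.x, x1, p.E, 4);
      h_track[reg] += p.w * p.E;
      led.deposited += p.w * p.E;
      break;
    }
    h_track[reg] += p.w * dE;
    led.deposited += p.w * dE;
    double x1[3] = { p.x[0] + step * p.u[0], p.x[1] + step * p.u[1],
                     p.x[2] + step * p.u[2] };
    if (trk && dense) trk->add(hist, 1, reg, p.x, x1, p.E, 0);
    bool at_boundary = (step == dbound);
    for (int i = 0; i < 3; ++i)
      p.x[i] = x1[i] + (at_boundary ? NUDGE * p.u[i] : 0.0);
    p.E -= dE;
    if (at_boundary) led.crossings++;
    if (cfg.scatter && dense && p.E >= cfg.proton_cutoff) {
      double gamma = 1 + p.E / mp;
      double beta2 = 1 - 1 / (gamma * gamma);
      double pc = std::sqrt((p.E + mp) * (p.E + mp) - mp * mp);
      double betapc = std::sqrt(beta2) * pc;
      double t = step / M.tabs[m].X0;
      double th0 = 13.6 / betapc * std::sqrt(t) *
                   std::max(0.0, 1 + 0.038 * std::log(t));
      if (th0 > 0) {
        double e1[3], e2[3];
        double u0[3] = { p.u[0], p.u[1], p.u[2] };
        if (std::fabs(u0[2]) < 0.99) { e1[0] = -u0[1]; e1[1] = u0[0]; e1[2] = 0; }
        else { e1[0] = 1; e1[1] = 0; e1[2] = 0; }
        double dot = e1[0] * u0[0] + e1[1] * u0[1] + e1[2] * u0[2];
        for (int i = 0; i < 3; ++i) e1[i] -= dot * u0[i];
        double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
        for (int i = 0; i < 3; ++i) e1[i] /= n1;
        e2[0] = u0[1] * e1[2] - u0[2] * e1[1];
        e2[1] = u0[2] * e1[0] - u0[0] * e1[2];
        e2[2] = u0[0] * e1[1] - u0[1] * e1[0];
        double tx = th0 * rng.normal(), ty = th0 * rng.normal();
        double nn = 0;
        for (int i = 0; i < 3; ++i) {
          p.u[i] = u0[i] + tx * e1[i] + ty * e2[i];
          nn += p.u[i] * p.u[i];
        }
        nn = std::sqrt(nn);
        for (int i = 0; i < 3; ++i) p.u[i] /= nn;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_run(List geom, List mats, List beam, List config, double n_histories,
             int seed, bool tracks) {
  Geometry g = parse_geometry(geom);
  Mats M = parse_mats(mats);
  Beam b = parse_beam(beam);
  Config cfg;
  cfg.photon_cutoff = as<double>(config["photon_cutoff"]);
  cfg.proton_cutoff = as<double>(config["proton_cutoff"]);
  cfg.max_step = as<double>(config["max_step"]);
  cfg.max_floss = as<double>(config["max_floss"]);
  cfg.straggle = as<bool>(config["straggle"]);
  cfg.scatter = as<bool>(config["scatter"]);
  cfg.track_cap = as<int>(config["track_cap"]);

  int nreg = g.n_regions();
  std::vector<double> sum_t(nreg, 0), sumsq_t(nreg, 0), sum_c(nreg, 0),
      sumsq_c(nreg, 0), h_track(nreg), h_coll(nreg);
  Ledger led;
  Tracks trk;
  trk.cap = cfg.track_cap;
  Tracks* trkp = tracks ? &trk : nullptr;

  long n = (long)n_histories;
  for (long i = 0; i < n; ++i) {
    if (i % 8192 == 0) Rcpp::checkUserInterrupt();
    RNG rng = history_rng((uint64_t)seed, (uint64_t)i);
    Particle p = sample_primary(b, rng);
    led.primary += p.w * p.E;
    std::fill(h_track.begin(), h_track.end(), 0.0);
    std::fill(h_coll.begin(), h_coll.end(), 0.0);
    if (b.modality == 0) {
      transport_photon_rng(p, g, M, cfg, h_track, h_coll, led, trkp, (int)i,
                           rng);
    } else {
      transport_proton_rng(p, g, M, cfg, h_track, led, trkp, (int)i, rng);
    }
    for (int r = 0; r < nreg; ++r) {
      sum_t[r] += h_track[r];
      sumsq_t[r] += h_track[r] * h_track[r];
      sum_c[r] += h_coll[r];
      sumsq_c[r] += h_coll[r] * h_coll[r];
    }
  }

  List out = List::create(
    _["sum_track"] = NumericVector(sum_t.begin(), sum_t.end()),
    _["sumsq_track"] = NumericVector(sumsq_t.begin(), sumsq_t.end()),
    _["sum_coll"] = NumericVector(sum_c.begin(), sum_c.end()),
    _["sumsq_coll"] = NumericVector(sumsq_c.begin(), sumsq_c.end()),
    _["n"] = (double)n,
    _["ledger"] = List::create(
      _["primary"] = led.primary, _["created"] = led.created,
      _["transferred"] = led.transferred, _["cutoff"] = led.cutoff,
      _["deposited"] = led.deposited, _["escaped"] = led.escaped),
    _["counters"] = List::create(
      _["collisions"] = (double)led.collisions,
      _["crossings"] = (double)led.crossings, _["lost"] = (double)led.lost));
  if (tracks) {
    int nrow = (int)(trk.rows.size() / 11);
    NumericMatrix tm(nrow, 11);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 11; ++j) tm(i, j) = trk.rows[i * 11 + j];
    out["tracks"] = tm;
  }
  return out;
}
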