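// Coupled photon-electron Monte Carlo transport in water voxel phantoms.
//
// Photons: Woodcock (majorant) tracking with Compton (Klein-Nishina),
// photoelectric and pair-production interactions; 50 keV absorption cutoff.
// Electrons: straight-line continuous-slowing-down deposition driven by a
// CSDA range table; 200 keV threshold separates locally absorbed from
// transported electrons (both follow the same density-scaled march).
// Scoring: analog energy deposition on the voxel grid with history-batch
// variance, or a track-length collision-kerma estimator in a small region
// for point-dose (output factor) estimates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double MEC2 = 0.510998928;  // electron rest energy, MeV

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256**, one independent stream per batch.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t nextu() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (nextu() >> 11) * 0x1.0p-53; }  // in [0,1)
};

// ---------------------------------------------------------------------------
// log-log interpolated 1D table (monotone increasing x)
// ---------------------------------------------------------------------------
struct LogTable {
  std::vector<double> lx, ly;
  mutable double lastx = -1.0, lasty = 0.0;   // photons mostly sit on the
  void build(const NumericVector &x, const NumericVector &y) {  // two lines
    int n = x.size();
    lx.resize(n); ly.resize(n);
    for (int i = 0; i < n; ++i) {
      lx[i] = std::log(x[i]);
      ly[i] = std::log(std::max(y[i], 1e-300));
    }
  }
  double at(double x) const {
    if (x == lastx) return lasty;
    lastx = x;
    lasty = atRaw(x);
    return lasty;
  }
  double atRaw(double x) const {
    double l = std::log(x);
    int n = lx.size();
    if (l <= lx[0]) return std::exp(ly[0]);
    if (l >= lx[n - 1]) return std::exp(ly[n - 1]);
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int m = (lo + hi) / 2; (lx[m] <= l ? lo : hi) = m; }
    double f = (l - lx[lo]) / (lx[lo + 1] - lx[lo]);
    return std::exp(ly[lo] + f * (ly[lo + 1] - ly[lo]));
  }
};

// ---------------------------------------------------------------------------
// Walker alias sampler
// ---------------------------------------------------------------------------
struct Alias {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double> &w) {
    int n = w.size();
    prob.assign(n, 0.0); alias.assign(n, 0);
    double tot = 0; for (double v : w) tot += v;
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / tot;
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s]; alias[s] = l;
      p[l] = p[l] + p[s] - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    for (int i : small) prob[i] = 1.0;
    for (int i : large) prob[i] = 1.0;
  }
  int draw(Rng &rng) const {
    int n = prob.size();
    double u = rng.unif() * n;
    int i = (int)u; if (i >= n) i = n - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
};

// ---------------------------------------------------------------------------
// geometry helpers
// ---------------------------------------------------------------------------
struct Vec { double x, y, z; };

static inline void rotateDirection(double &ux, double &uy, double &uz,
                                   double cost, double phi) {
  // rotate unit vector u by polar angle acos(cost) about itself, azimuth phi
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double uz2 = uz * uz;
  if (uz2 > 1.0 - 1e-12) {
    double sgn = uz > 0 ? 1.0 : -1.0;
    ux = sint * cphi; uy = sint * sphi; uz = sgn * cost;
  } else {
    double r = std::sqrt(1.0 - uz2);
    double nx = ux * cost + sint * (ux * uz * cphi - uy * sphi) / r;
    double ny = uy * cost + sint * (uy * uz * cphi + ux * sphi) / r;
    double nz = uz * cost - sint * r * cphi;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

// entry distance of ray into AABB, or -1 if it misses; 0 if inside
static double rayBoxEntry(double px, double py, double pz,
                          double ux, double uy, double uz,
                          const double lo[3], const double hi[3]) {
  double p[3] = {px, py, pz}, u[3] = {ux, uy, uz};
  double tmin = 0.0, tmax = 1e300;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(u[a]) < 1e-300) {
      if (p[a] < lo[a] || p[a] > hi[a]) return -1.0;
    } else {
      double t1 = (lo[a] - p[a]) / u[a], t2 = (hi[a] - p[a]) / u[a];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
      if (tmin > tmax) return -1.0;
    }
  }
  return tmin;
}

// overlap length of segment [p, p+s*u] with AABB
static double segBoxOverlap(double px, double py, double pz,
                            double ux, double uy, double uz, double s,
                            const double lo[3], const double hi[3]) {
  double p[3] = {px, py, pz}, u[3] = {ux, uy, uz};
  double t0 = 0.0, t1 = s;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(u[a]) < 1e-300) {
      if (p[a] < lo[a] || p[a] > hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p[a]) / u[a], tb = (hi[a] - p[a]) / u[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      if (t0 >= t1) return 0.0;
    }
  }
  return t1 - t0;
}

// ---------------------------------------------------------------------------
// Klein-Nishina sampling (two-branch composition-rejection)
// returns tau = E'/E and cos(theta)
// ---------------------------------------------------------------------------
static inline void sampleKN(double E, Rng &rng, double &tau, double &cost) {
  double a = E / MEC2;
  double tmin = 1.0 / (1.0 + 2.0 * a);
  double a1 = std::log(1.0 / tmin);
  double a2 = 0.5 * (1.0 - tmin * tmin);
  for (;;) {
    double t;
    if (rng.unif() * (a1 + a2) < a1) t = std::pow(tmin, rng.unif());
    else t = std::sqrt(tmin * tmin + rng.unif() * (1.0 - tmin * tmin));
    double ct = 1.0 - (1.0 - t) / (a * t);
    if (ct < -1.0) ct = -1.0;
    if (ct > 1.0) ct = 1.0;
    double sin2 = 1.0 - ct * ct;
    double rej = 1.0 - t * sin2 / (1.0 + t * t);
    if (rng.unif() <= rej) { tau = t; cost = ct; return; }
  }
}

// ---------------------------------------------------------------------------
// engine state
// ---------------------------------------------------------------------------
struct MapData {
  int nx, ny;
  double x0, y0, pitch, R;
  std::vector<int> pix;      // linear pixel index iy + ny*ix of positive pixels
  Alias alias;
};

struct Engine {
  // phantom
  const double *rho;
  int nx, ny, nz;
  double vox, ox, oy, oz;      // voxel mm, origin = centre of voxel (0,0,0)
  double blo[3], bhi[3];       // bounding box, mm
  double rhoMax;
  // cross sections (mass coefficients cm^2/g)
  LogTable muC, muP, muPair, muTot, muEn;
  LogTable csdaR, csdaE;       // E->range(g/cm^2) and inverse
  // spectrum
  std::vector<double> lineE, lineCdf;
  std::vector<double> contEdge, contCdf;
  double pLine;
  // sources
  std::vector<MapData> maps;
  struct Inst { int map; double sx, sy, sz, cosr, sinr, tx, ty, tz; };
  std::vector<Inst> inst;
  Alias instAlias;
  // options
  double ecutPh, ecutEl;
  bool kermaMode, brems;
  double rlo[3], rhi[3];       // kerma region, mm
  double regionVolCm3;
  // per-history tallies
  std::vector<double> batchGrid;       // edep: energy per voxel, this batch
  double kermaScore;                   // kerma: this history
  double histDeposit, histEscape;

  int voxelIndex(double x, double y, double z) const {
    int i = (int)std::floor((x - ox) / vox + 0.5);
    int j = (int)std::floor((y - oy) / vox + 0.5);
    int k = (int)std::floor((z - oz) / vox + 0.5);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return i + nx * (j + (size_t)ny * k);
  }
  bool inBox(double x, double y, double z) const {
    return x >= blo[0] && x <= bhi[0] && y >= blo[1] && y <= bhi[1] &&
           z >= blo[2] && z <= bhi[2];
  }
  void deposit(int v, double e) {
    if (v >= 0) { batchGrid[v] += e; histDeposit += e; }
    else histEscape += e;
  }

  // distance (mm) to exit of current voxel along u
  double voxelExit(double x, double y, double z,
                   double ux, double uy, double uz) const {
    double t = 1e300;
    double p[3] = {x, y, z}, u[3] = {ux, uy, uz}, o[3] = {ox, oy, oz};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(u[a]) < 1e-12) continue;
      double rel = (p[a] - o[a]) / vox + 0.5;
      double cell = std::floor(rel);
      double bound = u[a] > 0 ? (cell + 1.0) : cell;
      double ta = ((bound - rel) * vox) / u[a];
      if (ta < t) t = ta;
    }
    return std::max(t, 1e-9);
  }

  // straight-line CSDA electron march, density-scaled
  void electron(double E, double x, double y, double z,
                double ux, double uy, double uz,
                std::vector<double> *photBuf) {
    if (E <= 0) return;
    for (;;) {
      if (!inBox(x, y, z)) { histEscape += E; return; }
      int v = voxelIndex(x, y, z);
      if (v < 0) { histEscape += E; return; }
      double d = rho[v];
      if (d <= 1e-6) {  // vacuum: free flight across the voxel
        double t = voxelExit(x, y, z, ux, uy, uz);
        x += (t + 1e-6) * ux; y += (t + 1e-6) * uy; z += (t + 1e-6) * uz;
        continue;
      }
      double range_mm = 10.0 * csdaR.at(E) / d;
      double t = voxelExit(x, y, z, ux, uy, uz);
      if (range_mm <= t || range_mm < 0.5 * vox) { deposit(v, E); return; }
      double rNew = csdaR.at(E) - t * d / 10.0;
      double eNew = (rNew <= csdaR.ly.size() * 0 + 1e-9) ? 0.0 : csdaE.at(rNew);
      if (eNew >= E) eNew = 0.0;  // guard against table round-off
      double dE = E - eNew;
      if (brems && E > ecutEl && photBuf) {
        double frac = std::min(0.05, 0.0116 * E);  // crude radiative yield
        double eRad = dE * frac;
        dE -= eRad;
        photBuf->push_back(eRad);  // emitted along current direction
        photBuf->push_back(x); photBuf->push_back(y); photBuf->push_back(z);
        photBuf->push_back(ux); photBuf->push_back(uy); photBuf->push_back(uz);
      }
      deposit(v, dE);
      E = eNew;
      if (E <= 1e-6) return;
      x += (t + 1e-6) * ux; y += (t + 1e-6) * uy; z += (t + 1e-6) * uz;
    }
  }

  double sampleEnergy(Rng &rng) const {
    if (rng.unif() < pLine) {
      double u = rng.unif();
      for (size_t i = 0; i < lineE.size(); ++i)
        if (u <= lineCdf[i]) return lineE[i];
      return lineE.back();
    }
    double u = rng.unif();
    size_t n = contCdf.size();  // cdf at right edges, contEdge has n+1 entries
    size_t lo = 0;
    while (lo < n - 1 && contCdf[lo] < u) ++lo;
    double c0 = lo == 0 ? 0.0 : contCdf[lo - 1];
    double f = (u - c0) / std::max(contCdf[lo] - c0, 1e-300);
    return contEdge[lo] + f * (contEdge[lo + 1] - contEdge[lo]);
  }

  // transport one photon (and its secondaries) to completion
  void photon(double E0, double x, double y, double z,
              double ux, double uy, double uz, Rng &rng) {
    struct Ph { double E, x, y, z, ux, uy, uz; };
    std::vector<Ph> stack;
    stack.push_back({E0, x, y, z, ux, uy, uz});
    std::vector<double> photBuf;
    while (!stack.empty()) {
      Ph p = stack.back(); stack.pop_back();
      double E = p.E;
      x = p.x; y = p.y; z = p.z; ux = p.ux; uy = p.uy; uz = p.uz;
      for (;;) {
        if (E <= ecutPh) {  // local absorption
          if (!kermaMode) deposit(voxelIndex(x, y, z), E);
          break;
        }
        if (!inBox(x, y, z)) {
          double t = rayBoxEntry(x, y, z, ux, uy, uz, blo, bhi);
          if (t < 0) { histEscape += E; break; }
          x += (t + 1e-6) * ux; y += (t + 1e-6) * uy; z += (t + 1e-6) * uz;
          if (!inBox(x, y, z)) { histEscape += E; break; }
        }
        double muMass = muTot.at(E);
        double muMaj = muMass * rhoMax;       // cm^-1
        if (muMaj <= 0) { histEscape += E; break; }
        // Woodcock flight
        bool interacted = false;
        for (;;) {
          double s_mm = -std::log(1.0 - rng.unif()) / muMaj * 10.0;
          if (kermaMode) {
            double l = segBoxOverlap(x, y, z, ux, uy, uz, s_mm, rlo, rhi);
            if (l > 0) kermaScore += E * muEn.at(E) * (l / 10.0) / regionVolCm3;
          }
          x += s_mm * ux; y += s_mm * uy; z += s_mm * uz;
          if (!inBox(x, y, z)) { histEscape += E; break; }
          int v = voxelIndex(x, y, z);
          if (v < 0) { histEscape += E; break; }
          if (rng.unif() < rho[v] / rhoMax) { interacted = true; break; }
        }
        if (!interacted) break;
        // choose process by partial mass coefficients
        double mC = muC.at(E), mP = muP.at(E),
               mPP = E > 2.0 * MEC2 ? muPair.at(E) : 0.0;
        double u = rng.unif() * (mC + mP + mPP);
        if (u < mC) {  // Compton
          double tau, cost;
          sampleKN(E, rng, tau, cost);
          double Ee = E * (1.0 - tau);
          double phi = 2.0 * M_PI * rng.unif();
          if (!kermaMode && Ee > 0) {
            double a = E / MEC2;
            double tanHalf = std::sqrt(std::max(0.0, (1.0 - cost) /
                                                 std::max(1.0 + cost, 1e-12)));
            double cotE = (1.0 + a) * tanHalf;
            double costE = cotE / std::sqrt(1.0 + cotE * cotE);
            double ex = ux, ey = uy, ez = uz;
            rotateDirection(ex, ey, ez, costE, phi + M_PI);
            photBuf.clear();
            electron(Ee, x, y, z, ex, ey, ez, brems ? &photBuf : nullptr);
            for (size_t b = 0; b + 6 < photBuf.size() + 1; b += 7)
              if (photBuf.size() >= b + 7 && photBuf[b] > 0)
                stack.push_back({photBuf[b], photBuf[b + 1], photBuf[b + 2],
                                 photBuf[b + 3], photBuf[b + 4], photBuf[b + 5],
                                 photBuf[b + 6]});
          } else if (kermaMode) {
            // kerma estimator accounts for transferred energy via mu_en
          }
          E *= tau;
          rotateDirection(ux, uy, uz, cost, phi);
          continue;
        } else if (u < mC + mP) {  // photoelectric
          if (!kermaMode) electron(E, x, y, z, ux, uy, uz, nullptr);
          break;
        } else {  // pair production
          double Ee = 0.5 * (E - 2.0 * MEC2);
          if (!kermaMode && Ee > 0) {
            electron(Ee, x, y, z, ux, uy, uz, nullptr);
            electron(Ee, x, y, z, ux, uy, uz, nullptr);
          }
          // annihilation at the interaction site (positron range neglected)
          double cost = 2.0 * rng.unif() - 1.0;
          double phi = 2.0 * M_PI * rng.unif();
          double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
          double gx = sint * std::cos(phi), gy = sint * std::sin(phi), gz = cost;
          stack.push_back({MEC2, x, y, z, gx, gy, gz});
          stack.push_back({MEC2, x, y, z, -gx, -gy, -gz});
          break;
        }
      }
    }
  }
};

static void buildEngine(Engine &eng, List phantom, List xsec, List spectrum,
                        List maps, DataFrame instances, List opts) {
  NumericVector dens = phantom["density"];
  eng.rho = REAL(dens);
  IntegerVector dims = phantom["dims"];
  eng.nx = dims[0]; eng.ny = dims[1]; eng.nz = dims[2];
  eng.vox = as<double>(phantom["voxel"]);
  NumericVector org = phantom["origin"];
  eng.ox = org[0]; eng.oy = org[1]; eng.oz = org[2];
  eng.blo[0] = eng.ox - 0.5 * eng.vox; eng.bhi[0] = eng.ox + (eng.nx - 0.5) * eng.vox;
  eng.blo[1] = eng.oy - 0.5 * eng.vox; eng.bhi[1] = eng.oy + (eng.ny - 0.5) * eng.vox;
  eng.blo[2] = eng.oz - 0.5 * eng.vox; eng.bhi[2] = eng.oz + (eng.nz - 0.5) * eng.vox;
  eng.rhoMax = 0;
  size_t nvox = (size_t)eng.nx * eng.ny * eng.nz;
  for (size_t i = 0; i < nvox; ++i) eng.rhoMax = std::max(eng.rhoMax, eng.rho[i]);

  NumericVector xe = xsec["energy"];
  eng.muC.build(xe, xsec["mu_compton"]);
  eng.muP.build(xe, xsec["mu_photo"]);
  eng.muTot.build(xe, xsec["mu_total"]);
  eng.muEn.build(xe, xsec["mu_en"]);
  {  // pair production: avoid log(0) below threshold, clamp in at()
    NumericVector mp = xsec["mu_pair"];
    NumericVector e2, m2;
    for (int i = 0; i < xe.size(); ++i)
      if (mp[i] > 0) { e2.push_back(xe[i]); m2.push_back(mp[i]); }
    if (e2.size() < 2) { e2 = NumericVector::create(1.022, 1.4);
                         m2 = NumericVector::create(1e-30, 1e-30); }
    eng.muPair.build(e2, m2);
  }
  NumericVector ce = xsec["csda_energy"], cr = xsec["csda_range"];
  eng.csdaR.build(ce, cr);
  eng.csdaE.build(cr, ce);

  NumericVector lE = spectrum["line_energy"], lP = spectrum["line_prob"];
  eng.pLine = as<double>(spectrum["p_line"]);
  double c = 0, tot = 0;
  for (int i = 0; i < lP.size(); ++i) tot += lP[i];
  for (int i = 0; i < lE.size(); ++i) {
    eng.lineE.push_back(lE[i]); c += lP[i] / tot; eng.lineCdf.push_back(c);
  }
  NumericVector cEdge = spectrum["cont_edges"], cCdf = spectrum["cont_cdf"];
  for (double v : cEdge) eng.contEdge.push_back(v);
  for (double v : cCdf) eng.contCdf.push_back(v);

  // fluence maps and instances
  for (int m = 0; m < maps.size(); ++m) {
    List mm = maps[m];
    NumericMatrix vals = mm["values"];
    MapData md;
    md.ny = vals.nrow(); md.nx = vals.ncol();
    md.x0 = as<double>(mm["x0"]); md.y0 = as<double>(mm["y0"]);
    md.pitch = as<double>(mm["pitch"]); md.R = as<double>(mm["R"]);
    std::vector<double> w;
    for (int ix = 0; ix < md.nx; ++ix)
      for (int iy = 0; iy < md.ny; ++iy)
        if (vals(iy, ix) > 0) {
          md.pix.push_back(iy + md.ny * ix);
          w.push_back(vals(iy, ix));
        }
    md.alias.build(w);
    eng.maps.push_back(std::move(md));
  }
  IntegerVector mi = instances["map_id"];
  NumericVector sx = instances["sx"], sy = instances["sy"], sz = instances["sz"],
                rot = instances["rot_deg"], wt = instances["weight"],
                tx = instances["tx"], ty = instances["ty"], tz = instances["tz"];
  std::vector<double> iw;
  for (int i = 0; i < mi.size(); ++i) {
    Engine::Inst in;
    in.map = mi[i] - 1;
    in.sx = sx[i]; in.sy = sy[i]; in.sz = sz[i];
    double r = rot[i] * M_PI / 180.0;
    in.cosr = std::cos(r); in.sinr = std::sin(r);
    in.tx = tx[i]; in.ty = ty[i]; in.tz = tz[i];
    eng.inst.push_back(in);
    iw.push_back(wt[i]);
  }
  eng.instAlias.build(iw);

  eng.ecutPh = as<double>(opts["e_cut_photon"]);
  eng.ecutEl = as<double>(opts["e_cut_electron"]);
  eng.kermaMode = as<std::string>(opts["mode"]) == "kerma";
  eng.brems = as<bool>(opts["brems"]);
  if (eng.kermaMode) {
    NumericVector rl = opts["region_lo"], rh = opts["region_hi"];
    for (int a = 0; a < 3; ++a) { eng.rlo[a] = rl[a]; eng.rhi[a] = rh[a]; }
    eng.regionVolCm3 = (eng.rhi[0] - eng.rlo[0]) * (eng.rhi[1] - eng.rlo[1]) *
                       (eng.rhi[2] - eng.rlo[2]) / 1000.0;
  }
}

// [[Rcpp::export]]
List cpp_run_transport(List maps, DataFrame instances, List spectrum,
                       List xsec, List phantom, List opts) {
  Engine eng;
  buildEngine(eng, phantom, xsec, spectrum, maps, instances, opts);
  long long nHist = (long long)as<double>(opts["n_histories"]);
  int nBatch = as<int>(opts["batches"]);
  uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  size_t nvox = (size_t)eng.nx * eng.ny * eng.nz;

  bool kerma = eng.kermaMode;
  std::vector<double> sum, sumsq;
  if (!kerma) {
    eng.batchGrid.assign(nvox, 0.0);
    sum.assign(nvox, 0.0); sumsq.assign(nvox, 0.0);
  } else eng.batchGrid.assign(1, 0.0);

  NumericVector kBatchMean(nBatch), kBatchN(nBatch);
  double totEmit = 0, totDep = 0, totEsc = 0;

  long long per = nHist / nBatch;
  for (int b = 0; b < nBatch; ++b) {
    long long nb = (b == nBatch - 1) ? nHist - per * (nBatch - 1) : per;
    uint64_t sx = seed * 0x9e3779b97f4a7c15ULL + (uint64_t)(b + 1) * 0x100000001b3ULL;
    Rng rng(sx);
    if (!kerma) std::fill(eng.batchGrid.begin(), eng.batchGrid.end(), 0.0);
    double kSum = 0;
    for (long long h = 0; h < nb; ++h) {
      const Engine::Inst &in = eng.inst[eng.instAlias.draw(rng)];
      const MapData &md = eng.maps[in.map];
      int pick = md.alias.draw(rng);
      int lin = md.pix[pick];
      int iy = lin % md.ny, ix = lin / md.ny;
      double xs = md.x0 + ix * md.pitch + (rng.unif() - 0.5) * md.pitch;
      double ys = md.y0 + iy * md.pitch + (rng.unif() - 0.5) * md.pitch;
      double ang = xs / md.R;
      double px0 = md.R * std::cos(ang), py0 = md.R * std::sin(ang);
      double px = in.cosr * px0 - in.sinr * py0 + in.tx;
      double py = in.sinr * px0 + in.cosr * py0 + in.ty;
      double pz = ys + in.tz;
      double ux = px - in.sx, uy = py - in.sy, uz = pz - in.sz;
      double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= nrm; uy /= nrm; uz /= nrm;
      double E = eng.sampleEnergy(rng);
      eng.kermaScore = 0; eng.histDeposit = 0; eng.histEscape = 0;
      eng.photon(E, px, py, pz, ux, uy, uz, rng);
      totEmit += E; totDep += eng.histDeposit; totEsc += eng.histEscape;
      if (kerma) kSum += eng.kermaScore;
    }
    if (kerma) { kBatchMean[b] = kSum / nb; kBatchN[b] = nb; }
    else
      for (size_t v = 0; v < nvox; ++v) {
        double m = eng.batchGrid[v] / nb;
        sum[v] += m * ((double)nb / nHist) * nBatch;  // weighted batch mean
        sumsq[v] += m * m;
      }
  }

  List out;
  if (kerma) {
    double m = 0, nTot = 0;
    for (int b = 0; b < nBatch; ++b) { m += kBatchMean[b] * kBatchN[b]; nTot += kBatchN[b]; }
    m /= nTot;
    double var = 0;
    for (int b = 0; b < nBatch; ++b) var += (kBatchMean[b] - m) * (kBatchMean[b] - m);
    var /= (nBatch - 1.0) * nBatch;
    out["value"] = m;                      // MeV/g per history
    out["se"] = std::sqrt(var);
    out["batch_means"] = kBatchMean;
  } else {
    NumericVector mean(nvox), relerr(nvox);
    for (size_t v = 0; v < nvox; ++v) {
      double m = sum[v] / nBatch;
      double var = (sumsq[v] / nBatch - m * m) / std::max(nBatch - 1, 1);
      mean[v] = m;                         // MeV per voxel per history
      relerr[v] = m > 0 ? std::sqrt(std::max(var, 0.0)) / m : 0.0;
    }
    mean.attr("dim") = IntegerVector::create(eng.nx, eng.ny, eng.nz);
    relerr.attr("dim") = IntegerVector::create(eng.nx, eng.ny, eng.nz);
    out["energy"] = mean;
    out["relerr"] = relerr;
  }
  out["emitted"] = totEmit / nHist;
  out["deposited"] = totDep / nHist;
  out["escaped"] = totEsc / nHist;
  out["n_histories"] = (double)nHist;
  return out;
}

// Straight-line CSDA electron march exposed for range/conservation tests:
// returns per-voxel deposits (index 1-based into the phantom array), the
// total deposited and escaped energy.
// [[Rcpp::export]]
List cpp_electron_track(double E, NumericVector start, NumericVector dir,
                        List phantom, List xsec) {
  Engine eng;
  List dummySpec = List::create(
    _["line_energy"] = NumericVector::create(1.25),
    _["line_prob"] = NumericVector::create(1.0), _["p_line"] = 1.0,
    _["cont_edges"] = NumericVector::create(0.1, 0.2),
    _["cont_cdf"] = NumericVector::create(1.0));
  NumericMatrix vv(1, 1); vv(0, 0) = 1.0;
  List dummyMap = List::create(_["values"] = vv, _["x0"] = 0.0,
                               _["y0"] = 0.0, _["pitch"] = 1.0,
                               _["R"] = 113.0);
  DataFrame dummyInst = DataFrame::create(
    _["map_id"] = IntegerVector::create(1),
    _["sx"] = 0.0, _["sy"] = 0.0, _["sz"] = 0.0, _["rot_deg"] = 0.0,
    _["weight"] = 1.0, _["tx"] = 0.0, _["ty"] = 0.0, _["tz"] = 0.0);
  List opts = List::create(_["e_cut_photon"] = 0.05, _["e_cut_electron"] = 0.2,
                           _["mode"] = "edep", _["brems"] = false);
  buildEngine(eng, phantom, xsec, dummySpec, List::create(dummyMap),
              dummyInst, opts);
  size_t nvox = (size_t)eng.nx * eng.ny * eng.nz;
  eng.batchGrid.assign(nvox, 0.0);
  eng.histDeposit = 0; eng.histEscape = 0;
  double nrm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  eng.electron(E, start[0], start[1], start[2], dir[0] / nrm, dir[1] / nrm,
               dir[2] / nrm, nullptr);
  std::vector<int> idx;
  std::vector<double> dep;
  for (size_t v = 0; v < nvox; ++v)
    if (eng.batchGrid[v] > 0) { idx.push_back((int)v + 1);
                                dep.push_back(eng.batchGrid[v]); }
  return List::create(_["voxel"] = wrap(idx), _["energy"] = wrap(dep),
                      _["deposited"] = eng.histDeposit,
                      _["escaped"] = eng.histEscape);
}

// Klein-Nishina sampler exposed for distributional tests
// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E, int n, double seed) {
  Rng rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 1);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double tau, cost;
    sampleKN(E, rng, tau, cost);
    out(i, 0) = cost;
    out(i, 1) = tau * E;
  }
  colnames(out) = CharacterVector::create("cos_theta", "energy_scattered");
  return out;
}

// first real interaction: depth (mm) from entry and process id
// (1=Compton, 2=photoelectric, 3=pair); depth<0 means the photon escaped.
// Used to verify Woodcock free-path sampling and process selection against
// the attenuation table.
// [[Rcpp::export]]
List cpp_first_interaction(double E, int n, double seed, List xsec,
                           List phantom, NumericVector start,
                           NumericVector dir) {
  Engine eng;
  // minimal build: phantom + xsec only
  List dummySpec = List::create(
    _["line_energy"] = NumericVector::create(E),
    _["line_prob"] = NumericVector::create(1.0), _["p_line"] = 1.0,
    _["cont_edges"] = NumericVector::create(0.1, 0.2),
    _["cont_cdf"] = NumericVector::create(1.0));
  List dummyMap = List::create(_["values"] = NumericMatrix(1, 1),
                               _["x0"] = 0.0, _["y0"] = 0.0,
                               _["pitch"] = 1.0, _["R"] = 113.0);
  // one positive pixel
  NumericMatrix vv(1, 1); vv(0, 0) = 1.0; dummyMap["values"] = vv;
  DataFrame dummyInst = DataFrame::create(
    _["map_id"] = IntegerVector::create(1),
    _["sx"] = 0.0, _["sy"] = 0.0, _["sz"] = 0.0, _["rot_deg"] = 0.0,
    _["weight"] = 1.0, _["tx"] = 0.0, _["ty"] = 0.0, _["tz"] = 0.0);
  List opts = List::create(_["e_cut_photon"] = 0.001, _["e_cut_electron"] = 0.2,
                           _["mode"] = "edep", _["brems"] = false);
  buildEngine(eng, phantom, xsec, dummySpec, List::create(dummyMap),
              dummyInst, opts);
  Rng rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 7);
  NumericVector depth(n);
  IntegerVector proc(n);
  for (int i = 0; i < n; ++i) {
    double x = start[0], y = start[1], z = start[2];
    double ux = dir[0], uy = dir[1], uz = dir[2];
    double muMaj = eng.muTot.at(E) * eng.rhoMax;
    double d = 0; int pr = 0;
    if (!eng.inBox(x, y, z)) {
      double t = rayBoxEntry(x, y, z, ux, uy, uz, eng.blo, eng.bhi);
      if (t >= 0) { x += (t + 1e-6) * ux; y += (t + 1e-6) * uy; z += (t + 1e-6) * uz; }
    }
    double x0 = x, y0 = y, z0 = z;
    if (muMaj > 0) for (;;) {
      double s = -std::log(1.0 - rng.unif()) / muMaj * 10.0;
      x += s * ux; y += s * uy; z += s * uz;
      if (!eng.inBox(x, y, z)) { pr = 0; break; }
      int v = eng.voxelIndex(x, y, z);
      if (v < 0) { pr = 0; break; }
      if (rng.unif() < eng.rho[v] / eng.rhoMax) {
        d = std::sqrt((x - x0) * (x - x0) + (y - y0) * (y - y0) +
                      (z - z0) * (z - z0));
        double mC = eng.muC.at(E), mP = eng.muP.at(E),
               mPP = E > 2.0 * MEC2 ? eng.muPair.at(E) : 0.0;
        double u = rng.unif() * (mC + mP + mPP);
        pr = u < mC ? 1 : (u < mC + mP ? 2 : 3);
        break;
      }
    }
    depth[i] = pr == 0 ? -1.0 : d;
    proc[i] = pr;
  }
  return List::create(_["depth_mm"] = depth, _["process"] = proc);
}
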