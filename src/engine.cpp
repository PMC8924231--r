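// Langevin bead-spring engine: cell-list nonbonded forces (shifted
// Lennard-Jones or Wang-Frenkel), harmonic bonds with 1-2 exclusion,
// BAOAB splitting integrator, counter-based Gaussian noise so that a run is
// a pure function of (seed, step counter) independent of execution order.
//
// Units: sigma = 1 (length), kBT-scale epsilon (energy), m = 1,
// tau* = sigma*sqrt(m/eps) (time). Boxes are orthorhombic and periodic.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

// minimum image for differences of in-box coordinates (|d| < L)
static inline double mi(double d, double L, double halfL) {
  if (d > halfL) return d - L;
  if (d < -halfL) return d + L;
  return d;
}

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0,1): 53-bit mantissa plus half-ulp offset
  return ((h >> 11) * (1.0 / 9007199254740992.0)) + (1.0 / 18014398509481984.0);
}

// One standard normal per (seed, step, bead, axis); stateless.
static inline double ctr_gauss(uint64_t seed, uint64_t step, uint64_t bead,
                               uint64_t axis) {
  uint64_t k = sm64(seed ^ 0xD1B54A32D192ED03ULL);
  k = sm64(k ^ step);
  k = sm64(k ^ ((bead << 2) | axis));
  double u1 = u01(k);
  double u2 = u01(sm64(k));
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

struct PairModel {
  int form;              // 0 = Lennard-Jones, 1 = Wang-Frenkel (mu = nu = 1)
  double sigma, cutoff, cutoff2;
  bool shift;
  double eps[3][3];
  double c_shift;        // LJ energy shift per unit epsilon at the cutoff
  double wf_alpha;       // WF prefactor (depth exactly -eps at the minimum)

  void init() {
    cutoff2 = cutoff * cutoff;
    double src2 = (sigma * sigma) / cutoff2;
    double src6 = src2 * src2 * src2;
    c_shift = shift ? 4.0 * (src6 * src6 - src6) : 0.0;
    double rs2 = cutoff2 / (sigma * sigma);
    double t = 3.0 / (2.0 * (rs2 - 1.0));
    wf_alpha = 2.0 * rs2 * t * t * t;
  }

  // energy and -(dE/dr)/r for one pair at squared distance r2
  inline void eval(double r2, double e, double &en, double &fr) const {
    if (form == 0) {
      double sr2 = (sigma * sigma) / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      en = e * (4.0 * (sr12 - sr6) - c_shift);
      fr = e * 24.0 * (2.0 * sr12 - sr6) / r2;
    } else {
      double s2 = (sigma * sigma) / r2;
      double c2 = cutoff2 / r2;
      double cm1 = c2 - 1.0;
      en = e * wf_alpha * (s2 - 1.0) * cm1 * cm1;
      fr = e * wf_alpha * 2.0 * (s2 * cm1 * cm1 + 2.0 * (s2 - 1.0) * cm1 * c2) / r2;
    }
  }
};

struct Excl {
  // per-bead list of excluded partners (1-2 bonded); linear chains have <= 2
  std::vector<int> idx;
  std::vector<int> start;
  void build(int n, const IntegerMatrix &bonds) {
    std::vector<std::vector<int> > tmp(n);
    for (int b = 0; b < bonds.nrow(); ++b) {
      tmp[bonds(b, 0)].push_back(bonds(b, 1));
      tmp[bonds(b, 1)].push_back(bonds(b, 0));
    }
    start.resize(n + 1);
    start[0] = 0;
    for (int i = 0; i < n; ++i) start[i + 1] = start[i] + (int)tmp[i].size();
    idx.resize(start[n]);
    for (int i = 0; i < n; ++i)
      for (size_t k = 0; k < tmp[i].size(); ++k) idx[start[i] + k] = tmp[i][k];
  }
  inline bool excluded(int i, int j) const {
    for (int k = start[i]; k < start[i + 1]; ++k)
      if (idx[k] == j) return true;
    return false;
  }
};

class CellList {
public:
  int nc[3];
  double L[3];
  std::vector<int> head, nxt;
  bool usable;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const double box[3], double cutoff) {
    int n = (int)x.size();
    for (int d = 0; d < 3; ++d) {
      L[d] = box[d];
      nc[d] = (int)std::floor(box[d] / cutoff);
      if (nc[d] < 1) nc[d] = 1;
    }
    usable = (nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3);
    if (!usable) return;
    head.assign(nc[0] * nc[1] * nc[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampc(double v, double len, int ncd) const {
    int c = (int)std::floor(v / len * ncd);
    if (c < 0) c = 0;
    if (c >= ncd) c = ncd - 1;
    return c;
  }
  inline int cell_of(double xi, double yi, double zi) const {
    return clampc(xi, L[0], nc[0]) +
           nc[0] * (clampc(yi, L[1], nc[1]) + nc[1] * clampc(zi, L[2], nc[2]));
  }
};

// Verlet neighbor list built through the cell grid; rebuilt whenever any
// bead has moved more than half the skin since the last build, so no pair
// inside the interaction cutoff can ever be missed.
struct NeighborList {
  double skin;
  std::vector<int> list, start;     // half list: j > partners of i
  std::vector<double> rx, ry, rz;   // unwrapped positions at last build

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const double box[3],
             double cutoff, const Excl &ex) {
    int n = (int)x.size();
    double rl = cutoff + skin, rl2 = rl * rl;
    std::vector<std::vector<int> > tmp(n);
    CellList cl;
    cl.build(x, y, z, box, rl);
    auto consider = [&](int i, int j) {
      if (ex.excluded(i, j)) return;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      dx -= box[0] * std::nearbyint(dx / box[0]);
      dy -= box[1] * std::nearbyint(dy / box[1]);
      dz -= box[2] * std::nearbyint(dz / box[2]);
      if (dx * dx + dy * dy + dz * dz < rl2)
        tmp[i < j ? i : j].push_back(i < j ? j : i);
    };
    if (!cl.usable) {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) consider(i, j);
    } else {
      static const int off[13][3] = {{1, 0, 0},  {0, 1, 0},  {0, 0, 1},
                                     {1, 1, 0},  {1, -1, 0}, {1, 0, 1},
                                     {1, 0, -1}, {0, 1, 1},  {0, 1, -1},
                                     {1, 1, 1},  {1, 1, -1}, {1, -1, 1},
                                     {1, -1, -1}};
      for (int cz = 0; cz < cl.nc[2]; ++cz)
        for (int cy = 0; cy < cl.nc[1]; ++cy)
          for (int cx = 0; cx < cl.nc[0]; ++cx) {
            int c = cx + cl.nc[0] * (cy + cl.nc[1] * cz);
            for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
              for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j]) consider(i, j);
            for (int k = 0; k < 13; ++k) {
              int ox = (cx + off[k][0] + cl.nc[0]) % cl.nc[0];
              int oy = (cy + off[k][1] + cl.nc[1]) % cl.nc[1];
              int oz = (cz + off[k][2] + cl.nc[2]) % cl.nc[2];
              int c2 = ox + cl.nc[0] * (oy + cl.nc[1] * oz);
              for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
                for (int j = cl.head[c2]; j >= 0; j = cl.nxt[j]) consider(i, j);
            }
          }
    }
    start.resize(n + 1);
    start[0] = 0;
    for (int i = 0; i < n; ++i) start[i + 1] = start[i] + (int)tmp[i].size();
    list.resize(start[n]);
    for (int i = 0; i < n; ++i)
      for (size_t k = 0; k < tmp[i].size(); ++k) list[start[i] + k] = tmp[i][k];
  }

  void mark(const std::vector<double> &ux, const std::vector<double> &uy,
            const std::vector<double> &uz) {
    rx = ux; ry = uy; rz = uz;
  }

  bool stale(const std::vector<double> &ux, const std::vector<double> &uy,
             const std::vector<double> &uz) const {
    double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < ux.size(); ++i) {
      double dx = ux[i] - rx[i], dy = uy[i] - ry[i], dz = uz[i] - rz[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// Evaluate forces/energy from a prebuilt neighbor list.
static double forces_from_list(const std::vector<double> &x,
                               const std::vector<double> &y,
                               const std::vector<double> &z,
                               const double box[3], const IntegerVector &type,
                               const PairModel &pm, const IntegerMatrix &bonds,
                               double kbond, double r0, const NeighborList &nl,
                               std::vector<double> &fx, std::vector<double> &fy,
                               std::vector<double> &fz, long *overlap_count) {
  int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double pe = 0.0;
  double ov2 = 0.25 * pm.sigma * pm.sigma;
  const double B0 = box[0], B1 = box[1], B2 = box[2];
  const double h0 = 0.5 * B0, h1 = 0.5 * B1, h2 = 0.5 * B2;
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i], zi = z[i];
    double fxi = 0, fyi = 0, fzi = 0;
    int ti = type[i];
    for (int k = nl.start[i]; k < nl.start[i + 1]; ++k) {
      int j = nl.list[k];
      double dx = mi(xi - x[j], B0, h0);
      double dy = mi(yi - y[j], B1, h1);
      double dz = mi(zi - z[j], B2, h2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pm.cutoff2 || r2 <= 0.0) continue;
      if (r2 < ov2) ++(*overlap_count);
      double en, fr;
      pm.eval(r2, pm.eps[ti][type[j]], en, fr);
      pe += en;
      fxi += fr * dx; fyi += fr * dy; fzi += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    dx -= box[0] * std::nearbyint(dx / box[0]);
    dy -= box[1] * std::nearbyint(dy / box[1]);
    dz -= box[2] * std::nearbyint(dz / box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0) continue;
    double dr = r - r0;
    pe += 0.5 * kbond * dr * dr;
    double fr = -kbond * dr / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  return pe;
}

// Core force/energy evaluation. Positions must be wrapped into [0, L).
static double forces_core(const std::vector<double> &x,
                          const std::vector<double> &y,
                          const std::vector<double> &z, const double box[3],
                          const IntegerVector &type, const PairModel &pm,
                          const IntegerMatrix &bonds, double kbond, double r0,
                          const Excl &ex, std::vector<double> &fx,
                          std::vector<double> &fy, std::vector<double> &fz,
                          long *overlap_count) {
  int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double pe = 0.0;
  double ov2 = 0.25 * pm.sigma * pm.sigma;  // (0.5 sigma)^2 overlap guard

  CellList cl;
  cl.build(x, y, z, box, pm.cutoff);

  auto pair_ij = [&](int i, int j) {
    if (ex.excluded(i, j)) return;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    dx -= box[0] * std::nearbyint(dx / box[0]);
    dy -= box[1] * std::nearbyint(dy / box[1]);
    dz -= box[2] * std::nearbyint(dz / box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pm.cutoff2 || r2 <= 0.0) return;
    if (r2 < ov2) ++(*overlap_count);
    double en, fr;
    pm.eval(r2, pm.eps[type[i]][type[j]], en, fr);
    pe += en;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  };

  if (!cl.usable) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) pair_ij(i, j);
  } else {
    for (int cz = 0; cz < cl.nc[2]; ++cz)
      for (int cy = 0; cy < cl.nc[1]; ++cy)
        for (int cx = 0; cx < cl.nc[0]; ++cx) {
          int c = cx + cl.nc[0] * (cy + cl.nc[1] * cz);
          // same cell
          for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
            for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j]) pair_ij(i, j);
          // half stencil of 13 neighbor cells
          static const int off[13][3] = {
              {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
              {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
              {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
          for (int k = 0; k < 13; ++k) {
            int ox = (cx + off[k][0] + cl.nc[0]) % cl.nc[0];
            int oy = (cy + off[k][1] + cl.nc[1]) % cl.nc[1];
            int oz = (cz + off[k][2] + cl.nc[2]) % cl.nc[2];
            int c2 = ox + cl.nc[0] * (oy + cl.nc[1] * oz);
            for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
              for (int j = cl.head[c2]; j >= 0; j = cl.nxt[j]) pair_ij(i, j);
          }
        }
  }

  // harmonic bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    dx -= box[0] * std::nearbyint(dx / box[0]);
    dy -= box[1] * std::nearbyint(dy / box[1]);
    dz -= box[2] * std::nearbyint(dz / box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0) continue;
    double dr = r - r0;
    pe += 0.5 * kbond * dr * dr;
    double fr = -kbond * dr / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  return pe;
}

static void cap_forces(std::vector<double> &fx, std::vector<double> &fy,
                       std::vector<double> &fz, double cap) {
  if (cap <= 0) return;
  for (size_t i = 0; i < fx.size(); ++i) {
    double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
    if (f2 > cap * cap) {
      double s = cap / std::sqrt(f2);
      fx[i] *= s; fy[i] *= s; fz[i] *= s;
    }
  }
}

static PairModel make_pm(int form, double sigma, double cutoff, bool shift,
                         const NumericMatrix &eps) {
  PairModel pm;
  pm.form = form;
  pm.sigma = sigma;
  pm.cutoff = cutoff;
  pm.shift = shift;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) pm.eps[a][b] = eps(a, b);
  pm.init();
  return pm;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericVector box,
                        IntegerVector type, NumericMatrix eps, int form,
                        double sigma, double cutoff, bool shift,
                        IntegerMatrix bonds, double kbond, double r0,
                        double force_cap) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  double B[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0) - B[0] * std::floor(pos(i, 0) / B[0]);
    y[i] = pos(i, 1) - B[1] * std::floor(pos(i, 1) / B[1]);
    z[i] = pos(i, 2) - B[2] * std::floor(pos(i, 2) / B[2]);
  }
  PairModel pm = make_pm(form, sigma, cutoff, shift, eps);
  Excl ex;
  ex.build(n, bonds);
  long ov = 0;
  double pe = forces_core(x, y, z, B, type, pm, bonds, kbond, r0, ex, fx, fy,
                          fz, &ov);
  cap_forces(fx, fy, fz, force_cap);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return List::create(_["forces"] = F, _["energy"] = pe,
                      _["n_overlaps"] = (double)ov);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, IntegerMatrix img, NumericMatrix vel,
                      NumericVector box, IntegerVector type, NumericMatrix eps,
                      int form, double sigma, double cutoff, bool shift,
                      IntegerMatrix bonds, double kbond, double r0, double dt,
                      double gamma, double kT, int nsteps, double seed,
                      double step0, int record_stride, double force_cap,
                      double skin) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), fx(n), fy(n),
      fz(n);
  std::vector<int> ix(n), iy(n), iz(n);
  double B[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    ix[i] = img(i, 0); iy[i] = img(i, 1); iz[i] = img(i, 2);
  }
  PairModel pm = make_pm(form, sigma, cutoff, shift, eps);
  Excl ex;
  ex.build(n, bonds);

  uint64_t useed = (uint64_t)seed;
  uint64_t ustep0 = (uint64_t)step0;
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(kT * (1.0 - c1 * c1)) : 0.0;

  int nrec = (record_stride > 0) ? nsteps / record_stride : 0;
  NumericVector frames(nrec > 0 ? (R_xlen_t)nrec * n * 3 : 0);
  NumericVector rec_times(nrec), rec_pe(nrec), rec_ke(nrec);

  long ov = 0;
  NeighborList nl;
  nl.skin = (skin > 0) ? skin : 0.4;
  std::vector<double> ux(n), uy(n), uz(n);
  auto unwrap_now = [&]() {
    for (int i = 0; i < n; ++i) {
      ux[i] = x[i] + ix[i] * B[0];
      uy[i] = y[i] + iy[i] * B[1];
      uz[i] = z[i] + iz[i] * B[2];
    }
  };
  unwrap_now();
  nl.build(x, y, z, B, pm.cutoff, ex);
  nl.mark(ux, uy, uz);
  double pe = forces_from_list(x, y, z, B, type, pm, bonds, kbond, r0, nl, fx,
                               fy, fz, &ov);
  cap_forces(fx, fy, fz, force_cap);

  auto wrap1 = [](double &v, int &im, double L) {
    double s = std::floor(v / L);
    if (s != 0.0) { v -= s * L; im += (int)s; }
  };

  int irec = 0;
  for (int s = 1; s <= nsteps; ++s) {
    uint64_t gstep = ustep0 + (uint64_t)s;
    double h = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];   // B
      x[i] += h * vx[i]; y[i] += h * vy[i]; z[i] += h * vz[i];      // A
      if (gamma > 0) {                                              // O
        vx[i] = c1 * vx[i] + c2 * ctr_gauss(useed, gstep, (uint64_t)i, 0);
        vy[i] = c1 * vy[i] + c2 * ctr_gauss(useed, gstep, (uint64_t)i, 1);
        vz[i] = c1 * vz[i] + c2 * ctr_gauss(useed, gstep, (uint64_t)i, 2);
      }
      x[i] += h * vx[i]; y[i] += h * vy[i]; z[i] += h * vz[i];      // A
      wrap1(x[i], ix[i], B[0]); wrap1(y[i], iy[i], B[1]); wrap1(z[i], iz[i], B[2]);
    }
    unwrap_now();
    if (nl.stale(ux, uy, uz)) {
      nl.build(x, y, z, B, pm.cutoff, ex);
      nl.mark(ux, uy, uz);
    }
    pe = forces_from_list(x, y, z, B, type, pm, bonds, kbond, r0, nl, fx, fy,
                          fz, &ov);
    cap_forces(fx, fy, fz, force_cap);
    for (int i = 0; i < n; ++i) {
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];   // B
    }
    if (record_stride > 0 && s % record_stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        double ux = x[i] + ix[i] * B[0];
        double uy = y[i] + iy[i] * B[1];
        double uz = z[i] + iz[i] * B[2];
        if (!std::isfinite(ux) || !std::isfinite(uy) || !std::isfinite(uz))
          stop("non-finite coordinates at step %d", s);
        frames[(R_xlen_t)irec + (R_xlen_t)nrec * i] = ux;
        frames[(R_xlen_t)irec + (R_xlen_t)nrec * (i + (R_xlen_t)n)] = uy;
        frames[(R_xlen_t)irec + (R_xlen_t)nrec * (i + 2 * (R_xlen_t)n)] = uz;
      }
      rec_times[irec] = (double)(ustep0 + (uint64_t)s) * dt;
      rec_pe[irec] = pe;
      rec_ke[irec] = ke;
      ++irec;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("non-finite coordinates at end of run (step %d)", nsteps);

  NumericMatrix P(n, 3), V(n, 3);
  IntegerMatrix I(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i];
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
    I(i, 0) = ix[i]; I(i, 1) = iy[i]; I(i, 2) = iz[i];
  }
  if (nrec > 0) frames.attr("dim") = IntegerVector::create(nrec, n, 3);
  return List::create(
      _["pos"] = P, _["img"] = I, _["vel"] = V, _["pe"] = pe,
      _["frames"] = frames, _["times"] = rec_times, _["rec_pe"] = rec_pe,
      _["rec_ke"] = rec_ke, _["n_overlaps"] = (double)ov,
      _["step_count"] = (double)(ustep0 + (uint64_t)nsteps));
}

// All bead pairs closer than cutoff (minimum image); 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  double B[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0) - B[0] * std::floor(pos(i, 0) / B[0]);
    y[i] = pos(i, 1) - B[1] * std::floor(pos(i, 1) / B[1]);
    z[i] = pos(i, 2) - B[2] * std::floor(pos(i, 2) / B[2]);
  }
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  CellList cl;
  cl.build(x, y, z, B, cutoff);
  auto check = [&](int i, int j) {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    dx -= B[0] * std::nearbyint(dx / B[0]);
    dy -= B[1] * std::nearbyint(dy / B[1]);
    dz -= B[2] * std::nearbyint(dz / B[2]);
    if (dx * dx + dy * dy + dz * dz < c2) {
      ii.push_back(i + 1);
      jj.push_back(j + 1);
    }
  };
  if (!cl.usable) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) check(i, j);
  } else {
    static const int off[13][3] = {{1, 0, 0},  {0, 1, 0},  {0, 0, 1},
                                   {1, 1, 0},  {1, -1, 0}, {1, 0, 1},
                                   {1, 0, -1}, {0, 1, 1},  {0, 1, -1},
                                   {1, 1, 1},  {1, 1, -1}, {1, -1, 1},
                                   {1, -1, -1}};
    for (int cz = 0; cz < cl.nc[2]; ++cz)
      for (int cy = 0; cy < cl.nc[1]; ++cy)
        for (int cx = 0; cx < cl.nc[0]; ++cx) {
          int c = cx + cl.nc[0] * (cy + cl.nc[1] * cz);
          for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
            for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j]) check(i, j);
          for (int k = 0; k < 13; ++k) {
            int ox = (cx + off[k][0] + cl.nc[0]) % cl.nc[0];
            int oy = (cy + off[k][1] + cl.nc[1]) % cl.nc[1];
            int oz = (cz + off[k][2] + cl.nc[2]) % cl.nc[2];
            int cn = ox + cl.nc[0] * (oy + cl.nc[1] * oz);
            for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
              for (int j = cl.head[cn]; j >= 0; j = cl.nxt[j]) check(i, j);
          }
        }
  }
  IntegerMatrix out((int)ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
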