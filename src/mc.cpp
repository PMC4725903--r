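// Metropolis Monte Carlo of translational and rotational protein diffusion
// driven by tabulated thickness-mediated pair potentials, with linear-cooling
// simulated annealing, periodic boundary conditions and cell lists.
//
// Angle convention for lookups: for the pair (i, j) the tabulated
// orientations are measured relative to the center-to-center bond direction,
// w1 = omega_i - alpha(i->j), w2 = omega_j - alpha(i->j), reduced into one
// symmetry sector per species. Energies are in kBT at room temperature and
// the Metropolis temperature is in units of room temperature.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

struct PairTab {
  std::vector<double> E;     // [id + nd*(iw1 + nw1*iw2)]
  std::vector<double> dmin;  // [iw1 + nw1*iw2]
  std::vector<int> v0;       // first valid d row per orientation pair
  double d0, dd, dcut, dw1, dw2;
  int nd, nw1, nw2;
};

inline int wrap_idx(double w, double dw, int nw) {
  int i = (int)std::lround(w / dw);
  i %= nw;
  if (i < 0) i += nw;
  return i;
}

// returns energy; sets *overlap if d violates the steric minimum (or clamps
// to the contact row when clamp_steric is set)
inline double tab_lookup(const PairTab& t, double d, double w1, double w2,
                         bool* overlap, bool clamp_steric = false) {
  if (d >= t.dcut) return 0.0;
  int i1 = wrap_idx(w1, t.dw1, t.nw1);
  int i2 = wrap_idx(w2, t.dw2, t.nw2);
  int iw = i1 + t.nw1 * i2;
  if (d < t.dmin[iw]) {
    if (!clamp_steric) { *overlap = true; return 0.0; }
    d = t.dmin[iw];
  }
  double s = (d - t.d0) / t.dd;
  int i0 = (int)std::floor(s);
  int lo = t.v0[iw];
  if (i0 < lo) return t.E[lo + t.nd * iw]; // between dmin and first grid row
  if (i0 >= t.nd - 1) return t.E[(t.nd - 1) + t.nd * iw];
  double fr = s - i0;
  double e0 = t.E[i0 + t.nd * iw], e1 = t.E[i0 + 1 + t.nd * iw];
  return e0 + fr * (e1 - e0);
}

std::vector<PairTab> unpack_tables(List tables, int S) {
  std::vector<PairTab> out((size_t)S * S);
  for (int a = 0; a < S; ++a) for (int b = 0; b < S; ++b) {
    List tl = tables[a * S + b];
    PairTab& t = out[a * S + b];
    t.E = as<std::vector<double>>(tl["E"]);
    t.dmin = as<std::vector<double>>(tl["dmin"]);
    t.v0 = as<std::vector<int>>(tl["v0"]);
    t.d0 = as<double>(tl["d0"]); t.dd = as<double>(tl["dd"]);
    t.dcut = as<double>(tl["dcut"]);
    t.nd = as<int>(tl["nd"]); t.nw1 = as<int>(tl["nw1"]); t.nw2 = as<int>(tl["nw2"]);
    t.dw1 = as<double>(tl["sector1"]) / t.nw1;
    t.dw2 = as<double>(tl["sector2"]) / t.nw2;
  }
  return out;
}

struct System {
  int n, S;
  std::vector<double> x, y, w;
  std::vector<int> sp;
  double Lx, Ly;
  bool pbc;
  bool clamp_steric = false;
  std::vector<PairTab> tabs;
  double dcut_max;
  // cell list
  bool use_cells;
  int ncx, ncy;
  std::vector<int> head, nxt, cellof;

  inline void min_image(double& dx, double& dy) const {
    if (pbc) {
      dx -= Lx * std::nearbyint(dx / Lx);
      dy -= Ly * std::nearbyint(dy / Ly);
    }
  }
  inline int cell_index(double xx, double yy) const {
    int cx = (int)std::floor(xx / Lx * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(yy / Ly * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    return cx + ncx * cy;
  }
  void build_cells() {
    head.assign((size_t)ncx * ncy, -1);
    nxt.assign(n, -1);
    cellof.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_index(x[i], y[i]);
      cellof[i] = c; nxt[i] = head[c]; head[c] = i;
    }
  }
  void cell_remove(int i) {
    int c = cellof[i];
    int j = head[c];
    if (j == i) { head[c] = nxt[i]; return; }
    while (nxt[j] != i) j = nxt[j];
    nxt[j] = nxt[i];
  }
  void cell_insert(int i, int c) { cellof[i] = c; nxt[i] = head[c]; head[c] = i; }

  inline double pair_energy(int i, int j, double xi, double yi, double wi,
                            bool* overlap) const {
    double dx = x[j] - xi, dy = y[j] - yi;
    min_image(dx, dy);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d >= dcut_max) return 0.0;
    double alpha = std::atan2(dy, dx);
    const PairTab& t = tabs[sp[i] * S + sp[j]];
    return tab_lookup(t, d, wi - alpha, w[j] - alpha, overlap, clamp_steric);
  }

  // interaction energy of particle i at trial state (xi, yi, wi)
  double particle_energy(int i, double xi, double yi, double wi, bool* overlap) const {
    double E = 0.0;
    if (use_cells) {
      int cx = (int)std::floor(xi / Lx * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
      int cy = (int)std::floor(yi / Ly * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
      for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) {
        int ccx = (cx + ox + ncx) % ncx, ccy = (cy + oy + ncy) % ncy;
        for (int j = head[ccx + ncx * ccy]; j >= 0; j = nxt[j]) {
          if (j == i) continue;
          E += pair_energy(i, j, xi, yi, wi, overlap);
          if (*overlap) return 0.0;
        }
      }
    } else {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        E += pair_energy(i, j, xi, yi, wi, overlap);
        if (*overlap) return 0.0;
      }
    }
    return E;
  }

  double total_energy(bool* overlap) const {
    double E = 0.0;
    for (int i = 0; i < n; ++i) {
      E += particle_energy(i, x[i], y[i], w[i], overlap);
      if (*overlap) return 0.0;
    }
    return 0.5 * E;
  }
};

System make_system(NumericVector x, NumericVector y, NumericVector w,
                   IntegerVector sp, int S, List tables,
                   double Lx, double Ly, bool pbc, bool want_cells) {
  System s;
  s.n = x.size(); s.S = S;
  s.x = as<std::vector<double>>(x);
  s.y = as<std::vector<double>>(y);
  s.w = as<std::vector<double>>(w);
  s.sp = as<std::vector<int>>(sp); // 0-based species
  s.Lx = Lx; s.Ly = Ly; s.pbc = pbc;
  s.tabs = unpack_tables(tables, S);
  s.dcut_max = 0;
  for (auto& t : s.tabs) s.dcut_max = std::max(s.dcut_max, t.dcut);
  s.ncx = (int)std::floor(Lx / s.dcut_max);
  s.ncy = (int)std::floor(Ly / s.dcut_max);
  s.use_cells = want_cells && pbc && s.ncx >= 3 && s.ncy >= 3 && s.n > 12;
  if (s.use_cells) s.build_cells();
  if (s.pbc) {
    for (int i = 0; i < s.n; ++i) {
      s.x[i] -= Lx * std::floor(s.x[i] / Lx);
      s.y[i] -= Ly * std::floor(s.y[i] / Ly);
    }
    if (s.use_cells) s.build_cells();
  }
  return s;
}

} // namespace

// [[Rcpp::export(name = ".mc_total_energy")]]
double mc_total_energy(NumericVector x, NumericVector y, NumericVector w,
                       IntegerVector sp, int S, List tables,
                       double Lx, double Ly, bool pbc, bool use_cells,
                       bool clamp_steric) {
  System s = make_system(x, y, w, sp, S, tables, Lx, Ly, pbc, use_cells);
  s.clamp_steric = clamp_steric;
  bool overlap = false;
  double E = s.total_energy(&overlap);
  if (overlap) stop("overlap error: configuration violates steric minimum distance");
  return E;
}

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericVector x, NumericVector y, NumericVector w,
            IntegerVector sp, int S, List tables,
            double Lx, double Ly, bool pbc,
            int n_steps, double T_start, double T_end,
            double disp, double rot, bool rotational_only,
            int trace_stride, double seed) {
  System s = make_system(x, y, w, sp, S, tables, Lx, Ly, pbc, true);
  int n = s.n;
  bool overlap = false;
  double E = s.total_energy(&overlap);
  if (overlap) stop("overlap error: initial configuration violates steric minimum distance");

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  std::vector<double> trace;
  trace.reserve(n_steps / std::max(trace_stride, 1) + 2);
  long acc_d = 0, tot_d = 0, acc_r = 0, tot_r = 0;

  if (n >= 2) {
    int ntrial = rotational_only ? n : 2 * n;
    std::vector<int> order(ntrial);
    for (int k = 0; k < ntrial; ++k) order[k] = k;

    for (int step = 0; step < n_steps; ++step) {
      double T = n_steps > 1
        ? T_start + (T_end - T_start) * (double)step / (double)(n_steps - 1)
        : T_end;
      std::shuffle(order.begin(), order.end(), rng);
      for (int k = 0; k < ntrial; ++k) {
        int i = order[k] % n;
        bool is_rot = rotational_only || order[k] >= n;
        if (is_rot) {
          ++tot_r;
          double wn = s.w[i] + rot * (2.0 * U01(rng) - 1.0);
          bool ov = false;
          double e_old = s.particle_energy(i, s.x[i], s.y[i], s.w[i], &ov);
          double e_new = s.particle_energy(i, s.x[i], s.y[i], wn, &ov);
          if (ov) continue;
          double dE = e_new - e_old;
          if (dE <= 0.0 || U01(rng) < std::exp(-dE / T)) {
            const double twopi = 2.0 * M_PI;
            s.w[i] = wn - twopi * std::floor(wn / twopi);
            E += dE; ++acc_r;
          }
        } else {
          ++tot_d;
          double xn = s.x[i] + disp * (2.0 * U01(rng) - 1.0);
          double yn = s.y[i] + disp * (2.0 * U01(rng) - 1.0);
          if (s.pbc) {
            xn -= Lx * std::floor(xn / Lx);
            yn -= Ly * std::floor(yn / Ly);
          }
          bool ov = false;
          double e_old = s.particle_energy(i, s.x[i], s.y[i], s.w[i], &ov);
          double e_new = s.particle_energy(i, xn, yn, s.w[i], &ov);
          if (ov) continue; // immediate rejection on steric violation
          double dE = e_new - e_old;
          if (dE <= 0.0 || U01(rng) < std::exp(-dE / T)) {
            if (s.use_cells) {
              int cnew = s.cell_index(xn, yn);
              if (cnew != s.cellof[i]) { s.cell_remove(i); s.cell_insert(i, cnew); }
            }
            s.x[i] = xn; s.y[i] = yn;
            E += dE; ++acc_d;
          }
        }
      }
      if (trace_stride > 0 && (step % trace_stride == 0 || step == n_steps - 1))
        trace.push_back(E);
      if (s.use_cells && step > 0 && step % 10000 == 0) s.build_cells(); // guard rebuild
    }
  }

  bool ov2 = false;
  double Efinal = s.total_energy(&ov2);
  return List::create(
    _["x"] = s.x, _["y"] = s.y, _["w"] = s.w,
    _["energy"] = Efinal, _["trace"] = trace,
    _["acc_disp"] = (double)acc_d, _["tot_disp"] = (double)tot_d,
    _["acc_rot"] = (double)acc_r, _["tot_rot"] = (double)tot_r);
}
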