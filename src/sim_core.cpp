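#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

// Periodic cell list over a cubic box (head/next linked lists, no per-cell
// allocation). Coordinates are interleaved (x,y,z per bead, contiguous).
// Pair iteration walks only occupied cells and visits every candidate pair
// exactly once (13 half-space neighbour offsets + the cell itself); callers
// fall back to all-pairs when ncell < 3. Correctness of everything built on
// it is pinned to the brute-force O(n^2) oracle in the test suite.
struct CellList {
  int ncell;
  double cell;
  double box;
  std::vector<int> head, next, wrap;
  std::vector<int> occupied;  // cells made non-empty by the last fill

  CellList(double box_, double rcut, int n) : box(box_) {
    ncell = std::max(1, (int)std::floor(box / rcut));
    if (ncell > 48) ncell = 48;  // keep the head array cache-resident
    cell = box / ncell;
    head.assign((size_t)ncell * ncell * ncell, -1);
    next.assign(n, -1);
    wrap.resize(ncell + 2);
    for (int c = 0; c < ncell + 2; ++c) wrap[c] = (c - 1 + ncell) % ncell;
    occupied.reserve(n);
  }
  inline int coord_cell(double v) const {
    int c = (int)(v / cell);
    if (c < 0) c = 0;
    if (c >= ncell) c = ncell - 1;
    return c;
  }
  inline int index_of(const double *p) const {
    return (coord_cell(p[0]) * ncell + coord_cell(p[1])) * ncell +
           coord_cell(p[2]);
  }
  // O(n) refill: clear only the cells occupied last time; `idx` selects the
  // beads to insert (e.g. stickers only)
  void fill(const std::vector<double> &xx, const std::vector<int> &idx) {
    for (size_t k = 0; k < occupied.size(); ++k) head[occupied[k]] = -1;
    occupied.clear();
    for (size_t k = 0; k < idx.size(); ++k) {
      int i = idx[k];
      int c = index_of(&xx[3 * i]);
      if (head[c] < 0) occupied.push_back(c);
      next[i] = head[c];
      head[c] = i;
    }
  }
  // call f(i, j) once for every candidate pair in cells within one cell of
  // each other
  template <typename F> void for_pairs(F f) const {
    static const int half[13][3] = {
        {1, -1, -1}, {1, -1, 0}, {1, -1, 1}, {1, 0, -1}, {1, 0, 0},
        {1, 0, 1},   {1, 1, -1}, {1, 1, 0},  {1, 1, 1},  {0, 1, -1},
        {0, 1, 0},   {0, 1, 1},  {0, 0, 1}};
    int n2 = ncell * ncell;
    for (size_t k = 0; k < occupied.size(); ++k) {
      int c = occupied[k];
      int cz = c % ncell, cy = (c / ncell) % ncell, cx = c / n2;
      for (int i = head[c]; i >= 0; i = next[i])
        for (int j = next[i]; j >= 0; j = next[j]) f(i, j);
      for (int o = 0; o < 13; ++o) {
        int c2 = (wrap[cx + half[o][0] + 1] * ncell +
                  wrap[cy + half[o][1] + 1]) * ncell +
                 wrap[cz + half[o][2] + 1];
        int j0 = head[c2];
        if (j0 < 0) continue;
        for (int i = head[c]; i >= 0; i = next[i])
          for (int j = j0; j >= 0; j = next[j]) f(i, j);
      }
    }
  }
};

static inline double min_image(double d, double box) {
  d -= box * std::round(d / box);
  return d;
}

// cheap minimum image for already-wrapped coordinates (|d| < box)
static inline double min_image_wrapped(double d, double box, double hbox) {
  if (d > hbox) return d - box;
  if (d < -hbox) return d + box;
  return d;
}

static inline double dist2(const NumericMatrix &x, int i, int j, double box) {
  double dx = min_image(x(i, 0) - x(j, 0), box);
  double dy = min_image(x(i, 1) - x(j, 1), box);
  double dz = min_image(x(i, 2) - x(j, 2), box);
  return dx * dx + dy * dy + dz * dz;
}

static std::unordered_set<long long> bond_set(const IntegerMatrix &bonds, int n) {
  std::unordered_set<long long> s;
  for (int r = 0; r < bonds.nrow(); ++r) {
    long long a = bonds(r, 0) - 1, b = bonds(r, 1) - 1;
    if (a > b) std::swap(a, b);
    s.insert(a * n + b);
  }
  return s;
}

// Bead pairs (1-based, i < j) closer than `cutoff` under minimum image,
// excluding bonded pairs and same-chain pairs whose residue separation is
// below `exclusion`.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix coords, double box, double cutoff,
                                IntegerVector chain, IntegerVector residue,
                                IntegerMatrix bonds, int exclusion) {
  int n = coords.nrow();
  double c2 = cutoff * cutoff;
  std::unordered_set<long long> bonded = bond_set(bonds, n);
  std::vector<int> ai, aj;
  auto consider = [&](int i, int j) {
    if (j < i) std::swap(i, j);
    if (chain[i] == chain[j]) {
      if (std::abs(residue[i] - residue[j]) < exclusion) return;
      if (bonded.count((long long)i * n + j)) return;
    }
    if (dist2(coords, i, j, box) < c2) { ai.push_back(i + 1); aj.push_back(j + 1); }
  };
  CellList cl(box, cutoff, n);
  if (cl.ncell >= 3) {
    std::vector<double> xx(3 * (size_t)n);
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) {
      all[i] = i;
      xx[3 * i] = coords(i, 0);
      xx[3 * i + 1] = coords(i, 1);
      xx[3 * i + 2] = coords(i, 2);
    }
    cl.fill(xx, all);
    cl.for_pairs([&](int i, int j) { consider(i, j); });
  } else {
    for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) consider(i, j);
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = aj[k]; }
  return out;
}

// Overdamped Langevin sticker-spacer dynamics in a periodic cubic box.
//   dx = F D dt / kT + sqrt(2 D dt) * N(0,1)
// with U = harmonic bonds + soft repulsion (r < sigma) + Gaussian sticker
// wells scaled by chi(t). Noise comes from a mt19937_64 stream seeded with
// `seed`, so runs are bit-reproducible from the seed alone (R's RNG is too
// slow for the ~1e9 draws of a microsecond-scale run). Returns frames saved
// every `save_every` steps (not including the start frame).
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix coords0, double box, IntegerMatrix bonds,
                  double b0, double k_bond, double sigma, double eps_rep,
                  double r0, double delta, IntegerVector sticker_class,
                  NumericMatrix eps_class, double eps_bg,
                  NumericVector chi_steps,
                  double kT, double diffusion, double dt,
                  int n_steps, int save_every, double t0, int seed) {
  int n = coords0.nrow();
  double hbox = box / 2.0;
  std::unordered_set<long long> bonded = bond_set(bonds, n);
  double r_attr = r0 + 3.0 * delta;
  double sigma2 = sigma * sigma, r_attr2 = r_attr * r_attr;
  double mob = diffusion * dt / kT;         // F -> displacement
  double noise = std::sqrt(2.0 * diffusion * dt);
  bool any_attr = false;
  for (int a = 0; a < 9; ++a) if (eps_class[a] > 0) any_attr = true;
  double chi_max = 0.0;
  for (int s = 0; s < chi_steps.size(); ++s)
    if (chi_steps[s] > chi_max) chi_max = chi_steps[s];
  if (chi_max == 0.0) { any_attr = false; eps_bg = 0.0; }
  bool any_bg = eps_bg > 0;

  // interleaved working coordinates
  std::vector<double> xx(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    xx[3 * i] = coords0(i, 0);
    xx[3 * i + 1] = coords0(i, 1);
    xx[3 * i + 2] = coords0(i, 2);
  }
  std::vector<double> f(3 * (size_t)n);
  std::vector<int> all(n), stickers;
  for (int i = 0; i < n; ++i) {
    all[i] = i;
    if (sticker_class[i] > 0) stickers.push_back(i);
  }
  // interleaved bonds with precomputed indices
  std::vector<int> bi(bonds.nrow()), bj(bonds.nrow());
  for (int r = 0; r < bonds.nrow(); ++r) { bi[r] = bonds(r, 0) - 1; bj[r] = bonds(r, 1) - 1; }
  // bonds span at most 2 bead indices for 1- and 2-bead mappings; a flat
  // flag array then beats the hash set in the pair loops
  int max_span = 0;
  for (size_t r = 0; r < bi.size(); ++r)
    max_span = std::max(max_span, std::abs(bj[r] - bi[r]));
  bool use_flags = max_span <= 2;
  std::vector<unsigned char> bflag(use_flags ? 2 * (size_t)n : 0, 0);
  if (use_flags)
    for (size_t r = 0; r < bi.size(); ++r) {
      int a = std::min(bi[r], bj[r]), sp = std::abs(bj[r] - bi[r]);
      if (sp >= 1) bflag[2 * a + sp - 1] = 1;
    }
  auto is_bonded = [&](int i, int j) {  // requires i < j
    int sp = j - i;
    if (use_flags) return sp <= 2 && bflag[2 * i + sp - 1] != 0;
    return bonded.count((long long)i * n + j) > 0;
  };

  // two grids: repulsion among all beads (range sigma), attraction among
  // sticker beads only (range r_attr) -- dense phases stay tractable
  CellList cl_rep(box, sigma, n);
  CellList cl_att(box, r_attr, n);
  CellList cl_stk(box, r_attr, n);
  bool pairwise = cl_rep.ncell < 3 || cl_att.ncell < 3;
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> tsave;
  std::vector<NumericMatrix> saved;

  // force scalars s(r^2) tabulated on an r^2 grid with linear interpolation
  // (displacement contribution is s * (dx, dy, dz)); sqrt/exp per pair are
  // the hot-loop cost otherwise. Sticker and background wells share a shape,
  // so one unit-depth well table serves both.
  const int NT = 4096;
  const double dz2 = r_attr2 / NT;
  std::vector<double> tab_rep(NT + 2, 0.0), tab_well(NT + 2, 0.0);
  for (int k = 0; k <= NT + 1; ++k) {
    double d = std::sqrt(std::min((double)k * dz2, r_attr2));
    if (d < 0.03) d = 0.03;  // cap the wall force at tiny overlaps
    if (d < sigma) tab_rep[k] = 2.0 * eps_rep * (1.0 - d / sigma) / (sigma * d);
    double u = (d - r0) / delta;
    tab_well[k] = -(d - r0) / (delta * delta) * std::exp(-0.5 * u * u) / d;
  }
  auto interp = [&](const std::vector<double> &t, double z) {
    double a = z / dz2;
    int k = (int)a;
    return t[k] + (a - k) * (t[k + 1] - t[k]);
  };

  auto rep_force = [&](int i, int j) {
    if (j < i) std::swap(i, j);
    const double *pi = &xx[3 * i], *pj = &xx[3 * j];
    double dx = min_image_wrapped(pi[0] - pj[0], box, hbox);
    double dy = min_image_wrapped(pi[1] - pj[1], box, hbox);
    double dz = min_image_wrapped(pi[2] - pj[2], box, hbox);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= sigma2) return;
    if (is_bonded(i, j)) return;
    double s = interp(tab_rep, d2);
    double *gi = &f[3 * i], *gj = &f[3 * j];
    gi[0] += s * dx; gi[1] += s * dy; gi[2] += s * dz;
    gj[0] -= s * dx; gj[1] -= s * dy; gj[2] -= s * dz;
  };

  for (int step = 0; step < n_steps; ++step) {
    double chi = chi_steps.size() == 1 ? chi_steps[0] : chi_steps[step];
    std::fill(f.begin(), f.end(), 0.0);

    // bonds
    for (size_t r = 0; r < bi.size(); ++r) {
      int i = bi[r], j = bj[r];
      const double *pi = &xx[3 * i], *pj = &xx[3 * j];
      double dx = min_image_wrapped(pi[0] - pj[0], box, hbox);
      double dy = min_image_wrapped(pi[1] - pj[1], box, hbox);
      double dz = min_image_wrapped(pi[2] - pj[2], box, hbox);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-12) continue;
      double s = -k_bond * (d - b0) / d;  // along (xi - xj)
      double *gi = &f[3 * i], *gj = &f[3 * j];
      gi[0] += s * dx; gi[1] += s * dy; gi[2] += s * dz;
      gj[0] -= s * dx; gj[1] -= s * dy; gj[2] -= s * dz;
    }

    // non-bonded: soft repulsion (all beads) + sticker wells (stickers only)
    auto att_force = [&](int i, int j) {
      if (j < i) std::swap(i, j);
      const double *pi = &xx[3 * i], *pj = &xx[3 * j];
      double dx = min_image_wrapped(pi[0] - pj[0], box, hbox);
      double dy = min_image_wrapped(pi[1] - pj[1], box, hbox);
      double dz = min_image_wrapped(pi[2] - pj[2], box, hbox);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= r_attr2) return;
      double e = eps_class(sticker_class[i] - 1, sticker_class[j] - 1) * chi;
      if (e <= 0) return;
      if (is_bonded(i, j)) return;
      double s = e * interp(tab_well, d2);
      double *gi = &f[3 * i], *gj = &f[3 * j];
      gi[0] += s * dx; gi[1] += s * dy; gi[2] += s * dz;
      gj[0] -= s * dx; gj[1] -= s * dy; gj[2] -= s * dz;
    };
    auto bg_pair = [&](int i, int j) {
      if (j < i) std::swap(i, j);
      const double *pi = &xx[3 * i], *pj = &xx[3 * j];
      double dx = min_image_wrapped(pi[0] - pj[0], box, hbox);
      double dy = min_image_wrapped(pi[1] - pj[1], box, hbox);
      double dz = min_image_wrapped(pi[2] - pj[2], box, hbox);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= r_attr2) return;
      if (is_bonded(i, j)) return;
      double s = interp(tab_rep, d2) + eps_bg * chi * interp(tab_well, d2);
      double *gi = &f[3 * i], *gj = &f[3 * j];
      gi[0] += s * dx; gi[1] += s * dy; gi[2] += s * dz;
      gj[0] -= s * dx; gj[1] -= s * dy; gj[2] -= s * dz;
    };
    if (pairwise) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (any_bg && chi > 0) bg_pair(i, j); else rep_force(i, j);
          if (any_attr && chi > 0 && sticker_class[i] > 0 &&
              sticker_class[j] > 0)
            att_force(i, j);
        }
    } else if (any_bg && chi > 0) {
      // one grid at the attraction range carries repulsion + background
      cl_att.fill(xx, all);
      cl_att.for_pairs([&](int i, int j) { bg_pair(i, j); });
      if (any_attr) {
        cl_stk.fill(xx, stickers);
        cl_stk.for_pairs([&](int i, int j) { att_force(i, j); });
      }
    } else {
      cl_rep.fill(xx, all);
      cl_rep.for_pairs([&](int i, int j) { rep_force(i, j); });
      if (any_attr && chi > 0) {
        cl_stk.fill(xx, stickers);
        cl_stk.for_pairs([&](int i, int j) { att_force(i, j); });
      }
    }

    bool bad = false;
    for (int i = 0; i < 3 * n; ++i) {
      double v = xx[i] + f[i] * mob + noise * gauss(rng);
      if (!std::isfinite(v)) { bad = true; break; }
      xx[i] = v - box * std::floor(v / box);
    }
    if (bad) stop("non-finite coordinates at integration step %d", step + 1);

    if ((step + 1) % save_every == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = xx[3 * i];
        fr(i, 1) = xx[3 * i + 1];
        fr(i, 2) = xx[3 * i + 2];
      }
      saved.push_back(fr);
      tsave.push_back(t0 + (step + 1) * dt);
    }
  }

  List fl(saved.size());
  NumericVector tv(tsave.size());
  for (size_t k = 0; k < saved.size(); ++k) { fl[k] = saved[k]; tv[k] = tsave[k]; }
  return List::create(_["frames"] = fl, _["times"] = tv);
}

// Total potential energy of a configuration (finite-energy check and tests).
// [[Rcpp::export]]
double cpp_energy(NumericMatrix x, double box, IntegerMatrix bonds,
                  double b0, double k_bond, double sigma, double eps_rep,
                  double r0, double delta, IntegerVector sticker_class,
                  NumericMatrix eps_class, double eps_bg, double chi) {
  int n = x.nrow();
  std::unordered_set<long long> bonded = bond_set(bonds, n);
  double e = 0.0;
  for (int r = 0; r < bonds.nrow(); ++r) {
    int i = bonds(r, 0) - 1, j = bonds(r, 1) - 1;
    double d = std::sqrt(dist2(x, i, j, box));
    e += 0.5 * k_bond * (d - b0) * (d - b0);
  }
  double r_attr = r0 + 3.0 * delta;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (bonded.count((long long)i * n + j)) continue;
      double d = std::sqrt(dist2(x, i, j, box));
      if (d < sigma) { double t = 1.0 - d / sigma; e += eps_rep * t * t; }
      if (chi > 0 && d < r_attr) {
        double eps = eps_bg * chi;
        if (sticker_class[i] > 0 && sticker_class[j] > 0)
          eps += eps_class(sticker_class[i] - 1, sticker_class[j] - 1) * chi;
        if (eps > 0) {
          double u = (d - r0) / delta;
          e -= eps * std::exp(-0.5 * u * u);
        }
      }
    }
  return e;
}
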