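// Cellular Potts engine: energy bookkeeping, biased Metropolis copy attempts,
// and cell geometry caches on a periodic lattice.
//
// Conventions (documented in the package vignette):
//  - grid[x] = 0 for medium, n >= 1 for the n-th cell; column-major nx x ny.
//  - interface energy: sum over unordered 1st/2nd-order neighbour pairs of
//    w * J[tau,tau'] * dx with w = 1 (1st order) or `w2` (2nd order, default
//    1/2) and the same-cell pairs excluded.
//  - cell restraints: la*(a-a0)^2 + lp*p + ll*phi/max(l, dx), with a the site
//    count * dx^2, p the 1st-order boundary-edge count * dx, l the maximum
//    pairwise site-centre distance under the periodic minimal image.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double J11, J10, J00;   // J10 == J01 (symmetric interface energy)
  double la, lp, ll, a0;  // area, perimeter, length restraints
  double muh;             // haptotaxis strength
  double dx;              // lattice spacing (um)
  double w2;              // 2nd-order neighbour weight
  int connectivity;       // reject retractions that would split a cell
};

inline double Jval(const Params& pr, int tau_a, int tau_b) {
  if (tau_a && tau_b) return pr.J11;
  if (tau_a || tau_b) return pr.J10;
  return pr.J00;
}

struct Engine {
  int nx, ny, N, ncell;
  int* grid;                       // borrowed from R (modified in place)
  const int* phi;
  Params pr;
  std::vector<std::vector<int>> sites;  // site indices per cell (1-based cells)
  std::vector<int> pos;                 // position of site within its cell list
  std::vector<int> nsite;               // per-cell site count
  std::vector<int> pedge;               // per-cell boundary edge count
  std::vector<double> lmax;             // max pairwise distance (site units)
  std::vector<int> lp1, lp2;            // cached endpoints of a maximal pair
  // circular centroid accumulators
  std::vector<double> sx_c, sx_s, sy_c, sy_s;

  inline int wrap(int i, int n) const { return i < 0 ? i + n : (i >= n ? i - n : i); }
  inline int idx(int i, int j) const { return i + nx * j; }

  inline double pdist(int a, int b) const {
    int ai = a % nx, aj = a / nx, bi = b % nx, bj = b / nx;
    int di = std::abs(ai - bi); if (di > nx - di) di = nx - di;
    int dj = std::abs(aj - bj); if (dj > ny - dj) dj = ny - dj;
    return std::sqrt((double)(di * di + dj * dj));
  }

  void n1(int t, int* out) const {
    int i = t % nx, j = t / nx;
    out[0] = idx(wrap(i + 1, nx), j);
    out[1] = idx(wrap(i - 1, nx), j);
    out[2] = idx(i, wrap(j + 1, ny));
    out[3] = idx(i, wrap(j - 1, ny));
  }
  void n2(int t, int* out) const {
    int i = t % nx, j = t / nx;
    out[0] = idx(wrap(i + 1, nx), wrap(j + 1, ny));
    out[1] = idx(wrap(i + 1, nx), wrap(j - 1, ny));
    out[2] = idx(wrap(i - 1, nx), wrap(j + 1, ny));
    out[3] = idx(wrap(i - 1, nx), wrap(j - 1, ny));
  }

  void build(IntegerMatrix g, const IntegerVector& phi_, const Params& p) {
    nx = g.nrow(); ny = g.ncol(); N = nx * ny;
    grid = INTEGER(g); phi = INTEGER(phi_); pr = p;
    ncell = phi_.size();
    sites.assign(ncell + 1, {});
    pos.assign(N, -1);
    nsite.assign(ncell + 1, 0);
    pedge.assign(ncell + 1, 0);
    lmax.assign(ncell + 1, 0.0);
    lp1.assign(ncell + 1, -1); lp2.assign(ncell + 1, -1);
    sx_c.assign(ncell + 1, 0.0); sx_s.assign(ncell + 1, 0.0);
    sy_c.assign(ncell + 1, 0.0); sy_s.assign(ncell + 1, 0.0);
    for (int t = 0; t < N; ++t) {
      int s = grid[t];
      if (s < 0 || s > ncell) stop("grid holds a cell index absent from the registry");
      if (s > 0) {
        pos[t] = (int)sites[s].size();
        sites[s].push_back(t);
        nsite[s]++;
        add_centroid(s, t, +1.0);
      }
    }
    int nb[4];
    for (int t = 0; t < N; ++t) {
      int s = grid[t]; if (s == 0) continue;
      n1(t, nb);
      for (int k = 0; k < 4; ++k) if (grid[nb[k]] != s) pedge[s]++;
    }
    for (int s = 1; s <= ncell; ++s) recompute_lmax(s);
  }

  void add_centroid(int s, int t, double sign) {
    int i = t % nx, j = t / nx;
    double ax = 2.0 * M_PI * (i + 0.5) / nx, ay = 2.0 * M_PI * (j + 0.5) / ny;
    sx_c[s] += sign * std::cos(ax); sx_s[s] += sign * std::sin(ax);
    sy_c[s] += sign * std::cos(ay); sy_s[s] += sign * std::sin(ay);
  }

  // centroid in um within [0, n*dx)
  void centroid(int s, double* cx, double* cy) const {
    double tx = std::atan2(sx_s[s], sx_c[s]) / (2.0 * M_PI);
    double ty = std::atan2(sy_s[s], sy_c[s]) / (2.0 * M_PI);
    if (tx < 0) tx += 1.0;
    if (ty < 0) ty += 1.0;
    *cx = tx * nx * pr.dx; *cy = ty * ny * pr.dx;
  }

  void recompute_lmax(int s) {
    const std::vector<int>& v = sites[s];
    double best = 0.0; int b1 = -1, b2 = -1;
    int n = (int)v.size();
    if (n > 0) { b1 = b2 = v[0]; }
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double d = pdist(v[a], v[b]);
        if (d > best) { best = d; b1 = v[a]; b2 = v[b]; }
      }
    lmax[s] = best; lp1[s] = b1; lp2[s] = b2;
  }

  // l (site units) after hypothetically adding site t to cell s
  double lmax_with(int s, int t) const {
    double best = lmax[s];
    for (int a : sites[s]) { double d = pdist(t, a); if (d > best) best = d; }
    return best;
  }
  // l after hypothetically removing site t from cell s
  double lmax_without(int s, int t) const {
    if (t != lp1[s] && t != lp2[s]) return lmax[s];
    const std::vector<int>& v = sites[s];
    double best = 0.0;
    int n = (int)v.size();
    for (int a = 0; a < n; ++a) {
      if (v[a] == t) continue;
      for (int b = a + 1; b < n; ++b) {
        if (v[b] == t) continue;
        double d = pdist(v[a], v[b]);
        if (d > best) best = d;
      }
    }
    return best;
  }

  // Local connectivity guard: removing site t from cell s is safe when the
  // s-sites in t's 8-neighbour ring form a single contiguous arc (standard
  // CPM connectivity constraint; consecutive ring sites are mutually
  // adjacent, so one arc stays connected without t).
  bool retraction_splits(int t, int s) const {
    int i = t % nx, j = t / nx;
    static const int di[8] = {1, 1, 0, -1, -1, -1, 0, 1};
    static const int dj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
    int ring[8];
    for (int k = 0; k < 8; ++k) {
      ring[k] = grid[idx(wrap(i + di[k], nx), wrap(j + dj[k], ny))] == s;
    }
    int arcs = 0;
    for (int k = 0; k < 8; ++k) {
      if (ring[k] && !ring[(k + 7) % 8]) arcs++;
    }
    return arcs > 1;
  }

  inline double leff(double l_sites) const {
    double l = l_sites * pr.dx;
    return l < pr.dx ? pr.dx : l;  // floor at one lattice spacing
  }

  // Energy change for copying state `snew` onto site t (currently sold).
  // Returns +Inf for a move that would annihilate a cell.
  double delta(int t, int snew) const {
    int sold = grid[t];
    if (sold == snew) return 0.0;
    if (sold > 0 && nsite[sold] == 1) return R_PosInf;
    if (pr.connectivity && sold > 0 && retraction_splits(t, sold)) return R_PosInf;
    double dh = 0.0;
    int nb[4];
    int tau_old = sold > 0, tau_new = snew > 0;
    // interface term
    n1(t, nb);
    int same_old = 0, same_new = 0;
    for (int k = 0; k < 4; ++k) {
      int sy = grid[nb[k]]; int ty = sy > 0;
      dh += pr.dx * (Jval(pr, tau_new, ty) * (snew != sy) -
                     Jval(pr, tau_old, ty) * (sold != sy));
      if (sy == sold) same_old++;
      if (sy == snew) same_new++;
    }
    n2(t, nb);
    for (int k = 0; k < 4; ++k) {
      int sy = grid[nb[k]]; int ty = sy > 0;
      dh += pr.w2 * pr.dx * (Jval(pr, tau_new, ty) * (snew != sy) -
                             Jval(pr, tau_old, ty) * (sold != sy));
    }
    double dx2 = pr.dx * pr.dx;
    if (snew > 0) {
      double a_b = nsite[snew] * dx2, a_a = a_b + dx2;
      dh += pr.la * ((a_a - pr.a0) * (a_a - pr.a0) - (a_b - pr.a0) * (a_b - pr.a0));
      dh += pr.lp * pr.dx * ((4 - same_new) - same_new);
      if (phi[snew - 1]) {
        double lb = leff(lmax[snew]), la_ = leff(lmax_with(snew, t));
        dh += pr.ll * (1.0 / la_ - 1.0 / lb);
      }
    }
    if (sold > 0) {
      double a_b = nsite[sold] * dx2, a_a = a_b - dx2;
      dh += pr.la * ((a_a - pr.a0) * (a_a - pr.a0) - (a_b - pr.a0) * (a_b - pr.a0));
      dh += pr.lp * pr.dx * (same_old - (4 - same_old));
      if (phi[sold - 1]) {
        double lb = leff(lmax[sold]), la_ = leff(lmax_without(sold, t));
        dh += pr.ll * (1.0 / la_ - 1.0 / lb);
      }
    }
    return dh;
  }

  void apply(int t, int snew) {
    int sold = grid[t];
    if (sold == snew) return;
    int nb[4];
    n1(t, nb);
    int same_old = 0, same_new = 0;
    for (int k = 0; k < 4; ++k) {
      if (grid[nb[k]] == sold) same_old++;
      if (grid[nb[k]] == snew) same_new++;
    }
    if (sold > 0) {
      pedge[sold] += same_old - (4 - same_old);
      // swap-pop from site list
      std::vector<int>& v = sites[sold];
      int p = pos[t], last = v.back();
      v[p] = last; pos[last] = p; v.pop_back();
      nsite[sold]--;
      add_centroid(sold, t, -1.0);
      pos[t] = -1;
      if (t == lp1[sold] || t == lp2[sold]) recompute_lmax(sold);
    }
    grid[t] = snew;
    if (snew > 0) {
      pedge[snew] += (4 - same_new) - same_new;
      double best = lmax[snew]; int b1 = lp1[snew], b2 = lp2[snew];
      for (int a : sites[snew]) {
        double d = pdist(t, a);
        if (d > best) { best = d; b1 = t; b2 = a; }
      }
      if (sites[snew].empty()) { b1 = b2 = t; }
      pos[t] = (int)sites[snew].size();
      sites[snew].push_back(t);
      nsite[snew]++;
      add_centroid(snew, t, +1.0);
      lmax[snew] = best; lp1[snew] = b1; lp2[snew] = b2;
    }
  }
};

Params params_from(List par) {
  Params p;
  p.J11 = as<double>(par["J11"]);
  p.J10 = as<double>(par["J10"]);
  p.J00 = as<double>(par["J00"]);
  p.la = as<double>(par["lambda_a"]);
  p.lp = as<double>(par["lambda_p"]);
  p.ll = as<double>(par["lambda_l"]);
  p.a0 = as<double>(par["a0"]);
  p.muh = as<double>(par["mu_h"]);
  p.dx = as<double>(par["dx"]);
  p.w2 = as<double>(par["neighbor_weight_order2"]);
  p.connectivity = par.containsElementNamed("connectivity")
    ? as<int>(par["connectivity"]) : 1;
  return p;
}

}  // namespace

// [[Rcpp::export]]
double cpp_hamiltonian(IntegerMatrix grid, IntegerVector phi, List par) {
  Params pr = params_from(par);
  Engine e; e.build(grid, phi, pr);
  double H = 0.0;
  int nb[4];
  // each unordered pair visited once: take right/up (and two diagonal) moves
  for (int t = 0; t < e.N; ++t) {
    int i = t % e.nx, j = t / e.nx;
    int st = e.grid[t], tt = st > 0;
    int r = e.idx(e.wrap(i + 1, e.nx), j), u = e.idx(i, e.wrap(j + 1, e.ny));
    int d1 = e.idx(e.wrap(i + 1, e.nx), e.wrap(j + 1, e.ny));
    int d2 = e.idx(e.wrap(i + 1, e.nx), e.wrap(j - 1, e.ny));
    int sy;
    sy = e.grid[r]; H += pr.dx * Jval(pr, tt, sy > 0) * (st != sy);
    sy = e.grid[u]; H += pr.dx * Jval(pr, tt, sy > 0) * (st != sy);
    sy = e.grid[d1]; H += pr.w2 * pr.dx * Jval(pr, tt, sy > 0) * (st != sy);
    sy = e.grid[d2]; H += pr.w2 * pr.dx * Jval(pr, tt, sy > 0) * (st != sy);
  }
  (void)nb;
  double dx2 = pr.dx * pr.dx;
  for (int s = 1; s <= e.ncell; ++s) {
    if (e.nsite[s] == 0) continue;
    double a = e.nsite[s] * dx2;
    H += pr.la * (a - pr.a0) * (a - pr.a0);
    H += pr.lp * e.pedge[s] * pr.dx;
    if (phi[s - 1]) H += pr.ll / e.leff(e.lmax[s]);
  }
  return H;
}

// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix grid, IntegerVector phi, int from, int to, List par) {
  // `from`/`to` are 0-based linear site indices; proposes copying sigma[from]
  // onto site `to`.
  Params pr = params_from(par);
  Engine e; e.build(grid, phi, pr);
  if (from < 0 || from >= e.N || to < 0 || to >= e.N) stop("site index out of range");
  return e.delta(to, e.grid[from]);
}

// [[Rcpp::export]]
List cpp_cell_stats(IntegerMatrix grid, int ncell, double dx,
                    Nullable<NumericMatrix> field = R_NilValue) {
  IntegerVector phi(ncell);  // geometry does not depend on phi
  Params pr; pr.J11 = pr.J10 = pr.J00 = 0; pr.la = pr.lp = pr.ll = 0;
  pr.a0 = 0; pr.muh = 0; pr.dx = dx; pr.w2 = 0.5; pr.connectivity = 0;
  Engine e; e.build(grid, phi, pr);
  IntegerVector nsites(ncell), edges(ncell), empty_edges(ncell);
  NumericVector lmax_um(ncell), cx(ncell), cy(ncell), fsum(ncell);
  const double* f = nullptr;
  if (field.isNotNull()) {
    NumericMatrix fm(field);
    if (fm.nrow() != e.nx || fm.ncol() != e.ny) stop("field dimensions differ from grid");
    f = REAL(fm);
  }
  int nb[4];
  std::vector<int> emptye(ncell + 1, 0);
  std::vector<double> fs(ncell + 1, 0.0);
  for (int t = 0; t < e.N; ++t) {
    int s = e.grid[t]; if (s == 0) continue;
    e.n1(t, nb);
    for (int k = 0; k < 4; ++k) if (e.grid[nb[k]] == 0) emptye[s]++;
    if (f) fs[s] += f[t];
  }
  for (int s = 1; s <= ncell; ++s) {
    nsites[s - 1] = e.nsite[s];
    edges[s - 1] = e.pedge[s];
    empty_edges[s - 1] = emptye[s];
    lmax_um[s - 1] = e.lmax[s] * dx;
    fsum[s - 1] = fs[s];
    if (e.nsite[s] > 0) {
      double a, b; e.centroid(s, &a, &b); cx[s - 1] = a; cy[s - 1] = b;
    } else { cx[s - 1] = NA_REAL; cy[s - 1] = NA_REAL; }
  }
  return List::create(_["nsites"] = nsites, _["edges"] = edges,
                      _["empty_edges"] = empty_edges, _["lmax"] = lmax_um,
                      _["cx"] = cx, _["cy"] = cy, _["field_sum"] = fsum);
}

// [[Rcpp::export]]
List cpp_mcs(IntegerMatrix grid, IntegerVector phi, NumericMatrix b, List par,
             int nsweeps = 1) {
  // Performs `nsweeps` Monte-Carlo steps in place. Uses R's RNG stream so a
  // single set.seed() governs the whole run. Returns per-sweep centroids.
  Params pr = params_from(par);
  Engine e; e.build(grid, phi, pr);
  if (b.nrow() != e.nx || b.ncol() != e.ny) stop("bound-VEGF field dimensions differ from grid");
  const double* bf = REAL(b);
  int ncell = e.ncell;
  NumericVector cxs(ncell * nsweeps), cys(ncell * nsweeps);
  IntegerVector accepted(nsweeps);
  // neighbour selection: 4 first-order (weight 1) then 4 second-order (w2)
  double wtot = 4.0 + 4.0 * pr.w2;
  int nb1[4], nb2[4];
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    int acc = 0;
    for (int rep = 0; rep < e.N; ++rep) {
      int x = (int)(unif_rand() * e.N); if (x == e.N) x = e.N - 1;
      double u = unif_rand() * wtot;
      int xp;
      if (u < 4.0) { e.n1(x, nb1); xp = nb1[(int)u]; }
      else {
        int k = (int)((u - 4.0) / pr.w2); if (k > 3) k = 3;
        e.n2(x, nb2); xp = nb2[k];
      }
      int snew = e.grid[x], sold = e.grid[xp];
      if (snew == sold) continue;
      double dh = e.delta(xp, snew);
      if (!R_finite(dh) && dh > 0) continue;  // annihilation guard
      double dhm = dh;
      int taux = snew > 0, tauxp = sold > 0;
      if (taux != tauxp) dhm -= pr.muh * (bf[xp] - bf[x]);
      double p = dhm <= 0 ? 1.0 : std::exp(-dhm);
      if (p >= 1.0 || unif_rand() < p) { e.apply(xp, snew); acc++; }
    }
    accepted[sweep] = acc;
    for (int s = 1; s <= ncell; ++s) {
      double a = NA_REAL, bb = NA_REAL;
      if (e.nsite[s] > 0) e.centroid(s, &a, &bb);
      cxs[(s - 1) + ncell * sweep] = a;
      cys[(s - 1) + ncell * sweep] = bb;
    }
  }
  cxs.attr("dim") = Dimension(ncell, nsweeps);
  cys.attr("dim") = Dimension(ncell, nsweeps);
  return List::create(_["cx"] = cxs, _["cy"] = cys, _["accepted"] = accepted);
}

// [[Rcpp::export]]
IntegerMatrix cpp_apply_copy(IntegerMatrix grid, int to, int snew) {
  // test helper: returns a copy of the grid with sigma[to] := snew
  IntegerMatrix g = clone(grid);
  g[to] = snew;
  return g;
}
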