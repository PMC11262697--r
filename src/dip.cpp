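// Hartigan dip statistic, computed from its definition: the minimal
// sup-distance between the empirical cdf and the class of unimodal cdfs
// (convex on (-inf, m], concave on [m, inf), an atom allowed at the mode m).
//
// For a tolerance eps, a unimodal cdf inside the eps-tube around the
// empirical cdf exists iff some mode placement admits a convex interpolant
// of the per-point constraint intervals to its left and a concave one to
// its right, both anchored at the mode point whose value is tube-bounded.
// Candidate modes are the support points and the support-gap midpoints
// (the anchoring is what rejects well-separated bimodal samples: without
// it either hull side could ignore the flat tube across the gap). Each
// side reduces to an incremental lower-convex-hull pass over the interval
// bounds; the dip is then found by bisection on eps.
//
// Binned direction histograms are handled by spreading the observations of
// each bin uniformly across the bin width (the standard treatment of ties
// for the dip test), identically for observed samples and the bootstrap
// null.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double TOL = 1e-12;

// One left-to-right pass over points (v, [lb, ub]) maintaining the lower
// convex hull of the upper bounds. Outputs, for each prefix:
//   pre[j]:  first j points admit a convex interpolant (interior bounds)
//   preR[j]: same with the j-th point's lower bound relaxed (mode on it)
//   gapok[k]: prefix of k+1 points extended by a pseudo mode point at the
//             midpoint of gap (k, k+1) with upper bound gapub[k] stays
//             feasible (the pseudo point's lower bound never binds).
void convex_prefixes(const std::vector<double>& v, const std::vector<double>& lb,
                     const std::vector<double>& ub,
                     const std::vector<double>& gapx,
                     const std::vector<double>& gapub,
                     std::vector<char>& pre, std::vector<char>& preR,
                     std::vector<char>& gapok) {
  int m = (int)v.size();
  pre.assign(m + 1, 0); preR.assign(m + 1, 0);
  gapok.assign(m > 0 ? m - 1 : 0, 0);
  pre[0] = 1; preR[0] = 1;
  std::vector<int> h;  // hull vertex indices over (v, ub)
  bool ok = true;
  for (int k = 0; k < m && ok; ++k) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cross = (v[b] - v[a]) * (ub[k] - ub[a]) - (ub[b] - ub[a]) * (v[k] - v[a]);
      if (cross <= 0) h.pop_back(); else break;
    }
    bool viol = false;
    if (!h.empty()) {
      int a = h.back();
      for (int t = a + 1; t < k; ++t) {
        double hv = ub[a] + (ub[k] - ub[a]) * (v[t] - v[a]) / (v[k] - v[a]);
        if (hv < lb[t] - TOL) { viol = true; break; }
      }
    }
    char pR = (char)(pre[k] && !viol);
    preR[k + 1] = pR;  // hull value at v[k] equals ub[k] >= relaxed bound
    pre[k + 1] = (char)(pR && ub[k] >= lb[k] - TOL);
    h.push_back(k);
    // simulated insertion of the gap pseudo point (not committed)
    if (k < m - 1) {
      char g = pre[k + 1];
      if (g) {
        // find the surviving anchor vertex for the pseudo point
        int top = (int)h.size();
        while (top >= 2) {
          int a = h[top - 2], b = h[top - 1];
          double cross = (v[b] - v[a]) * (gapub[k] - ub[a]) -
                         (ub[b] - ub[a]) * (gapx[k] - v[a]);
          if (cross <= 0) top--; else break;
        }
        int a = h[top - 1];
        for (int t = a + 1; t <= k; ++t) {
          double hv = ub[a] + (gapub[k] - ub[a]) * (v[t] - v[a]) / (gapx[k] - v[a]);
          if (hv < lb[t] - TOL) { g = 0; break; }
        }
      }
      gapok[k] = g;
    }
    ok = pre[k + 1] != 0;
  }
}

// distinct support values v (ascending) with cumulative probabilities P
// (P[m-1] = 1); jump k has mass P[k] - P[k-1]
bool tube_feasible(const std::vector<double>& v, const std::vector<double>& P,
                   double eps) {
  int m = (int)v.size();
  if (m <= 1) return true;
  auto Pk = [&](int k) { return k < 0 ? 0.0 : P[k]; };
  // left (convex) side: interior interval at point k is [P[k]-eps, P[k-1]+eps];
  // a pseudo mode point in gap (k, k+1) carries [P[k]-eps, P[k]+eps]
  std::vector<double> lb(m), ub(m), gapx(m - 1), gapub(m - 1);
  for (int k = 0; k < m; ++k) { lb[k] = Pk(k) - eps; ub[k] = Pk(k - 1) + eps; }
  for (int k = 0; k + 1 < m; ++k) {
    gapx[k] = 0.5 * (v[k] + v[k + 1]);
    gapub[k] = Pk(k) + eps;
  }
  std::vector<char> pre, preR, gapL;
  convex_prefixes(v, lb, ub, gapx, gapub, pre, preR, gapL);
  // right (concave) side, mirrored into a convex prefix problem:
  // w = -v reversed, G' = -G; bounds swap and negate.
  std::vector<double> w(m), lb2(m), ub2(m), gapx2(m - 1), gapub2(m - 1);
  for (int k = 0; k < m; ++k) {
    int s = m - 1 - k;
    w[k] = -v[s];
    lb2[k] = -(Pk(s - 1) + eps);
    ub2[k] = -(Pk(s) - eps);
  }
  for (int k = 0; k + 1 < m; ++k) {
    // mirrored gap after w[k] is the original gap (s-1, s) with s = m-1-k;
    // the pseudo point's original interval is [P[s-1]-eps, P[s-1]+eps],
    // so its mirrored upper bound is -(P[s-1]-eps)
    int s = m - 1 - k;
    gapx2[k] = 0.5 * (w[k] + w[k + 1]);
    gapub2[k] = -(Pk(s - 1) - eps);
  }
  std::vector<char> suf, sufR, gapRm;
  convex_prefixes(w, lb2, ub2, gapx2, gapub2, suf, sufR, gapRm);
  // mode on support point j: preR[j+1] && sufR[m-j]
  for (int j = 0; j < m; ++j) {
    if (preR[j + 1] && sufR[m - j]) return true;
  }
  // mode at the midpoint of gap (j, j+1): gapL[j] on the left and the
  // mirrored gap flag on the right (mirrored index m-2-j)
  for (int j = 0; j + 1 < m; ++j) {
    if (gapL[j] && gapRm[m - 2 - j]) return true;
  }
  return false;
}

double dip_from_cdf(const std::vector<double>& v, const std::vector<double>& P) {
  if (v.size() <= 1) return 0.0;
  if (tube_feasible(v, P, 0.0)) return 0.0;
  double lo = 0.0, hi = 0.5;
  for (int it = 0; it < 50; ++it) {
    double mid = 0.5 * (lo + hi);
    if (tube_feasible(v, P, mid)) hi = mid; else lo = mid;
  }
  return hi;
}

double dip_sorted(std::vector<double>& s) {
  int n = (int)s.size();
  std::vector<double> v, P;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && s[j] == s[i]) j++;
    v.push_back(s[i]);
    P.push_back((double)j / n);
    i = j;
  }
  return dip_from_cdf(v, P);
}

// spread the counts of each bin uniformly across its unit-width bin
void spread_counts(const int* counts, int K, std::vector<double>& out) {
  out.clear();
  for (int k = 0; k < K; ++k) {
    int m = counts[k];
    for (int j = 0; j < m; ++j) {
      out.push_back((k + 1) + (j + 0.5) / m - 0.5);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
double cpp_dip(NumericVector x) {
  int n = x.size();
  if (n == 0) return NA_REAL;
  std::vector<double> s(x.begin(), x.end());
  std::sort(s.begin(), s.end());
  return dip_sorted(s);
}

// [[Rcpp::export]]
double cpp_dip_counts(IntegerVector counts) {
  // dip of a binned sample over bins 1..K with observations spread uniformly
  // within each bin
  int K = counts.size();
  long n = 0;
  for (int k = 0; k < K; ++k) n += counts[k];
  if (n == 0) return NA_REAL;
  std::vector<double> s;
  spread_counts(&counts[0], K, s);
  return dip_sorted(s);
}

// [[Rcpp::export]]
NumericVector cpp_dip_null(int n, int nbins, int B) {
  // Bootstrap null: dip of uniform multinomial samples over `nbins` bins,
  // after rotating the histogram so the modal bin sits at the centre and
  // spreading within bins, mirroring the treatment of observed samples.
  // Uses R's RNG stream.
  NumericVector out(B);
  std::vector<int> cnt(nbins), rot(nbins);
  std::vector<double> s;
  int centre = nbins / 2;  // 0-based target position of the modal bin
  for (int b = 0; b < B; ++b) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * nbins); if (k == nbins) k = nbins - 1;
      cnt[k]++;
    }
    int mode = 0;
    for (int k = 1; k < nbins; ++k) if (cnt[k] > cnt[mode]) mode = k;
    for (int k = 0; k < nbins; ++k) rot[(k - mode + centre + nbins) % nbins] = cnt[k];
    spread_counts(rot.data(), nbins, s);
    out[b] = dip_sorted(s);
  }
  return out;
}
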