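// Fast marching on a triangle mesh: first-arrival geodesic distance from a
// set of source vertices, solving the surface Eikonal equation with unit
// speed. Triangle update follows the standard Gram-matrix formulation
// (plane-wave solve with causality check), with edge-based fallback when the
// characteristic leaves the triangle (e.g. obtuse corners); optional
// Gauss-Seidel sweeps afterwards relax any fallback-induced overestimates.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline double edist(const NumericMatrix &V, int a, int b) {
  double dx = V(a, 0) - V(b, 0), dy = V(a, 1) - V(b, 1),
         dz = V(a, 2) - V(b, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Update value at vertex x from triangle (x, x1, x2) with values d1, d2.
static double tri_update(const NumericMatrix &V, int x, int x1, int x2,
                         double d1, double d2) {
  double best = INF;
  if (R_finite(d1)) best = std::min(best, d1 + edist(V, x, x1));
  if (R_finite(d2)) best = std::min(best, d2 + edist(V, x, x2));
  if (!R_finite(d1) || !R_finite(d2)) return best;
  double e1[3], e2[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = V(x1, k) - V(x, k);
    e2[k] = V(x2, k) - V(x, k);
  }
  double c11 = e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2];
  double c22 = e2[0]*e2[0] + e2[1]*e2[1] + e2[2]*e2[2];
  double c12 = e1[0]*e2[0] + e1[1]*e2[1] + e1[2]*e2[2];
  double det = c11 * c22 - c12 * c12;
  if (det <= 0) return best;
  // Q = Gram inverse; alpha = 1'Q1, beta = 1'Qd, gamma = d'Qd - 1
  double q11 = c22 / det, q22 = c11 / det, q12 = -c12 / det;
  double alpha = q11 + 2 * q12 + q22;
  double beta = q11 * d1 + q12 * (d1 + d2) + q22 * d2;
  double gamma = q11 * d1 * d1 + 2 * q12 * d1 * d2 + q22 * d2 * d2 - 1.0;
  double disc = beta * beta - alpha * gamma;
  if (disc < 0) return best;
  double U = (beta + std::sqrt(disc)) / alpha;
  if (U < std::max(d1, d2)) return best;
  // causality: characteristic must come through the triangle interior
  double l1 = q11 * (U - d1) + q12 * (U - d2);
  double l2 = q12 * (U - d1) + q22 * (U - d2);
  if (l1 <= 0 || l2 <= 0) return best;
  return std::min(best, U);
}

// [[Rcpp::export(name = ".fmm_geodesic_cpp")]]
NumericVector fmm_geodesic_cpp(NumericMatrix V, IntegerMatrix F,
                               IntegerVector sources, int nSweeps = 2) {
  int nv = V.nrow(), nf = F.nrow();
  // incident triangles per vertex
  std::vector<std::vector<int>> inc(nv);
  for (int t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k)
      inc[F(t, k) - 1].push_back(t);
  std::vector<double> d(nv, INF);
  std::vector<char> frozen(nv, 0);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> heap;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i] - 1;
    if (s < 0 || s >= nv) stop("source vertex out of range");
    d[s] = 0.0;
    heap.push(Node(0.0, s));
  }
  while (!heap.empty()) {
    Node nd = heap.top(); heap.pop();
    int v = nd.second;
    if (frozen[v]) continue;
    frozen[v] = 1;
    for (size_t ti = 0; ti < inc[v].size(); ++ti) {
      int t = inc[v][ti];
      int vs[3] = {F(t, 0) - 1, F(t, 1) - 1, F(t, 2) - 1};
      for (int k = 0; k < 3; ++k) {
        int w = vs[k];
        if (frozen[w]) continue;
        int a = vs[(k + 1) % 3], b = vs[(k + 2) % 3];
        double cand = tri_update(V, w, a, b, d[a], d[b]);
        if (cand < d[w]) {
          d[w] = cand;
          heap.push(Node(cand, w));
        }
      }
    }
  }
  // relaxation sweeps: re-apply the triangle update until fixed point
  for (int sweep = 0; sweep < nSweeps; ++sweep) {
    bool changed = false;
    for (int t = 0; t < nf; ++t) {
      int vs[3] = {F(t, 0) - 1, F(t, 1) - 1, F(t, 2) - 1};
      for (int k = 0; k < 3; ++k) {
        int w = vs[k], a = vs[(k + 1) % 3], b = vs[(k + 2) % 3];
        double cand = tri_update(V, w, a, b, d[a], d[b]);
        if (cand < d[w] - 1e-12) { d[w] = cand; changed = true; }
      }
    }
    if (!changed) break;
  }
  return NumericVector(d.begin(), d.end());
}
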