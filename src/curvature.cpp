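// Per-vertex principal curvature estimation by local quadric (Monge patch)
// fitting: vertex normal from area-weighted incident face normals (oriented
// away from the mesh centroid), neighbours projected into the tangent frame,
// height fitted as z = a x^2 + b xy + c y^2 + d x + e y, and principal
// curvatures taken from the Weingarten map. Sign convention: convex regions
// (bulging along the outward normal) have positive curvature, so a sphere of
// radius r has MC = 1/r and GC = 1/r^2.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// solve 5x5 symmetric system in place (Gaussian elimination, partial pivot)
static bool solve5(double A[5][5], double b[5], double x[5]) {
  int idx[5] = {0, 1, 2, 3, 4};
  for (int col = 0; col < 5; ++col) {
    int piv = col;
    for (int r = col + 1; r < 5; ++r)
      if (std::fabs(A[idx[r]][col]) > std::fabs(A[idx[piv]][col])) piv = r;
    std::swap(idx[col], idx[piv]);
    double p = A[idx[col]][col];
    if (std::fabs(p) < 1e-12) return false;
    for (int r = col + 1; r < 5; ++r) {
      double f = A[idx[r]][col] / p;
      for (int c = col; c < 5; ++c) A[idx[r]][c] -= f * A[idx[col]][c];
      b[idx[r]] -= f * b[idx[col]];
    }
  }
  for (int col = 4; col >= 0; --col) {
    double s = b[idx[col]];
    for (int c = col + 1; c < 5; ++c) s -= A[idx[col]][c] * x[c];
    x[col] = s / A[idx[col]][col];
  }
  return true;
}

// [[Rcpp::export(name = ".mesh_curvature_cpp")]]
List mesh_curvature_cpp(NumericMatrix V, IntegerMatrix F, List nbrs,
                        IntegerVector which) {
  int nv = V.nrow(), nf = F.nrow();
  // area-weighted vertex normals
  std::vector<double> nx(nv, 0), ny(nv, 0), nz(nv, 0);
  for (int t = 0; t < nf; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double u[3], w[3], n[3];
    for (int k = 0; k < 3; ++k) {
      u[k] = V(b, k) - V(a, k);
      w[k] = V(c, k) - V(a, k);
    }
    n[0] = u[1] * w[2] - u[2] * w[1];
    n[1] = u[2] * w[0] - u[0] * w[2];
    n[2] = u[0] * w[1] - u[1] * w[0];
    int vs[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      nx[vs[k]] += n[0]; ny[vs[k]] += n[1]; nz[vs[k]] += n[2];
    }
  }
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < nv; ++i) { cx += V(i,0); cy += V(i,1); cz += V(i,2); }
  cx /= nv; cy /= nv; cz /= nv;
  int nq = which.size();
  NumericVector kmax(nq, NA_REAL), kmin(nq, NA_REAL);
  for (int qi = 0; qi < nq; ++qi) {
    int i = which[qi] - 1;
    double n0 = nx[i], n1 = ny[i], n2 = nz[i];
    double nn = std::sqrt(n0*n0 + n1*n1 + n2*n2);
    if (nn == 0) continue;
    n0 /= nn; n1 /= nn; n2 /= nn;
    // orient away from centroid
    if (n0 * (V(i,0)-cx) + n1 * (V(i,1)-cy) + n2 * (V(i,2)-cz) < 0) {
      n0 = -n0; n1 = -n1; n2 = -n2;
    }
    // tangent frame (t1, t2, n) right-handed
    double t1[3];
    if (std::fabs(n0) < 0.9) { t1[0] = 1; t1[1] = 0; t1[2] = 0; }
    else { t1[0] = 0; t1[1] = 1; t1[2] = 0; }
    double dp = t1[0]*n0 + t1[1]*n1 + t1[2]*n2;
    t1[0] -= dp * n0; t1[1] -= dp * n1; t1[2] -= dp * n2;
    double tn = std::sqrt(t1[0]*t1[0] + t1[1]*t1[1] + t1[2]*t1[2]);
    t1[0] /= tn; t1[1] /= tn; t1[2] /= tn;
    double t2[3] = {n1 * t1[2] - n2 * t1[1],
                    n2 * t1[0] - n0 * t1[2],
                    n0 * t1[1] - n1 * t1[0]};
    IntegerVector nb = nbrs[i];
    if (nb.size() < 6) continue;  // caller reports which landmark failed
    double A[5][5] = {{0}}, rhs[5] = {0};
    for (int j = 0; j < nb.size(); ++j) {
      int v = nb[j] - 1;
      double dxv = V(v,0) - V(i,0), dyv = V(v,1) - V(i,1),
             dzv = V(v,2) - V(i,2);
      double px = dxv*t1[0] + dyv*t1[1] + dzv*t1[2];
      double py = dxv*t2[0] + dyv*t2[1] + dzv*t2[2];
      double pz = dxv*n0 + dyv*n1 + dzv*n2;
      double row[5] = {px*px, px*py, py*py, px, py};
      for (int r = 0; r < 5; ++r) {
        for (int c = 0; c < 5; ++c) A[r][c] += row[r] * row[c];
        rhs[r] += row[r] * pz;
      }
    }
    double coef[5];
    if (!solve5(A, rhs, coef)) continue;
    double a = coef[0], b = coef[1], c = coef[2], d = coef[3], e = coef[4];
    double w2 = 1 + d*d + e*e, w = std::sqrt(w2);
    // first and second fundamental forms of the Monge patch at the origin
    double E = 1 + d*d, Fq = d*e, G = 1 + e*e;
    double L = 2*a / w, M = b / w, N = 2*c / w;
    double detI = E*G - Fq*Fq;
    // Weingarten map W = II * I^{-1}; curvatures with convex-positive sign
    double K = (L*N - M*M) / detI;                       // Gaussian (of -n... sign-free)
    double H = (E*N - 2*Fq*M + G*L) / (2*detI);          // mean, z-up convention
    // flip: Monge height along outward normal means convex caps have
    // negative a, c; convex-positive requires negating both curvatures
    H = -H;
    double disc = H*H - K;
    if (disc < 0) disc = 0;
    double k1 = H + std::sqrt(disc), k2 = H - std::sqrt(disc);
    if (std::fabs(k1) >= std::fabs(k2)) { kmax[qi] = k1; kmin[qi] = k2; }
    else { kmax[qi] = k2; kmin[qi] = k1; }
  }
  return List::create(Named("kmax") = kmax, Named("kmin") = kmin);
}
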