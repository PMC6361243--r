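#include <Rcpp.h>
using namespace Rcpp;

// Minimum of d2 over atom-level groups: d2 is (sum of atoms in A-groups) x
// (atoms in B-groups); ra/rb give the 1-based residue group of each row/col.
// [[Rcpp::export]]
NumericMatrix min_by_group(NumericMatrix d2, IntegerVector ra, IntegerVector rb,
                           int ga, int gb) {
  NumericMatrix out(ga, gb);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < d2.nrow(); ++i) {
    int a = ra[i] - 1;
    for (int j = 0; j < d2.ncol(); ++j) {
      int b = rb[j] - 1;
      if (d2(i, j) < out(a, b)) out(a, b) = d2(i, j);
    }
  }
  return out;
}

// Delaunay edge set of a 3-D point cloud by empty-circumsphere tetrahedron
// enumeration.  Two points are adjacent iff they are joined by an edge of
// some tetrahedron whose circumsphere contains no other point strictly
// inside.  O(n^5) worst case; intended for chain-sized clouds (n <~ 150).
// Returns a symmetric logical adjacency matrix.  For n <= 4 every pair is
// adjacent (the tessellation is a single, possibly degenerate, simplex).
// [[Rcpp::export]]
LogicalMatrix delaunay_adjacency(NumericMatrix pts, double tol = 1e-9) {
  int n = pts.nrow();
  LogicalMatrix adj(n, n);
  if (n <= 4) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) adj(i, j) = (i != j);
    return adj;
  }
  std::vector<double> x(n), y(n), z(n), nrm(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
    nrm[i] = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
  }
  int quad[4];
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j)
      for (int k = j + 1; k < n - 1; ++k)
        for (int l = k + 1; l < n; ++l) {
          // circumsphere centre: solve 2 (p - p_i) . c = |p|^2 - |p_i|^2
          double a11 = 2 * (x[j] - x[i]), a12 = 2 * (y[j] - y[i]), a13 = 2 * (z[j] - z[i]);
          double a21 = 2 * (x[k] - x[i]), a22 = 2 * (y[k] - y[i]), a23 = 2 * (z[k] - z[i]);
          double a31 = 2 * (x[l] - x[i]), a32 = 2 * (y[l] - y[i]), a33 = 2 * (z[l] - z[i]);
          double b1 = nrm[j] - nrm[i], b2 = nrm[k] - nrm[i], b3 = nrm[l] - nrm[i];
          double det = a11 * (a22 * a33 - a23 * a32)
                     - a12 * (a21 * a33 - a23 * a31)
                     + a13 * (a21 * a32 - a22 * a31);
          if (std::fabs(det) < 1e-10) continue;  // coplanar quadruple
          double cx = (b1 * (a22 * a33 - a23 * a32)
                     - a12 * (b2 * a33 - a23 * b3)
                     + a13 * (b2 * a32 - a22 * b3)) / det;
          double cy = (a11 * (b2 * a33 - a23 * b3)
                     - b1 * (a21 * a33 - a23 * a31)
                     + a13 * (a21 * b3 - b2 * a31)) / det;
          double cz = (a11 * (a22 * b3 - b2 * a32)
                     - a12 * (a21 * b3 - b2 * a31)
                     + b1 * (a21 * a32 - a22 * a31)) / det;
          double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
          double r2 = dx * dx + dy * dy + dz * dz;
          double eps = tol * (1.0 + r2);
          bool empty = true;
          for (int m = 0; m < n && empty; ++m) {
            if (m == i || m == j || m == k || m == l) continue;
            double ex = x[m] - cx, ey = y[m] - cy, ez = z[m] - cz;
            if (ex * ex + ey * ey + ez * ez < r2 - eps) empty = false;
          }
          if (!empty) continue;
          quad[0] = i; quad[1] = j; quad[2] = k; quad[3] = l;
          for (int u = 0; u < 4; ++u)
            for (int v = u + 1; v < 4; ++v) {
              adj(quad[u], quad[v]) = true;
              adj(quad[v], quad[u]) = true;
            }
        }
  return adj;
}

// Shrake-Rupley solvent-accessible surface area.  Test points on each
// enlarged atom sphere come from a deterministic golden-spiral lattice.
// Returns per-atom SASA in A^2.
// [[Rcpp::export]]
NumericVector sasa_atoms(NumericMatrix xyz, NumericVector radii,
                         double probe = 1.4, int n_sphere = 100) {
  int n = xyz.nrow();
  NumericVector out(n);
  // golden-spiral unit sphere points
  std::vector<double> sx(n_sphere), sy(n_sphere), sz(n_sphere);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_sphere; ++p) {
    double zc = 1.0 - 2.0 * (p + 0.5) / n_sphere;
    double r = std::sqrt(std::max(0.0, 1.0 - zc * zc));
    double th = golden * p;
    sx[p] = r * std::cos(th); sy[p] = r * std::sin(th); sz[p] = zc;
  }
  for (int i = 0; i < n; ++i) {
    double Ri = radii[i] + probe;
    // neighbours that can occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double lim = Ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_sphere; ++p) {
      double px = xyz(i, 0) + Ri * sx[p], py = xyz(i, 1) + Ri * sy[p],
             pz = xyz(i, 2) + Ri * sz[p];
      bool free_pt = true;
      for (size_t q = 0; q < nb.size() && free_pt; ++q) {
        int j = nb[q];
        double Rj = radii[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) free_pt = false;
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * Ri * Ri * acc / n_sphere;
  }
  return out;
}
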