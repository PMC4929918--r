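#include <Rcpp.h>
#include "ncav_mesh.h"

using namespace Rcpp;
using ncav::MeshCore;
using ncav::Vec3;

static MeshCore make_core(const NumericMatrix& X, const IntegerMatrix& tri,
                          double L, double a0, double link_max_factor) {
  int n = X.nrow();
  std::vector<Vec3> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = Vec3(X(i, 0), X(i, 1), X(i, 2));
  std::vector<std::array<int, 3>> ts(tri.nrow());
  for (int t = 0; t < tri.nrow(); ++t)
    ts[t] = {tri(t, 0) - 1, tri(t, 1) - 1, tri(t, 2) - 1};
  MeshCore m;
  m.build(n, xs, ts, L, a0, link_max_factor);
  return m;
}

// [[Rcpp::export]]
List cpp_mesh_info(NumericMatrix X, IntegerMatrix tri, double L, double a0,
                   double link_max_factor) {
  MeshCore m = make_core(X, tri, L, a0, link_max_factor);
  int ne = m.n_edges();
  NumericVector lens(ne);
  IntegerMatrix links(ne, 2);
  for (int e = 0; e < ne; ++e) {
    links(e, 0) = m.edge_list[e].first + 1;
    links(e, 1) = m.edge_list[e].second + 1;
    lens[e] = m.link_length(m.edge_list[e].first, m.edge_list[e].second);
  }
  return List::create(_["n_vertices"] = m.n, _["n_triangles"] = m.n_tri(),
                      _["n_links"] = ne, _["euler_defect"] = m.euler_defect(),
                      _["links"] = links, _["link_lengths"] = lens,
                      _["area"] = m.total_area(),
                      _["has_boundary"] = m.has_boundary());
}

// [[Rcpp::export]]
List cpp_vertex_curvature(NumericMatrix X, IntegerMatrix tri, double L,
                          double a0, double link_max_factor) {
  MeshCore m = make_core(X, tri, L, a0, link_max_factor);
  int n = m.n;
  NumericVector Av(n), H(n), Kg(n), c1(n), c2(n);
  NumericMatrix normals(n, 3);
  LogicalVector boundary(n);
  for (int v = 0; v < n; ++v) {
    double av, h, kg;
    Vec3 nrm;
    bool ok = m.vertex_curvature(v, av, h, kg, nrm);
    boundary[v] = !ok;
    if (!ok) {
      Av[v] = H[v] = Kg[v] = c1[v] = c2[v] = NA_REAL;
      normals(v, 0) = normals(v, 1) = normals(v, 2) = NA_REAL;
      continue;
    }
    double disc = std::sqrt(std::max(h * h - kg, 0.0));
    Av[v] = av;
    H[v] = h;
    Kg[v] = kg;
    c1[v] = h + disc;
    c2[v] = h - disc;
    normals(v, 0) = nrm.x;
    normals(v, 1) = nrm.y;
    normals(v, 2) = nrm.z;
  }
  return List::create(_["A_v"] = Av, _["H"] = H, _["K"] = Kg, _["c1"] = c1,
                      _["c2"] = c2, _["normal"] = normals,
                      _["boundary"] = boundary);
}

// [[Rcpp::export]]
List cpp_helfrich(NumericMatrix X, IntegerMatrix tri, double L, double a0,
                  double link_max_factor, double kappa, double sigma) {
  MeshCore m = make_core(X, tri, L, a0, link_max_factor);
  double bend = 0, area = 0;
  for (int v = 0; v < m.n; ++v) {
    double av, h, kg;
    Vec3 nrm;
    if (!m.vertex_curvature(v, av, h, kg, nrm))
      stop("membrane energy undefined at boundary vertex %d", v + 1);
    bend += 0.5 * kappa * (2.0 * h) * (2.0 * h) * av;
    area += av;
  }
  return List::create(_["bending"] = bend, _["tension"] = sigma * area,
                      _["total"] = bend + sigma * area, _["area"] = area);
}

// Monge-gauge height field: barycentric interpolation of vertex heights onto
// a regular grid_n x grid_n periodic grid over the reference plane.
// fold_action: 0 = error when any projected triangle is inverted,
//              1 = skip inverted triangles, fill leftover points from the
//                  nearest projected vertex.
// [[Rcpp::export]]
List cpp_height_field(NumericMatrix X, IntegerMatrix tri, double L,
                      int grid_n, int fold_action) {
  if (L <= 0) stop("height field requires a periodic patch (L > 0)");
  int n = X.nrow(), nt = tri.nrow();
  double g = L / grid_n;
  NumericMatrix h(grid_n, grid_n);
  LogicalMatrix done(grid_n, grid_n);
  int n_inverted = 0;
  auto wrap = [&](double d) { return d - L * std::nearbyint(d / L); };
  auto modn = [&](int i) { int r = i % grid_n; return r < 0 ? r + grid_n : r; };
  for (int t = 0; t < nt; ++t) {
    int i0 = tri(t, 0) - 1, i1 = tri(t, 1) - 1, i2 = tri(t, 2) - 1;
    double x0 = X(i0, 0), y0 = X(i0, 1);
    double x1 = x0 + wrap(X(i1, 0) - x0), y1 = y0 + wrap(X(i1, 1) - y0);
    double x2 = x0 + wrap(X(i2, 0) - x0), y2 = y0 + wrap(X(i2, 1) - y0);
    double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (det <= 1e-12) {
      ++n_inverted;
      if (fold_action == 0)
        stop("Monge gauge violated: projected triangle %d is inverted "
             "(%d inverted in total would follow)", t + 1, n_inverted);
      continue;
    }
    double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    int jlo = static_cast<int>(std::ceil(xmin / g)) - 1;
    int jhi = static_cast<int>(std::floor(xmax / g)) + 1;
    int klo = static_cast<int>(std::ceil(ymin / g)) - 1;
    int khi = static_cast<int>(std::floor(ymax / g)) + 1;
    double tol = -1e-9 * std::abs(det);
    for (int j = jlo; j <= jhi; ++j) {
      double px = j * g;
      for (int k = klo; k <= khi; ++k) {
        double py = k * g;
        double w1 = (px - x0) * (y2 - y0) - (x2 - x0) * (py - y0);
        double w2 = (x1 - x0) * (py - y0) - (px - x0) * (y1 - y0);
        double w0 = det - w1 - w2;
        if (w0 >= tol && w1 >= tol && w2 >= tol) {
          double hv = (w0 * X(i0, 2) + w1 * X(i1, 2) + w2 * X(i2, 2)) / det;
          int jj = modn(j), kk = modn(k);
          if (!done(jj, kk) || hv > h(jj, kk)) h(jj, kk) = hv;
          done(jj, kk) = true;
        }
      }
    }
  }
  // fill any points missed by fp edge cases (or skipped folds) from the
  // nearest projected vertex
  int n_missed = 0;
  for (int j = 0; j < grid_n; ++j)
    for (int k = 0; k < grid_n; ++k)
      if (!done(j, k)) {
        ++n_missed;
        double px = j * g, py = k * g, best = 1e300, bh = 0;
        for (int v = 0; v < n; ++v) {
          double dx = wrap(X(v, 0) - px), dy = wrap(X(v, 1) - py);
          double d2 = dx * dx + dy * dy;
          if (d2 < best) { best = d2; bh = X(v, 2); }
        }
        h(j, k) = bh;
      }
  return List::create(_["h"] = h, _["n_inverted"] = n_inverted,
                      _["n_filled"] = n_missed);
}
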