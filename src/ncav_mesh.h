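#ifndef NCAV_MESH_H
#define NCAV_MESH_H

#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <stdexcept>
#include <string>

namespace ncav {

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
  Vec3 unit() const {
    double n = norm();
    return n > 0 ? Vec3(x / n, y / n, z / n) : Vec3(0, 0, 0);
  }
};

// Periodic triangulated membrane patch (torus topology when L > 0).
// Vertices carry absolute coordinates; all pairwise geometry uses the
// in-plane minimum image so the mesh may drift across the box seam.
struct MeshCore {
  int n = 0;                       // vertices
  double L = 0;                    // in-plane box side (nm); <= 0 disables PBC
  double lmin = 0, lmax = 0;       // tether bounds on link lengths
  std::vector<Vec3> X;
  std::vector<std::array<int, 3>> tri;            // oriented triangles
  std::vector<std::vector<int>> v_tri;            // vertex -> incident triangles
  std::vector<std::vector<int>> v_nbr;            // vertex -> neighbour vertices
  std::unordered_map<int64_t, std::pair<int, int>> edge_tri;  // edge -> (t1,t2)
  std::vector<std::pair<int, int>> edge_list;     // for uniform edge draws
  std::unordered_map<int64_t, int> edge_pos;      // edge -> index in edge_list

  int64_t ekey(int a, int b) const {
    if (a > b) std::swap(a, b);
    return static_cast<int64_t>(a) * n + b;
  }

  double wrap1(double d) const { return (L > 0) ? d - L * std::nearbyint(d / L) : d; }

  // minimum-image displacement from a to b (wrap in x,y only; z is free)
  Vec3 disp(const Vec3& a, const Vec3& b) const {
    return Vec3(wrap1(b.x - a.x), wrap1(b.y - a.y), b.z - a.z);
  }

  void build(int nv, const std::vector<Vec3>& xs,
             const std::vector<std::array<int, 3>>& ts, double box,
             double a0, double link_max_factor) {
    n = nv;
    X = xs;
    tri = ts;
    L = box;
    lmin = a0;
    lmax = link_max_factor * a0;
    v_tri.assign(n, {});
    v_nbr.assign(n, {});
    edge_tri.clear();
    edge_list.clear();
    edge_pos.clear();
    for (size_t t = 0; t < tri.size(); ++t) {
      for (int k = 0; k < 3; ++k) {
        int a = tri[t][k], b = tri[t][(k + 1) % 3];
        if (a < 0 || a >= n || b < 0 || b >= n || a == b)
          throw std::runtime_error("triangle references invalid vertex id");
        int64_t key = ekey(a, b);
        auto it = edge_tri.find(key);
        if (it == edge_tri.end()) {
          edge_tri[key] = {static_cast<int>(t), -1};
          edge_pos[key] = static_cast<int>(edge_list.size());
          edge_list.push_back({std::min(a, b), std::max(a, b)});
          v_nbr[a].push_back(b);
          v_nbr[b].push_back(a);
        } else {
          if (it->second.second != -1)
            throw std::runtime_error("non-manifold edge (more than two incident triangles)");
          it->second.second = static_cast<int>(t);
        }
      }
      for (int k = 0; k < 3; ++k) v_tri[tri[t][k]].push_back(static_cast<int>(t));
    }
  }

  // Rebuild all adjacency containers in an explicitly given order (used to
  // restore checkpoints bit-exactly: edge draw order and floating-point
  // summation orders depend on container order, which flips permute).
  void build_ordered(int nv, const std::vector<Vec3>& xs,
                     const std::vector<std::array<int, 3>>& ts, double box,
                     double a0, double link_max_factor,
                     const std::vector<std::array<int, 4>>& edges,
                     const std::vector<std::vector<int>>& nbr,
                     const std::vector<std::vector<int>>& vtri) {
    n = nv;
    X = xs;
    tri = ts;
    L = box;
    lmin = a0;
    lmax = link_max_factor * a0;
    v_nbr = nbr;
    v_tri = vtri;
    edge_tri.clear();
    edge_list.clear();
    edge_pos.clear();
    for (size_t e = 0; e < edges.size(); ++e) {
      int a = edges[e][0], b = edges[e][1];
      int64_t key = ekey(a, b);
      edge_tri[key] = {edges[e][2], edges[e][3]};
      edge_pos[key] = static_cast<int>(e);
      edge_list.push_back({a, b});
    }
  }

  int n_edges() const { return static_cast<int>(edge_list.size()); }
  int n_tri() const { return static_cast<int>(tri.size()); }
  int euler_defect() const { return n + n_tri() - n_edges(); }

  bool has_boundary() const {
    for (const auto& kv : edge_tri)
      if (kv.second.second < 0) return true;
    return false;
  }

  bool edge_exists(int a, int b) const { return edge_tri.count(ekey(a, b)) > 0; }

  double link_length(int a, int b) const { return disp(X[a], X[b]).norm(); }

  void tri_coords(int t, Vec3& p0, Vec3& p1, Vec3& p2) const {
    p0 = X[tri[t][0]];
    p1 = p0 + disp(p0, X[tri[t][1]]);
    p2 = p0 + disp(p0, X[tri[t][2]]);
  }

  double tri_area(int t) const {
    Vec3 p0, p1, p2;
    tri_coords(t, p0, p1, p2);
    return 0.5 * (p1 - p0).cross(p2 - p0).norm();
  }

  double total_area() const {
    double a = 0;
    for (int t = 0; t < n_tri(); ++t) a += tri_area(t);
    return a;
  }

  // Per-vertex discrete curvature: cotangent mean-curvature vector plus
  // angle-deficit Gaussian curvature; A_v is one third of the incident
  // triangle area.  Sign convention: positive mean curvature when the
  // surface bulges along the vertex normal (outward-oriented sphere of
  // radius R gives H = +1/R).  Returns false at boundary vertices.
  bool vertex_curvature(int v, double& Av, double& H, double& Kg,
                        Vec3& normal) const {
    if (v_tri[v].size() < 3 || v_tri[v].size() != v_nbr[v].size()) return false;
    double area3 = 0, angle_sum = 0, a_mixed = 0;
    Vec3 Kvec(0, 0, 0), nsum(0, 0, 0);
    const Vec3 xv = X[v];
    for (int t : v_tri[v]) {
      int i = 0;
      while (tri[t][i] != v) ++i;
      int p = tri[t][(i + 1) % 3], q = tri[t][(i + 2) % 3];
      Vec3 up = disp(xv, X[p]);   // v -> p
      Vec3 uq = disp(xv, X[q]);   // v -> q
      Vec3 pq = uq - up;          // p -> q
      Vec3 cr = up.cross(uq);
      double a2 = cr.norm();      // 2 * area
      if (a2 < 1e-12)
        throw std::runtime_error("degenerate (zero-area) triangle " + std::to_string(t + 1));
      area3 += 0.5 * a2;
      nsum = nsum + cr * 0.5;     // area-weighted face normal
      angle_sum += std::atan2(a2, up.dot(uq));
      // cot at p (angle between p->v and p->q), opposite edge (v,q)
      Vec3 pv = up * -1.0;
      double cot_p = pv.dot(pq) / pv.cross(pq).norm();
      // cot at q (angle between q->v and q->p), opposite edge (v,p)
      Vec3 qv = uq * -1.0, qp = pq * -1.0;
      double cot_q = qv.dot(qp) / qv.cross(qp).norm();
      // mean-curvature vector: edge (v,p) weighted by cot at q, (v,q) by cot at p
      Kvec = Kvec + (up * -1.0) * cot_q + (uq * -1.0) * cot_p;
      // mixed Voronoi area (obtuse-safe) used to normalize the curvature
      // estimates; the reported A_v stays the barycentric third so that
      // sum(A_v) tiles the curvilinear area exactly
      double cot_u = up.dot(uq) / a2;
      if (cot_u <= 0) a_mixed += 0.25 * a2;               // obtuse at v
      else if (cot_p <= 0 || cot_q <= 0) a_mixed += 0.125 * a2;
      else a_mixed += 0.125 * (up.dot(up) * cot_q + uq.dot(uq) * cot_p);
    }
    Av = area3 / 3.0;
    normal = nsum.unit();
    Vec3 mean_vec = Kvec * (1.0 / (2.0 * a_mixed));  // magnitude 2|H|
    H = 0.5 * mean_vec.dot(normal);
    Kg = (2.0 * M_PI - angle_sum) / a_mixed;
    return true;
  }

  // Membrane (Helfrich) energy attributed to vertex v, in kBT:
  //   E_v = kappa/2 (c1+c2)^2 A_v + sigma A_v,   with (c1+c2) = 2H
  double vertex_energy(int v, double kappa, double sigma) const {
    double Av, H, Kg;
    Vec3 nrm;
    if (!vertex_curvature(v, Av, H, Kg, nrm))
      throw std::runtime_error("membrane energy undefined at boundary vertex " +
                               std::to_string(v + 1));
    return 0.5 * kappa * (2.0 * H) * (2.0 * H) * Av + sigma * Av;
  }

  Vec3 vertex_normal(int v) const {
    Vec3 nsum(0, 0, 0);
    const Vec3 xv = X[v];
    for (int t : v_tri[v]) {
      int i = 0;
      while (tri[t][i] != v) ++i;
      Vec3 up = disp(xv, X[tri[t][(i + 1) % 3]]);
      Vec3 uq = disp(xv, X[tri[t][(i + 2) % 3]]);
      nsum = nsum + up.cross(uq);
    }
    return nsum.unit();
  }

  // Flip the diagonal of the two triangles adjacent to edge (a,b):
  //   (a,b,c) + (b,a,d)  ->  (a,d,c) + (d,b,c).
  // Connectivity checks only; returns false (mesh untouched) when the flip
  // is topologically inadmissible.  Length bounds are the caller's job.
  // The flip is an involution: flipping the new diagonal (c,d) restores the
  // original configuration (used for move rejection).
  bool flip_edge(int a, int b, int& c_out, int& d_out) {
    int64_t key = ekey(a, b);
    auto it = edge_tri.find(key);
    if (it == edge_tri.end() || it->second.second < 0) return false;
    int t1 = it->second.first, t2 = it->second.second;
    bool t1_has_ab = false;
    for (int k = 0; k < 3; ++k)
      if (tri[t1][k] == a && tri[t1][(k + 1) % 3] == b) t1_has_ab = true;
    if (!t1_has_ab) std::swap(t1, t2);
    int c = -1, d = -1;
    for (int k = 0; k < 3; ++k) {
      if (tri[t1][k] != a && tri[t1][k] != b) c = tri[t1][k];
      if (tri[t2][k] != a && tri[t2][k] != b) d = tri[t2][k];
    }
    if (c < 0 || d < 0 || c == d) return false;
    if (edge_exists(c, d)) return false;
    if (v_nbr[a].size() <= 3 || v_nbr[b].size() <= 3) return false;
    tri[t1] = {a, d, c};
    tri[t2] = {d, b, c};
    auto drop_tri = [&](int v, int t) {
      auto& vt = v_tri[v];
      for (size_t i = 0; i < vt.size(); ++i)
        if (vt[i] == t) { vt[i] = vt.back(); vt.pop_back(); return; }
    };
    drop_tri(b, t1);
    drop_tri(a, t2);
    v_tri[d].push_back(t1);
    v_tri[c].push_back(t2);
    edge_tri.erase(key);
    int pos = edge_pos[key];
    edge_pos.erase(key);
    int64_t last_key = ekey(edge_list.back().first, edge_list.back().second);
    edge_list[pos] = edge_list.back();
    edge_list.pop_back();
    if (static_cast<size_t>(pos) < edge_list.size()) edge_pos[last_key] = pos;
    int64_t kcd = ekey(c, d);
    edge_tri[kcd] = {t1, t2};
    edge_pos[kcd] = static_cast<int>(edge_list.size());
    edge_list.push_back({std::min(c, d), std::max(c, d)});
    auto reassign = [&](int u, int v, int from, int to) {
      auto& pr = edge_tri[ekey(u, v)];
      if (pr.first == from) pr.first = to;
      else if (pr.second == from) pr.second = to;
    };
    reassign(a, d, t2, t1);
    reassign(b, c, t1, t2);
    auto drop_nbr = [&](int u, int v) {
      auto& nb = v_nbr[u];
      for (size_t i = 0; i < nb.size(); ++i)
        if (nb[i] == v) { nb[i] = nb.back(); nb.pop_back(); return; }
    };
    drop_nbr(a, b);
    drop_nbr(b, a);
    v_nbr[c].push_back(d);
    v_nbr[d].push_back(c);
    c_out = c;
    d_out = d;
    return true;
  }
};

}  // namespace ncav

#endif
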