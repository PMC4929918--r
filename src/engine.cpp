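// Metropolis Monte Carlo engine for the coupled nanocarrier-membrane system.
//
// Seven elementary moves:
//   1 vertex displacement        (membrane thermal fluctuations)
//   2 link flip                  (membrane fluidity)
//   3 carrier translation
//   4 carrier rotation
//   5 receptor diffusion         (base hop to an adjacent free vertex)
//   6 receptor flexure           (configurational-bias / Rosenbluth, k trials)
//   7 bond make/break            (joint Rosenbluth regrowth of orientation +
//                                 bond label, exact enumeration of formable
//                                 ligands per trial orientation)
//
// Energies are in kBT, lengths in nm.  A formed bond is constrained to
// d <= d*: any move stretching a bond past the reaction range is rejected,
// so the bonded/unbonded label always matches the piecewise Bell potential.

#include <Rcpp.h>
#include "ncav_mesh.h"
#include <random>
#include <sstream>

using namespace Rcpp;
using ncav::MeshCore;
using ncav::Vec3;

namespace {

struct Quat {
  double w, x, y, z;
  Quat(double w_ = 1, double x_ = 0, double y_ = 0, double z_ = 0)
      : w(w_), x(x_), y(y_), z(z_) {}
  Quat mul(const Quat& o) const {
    return Quat(w * o.w - x * o.x - y * o.y - z * o.z,
                w * o.x + x * o.w + y * o.z - z * o.y,
                w * o.y - x * o.z + y * o.w + z * o.x,
                w * o.z + x * o.y - y * o.x + z * o.w);
  }
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
  Vec3 rotate(const Vec3& v) const {
    Quat p(0, v.x, v.y, v.z);
    Quat c(w, -x, -y, -z);
    Quat r = mul(p).mul(c);
    return Vec3(r.x, r.y, r.z);
  }
};

struct Engine {
  MeshCore m;
  std::vector<char> pinned;
  std::vector<int> movable;
  double kappa = 20, sigma = 0;

  int n_rec = 0;
  std::vector<int> rec_v;
  std::vector<double> rec_th, rec_ph;
  std::vector<int> rec_bond;   // ligand index or -1
  std::vector<int> v_rec;      // vertex -> receptor index or -1
  double L_an = 19, kappa_f = 1690;

  bool has_nc = false;
  Vec3 Rnc;
  Quat quat;
  double r_nc = 50, L_ab = 15;
  std::vector<Vec3> body_dirs, lig_tip;
  std::vector<int> lig_bond;   // receptor index or -1
  double H0 = -19.266, kb_bond = 241.5, dstar = 1.0, Lz = 500;
  int n_bonds = 0;

  bool bias_on = false;
  double k_bias = 0.5, dR0 = 0;

  // caches
  std::vector<double> Ev;          // per-vertex membrane energy
  std::vector<double> tarea;       // per-triangle area
  double Hm = 0, Hf = 0, Hb = 0, Ub = 0, area = 0;
  std::vector<char> in_ball, in_cyl;
  Vec3 ball_sum, cyl_sum;          // sums of min-image displacements from Rnc
  int ball_n = 0, cyl_n = 0;

  std::mt19937_64 rng;
  int k_trials = 8;
  double delta_v = 1.0, delta_vz = 1.0, delta_nc = 2.0, delta_rot = 0.2;
  int last_vertex_variant = 0;   // 0 = 3-D cube, 1 = height-only

  double runif() { return std::uniform_real_distribution<double>(0, 1)(rng); }
  int rint(int n) { return std::uniform_int_distribution<int>(0, n - 1)(rng); }

  double bond_E(double d) const { return H0 + 0.5 * kb_bond * (d - dstar) * (d - dstar); }
  double flex_E(double th) const { return 0.5 * kappa_f * th * th; }

  Vec3 rec_tip_at(int v, double th, double ph) const {
    Vec3 n = m.vertex_normal(v);
    Vec3 t1 = Vec3(1, 0, 0) - n * n.x;
    if (t1.norm() < 1e-6) { t1 = Vec3(0, 1, 0) - n * n.y; }
    t1 = t1.unit();
    Vec3 t2 = n.cross(t1);
    Vec3 dir = n * std::cos(th) + (t1 * std::cos(ph) + t2 * std::sin(ph)) * std::sin(th);
    return m.X[v] + dir * L_an;
  }

  double pair_dist(const Vec3& a, const Vec3& b) const { return m.disp(a, b).norm(); }

  void update_lig_tips() {
    for (size_t j = 0; j < body_dirs.size(); ++j)
      lig_tip[j] = Rnc + quat.rotate(body_dirs[j]) * (r_nc + L_ab);
  }

  // ---- order parameter bookkeeping -------------------------------------
  void rebuild_selection() {
    if (!has_nc) return;
    in_ball.assign(m.n, 0);
    in_cyl.assign(m.n, 0);
    ball_sum = Vec3(); cyl_sum = Vec3();
    ball_n = cyl_n = 0;
    double r2 = 4.0 * r_nc * r_nc;
    for (int v = 0; v < m.n; ++v) {
      Vec3 d = m.disp(Rnc, m.X[v]);
      double lat = d.x * d.x + d.y * d.y;
      if (lat <= r2) { in_cyl[v] = 1; cyl_sum = cyl_sum + d; ++cyl_n; }
      if (lat + d.z * d.z <= r2) { in_ball[v] = 1; ball_sum = ball_sum + d; ++ball_n; }
    }
  }

  double deltaR() const {
    if (!has_nc) return NA_REAL;
    if (ball_n > 0) return (ball_sum * (1.0 / ball_n)).norm();
    if (cyl_n > 0) return (cyl_sum * (1.0 / cyl_n)).norm();
    return NA_REAL;
  }

  double bias_E(double dR) const {
    return bias_on ? 0.5 * k_bias * (dR - dR0) * (dR - dR0) : 0.0;
  }

  // ---- full recomputation (initialisation + drift control) -------------
  void recompute_all() {
    Ev.assign(m.n, 0);
    Hm = 0;
    for (int v = 0; v < m.n; ++v) { Ev[v] = m.vertex_energy(v, kappa, sigma); Hm += Ev[v]; }
    tarea.assign(m.n_tri(), 0);
    area = 0;
    for (int t = 0; t < m.n_tri(); ++t) { tarea[t] = m.tri_area(t); area += tarea[t]; }
    Hf = 0;
    for (int r = 0; r < n_rec; ++r) Hf += flex_E(rec_th[r]);
    Hb = 0;
    if (has_nc) {
      update_lig_tips();
      for (int r = 0; r < n_rec; ++r)
        if (rec_bond[r] >= 0)
          Hb += bond_E(pair_dist(rec_tip_at(rec_v[r], rec_th[r], rec_ph[r]),
                                 lig_tip[rec_bond[r]]));
    }
    rebuild_selection();
    Ub = bias_E(deltaR());
  }

  bool metropolis(double dE) {
    if (std::isnan(dE)) throw std::runtime_error("NaN energy change in MC move");
    if (dE <= 0) return true;
    if (dE > 700) return false;
    return runif() < std::exp(-dE);
  }

  // ---- move 1: vertex displacement -------------------------------------
  // Half of the proposals displace the height only (the Monge-gauge degree
  // of freedom, unconstrained by the lower tether bound on a grid at the
  // bound); the other half are isotropic cube displacements that relax the
  // in-plane metric.  Both proposals are symmetric.
  bool move_vertex() {
    if (movable.empty()) return false;
    int v = movable[rint(static_cast<int>(movable.size()))];
    Vec3 old = m.X[v];
    last_vertex_variant = runif() < 0.5 ? 1 : 0;
    Vec3 prop = old;
    if (last_vertex_variant == 1) {
      prop.z += (runif() - 0.5) * delta_vz;
    } else {
      prop.x += (runif() - 0.5) * delta_v;
      prop.y += (runif() - 0.5) * delta_v;
      prop.z += (runif() - 0.5) * delta_v;
    }
    for (int w : m.v_nbr[v]) {
      double l = m.disp(prop, m.X[w]).norm();
      if (l < m.lmin || l > m.lmax) return false;
    }
    if (has_nc && m.disp(Rnc, prop).norm() < r_nc) return false;
    // affected vertices: v and its neighbours
    double dHm = 0;
    std::vector<std::pair<int, double>> newE;
    newE.reserve(m.v_nbr[v].size() + 1);
    m.X[v] = prop;
    bool fail = false;
    double dHb = 0;
    std::vector<std::pair<int, double>> bond_updates;  // receptor, new bond E
    try {
      double e = m.vertex_energy(v, kappa, sigma);
      newE.push_back({v, e});
      dHm += e - Ev[v];
      for (int w : m.v_nbr[v]) {
        double ew = m.vertex_energy(w, kappa, sigma);
        newE.push_back({w, ew});
        dHm += ew - Ev[w];
      }
      // bonded receptors whose base normal/position changed
      for (auto& pr : newE) {
        int r = v_rec[pr.first];
        if (r >= 0 && rec_bond[r] >= 0) {
          double dn = pair_dist(rec_tip_at(rec_v[r], rec_th[r], rec_ph[r]),
                                lig_tip[rec_bond[r]]);
          if (dn > dstar) { fail = true; break; }
          // old bond energy from pre-move geometry
          m.X[v] = old;
          double dold = pair_dist(rec_tip_at(rec_v[r], rec_th[r], rec_ph[r]),
                                  lig_tip[rec_bond[r]]);
          m.X[v] = prop;
          dHb += bond_E(dn) - bond_E(dold);
          bond_updates.push_back({r, bond_E(dn)});
        }
      }
    } catch (...) { fail = true; }
    if (fail) { m.X[v] = old; return false; }
    // bias
    double dUb = 0;
    Vec3 ball_sum_new = ball_sum, cyl_sum_new = cyl_sum;
    int ball_n_new = ball_n, cyl_n_new = cyl_n;
    char nb = 0, nc = 0;
    if (has_nc) {
      Vec3 dold = m.disp(Rnc, old), dnew = m.disp(Rnc, prop);
      double r2 = 4.0 * r_nc * r_nc;
      if (in_ball[v]) { ball_sum_new = ball_sum_new - dold; --ball_n_new; }
      if (in_cyl[v]) { cyl_sum_new = cyl_sum_new - dold; --cyl_n_new; }
      double lat = dnew.x * dnew.x + dnew.y * dnew.y;
      nc = lat <= r2;
      nb = nc && (lat + dnew.z * dnew.z <= r2);
      if (nc) { cyl_sum_new = cyl_sum_new + dnew; ++cyl_n_new; }
      if (nb) { ball_sum_new = ball_sum_new + dnew; ++ball_n_new; }
      if (bias_on) {
        double dRn = ball_n_new > 0 ? (ball_sum_new * (1.0 / ball_n_new)).norm()
                     : cyl_n_new > 0 ? (cyl_sum_new * (1.0 / cyl_n_new)).norm() : NA_REAL;
        dUb = bias_E(dRn) - Ub;
      }
    }
    double dA = 0;
    for (int t : m.v_tri[v]) dA += m.tri_area(t) - tarea[t];
    if (!metropolis(dHm + dHb + dUb)) { m.X[v] = old; return false; }
    for (auto& pr : newE) { Hm += pr.second - Ev[pr.first]; Ev[pr.first] = pr.second; }
    Hb += dHb;
    Ub += dUb;
    for (int t : m.v_tri[v]) { double a = m.tri_area(t); area += a - tarea[t]; tarea[t] = a; }
    (void)dA;
    if (has_nc) {
      ball_sum = ball_sum_new; cyl_sum = cyl_sum_new;
      ball_n = ball_n_new; cyl_n = cyl_n_new;
      in_ball[v] = nb; in_cyl[v] = nc;
    }
    (void)bond_updates;
    return true;
  }

  // ---- move 2: link flip ----------------------------------------------
  int flip_violations = 0;
  bool move_flip(bool debug) {
    int e = rint(m.n_edges());
    int a = m.edge_list[e].first, b = m.edge_list[e].second;
    // identify opposite vertices without mutating (checks in flip_edge)
    double oldE_a = Ev[a], oldE_b = Ev[b];
    int c, d;
    // save bond state of receptors at the four corners (old energies)
    if (!m.flip_edge(a, b, c, d)) return false;
    // length bound on new diagonal
    double lcd = m.link_length(c, d);
    bool fail = lcd < m.lmin || lcd > m.lmax;
    int quad[4] = {a, b, c, d};
    double dHm = 0, dHb = 0;
    std::vector<std::pair<int, double>> newE;
    if (!fail) {
      try {
        for (int u : quad) {
          double eu = m.vertex_energy(u, kappa, sigma);
          newE.push_back({u, eu});
          dHm += eu - Ev[u];
        }
        for (int u : quad) {
          int r = v_rec[u];
          if (r >= 0 && rec_bond[r] >= 0) {
            double dn = pair_dist(rec_tip_at(u, rec_th[r], rec_ph[r]),
                                  lig_tip[rec_bond[r]]);
            if (dn > dstar) { fail = true; break; }
            int cc, dd;
            m.flip_edge(c, d, cc, dd);  // temporarily restore
            double dold = pair_dist(rec_tip_at(u, rec_th[r], rec_ph[r]),
                                    lig_tip[rec_bond[r]]);
            m.flip_edge(a, b, cc, dd);
            dHb += bond_E(dn) - bond_E(dold);
          }
        }
      } catch (...) { fail = true; }
    }
    if (fail || !metropolis(dHm + dHb)) {
      int cc, dd;
      m.flip_edge(c, d, cc, dd);  // revert
      return false;
    }
    for (auto& pr : newE) { Hm += pr.second - Ev[pr.first]; Ev[pr.first] = pr.second; }
    Hb += dHb;
    // the two rebuilt triangles changed area
    auto& pr = m.edge_tri[m.ekey(c, d)];
    for (int t : {pr.first, pr.second}) {
      double an = m.tri_area(t);
      area += an - tarea[t];
      tarea[t] = an;
    }
    if (debug) {
      if (m.euler_defect() != 0) ++flip_violations;
      if (m.tri_area(pr.first) <= 0 || m.tri_area(pr.second) <= 0) ++flip_violations;
    }
    (void)oldE_a; (void)oldE_b;
    return true;
  }

  // ---- move 3: carrier translation -------------------------------------
  bool move_nc_translate() {
    if (!has_nc) return false;
    Vec3 prop(Rnc.x + (runif() - 0.5) * delta_nc,
              Rnc.y + (runif() - 0.5) * delta_nc,
              Rnc.z + (runif() - 0.5) * delta_nc);
    if (prop.z > Lz - r_nc || prop.z < -Lz) return false;
    if (m.L > 0) {
      prop.x -= m.L * std::floor(prop.x / m.L);
      prop.y -= m.L * std::floor(prop.y / m.L);
    }
    for (int v = 0; v < m.n; ++v)
      if (m.disp(prop, m.X[v]).norm() < r_nc) return false;
    // bond energies under rigid shift of ligand tips
    double dHb = 0;
    Vec3 shift = prop - Rnc;
    for (int r = 0; r < n_rec; ++r) {
      if (rec_bond[r] < 0) continue;
      Vec3 tip = rec_tip_at(rec_v[r], rec_th[r], rec_ph[r]);
      double dold = pair_dist(tip, lig_tip[rec_bond[r]]);
      double dn = pair_dist(tip, lig_tip[rec_bond[r]] + shift);
      if (dn > dstar) return false;
      dHb += bond_E(dn) - bond_E(dold);
    }
    // bias: rebuild selection about the proposed centre
    double dUb = 0;
    Vec3 old = Rnc;
    if (bias_on) {
      Rnc = prop;
      rebuild_selection();
      double dRn = deltaR();
      Rnc = old;
      dUb = bias_E(dRn) - Ub;
    }
    if (!metropolis(dHb + dUb)) {
      if (bias_on) rebuild_selection();
      return false;
    }
    Rnc = prop;
    for (size_t j = 0; j < lig_tip.size(); ++j) lig_tip[j] = lig_tip[j] + shift;
    rebuild_selection();
    Hb += dHb;
    Ub += dUb;
    return true;
  }

  // ---- move 4: carrier rotation ----------------------------------------
  bool move_nc_rotate() {
    if (!has_nc) return false;
    double ang = (runif() - 0.5) * delta_rot;
    double u1 = runif(), u2 = runif();
    double zz = 2 * u1 - 1, rr = std::sqrt(std::max(0.0, 1 - zz * zz));
    Vec3 axis(rr * std::cos(2 * M_PI * u2), rr * std::sin(2 * M_PI * u2), zz);
    Quat dq(std::cos(ang / 2), axis.x * std::sin(ang / 2),
            axis.y * std::sin(ang / 2), axis.z * std::sin(ang / 2));
    Quat qn = dq.mul(quat);
    qn.normalize();
    double dHb = 0;
    std::vector<Vec3> tips_new(lig_tip.size());
    for (size_t j = 0; j < body_dirs.size(); ++j)
      tips_new[j] = Rnc + qn.rotate(body_dirs[j]) * (r_nc + L_ab);
    for (int r = 0; r < n_rec; ++r) {
      if (rec_bond[r] < 0) continue;
      Vec3 tip = rec_tip_at(rec_v[r], rec_th[r], rec_ph[r]);
      double dold = pair_dist(tip, lig_tip[rec_bond[r]]);
      double dn = pair_dist(tip, tips_new[rec_bond[r]]);
      if (dn > dstar) return false;
      dHb += bond_E(dn) - bond_E(dold);
    }
    if (!metropolis(dHb)) return false;
    quat = qn;
    lig_tip = tips_new;
    Hb += dHb;
    return true;
  }

  // ---- move 5: receptor diffusion --------------------------------------
  bool move_rec_hop() {
    if (n_rec == 0) return false;
    int r = rint(n_rec);
    int v = rec_v[r];
    const auto& nb = m.v_nbr[v];
    int w = nb[rint(static_cast<int>(nb.size()))];
    if (v_rec[w] >= 0) return false;  // occupied
    double dHb = 0;
    if (rec_bond[r] >= 0) {
      double dold = pair_dist(rec_tip_at(v, rec_th[r], rec_ph[r]), lig_tip[rec_bond[r]]);
      double dn = pair_dist(rec_tip_at(w, rec_th[r], rec_ph[r]), lig_tip[rec_bond[r]]);
      if (dn > dstar) return false;
      dHb += bond_E(dn) - bond_E(dold);
    }
    if (!metropolis(dHb)) return false;
    v_rec[v] = -1;
    v_rec[w] = r;
    rec_v[r] = w;
    Hb += dHb;
    return true;
  }

  // ---- configurational-bias helpers ------------------------------------
  struct TrialOption { double th, ph, logw; int lig; };  // lig -1 = unbonded

  // enumerate composite options for one trial orientation of receptor r.
  // bond_move = true : unbonded option plus every formable free ligand;
  // bond_move = false: the current bond label is frozen (pure flexure), so a
  //                    bonded receptor's trial is weighted by flexure + bond
  //                    (zero weight when the trial tip violates d <= d*).
  // Flexure trial orientations are drawn from the flexural Boltzmann
  // distribution itself when kappa_f is appreciable (Rayleigh draw with a
  // sin(theta)/theta rejection step), in which case the flexure factor
  // cancels out of the Rosenbluth weights and only bond factors remain.
  // For floppy receptors (kappa_f < 5 kBT) trials are uniform on the
  // hemisphere and the flexure energy stays in the weight.
  bool biased_flexure() const { return kappa_f >= 5.0; }

  double sample_trial_theta() {
    if (!biased_flexure()) return std::acos(runif());
    double sig = 1.0 / std::sqrt(kappa_f);
    for (int it = 0; it < 1000; ++it) {
      double th = sig * std::sqrt(-2.0 * std::log(1.0 - runif()));
      if (th <= M_PI / 2 && runif() < std::sin(th) / th) return th;
    }
    return sig;  // unreachable in practice
  }

  void trial_options(int r, double th, double ph, bool bond_move,
                     const Vec3& base, const Vec3& n, const Vec3& t1,
                     const Vec3& t2, bool in_reach,
                     std::vector<TrialOption>& out) const {
    double lw_f = biased_flexure() ? 0.0 : -flex_E(th);
    Vec3 dir = n * std::cos(th) + (t1 * std::cos(ph) + t2 * std::sin(ph)) * std::sin(th);
    Vec3 tip = base + dir * L_an;
    if (!bond_move) {
      int j0 = rec_bond[r];
      if (j0 < 0) {
        out.push_back({th, ph, lw_f, -1});
      } else {
        double d = pair_dist(tip, lig_tip[j0]);
        if (d <= dstar) out.push_back({th, ph, lw_f - bond_E(d), j0});
      }
      return;
    }
    out.push_back({th, ph, lw_f, -1});
    if (!has_nc || !in_reach) return;
    for (size_t j = 0; j < lig_tip.size(); ++j) {
      int lb = lig_bond[j];
      if (lb >= 0 && lb != r) continue;  // ligand taken by another receptor
      double d = pair_dist(tip, lig_tip[j]);
      if (d <= dstar) out.push_back({th, ph, lw_f - bond_E(d), static_cast<int>(j)});
    }
  }

  // Rosenbluth regrowth of receptor orientation (and, for bond_move, the
  // bond label).  Returns true when the move is accepted.
  bool cbmc_receptor(int r, bool bond_move) {
    int v = rec_v[r];
    Vec3 n = m.vertex_normal(v);
    Vec3 t1 = Vec3(1, 0, 0) - n * n.x;
    if (t1.norm() < 1e-6) t1 = Vec3(0, 1, 0) - n * n.y;
    t1 = t1.unit();
    Vec3 t2 = n.cross(t1);
    const Vec3& base = m.X[v];
    bool in_reach = has_nc &&
        m.disp(Rnc, base).norm() <= r_nc + L_ab + L_an + dstar;
    std::vector<TrialOption> new_opts, old_opts;
    for (int t = 0; t < k_trials; ++t) {
      double th = sample_trial_theta(), ph = 2 * M_PI * runif();
      trial_options(r, th, ph, bond_move, base, n, t1, t2, in_reach, new_opts);
    }
    // old trial set: current orientation plus k-1 fresh orientations
    trial_options(r, rec_th[r], rec_ph[r], bond_move, base, n, t1, t2,
                  in_reach, old_opts);
    for (int t = 0; t < k_trials - 1; ++t) {
      double th = sample_trial_theta(), ph = 2 * M_PI * runif();
      trial_options(r, th, ph, bond_move, base, n, t1, t2, in_reach, old_opts);
    }
    if (new_opts.empty() || old_opts.empty()) return false;
    double shift = -1e300;
    for (auto& o : new_opts) shift = std::max(shift, o.logw);
    for (auto& o : old_opts) shift = std::max(shift, o.logw);
    double Wnew = 0, Wold = 0;
    for (auto& o : new_opts) Wnew += std::exp(o.logw - shift);
    for (auto& o : old_opts) Wold += std::exp(o.logw - shift);
    double u = runif() * Wnew, cumw = 0;
    size_t pick = new_opts.size() - 1;
    for (size_t i = 0; i < new_opts.size(); ++i) {
      cumw += std::exp(new_opts[i].logw - shift);
      if (u <= cumw) { pick = i; break; }
    }
    if (runif() >= Wnew / Wold) return false;
    const TrialOption& sel = new_opts[pick];
    // commit
    Hf += flex_E(sel.th) - flex_E(rec_th[r]);
    auto bond_d = [&](double th, double ph, int j) {
      Vec3 dir = n * std::cos(th) + (t1 * std::cos(ph) + t2 * std::sin(ph)) * std::sin(th);
      return pair_dist(base + dir * L_an, lig_tip[j]);
    };
    int old_lig = rec_bond[r];
    if (old_lig >= 0) Hb -= bond_E(bond_d(rec_th[r], rec_ph[r], old_lig));
    if (sel.lig >= 0) Hb += bond_E(bond_d(sel.th, sel.ph, sel.lig));
    if (bond_move) {
      if (old_lig >= 0) { lig_bond[old_lig] = -1; --n_bonds; }
      rec_bond[r] = sel.lig;
      if (sel.lig >= 0) { lig_bond[sel.lig] = r; ++n_bonds; }
    }
    rec_th[r] = sel.th;
    rec_ph[r] = sel.ph;
    return true;
  }

  bool move_flexure() {
    if (n_rec == 0) return false;
    return cbmc_receptor(rint(n_rec), false);
  }

  bool move_bond() {
    if (n_rec == 0 || !has_nc) return false;
    return cbmc_receptor(rint(n_rec), true);
  }
};

}  // namespace

static Engine* unpack(List state, List cfg) {
  Engine* E = new Engine();
  NumericMatrix X = state["vertices"];
  IntegerMatrix tri = state["triangles"];
  double L = as<double>(state["L"]);
  double a0 = as<double>(state["a0"]);
  double lmf = as<double>(state["link_max_factor"]);
  int n = X.nrow();
  std::vector<Vec3> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = Vec3(X(i, 0), X(i, 1), X(i, 2));
  std::vector<std::array<int, 3>> ts(tri.nrow());
  for (int t = 0; t < tri.nrow(); ++t)
    ts[t] = {tri(t, 0) - 1, tri(t, 1) - 1, tri(t, 2) - 1};
  if (state.containsElementNamed("adjacency") &&
      !Rf_isNull(state["adjacency"])) {
    List adj = state["adjacency"];
    IntegerMatrix em = adj["edges"];
    std::vector<std::array<int, 4>> edges(em.nrow());
    for (int e = 0; e < em.nrow(); ++e)
      edges[e] = {em(e, 0) - 1, em(e, 1) - 1, em(e, 2) - 1, em(e, 3) - 1};
    auto unflatten = [&](IntegerVector flat, IntegerVector off) {
      std::vector<std::vector<int>> out(n);
      for (int v = 0; v < n; ++v)
        for (int i = off[v]; i < off[v + 1]; ++i)
          out[v].push_back(flat[i] - 1);
      return out;
    };
    E->m.build_ordered(n, xs, ts, L, a0, lmf, edges,
                       unflatten(adj["nbr"], adj["nbr_off"]),
                       unflatten(adj["vtri"], adj["vtri_off"]));
  } else {
    E->m.build(n, xs, ts, L, a0, lmf);
  }
  E->kappa = as<double>(state["kappa"]);
  E->sigma = as<double>(state["sigma"]);
  E->pinned.assign(n, 0);
  IntegerVector pv = state["pinned"];
  for (int i = 0; i < pv.size(); ++i) E->pinned[pv[i] - 1] = 1;
  for (int v = 0; v < n; ++v)
    if (!E->pinned[v]) E->movable.push_back(v);
  // receptors
  IntegerVector rv = state["rec_vertex"];
  NumericVector rth = state["rec_theta"], rph = state["rec_phi"];
  IntegerVector rb = state["rec_bond"];
  E->n_rec = rv.size();
  E->rec_v.resize(E->n_rec);
  E->rec_th.resize(E->n_rec);
  E->rec_ph.resize(E->n_rec);
  E->rec_bond.resize(E->n_rec);
  E->v_rec.assign(n, -1);
  for (int r = 0; r < E->n_rec; ++r) {
    E->rec_v[r] = rv[r] - 1;
    E->rec_th[r] = rth[r];
    E->rec_ph[r] = rph[r];
    E->rec_bond[r] = rb[r] - 1;  // R uses 0 = none
    if (E->v_rec[E->rec_v[r]] >= 0) { delete E; throw std::runtime_error("two receptors share a vertex"); }
    E->v_rec[E->rec_v[r]] = r;
  }
  E->L_an = as<double>(state["L_an"]);
  E->kappa_f = as<double>(state["kappa_f"]);
  E->has_nc = as<bool>(state["has_nc"]);
  if (E->has_nc) {
    NumericVector rc = state["R_nc"];
    E->Rnc = Vec3(rc[0], rc[1], rc[2]);
    NumericVector qv = state["quat"];
    E->quat = Quat(qv[0], qv[1], qv[2], qv[3]);
    E->r_nc = as<double>(state["r_nc"]);
    E->L_ab = as<double>(state["L_ab"]);
    NumericMatrix bd = state["ligand_dirs"];
    E->body_dirs.resize(bd.nrow());
    for (int j = 0; j < bd.nrow(); ++j)
      E->body_dirs[j] = Vec3(bd(j, 0), bd(j, 1), bd(j, 2)).unit();
    E->lig_tip.resize(bd.nrow());
    IntegerVector lb = state["lig_bond"];
    E->lig_bond.resize(lb.size());
    for (int j = 0; j < lb.size(); ++j) E->lig_bond[j] = lb[j] - 1;
    E->H0 = as<double>(state["H0"]);
    E->kb_bond = as<double>(state["kappa_b"]);
    E->dstar = as<double>(state["d_star"]);
    E->Lz = as<double>(state["L_z"]);
    E->n_bonds = 0;
    for (int r = 0; r < E->n_rec; ++r)
      if (E->rec_bond[r] >= 0) ++E->n_bonds;
  }
  // config
  E->k_trials = as<int>(cfg["k_trials"]);
  NumericVector deltas = cfg["deltas"];
  E->delta_v = deltas[0];
  E->delta_vz = deltas[1];
  E->delta_nc = deltas[2];
  E->delta_rot = deltas[3];
  E->bias_on = as<bool>(cfg["bias_on"]);
  if (E->bias_on) {
    E->k_bias = as<double>(cfg["k_bias"]);
    E->dR0 = as<double>(cfg["dR0"]);
  }
  // RNG
  std::string rst = as<std::string>(cfg["rng_state"]);
  if (rst.empty()) {
    E->rng.seed(static_cast<uint64_t>(as<double>(cfg["seed"])));
  } else {
    std::istringstream ss(rst);
    ss >> E->rng;
  }
  E->recompute_all();
  return E;
}

// [[Rcpp::export]]
List cpp_run_mc(List state, List cfg) {
  Engine* E = unpack(state, cfg);
  long steps = static_cast<long>(as<double>(cfg["steps"]));
  long burnin = static_cast<long>(as<double>(cfg["burnin"]));
  long record_every = static_cast<long>(as<double>(cfg["record_every"]));
  long bound_every = static_cast<long>(as<double>(cfg["bound_every"]));
  long snapshot_every = static_cast<long>(as<double>(cfg["snapshot_every"]));
  bool tune = as<bool>(cfg["tune"]);
  bool debug = as<bool>(cfg["debug"]);
  NumericVector wts = cfg["move_weights"];
  double cum[7];
  double s = 0;
  for (int k = 0; k < 7; ++k) { s += wts[k]; cum[k] = s; }
  for (int k = 0; k < 7; ++k) cum[k] /= s;

  long n_rec_rows = record_every > 0 ? steps / record_every : 0;
  NumericVector rec_step(n_rec_rows), rec_dR(n_rec_rows), rec_nb(n_rec_rows),
      rec_Hm(n_rec_rows), rec_Hf(n_rec_rows), rec_Hb(n_rec_rows),
      rec_E(n_rec_rows), rec_area(n_rec_rows), rec_th1(n_rec_rows),
      rec_ph1(n_rec_rows);
  NumericMatrix rec_nc(E->has_nc ? n_rec_rows : 0, 7);  // x,y,z,qw,qx,qy,qz
  std::vector<double> brec;  // sample idx, receptor id, x, y, z
  List snapshots;
  std::vector<long> att(7, 0), acc(7, 0);
  // per-kind tuning tallies (slot 7 = height-only vertex variant)
  std::vector<long> t_att(8, 0), t_acc(8, 0);
  long refresh_every = 100000;
  double max_drift = 0;
  long irow = 0;

  for (long step = 1; step <= steps; ++step) {
    double u = E->runif();
    int kind = 0;
    while (kind < 6 && u > cum[kind]) ++kind;
    bool ok = false;
    switch (kind) {
      case 0: ok = E->move_vertex(); break;
      case 1: ok = E->move_flip(debug); break;
      case 2: ok = E->move_nc_translate(); break;
      case 3: ok = E->move_nc_rotate(); break;
      case 4: ok = E->move_rec_hop(); break;
      case 5: ok = E->move_flexure(); break;
      case 6: ok = E->move_bond(); break;
    }
    ++att[kind];
    if (ok) ++acc[kind];
    if (tune && step <= burnin && (kind == 0 || kind == 2 || kind == 3)) {
      int slot = (kind == 0 && E->last_vertex_variant == 1) ? 7 : kind;
      ++t_att[slot];
      if (ok) ++t_acc[slot];
      if (t_att[slot] == 2000) {
        double rate = static_cast<double>(t_acc[slot]) / 2000.0;
        double* d = slot == 0 ? &E->delta_v : slot == 7 ? &E->delta_vz
                  : slot == 2 ? &E->delta_nc : &E->delta_rot;
        if (rate > 0.5) *d *= 1.15;
        else if (rate < 0.3) *d *= 0.85;
        if (slot == 3 && *d > M_PI) *d = M_PI;
        if (*d < 1e-4) *d = 1e-4;
        t_att[slot] = t_acc[slot] = 0;
      }
    }
    if (step % refresh_every == 0) {
      double hm_old = E->Hm, hb_old = E->Hb, a_old = E->area;
      E->recompute_all();
      max_drift = std::max(max_drift, std::abs(hm_old - E->Hm));
      max_drift = std::max(max_drift, std::abs(hb_old - E->Hb));
      max_drift = std::max(max_drift, std::abs(a_old - E->area) / std::max(1.0, E->area));
    }
    if (record_every > 0 && step % record_every == 0 && irow < n_rec_rows) {
      rec_step[irow] = static_cast<double>(step);
      rec_dR[irow] = E->deltaR();
      rec_nb[irow] = E->n_bonds;
      rec_Hm[irow] = E->Hm;
      rec_Hf[irow] = E->Hf;
      rec_Hb[irow] = E->Hb;
      rec_E[irow] = E->Hm + E->Hf + E->Hb;
      rec_area[irow] = E->area;
      rec_th1[irow] = E->n_rec > 0 ? E->rec_th[0] : NA_REAL;
      rec_ph1[irow] = E->n_rec > 0 ? E->rec_ph[0] : NA_REAL;
      if (E->has_nc) {
        rec_nc(irow, 0) = E->Rnc.x; rec_nc(irow, 1) = E->Rnc.y; rec_nc(irow, 2) = E->Rnc.z;
        rec_nc(irow, 3) = E->quat.w; rec_nc(irow, 4) = E->quat.x;
        rec_nc(irow, 5) = E->quat.y; rec_nc(irow, 6) = E->quat.z;
      }
      if (bound_every > 0 && step % bound_every == 0) {
        for (int r = 0; r < E->n_rec; ++r)
          if (E->rec_bond[r] >= 0) {
            const Vec3& xb = E->m.X[E->rec_v[r]];
            brec.push_back(static_cast<double>(irow + 1));
            brec.push_back(static_cast<double>(r + 1));
            brec.push_back(xb.x); brec.push_back(xb.y); brec.push_back(xb.z);
          }
      }
      ++irow;
    }
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      NumericMatrix snap(E->m.n, 3);
      for (int v = 0; v < E->m.n; ++v) {
        snap(v, 0) = E->m.X[v].x; snap(v, 1) = E->m.X[v].y; snap(v, 2) = E->m.X[v].z;
      }
      snapshots.push_back(snap);
    }
  }

  // energy drift diagnostic at the end
  double hm_cached = E->Hm, hf_cached = E->Hf, hb_cached = E->Hb;
  E->recompute_all();
  max_drift = std::max(max_drift, std::abs(hm_cached - E->Hm));
  max_drift = std::max(max_drift, std::abs(hf_cached - E->Hf));
  max_drift = std::max(max_drift, std::abs(hb_cached - E->Hb));

  // pack final state
  NumericMatrix Xout(E->m.n, 3);
  for (int v = 0; v < E->m.n; ++v) {
    Xout(v, 0) = E->m.X[v].x; Xout(v, 1) = E->m.X[v].y; Xout(v, 2) = E->m.X[v].z;
  }
  IntegerMatrix tout(E->m.n_tri(), 3);
  for (int t = 0; t < E->m.n_tri(); ++t)
    for (int k = 0; k < 3; ++k) tout(t, k) = E->m.tri[t][k] + 1;
  IntegerVector rvout(E->n_rec), rbout(E->n_rec);
  NumericVector rthout(E->n_rec), rphout(E->n_rec);
  for (int r = 0; r < E->n_rec; ++r) {
    rvout[r] = E->rec_v[r] + 1;
    rbout[r] = E->rec_bond[r] + 1;
    rthout[r] = E->rec_th[r];
    rphout[r] = E->rec_ph[r];
  }
  IntegerVector lbout(E->lig_bond.size());
  for (size_t j = 0; j < E->lig_bond.size(); ++j) lbout[j] = E->lig_bond[j] + 1;
  // adjacency snapshot for bit-exact restarts
  IntegerMatrix em(E->m.n_edges(), 4);
  for (int e = 0; e < E->m.n_edges(); ++e) {
    int a = E->m.edge_list[e].first, b = E->m.edge_list[e].second;
    auto pr = E->m.edge_tri[E->m.ekey(a, b)];
    em(e, 0) = a + 1; em(e, 1) = b + 1;
    em(e, 2) = pr.first + 1; em(e, 3) = pr.second + 1;
  }
  auto flatten = [&](const std::vector<std::vector<int>>& vv,
                     IntegerVector& flat, IntegerVector& off) {
    int tot = 0;
    for (auto& v : vv) tot += static_cast<int>(v.size());
    flat = IntegerVector(tot);
    off = IntegerVector(static_cast<int>(vv.size()) + 1);
    int k = 0;
    for (size_t v = 0; v < vv.size(); ++v) {
      off[v] = k;
      for (int x : vv[v]) flat[k++] = x + 1;
    }
    off[vv.size()] = k;
  };
  IntegerVector nbr_flat, nbr_off, vtri_flat, vtri_off;
  flatten(E->m.v_nbr, nbr_flat, nbr_off);
  flatten(E->m.v_tri, vtri_flat, vtri_off);
  List adj = List::create(_["edges"] = em, _["nbr"] = nbr_flat,
                          _["nbr_off"] = nbr_off, _["vtri"] = vtri_flat,
                          _["vtri_off"] = vtri_off);
  std::ostringstream ss;
  ss << E->rng;
  List final_state = List::create(
      _["vertices"] = Xout, _["triangles"] = tout,
      _["rec_vertex"] = rvout, _["rec_theta"] = rthout, _["rec_phi"] = rphout,
      _["rec_bond"] = rbout, _["lig_bond"] = lbout,
      _["R_nc"] = E->has_nc
          ? NumericVector::create(E->Rnc.x, E->Rnc.y, E->Rnc.z)
          : NumericVector(0),
      _["quat"] = E->has_nc
          ? NumericVector::create(E->quat.w, E->quat.x, E->quat.y, E->quat.z)
          : NumericVector(0),
      _["rng_state"] = ss.str(),
      _["adjacency"] = adj,
      _["deltas"] = NumericVector::create(E->delta_v, E->delta_vz, E->delta_nc,
                                          E->delta_rot));
  NumericMatrix bmat(brec.size() / 5, 5);
  for (size_t i = 0; i < brec.size() / 5; ++i)
    for (int k = 0; k < 5; ++k) bmat(i, k) = brec[5 * i + k];
  List records = List::create(
      _["step"] = rec_step, _["dR"] = rec_dR, _["n_b"] = rec_nb,
      _["H_m"] = rec_Hm, _["H_f"] = rec_Hf, _["H_b"] = rec_Hb,
      _["E_total"] = rec_E, _["area"] = rec_area, _["theta1"] = rec_th1,
      _["phi1"] = rec_ph1, _["nc"] = rec_nc);
  List counters = List::create(
      _["attempted"] = NumericVector(att.begin(), att.end()),
      _["accepted"] = NumericVector(acc.begin(), acc.end()));
  List out = List::create(
      _["state"] = final_state, _["records"] = records, _["bound"] = bmat,
      _["snapshots"] = snapshots, _["counters"] = counters,
      _["max_drift"] = max_drift, _["flip_violations"] = E->flip_violations,
      _["energy"] = NumericVector::create(
          _["H_m"] = E->Hm, _["H_f"] = E->Hf, _["H_b"] = E->Hb,
          _["U_bias"] = E->Ub, _["area"] = E->area));
  delete E;
  return out;
}

// [[Rcpp::export]]
List cpp_system_energy(List state) {
  List cfg = List::create(
      _["k_trials"] = 8,
      _["deltas"] = NumericVector::create(1.0, 1.0, 2.0, 0.2),
      _["bias_on"] = false, _["rng_state"] = std::string(""), _["seed"] = 1.0);
  Engine* E = unpack(state, cfg);
  List out = List::create(
      _["H_m"] = E->Hm, _["H_f"] = E->Hf, _["H_b"] = E->Hb,
      _["total"] = E->Hm + E->Hf + E->Hb, _["area"] = E->area,
      _["n_bonds"] = E->n_bonds, _["dR"] = E->deltaR());
  delete E;
  return out;
}

// receptor tip helper exposed for the molecular-geometry layer
// [[Rcpp::export]]
NumericVector cpp_receptor_tip(NumericMatrix X, IntegerMatrix tri, double L,
                               double a0, double lmf, int vertex, double theta,
                               double phi, double L_an) {
  int n = X.nrow();
  std::vector<Vec3> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = Vec3(X(i, 0), X(i, 1), X(i, 2));
  std::vector<std::array<int, 3>> ts(tri.nrow());
  for (int t = 0; t < tri.nrow(); ++t)
    ts[t] = {tri(t, 0) - 1, tri(t, 1) - 1, tri(t, 2) - 1};
  MeshCore m;
  m.build(n, xs, ts, L, a0, lmf);
  Vec3 nv = m.vertex_normal(vertex - 1);
  if (nv.norm() < 0.5) stop("degenerate normal at vertex %d", vertex);
  Vec3 t1 = Vec3(1, 0, 0) - nv * nv.x;
  if (t1.norm() < 1e-6) t1 = Vec3(0, 1, 0) - nv * nv.y;
  t1 = t1.unit();
  Vec3 t2 = nv.cross(t1);
  Vec3 dir = nv * std::cos(theta) +
             (t1 * std::cos(phi) + t2 * std::sin(phi)) * std::sin(theta);
  Vec3 tip = m.X[vertex - 1] + dir * L_an;
  return NumericVector::create(tip.x, tip.y, tip.z);
}
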