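// Core molecular-dynamics kernels: pair/bond/wall forces for the
// Kremer-Grest brush + nanoparticle model, Verlet neighbor lists backed by a
// cell grid, and a Langevin velocity-Verlet (BAOAB splitting) integrator.
// Species codes: 0 = monomer, 1 = nanoparticle.
// Geometry codes: 0 = planar slab (periodic x,y; walls at z=0 and z=Lz),
//                 1 = cylinder in a fully periodic box (axis along x).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct FF {
  double eps, sigma_m, sigma_n, eps_b;
  double fene_k, fene_r0;
  double rc_m, rcut_nm, delta, rc_nn;
  bool shift_nm;
  double unm_shift;      // energy at rcut when shift_nm is on, else 0
  double sm6, sn6, r02;
};

struct Geom {
  int kind;              // 0 planar, 1 cylinder
  double box[3];
  bool pbc[3];
  double R, cy, cz;      // cylinder radius and axis position (y,z), axis = x
  bool wall_on_np;       // planar walls act on nanoparticles; cylinder wall does not
  double eps_w, sigw_m, sigw_n;
};

FF parse_ff(const List& ff) {
  FF f;
  f.eps = as<double>(ff["epsilon"]);
  f.sigma_m = as<double>(ff["sigma_m"]);
  f.sigma_n = as<double>(ff["sigma_n"]);
  f.eps_b = as<double>(ff["eps_b"]);
  f.fene_k = as<double>(ff["fene_k"]);
  f.fene_r0 = as<double>(ff["fene_r0"]);
  f.rc_m = as<double>(ff["rc_m"]);
  f.rcut_nm = as<double>(ff["r_cut_nm"]);
  f.delta = as<double>(ff["delta"]);
  f.rc_nn = as<double>(ff["rc_nn"]);
  f.shift_nm = as<bool>(ff["shift_nm"]);
  f.sm6 = std::pow(f.sigma_m, 6);
  f.sn6 = std::pow(f.sigma_n, 6);
  f.r02 = f.fene_r0 * f.fene_r0;
  f.unm_shift = 0.0;
  if (f.shift_nm) {
    double rs = f.rcut_nm - f.delta;
    double q = f.sm6 / std::pow(rs, 6);
    f.unm_shift = 4.0 * f.eps_b * (q * q - q);
  }
  return f;
}

Geom parse_geom(const List& g) {
  Geom gm;
  gm.kind = as<int>(g["kind_code"]);
  NumericVector box = g["box"];
  LogicalVector pbc = g["pbc"];
  for (int d = 0; d < 3; ++d) { gm.box[d] = box[d]; gm.pbc[d] = pbc[d]; }
  gm.R = g.containsElementNamed("R") && !Rf_isNull(g["R"]) ? as<double>(g["R"]) : -1.0;
  gm.cy = gm.box[1] * 0.5; gm.cz = gm.box[2] * 0.5;
  gm.wall_on_np = as<bool>(g["wall_on_np"]);
  gm.eps_w = as<double>(g["eps_w"]);
  gm.sigw_m = as<double>(g["sigw_m"]);
  gm.sigw_n = as<double>(g["sigw_n"]);
  return gm;
}

inline double min_image(double d, double L, bool per) {
  if (!per) return d;
  return d - L * std::nearbyint(d / L);
}

struct Sim {
  int n;
  std::vector<double> x, v, fbuf;   // 3n, layout x0 y0 z0 x1 ...
  std::vector<int> spec;
  std::vector<char> frozen;
  std::vector<int> b1, b2;          // FENE bonds, 0-based
  FF ff; Geom gm;
  double skin;
  // neighbor machinery
  std::vector<int> nl_i, nl_j;
  std::vector<double> x_build;
  long n_rebuild = 0;
  // cutoffs squared per species-pair key (i+j): 0 mm, 1 nm, 2 nn
  double rc2[3], rl2[3], maxcut;
  // energies from last force evaluation
  double e_pair = 0, e_bond = 0, e_wall = 0;
  long step_now = 0;

  void init_cutoffs(bool has_np) {
    double c0 = ff.rc_m, c1 = ff.rcut_nm, c2 = ff.rc_nn;
    rc2[0] = c0 * c0; rc2[1] = c1 * c1; rc2[2] = c2 * c2;
    maxcut = has_np ? std::max(c0, std::max(c1, c2)) : c0;
    for (int k = 0; k < 3; ++k) {
      double rl = std::sqrt(rc2[k]) + skin;
      rl2[k] = rl * rl;
    }
  }

  void wrap() {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        if (!gm.pbc[d]) continue;
        double& q = x[3 * i + d];
        double L = gm.box[d];
        q -= L * std::floor(q / L);
      }
  }

  void build_list() {
    double cs = maxcut + skin;
    int nc[3]; double cw[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(gm.box[d] / cs));
      cw[d] = gm.box[d] / nc[d];
    }
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1), cell_of(n);
    for (int i = 0; i < n; ++i) {
      int ic[3];
      for (int d = 0; d < 3; ++d) {
        int k = (int)std::floor(x[3 * i + d] / cw[d]);
        if (k < 0) k = 0;
        if (k >= nc[d]) k = nc[d] - 1;
        ic[d] = k;
      }
      int c = (ic[2] * nc[1] + ic[1]) * nc[0] + ic[0];
      cell_of[i] = c; nxt[i] = head[c]; head[c] = i;
    }
    nl_i.clear(); nl_j.clear();
    std::vector<int> nbr; nbr.reserve(27);
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c = (cz * nc[1] + cy) * nc[0] + cx;
          nbr.clear();
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ix = cx + dx, iy = cy + dy, iz = cz + dz;
                if (gm.pbc[0]) ix = (ix + nc[0]) % nc[0]; else if (ix < 0 || ix >= nc[0]) continue;
                if (gm.pbc[1]) iy = (iy + nc[1]) % nc[1]; else if (iy < 0 || iy >= nc[1]) continue;
                if (gm.pbc[2]) iz = (iz + nc[2]) % nc[2]; else if (iz < 0 || iz >= nc[2]) continue;
                int c2 = (iz * nc[1] + iy) * nc[0] + ix;
                if (c2 >= c) nbr.push_back(c2);
              }
          std::sort(nbr.begin(), nbr.end());
          nbr.erase(std::unique(nbr.begin(), nbr.end()), nbr.end());
          for (int c2 : nbr) {
            for (int i = head[c]; i >= 0; i = nxt[i]) {
              int jstart = (c2 == c) ? nxt[i] : head[c2];
              for (int j = jstart; j >= 0; j = nxt[j]) {
                double d0 = min_image(x[3 * i] - x[3 * j], gm.box[0], gm.pbc[0]);
                double d1 = min_image(x[3 * i + 1] - x[3 * j + 1], gm.box[1], gm.pbc[1]);
                double d2 = min_image(x[3 * i + 2] - x[3 * j + 2], gm.box[2], gm.pbc[2]);
                double r2 = d0 * d0 + d1 * d1 + d2 * d2;
                int key = spec[i] + spec[j];
                if (r2 < rl2[key]) { nl_i.push_back(i); nl_j.push_back(j); }
              }
            }
          }
        }
    x_build = x;
    ++n_rebuild;
  }

  bool need_rebuild() const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = min_image(x[3 * i + d] - x_build[3 * i + d], gm.box[d], gm.pbc[d]);
        s += dd * dd;
      }
      if (s > lim2) return true;
    }
    return false;
  }

  void wall_force(int i, double* f) {
    bool is_np = spec[i] == 1;
    double sw = is_np ? gm.sigw_n : gm.sigw_m;
    double cut = std::pow(2.0, 1.0 / 6.0) * sw;
    double sw6 = std::pow(sw, 6);
    if (gm.kind == 0) {
      if (is_np && !gm.wall_on_np) return;
      // bottom wall d = z, top wall d = Lz - z
      for (int w = 0; w < 2; ++w) {
        double z = x[3 * i + 2];
        double d = (w == 0) ? z : gm.box[2] - z;
        if (d >= cut) continue;
        if (d <= 0)
          stop("particle %d escaped the slab (z = %g) at step %ld", i + 1, z, step_now);
        double d2 = d * d;
        double q = sw6 / (d2 * d2 * d2);
        e_wall += 4.0 * gm.eps_w * (q * q - q) + gm.eps_w;
        double dUdd = (24.0 * gm.eps_w / d) * (q - 2.0 * q * q);
        f[2] += (w == 0) ? -dUdd : dUdd;
      }
    } else {
      if (is_np) return;  // cylinder wall transparent to nanoparticles
      double ry = x[3 * i + 1] - gm.cy, rz = x[3 * i + 2] - gm.cz;
      double rad = std::sqrt(ry * ry + rz * rz);
      double d = gm.R - rad;
      if (d >= cut) return;
      if (d <= 0)
        stop("monomer %d escaped the cylinder (rad = %g) at step %ld", i + 1, rad, step_now);
      double d2 = d * d;
      double q = sw6 / (d2 * d2 * d2);
      e_wall += 4.0 * gm.eps_w * (q * q - q) + gm.eps_w;
      double dUdd = (24.0 * gm.eps_w / d) * (q - 2.0 * q * q);
      if (rad > 1e-12) {
        f[1] += dUdd * ry / rad;
        f[2] += dUdd * rz / rad;
      }
    }
  }

  void forces() {
    e_pair = e_bond = e_wall = 0;
    std::fill(fbuf.begin(), fbuf.end(), 0.0);
    const double eps = ff.eps, eps_b = ff.eps_b;
    size_t np = nl_i.size();
    for (size_t p = 0; p < np; ++p) {
      int i = nl_i[p], j = nl_j[p];
      double d0 = min_image(x[3 * i] - x[3 * j], gm.box[0], gm.pbc[0]);
      double d1 = min_image(x[3 * i + 1] - x[3 * j + 1], gm.box[1], gm.pbc[1]);
      double d2 = min_image(x[3 * i + 2] - x[3 * j + 2], gm.box[2], gm.pbc[2]);
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      int key = spec[i] + spec[j];
      if (r2 >= rc2[key]) continue;
      double fcoef = 0.0;
      if (key == 1) {
        // monomer-nanoparticle: LJ displaced by delta, well depth eps_b
        if (eps_b == 0.0) continue;
        double r = std::sqrt(r2);
        double rs = r - ff.delta;
        if (rs <= 0.05 * ff.sigma_m)
          stop("monomer-nanoparticle hard-core overlap (r = %g) at step %ld", r, step_now);
        double rs2 = rs * rs;
        double q = ff.sm6 / (rs2 * rs2 * rs2);
        e_pair += 4.0 * eps_b * (q * q - q) - ff.unm_shift;
        double dUdr = (24.0 * eps_b / rs) * (q - 2.0 * q * q);
        fcoef = -dUdr / r;
      } else {
        // WCA repulsion, sigma_m (monomer pair) or sigma_n (nanoparticle pair)
        double s6 = (key == 0) ? ff.sm6 : ff.sn6;
        double q = s6 / (r2 * r2 * r2);
        e_pair += 4.0 * eps * (q * q - q) + eps;
        fcoef = (24.0 * eps / r2) * (2.0 * q * q - q);
      }
      fbuf[3 * i] += fcoef * d0; fbuf[3 * j] -= fcoef * d0;
      fbuf[3 * i + 1] += fcoef * d1; fbuf[3 * j + 1] -= fcoef * d1;
      fbuf[3 * i + 2] += fcoef * d2; fbuf[3 * j + 2] -= fcoef * d2;
    }
    // FENE bonds
    for (size_t b = 0; b < b1.size(); ++b) {
      int i = b1[b], j = b2[b];
      double d0 = min_image(x[3 * i] - x[3 * j], gm.box[0], gm.pbc[0]);
      double d1 = min_image(x[3 * i + 1] - x[3 * j + 1], gm.box[1], gm.pbc[1]);
      double d2 = min_image(x[3 * i + 2] - x[3 * j + 2], gm.box[2], gm.pbc[2]);
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      if (r2 >= ff.r02)
        stop("FENE bond %d-%d overstretched (r = %g >= r0) at step %ld",
             i + 1, j + 1, std::sqrt(r2), step_now);
      double frac = 1.0 - r2 / ff.r02;
      e_bond += -0.5 * ff.fene_k * ff.r02 * std::log(frac);
      double fcoef = -ff.fene_k / frac;
      fbuf[3 * i] += fcoef * d0; fbuf[3 * j] -= fcoef * d0;
      fbuf[3 * i + 1] += fcoef * d1; fbuf[3 * j + 1] -= fcoef * d1;
      fbuf[3 * i + 2] += fcoef * d2; fbuf[3 * j + 2] -= fcoef * d2;
    }
    for (int i = 0; i < n; ++i)
      if (!frozen[i]) wall_force(i, &fbuf[3 * i]);
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      ke += 0.5 * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                   v[3 * i + 2] * v[3 * i + 2]);
    }
    return ke;
  }
};

Sim make_sim(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
             IntegerMatrix bonds, LogicalVector frozen, List ff, List geom,
             double skin) {
  Sim s;
  s.n = pos.nrow();
  s.x.resize(3 * s.n); s.v.resize(3 * s.n); s.fbuf.resize(3 * s.n);
  s.spec.resize(s.n); s.frozen.resize(s.n);
  bool has_np = false;
  for (int i = 0; i < s.n; ++i) {
    for (int d = 0; d < 3; ++d) { s.x[3 * i + d] = pos(i, d); s.v[3 * i + d] = vel(i, d); }
    s.spec[i] = species[i];
    if (species[i] == 1) has_np = true;
    s.frozen[i] = frozen[i];
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    s.b1.push_back(bonds(b, 0) - 1);
    s.b2.push_back(bonds(b, 1) - 1);
  }
  s.ff = parse_ff(ff);
  s.gm = parse_geom(geom);
  s.skin = skin;
  s.init_cutoffs(has_np);
  s.wrap();
  s.build_list();
  return s;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                IntegerMatrix bonds, LogicalVector frozen, List ff, List geom,
                double dt, double gamma, double temperature, int n_steps,
                int snap_stride, int log_stride, int seed, bool record,
                double skin = 0.4) {
  Sim s = make_sim(pos, vel, species, bonds, frozen, ff, geom, skin);
  int n = s.n;
  int n_mobile = 0;
  for (int i = 0; i < n; ++i) if (!s.frozen[i]) ++n_mobile;

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(temperature * (1.0 - c1 * c1)) : 0.0;

  int n_frames = (record && snap_stride > 0) ? n_steps / snap_stride : 0;
  NumericVector frames(Dimension(n, 3, std::max(n_frames, 0)));
  IntegerVector frame_steps(std::max(n_frames, 0));
  int n_logs = (log_stride > 0) ? n_steps / log_stride : 0;
  NumericMatrix log(n_logs, 7);
  colnames(log) = CharacterVector::create("step", "T_inst", "E_pair", "E_bond",
                                          "E_wall", "E_kin", "E_tot");

  s.forces();
  int iframe = 0, ilog = 0;
  for (int step = 1; step <= n_steps; ++step) {
    s.step_now = step;
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) s.v[3 * i + d] += 0.5 * dt * s.fbuf[3 * i + d];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) s.x[3 * i + d] += 0.5 * dt * s.v[3 * i + d];
    }
    // O: Ornstein-Uhlenbeck velocity update (skipped when gamma == 0 -> NVE)
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        if (s.frozen[i]) continue;
        for (int d = 0; d < 3; ++d)
          s.v[3 * i + d] = c1 * s.v[3 * i + d] + c2 * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) s.x[3 * i + d] += 0.5 * dt * s.v[3 * i + d];
    }
    s.wrap();
    if (s.need_rebuild()) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(s.x[i]))
          stop("non-finite coordinate at step %d", step);
      s.build_list();
    }
    s.forces();
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) s.v[3 * i + d] += 0.5 * dt * s.fbuf[3 * i + d];
    }
    if (log_stride > 0 && step % log_stride == 0 && ilog < n_logs) {
      double ke = s.kinetic();
      log(ilog, 0) = step;
      log(ilog, 1) = (n_mobile > 0) ? 2.0 * ke / (3.0 * n_mobile) : 0.0;
      log(ilog, 2) = s.e_pair; log(ilog, 3) = s.e_bond; log(ilog, 4) = s.e_wall;
      log(ilog, 5) = ke;
      log(ilog, 6) = ke + s.e_pair + s.e_bond + s.e_wall;
      ++ilog;
    }
    if (record && snap_stride > 0 && step % snap_stride == 0 && iframe < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[i + (size_t)n * d + (size_t)3 * n * iframe] = s.x[3 * i + d];
      frame_steps[iframe] = step;
      ++iframe;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = s.x[3 * i + d];
      vel_out(i, d) = s.v[3 * i + d];
    }
  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out,
                      _["frames"] = frames, _["frame_steps"] = frame_steps,
                      _["log"] = log, _["n_rebuilds"] = (double)s.n_rebuild);
}

// [[Rcpp::export]]
List cpp_energies(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                  IntegerMatrix bonds, LogicalVector frozen, List ff, List geom,
                  double skin = 0.4) {
  Sim s = make_sim(pos, vel, species, bonds, frozen, ff, geom, skin);
  s.forces();
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int d = 0; d < 3; ++d) f(i, d) = s.fbuf[3 * i + d];
  return List::create(_["E_pair"] = s.e_pair, _["E_bond"] = s.e_bond,
                      _["E_wall"] = s.e_wall, _["E_kin"] = s.kinetic(),
                      _["forces"] = f);
}

// Grow nearly-straight stretched chains inside a cylinder (axis = x, centred
// in the y-z cross-section).  Each chain starts at its graft anchor on the
// inner surface and walks inward with a fixed per-chain preferred direction
// (cos_alpha toward the axis, the rest along +-x), small angular jitter and
// hard rejection of positions closer than min_sep to any placed bead or
// outside the allowed radial band.  Returns an (n_chains*N) x 3 matrix,
// chain-major.
// [[Rcpp::export]]
NumericMatrix cpp_grow_chains(NumericMatrix anchors, NumericVector cos_alpha,
                              NumericVector x_sign, int N, double bond_len,
                              NumericVector box, double R, double r_min,
                              double r_max, double min_sep, double jitter,
                              int seed) {
  int nch = anchors.nrow();
  int ntot = nch * N;
  NumericMatrix out(ntot, 3);
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 13ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double cy = box[1] * 0.5, cz = box[2] * 0.5;
  // cell grid over the full box, periodic in x only
  double cs = std::max(min_sep, 0.5);
  int nc[3]; double cw[3];
  bool per[3] = {true, false, false};
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(box[d] / cs));
    cw[d] = box[d] / nc[d];
  }
  std::vector<std::vector<int>> cells(nc[0] * nc[1] * nc[2]);
  std::vector<int> chain_of(ntot), index_in_chain(ntot);
  double ms2 = min_sep * min_sep;

  auto cell_index = [&](const double* p) {
    int ic[3];
    for (int d = 0; d < 3; ++d) {
      double q = p[d];
      if (per[d]) q -= box[d] * std::floor(q / box[d]);
      int k = (int)std::floor(q / cw[d]);
      if (k < 0) k = 0;
      if (k >= nc[d]) k = nc[d] - 1;
      ic[d] = k;
    }
    return (ic[2] * nc[1] + ic[1]) * nc[0] + ic[0];
  };
  auto clashes = [&](const double* p, int ch, int kidx) {
    int ic[3];
    for (int d = 0; d < 3; ++d) {
      double q = p[d];
      if (per[d]) q -= box[d] * std::floor(q / box[d]);
      int k = (int)std::floor(q / cw[d]);
      if (k < 0) k = 0;
      if (k >= nc[d]) k = nc[d] - 1;
      ic[d] = k;
    }
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = ic[0] + dx, iy = ic[1] + dy, iz = ic[2] + dz;
          if (per[0]) ix = (ix + nc[0]) % nc[0]; else if (ix < 0 || ix >= nc[0]) continue;
          if (iy < 0 || iy >= nc[1]) continue;
          if (iz < 0 || iz >= nc[2]) continue;
          for (int q : cells[(iz * nc[1] + iy) * nc[0] + ix]) {
            if (chain_of[q] == ch && std::abs(index_in_chain[q] - kidx) <= 1) continue;
            double s = 0;
            for (int d = 0; d < 3; ++d) {
              double dd = p[d] - out(q, d);
              if (per[d]) dd = min_image(dd, box[d], true);
              s += dd * dd;
            }
            if (s < ms2) return true;
          }
        }
    return false;
  };
  auto place = [&](const double* p, int row, int ch, int kidx) {
    for (int d = 0; d < 3; ++d) out(row, d) = p[d];
    chain_of[row] = ch; index_in_chain[row] = kidx;
    cells[cell_index(p)].push_back(row);
  };

  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  for (int ch = 0; ch < nch; ++ch) {
    double a[3] = {anchors(ch, 0), anchors(ch, 1), anchors(ch, 2)};
    int chain_attempt = 0;
  restart_chain:
    if (chain_attempt > 60)
      stop("packing error: could not grow chain %d", ch + 1);
    // on restart, clear the partial chain from the grid and re-draw the tilt
    if (chain_attempt > 0) {
      for (auto& cell : cells)
        cell.erase(std::remove_if(cell.begin(), cell.end(),
                                  [&](int q) { return chain_of[q] == ch; }),
                   cell.end());
    }
    double ca = cos_alpha[ch], sa;
    if (chain_attempt > 0) {
      ca *= 0.8 + 0.4 * unif01(rng);
      if (ca > 0.995) ca = 0.995;
      if (ca < 0.05) ca = 0.05;
    }
    sa = std::sqrt(std::max(0.0, 1.0 - ca * ca));
    double xsg = (chain_attempt == 0) ? x_sign[ch]
                 : (unif01(rng) < 0.5 ? -1.0 : 1.0);
    place(a, ch * N, ch, 0);
    double prev[3] = {a[0], a[1], a[2]};
    for (int k = 1; k < N; ++k) {
      // local inward normal at the current bead
      double py0 = prev[1] - cy, pz0 = prev[2] - cz;
      double rad0 = std::sqrt(py0 * py0 + pz0 * pz0);
      double nin[3] = {0.0, -py0 / rad0, -pz0 / rad0};
      // descend straight inward while still close to the wall, then tilt
      bool near_wall = rad0 > R - 2.0;
      double upref[3];
      if (near_wall) {
        upref[0] = 0.0; upref[1] = nin[1]; upref[2] = nin[2];
      } else {
        upref[0] = sa * xsg;
        upref[1] = ca * nin[1]; upref[2] = ca * nin[2];
      }
      bool ok = false;
      double p[3];
      for (int attempt = 0; attempt < 200 && !ok; ++attempt) {
        double jj = (near_wall ? 0.4 * jitter : jitter) * (1.0 + attempt / 40.0);
        double dir[3], norm = 0;
        for (int d = 0; d < 3; ++d) { dir[d] = upref[d] + jj * gauss(rng); norm += dir[d] * dir[d]; }
        norm = std::sqrt(norm);
        for (int d = 0; d < 3; ++d) p[d] = prev[d] + bond_len * dir[d] / norm;
        double py = p[1] - cy, pz = p[2] - cz;
        double rad = std::sqrt(py * py + pz * pz);
        if (rad < r_min || rad > r_max) continue;
        if (k >= 2) {  // next-nearest bead along the chain: no sharp turns
          double s2 = 0;
          for (int d = 0; d < 3; ++d) {
            double dd = p[d] - out(ch * N + k - 2, d);
            if (per[d]) dd = min_image(dd, box[d], true);
            s2 += dd * dd;
          }
          if (s2 < 1.3 * 1.3) continue;
        }
        if (clashes(p, ch, k)) continue;
        ok = true;
      }
      if (!ok) { ++chain_attempt; goto restart_chain; }
      place(p, ch * N + k, ch, k);
      for (int d = 0; d < 3; ++d) prev[d] = p[d];
    }
  }
  return out;
}

// Random sequential insertion of points with a minimum separation, used for
// nanoparticle placement.  Optionally excludes (or restricts to) the interior
// of a cylinder of radius excl_R centred in the y-z cross-section, axis x.
// [[Rcpp::export]]
NumericMatrix cpp_insert_points(int n, NumericVector lo, NumericVector hi,
                                double min_sep, NumericVector box,
                                LogicalVector pbc, double excl_R, int seed,
                                int max_retry = 1000000) {
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  NumericMatrix out(n, 3);
  double cs = std::max(min_sep, 1e-9);
  int nc[3]; double cw[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(box[d] / cs));
    cw[d] = box[d] / nc[d];
  }
  std::vector<std::vector<int>> cells(nc[0] * nc[1] * nc[2]);
  double cy = box[1] * 0.5, cz = box[2] * 0.5;
  double ms2 = min_sep * min_sep;
  int placed = 0;
  for (long t = 0; t < (long)max_retry && placed < n; ++t) {
    double p[3];
    for (int d = 0; d < 3; ++d) p[d] = lo[d] + (hi[d] - lo[d]) * unif(rng);
    if (excl_R > 0) {
      double ry = p[1] - cy, rz = p[2] - cz;
      if (ry * ry + rz * rz < excl_R * excl_R) continue;
    }
    int ic[3];
    for (int d = 0; d < 3; ++d) {
      int k = (int)std::floor(p[d] / cw[d]);
      if (k < 0) k = 0;
      if (k >= nc[d]) k = nc[d] - 1;
      ic[d] = k;
    }
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; ++dz)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          int ix = ic[0] + dx, iy = ic[1] + dy, iz = ic[2] + dz;
          if (pbc[0]) ix = (ix + nc[0]) % nc[0]; else if (ix < 0 || ix >= nc[0]) continue;
          if (pbc[1]) iy = (iy + nc[1]) % nc[1]; else if (iy < 0 || iy >= nc[1]) continue;
          if (pbc[2]) iz = (iz + nc[2]) % nc[2]; else if (iz < 0 || iz >= nc[2]) continue;
          for (int q : cells[(iz * nc[1] + iy) * nc[0] + ix]) {
            double s = 0;
            for (int d = 0; d < 3; ++d) {
              double dd = min_image(p[d] - out(q, d), box[d], pbc[d]);
              s += dd * dd;
            }
            if (s < ms2) { ok = false; break; }
          }
        }
    if (!ok) continue;
    for (int d = 0; d < 3; ++d) out(placed, d) = p[d];
    cells[(ic[2] * nc[1] + ic[1]) * nc[0] + ic[0]].push_back(placed);
    ++placed;
  }
  if (placed < n)
    stop("packing error: placed %d of %d points within retry budget", placed, n);
  return out;
}
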