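// Langevin-dynamics engine for coarse-grained polyelectrolyte translocation.
//
// Model: bead-spring chain (harmonic bonds) + explicit counterions and salt,
// WCA excluded volume, damped shifted-force (DSF) real-space Coulomb, an
// analytic slab wall pierced by a cylindrical pore along x, a uniform
// driving field confined to the pore, and a one-sided barrier at the pore
// exit acting on the head monomer only. Integration is BAOAB Langevin with
// a deterministic xoshiro256++ noise stream so a seed reproduces a
// trajectory bit for bit.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG -----
struct Xoshiro {
  uint64_t s[4];
  bool have_g = false;
  double g2 = 0.0;
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia polar method (deterministic, no library distribution objects)
  double norm() {
    if (have_g) { have_g = false; return g2; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    g2 = v * f; have_g = true;
    return u * f;
  }
};

// ------------------------------------------------------------- engine -----
struct Engine {
  int n = 0, Nm = 0, head = 0;
  std::vector<double> px, py, pz, vx, vy, vz, fx, fy, fz, q;
  std::vector<int> frozen;
  double Lx, Ly, Lz;
  double xw, y0c, z0c, d2, rp;
  double eps_pp, sig_pp, eps_pw, sig_pw, kb, b0, E, lB, alpha, rc, bar_sig;
  double dt, gamma;
  bool wall_on, barrier_on, field_on, thermostat_on = true;
  bool tether_on = false;
  double tx = 0, ty = 0, tz = 0;
  double U = 0.0;           // potential energy from the last force pass
  double ec = 0, fshift = 0, wca_cut2 = 0, rc2 = 0, wall_cut = 0;

  void init(const NumericMatrix& pos, const NumericMatrix& vel,
            const NumericVector& charges, const List& par) {
    n = pos.nrow();
    px.assign(n, 0); py.assign(n, 0); pz.assign(n, 0);
    vx.assign(n, 0); vy.assign(n, 0); vz.assign(n, 0);
    fx.assign(n, 0); fy.assign(n, 0); fz.assign(n, 0);
    q.assign(n, 0); frozen.assign(n, 0);
    for (int i = 0; i < n; ++i) {
      px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
      vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
      q[i] = charges[i];
    }
    NumericVector box = par["box"];
    Lx = box[0]; Ly = box[1]; Lz = box[2];
    Nm = as<int>(par["Nm"]);
    head = 0;
    xw = as<double>(par["x_wall"]);
    y0c = as<double>(par["y0"]); z0c = as<double>(par["z0"]);
    d2 = as<double>(par["wall_thickness"]) / 2.0;
    rp = as<double>(par["pore_radius"]);
    eps_pp = as<double>(par["eps_pp"]); sig_pp = as<double>(par["sigma_pp"]);
    eps_pw = as<double>(par["eps_pw"]); sig_pw = as<double>(par["sigma_pw"]);
    kb = as<double>(par["k_bond"]); b0 = as<double>(par["b0"]);
    E = as<double>(par["E"]); lB = as<double>(par["lambda_B"]);
    alpha = as<double>(par["dsf_alpha"]);
    rc = as<double>(par["coulomb_cutoff"]);
    bar_sig = as<double>(par["barrier_sigma"]);
    dt = as<double>(par["dt"]);
    gamma = 1.0 / as<double>(par["damping_time"]);
    wall_on = as<bool>(par["wall_on"]);
    barrier_on = as<bool>(par["barrier_on"]);
    field_on = as<bool>(par["field_on"]);
    NumericVector teth = par["tether"];
    if (teth.size() == 3) {
      tether_on = true; tx = teth[0]; ty = teth[1]; tz = teth[2];
    }
    const double wc = std::pow(2.0, 1.0 / 6.0);
    wca_cut2 = wc * sig_pp * wc * sig_pp;
    rc2 = rc * rc;
    wall_cut = wc * sig_pw;
    // DSF shift constants: zero energy and zero force at the cutoff
    ec = std::erfc(alpha * rc) / rc;
    fshift = ec / rc +
      2.0 * alpha / std::sqrt(M_PI) * std::exp(-alpha * alpha * rc * rc) / rc;
  }

  inline double mi(double d, double L) const {
    return d - L * std::nearbyint(d / L);
  }

  // WCA force magnitude (positive = repulsive) and energy accumulation
  inline double wca_pair(double r2, double sig, double eps, double& u) const {
    const double s2 = sig * sig / r2;
    const double s6 = s2 * s2 * s2;
    u += 4.0 * eps * (s6 * s6 - s6) + eps;
    return 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;  // = F/r
  }

  void forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    U = 0.0;
    const bool coul = (lB > 0.0);
    const bool any_pair = coul || eps_pp > 0.0;
    const double pref = 2.0 * alpha / std::sqrt(M_PI);
    for (int i = 0; any_pair && i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (j == i + 1 && j < Nm) continue;   // 1-2 exclusion along the chain
        double dx = mi(px[j] - px[i], Lx);
        double dy = mi(py[j] - py[i], Ly);
        double dz = mi(pz[j] - pz[i], Lz);
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= 1e-12)
          stop("overlapping particles: pair distance ~ 0");
        double fr = 0.0;
        if (r2 < wca_cut2 && eps_pp > 0.0) {
          double u0 = 0.0;
          fr += wca_pair(r2, sig_pp, eps_pp, u0);
          U += u0;
        }
        if (coul && r2 < rc2) {
          const double qq = q[i] * q[j];
          if (qq != 0.0) {
            const double r = std::sqrt(r2);
            const double er = std::erfc(alpha * r);
            U += lB * qq * (er / r - ec + fshift * (r - rc));
            const double fmag = lB * qq *
              (er / r2 + pref * std::exp(-alpha * alpha * r2) / r - fshift);
            fr += fmag / r;
          }
        }
        if (fr != 0.0) {
          fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
          fx[j] += fr * dx; fy[j] += fr * dy; fz[j] += fr * dz;
        }
      }
    }
    // chain bonds (consecutive monomers 0..Nm-1)
    for (int i = 0; i + 1 < Nm; ++i) {
      double dx = mi(px[i + 1] - px[i], Lx);
      double dy = mi(py[i + 1] - py[i], Ly);
      double dz = mi(pz[i + 1] - pz[i], Lz);
      const double b = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (b < 1e-9)
        stop("overlapping particles: bond length ~ 0");
      U += 0.5 * kb * (b - b0) * (b - b0);
      const double fm = -kb * (b - b0) / b;   // along +d on particle i+1
      fx[i + 1] += fm * dx; fy[i + 1] += fm * dy; fz[i + 1] += fm * dz;
      fx[i] -= fm * dx; fy[i] -= fm * dy; fz[i] -= fm * dz;
    }
    if (tether_on) {
      double dx = mi(px[head] - tx, Lx);
      double dy = mi(py[head] - ty, Ly);
      double dz = mi(pz[head] - tz, Lz);
      const double b = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (b > 1e-12) {
        U += 0.5 * kb * (b - b0) * (b - b0);
        const double fm = -kb * (b - b0) / b;
        fx[head] += fm * dx; fy[head] += fm * dy; fz[head] += fm * dz;
      }
    }
    if (wall_on) wall_forces();
    if (barrier_on) barrier_force();
    if (field_on && E > 0.0) field_force();
  }

  void wall_forces() {
    for (int i = 0; i < n; ++i) {
      double dxw = mi(px[i] - xw, Lx);
      const double adx = std::fabs(dxw);
      const double sx = (dxw >= 0.0) ? 1.0 : -1.0;
      double dy = mi(py[i] - y0c, Ly);
      double dz = mi(pz[i] - z0c, Lz);
      const double r = std::sqrt(dy * dy + dz * dz);
      double gap, ux = 0, uy = 0, uz = 0;   // unit vector away from the solid
      if (r >= rp) {
        if (adx > d2) {
          gap = adx - d2; ux = sx;
        } else {
          // inside the solid: push out through the nearest surface
          gap = 1e-3;
          if (r - rp < d2 - adx && r > 1e-9) { uy = -dy / r; uz = -dz / r; }
          else ux = sx;
        }
      } else {
        const double a = rp - r;
        if (adx <= d2) {
          gap = a;
          if (r > 1e-9) { uy = -dy / r; uz = -dz / r; }
          else { uy = 1.0; }             // on-axis: no force at this gap anyway
        } else {
          const double ax = adx - d2;
          gap = std::sqrt(a * a + ax * ax);
          if (r > 1e-9) {
            ux = ax * sx / gap; uy = -a * dy / (r * gap); uz = -a * dz / (r * gap);
          } else { ux = sx; }
        }
      }
      if (gap < wall_cut) {
        double u0 = 0.0;
        const double g2 = gap * gap;
        const double fr = wca_pair(g2, sig_pw, eps_pw, u0) * gap; // magnitude
        U += u0;
        fx[i] += fr * ux; fy[i] += fr * uy; fz[i] += fr * uz;
      }
    }
  }

  void barrier_force() {
    const double h = mi(px[head] - xw, Lx) - d2;
    if (h <= 0)
      stop("head monomer behind the exit barrier (instability)");
    const double cut = std::pow(2.0, 1.0 / 6.0) * bar_sig;
    if (h < cut) {
      double u0 = 0.0;
      const double fr = wca_pair(h * h, bar_sig, eps_pw, u0) * h;
      U += u0;
      fx[head] += fr;
    }
  }

  void field_force() {
    for (int i = 0; i < n; ++i) {
      if (q[i] == 0.0) continue;
      const double adx = std::fabs(mi(px[i] - xw, Lx));
      if (adx > d2) continue;
      const double dy = mi(py[i] - y0c, Ly);
      const double dz = mi(pz[i] - z0c, Lz);
      if (dy * dy + dz * dz <= rp * rp) fx[i] += q[i] * (-E);
    }
  }

  // one BAOAB step; forces must be current on entry, are current on exit
  void step(Xoshiro& rng) {
    const double h2 = 0.5 * dt;
    const double maxd = 0.25;     // per half-drift, so <= 0.5 sigma per step
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) { vx[i] = vy[i] = vz[i] = 0.0; continue; }
      vx[i] += h2 * fx[i]; vy[i] += h2 * fy[i]; vz[i] += h2 * fz[i];
      if (std::fabs(vx[i]) * h2 > maxd || std::fabs(vy[i]) * h2 > maxd ||
          std::fabs(vz[i]) * h2 > maxd)
        stop("instability: displacement per step exceeded 0.5 sigma; "
             "reduce dt");
      px[i] += h2 * vx[i]; py[i] += h2 * vy[i]; pz[i] += h2 * vz[i];
    }
    if (thermostat_on && gamma > 0.0) {
      const double c1 = std::exp(-gamma * dt);
      const double c2 = std::sqrt(1.0 - c1 * c1);   // kBT = m = 1
      for (int i = 0; i < n; ++i) {
        if (frozen[i]) continue;
        vx[i] = c1 * vx[i] + c2 * rng.norm();
        vy[i] = c1 * vy[i] + c2 * rng.norm();
        vz[i] = c1 * vz[i] + c2 * rng.norm();
      }
    }
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      px[i] += h2 * vx[i]; py[i] += h2 * vy[i]; pz[i] += h2 * vz[i];
    }
    forces();
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      vx[i] += h2 * fx[i]; vy[i] += h2 * fy[i]; vz[i] += h2 * fz[i];
    }
  }

  // monomer region counts relative to the wall (minimum image)
  void regions(int& cis, int& pore, int& trans) const {
    cis = pore = trans = 0;
    for (int i = 0; i < Nm; ++i) {
      const double dxw = mi(px[i] - xw, Lx);
      if (dxw < -d2) ++cis;
      else if (dxw > d2) ++trans;
      else ++pore;
    }
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return ke;
  }

  NumericMatrix pos_matrix() const {
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i) { m(i,0)=px[i]; m(i,1)=py[i]; m(i,2)=pz[i]; }
    return m;
  }
  NumericMatrix vel_matrix() const {
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i) { m(i,0)=vx[i]; m(i,1)=vy[i]; m(i,2)=vz[i]; }
    return m;
  }
};

} // namespace

// [[Rcpp::export(name = ".ps_forces")]]
List ps_forces(NumericMatrix pos, NumericMatrix vel, NumericVector charges,
               List par) {
  Engine e;
  e.init(pos, vel, charges, par);
  e.forces();
  NumericMatrix f(e.n, 3);
  for (int i = 0; i < e.n; ++i) {
    f(i, 0) = e.fx[i]; f(i, 1) = e.fy[i]; f(i, 2) = e.fz[i];
  }
  return List::create(_["forces"] = f, _["energy"] = e.U);
}

// [[Rcpp::export(name = ".ps_run_nvt")]]
List ps_run_nvt(NumericMatrix pos, NumericMatrix vel, NumericVector charges,
                List par, double time, int sample_every,
                bool freeze_head, bool thermostat, double seed) {
  Engine e;
  e.init(pos, vel, charges, par);
  e.thermostat_on = thermostat;
  if (freeze_head) e.frozen[e.head] = 1;
  Xoshiro rng((uint64_t)seed);
  const long nsteps = (long)std::ceil(time / e.dt);
  std::vector<double> ke, u, tser, v1x, v1y, v1z;
  e.forces();
  for (long s = 0; s < nsteps; ++s) {
    e.step(rng);
    if ((s + 1) % sample_every == 0) {
      ke.push_back(e.kinetic());
      u.push_back(e.U);
      tser.push_back((s + 1) * e.dt);
      v1x.push_back(e.vx[0]); v1y.push_back(e.vy[0]); v1z.push_back(e.vz[0]);
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix v1((int)v1x.size(), 3);
  for (int i = 0; i < (int)v1x.size(); ++i) {
    v1(i, 0) = v1x[i]; v1(i, 1) = v1y[i]; v1(i, 2) = v1z[i];
  }
  return List::create(_["t"] = tser, _["kinetic"] = ke, _["potential"] = u,
                      _["v1"] = v1,
                      _["positions"] = e.pos_matrix(),
                      _["velocities"] = e.vel_matrix());
}

// [[Rcpp::export(name = ".ps_run_translocation")]]
List ps_run_translocation(NumericMatrix pos, NumericMatrix vel,
                          NumericVector charges, List par,
                          double equil_time, double max_time,
                          double sample_dt, double seed) {
  Engine e;
  e.init(pos, vel, charges, par);
  Xoshiro rng((uint64_t)seed);

  // constrained equilibration: head frozen, field off
  const bool field_saved = e.field_on;
  e.field_on = false;
  e.frozen[e.head] = 1;
  e.forces();
  const long neq = (long)std::ceil(equil_time / e.dt);
  for (long s = 0; s < neq; ++s) {
    e.step(rng);
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  // release and switch the field on
  e.frozen[e.head] = 0;
  e.field_on = field_saved;
  e.forces();

  const long nmax = (long)std::ceil(max_time / e.dt);
  const int sample_every = std::max(1, (int)std::round(sample_dt / e.dt));
  const int check_every = 10;
  std::vector<double> tser; std::vector<int> nser, cser;
  int cis, pore, trans;
  e.regions(cis, pore, trans);
  // translocation coordinate: monomers transported out of the cis region,
  // n = N - cis_count clamped to [0, N] with N = Nm - 5
  const int Ntr = e.Nm - 5;
  tser.push_back(0.0);
  nser.push_back(std::max(0, std::min(Ntr, Ntr - cis)));
  cser.push_back(cis);
  double last_cis_time = 0.0;
  if (cis > 0) last_cis_time = 0.0;
  double min_head_gap = e.mi(e.px[e.head] - e.xw, e.Lx) - e.d2;
  bool done = false;
  double tau = NA_REAL;
  long s = 0;
  for (; s < nmax; ++s) {
    e.step(rng);
    const double t = (s + 1) * e.dt;
    const double hg = e.mi(e.px[e.head] - e.xw, e.Lx) - e.d2;
    if (hg < min_head_gap) min_head_gap = hg;
    if ((s + 1) % check_every == 0 || (s + 1) % sample_every == 0) {
      e.regions(cis, pore, trans);
      if (cis > 0) last_cis_time = t;
      if ((s + 1) % sample_every == 0) {
        tser.push_back(t);
        nser.push_back(std::max(0, std::min(Ntr, Ntr - cis)));
        cser.push_back(cis);
      }
      if (cis == 0 && pore == 0) {
        // hysteresis: chain centre of mass one Rg beyond the wall
        double cx = 0;
        for (int i = 0; i < e.Nm; ++i) cx += e.mi(e.px[i] - e.xw, e.Lx);
        cx /= e.Nm;
        double rg2 = 0, mx = 0, my = 0, mz = 0;
        for (int i = 0; i < e.Nm; ++i) { mx += e.px[i]; my += e.py[i]; mz += e.pz[i]; }
        mx /= e.Nm; my /= e.Nm; mz /= e.Nm;
        for (int i = 0; i < e.Nm; ++i) {
          const double ddx = e.px[i] - mx, ddy = e.py[i] - my,
                       ddz = e.pz[i] - mz;
          rg2 += ddx * ddx + ddy * ddy + ddz * ddz;
        }
        const double rg = std::sqrt(rg2 / e.Nm);
        if (cx > e.d2 + rg) {
          tau = last_cis_time;
          done = true;
          if (tser.back() != t) {
            tser.push_back(t);
            nser.push_back(std::max(0, std::min(Ntr, Ntr - cis)));
            cser.push_back(cis);
          }
          break;
        }
      }
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["tau"] = tau,
      _["status"] = done ? "completed" : "max_time_reached",
      _["t"] = tser, _["n"] = nser, _["cis"] = cser,
      _["min_head_gap"] = min_head_gap,
      _["positions"] = e.pos_matrix(),
      _["velocities"] = e.vel_matrix());
}

// mode 0: tethered chain (mean distance of monomer m to the tether point)
// mode 1: free chain (mean pair distance by bond separation)
// [[Rcpp::export(name = ".ps_run_static")]]
List ps_run_static(NumericMatrix pos, NumericMatrix vel,
                   NumericVector charges, List par, int mode,
                   double burn_time, double sample_dt, int n_samples,
                   double seed) {
  Engine e;
  e.init(pos, vel, charges, par);
  Xoshiro rng((uint64_t)seed);
  e.forces();
  const long nburn = (long)std::ceil(burn_time / e.dt);
  for (long s = 0; s < nburn; ++s) {
    e.step(rng);
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  const long gap = std::max(1L, (long)std::round(sample_dt / e.dt));
  std::vector<double> acc;
  std::vector<long> cnt;
  if (mode == 0) { acc.assign(e.Nm, 0.0); cnt.assign(e.Nm, 0); }
  else { acc.assign(e.Nm, 0.0); cnt.assign(e.Nm, 0); } // index = separation
  for (int k = 0; k < n_samples; ++k) {
    for (long s = 0; s < gap; ++s) e.step(rng);
    if (mode == 0) {
      for (int m = 0; m < e.Nm; ++m) {
        const double dx = e.px[m] - e.tx, dy = e.py[m] - e.ty,
                     dz = e.pz[m] - e.tz;
        acc[m] += std::sqrt(dx * dx + dy * dy + dz * dz);
        cnt[m] += 1;
      }
    } else {
      for (int sep = 1; sep < e.Nm; ++sep) {
        for (int i = 0; i + sep < e.Nm; ++i) {
          const double dx = e.px[i + sep] - e.px[i],
                       dy = e.py[i + sep] - e.py[i],
                       dz = e.pz[i + sep] - e.pz[i];
          acc[sep] += std::sqrt(dx * dx + dy * dy + dz * dz);
          cnt[sep] += 1;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["acc"] = acc, _["cnt"] = cnt,
                      _["positions"] = e.pos_matrix(),
                      _["velocities"] = e.vel_matrix());
}
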