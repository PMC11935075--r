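#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Unit system: lengths in Angstrom, energies in kcal/mol, masses in amu,
// time in ps.  Forces in kcal/mol/A are converted to internal acceleration
// units through KCAL = 418.4 amu A^2 ps^-2 per kcal/mol.
static const double KCAL = 418.4;

struct ToySystem {
  int n;
  NumericVector mass;
  NumericMatrix bonds;   // i, j (1-based), r0, k
  NumericMatrix angles;  // i, j, k (1-based), theta0, k
  NumericMatrix sites;   // x, y of repulsive rods
  double site_eps, site_sigma;
  double well_x, well_y, well_z, well_depth, well_width;
  double z_lo, z_hi, wall_k;
  bool has_wall;
};

static ToySystem unpack_system(const List& sys) {
  ToySystem s;
  s.mass = as<NumericVector>(sys["masses"]);
  s.n = s.mass.size();
  s.bonds = as<NumericMatrix>(sys["bonds"]);
  s.angles = as<NumericMatrix>(sys["angles"]);
  s.sites = as<NumericMatrix>(sys["sites"]);
  s.site_eps = as<double>(sys["site_eps"]);
  s.site_sigma = as<double>(sys["site_sigma"]);
  NumericVector wc = as<NumericVector>(sys["well_center"]);
  s.well_x = wc[0]; s.well_y = wc[1]; s.well_z = wc[2];
  s.well_depth = as<double>(sys["well_depth"]);
  s.well_width = as<double>(sys["well_width"]);
  s.z_lo = as<double>(sys["z_lo"]);
  s.z_hi = as<double>(sys["z_hi"]);
  s.wall_k = as<double>(sys["wall_k"]);
  s.has_wall = s.wall_k > 0.0;
  return s;
}

// Conservative forces of the toy system, in kcal/mol/A.  Returns potential
// energy; fills fx/fy/fz (overwritten).
static double system_forces(const ToySystem& s,
                            const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& z,
                            std::vector<double>& fx,
                            std::vector<double>& fy,
                            std::vector<double>& fz) {
  double pe = 0.0;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  // harmonic bonds: E = 1/2 k (r - r0)^2
  for (int b = 0; b < s.bonds.nrow(); ++b) {
    int i = (int)s.bonds(b, 0) - 1, j = (int)s.bonds(b, 1) - 1;
    double r0 = s.bonds(b, 2), kb = s.bonds(b, 3);
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double dr = r - r0;
    pe += 0.5 * kb * dr * dr;
    double f = -kb * dr / r;  // along j - i, applied to j
    fx[j] += f * dx; fy[j] += f * dy; fz[j] += f * dz;
    fx[i] -= f * dx; fy[i] -= f * dy; fz[i] -= f * dz;
  }

  // harmonic angles: E = 1/2 k (theta - theta0)^2
  for (int a = 0; a < s.angles.nrow(); ++a) {
    int i = (int)s.angles(a, 0) - 1, j = (int)s.angles(a, 1) - 1,
        k = (int)s.angles(a, 2) - 1;
    double th0 = s.angles(a, 3), ka = s.angles(a, 4);
    double ax = x[i] - x[j], ay = y[i] - y[j], az = z[i] - z[j];
    double bx = x[k] - x[j], by = y[k] - y[j], bz = z[k] - z[j];
    double ra = std::sqrt(ax * ax + ay * ay + az * az);
    double rb = std::sqrt(bx * bx + by * by + bz * bz);
    if (ra < 1e-12 || rb < 1e-12) continue;
    double cosang = (ax * bx + ay * by + az * bz) / (ra * rb);
    cosang = std::max(-1.0, std::min(1.0, cosang));
    double th = std::acos(cosang);
    double sinang = std::sqrt(std::max(1e-12, 1.0 - cosang * cosang));
    double dth = th - th0;
    pe += 0.5 * ka * dth * dth;
    double coef = ka * dth / sinang;  // dE/dcos
    // dcos/dri and dcos/drk
    double dcax = (bx / (ra * rb)) - cosang * ax / (ra * ra);
    double dcay = (by / (ra * rb)) - cosang * ay / (ra * ra);
    double dcaz = (bz / (ra * rb)) - cosang * az / (ra * ra);
    double dcbx = (ax / (ra * rb)) - cosang * bx / (rb * rb);
    double dcby = (ay / (ra * rb)) - cosang * by / (rb * rb);
    double dcbz = (az / (ra * rb)) - cosang * bz / (rb * rb);
    fx[i] += coef * dcax; fy[i] += coef * dcay; fz[i] += coef * dcaz;
    fx[k] += coef * dcbx; fy[k] += coef * dcby; fz[k] += coef * dcbz;
    fx[j] -= coef * (dcax + dcbx);
    fy[j] -= coef * (dcay + dcby);
    fz[j] -= coef * (dcaz + dcbz);
  }

  // repulsive subunit rods (z-independent Gaussians in xy):
  // E = eps * exp(-rho^2 / (2 sigma^2))
  double s2 = s.site_sigma * s.site_sigma;
  for (int m = 0; m < s.sites.nrow(); ++m) {
    double sx = s.sites(m, 0), sy = s.sites(m, 1);
    for (int i = 0; i < s.n; ++i) {
      double dx = x[i] - sx, dy = y[i] - sy;
      double r2 = dx * dx + dy * dy;
      if (r2 > 25.0 * s2) continue;
      double e = s.site_eps * std::exp(-0.5 * r2 / s2);
      pe += e;
      double f = e / s2;  // -dE/dr along +d
      fx[i] += f * dx; fy[i] += f * dy;
    }
  }

  // attractive binding well (3D Gaussian): E = -depth * exp(-r^2/(2 w^2))
  if (s.well_depth != 0.0) {
    double w2 = s.well_width * s.well_width;
    for (int i = 0; i < s.n; ++i) {
      double dx = x[i] - s.well_x, dy = y[i] - s.well_y, dz = z[i] - s.well_z;
      double r2 = dx * dx + dy * dy + dz * dz;
      double e = -s.well_depth * std::exp(-0.5 * r2 / w2);
      pe += e;
      double f = e / w2;  // note e < 0: pulls toward center
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    }
  }

  // flat-bottom membrane walls in z: E = 1/2 k (z - bound)^2 outside slab
  if (s.has_wall) {
    for (int i = 0; i < s.n; ++i) {
      if (z[i] > s.z_hi) {
        double d = z[i] - s.z_hi;
        pe += 0.5 * s.wall_k * d * d;
        fz[i] -= s.wall_k * d;
      } else if (z[i] < s.z_lo) {
        double d = z[i] - s.z_lo;
        pe += 0.5 * s.wall_k * d * d;
        fz[i] -= s.wall_k * d;
      }
    }
  }
  return pe;
}

// Umbrella bias on the group-COM xy-distance to an anchor:
// E = 1/2 k (xi - xi0)^2, xi = sqrt((X-ax)^2 + (Y-ay)^2).
struct UmbrellaBias {
  bool active;
  std::vector<int> group;   // 0-based
  double gmass;
  double ax, ay, k, center;
};

static double apply_umbrella(const UmbrellaBias& u, const NumericVector& mass,
                             const std::vector<double>& x,
                             const std::vector<double>& y,
                             std::vector<double>& fx, std::vector<double>& fy,
                             double* xi_out) {
  if (!u.active) return 0.0;
  double X = 0.0, Y = 0.0;
  for (int idx : u.group) { X += mass[idx] * x[idx]; Y += mass[idx] * y[idx]; }
  X /= u.gmass; Y /= u.gmass;
  double dx = X - u.ax, dy = Y - u.ay;
  double xi = std::sqrt(dx * dx + dy * dy);
  if (xi_out) *xi_out = xi;
  if (xi < 1e-10) return 0.5 * u.k * u.center * u.center;
  double dxi = xi - u.center;
  double fmag = -u.k * dxi;  // dE/dxi, force along gradient
  double ux = dx / xi, uy = dy / xi;
  for (int idx : u.group) {
    double wgt = mass[idx] / u.gmass;
    fx[idx] += wgt * fmag * ux;
    fy[idx] += wgt * fmag * uy;
  }
  return 0.5 * u.k * dxi * dxi;
}

static void check_finite(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z, long step) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("numerical failure: non-finite coordinate at step %d (bead %d)",
           (int)step, (int)i + 1);
  }
}

// One BAOAB Langevin step for the whole bead set.  fext is a constant
// per-bead external force (kcal/mol/A); force arrays are assumed current on
// entry and are current on exit.
struct Propagator {
  const ToySystem* sys;
  const NumericMatrix* fext;  // may be null
  UmbrellaBias umb;
  double dt, c1, c2, kT;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  double pe;
  double last_xi;

  void eval_forces() {
    pe = system_forces(*sys, x, y, z, fx, fy, fz);
    if (fext) {
      for (int i = 0; i < sys->n; ++i) {
        fx[i] += (*fext)(i, 0);
        fy[i] += (*fext)(i, 1);
        fz[i] += (*fext)(i, 2);
      }
    }
    pe += apply_umbrella(umb, sys->mass, x, y, fx, fy, &last_xi);
  }

  void step() {
    int n = sys->n;
    double h = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      double im = KCAL / sys->mass[i];
      vx[i] += h * fx[i] * im;
      vy[i] += h * fy[i] * im;
      vz[i] += h * fz[i] * im;
      x[i] += h * vx[i]; y[i] += h * vy[i]; z[i] += h * vz[i];
    }
    if (c2 > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kT * KCAL / sys->mass[i]);
        vx[i] = c1 * vx[i] + c2 * sd * norm_rand();
        vy[i] = c1 * vy[i] + c2 * sd * norm_rand();
        vz[i] = c1 * vz[i] + c2 * sd * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i] += h * vx[i]; y[i] += h * vy[i]; z[i] += h * vz[i];
    }
    eval_forces();
    for (int i = 0; i < n; ++i) {
      double im = KCAL / sys->mass[i];
      vx[i] += h * fx[i] * im;
      vy[i] += h * fy[i] * im;
      vz[i] += h * fz[i] * im;
    }
  }
};

static Propagator make_prop(const NumericMatrix& pos, const NumericMatrix& vel,
                            const ToySystem& s, double dt, double gamma,
                            double kT) {
  Propagator p;
  p.sys = &s;
  p.fext = nullptr;
  p.umb.active = false;
  p.dt = dt;
  p.kT = kT;
  p.c1 = std::exp(-gamma * dt);
  p.c2 = (gamma > 0.0) ? std::sqrt(1.0 - p.c1 * p.c1) : 0.0;
  int n = s.n;
  p.x.resize(n); p.y.resize(n); p.z.resize(n);
  p.vx.resize(n); p.vy.resize(n); p.vz.resize(n);
  p.fx.resize(n); p.fy.resize(n); p.fz.resize(n);
  for (int i = 0; i < n; ++i) {
    p.x[i] = pos(i, 0); p.y[i] = pos(i, 1); p.z[i] = pos(i, 2);
    p.vx[i] = vel(i, 0); p.vy[i] = vel(i, 1); p.vz[i] = vel(i, 2);
  }
  return p;
}

static NumericMatrix snap(const Propagator& p, bool velocities) {
  int n = p.sys->n;
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    if (velocities) {
      m(i, 0) = p.vx[i]; m(i, 1) = p.vy[i]; m(i, 2) = p.vz[i];
    } else {
      m(i, 0) = p.x[i]; m(i, 1) = p.y[i]; m(i, 2) = p.z[i];
    }
  }
  return m;
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, List sys, double dt,
                double gamma, double kT, long n_steps, long stride,
                Nullable<NumericMatrix> fext, Nullable<List> umbrella) {
  RNGScope scope;
  ToySystem s = unpack_system(sys);
  Propagator p = make_prop(pos, vel, s, dt, gamma, kT);
  NumericMatrix fext_m;
  if (fext.isNotNull()) { fext_m = fext.get(); p.fext = &fext_m; }
  if (umbrella.isNotNull()) {
    List u(umbrella.get());
    p.umb.active = true;
    IntegerVector g = as<IntegerVector>(u["group"]);
    p.umb.gmass = 0.0;
    for (int i = 0; i < g.size(); ++i) {
      p.umb.group.push_back(g[i] - 1);
      p.umb.gmass += s.mass[g[i] - 1];
    }
    p.umb.ax = as<double>(u["anchor_x"]);
    p.umb.ay = as<double>(u["anchor_y"]);
    p.umb.k = as<double>(u["k"]);
    p.umb.center = as<double>(u["center"]);
  }
  p.eval_forces();

  long n_frames = n_steps / stride + 1;
  List frames(n_frames), vels(n_frames);
  NumericVector times(n_frames), energies(n_frames), xis(n_frames);
  long fidx = 0;
  frames[fidx] = snap(p, false);
  vels[fidx] = snap(p, true);
  times[fidx] = 0.0;
  energies[fidx] = p.pe;
  xis[fidx] = p.umb.active ? p.last_xi : NA_REAL;
  ++fidx;
  for (long st = 1; st <= n_steps; ++st) {
    p.step();
    if (st % 1000 == 0) check_finite(p.x, p.y, p.z, st);
    if (st % stride == 0 && fidx < n_frames) {
      check_finite(p.x, p.y, p.z, st);
      frames[fidx] = snap(p, false);
      vels[fidx] = snap(p, true);
      times[fidx] = st * dt;
      energies[fidx] = p.pe;
      xis[fidx] = p.umb.active ? p.last_xi : NA_REAL;
      ++fidx;
    }
  }
  check_finite(p.x, p.y, p.z, n_steps);
  return List::create(_["frames"] = frames, _["velocities"] = vels,
                      _["times"] = times, _["potential"] = energies,
                      _["xi"] = xis, _["final_pos"] = snap(p, false),
                      _["final_vel"] = snap(p, true));
}

// [[Rcpp::export]]
double cpp_system_energy(NumericMatrix pos, List sys) {
  ToySystem s = unpack_system(sys);
  int n = s.n;
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  return system_forces(s, x, y, z, fx, fy, fz);
}

static void group_com(const Propagator& p, const std::vector<int>& g,
                      double gm, double* cx, double* cy, double* cz) {
  double X = 0, Y = 0, Z = 0;
  for (int idx : g) {
    X += p.sys->mass[idx] * p.x[idx];
    Y += p.sys->mass[idx] * p.y[idx];
    Z += p.sys->mass[idx] * p.z[idx];
  }
  *cx = X / gm; *cy = Y / gm; *cz = Z / gm;
}

// S-RaMD-MD controller.  The RaMD force (magnitude a * m_group, kcal/mol/A)
// acts on the force group along a random unit direction; at the end of every
// phase window (biased or relaxation) progress of the force-group COM is
// evaluated and the direction is redrawn when progress < d.  The event
// criterion is the mid-tail COM crossing the ring radius while inside the
// membrane slab.
// [[Rcpp::export]]
List cpp_sramd_run(NumericMatrix pos, NumericMatrix vel, List sys, double dt,
                   double gamma, double kT, IntegerVector group,
                   IntegerVector midtail, double accel, double thr_d,
                   long eval_window, long md_relax, long max_steps,
                   long stride, double ring_radius, int displacement_mode) {
  RNGScope scope;
  ToySystem s = unpack_system(sys);
  Propagator p = make_prop(pos, vel, s, dt, gamma, kT);

  std::vector<int> g, mt;
  double gmass = 0.0, mtmass = 0.0;
  for (int i = 0; i < group.size(); ++i) {
    g.push_back(group[i] - 1);
    gmass += s.mass[group[i] - 1];
  }
  for (int i = 0; i < midtail.size(); ++i) {
    mt.push_back(midtail[i] - 1);
    mtmass += s.mass[midtail[i] - 1];
  }

  NumericMatrix fext(s.n, 3);
  auto set_dir = [&](double dx, double dy, double dz, bool on) {
    for (int idx : g) {
      double f = on ? accel * s.mass[idx] : 0.0;
      fext(idx, 0) = f * dx; fext(idx, 1) = f * dy; fext(idx, 2) = f * dz;
    }
  };
  auto draw_dir = [&](double* dx, double* dy, double* dz) {
    double nx, ny, nz, nrm;
    do {
      nx = norm_rand(); ny = norm_rand(); nz = norm_rand();
      nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
    } while (nrm < 1e-8);
    *dx = nx / nrm; *dy = ny / nrm; *dz = nz / nrm;
  };

  double dx, dy, dz;
  draw_dir(&dx, &dy, &dz);
  p.fext = &fext;
  p.eval_forces();

  long n_frames = max_steps / stride + 2;
  List frames(n_frames);
  NumericVector times(n_frames);
  long fidx = 0;
  frames[fidx] = snap(p, false);
  times[fidx] = 0.0;
  ++fidx;

  // phase log rows: window, phase (0 ramd / 1 md), displacement, redrawn,
  // dir x/y/z
  std::vector<double> log_rows;
  bool event = false;
  long event_step = -1;
  double exit_x = NA_REAL, exit_y = NA_REAL, exit_z = NA_REAL;

  auto midtail_out = [&](double* ex, double* ey, double* ez) {
    double cx, cy, cz;
    group_com(p, mt, mtmass, &cx, &cy, &cz);
    double rho = std::sqrt(cx * cx + cy * cy);
    if (rho > ring_radius && cz >= s.z_lo && cz <= s.z_hi) {
      *ex = cx; *ey = cy; *ez = cz;
      return true;
    }
    return false;
  };

  long step = 0, window = 0;
  bool ramd_phase = true;
  while (step < max_steps && !event) {
    long phase_len = ramd_phase ? eval_window : md_relax;
    if (phase_len <= 0) { ramd_phase = !ramd_phase; continue; }
    phase_len = std::min(phase_len, max_steps - step);
    set_dir(dx, dy, dz, ramd_phase);
    p.eval_forces();

    double r0;
    double cx, cy, cz, lx, ly, lz;
    group_com(p, g, gmass, &cx, &cy, &cz);
    double tot = 0.0;
    lx = ly = lz = 0.0;
    for (int i = 0; i < s.n; ++i) {
      lx += s.mass[i] * p.x[i]; ly += s.mass[i] * p.y[i];
      lz += s.mass[i] * p.z[i]; tot += s.mass[i];
    }
    lx /= tot; ly /= tot; lz /= tot;
    double gx0 = cx, gy0 = cy, gz0 = cz;
    r0 = std::sqrt((cx - lx) * (cx - lx) + (cy - ly) * (cy - ly) +
                   (cz - lz) * (cz - lz));

    for (long k = 0; k < phase_len; ++k) {
      p.step();
      ++step;
      if (step % stride == 0 && fidx < n_frames) {
        check_finite(p.x, p.y, p.z, step);
        frames[fidx] = snap(p, false);
        times[fidx] = step * dt;
        ++fidx;
      }
      if (step % 10 == 0 || k == phase_len - 1) {
        check_finite(p.x, p.y, p.z, step);
        if (midtail_out(&exit_x, &exit_y, &exit_z)) {
          event = true;
          event_step = step;
          break;
        }
      }
    }

    // stall evaluation at the window boundary
    group_com(p, g, gmass, &cx, &cy, &cz);
    tot = 0.0; lx = ly = lz = 0.0;
    for (int i = 0; i < s.n; ++i) {
      lx += s.mass[i] * p.x[i]; ly += s.mass[i] * p.y[i];
      lz += s.mass[i] * p.z[i]; tot += s.mass[i];
    }
    lx /= tot; ly /= tot; lz /= tot;
    double disp;
    if (displacement_mode == 0) {
      double r1 = std::sqrt((cx - lx) * (cx - lx) + (cy - ly) * (cy - ly) +
                            (cz - lz) * (cz - lz));
      disp = r1 - r0;
    } else {
      disp = std::sqrt((cx - gx0) * (cx - gx0) + (cy - gy0) * (cy - gy0) +
                       (cz - gz0) * (cz - gz0));
    }
    bool redraw = disp < thr_d;
    log_rows.push_back((double)window);
    log_rows.push_back(ramd_phase ? 0.0 : 1.0);
    log_rows.push_back(disp);
    log_rows.push_back(redraw ? 1.0 : 0.0);
    log_rows.push_back(dx); log_rows.push_back(dy); log_rows.push_back(dz);
    if (redraw && !event) draw_dir(&dx, &dy, &dz);
    ++window;
    if (md_relax > 0) ramd_phase = !ramd_phase;
  }

  if (fidx < n_frames) {  // always record the final frame
    frames[fidx] = snap(p, false);
    times[fidx] = step * dt;
    ++fidx;
  }
  List out_frames(fidx);
  NumericVector out_times(fidx);
  for (long i = 0; i < fidx; ++i) {
    out_frames[i] = frames[i];
    out_times[i] = times[i];
  }
  int nlog = log_rows.size() / 7;
  NumericMatrix logm(nlog, 7);
  for (int r = 0; r < nlog; ++r)
    for (int c = 0; c < 7; ++c) logm(r, c) = log_rows[r * 7 + c];

  return List::create(
      _["frames"] = out_frames, _["times"] = out_times, _["log"] = logm,
      _["occurred"] = event, _["event_step"] = event_step,
      _["exit"] = NumericVector::create(exit_x, exit_y, exit_z),
      _["final_pos"] = snap(p, false), _["final_vel"] = snap(p, true),
      _["n_steps"] = (double)step);
}

// Analytic 1D reference potentials.  kind: 0 flat(c), 1 harmonic(k, x0),
// 2 double_well(B, a, tilt) with
//   F(x) = B ((x/a)^2 - 1)^2 + tilt * x / (2 a).
static double pmf_force(int kind, const NumericVector& par, double x,
                        double* energy) {
  switch (kind) {
    case 0:
      *energy = par[0];
      return 0.0;
    case 1: {
      double k = par[0], x0 = par[1];
      *energy = 0.5 * k * (x - x0) * (x - x0);
      return -k * (x - x0);
    }
    case 2: {
      double B = par[0], a = par[1], tilt = par[2];
      double u = x / a, q = u * u - 1.0;
      *energy = B * q * q + 0.5 * tilt * u;
      return -(4.0 * B * u * q / a + 0.5 * tilt / a);
    }
    default:
      stop("cannot integrate this potential kind");
  }
  return 0.0;
}

// Single-coordinate BAOAB sampler on an analytic potential, optionally with
// a harmonic umbrella bias.  Used for engine-level statistical-mechanics
// oracles and for biased-window sampling on reference landscapes.
// [[Rcpp::export]]
List cpp_langevin_xi(double x0, double v0, double mass, double dt,
                     double gamma, double kT, long n_steps, long stride,
                     int kind, NumericVector params, double bias_k,
                     double bias_center) {
  RNGScope scope;
  double c1 = std::exp(-gamma * dt);
  double c2 = (gamma > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  double sd = std::sqrt(kT * KCAL / mass);
  double im = KCAL / mass;
  long n_out = n_steps / stride;
  NumericVector xs(n_out), vs(n_out);
  double x = x0, v = v0, e;
  double f = pmf_force(kind, params, x, &e) - bias_k * (x - bias_center);
  long oidx = 0;
  for (long st = 1; st <= n_steps; ++st) {
    v += 0.5 * dt * f * im;
    x += 0.5 * dt * v;
    if (c2 > 0.0) v = c1 * v + c2 * sd * norm_rand();
    x += 0.5 * dt * v;
    f = pmf_force(kind, params, x, &e) - bias_k * (x - bias_center);
    v += 0.5 * dt * f * im;
    if (st % stride == 0 && oidx < n_out) {
      if (!std::isfinite(x))
        stop("numerical failure: non-finite coordinate at step %d", (int)st);
      xs[oidx] = x;
      vs[oidx] = v;
      ++oidx;
    }
  }
  return List::create(_["x"] = xs, _["v"] = vs, _["final_x"] = x,
                      _["final_v"] = v);
}
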