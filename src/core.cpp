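#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Units: nm, kJ/mol, g/mol (amu), ps. 1 kJ/mol = 1 amu nm^2/ps^2, so
// F[kJ/mol/nm] / m[amu] = a[nm/ps^2] with no conversion factor.
static const double KB = 0.008314462618; // kJ/mol/K

struct Pot { double k, r0, rc; };

static inline const Pot& resolve(const Pot& pp, const Pot& pd, const Pot& dd,
                                 int si, int sj) {
  if (si == 1 && sj == 1) return pp;
  if (si == 2 && sj == 2) return dd;
  return pd;
}

// One force/energy/virial pass over the fixed bond topology.
// When detect = true also records newly broken bonds (current species'
// cutoff) and pristine blocks with a neighbour at >= switch_rc.
struct ForcePass {
  double pe, wxx, wyy, wxy, maxf2;
  int n_broken_new;
};

static ForcePass compute_forces(
    const std::vector<double>& x, const std::vector<double>& y,
    const IntegerVector& bi, const IntegerVector& bj,
    const std::vector<int>& species,
    const Pot& pp, const Pot& pd, const Pot& dd,
    const std::vector<char>& clamped,
    bool periodic_x, double lx,
    std::vector<double>& fx, std::vector<double>& fy,
    bool detect, double switch_rc, int step,
    std::vector<int>& broken_first, std::vector<double>& broken_len,
    std::vector<char>& to_switch) {
  const int n = (int)x.size();
  const int m = bi.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  ForcePass out{0.0, 0.0, 0.0, 0.0, 0.0, 0};
  for (int b = 0; b < m; ++b) {
    const int i = bi[b], j = bj[b];
    double dx = x[j] - x[i], dy = y[j] - y[i];
    if (periodic_x) dx -= lx * std::round(dx / lx);
    const double r = std::sqrt(dx * dx + dy * dy);
    const Pot& p = resolve(pp, pd, dd, species[i], species[j]);
    if (r <= p.rc) {
      const double dr = r - p.r0;
      out.pe += p.k * (dr * dr - (p.rc - p.r0) * (p.rc - p.r0));
      const double fscal = -2.0 * p.k * dr; // >0 repulsive
      const double fr = fscal / r;
      // force on j = +fscal * u, u = (dx,dy)/r pointing i -> j
      fx[j] += fr * dx; fy[j] += fr * dy;
      fx[i] -= fr * dx; fy[i] -= fr * dy;
      out.wxx += fr * dx * dx;
      out.wyy += fr * dy * dy;
      out.wxy += fr * dx * dy;
    }
    if (detect) {
      if (r >= p.rc && broken_first[b] == NA_INTEGER) {
        broken_first[b] = step;
        broken_len[b] = r;
        ++out.n_broken_new;
      }
      if (r >= switch_rc) {
        if (species[i] == 1) to_switch[i] = 1;
        if (species[j] == 1) to_switch[j] = 1;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    // grips fix the loading-axis (x) coordinate only; y stays a free DOF
    const double f2 = clamped[i] ? fy[i] * fy[i]
                                 : fx[i] * fx[i] + fy[i] * fy[i];
    if (f2 > out.maxf2) out.maxf2 = f2;
  }
  return out;
}

// [[Rcpp::export]]
List cg_run(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species0,
            NumericVector mass, IntegerMatrix bonds, LogicalVector clamped0,
            NumericVector pot_pp, NumericVector pot_pd, NumericVector pot_dd,
            double dt, int n_steps, double temperature, double friction,
            int series_every, int snapshot_every, double force_tol,
            bool periodic_x, double box_lx,
            IntegerVector broken_first0, NumericVector broken_len0,
            double time0) {
  const int n = pos0.nrow();
  const int m = bonds.nrow();
  Pot pp{pot_pp[0], pot_pp[1], pot_pp[2]};
  Pot pd{pot_pd[0], pot_pd[1], pot_pd[2]};
  Pot dd{pot_dd[0], pot_dd[1], pot_dd[2]};
  const double switch_rc = pp.rc;        // pristine rupture cutoff drives switching
  const double disp_guard = pp.r0;       // per-step displacement > r0 => divergence

  std::vector<double> x(n), y(n), vx(n), vy(n), fx(n), fy(n), xprev(n), yprev(n);
  std::vector<int> species(n);
  std::vector<char> clamped(n), to_switch(n, 0);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
    species[i] = species0[i];
    clamped[i] = clamped0[i] ? 1 : 0;
  }
  IntegerVector bi(m), bj(m);
  for (int b = 0; b < m; ++b) { bi[b] = bonds(b, 0) - 1; bj[b] = bonds(b, 1) - 1; }

  std::vector<int> broken_first(m);
  std::vector<double> broken_len(m);
  for (int b = 0; b < m; ++b) {
    broken_first[b] = broken_first0[b];
    broken_len[b] = broken_len0[b];
  }
  int n_damaged = 0, n_broken = 0;
  for (int i = 0; i < n; ++i) if (species[i] == 2) ++n_damaged;
  for (int b = 0; b < m; ++b) if (broken_first[b] != NA_INTEGER) ++n_broken;

  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = (friction > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;

  std::vector<double> series; // step,time,sxx,syy,sxy,pe,n_damaged,n_broken
  std::vector<int> sw_step, sw_id;
  List snapshots;

  auto area = [&]() -> double {
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    const double w = periodic_x ? box_lx : (xmax - xmin);
    return w * (ymax - ymin);
  };

  ForcePass fp = compute_forces(x, y, bi, bj, species, pp, pd, dd, clamped,
                                periodic_x, box_lx, fx, fy,
                                false, switch_rc, 0, broken_first, broken_len,
                                to_switch);

  auto record = [&](int step) {
    const double A = area();
    double kxx = 0.0, kyy = 0.0, kxy = 0.0;
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) continue;
      kxx += mass[i] * vx[i] * vx[i];
      kyy += mass[i] * vy[i] * vy[i];
      kxy += mass[i] * vx[i] * vy[i];
    }
    const double inv = (A > 0.0) ? 1.0 / A : NA_REAL;
    series.push_back((double)step);
    series.push_back(time0 + step * dt);
    series.push_back((fp.wxx + kxx) * inv);
    series.push_back((fp.wyy + kyy) * inv);
    series.push_back((fp.wxy + kxy) * inv);
    series.push_back(fp.pe);
    series.push_back((double)n_damaged);
    series.push_back((double)n_broken);
  };
  auto snapshot = [&](int step) {
    NumericMatrix P(n, 2), V(n, 2);
    IntegerVector S(n);
    for (int i = 0; i < n; ++i) {
      P(i, 0) = x[i]; P(i, 1) = y[i];
      V(i, 0) = vx[i]; V(i, 1) = vy[i];
      S[i] = species[i];
    }
    snapshots.push_back(List::create(_["step"] = step,
                                     _["time_ps"] = time0 + step * dt,
                                     _["positions"] = P, _["velocities"] = V,
                                     _["species"] = S));
  };

  if (series_every > 0) record(0);
  if (snapshot_every > 0) snapshot(0);

  int steps_done = 0;
  bool converged = (force_tol > 0.0) && (std::sqrt(fp.maxf2) < force_tol);

  for (int step = 1; step <= n_steps && !converged; ++step) {
    xprev = x; yprev = y;
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (!clamped[i]) vx[i] += 0.5 * dt * fx[i] / mass[i];
      vy[i] += 0.5 * dt * fy[i] / mass[i];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (!clamped[i]) x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
    }
    // O: Ornstein-Uhlenbeck velocity update (exact for the free particle)
    if (friction > 0.0) {
      for (int i = 0; i < n; ++i) {
        const double sig = std::sqrt(KB * temperature / mass[i]);
        if (!clamped[i]) vx[i] = c1 * vx[i] + c2 * sig * norm_rand();
        vy[i] = c1 * vy[i] + c2 * sig * norm_rand();
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (!clamped[i]) x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
    }
    // divergence guard
    for (int i = 0; i < n; ++i) {
      const double ddx = x[i] - xprev[i], ddy = y[i] - yprev[i];
      if (ddx * ddx + ddy * ddy > disp_guard * disp_guard)
        stop("dynamics unstable: block %d moved more than r0 in one step (step %d)",
             i + 1, step);
    }
    // force at new positions + rupture/switch detection (pre-switch species)
    std::fill(to_switch.begin(), to_switch.end(), 0);
    fp = compute_forces(x, y, bi, bj, species, pp, pd, dd, clamped,
                        periodic_x, box_lx, fx, fy,
                        true, switch_rc, step, broken_first, broken_len,
                        to_switch);
    n_broken += fp.n_broken_new;
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (!clamped[i]) vx[i] += 0.5 * dt * fx[i] / mass[i];
      vy[i] += 0.5 * dt * fy[i] / mass[i];
    }
    // apply all switches simultaneously; refresh forces if species changed
    int n_sw = 0;
    for (int i = 0; i < n; ++i) {
      if (to_switch[i]) {
        species[i] = 2;
        sw_step.push_back(step);
        sw_id.push_back(i + 1);
        ++n_damaged;
        ++n_sw;
      }
    }
    if (n_sw > 0) {
      fp = compute_forces(x, y, bi, bj, species, pp, pd, dd, clamped,
                          periodic_x, box_lx, fx, fy,
                          false, switch_rc, step, broken_first, broken_len,
                          to_switch);
    }
    steps_done = step;
    if (series_every > 0 && step % series_every == 0) record(step);
    if (snapshot_every > 0 && step % snapshot_every == 0) snapshot(step);
    if (force_tol > 0.0 && std::sqrt(fp.maxf2) < force_tol) converged = true;
    if (step % 4096 == 0) checkUserInterrupt();
  }

  NumericMatrix pos(n, 2), vel(n, 2);
  IntegerVector spec(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = x[i]; pos(i, 1) = y[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i];
    spec[i] = species[i];
  }
  const int nrow_series = (int)series.size() / 8;
  NumericMatrix S(nrow_series, 8);
  for (int r = 0; r < nrow_series; ++r)
    for (int c = 0; c < 8; ++c) S(r, c) = series[r * 8 + c];
  colnames(S) = CharacterVector::create("step", "time_ps", "sigma_xx", "sigma_yy",
                                        "sigma_xy", "potential_energy",
                                        "n_damaged", "n_broken_bonds");
  IntegerVector bf(m);
  NumericVector bl(m);
  for (int b = 0; b < m; ++b) { bf[b] = broken_first[b]; bl[b] = broken_len[b]; }

  return List::create(
    _["positions"] = pos, _["velocities"] = vel, _["species"] = spec,
    _["series"] = S,
    _["switch_step"] = wrap(sw_step), _["switch_id"] = wrap(sw_id),
    _["broken_first_step"] = bf, _["broken_length"] = bl,
    _["steps_done"] = steps_done,
    _["converged"] = converged,
    _["max_force"] = std::sqrt(fp.maxf2),
    _["potential_energy"] = fp.pe,
    _["snapshots"] = snapshots,
    _["time_ps"] = time0 + steps_done * dt);
}
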