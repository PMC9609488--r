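// Damped bead-spring dynamics for fiber non-penetration enforcement.
// Fibers are chains of spherical particles joined by harmonic bonds and
// cosine angle potentials; non-bonded particles closer than the contact
// cutoff Rc = (d_i + d_j)/2 repel through a soft sinusoidal potential.
// All geometry uses the minimum-image convention in a cubic periodic box.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double wrap_delta(double d, double L) {
  // minimum-image displacement component; truncating cast is much cheaper
  // than std::round on generic x86 targets and exact away from half-box ties
  double q = d / L;
  d -= L * (double)(long long)(q >= 0 ? q + 0.5 : q - 0.5);
  return d;
}

struct PairList {
  std::vector<int> i, j;
  std::vector<double> ref; // positions at last build (flattened)
  double skin = 0.0;
};

// contact exclusion: bonded pairs and angle trios, i.e. particles of the
// same fiber at most 2 apart along the chain
static inline bool excluded(const IntegerVector& fib, const IntegerVector& idx,
                            int a, int b) {
  return fib[a] == fib[b] && std::abs(idx[a] - idx[b]) <= 2;
}

static void build_pairs(const NumericMatrix& pos, const IntegerVector& fib,
                        const IntegerVector& idx, double L, double cutoff,
                        double skin, PairList& pl) {
  const int n = pos.nrow();
  const double reach = cutoff + skin;
  pl.i.clear(); pl.j.clear();
  pl.skin = skin;
  pl.ref.assign(3 * (size_t)n, 0.0);
  for (int a = 0; a < n; ++a)
    for (int k = 0; k < 3; ++k) pl.ref[3 * (size_t)a + k] = pos(a, k);

  int nc = std::max(1, (int)std::floor(L / reach));
  if (nc < 3) {
    // box too small for cell lists: all pairs
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        if (excluded(fib, idx, a, b)) continue;
        double dx = wrap_delta(pos(a,0) - pos(b,0), L);
        double dy = wrap_delta(pos(a,1) - pos(b,1), L);
        double dz = wrap_delta(pos(a,2) - pos(b,2), L);
        if (dx*dx + dy*dy + dz*dz < reach * reach) {
          pl.i.push_back(a); pl.j.push_back(b);
        }
      }
    return;
  }
  double cell = L / nc;
  std::vector<int> head((size_t)nc * nc * nc, -1), next(n, -1);
  auto cidx = [&](double x) {
    int c = (int)std::floor(x / cell);
    c %= nc; if (c < 0) c += nc;
    return c;
  };
  for (int a = 0; a < n; ++a) {
    int cx = cidx(pos(a,0)), cy = cidx(pos(a,1)), cz = cidx(pos(a,2));
    int c = cx + nc * (cy + nc * cz);
    next[a] = head[c]; head[c] = a;
  }
  const double r2max = reach * reach;
  for (int cz = 0; cz < nc; ++cz)
  for (int cy = 0; cy < nc; ++cy)
  for (int cx = 0; cx < nc; ++cx) {
    int c = cx + nc * (cy + nc * cz);
    for (int a = head[c]; a >= 0; a = next[a]) {
      for (int oz = -1; oz <= 1; ++oz)
      for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        int dx_ = (cx + ox + nc) % nc, dy_ = (cy + oy + nc) % nc,
            dz_ = (cz + oz + nc) % nc;
        int c2 = dx_ + nc * (dy_ + nc * dz_);
        for (int b = head[c2]; b >= 0; b = next[b]) {
          if (b <= a) continue;
          if (excluded(fib, idx, a, b)) continue;
          double ddx = wrap_delta(pos(a,0) - pos(b,0), L);
          double ddy = wrap_delta(pos(a,1) - pos(b,1), L);
          double ddz = wrap_delta(pos(a,2) - pos(b,2), L);
          if (ddx*ddx + ddy*ddy + ddz*ddz < r2max) {
            pl.i.push_back(a); pl.j.push_back(b);
          }
        }
      }
    }
  }
}

// f_i = -2 kb (Rij - R0) rij/Rij, f_j = -f_i
static void add_bond_forces(const NumericMatrix& pos, const IntegerMatrix& bonds,
                            const NumericVector& r0, const NumericVector& kb,
                            double L, NumericMatrix& f, double* energy) {
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = wrap_delta(pos(i,0) - pos(j,0), L);
    double dy = wrap_delta(pos(i,1) - pos(j,1), L);
    double dz = wrap_delta(pos(i,2) - pos(j,2), L);
    double R = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (R <= 0) stop("singular geometry: coincident bonded particles");
    double mag = -2.0 * kb[b] * (R - r0[b]) / R;
    f(i,0) += mag * dx; f(i,1) += mag * dy; f(i,2) += mag * dz;
    f(j,0) -= mag * dx; f(j,1) -= mag * dy; f(j,2) -= mag * dz;
    if (energy) *energy += kb[b] * (R - r0[b]) * (R - r0[b]);
  }
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}

// angle at j between arms j->i and j->k; restoring forces on i and k
// perpendicular to their arms, reaction on j
static void add_angle_forces(const NumericMatrix& pos, const IntegerMatrix& angles,
                             const NumericVector& th0, const NumericVector& kth,
                             double L, NumericMatrix& f, double* energy) {
  for (int t = 0; t < angles.nrow(); ++t) {
    int i = angles(t, 0) - 1, j = angles(t, 1) - 1, k = angles(t, 2) - 1;
    double rij[3] = { wrap_delta(pos(i,0)-pos(j,0), L),
                      wrap_delta(pos(i,1)-pos(j,1), L),
                      wrap_delta(pos(i,2)-pos(j,2), L) };
    double rkj[3] = { wrap_delta(pos(k,0)-pos(j,0), L),
                      wrap_delta(pos(k,1)-pos(j,1), L),
                      wrap_delta(pos(k,2)-pos(j,2), L) };
    double Ri = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
    double Rk = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
    if (Ri <= 0 || Rk <= 0) stop("singular geometry: coincident angle particles");
    double cth = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (Ri * Rk);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double mag = kth[t] * std::sin(th - th0[t]);
    if (energy) *energy += kth[t] * (1.0 - std::cos(th - th0[t]));
    if (mag == 0.0) continue;
    double cr[3], di[3], dk[3];
    cross3(rij, rkj, cr);
    double ncr = std::sqrt(cr[0]*cr[0] + cr[1]*cr[1] + cr[2]*cr[2]);
    if (ncr < 1e-8 * Ri * Rk) {
      // collinear arms: force direction undefined, pick any perpendicular
      double ref[3] = {1.0, 0.0, 0.0};
      if (std::fabs(rij[0]) > 0.9 * Ri) { ref[0] = 0.0; ref[1] = 1.0; }
      cross3(rij, ref, cr);
    }
    cross3(cr, rij, di);
    double ndi = std::sqrt(di[0]*di[0] + di[1]*di[1] + di[2]*di[2]);
    double crk[3] = {-cr[0], -cr[1], -cr[2]}; // rkj x rij = -(rij x rkj)
    cross3(crk, rkj, dk);
    double ndk = std::sqrt(dk[0]*dk[0] + dk[1]*dk[1] + dk[2]*dk[2]);
    if (ndi <= 0 || ndk <= 0) continue;
    for (int c = 0; c < 3; ++c) {
      double fi = mag * di[c] / ndi;
      double fk = mag * dk[c] / ndk;
      f(i,c) += fi; f(k,c) += fk; f(j,c) -= fi + fk;
    }
  }
}

// soft repulsive contact: |f| = (pi kc / Rc) sin(pi R / Rc) for R < Rc
static void add_contact_forces(const NumericMatrix& pos, const NumericVector& diam,
                               double E, double nu, double L,
                               const PairList& pl, NumericMatrix& f,
                               double* energy) {
  const double nucbrt = std::cbrt(nu);
  for (size_t p = 0; p < pl.i.size(); ++p) {
    int a = pl.i[p], b = pl.j[p];
    double Rc = 0.5 * (diam[a] + diam[b]);
    double dx = wrap_delta(pos(a,0) - pos(b,0), L);
    double dy = wrap_delta(pos(a,1) - pos(b,1), L);
    double dz = wrap_delta(pos(a,2) - pos(b,2), L);
    double R2 = dx*dx + dy*dy + dz*dz;
    if (R2 >= Rc * Rc) continue;
    double R = std::sqrt(R2);
    double Reff = diam[a] * diam[b] / (diam[a] + diam[b]);
    double kc = E / 16.0 * nucbrt * std::sqrt(Reff);
    if (energy) *energy += kc * (std::cos(M_PI * R / Rc) + 1.0);
    if (R <= 0) continue; // soft core: zero force at zero separation
    double mag = M_PI * kc / Rc * std::sin(M_PI * R / Rc) / R;
    f(a,0) += mag * dx; f(a,1) += mag * dy; f(a,2) += mag * dz;
    f(b,0) -= mag * dx; f(b,1) -= mag * dy; f(b,2) -= mag * dz;
  }
}

// Stokes drag f = -3 pi eta d v
static void add_drag_forces(const NumericMatrix& vel, const NumericVector& diam,
                            double eta, NumericMatrix& f) {
  for (int a = 0; a < vel.nrow(); ++a) {
    double c = 3.0 * M_PI * eta * diam[a];
    for (int k = 0; k < 3; ++k) f(a,k) -= c * vel(a,k);
  }
}

// [[Rcpp::export]]
NumericMatrix bond_forces_cpp(NumericMatrix pos, IntegerMatrix bonds,
                              NumericVector r0, NumericVector kb, double box) {
  NumericMatrix f(pos.nrow(), 3);
  add_bond_forces(pos, bonds, r0, kb, box, f, nullptr);
  return f;
}

// [[Rcpp::export]]
NumericMatrix angle_forces_cpp(NumericMatrix pos, IntegerMatrix angles,
                               NumericVector theta0, NumericVector ktheta,
                               double box) {
  NumericMatrix f(pos.nrow(), 3);
  add_angle_forces(pos, angles, theta0, ktheta, box, f, nullptr);
  return f;
}

// [[Rcpp::export]]
NumericMatrix contact_forces_cpp(NumericMatrix pos, NumericVector diam,
                                 IntegerVector fiber_id, IntegerVector chain_idx,
                                 double youngs, double poisson, double box) {
  NumericMatrix f(pos.nrow(), 3);
  double cutoff = max(diam);
  PairList pl;
  build_pairs(pos, fiber_id, chain_idx, box, cutoff, 0.0, pl);
  add_contact_forces(pos, diam, youngs, poisson, box, pl, f, nullptr);
  return f;
}

// [[Rcpp::export]]
NumericMatrix drag_forces_cpp(NumericMatrix vel, NumericVector diam, double eta) {
  NumericMatrix f(vel.nrow(), 3);
  add_drag_forces(vel, diam, eta, f);
  return f;
}

// analytic sphere-sphere intersection (lens) volume
static double lens_volume(double r1, double r2, double d) {
  if (d >= r1 + r2) return 0.0;
  double rmin = std::min(r1, r2);
  if (d <= std::fabs(r1 - r2)) return 4.0 / 3.0 * M_PI * rmin * rmin * rmin;
  double num = (r1 + r2 - d) * (r1 + r2 - d) *
    (d*d + 2.0*d*(r1 + r2) - 3.0*(r1 - r2)*(r1 - r2));
  return M_PI * num / (12.0 * d);
}

// [[Rcpp::export]]
double pfo_cpp(NumericMatrix pos, NumericVector radii, IntegerVector fiber_id,
               IntegerVector chain_idx, double box) {
  const int n = pos.nrow();
  double cutoff = 2.0 * max(radii);
  PairList pl;
  build_pairs(pos, fiber_id, chain_idx, box, cutoff, 0.0, pl);
  double overlap = 0.0, total = 0.0;
  for (int a = 0; a < n; ++a)
    total += 4.0 / 3.0 * M_PI * radii[a] * radii[a] * radii[a];
  for (size_t p = 0; p < pl.i.size(); ++p) {
    int a = pl.i[p], b = pl.j[p];
    double dx = wrap_delta(pos(a,0) - pos(b,0), box);
    double dy = wrap_delta(pos(a,1) - pos(b,1), box);
    double dz = wrap_delta(pos(a,2) - pos(b,2), box);
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    overlap += lens_volume(radii[a], radii[b], d);
  }
  return total > 0 ? 100.0 * overlap / total : 0.0;
}

// [[Rcpp::export]]
List total_forces_cpp(NumericMatrix pos, NumericMatrix vel,
                      IntegerMatrix bonds, NumericVector r0, NumericVector kb,
                      IntegerMatrix angles, NumericVector theta0, NumericVector ktheta,
                      NumericVector diam, IntegerVector fiber_id,
                      IntegerVector chain_idx, double youngs, double poisson,
                      double eta, double box, bool with_energy = false) {
  NumericMatrix f(pos.nrow(), 3);
  double energy = 0.0;
  double* ep = with_energy ? &energy : nullptr;
  add_bond_forces(pos, bonds, r0, kb, box, f, ep);
  add_angle_forces(pos, angles, theta0, ktheta, box, f, ep);
  PairList pl;
  build_pairs(pos, fiber_id, chain_idx, box, max(diam), 0.0, pl);
  add_contact_forces(pos, diam, youngs, poisson, box, pl, f, ep);
  add_drag_forces(vel, diam, eta, f);
  return List::create(_["forces"] = f, _["potential"] = energy);
}

// Full damped velocity-Verlet relaxation loop.
// Ends of each fiber are frozen for the first fixed_end_steps; the run
// stops when the percent fiber overlap plateaus (relative change over a
// trailing window below stop_tol) after the ends are released, when the
// overlap vanishes, or at max_steps.
// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos_in, NumericVector radii, NumericVector diam,
               NumericVector mass,
               IntegerMatrix bonds, NumericVector r0, NumericVector kb,
               IntegerMatrix angles, NumericVector theta0, NumericVector ktheta,
               IntegerVector fiber_id, IntegerVector chain_idx,
               IntegerVector fixed_idx, double youngs, double poisson,
               double eta, double box, double dt,
               int fixed_end_steps, int max_steps, double stop_tol,
               int pfo_every, int window_steps, double stop_below) {
  const int n = pos_in.nrow();
  NumericMatrix pos = clone(pos_in);
  NumericMatrix vel(n, 3), f(n, 3);
  std::vector<bool> is_fixed(n, false);
  for (int q = 0; q < fixed_idx.size(); ++q) is_fixed[fixed_idx[q] - 1] = true;

  double cutoff = max(diam);
  double skin = 0.3 * cutoff;
  PairList pl;
  build_pairs(pos, fiber_id, chain_idx, box, cutoff, skin, pl);

  auto compute_forces = [&](NumericMatrix& fout) {
    std::fill(fout.begin(), fout.end(), 0.0);
    add_bond_forces(pos, bonds, r0, kb, box, fout, nullptr);
    add_angle_forces(pos, angles, theta0, ktheta, box, fout, nullptr);
    add_contact_forces(pos, diam, youngs, poisson, box, pl, fout, nullptr);
    add_drag_forces(vel, diam, eta, fout);
  };

  std::vector<double> trace_pfo;
  std::vector<int> trace_step;
  double pfo0 = pfo_cpp(pos, radii, fiber_id, chain_idx, box);
  trace_pfo.push_back(pfo0); trace_step.push_back(0);

  compute_forces(f);
  int window_pts = std::max(2, window_steps / std::max(1, pfo_every));
  int step = 0;
  double cum_disp = 0.0; // conservative bound on max displacement since build
  for (step = 1; step <= max_steps; ++step) {
    bool frozen = step <= fixed_end_steps;
    // half-kick + drift
    double v2max = 0.0;
    for (int a = 0; a < n; ++a) {
      if (frozen && is_fixed[a]) {
        vel(a,0) = vel(a,1) = vel(a,2) = 0.0;
        continue;
      }
      double v2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        vel(a,k) += 0.5 * dt * f(a,k) / mass[a];
        double x = pos(a,k) + dt * vel(a,k);
        x -= box * std::floor(x / box);
        pos(a,k) = x;
        v2 += vel(a,k) * vel(a,k);
      }
      if (v2 > v2max) v2max = v2;
    }
    cum_disp += dt * std::sqrt(v2max);
    if (cum_disp > 0.5 * skin) {
      build_pairs(pos, fiber_id, chain_idx, box, cutoff, skin, pl);
      cum_disp = 0.0;
    }
    compute_forces(f);
    for (int a = 0; a < n; ++a) {
      if (frozen && is_fixed[a]) continue;
      for (int k = 0; k < 3; ++k) vel(a,k) += 0.5 * dt * f(a,k) / mass[a];
    }
    if (step % pfo_every == 0) {
      if (!std::isfinite(pos(0,0)))
        stop("instability: non-finite positions (dt = %f too large)", dt);
      double pfo = pfo_cpp(pos, radii, fiber_id, chain_idx, box);
      trace_pfo.push_back(pfo); trace_step.push_back(step);
      if (pfo <= 1e-12) break; // nothing left to relax
      // overlap-removed and plateau stops apply only once the fiber ends
      // are free, so frozen-end configurations can still equilibrate
      if (step > fixed_end_steps) {
        if (pfo <= stop_below) break;
        if ((int)trace_pfo.size() > window_pts) {
          double prev = trace_pfo[trace_pfo.size() - 1 - window_pts];
          if (prev > 0 && std::fabs(pfo - prev) / prev < stop_tol) break;
        }
      }
    }
  }
  for (int a = 0; a < n; ++a)
    for (int k = 0; k < 3; ++k)
      if (!std::isfinite(pos(a,k)))
        stop("instability: non-finite positions (dt = %f too large)", dt);
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["pfo"] = wrap(trace_pfo), _["pfo_step"] = wrap(trace_step),
                      _["steps"] = std::min(step, max_steps));
}
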