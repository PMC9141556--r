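#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Toy-unit conventions: energies kJ/mol, lengths Angstrom (or reduced CV
// units), time ps, unit mass in kJ mol^-1 ps^2 per length^2 so that
// acceleration = force/mass without unit conversion factors.
static const double KB = 0.0083144621; // kJ/mol/K

static inline double dw_force(double x, double h, double a) {
  // U = h ((x/a)^2 - 1)^2 ; F = -dU/dx
  double u = x / a;
  return -4.0 * h * u * (u * u - 1.0) / a;
}

// Overdamped Langevin in the double well. Uses R's RNG (seed from R side).
// [[Rcpp::export]]
NumericVector langevin_double_well(int n_steps, double dt, double temperature,
                                   double friction, double barrier_height,
                                   double well_separation, double x0) {
  NumericVector out(n_steps);
  double x = x0;
  const double mob = 1.0 / friction; // 1/(gamma m), m = 1
  const double noise = std::sqrt(2.0 * KB * temperature * dt * mob);
  for (int t = 0; t < n_steps; ++t) {
    double f = dw_force(x, barrier_height, well_separation);
    x += f * mob * dt + noise * norm_rand();
    out[t] = x;
  }
  return out;
}

// Well-tempered metadynamics on a 1-D overdamped Langevin particle.
// potential: 0 = double well (pot_a = h, pot_b = a); 1 = harmonic
// (pot_a = k, U = 0.5 k x^2). The CV is x itself. One norm_rand() per step,
// deposits draw nothing, so height0 = 0 reproduces the unbiased stream
// exactly.
// [[Rcpp::export]]
List metad_langevin_1d(int n_steps, double dt, double temperature,
                       double friction, int potential, double pot_a,
                       double pot_b, double x0, double height0, double width,
                       int pace, double bias_factor, int sample_every) {
  std::vector<double> hc, hh;
  std::vector<int> hstep;
  std::vector<double> xs;
  xs.reserve(n_steps / sample_every + 1);
  double x = x0;
  const double mob = 1.0 / friction;
  const double noise = std::sqrt(2.0 * KB * temperature * dt * mob);
  const double dT = (bias_factor - 1.0) * temperature;
  const double w2 = width * width;
  for (int t = 0; t < n_steps; ++t) {
    // physical force
    double f = (potential == 0) ? dw_force(x, pot_a, pot_b) : -pot_a * x;
    // bias value and force at x
    double vb = 0.0, fb = 0.0;
    for (size_t i = 0; i < hc.size(); ++i) {
      double d = x - hc[i];
      double g = hh[i] * std::exp(-0.5 * d * d / w2);
      vb += g;
      fb += g * d / w2; // -dV/dx = +g d / w^2
    }
    if (height0 > 0.0 && pace > 0 && t % pace == 0) {
      double h = height0 * std::exp(-vb / (KB * dT));
      hc.push_back(x);
      hh.push_back(h);
      hstep.push_back(t);
    }
    x += (f + fb) * mob * dt + noise * norm_rand();
    if (!std::isfinite(x)) stop("non-finite coordinate at step %d", t);
    if ((t + 1) % sample_every == 0) xs.push_back(x);
  }
  return List::create(_["x"] = wrap(xs), _["hill_center"] = wrap(hc),
                      _["hill_height"] = wrap(hh),
                      _["hill_step"] = wrap(hstep));
}

// Underdamped Langevin (BAOAB) bead chain with harmonic bonds and
// flat-bottom upper-limit distance restraints. mode: 0 = instantaneous,
// 1 = time-averaged (exponential memory of r^-p; force from r_bar applied
// along the current pair vector, no (r_bar/r)^(p+1) correction).
// friction = 0 gives plain velocity-Verlet NVE.
// [[Rcpp::export]]
List run_chain_dynamics(NumericMatrix coords0, double bond_length,
                        double k_bond, double temperature, double friction,
                        double dt, int n_steps, int sample_every,
                        IntegerVector rest_i, IntegerVector rest_j,
                        NumericVector rest_upper, double k_rest, int mode,
                        double tau, double p_exp) {
  const int n = coords0.nrow();
  const int nr = rest_i.size();
  std::vector<double> x(3 * n), v(3 * n, 0.0), fr(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords0(i, k);
  const double kT = KB * temperature;
  // thermalized initial velocities only when thermostatted
  if (friction > 0.0) {
    double sv = std::sqrt(kT);
    for (int i = 0; i < 3 * n; ++i) v[i] = sv * norm_rand();
  }
  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = (friction > 0.0) ? std::sqrt((1.0 - c1 * c1) * kT) : 0.0;
  std::vector<double> mem(nr, -1.0), rbar(nr, 0.0);
  const double decay = (tau > 0.0) ? std::exp(-dt / tau) : 0.0;

  int n_samp = n_steps / sample_every;
  NumericVector traj(n_samp * n * 3);
  NumericVector e_rest(n_samp), e_tot(n_samp);
  NumericMatrix rbar_out(n_samp, nr);

  // compute forces + potential energy; also updates rbar-dependent parts
  // using the *current* memory state (memory itself advanced separately)
  double e_pot = 0.0, e_restr = 0.0;
  auto forces = [&](bool use_memory) {
    std::fill(fr.begin(), fr.end(), 0.0);
    e_pot = 0.0;
    for (int b = 0; b < n - 1; ++b) {
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        d[k] = x[3 * (b + 1) + k] - x[3 * b + k];
        r2 += d[k] * d[k];
      }
      double r = std::sqrt(r2);
      double dr = r - bond_length;
      e_pot += 0.5 * k_bond * dr * dr;
      double fmag = -k_bond * dr / r;
      for (int k = 0; k < 3; ++k) {
        fr[3 * (b + 1) + k] += fmag * d[k];
        fr[3 * b + k] -= fmag * d[k];
      }
    }
    e_restr = 0.0;
    for (int q = 0; q < nr; ++q) {
      int i = rest_i[q] - 1, j = rest_j[q] - 1;
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        d[k] = x[3 * j + k] - x[3 * i + k];
        r2 += d[k] * d[k];
      }
      double r = std::sqrt(r2);
      if (r <= 0.0) stop("overlapping restrained atoms");
      double rdrive = r;
      if (use_memory && mem[q] > 0.0) rdrive = std::pow(mem[q], -1.0 / p_exp);
      rbar[q] = rdrive;
      double over = rdrive - rest_upper[q];
      if (over > 0.0) {
        e_restr += 0.5 * k_rest * over * over;
        double fmag = -k_rest * over / r; // along current pair vector
        for (int k = 0; k < 3; ++k) {
          fr[3 * j + k] += fmag * d[k];
          fr[3 * i + k] -= fmag * d[k];
        }
      }
    }
    e_pot += e_restr;
  };

  auto update_memory = [&]() {
    for (int q = 0; q < nr; ++q) {
      int i = rest_i[q] - 1, j = rest_j[q] - 1;
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dd = x[3 * j + k] - x[3 * i + k];
        r2 += dd * dd;
      }
      double rp = std::pow(std::sqrt(r2), -p_exp);
      mem[q] = (mem[q] < 0.0) ? rp : mem[q] * decay + rp * (1.0 - decay);
    }
  };

  bool use_mem = (mode == 1);
  if (use_mem) update_memory();
  forces(use_mem);
  int samp = 0;
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * fr[i]; // B
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];  // A
    if (friction > 0.0)
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * norm_rand(); // O
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];  // A
    if (use_mem) update_memory();
    forces(use_mem);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * fr[i]; // B
    for (int i = 0; i < 3 * n; ++i)
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6)
        stop("integrator blow-up at step %d", t);
    if ((t + 1) % sample_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          traj[samp + n_samp * (i + n * k)] = x[3 * i + k];
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * v[i] * v[i];
      e_rest[samp] = e_restr;
      e_tot[samp] = e_pot + ke;
      for (int q = 0; q < nr; ++q) rbar_out(samp, q) = rbar[q];
      ++samp;
    }
  }
  traj.attr("dim") = IntegerVector::create(n_samp, n, 3);
  return List::create(_["coords"] = traj, _["e_restraint"] = e_rest,
                      _["e_total"] = e_tot, _["r_bar"] = rbar_out);
}
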