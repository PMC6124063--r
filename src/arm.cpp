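// Compiled core for the auxiliary-region hybrid method.
//
// All randomness is drawn from R's RNG (unif_rand/norm_rand/exp_rand) so that
// set.seed() on the R side makes every simulation bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// theta-method step on a cell-centred grid with conservative (ghost-cell)
// boundaries.  Solves (I - theta*dt*D*L) c_new = (I + (1-theta)*dt*D*L) c_old
// + dt*src with L the zero-flux discrete Laplacian.  Column sums of both
// operators equal one, so discrete mass is conserved exactly (up to rounding)
// apart from the explicit source term.
// ---------------------------------------------------------------------------
static void theta_solve_core(std::vector<double> &c, double hp, double dt,
                             double D, double theta,
                             const std::vector<double> &src) {
  const int n = (int)c.size();
  if (n == 0) return;
  const double r = D * dt / (hp * hp);
  if (n == 1) { // single cell: diffusion is a no-op
    c[0] += dt * (src.empty() ? 0.0 : src[0]);
    return;
  }
  // rhs = c + (1-theta)*r*(L c)*hp^2/hp^2 + dt*src
  std::vector<double> b(n);
  const double re = (1.0 - theta) * r;
  b[0] = c[0] + re * (c[1] - c[0]);
  for (int i = 1; i < n - 1; ++i)
    b[i] = c[i] + re * (c[i - 1] - 2.0 * c[i] + c[i + 1]);
  b[n - 1] = c[n - 1] + re * (c[n - 2] - c[n - 1]);
  if (!src.empty())
    for (int i = 0; i < n; ++i) b[i] += dt * src[i];
  // Thomas algorithm for tridiagonal (I - theta*r*L)
  const double ri = theta * r;
  std::vector<double> diag(n), cp(n);
  diag[0] = 1.0 + ri;
  for (int i = 1; i < n - 1; ++i) diag[i] = 1.0 + 2.0 * ri;
  diag[n - 1] = 1.0 + ri;
  const double off = -ri;
  cp[0] = off / diag[0];
  b[0] = b[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    const double m = diag[i] - off * cp[i - 1];
    cp[i] = off / m;
    b[i] = (b[i] - off * b[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) b[i] -= cp[i] * b[i + 1];
  c.swap(b);
}

// [[Rcpp::export]]
NumericVector cpp_theta_solve(NumericVector values, double hp, double dt,
                              double D, double theta, NumericVector src) {
  std::vector<double> c(values.begin(), values.end());
  std::vector<double> s;
  if (src.size() > 0) s.assign(src.begin(), src.end());
  theta_solve_core(c, hp, dt, D, theta, s);
  return wrap(c);
}

// ---------------------------------------------------------------------------
// reflection into [lo, hi] by repeated mirroring (exact fold)
// ---------------------------------------------------------------------------
static inline double reflect(double x, double lo, double hi) {
  const double w = hi - lo;
  if (w <= 0.0) return lo;
  const double p = 2.0 * w;
  double y = x - lo;
  y -= std::floor(y / p) * p; // y in [0, 2w)
  if (y > w) y = p - y;
  return lo + y;
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_reflect(NumericMatrix pos, double sd,
                                  NumericVector lower, NumericVector upper) {
  const int n = pos.nrow(), d = pos.ncol();
  NumericMatrix out(n, d);
  for (int j = 0; j < d; ++j) {
    const double lo = lower[j], hi = upper[j];
    for (int i = 0; i < n; ++i)
      out(i, j) = reflect(pos(i, j) + sd * norm_rand(), lo, hi);
  }
  return out;
}

// ---------------------------------------------------------------------------
// lambda-rho bimolecular step (2A -> 0).  Pairs closer than rho, with at
// least one member outside the exclusion slab [ex_lo, ex_hi) in x, react
// with probability P_lambda.  Pairs are processed in randomized order and a
// particle reacts at most once per step.  Candidate search sweeps an x-sorted
// index so the cost is O(n * n_local) rather than O(n^2).
// ---------------------------------------------------------------------------
static void lambda_rho_core(std::vector<double> &px, std::vector<double> &py,
                            std::vector<double> &pz, int dim, double rho,
                            double P_lambda, bool use_excl, double ex_lo,
                            double ex_hi, long &pairs_reacted) {
  const int n = (int)px.size();
  if (n < 2 || P_lambda <= 0.0 || rho <= 0.0) return;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return px[a] < px[b]; });
  const double rho2 = rho * rho;
  std::vector<std::pair<int, int> > cand;
  for (int a = 0; a < n; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < n; ++b) {
      const int j = ord[b];
      const double dx = px[j] - px[i];
      if (dx >= rho) break;
      double d2 = dx * dx;
      if (dim == 3) {
        const double dy = py[j] - py[i], dz = pz[j] - pz[i];
        d2 += dy * dy + dz * dz;
      }
      if (d2 >= rho2) continue;
      if (use_excl) {
        const bool in_i = (px[i] >= ex_lo && px[i] < ex_hi);
        const bool in_j = (px[j] >= ex_lo && px[j] < ex_hi);
        if (in_i && in_j) continue; // handled by the compartment SSA
      }
      cand.push_back(std::make_pair(i, j));
    }
  }
  const int m = (int)cand.size();
  if (m == 0) return;
  // Fisher-Yates shuffle using R's RNG
  for (int a = m - 1; a > 0; --a) {
    int b = (int)std::floor(unif_rand() * (a + 1));
    if (b > a) b = a;
    std::swap(cand[a], cand[b]);
  }
  std::vector<char> dead(n, 0);
  for (int a = 0; a < m; ++a) {
    const int i = cand[a].first, j = cand[a].second;
    if (dead[i] || dead[j]) continue;
    if (unif_rand() < P_lambda) {
      dead[i] = dead[j] = 1;
      ++pairs_reacted;
    }
  }
  // compact
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (!dead[i]) {
      px[k] = px[i];
      if (dim == 3) { py[k] = py[i]; pz[k] = pz[i]; }
      ++k;
    }
  }
  px.resize(k);
  if (dim == 3) { py.resize(k); pz.resize(k); }
}

// [[Rcpp::export]]
List cpp_lambda_rho(NumericMatrix pos, double rho, double P_lambda,
                    bool use_excl, double ex_lo, double ex_hi) {
  const int n = pos.nrow(), dim = pos.ncol() >= 3 ? 3 : 1;
  std::vector<double> px(n), py, pz;
  for (int i = 0; i < n; ++i) px[i] = pos(i, 0);
  if (dim == 3) {
    py.resize(n); pz.resize(n);
    for (int i = 0; i < n; ++i) { py[i] = pos(i, 1); pz[i] = pos(i, 2); }
  }
  long reacted = 0;
  lambda_rho_core(px, py, pz, dim, rho, P_lambda, use_excl, ex_lo, ex_hi,
                  reacted);
  const int k = (int)px.size();
  NumericMatrix out(k, dim);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = px[i];
    if (dim == 3) { out(i, 1) = py[i]; out(i, 2) = pz[i]; }
  }
  return List::create(_["pos"] = out, _["n_pairs_reacted"] = (double)reacted);
}

// ---------------------------------------------------------------------------
// the hybrid engine
// ---------------------------------------------------------------------------
struct Ledger {
  double influx = 0.0;       // mass entering through the prescribed-flux BC
  double pde_react = 0.0;    // net mass change from the PDE reaction operator
  long bd_decay = 0;         // particles removed by first-order decay
  long births = 0;           // zeroth-order particle initializations
  long micro_pairs = 0;      // lambda-rho pair reactions enacted
  long aux_react = 0;        // compartment (SSA) reactions in the aux region
  long jumps_pb = 0, jumps_bp = 0;
  long clamps = 0;           // SSA propensity evaluations with N_PA < 1 clamp
  long moves_left = 0, moves_right = 0, moves_suppressed = 0;
  long neg_cells = 0;        // cells observed below -1e-9 * max density
  double mass_flag = 0.0;    // unresolvable conversion discrepancy (M_rest=0)
  double max_drift = 0.0;    // max |mass - expected| / max(1, mass0)
};

struct Engine {
  // geometry / numerics
  double x0, x1, iface, ha, hp, dt, theta;
  int naux, dim;
  double Ly, Lz, area;
  // rates
  double D, mu, lambda_flux, kappa1, kappa2, rho, P_lambda;
  bool pde_on, bd_on, ssa_on, micro_only, adaptive;
  double beta_l, beta_u;
  // state
  std::vector<double> c; // reduced density, particles/length, origin x0
  std::vector<double> px, py, pz;
  double d_jump;
  Ledger led;
  double expected_mass;

  double pde_mass() const {
    double s = 0.0;
    for (double v : c) s += v;
    return s * hp;
  }
  double npa() const {
    double s = 0.0;
    const int n = (int)c.size();
    for (int i = n - naux; i < n; ++i)
      if (i >= 0) s += c[i];
    return s * hp;
  }
  int nba() const {
    const double lo = iface, hi = iface + ha;
    int k = 0;
    for (double x : px)
      if (x >= lo && x < hi) ++k;
    return k;
  }
  double total_mass() const { return pde_mass() + (double)px.size(); }

  void add_particle(double x, double y, double z) {
    px.push_back(x);
    if (dim == 3) { py.push_back(y); pz.push_back(z); }
  }
  void remove_particle(int i) {
    px[i] = px.back(); px.pop_back();
    if (dim == 3) {
      py[i] = py.back(); py.pop_back();
      pz[i] = pz.back(); pz.pop_back();
    }
  }
  std::vector<int> aux_indices() const {
    std::vector<int> idx;
    const double lo = iface, hi = iface + ha;
    for (int i = 0; i < (int)px.size(); ++i)
      if (px[i] >= lo && px[i] < hi) idx.push_back(i);
    return idx;
  }

  void enact_p_to_b() {
    const int n = (int)c.size();
    for (int i = n - naux; i < n; ++i) c[i] -= 1.0 / ha;
    add_particle(iface + unif_rand() * ha, Ly * unif_rand(), Lz * unif_rand());
    ++led.jumps_pb;
  }
  void enact_b_to_p() {
    std::vector<int> idx = aux_indices();
    if (idx.empty()) stop("internal fault: B->P jump with empty auxiliary region");
    int k = (int)std::floor(unif_rand() * idx.size());
    if (k >= (int)idx.size()) k = (int)idx.size() - 1;
    remove_particle(idx[k]);
    const int n = (int)c.size();
    for (int i = n - naux; i < n; ++i) c[i] += 1.0 / ha;
    ++led.jumps_bp;
  }
  void enact_aux_pair() { // 2A -> 0 inside the Brownian auxiliary region
    std::vector<int> idx = aux_indices();
    if ((int)idx.size() < 2)
      stop("internal fault: auxiliary pair reaction with fewer than 2 particles");
    int a = (int)std::floor(unif_rand() * idx.size());
    if (a >= (int)idx.size()) a = (int)idx.size() - 1;
    int b = (int)std::floor(unif_rand() * (idx.size() - 1));
    if (b >= (int)idx.size() - 1) b = (int)idx.size() - 2;
    if (b >= a) ++b;
    int i = idx[a], j = idx[b];
    if (i < j) std::swap(i, j); // remove the larger index first
    remove_particle(i);
    remove_particle(j);
    ++led.aux_react;
    expected_mass -= 2.0;
  }

  // SSA sub-loop within (t0, t1]; events at exactly t1 are processed first
  void ssa_until(double t0, double t1) {
    double t = t0;
    while (true) {
      const double NPA = npa();
      const int NBA = nba();
      double aP = d_jump * NPA;
      if (NPA < 1.0) {
        if (aP > 0.0) ++led.clamps;
        aP = 0.0;
      }
      const double aB = d_jump * (double)NBA;
      double ar = 0.0;
      if (kappa1 > 0.0 && NBA >= 2)
        ar = 0.5 * (double)NBA * (double)(NBA - 1) * kappa1 / (ha * area);
      const double a0 = aP + aB + ar;
      if (a0 <= 0.0) return;
      const double tau = exp_rand() / a0;
      if (t + tau > t1) return; // stale putative event discarded; redrawn next
      t += tau;
      const double u = unif_rand() * a0;
      if (u < aP) enact_p_to_b();
      else if (u < aP + aB) enact_b_to_p();
      else enact_aux_pair();
    }
  }

  void pde_step() {
    const int n = (int)c.size();
    if (n == 0) return;
    std::vector<double> src(n, 0.0);
    double react_mass = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = 0.0;
      if (mu > 0.0) f -= mu * c[i];
      if (kappa2 > 0.0) f += kappa2 * area;
      if (kappa1 > 0.0) f -= kappa1 * c[i] * c[i] / area;
      src[i] = f;
      react_mass += f;
    }
    react_mass *= dt * hp;
    double influx = 0.0;
    if (lambda_flux != 0.0) {
      src[0] += D * lambda_flux / hp; // influx exactly D*lambda per unit time
      influx = D * lambda_flux * dt;
    }
    theta_solve_core(c, hp, dt, D, theta, src);
    led.influx += influx;
    led.pde_react += react_mass;
    expected_mass += react_mass + influx;
    double mx = 0.0;
    for (double v : c) {
      if (!std::isfinite(v)) stop("numerical failure: non-finite PDE density");
      if (v > mx) mx = v;
    }
    for (double v : c)
      if (v < -1e-9 * std::max(mx, 1.0)) ++led.neg_cells;
  }

  void bd_step() {
    const int n = (int)px.size();
    const double sd = std::sqrt(2.0 * D * dt);
    const double lo = micro_only ? x0 : iface;
    for (int i = 0; i < n; ++i) {
      px[i] = reflect(px[i] + sd * norm_rand(), lo, x1);
      if (dim == 3) {
        py[i] = reflect(py[i] + sd * norm_rand(), 0.0, Ly);
        pz[i] = reflect(pz[i] + sd * norm_rand(), 0.0, Lz);
      }
    }
    if (mu > 0.0) {
      const double p_rm = -std::expm1(-mu * dt);
      for (int i = (int)px.size() - 1; i >= 0; --i)
        if (unif_rand() < p_rm) {
          remove_particle(i);
          ++led.bd_decay;
          expected_mass -= 1.0;
        }
    }
    if (kappa2 > 0.0) {
      const double VB = (x1 - lo) * area;
      if (unif_rand() < kappa2 * dt * VB) {
        add_particle(lo + unif_rand() * (x1 - lo), Ly * unif_rand(),
                     Lz * unif_rand());
        ++led.births;
        expected_mass += 1.0;
      }
    }
    if (kappa1 > 0.0 && rho > 0.0) {
      long before = led.micro_pairs;
      lambda_rho_core(px, py, pz, dim, rho, P_lambda, !micro_only, iface,
                      iface + ha, led.micro_pairs);
      expected_mass -= 2.0 * (double)(led.micro_pairs - before);
    }
  }

  void adaptive_check() {
    const double NPA = npa();
    const int NBA = nba();
    if (NPA < beta_l) { // move towards the PDE subdomain
      if (iface - ha - x0 < ha - 1e-12) { ++led.moves_suppressed; return; }
      // convert Omega_PA to particles
      const int nfloor = (int)std::floor(NPA);
      const double frac = NPA - nfloor;
      const int nnew = nfloor + (unif_rand() < frac ? 1 : 0);
      const int n = (int)c.size();
      c.resize(n - naux);
      double M_rest = pde_mass();
      if (M_rest > 0.0) {
        const double fac = (M_rest + NPA - (double)nnew) / M_rest;
        for (double &v : c) v *= fac;
      } else if (NPA != (double)nnew) {
        led.mass_flag += NPA - (double)nnew;
        expected_mass += (double)nnew - NPA;
      }
      iface -= ha;
      for (int k = 0; k < nnew; ++k)
        add_particle(iface + unif_rand() * ha, Ly * unif_rand(),
                     Lz * unif_rand());
      ++led.moves_left;
    } else if ((double)NBA > beta_u) { // move towards the Brownian subdomain
      if (x1 - (iface + ha) < ha - 1e-12) { ++led.moves_suppressed; return; }
      std::vector<int> idx = aux_indices();
      std::sort(idx.rbegin(), idx.rend());
      for (int i : idx) remove_particle(i);
      const double dens = (double)NBA / ha; // reduced density, particles/length
      for (int k = 0; k < naux; ++k) c.push_back(dens);
      iface += ha;
      ++led.moves_right;
    }
  }
};

// [[Rcpp::export]]
List cpp_run_hybrid(List cfg) {
  Engine e;
  e.x0 = as<double>(cfg["x0"]);
  e.x1 = as<double>(cfg["x1"]);
  e.iface = as<double>(cfg["iface"]);
  e.ha = as<double>(cfg["ha"]);
  e.hp = as<double>(cfg["hp"]);
  e.dt = as<double>(cfg["dt"]);
  e.theta = as<double>(cfg["theta"]);
  e.dim = as<int>(cfg["dim"]);
  e.Ly = as<double>(cfg["Ly"]);
  e.Lz = as<double>(cfg["Lz"]);
  e.area = (e.dim == 3) ? e.Ly * e.Lz : 1.0;
  e.D = as<double>(cfg["D"]);
  e.mu = as<double>(cfg["mu"]);
  e.lambda_flux = as<double>(cfg["lambda_flux"]);
  e.kappa1 = as<double>(cfg["kappa1"]);
  e.kappa2 = as<double>(cfg["kappa2"]);
  e.rho = as<double>(cfg["rho"]);
  e.P_lambda = as<double>(cfg["P_lambda"]);
  e.pde_on = as<bool>(cfg["pde_on"]);
  e.bd_on = as<bool>(cfg["bd_on"]);
  e.ssa_on = as<bool>(cfg["ssa_on"]);
  e.micro_only = as<bool>(cfg["micro_only"]);
  e.adaptive = as<bool>(cfg["adaptive"]);
  e.beta_l = as<double>(cfg["beta_l"]);
  e.beta_u = as<double>(cfg["beta_u"]);
  e.naux = (int)std::lround(e.ha / e.hp);
  e.d_jump = e.D / (e.ha * e.ha);

  NumericVector c0 = cfg["pde_init"];
  e.c.assign(c0.begin(), c0.end());
  NumericMatrix b0 = cfg["bd_init"];
  for (int i = 0; i < b0.nrow(); ++i) {
    e.px.push_back(b0(i, 0));
    if (e.dim == 3) { e.py.push_back(b0(i, 1)); e.pz.push_back(b0(i, 2)); }
  }

  const int nsteps = as<int>(cfg["nsteps"]);
  IntegerVector snap_steps = cfg["snap_steps"]; // sorted, may include 0
  const bool record_particles = as<bool>(cfg["record_particles"]);

  const double mass0 = e.total_mass();
  e.expected_mass = mass0;

  const int nsnap = snap_steps.size();
  NumericVector s_t(nsnap), s_iface(nsnap), s_npa(nsnap), s_nba(nsnap),
      s_pmass(nsnap), s_total(nsnap);
  IntegerVector s_nb(nsnap);
  List s_pde(nsnap), s_particles(nsnap);

  int isnap = 0;
  auto record = [&](int step) {
    while (isnap < nsnap && snap_steps[isnap] == step) {
      s_t[isnap] = step * e.dt;
      s_iface[isnap] = e.iface;
      s_npa[isnap] = e.npa();
      s_nba[isnap] = (double)e.nba();
      s_pmass[isnap] = e.pde_mass();
      s_total[isnap] = e.total_mass();
      s_nb[isnap] = (int)e.px.size();
      s_pde[isnap] = wrap(e.c);
      if (record_particles) {
        NumericMatrix P((int)e.px.size(), e.dim);
        for (int i = 0; i < (int)e.px.size(); ++i) {
          P(i, 0) = e.px[i];
          if (e.dim == 3) { P(i, 1) = e.py[i]; P(i, 2) = e.pz[i]; }
        }
        s_particles[isnap] = P;
      }
      ++isnap;
    }
  };

  record(0);
  for (int step = 1; step <= nsteps; ++step) {
    const double t0 = (step - 1) * e.dt, t1 = step * e.dt;
    if (e.ssa_on) e.ssa_until(t0, t1);
    if (e.pde_on) e.pde_step();
    if (e.bd_on) e.bd_step();
    if (e.adaptive) e.adaptive_check();
    const double drift =
        std::fabs(e.total_mass() - e.expected_mass) / std::max(1.0, mass0);
    if (drift > e.led.max_drift) e.led.max_drift = drift;
    record(step);
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List ledger = List::create(
      _["influx"] = e.led.influx, _["pde_react"] = e.led.pde_react,
      _["bd_decay"] = (double)e.led.bd_decay,
      _["births"] = (double)e.led.births,
      _["micro_pairs"] = (double)e.led.micro_pairs,
      _["aux_reactions"] = (double)e.led.aux_react,
      _["jumps_pb"] = (double)e.led.jumps_pb,
      _["jumps_bp"] = (double)e.led.jumps_bp,
      _["clamps"] = (double)e.led.clamps,
      _["moves_left"] = (double)e.led.moves_left,
      _["moves_right"] = (double)e.led.moves_right,
      _["moves_suppressed"] = (double)e.led.moves_suppressed,
      _["neg_cells"] = (double)e.led.neg_cells,
      _["mass_flag"] = e.led.mass_flag, _["max_drift"] = e.led.max_drift,
      _["mass0"] = mass0, _["expected_mass"] = e.expected_mass,
      _["final_mass"] = e.total_mass());

  return List::create(
      _["t"] = s_t, _["iface"] = s_iface, _["npa"] = s_npa, _["nba"] = s_nba,
      _["pde_mass"] = s_pmass, _["total_mass"] = s_total, _["n_b"] = s_nb,
      _["pde"] = s_pde, _["particles"] = s_particles, _["ledger"] = ledger,
      _["x0"] = e.x0, _["hp"] = e.hp, _["ha"] = e.ha, _["dim"] = e.dim);
}
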