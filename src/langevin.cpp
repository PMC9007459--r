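#include <Rcpp.h>
using namespace Rcpp;

// Calpha Go-model potential and BAOAB Langevin integrator.
//
// Units: length A, energy kcal/mol, mass amu, time fs, temperature K.
// Acceleration conversion: 1 (kcal/mol/A)/amu = 4.184e-4 A/fs^2.
static const double KCAL_ACC = 4.184e-4;    // (kcal/mol/A)/amu -> A/fs^2
static const double KB       = 0.0019872041; // kcal/mol/K

struct GoTerms {
  IntegerMatrix bonds;    NumericVector bond_r0, bond_k;   // V = k (r - r0)^2
  IntegerMatrix angles;   NumericVector ang_th0, ang_k;    // V = k (th - th0)^2
  IntegerMatrix contacts; NumericVector con_sig, con_eps;  // 12-10 well
  IntegerMatrix reps;     double rep_sig, rep_eps;         // (sig/r)^12
};

// fills forces (n x 3), returns potential energy
static double go_forces(const NumericMatrix &x, const GoTerms &t,
                        std::vector<double> &fx) {
  const int n = x.nrow();
  std::fill(fx.begin(), fx.end(), 0.0);
  double pe = 0.0;

  for (int b = 0; b < t.bonds.nrow(); ++b) {
    int i = t.bonds(b, 0) - 1, j = t.bonds(b, 1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - t.bond_r0[b];
    pe += t.bond_k[b] * dr * dr;
    double f = -2.0 * t.bond_k[b] * dr / r; // along (i - j)
    fx[i]     += f * dx; fx[i+n]   += f * dy; fx[i+2*n] += f * dz;
    fx[j]     -= f * dx; fx[j+n]   -= f * dy; fx[j+2*n] -= f * dz;
  }

  for (int a = 0; a < t.angles.nrow(); ++a) {
    int i = t.angles(a,0) - 1, j = t.angles(a,1) - 1, k = t.angles(a,2) - 1;
    double aij[3] = { x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2) };
    double akj[3] = { x(k,0)-x(j,0), x(k,1)-x(j,1), x(k,2)-x(j,2) };
    double rij = std::sqrt(aij[0]*aij[0]+aij[1]*aij[1]+aij[2]*aij[2]);
    double rkj = std::sqrt(akj[0]*akj[0]+akj[1]*akj[1]+akj[2]*akj[2]);
    for (int d = 0; d < 3; ++d) { aij[d] /= rij; akj[d] /= rkj; }
    double ct = aij[0]*akj[0] + aij[1]*akj[1] + aij[2]*akj[2];
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - t.ang_th0[a];
    pe += t.ang_k[a] * dth * dth;
    double st = std::sqrt(std::max(1.0 - ct*ct, 1e-12));
    double coef = -2.0 * t.ang_k[a] * dth; // -dV/dth
    for (int d = 0; d < 3; ++d) {
      double dthdi = (ct * aij[d] - akj[d]) / (rij * st);
      double dthdk = (ct * akj[d] - aij[d]) / (rkj * st);
      double fi = coef * dthdi, fk = coef * dthdk;
      fx[i + d*n] += fi;
      fx[k + d*n] += fk;
      fx[j + d*n] -= (fi + fk);
    }
  }

  for (int c = 0; c < t.contacts.nrow(); ++c) {
    int i = t.contacts(c,0) - 1, j = t.contacts(c,1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double s = t.con_sig[c] / r;
    double s2 = s*s, s10 = s2*s2*s2*s2*s2, s12 = s10*s2;
    pe += t.con_eps[c] * (5.0 * s12 - 6.0 * s10);
    // -dV/dr = 60 eps (s12 - s10)/r ; radial force along (i - j)
    double f = 60.0 * t.con_eps[c] * (s12 - s10) / (r * r);
    fx[i]     += f * dx; fx[i+n]   += f * dy; fx[i+2*n] += f * dz;
    fx[j]     -= f * dx; fx[j+n]   -= f * dy; fx[j+2*n] -= f * dz;
  }

  const double cut2 = 9.0 * t.rep_sig * t.rep_sig;
  for (int p = 0; p < t.reps.nrow(); ++p) {
    int i = t.reps(p,0) - 1, j = t.reps(p,1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > cut2) continue;
    double r = std::sqrt(d2);
    double s = t.rep_sig / r;
    double s2 = s*s, s12 = s2*s2*s2*s2*s2*s2;
    pe += t.rep_eps * s12;
    double f = 12.0 * t.rep_eps * s12 / d2; // -dV/dr / r
    fx[i]     += f * dx; fx[i+n]   += f * dy; fx[i+2*n] += f * dz;
    fx[j]     -= f * dx; fx[j+n]   -= f * dy; fx[j+2*n] -= f * dz;
  }
  return pe;
}

static GoTerms make_terms(List model) {
  GoTerms t;
  t.bonds    = as<IntegerMatrix>(model["bonds_ij"]);
  t.bond_r0  = as<NumericVector>(model["bond_r0"]);
  t.bond_k   = as<NumericVector>(model["bond_k"]);
  t.angles   = as<IntegerMatrix>(model["angles_ijk"]);
  t.ang_th0  = as<NumericVector>(model["angle_theta0"]);
  t.ang_k    = as<NumericVector>(model["angle_k"]);
  t.contacts = as<IntegerMatrix>(model["contacts_ij"]);
  t.con_sig  = as<NumericVector>(model["contact_sigma"]);
  t.con_eps  = as<NumericVector>(model["contact_eps"]);
  t.reps     = as<IntegerMatrix>(model["rep_ij"]);
  t.rep_sig  = as<double>(model["rep_sigma"]);
  t.rep_eps  = as<double>(model["rep_eps"]);
  return t;
}

// [[Rcpp::export]]
double cpp_go_energy(NumericMatrix coords, List model) {
  GoTerms t = make_terms(model);
  std::vector<double> fx(3 * coords.nrow());
  return go_forces(coords, t, fx);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords0, List model, double mass,
                      double temperature, int nSteps, double dt,
                      double gammaFs, int saveInterval) {
  GoTerms t = make_terms(coords0.nrow() > 0 ? model : model);
  const int n = coords0.nrow();
  NumericMatrix x = clone(coords0);
  std::vector<double> v(3 * n), f(3 * n);
  RNGScope scope;

  const double kT = KB * temperature;
  // Maxwell-Boltzmann start; velocity unit A/fs
  const double vsig = std::sqrt(kT * KCAL_ACC / mass);
  for (int i = 0; i < 3 * n; ++i) v[i] = vsig * norm_rand();

  const double c1 = std::exp(-gammaFs * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1) * vsig;

  double pe = go_forces(x, t, f);
  const int nSaved = nSteps / saveInterval;
  NumericMatrix frames(nSaved, 3 * n);
  NumericVector peOut(nSaved), keOut(nSaved);
  int isave = 0;

  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[i + d*n] += 0.5 * dt * f[i + d*n] * KCAL_ACC / mass;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += 0.5 * dt * v[i + d*n];
    for (int i = 0; i < 3 * n; ++i)
      v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += 0.5 * dt * v[i + d*n];
    pe = go_forces(x, t, f);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[i + d*n] += 0.5 * dt * f[i + d*n] * KCAL_ACC / mass;

    if (!std::isfinite(pe) || std::fabs(pe) > 1e6)
      stop("potential energy diverged (|E| > 1e6 kcal/mol) at step %d; "
           "reduce the timestep", step);

    if (step % saveInterval == 0) {
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += v[i] * v[i];
      ke *= 0.5 * mass / KCAL_ACC;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames(isave, i + d*n) = x(i, d);
      peOut[isave] = pe;
      keOut[isave] = ke;
      ++isave;
    }
  }
  return List::create(_["frames"] = frames, _["pe"] = peOut, _["ke"] = keOut);
}
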