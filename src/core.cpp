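#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- counter-based Gaussian noise -----------------------------------------
// splitmix64 mixing of a (seed, step, bead, axis) counter; reproducible
// independent of threading and of R's RNG state.

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t x) {
  // strictly inside (0,1)
  return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double counter_gauss(uint64_t seed, uint64_t step,
                                   uint64_t bead, uint64_t axis) {
  uint64_t key = sm64(seed ^ (step * 0xA24BAED4963EE407ULL) ^
                      (bead * 0x9FB21C651E98DF25ULL) ^ axis);
  double u1 = u01(sm64(key));
  double u2 = u01(sm64(key ^ 0xD6E8FEB86659FD93ULL));
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

static inline double min_img(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

static const double KB = 0.0019872041;  // kcal/(mol K)

// ---- pairwise forces -------------------------------------------------------
// Harmonic bonds E = 0.5 k (r - r0)^2 along each chain; intermolecular 12-6
// LJ (Lorentz-Berthelot) + Coulomb kC qi qj / (eps_r r); intramolecular
// nonbonded pairs excluded. Minimum image on nonbonded pairs; bonds act on
// stored (unwrapped) coordinates.

struct EnergyParts { double vdw, ele, bond; };

static inline double fold(double d, double box, double half) {
  // minimum image for possibly multi-box separations (unwrapped coords)
  while (d > half) d -= box;
  while (d < -half) d += box;
  return d;
}

// Raw-pointer inner loop; x/f are n x 3 column-major arrays.
static EnergyParts forces_inner(const double* x, int n, const int* mol,
                                const double* q, const double* eps,
                                const double* sig, const int* bi,
                                const int* bj, int nb,
                                double box, double kC, double diel,
                                double bond_k, double bond_r0,
                                double cutoff, double* f) {
  std::fill(f, f + 3 * n, 0.0);
  EnergyParts e = {0.0, 0.0, 0.0};
  const bool use_cut = cutoff > 0.0;
  const double cut2 = cutoff * cutoff;
  const double half = 0.5 * box;
  const double kCd = kC / diel;
  const double* X = x; const double* Y = x + n; const double* Z = x + 2 * n;
  double* FX = f; double* FY = f + n; double* FZ = f + 2 * n;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i];
    const double qi = q[i] * kCd, ei = eps[i], si = sig[i];
    const int mi = mol[i];
    double fxi = 0, fyi = 0, fzi = 0;
    for (int j = i + 1; j < n; ++j) {
      if (mi == mol[j]) continue;
      double dx = fold(xi - X[j], box, half);
      double dy = fold(yi - Y[j], box, half);
      double dz = fold(zi - Z[j], box, half);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cut && r2 > cut2) continue;
      if (r2 < 1e-12)
        stop("singularity: beads %d and %d closer than 1e-6 A", i + 1, j + 1);
      double inv_r2 = 1.0 / r2;
      double sij = 0.5 * (si + sig[j]);
      double eij = std::sqrt(ei * eps[j]);
      double sr2 = sij * sij * inv_r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      e.vdw += 4.0 * eij * (sr12 - sr6);
      // dE/dr = -4 eij (12 sr12 - 6 sr6) / r ; force along +dx on i
      double fmag = 4.0 * eij * (12.0 * sr12 - 6.0 * sr6) * inv_r2;
      double qq = qi * q[j];
      if (qq != 0.0) {
        double ec = qq * std::sqrt(inv_r2);
        e.ele += ec;
        fmag += ec * inv_r2;
      }
      fxi += fmag * dx; fyi += fmag * dy; fzi += fmag * dz;
      FX[j] -= fmag * dx; FY[j] -= fmag * dy; FZ[j] -= fmag * dz;
    }
    FX[i] += fxi; FY[i] += fyi; FZ[i] += fzi;
  }
  for (int b = 0; b < nb; ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    double dx = X[i] - X[j];
    double dy = Y[i] - Y[j];
    double dz = Z[i] - Z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12)
      stop("singularity: bonded beads %d and %d coincide", i + 1, j + 1);
    double dr = r - bond_r0;
    e.bond += 0.5 * bond_k * dr * dr;
    double fmag = -bond_k * dr / r;  // along +d on i
    FX[i] += fmag * dx; FY[i] += fmag * dy; FZ[i] += fmag * dz;
    FX[j] -= fmag * dx; FY[j] -= fmag * dy; FZ[j] -= fmag * dz;
  }
  return e;
}

static EnergyParts forces_mat(const NumericMatrix& x,
                              const IntegerVector& mol,
                              const NumericVector& q,
                              const NumericVector& eps,
                              const NumericVector& sig,
                              const IntegerMatrix& bonds,
                              double box, double kC, double diel,
                              double bond_k, double bond_r0,
                              double cutoff, NumericMatrix& f) {
  const int nb = bonds.nrow();
  std::vector<int> bi(nb), bj(nb);
  for (int b = 0; b < nb; ++b) { bi[b] = bonds(b, 0); bj[b] = bonds(b, 1); }
  return forces_inner(REAL(x), x.nrow(), INTEGER(mol), REAL(q), REAL(eps),
                      REAL(sig), bi.data(), bj.data(), nb, box, kC, diel,
                      bond_k, bond_r0, cutoff, REAL(f));
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericMatrix coords, IntegerVector mol,
                        NumericVector charge, NumericVector eps,
                        NumericVector sigma, IntegerMatrix bonds,
                        double box, double kC, double dielectric,
                        double bond_k, double bond_r0, double cutoff) {
  NumericMatrix f(coords.nrow(), 3);
  EnergyParts e = forces_mat(coords, mol, charge, eps, sigma, bonds, box,
                             kC, dielectric, bond_k, bond_r0, cutoff, f);
  return List::create(
    _["forces"] = f,
    _["e_vdw"] = e.vdw, _["e_ele"] = e.ele, _["e_bond"] = e.bond,
    _["e_total"] = e.vdw + e.ele + e.bond);
}

// ---- BAOAB Langevin integrator --------------------------------------------

// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix coords, NumericMatrix vel,
                      NumericVector mass, IntegerVector mol,
                      NumericVector charge, NumericVector eps,
                      NumericVector sigma, IntegerMatrix bonds,
                      double box, double kC, double dielectric,
                      double bond_k, double bond_r0, double cutoff,
                      double dt, double friction, double temperature,
                      int n_steps, int save_every, int seed) {
  const int n = coords.nrow();
  NumericMatrix x = clone(coords), v = clone(vel), f(n, 3);
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double kT = KB * temperature;
  const bool noisy = (friction > 0.0) && (temperature > 0.0);
  const int n_frames = n_steps / save_every + 1;
  List frames_x(n_frames), frames_v(n_frames);
  NumericVector t_out(n_frames), pe(n_frames), ke(n_frames),
      evdw(n_frames), eele(n_frames), ebond(n_frames);

  const int nb = bonds.nrow();
  std::vector<int> bvi(nb), bvj(nb);
  for (int b = 0; b < nb; ++b) { bvi[b] = bonds(b, 0); bvj[b] = bonds(b, 1); }
  double* px = REAL(x); double* pv = REAL(v); double* pf = REAL(f);
  const double* pm = REAL(mass);
  EnergyParts e = forces_inner(px, n, INTEGER(mol), REAL(charge), REAL(eps),
                               REAL(sigma), bvi.data(), bvj.data(), nb, box,
                               kC, dielectric, bond_k, bond_r0, cutoff, pf);
  int fr = 0;
  auto record = [&](int step, const EnergyParts& ep) {
    frames_x[fr] = clone(x);
    frames_v[fr] = clone(v);
    t_out[fr] = step * dt;
    double k = 0.0;
    for (int i = 0; i < n; ++i)
      k += 0.5 * mass[i] *
           (v(i, 0) * v(i, 0) + v(i, 1) * v(i, 1) + v(i, 2) * v(i, 2));
    ke[fr] = k;
    pe[fr] = ep.vdw + ep.ele + ep.bond;
    evdw[fr] = ep.vdw; eele[fr] = ep.ele; ebond[fr] = ep.bond;
    ++fr;
  };
  record(0, e);

  const uint64_t useed = static_cast<uint64_t>(seed);
  for (int step = 1; step <= n_steps; ++step) {
    for (int a = 0; a < 3; ++a) {
      double* xa = px + a * n; double* va = pv + a * n;
      const double* fa = pf + a * n;
      for (int i = 0; i < n; ++i) {
        va[i] += 0.5 * dt * fa[i] / pm[i];
        xa[i] += 0.5 * dt * va[i];
      }
    }
    if (friction > 0.0) {
      for (int i = 0; i < n; ++i) {
        double s = noisy ? c2 * std::sqrt(kT / pm[i]) : 0.0;
        for (int a = 0; a < 3; ++a) {
          double xi = noisy ? counter_gauss(useed, step, i, a) : 0.0;
          pv[i + a * n] = c1 * pv[i + a * n] + s * xi;
        }
      }
    }
    for (int a = 0; a < 3; ++a) {
      double* xa = px + a * n; const double* va = pv + a * n;
      for (int i = 0; i < n; ++i) xa[i] += 0.5 * dt * va[i];
    }
    e = forces_inner(px, n, INTEGER(mol), REAL(charge), REAL(eps),
                     REAL(sigma), bvi.data(), bvj.data(), nb, box, kC,
                     dielectric, bond_k, bond_r0, cutoff, pf);
    double etot = e.vdw + e.ele + e.bond;
    if (!std::isfinite(etot) || etot > 1e6)
      stop("integration diverged at step %d (potential energy %g kcal/mol); "
           "reduce dt", step, etot);
    for (int a = 0; a < 3; ++a) {
      double* va = pv + a * n; const double* fa = pf + a * n;
      for (int i = 0; i < n; ++i) va[i] += 0.5 * dt * fa[i] / pm[i];
    }
    if (step % save_every == 0) record(step, e);
  }
  return List::create(
    _["frames_x"] = frames_x, _["frames_v"] = frames_v,
    _["times"] = t_out, _["potential"] = pe, _["kinetic"] = ke,
    _["vdw"] = evdw, _["ele"] = eele, _["bond"] = ebond);
}

// ---- Shrake-Rupley SASA ----------------------------------------------------
// Deterministic Fibonacci-lattice quadrature on each inflated sphere; a
// point is accessible when outside every other bead's inflated sphere.
// Open-space geometry (molecules are kept whole by the caller).

// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  // Fibonacci sphere point set
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = ga * k;
    px[k] = rk * std::cos(th);
    py[k] = rk * std::sin(th);
    pz[k] = zk;
  }
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = ri + rj;
      if (d2 < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = coords(i, 0) + ri * px[k];
      double qy = coords(i, 1) + ri * py[k];
      double qz = coords(i, 2) + ri * pz[k];
      bool free_pt = true;
      for (int j : nbr) {
        double rj = radii[j] + probe;
        double dx = qx - coords(j, 0);
        double dy = qy - coords(j, 1);
        double dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}
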