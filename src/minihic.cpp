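// Compiled inner loops: Monte Carlo simulated annealing of restraint-based
// chromosome models, pairwise superposition RMSD for ensemble clustering,
// and the pairwise co-expression tendency (concordance) statistic.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// --- deterministic, platform-independent RNG (splitmix64 + xoshiro-like use)

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0) + 5e-17;
  }
  double norm() {  // Box-Muller
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// restraint kinds: 0 = harmonic (adjacent/attract), 1 = one-sided lower bound

static inline double pair_energy(double d, int kind, double d0, double k) {
  if (kind == 0) {
    double e = d - d0;
    return k * e * e;
  }
  if (d < d0) {
    double e = d0 - d;
    return k * e * e;
  }
  return 0.0;
}

static inline double dist3(const std::vector<double>& x, int a, int b) {
  double dx = x[3 * a] - x[3 * b];
  double dy = x[3 * a + 1] - x[3 * b + 1];
  double dz = x[3 * a + 2] - x[3 * b + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Energy of all restraints touching particle p.
static double particle_energy(const std::vector<double>& x, int p,
                              const std::vector<std::vector<int>>& byp,
                              const IntegerVector& ri, const IntegerVector& rj,
                              const IntegerVector& kind, const NumericVector& d0,
                              const NumericVector& kf) {
  double e = 0.0;
  for (int idx : byp[p]) {
    int a = ri[idx], b = rj[idx];
    e += pair_energy(dist3(x, a, b), kind[idx], d0[idx], kf[idx]);
  }
  return e;
}

static double total_energy(const std::vector<double>& x,
                           const IntegerVector& ri, const IntegerVector& rj,
                           const IntegerVector& kind, const NumericVector& d0,
                           const NumericVector& kf) {
  double e = 0.0;
  for (int idx = 0; idx < ri.size(); ++idx) {
    e += pair_energy(dist3(x, ri[idx], rj[idx]), kind[idx], d0[idx], kf[idx]);
  }
  return e;
}

// [[Rcpp::export(name = ".anneal_ensemble")]]
List anneal_ensemble(int n_particles, IntegerVector ri, IntegerVector rj,
                     IntegerVector kind, NumericVector d0, NumericVector kf,
                     int n_models, double t0, double cooling, int n_temps,
                     int sweeps_per_temp, double move_sigma, int quench_sweeps,
                     double init_radius, double seed) {
  int nr = ri.size();
  std::vector<std::vector<int>> byp(n_particles);
  for (int idx = 0; idx < nr; ++idx) {
    byp[ri[idx]].push_back(idx);
    byp[rj[idx]].push_back(idx);
  }
  NumericVector penalties(n_models);
  NumericVector initial(n_models);
  NumericVector coords(3 * n_particles * n_models);

  for (int m = 0; m < n_models; ++m) {
    Rng rng(static_cast<uint64_t>(seed) * 1000003ULL + static_cast<uint64_t>(m) + 1ULL);
    std::vector<double> x(3 * n_particles);
    for (int p = 0; p < n_particles; ++p) {
      // random point in a ball of radius init_radius
      double nx, ny, nz;
      do {
        nx = 2.0 * rng.unif() - 1.0;
        ny = 2.0 * rng.unif() - 1.0;
        nz = 2.0 * rng.unif() - 1.0;
      } while (nx * nx + ny * ny + nz * nz > 1.0);
      x[3 * p] = nx * init_radius;
      x[3 * p + 1] = ny * init_radius;
      x[3 * p + 2] = nz * init_radius;
    }
    initial[m] = total_energy(x, ri, rj, kind, d0, kf);

    double T = t0;
    for (int t = 0; t < n_temps; ++t) {
      double sigma = move_sigma * std::sqrt(T / t0);
      if (sigma < 1e-3) sigma = 1e-3;
      for (int s = 0; s < sweeps_per_temp; ++s) {
        for (int p = 0; p < n_particles; ++p) {
          double e0 = particle_energy(x, p, byp, ri, rj, kind, d0, kf);
          double ox = x[3 * p], oy = x[3 * p + 1], oz = x[3 * p + 2];
          x[3 * p] += sigma * rng.norm();
          x[3 * p + 1] += sigma * rng.norm();
          x[3 * p + 2] += sigma * rng.norm();
          double e1 = particle_energy(x, p, byp, ri, rj, kind, d0, kf);
          double dE = e1 - e0;
          if (dE > 0 && rng.unif() >= std::exp(-dE / T)) {
            x[3 * p] = ox; x[3 * p + 1] = oy; x[3 * p + 2] = oz;
          }
        }
      }
      T *= cooling;
    }
    // zero-temperature quench with shrinking moves
    double sigma = move_sigma * 0.2;
    for (int q = 0; q < quench_sweeps; ++q) {
      for (int p = 0; p < n_particles; ++p) {
        double e0 = particle_energy(x, p, byp, ri, rj, kind, d0, kf);
        double ox = x[3 * p], oy = x[3 * p + 1], oz = x[3 * p + 2];
        x[3 * p] += sigma * rng.norm();
        x[3 * p + 1] += sigma * rng.norm();
        x[3 * p + 2] += sigma * rng.norm();
        if (particle_energy(x, p, byp, ri, rj, kind, d0, kf) >= e0) {
          x[3 * p] = ox; x[3 * p + 1] = oy; x[3 * p + 2] = oz;
        }
      }
      sigma *= 0.98;
      if (sigma < 0.05) sigma = 0.05;
    }
    double e = total_energy(x, ri, rj, kind, d0, kf);
    if (!std::isfinite(e)) stop("non-finite objective in model %d", m + 1);
    penalties[m] = e;
    std::copy(x.begin(), x.end(), coords.begin() + 3 * n_particles * m);
  }
  return List::create(_["coords"] = coords, _["penalty"] = penalties,
                      _["initial_penalty"] = initial);
}

// --- superposition RMSD ----------------------------------------------------

// eigenvalues of a symmetric 3x3 matrix (analytic, ascending order)
static void sym3_eigenvalues(const double a[3][3], double ev[3]) {
  double p1 = a[0][1] * a[0][1] + a[0][2] * a[0][2] + a[1][2] * a[1][2];
  double q = (a[0][0] + a[1][1] + a[2][2]) / 3.0;
  if (p1 < 1e-30) {
    ev[0] = a[0][0]; ev[1] = a[1][1]; ev[2] = a[2][2];
    if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
    if (ev[1] > ev[2]) std::swap(ev[1], ev[2]);
    if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
    return;
  }
  double p2 = (a[0][0] - q) * (a[0][0] - q) + (a[1][1] - q) * (a[1][1] - q) +
              (a[2][2] - q) * (a[2][2] - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double b[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) b[i][j] = (a[i][j] - (i == j ? q : 0.0)) / p;
  double detb = b[0][0] * (b[1][1] * b[2][2] - b[1][2] * b[2][1]) -
                b[0][1] * (b[1][0] * b[2][2] - b[1][2] * b[2][0]) +
                b[0][2] * (b[1][0] * b[2][1] - b[1][1] * b[2][0]);
  double r = detb / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  ev[2] = q + 2.0 * p * std::cos(phi);
  ev[0] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Optimal-superposition RMSD between two centered n x 3 coordinate sets,
// via singular values of the 3x3 covariance; reflections disallowed unless
// allow_reflection (mirror images then superpose poorly, by design).
static double kabsch_rmsd(const double* P, const double* Q, int n, bool allow_reflection) {
  double cP[3] = {0, 0, 0}, cQ[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      cP[d] += P[i + d * n];
      cQ[d] += Q[i + d * n];
    }
  for (int d = 0; d < 3; ++d) { cP[d] /= n; cQ[d] /= n; }
  double H[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  double gp = 0.0, gq = 0.0;
  for (int i = 0; i < n; ++i) {
    double p[3], q[3];
    for (int d = 0; d < 3; ++d) {
      p[d] = P[i + d * n] - cP[d];
      q[d] = Q[i + d * n] - cQ[d];
      gp += p[d] * p[d];
      gq += q[d] * q[d];
    }
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) H[r][c] += p[r] * q[c];
  }
  double HtH[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      HtH[r][c] = 0.0;
      for (int k = 0; k < 3; ++k) HtH[r][c] += H[k][r] * H[k][c];
    }
  double ev[3];
  sym3_eigenvalues(HtH, ev);
  double sv[3];
  for (int d = 0; d < 3; ++d) sv[d] = std::sqrt(std::max(ev[d], 0.0));  // ascending
  double detH = H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
                H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
                H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
  double trace = sv[0] + sv[1] + sv[2];
  if (!allow_reflection && detH < 0) trace = sv[1] + sv[2] - sv[0];
  double msd = (gp + gq - 2.0 * trace) / n;
  return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export(name = ".pairwise_rmsd")]]
NumericMatrix pairwise_rmsd(NumericVector coords, int n_particles, int n_models,
                            bool allow_reflection) {
  NumericMatrix out(n_models, n_models);
  int stride = 3 * n_particles;
  // coords are stored model-major as (x1,y1,z1,x2,...) per model; repack to
  // column-major n x 3 blocks
  std::vector<double> packed(static_cast<size_t>(stride) * n_models);
  for (int m = 0; m < n_models; ++m)
    for (int i = 0; i < n_particles; ++i)
      for (int d = 0; d < 3; ++d)
        packed[static_cast<size_t>(m) * stride + i + d * n_particles] =
            coords[static_cast<size_t>(m) * stride + 3 * i + d];
  for (int a = 0; a < n_models; ++a)
    for (int b = a + 1; b < n_models; ++b) {
      double r = kabsch_rmsd(&packed[static_cast<size_t>(a) * stride],
                             &packed[static_cast<size_t>(b) * stride],
                             n_particles, allow_reflection);
      out(a, b) = r;
      out(b, a) = r;
    }
  return out;
}

// --- co-expression tendency ------------------------------------------------

// For genes g, h over samples: (concordant - discordant sample pairs) /
// total sample pairs; ties count to neither but stay in the denominator.
// [[Rcpp::export(name = ".tendency_matrix")]]
NumericMatrix tendency_matrix(NumericMatrix expr) {
  int g = expr.nrow(), m = expr.ncol();
  double total = m * (m - 1) / 2.0;
  NumericMatrix out(g, g);
  std::vector<double> sgn(static_cast<size_t>(g));
  for (int a = 0; a < g; ++a) out(a, a) = 1.0;
  for (int s = 0; s < m; ++s) {
    for (int t = s + 1; t < m; ++t) {
      for (int a = 0; a < g; ++a) {
        double d = expr(a, s) - expr(a, t);
        sgn[a] = (d > 0) - (d < 0);
      }
      for (int a = 0; a < g; ++a) {
        if (sgn[a] == 0) continue;
        for (int b = a + 1; b < g; ++b) out(a, b) += sgn[a] * sgn[b];
      }
    }
  }
  for (int a = 0; a < g; ++a)
    for (int b = a + 1; b < g; ++b) {
      double v = out(a, b) / total;
      out(a, b) = v;
      out(b, a) = v;
    }
  return out;
}
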