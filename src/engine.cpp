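#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hard-core diameter d is the unit of length throughout (d = 1).

static inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  // roundoff can land exactly on L; keep the half-open contract [0, L)
  if (x >= L) x -= L;
  if (x < 0.0) x = 0.0;
  return x;
}

static inline double mindiff(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

// Stripe lookup: edges are the cumulative upper boundaries (last == L).
static inline double factor_at(double x, const NumericVector& edges,
                               const NumericVector& factors) {
  int n = edges.size();
  for (int i = 0; i < n - 1; ++i)
    if (x < edges[i]) return factors[i];
  return factors[n - 1];
}

// Energy of a particle at (px, py) against nf frozen particles, with the
// triangular well depth eps/U taken from the particle's own region.
// Returns +Inf on hard-core overlap.
static double penergy(double px, double py,
                      const double* fx, const double* fy, int nf,
                      double L, double lambda, double eps, double U) {
  const double lam2 = lambda * lambda;
  const double invw = 1.0 / (lambda - 1.0);
  double e = 0.0;
  for (int j = 0; j < nf; ++j) {
    double dx = mindiff(px - fx[j], L);
    double dy = mindiff(py - fy[j], L);
    double r2 = dx * dx + dy * dy;
    if (r2 < 1.0) return R_PosInf;
    if (r2 <= lam2) {
      double r = std::sqrt(r2);
      e += -(eps / U) * (lambda - r) * invw;
    }
  }
  return e;
}

// [[Rcpp::export]]
double cpp_particle_energy(double px, double py,
                           NumericVector fx, NumericVector fy,
                           double L, double lambda, double eps,
                           NumericVector edges, NumericVector factors) {
  double U = factor_at(px, edges, factors);
  return penergy(px, py, fx.begin(), fy.begin(), fx.size(), L, lambda, eps, U);
}

// One full sequential-quenching realization: insert with hard-core
// rejection, diffuse the newest particle by Metropolis among its frozen
// predecessors, quench, repeat until n_target particles are placed.
// Uses R's RNG (seeded from R via set.seed).
// Uniform cell list over the frozen particles. Cell edge >= lambda*d, so
// every particle within the interaction range of a point lies in the 3x3
// block around the point's cell. Per-cell index lists are kept in
// increasing insertion order and candidates are re-sorted globally, so the
// energy sum visits exactly the same terms in exactly the same order as
// the brute-force loop and is bit-identical to it.
struct CellGrid {
  int nc;                 // cells per axis (>= 3 to be usable)
  double cell;            // cell edge
  double L;
  std::vector<std::vector<int> > bins;

  CellGrid(double L_, double range) : L(L_) {
    nc = (int)std::floor(L_ / range);
    if (nc > 0) {
      cell = L_ / nc;
      bins.resize((size_t)nc * nc);
    } else {
      cell = L_;
    }
  }
  bool usable() const { return nc >= 3; }
  int cell_of(double x, double y) const {
    int ix = (int)(x / cell); if (ix >= nc) ix = nc - 1;
    int iy = (int)(y / cell); if (iy >= nc) iy = nc - 1;
    return ix * nc + iy;
  }
  void add(int idx, double x, double y) {
    bins[cell_of(x, y)].push_back(idx);
  }
  // indices of all frozen particles in the 3x3 neighbourhood, sorted
  void candidates(double x, double y, std::vector<int>& out) const {
    out.clear();
    int ix = (int)(x / cell); if (ix >= nc) ix = nc - 1;
    int iy = (int)(y / cell); if (iy >= nc) iy = nc - 1;
    for (int dx = -1; dx <= 1; ++dx) {
      int jx = (ix + dx + nc) % nc;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = (iy + dy + nc) % nc;
        const std::vector<int>& b = bins[(size_t)jx * nc + jy];
        out.insert(out.end(), b.begin(), b.end());
      }
    }
    std::sort(out.begin(), out.end());
  }
};

// Cell-list energy: same terms, same order, same arithmetic as penergy.
static double penergy_cells(double px, double py,
                            const double* fx, const double* fy,
                            const CellGrid& grid, std::vector<int>& buf,
                            double L, double lambda, double eps, double U) {
  const double lam2 = lambda * lambda;
  const double invw = 1.0 / (lambda - 1.0);
  grid.candidates(px, py, buf);
  double e = 0.0;
  for (size_t k = 0; k < buf.size(); ++k) {
    int j = buf[k];
    double dx = mindiff(px - fx[j], L);
    double dy = mindiff(py - fy[j], L);
    double r2 = dx * dx + dy * dy;
    if (r2 < 1.0) return R_PosInf;
    if (r2 <= lam2) {
      double r = std::sqrt(r2);
      e += -(eps / U) * (lambda - r) * invw;
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_run_realization(int n_target, double L, int moves, double max_disp,
                         double lambda, double eps, double tstar,
                         NumericVector edges, NumericVector factors,
                         double retry_cap) {
  NumericVector X(n_target), Y(n_target);
  NumericVector E(n_target);       // energy at quench
  NumericVector E0(n_target);      // energy at insertion
  const double beta = 1.0 / (tstar * eps);

  CellGrid grid(L, lambda);
  const bool use_cells = grid.usable();
  std::vector<int> buf;

  for (int i = 0; i < n_target; ++i) {
    // insertion with overlap rejection
    double x = 0.0, y = 0.0, e = R_PosInf;
    double attempts = 0.0;
    for (;;) {
      attempts += 1.0;
      if (attempts > retry_cap)
        stop("insertion jammed after %.0f attempts (particle %d of %d): "
             "density or pattern infeasible", retry_cap, i + 1, n_target);
      x = unif_rand() * L;
      y = unif_rand() * L;
      double U = factor_at(x, edges, factors);
      e = use_cells
        ? penergy_cells(x, y, X.begin(), Y.begin(), grid, buf, L, lambda,
                        eps, U)
        : penergy(x, y, X.begin(), Y.begin(), i, L, lambda, eps, U);
      if (R_FINITE(e)) break;
    }
    E0[i] = e;

    // Metropolis surface diffusion among frozen predecessors
    for (int m = 0; m < moves; ++m) {
      double nx = wrap1(x + (unif_rand() * 2.0 - 1.0) * max_disp, L);
      double ny = wrap1(y + (unif_rand() * 2.0 - 1.0) * max_disp, L);
      double U = factor_at(nx, edges, factors);
      double ne = use_cells
        ? penergy_cells(nx, ny, X.begin(), Y.begin(), grid, buf, L, lambda,
                        eps, U)
        : penergy(nx, ny, X.begin(), Y.begin(), i, L, lambda, eps, U);
      if (!R_FINITE(ne)) continue;                    // overlap: certain rejection
      double de = ne - e;
      if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
        x = nx; y = ny; e = ne;
      }
    }

    X[i] = x; Y[i] = y; E[i] = e;                    // quench
    if (use_cells) grid.add(i, x, y);
  }

  return List::create(_["x"] = X, _["y"] = Y,
                      _["energy"] = E, _["energy_init"] = E0);
}

// Metropolis walk of a single mobile particle in a frozen landscape.
// Records the position every `record_every` attempted moves (the final
// position is always recorded last); record_every <= 0 records only the
// final position.
// [[Rcpp::export]]
NumericMatrix cpp_metropolis_walk(double x0, double y0,
                                  NumericVector fx, NumericVector fy,
                                  double L, double lambda, double eps,
                                  double tstar,
                                  NumericVector edges, NumericVector factors,
                                  double max_disp, int nsteps,
                                  int record_every) {
  const double beta = 1.0 / (tstar * eps);
  double x = x0, y = y0;
  double e = penergy(x, y, fx.begin(), fy.begin(), fx.size(), L, lambda, eps,
                     factor_at(x, edges, factors));
  if (!R_FINITE(e))
    stop("starting position overlaps a frozen particle");

  int nrec = (record_every > 0) ? nsteps / record_every : 0;
  NumericMatrix out(nrec + 1, 2);
  int k = 0;
  for (int m = 1; m <= nsteps; ++m) {
    double nx = wrap1(x + (unif_rand() * 2.0 - 1.0) * max_disp, L);
    double ny = wrap1(y + (unif_rand() * 2.0 - 1.0) * max_disp, L);
    double U = factor_at(nx, edges, factors);
    double ne = penergy(nx, ny, fx.begin(), fy.begin(), fx.size(), L, lambda,
                        eps, U);
    if (R_FINITE(ne)) {
      double de = ne - e;
      if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
        x = nx; y = ny; e = ne;
      }
    }
    if (record_every > 0 && m % record_every == 0 && k < nrec) {
      out(k, 0) = x; out(k, 1) = y; ++k;
    }
  }
  out(nrec, 0) = x; out(nrec, 1) = y;
  return out;
}

// Minimum-image pair-distance histogram for one configuration.
// Half-open bins [i*dr, (i+1)*dr); unordered pairs counted once.
// [[Rcpp::export]]
IntegerVector cpp_pair_histogram(NumericVector x, NumericVector y,
                                 double L, double dr, int nbins) {
  IntegerVector counts(nbins);
  int n = x.size();
  double rmax = nbins * dr;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = mindiff(x[i] - x[j], L);
      double dy = mindiff(y[i] - y[j], L);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < rmax) counts[(int)(r / dr)] += 1;
    }
  }
  return counts;
}
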