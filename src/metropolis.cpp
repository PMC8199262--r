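#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Confidence-weighted truncated Lennard-Jones pair term, on the squared
// distance to avoid sqrt in the hot loop. Zero beyond the cutoff or at
// theta = 0; d2 = 0 never reaches here (occupancy forbids overlaps).
static inline double pair_term(double theta, double d2, double rm2,
                               int n, double beta, double cutoff2) {
  if (theta <= 0.0 || d2 > cutoff2) return 0.0;
  double s2 = rm2 / d2;
  double s6 = s2 * s2 * s2;
  double w = theta;
  for (int k = 1; k < n; ++k) w *= theta;
  return beta * w * (s6 * s6 - 2.0 * s6);
}

static inline double sq_dist(const IntegerMatrix& xyz, int i, int j) {
  double dx = xyz(i, 0) - xyz(j, 0);
  double dy = xyz(i, 1) - xyz(j, 1);
  double dz = xyz(i, 2) - xyz(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
double total_loss_cpp(IntegerMatrix xyz, NumericMatrix th, double rm,
                      int n, double beta, double cutoff) {
  int l = xyz.nrow();
  double rm2 = rm * rm, cutoff2 = cutoff * cutoff, total = 0.0;
  for (int i = 0; i < l - 1; ++i)
    for (int j = i + 1; j < l; ++j)
      total += pair_term(th(i, j), sq_dist(xyz, i, j), rm2, n, beta, cutoff2);
  return total;
}

static double bead_delta(const IntegerMatrix& xyz, const NumericMatrix& th,
                         double rm2, int n, double beta, double cutoff2,
                         int b, int nx, int ny, int nz) {
  int l = xyz.nrow();
  double delta = 0.0;
  for (int j = 0; j < l; ++j) {
    if (j == b) continue;
    double theta = th(b, j);
    if (theta <= 0.0) continue;
    double dx = nx - xyz(j, 0), dy = ny - xyz(j, 1), dz = nz - xyz(j, 2);
    double d2new = dx * dx + dy * dy + dz * dz;
    delta += pair_term(theta, d2new, rm2, n, beta, cutoff2)
           - pair_term(theta, sq_dist(xyz, b, j), rm2, n, beta, cutoff2);
  }
  return delta;
}

// [[Rcpp::export]]
double delta_loss_cpp(IntegerMatrix xyz, NumericMatrix th, double rm,
                      int n, double beta, double cutoff, int bead,
                      IntegerVector new_pos) {
  return bead_delta(xyz, th, rm * rm, n, beta, cutoff * cutoff,
                    bead, new_pos[0], new_pos[1], new_pos[2]);
}

static const int NB[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},{1,-1,-1},
  {1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},
  {1,1,0},{1,1,1}
};

static inline long long site_key(int x, int y, int z, long long side) {
  return (long long)x + side * ((long long)y + side * (long long)z);
}

// Metropolis-Hastings over 26-neighbour single-bead moves, one level per
// temperature in `temps`. A level ends when attempts reach attempts_cap or
// accepted moves reach accepts_cap. Out-of-lattice and occupied-site
// proposals count as attempts but are never accepted. Uses R's RNG, so the
// run is reproducible from set.seed() on the R side.
// [[Rcpp::export]]
List metropolis_run_cpp(IntegerMatrix coords, NumericMatrix th, double rm,
                        int n, double beta, double cutoff,
                        NumericVector temps, int attempts_cap,
                        double accepts_cap, int lattice_side) {
  IntegerMatrix xyz = clone(coords);
  int l = xyz.nrow();
  long long side = lattice_side;
  double rm2 = rm * rm, cutoff2 = cutoff * cutoff;

  std::unordered_set<long long> occ;
  occ.reserve(l * 2);
  for (int i = 0; i < l; ++i)
    occ.insert(site_key(xyz(i, 0), xyz(i, 1), xyz(i, 2), side));

  double loss = total_loss_cpp(xyz, th, rm, n, beta, cutoff);
  int n_levels = temps.size();
  NumericMatrix trace(n_levels, 4);  // temp, loss, accept_rate, attempts

  for (int lev = 0; lev < n_levels; ++lev) {
    double tc = temps[lev];
    int attempts = 0, accepted = 0;
    while (attempts < attempts_cap && accepted < accepts_cap) {
      ++attempts;
      int b = (int)(unif_rand() * l);
      if (b == l) b = l - 1;
      int m = (int)(unif_rand() * 26);
      if (m == 26) m = 25;
      int nx = xyz(b, 0) + NB[m][0];
      int ny = xyz(b, 1) + NB[m][1];
      int nz = xyz(b, 2) + NB[m][2];
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= lattice_side || ny >= lattice_side || nz >= lattice_side)
        continue;
      long long key = site_key(nx, ny, nz, side);
      if (occ.count(key)) continue;
      double delta = bead_delta(xyz, th, rm2, n, beta, cutoff2,
                                b, nx, ny, nz);
      bool accept = (delta <= 0.0) || (unif_rand() < std::exp(-delta / tc));
      if (accept) {
        occ.erase(site_key(xyz(b, 0), xyz(b, 1), xyz(b, 2), side));
        occ.insert(key);
        xyz(b, 0) = nx; xyz(b, 1) = ny; xyz(b, 2) = nz;
        loss += delta;
        ++accepted;
      }
    }
    // full recomputation once per level: kills incremental drift and keeps
    // the trace exact
    loss = total_loss_cpp(xyz, th, rm, n, beta, cutoff);
    trace(lev, 0) = tc;
    trace(lev, 1) = loss;
    trace(lev, 2) = attempts > 0 ? (double)accepted / attempts : 0.0;
    trace(lev, 3) = attempts;
  }

  return List::create(_["coords"] = xyz, _["trace"] = trace,
                      _["loss"] = loss);
}
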