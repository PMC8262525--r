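#include <Rcpp.h>
using namespace Rcpp;

// Simulate first-exit times for a batch of walkers on the layered lattice.
// p_left / p_right are indexed by position (element x corresponds to lattice
// position x, so p_left[0] belongs to the absorbing site and is never used).
// Draws come from R's RNG stream, so set.seed() in R controls reproducibility.
// [[Rcpp::export]]
IntegerVector walk_exit_times(NumericVector p_left, NumericVector p_right,
                              IntegerVector release, double step_cap) {
  const int n_rec = release.size();
  const int L = p_left.size() - 1;
  IntegerVector out(n_rec);
  for (int r = 0; r < n_rec; ++r) {
    int x = release[r];
    if (x < 1 || x > L)
      stop("release position %d is outside (0, %d]", x, L);
    double steps = 0.0;
    while (x > 0) {
      const double u = unif_rand();
      if (u < p_left[x]) {
        --x;
      } else if (u < p_left[x] + p_right[x]) {
        ++x;
      }
      steps += 1.0;
      if (steps >= step_cap)
        stop("walker exceeded the step cap (%.0f steps) without exiting",
             step_cap);
    }
    out[r] = static_cast<int>(steps);
  }
  return out;
}

// Iterated banded propagation of the occupancy vector: returns the exit-time
// CDF F(t) = mass absorbed at position 0 by step t, for t = 0..t_max.
// O(L) per step; used as the reference route cross-checking the spectral path.
// [[Rcpp::export]]
NumericVector propagate_exit_cdf(NumericVector p_left, NumericVector p_right,
                                 int release, int t_max) {
  const int L = p_left.size() - 1;
  if (release < 1 || release > L)
    stop("release position must lie in (0, L]");
  std::vector<double> p(L + 1, 0.0), q(L + 1, 0.0);
  p[release] = 1.0;
  NumericVector F(t_max + 1);
  F[0] = 0.0;
  for (int t = 1; t <= t_max; ++t) {
    // absorbing site accumulates; transient sites receive tridiagonal flow
    q[0] = p[0] + p_left[1] * p[1];
    for (int x = 1; x <= L; ++x) {
      double stay = (1.0 - p_left[x] - p_right[x]) * p[x];
      double from_left = (x >= 2) ? p_right[x - 1] * p[x - 1] : 0.0;
      double from_right = (x < L) ? p_left[x + 1] * p[x + 1] : 0.0;
      q[x] = stay + from_left + from_right;
    }
    p.swap(q);
    F[t] = p[0];
  }
  return F;
}
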