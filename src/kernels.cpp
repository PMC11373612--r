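// Inner loops: stochastic integrators, absorbing-boundary runs, and
// multiple-time-origin lagged correlators. All random numbers come from
// R's RNG stream (norm_rand), so results are reproducible from set.seed()
// and identical to the R reference integrators draw for draw.
#include <Rcpp.h>
using namespace Rcpp;

static const double KCAL = 418.4; // amu Å^2/ps^2 per kcal/mol

// Family potential parameters packed as (a_c, h, w, p, c); a_c = 0 means
// no confinement term (flat/free families).
struct Pot {
  double ac, h, w, p, c;
  bool confine;
  explicit Pot(const NumericVector& pp)
      : ac(pp[0]), h(pp[1]), w(pp[2]), p(pp[3]), c(pp[4]), confine(pp[0] > 0) {}
  inline double ipow(double x, int n) const {
    double r = 1.0;
    while (n > 0) { if (n & 1) r *= x; x *= x; n >>= 1; }
    return r;
  }
  inline double force(double z) const {
    double f = 0.0;
    if (confine) {
      double u = z / ac;
      f -= 12.0 * ipow(u, 11) / ac;
    }
    if (h != 0.0) {
      int ip = (int)p;
      double v = z / w;
      double vp = (p == (double)ip) ? ipow(v, ip) : std::pow(v, p);
      double vpm1 = (p == (double)ip) ? ipow(v, ip - 1) : std::pow(v, p - 1.0);
      f += h * std::exp(-vp) * p * vpm1 / w;
    }
    return f;
  }
};

static inline void check_domain(double z, double lo, double hi, long step) {
  if (z < lo || z > hi)
    stop("trajectory escaped the evaluation domain at step %ld (z = %g); "
         "reduce dt or widen the domain", step, z);
}

// Overdamped Euler–Maruyama: z' = z + (D/kBT) F dt + sqrt(2 D dt) G
// [[Rcpp::export(name = ".bd_kernel")]]
NumericVector bd_kernel(double z0, double dt, double n_steps_d, int stride,
                        double kBT, double D, NumericVector pp,
                        double lo, double hi) {
  long n_steps = (long)n_steps_d;
  Pot pot(pp);
  const double mob = D / kBT * dt;
  const double sig = std::sqrt(2.0 * D * dt);
  long n_out = n_steps / stride + 1;
  NumericVector out(n_out);
  RNGScope scope;
  double z = z0;
  check_domain(z, lo, hi, 0);
  out[0] = z;
  long k = 1;
  for (long i = 1; i <= n_steps; ++i) {
    z += mob * pot.force(z) + sig * norm_rand();
    if (z < lo || z > hi) check_domain(z, lo, hi, i);
    if (i % stride == 0) out[k++] = z;
  }
  return out;
}

// Langevin BAOAB splitting with friction gamma = kBT/(m D).
// [[Rcpp::export(name = ".baoab_kernel")]]
List baoab_kernel(double z0, double v0, double dt, double n_steps_d,
                  int stride, double kBT, double D, double mass,
                  NumericVector pp, double lo, double hi) {
  long n_steps = (long)n_steps_d;
  Pot pot(pp);
  const double gamma = kBT * KCAL / (mass * D);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kBT * KCAL / mass);
  const double fh = 0.5 * dt * KCAL / mass; // half-kick factor (F in kcal/mol/Å)
  long n_out = n_steps / stride + 1;
  NumericVector zs(n_out), vs(n_out);
  RNGScope scope;
  double z = z0, v = v0;
  check_domain(z, lo, hi, 0);
  zs[0] = z; vs[0] = v;
  long k = 1;
  for (long i = 1; i <= n_steps; ++i) {
    v += fh * pot.force(z);
    z += 0.5 * dt * v;
    v = c1 * v + c2 * norm_rand();
    z += 0.5 * dt * v;
    if (z < lo || z > hi) check_domain(z, lo, hi, i);
    v += fh * pot.force(z);
    if (i % stride == 0) { zs[k] = z; vs[k] = v; ++k; }
  }
  return List::create(_["positions"] = zs, _["velocities"] = vs);
}

// Run one walker until absorption at z1 (outcome 0) or z2 (outcome 1);
// outcome 2 = censored at max_steps. Returns (outcome, steps).
// [[Rcpp::export(name = ".absorb_kernel")]]
NumericVector absorb_kernel(double z0, double v0, double dt, double max_steps_d,
                            double kBT, double D, double mass, bool langevin,
                            NumericVector pp, double z1, double z2) {
  long max_steps = (long)max_steps_d;
  Pot pot(pp);
  RNGScope scope;
  double z = z0, v = v0;
  if (langevin) {
    const double gamma = kBT * KCAL / (mass * D);
    const double c1 = std::exp(-gamma * dt);
    const double c2 = std::sqrt((1.0 - c1 * c1) * kBT * KCAL / mass);
    const double fh = 0.5 * dt * KCAL / mass;
    for (long i = 1; i <= max_steps; ++i) {
      v += fh * pot.force(z);
      z += 0.5 * dt * v;
      v = c1 * v + c2 * norm_rand();
      z += 0.5 * dt * v;
      v += fh * pot.force(z);
      if (z <= z1) return NumericVector::create(0, (double)i);
      if (z >= z2) return NumericVector::create(1, (double)i);
    }
  } else {
    const double mob = D / kBT * dt;
    const double sig = std::sqrt(2.0 * D * dt);
    for (long i = 1; i <= max_steps; ++i) {
      z += mob * pot.force(z) + sig * norm_rand();
      if (z <= z1) return NumericVector::create(0, (double)i);
      if (z >= z2) return NumericVector::create(1, (double)i);
    }
  }
  return NumericVector::create(2, (double)max_steps);
}

// Transmission-coefficient shots: integrate n Langevin trajectories from
// (z_dagger, v0[i]) and record the B-indicator H_B(z(t)) = theta(z - z_dagger)
// at every stored frame. Returns an (n_shots x n_frames) 0/1 matrix.
// [[Rcpp::export(name = ".kappa_shots_kernel")]]
IntegerMatrix kappa_shots_kernel(double z_dagger, NumericVector v0, double dt,
                                 int n_steps, int stride, double kBT, double D,
                                 double mass, NumericVector pp,
                                 double lo, double hi) {
  Pot pot(pp);
  const double gamma = kBT * KCAL / (mass * D);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kBT * KCAL / mass);
  const double fh = 0.5 * dt * KCAL / mass;
  int n_frames = n_steps / stride;
  int n_shots = v0.size();
  IntegerMatrix H(n_shots, n_frames);
  RNGScope scope;
  for (int s = 0; s < n_shots; ++s) {
    double z = z_dagger, v = v0[s];
    int k = 0;
    for (int i = 1; i <= n_steps; ++i) {
      v += fh * pot.force(z);
      z += 0.5 * dt * v;
      v = c1 * v + c2 * norm_rand();
      z += 0.5 * dt * v;
      check_domain(z, lo, hi, i);
      v += fh * pot.force(z);
      if (i % stride == 0) H(s, k++) = (z >= z_dagger) ? 1 : 0;
    }
  }
  return H;
}

// Lagged correlators with contiguous-block errors. For each lag l (in
// sampling intervals) the estimator is the multiple-time-origin mean over
// i of a per-origin product; origins are split into nblocks contiguous
// blocks and the standard error is sd(block means)/sqrt(nblocks).

// mean of x_i * y_{i+l}
// [[Rcpp::export(name = ".lag_mean_prod")]]
List lag_mean_prod(NumericVector x, NumericVector y, IntegerVector lags,
                   int nblocks) {
  long n = x.size();
  int nl = lags.size();
  NumericVector mean_out(nl), se_out(nl);
  std::vector<double> bm(nblocks);
  for (int j = 0; j < nl; ++j) {
    long l = lags[j];
    if (l >= n) stop("lag exceeds trajectory length");
    long m = n - l;
    long bs = m / nblocks;
    if (bs < 1) stop("too few origins for %d blocks", nblocks);
    double tot = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      long i0 = b * bs;
      long i1 = (b == nblocks - 1) ? m : i0 + bs;
      double s = 0.0;
      for (long i = i0; i < i1; ++i) s += x[i] * y[i + l];
      bm[b] = s / (i1 - i0);
      tot += s;
    }
    mean_out[j] = tot / m;
    double v = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      double d = bm[b] - mean_out[j];
      v += d * d;
    }
    se_out[j] = std::sqrt(v / (nblocks - 1) / nblocks);
    if (l == 0) se_out[j] = se_out[j]; // lag-0 error kept as-is
  }
  return List::create(_["mean"] = mean_out, _["se"] = se_out);
}

// mean of x_i * (y_i - y_{i+l}); exactly 0 at l = 0
// [[Rcpp::export(name = ".lag_mean_cdiff")]]
List lag_mean_cdiff(NumericVector x, NumericVector y, IntegerVector lags,
                    int nblocks) {
  long n = x.size();
  int nl = lags.size();
  NumericVector mean_out(nl), se_out(nl);
  std::vector<double> bm(nblocks);
  for (int j = 0; j < nl; ++j) {
    long l = lags[j];
    if (l >= n) stop("lag exceeds trajectory length");
    long m = n - l;
    long bs = m / nblocks;
    if (bs < 1) stop("too few origins for %d blocks", nblocks);
    double tot = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      long i0 = b * bs;
      long i1 = (b == nblocks - 1) ? m : i0 + bs;
      double s = 0.0;
      for (long i = i0; i < i1; ++i) s += x[i] * (y[i] - y[i + l]);
      bm[b] = s / (i1 - i0);
      tot += s;
    }
    mean_out[j] = tot / m;
    double v = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      double d = bm[b] - mean_out[j];
      v += d * d;
    }
    se_out[j] = std::sqrt(v / (nblocks - 1) / nblocks);
  }
  return List::create(_["mean"] = mean_out, _["se"] = se_out);
}

// indicator-restricted committor correlator:
// mean of theta(qdag - q_i) * theta(q_{i+l} - qdag) * (q_{i+l} - q_i)
// [[Rcpp::export(name = ".lag_mean_abqq")]]
List lag_mean_abqq(NumericVector q, double qdag, IntegerVector lags,
                   int nblocks) {
  long n = q.size();
  int nl = lags.size();
  NumericVector mean_out(nl), se_out(nl);
  std::vector<double> bm(nblocks);
  for (int j = 0; j < nl; ++j) {
    long l = lags[j];
    if (l >= n) stop("lag exceeds trajectory length");
    long m = n - l;
    long bs = m / nblocks;
    if (bs < 1) stop("too few origins for %d blocks", nblocks);
    double tot = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      long i0 = b * bs;
      long i1 = (b == nblocks - 1) ? m : i0 + bs;
      double s = 0.0;
      for (long i = i0; i < i1; ++i) {
        // half-open convention: q >= qdag belongs to B
        if (q[i] < qdag && q[i + l] >= qdag) s += q[i + l] - q[i];
      }
      bm[b] = s / (i1 - i0);
      tot += s;
    }
    mean_out[j] = tot / m;
    double v = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      double d = bm[b] - mean_out[j];
      v += d * d;
    }
    se_out[j] = std::sqrt(v / (nblocks - 1) / nblocks);
  }
  return List::create(_["mean"] = mean_out, _["se"] = se_out);
}

// transition-count matrix at a given lag (in sampling intervals) for a
// pre-binned integer series (1-based bin indices, 0 = out of range)
// [[Rcpp::export(name = ".count_transitions")]]
NumericMatrix count_transitions(IntegerVector bins, int nbins, int lag) {
  long n = bins.size();
  if (lag < 1 || lag >= n) stop("lag out of range");
  NumericMatrix C(nbins, nbins);
  for (long i = 0; i + lag < n; ++i) {
    int a = bins[i], b = bins[i + lag];
    if (a >= 1 && a <= nbins && b >= 1 && b <= nbins) C(a - 1, b - 1) += 1.0;
  }
  return C;
}
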