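// Gillespie direct-method simulation of the transcription/translation/
// degradation network, with a self-contained counter-based RNG so that
// ensembles are bitwise reproducible for a given master seed regardless of
// the order in which runs execute.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

// xoshiro256++ seeded from (seed, stream) through splitmix64, giving an
// independent deterministic stream per ensemble member.
struct Rng {
  uint64_t s[4];
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t sm = seed * 0x9E3779B97F4A7C15ULL ^
                  (stream + 1) * 0xD2B74407B1CE6E93ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]
  double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

struct Net {
  int n;
  const IntegerMatrix &topo;
  const NumericVector &km, &kx, &gm, &gx, &eps;
  const NumericMatrix &K, &nh;

  Net(int n_, const IntegerMatrix &topo_, const NumericVector &km_,
      const NumericVector &kx_, const NumericVector &gm_,
      const NumericVector &gx_, const NumericVector &eps_,
      const NumericMatrix &K_, const NumericMatrix &nh_)
      : n(n_), topo(topo_), km(km_), kx(kx_), gm(gm_), gx(gx_), eps(eps_),
        K(K_), nh(nh_) {}

  double input(int i, const std::vector<int> &x) const {
    double prod = 1.0;
    for (int j = 0; j < n; ++j) {
      int t = topo(i, j);
      if (t == 0) continue;
      double xn = std::pow((double)x[j], nh(i, j));
      double Kn = std::pow(K(i, j), nh(i, j));
      prod *= (t > 0) ? xn / (Kn + xn) : Kn / (Kn + xn);
    }
    return eps[i] + (1.0 - eps[i]) * prod;
  }

  // propensities, per gene: transcription, translation, mRNA deg, protein deg
  double fill(std::vector<double> &a, const std::vector<int> &m,
              const std::vector<int> &x) const {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      a[4 * i + 0] = km[i] * input(i, x);
      a[4 * i + 1] = kx[i] * m[i];
      a[4 * i + 2] = gm[i] * m[i];
      a[4 * i + 3] = gx[i] * x[i];
      tot += a[4 * i] + a[4 * i + 1] + a[4 * i + 2] + a[4 * i + 3];
    }
    return tot;
  }
};

inline void apply_reaction(int mu, std::vector<int> &m, std::vector<int> &x) {
  int gene = mu / 4, kind = mu % 4;
  switch (kind) {
    case 0: m[gene] += 1; break;
    case 1: x[gene] += 1; break;
    case 2: m[gene] -= 1; break;
    case 3: x[gene] -= 1; break;
  }
}

} // namespace

// One SSA run recorded on a uniform/explicit grid of times (piecewise
// constant: state at the largest event time <= t). Returns the recorded
// copy-number matrices and the event count.
// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(IntegerMatrix topo, NumericVector km, NumericVector kx,
                 NumericVector gm, NumericVector gx, NumericVector eps,
                 NumericMatrix K, NumericMatrix nh,
                 IntegerVector m0, IntegerVector x0, double t0,
                 NumericVector record_times, double seed, double stream) {
  int n = topo.nrow();
  Net net(n, topo, km, kx, gm, gx, eps, K, nh);
  Rng rng((uint64_t)seed, (uint64_t)stream);

  std::vector<int> m(m0.begin(), m0.end()), x(x0.begin(), x0.end());
  std::vector<double> a(4 * n);
  int nrec = record_times.size();
  IntegerMatrix mrec(nrec, n), xrec(nrec, n);
  double t = t0;
  double t_end = record_times[nrec - 1];
  int rpos = 0;
  long long n_events = 0;

  while (true) {
    double tot = net.fill(a, m, x);
    if (!std::isfinite(tot))
      stop("non-finite total propensity encountered (t = %f)", t);
    double t_next = (tot > 0.0) ? t + rng.expo(tot) : R_PosInf;
    // flush records strictly before the next event
    while (rpos < nrec && record_times[rpos] < t_next) {
      for (int i = 0; i < n; ++i) { mrec(rpos, i) = m[i]; xrec(rpos, i) = x[i]; }
      ++rpos;
    }
    if (rpos >= nrec || t_next > t_end) break;
    t = t_next;
    // pick reaction proportionally to propensity (linear scan)
    double u = rng.unif() * tot, acc = 0.0;
    int mu = 4 * n - 1;
    for (int r = 0; r < 4 * n; ++r) {
      acc += a[r];
      if (u <= acc) { mu = r; break; }
    }
    apply_reaction(mu, m, x);
    ++n_events;
    if ((n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mrna"] = mrec, _["protein"] = xrec,
                      _["n_events"] = (double)n_events);
}

// One SSA run with the full event list (times and states after each event).
// [[Rcpp::export(name = ".ssa_events_cpp")]]
List ssa_events_cpp(IntegerMatrix topo, NumericVector km, NumericVector kx,
                    NumericVector gm, NumericVector gx, NumericVector eps,
                    NumericMatrix K, NumericMatrix nh,
                    IntegerVector m0, IntegerVector x0, double t0,
                    double t_end, double seed, double stream,
                    double max_events) {
  int n = topo.nrow();
  Net net(n, topo, km, kx, gm, gx, eps, K, nh);
  Rng rng((uint64_t)seed, (uint64_t)stream);

  std::vector<int> m(m0.begin(), m0.end()), x(x0.begin(), x0.end());
  std::vector<double> a(4 * n), times;
  std::vector<int> mhist, xhist, reactions;
  double t = t0;
  long long cap = (long long)max_events;

  while (true) {
    double tot = net.fill(a, m, x);
    if (!std::isfinite(tot))
      stop("non-finite total propensity encountered (t = %f)", t);
    if (tot <= 0.0) break; // absorbing state: freeze until t_end
    double dt = rng.expo(tot);
    if (t + dt > t_end) break;
    t += dt;
    double u = rng.unif() * tot, acc = 0.0;
    int mu = 4 * n - 1;
    for (int r = 0; r < 4 * n; ++r) {
      acc += a[r];
      if (u <= acc) { mu = r; break; }
    }
    apply_reaction(mu, m, x);
    times.push_back(t);
    reactions.push_back(mu + 1);
    for (int i = 0; i < n; ++i) mhist.push_back(m[i]);
    for (int i = 0; i < n; ++i) xhist.push_back(x[i]);
    if ((long long)times.size() >= cap)
      stop("event list exceeded max_events = %g; record on a grid instead",
           max_events);
  }
  int ne = times.size();
  IntegerMatrix mrec(ne, n), xrec(ne, n);
  for (int e = 0; e < ne; ++e)
    for (int i = 0; i < n; ++i) {
      mrec(e, i) = mhist[(size_t)e * n + i];
      xrec(e, i) = xhist[(size_t)e * n + i];
    }
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["reaction"] = IntegerVector(reactions.begin(), reactions.end()),
                      _["mrna"] = mrec, _["protein"] = xrec,
                      _["final_t"] = t);
}

// Ensemble of independent runs recorded at t_points; run r uses stream r.
// Output arrays are (n_runs x n_genes x n_times).
// [[Rcpp::export(name = ".ssa_ensemble_cpp")]]
List ssa_ensemble_cpp(IntegerMatrix topo, NumericVector km, NumericVector kx,
                      NumericVector gm, NumericVector gx, NumericVector eps,
                      NumericMatrix K, NumericMatrix nh,
                      IntegerVector m0, IntegerVector x0, double t0,
                      NumericVector t_points, int n_runs, double seed) {
  int n = topo.nrow();
  Net net(n, topo, km, kx, gm, gx, eps, K, nh);
  int nt = t_points.size();
  NumericVector mout(Dimension(n_runs, n, nt)), xout(Dimension(n_runs, n, nt));
  double t_end = t_points[nt - 1];
  std::vector<double> a(4 * n);

  for (int run = 0; run < n_runs; ++run) {
    Rng rng((uint64_t)seed, (uint64_t)run);
    std::vector<int> m(m0.begin(), m0.end()), x(x0.begin(), x0.end());
    double t = t0;
    int rpos = 0;
    while (true) {
      double tot = net.fill(a, m, x);
      if (!std::isfinite(tot))
        stop("non-finite total propensity encountered (run %d)", run + 1);
      double t_next = (tot > 0.0) ? t + rng.expo(tot) : R_PosInf;
      while (rpos < nt && t_points[rpos] < t_next) {
        for (int i = 0; i < n; ++i) {
          mout[run + (size_t)n_runs * (i + (size_t)n * rpos)] = m[i];
          xout[run + (size_t)n_runs * (i + (size_t)n * rpos)] = x[i];
        }
        ++rpos;
      }
      if (rpos >= nt || t_next > t_end) break;
      t = t_next;
      double u = rng.unif() * tot, acc = 0.0;
      int mu = 4 * n - 1;
      for (int r = 0; r < 4 * n; ++r) {
        acc += a[r];
        if (u <= acc) { mu = r; break; }
      }
      apply_reaction(mu, m, x);
    }
    if ((run & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mrna"] = mout, _["protein"] = xout);
}
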