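#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Uniform deviate in (0,1) with the same rejection loop R's runif() uses,
// so the compiled engine and the R reference implementation consume R's
// random stream identically draw-for-draw.
inline double ru() {
  double u;
  do {
    u = unif_rand();
  } while (u <= 0.0 || u >= 1.0);
  return u;
}

inline double draw_noise(double delta) { return -delta + 2.0 * delta * ru(); }

inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// 0-based index in 0..n-1, one uniform consumed.
inline int draw_index(int n) {
  int k = static_cast<int>(ru() * n);
  return k >= n ? n - 1 : k;
}

inline double cred(double aij, double aii, double sigma) {
  return 1.0 / (1.0 + std::exp(-(aij - aii) / sigma));
}

struct Model {
  int n;
  int k;
  double delta;
  double sgp;
  double lo;
  double hi;
  std::vector<double> sigma;
  std::vector<std::vector<int> > members;  // [0] = S, [1] = L, ascending
  std::vector<int> group;                  // 0 = S, 1 = L
};

// Listener i absorbs speaker j's (noisy) esteem of i and of j itself, at
// weight p computed from the pre-update values; both entries clipped.
inline void influence(NumericMatrix& a, int i, int j, const Model& m) {
  double p = cred(a(i, j), a(i, i), m.sigma[i]);
  double u1 = draw_noise(m.delta);
  a(i, i) = clip(a(i, i) + p * (a(j, i) - a(i, i) + u1), m.lo, m.hi);
  double u2 = draw_noise(m.delta);
  a(i, j) = clip(a(i, j) + p * (a(j, j) - a(i, j) + u2), m.lo, m.hi);
}

// p is computed once per directed call; z is drawn independently each of the
// k repetitions from agents other than i and j (repeats allowed).
inline void gossip(NumericMatrix& a, int i, int j, const Model& m) {
  if (m.k == 0) return;
  double p = cred(a(i, j), a(i, i), m.sigma[i]);
  int zlo = std::min(i, j);
  int zhi = std::max(i, j);
  for (int r = 0; r < m.k; ++r) {
    int z = draw_index(m.n - 2);
    if (z >= zlo) ++z;
    if (z >= zhi) ++z;
    double u = draw_noise(m.delta);
    a(i, z) = clip(a(i, z) + p * (a(j, z) - a(i, z) + u), m.lo, m.hi);
  }
}

// Uniform draw from mem excluding excl (which must be a member of mem).
inline int pick_excluding(const std::vector<int>& mem, int excl) {
  int msz = static_cast<int>(mem.size()) - 1;
  int idx = draw_index(msz);
  int pos = static_cast<int>(
      std::lower_bound(mem.begin(), mem.end(), excl) - mem.begin());
  if (idx >= pos) ++idx;
  return mem[idx];
}

// Same-group partner with probability sgp, else other group; empty pools
// fall back to the other pool so j != i always holds for n >= 2.
inline int select_partner(int i, const Model& m) {
  bool same = ru() < m.sgp;
  int own = m.group[i];
  const std::vector<int>& mo = m.members[own];
  const std::vector<int>& mx = m.members[1 - own];
  if (same) {
    if (mo.size() >= 2) return pick_excluding(mo, i);
    if (!mx.empty()) return mx[draw_index(static_cast<int>(mx.size()))];
  } else {
    if (!mx.empty()) return mx[draw_index(static_cast<int>(mx.size()))];
    if (mo.size() >= 2) return pick_excluding(mo, i);
  }
  stop("no eligible partner");
}

inline void one_iteration(NumericMatrix& a, const Model& m) {
  int npairs = m.n / 2;
  for (int s = 0; s < npairs; ++s) {
    int i = draw_index(m.n);
    int j = select_partner(i, m);
    influence(a, i, j, m);
    influence(a, j, i, m);
    gossip(a, i, j, m);
    gossip(a, j, i, m);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix init, IntegerVector group, NumericVector sigma,
                  double delta, int gossip_k, double same_group_prob,
                  NumericVector bounds, int n_iterations, int measure_every) {
  int n = init.nrow();
  if (init.ncol() != n) stop("esteem matrix must be square");
  if (group.size() != n || sigma.size() != n) {
    stop("group and sigma must have one entry per agent");
  }
  if (gossip_k > 0 && n < 3) stop("gossip requires at least 3 agents");

  Model m;
  m.n = n;
  m.k = gossip_k;
  m.delta = delta;
  m.sgp = same_group_prob;
  m.lo = bounds[0];
  m.hi = bounds[1];
  m.sigma.assign(sigma.begin(), sigma.end());
  m.group.assign(group.begin(), group.end());
  m.members.assign(2, std::vector<int>());
  for (int i = 0; i < n; ++i) m.members[m.group[i]].push_back(i);

  std::vector<int> times;
  times.push_back(0);
  for (int t = measure_every; t <= n_iterations; t += measure_every) {
    times.push_back(t);
  }
  if (times.back() != n_iterations) times.push_back(n_iterations);

  NumericMatrix a = clone(init);
  List snaps(times.size());
  snaps[0] = clone(a);
  int si = 1;
  for (int t = 1; t <= n_iterations; ++t) {
    one_iteration(a, m);
    if (si < static_cast<int>(times.size()) && times[si] == t) {
      snaps[si] = clone(a);
      ++si;
    }
    if (t % 4096 == 0) checkUserInterrupt();
  }

  return List::create(_["times"] = wrap(times), _["snapshots"] = snaps);
}
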