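#include <Rcpp.h>
using namespace Rcpp;

// Event-driven (Gillespie) simulation of the noisy voter model on a fixed
// graph.  Node i in state s_i flips at rate a + h * d_i / k_i, where d_i is
// the number of neighbours currently disagreeing with i.  Node selection is
// done with a Fenwick (binary indexed) tree over the per-node rates, so each
// event costs O(k_i log N).  Observables are sampled on a fixed time grid by
// carrying the last value forward (the process is piecewise constant).

namespace {

struct Fenwick {
  int n;
  std::vector<double> t;
  explicit Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double dv) {
    for (++i; i <= n; i += i & -i) t[i] += dv;
  }
  double total() const {
    double s = 0.0;
    for (int i = n; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // smallest index with prefix sum > u
  int search(double u) const {
    int pos = 0, logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] < u) {
        pos += pw;
        u -= t[pos];
      }
    }
    return pos; // 0-based node id (may be n-1+1 on fp edge; caller clamps)
  }
};

} // namespace

// [[Rcpp::export]]
List nvm_gillespie_cpp(IntegerVector adj, IntegerVector ptr, IntegerVector s0,
                       double a, double h, double t_max, double dt,
                       bool record_rho) {
  const int N = ptr.size() - 1;
  const long nedge2 = adj.size(); // 2 * number of edges
  std::vector<int> s(s0.begin(), s0.end());
  std::vector<int> deg(N), dis(N);
  for (int i = 0; i < N; ++i) deg[i] = ptr[i + 1] - ptr[i];

  long n1 = 0;
  for (int i = 0; i < N; ++i) n1 += s[i];
  long Dsum = 0; // sum_i dis_i = 2 * (number of active links)
  for (int i = 0; i < N; ++i) {
    int d = 0;
    for (int p = ptr[i]; p < ptr[i + 1]; ++p)
      if (s[adj[p]] != s[i]) ++d;
    dis[i] = d;
    Dsum += d;
  }

  Fenwick fw(N);
  std::vector<double> rate(N);
  for (int i = 0; i < N; ++i) {
    rate[i] = a + h * (double)dis[i] / (double)deg[i];
    fw.add(i, rate[i]);
  }

  const int nsamp = (int)std::floor(t_max / dt + 1e-9) + 1;
  NumericVector ts(nsamp), ns(nsamp);
  NumericVector rhos(record_rho ? nsamp : 0);

  RNGScope scope;
  double t = 0.0;
  int g = 0;          // next grid index to fill
  long long events = 0;
  long long refresh = 0;
  double R = fw.total();

  while (g < nsamp) {
    double tnext;
    if (R <= 0.0) {
      tnext = R_PosInf; // frozen (a = 0 in a homogeneous configuration)
    } else {
      tnext = t + ::exp_rand() / R;
    }
    // fill grid samples up to the event time
    while (g < nsamp && g * dt <= tnext + 1e-12) {
      double tg = g * dt;
      if (tg > t_max + 1e-12) break;
      ts[g] = tg;
      ns[g] = (double)n1;
      if (record_rho) rhos[g] = (double)Dsum / (double)nedge2;
      ++g;
    }
    if (g >= nsamp || !R_finite(tnext)) break;
    t = tnext;

    // pick node proportional to rate
    double u = ::unif_rand() * R;
    int i = fw.search(u);
    if (i >= N) i = N - 1;

    int snew = 1 - s[i];
    s[i] = snew;
    n1 += (snew == 1) ? 1 : -1;
    // i's disagreement count flips
    Dsum += (long)(deg[i] - dis[i]) - (long)dis[i];
    dis[i] = deg[i] - dis[i];
    double dv = a + h * (double)dis[i] / (double)deg[i] - rate[i];
    fw.add(i, dv);
    R += dv;
    rate[i] += dv;
    // each neighbour j gains/loses one disagreeing neighbour
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
      int j = adj[p];
      int delta = (s[j] == snew) ? -1 : 1;
      dis[j] += delta;
      Dsum += delta;
      double dj = h * (double)delta / (double)deg[j];
      fw.add(j, dj);
      R += dj;
      rate[j] += dj;
    }
    ++events;
    // periodically rebuild sums to cap floating-point drift
    if (++refresh >= (1LL << 21)) {
      refresh = 0;
      std::fill(fw.t.begin(), fw.t.end(), 0.0);
      for (int k = 0; k < N; ++k) {
        rate[k] = a + h * (double)dis[k] / (double)deg[k];
        fw.add(k, rate[k]);
      }
      R = fw.total();
      if ((events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  IntegerVector sfin(s.begin(), s.end());
  return List::create(_["t"] = ts, _["n"] = ns, _["rho"] = rhos,
                      _["events"] = (double)events, _["s_final"] = sfin);
}

// Exact simulation of the annealed (weighted fully-connected) dynamics for a
// network made of degree classes.  Under the annealed weights the flip rates
// depend on the state only through the degree-weighted magnetization
// m = sum_c k_c n_c / sum_c k_c N_c: an up-flip of any 0-node has rate
// a + h m and a down-flip of any 1-node has rate a + h (1 - m), so the class
// occupation counts form a small exact Markov chain.

// [[Rcpp::export]]
List nvm_annealed_cpp(IntegerVector sizes, NumericVector degs,
                      IntegerVector n0, double a, double h, double t_max,
                      double dt) {
  const int C = sizes.size();
  std::vector<double> n(C);
  double L = 0.0, W = 0.0, ntot = 0.0, Ntot = 0.0;
  for (int c = 0; c < C; ++c) {
    n[c] = n0[c];
    L += degs[c] * n[c];
    W += degs[c] * sizes[c];
    ntot += n[c];
    Ntot += sizes[c];
  }
  const int nsamp = (int)std::floor(t_max / dt + 1e-9) + 1;
  NumericVector ts(nsamp), ns(nsamp);
  RNGScope scope;
  double t = 0.0;
  int g = 0;
  long long events = 0;
  std::vector<double> rates(2 * C);
  while (g < nsamp) {
    double m = L / W;
    double R = 0.0;
    for (int c = 0; c < C; ++c) {
      rates[2 * c] = (sizes[c] - n[c]) * (a + h * m);
      rates[2 * c + 1] = n[c] * (a + h * (1.0 - m));
      R += rates[2 * c] + rates[2 * c + 1];
    }
    double tnext = (R > 0.0) ? t + ::exp_rand() / R : R_PosInf;
    while (g < nsamp && g * dt <= tnext + 1e-12) {
      ts[g] = g * dt;
      ns[g] = ntot;
      ++g;
    }
    if (g >= nsamp || !R_finite(tnext)) break;
    t = tnext;
    double u = ::unif_rand() * R;
    int pick = 2 * C - 1;
    for (int r = 0; r < 2 * C; ++r) {
      if (u < rates[r]) { pick = r; break; }
      u -= rates[r];
    }
    int c = pick / 2;
    if (pick % 2 == 0) { n[c] += 1; ntot += 1; L += degs[c]; }
    else               { n[c] -= 1; ntot -= 1; L -= degs[c]; }
    ++events;
    if ((events & 0xFFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = ts, _["n"] = ns, _["events"] = (double)events);
}
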