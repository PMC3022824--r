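// Sequential information bottleneck core: draw-and-reinsert sweeps with
// exact incremental evaluation of L = H(C) - beta * I(C;Y) under hard
// assignments and uniform sample mass p(x) = 1/n.
//
// With p(c) = m_c/n and p(c,y) = T_c[y]/n (T_c = sum of member profiles),
//   L = sum_c S(c) + beta * sum_y p(y) log2 p(y),   where
//   S(c) = -(1-beta) * p(c) log2 p(c) - beta * sum_y p(c,y) log2 p(c,y).
// Moving one sample touches only the source and target clusters' S terms.
// Every profile puts mass w = 1/s on s tokens, so every cluster token sum
// is an integer multiple of w and every x*log2(x) the sweep needs comes
// from a precomputed table over counts 0..n — the hot loop does no logs.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2 = 0.6931471805599453;

static inline double xlog2x(double t) {
  return (t > 0.0) ? t * (std::log(t) / LOG2) : 0.0;
}

// xorshift64*: deterministic across platforms, independent of R's RNG
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct SibState {
  int n, s, K, ntok;
  double beta, w, n_inv, log2n;
  const int* tok;                  // n x s token indices (column-major)
  std::vector<int> C;              // K x ntok integer token counts
  std::vector<double> G;           // per-cluster sum_y xlog2x(count*w)
  std::vector<int> m;              // cluster sizes
  std::vector<int> assign;
  std::vector<double> tab_xw;      // xlog2x(j * w), j = 0..n
  std::vector<double> tab_xp;      // xlog2x(j / n), j = 0..n

  void init_tables() {
    tab_xw.resize(n + 1); tab_xp.resize(n + 1);
    for (int j = 0; j <= n; ++j) {
      tab_xw[j] = xlog2x(j * w);
      tab_xp[j] = xlog2x(j * n_inv);
    }
  }

  inline double Sc_from(int mc, double Gc) const {
    if (mc == 0) return 0.0;
    double sum_plogp = n_inv * (Gc - (double)mc * log2n);
    return -(1.0 - beta) * tab_xp[mc] - beta * sum_plogp;
  }
  inline double Sc(int c) const { return Sc_from(m[c], G[c]); }

  inline void apply(int i, int c, int sign) {
    int* Cc = &C[(size_t)c * ntok];
    for (int k = 0; k < s; ++k) {
      int y = tok[i + (size_t)k * n];
      int cnt = Cc[y];
      G[c] += tab_xw[cnt + sign] - tab_xw[cnt];
      Cc[y] = cnt + sign;
    }
    m[c] += sign;
  }

  double total_S() const {
    double L = 0.0;
    for (int c = 0; c < K; ++c) L += Sc(c);
    return L;
  }

  // exact recomputation from the partition (audit path)
  double recompute() {
    std::fill(C.begin(), C.end(), 0);
    std::fill(G.begin(), G.end(), 0.0);
    std::fill(m.begin(), m.end(), 0);
    for (int i = 0; i < n; ++i) {
      int c = assign[i];
      m[c]++;
      for (int k = 0; k < s; ++k) C[(size_t)c * ntok + tok[i + (size_t)k * n]]++;
    }
    for (int c = 0; c < K; ++c) {
      double g = 0.0;
      const int* Cc = &C[(size_t)c * ntok];
      for (int y = 0; y < ntok; ++y) g += tab_xw[Cc[y]];
      G[c] = g;
    }
    return total_S();
  }
};

// [[Rcpp::export(name = ".sib_fit_cpp")]]
List sib_fit_cpp(IntegerMatrix codes, int K, double beta,
                 int n_restarts, int max_sweeps, double seed,
                 bool record_trace = false) {
  const int n = codes.nrow(), s = codes.ncol();
  if (n < 1 || s < 1) stop("empty profile set");
  SibState st;
  st.n = n; st.s = s; st.K = K; st.ntok = 3 * s;
  st.beta = beta; st.w = 1.0 / s; st.n_inv = 1.0 / n;
  st.log2n = std::log((double)n) / LOG2;
  st.init_tables();

  // token index of sample i, SNP k: 3*k + code
  std::vector<int> tok((size_t)n * s);
  for (int k = 0; k < s; ++k)
    for (int i = 0; i < n; ++i) {
      int g = codes(i, k);
      if (g < 0 || g > 2) stop("genotype codes must be 0/1/2 (impute first)");
      tok[i + (size_t)k * n] = 3 * k + g;
    }
  st.tok = tok.data();
  st.C.assign((size_t)K * st.ntok, 0);
  st.G.assign(K, 0.0);
  st.m.assign(K, 0);
  st.assign.assign(n, 0);

  // constant term beta * sum_y p(y) log2 p(y)
  std::vector<int> ycnt(st.ntok, 0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < s; ++k) ycnt[tok[i + (size_t)k * n]]++;
  double const_term = 0.0;
  for (int y = 0; y < st.ntok; ++y) const_term += xlog2x(ycnt[y] * st.w * st.n_inv);
  const_term *= beta;

  XRng rng((uint64_t)seed);
  std::vector<int> order(n);
  std::vector<int> best_assign(n, 0);
  double best_L = R_PosInf;
  int best_restart = -1;
  std::vector<double> trace;
  std::vector<int> trace_restart;
  NumericVector restart_L(n_restarts);

  for (int r = 0; r < n_restarts; ++r) {
    for (int i = 0; i < n; ++i) st.assign[i] = rng.below(K);
    double L = st.recompute();   // running sum of S(c); const added on output

    int sweep = 0;
    bool moved = true;
    while (moved && sweep < max_sweeps) {
      moved = false;
      ++sweep;
      for (int i = 0; i < n; ++i) order[i] = i;
      for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);
      for (int oi = 0; oi < n; ++oi) {
        int i = order[oi];
        int a = st.assign[i];
        double Sa_old = st.Sc(a);
        st.apply(i, a, -1);
        L += st.Sc(a) - Sa_old;
        // best insertion (including back into a); ties -> lowest index
        int best_c = -1;
        double best_d = R_PosInf;
        for (int c = 0; c < K; ++c) {
          double gd = 0.0;
          const int* Cc = &st.C[(size_t)c * st.ntok];
          for (int k = 0; k < s; ++k) {
            int cnt = Cc[st.tok[i + (size_t)k * n]];
            gd += st.tab_xw[cnt + 1] - st.tab_xw[cnt];
          }
          double d = st.Sc_from(st.m[c] + 1, st.G[c] + gd) - st.Sc(c);
          if (d < best_d) { best_d = d; best_c = c; }
        }
        st.apply(i, best_c, +1);
        L += best_d;
        st.assign[i] = best_c;
        if (best_c != a) moved = true;
        if (record_trace) {
          trace.push_back(L + const_term);
          trace_restart.push_back(r + 1);
        }
      }
    }
    double L_exact = st.recompute() + const_term;
    restart_L[r] = L_exact;
    if (L_exact < best_L) {
      best_L = L_exact;
      best_assign = st.assign;
      best_restart = r + 1;
    }
  }

  // rebuild state for the winning partition and export it
  st.assign = best_assign;
  st.recompute();
  NumericMatrix Tout(K, st.ntok);
  for (int c = 0; c < K; ++c)
    for (int y = 0; y < st.ntok; ++y)
      Tout(c, y) = st.C[(size_t)c * st.ntok + y] * st.w;
  IntegerVector asg(n);
  for (int i = 0; i < n; ++i) asg[i] = best_assign[i] + 1;

  List out = List::create(
    _["assignment"] = asg,
    _["objective"] = best_L,
    _["cluster_token_sums"] = Tout,
    _["cluster_sizes"] = IntegerVector(st.m.begin(), st.m.end()),
    _["restart_objectives"] = restart_L,
    _["best_restart"] = best_restart);
  if (record_trace) {
    out["trace"] = NumericVector(trace.begin(), trace.end());
    out["trace_restart"] = IntegerVector(trace_restart.begin(), trace_restart.end());
  }
  return out;
}

// Assign new samples to the frozen clusters by minimal weighted
// Jensen-Shannon insertion cost (p_x + p_c) * JS_{pi}(p(y|x), p(y|c)),
// p_x = 1/n_train; empty clusters are skipped; ties -> lowest index.
// [[Rcpp::export(name = ".sib_assign_cpp")]]
IntegerVector sib_assign_cpp(IntegerMatrix codes, NumericMatrix T,
                             IntegerVector m, int n_train) {
  const int n = codes.nrow(), s = codes.ncol();
  const int K = T.nrow(), ntok = T.ncol();
  if (ntok != 3 * s) stop("token space mismatch between model and profiles");
  bool any_nonempty = false;
  for (int c = 0; c < K; ++c) if (m[c] > 0) any_nonempty = true;
  if (!any_nonempty) stop("all clusters are empty");
  const double w = 1.0 / s, px = 1.0 / n_train;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best_c = -1;
    double best_cost = R_PosInf;
    for (int c = 0; c < K; ++c) {
      if (m[c] == 0) continue;
      double pc = (double)m[c] / n_train;
      double w1 = px / (px + pc), w2 = pc / (px + pc);
      double js = 0.0;
      // KL(p_x || mix) over x's s tokens; KL(p_c || mix) over all tokens
      for (int k = 0; k < s; ++k) {
        int y = 3 * k + codes(i, k);
        double q = T(c, y) / m[c];
        double mix = w1 * w + w2 * q;
        js += w1 * w * (std::log(w / mix) / LOG2);
      }
      for (int y = 0; y < ntok; ++y) {
        double q = T(c, y) / m[c];
        if (q <= 0.0) continue;
        int k = y / 3;
        double pxy = (codes(i, k) == y - 3 * k) ? w : 0.0;
        double mix = w1 * pxy + w2 * q;
        js += w2 * q * (std::log(q / mix) / LOG2);
      }
      double cost = (px + pc) * js;
      if (cost < best_cost) { best_cost = cost; best_c = c; }
    }
    out[i] = best_c + 1;
  }
  return out;
}
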