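#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <deque>
using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (incl. N) is invalid.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Fixed 64-bit finalizer (splitmix64). Deterministic across runs/platforms.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Hashes are masked to 53 bits so they are exactly representable as doubles.
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

// Per-position canonical k-mer hash over a sequence. Rolling 2-bit encoding
// of the forward k-mer and its reverse complement; canonical = smaller of the
// two encodings; strand records which one won (+1 forward, -1 revcomp, 0 tie,
// i.e. palindromic k-mer). Positions whose k-mer spans an invalid base get
// hash NA.
static void kmer_scan(const std::string& s, int k,
                      std::vector<double>& hash, std::vector<int>& strand) {
  int n = (int) s.size();
  int nk = n - k + 1;
  if (nk < 0) nk = 0;
  hash.assign(nk, NA_REAL);
  strand.assign(nk, 0);
  if (nk == 0) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int run = 0; // consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
    ++run;
    if (run >= k) {
      int pos = i - k + 1;
      uint64_t canon;
      int st;
      if (fwd < rev)      { canon = fwd; st = 1; }
      else if (rev < fwd) { canon = rev; st = -1; }
      else                { canon = fwd; st = 0; }
      hash[pos] = (double) (mix64(canon) & HASH_MASK);
      strand[pos] = st;
    }
  }
}

// [[Rcpp::export]]
List cpp_kmer_hashes(std::string seq, int k) {
  std::vector<double> h;
  std::vector<int> st;
  kmer_scan(seq, k, h, st);
  return List::create(_["hash"] = NumericVector(h.begin(), h.end()),
                      _["strand"] = IntegerVector(st.begin(), st.end()));
}

// (w,k)-minimizer sketch: for every window of w consecutive valid k-mers the
// smallest canonical hash is selected (leftmost on ties); duplicates
// collapsed; runs of valid k-mers shorter than w yield nothing.
// [[Rcpp::export]]
List cpp_sketch(std::string seq, int k, int w) {
  std::vector<double> h;
  std::vector<int> st;
  kmer_scan(seq, k, h, st);
  int nk = (int) h.size();
  std::vector<double> out_h;
  std::vector<int> out_p, out_s;
  if (nk == 0 || w < 1)
    return List::create(_["hash"] = NumericVector(0),
                        _["pos"] = IntegerVector(0),
                        _["strand"] = IntegerVector(0));
  int i = 0;
  while (i < nk) {
    if (ISNA(h[i])) { ++i; continue; }
    int run_start = i;
    while (i < nk && !ISNA(h[i])) ++i; // [run_start, i) valid
    int run_len = i - run_start;
    if (run_len < w) continue;
    // monotone deque of indices with increasing hash; leftmost-min on ties
    std::deque<int> dq;
    int last_emit = -1;
    for (int j = run_start; j < run_start + run_len; ++j) {
      while (!dq.empty() && h[dq.back()] > h[j]) dq.pop_back();
      dq.push_back(j);
      if (!dq.empty() && dq.front() <= j - w) dq.pop_front();
      if (j - run_start >= w - 1) {
        int m = dq.front();
        if (m != last_emit) {
          out_h.push_back(h[m]);
          out_p.push_back(m);
          out_s.push_back(st[m]);
          last_emit = m;
        }
      }
    }
  }
  return List::create(_["hash"] = NumericVector(out_h.begin(), out_h.end()),
                      _["pos"] = IntegerVector(out_p.begin(), out_p.end()),
                      _["strand"] = IntegerVector(out_s.begin(), out_s.end()));
}

// Longest collinear chain per hit group (one group = one query/target/strand
// combination). Hits must arrive sorted by group then query position. For
// reverse-strand groups the caller supplies rev = true and target positions
// are negated internally so that a chainable hit always increases both
// coordinates. Gaps on either read larger than max_gap break the chain.
// Returns, per group, the best chain size and its end coordinates in k-mer
// start positions (q/t on the forward strands of both reads).
// [[Rcpp::export]]
DataFrame cpp_chain_groups(IntegerVector group, IntegerVector qpos,
                           IntegerVector tpos, LogicalVector rev,
                           int max_gap) {
  int n = group.size();
  std::vector<int> g_id, g_n, g_qs, g_qe, g_ts, g_te;
  int i = 0;
  std::vector<int> score, pred;
  while (i < n) {
    int j = i;
    while (j < n && group[j] == group[i]) ++j; // [i, j) one group
    int m = j - i;
    bool is_rev = rev[i];
    score.assign(m, 1);
    pred.assign(m, -1);
    int best = 0;
    for (int a = 1; a < m; ++a) {
      int qa = qpos[i + a];
      int ta = is_rev ? -tpos[i + a] : tpos[i + a];
      for (int b = a - 1; b >= 0; --b) {
        int qb = qpos[i + b];
        if (qa - qb > max_gap) break; // sorted by qpos: earlier b only worse
        int tb = is_rev ? -tpos[i + b] : tpos[i + b];
        if (qa > qb && ta > tb && ta - tb <= max_gap) {
          if (score[b] + 1 > score[a]) { score[a] = score[b] + 1; pred[a] = b; }
        }
      }
      if (score[a] > score[best]) best = a;
    }
    // walk the best chain to recover its span
    int q_lo = qpos[i + best], q_hi = qpos[i + best];
    int t_lo = tpos[i + best], t_hi = tpos[i + best];
    int cur = best;
    while (pred[cur] >= 0) {
      cur = pred[cur];
      int q = qpos[i + cur], t = tpos[i + cur];
      if (q < q_lo) q_lo = q;
      if (q > q_hi) q_hi = q;
      if (t < t_lo) t_lo = t;
      if (t > t_hi) t_hi = t;
    }
    g_id.push_back(group[i]);
    g_n.push_back(score[best]);
    g_qs.push_back(q_lo);
    g_qe.push_back(q_hi);
    g_ts.push_back(t_lo);
    g_te.push_back(t_hi);
    i = j;
  }
  return DataFrame::create(_["group"] = IntegerVector(g_id.begin(), g_id.end()),
                           _["n_shared"] = IntegerVector(g_n.begin(), g_n.end()),
                           _["q_first"] = IntegerVector(g_qs.begin(), g_qs.end()),
                           _["q_last"] = IntegerVector(g_qe.begin(), g_qe.end()),
                           _["t_first"] = IntegerVector(g_ts.begin(), g_ts.end()),
                           _["t_last"] = IntegerVector(g_te.begin(), g_te.end()));
}

// Shannon entropy (bits, base ACGT; N ignored) of tiled windows.
// A sequence shorter than one window is treated as a single window.
// [[Rcpp::export]]
NumericVector cpp_window_entropy(std::string seq, int window, int step) {
  int n = (int) seq.size();
  std::vector<double> out;
  if (n == 0) return NumericVector(0);
  int nw = (n <= window) ? 1 : 1 + (n - window) / step;
  for (int wi = 0; wi < nw; ++wi) {
    int s = wi * step;
    int e = s + window;
    if (e > n) e = n;
    int cnt[4] = {0, 0, 0, 0};
    int tot = 0;
    for (int i = s; i < e; ++i) {
      int c = base_code(seq[i]);
      if (c >= 0) { ++cnt[c]; ++tot; }
    }
    double H = 0.0;
    if (tot > 0) {
      for (int c = 0; c < 4; ++c) {
        if (cnt[c] > 0) {
          double p = (double) cnt[c] / tot;
          H -= p * std::log2(p);
        }
      }
    }
    out.push_back(H);
  }
  return NumericVector(out.begin(), out.end());
}
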