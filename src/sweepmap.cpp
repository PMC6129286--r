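#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <set>
#include <tuple>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Fixed hash seed: all hashes are deterministic across runs and platforms.
static const uint64_t HASH_SEED = 0x5EEDBA5ECAFEF00DULL;

// splitmix64 finalizer: bijective, well-mixed 64-bit hash.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Canonical hash of every k-mer: min over the k-mer and its reverse
// complement of the seeded hash, truncated to the top 53 bits so the value
// is exactly representable as an R double.  Positions whose k-mer contains
// a non-ACGT character get UINT64_MAX (exported as NA).
static void scan_kmers(const std::string& s, int k,
                       std::vector<uint64_t>& canon, std::vector<int>& strand) {
  int n = (int)s.size() - k + 1;
  if (n < 0) n = 0;
  canon.assign(n, UINT64_MAX);
  strand.assign(n, 0);
  if (n == 0) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      int pos = i - k + 1;
      uint64_t hf = mix64(fwd ^ HASH_SEED) >> 11;
      uint64_t hr = mix64(rc ^ HASH_SEED) >> 11;
      if (hf <= hr) { canon[pos] = hf; strand[pos] = 1; }
      else          { canon[pos] = hr; strand[pos] = -1; }
    }
  }
}

// [[Rcpp::export]]
NumericVector canonical_hashes_cpp(std::string seq, int k) {
  std::vector<uint64_t> canon;
  std::vector<int> strand;
  scan_kmers(seq, k, canon, strand);
  NumericVector out(canon.size());
  for (size_t i = 0; i < canon.size(); ++i)
    out[i] = (canon[i] == UINT64_MAX) ? NA_REAL : (double)canon[i];
  return out;
}

// Winnowing: for every window of w consecutive k-mer positions report the
// k-mer with smallest canonical hash (leftmost on ties), deduplicated.
// If the sequence holds fewer than w k-mers the whole sequence is one window.
// Ambiguous k-mers are never selected.
// [[Rcpp::export]]
DataFrame winnow_cpp(std::string seq, int k, int w) {
  std::vector<uint64_t> canon;
  std::vector<int> strand;
  scan_kmers(seq, k, canon, strand);
  int n = (int)canon.size();
  std::vector<double> oh;
  std::vector<int> op, os;
  if (n > 0 && w >= 1) {
    std::deque<int> dq;
    int first_full = std::min(w, n) - 1;
    int last_sel = -1;
    for (int j = 0; j < n; ++j) {
      if (canon[j] != UINT64_MAX) {
        while (!dq.empty() && canon[dq.back()] > canon[j]) dq.pop_back();
        dq.push_back(j);
      }
      while (!dq.empty() && dq.front() <= j - w) dq.pop_front();
      if (j >= first_full && !dq.empty() && dq.front() != last_sel) {
        last_sel = dq.front();
        oh.push_back((double)canon[last_sel]);
        op.push_back(last_sel);
        os.push_back(strand[last_sel]);
      }
    }
  }
  return DataFrame::create(_["hash"] = oh, _["pos"] = op, _["strand"] = os);
}

// ---------------------------------------------------------------------------
// Candidate-window scan for fragment mapping.
//
// pos  : sorted 0-based reference positions of minimizers whose hash is in
//        the fragment sketch (one row per occurrence)
// hid  : 0-based index of the matching sketch hash (for distinct counting)
// prod : product of fragment-minimizer strand and reference-minimizer strand
// For each matched position i consider the reference window
// [min(pos[i], ref_len - flen), +flen).  A window is a candidate when the
// count of *distinct* shared sketch hashes is >= m.  Runs of overlapping
// candidate windows are reduced to the window maximising the shared count
// (leftmost on ties); strand is the sign of the sum of strand products in
// that window.
// [[Rcpp::export]]
DataFrame scan_windows_cpp(IntegerVector pos, IntegerVector hid,
                           IntegerVector prod, int flen, int m,
                           int s_used, int ref_len) {
  int n = pos.size();
  std::vector<int> wb, shared, str;
  if (n > 0 && s_used > 0) {
    int max_start = std::max(0, ref_len - flen);
    std::vector<int> ws(n), D(n);
    std::vector<int> cnt(s_used, 0);
    int l = 0, r = 0, d = 0;
    for (int i = 0; i < n; ++i) {
      int w0 = std::min(pos[i], max_start);
      while (r < n && pos[r] < w0 + flen) { if (cnt[hid[r]]++ == 0) ++d; ++r; }
      while (l < n && pos[l] < w0)        { if (--cnt[hid[l]] == 0) --d; ++l; }
      ws[i] = w0;
      D[i] = d;
    }
    std::vector<int> cand;
    for (int i = 0; i < n; ++i) if (D[i] >= m) cand.push_back(i);
    size_t a = 0;
    while (a < cand.size()) {
      size_t b = a;
      int best = cand[a];
      while (b + 1 < cand.size() && ws[cand[b + 1]] - ws[cand[b]] < flen) {
        ++b;
        if (D[cand[b]] > D[best]) best = cand[b];
      }
      int w0 = ws[best], sum = 0;
      for (int t = 0; t < n; ++t)
        if (pos[t] >= w0 && pos[t] < w0 + flen) sum += prod[t];
      wb.push_back(w0);
      shared.push_back(D[best]);
      str.push_back(sum >= 0 ? 1 : -1);
      a = b + 1;
    }
  }
  return DataFrame::create(_["r_begin"] = wb, _["shared"] = shared,
                           _["strand"] = str);
}

// ---------------------------------------------------------------------------
// Plane sweep over weighted closed intervals.
//
// Total order in the sweep status: higher score greater; equal score ->
// later begin greater; final tiebreak on id.  Events are the 2n endpoints in
// ascending coordinate order, inserts before removals at equal coordinate.
// After the inserts at each halting point, segments tied at the maximum
// score are marked good, descending from the maximum and stopping at the
// first segment already marked (each segment is marked at most once, so
// total marking work is O(n log n)).
struct Seg {
  double score, begin;
  int id;
};
struct SegCmp {
  bool operator()(const Seg& a, const Seg& b) const {
    if (a.score != b.score) return a.score < b.score;
    if (a.begin != b.begin) return a.begin < b.begin;
    return a.id < b.id;
  }
};

// [[Rcpp::export]]
LogicalVector plane_sweep_cpp(NumericVector begin, NumericVector end,
                              NumericVector score) {
  int n = begin.size();
  LogicalVector good(n, false);
  if (n == 0) return good;
  std::vector<std::tuple<double, int, int> > ev;
  ev.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    ev.push_back(std::make_tuple(begin[i], 0, i));
    ev.push_back(std::make_tuple(end[i], 1, i));
  }
  std::sort(ev.begin(), ev.end());
  std::set<Seg, SegCmp> status;
  size_t i = 0, N = ev.size();
  while (i < N) {
    double c = std::get<0>(ev[i]);
    size_t j = i;
    while (j < N && std::get<0>(ev[j]) == c && std::get<1>(ev[j]) == 0) {
      int id = std::get<2>(ev[j]);
      Seg s = {score[id], begin[id], id};
      status.insert(s);
      ++j;
    }
    if (!status.empty()) {
      std::set<Seg, SegCmp>::reverse_iterator it = status.rbegin();
      double maxs = it->score;
      while (it != status.rend() && it->score == maxs) {
        if (good[it->id]) break;
        good[it->id] = true;
        ++it;
      }
    }
    while (j < N && std::get<0>(ev[j]) == c) {
      int id = std::get<2>(ev[j]);
      Seg s = {score[id], begin[id], id};
      status.erase(s);
      ++j;
    }
    i = j;
  }
  return good;
}
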