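#include <Rcpp.h>
#include <cstring>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// Alphabet: $ < A < C < G < N < T (sentinel smallest; others in ASCII order).
// Internal codes 0..5.  Construction shifts codes by +1 and appends a unique
// 0 terminator so induced sorting sees a strictly smallest final symbol.
static const int NSYM = 6;

static inline int code_of(char c) {
  switch (c) {
    case '$': return 0;
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 3;
    case 'N': return 4;
    case 'T': return 5;
    default:  return -1;
  }
}

static inline char char_of(int c) {
  static const char tab[NSYM + 1] = "$ACGNT";
  return tab[c];
}

// ---------------------------------------------------------------------------
// SA-IS induced-sorting suffix array construction (linear time).
// s: values in 0..K-1, s[n-1] must be the unique smallest symbol.
// ---------------------------------------------------------------------------

namespace sais {

static void get_buckets(const int *s, int n, int K, std::vector<int> &bkt,
                        bool end) {
  std::fill(bkt.begin(), bkt.end(), 0);
  for (int i = 0; i < n; ++i) bkt[s[i]]++;
  int sum = 0;
  for (int i = 0; i < K; ++i) {
    sum += bkt[i];
    bkt[i] = end ? sum : sum - bkt[i];
  }
}

static void induce_L(const std::vector<char> &t, int *sa, const int *s, int n,
                     int K, std::vector<int> &bkt) {
  get_buckets(s, n, K, bkt, false);
  for (int i = 0; i < n; ++i) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && !t[j]) sa[bkt[s[j]]++] = j;
  }
}

static void induce_S(const std::vector<char> &t, int *sa, const int *s, int n,
                     int K, std::vector<int> &bkt) {
  get_buckets(s, n, K, bkt, true);
  for (int i = n - 1; i >= 0; --i) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && t[j]) sa[--bkt[s[j]]] = j;
  }
}

static inline bool is_lms(const std::vector<char> &t, int i) {
  return i > 0 && t[i] && !t[i - 1];
}

static void sa_is(const int *s, int *sa, int n, int K) {
  if (n == 1) { sa[0] = 0; return; }
  std::vector<char> t(n);
  t[n - 1] = 1;
  for (int i = n - 2; i >= 0; --i)
    t[i] = (s[i] < s[i + 1] || (s[i] == s[i + 1] && t[i + 1])) ? 1 : 0;

  std::vector<int> bkt(K);
  std::fill(sa, sa + n, -1);
  get_buckets(s, n, K, bkt, true);
  for (int i = 1; i < n; ++i)
    if (is_lms(t, i)) sa[--bkt[s[i]]] = i;
  induce_L(t, sa, s, n, K, bkt);
  induce_S(t, sa, s, n, K, bkt);

  // Compact sorted LMS suffixes into sa[0..n1).
  int n1 = 0;
  for (int i = 0; i < n; ++i)
    if (is_lms(t, sa[i])) sa[n1++] = sa[i];

  // Name LMS substrings in sa[n1..n).
  std::fill(sa + n1, sa + n, -1);
  int name = 0, prev = -1;
  for (int i = 0; i < n1; ++i) {
    int pos = sa[i];
    bool diff = false;
    if (prev < 0) diff = true;
    else {
      for (int d = 0; d < n; ++d) {
        if (s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
          diff = true;
          break;
        }
        if (d > 0 && (is_lms(t, pos + d) || is_lms(t, prev + d))) break;
      }
    }
    if (diff) { ++name; prev = pos; }
    sa[n1 + pos / 2] = name - 1;
  }
  for (int i = n - 1, j = n - 1; i >= n1; --i)
    if (sa[i] >= 0) sa[j--] = sa[i];

  int *s1 = sa + n - n1;
  int *sa1 = sa;
  if (name < n1) {
    sa_is(s1, sa1, n1, name);
  } else {
    for (int i = 0; i < n1; ++i) sa1[s1[i]] = i;
  }

  // Map back: collect LMS positions in order of appearance.
  std::vector<int> lms(n1);
  for (int i = 1, j = 0; i < n; ++i)
    if (is_lms(t, i)) lms[j++] = i;
  for (int i = 0; i < n1; ++i) sa1[i] = lms[sa1[i]];

  // Induce final SA from sorted LMS suffixes.
  std::fill(sa + n1, sa + n, -1);
  get_buckets(s, n, K, bkt, true);
  for (int i = n1 - 1; i >= 0; --i) {
    int j = sa[i];
    sa[i] = -1;
    sa[--bkt[s[j]]] = j;
  }
  induce_L(t, sa, s, n, K, bkt);
  induce_S(t, sa, s, n, K, bkt);
}

} // namespace sais

// Encode a text string to codes 0..5; error on anything else.
static std::vector<int> encode_text(const std::string &text) {
  int n = (int)text.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    int c = code_of(text[i]);
    if (c < 0)
      stop("text contains symbol '%c' outside the {$,A,C,G,N,T} alphabet at position %d",
           text[i], i + 1);
    s[i] = c;
  }
  return s;
}

// Suffix array of `text` under the $<A<C<G<N<T order.  Multiple sentinels are
// allowed; suffixes are compared fully lexicographically (a virtual terminator
// smaller than '$' closes the text), which resolves all ties deterministically.
static std::vector<int> suffix_array_codes(const std::vector<int> &codes) {
  int n = (int)codes.size();
  std::vector<int> s(n + 1);
  for (int i = 0; i < n; ++i) s[i] = codes[i] + 1;
  s[n] = 0;
  std::vector<int> sa(n + 1);
  sais::sa_is(s.data(), sa.data(), n + 1, NSYM + 1);
  // Drop the terminator row (always first).
  std::vector<int> out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i + 1];
  return out;
}

// [[Rcpp::export(name = ".sa_build_cpp")]]
IntegerVector sa_build_cpp(std::string text) {
  if (text.empty()) stop("text must be non-empty");
  std::vector<int> codes = encode_text(text);
  std::vector<int> sa = suffix_array_codes(codes);
  return IntegerVector(sa.begin(), sa.end());
}

// ---------------------------------------------------------------------------
// FM-index bundle construction.
// Components (all 0-based):
//   bwt        raw vector of codes, length n
//   cbefore    int[NSYM+1]: cbefore[c] = # symbols with code < c (C table)
//   occ_cp     int matrix flattened: occ_cp[blk*NSYM + c] = occ(c, blk*STRIDE)
//   slots      sorted int vector: SA slots whose SA value is sampled
//   samples    int vector aligned with slots: the SA values
// ---------------------------------------------------------------------------

static const int STRIDE = 64;

struct FMView {
  const unsigned char *bwt;
  const int *cbefore;
  const int *occ_cp;
  const int *slots;
  const int *samples;
  const int *sent_rows;
  const int *sent_targets;
  int n;
  int nslots;
  int nsent;
};

static inline int occ(const FMView &f, int c, int p) {
  // # of c in bwt[0..p-1]
  int blk = p / STRIDE;
  int cnt = f.occ_cp[blk * NSYM + c];
  for (int i = blk * STRIDE; i < p; ++i)
    if (f.bwt[i] == (unsigned char)c) ++cnt;
  return cnt;
}

// LF mapping.  Rank-based LF is exact for A/C/G/N/T.  Rows whose BWT symbol
// is the shared sentinel would need per-sentinel ranks, so their targets are
// precomputed at build time and looked up directly.
static inline int lf(const FMView &f, int i) {
  int c = f.bwt[i];
  if (c == 0) {
    const int *it = std::lower_bound(f.sent_rows, f.sent_rows + f.nsent, i);
    return f.sent_targets[it - f.sent_rows];
  }
  return f.cbefore[c] + occ(f, c, i);
}

static int sa_lookup(const FMView &f, int row) {
  int t = 0;
  int r = row;
  while (true) {
    const int *it = std::lower_bound(f.slots, f.slots + f.nslots, r);
    if (it != f.slots + f.nslots && *it == r)
      return f.samples[it - f.slots] + t;
    r = lf(f, r);
    ++t;
  }
}

// [[Rcpp::export(name = ".fm_build_cpp")]]
List fm_build_cpp(std::string text, int sample_rate) {
  if (text.empty()) stop("text must be non-empty");
  if (sample_rate < 1) stop("sample_rate must be >= 1");
  int n = (int)text.size();
  std::vector<int> codes = encode_text(text);
  if (codes[n - 1] != 0) stop("text must end with the sentinel '$'");
  std::vector<int> sa = suffix_array_codes(codes);

  RawVector bwt(n);
  for (int i = 0; i < n; ++i) {
    int p = sa[i];
    bwt[i] = (unsigned char)(p == 0 ? codes[n - 1] : codes[p - 1]);
  }

  IntegerVector cbefore(NSYM + 1);
  {
    std::vector<int> tot(NSYM, 0);
    for (int i = 0; i < n; ++i) tot[codes[i]]++;
    int sum = 0;
    for (int c = 0; c < NSYM; ++c) { cbefore[c] = sum; sum += tot[c]; }
    cbefore[NSYM] = sum;
  }

  int nblk = n / STRIDE + 1;
  IntegerVector occ_cp(nblk * NSYM);
  {
    std::vector<int> run(NSYM, 0);
    for (int i = 0; i < n; ++i) {
      if (i % STRIDE == 0) {
        int blk = i / STRIDE;
        for (int c = 0; c < NSYM; ++c) occ_cp[blk * NSYM + c] = run[c];
      }
      run[bwt[i]]++;
    }
    if ((n % STRIDE) != 0 || n == 0) {
      // final partial block checkpoint already written at its start
    }
    int lastblk = n / STRIDE;
    if (lastblk * STRIDE == n && lastblk < nblk)
      for (int c = 0; c < NSYM; ++c) occ_cp[lastblk * NSYM + c] = run[c];
  }

  std::vector<int> slots_v, samples_v;
  for (int i = 0; i < n; ++i) {
    if (sa[i] % sample_rate == 0) {
      slots_v.push_back(i);
      samples_v.push_back(sa[i]);
    }
  }

  // Explicit LF targets for rows whose BWT symbol is the sentinel.
  std::vector<int> isa(n);
  for (int i = 0; i < n; ++i) isa[sa[i]] = i;
  std::vector<int> sent_rows_v, sent_targets_v;
  for (int i = 0; i < n; ++i) {
    if (bwt[i] == 0) {
      int p = sa[i];
      int pred = (p == 0) ? n - 1 : p - 1;
      sent_rows_v.push_back(i);
      sent_targets_v.push_back(isa[pred]);
    }
  }

  return List::create(
      _["bwt"] = bwt, _["cbefore"] = cbefore, _["occ_cp"] = occ_cp,
      _["slots"] = IntegerVector(slots_v.begin(), slots_v.end()),
      _["samples"] = IntegerVector(samples_v.begin(), samples_v.end()),
      _["sent_rows"] = IntegerVector(sent_rows_v.begin(), sent_rows_v.end()),
      _["sent_targets"] =
          IntegerVector(sent_targets_v.begin(), sent_targets_v.end()),
      _["n"] = n, _["sample_rate"] = sample_rate);
}

static FMView make_view(const List &idx) {
  FMView f;
  RawVector bwt = idx["bwt"];
  IntegerVector cb = idx["cbefore"], cp = idx["occ_cp"], slots = idx["slots"],
                samples = idx["samples"], srows = idx["sent_rows"],
                stgt = idx["sent_targets"];
  f.bwt = RAW(bwt);
  f.cbefore = INTEGER(cb);
  f.occ_cp = INTEGER(cp);
  f.slots = INTEGER(slots);
  f.samples = INTEGER(samples);
  f.sent_rows = INTEGER(srows);
  f.sent_targets = INTEGER(stgt);
  f.n = as<int>(idx["n"]);
  f.nslots = (int)slots.size();
  f.nsent = (int)srows.size();
  return f;
}

// Backward search: half-open SA interval [lo, hi) of suffixes prefixed by
// pattern.  Any symbol outside the read alphabet (or the sentinel) yields the
// empty interval.
static void bw_interval(const FMView &f, const std::string &pat, int &lo,
                        int &hi) {
  int m = (int)pat.size();
  lo = 0; hi = 0;
  if (m == 0) return;
  int c = code_of(pat[m - 1]);
  if (c <= 0) return; // unknown symbol or sentinel
  lo = f.cbefore[c];
  hi = f.cbefore[c + 1];
  for (int i = m - 2; i >= 0 && lo < hi; --i) {
    c = code_of(pat[i]);
    if (c <= 0) { lo = hi = 0; return; }
    lo = f.cbefore[c] + occ(f, c, lo);
    hi = f.cbefore[c] + occ(f, c, hi);
  }
  if (lo >= hi) { lo = 0; hi = 0; }
}

// [[Rcpp::export(name = ".fm_interval_cpp")]]
IntegerMatrix fm_interval_cpp(List idx, CharacterVector patterns) {
  FMView f = make_view(idx);
  int m = patterns.size();
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    int lo, hi;
    bw_interval(f, as<std::string>(patterns[i]), lo, hi);
    out(i, 0) = lo;
    out(i, 1) = hi;
  }
  return out;
}

// Batched count + locate.  For each pattern returns the occurrence count and,
// when count <= max_hits, the sorted text positions; otherwise positions are
// NULL (overflow: count alone is carried to the collation stage).
// max_hits < 0 disables the ceiling.
// [[Rcpp::export(name = ".fm_search_cpp")]]
List fm_search_cpp(List idx, CharacterVector patterns, int max_hits,
                   bool locate) {
  FMView f = make_view(idx);
  int m = patterns.size();
  IntegerVector counts(m);
  List positions(m);
  for (int i = 0; i < m; ++i) {
    int lo, hi;
    bw_interval(f, as<std::string>(patterns[i]), lo, hi);
    int cnt = hi - lo;
    counts[i] = cnt;
    if (!locate || cnt == 0 || (max_hits >= 0 && cnt > max_hits)) {
      positions[i] = R_NilValue;
      continue;
    }
    std::vector<int> pos(cnt);
    for (int r = lo; r < hi; ++r) pos[r - lo] = sa_lookup(f, r);
    std::sort(pos.begin(), pos.end());
    positions[i] = IntegerVector(pos.begin(), pos.end());
  }
  return List::create(_["count"] = counts, _["positions"] = positions);
}

// Invert the BWT back to the original text (validation utility).
// [[Rcpp::export(name = ".fm_invert_cpp")]]
std::string fm_invert_cpp(List idx) {
  FMView f = make_view(idx);
  int n = f.n;
  std::string out(n, ' ');
  // Row of suffix 0: locate the slot whose SA value is 0 (always sampled).
  int row0 = -1;
  for (int i = 0; i < f.nslots; ++i)
    if (f.samples[i] == 0) { row0 = f.slots[i]; break; }
  if (row0 < 0) stop("corrupt index: suffix 0 not sampled");
  int r = row0;
  for (int k = n - 1; k >= 0; --k) {
    out[k] = char_of(f.bwt[r]);
    r = lf(f, r);
  }
  return out;
}
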