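#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

static inline std::string rc(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (auto &c : out) c = comp(c);
  return out;
}

static inline bool clean_acgt(const std::string &s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = rc(as<std::string>(seqs[i]));
  out.names() = seqs.names();
  return out;
}

// Canonical k-mer counting over a set of sequences. k-mers containing
// non-ACGT characters are skipped entirely.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      std::string w = s.substr(p, k);
      if (!clean_acgt(w)) continue;
      std::string r = rc(w);
      counts[w < r ? w : r]++;
    }
  }
  CharacterVector km(counts.size());
  IntegerVector ct(counts.size());
  R_xlen_t i = 0;
  for (auto &kv : counts) { km[i] = kv.first; ct[i] = kv.second; ++i; }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// All k-length windows of a sequence (canonical if canonical = TRUE);
// windows with non-ACGT characters become NA.
// [[Rcpp::export]]
CharacterVector cpp_window_kmers(std::string s, int k, bool canonical) {
  if ((int)s.size() < k) return CharacterVector(0);
  R_xlen_t n = s.size() - k + 1;
  CharacterVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    std::string w = s.substr(p, k);
    if (!clean_acgt(w)) { out[p] = NA_STRING; continue; }
    if (canonical) {
      std::string r = rc(w);
      out[p] = (w < r) ? w : r;
    } else out[p] = w;
  }
  return out;
}

// Number of distinct canonical k-mers shared between each read and a bait set.
// [[Rcpp::export]]
IntegerVector cpp_shared_kmer_counts(CharacterVector reads, CharacterVector bait, int k) {
  std::unordered_map<std::string, char> b;
  for (R_xlen_t i = 0; i < bait.size(); ++i) b[as<std::string>(bait[i])] = 1;
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    int shared = 0;
    if ((int)s.size() >= k) {
      std::unordered_map<std::string, char> seen;
      for (size_t p = 0; p + k <= s.size(); ++p) {
        std::string w = s.substr(p, k);
        if (!clean_acgt(w)) continue;
        std::string r = rc(w);
        std::string c = (w < r) ? w : r;
        if (b.count(c) && !seen.count(c)) { seen[c] = 1; ++shared; }
      }
    }
    out[i] = shared;
  }
  return out;
}

// Lexicographically minimal rotation (Booth's algorithm).
// [[Rcpp::export]]
int cpp_min_rotation(std::string s) {
  int n = s.size();
  if (n == 0) return 0;
  std::string ss = s + s;
  int i = 0, j = 1, kk = 0;
  while (i < n && j < n && kk < n) {
    char a = ss[i + kk], b = ss[j + kk];
    if (a == b) { ++kk; continue; }
    if (a > b) i = i + kk + 1; else j = j + kk + 1;
    if (i == j) ++j;
    kk = 0;
  }
  return std::min(i, j);
}

// Positional (gap-free) identity between two strings from given offsets.
// Returns matches and compared length; mask (optional, same length as b)
// restricts comparison to positions where mask is TRUE.
// [[Rcpp::export]]
List cpp_positional_identity(std::string a, int a_off, std::string b, int b_off,
                             int len, LogicalVector mask) {
  int m = 0, n = 0;
  bool use_mask = mask.size() > 0;
  for (int t = 0; t < len; ++t) {
    int ia = a_off + t, ib = b_off + t;
    if (ia < 0 || ib < 0 || ia >= (int)a.size() || ib >= (int)b.size()) break;
    if (use_mask && !mask[ib]) continue;
    ++n;
    if (a[ia] == b[ib]) ++m;
  }
  return List::create(_["matches"] = m, _["compared"] = n);
}

// Exact occurrences of `pattern` in `text` (forward strand only), 0-based.
// [[Rcpp::export]]
IntegerVector cpp_exact_find(std::string text, std::string pattern) {
  std::vector<int> hits;
  if (!pattern.empty() && pattern.size() <= text.size()) {
    size_t p = text.find(pattern, 0);
    while (p != std::string::npos) {
      hits.push_back((int)p);
      p = text.find(pattern, p + 1);
    }
  }
  return wrap(hits);
}

// Hamming mismatch count between pattern and text starting at pos (0-based);
// returns -1 if the window falls off the text.
// [[Rcpp::export]]
int cpp_mismatch_at(std::string text, std::string pattern, int pos) {
  if (pos < 0 || pos + pattern.size() > text.size()) return -1;
  int mm = 0;
  for (size_t t = 0; t < pattern.size(); ++t)
    if (text[pos + t] != pattern[t]) ++mm;
  return mm;
}

// Read pairs held in C++ so fork adjudication does not re-marshal strings
// on every call.
struct PairData {
  // mates[0..3] = m1, m2, rc(m1), rc(m2); prefix_idx maps the first
  // PREFIX_K characters of every oriented mate to its (pair, orientation)
  static const int PREFIX_K = 16;
  std::vector<std::string> mates[4];
  std::unordered_multimap<std::string, int> prefix_idx; // key -> 4*i + j
};

// [[Rcpp::export]]
SEXP cpp_make_pair_index(CharacterVector r1, CharacterVector r2) {
  XPtr<PairData> ptr(new PairData(), true);
  int n = r1.size();
  for (int j = 0; j < 4; ++j) ptr->mates[j].reserve(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string b = as<std::string>(r2[i]);
    ptr->mates[0].push_back(a); ptr->mates[1].push_back(b);
    ptr->mates[2].push_back(rc(a)); ptr->mates[3].push_back(rc(b));
  }
  const int K = PairData::PREFIX_K;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j)
      if ((int)ptr->mates[j][i].size() >= K)
        ptr->prefix_idx.insert({ptr->mates[j][i].substr(0, K), 4 * i + j});
  return ptr;
}

// Read-pair phase check around an assembly fork.
//
// x          : contig + candidate extension (plain ACGT string)
// from_, to_ : 0-based half-open region of x to adjudicate
// pairs      : XPtr from cpp_make_pair_index (FR orientation: r2 is the
//              reverse complement of the fragment 3' end)
// imin, imax : admissible fragment lengths (insert model window)
// reach      : phasing reach in bp
//
// A candidate extension is phase-consistent when every pair of positions
// (a, b) with b in the region and b - a <= reach is jointly covered either
// by one exactly placed read, or by the two mates of a placed fragment
// whose implied insert lies in [imin, imax]. A chimeric join between the
// two control-region copies leaves the position pair straddling it jointly
// uncovered — no read or properly sized fragment links the two haplotypes —
// while every pair on the true path is linked at deep coverage. Returns -1
// when consistent, else the x-coordinate of the first unphaseable b.
// [[Rcpp::export]]
int cpp_phase_check(std::string x, int from_, int to_, SEXP pairs,
                    int imin, int imax, int reach) {
  XPtr<PairData> pd(pairs);
  int xn = x.size();
  if (from_ < 0) from_ = 0;
  if (to_ > xn) to_ = xn;
  if (to_ <= from_) return -1;

  // scan x once: every oriented mate whose prefix matches an x position is
  // verified in full and recorded as a placement
  int scan_lo = std::max(0, from_ - imax - 200);
  const int K = PairData::PREFIX_K;
  std::vector<std::pair<int, int>> reads_placed;        // single-mate intervals
  // per (pair, orientation) placements, for fragment pairing
  std::unordered_map<int, std::vector<int>> placed_at;
  for (int p = scan_lo; p + K <= to_; ++p) {
    auto range = pd->prefix_idx.equal_range(x.substr(p, K));
    for (auto it = range.first; it != range.second; ++it) {
      int code = it->second;
      const std::string &m = pd->mates[code % 4][code / 4];
      if (p + (int)m.size() <= xn && x.compare(p, m.size(), m) == 0) {
        reads_placed.push_back({p, p + (int)m.size()});
        placed_at[code].push_back(p);
      }
    }
  }
  struct Frag { int p, pl, q, ql; };
  std::vector<Frag> frags;                              // valid placed fragments
  int n = pd->mates[0].size();
  auto pair_up = [&](int code_l, int code_r) {
    auto il = placed_at.find(code_l);
    auto ir = placed_at.find(code_r);
    if (il == placed_at.end() || ir == placed_at.end()) return;
    int ll = pd->mates[code_l % 4][code_l / 4].size();
    int lr = pd->mates[code_r % 4][code_r / 4].size();
    for (int p : il->second) for (int q : ir->second) {
      int ins = q + lr - p;
      if (q >= p && ins >= imin && ins <= imax)
        frags.push_back({p, ll, q, lr});
    }
  };
  for (auto &kv : placed_at) {
    int code = kv.first, i = code / 4, j = code % 4;
    if (j == 0) pair_up(code, 4 * i + 3);  // m1 fwd + rc(m2) downstream
    if (j == 1) pair_up(code, 4 * i + 2);  // m2 fwd + rc(m1) downstream
  }
  (void)n;

  // maxend[a]: furthest end of any placed read starting at or before a —
  // cells (a, b) with maxend[a] > b are read-contained
  int alo = std::max(0, from_ - reach);
  int na = to_ - alo;
  std::vector<int> maxend(na, -1);
  for (auto &rp : reads_placed) {
    int s = std::max(rp.first, alo);
    if (s < to_ && rp.second > maxend[s - alo]) maxend[s - alo] = rp.second;
  }
  for (int a = 1; a < na; ++a) maxend[a] = std::max(maxend[a], maxend[a - 1]);

  // fragments linking into each b: left-mate intervals
  std::vector<std::vector<std::pair<int, int>>> links(to_ - from_);
  for (auto &f : frags) {
    int blo = std::max(f.q, from_), bhi = std::min(f.q + f.ql, to_);
    for (int b = blo; b < bhi; ++b)
      links[b - from_].push_back({f.p, f.p + f.pl});
  }

  for (int b = from_; b < to_; ++b) {
    int lo = std::max(0, b - reach);
    // a0: first a with maxend[a] > b (maxend is monotone nondecreasing)
    int a0 = b;
    {
      int loi = lo - alo, hii = b - alo; // search in [loi, hii)
      while (loi < hii) {
        int mid = (loi + hii) / 2;
        if (maxend[mid] > b) hii = mid; else loi = mid + 1;
      }
      a0 = loi + alo;
    }
    if (a0 <= lo) continue; // whole band read-contained
    // [lo, a0) must be covered by the union of linking left-mate intervals
    auto &L = links[b - from_];
    std::sort(L.begin(), L.end());
    int covered_to = lo;
    for (auto &iv : L) {
      if (iv.first > covered_to) break;
      if (iv.second > covered_to) covered_to = iv.second;
    }
    if (covered_to < a0) return b;
  }
  return -1;
}
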