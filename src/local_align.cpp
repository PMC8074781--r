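#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Banded Smith-Waterman with affine gaps over a query/subject window pair,
// plus word seeding and diagonal clustering: the engine behind the NUMT
// search. Scores follow the blastn convention (positive match reward,
// negative mismatch, positive gap penalties).

struct Hit {
  int qs, qe, ss, se;     // 0-based half-open, region-local
  int score, matches, mismatches, qgaps, sgaps;
};

// One banded local alignment of Q vs S with diagonal offsets (j - i)
// restricted to [dlo, dhi]. Returns highest-scoring local alignment.
static Hit banded_sw(const std::string &Q, const std::string &S,
                     int dlo, int dhi,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int m = Q.size(), n = S.size();
  const int w = dhi - dlo + 1;
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> H((m + 1) * w, 0), E((m + 1) * w, NEG), F((m + 1) * w, NEG);
  std::vector<unsigned char> TH((m + 1) * w, 0), TE((m + 1) * w, 0), TF((m + 1) * w, 0);
  auto at = [&](int i, int t) { return i * w + t; };

  int best = 0, bi = -1, bt = -1;
  for (int i = 1; i <= m; ++i) {
    for (int t = 0; t < w; ++t) {
      int j = i + dlo + t;               // 1-based subject position
      if (j < 1 || j > n) { H[at(i, t)] = 0; E[at(i, t)] = NEG; F[at(i, t)] = NEG; continue; }
      // E: gap in query (move along subject): from (i, j-1) => t-1
      int e = NEG; unsigned char te = 0;
      if (t - 1 >= 0) {
        int hprev = H[at(i, t - 1)], eprev = E[at(i, t - 1)];
        if (hprev - go >= eprev - ge) { e = hprev - go; te = 0; }
        else { e = eprev - ge; te = 1; }
      }
      // F: gap in subject (move along query): from (i-1, j) => t+1 in row i-1
      int f = NEG; unsigned char tf = 0;
      if (t + 1 < w) {
        int hup = H[at(i - 1, t + 1)], fup = F[at(i - 1, t + 1)];
        if (hup - go >= fup - ge) { f = hup - go; tf = 0; }
        else { f = fup - ge; tf = 1; }
      }
      // diagonal: (i-1, j-1) => same t in row i-1
      int sub = (Q[i - 1] == S[j - 1]) ? match : mismatch;
      int d = H[at(i - 1, t)] + sub;
      int h = 0; unsigned char th = 0;
      if (d >= h) { h = d; th = 1; }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      H[at(i, t)] = h; E[at(i, t)] = e; F[at(i, t)] = f;
      TH[at(i, t)] = th; TE[at(i, t)] = te; TF[at(i, t)] = tf;
      if (h > best) { best = h; bi = i; bt = t; }
    }
  }
  Hit hit; hit.score = best;
  hit.matches = hit.mismatches = hit.qgaps = hit.sgaps = 0;
  if (best <= 0) { hit.qs = hit.qe = hit.ss = hit.se = 0; return hit; }
  int i = bi, t = bt;
  hit.qe = i; hit.se = i + dlo + t;
  int state = 0; // 0 = in H
  while (true) {
    if (state == 0) {
      unsigned char th = TH[at(i, t)];
      if (th == 0) break;
      if (th == 1) {
        int j = i + dlo + t;
        if (Q[i - 1] == S[j - 1]) ++hit.matches; else ++hit.mismatches;
        --i; // t unchanged on diagonal move
        if (TH[at(i, t)] == 0 && H[at(i, t)] == 0) { /* will break next loop */ }
      } else if (th == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // E: gap in query, consumed subject base
      unsigned char te = TE[at(i, t)];
      ++hit.qgaps;
      --t;
      if (te == 0) state = 0;
    } else {                 // F: gap in subject, consumed query base
      unsigned char tf = TF[at(i, t)];
      ++hit.sgaps;
      --i; ++t;
      if (tf == 0) state = 0;
    }
    if (i <= 0 || t < 0 || t >= w) break;
  }
  hit.qs = i; hit.ss = i + dlo + t;
  if (hit.qs < 0) hit.qs = 0;
  if (hit.ss < 0) hit.ss = 0;
  return hit;
}

// Seeded local search of query against subject (both plain ACGT strings,
// forward strands). Returns one row per seed cluster whose banded local
// alignment reaches min_score. Coordinates are 0-based half-open.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject, int word,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int min_score, int band_pad) {
  // index subject words
  std::unordered_map<std::string, std::vector<int>> idx;
  for (int p = 0; p + word <= (int)subject.size(); ++p) {
    std::string wrd = subject.substr(p, word);
    bool ok = true;
    for (char c : wrd) if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    if (ok) idx[wrd].push_back(p);
  }
  // collect seeds
  struct Seed { int q, s, d; };
  std::vector<Seed> seeds;
  for (int q = 0; q + word <= (int)query.size(); ++q) {
    auto it = idx.find(query.substr(q, word));
    if (it == idx.end()) continue;
    for (int s : it->second) seeds.push_back({q, s, s - q});
  }
  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    return a.s == b.s ? a.q < b.q : a.s < b.s;
  });
  // greedy diagonal clustering
  struct Clus { int qlo, qhi, slo, shi, dlo, dhi, last_s, nseeds; };
  std::vector<Clus> clus;
  const int DIAG_SLOP = 30, S_GAP = 400;
  for (auto &sd : seeds) {
    bool placed = false;
    for (auto &c : clus) {
      if (sd.s - c.last_s <= S_GAP && sd.d >= c.dlo - DIAG_SLOP && sd.d <= c.dhi + DIAG_SLOP) {
        c.qlo = std::min(c.qlo, sd.q); c.qhi = std::max(c.qhi, sd.q + word);
        c.slo = std::min(c.slo, sd.s); c.shi = std::max(c.shi, sd.s + word);
        c.dlo = std::min(c.dlo, sd.d); c.dhi = std::max(c.dhi, sd.d);
        c.last_s = std::max(c.last_s, sd.s);
        ++c.nseeds;
        placed = true;
        break;
      }
    }
    if (!placed) clus.push_back({sd.q, sd.q + word, sd.s, sd.s + word, sd.d, sd.d, sd.s, 1});
  }
  std::vector<Hit> hits;
  std::vector<int> hq0, hs0;
  const int FLANK = 250;
  for (auto &c : clus) {
    int q0 = std::max(0, c.qlo - FLANK), q1 = std::min((int)query.size(), c.qhi + FLANK);
    int s0 = std::max(0, c.slo - FLANK), s1 = std::min((int)subject.size(), c.shi + FLANK);
    std::string Q = query.substr(q0, q1 - q0), S = subject.substr(s0, s1 - s0);
    int dlo = (c.dlo - s0 + q0) - band_pad, dhi = (c.dhi - s0 + q0) + band_pad;
    Hit h = banded_sw(Q, S, dlo, dhi, match, mismatch, gap_open, gap_extend);
    if (h.score >= min_score) { hits.push_back(h); hq0.push_back(q0); hs0.push_back(s0); }
  }
  int nh = hits.size();
  IntegerVector qs(nh), qe(nh), ss(nh), se(nh), score(nh), matches(nh),
      mismatches(nh), qgaps(nh), sgaps(nh);
  for (int i = 0; i < nh; ++i) {
    qs[i] = hits[i].qs + hq0[i]; qe[i] = hits[i].qe + hq0[i];
    ss[i] = hits[i].ss + hs0[i]; se[i] = hits[i].se + hs0[i];
    score[i] = hits[i].score; matches[i] = hits[i].matches;
    mismatches[i] = hits[i].mismatches; qgaps[i] = hits[i].qgaps; sgaps[i] = hits[i].sgaps;
  }
  return DataFrame::create(
      _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
      _["score"] = score, _["matches"] = matches, _["mismatches"] = mismatches,
      _["q_gaps"] = qgaps, _["s_gaps"] = sgaps);
}
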