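#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
using namespace Rcpp;

// Banded local alignment with affine gaps (Gotoh) restricted to diagonals
// d = j - i in [dlo, dhi] (i: query index, j: subject index). A gap of
// length L costs gap_open + (L - 1) * gap_ext (both negative).
//
// Returns the best local alignment as score, 0-based half-open query and
// subject ranges, the number of matching columns and the total number of
// alignment columns (for identity = matches / columns).
// [[Rcpp::export]]
List band_align(std::string q, std::string s, int dlo, int dhi,
                double match = 1.0, double mismatch = -1.0,
                double gap_open = -2.0, double gap_ext = -1.0) {
  int n = (int)q.size(), m = (int)s.size();
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  List empty = List::create(_["score"] = 0.0, _["q_start"] = 0,
                            _["q_end"] = 0, _["s_start"] = 0, _["s_end"] = 0,
                            _["matches"] = 0, _["columns"] = 0);
  if (dhi < dlo || n == 0 || m == 0) return empty;
  int w = dhi - dlo + 1;
  const double NEG = -1e18;
  size_t sz = (size_t)(n + 1) * w;
  std::vector<double> H(sz, NEG), E(sz, NEG), F(sz, NEG);
  // traceback codes -- H: 0 stop, 1 diag, 2 from E, 3 from F
  //                    E: 0 open (from H), 1 extend; F likewise
  std::vector<unsigned char> tH(sz, 0), tE(sz, 0), tF(sz, 0);
  auto idx = [&](int i, int k) { return (size_t)i * w + k; };

  double best = 0.0; int bi = -1, bk = -1;
  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k < w; ++k) {
      int j = i + dlo + k;
      if (j < 0 || j > m) continue;
      size_t c = idx(i, k);
      if (i == 0 || j == 0) { H[c] = 0.0; tH[c] = 0; continue; }
      // E: gap in query (left move, from (i, j-1) => k-1)
      if (k - 1 >= 0) {
        size_t l = idx(i, k - 1);
        double eo = (H[l] > NEG / 2) ? H[l] + gap_open : NEG;
        double ee = (E[l] > NEG / 2) ? E[l] + gap_ext : NEG;
        if (eo >= ee) { E[c] = eo; tE[c] = 0; } else { E[c] = ee; tE[c] = 1; }
      }
      // F: gap in subject (up move, from (i-1, j) => k+1)
      if (k + 1 < w) {
        size_t u = idx(i - 1, k + 1);
        double fo = (H[u] > NEG / 2) ? H[u] + gap_open : NEG;
        double fe = (F[u] > NEG / 2) ? F[u] + gap_ext : NEG;
        if (fo >= fe) { F[c] = fo; tF[c] = 0; } else { F[c] = fe; tF[c] = 1; }
      }
      size_t d = idx(i - 1, k);
      double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double hd = (H[d] > NEG / 2) ? H[d] + sub : NEG;
      double hv = 0.0; unsigned char tv = 0;
      if (hd > hv) { hv = hd; tv = 1; }
      if (E[c] > hv) { hv = E[c]; tv = 2; }
      if (F[c] > hv) { hv = F[c]; tv = 3; }
      H[c] = hv; tH[c] = tv;
      if (hv > best) { best = hv; bi = i; bk = k; }
    }
  }
  if (bi < 0 || best <= 0.0) return empty;

  // traceback from (bi, bk) in state H
  int i = bi, k = bk;
  int q_end = bi, s_end = bi + dlo + bk;
  int matches = 0, columns = 0;
  char state = 'H';
  while (true) {
    size_t c = idx(i, k);
    int j = i + dlo + k;
    if (state == 'H') {
      unsigned char t = tH[c];
      if (t == 0) break;
      if (t == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1]) ++matches;
        i -= 1; // diag: same k
      } else if (t == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      ++columns;           // one subject base against a gap
      unsigned char t = tE[c];
      k -= 1;              // move to (i, j-1)
      if (t == 0) state = 'H';
    } else { // F
      ++columns;           // one query base against a gap
      unsigned char t = tF[c];
      i -= 1; k += 1;      // move to (i-1, j)
      if (t == 0) state = 'H';
    }
  }
  int q_start = i, s_start = i + dlo + k;
  return List::create(_["score"] = best, _["q_start"] = q_start,
                      _["q_end"] = q_end, _["s_start"] = s_start,
                      _["s_end"] = s_end, _["matches"] = matches,
                      _["columns"] = columns);
}

// Positions (0-based) of every shared k-mer between q and s, returned as a
// two-column integer matrix (q_pos, s_pos). Used for seeding.
// [[Rcpp::export]]
IntegerMatrix kmer_seeds(std::string q, std::string s, int k = 15) {
  int n = (int)q.size(), m = (int)s.size();
  std::vector<int> qp, sp;
  if (n >= k && m >= k) {
    std::unordered_map<std::string, std::vector<int> > map;
    map.reserve(m);
    for (int j = 0; j + k <= m; ++j) map[s.substr(j, k)].push_back(j);
    for (int i = 0; i + k <= n; ++i) {
      auto it = map.find(q.substr(i, k));
      if (it == map.end()) continue;
      for (int j : it->second) { qp.push_back(i); sp.push_back(j); }
    }
  }
  IntegerMatrix out((int)qp.size(), 2);
  for (size_t r = 0; r < qp.size(); ++r) { out(r, 0) = qp[r]; out(r, 1) = sp[r]; }
  return out;
}
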