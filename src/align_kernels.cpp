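#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// N (or any non-ACGT) never matches anything, including itself.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline bool base_match(char a, char b) {
  return a == b && base_code(a) >= 0;
}

// Maximal exact matches of length >= min_len between q and r, forward
// strand. Seeds are 2-bit packed k-mers (k = min(min_len, 31)); every
// maximal match of length >= k contains a left-maximal seed at its start,
// so extending only left-maximal seed hits enumerates each MEM once.
// [[Rcpp::export(name = ".find_mems_cpp")]]
DataFrame find_mems_cpp(std::string q, std::string r, int min_len) {
  int qn = (int)q.size(), rn = (int)r.size();
  std::vector<int> qs_out, rs_out, len_out;
  int k = min_len < 31 ? min_len : 31;
  if (k < 1 || qn < k || rn < k) {
    return DataFrame::create(_["q_start"] = IntegerVector(0),
                             _["r_start"] = IntegerVector(0),
                             _["length"] = IntegerVector(0));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve((size_t)rn * 2);
  {
    uint64_t key = 0;
    int valid = 0; // number of consecutive valid bases ending here
    for (int i = 0; i < rn; ++i) {
      int c = base_code(r[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) index[key].push_back(i - k + 1);
    }
  }

  uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < qn; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid < k) continue;
    int qi = i - k + 1;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
      index.find(key);
    if (it == index.end()) continue;
    const std::vector<int>& hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      int ri = hits[h];
      // left-maximality: only extend from the start of the maximal match
      if (qi > 0 && ri > 0 && base_match(q[qi - 1], r[ri - 1])) continue;
      int e = k;
      while (qi + e < qn && ri + e < rn && base_match(q[qi + e], r[ri + e])) ++e;
      if (e >= min_len) {
        qs_out.push_back(qi);
        rs_out.push_back(ri);
        len_out.push_back(e);
      }
    }
  }
  return DataFrame::create(_["q_start"] = wrap(qs_out),
                           _["r_start"] = wrap(rs_out),
                           _["length"] = wrap(len_out));
}

// Unit-cost (Levenshtein) global alignment with full traceback.
// Returns the optimal edit path as a string over {=, X, I, D}, where I
// consumes the first sequence (query) and D consumes the second (reference).
// Every cell stores the bitmask of cost-optimal moves; the traceback
// prefers extending the gap run it is already in, then the diagonal, then
// D, then I. This keeps equal-cost indels contiguous without rewriting
// tied mismatch pairs as gap/match/gap, and is deterministic.
// [[Rcpp::export(name = ".edit_align_cpp")]]
List edit_align_cpp(std::string a, std::string b, double max_cells = 6e7) {
  size_t n = a.size(), m = b.size();
  if ((double)(n + 1) * (double)(m + 1) > max_cells)
    stop("alignment problem too large: %d x %d cells", (int)n, (int)m);

  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((n + 1) * (m + 1)); // bit 1 diag, 2 up(I), 4 left(D)
  for (size_t j = 0; j <= m; ++j) { prev[j] = (int)j; tb[j] = 4; }
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    tb[i * (m + 1)] = 2;
    for (size_t j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
      int up = prev[j] + 1;      // consume a -> I
      int left = cur[j - 1] + 1; // consume b -> D
      int best = diag < up ? diag : up;
      if (left < best) best = left;
      uint8_t bits = 0;
      if (diag == best) bits |= 1;
      if (up == best) bits |= 2;
      if (left == best) bits |= 4;
      cur[j] = best;
      tb[i * (m + 1) + j] = bits;
    }
    std::swap(prev, cur);
  }
  int dist = prev[m];

  std::string ops;
  ops.reserve(n + m);
  size_t i = n, j = m;
  char last = 0;
  while (i > 0 || j > 0) {
    uint8_t bits = tb[i * (m + 1) + j];
    char op;
    if (i == 0) op = 'D';
    else if (j == 0) op = 'I';
    else if (last == 'I' && (bits & 2)) op = 'I';
    else if (last == 'D' && (bits & 4)) op = 'D';
    else if (bits & 1) op = '=';
    else if (bits & 4) op = 'D';
    else op = 'I';
    if (op == '=') {
      ops.push_back(base_match(a[i - 1], b[j - 1]) ? '=' : 'X');
      last = '=';
      --i; --j;
    } else if (op == 'I') {
      ops.push_back('I'); last = 'I'; --i;
    } else {
      ops.push_back('D'); last = 'D'; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = ops, _["distance"] = dist);
}
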