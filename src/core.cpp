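#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Characters are plain ASCII over {A,C,G,T,N}; byte comparison realizes the
// documented lexicographic order A < C < G < T (N never occurs in library
// M-mers, so its ASCII slot between G and T only affects queries).

// 'N' mismatches every character, including another 'N'.
static inline bool base_mismatch(char x, char y) {
  return x != y || x == 'N';
}

// Compare the permuted M-mer starting at genome position a with the one at b.
// ord holds 0-based source offsets: permuted character r is genome[pos + ord[r]].
static inline int cmp_permuted(const char* g, int a, int b, const int* ord,
                               int m) {
  for (int r = 0; r < m; ++r) {
    const char ca = g[a + ord[r]];
    const char cb = g[b + ord[r]];
    if (ca != cb) return ca < cb ? -1 : 1;
  }
  return 0;
}

// Compare the permuted M-mer at genome position a with the first l characters
// of an already-permuted query q.
static inline int cmp_permuted_query(const char* g, int a, const int* ord,
                                     const char* q, int l) {
  for (int r = 0; r < l; ++r) {
    const char ca = g[a + ord[r]];
    if (ca != q[r]) return ca < q[r] ? -1 : 1;
  }
  return 0;
}

// [[Rcpp::export]]
std::string cpp_apply_perm(std::string s, IntegerVector ord0) {
  const int m = ord0.size();
  std::string out(m, 'N');
  for (int r = 0; r < m; ++r) out[r] = s[ord0[r]];
  return out;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("strings must have equal length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (base_mismatch(a[i], b[i]) || base_mismatch(b[i], a[i])) ++d;
  return d;
}

// Hamming distance of `read` against the M-mer at each 0-based genome position.
// [[Rcpp::export]]
IntegerVector cpp_hamming_at(CharacterVector genome, IntegerVector pos0,
                             std::string read) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  const int m = read.size();
  const int n = pos0.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* x = g + pos0[i];
    int d = 0;
    for (int r = 0; r < m; ++r)
      if (base_mismatch(x[r], read[r]) || base_mismatch(read[r], x[r])) ++d;
    out[i] = d;
  }
  return out;
}

// Full-scan nearest neighbour: minimum Hamming distance over all library
// positions, plus every argmin position (used as a brute-force oracle).
// [[Rcpp::export]]
List cpp_min_hamming(CharacterVector genome, IntegerVector pos0,
                     std::string read) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  const int m = read.size();
  int best = m + 1;
  std::vector<int> arg;
  for (int i = 0; i < pos0.size(); ++i) {
    const char* x = g + pos0[i];
    int d = 0;
    for (int r = 0; r < m && d < best; ++r)
      if (base_mismatch(x[r], read[r]) || base_mismatch(read[r], x[r])) ++d;
    if (d < best) {
      best = d;
      arg.clear();
      arg.push_back(pos0[i]);
    } else if (d == best) {
      // early-exit loop leaves d == best only when the full M-mer was scanned
      int full = 0;
      for (int r = 0; r < m; ++r)
        if (base_mismatch(x[r], read[r]) || base_mismatch(read[r], x[r])) ++full;
      if (full == best) arg.push_back(pos0[i]);
    }
  }
  return List::create(_["distance"] = best, _["positions"] = wrap(arg));
}

// 0-based start positions of N-free M-mers.
// [[Rcpp::export]]
IntegerVector cpp_valid_mmer_starts(CharacterVector genome, int m) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  const int n = LENGTH(STRING_ELT(genome, 0));
  std::vector<int> out;
  int lastN = -1;
  for (int i = 0; i < n; ++i) {
    if (g[i] == 'N') lastN = i;
    const int start = i - m + 1;
    if (start >= 0 && lastN < start) out.push_back(start);
  }
  return wrap(out);
}

// Sort library positions by permuted M-mer (ties by genome position).
// Permuted strings are materialized lazily inside the comparator; only the
// position array is returned. The number of M-mer comparisons is attached as
// an attribute for the complexity contract tests.
// [[Rcpp::export]]
IntegerVector cpp_sort_index(CharacterVector genome, IntegerVector pos0,
                             IntegerVector ord0) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  const int m = ord0.size();
  std::vector<int> ord(ord0.begin(), ord0.end());
  std::vector<int> p(pos0.begin(), pos0.end());
  long long ncmp = 0;
  std::sort(p.begin(), p.end(), [&](int a, int b) {
    ++ncmp;
    const int c = cmp_permuted(g, a, b, ord.data(), m);
    return c != 0 ? c < 0 : a < b;
  });
  IntegerVector out = wrap(p);
  out.attr("comparisons") = (double)ncmp;
  return out;
}

// Leftmost insertion point of the (already permuted) query q in the sorted
// index: the count of entries strictly less than q.
// [[Rcpp::export]]
List cpp_lex_position(CharacterVector genome, IntegerVector order0,
                      IntegerVector ord0, std::string q) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  const int m = ord0.size();
  if ((int)q.size() != m) stop("query length must equal m");
  std::vector<int> ord(ord0.begin(), ord0.end());
  int lo = 0, hi = order0.size(), ncmp = 0;
  while (lo < hi) {
    const int mid = lo + (hi - lo) / 2;
    ++ncmp;
    if (cmp_permuted_query(g, order0[mid], ord.data(), q.c_str(), m) < 0)
      lo = mid + 1;
    else
      hi = mid;
  }
  return List::create(_["rank"] = lo, _["comparisons"] = ncmp);
}

// Half-open range [lo, hi) of index entries whose permuted M-mer shares the
// l-long prefix of the permuted query q; two binary searches.
// [[Rcpp::export]]
IntegerVector cpp_prefix_range(CharacterVector genome, IntegerVector order0,
                               IntegerVector ord0, std::string q, int l) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  std::vector<int> ord(ord0.begin(), ord0.end());
  const int n = order0.size();
  int lo = 0, hi = n;
  while (lo < hi) {  // first entry with prefix >= q[0:l]
    const int mid = lo + (hi - lo) / 2;
    if (cmp_permuted_query(g, order0[mid], ord.data(), q.c_str(), l) < 0)
      lo = mid + 1;
    else
      hi = mid;
  }
  const int first = lo;
  hi = n;
  while (lo < hi) {  // first entry with prefix > q[0:l]
    const int mid = lo + (hi - lo) / 2;
    if (cmp_permuted_query(g, order0[mid], ord.data(), q.c_str(), l) <= 0)
      lo = mid + 1;
    else
      hi = mid;
  }
  return IntegerVector::create(first, lo);
}

static const int kInf = 1 << 28;

// Banded global edit distance (unit costs) with traceback. Exact whenever the
// true distance is within the band; the effective band is widened to the
// length difference so the final corner is always reachable.
// [[Rcpp::export]]
List cpp_banded_edit(std::string a, std::string b, int band) {
  const int la = a.size(), lb = b.size();
  const int w = std::max(band, std::abs(la - lb));
  if ((double)(la + 1) * (lb + 1) > 6.4e7) stop("strings too long for traceback DP");
  std::vector<int> D((la + 1) * (lb + 1), kInf);
  auto at = [&](int i, int j) -> int& { return D[i * (lb + 1) + j]; };
  for (int i = 0; i <= la; ++i) {
    const int jlo = std::max(0, i - w), jhi = std::min(lb, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) { at(i, j) = 0; continue; }
      int best = kInf;
      if (i > 0 && j > 0) {
        const int sub = base_mismatch(a[i - 1], b[j - 1]) ? 1 : 0;
        best = std::min(best, at(i - 1, j - 1) + sub);
      }
      if (i > 0 && at(i - 1, j) < kInf) best = std::min(best, at(i - 1, j) + 1);
      if (j > 0 && at(i, j - 1) < kInf) best = std::min(best, at(i, j - 1) + 1);
      at(i, j) = best;
    }
  }
  const int dist = at(la, lb);
  // traceback, preferring diagonal, then insertion (read consumed), then deletion
  std::string rev;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      const int sub = base_mismatch(a[i - 1], b[j - 1]) ? 1 : 0;
      if (at(i - 1, j - 1) < kInf && at(i, j) == at(i - 1, j - 1) + sub) {
        rev.push_back(sub ? 'X' : 'M');
        --i; --j;
        continue;
      }
    }
    if (i > 0 && at(i - 1, j) < kInf && at(i, j) == at(i - 1, j) + 1) {
      rev.push_back('I');
      --i;
      continue;
    }
    rev.push_back('D');
    --j;
  }
  std::string transcript(rev.rbegin(), rev.rend());
  // collapse to CIGAR, folding X into M
  std::string cigar;
  size_t k = 0;
  while (k < transcript.size()) {
    char op = transcript[k] == 'X' ? 'M' : transcript[k];
    size_t k2 = k;
    while (k2 < transcript.size() &&
           (transcript[k2] == 'X' ? 'M' : transcript[k2]) == op)
      ++k2;
    cigar += std::to_string(k2 - k);
    cigar.push_back(op);
    k = k2;
  }
  if (cigar.empty()) cigar = "*";
  return List::create(_["distance"] = dist, _["transcript"] = transcript,
                      _["cigar"] = cigar);
}

// Distance-only banded edit distance of `mate` against the same-length genome
// window at each 0-based offset (used by the mate-rescue scan).
// [[Rcpp::export]]
IntegerVector cpp_band_dist_multi(CharacterVector genome, IntegerVector off0,
                                  std::string mate, int band) {
  const char* g = CHAR(STRING_ELT(genome, 0));
  const int len = mate.size();
  const int w = std::max(band, 1);
  IntegerVector out(off0.size());
  std::vector<int> prev(len + 1), cur(len + 1);
  for (int t = 0; t < off0.size(); ++t) {
    const char* ref = g + off0[t];
    for (int j = 0; j <= len; ++j) prev[j] = j <= w ? j : kInf;
    for (int i = 1; i <= len; ++i) {
      const int jlo = std::max(1, i - w), jhi = std::min(len, i + w);
      std::fill(cur.begin(), cur.end(), kInf);
      if (i - w <= 0) cur[0] = i;
      for (int j = jlo; j <= jhi; ++j) {
        const int sub = base_mismatch(mate[i - 1], ref[j - 1]) ? 1 : 0;
        int best = prev[j - 1] == kInf ? kInf : prev[j - 1] + sub;
        if (prev[j] < kInf) best = std::min(best, prev[j] + 1);
        if (cur[j - 1] < kInf) best = std::min(best, cur[j - 1] + 1);
        cur[j] = best;
      }
      std::swap(prev, cur);
    }
    out[t] = prev[len] >= kInf ? NA_INTEGER : prev[len];
  }
  return out;
}

// FNV-1a hash of the reference, recorded in persisted indexes so a reloaded
// order array is never applied to a different genome.
// [[Rcpp::export]]
std::string cpp_string_hash(CharacterVector s) {
  const char* g = CHAR(STRING_ELT(s, 0));
  const int n = LENGTH(STRING_ELT(s, 0));
  unsigned long long h = 1469598103934665603ULL;
  for (int i = 0; i < n; ++i) {
    h ^= (unsigned char)g[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", h);
  return std::string(buf);
}

// Reverse complement over {A,C,G,T,N} (N maps to N); other bytes unchanged.
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  static char tab[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) tab[i] = (char)i;
    tab['A'] = 'T'; tab['C'] = 'G'; tab['G'] = 'C'; tab['T'] = 'A';
    tab['N'] = 'N';
    init = true;
  }
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    const int n = LENGTH(STRING_ELT(x, i));
    std::string r(n, ' ');
    for (int j = 0; j < n; ++j) r[n - 1 - j] = tab[(unsigned char)s[j]];
    out[i] = r;
  }
  return out;
}
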