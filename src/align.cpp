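#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Global Needleman-Wunsch with linear gap penalty. Identity is defined as
// matching columns / total alignment columns (gap columns included) of the
// optimal-score alignment recovered by a deterministic traceback that prefers
// diagonal over up (gap in b) over left (gap in a) on score ties. The R-side
// test oracle mirrors this tie-break exactly.

struct NwResult {
  int score;
  int matches;
  int columns;
};

static NwResult nw_core(const std::string& a, const std::string& b,
                        int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  static std::vector<int> S;  // full score matrix, reused across calls
  S.assign((size_t)(n + 1) * (m + 1), 0);
  auto at = [&](int i, int j) -> int& { return S[(size_t)i * (m + 1) + j]; };
  for (int j = 0; j <= m; ++j) at(0, j) = gap * j;
  for (int i = 1; i <= n; ++i) {
    at(i, 0) = gap * i;
    const char ai = a[i - 1];
    const int* prev = &S[(size_t)(i - 1) * (m + 1)];
    int* cur = &S[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      int u = prev[j] + gap;
      int l = cur[j - 1] + gap;
      int best = d >= u ? d : u;
      if (l > best) best = l;
      cur[j] = best;
    }
  }
  NwResult res;
  res.score = at(n, m);
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        at(i, j) == at(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && at(i, j) == at(i - 1, j) + gap) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  res.matches = matches;
  res.columns = columns;
  return res;
}

// Alignments are computed with the lexicographically smaller sequence first:
// the score is orientation-independent anyway, and this makes the identity of
// the deterministically recovered optimal alignment symmetric as well.
static NwResult nw_canonical(const std::string& a, const std::string& b,
                             int match, int mismatch, int gap) {
  return (a <= b) ? nw_core(a, b, match, mismatch, gap)
                  : nw_core(b, a, match, mismatch, gap);
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
NumericVector nw_align_cpp(std::string a, std::string b,
                           int match, int mismatch, int gap) {
  NwResult r = nw_canonical(a, b, match, mismatch, gap);
  return NumericVector::create(
      _["identity"] = r.columns > 0 ? (double)r.matches / r.columns : 1.0,
      _["score"] = (double)r.score,
      _["matches"] = (double)r.matches,
      _["columns"] = (double)r.columns);
}

// [[Rcpp::export(name = ".nw_identity_matrix_cpp")]]
NumericMatrix nw_identity_matrix_cpp(CharacterVector a, CharacterVector b,
                                     int match, int mismatch, int gap) {
  NumericMatrix out(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i) {
    std::string ai = as<std::string>(a[i]);
    for (int j = 0; j < b.size(); ++j) {
      std::string bj = as<std::string>(b[j]);
      NwResult r = nw_canonical(ai, bj, match, mismatch, gap);
      out(i, j) = r.columns > 0 ? (double)r.matches / r.columns : 1.0;
    }
  }
  return out;
}

// --- k-mer prescreen -------------------------------------------------------
// Sound upper-bound filter for "NW identity >= t". If an optimal alignment has
// identity M/c >= t with d = c - M non-match columns, then d <= Lmin*(1-t)/t,
// M >= t*Lmax, and the shared-8mer multiset count T satisfies
// T >= M - (d+1)*(k-1) >= t*Lmax - (d_max+1)*(k-1). Observing T below that
// bound proves identity < t, so NW can be skipped. A slack of 2 guards float
// rounding. Windows containing non-ACGT characters are simply not emitted,
// which can only lower T for both sequences symmetrically but may weaken the
// bound; sequences shorter than k skip the prescreen entirely.

static const int KMER_K = 8;

static void kmerize(const std::string& s, std::vector<uint32_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < KMER_K) return;
  out.reserve(n - KMER_K + 1);
  for (int i = 0; i + KMER_K <= n; ++i) {
    uint32_t code = 0;
    bool ok = true;
    for (int j = 0; j < KMER_K; ++j) {
      int c;
      switch (s[i + j]) {
        case 'A': c = 0; break;
        case 'C': c = 1; break;
        case 'G': c = 2; break;
        case 'T': c = 3; break;
        default: ok = false; c = 0;
      }
      if (!ok) break;
      code = (code << 2) | (uint32_t)c;
    }
    if (ok) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
}

static int shared_kmers(const std::vector<uint32_t>& x,
                        const std::vector<uint32_t>& y) {
  size_t i = 0, j = 0;
  int c = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] == y[j]) { ++c; ++i; ++j; }
    else if (x[i] < y[j]) ++i;
    else ++j;
  }
  return c;
}

// Greedy centroid clustering over dereplicated sequences supplied in their
// canonical processing order. A sequence joins the FIRST centroid (creation
// order) whose NW identity meets the threshold, else founds a new centroid.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
List greedy_cluster_cpp(CharacterVector seqs, double threshold,
                        int match, int mismatch, int gap) {
  const int n = seqs.size();
  std::vector<std::string> sq(n);
  std::vector<std::vector<uint32_t> > km(n);
  for (int i = 0; i < n; ++i) {
    sq[i] = as<std::string>(seqs[i]);
    kmerize(sq[i], km[i]);
  }
  std::vector<int> centroid_of(n, -1);
  std::vector<double> ident(n, 1.0);
  std::vector<int> centroids;  // indices into seqs
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    int assigned = -1;
    double assigned_id = 1.0;
    const int Li = (int)sq[i].size();
    for (size_t c = 0; c < centroids.size(); ++c) {
      const int ci = centroids[c];
      const int Lc = (int)sq[ci].size();
      const int Lmin = std::min(Li, Lc), Lmax = std::max(Li, Lc);
      if ((double)Lmin / Lmax < threshold - eps) continue;  // terminal gaps alone kill it
      if (Lmin >= KMER_K && threshold > 0) {
        double dmax = std::floor(Lmin * (1.0 - threshold) / threshold);
        double minT = threshold * Lmax - (dmax + 1.0) * (KMER_K - 1) - 2.0;
        if (minT > 0 && shared_kmers(km[i], km[ci]) < minT) continue;
      }
      NwResult r = nw_canonical(sq[i], sq[ci], match, mismatch, gap);
      double id = r.columns > 0 ? (double)r.matches / r.columns : 1.0;
      if (id >= threshold - eps) {
        assigned = (int)c;
        assigned_id = id;
        break;
      }
    }
    if (assigned < 0) {
      centroids.push_back(i);
      centroid_of[i] = (int)centroids.size();  // 1-based cluster index
      ident[i] = 1.0;
    } else {
      centroid_of[i] = assigned + 1;
      ident[i] = assigned_id;
    }
  }
  IntegerVector cl(n);
  NumericVector idv(n);
  for (int i = 0; i < n; ++i) { cl[i] = centroid_of[i]; idv[i] = ident[i]; }
  IntegerVector ce(centroids.size());
  for (size_t c = 0; c < centroids.size(); ++c) ce[c] = centroids[c] + 1;
  return List::create(_["cluster"] = cl, _["identity"] = idv,
                      _["centroid_index"] = ce);
}
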