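#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Longest contiguous exact shared segment between two strings.
// Rolling single-row dynamic programme: O(len_a * len_b) time,
// O(min(len_a, len_b)) space.
static int lcs_len(const std::string& a, const std::string& b) {
  const std::string& s = (a.size() <= b.size()) ? a : b;   // short
  const std::string& l = (a.size() <= b.size()) ? b : a;   // long
  const int n = (int) s.size();
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  int best = 0;
  for (size_t i = 0; i < l.size(); ++i) {
    const char ci = l[i];
    for (int j = 1; j <= n; ++j) {
      if (ci == s[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".lcs_length_cpp")]]
IntegerVector lcs_length_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string sa = as<std::string>(a[i]);
    std::string sb = as<std::string>(b[i]);
    if (sa.empty() || sb.empty()) stop("empty sequence");
    out[i] = lcs_len(sa, sb);
  }
  return out;
}

// 2-bit encode a k-mer window; returns sorted unique k-mer codes.
static const int KMER = 21;
static std::vector<uint64_t> kmer_codes(const std::string& s) {
  std::vector<uint64_t> out;
  if ((int) s.size() < KMER) return out;
  uint64_t code = 0, mask = (1ULL << (2 * KMER)) - 1;
  int valid = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: b = -1;
    }
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    if (++valid >= KMER) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static bool share_kmer(const std::vector<uint64_t>& a,
                       const std::vector<uint64_t>& b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return true;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return false;
}

// All-pairs edge scan used by build_ssn(): evaluates every unordered pair
// and returns the pairs whose exact shared segment satisfies the coverage
// rule. When exactly one member of a pair is a short amplicon, coverage is
// tested on that member only. Two prefilters that cannot change the edge
// set: a length-ratio bound, and (when the required segment is at least
// KMER long) a shared-k-mer check -- a segment of length >= KMER implies a
// shared k-mer.
// [[Rcpp::export(name = ".ssn_edge_scan_cpp")]]
DataFrame ssn_edge_scan_cpp(CharacterVector seqs, LogicalVector short_amp,
                            double min_cov) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  std::vector<int> len(n);
  std::vector< std::vector<uint64_t> > km(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    if (s[i].empty()) stop("empty sequence at index %d", i + 1);
    len[i] = (int) s[i].size();
    km[i] = kmer_codes(s[i]);
  }
  std::vector<int> ia, ib, ml;
  std::vector<double> ca, cb;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // cheapest possible reject: even a full containment of the shorter
      // sequence cannot reach min_cov on the longer side (unless the
      // asymmetric short-amplicon rule waives that side)
      bool asym = (short_amp[i] != short_amp[j]);
      int shorter = std::min(len[i], len[j]);
      int longer  = std::max(len[i], len[j]);
      if (!asym && (double) shorter / (double) longer < min_cov) continue;
      // minimum segment length any edge would need
      double need = asym ? min_cov * (double) (short_amp[i] ? len[i] : len[j])
                         : min_cov * (double) longer;
      if (need >= (double) KMER && !share_kmer(km[i], km[j])) continue;
      int L = lcs_len(s[i], s[j]);
      if (L == 0) continue;
      double cov_i = (double) L / (double) len[i];
      double cov_j = (double) L / (double) len[j];
      bool ok;
      if (asym) {
        ok = short_amp[i] ? (cov_i >= min_cov) : (cov_j >= min_cov);
      } else {
        ok = (cov_i >= min_cov) && (cov_j >= min_cov);
      }
      if (ok) {
        ia.push_back(i + 1); ib.push_back(j + 1); ml.push_back(L);
        ca.push_back(cov_i); cb.push_back(cov_j);
      }
    }
  }
  return DataFrame::create(_["ia"] = ia, _["ib"] = ib,
                           _["match_len"] = ml,
                           _["coverage_a"] = ca, _["coverage_b"] = cb);
}
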