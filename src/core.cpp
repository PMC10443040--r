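#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Needleman-Wunsch global alignment with unit costs:
// match 0, mismatch 1, gap 2 (linear). Backtrace prefers the diagonal
// (mismatch over gap), then gaps in the reference (read insertion last),
// which places gaps as far left in the read as the optimum allows.
// Returns cost and a compact CIGAR over {=, X, I, D}; I consumes read only,
// D consumes reference only.
// [[Rcpp::export]]
List nw_align_cpp(std::string read, std::string ref) {
  const int n = read.size(), m = ref.size();
  const int GAP = 2, MIS = 1;
  std::vector<int> dp((n + 1) * (m + 1));
  std::vector<unsigned char> bt((n + 1) * (m + 1)); // 0 diag, 1 up(I), 2 left(D)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) { dp[at(i, 0)] = i * GAP; bt[at(i, 0)] = 1; }
  for (int j = 0; j <= m; ++j) { dp[at(0, j)] = j * GAP; bt[at(0, j)] = 2; }
  for (int i = 1; i <= n; ++i) {
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool match = is_acgt(ri) && ri == ref[j - 1];
      int best = dp[at(i - 1, j - 1)] + (match ? 0 : MIS);
      unsigned char dir = 0;
      const int up = dp[at(i - 1, j)] + GAP;
      if (up < best) { best = up; dir = 1; }
      const int left = dp[at(i, j - 1)] + GAP;
      if (left < best) { best = left; dir = 2; }
      dp[at(i, j)] = best;
      bt[at(i, j)] = dir;
    }
  }
  // backtrace
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir = (i == 0) ? 2 : (j == 0) ? 1 : bt[at(i, j)];
    if (dir == 0) {
      ops.push_back((is_acgt(read[i - 1]) && read[i - 1] == ref[j - 1]) ? '=' : 'X');
      --i; --j;
    } else if (dir == 1) {
      ops.push_back('I'); --i;
    } else {
      ops.push_back('D'); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // compress to CIGAR
  std::string cig;
  size_t k = 0;
  while (k < ops.size()) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cig += std::to_string(k2 - k);
    cig.push_back(ops[k]);
    k = k2;
  }
  return List::create(_["cost"] = dp[at(n, m)], _["cigar"] = cig);
}

// Overlap scan for read-pair merging. r2rc is the reverse complement of R2.
// All relative offsets d (start of r2rc minus start of r1) are scanned; an
// offset is a candidate if the overlap length is >= min_overlap and the
// number of mismatching overlap positions (difference or any non-ACGT) is
// <= max_mismatch. The candidate with the longest overlap wins; ties go to
// the smaller |d|, then to d >= 0. The merged sequence is the union of both
// reads, taking r1's base where the overlap disagrees.
// Returns NA when no candidate exists.
// [[Rcpp::export]]
CharacterVector merge_scan_cpp(CharacterVector r1v, CharacterVector r2rcv,
                               int max_mismatch, int min_overlap) {
  const int np = r1v.size();
  CharacterVector out(np);
  for (int p = 0; p < np; ++p) {
    std::string a = as<std::string>(r1v[p]);
    std::string b = as<std::string>(r2rcv[p]);
    const int n1 = a.size(), n2 = b.size();
    int best_ov = -1, best_d = 0;
    for (int d = -(n2 - 1); d <= n1 - 1; ++d) {
      const int lo = std::max(0, d);            // overlap start in r1 coords
      const int hi = std::min(n1, d + n2);      // overlap end (excl)
      const int ov = hi - lo;
      if (ov < min_overlap) continue;
      int mm = 0;
      for (int i = lo; i < hi; ++i) {
        const char ca = a[i], cb = b[i - d];
        if (ca != cb || !is_acgt(ca) || !is_acgt(cb)) {
          if (++mm > max_mismatch) break;
        }
      }
      if (mm > max_mismatch) continue;
      bool better = ov > best_ov;
      if (!better && ov == best_ov) {
        const int ad = d < 0 ? -d : d, abd = best_d < 0 ? -best_d : best_d;
        better = ad < abd || (ad == abd && d >= 0 && best_d < 0);
      }
      if (better) { best_ov = ov; best_d = d; }
    }
    if (best_ov < 0) {
      out[p] = NA_STRING;
      continue;
    }
    const int d = best_d;
    std::string merged;
    if (d > 0) merged = a.substr(0, d);
    else if (d < 0) merged = b.substr(0, -d);
    const int lo = std::max(0, d), hi = std::min(n1, d + n2);
    merged += a.substr(lo, hi - lo); // r1 wins inside the overlap
    if (d + n2 > n1) merged += b.substr(n1 - d);
    else if (n1 > hi) merged += a.substr(hi);
    out[p] = merged;
  }
  return out;
}

// Hamming distance of each sequence to a template of identical length.
// Returns NA for length-mismatched entries (caller raises).
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector seqs, std::string templ) {
  const int n = seqs.size();
  const int L = templ.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(seqs[k]);
    if ((int)s.size() != L) { out[k] = NA_INTEGER; continue; }
    int h = 0;
    for (int i = 0; i < L; ++i) if (s[i] != templ[i]) ++h;
    out[k] = h;
  }
  return out;
}
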