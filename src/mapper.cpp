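// Seed-and-extend ungapped read mapper over a 2-bit k-mer index.
// Mismatch-only alignment: synthetic reads carry substitutions, not indels.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct KmerIndex {
  std::string genome;
  int k;
  std::unordered_map<std::uint64_t, std::vector<int> > tbl;  // 0-based forward starts
};

// encode s[from .. from+k-1]; false if any non-ACGT base
bool encode_kmer(const std::string& s, int from, int k, std::uint64_t* key) {
  std::uint64_t v = 0;
  for (int i = from; i < from + k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (std::uint64_t)c;
  }
  *key = v;
  return true;
}

// Hamming distance of s placed at 0-based p0 on g; N (either side) mismatches
inline int count_mismatches(const std::string& g, const std::string& s, int p0) {
  int mm = 0;
  for (std::size_t i = 0; i < s.size(); ++i) {
    char a = g[p0 + i], b = s[i];
    if (a != b) ++mm;
    else if (base_code(a) < 0) ++mm;
  }
  return mm;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(std::string genome, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  if ((int)genome.size() < k) stop("genome shorter than k");
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  xp->genome = genome;
  xp->k = k;
  const std::string& g = xp->genome;
  const std::uint64_t mask = ((std::uint64_t)1 << (2 * k)) - 1;
  std::uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < (int)g.size(); ++i) {
    int c = base_code(g[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (std::uint64_t)c) & mask;
    if (++valid >= k) xp->tbl[key].push_back(i - k + 1);
  }
  return xp;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return xp->k;
}

// [[Rcpp::export]]
int cpp_index_genome_length(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return (int)xp->genome.size();
}

// Positions (1-based) where the k-mer occurs: "+" as given, "-" where its
// reverse complement matches the forward genome.
// [[Rcpp::export]]
List cpp_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<KmerIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("query length must equal index k");
  std::vector<int> pos;
  std::vector<std::string> strand;
  std::uint64_t key;
  if (encode_kmer(kmer, 0, xp->k, &key)) {
    std::unordered_map<std::uint64_t, std::vector<int> >::const_iterator it =
        xp->tbl.find(key);
    if (it != xp->tbl.end()) {
      for (std::size_t j = 0; j < it->second.size(); ++j) {
        pos.push_back(it->second[j] + 1);
        strand.push_back("+");
      }
    }
  }
  std::string rc = revcomp_str(kmer);
  if (encode_kmer(rc, 0, xp->k, &key)) {
    std::unordered_map<std::uint64_t, std::vector<int> >::const_iterator it =
        xp->tbl.find(key);
    if (it != xp->tbl.end()) {
      for (std::size_t j = 0; j < it->second.size(); ++j) {
        pos.push_back(it->second[j] + 1);
        strand.push_back("-");
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["strand"] = wrap(strand));
}

// Best ungapped end-to-end placement per read. Candidates come from seed
// k-mers spaced every floor(k/2) bases on both orientations; ties at the best
// mismatch count report the lowest coordinate with MAPQ 0.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp_, CharacterVector reads, double max_mismatch_frac) {
  XPtr<KmerIndex> xp(xp_);
  const std::string& g = xp->genome;
  const int k = xp->k;
  const int G = (int)g.size();
  const int n = reads.size();

  IntegerVector out_pos(n), out_mm(n), out_mapq(n);
  CharacterVector out_strand(n);
  LogicalVector out_mapped(n);

  const int step = std::max(1, k / 2);
  std::vector<std::pair<int, int> > cands;  // (pos0, strand 0='+' 1='-')

  for (int r = 0; r < n; ++r) {
    std::string fw = as<std::string>(reads[r]);
    const int L = (int)fw.size();
    out_pos[r] = NA_INTEGER;
    out_mm[r] = NA_INTEGER;
    out_mapq[r] = 0;
    out_strand[r] = NA_STRING;
    out_mapped[r] = false;
    if (L < k || L > G) continue;

    std::string rc = revcomp_str(fw);
    cands.clear();
    for (int sidx = 0; sidx < 2; ++sidx) {
      const std::string& s = (sidx == 0) ? fw : rc;
      int off = 0;
      for (;;) {
        std::uint64_t key;
        if (encode_kmer(s, off, k, &key)) {
          std::unordered_map<std::uint64_t, std::vector<int> >::const_iterator
              it = xp->tbl.find(key);
          if (it != xp->tbl.end()) {
            for (std::size_t j = 0; j < it->second.size(); ++j) {
              int p0 = it->second[j] - off;
              if (p0 >= 0 && p0 + L <= G) cands.push_back(std::make_pair(p0, sidx));
            }
          }
        }
        if (off == L - k) break;
        off = std::min(off + step, L - k);
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best = INT_MAX, second = INT_MAX, best_pos = -1, best_strand = 0, n_best = 0;
    for (std::size_t ci = 0; ci < cands.size(); ++ci) {
      const std::string& s = cands[ci].second ? rc : fw;
      int m = count_mismatches(g, s, cands[ci].first);
      if (m < best) {
        second = best;
        best = m;
        best_pos = cands[ci].first;
        best_strand = cands[ci].second;
        n_best = 1;
      } else if (m == best) {
        ++n_best;
        second = m;
      } else if (m < second) {
        second = m;
      }
    }

    const int max_mm = (int)std::floor(max_mismatch_frac * L + 1e-9);
    if (best > max_mm) continue;

    int q;
    if (n_best > 1) {
      q = 0;
    } else if (second == INT_MAX) {
      q = 60;
    } else {
      double ratio = (double)(L - second) / (double)(L - best);
      q = (int)std::floor(60.0 * (1.0 - ratio) + 0.5);
      if (q < 0) q = 0;
      if (q > 60) q = 60;
    }
    out_pos[r] = best_pos + 1;
    out_strand[r] = best_strand ? "-" : "+";
    out_mm[r] = best;
    out_mapq[r] = q;
    out_mapped[r] = true;
  }

  return DataFrame::create(_["pos"] = out_pos, _["strand"] = out_strand,
                           _["mismatches"] = out_mm, _["mapq"] = out_mapq,
                           _["mapped"] = out_mapped,
                           _["stringsAsFactors"] = false);
}

// Mismatch count of query at every start on subject (used by the fusion
// scanner, where junction sequences are short enough for exhaustive scans).
// [[Rcpp::export]]
IntegerVector cpp_hamming_profile(std::string subject, std::string query) {
  const int S = (int)subject.size(), Q = (int)query.size();
  if (Q > S) return IntegerVector(0);
  IntegerVector out(S - Q + 1);
  for (int p = 0; p <= S - Q; ++p) out[p] = count_mismatches(subject, query, p);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }
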