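// Pileup over ungapped alignments: per-base counts genome-wide, then full
// observation vectors at candidate sites (>= min_alt reads of one non-ref
// base). Mirrors an mpileup-style candidate screen so genotype likelihoods
// only need evaluating where variant evidence exists.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {
inline int base_code5(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N
  }
}
const char BASES[5] = {'A', 'C', 'G', 'T', 'N'};
}  // namespace

// [[Rcpp::export]]
List cpp_pileup_candidates(std::string genome, IntegerVector pos,
                           CharacterVector seq, CharacterVector qual,
                           IntegerVector mapq, LogicalVector rev,
                           int min_alt) {
  const int G = (int)genome.size();
  const int n = pos.size();
  std::vector<int> cnt(5L * (G + 1), 0);
  std::vector<int> depth(G + 1, 0);
  long clipped = 0;

  for (int i = 0; i < n; ++i) {
    if (pos[i] == NA_INTEGER) stop("unmapped record in pileup input");
    const char* s = CHAR(STRING_ELT(seq, i));
    int L = (int)LENGTH(STRING_ELT(seq, i));
    int p = pos[i];
    for (int j = 0; j < L; ++j) {
      int gp = p + j;
      if (gp < 1 || gp > G) { ++clipped; continue; }
      ++cnt[5L * gp + base_code5(s[j])];
      ++depth[gp];
    }
  }

  // candidate sites: top non-ref ACGT count >= min_alt
  std::vector<int> cand_pos;
  std::vector<int> cand_id(G + 1, -1);
  for (int gp = 1; gp <= G; ++gp) {
    if (depth[gp] == 0) continue;
    int refc = base_code5(genome[gp - 1]);
    int top_alt = 0;
    for (int c = 0; c < 4; ++c) {
      if (c == refc) continue;
      if (cnt[5L * gp + c] > top_alt) top_alt = cnt[5L * gp + c];
    }
    if (top_alt >= min_alt) {
      cand_id[gp] = (int)cand_pos.size();
      cand_pos.push_back(gp);
    }
  }

  const int nc = (int)cand_pos.size();
  IntegerVector site_pos(nc), site_depth(nc);
  CharacterVector site_ref(nc);
  for (int i = 0; i < nc; ++i) {
    site_pos[i] = cand_pos[i];
    site_depth[i] = depth[cand_pos[i]];
    site_ref[i] = std::string(1, genome[cand_pos[i] - 1]);
  }

  // second pass: collect per-observation data at candidate sites
  std::vector<int> o_site, o_bq, o_mq, o_end;
  std::vector<char> o_base;
  std::vector<int> o_rev;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    int L = (int)LENGTH(STRING_ELT(seq, i));
    int p = pos[i];
    for (int j = 0; j < L; ++j) {
      int gp = p + j;
      if (gp < 1 || gp > G) continue;
      int id = cand_id[gp];
      if (id < 0) continue;
      o_site.push_back(id + 1);
      o_base.push_back(s[j]);
      o_bq.push_back((int)q[j] - 33);
      o_mq.push_back(mapq[i]);
      o_rev.push_back(rev[i] ? 1 : 0);
      int d = j + 1 < L - j ? j + 1 : L - j;  // distance to nearer read end
      o_end.push_back(d);
    }
  }

  const int no = (int)o_site.size();
  CharacterVector obs_base(no);
  for (int i = 0; i < no; ++i) obs_base[i] = std::string(1, o_base[i]);

  return List::create(
      _["pos"] = site_pos, _["ref"] = site_ref, _["depth"] = site_depth,
      _["obs_site"] = wrap(o_site), _["obs_base"] = obs_base,
      _["obs_bq"] = wrap(o_bq), _["obs_mq"] = wrap(o_mq),
      _["obs_rev"] = wrap(o_rev), _["obs_end"] = wrap(o_end),
      _["clipped"] = (double)clipped);
}
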