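// Exact canonical k-mer read assignment.
//
// A read is assigned to the contig sharing the most k-mers with it: each of
// the read's k-mer positions contributes 1 to every contig containing that
// canonical k-mer (a k-mer and its reverse complement are one key). Ties go
// to the contig earliest in the supplied order (callers pass contigs sorted
// by contig_id, giving the documented lexicographic tie-break). The read's
// placement is the modal seed diagonal (contig position minus read position)
// on the winning contig, ties to the smallest diagonal.
//
// kmer_assign_multi_cpp indexes the contigs once and assigns several read
// libraries against the same index.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct IdentityHash {
  size_t operator()(uint64_t x) const noexcept {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL; x ^= x >> 33;
    return (size_t)x;
  }
};

typedef std::unordered_map<uint64_t,
                           std::vector<std::pair<int32_t, int32_t>>,
                           IdentityHash> KmerIndex;

static void build_index(KmerIndex& index, const CharacterVector& contigs,
                        int k, uint64_t mask, int shift_rc) {
  size_t total = 0;
  for (int ci = 0; ci < contigs.size(); ++ci)
    total += LENGTH(STRING_ELT(contigs, ci));
  index.reserve(total);
  for (int ci = 0; ci < contigs.size(); ++ci) {
    const char* s = CHAR(STRING_ELT(contigs, ci));
    int len = LENGTH(STRING_ELT(contigs, ci));
    if (len < k) continue;
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; fwd = rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        index[canon].emplace_back(ci, i - k + 1);
      }
    }
  }
}

static DataFrame assign_reads(const KmerIndex& index,
                              const CharacterVector& reads, int nc, int k,
                              uint64_t mask, int shift_rc) {
  const int nr = reads.size();
  IntegerVector best_contig(nr), shared(nr), pos(nr);
  std::vector<int> cnt(nc, 0), stamp(nc, -1);
  std::vector<int32_t> touched;
  std::vector<std::pair<int32_t, int32_t>> seeds;  // (contig, diagonal)

  for (int ri = 0; ri < nr; ++ri) {
    const char* s = CHAR(STRING_ELT(reads, ri));
    int len = LENGTH(STRING_ELT(reads, ri));
    touched.clear();
    seeds.clear();
    if (len >= k) {
      uint64_t fwd = 0, rc = 0;
      int valid = 0;
      for (int i = 0; i < len; ++i) {
        int b = base_code(s[i]);
        if (b < 0) { valid = 0; fwd = rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
        if (++valid >= k) {
          uint64_t canon = fwd < rc ? fwd : rc;
          auto it = index.find(canon);
          if (it == index.end()) continue;
          int rpos = i - k + 1;
          // occurrences are grouped by contig (built in contig order):
          // count at most 1 per contig for this read position
          int32_t prev = -1;
          for (auto& occ : it->second) {
            seeds.emplace_back(occ.first, occ.second - rpos);
            if (occ.first == prev) continue;
            prev = occ.first;
            if (stamp[occ.first] != ri) {
              stamp[occ.first] = ri; cnt[occ.first] = 0;
              touched.push_back(occ.first);
            }
            cnt[occ.first] += 1;
          }
        }
      }
    }
    int best = -1, bestCnt = 0;
    for (int32_t ci : touched) {
      if (cnt[ci] == 0) continue;
      if (best < 0 || cnt[ci] > bestCnt || (cnt[ci] == bestCnt && ci < best)) {
        best = ci; bestCnt = cnt[ci];
      }
    }
    if (best < 0) {
      best_contig[ri] = NA_INTEGER; shared[ri] = 0; pos[ri] = NA_INTEGER;
      continue;
    }
    // modal diagonal on the winning contig, ties to the smallest diagonal
    std::unordered_map<int32_t, int> diag;
    for (auto& sd : seeds)
      if (sd.first == best) diag[sd.second] += 1;
    int32_t bestDiag = 0; int bestDiagCnt = -1;
    for (auto& d : diag)
      if (d.second > bestDiagCnt ||
          (d.second == bestDiagCnt && d.first < bestDiag)) {
        bestDiag = d.first; bestDiagCnt = d.second;
      }
    best_contig[ri] = best + 1;  // 1-based for R
    shared[ri] = bestCnt;
    pos[ri] = bestDiag;
  }

  return DataFrame::create(_["contig"] = best_contig, _["shared"] = shared,
                           _["pos"] = pos);
}

// [[Rcpp::export]]
DataFrame kmer_assign_cpp(CharacterVector reads, CharacterVector contigs,
                          int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);
  KmerIndex index;
  build_index(index, contigs, k, mask, shift_rc);
  return assign_reads(index, reads, contigs.size(), k, mask, shift_rc);
}

// [[Rcpp::export]]
List kmer_assign_multi_cpp(List read_sets, CharacterVector contigs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);
  KmerIndex index;
  build_index(index, contigs, k, mask, shift_rc);
  List out(read_sets.size());
  for (int i = 0; i < read_sets.size(); ++i)
    out[i] = assign_reads(index, as<CharacterVector>(read_sets[i]),
                          contigs.size(), k, mask, shift_rc);
  out.names() = read_sets.names();
  return out;
}
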