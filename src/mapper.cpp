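// Exact short-fragment mapper: non-overlapping exact seeds + full Hamming
// verification on both strands. With seed length k <= floor(len/(m+1)) the
// pigeonhole principle guarantees every placement with <= m mismatches over
// {A,C,G,T} carries at least one exact seed, so the search is equivalent to
// an all-positions Hamming scan. N never matches anything (closed alphabet).
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct KmerEntry {
  uint64_t kmer;
  uint32_t gpos; // global position in concatenated target
  bool operator<(const KmerEntry& o) const {
    return kmer < o.kmer || (kmer == o.kmer && gpos < o.gpos);
  }
};

class TargetIndex {
public:
  std::vector<std::string> seqs;
  std::vector<uint64_t> offsets; // global offset of each chrom
  uint64_t total;
  int k;
  std::vector<KmerEntry> entries;

  TargetIndex(const std::vector<std::string>& s, int k_) : seqs(s), k(k_) {
    total = 0;
    for (size_t i = 0; i < seqs.size(); ++i) {
      offsets.push_back(total);
      total += seqs[i].size();
    }
    build();
  }

  void build() {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (size_t c = 0; c < seqs.size(); ++c) {
      const std::string& s = seqs[c];
      if ((int)s.size() < k) continue;
      uint64_t kmer = 0;
      int valid = 0; // length of current N-free suffix
      for (size_t i = 0; i < s.size(); ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          KmerEntry e;
          e.kmer = kmer;
          e.gpos = (uint32_t)(offsets[c] + i - k + 1);
          entries.push_back(e);
        }
      }
    }
    std::sort(entries.begin(), entries.end());
  }

  // chrom index for a global position
  int chrom_of(uint64_t g) const {
    int lo = 0, hi = (int)offsets.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (offsets[mid] <= g) lo = mid; else hi = mid - 1;
    }
    return lo;
  }

  void lookup(uint64_t kmer, std::vector<uint32_t>& out) const {
    KmerEntry key; key.kmer = kmer; key.gpos = 0;
    auto it = std::lower_bound(entries.begin(), entries.end(), key);
    for (; it != entries.end() && it->kmer == kmer; ++it) out.push_back(it->gpos);
  }
};

static bool encode_kmer(const std::string& s, size_t from, int k, uint64_t& kmer) {
  kmer = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[from + i]);
    if (b < 0) return false;
    kmer = (kmer << 2) | (uint64_t)b;
  }
  return true;
}

static int hamming_at(const std::string& target, size_t pos,
                      const std::string& frag, int maxmm) {
  int mm = 0;
  for (size_t i = 0; i < frag.size(); ++i) {
    char t = target[pos + i], f = frag[i];
    if (t != f || t == 'N') {
      if (++mm > maxmm) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_map_fragments(CharacterVector target_seqs,
                            CharacterVector fragment_seqs,
                            int max_mismatches,
                            int seed_len) {
  std::vector<std::string> tgt(target_seqs.size());
  for (int i = 0; i < target_seqs.size(); ++i) tgt[i] = as<std::string>(target_seqs[i]);
  TargetIndex idx(tgt, seed_len);

  std::vector<int> out_frag, out_chrom, out_start, out_mm, out_nbest;
  std::vector<std::string> out_strand;

  std::vector<uint32_t> hits;
  for (int f = 0; f < fragment_seqs.size(); ++f) {
    std::string fwd = as<std::string>(fragment_seqs[f]);
    int flen = (int)fwd.size();
    if (flen < seed_len) continue;
    std::string rev(flen, 'N');
    for (int i = 0; i < flen; ++i) rev[flen - 1 - i] = comp(fwd[i]);

    // candidate placements: (strand, chrom, local start, mismatches)
    struct Cand { int strand; int chrom; int start; int mm; };
    std::vector<Cand> cands;
    int best = max_mismatches + 1;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& frag = strand == 0 ? fwd : rev;
      std::unordered_set<uint64_t> seen; // starts already verified this strand
      int nseeds = flen / seed_len;
      for (int s = 0; s < nseeds; ++s) {
        size_t off = (size_t)s * seed_len;
        uint64_t kmer;
        if (!encode_kmer(frag, off, seed_len, kmer)) continue;
        hits.clear();
        idx.lookup(kmer, hits);
        for (uint32_t g : hits) {
          if ((uint64_t)g < off) continue;
          uint64_t gstart = (uint64_t)g - off;
          int c = idx.chrom_of(gstart);
          uint64_t local = gstart - idx.offsets[c];
          if (local + flen > idx.seqs[c].size()) continue;
          if (!seen.insert(gstart).second) continue;
          int mm = hamming_at(idx.seqs[c], (size_t)local, frag, max_mismatches);
          if (mm <= max_mismatches) {
            Cand cd; cd.strand = strand; cd.chrom = c; cd.start = (int)local; cd.mm = mm;
            cands.push_back(cd);
            if (mm < best) best = mm;
          }
        }
      }
    }
    if (best > max_mismatches) continue;
    int nbest = 0;
    for (auto& cd : cands) if (cd.mm == best) ++nbest;
    for (auto& cd : cands) {
      if (cd.mm != best) continue;
      out_frag.push_back(f + 1);
      out_chrom.push_back(cd.chrom + 1);
      out_start.push_back(cd.start);
      out_strand.push_back(cd.strand == 0 ? "+" : "-");
      out_mm.push_back(cd.mm);
      out_nbest.push_back(nbest);
    }
  }

  return DataFrame::create(
    _["fragment"] = out_frag,
    _["chrom_index"] = out_chrom,
    _["start"] = out_start,
    _["strand"] = out_strand,
    _["mismatches"] = out_mm,
    _["n_best_locations"] = out_nbest,
    _["stringsAsFactors"] = false);
}
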