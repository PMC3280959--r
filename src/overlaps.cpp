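// Suffix-prefix overlap detection between pooled sequencing reads.
//
// An edge joins two reads when some suffix-prefix arrangement of the pair
// (either read on the left, either strand) aligns over >= min_overlap bases
// with a mismatch fraction <= max_mismatch_rate (0 = exact match).
//
// Strategy: index short exact seed words taken from the prefix of every read
// in both orientations, slide a rolling 2-bit-packed window along each read
// (again both orientations), and verify every seed hit over the full implied
// overlap. With mismatch rate 0 a single seed of length min(min_overlap, 31)
// suffices; in permissive mode several shorter seeds are planted across the
// first min_overlap bases so that a seed survives scattered substitutions.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N or other ambiguity codes never match
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

struct SeedHit {
  int32_t read;
  uint8_t strand;   // 0 forward, 1 reverse complement
  uint16_t offset;  // seed start within the read prefix
};

// count mismatches between a[qa..qa+m) and b[0..m); bail early past 'allowed'
static inline int mismatches(const std::string& a, int qa, const std::string& b,
                             int m, int allowed) {
  int mm = 0;
  for (int t = 0; t < m; ++t) {
    char x = a[qa + t], y = b[t];
    if (x != y || base2bits(x) < 0) {
      if (++mm > allowed) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List overlap_edges_seq_cpp(CharacterVector reads, int min_overlap,
                           double max_mismatch_rate) {
  const int n = reads.size();
  std::vector<std::string> seq(2 * n);  // [2i] forward, [2i+1] revcomp
  for (int i = 0; i < n; ++i) {
    seq[2 * i] = as<std::string>(reads[i]);
    seq[2 * i + 1] = revcomp(seq[2 * i]);
  }

  int seed_len;
  std::vector<int> offsets;
  if (max_mismatch_rate <= 0.0) {
    seed_len = std::min(min_overlap, 31);
    offsets.push_back(0);
  } else {
    seed_len = std::min(min_overlap, 12);
    // several short seeds planted across the first min_overlap bases, so a
    // true overlap survives scattered substitutions with high probability
    for (int o = 0; o + seed_len <= min_overlap && (int)offsets.size() < 4;
         o += seed_len + 1)
      offsets.push_back(o);
  }
  const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);

  std::unordered_multimap<uint64_t, SeedHit> index;
  index.reserve((size_t)4 * n * offsets.size());
  for (int i = 0; i < n; ++i) {
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = seq[2 * i + strand];
      for (int off : offsets) {
        if (off + seed_len > (int)s.size()) continue;
        uint64_t h = 0;
        bool ok = true;
        for (int t = 0; t < seed_len; ++t) {
          int b = base2bits(s[off + t]);
          if (b < 0) { ok = false; break; }
          h = (h << 2) | (uint64_t)b;
        }
        if (ok)
          index.emplace(h, SeedHit{(int32_t)i, (uint8_t)strand, (uint16_t)off});
      }
    }
  }

  std::unordered_set<uint64_t> edges;
  edges.reserve(1 << 20);

  for (int a = 0; a < n; ++a) {
    for (int astrand = 0; astrand < 2; ++astrand) {
      const std::string& A = seq[2 * a + astrand];
      const int lenA = (int)A.size();
      if (lenA < seed_len) continue;
      uint64_t h = 0;
      int valid = 0;  // number of consecutive valid bases ending at current pos
      for (int p = 0; p < lenA; ++p) {
        int b = base2bits(A[p]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++valid < seed_len) continue;
        const int wstart = p - seed_len + 1;  // seed window start in A
        auto range = index.equal_range(h);
        for (auto it = range.first; it != range.second; ++it) {
          const SeedHit& hit = it->second;
          if (hit.read == a) continue;
          const int q = wstart - hit.offset;  // overlap start in A
          if (q < 0) continue;
          const std::string& B = seq[2 * hit.read + hit.strand];
          int m = lenA - q;
          if (m > (int)B.size()) m = (int)B.size();
          if (m < min_overlap) continue;
          uint64_t key = (uint64_t)std::min(a, (int)hit.read) * (uint64_t)n +
                         (uint64_t)std::max(a, (int)hit.read);
          if (edges.count(key)) continue;
          int allowed = (int)(max_mismatch_rate * m);
          if (mismatches(A, q, B, m, allowed) <= allowed) edges.insert(key);
        }
      }
    }
  }

  const size_t ne = edges.size();
  IntegerVector from(ne), to(ne);
  size_t j = 0;
  for (uint64_t key : edges) {
    from[j] = (int)(key / n) + 1;  // 1-based for R
    to[j] = (int)(key % n) + 1;
    ++j;
  }
  return List::create(_["from"] = from, _["to"] = to);
}

// Positional overlap: reads given as (genome, start, length); edge when two
// reads on the same genome physically overlap by strictly more than
// min_overlap bases. Sorted sweep per genome.
// [[Rcpp::export]]
List overlap_edges_pos_cpp(IntegerVector genome, IntegerVector start,
                           IntegerVector len, int min_overlap) {
  const int n = genome.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (genome[a] != genome[b]) return genome[a] < genome[b];
    return start[a] < start[b];
  });
  std::vector<int> from, to;
  for (int ii = 0; ii < n; ++ii) {
    const int i = ord[ii];
    const int gi = genome[i], si = start[i], ei = si + len[i];
    for (int jj = ii + 1; jj < n; ++jj) {
      const int j = ord[jj];
      if (genome[j] != gi) break;
      if (start[j] >= ei - min_overlap) break;  // overlap <= min_overlap
      const int ov = std::min(ei, start[j] + len[j]) - start[j];
      if (ov > min_overlap) {
        from.push_back(i + 1);
        to.push_back(j + 1);
      }
    }
  }
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to));
}
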