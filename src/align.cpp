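// Semi-global (overlap, end-gaps-free) pairwise alignment kernel.
//
// Queries are amplicon substrings of the references, so the true diagonal
// is found by 12-mer diagonal voting and the DP is banded around it
// (default +/- 16, generous for the indel rates of amplicon reads); when
// no seed exists the full DP matrix is used.  Distance statistics are
// collected over the aligned columns where both sequences carry a plain
// base: column count, mismatches, and transitions (for the Kimura
// two-parameter correction).  Scoring: match +1, mismatch -1, gap -2
// (linear); end gaps on either sequence are free.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // ambiguous: aligned but excluded from counts
  }
}

enum { NONE = 0, DIAG = 1, UP = 2, LEFT = 3 };
static const int NEG_INF = -100000000;
static const int KMER = 12;

// positions of each 2-bit-encoded 12-mer of the reference
typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static void index_kmers(const std::vector<int> &code, KmerIndex &idx) {
  const int n = (int)code.size();
  uint32_t key = 0, mask = (1u << (2 * KMER)) - 1u;
  int run = 0;
  for (int j = 0; j < n; ++j) {
    if (code[j] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)code[j]) & mask;
    if (++run >= KMER) idx[key].push_back(j - KMER + 1);
  }
}

static int vote_diagonal(const std::vector<int> &qc, const KmerIndex &idx,
                         int *max_votes) {
  std::unordered_map<int, int> votes;
  const int m = (int)qc.size();
  uint32_t key = 0, mask = (1u << (2 * KMER)) - 1u;
  int run = 0, best_d = 0, best_v = 0;
  for (int i = 0; i < m; ++i) {
    if (qc[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)qc[i]) & mask;
    if (++run < KMER) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<int> &pos = it->second;
    for (size_t t = 0; t < pos.size(); ++t) {
      int d = pos[t] - (i - KMER + 1);
      int v = ++votes[d];
      if (v > best_v) { best_v = v; best_d = d; }
    }
  }
  *max_votes = best_v;
  return best_d;
}

// banded semi-global alignment of q against r around diagonal d0;
// fills stats = {aligned_cols, mismatches, transitions}
static void align_banded(const std::vector<int> &qc,
                         const std::vector<int> &rc,
                         int d0, int band, int stats[3]) {
  const int m = (int)qc.size(), n = (int)rc.size();
  const int MATCH = 1, MIS = -1, GAP = -2;
  const int W = 2 * band + 1;

  std::vector<int> prev(n + 2, NEG_INF), cur(n + 2, NEG_INF);
  std::vector<int> lastcol(m + 1, NEG_INF);
  std::vector<unsigned char> tb((size_t)(m + 1) * W, NONE);

  // row 0: free leading reference gap within the band
  {
    int lo = std::max(0, d0 - band), hi = std::min(n, d0 + band);
    for (int j = lo; j <= hi; ++j) prev[j] = 0;
    if (hi == n) lastcol[0] = 0;
  }

  for (int i = 1; i <= m; ++i) {
    const int center = i + d0;
    const int lo = std::max(1, center - band);
    const int hi = std::min(n, center + band);
    if (lo > hi) continue;  // band does not intersect this row
    cur[lo - 1] = (lo - 1 == 0) ? 0 : NEG_INF;  // free leading query gap
    unsigned char *tbrow = &tb[(size_t)i * W];
    for (int j = lo; j <= hi; ++j) {
      int s = (qc[i - 1] >= 0 && rc[j - 1] >= 0)
                  ? (qc[i - 1] == rc[j - 1] ? MATCH : MIS)
                  : 0;
      int d = prev[j - 1] + s;
      int u = prev[j] + GAP;
      int l = cur[j - 1] + GAP;
      int best = d;
      unsigned char dir = DIAG;
      if (u > best) { best = u; dir = UP; }
      if (l > best) { best = l; dir = LEFT; }
      cur[j] = best;
      tbrow[j - center + band] = dir;
    }
    if (hi + 1 <= n + 1) cur[hi + 1] = NEG_INF;
    if (lo - 2 >= 0) cur[lo - 2] = NEG_INF;
    if (hi == n) lastcol[i] = cur[n];
    std::swap(prev, cur);
  }

  // best end cell: last row (within its band) or last column
  int bi = -1, bj = -1, bscore = NEG_INF;
  {
    const int center = m + d0;
    const int lo = std::max(0, center - band);
    const int hi = std::min(n, center + band);
    for (int j = lo; j <= hi; ++j)
      if (prev[j] > bscore) { bscore = prev[j]; bi = m; bj = j; }
  }
  for (int i = 0; i <= m; ++i)
    if (lastcol[i] > bscore) { bscore = lastcol[i]; bi = i; bj = n; }

  int aligned = 0, mism = 0, trans = 0;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
      int c = j - (i + d0) + band;
      if (c < 0 || c >= W) break;  // fell off the band edge: stop
      unsigned char dir = tb[(size_t)i * W + c];
      if (dir == DIAG) {
        int a = qc[i - 1], b = rc[j - 1];
        if (a >= 0 && b >= 0) {
          ++aligned;
          if (a != b) {
            ++mism;
            if ((a ^ b) == 2) ++trans;  // A<->G (0,2), C<->T (1,3)
          }
        }
        --i; --j;
      } else if (dir == UP) {
        --i;
      } else if (dir == LEFT) {
        --j;
      } else {
        break;  // reached a free edge inside the band
      }
    }
  }
  stats[0] = aligned; stats[1] = mism; stats[2] = trans;
}

// [[Rcpp::export(name = ".align_stats_cpp")]]
IntegerMatrix align_stats_cpp(CharacterVector queries, std::string ref,
                              int band = 16) {
  const int nq = queries.size();
  IntegerMatrix out(nq, 3);
  colnames(out) = CharacterVector::create("aligned", "mismatch",
                                          "transition");
  const int n = (int)ref.size();
  std::vector<int> rc(n);
  for (int j = 0; j < n; ++j) rc[j] = base_code(ref[j]);
  KmerIndex idx;
  index_kmers(rc, idx);

  for (int qi = 0; qi < nq; ++qi) {
    const std::string q = as<std::string>(queries[qi]);
    const int m = (int)q.size();
    std::vector<int> qc(m);
    for (int i = 0; i < m; ++i) qc[i] = base_code(q[i]);

    int votes = 0;
    int d0 = vote_diagonal(qc, idx, &votes);
    int stats[3];
    if (votes >= 3) {
      align_banded(qc, rc, d0, band, stats);
    } else {
      // no reliable seed: full-width band centered to cover the matrix
      int full_d0 = (n - m) / 2;
      int full_band = (n + m) / 2 + 2;
      align_banded(qc, rc, full_d0, full_band, stats);
    }
    out(qi, 0) = stats[0];
    out(qi, 1) = stats[1];
    out(qi, 2) = stats[2];
  }
  return out;
}
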