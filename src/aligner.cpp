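#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside {A,C,G,T}
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// Counting-sort k-mer index over a set of fragments: offsets[code]..offsets[code+1]
// delimit postings (fragment ordinal, offset) for that k-mer. Forward strand only.
// [[Rcpp::export]]
List cpp_build_kmer_index(CharacterVector frags, int k) {
  if (k < 1 || k > 13) stop("k-mer size must be between 1 and 13");
  const int nfrag = frags.size();
  const R_xlen_t nslots = (R_xlen_t(1) << (2 * k)) + 1;
  IntegerVector offsets(nslots, 0);
  const int mask = (k == 16) ? -1 : ((1 << (2 * k)) - 1);

  // pass 1: count valid k-mers per code
  std::vector<std::string> seqs(nfrag);
  for (int f = 0; f < nfrag; ++f) seqs[f] = as<std::string>(frags[f]);
  long total = 0;
  for (int f = 0; f < nfrag; ++f) {
    const std::string& s = seqs[f];
    int code = 0, run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++run >= k) { offsets[code + 1]++; total++; }
    }
  }
  for (R_xlen_t i = 1; i < nslots; ++i) offsets[i] += offsets[i - 1];

  // pass 2: fill postings
  IntegerVector post_frag(total), post_pos(total);
  std::vector<int> cursor(offsets.begin(), offsets.end() - 1);
  for (int f = 0; f < nfrag; ++f) {
    const std::string& s = seqs[f];
    int code = 0, run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++run >= k) {
        int slot = cursor[code]++;
        post_frag[slot] = f + 1;              // 1-based fragment ordinal
        post_pos[slot] = (int)i - k + 1;      // 0-based k-mer start
      }
    }
  }
  return List::create(_["offsets"] = offsets,
                      _["frag"] = post_frag,
                      _["pos"] = post_pos,
                      _["k"] = k);
}

// Postings for one k-mer string; empty matrix if absent or invalid.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_postings(IntegerVector offsets, IntegerVector post_frag,
                                IntegerVector post_pos, int k, std::string kmer) {
  if ((int)kmer.size() != k) stop("query length must equal indexed k");
  int code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) return IntegerMatrix(0, 2);
    code = (code << 2) | b;
  }
  int lo = offsets[code], hi = offsets[code + 1];
  IntegerMatrix out(hi - lo, 2);
  for (int i = lo; i < hi; ++i) {
    out(i - lo, 0) = post_frag[i];
    out(i - lo, 1) = post_pos[i];
  }
  colnames(out) = CharacterVector::create("frag", "pos");
  return out;
}

// Banded affine-gap local alignment restricted to diagonals [dlo, dhi]
// (diagonal d = ref_pos - query_pos). Gap of length L costs open + L*extend.
// Operates on 2-bit-encoded sequences; NEG is deep enough that subtracting
// gap costs never underflows int.
static int banded_sw_enc(const int8_t* q, int m, const int8_t* r, int n,
                         int dlo, int dhi,
                         int match, int mismatch, int gap_open, int gap_extend) {
  const int NEG = -(1 << 28);
  if (m == 0 || n == 0) return 0;
  if (dlo < -(m - 1)) dlo = -(m - 1);
  if (dhi > n - 1) dhi = n - 1;
  if (dlo > dhi) return 0;
  const int W = dhi - dlo + 1;
  const int goe = gap_open + gap_extend;
  std::vector<int> Hprev(W + 1, 0), Fprev(W + 1, NEG), Hcur(W + 1, NEG), Fcur(W + 1, NEG);
  int best = 0;
  for (int i = 0; i < m; ++i) {
    // valid ref positions this row: j in [max(0, i+dlo), min(n-1, i+dhi)]
    int blo = (i + dlo < 0) ? -(i + dlo) : 0;
    int bhi = (i + dhi > n - 1) ? (n - 1 - i - dlo) : W - 1;
    if (blo > W) blo = W;
    if (bhi < -1) bhi = -1;
    if (blo > 0 && blo <= W) { Hcur[blo - 1] = NEG; Fcur[blo - 1] = NEG; }
    int Eleft = NEG;
    const int8_t qi = q[i];
    for (int b = blo; b <= bhi; ++b) {
      const int j = i + dlo + b;
      int diag = Hprev[b]; // (i-1, j-1): same band offset in previous row
      if (diag < 0) diag = 0; // local: fresh start anywhere (also masks NEG)
      int h = diag + (qi == r[j] ? match : mismatch);
      const int f = std::max(Hprev[b + 1] - goe, Fprev[b + 1] - gap_extend);
      if (Eleft > h) h = Eleft;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hcur[b] = h;
      Fcur[b] = f;
      Eleft = std::max(h - goe, Eleft - gap_extend);
      if (h > best) best = h;
    }
    if (bhi + 1 >= 0 && bhi + 1 <= W) { // cells beyond the band are unreachable
      Hcur[bhi + 1] = NEG;
      Fcur[bhi + 1] = NEG;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// sentinel: code for non-ACGT bases; query and reference use different
// sentinels so an N never matches anything
static std::vector<int8_t> encode_seq(const std::string& s, int8_t sentinel) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    v[i] = b < 0 ? sentinel : (int8_t)b;
  }
  return v;
}

// Full-matrix affine-gap Smith-Waterman score; independent reference
// implementation (simple three-state DP, no banding, no shared code path).
// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend) {
  const int NEG = -1000000000;
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(n + 1, NEG));
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_extend,
                         E[i][j - 1] > NEG / 2 ? E[i][j - 1] - gap_extend : NEG);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_extend,
                         F[i - 1][j] > NEG / 2 ? F[i - 1][j] - gap_extend : NEG);
      int s = (base_code(a[i - 1]) == base_code(b[j - 1])) ? match : mismatch;
      int h = H[i - 1][j - 1] + s;
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

struct Cand {
  int dmin, dmax, nseeds;
};

// Seed-and-extend alignment of a read batch against an indexed fragment set.
// Both strands of each read are searched; per (read, fragment) the best score
// across strands is reported when it reaches min_report.
// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector reads, CharacterVector frags,
                          IntegerVector offsets, IntegerVector post_frag,
                          IntegerVector post_pos, int k,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int band, int min_seed, int min_report,
                          int max_kmer_hits) {
  const int nread = reads.size();
  const int nfrag = frags.size();
  const int mask = (1 << (2 * k)) - 1;
  std::vector<std::vector<int8_t>> fenc(nfrag);
  for (int f = 0; f < nfrag; ++f)
    fenc[f] = encode_seq(as<std::string>(frags[f]), 4);

  std::vector<int> out_read, out_frag, out_strand, out_score, out_seeds;

  for (int ri = 0; ri < nread; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    if ((int)fwd.size() < k) continue; // shorter than seed: no hit possible
    // per-fragment best over both strands
    std::unordered_map<int, std::pair<int, int>> best; // frag -> (score, strand)
    std::unordered_map<int, int> best_seeds;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fwd : revcomp(fwd);
      std::vector<int8_t> qenc = encode_seq(q, 5);
      std::unordered_map<int, Cand> cands;
      int code = 0, run = 0;
      for (size_t i = 0; i < q.size(); ++i) {
        int bcode = base_code(q[i]);
        if (bcode < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | bcode) & mask;
        if (++run < k) continue;
        int lo = offsets[code], hi = offsets[code + 1];
        if (hi - lo > max_kmer_hits) continue; // repetitive seed, skip
        int qpos = (int)i - k + 1;
        for (int p = lo; p < hi; ++p) {
          int f = post_frag[p] - 1;
          int d = post_pos[p] - qpos;
          auto it = cands.find(f);
          if (it == cands.end()) {
            cands[f] = {d, d, 1};
          } else {
            Cand& c = it->second;
            if (d < c.dmin) c.dmin = d;
            if (d > c.dmax) c.dmax = d;
            c.nseeds++;
          }
        }
      }
      for (auto& kv : cands) {
        if (kv.second.nseeds < min_seed) continue;
        const std::vector<int8_t>& rf = fenc[kv.first];
        int s = banded_sw_enc(qenc.data(), (int)qenc.size(),
                              rf.data(), (int)rf.size(),
                              kv.second.dmin - band, kv.second.dmax + band,
                              match, mismatch, gap_open, gap_extend);
        if (s < min_report) continue;
        auto it = best.find(kv.first);
        if (it == best.end() || s > it->second.first) {
          best[kv.first] = {s, strand};
          best_seeds[kv.first] = kv.second.nseeds;
        }
      }
    }
    for (auto& kv : best) {
      out_read.push_back(ri + 1);
      out_frag.push_back(kv.first + 1);
      out_strand.push_back(kv.second.second == 0 ? 1 : -1);
      out_score.push_back(kv.second.first);
      out_seeds.push_back(best_seeds[kv.first]);
    }
  }
  return DataFrame::create(_["read"] = out_read, _["frag"] = out_frag,
                           _["strand"] = out_strand, _["score"] = out_score,
                           _["n_seeds"] = out_seeds);
}

// Vectorised reverse complement (simulator utility).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
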