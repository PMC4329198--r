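// Seed-and-extend ungapped read matcher with best-stratum reporting.
//
// Semantics: a read placement is end-to-end and ungapped on a reference
// (forward or reverse-complement of the read), scored by Hamming mismatches
// over the full read length; any position where either base is not A/C/G/T
// counts as a mismatch. A placement is discoverable iff read and reference
// share at least one exact k-mer at a compatible offset (so detection is
// guaranteed when L >= k*(budget+1), by pigeonhole). Only placements within
// the mismatch budget are kept, and of those only the minimal-mismatch
// stratum is reported, deduplicated by (ref, offset, strand).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
#include <cmath>
#include <climits>

using namespace Rcpp;

struct SeedIndex {
  int k;
  std::vector<std::string> ids;
  std::vector<std::vector<int8_t>> seqs;  // 0..3 = ACGT, -1 = other
  std::unordered_map<uint64_t, std::vector<std::pair<uint32_t, uint32_t>>> table;
  double n_postings;
};

static std::vector<int8_t> encode_dna(const char* s, size_t n) {
  std::vector<int8_t> v(n);
  for (size_t i = 0; i < n; i++) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = -1;
    }
  }
  return v;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->n_postings = 0.0;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  size_t n = seqs.size();
  bool any_long_enough = false;
  for (size_t r = 0; r < n; r++) {
    std::string s = as<std::string>(seqs[r]);
    idx->ids.push_back(as<std::string>(ids[r]));
    idx->seqs.push_back(encode_dna(s.c_str(), s.size()));
    const std::vector<int8_t>& e = idx->seqs.back();
    if ((int)e.size() >= k) any_long_enough = true;
    uint64_t kmer = 0;
    int run = 0;
    for (size_t i = 0; i < e.size(); i++) {
      if (e[i] < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)e[i]) & mask;
      run++;
      if (run >= k) {
        idx->table[kmer].emplace_back((uint32_t)r, (uint32_t)(i - k + 1));
        idx->n_postings += 1.0;
      }
    }
  }
  if (!any_long_enough) {
    delete idx;
    stop("seed length k exceeds the length of every reference");
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  size_t n = idx->ids.size();
  CharacterVector ids(n);
  IntegerVector lens(n);
  for (size_t i = 0; i < n; i++) {
    ids[i] = idx->ids[i];
    lens[i] = (int)idx->seqs[i].size();
  }
  return List::create(_["n_refs"] = (int)n, _["k"] = idx->k,
                      _["n_postings"] = idx->n_postings,
                      _["ref_ids"] = ids, _["ref_lengths"] = lens);
}

// [[Rcpp::export]]
List cpp_align(SEXP xp, CharacterVector read_ids, CharacterVector read_seqs,
               double min_identity) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<std::string> o_read, o_ref;
  std::vector<int> o_off, o_mm, o_len;
  std::vector<char> o_strand;
  std::vector<std::string> short_reads;

  size_t n = read_seqs.size();
  std::vector<std::tuple<uint32_t, uint32_t, int, int>> hits;  // ref, off, strand, mm
  std::unordered_set<uint64_t> cand;

  for (size_t ri = 0; ri < n; ri++) {
    std::string s = as<std::string>(read_seqs[ri]);
    const int L = (int)s.size();
    if (L < k) {
      short_reads.push_back(as<std::string>(read_ids[ri]));
      continue;
    }
    const int budget = (int)std::floor((1.0 - min_identity) * L + 1e-9);
    std::vector<int8_t> fwd = encode_dna(s.c_str(), s.size());
    std::vector<int8_t> rev(L);
    for (int i = 0; i < L; i++) {
      int8_t b = fwd[L - 1 - i];
      rev[i] = (b < 0) ? (int8_t)-1 : (int8_t)(3 - b);
    }
    hits.clear();
    for (int strand = 0; strand < 2; strand++) {
      const std::vector<int8_t>& q = strand ? rev : fwd;
      cand.clear();
      uint64_t kmer = 0;
      int run = 0;
      for (int i = 0; i < L; i++) {
        if (q[i] < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)q[i]) & mask;
        run++;
        if (run < k) continue;
        auto it = idx->table.find(kmer);
        if (it == idx->table.end()) continue;
        const int qpos = i - k + 1;
        for (const auto& pr : it->second) {
          const long diag = (long)pr.second - qpos;
          if (diag < 0) continue;
          if (diag + L > (long)idx->seqs[pr.first].size()) continue;
          cand.insert(((uint64_t)pr.first << 32) | (uint64_t)diag);
        }
      }
      for (uint64_t key : cand) {
        const uint32_t r = (uint32_t)(key >> 32);
        const uint32_t off = (uint32_t)(key & 0xffffffffULL);
        const std::vector<int8_t>& ref = idx->seqs[r];
        int mm = 0;
        for (int j = 0; j < L; j++) {
          const int8_t a = q[j], b = ref[off + j];
          if (a < 0 || b < 0 || a != b) {
            if (++mm > budget) break;
          }
        }
        if (mm <= budget) hits.emplace_back(r, off, strand, mm);
      }
    }
    if (hits.empty()) continue;
    int best = INT_MAX;
    for (const auto& h : hits) best = std::min(best, std::get<3>(h));
    std::string rid = as<std::string>(read_ids[ri]);
    for (const auto& h : hits) {
      if (std::get<3>(h) != best) continue;
      o_read.push_back(rid);
      o_ref.push_back(idx->ids[std::get<0>(h)]);
      o_off.push_back((int)std::get<1>(h));
      o_strand.push_back(std::get<2>(h) ? '-' : '+');
      o_mm.push_back(std::get<3>(h));
      o_len.push_back(L);
    }
  }

  size_t m = o_read.size();
  CharacterVector rds(m), rfs(m), strd(m);
  IntegerVector off(m), mm(m), len(m);
  NumericVector ident(m);
  for (size_t i = 0; i < m; i++) {
    rds[i] = o_read[i];
    rfs[i] = o_ref[i];
    strd[i] = std::string(1, o_strand[i]);
    off[i] = o_off[i];
    mm[i] = o_mm[i];
    len[i] = o_len[i];
    ident[i] = (double)(o_len[i] - o_mm[i]) / (double)o_len[i];
  }
  DataFrame df = DataFrame::create(
      _["read_id"] = rds, _["ref_id"] = rfs, _["strand"] = strd,
      _["offset"] = off, _["mismatches"] = mm, _["read_length"] = len,
      _["identity"] = ident, _["stringsAsFactors"] = false);
  return List::create(_["hits"] = df, _["short_reads"] = wrap(short_reads));
}
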