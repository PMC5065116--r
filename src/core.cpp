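#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---- nucleotide helpers -----------------------------------------------------

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;  // N or anything else: not encodable
  }
}

static inline char bits2base(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// encode s[pos..pos+k) into 2-bit kmer; returns false if any non-ACGT base
static inline bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static inline uint64_t rc_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

static std::string decode_kmer(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bits2base((int)(v & 3)); v >>= 2; }
  return s;
}

// ---- k-mer index ------------------------------------------------------------

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // kmer -> list of (ref, 0-based offset), forward strand of references only
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
  }
  for (size_t r = 0; r < idx->seqs.size(); ++r) {
    const std::string& s = idx->seqs[r];
    if ((int)s.size() < k) continue;  // skipped; warning issued at R level
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t v;
      if (!encode_kmer(s, p, k, v)) continue;  // k-mers spanning N excluded
      idx->map[v].emplace_back((int32_t)r, (int32_t)p);
      ++total;
    }
  }
  (void)total;
  XPtr<KmerIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export(name = ".cpp_index_k")]]
int cpp_index_k(SEXP xp_) { XPtr<KmerIndex> xp(xp_); return xp->k; }

// [[Rcpp::export(name = ".cpp_index_size")]]
double cpp_index_size(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  double n = 0;
  for (auto& kv : xp->map) n += kv.second.size();
  return n;
}

// [[Rcpp::export(name = ".cpp_index_lookup")]]
DataFrame cpp_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<KmerIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("query length must equal index k");
  std::vector<std::string> ref; std::vector<int> off; std::vector<std::string> strand;
  uint64_t v;
  if (encode_kmer(kmer, 0, xp->k, v)) {
    auto it = xp->map.find(v);
    if (it != xp->map.end())
      for (auto& h : it->second) {
        ref.push_back(xp->names[h.first]); off.push_back(h.second); strand.push_back("+");
      }
    uint64_t rc = rc_kmer(v, xp->k);
    if (rc != v) {
      it = xp->map.find(rc);
      if (it != xp->map.end())
        for (auto& h : it->second) {
          ref.push_back(xp->names[h.first]); off.push_back(h.second); strand.push_back("-");
        }
    }
  }
  return DataFrame::create(_["ref"] = ref, _["offset"] = off, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// full-length ungapped mismatch count; N never matches
static inline int count_mismatches(const std::string& read, const std::string& ref,
                                   size_t start, int best_so_far) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char a = read[i], b = ref[start + i];
    if (a != b || a == 'N') {
      if (++mm > best_so_far) return mm;  // early exit
    }
  }
  return mm;
}

// seed-and-extend ungapped mapping of many reads against the index.
// Best placement = fewest mismatches; ties broken by (reference name, offset,
// strand '+' before '-'). Unmapped when no seed hit or mismatch fraction >
// max_mm_frac. n_best_refs counts distinct references achieving the minimum
// (used downstream to drop ambiguous reads).
// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(SEXP xp_, CharacterVector reads, double max_mm_frac) {
  XPtr<KmerIndex> xp(xp_);
  const int k = xp->k;
  R_xlen_t n = reads.size();
  CharacterVector out_ref(n, NA_STRING);
  CharacterVector out_strand(n, NA_STRING);
  IntegerVector out_off(n, NA_INTEGER);
  IntegerVector out_mm(n, NA_INTEGER);
  NumericVector out_ident(n, NA_REAL);
  IntegerVector out_nbest(n, 0);

  struct Cand { int32_t ref; int32_t start; char strand; };

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev = revcomp(fwd);
    int max_mm = (int)std::floor(max_mm_frac * L + 1e-9);

    std::vector<int> seed_offs;
    for (int off = 0; off + k <= L; off += k) seed_offs.push_back(off);
    if (seed_offs.back() != L - k) seed_offs.push_back(L - k);

    std::vector<Cand> cands;
    std::unordered_set<uint64_t> seen;  // (ref,start,strand) packed
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = (strand == 0) ? fwd : rev;
      for (int off : seed_offs) {
        uint64_t v;
        if (!encode_kmer(s, off, k, v)) continue;
        auto it = xp->map.find(v);
        if (it == xp->map.end()) continue;
        for (auto& h : it->second) {
          int32_t start = h.second - off;
          if (start < 0) continue;
          const std::string& refseq = xp->seqs[h.first];
          if ((size_t)start + L > refseq.size()) continue;
          uint64_t key = ((uint64_t)h.first << 33) | ((uint64_t)(uint32_t)start << 1) | strand;
          if (seen.insert(key).second)
            cands.push_back({h.first, start, strand == 0 ? '+' : '-'});
        }
      }
    }
    if (cands.empty()) continue;

    int best_mm = max_mm + 1;
    const Cand* best = nullptr;
    for (auto& c : cands) {
      const std::string& s = (c.strand == '+') ? fwd : rev;
      int mm = count_mismatches(s, xp->seqs[c.ref], c.start, best_mm);
      if (mm > max_mm) continue;
      bool better = false;
      if (mm < best_mm) better = true;
      else if (mm == best_mm && best) {
        const std::string& bn = xp->names[best->ref];
        const std::string& cn = xp->names[c.ref];
        if (cn < bn) better = true;
        else if (cn == bn) {
          if (c.start < best->start) better = true;
          else if (c.start == best->start && c.strand == '+' && best->strand == '-') better = true;
        }
      }
      if (better) { best_mm = mm; best = &c; }
    }
    if (!best) continue;

    // distinct references tied at the minimum
    std::unordered_set<int32_t> tied;
    for (auto& c : cands) {
      const std::string& s = (c.strand == '+') ? fwd : rev;
      int mm = count_mismatches(s, xp->seqs[c.ref], c.start, best_mm);
      if (mm == best_mm) tied.insert(c.ref);
    }
    out_ref[i] = xp->names[best->ref];
    out_strand[i] = std::string(1, best->strand);
    out_off[i] = best->start;
    out_mm[i] = best_mm;
    out_ident[i] = 1.0 - (double)best_mm / L;
    out_nbest[i] = (int)tied.size();
  }
  return DataFrame::create(_["ref"] = out_ref, _["strand"] = out_strand,
                           _["offset"] = out_off, _["mismatches"] = out_mm,
                           _["identity"] = out_ident, _["n_best_refs"] = out_nbest,
                           _["stringsAsFactors"] = false);
}

// ---- Smith-Waterman local alignment (linear gap) ---------------------------

// score matrix given over `alphabet`; characters absent from the alphabet are
// mapped to 'X' when present, otherwise rejected.
// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(std::string a, std::string b, std::string alphabet,
                  NumericMatrix scores, double gap) {
  int tab[256];
  std::fill(tab, tab + 256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i) tab[(unsigned char)alphabet[i]] = (int)i;
  int xcode = tab[(unsigned char)'X'];
  auto code = [&](char c) {
    int v = tab[(unsigned char)c];
    if (v < 0) {
      if (xcode >= 0) return xcode;
      stop("character '%s' not in alphabet", std::string(1, c).c_str());
    }
    return v;
  };
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  std::vector<int> ac(n), bc(m);
  for (int i = 0; i < n; ++i) ac[i] = code(a[i]);
  for (int j = 0; j < m; ++j) bc[j] = code(b[j]);

  // full DP with traceback pointers (0 stop, 1 diag, 2 up, 3 left)
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<uint8_t> T((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t id = (size_t)i * (m + 1) + j;
      double diag = H[id - (m + 2)] + scores(ac[i - 1], bc[j - 1]);
      double up = H[id - (m + 1)] - gap;
      double left = H[id - 1] - gap;
      double h = 0.0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (up > h) { h = up; t = 2; }
      if (left > h) { h = left; t = 3; }
      H[id] = h; T[id] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER,
                        _["matches"] = 0, _["align_len"] = 0);
  int i = bi, j = bj, matches = 0, cols = 0;
  while (T[(size_t)i * (m + 1) + j] != 0) {
    uint8_t t = T[(size_t)i * (m + 1) + j];
    ++cols;
    if (t == 1) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'X') ++matches;
      --i; --j;
    } else if (t == 2) { --i; } else { --j; }
  }
  return List::create(_["score"] = best, _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["matches"] = matches, _["align_len"] = cols);
}

// score-only batch Smith-Waterman (linear gap, two-row DP): best local score
// of `a` against every sequence in `bs`
// [[Rcpp::export(name = ".cpp_sw_score_batch")]]
NumericVector cpp_sw_score_batch(std::string a, CharacterVector bs,
                                 std::string alphabet, NumericMatrix scores,
                                 double gap) {
  int tab[256];
  std::fill(tab, tab + 256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i) tab[(unsigned char)alphabet[i]] = (int)i;
  int xcode = tab[(unsigned char)'X'];
  auto code = [&](char c) {
    int v = tab[(unsigned char)c];
    if (v < 0) {
      if (xcode >= 0) return xcode;
      stop("character '%s' not in alphabet", std::string(1, c).c_str());
    }
    return v;
  };
  const int n = (int)a.size();
  std::vector<int> ac(n);
  for (int i = 0; i < n; ++i) ac[i] = code(a[i]);
  NumericVector out(bs.size());
  std::vector<double> prev, cur;
  for (R_xlen_t bi = 0; bi < bs.size(); ++bi) {
    std::string b = as<std::string>(bs[bi]);
    const int m = (int)b.size();
    if (n == 0 || m == 0) { out[bi] = 0.0; continue; }
    std::vector<int> bc(m);
    for (int j = 0; j < m; ++j) bc[j] = code(b[j]);
    prev.assign(m + 1, 0.0);
    cur.assign(m + 1, 0.0);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      cur[0] = 0.0;
      const double* srow = &scores(ac[i - 1], 0);
      const int nrow = scores.nrow();
      for (int j = 1; j <= m; ++j) {
        double h = prev[j - 1] + srow[(size_t)bc[j - 1] * nrow];
        double up = prev[j] - gap;
        double left = cur[j - 1] - gap;
        if (up > h) h = up;
        if (left > h) h = left;
        if (h < 0) h = 0;
        cur[j] = h;
        if (h > best) best = h;
      }
      std::swap(prev, cur);
    }
    out[bi] = best;
  }
  return out;
}

// ---- de Bruijn unitig assembler ---------------------------------------------

// canonical k-mer counting over reads; k-mers with count < min_support are
// dropped; unitigs = maximal non-branching paths over the surviving graph
// (both orientations walked, deduplicated canonically).
// [[Rcpp::export(name = ".cpp_assemble")]]
DataFrame cpp_assemble(CharacterVector reads, int k, int min_support,
                       double auto_cutoff_frac) {
  if (k < 3 || k > 31 || k % 2 == 0) stop("assembler k must be odd and in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;  // canonical kmer -> multiplicity
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t v;
      if (!encode_kmer(s, p, k, v)) continue;
      uint64_t rc = rc_kmer(v, k);
      counts[std::min(v, rc)]++;
    }
  }
  // optional coverage cutoff: prune k-mers far below the typical coverage
  // (occurrence-weighted median), suppressing error-induced bubbles in
  // high-coverage pools; reduces to min_support at low coverage
  int cutoff = min_support;
  if (auto_cutoff_frac > 0 && !counts.empty()) {
    std::vector<uint32_t> cnts;
    cnts.reserve(counts.size());
    double total = 0;
    for (auto& kv : counts) { cnts.push_back(kv.second); total += kv.second; }
    std::sort(cnts.begin(), cnts.end());
    double cum = 0; uint32_t wmedian = cnts.back();
    for (auto c : cnts) { cum += c; if (cum >= total / 2) { wmedian = c; break; } }
    int dyn = (int)std::floor(auto_cutoff_frac * wmedian + 0.5);
    if (dyn > cutoff) cutoff = dyn;
  }
  // surviving node set, both orientations
  std::unordered_set<uint64_t> nodes;
  for (auto it = counts.begin(); it != counts.end();) {
    if ((int)it->second < cutoff) { it = counts.erase(it); }
    else {
      nodes.insert(it->first);
      nodes.insert(rc_kmer(it->first, k));
      ++it;
    }
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  auto successors = [&](uint64_t u, uint64_t out[4]) {
    int cnt = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t v = ((u << 2) | b) & mask;
      if (nodes.count(v)) out[cnt++] = v;
    }
    return cnt;
  };
  auto predecessors = [&](uint64_t u, uint64_t out[4]) {
    int cnt = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t v = (b << (2 * (k - 1))) | (u >> 2);
      if (nodes.count(v)) out[cnt++] = v;
    }
    return cnt;
  };
  std::unordered_set<uint64_t> visited;
  std::vector<std::pair<std::string, uint32_t>> unitigs;  // (canonical seq, support)

  auto walk = [&](uint64_t start) {
    std::vector<uint64_t> path{start};
    visited.insert(start);
    uint64_t cur = start;
    uint64_t succ[4], pred[4];
    while (true) {
      if (successors(cur, succ) != 1) break;
      uint64_t nxt = succ[0];
      if (predecessors(nxt, pred) != 1) break;
      if (visited.count(nxt)) break;
      path.push_back(nxt);
      visited.insert(nxt);
      cur = nxt;
    }
    std::string seq = decode_kmer(path[0], k);
    uint32_t support = UINT32_MAX;
    for (auto v : path) {
      uint64_t rc = rc_kmer(v, k);
      support = std::min(support, counts[std::min(v, rc)]);
    }
    for (size_t i = 1; i < path.size(); ++i) seq.push_back(bits2base((int)(path[i] & 3)));
    std::string rc = revcomp(seq);
    if (rc < seq) seq = rc;
    unitigs.emplace_back(seq, support);
  };

  // pass 1: nodes that cannot be uniquely extended leftwards
  std::vector<uint64_t> all(nodes.begin(), nodes.end());
  std::sort(all.begin(), all.end());  // deterministic walk order
  uint64_t succ[4], pred[4];
  for (auto u : all) {
    if (visited.count(u)) continue;
    bool left_ext = predecessors(u, pred) == 1 && successors(pred[0], succ) == 1;
    if (!left_ext) walk(u);
  }
  // pass 2: remaining nodes lie on cycles
  for (auto u : all) if (!visited.count(u)) walk(u);

  // canonical dedupe (each unitig is discovered in both orientations)
  std::unordered_set<std::string> seen;
  std::vector<std::pair<std::string, uint32_t>> keep;
  for (auto& u : unitigs) if (seen.insert(u.first).second) keep.push_back(u);
  std::sort(keep.begin(), keep.end(), [](const std::pair<std::string, uint32_t>& x,
                                         const std::pair<std::string, uint32_t>& y) {
    if (x.first.size() != y.first.size()) return x.first.size() > y.first.size();
    return x.first < y.first;
  });
  CharacterVector seqs(keep.size());
  IntegerVector supp(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) { seqs[i] = keep[i].first; supp[i] = (int)keep[i].second; }
  return DataFrame::create(_["sequence"] = seqs, _["support"] = supp,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
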