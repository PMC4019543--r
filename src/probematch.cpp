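// Exact 25-mer probe matching against a cDNA database.
//
// Two independent search paths are provided: a k-mer seed-and-extend index
// (the production path) and an O(n*m) sliding-window scanner (a reference
// path used for validation). Both classify candidate alignments into the
// same tier vocabulary: EXACT (all 25 bases), END_MM (contiguous core >= 23,
// all mismatches terminal), TANDEM (contiguous core >= min_tandem), RESCUE
// (all mismatches terminal, core >= 25 - rescue_max_end_mismatch).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const int PROBE_LEN = 25;

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or other ambiguity codes never match
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

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct SeedIdx {
  int k;
  // kmer code -> packed (transcript << 32 | offset)
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
  std::vector<std::string> seqs;
  std::vector<std::string> ids;
  std::vector<std::string> genes;
};

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, CharacterVector ids,
                     CharacterVector genes, int k) {
  SeedIdx* idx = new SeedIdx();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    idx->seqs.push_back(as<std::string>(seqs[t]));
    idx->ids.push_back(as<std::string>(ids[t]));
    idx->genes.push_back(as<std::string>(genes[t]));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (size_t t = 0; t < idx->seqs.size(); ++t) {
    const std::string& s = idx->seqs[t];
    if ((int)s.size() < k) continue;
    uint64_t code = 0;
    int valid = 0; // run length of non-N bases ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2code(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t off = (uint64_t)(i + 1 - k);
        idx->map[code].push_back(((uint64_t)t << 32) | off);
      }
    }
  }
  XPtr<SeedIdx> ptr(idx, true);
  return ptr;
}

// Dump of indexed positions (testing aid; forward strand as stored).
// [[Rcpp::export]]
DataFrame cpp_index_dump(SEXP idx_ptr) {
  XPtr<SeedIdx> idx(idx_ptr);
  std::vector<std::string> tid, kmer;
  std::vector<int> off;
  for (auto& kv : idx->map) {
    for (uint64_t packed : kv.second) {
      size_t t = packed >> 32;
      int o = (int)(packed & 0xffffffffULL);
      tid.push_back(idx->ids[t]);
      kmer.push_back(idx->seqs[t].substr(o, idx->k));
      off.push_back(o);
    }
  }
  return DataFrame::create(_["kmer"] = kmer, _["transcript_id"] = tid,
                           _["offset"] = off,
                           _["stringsAsFactors"] = false);
}

struct HitRow {
  int probe, tx;
  int offset;
  char strand;
  int core_start, core_len, mm_left, mm_right;
  int tier; // 4 EXACT, 3 END_MM, 2 TANDEM, 1 RESCUE
};

struct MatchCfg {
  int min_tandem;
  int max_end_mismatch;
  bool rescue;
  int rescue_max_end_mismatch;
  bool search_rc;
};

// Classify the alignment of an oriented probe at `offset` on transcript
// `seq`. Returns tier 0 when no tier qualifies. Positions outside the
// transcript and transcript N bases count as mismatches.
static int classify_window(const std::string& probe, const std::string& seq,
                           int offset, const MatchCfg& cfg,
                           int* core_start, int* core_len,
                           int* mm_left, int* mm_right) {
  const int len = (int)seq.size();
  bool match[PROBE_LEN];
  int total = 0;
  for (int j = 0; j < PROBE_LEN; ++j) {
    int p = offset + j;
    bool m = p >= 0 && p < len && base2code(seq[p]) >= 0 && seq[p] == probe[j];
    match[j] = m;
    if (m) ++total;
  }
  // longest contiguous run of matches; leftmost on ties
  int best_start = 0, best_len = 0, run_start = 0, run_len = 0;
  for (int j = 0; j < PROBE_LEN; ++j) {
    if (match[j]) {
      if (run_len == 0) run_start = j;
      if (++run_len > best_len) { best_len = run_len; best_start = run_start; }
    } else {
      run_len = 0;
    }
  }
  *core_start = best_start;
  *core_len = best_len;
  int left = 0, right = 0;
  for (int j = 0; j < best_start; ++j) if (!match[j]) ++left;
  for (int j = best_start + best_len; j < PROBE_LEN; ++j) if (!match[j]) ++right;
  *mm_left = left;
  *mm_right = right;
  // mismatches are "terminal" when they sit outside the longest core
  // (before core_start or after core end); left + right counts them all
  int nmm = PROBE_LEN - total;
  if (best_len == PROBE_LEN) return 4;
  if (best_len >= 23 && nmm <= cfg.max_end_mismatch) return 3;
  if (best_len >= cfg.min_tandem) return 2;
  if (cfg.rescue && nmm <= cfg.rescue_max_end_mismatch &&
      best_len >= PROBE_LEN - cfg.rescue_max_end_mismatch) return 1;
  return 0;
}

static DataFrame hits_to_df(std::vector<HitRow>& hits,
                            const CharacterVector& probe_ids,
                            const std::vector<std::string>& tids,
                            const std::vector<std::string>& tgenes) {
  // total order: probe_id, transcript_id, offset, strand
  std::sort(hits.begin(), hits.end(), [&](const HitRow& a, const HitRow& b) {
    const std::string pa = as<std::string>(probe_ids[a.probe]);
    const std::string pb = as<std::string>(probe_ids[b.probe]);
    if (pa != pb) return pa < pb;
    if (tids[a.tx] != tids[b.tx]) return tids[a.tx] < tids[b.tx];
    if (a.offset != b.offset) return a.offset < b.offset;
    return a.strand < b.strand;
  });
  const char* tier_names[5] = {"", "RESCUE", "TANDEM", "END_MM", "EXACT"};
  R_xlen_t n = hits.size();
  CharacterVector pid(n), tid(n), gid(n), strand(n), tier(n);
  IntegerVector off(n), cs(n), cl(n), ml(n), mr(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const HitRow& h = hits[i];
    pid[i] = probe_ids[h.probe];
    tid[i] = tids[h.tx];
    gid[i] = tgenes[h.tx];
    off[i] = h.offset;
    strand[i] = h.strand == '+' ? "+" : "-";
    cs[i] = h.core_start;
    cl[i] = h.core_len;
    ml[i] = h.mm_left;
    mr[i] = h.mm_right;
    tier[i] = tier_names[h.tier];
  }
  return DataFrame::create(
    _["probe_id"] = pid, _["transcript_id"] = tid, _["gene_id"] = gid,
    _["offset"] = off, _["strand"] = strand,
    _["core_start"] = cs, _["core_len"] = cl,
    _["n_end_mismatch_left"] = ml, _["n_end_mismatch_right"] = mr,
    _["tier"] = tier, _["stringsAsFactors"] = false);
}

static MatchCfg cfg_from_args(int min_tandem, int max_end_mismatch,
                              bool rescue, int rescue_max_end_mismatch,
                              bool search_rc) {
  MatchCfg cfg;
  cfg.min_tandem = min_tandem;
  cfg.max_end_mismatch = max_end_mismatch;
  cfg.rescue = rescue;
  cfg.rescue_max_end_mismatch = rescue_max_end_mismatch;
  cfg.search_rc = search_rc;
  return cfg;
}

// Seed-and-extend search through the k-mer index.
// [[Rcpp::export]]
DataFrame cpp_find_hits(SEXP idx_ptr, CharacterVector probe_ids,
                        CharacterVector probe_seqs,
                        int min_tandem, int max_end_mismatch,
                        bool rescue, int rescue_max_end_mismatch,
                        bool search_rc) {
  XPtr<SeedIdx> idx(idx_ptr);
  MatchCfg cfg = cfg_from_args(min_tandem, max_end_mismatch, rescue,
                               rescue_max_end_mismatch, search_rc);
  const int k = idx->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::vector<HitRow> hits;
  std::vector<uint64_t> seen; // packed (tx, offset+64) per orientation
  for (R_xlen_t p = 0; p < probe_seqs.size(); ++p) {
    std::string fwd = as<std::string>(probe_seqs[p]);
    int n_orient = cfg.search_rc ? 2 : 1;
    for (int o = 0; o < n_orient; ++o) {
      std::string q = (o == 0) ? fwd : revcomp(fwd);
      char strand = (o == 0) ? '+' : '-';
      seen.clear();
      uint64_t code = 0;
      int valid = 0;
      for (int i = 0; i < PROBE_LEN; ++i) {
        int b = base2code(q[i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        int qpos = i + 1 - k;
        auto it = idx->map.find(code);
        if (it == idx->map.end()) continue;
        for (uint64_t packed : it->second) {
          int tx = (int)(packed >> 32);
          int toff = (int)(packed & 0xffffffffULL);
          int offset = toff - qpos;
          uint64_t key = ((uint64_t)tx << 32) | (uint64_t)(offset + 64);
          if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
          seen.push_back(key);
          HitRow h;
          h.probe = (int)p;
          h.tx = tx;
          h.offset = offset;
          h.strand = strand;
          h.tier = classify_window(q, idx->seqs[tx], offset, cfg,
                                   &h.core_start, &h.core_len,
                                   &h.mm_left, &h.mm_right);
          if (h.tier > 0) hits.push_back(h);
        }
      }
    }
  }
  return hits_to_df(hits, probe_ids, idx->ids, idx->genes);
}

// Reference scanner: every transcript, every admissible offset, both
// orientations. Independent of the index path; used to validate it.
// [[Rcpp::export]]
DataFrame cpp_find_hits_brute(CharacterVector tseqs, CharacterVector tids,
                              CharacterVector tgenes,
                              CharacterVector probe_ids,
                              CharacterVector probe_seqs,
                              int min_tandem, int max_end_mismatch,
                              bool rescue, int rescue_max_end_mismatch,
                              bool search_rc) {
  MatchCfg cfg = cfg_from_args(min_tandem, max_end_mismatch, rescue,
                               rescue_max_end_mismatch, search_rc);
  int min_core = std::min(min_tandem, PROBE_LEN - max_end_mismatch);
  if (rescue) min_core = std::min(min_core,
                                  PROBE_LEN - rescue_max_end_mismatch);
  std::vector<std::string> seqs, ids, genes;
  for (R_xlen_t t = 0; t < tseqs.size(); ++t) {
    seqs.push_back(as<std::string>(tseqs[t]));
    ids.push_back(as<std::string>(tids[t]));
    genes.push_back(as<std::string>(tgenes[t]));
  }
  std::vector<HitRow> hits;
  for (R_xlen_t p = 0; p < probe_seqs.size(); ++p) {
    std::string fwd = as<std::string>(probe_seqs[p]);
    int n_orient = cfg.search_rc ? 2 : 1;
    for (int o = 0; o < n_orient; ++o) {
      std::string q = (o == 0) ? fwd : revcomp(fwd);
      char strand = (o == 0) ? '+' : '-';
      for (size_t t = 0; t < seqs.size(); ++t) {
        const std::string& s = seqs[t];
        int len = (int)s.size();
        for (int offset = -(PROBE_LEN - min_core);
             offset <= len - min_core; ++offset) {
          // cheap gate: a qualifying hit needs >= min_core matches in total
          int nmatch = 0;
          int lo = std::max(0, -offset), hi = std::min(PROBE_LEN, len - offset);
          for (int j = lo; j < hi; ++j) {
            char c = s[offset + j];
            if (base2code(c) >= 0 && c == q[j]) ++nmatch;
          }
          if (nmatch < min_core) continue;
          HitRow h;
          h.probe = (int)p;
          h.tx = (int)t;
          h.offset = offset;
          h.strand = strand;
          // independent classification: mismatch-position bookkeeping
          std::vector<int> mmpos;
          for (int j = 0; j < PROBE_LEN; ++j) {
            int pos = offset + j;
            bool m = pos >= 0 && pos < len && base2code(s[pos]) >= 0 &&
              s[pos] == q[j];
            if (!m) mmpos.push_back(j);
          }
          // longest gap between consecutive mismatch positions
          int best_len = 0, best_start = 0, prev = -1;
          for (size_t mi = 0; mi <= mmpos.size(); ++mi) {
            int cur = (mi < mmpos.size()) ? mmpos[mi] : PROBE_LEN;
            int gap = cur - prev - 1;
            if (gap > best_len) { best_len = gap; best_start = prev + 1; }
            prev = cur;
          }
          h.core_start = best_start;
          h.core_len = best_len;
          h.mm_left = 0;
          h.mm_right = 0;
          for (int mp : mmpos) {
            if (mp < best_start) ++h.mm_left;
            else if (mp >= best_start + best_len) ++h.mm_right;
          }
          bool terminal_only =
            (int)mmpos.size() == h.mm_left + h.mm_right;
          int tier = 0;
          if (mmpos.empty()) tier = 4;
          else if (terminal_only && best_len >= 23 &&
                   (int)mmpos.size() <= cfg.max_end_mismatch) tier = 3;
          else if (best_len >= cfg.min_tandem) tier = 2;
          else if (cfg.rescue && terminal_only &&
                   (int)mmpos.size() <= cfg.rescue_max_end_mismatch &&
                   best_len >= PROBE_LEN - cfg.rescue_max_end_mismatch)
            tier = 1;
          if (tier > 0) {
            h.tier = tier;
            hits.push_back(h);
          }
        }
      }
    }
  }
  return hits_to_df(hits, probe_ids, ids, genes);
}
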