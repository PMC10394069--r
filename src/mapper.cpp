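// Seed-and-extend mapper for short reads against a circular reference,
// plus pileup and terminal-misincorporation counters shared by the
// alignment and damage-profiling stages.
//
// Mapping model: exact k-mer seeds on both strands against the doubled
// reference, diagonal voting, then a fitting (glocal) alignment of the full
// read inside a window of +/- `band` around each candidate diagonal with
// scores match +1 / mismatch -1 / gap -2.  The best location is reported;
// the runner-up score at a distinct location feeds the mapping-quality
// proxy computed on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

struct FitResult {
  int score = INT32_MIN;
  int ref_start0 = -1;   // 0-based start within the doubled reference
  int ref_span = 0;      // reference bases consumed
  int nmis = 0, ngap = 0, alen = 0;
  std::string raln, qaln;
};

// Fitting alignment: the whole query must align; reference start/end are free
// within the window.  Window is ref2[ws, ws+wlen).
static FitResult fit_align(const std::string& q, const std::string& ref2,
                           int ws, int wlen, bool traceback) {
  const int m = (int)q.size();
  if (ws < 0) { wlen += ws; ws = 0; }
  if (ws + wlen > (int)ref2.size()) wlen = (int)ref2.size() - ws;
  FitResult res;
  if (wlen <= 0 || m == 0) return res;

  const int W = wlen;
  std::vector<int> prev(W + 1), cur(W + 1);
  // tb codes: 0 diag, 1 up (query gap vs ref? = insertion in read), 2 left
  std::vector<uint8_t> tb;
  if (traceback) tb.assign((size_t)(m + 1) * (W + 1), 0);

  for (int j = 0; j <= W; ++j) prev[j] = 0;          // free ref start
  for (int i = 1; i <= m; ++i) {
    cur[0] = -2 * i;                                  // query consumed, no ref
    if (traceback) tb[(size_t)i * (W + 1)] = 1;
    const char qc = q[i - 1];
    for (int j = 1; j <= W; ++j) {
      const char rc = ref2[ws + j - 1];
      const int sub = prev[j - 1] + ((qc == rc) ? 1 : -1);
      const int up  = prev[j] - 2;   // consume query base, gap in reference
      const int lef = cur[j - 1] - 2; // consume ref base, gap in query
      int best = sub; uint8_t dir = 0;
      if (up > best)  { best = up;  dir = 1; }
      if (lef > best) { best = lef; dir = 2; }
      cur[j] = best;
      if (traceback) tb[(size_t)i * (W + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  // best end over last row (free ref end)
  int bestj = 0, best = prev[0];
  for (int j = 1; j <= W; ++j)
    if (prev[j] > best) { best = prev[j]; bestj = j; }
  res.score = best;
  if (!traceback) return res;

  // traceback from (m, bestj)
  std::string ra, qa;
  int i = m, j = bestj;
  while (i > 0) {
    uint8_t dir = tb[(size_t)i * (W + 1) + j];
    if (dir == 0 && j > 0) {
      ra.push_back(ref2[ws + j - 1]); qa.push_back(q[i - 1]);
      --i; --j;
    } else if (dir == 1 || j == 0) {
      ra.push_back('-'); qa.push_back(q[i - 1]);
      --i;
    } else {
      ra.push_back(ref2[ws + j - 1]); qa.push_back('-');
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  res.ref_start0 = ws + j;
  res.raln = ra; res.qaln = qa;
  res.alen = (int)ra.size();
  for (size_t c = 0; c < ra.size(); ++c) {
    if (ra[c] == '-' || qa[c] == '-') res.ngap++;
    else if (ra[c] != qa[c]) res.nmis++;
  }
  res.ref_span = 0;
  for (char c : ra) if (c != '-') res.ref_span++;
  return res;
}

typedef std::unordered_map<uint64_t, std::vector<int>> KmerIndex;

static KmerIndex build_index(const std::string& ref2, int k) {
  KmerIndex idx;
  const int n = (int)ref2.size();
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(ref2[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
  return idx;
}

static bool encode_kmer(const std::string& s, int off, int k, uint64_t& key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[off + i]);
    if (c < 0) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string ref, int k = 13,
                   int band = 16, int max_candidates = 6) {
  const int L = (int)ref.size();
  std::string ref2 = ref + ref;
  KmerIndex idx = build_index(ref2, k);
  const int n = reads.size();

  LogicalVector mapped(n);
  CharacterVector strand(n), read_aln(n), ref_aln(n);
  IntegerVector ref_start(n), ref_span(n), score(n), second(n),
                nmis(n), ngap(n), alen(n);

  for (int r = 0; r < n; ++r) {
    std::string q = as<std::string>(reads[r]);
    const int m = (int)q.size();
    mapped[r] = false;
    second[r] = NA_INTEGER;
    if (m < k) continue;

    // candidate diagonals per strand, by seed voting
    struct Cand { int diag; int votes; bool minus; };
    std::vector<Cand> cands;
    std::string qrc = revcomp_str(q);
    for (int s = 0; s < 2; ++s) {
      const std::string& qs = s ? qrc : q;
      std::unordered_map<int, int> votes;
      int step = std::max(1, (m - k) / 4);
      for (int off = 0; off <= m - k; off += step) {
        uint64_t key;
        if (!encode_kmer(qs, off, k, key)) continue;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        if ((int)it->second.size() > 64) continue;  // uninformative repeat
        for (int p : it->second) {
          int d = ((p - off) % L + L) % L;
          votes[d]++;
        }
      }
      for (auto& kv : votes)
        cands.push_back({kv.first, kv.second, s == 1});
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.votes != b.votes) return a.votes > b.votes;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.minus < b.minus;
    });
    // merge near-identical diagonals on the same strand (window covers them)
    std::vector<Cand> kept;
    for (const auto& c : cands) {
      bool dup = false;
      for (const auto& kc : kept)
        if (kc.minus == c.minus && std::abs(kc.diag - c.diag) <= band) {
          dup = true; break;
        }
      if (!dup) kept.push_back(c);
      if ((int)kept.size() >= max_candidates) break;
    }

    int best_score = INT32_MIN, best_i = -1, best_diag = -1;
    bool best_minus = false;
    int second_score = INT32_MIN;
    std::vector<int> scores(kept.size());
    for (size_t ci = 0; ci < kept.size(); ++ci) {
      const std::string& qs = kept[ci].minus ? qrc : q;
      FitResult f = fit_align(qs, ref2, kept[ci].diag - band,
                              m + 2 * band, false);
      scores[ci] = f.score;
      if (f.score > best_score) {
        best_score = f.score; best_i = (int)ci;
        best_diag = kept[ci].diag; best_minus = kept[ci].minus;
      }
    }
    for (size_t ci = 0; ci < kept.size(); ++ci) {
      if ((int)ci == best_i) continue;
      int dd = std::abs(kept[ci].diag - best_diag);
      dd = std::min(dd, L - dd);
      bool distinct = (dd > 2 * band) || (kept[ci].minus != best_minus);
      if (distinct && scores[ci] > second_score) second_score = scores[ci];
    }
    if (best_i < 0) continue;

    const std::string& qs = best_minus ? qrc : q;
    FitResult f = fit_align(qs, ref2, best_diag - band, m + 2 * band, true);
    mapped[r] = true;
    strand[r] = best_minus ? "-" : "+";
    ref_start[r] = (f.ref_start0 % L) + 1;   // 1-based on the circle
    ref_span[r] = f.ref_span;
    score[r] = f.score;
    if (second_score > INT32_MIN) second[r] = second_score;
    nmis[r] = f.nmis; ngap[r] = f.ngap; alen[r] = f.alen;
    read_aln[r] = f.qaln; ref_aln[r] = f.raln;
  }

  return List::create(
    _["mapped"] = mapped, _["strand"] = strand, _["ref_start"] = ref_start,
    _["ref_span"] = ref_span, _["score"] = score, _["second"] = second,
    _["n_mismatch"] = nmis, _["n_gap"] = ngap, _["aln_len"] = alen,
    _["read_aln"] = read_aln, _["ref_aln"] = ref_aln);
}

// Per-position base/deletion counts over a circular reference; insertions
// recorded separately, keyed by the 1-based position of the flanking
// (preceding) reference base.
// [[Rcpp::export]]
List cpp_build_pileup(CharacterVector ref_aln, CharacterVector read_aln,
                      IntegerVector ref_start, int L) {
  IntegerMatrix counts(5, L);   // rows A, C, G, T, del
  std::unordered_map<std::string, int> ins;
  const int n = ref_aln.size();
  for (int r = 0; r < n; ++r) {
    std::string ra = as<std::string>(ref_aln[r]);
    std::string qa = as<std::string>(read_aln[r]);
    int pos0 = ref_start[r] - 1;   // 0-based position of next reference base
    std::string pending;
    for (size_t c = 0; c < ra.size(); ++c) {
      if (ra[c] == '-') {
        if (qa[c] != '-') pending.push_back(qa[c]);
        continue;
      }
      if (!pending.empty()) {
        int flank = ((pos0 - 1) % L + L) % L;  // base before the insertion
        ins[std::to_string(flank + 1) + ":" + pending]++;
        pending.clear();
      }
      int p = pos0 % L;
      if (qa[c] == '-') counts(4, p)++;
      else {
        int b = base_code(qa[c]);
        if (b >= 0) counts(b, p)++;
      }
      pos0++;
    }
    if (!pending.empty()) {
      int flank = ((pos0 - 1) % L + L) % L;
      ins[std::to_string(flank + 1) + ":" + pending]++;
    }
  }
  std::vector<int> ipos; std::vector<std::string> iseq; std::vector<int> icnt;
  for (auto& kv : ins) {
    size_t colon = kv.first.find(':');
    ipos.push_back(std::stoi(kv.first.substr(0, colon)));
    iseq.push_back(kv.first.substr(colon + 1));
    icnt.push_back(kv.second);
  }
  return List::create(_["counts"] = counts,
                      _["ins_pos"] = wrap(ipos), _["ins_seq"] = wrap(iseq),
                      _["ins_count"] = wrap(icnt));
}

// Terminal misincorporation tallies.  Alignments arrive in reference
// orientation with a strand flag; minus-strand records are reverse
// complemented first so counting happens in read (biochemical 5'->3')
// orientation: C->T against reference-C columns by distance from the 5' end,
// G->A against reference-G columns by distance from the 3' end, plus
// mid-read background tallies beyond W from either end.
// [[Rcpp::export]]
List cpp_misinc_counts(CharacterVector ref_aln, CharacterVector read_aln,
                       CharacterVector strand, int W = 25) {
  IntegerVector num_ct5(W), den_ct5(W), num_ga3(W), den_ga3(W);
  int bg_num_ct = 0, bg_den_ct = 0, bg_num_ga = 0, bg_den_ga = 0;
  const int n = ref_aln.size();
  for (int r = 0; r < n; ++r) {
    std::string ra = as<std::string>(ref_aln[r]);
    std::string qa = as<std::string>(read_aln[r]);
    if (as<std::string>(strand[r]) == "-") {
      ra = revcomp_str(ra); qa = revcomp_str(qa);
      // '-' complements to 'N'; restore gap characters
      for (auto& c : ra) if (c == 'N') c = '-';
      for (auto& c : qa) if (c == 'N') c = '-';
    }
    int nread = 0;
    for (char c : qa) if (c != '-') nread++;
    int qpos = 0;
    for (size_t c = 0; c < ra.size(); ++c) {
      if (qa[c] == '-') continue;
      qpos++;                      // 1-based read coordinate
      if (ra[c] == '-') continue;  // insertion column: no reference base
      int d5 = qpos, d3 = nread - qpos + 1;
      if (ra[c] == 'C') {
        if (d5 <= W) {
          den_ct5[d5 - 1]++;
          if (qa[c] == 'T') num_ct5[d5 - 1]++;
        } else if (d3 > W) {
          bg_den_ct++;
          if (qa[c] == 'T') bg_num_ct++;
        }
      } else if (ra[c] == 'G') {
        if (d3 <= W) {
          den_ga3[d3 - 1]++;
          if (qa[c] == 'A') num_ga3[d3 - 1]++;
        } else if (d5 > W) {
          bg_den_ga++;
          if (qa[c] == 'A') bg_num_ga++;
        }
      }
    }
  }
  return List::create(
    _["num_ct5"] = num_ct5, _["den_ct5"] = den_ct5,
    _["num_ga3"] = num_ga3, _["den_ga3"] = den_ga3,
    _["bg_num_ct"] = bg_num_ct, _["bg_den_ct"] = bg_den_ct,
    _["bg_num_ga"] = bg_num_ga, _["bg_den_ga"] = bg_den_ga);
}
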