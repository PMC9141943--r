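#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct AlnResult {
  int score = 0;         // best local score; 0 == nothing aligned
  int ref_start = 0;     // 0-based inclusive, relative to the sequence given
  int q_start = 0;       // 0-based inclusive on the query
  int q_end = -1;        // 0-based inclusive
  int nm = 0;            // mismatches + gap bases within the aligned region
  std::string cigar;     // M/I/D runs only (soft clips added by caller)
};

// Local (Smith-Waterman) alignment with affine gaps and full traceback.
// A gap of length L costs gap_open + (L-1) * gap_extend (both negative).
// Deterministic tie-breaks: best cell = highest score, then smallest ref
// column, then smallest query row; path preference diag > D > I.
static AlnResult sw_align(const std::string& q, const std::string& r,
                          int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)r.size();
  AlnResult out;
  if (m == 0 || n == 0) return out;
  const int NEG = -1000000000;
  // DP rows (rolling) + traceback matrices (full, char-coded)
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);   // gap consuming ref (D)
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG);   // gap consuming query (I)
  // traceback codes for H: 0 stop, 1 diag, 2 from E(D), 3 from F(I)
  // for E: 0 opened from H, 1 extended; same for F
  std::vector<char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<char> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<char> tbF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    const char qc = q[(size_t)i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * (n + 1) + j;
      // E: gap in query row (consumes ref, op D)
      int e_open = Hcur[j - 1] + gap_open;
      int e_ext  = Ecur[j - 1] + gap_extend;
      int e = std::max(e_open, e_ext);
      tbE[idx] = (char)(e_ext > e_open ? 1 : 0);
      Ecur[j] = e;
      // F: gap in ref (consumes query, op I)
      int f_open = Hprev[j] + gap_open;
      int f_ext  = Fprev[j] + gap_extend;
      int f = std::max(f_open, f_ext);
      tbF[idx] = (char)(f_ext > f_open ? 1 : 0);
      Fcur[j] = f;
      // H
      int s = (base_code(qc) >= 0 && base_code(qc) == base_code(r[(size_t)j - 1]))
        ? match : mismatch;
      int diag = Hprev[j - 1] + s;
      int h = 0; char code = 0;
      if (diag > h) { h = diag; code = 1; }
      if (e > h)    { h = e;    code = 2; }
      if (f > h)    { h = f;    code = 3; }
      tbH[idx] = code;
      Hcur[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  if (best <= 0) return out;
  // traceback from (bi, bj)
  int i = bi, j = bj, state = 0; // 0 = H
  std::string ops; ops.reserve(m + 16);
  int nm = 0;
  while (true) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      char c = tbH[idx];
      if (c == 0) break;
      if (c == 1) {
        ops.push_back('M');
        if (base_code(q[(size_t)i - 1]) != base_code(r[(size_t)j - 1])) ++nm;
        --i; --j;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: D op
      ops.push_back('D'); ++nm;
      char c = tbE[idx];
      --j;
      if (c == 0) state = 0;
    } else { // F: I op
      ops.push_back('I'); ++nm;
      char c = tbF[idx];
      --i;
      if (c == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cig += std::to_string(k2 - k); cig.push_back(ops[k]);
    k = k2;
  }
  out.score = best;
  out.ref_start = j;        // 0-based
  out.q_start = i;          // 0-based
  out.q_end = bi - 1;       // 0-based inclusive
  out.nm = nm;
  out.cigar = cig;
  return out;
}

// ---------------------------------------------------------------------------
// Seed index + batch alignment
// ---------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string& ref, int k, KmerIndex& idx) {
  const int n = (int)ref.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(ref[(size_t)i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx[code].push_back(i - k + 1);
  }
}

struct Oriented { AlnResult aln; bool fwd = true; bool found = false; };

static void try_orientation(const std::string& oread, const std::string& ref,
                            const KmerIndex& idx, int k, int match, int mismatch,
                            int gap_open, int gap_extend, int band,
                            bool fwd, Oriented& best) {
  const int m = (int)oread.size(), n = (int)ref.size();
  if (m < k) return;
  const size_t MAX_HITS_PER_KMER = 64;
  std::vector<int> diags;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int b = base_code(oread[(size_t)i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      KmerIndex::const_iterator it = idx.find(code);
      if (it != idx.end() && it->second.size() <= MAX_HITS_PER_KMER) {
        int qpos = i - k + 1;
        for (int p : it->second) diags.push_back(p - qpos);
      }
    }
  }
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  // group diagonals within `band` of each other; align read vs each window
  size_t g0 = 0;
  for (size_t g = 1; g <= diags.size(); ++g) {
    if (g == diags.size() || diags[g] - diags[g - 1] > band) {
      int dmin = diags[g0], dmax = diags[g - 1];
      int w0 = std::max(0, dmin - band);
      int w1 = std::min(n, dmax + m + band); // exclusive
      if (w1 > w0) {
        AlnResult a = sw_align(oread, ref.substr((size_t)w0, (size_t)(w1 - w0)),
                               match, mismatch, gap_open, gap_extend);
        if (a.score > 0) {
          a.ref_start += w0;
          bool better = !best.found || a.score > best.aln.score ||
            (a.score == best.aln.score &&
             (a.ref_start < best.aln.ref_start ||
              (a.ref_start == best.aln.ref_start && fwd && !best.fwd)));
          if (better) { best.aln = a; best.fwd = fwd; best.found = true; }
        }
      }
      g0 = g;
    }
  }
}

// Align a batch of reads against a single reference sequence.
// Returns 1-based ref_start, full CIGAR including terminal soft clips,
// strand, score, NM, mapped flag and the query in reference orientation.
// [[Rcpp::export]]
DataFrame align_batch_cpp(CharacterVector reads, std::string ref, int seed_k,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int band, int min_report_score) {
  KmerIndex idx;
  build_index(ref, seed_k, idx);
  const int nreads = reads.size();
  IntegerVector ref_start(nreads), score(nreads), nm(nreads);
  CharacterVector cigar(nreads), strand(nreads), oseq(nreads);
  LogicalVector mapped(nreads);
  for (int t = 0; t < nreads; ++t) {
    std::string fwd = as<std::string>(reads[t]);
    std::string rev = revcomp_str(fwd);
    Oriented best;
    if ((int)fwd.size() >= seed_k) {
      try_orientation(fwd, ref, idx, seed_k, match, mismatch, gap_open,
                      gap_extend, band, true, best);
      try_orientation(rev, ref, idx, seed_k, match, mismatch, gap_open,
                      gap_extend, band, false, best);
      // fall back to exhaustive local alignment when seeding found nothing
      // convincing -- guarantees the reported score is the global optimum of
      // the scoring scheme for weak alignments too
      if (!best.found || best.aln.score < min_report_score) {
        AlnResult af = sw_align(fwd, ref, match, mismatch, gap_open, gap_extend);
        AlnResult ar = sw_align(rev, ref, match, mismatch, gap_open, gap_extend);
        Oriented ex;
        if (af.score > 0) { ex.aln = af; ex.fwd = true; ex.found = true; }
        if (ar.score > 0) {
          bool better = !ex.found || ar.score > ex.aln.score ||
            (ar.score == ex.aln.score && ar.ref_start < ex.aln.ref_start);
          if (better) { ex.aln = ar; ex.fwd = false; ex.found = true; }
        }
        if (ex.found && (!best.found || ex.aln.score >= best.aln.score)) best = ex;
      }
    }
    if (!best.found || best.aln.score < min_report_score) {
      ref_start[t] = NA_INTEGER; score[t] = best.found ? best.aln.score : 0;
      nm[t] = NA_INTEGER; cigar[t] = NA_STRING; strand[t] = NA_STRING;
      oseq[t] = fwd; mapped[t] = false;
      continue;
    }
    const std::string& os = best.fwd ? fwd : rev;
    const AlnResult& a = best.aln;
    std::string cig;
    if (a.q_start > 0) cig += std::to_string(a.q_start) + "S";
    cig += a.cigar;
    int right = (int)os.size() - 1 - a.q_end;
    if (right > 0) cig += std::to_string(right) + "S";
    ref_start[t] = a.ref_start + 1;
    score[t] = a.score; nm[t] = a.nm;
    cigar[t] = cig; strand[t] = best.fwd ? "+" : "-";
    oseq[t] = os; mapped[t] = true;
  }
  return DataFrame::create(
    _["ref_start"] = ref_start, _["cigar"] = cigar, _["strand"] = strand,
    _["score"] = score, _["edit_distance"] = nm, _["mapped"] = mapped,
    _["oriented_seq"] = oseq, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Semi-global ("fit") alignment of a shorter sequence onto a longer one:
// global in the shorter, end gaps in the longer are free. Used for the
// shorter-sequence identity convention of greedy 95% clustering.
// Returns matches and total alignment columns of the fitted region.
// [[Rcpp::export]]
List fit_align_cpp(std::string shorter, std::string longer,
                   int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)shorter.size(), n = (int)longer.size();
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1), Hcur(n + 1);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<char> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<char> tbF((size_t)(m + 1) * (n + 1), 0);
  for (int j = 0; j <= n; ++j) Hprev[j] = 0;          // free leading gap in longer
  // leading gap in shorter is a real gap
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = gap_open + (i - 1) * gap_extend;
    tbH[(size_t)i * (n + 1)] = 3;
    Ecur[0] = NEG; Fcur[0] = Hcur[0];
    const char qc = shorter[(size_t)i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * (n + 1) + j;
      int e_open = Hcur[j - 1] + gap_open, e_ext = Ecur[j - 1] + gap_extend;
      int e = std::max(e_open, e_ext); tbE[idx] = (char)(e_ext > e_open); Ecur[j] = e;
      int f_open = Hprev[j] + gap_open, f_ext = Fprev[j] + gap_extend;
      int f = std::max(f_open, f_ext); tbF[idx] = (char)(f_ext > f_open); Fcur[j] = f;
      int s = (base_code(qc) >= 0 && base_code(qc) == base_code(longer[(size_t)j - 1]))
        ? match : mismatch;
      int h = Hprev[j - 1] + s; char code = 1;
      if (e > h) { h = e; code = 2; }
      if (f > h) { h = f; code = 3; }
      Hcur[j] = h; tbH[idx] = code;
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  // free trailing gap in longer: best over final row
  int best = NEG, bj = n;
  for (int j = n; j >= 0; --j) if (Hprev[j] > best) { best = Hprev[j]; bj = j; }
  // traceback to row 0
  int i = m, j = bj, state = 0, matches = 0, columns = 0;
  while (i > 0) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      char c = tbH[idx];
      if (c == 1) {
        ++columns;
        if (base_code(shorter[(size_t)i - 1]) == base_code(longer[(size_t)j - 1]))
          ++matches;
        --i; --j;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns; char c = tbE[idx]; --j; if (!c) state = 0;
    } else {
      ++columns;
      char c = (j > 0) ? tbF[idx] : (char)(i > 1);
      --i; if (!c) state = 0;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["identity"] = columns > 0 ? (double)matches / columns : 0.0);
}

// ---------------------------------------------------------------------------
// Pileup: CIGAR walk over aligned reads
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pileup_cpp(IntegerVector ref_start, CharacterVector cigar,
                CharacterVector oriented_seq, std::string ref) {
  const int L = (int)ref.size();
  IntegerMatrix counts(4, L); // rows A,C,G,T
  IntegerVector depth(L);
  std::map<std::pair<int, std::string>, int> dels, inss;
  const int nr = ref_start.size();
  for (int t = 0; t < nr; ++t) {
    if (ref_start[t] == NA_INTEGER) continue;
    std::string cig = as<std::string>(cigar[t]);
    std::string seq = as<std::string>(oriented_seq[t]);
    int rpos = ref_start[t] - 1; // 0-based
    size_t qpos = 0, k = 0;
    while (k < cig.size()) {
      long len = 0;
      while (k < cig.size() && isdigit(cig[k])) { len = len * 10 + (cig[k] - '0'); ++k; }
      char op = cig[k++];
      if (op == 'S') {
        qpos += (size_t)len;
      } else if (op == 'M') {
        for (long x = 0; x < len; ++x) {
          if (rpos >= L) stop("alignment extends past locus end");
          int b = base_code(seq[qpos]);
          if (b >= 0) counts(b, rpos) += 1;
          depth[rpos] += 1;
          ++rpos; ++qpos;
        }
      } else if (op == 'D') {
        if (rpos + len > L) stop("alignment extends past locus end");
        std::string dseq = ref.substr((size_t)rpos, (size_t)len);
        // anchor = 1-based position of the base before the deleted run
        dels[std::make_pair(rpos, dseq)] += 1;
        for (long x = 0; x < len; ++x) { depth[rpos] += 1; ++rpos; }
      } else if (op == 'I') {
        std::string iseq = seq.substr(qpos, (size_t)len);
        inss[std::make_pair(rpos, iseq)] += 1; // anchor = base before insertion
        qpos += (size_t)len;
      } else {
        stop("unsupported CIGAR op");
      }
    }
  }
  int nd = (int)dels.size(), ni = (int)inss.size();
  IntegerVector dpos(nd), dcount(nd); CharacterVector dseqv(nd);
  int z = 0;
  for (auto& kv : dels) {
    dpos[z] = kv.first.first; dseqv[z] = kv.first.second; dcount[z] = kv.second; ++z;
  }
  IntegerVector ipos(ni), icount(ni); CharacterVector iseqv(ni);
  z = 0;
  for (auto& kv : inss) {
    ipos[z] = kv.first.first; iseqv[z] = kv.first.second; icount[z] = kv.second; ++z;
  }
  return List::create(
    _["counts"] = counts, _["depth"] = depth,
    _["deletions"] = DataFrame::create(_["anchor"] = dpos, _["seq"] = dseqv,
                                       _["count"] = dcount,
                                       _["stringsAsFactors"] = false),
    _["insertions"] = DataFrame::create(_["anchor"] = ipos, _["seq"] = iseqv,
                                        _["count"] = icount,
                                        _["stringsAsFactors"] = false));
}
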