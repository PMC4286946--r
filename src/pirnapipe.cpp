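#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// ---------------------------------------------------------------------------
// Read cleaning: adapter trim -> mean-quality filter -> length filter -> N.
// Adapter: earliest position p where suffix(read from p) matches
// prefix(adapter) over >= min_overlap bases with <= floor(frac*overlap)
// mismatches; trim at p.
// reason codes: 0 keep, 1 low quality, 2 too short, 3 too long, 4 contains N
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_clean_reads(CharacterVector seqs, CharacterVector quals,
                     std::string adapter, int min_overlap,
                     double max_mismatch_frac, double min_mean_quality,
                     int min_length, int max_length) {
  const int n = seqs.size();
  IntegerVector trim_len(n);
  NumericVector mean_q(n);
  LogicalVector keep(n);
  IntegerVector reason(n);
  const int alen = (int) adapter.size();

  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    const int len = (int) LENGTH(STRING_ELT(seqs, i));

    int cut = len;
    for (int p = 0; p <= len - min_overlap; ++p) {
      int ov = std::min(len - p, alen);
      if (ov < min_overlap) break;
      int allowed = (int) std::floor(max_mismatch_frac * ov);
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < ov; ++j) {
        if (s[p + j] != adapter[(size_t) j]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) { cut = p; break; }
    }
    trim_len[i] = cut;

    double qs = 0.0;
    bool hasN = false;
    for (int j = 0; j < cut; ++j) {
      qs += (double) (q[j] - 33);
      if (base_code(s[j]) == 4) hasN = true;
    }
    double mq = cut > 0 ? qs / cut : 0.0;
    mean_q[i] = mq;

    if (cut < min_length) { keep[i] = false; reason[i] = 2; }
    else if (cut > max_length) { keep[i] = false; reason[i] = 3; }
    else if (mq < min_mean_quality) { keep[i] = false; reason[i] = 1; }
    else if (hasN) { keep[i] = false; reason[i] = 4; }
    else { keep[i] = true; reason[i] = 0; }
  }
  return List::create(_["trim_len"] = trim_len, _["mean_q"] = mean_q,
                      _["keep"] = keep, _["reason"] = reason);
}

// ---------------------------------------------------------------------------
// Seed-and-extend ungapped mapper honouring identity/coverage thresholds.
// A tag of length L maps at a locus if some ungapped alignment of
// m >= ceil(min_coverage * L) consecutive tag bases has
// <= floor((1 - min_identity) * m) mismatches.  All loci on both strands
// are reported; per (start, end, strand) the best (max m, then min
// mismatches) alignment is kept.
// ---------------------------------------------------------------------------

struct Locus {
  int chrom, start, end; // 0-based half-open
  char strand;
  int m, mm;             // aligned length, mismatches
};

static void scan_tag(const std::vector<uint8_t> &g,
                     const std::vector<int> &chrom_of,
                     const std::vector<int> &chrom_off,
                     const std::vector<int> &idx_start,
                     const std::vector<int> &idx_pos,
                     int k,
                     const std::vector<uint8_t> &tag, char strand,
                     double min_identity, double min_coverage,
                     std::vector<Locus> &out) {
  const int L = (int) tag.size();
  if (L < k) return;
  const int G = (int) g.size();
  const int m_min = (int) std::ceil(min_coverage * L - 1e-9);

  // candidate diagonals from exact k-mer seeds at every tag offset
  std::vector<int> diags;
  uint32_t key = 0, mask = (1u << (2 * k)) - 1u;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int c = tag[i];
    if (c >= 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t) c) & mask;
    if (++run >= k) {
      int o = i - k + 1; // seed start on tag
      for (int t = idx_start[key]; t < idx_start[key + 1]; ++t)
        diags.push_back(idx_pos[t] - o);
    }
  }
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

  std::vector<uint8_t> mis(L), inv(L);
  for (int d : diags) {
    // per-position mismatch / validity over the full diagonal
    for (int i = 0; i < L; ++i) {
      int gi = d + i;
      if (gi < 0 || gi >= G || g[gi] >= 4) { inv[i] = 1; mis[i] = 1; }
      else { inv[i] = 0; mis[i] = (uint8_t) (g[gi] != tag[i] || tag[i] >= 4); }
    }
    // prefix sums
    std::vector<int> pm(L + 1, 0), pv(L + 1, 0);
    for (int i = 0; i < L; ++i) {
      pm[i + 1] = pm[i] + mis[i];
      pv[i + 1] = pv[i] + inv[i];
    }
    bool found = false;
    for (int m = L; m >= m_min && !found; --m) {
      int allowed = (int) std::floor((1.0 - min_identity) * m + 1e-9);
      int best_mm = allowed + 1, best_s = -1;
      for (int s = 0; s + m <= L; ++s) {
        if (pv[s + m] - pv[s] > 0) continue;
        int mm = pm[s + m] - pm[s];
        if (mm < best_mm) { best_mm = mm; best_s = s; }
      }
      if (best_s >= 0 && best_mm <= allowed) {
        int gstart = d + best_s;
        int ci = chrom_of[gstart];
        Locus lo;
        lo.chrom = ci;
        lo.start = gstart - chrom_off[ci];
        lo.end = lo.start + m;
        lo.strand = strand;
        lo.m = m;
        lo.mm = best_mm;
        out.push_back(lo);
        found = true;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_map_tags(CharacterVector tags, CharacterVector chrom_seqs,
                  int seed_len, double min_identity, double min_coverage,
                  int max_loci) {
  const int k = seed_len;
  if (k < 4 || k > 14) stop("seed_len must be in [4, 14]");
  const int SEP = 50; // N-gap between chromosomes; > max tag length

  // concatenated genome codes
  int nchrom = chrom_seqs.size();
  std::vector<int> chrom_off(nchrom);
  size_t total = 0;
  for (int c = 0; c < nchrom; ++c)
    total += LENGTH(STRING_ELT(chrom_seqs, c)) + SEP;
  std::vector<uint8_t> g;
  g.reserve(total);
  std::vector<int> chrom_of;
  chrom_of.reserve(total);
  for (int c = 0; c < nchrom; ++c) {
    chrom_off[c] = (int) g.size();
    const char *s = CHAR(STRING_ELT(chrom_seqs, c));
    int len = (int) LENGTH(STRING_ELT(chrom_seqs, c));
    for (int i = 0; i < len; ++i) {
      g.push_back((uint8_t) base_code(s[i]));
      chrom_of.push_back(c);
    }
    for (int i = 0; i < SEP; ++i) { g.push_back(4); chrom_of.push_back(c); }
  }
  const int G = (int) g.size();

  // k-mer index (CSR layout)
  const size_t nkeys = ((size_t) 1) << (2 * k);
  std::vector<int> cnt(nkeys + 1, 0);
  uint32_t key = 0, mask = (uint32_t) (nkeys - 1);
  int run = 0;
  for (int i = 0; i < G; ++i) {
    int c = g[i];
    if (c >= 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t) c) & mask;
    if (++run >= k) cnt[key + 1]++;
  }
  std::vector<int> idx_start(nkeys + 1, 0);
  for (size_t i = 1; i <= nkeys; ++i) idx_start[i] = idx_start[i - 1] + cnt[i];
  std::vector<int> idx_pos(idx_start[nkeys]);
  std::vector<int> fill(nkeys, 0);
  key = 0; run = 0;
  for (int i = 0; i < G; ++i) {
    int c = g[i];
    if (c >= 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t) c) & mask;
    if (++run >= k) {
      int p = i - k + 1;
      idx_pos[idx_start[key] + fill[key]++] = p;
    }
  }

  const int ntags = tags.size();
  std::vector<int> out_tag, out_chrom, out_start, out_end, out_m, out_mm;
  std::vector<char> out_strand;
  IntegerVector n_loci(ntags);
  LogicalVector overflow(ntags);

  std::vector<Locus> loci;
  for (int t = 0; t < ntags; ++t) {
    const char *s = CHAR(STRING_ELT(tags, t));
    int L = (int) LENGTH(STRING_ELT(tags, t));
    std::vector<uint8_t> fwd(L), rev(L);
    for (int i = 0; i < L; ++i) {
      int c = base_code(s[i]);
      if (c >= 4) stop("tag %d contains a non-ACGT character", t + 1);
      fwd[i] = (uint8_t) c;
      rev[L - 1 - i] = (uint8_t) (3 - c);
    }
    loci.clear();
    scan_tag(g, chrom_of, chrom_off, idx_start, idx_pos, k, fwd, '+',
             min_identity, min_coverage, loci);
    scan_tag(g, chrom_of, chrom_off, idx_start, idx_pos, k, rev, '-',
             min_identity, min_coverage, loci);
    // order by (chrom, start, strand); dedupe identical intervals keeping
    // the best alignment
    std::sort(loci.begin(), loci.end(), [](const Locus &a, const Locus &b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.start != b.start) return a.start < b.start;
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.end != b.end) return a.end < b.end;
      if (a.m != b.m) return a.m > b.m;
      return a.mm < b.mm;
    });
    std::vector<Locus> uniq;
    for (const Locus &lo : loci) {
      if (!uniq.empty()) {
        const Locus &u = uniq.back();
        if (u.chrom == lo.chrom && u.start == lo.start &&
            u.end == lo.end && u.strand == lo.strand)
          continue;
      }
      uniq.push_back(lo);
    }
    n_loci[t] = (int) uniq.size();
    overflow[t] = (int) uniq.size() > max_loci;
    int emit = std::min((int) uniq.size(), max_loci);
    for (int j = 0; j < emit; ++j) {
      const Locus &lo = uniq[j];
      out_tag.push_back(t + 1);
      out_chrom.push_back(lo.chrom + 1);
      out_start.push_back(lo.start);
      out_end.push_back(lo.end);
      out_strand.push_back(lo.strand);
      out_m.push_back(lo.m);
      out_mm.push_back(lo.mm);
    }
  }

  int nl = (int) out_tag.size();
  CharacterVector strand_col(nl);
  for (int i = 0; i < nl; ++i)
    strand_col[i] = out_strand[i] == '+' ? "+" : "-";
  return List::create(
    _["tag"] = IntegerVector(out_tag.begin(), out_tag.end()),
    _["chrom"] = IntegerVector(out_chrom.begin(), out_chrom.end()),
    _["start"] = IntegerVector(out_start.begin(), out_start.end()),
    _["end"] = IntegerVector(out_end.begin(), out_end.end()),
    _["strand"] = strand_col,
    _["aligned"] = IntegerVector(out_m.begin(), out_m.end()),
    _["mismatches"] = IntegerVector(out_mm.begin(), out_mm.end()),
    _["n_loci"] = n_loci,
    _["overflow"] = overflow);
}
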