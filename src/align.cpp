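#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide code -> 4-bit mask over A/C/G/T.
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 4;
  case 'T': case 't': case 'U': case 'u': return 8;
  case 'R': case 'r': return 1 | 4;
  case 'Y': case 'y': return 2 | 8;
  case 'S': case 's': return 2 | 4;
  case 'W': case 'w': return 1 | 8;
  case 'K': case 'k': return 4 | 8;
  case 'M': case 'm': return 1 | 2;
  case 'B': case 'b': return 2 | 4 | 8;
  case 'D': case 'd': return 1 | 4 | 8;
  case 'H': case 'h': return 1 | 2 | 8;
  case 'V': case 'v': return 1 | 2 | 4;
  case 'N': case 'n': return 15;
  default: return 0;
  }
}

// [[Rcpp::export(name = ".iupacMatchCountCpp")]]
IntegerVector iupac_mismatch_window(CharacterVector seqs, std::string primer,
                                    IntegerVector starts) {
  // Mismatches of `primer` (IUPAC) against each seq at the given 0-based start.
  int n = seqs.size();
  int plen = primer.size();
  std::vector<int> pmask(plen);
  for (int k = 0; k < plen; ++k) pmask[k] = iupac_mask(primer[k]);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = std::strlen(s), st = starts[i], mm = 0;
    if (st < 0 || st + plen > L) { out[i] = NA_INTEGER; continue; }
    for (int k = 0; k < plen; ++k)
      if (!(pmask[k] & iupac_mask(s[st + k]))) ++mm;
    out[i] = mm;
  }
  return out;
}

// [[Rcpp::export(name = ".findPrimerCpp")]]
List find_primer(CharacterVector seqs, std::string primer, int max_mm,
                 bool from_end, int window) {
  // Best (fewest-mismatch) placement of an IUPAC primer near the 5' start
  // (offsets 0..window) or ending within `window` of the 3' end.
  // Ties prefer the position closest to the respective sequence end.
  int n = seqs.size();
  int plen = primer.size();
  std::vector<int> pmask(plen);
  for (int k = 0; k < plen; ++k) pmask[k] = iupac_mask(primer[k]);
  IntegerVector pos(n), mmv(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = std::strlen(s);
    int best_pos = -1, best_mm = max_mm + 1;
    for (int off = 0; off <= window; ++off) {
      int st = from_end ? (L - plen - off) : off;
      if (st < 0 || st + plen > L) break;
      int mm = 0;
      for (int k = 0; k < plen && mm < best_mm; ++k)
        if (!(pmask[k] & iupac_mask(s[st + k]))) ++mm;
      if (mm < best_mm) { best_mm = mm; best_pos = st; }
    }
    if (best_mm > max_mm) { pos[i] = NA_INTEGER; mmv[i] = NA_INTEGER; }
    else { pos[i] = best_pos; mmv[i] = best_mm; }
  }
  return List::create(_["pos"] = pos, _["mismatches"] = mmv);
}

// Needleman-Wunsch with match +1 / mismatch -1 / gap -1, counting matches and
// aligned columns along the traceback. ends_free = semi-global: terminal gaps
// are free and excluded from the column count (p-distance convention);
// otherwise global with terminal gaps counted as columns.
static void nw_counts(const char *a, int n, const char *b, int m,
                      bool ends_free, int &matches, int &columns) {
  std::vector<int> S((n + 1) * (m + 1));
  std::vector<signed char> T((n + 1) * (m + 1)); // 0 diag, 1 up(a gap in b), 2 left
  const int W = m + 1;
  S[0] = 0;
  for (int j = 1; j <= m; ++j) { S[j] = ends_free ? 0 : -j; T[j] = 2; }
  for (int i = 1; i <= n; ++i) { S[i * W] = ends_free ? 0 : -i; T[i * W] = 1; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = S[(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1);
      int up = S[(i - 1) * W + j] - 1;
      int left = S[i * W + (j - 1)] - 1;
      int best = sub; signed char tb = 0;
      if (up > best) { best = up; tb = 1; }
      if (left > best) { best = left; tb = 2; }
      S[i * W + j] = best; T[i * W + j] = tb;
    }
  }
  int ei = n, ej = m;
  if (ends_free) {
    // free end gaps: start traceback at the best cell on the last row/column
    int best = S[n * W + m];
    for (int j = 0; j <= m; ++j)
      if (S[n * W + j] > best) { best = S[n * W + j]; ei = n; ej = j; }
    for (int i = 0; i <= n; ++i)
      if (S[i * W + m] > best) { best = S[i * W + m]; ei = i; ej = m; }
  }
  matches = 0; columns = 0;
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && T[i * W + j] == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      ++columns; --i; --j;
    } else if (i > 0 && (j == 0 || T[i * W + j] == 1)) {
      if (!(ends_free && j == 0)) ++columns;
      --i;
    } else {
      if (!(ends_free && i == 0)) ++columns;
      --j;
    }
  }
}

// [[Rcpp::export(name = ".alignIdentityCpp")]]
NumericMatrix align_identity(CharacterVector a, CharacterVector b, bool ends_free) {
  // Pairwise (elementwise) matches/columns for two equal-length vectors.
  int n = a.size();
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("matches", "columns");
  for (int i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    int matches, columns;
    nw_counts(sa, std::strlen(sa), sb, std::strlen(sb), ends_free, matches, columns);
    out(i, 0) = matches; out(i, 1) = columns;
  }
  return out;
}

// [[Rcpp::export(name = ".distMatrixCpp")]]
NumericMatrix dist_matrix(CharacterVector seqs, bool ends_free) {
  // All-vs-all 1 - matches/columns.
  int n = seqs.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(seqs, i));
    int na = std::strlen(sa);
    for (int j = i + 1; j < n; ++j) {
      const char *sb = CHAR(STRING_ELT(seqs, j));
      int matches, columns;
      nw_counts(sa, na, sb, std::strlen(sb), ends_free, matches, columns);
      double dist = columns > 0 ? 1.0 - (double)matches / columns : 1.0;
      d(i, j) = dist; d(j, i) = dist;
    }
  }
  return d;
}

// [[Rcpp::export(name = ".mergeOverlapCpp")]]
List merge_overlap(CharacterVector r1, CharacterVector q1,
                   CharacterVector rc2, CharacterVector qrc2,
                   int min_overlap, double max_mismatch_frac) {
  // Best ungapped suffix(r1)/prefix(revcomp r2) overlap maximizing matched
  // bases, subject to mismatch fraction <= max_mismatch_frac. Consensus takes
  // the higher-quality base at overlap mismatches; agreeing bases get summed
  // Phred (capped at 60), disagreeing ones |q1-q2| floored at 2.
  int n = r1.size();
  CharacterVector seq(n), qual(n);
  IntegerVector ov(n), mism(n);
  LogicalVector merged(n);
  std::string sbuf, qbuf;
  for (int i = 0; i < n; ++i) {
    const char *s1 = CHAR(STRING_ELT(r1, i));
    const char *u1 = CHAR(STRING_ELT(q1, i));
    const char *s2 = CHAR(STRING_ELT(rc2, i));
    const char *u2 = CHAR(STRING_ELT(qrc2, i));
    int n1 = std::strlen(s1), n2 = std::strlen(s2);
    int best_o = -1, best_matches = -1, best_mm = 0;
    int omax = std::min(n1, n2);
    for (int o = min_overlap; o <= omax; ++o) {
      int allowed = (int)std::floor(o * max_mismatch_frac + 1e-9);
      int mm = 0;
      const char *p1 = s1 + (n1 - o);
      bool ok = true;
      for (int k = 0; k < o; ++k) {
        if (p1[k] != s2[k] && ++mm > allowed) { ok = false; break; }
      }
      if (!ok) continue;
      int matches = o - mm;
      if (matches > best_matches || (matches == best_matches && o > best_o)) {
        best_matches = matches; best_o = o; best_mm = mm;
      }
    }
    if (best_o < 0) {
      merged[i] = false; seq[i] = NA_STRING; qual[i] = NA_STRING;
      ov[i] = NA_INTEGER; mism[i] = NA_INTEGER;
      continue;
    }
    int o = best_o;
    sbuf.assign(s1, n1 - o);
    qbuf.assign(u1, n1 - o);
    for (int k = 0; k < o; ++k) {
      char b1 = s1[n1 - o + k], b2 = s2[k];
      int p1q = u1[n1 - o + k] - 33, p2q = u2[k] - 33;
      if (b1 == b2) {
        sbuf.push_back(b1);
        qbuf.push_back((char)(33 + std::min(60, p1q + p2q)));
      } else if (p1q >= p2q) {
        sbuf.push_back(b1);
        qbuf.push_back((char)(33 + std::max(2, p1q - p2q)));
      } else {
        sbuf.push_back(b2);
        qbuf.push_back((char)(33 + std::max(2, p2q - p1q)));
      }
    }
    sbuf.append(s2 + o, n2 - o);
    qbuf.append(u2 + o, n2 - o);
    seq[i] = sbuf; qual[i] = qbuf;
    ov[i] = o; mism[i] = best_mm; merged[i] = true;
  }
  return List::create(_["merged"] = merged, _["seq"] = seq, _["qual"] = qual,
                      _["overlap"] = ov, _["mismatches"] = mism);
}

// [[Rcpp::export(name = ".injectErrorsCpp")]]
CharacterVector inject_errors(CharacterVector seqs, double rate) {
  // Per-base substitution errors at `rate`, drawn from R's RNG stream so the
  // caller's set.seed() governs reproducibility.
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  if (rate <= 0) return clone(seqs);
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    buf.assign(s);
    for (size_t k = 0; k < buf.size(); ++k) {
      if (unif_rand() < rate) {
        char cur = buf[k];
        char sub = bases[(int)(unif_rand() * 4) & 3];
        while (sub == cur) sub = bases[(int)(unif_rand() * 4) & 3];
        buf[k] = sub;
      }
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".simReadsCpp")]]
List sim_reads(CharacterVector seqs, double rate) {
  // Per-base qualities are drawn from a four-level MiSeq-like profile
  // (mostly high-quality bases with a low-quality tail), rescaled so the
  // mean per-base error probability equals `rate`; substitutions are then
  // injected at each base's quality-implied probability, and the written
  // quality encodes that probability (Sanger offset 33).
  static const double pcat[4] = {2e-4, 1e-3, 5e-3, 3.16e-2};
  static const double wcum[4] = {0.70, 0.85, 0.95, 1.0};
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const double pmean = 0.70 * pcat[0] + 0.15 * pcat[1] + 0.10 * pcat[2] +
                       0.05 * pcat[3];
  const double factor = rate > 0 ? rate / pmean : 0.0;
  int n = seqs.size();
  CharacterVector seq(n), qual(n);
  std::string sbuf, qbuf;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    sbuf.assign(s);
    qbuf.assign(sbuf.size(), (char)(33 + 40));
    if (rate > 0) {
      for (size_t k = 0; k < sbuf.size(); ++k) {
        double u = unif_rand();
        int c = 0;
        while (u > wcum[c]) ++c;
        double p = std::min(0.75, pcat[c] * factor);
        int q = (int)std::lround(-10.0 * std::log10(p));
        if (q < 2) q = 2; else if (q > 41) q = 41;
        qbuf[k] = (char)(33 + q);
        if (unif_rand() < p) {
          char cur = sbuf[k];
          char sub = bases[(int)(unif_rand() * 4) & 3];
          while (sub == cur) sub = bases[(int)(unif_rand() * 4) & 3];
          sbuf[k] = sub;
        }
      }
    }
    seq[i] = sbuf; qual[i] = qbuf;
  }
  return List::create(_["seq"] = seq, _["qual"] = qual);
}

// [[Rcpp::export(name = ".expectedErrorsCpp")]]
NumericVector expected_errors(CharacterVector quals) {
  // Sum of 10^(-Q/10) over a Sanger-offset quality string.
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    double ee = 0.0;
    for (; *q; ++q) ee += std::pow(10.0, -(*q - 33) / 10.0);
    out[i] = ee;
  }
  return out;
}
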