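#include <Rcpp.h>
#include <array>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Maximum number of identical aligned residue pairs over all global
// alignments of a and b. With match reward 1 and free gaps/mismatches this
// is the longest-common-subsequence length, computed with a two-row DP.
static int match_count_dp(const char *a, int n, const char *b, int m) {
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded variant: exact whenever the true value is >= cmin (an optimal
// equal-length alignment with M matches never strays more than n - M cells
// from the diagonal, so a band of half-width n - cmin + 1 contains it);
// below cmin it is a lower bound, which callers only compare against cmin.
static int match_count_banded(const char *a, const char *b, int n, int w) {
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int lo = i - w > 1 ? i - w : 1;
    int hi = i + w < n ? i + w : n;
    cur[lo - 1] = 0;
    for (int j = lo; j <= hi; ++j) {
      int v = a[i - 1] == b[j - 1] ? prev[j - 1] + 1 : 0;
      if (prev[j] > v) v = prev[j];
      if (cur[j - 1] > v) v = cur[j - 1];
      cur[j] = v;
    }
    if (hi < n) cur[hi + 1] = 0;
    std::swap(prev, cur);
  }
  return prev[n];
}

static int hamming_matches(const char *a, const char *b, int n) {
  int h = 0;
  for (int i = 0; i < n; ++i)
    if (a[i] == b[i]) ++h;
  return h;
}

static std::array<int, 26> letter_counts(const char *s, int n) {
  std::array<int, 26> c{};
  for (int i = 0; i < n; ++i) {
    int k = s[i] - 'A';
    if (k >= 0 && k < 26) ++c[k];
  }
  return c;
}

// Upper bound on aligned matches: no alignment can pair more copies of a
// letter than both sequences carry.
static int count_bound(const std::array<int, 26> &a,
                       const std::array<int, 26> &b) {
  int u = 0;
  for (int k = 0; k < 26; ++k)
    u += a[k] < b[k] ? a[k] : b[k];
  return u;
}

// [[Rcpp::export(name = ".seq_identity_cpp")]]
NumericVector seq_identity_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    int la = (int)std::strlen(sa), lb = (int)std::strlen(sb);
    if (la == 0 || lb == 0)
      stop("empty sequence");
    int denom = la < lb ? la : lb;
    int h = (la == lb) ? hamming_matches(sa, sb, la) : -1;
    int m;
    if (la == lb && la - h <= 1)
      m = h; // a single mismatch cannot be rescued by gaps
    else
      m = match_count_dp(sa, la, sb, lb);
    out[i] = (double)m / (double)denom;
  }
  return out;
}

// Greedy incremental clustering of pre-sorted sequences. Sequences must be
// uppercase A-Z. Each sequence is compared against every earlier-founded
// representative of the same length and joins the representative with the
// highest identity >= threshold (ties -> lowest cluster id), else founds a
// new cluster. Per-letter count bounds and the Hamming lower bound prune
// comparisons without changing the result.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
List greedy_cluster_cpp(CharacterVector seqs, double threshold) {
  int n = seqs.size();
  IntegerVector assign(n);
  NumericVector ident(n);
  std::vector<int> rep_idx;
  std::vector<int> rep_len;
  std::vector<std::array<int, 26>> rep_cnt;

  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = (int)std::strlen(s);
    if (len == 0)
      stop("empty sequence");
    std::array<int, 26> cnt = letter_counts(s, len);
    // smallest match count reaching the threshold
    int cmin = (int)std::ceil(threshold * len - 1e-9);
    if (cmin < 0) cmin = 0;
    int best = -1, best_m = -1;
    for (size_t r = 0; r < rep_idx.size(); ++r) {
      if (rep_len[r] != len)
        continue;
      int U = count_bound(cnt, rep_cnt[r]);
      if (U < cmin || U <= best_m)
        continue;
      const char *t = CHAR(STRING_ELT(seqs, rep_idx[r]));
      int h = hamming_matches(s, t, len);
      int m = (len - h <= 1 || h == U)
                  ? h
                  : match_count_banded(s, t, len, len - cmin + 1);
      if (m >= cmin && m > best_m) {
        best_m = m;
        best = (int)r;
      }
    }
    if (best >= 0) {
      assign[i] = best;
      ident[i] = (double)best_m / (double)len;
    } else {
      assign[i] = (int)rep_idx.size();
      ident[i] = 1.0;
      rep_idx.push_back(i);
      rep_len.push_back(len);
      rep_cnt.push_back(cnt);
    }
  }
  IntegerVector reps(rep_idx.begin(), rep_idx.end());
  return List::create(_["cluster"] = assign, _["identity"] = ident,
                      _["rep_index"] = reps);
}

// TRUE if any pair of equal-length sequences reaches the identity threshold
// (used by the simulator to detect lineage collisions).
// [[Rcpp::export(name = ".any_identity_ge_cpp")]]
bool any_identity_ge_cpp(CharacterVector seqs, double threshold) {
  int n = seqs.size();
  std::vector<const char *> s(n);
  std::vector<int> len(n);
  std::vector<std::array<int, 26>> cnt(n);
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = (int)std::strlen(s[i]);
    cnt[i] = letter_counts(s[i], len[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (len[i] != len[j])
        continue;
      int cmin = (int)std::ceil(threshold * len[i] - 1e-9);
      if (count_bound(cnt[i], cnt[j]) < cmin)
        continue;
      int h = hamming_matches(s[i], s[j], len[i]);
      int m = (len[i] - h <= 1) ? h : match_count_dp(s[i], len[i], s[j], len[j]);
      if (m >= cmin)
        return true;
    }
  }
  return false;
}

static char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'W': return 'W';
  default: return 'N';
  }
}

// Overlap-merge paired reads. The reverse mate is reverse-complemented, then
// every suffix(fwd)/prefix(revcomp) overlap of length >= min_overlap is
// scored; the overlap with the lowest mismatch fraction wins (ties -> longest
// overlap). 'N' never counts as a match. At overlapping positions the
// higher-quality base is kept: quality max(q1,q2) when the bases agree,
// |q1-q2| when they disagree (forward base on an exact quality tie); a
// non-'N' base always beats 'N'.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector rev,
                     CharacterVector fwd_qual, CharacterVector rev_qual,
                     int min_overlap, double max_mismatch_rate) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mism(n);
  LogicalVector joined(n);
  std::string rc, rq, out, outq;
  for (int i = 0; i < n; ++i) {
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *r = CHAR(STRING_ELT(rev, i));
    const char *fq = CHAR(STRING_ELT(fwd_qual, i));
    const char *q2 = CHAR(STRING_ELT(rev_qual, i));
    int n1 = (int)std::strlen(f), n2 = (int)std::strlen(r);
    if (n1 == 0 || n2 == 0)
      stop("empty sequence in read pair");
    if ((int)std::strlen(fq) != n1 || (int)std::strlen(q2) != n2)
      stop("sequence/quality length mismatch");
    rc.resize(n2);
    rq.resize(n2);
    for (int k = 0; k < n2; ++k) {
      rc[k] = comp_base(r[n2 - 1 - k]);
      rq[k] = q2[n2 - 1 - k];
    }
    int maxo = n1 < n2 ? n1 : n2;
    int best_o = -1, best_mm = 0;
    double best_fr = 2.0;
    for (int o = min_overlap; o <= maxo; ++o) {
      // an overlap is only useful if its mismatch fraction is admissible
      // and not worse than the best so far; bail out of the scan as soon
      // as the mismatch count exceeds that ceiling
      double cap = best_fr < max_mismatch_rate ? best_fr : max_mismatch_rate;
      int mm_cap = (int)std::floor(cap * o + 1e-9);
      int mm = 0;
      const char *fs = f + (n1 - o);
      for (int k = 0; k < o; ++k) {
        char a = fs[k], b = rc[k];
        if (a != b || a == 'N') {
          if (++mm > mm_cap)
            break;
        }
      }
      if (mm > mm_cap)
        continue;
      double fr = (double)mm / (double)o;
      if (fr < best_fr - 1e-12 ||
          (std::fabs(fr - best_fr) <= 1e-12 && o > best_o)) {
        best_fr = fr;
        best_o = o;
        best_mm = mm;
      }
    }
    if (best_o < 0 || best_fr > max_mismatch_rate + 1e-12) {
      mseq[i] = NA_STRING;
      mqual[i] = NA_STRING;
      overlap[i] = NA_INTEGER;
      mism[i] = NA_INTEGER;
      joined[i] = false;
      continue;
    }
    int o = best_o;
    int total = n1 + n2 - o;
    out.assign(f, n1 - o);
    outq.assign(fq, n1 - o);
    for (int k = 0; k < o; ++k) {
      char a = f[n1 - o + k], b = rc[k];
      int qa = fq[n1 - o + k] - 33, qb = rq[k] - 33;
      char base, q;
      if (a == b) {
        base = a;
        q = (char)(33 + (qa > qb ? qa : qb));
      } else if (a == 'N' && b != 'N') {
        base = b;
        q = (char)(33 + qb);
      } else if (b == 'N' && a != 'N') {
        base = a;
        q = (char)(33 + qa);
      } else {
        base = qb > qa ? b : a;
        q = (char)(33 + (qa > qb ? qa - qb : qb - qa));
      }
      out.push_back(base);
      outq.push_back(q);
    }
    out.append(rc, o, std::string::npos);
    outq.append(rq, o, std::string::npos);
    if ((int)out.size() != total)
      stop("internal merge length error");
    mseq[i] = out;
    mqual[i] = outq;
    overlap[i] = o;
    mism[i] = best_mm;
    joined[i] = true;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = overlap, _["mismatches"] = mism,
                      _["joined"] = joined);
}

// [[Rcpp::export(name = ".mean_phred_cpp")]]
NumericVector mean_phred_cpp(CharacterVector qual) {
  int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = (int)std::strlen(q);
    if (len == 0) {
      out[i] = NA_REAL;
      continue;
    }
    long s = 0;
    for (int k = 0; k < len; ++k)
      s += q[k] - 33;
    out[i] = (double)s / (double)len;
  }
  return out;
}

// Inject i.i.d. per-base substitutions at the given rate, using R's RNG so
// results are reproducible under set.seed(). Substituted bases are drawn
// uniformly from the three alternatives.
// [[Rcpp::export(name = ".inject_substitutions_cpp")]]
List inject_substitutions_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  IntegerVector nerr(n);
  std::string s;
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(seqs, i));
    int len = (int)std::strlen(x);
    int k = (int)R::rbinom((double)len, rate);
    if (k == 0) {
      out[i] = seqs[i];
      nerr[i] = 0;
      continue;
    }
    s.assign(x, len);
    // sample k distinct positions
    std::vector<int> pos;
    pos.reserve(k);
    while ((int)pos.size() < k) {
      int p = (int)std::floor(unif_rand() * len);
      if (p >= len) p = len - 1;
      bool dup = false;
      for (int t : pos)
        if (t == p) { dup = true; break; }
      if (!dup)
        pos.push_back(p);
    }
    for (int p : pos) {
      char old = s[p];
      char nb;
      do {
        nb = bases[(int)std::floor(unif_rand() * 4) & 3];
      } while (nb == old);
      s[p] = nb;
    }
    out[i] = s;
    nerr[i] = k;
  }
  return List::create(_["seq"] = out, _["n_sub"] = nerr);
}
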