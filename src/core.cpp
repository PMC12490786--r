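#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N';
}

static inline double sub_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;   // N is scored 0 against anything
  return (a == b) ? match : mismatch;
}

// Global affine-gap alignment (Gotoh). End gaps are penalized: the first
// base of any gap costs gapOpen, each further base gapExtend. Traceback
// tie-break: substitution preferred over gap, gap-in-query preferred over
// gap-in-reference, applied while scanning back from the ends.
static void nw_one(const std::string& q, const std::string& r,
                   double match, double mismatch,
                   double gapOpen, double gapExtend,
                   double& score_out, std::string& aq, std::string& ar) {
  const int n = (int)q.size(), m = (int)r.size();
  for (int i = 0; i < n; ++i)
    if (!valid_base(q[i])) stop("non-DNA character in query: '%s'", std::string(1, q[i]));
  for (int j = 0; j < m; ++j)
    if (!valid_base(r[j])) stop("non-DNA character in reference: '%s'", std::string(1, r[j]));

  // state 0 = M (q[i] vs r[j]), 1 = X (gap in query, consumes r),
  // 2 = Y (gap in reference, consumes q)
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF), Y((n + 1) * W, NEG_INF);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1), tbY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[j] = -(gapOpen + (j - 1) * gapExtend);
    tbX[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Y[i * W] = -(gapOpen + (i - 1) * gapExtend);
    tbY[i * W] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      // M: diagonal; predecessor preference M > X > Y on ties
      {
        const int p = (i - 1) * W + (j - 1);
        double best = M[p]; signed char st = 0;
        if (X[p] > best) { best = X[p]; st = 1; }
        if (Y[p] > best) { best = Y[p]; st = 2; }
        if (best > NEG_INF) {
          M[c] = best + sub_score(q[i - 1], r[j - 1], match, mismatch);
          tbM[c] = st;
        }
      }
      // X: gap in query (consume r[j-1]); open from M or Y, extend from X
      {
        const int p = i * W + (j - 1);
        double best = M[p] - gapOpen; signed char st = 0;
        if (X[p] - gapExtend > best) { best = X[p] - gapExtend; st = 1; }
        if (Y[p] - gapOpen > best) { best = Y[p] - gapOpen; st = 2; }
        if (best > NEG_INF) { X[c] = best; tbX[c] = st; }
      }
      // Y: gap in reference (consume q[i-1])
      {
        const int p = (i - 1) * W + j;
        double best = M[p] - gapOpen; signed char st = 0;
        if (X[p] - gapOpen > best) { best = X[p] - gapOpen; st = 1; }
        if (Y[p] - gapExtend > best) { best = Y[p] - gapExtend; st = 2; }
        if (best > NEG_INF) { Y[c] = best; tbY[c] = st; }
      }
    }
  }

  const int e = n * W + m;
  double best = M[e]; int state = 0;
  if (X[e] > best) { best = X[e]; state = 1; }
  if (Y[e] > best) { best = Y[e]; state = 2; }
  // tie preference at the end: M over X over Y (>= handled by order above
  // since M initialised first and strict > used after)
  score_out = best;

  aq.clear(); ar.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      aq.push_back(q[i - 1]); ar.push_back(r[j - 1]);
      state = tbM[c]; --i; --j;
    } else if (state == 1) {
      aq.push_back('-'); ar.push_back(r[j - 1]);
      state = tbX[c]; --j;
    } else {
      aq.push_back(q[i - 1]); ar.push_back('-');
      state = tbY[c]; --i;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
}

// [[Rcpp::export]]
List nw_align_cpp(CharacterVector query, CharacterVector reference,
                  double match = 5.0, double mismatch = -4.0,
                  double gapOpen = 10.0, double gapExtend = 0.5) {
  const int nq = query.size();
  if (reference.size() != 1 && reference.size() != nq)
    stop("reference must have length 1 or length(query)");
  NumericVector scores(nq);
  CharacterVector aq(nq), ar(nq);
  for (int k = 0; k < nq; ++k) {
    std::string q = as<std::string>(query[k]);
    std::string r = as<std::string>(reference[reference.size() == 1 ? 0 : k]);
    if (q.empty() || r.empty()) stop("empty sequence");
    double s; std::string a, b;
    nw_one(q, r, match, mismatch, gapOpen, gapExtend, s, a, b);
    scores[k] = s; aq[k] = a; ar[k] = b;
  }
  return List::create(_["score"] = scores, _["query"] = aq, _["reference"] = ar);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int minOverlap = 10, double maxMismatchFrac = 0.25) {
  const int n = seq1.size();
  if (qual1.size() != n || seq2.size() != n || qual2.size() != n)
    stop("input vectors must have equal length");
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n);
  LogicalVector merged(n);
  for (int k = 0; k < n; ++k) {
    std::string s1 = as<std::string>(seq1[k]);
    std::string q1 = as<std::string>(qual1[k]);
    std::string s2 = as<std::string>(seq2[k]);
    std::string q2 = as<std::string>(qual2[k]);
    if (s1.size() != q1.size() || s2.size() != q2.size())
      stop("sequence/quality length mismatch at record %d", k + 1);
    // reverse-complement read 2 onto the forward strand
    std::string rc2(s2.rbegin(), s2.rend());
    for (size_t i = 0; i < rc2.size(); ++i) rc2[i] = comp_base(rc2[i]);
    std::string rq2(q2.rbegin(), q2.rend());

    const int L1 = (int)s1.size(), L2 = (int)rc2.size();
    const int maxL = std::min(L1, L2);
    int bestL = -1, bestMatches = -1;
    for (int L = minOverlap; L <= maxL; ++L) {
      int matches = 0;
      const char* a = s1.data() + (L1 - L);
      const char* b = rc2.data();
      for (int i = 0; i < L; ++i) if (a[i] == b[i]) ++matches;
      if ((double)(L - matches) / (double)L > maxMismatchFrac) continue;
      if (matches > bestMatches || (matches == bestMatches && L > bestL)) {
        bestMatches = matches; bestL = L;
      }
    }
    if (bestL < 0) { merged[k] = false; mseq[k] = ""; mqual[k] = ""; overlap[k] = 0; continue; }
    const int L = bestL;
    std::string os = s1.substr(0, L1 - L);
    std::string oq = q1.substr(0, L1 - L);
    for (int i = 0; i < L; ++i) {
      char c1 = s1[L1 - L + i], c2 = rc2[i];
      char p1 = q1[L1 - L + i], p2 = rq2[i];
      if (c1 == c2) { os.push_back(c1); oq.push_back(std::max(p1, p2)); }
      else if (p2 > p1) { os.push_back(c2); oq.push_back(p2); }
      else { os.push_back(c1); oq.push_back(std::max(p1, p2)); }
    }
    os.append(rc2.substr(L));
    oq.append(rq2.substr(L));
    merged[k] = true; mseq[k] = os; mqual[k] = oq; overlap[k] = L;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq,
                      _["qual"] = mqual, _["overlap"] = overlap);
}

// [[Rcpp::export]]
IntegerVector count_low_q_cpp(CharacterVector qual, int threshold = 20, int offset = 33) {
  const int n = qual.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char* q = CHAR(STRING_ELT(qual, k));
    int c = 0;
    for (const char* p = q; *p; ++p) if ((int)*p - offset < threshold) ++c;
    out[k] = c;
  }
  return out;
}

// Hamming distance of each string in x against pattern (equal lengths assumed;
// shorter/longer strings return NA)
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector x, std::string pattern) {
  const int n = x.size();
  const size_t L = pattern.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char* s = CHAR(STRING_ELT(x, k));
    if (std::strlen(s) != L) { out[k] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t i = 0; i < L; ++i) if (s[i] != pattern[i]) ++d;
    out[k] = d;
  }
  return out;
}
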