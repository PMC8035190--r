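#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise DP (Gotoh, three states) over short amplicon-scale
// sequences. States: M (diagonal), D (gap in query, consumes reference),
// I (gap in reference, consumes query). A gap of length L costs
// gap_open + L * gap_extend. Tie-breaking is fixed to M > D > I everywhere
// so alignments are reproducible across platforms.

static const int NEG = INT_MIN / 4;

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return 0; // N is scored 0 against anything
  return (a == b) ? match : mismatch;
}

// pick max with preference order M(0) > D(1) > I(2)
static inline int argmax3(int m, int d, int i, int &best) {
  best = m; int w = 0;
  if (d > best) { best = d; w = 1; }
  if (i > best) { best = i; w = 2; }
  return w;
}

// mode: 0 = global (both sequences end to end)
//       1 = fitting ("end-to-end" for the query, reference ends free)
//       2 = local (Smith-Waterman)
// [[Rcpp::export(name = ".align_cpp")]]
List align_cpp(std::string query, std::string ref,
               int match, int mismatch, int gap_open, int gap_extend,
               int mode) {
  const int n = (int) query.size(), m = (int) ref.size();
  const int W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), D((n + 1) * W, NEG), I((n + 1) * W, NEG);
  // traceback: predecessor state for each cell/state; 0=M,1=D,2=I, 3=START
  std::vector<unsigned char> pM((n + 1) * W, 3), pD((n + 1) * W, 3), pI((n + 1) * W, 3);

  M[0] = 0;
  for (int j = 1; j <= m; ++j) {
    if (mode == 0) { D[j] = gap_open + j * gap_extend; pD[j] = (j == 1) ? 0 : 1; }
    else M[j] = 0; // fitting/local: free start anywhere on the reference
  }
  for (int i = 1; i <= n; ++i) {
    if (mode != 2) { I[i * W] = gap_open + i * gap_extend; pI[i * W] = (i == 1) ? 0 : 2; }
    if (mode == 2) M[i * W] = NEG;
  }

  int bestScore = (mode == 2) ? 0 : NEG;
  int bi = 0, bj = 0, bs = 0; // local best end

  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, up = (i - 1) * W + j, left = c - 1, diag = up - 1;
      // D: gap in query (consumes ref)
      {
        int fromM = (M[left] <= NEG) ? NEG : M[left] + gap_open + gap_extend;
        int fromD = (D[left] <= NEG) ? NEG : D[left] + gap_extend;
        int fromI = (I[left] <= NEG) ? NEG : I[left] + gap_open + gap_extend;
        int best; int w = argmax3(fromM, fromD, fromI, best);
        D[c] = best; pD[c] = (unsigned char) w;
      }
      // I: gap in reference (consumes query)
      {
        int fromM = (M[up] <= NEG) ? NEG : M[up] + gap_open + gap_extend;
        int fromD = (D[up] <= NEG) ? NEG : D[up] + gap_open + gap_extend;
        int fromI = (I[up] <= NEG) ? NEG : I[up] + gap_extend;
        int best; int w = argmax3(fromM, fromD, fromI, best);
        I[c] = best; pI[c] = (unsigned char) w;
      }
      // M: diagonal
      {
        int s = subscore(qc, ref[j - 1], match, mismatch);
        int best; int w = argmax3(M[diag], D[diag], I[diag], best);
        if (mode == 2 && best < 0) { best = 0; w = 3; } // local restart
        M[c] = (best <= NEG) ? NEG : best + s;
        pM[c] = (unsigned char) w;
        if (mode == 2 && M[c] > bestScore) { bestScore = M[c]; bi = i; bj = j; bs = 0; }
      }
    }
  }

  // choose endpoint
  int ei = n, ej = m, es = 0;
  if (mode == 0) {
    int best; es = argmax3(M[n * W + m], D[n * W + m], I[n * W + m], best);
    bestScore = best;
  } else if (mode == 1) {
    bestScore = NEG; ej = 0; es = 0;
    for (int j = 0; j <= m; ++j) { // free trailing reference; prefer M, smaller j
      int best; int w = argmax3(M[n * W + j], NEG, I[n * W + j], best);
      if (best > bestScore) { bestScore = best; ej = j; es = (w == 2) ? 2 : 0; }
    }
    ei = n;
  } else {
    if (bestScore <= 0)
      return List::create(_["score"] = 0, _["ops"] = IntegerVector(0),
                          _["ref_start"] = 0, _["query_start"] = 0,
                          _["ref_end"] = 0, _["query_end"] = 0);
    ei = bi; ej = bj; es = bs;
  }

  // traceback; column codes: 0 match, 1 mismatch, 2 deletion (ref), 3 insertion (query)
  std::vector<int> cols;
  int i = ei, j = ej, s = es;
  while (!(i == 0 && j == 0)) {
    if (mode != 0 && s == 0 && i == 0) break;   // fitting/local: row 0 is a free start
    if (s == 0) {
      unsigned char p = pM[i * W + j];
      cols.push_back((query[i - 1] == ref[j - 1] &&
                      query[i - 1] != 'N' && ref[j - 1] != 'N') ? 0 : 1);
      --i; --j;
      if (mode == 2 && p == 3) break;           // local alignment start marker
      s = p;
    } else if (s == 1) {
      unsigned char p = pD[i * W + j];
      cols.push_back(2);
      --j; s = p;
    } else {
      unsigned char p = pI[i * W + j];
      cols.push_back(3);
      --i; s = p;
    }
  }
  std::reverse(cols.begin(), cols.end());
  return List::create(_["score"] = bestScore,
                      _["ops"] = IntegerVector(cols.begin(), cols.end()),
                      _["ref_start"] = j, _["query_start"] = i,
                      _["ref_end"] = ej, _["query_end"] = ei);
}

// Best paired-end overlap between read 1 and the reverse-complemented read 2.
// Chooses the overlap maximizing matched bases subject to the mismatch budget;
// ties broken toward the longer overlap. Returns 0 when nothing qualifies.
// [[Rcpp::export(name = ".best_overlap_cpp")]]
IntegerVector best_overlap_cpp(std::string a, std::string b,
                               int min_overlap, double max_mismatch_frac) {
  const int la = (int) a.size(), lb = (int) b.size();
  const int omax = std::min(la, lb);
  int best_o = 0, best_match = -1, best_mm = 0;
  for (int o = min_overlap; o <= omax; ++o) {
    int mm = 0, mt = 0;
    const int budget = (int) std::floor(o * max_mismatch_frac);
    const char *pa = a.data() + (la - o), *pb = b.data();
    for (int k = 0; k < o; ++k) {
      if (pa[k] == pb[k] && pa[k] != 'N') ++mt; else ++mm;
      if (mm > budget) break;
    }
    if (mm <= budget && mt >= best_match) { best_match = mt; best_o = o; best_mm = mm; }
  }
  return IntegerVector::create(best_o, best_mm < 0 ? 0 : best_mm);
}

// 3' adapter trimming: longest read suffix matching an adapter prefix with
// at most floor(o * max_mismatch_frac) mismatches, o >= min_overlap.
// Returns the number of bases to trim per read (0 = no match).
// [[Rcpp::export(name = ".trim3p_cpp")]]
IntegerVector trim3p_cpp(CharacterVector reads, std::string adapter,
                         int min_overlap, double max_mismatch_frac) {
  const int la = (int) adapter.size();
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    const int ls = (int) s.size();
    int trim = 0;
    const int omax = std::min(ls, la);
    for (int o = omax; o >= min_overlap; --o) {
      int mm = 0;
      const int budget = (int) std::floor(o * max_mismatch_frac);
      const char *ps = s.data() + (ls - o);
      for (int k = 0; k < o; ++k) {
        if (ps[k] != adapter[k]) ++mm;
        if (mm > budget) break;
      }
      if (mm <= budget) { trim = o; break; }
    }
    out[r] = trim;
  }
  return out;
}
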