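#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Gap-budgeted global alignment between an sgRNA spacer (guide row) and a
// genomic protospacer window (target row). Gaps are single-column indels,
// each consuming one unit of the gap budget; no affine extension. A gap in
// the guide row is a DNA bulge (unpaired genomic base), a gap in the target
// row an RNA bulge (unpaired spacer base).
//
// DP state (i, j, g): i guide bases consumed, j target bases consumed, g
// gap columns used. Within a state, ties on score keep the path with fewer
// mismatches; across final states ties prefer fewer gaps. Traceback at
// exact ties takes gap moves first, which (running right to left) places
// tied gap columns at the PAM-proximal end.

static const double NEG_INF = -1e18;

struct DPTables {
  std::vector<double> S;  // best score
  std::vector<int> M;     // min mismatches among best-score paths
  int n, m, G;
  inline int idx(int i, int j, int g) const {
    return (i * (m + 1) + j) * (G + 1) + g;
  }
};

static void fill_dp(const std::string &guide, const std::string &target,
                    double match, double mismatch, double gap, int max_gaps,
                    DPTables &T) {
  int n = guide.size(), m = target.size(), G = max_gaps;
  T.n = n; T.m = m; T.G = G;
  T.S.assign((n + 1) * (m + 1) * (G + 1), NEG_INF);
  T.M.assign((n + 1) * (m + 1) * (G + 1), 0);
  T.S[T.idx(0, 0, 0)] = 0.0;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      for (int g = 0; g <= G; ++g) {
        if (i == 0 && j == 0) continue;
        double best = NEG_INF; int bmis = 0;
        if (i > 0 && j > 0) {
          double prev = T.S[T.idx(i - 1, j - 1, g)];
          if (prev > NEG_INF / 2) {
            bool is_match = guide[i - 1] == target[j - 1];
            double sc = prev + (is_match ? match : mismatch);
            int mis = T.M[T.idx(i - 1, j - 1, g)] + (is_match ? 0 : 1);
            if (sc > best || (sc == best && mis < bmis)) { best = sc; bmis = mis; }
          }
        }
        if (g > 0) {
          if (i > 0) {  // RNA bulge: guide base over a gap in the target row
            double prev = T.S[T.idx(i - 1, j, g - 1)];
            if (prev > NEG_INF / 2) {
              double sc = prev + gap;
              int mis = T.M[T.idx(i - 1, j, g - 1)];
              if (sc > best || (sc == best && mis < bmis)) { best = sc; bmis = mis; }
            }
          }
          if (j > 0) {  // DNA bulge: target base over a gap in the guide row
            double prev = T.S[T.idx(i, j - 1, g - 1)];
            if (prev > NEG_INF / 2) {
              double sc = prev + gap;
              int mis = T.M[T.idx(i, j - 1, g - 1)];
              if (sc > best || (sc == best && mis < bmis)) { best = sc; bmis = mis; }
            }
          }
        }
        T.S[T.idx(i, j, g)] = best;
        T.M[T.idx(i, j, g)] = bmis;
      }
    }
  }
}

// [[Rcpp::export]]
List dp_align_cpp(std::string guide, std::string target, double match,
                  double mismatch, double gap, int max_gaps) {
  int n = guide.size(), m = target.size();
  if (std::abs(n - m) > max_gaps)
    stop("length difference %d exceeds the gap budget %d", std::abs(n - m), max_gaps);
  DPTables T;
  fill_dp(guide, target, match, mismatch, gap, max_gaps, T);

  // final state: max score, then fewest gaps, then fewest mismatches
  double best = NEG_INF; int bg = 0, bmis = 0;
  for (int g = 0; g <= max_gaps; ++g) {
    double sc = T.S[T.idx(n, m, g)];
    if (sc <= NEG_INF / 2) continue;
    int mis = T.M[T.idx(n, m, g)];
    if (sc > best || (sc == best && (g < bg || (g == bg && mis < bmis)))) {
      best = sc; bg = g; bmis = mis;
    }
  }
  if (best <= NEG_INF / 2) stop("no feasible alignment within the gap budget");

  // traceback; gap moves preferred at exact ties (PAM-proximal-most gaps)
  std::string ag, at;
  int i = n, j = m, g = bg;
  while (i > 0 || j > 0) {
    double cur = T.S[T.idx(i, j, g)];
    int curm = T.M[T.idx(i, j, g)];
    bool moved = false;
    if (g > 0 && j > 0) {  // DNA bulge column
      double prev = T.S[T.idx(i, j - 1, g - 1)];
      if (prev > NEG_INF / 2 && prev + gap == cur &&
          T.M[T.idx(i, j - 1, g - 1)] == curm) {
        ag.push_back('-'); at.push_back(target[j - 1]);
        --j; --g; moved = true;
      }
    }
    if (!moved && g > 0 && i > 0) {  // RNA bulge column
      double prev = T.S[T.idx(i - 1, j, g - 1)];
      if (prev > NEG_INF / 2 && prev + gap == cur &&
          T.M[T.idx(i - 1, j, g - 1)] == curm) {
        ag.push_back(guide[i - 1]); at.push_back('-');
        --i; --g; moved = true;
      }
    }
    if (!moved && i > 0 && j > 0) {
      bool is_match = guide[i - 1] == target[j - 1];
      double prev = T.S[T.idx(i - 1, j - 1, g)];
      if (prev > NEG_INF / 2 && prev + (is_match ? match : mismatch) == cur &&
          T.M[T.idx(i - 1, j - 1, g)] + (is_match ? 0 : 1) == curm) {
        ag.push_back(guide[i - 1]); at.push_back(target[j - 1]);
        --i; --j; moved = true;
      }
    }
    if (!moved) stop("internal error: traceback dead end");
  }
  std::reverse(ag.begin(), ag.end());
  std::reverse(at.begin(), at.end());

  int n_match = 0, n_mismatch = 0, n_dna = 0, n_rna = 0;
  for (size_t k = 0; k < ag.size(); ++k) {
    if (ag[k] == '-') ++n_dna;
    else if (at[k] == '-') ++n_rna;
    else if (ag[k] == at[k]) ++n_match;
    else ++n_mismatch;
  }
  return List::create(
    _["aligned_guide"] = ag, _["aligned_target"] = at, _["score"] = best,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_dna_bulge"] = n_dna, _["n_rna_bulge"] = n_rna);
}

static double score_only(const std::string &guide, const std::string &target,
                         double match, double mismatch, double gap, int max_gaps) {
  int n = guide.size(), m = target.size(), G = max_gaps;
  if (std::abs(n - m) > G) return NEG_INF;
  // rolling DP over i, keeping (j, g) planes
  std::vector<double> prev((m + 1) * (G + 1), NEG_INF), cur((m + 1) * (G + 1));
  prev[0] = 0.0;
  for (int j = 1; j <= m && j <= G; ++j)
    prev[j * (G + 1) + j] = gap * j;  // i = 0: j columns, all guide-row gaps
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    for (int j = 0; j <= m; ++j) {
      for (int g = 0; g <= G; ++g) {
        double best = NEG_INF;
        if (j > 0) {
          double p = prev[(j - 1) * (G + 1) + g];
          if (p > NEG_INF / 2) {
            double sc = p + (guide[i - 1] == target[j - 1] ? match : mismatch);
            if (sc > best) best = sc;
          }
        }
        if (g > 0) {
          double p = prev[j * (G + 1) + g - 1];
          if (p > NEG_INF / 2 && p + gap > best) best = p + gap;
          if (j > 0) {
            double q = cur[(j - 1) * (G + 1) + g - 1];
            if (q > NEG_INF / 2 && q + gap > best) best = q + gap;
          }
        }
        cur[j * (G + 1) + g] = best;
      }
    }
    std::swap(prev, cur);
  }
  double best = NEG_INF;
  for (int g = 0; g <= G; ++g) {
    double sc = prev[m * (G + 1) + g];
    if (sc > best) best = sc;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector dp_score_batch_cpp(CharacterVector guides, CharacterVector targets,
                                 double match, double mismatch, double gap,
                                 int max_gaps) {
  int n = guides.size();
  if (targets.size() != n) stop("guides and targets must have equal length");
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double sc = score_only(as<std::string>(guides[k]), as<std::string>(targets[k]),
                           match, mismatch, gap, max_gaps);
    out[k] = (sc <= NEG_INF / 2) ? NA_REAL : sc;
  }
  return out;
}

// Scores every (pair x grid point); rows collapsed to the max within `group`
// (0-based, contiguous not required). Grid column order: for each gap value,
// all mismatch values (column = g_idx * n_mismatch + m_idx).
// [[Rcpp::export]]
NumericMatrix dp_score_grid_cpp(CharacterVector guides, CharacterVector targets,
                                IntegerVector group, int n_groups, double match,
                                NumericVector mismatches, NumericVector gaps,
                                int max_gaps) {
  int n = guides.size();
  if (targets.size() != n || group.size() != n)
    stop("guides, targets and group must have equal length");
  int nm = mismatches.size(), ng = gaps.size();
  NumericMatrix out(n_groups, nm * ng);
  std::fill(out.begin(), out.end(), NEG_INF);
  for (int k = 0; k < n; ++k) {
    std::string gd = as<std::string>(guides[k]);
    std::string tg = as<std::string>(targets[k]);
    int grp = group[k];
    if (grp < 0 || grp >= n_groups) stop("group index out of range");
    for (int gi = 0; gi < ng; ++gi) {
      for (int mi = 0; mi < nm; ++mi) {
        double sc = score_only(gd, tg, match, mismatches[mi], gaps[gi], max_gaps);
        int col = gi * nm + mi;
        if (sc > out(grp, col)) out(grp, col) = sc;
      }
    }
  }
  for (int r = 0; r < n_groups; ++r)
    for (int c = 0; c < nm * ng; ++c)
      if (out(r, c) <= NEG_INF / 2) out(r, c) = NA_REAL;
  return out;
}
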