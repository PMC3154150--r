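#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Counts are stored one population per class as a 3^k x P integer matrix:
// column j holds the genotype-cell counts of dataset j, cell index
// sum_s g_s * 3^(k-1-s) (SNP 1 is the most significant base-3 digit).

static void mutate_class(IntegerMatrix C, int k, double rate, bool resampleSame) {
  const int G = C.nrow(), P = C.ncol();
  long total = 0;
  for (int i = 0; i < G * P; ++i) total += C[i];
  if (total == 0 || rate <= 0.0) return;

  std::vector<int> src, dst, col;
  std::vector<double> pos;

  for (int s = 0; s < k; ++s) {
    int stride = 1;
    for (int t = 0; t < k - 1 - s; ++t) stride *= 3;

    // Number of mutating entries at this SNP across every subject of every
    // dataset; allocating them to (cell, dataset) groups without replacement
    // reproduces independent Binomial(count, rate) thinning per group.
    int M = (int) R::rbinom((double) total, rate);
    if (M == 0) continue;

    pos.clear();
    pos.reserve(M);
    while ((int) pos.size() < M) {
      double p = std::floor(unif_rand() * (double) total);
      if (p >= (double) total) continue;
      pos.push_back(p);
    }
    std::sort(pos.begin(), pos.end());
    // entries must be distinct subjects; collisions are resampled
    bool dup = true;
    while (dup) {
      dup = false;
      for (int i = 1; i < M; ++i) {
        if (pos[i] == pos[i - 1]) {
          pos[i] = std::floor(unif_rand() * (double) total);
          dup = true;
        }
      }
      if (dup) std::sort(pos.begin(), pos.end());
    }

    src.clear(); dst.clear(); col.clear();
    double cum = 0.0;
    int idx = 0;
    for (int j = 0; j < P && idx < M; ++j) {
      for (int g = 0; g < G && idx < M; ++g) {
        cum += (double) C(g, j);
        while (idx < M && pos[idx] < cum) {
          int digit = (g / stride) % 3;
          int newdigit;
          if (resampleSame) {
            newdigit = (int) std::floor(unif_rand() * 3.0);
            if (newdigit > 2) newdigit = 2;
          } else {
            int shift = (unif_rand() < 0.5) ? 1 : 2;
            newdigit = (digit + shift) % 3;
          }
          if (newdigit != digit) {
            src.push_back(g + (newdigit - digit) * stride); // destination
            dst.push_back(g);                               // source
            col.push_back(j);
          }
          ++idx;
        }
      }
    }
    for (size_t e = 0; e < src.size(); ++e) {
      C(dst[e], col[e]) -= 1;
      C(src[e], col[e]) += 1;
    }
  }
}

// [[Rcpp::export]]
List cpp_mutate_counts(IntegerMatrix caseCounts, IntegerMatrix controlCounts,
                       int k, double rate, bool resampleSame) {
  IntegerMatrix ca = clone(caseCounts);
  IntegerMatrix co = clone(controlCounts);
  mutate_class(ca, k, rate, resampleSame);
  mutate_class(co, k, rate, resampleSame);
  return List::create(_["case"] = ca, _["control"] = co);
}

// Per-subset MDR accuracies for a whole population. `groups` is a 3^k x S
// integer matrix mapping each full cell to its margin cell (0-based) for
// each of the S subsets.
// [[Rcpp::export]]
NumericMatrix cpp_subset_accuracies(IntegerMatrix caseCounts,
                                    IntegerMatrix controlCounts,
                                    IntegerMatrix groups,
                                    IntegerVector marginSizes) {
  const int G = caseCounts.nrow(), P = caseCounts.ncol(), S = groups.ncol();
  NumericMatrix acc(S, P);
  const int* caseP = INTEGER(caseCounts);
  const int* ctrlP = INTEGER(controlCounts);
  const int* grpP = INTEGER(groups);
  int mc[243], mo[243];
  for (int j = 0; j < P; ++j) {
    const int* cj = caseP + (size_t) j * G;
    const int* oj = ctrlP + (size_t) j * G;
    int n = 0;
    for (int g = 0; g < G; ++g) n += cj[g] + oj[g];
    for (int s = 0; s < S; ++s) {
      const int* gs = grpP + (size_t) s * G;
      const int m = marginSizes[s];
      std::fill(mc, mc + m, 0);
      std::fill(mo, mo + m, 0);
      for (int g = 0; g < G; ++g) {
        mc[gs[g]] += cj[g];
        mo[gs[g]] += oj[g];
      }
      int correct = 0;
      for (int c = 0; c < m; ++c) correct += std::max(mc[c], mo[c]);
      acc(s, j) = (double) correct / (double) n;
    }
  }
  return acc;
}

static inline bool dominates_col(const NumericMatrix& obj, int a, int b, int d) {
  // all objectives minimized (caller sign-normalizes); strict in >= 1
  bool strict = false;
  for (int i = 0; i < d; ++i) {
    double va = obj(i, a), vb = obj(i, b);
    if (va > vb) return false;
    if (va < vb) strict = true;
  }
  return strict;
}

// Non-dominated mask over columns of a d x n matrix (all objectives minimized).
// [[Rcpp::export]]
LogicalVector cpp_nondominated(NumericMatrix obj) {
  const int n = obj.ncol(), d = obj.nrow();
  LogicalVector keep(n, true);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dominates_col(obj, j, i, d)) { keep[i] = false; break; }
    }
  }
  return keep;
}

// Streaming Pareto archive over columns of a d x n matrix (all minimized);
// returns the 0-based indices of the final archive in insertion order.
// [[Rcpp::export]]
IntegerVector cpp_stream_front(NumericMatrix obj) {
  const int n = obj.ncol(), d = obj.nrow();
  std::vector<int> archive;
  archive.reserve(256);
  for (int i = 0; i < n; ++i) {
    bool dominated = false;
    for (size_t a = 0; a < archive.size(); ++a) {
      if (dominates_col(obj, archive[a], i, d)) { dominated = true; break; }
    }
    if (dominated) continue;
    size_t w = 0;
    for (size_t a = 0; a < archive.size(); ++a) {
      if (!dominates_col(obj, i, archive[a], d)) archive[w++] = archive[a];
    }
    archive.resize(w);
    archive.push_back(i);
  }
  return IntegerVector(archive.begin(), archive.end());
}
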