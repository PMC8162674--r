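#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exhaustive enumeration of joint register assignments for the brute-force
// alignment oracle. idx holds the residue indices (1-based, alphabet order)
// of every candidate window, stacked peptide by peptide; mask marks which
// window positions are insert-derived (flank-derived positions score as
// background and enter neither the counts nor the column totals); pep maps
// rows to peptides. Maximizes the register-dependent part of the
// completed-data log-likelihood:
//   sum_jk c_jk * (log((c_jk + pc)/(n_j + 20 pc)) - log bg_k),
// with n_j the per-column insert-derived total. Enumeration is lexicographic
// in the per-peptide candidate indices with strict improvement, so ties
// resolve toward the smallest p1 indices.

// [[Rcpp::export]]
List bf_align_enumerate(IntegerMatrix idx, IntegerMatrix mask,
                        IntegerVector pep, IntegerVector n_cand,
                        double pseudocount, NumericVector log_bg,
                        NumericVector bonus) {
  const int n = n_cand.size();
  const int W = idx.ncol();
  std::vector<int> offset(n);
  int cum = 0;
  for (int i = 0; i < n; ++i) { offset[i] = cum; cum += n_cand[i]; }

  std::vector<int> counts(20 * W, 0);
  std::vector<int> coltot(W, 0);
  std::vector<int> cur(n, 0);

  // residue index table (0-based) and mask, row-major per candidate row
  std::vector<int> res(idx.nrow() * W);
  std::vector<int> msk(idx.nrow() * W);
  for (int r = 0; r < idx.nrow(); ++r)
    for (int j = 0; j < W; ++j) {
      res[r * W + j] = idx(r, j) - 1;
      msk[r * W + j] = mask(r, j);
    }

  double bonus_sum = 0.0;
  auto add = [&](int i, int reg, int d) {
    const int row = offset[i] + reg;
    bonus_sum += d * bonus[row];
    for (int j = 0; j < W; ++j)
      if (msk[row * W + j]) {
        counts[res[row * W + j] * W + j] += d;
        coltot[j] += d;
      }
  };
  for (int i = 0; i < n; ++i) add(i, 0, +1);

  std::vector<double> lg(n + 1), ld(n + 1);
  for (int c = 0; c <= n; ++c) {
    lg[c] = (c + pseudocount > 0) ? std::log(c + pseudocount) : 0.0;
    ld[c] = std::log(c + 20.0 * pseudocount);
  }

  auto objective = [&]() {
    double obj = 0.0;
    for (int k = 0; k < 20; ++k)
      for (int j = 0; j < W; ++j) {
        const int c = counts[k * W + j];
        if (c > 0) obj += c * (lg[c] - ld[coltot[j]] - log_bg[k]);
      }
    return obj + bonus_sum;
  };

  double best = objective();
  std::vector<int> best_cur = cur;
  double n_eval = 1.0;

  for (;;) {
    int i = n - 1;
    while (i >= 0) {
      if (cur[i] + 1 < n_cand[i]) {
        add(i, cur[i], -1);
        cur[i] += 1;
        add(i, cur[i], +1);
        break;
      }
      add(i, cur[i], -1);
      cur[i] = 0;
      add(i, 0, +1);
      --i;
    }
    if (i < 0) break;
    const double obj = objective();
    n_eval += 1.0;
    if (obj > best + 1e-12) {
      best = obj;
      best_cur = cur;
    }
  }

  return List::create(_["assignment"] = IntegerVector(best_cur.begin(),
                                                      best_cur.end()),
                      _["objective"] = best,
                      _["n_evaluated"] = n_eval);
}
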