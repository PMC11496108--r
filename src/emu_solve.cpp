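// Fast inner loop of the EMU cascade: for each EMU size level, assemble the
// linear balance system from precomputed integer plans and solve it. Called
// once per objective evaluation during flux fitting, so this is the hot path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".emu_solve_cpp")]]
List emu_solve_cpp(List levels, NumericVector w, NumericVector consVal,
                   List subMids, int nEmus, double pruneTol) {
  List solved(nEmus);
  for (int L = 0; L < levels.size(); L++) {
    List lv = levels[L];
    int s = as<int>(lv["size"]);
    IntegerVector gids = lv["gids"];
    IntegerVector metIdx = lv["met_idx"];
    int n = gids.size();
    arma::mat A(n, n, arma::fill::zeros);
    arma::mat R(n, s + 1, arma::fill::zeros);
    std::vector<bool> live(n);
    for (int i = 0; i < n; i++) {
      double c = consVal[metIdx[i] - 1];
      live[i] = c >= pruneTol;
      A(i, i) = live[i] ? c : 1.0;
      if (!live[i]) R(i, 0) = 1.0;
    }
    IntegerMatrix cp = lv["coupling_mat"];
    for (int r = 0; r < cp.nrow(); r++) {
      int i = cp(r, 0) - 1, j = cp(r, 1) - 1, k = cp(r, 2) - 1;
      if (w[k] > pruneTol && live[i]) A(i, j) -= w[k];
    }
    IntegerVector ti = lv["term_i"], tu = lv["term_uni"];
    IntegerVector st = lv["src_term"], sty = lv["src_type"],
                  si = lv["src_idx"];
    int p = 0, nsrc = st.size();
    std::vector<double> mid, tmp;
    for (int t = 0; t < ti.size(); t++) {
      int i = ti[t] - 1, k = tu[t] - 1;
      bool skip = (w[k] <= pruneTol) || !live[i];
      bool first = true;
      mid.clear();
      while (p < nsrc && st[p] == t + 1) {
        if (!skip) {
          NumericVector m = (sty[p] == 0)
            ? as<NumericVector>(subMids[si[p] - 1])
            : as<NumericVector>(solved[si[p] - 1]);
          if (first) {
            mid.assign(m.begin(), m.end());
            first = false;
          } else {
            tmp.assign(mid.size() + m.size() - 1, 0.0);
            for (size_t a = 0; a < mid.size(); a++)
              for (int b = 0; b < m.size(); b++)
                tmp[a + b] += mid[a] * m[b];
            mid.swap(tmp);
          }
        }
        p++;
      }
      if (skip || mid.empty()) continue;
      int lim = std::min((int)mid.size(), s + 1);
      for (int c = 0; c < lim; c++) R(i, c) += w[k] * mid[c];
    }
    arma::mat X;
    bool ok = arma::solve(X, A, R, arma::solve_opts::no_approx);
    if (!ok) stop("singular EMU balance at size %d", s);
    for (int i = 0; i < n; i++) {
      NumericVector v(s + 1);
      for (int c = 0; c <= s; c++) v[c] = X(i, c);
      solved[gids[i] - 1] = v;
    }
  }
  return solved;
}
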