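// Motif-motif comparison (column-correlation score over all offsets and
// both orientations, permutation null) and integer-score PWM scanning.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pearson correlation of two length-4 columns; 0 if either is constant.
static double col_cor(const rowvec& a, const rowvec& b) {
  const double ma = mean(a), mb = mean(b);
  rowvec da = a - ma, db = b - mb;
  const double va = accu(da % da), vb = accu(db % db);
  if (va < 1e-15 || vb < 1e-15) return 0.0;
  return accu(da % db) / std::sqrt(va * vb);
}

// reverse complement of a w x 4 frequency matrix (columns A,C,G,T)
static mat revcomp_pwm(const mat& M) {
  return flipud(fliplr(M));
}

// best mean column correlation of Q vs T over all shifts with at least
// min_overlap aligned columns
static void best_alignment(const mat& Q, const mat& T, int min_overlap,
                           double& best, int& best_shift, int& best_len) {
  const int wq = Q.n_rows, wt = T.n_rows;
  best = -datum::inf;
  best_shift = 0;
  best_len = 0;
  for (int s = min_overlap - wt; s <= wq - min_overlap; ++s) {
    const int q0 = std::max(0, s);
    const int t0 = std::max(0, -s);
    const int len = std::min(wq - q0, wt - t0);
    if (len < min_overlap) continue;
    double acc = 0;
    for (int j = 0; j < len; ++j) {
      acc += col_cor(Q.row(q0 + j), T.row(t0 + j));
    }
    acc /= len;
    if (acc > best || (acc == best && len > best_len)) {
      best = acc;
      best_shift = s;
      best_len = len;
    }
  }
}

// [[Rcpp::export(name = ".motif_compare_cpp")]]
Rcpp::List motif_compare_cpp(const arma::mat& Q, const arma::mat& T,
                             int min_overlap, const arma::umat& perms) {
  double s_fwd, s_rev;
  int sh_fwd, sh_rev, len_fwd, len_rev;
  best_alignment(Q, T, min_overlap, s_fwd, sh_fwd, len_fwd);
  mat Trc = revcomp_pwm(T);
  best_alignment(Q, Trc, min_overlap, s_rev, sh_rev, len_rev);
  const bool fwd = s_fwd >= s_rev;
  const double obs = fwd ? s_fwd : s_rev;
  // permutation null: shuffle target columns, keep best over offsets
  // and both orientations
  int hits = 0;
  const int nperm = perms.n_cols;
  for (int p = 0; p < nperm; ++p) {
    mat Tp(T.n_rows, 4);
    for (uword i = 0; i < T.n_rows; ++i) Tp.row(i) = T.row(perms(i, p));
    double b1, b2;
    int d1, d2, d3, d4;
    best_alignment(Q, Tp, min_overlap, b1, d1, d2);
    best_alignment(Q, revcomp_pwm(Tp), min_overlap, b2, d3, d4);
    if (std::max(b1, b2) >= obs) ++hits;
  }
  const double pval = (1.0 + hits) / (1.0 + nperm);
  return Rcpp::List::create(
    Rcpp::Named("score") = obs,
    Rcpp::Named("offset") = fwd ? sh_fwd : sh_rev,
    Rcpp::Named("overlap") = fwd ? len_fwd : len_rev,
    Rcpp::Named("orientation") = fwd ? "+" : "-",
    Rcpp::Named("p_value") = pval);
}

// Scan an integer-coded sequence (0..3; negative = ambiguous, window
// skipped) with an integerized score matrix; report 0-based positions and
// integer scores of windows scoring >= cutoff.
// [[Rcpp::export(name = ".scan_int_cpp")]]
Rcpp::List scan_int_cpp(const arma::imat& iscore,
                        const arma::ivec& seq, int cutoff) {
  const int w = iscore.n_rows;
  const int L = seq.n_elem;
  std::vector<int> pos, sc;
  for (int i = 0; i + w <= L; ++i) {
    long s = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      const int b = seq(i + j);
      if (b < 0) { ok = false; break; }
      s += iscore(j, b);
    }
    if (ok && s >= cutoff) {
      pos.push_back(i);
      sc.push_back((int)s);
    }
  }
  return Rcpp::List::create(Rcpp::Named("pos") = pos,
                            Rcpp::Named("score") = sc);
}
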