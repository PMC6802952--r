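// Hot loops: pairwise LDA leave-one-trial-out decoding and 1-D TFCE.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Leave-one-trial-out accuracy of a two-class LDA with shrinkage toward
// the scaled identity. Folds are paired: fold k holds out trial k of each
// class (classes with fewer trials stop contributing once exhausted), so
// every trial is tested exactly once and training sets stay balanced for
// equal trial counts.
static double lda_pair_loo(const mat& X1, const mat& X2, double shrinkage) {
  const uword n1 = X1.n_rows, n2 = X2.n_rows, p = X1.n_cols;
  const uword K = std::max(n1, n2);
  double correct = 0.0, total = 0.0;
  for (uword k = 0; k < K; ++k) {
    const bool hold1 = k < n1, hold2 = k < n2;
    uvec idx1 = regspace<uvec>(0, n1 - 1);
    uvec idx2 = regspace<uvec>(0, n2 - 1);
    if (hold1) idx1.shed_row(k);
    if (hold2) idx2.shed_row(k);
    mat A = X1.rows(idx1);
    mat B = X2.rows(idx2);
    rowvec m1 = mean(A, 0), m2 = mean(B, 0);
    mat C1 = A.each_row() - m1;
    mat C2 = B.each_row() - m2;
    double denom = static_cast<double>(A.n_rows + B.n_rows) - 2.0;
    if (denom < 1.0) denom = 1.0;
    mat S = (C1.t() * C1 + C2.t() * C2) / denom;
    double tr = trace(S) / static_cast<double>(p);
    S *= (1.0 - shrinkage);
    S.diag() += shrinkage * tr + 1e-12;
    vec d = (m1 - m2).t();
    vec w;
    if (!solve(w, S, d, solve_opts::no_approx)) {
      w = pinv(S) * d;
    }
    double c = dot(w, 0.5 * (m1 + m2).t());
    if (hold1) {
      total += 1.0;
      if (dot(w, X1.row(k).t()) - c > 0) correct += 1.0;
    }
    if (hold2) {
      total += 1.0;
      if (dot(w, X2.row(k).t()) - c < 0) correct += 1.0;
    }
  }
  return correct / total;
}

// [[Rcpp::export(name = ".lda_pair_loo")]]
double lda_pair_loo_r(const arma::mat& X1, const arma::mat& X2,
                      double shrinkage) {
  return lda_pair_loo(X1, X2, shrinkage);
}

// Pairwise decoding over all condition pairs and time points.
// epochs: trials x channels x time cube; labels: 1-based condition ids.
// Returns an npairs x ntime matrix; pair order is the column-major lower
// triangle (i > j, ordered by j then i), matching the package's pair order.
// [[Rcpp::export(name = ".decode_all")]]
arma::mat decode_all(const arma::cube& epochs,
                     const arma::ivec& labels,
                     int n_conditions, double shrinkage) {
  const uword T = epochs.n_slices;
  const uword C = static_cast<uword>(n_conditions);
  const uword npairs = C * (C - 1) / 2;
  mat out(npairs, T);
  std::vector<uvec> rows_of(C);
  for (uword c = 0; c < C; ++c) {
    rows_of[c] = find(labels == static_cast<sword>(c + 1));
  }
  for (uword t = 0; t < T; ++t) {
    mat X = epochs.slice(t); // trials x channels
    uword pr = 0;
    for (uword j = 0; j < C; ++j) {
      for (uword i = j + 1; i < C; ++i) {
        out(pr++, t) = lda_pair_loo(X.rows(rows_of[i]), X.rows(rows_of[j]),
                                    shrinkage);
      }
    }
  }
  return out;
}

// 1-D TFCE of a single non-negative-enhanced map.
// enhanced(t) = sum_h extent(h, t)^E * h^H * dh, h = dh, 2dh, ..., over
// suprathreshold runs (map > h); negative samples contribute 0.
static void tfce_row(const rowvec& map, double E, double H, double dh,
                     int n_steps, rowvec& out) {
  const uword T = map.n_elem;
  out.zeros(T);
  double mx = map.max();
  if (!(mx > 0)) return;
  double step = dh > 0 ? dh : mx / static_cast<double>(n_steps);
  int k_max = static_cast<int>(std::floor(mx / step + 1e-9));
  for (int kk = 1; kk <= k_max; ++kk) {
    double h = kk * step;
    uword t = 0;
    while (t < T) {
      if (map(t) > h) {
        uword start = t;
        while (t < T && map(t) > h) ++t;
        double extent = static_cast<double>(t - start);
        double add = std::pow(extent, E) * std::pow(h, H) * step;
        for (uword s = start; s < t; ++s) out(s) += add;
      } else {
        ++t;
      }
    }
  }
}

// [[Rcpp::export(name = ".tfce_batch")]]
arma::mat tfce_batch(const arma::mat& maps, double E, double H,
                     double dh, int n_steps) {
  mat out(maps.n_rows, maps.n_cols);
  rowvec buf;
  for (uword r = 0; r < maps.n_rows; ++r) {
    tfce_row(maps.row(r), E, H, dh, n_steps, buf);
    out.row(r) = buf;
  }
  return out;
}
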