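// Hot loops of the decoding stack: regularized LDA (shrinkage toward scaled
// identity, Woodbury identity in the p > n regime), cross-validated accuracy
// over feature matrices / per-timepoint channel features, single-feature
// searchlight maps, and cross-task temporal generalization.
//
// Conventions shared with the R surface:
//  - labels are 0/1 (class0 / class1); decision-value ties go to class0,
//    i.e. a trial is called class1 only when its decision value is > 0;
//  - the decision threshold is the midpoint of the projected class means;
//  - fold indices arrive 1-based from R and are converted here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// weights/bias of shrinkage LDA: S' = (1-l) S + l (tr(S)/p) I,
// w = S'^{-1} (mu1 - mu0), b = -w . (mu0 + mu1)/2
static void lda_train(const mat& X, const uvec& y, double lambda,
                      vec& w, double& b) {
  uvec i0 = find(y == 0), i1 = find(y == 1);
  if (i0.n_elem < 2 || i1.n_elem < 2)
    Rcpp::stop("need at least 2 training trials per class");
  rowvec mu0 = mean(X.rows(i0), 0), mu1 = mean(X.rows(i1), 0);
  mat Z0 = X.rows(i0); Z0.each_row() -= mu0;
  mat Z1 = X.rows(i1); Z1.each_row() -= mu1;
  mat Z = join_cols(Z0, Z1);                    // n x p, centered per class
  const double n = X.n_rows, p = X.n_cols;
  const double denom = n - 2.0;
  const double trS = accu(square(Z)) / denom;   // trace of pooled covariance
  const double a = lambda * trS / p;            // ridge toward scaled identity
  vec d = (mu1 - mu0).t();
  if (lambda >= 1.0) {
    if (a <= 0) Rcpp::stop("degenerate training data: zero total variance");
    w = d / a;
  } else if (p <= n) {
    mat S = (1.0 - lambda) * (Z.t() * Z) / denom;
    S.diag() += a;
    bool ok = solve(w, S, d, solve_opts::no_approx);
    if (!ok) Rcpp::stop("singular pooled covariance; use lambda > 0");
  } else {
    // Woodbury: (aI + BB')^{-1} d with B = sqrt((1-l)/(n-2)) Z'
    if (a <= 0) Rcpp::stop("singular pooled covariance (p > n); use lambda > 0");
    const double c = (1.0 - lambda) / denom;
    mat G = c * (Z * Z.t());                    // n x n
    G.diag() += a;
    vec t = solve(G, Z * d, solve_opts::likely_sympd);
    w = (d - c * (Z.t() * t)) / a;
  }
  b = -0.5 * dot(w, (mu0 + mu1).t());
}

static double fold_accuracy(const mat& Xtr, const uvec& ytr,
                            const mat& Xte, const uvec& yte, double lambda) {
  vec w; double b;
  lda_train(Xtr, ytr, lambda, w, b);
  vec s = Xte * w + b;
  uvec pred = conv_to<uvec>::from(s > 0);       // ties -> class0
  return accu(pred == yte) / double(yte.n_elem);
}

// fold-wise z-scoring fitted on the training rows; zero-variance features
// are mapped to 0 in both sets
static void zscore_pair(mat& Xtr, mat& Xte) {
  rowvec m = mean(Xtr, 0), s = stddev(Xtr, 0, 0);
  for (uword j = 0; j < Xtr.n_cols; ++j) {
    if (s(j) > 0) {
      Xtr.col(j) = (Xtr.col(j) - m(j)) / s(j);
      Xte.col(j) = (Xte.col(j) - m(j)) / s(j);
    } else {
      Xtr.col(j).zeros();
      Xte.col(j).zeros();
    }
  }
}

static uvec as_index(const Rcpp::IntegerVector& v) {
  uvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = v[i] - 1;
  return out;
}

// [[Rcpp::export]]
Rcpp::List lda_train_cpp(const arma::mat& X, const arma::uvec& y,
                         double lambda) {
  vec w; double b;
  lda_train(X, y, lambda, w, b);
  return Rcpp::List::create(Rcpp::Named("w") = w, Rcpp::Named("b") = b);
}

// mean over repeats and folds of the per-fold test accuracy
// [[Rcpp::export]]
double cv_accuracy_cpp(const arma::mat& X, const arma::uvec& y,
                       const Rcpp::List& partition, double lambda,
                       bool zscore) {
  double acc = 0.0; int nf = 0;
  for (int r = 0; r < partition.size(); ++r) {
    Rcpp::List rep = partition[r];
    for (int f = 0; f < rep.size(); ++f) {
      Rcpp::List fold = rep[f];
      uvec tr = as_index(fold["train"]), te = as_index(fold["test"]);
      mat Xtr = X.rows(tr), Xte = X.rows(te);
      if (zscore) zscore_pair(Xtr, Xte);
      acc += fold_accuracy(Xtr, y.elem(tr), Xte, y.elem(te), lambda);
      ++nf;
    }
  }
  return acc / nf;
}

// time-resolved decoding: features = all channels at one timepoint
// [[Rcpp::export]]
arma::vec decode_timecourse_cpp(const arma::cube& data, const arma::uvec& y,
                                const Rcpp::List& partition, double lambda) {
  vec out(data.n_slices);
  for (uword t = 0; t < data.n_slices; ++t) {
    mat X = data.slice(t);                       // trials x channels
    out(t) = cv_accuracy_cpp(X, y, partition, lambda, false);
  }
  return out;
}

// single-feature searchlight over the columns of a trials x cells matrix
// [[Rcpp::export]]
arma::vec searchlight_map_cpp(const arma::mat& X, const arma::uvec& y,
                              const Rcpp::List& partition) {
  const uword ncell = X.n_cols;
  vec out(ncell, fill::zeros);
  int nf = 0;
  for (int r = 0; r < partition.size(); ++r) {
    Rcpp::List rep = partition[r];
    for (int f = 0; f < rep.size(); ++f) {
      Rcpp::List fold = rep[f];
      uvec tr = as_index(fold["train"]), te = as_index(fold["test"]);
      uvec ytr = y.elem(tr);
      uvec yte = y.elem(te);
      ++nf;
      uvec tr0 = tr.elem(find(ytr == 0)), tr1 = tr.elem(find(ytr == 1));
      rowvec m0 = mean(X.rows(tr0), 0), m1 = mean(X.rows(tr1), 0);
      rowvec mid = 0.5 * (m0 + m1), dir = m1 - m0;
      const mat Xte = X.rows(te);
      for (uword c = 0; c < ncell; ++c) {
        vec s = (Xte.col(c) - mid(c)) * dir(c);
        uvec pred = conv_to<uvec>::from(s > 0);
        out(c) += accu(pred == yte) / double(yte.n_elem);
      }
    }
  }
  return out / nf;
}

// cross-task temporal generalization: train on all trials of the training
// task at each train timepoint, test at every timepoint of the test task
// [[Rcpp::export]]
arma::mat cross_matrix_cpp(const arma::cube& train, const arma::cube& test,
                           const arma::uvec& ytr, const arma::uvec& yte,
                           double lambda) {
  const uword Ttr = train.n_slices, Tte = test.n_slices;
  mat W(train.n_cols, Ttr);
  vec B(Ttr);
  for (uword t = 0; t < Ttr; ++t) {
    vec w; double b;
    lda_train(train.slice(t), ytr, lambda, w, b);
    W.col(t) = w;
    B(t) = b;
  }
  mat out(Ttr, Tte);
  const double nte = yte.n_elem;
  for (uword u = 0; u < Tte; ++u) {
    mat S = test.slice(u) * W;                  // n_te x Ttr decision values
    S.each_row() += B.t();
    for (uword t = 0; t < Ttr; ++t) {
      uvec pred = conv_to<uvec>::from(S.col(t) > 0);
      out(t, u) = accu(pred == yte) / nte;
    }
  }
  return out;
}
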