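// Leave-one-out regularized Fisher discriminant over a shrinkage grid.
//
// For every trial j and every lambda on the grid, the discriminant is fit on
// the remaining trials with class covariances shrunk towards nu*I
// (nu = trace(S)/D, so shrinkage preserves the trace) and the held-out trial
// is projected onto the fitted weight vector. The resulting out-of-sample
// projections give the leave-one-out ROC area (Az) per lambda.
//
// Removing one trial changes its class mean and scatter by rank-one terms,
// so the pooled matrix for all leave-outs within a class shares a common
// eigenbasis: S_c'(lambda) = (1-lambda) * (B - beta * u u^T) + lambda*c_j*I,
// with B fixed per class. After one symmetric eigendecomposition of B each
// (j, lambda) solve reduces to a diagonal system plus a Sherman-Morrison
// rank-one correction (O(D) per lambda). This is algebraically exact; the
// code falls back to a dense solve (with pseudo-inverse if needed) whenever
// the diagonal system is near-singular, e.g. at lambda = 0 with more
// channels than trials, or when a class would be left with fewer than two
// trials (its covariance then contributes zero, by package convention).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// rank-based AUC of scores y for class-1 (label 1) vs class-0, ties count 1/2
static double auc_rank(const vec& y, const uvec& lab) {
  const uword n = y.n_elem;
  uvec ord = sort_index(y);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && y(ord(j + 1)) == y(ord(i))) ++j;
    double r = 0.5 * (double(i + 1) + double(j + 1));  // average rank
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = r;
    i = j + 1;
  }
  double n1 = 0, n2 = 0, rsum = 0;
  for (uword k = 0; k < n; ++k) {
    if (lab(k) == 1) { n2 += 1; rsum += ranks(k); } else { n1 += 1; }
  }
  if (n1 == 0 || n2 == 0) return NA_REAL;
  return (rsum - n2 * (n2 + 1) / 2.0) / (n1 * n2);
}

// dense leave-one-out projection for trial j_out at one lambda
static double dense_proj(const mat& X, const uvec& lab, uword j_out,
                         double lam, bool& used_pinv) {
  const uword D = X.n_rows, N = X.n_cols;
  std::vector<uword> i1, i2;
  for (uword j = 0; j < N; ++j) {
    if (j == j_out) continue;
    if (lab(j) == 0) i1.push_back(j); else i2.push_back(j);
  }
  uvec idx1 = conv_to<uvec>::from(i1), idx2 = conv_to<uvec>::from(i2);
  vec m1 = mean(X.cols(idx1), 1), m2 = mean(X.cols(idx2), 1);
  mat Sc(D, D, fill::zeros);
  for (int c = 0; c < 2; ++c) {
    const uvec& idx = (c == 0) ? idx1 : idx2;
    const vec& m = (c == 0) ? m1 : m2;
    if (idx.n_elem < 2) continue;            // zero covariance, zero nu
    mat Xc = X.cols(idx);
    Xc.each_col() -= m;
    mat S = (Xc * Xc.t()) / double(idx.n_elem - 1);
    double nu = trace(S) / double(D);
    Sc += 0.5 * ((1.0 - lam) * S + lam * nu * eye(D, D));
  }
  vec dm = m2 - m1, w;
  bool ok = solve(w, Sc, dm, solve_opts::no_approx + solve_opts::likely_sympd);
  if (!ok) { w = pinv(Sc) * dm; used_pinv = true; }
  return dot(w, X.col(j_out));
}

// [[Rcpp::export]]
Rcpp::List fisher_loo_grid_cpp(const arma::mat& X, const arma::uvec& labels,
                               const arma::vec& lambdas) {
  const uword D = X.n_rows, N = X.n_cols, L = lambdas.n_elem;
  if (labels.n_elem != N) Rcpp::stop("labels length must match trial count");
  uvec idx1 = find(labels == 0), idx2 = find(labels == 1);
  const double n1 = idx1.n_elem, n2 = idx2.n_elem;
  if (n1 < 2 || n2 < 2) Rcpp::stop("need at least 2 trials per class");

  vec m1 = mean(X.cols(idx1), 1), m2 = mean(X.cols(idx2), 1);
  mat X1c = X.cols(idx1); X1c.each_col() -= m1;
  mat X2c = X.cols(idx2); X2c.each_col() -= m2;
  mat T1 = X1c * X1c.t(), T2 = X2c * X2c.t();
  const double tr1 = trace(T1), tr2 = trace(T2);
  mat S1 = T1 / (n1 - 1), S2 = T2 / (n2 - 1);
  vec dm = m2 - m1;
  bool used_pinv = false;

  mat yloo(N, L, fill::zeros);

  // one pass per class; cls = 0 handles leave-outs from class 1
  for (int cls = 0; cls < 2; ++cls) {
    const uvec& idx = (cls == 0) ? idx1 : idx2;
    const double na = (cls == 0) ? n1 : n2;      // size of the left-out class
    const double nb = (cls == 0) ? n2 : n1;
    const double tra = (cls == 0) ? tr1 : tr2;
    const double trb = (cls == 0) ? tr2 : tr1;
    const vec& ma = (cls == 0) ? m1 : m2;
    const double sgn = (cls == 0) ? +1.0 : -1.0; // dm shift direction

    if (na <= 2) {                               // leave-out leaves 1 trial
      for (uword k = 0; k < idx.n_elem; ++k)
        for (uword l = 0; l < L; ++l)
          yloo(idx(k), l) = dense_proj(X, labels, idx(k), lambdas(l),
                                       used_pinv);
      continue;
    }

    const mat& Ta = (cls == 0) ? T1 : T2;
    const mat& Sb = (cls == 0) ? S2 : S1;
    mat B = 0.5 * (Ta / (na - 2) + Sb);
    vec d; mat Q;
    eig_sym(d, Q, B);
    vec dmr = Q.t() * dm;
    const double beta = na / (2.0 * (na - 1) * (na - 2));
    const double nub = trb / ((nb - 1) * D);

    vec u(D), v(D), xt(D), r(D);
    for (uword k = 0; k < idx.n_elem; ++k) {
      const uword j = idx(k);
      u = X.col(j) - ma;
      v = Q.t() * u;
      xt = Q.t() * X.col(j);
      // leaving j out moves its class mean towards the rest:
      // m_a' = m_a - u/(na-1), so (m2 - m1) changes by sgn * u/(na-1)
      r = dmr + (sgn / (na - 1)) * v;
      double nua = (tra - (na / (na - 1)) * dot(u, u)) / ((na - 2) * D);
      double cj = 0.5 * (nua + nub);
      const double* dp = d.memptr();
      const double* vp = v.memptr();
      const double* rp = r.memptr();
      const double* xp = xt.memptr();

      for (uword l = 0; l < L; ++l) {
        const double lam = lambdas(l);
        // single fused pass over the eigenbasis: accumulate the four inner
        // products of the Sherman-Morrison solve and track the smallest
        // diagonal entry for the singularity guard
        double s = 0, t = 0, ax = 0, bx = 0, gmin = datum::inf, gmax = 0;
        for (uword q = 0; q < D; ++q) {
          const double g = (1.0 - lam) * dp[q] + lam * cj;
          const double ag = std::abs(g);
          if (g < gmin) gmin = g;
          if (ag > gmax) gmax = ag;
          const double vg = vp[q] / g;
          s += vg * rp[q];
          t += vg * vp[q];
          ax += rp[q] / g * xp[q];
          bx += vg * xp[q];
        }
        const double gamma = (1.0 - lam) * beta;
        const double denom = 1.0 - gamma * t;
        if (gmin <= 1e-10 * std::max(gmax, 1.0) ||
            std::abs(denom) < 1e-10) {
          yloo(j, l) = dense_proj(X, labels, j, lam, used_pinv);
          continue;
        }
        // Sherman-Morrison for (G - gamma v v^T)^{-1} r
        yloo(j, l) = ax + (gamma * s / denom) * bx;
      }
    }
  }

  vec az(L);
  for (uword l = 0; l < L; ++l) az(l) = auc_rank(yloo.col(l), labels);

  return Rcpp::List::create(Rcpp::Named("az") = az,
                            Rcpp::Named("y_loo") = yloo,
                            Rcpp::Named("used_pinv") = used_pinv);
}
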