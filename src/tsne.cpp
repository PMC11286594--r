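// Exact (dense) t-SNE for gene-coexpression embedding.
//
// Points are genes (rows of the z-scored expression matrix); feature
// dimensions are samples, so n is a few thousand at most and the O(n^2)
// exact gradient is affordable and fully deterministic. The initial layout
// is supplied by the caller so that all randomness stays in R's RNG. The
// inner loop works on preallocated buffers: one n x n affinity matrix and
// one n x n low-dimensional kernel matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Binary-search the Gaussian bandwidth of each point so the conditional
// distribution has the requested perplexity, then symmetrize.
static mat input_similarities(const mat& X, double perplexity) {
  const uword n = X.n_rows;
  vec sq = sum(square(X), 1);
  mat D = -2.0 * (X * X.t());
  D.each_col() += sq;
  D.each_row() += sq.t();
  D.diag().zeros();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });

  const double log_perp = std::log(perplexity);
  mat P(n, n, fill::zeros);
  rowvec Pi(n);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, beta_lo = -datum::inf, beta_hi = datum::inf;
    rowvec Di = D.row(i);
    for (int iter = 0; iter < 60; ++iter) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP <= 0.0) sumP = datum::eps;
      double H = std::log(sumP) + beta * accu(Di % Pi) / sumP;
      double diff = H - log_perp;
      if (std::abs(diff) < 1e-7) break;
      if (diff > 0) {            // entropy too high -> narrow the kernel
        beta_lo = beta;
        beta = std::isfinite(beta_hi) ? (beta + beta_hi) / 2.0 : beta * 2.0;
      } else {
        beta_hi = beta;
        beta = std::isfinite(beta_lo) ? (beta + beta_lo) / 2.0 : beta / 2.0;
      }
    }
    double sumP = accu(Pi);
    if (sumP <= 0.0) { Pi.fill(1.0 / (n - 1)); Pi(i) = 0.0; sumP = 1.0; }
    P.row(i) = Pi / sumP;
  }
  P = (P + P.t()) / (2.0 * n);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  P.diag().zeros();
  return P;
}

// [[Rcpp::export(name = ".tsne_exact")]]
arma::mat tsne_exact(const arma::mat& X, const arma::mat& Y0,
                     double perplexity, int max_iter, double eta,
                     double exaggeration, int exag_iter) {
  const uword n = X.n_rows;
  mat P = input_similarities(X, perplexity);
  mat Y = Y0;
  mat dY(n, 2, fill::zeros), gains(n, 2, fill::ones), grad(n, 2);
  mat num(n, n);

  for (int iter = 0; iter < max_iter; ++iter) {
    const double ex = (iter < exag_iter) ? exaggeration : 1.0;

    double Z = 0.0;
    const double* y1 = Y.colptr(0);
    const double* y2 = Y.colptr(1);
    for (uword i = 0; i < n; ++i) {
      num(i, i) = 0.0;
      for (uword j = i + 1; j < n; ++j) {
        const double d1 = y1[i] - y1[j], d2 = y2[i] - y2[j];
        const double q = 1.0 / (1.0 + d1 * d1 + d2 * d2);
        num(i, j) = q;
        num(j, i) = q;
        Z += 2.0 * q;
      }
    }
    if (Z <= 0.0) Z = datum::eps;
    const double invZ = 1.0 / Z;

    grad.zeros();
    double* g1 = grad.colptr(0);
    double* g2 = grad.colptr(1);
    for (uword i = 0; i < n; ++i) {
      const double* Pi = P.colptr(i);     // P symmetric: column == row
      const double* Ni = num.colptr(i);
      double a1 = 0.0, a2 = 0.0;
      for (uword j = 0; j < n; ++j) {
        const double w = (ex * Pi[j] - Ni[j] * invZ) * Ni[j];
        a1 += w * (y1[i] - y1[j]);
        a2 += w * (y2[i] - y2[j]);
      }
      g1[i] = 4.0 * a1;
      g2[i] = 4.0 * a2;
    }

    const double momentum = (iter < 250) ? 0.5 : 0.8;
    for (uword j = 0; j < grad.n_elem; ++j) {
      gains(j) = (std::signbit(grad(j)) != std::signbit(dY(j)))
                     ? gains(j) + 0.2 : gains(j) * 0.8;
      if (gains(j) < 0.01) gains(j) = 0.01;
    }
    dY = momentum * dY - eta * (gains % grad);
    Y += dY;
    Y.each_row() -= mean(Y, 0);
  }
  return Y;
}
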