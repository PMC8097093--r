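#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Simulation modes (kept in sync with mode_code() on the R side).
static const int MODE_INDEPENDENT = 0;
static const int MODE_DEPENDENT   = 1;
static const int MODE_COADAPT     = 2;
static const int MODE_PLAYBACK    = 3;

static const double DEGENERACY_TOL = 1e-12;

// n standard-normal draws from R's RNG stream, in index order, so that a
// set.seed() on the R side fully determines the simulation and an R-level
// reference loop can replay the identical stream.
static arma::vec draw_std_normal(const arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; ++i) z(i) = norm_rand();
  return z;
}

// Gram-Schmidt orthonormalization of the columns of A, in column order.
static arma::mat gram_schmidt(const arma::mat& A) {
  arma::mat U = A;
  for (arma::uword j = 0; j < A.n_cols; ++j) {
    for (arma::uword i = 0; i < j; ++i)
      U.col(j) -= arma::dot(U.col(j), U.col(i)) * U.col(i);
    const double nn = arma::norm(U.col(j));
    if (nn < 1e-10)
      stop("degenerate map: component %d is (near-)linearly dependent", (int)(j + 1));
    U.col(j) /= nn;
  }
  return U;
}

// One CCIPCA sweep over the columns of W: component i is updated on the
// residual of x after deflating components 1..i-1 (deflation uses the
// freshly updated direction).
static void ccipca_update(arma::mat& W, const arma::vec& xin, const double rate) {
  arma::vec x = xin;
  for (arma::uword i = 0; i < W.n_cols; ++i) {
    const double nw = arma::norm(W.col(i));
    if (nw < DEGENERACY_TOL)
      stop("degenerate component estimate %d: norm below 1e-12", (int)(i + 1));
    W.col(i) = (1.0 - rate) * W.col(i) + rate * (arma::dot(x, W.col(i)) / nw) * x;
    const double nn = arma::norm(W.col(i));
    if (nn < DEGENERACY_TOL)
      stop("degenerate component estimate %d: norm below 1e-12", (int)(i + 1));
    const arma::vec v = W.col(i) / nn;
    x -= arma::dot(x, v) * v;
  }
}

// Variance regularization: lam_hat = |lam + lam_C + z| with (a) each of the
// first m entries restored to its initial vigor (lam_C,j = lam0_j - lam_j for
// j <= m, so the first-m sum is conserved exactly and the model cannot
// collapse onto fewer than m task dimensions) and (b) the first-m variance
// fraction kept >= its initial value (multiplicative tail shrink, factor
// <= 1). The absolute value can in principle flip a noisy entry negative, so
// an additive equal-split correction is re-applied until the first-m sum is
// exact.
static arma::vec regularize_spectrum(const arma::vec& lam, const arma::vec& lam0,
                                     const int m, const arma::vec& z) {
  const arma::uword n = lam.n_elem;
  const double S0m = arma::accu(lam0.head(m));
  const double f0 = S0m / arma::accu(lam0);
  arma::vec t = lam + z;
  t.head(m) = lam0.head(m) + z.head(m);
  for (int it = 0; it < 16; ++it) {
    const double d = (S0m - arma::accu(t.head(m))) / m;
    t.head(m) += d;
    t = arma::abs(t);
    if (std::fabs(arma::accu(t.head(m)) - S0m) < 1e-12) break;
  }
  const double Stail = arma::accu(t.tail(n - m));
  const double Smax = S0m * (1.0 - f0) / f0;
  if (Stail > Smax && Stail > 0.0) t.tail(n - m) *= Smax / Stail;
  return t;
}

static arma::mat unit_columns(const arma::mat& W) {
  arma::mat V = W;
  for (arma::uword i = 0; i < V.n_cols; ++i) {
    const double nn = arma::norm(V.col(i));
    if (nn < DEGENERACY_TOL)
      stop("degenerate component estimate %d: norm below 1e-12", (int)(i + 1));
    V.col(i) /= nn;
  }
  return V;
}

// Largest principal angle (deg) between span(columns of Brows) and
// span(columns of U2), both orthonormal.
static double largest_principal_angle(const arma::mat& Brows, const arma::mat& U2) {
  arma::vec sv = arma::svd(Brows.t() * U2);
  double c = sv.min();
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) * 180.0 / M_PI;
}

// [[Rcpp::export]]
List sim_core_cpp(arma::mat W, arma::vec lam_reg, arma::vec mu, arma::mat Btilde,
                  arma::vec lam0, const int K, const double eta, const double gamma,
                  const double alpha, const double beta, const double noise_sd,
                  const int mode, const arma::mat& playback,
                  const int record_stride, int final_window) {
  const arma::uword n = W.n_rows;
  const int m = (int)Btilde.n_cols;

  if (W.n_cols != n) stop("user component matrix must be n x n");
  if (Btilde.n_rows != n) stop("map estimates must have n rows");
  if ((arma::uword)m >= n) stop("map output dimension must satisfy m < n");
  if (mode == MODE_PLAYBACK &&
      (playback.n_cols != n || playback.n_rows < (arma::uword)K))
    stop("playback sequence must have n columns and at least K rows");
  if (final_window > K) final_window = K;

  arma::mat Brows = gram_schmidt(Btilde);

  arma::vec s(n, arma::fill::zeros);
  if (mode == MODE_DEPENDENT || mode == MODE_COADAPT) {
    // ARMA smoother initialized with s0 = q0 (one extra generative draw)
    const arma::mat V0 = unit_columns(W);
    s = V0 * (arma::sqrt(lam_reg) % draw_std_normal(n));
  }

  const int n_rec = K / record_stride + ((K % record_stride) ? 1 : 0);
  arma::ivec rec_it(n_rec);
  arma::vec rec_pla(n_rec), rec_ang(n_rec), rec_vaf(n_rec), rec_rew(n_rec);
  arma::mat finwin(final_window, 5);   // iteration, planarity, angle, vaf, reward
  arma::vec cons_sum(K), cons_frac(K);
  int ri = 0;

  for (int k = 1; k <= K; ++k) {
    arma::vec q(n);
    if (mode == MODE_PLAYBACK) {
      q = playback.row(k - 1).t();
      s = q;
    } else {
      const arma::mat V = unit_columns(W);
      q = V * (arma::sqrt(lam_reg) % draw_std_normal(n));
      if (mode == MODE_INDEPENDENT) s = q;
      else s = alpha * s + beta * q;
    }

    const arma::vec p = Brows.t() * s;
    const double ss = arma::dot(s, s);
    double r = (ss > 0.0) ? arma::dot(p, p) / ss : 0.0;
    if (r > 1.0) r = 1.0;
    if (r < 0.0) r = 0.0;
    const double eta_k = eta * r;

    if (mode == MODE_PLAYBACK) mu = (1.0 - eta_k) * mu + eta_k * q;

    const arma::vec x = ((mode == MODE_INDEPENDENT) ? q : s) - mu;
    ccipca_update(W, x, eta_k);

    arma::vec lam(n);
    for (arma::uword i = 0; i < n; ++i) lam(i) = arma::norm(W.col(i));
    const arma::vec z = noise_sd * draw_std_normal(n);
    lam_reg = regularize_spectrum(lam, lam0, m, z);

    if (mode == MODE_COADAPT && gamma > 0.0) {
      ccipca_update(Btilde, s - mu, gamma);
      Brows = gram_schmidt(Btilde);
    }

    cons_sum(k - 1) = arma::accu(lam_reg.head(m));
    cons_frac(k - 1) = cons_sum(k - 1) / arma::accu(lam_reg);

    // metrics on the post-update sampling distribution Sigma = V LamHat V^T:
    // planarity and the top-2 basis come from the eigendecomposition of
    // Sigma itself, so they stay valid even when the tracked component
    // directions drift from exact orthogonality.
    const bool rec = (k % record_stride == 0 || k == K);
    const bool fin = (k > K - final_window);
    if (rec || fin) {
      const arma::mat V = unit_columns(W);
      arma::mat Sigma = V * arma::diagmat(lam_reg) * V.t();
      Sigma = (Sigma + Sigma.t()) / 2.0;
      arma::vec ev;
      arma::mat evec;
      arma::eig_sym(ev, evec, Sigma);            // ascending
      const double tot = arma::accu(ev);
      const double pla = (ev(n - 1) + ev(n - 2)) / tot;
      arma::mat U2(n, 2);
      U2.col(0) = evec.col(n - 1);
      U2.col(1) = evec.col(n - 2);
      const double ang = largest_principal_angle(Brows, U2);
      const arma::mat BS = Brows.t() * Sigma;
      const double vaf = arma::accu(arma::sum(BS % Brows.t(), 0)) / tot * 100.0;

      if (rec) {
        rec_it(ri) = k;
        rec_pla(ri) = pla;
        rec_ang(ri) = ang;
        rec_vaf(ri) = vaf;
        rec_rew(ri) = r;
        ++ri;
      }
      if (fin) {
        const int fi = k - (K - final_window) - 1;
        finwin(fi, 0) = k;
        finwin(fi, 1) = pla;
        finwin(fi, 2) = ang;
        finwin(fi, 3) = vaf;
        finwin(fi, 4) = r;
      }
    }
  }

  return List::create(
    _["iteration"] = rec_it.head(ri),
    _["planarity"] = rec_pla.head(ri),
    _["angle_deg"] = rec_ang.head(ri),
    _["vaf_pct"] = rec_vaf.head(ri),
    _["reward"] = rec_rew.head(ri),
    _["final_window"] = finwin,
    _["cons_sum_m"] = cons_sum,
    _["cons_frac"] = cons_frac,
    _["W"] = W,
    _["lambda_reg"] = lam_reg,
    _["mu"] = mu,
    _["Btilde"] = Btilde,
    _["Brows"] = Brows,
    _["s_last"] = s);
}
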