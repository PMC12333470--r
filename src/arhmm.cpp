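// Sticky AR-HMM core: blocked Gibbs sampling (forward-filter backward-sample
// labels + conjugate MNIW / Dirichlet parameter updates), Viterbi decoding,
// forward-algorithm likelihood, and small simulation helpers.
//
// All randomness goes through R's RNG so set.seed() on the R side makes every
// entry point bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int sample_cat(const arma::rowvec& w) {
  double u = unif_rand() * arma::accu(w);
  double c = 0.0;
  for (arma::uword j = 0; j < w.n_elem; ++j) {
    c += w[j];
    if (u <= c) return (int)j;
  }
  return (int)w.n_elem - 1;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_markov(const arma::mat& P, int T, const arma::rowvec& init) {
  IntegerVector z(T);
  int s = sample_cat(init);
  z[0] = s;
  for (int t = 1; t < T; ++t) {
    s = sample_cat(P.row(s));
    z[t] = s;
  }
  return z;  // 0-based
}

// Per-frame AR(1) pose deviations around per-syllable dynamics.
// [[Rcpp::export]]
arma::mat cpp_simulate_pose(const IntegerVector& labels, const List& ar_dynamics,
                            const List& ar_bias, const arma::vec& noise_scale) {
  int T = labels.size();
  int K = ar_dynamics.size();
  std::vector<arma::mat> A(K);
  std::vector<arma::vec> b(K);
  for (int k = 0; k < K; ++k) {
    A[k] = as<arma::mat>(ar_dynamics[k]);
    b[k] = as<arma::vec>(ar_bias[k]);
  }
  int d = A[0].n_rows;
  arma::mat out(T, d);
  arma::vec p(d, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    int k = labels[t];
    arma::vec eta(d);
    for (int i = 0; i < d; ++i) eta[i] = norm_rand() * noise_scale[k];
    p = A[k] * p + b[k] + eta;
    out.row(t) = p.t();
  }
  return out;
}

// ---------------------------------------------------------------------------
// AR-HMM machinery

struct ARData {
  arma::mat X;  // (T-L) x p design [y_{t-1},...,y_{t-L},1]
  arma::mat Y;  // (T-L) x d
};

static ARData build_design(const arma::mat& y, int L) {
  int T = y.n_rows, d = y.n_cols;
  int n = T - L, p = d * L + 1;
  ARData out;
  out.X.set_size(n, p);
  out.Y = y.rows(L, T - 1);
  for (int t = 0; t < n; ++t) {
    for (int l = 0; l < L; ++l)
      out.X(t, arma::span(l * d, (l + 1) * d - 1)) = y.row(L + t - 1 - l);
    out.X(t, p - 1) = 1.0;
  }
  return out;
}

// Gaussian AR log-likelihood matrix: n x K
static arma::mat loglik_matrix(const ARData& dat, const std::vector<arma::mat>& A,
                               const std::vector<arma::mat>& Sigma) {
  int n = dat.Y.n_rows, d = dat.Y.n_cols, K = A.size();
  arma::mat ll(n, K);
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    arma::mat Lc = arma::chol(Sigma[k], "lower");
    double logdet = 2.0 * arma::accu(arma::log(Lc.diag()));
    arma::mat E = dat.Y - dat.X * A[k].t();           // n x d
    arma::mat V = arma::solve(arma::trimatl(Lc), E.t());  // d x n
    ll.col(k) = (c0 - 0.5 * logdet) - 0.5 * arma::sum(arma::square(V), 0).t();
  }
  return ll;
}

// Forward filter (scaled); returns normalized alphas, accumulates loglik.
static arma::mat forward_filter(const arma::mat& ll, const arma::mat& P,
                                double* loglik_out) {
  int n = ll.n_rows, K = ll.n_cols;
  arma::mat alpha(n, K);
  double loglik = 0.0;
  arma::rowvec pred(K, arma::fill::value(1.0 / K));
  for (int t = 0; t < n; ++t) {
    if (t > 0) pred = alpha.row(t - 1) * P;
    double m = ll.row(t).max();
    arma::rowvec w = pred % arma::exp(ll.row(t) - m);
    double s = arma::accu(w);
    alpha.row(t) = w / s;
    loglik += std::log(s) + m;
  }
  if (loglik_out) *loglik_out = loglik;
  return alpha;
}

static arma::ivec backward_sample(const arma::mat& alpha, const arma::mat& P) {
  int n = alpha.n_rows;
  arma::ivec z(n);
  z[n - 1] = sample_cat(alpha.row(n - 1));
  for (int t = n - 2; t >= 0; --t) {
    arma::rowvec w = alpha.row(t) % P.col(z[t + 1]).t();
    z[t] = sample_cat(w);
  }
  return z;
}

// Bartlett-decomposition Wishart draw -> inverse Wishart Sigma ~ IW(S, nu)
static arma::mat riwish(const arma::mat& S, double nu) {
  int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat Lc = arma::chol(Sinv, "lower");
  arma::mat Ab(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    Ab(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) Ab(i, j) = norm_rand();
  }
  arma::mat LA = Lc * Ab;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// MNIW posterior draw for one state's AR parameters.
static void sample_mniw(const arma::mat& XtX, const arma::mat& XtY,
                        const arma::mat& YtY, double n_k,
                        const arma::mat& M0, const arma::mat& K0,
                        const arma::mat& S0, double nu0,
                        arma::mat& A_out, arma::mat& Sigma_out) {
  int d = M0.n_rows, p = M0.n_cols;
  arma::mat Kn = K0 + XtX;
  arma::mat RHS = M0 * K0 + XtY.t();                 // d x p
  arma::mat Mn = arma::solve(arma::symmatu(Kn), RHS.t()).t();
  arma::mat Sn = S0 + YtY + M0 * K0 * M0.t() - Mn * Kn * Mn.t();
  Sn = arma::symmatu(0.5 * (Sn + Sn.t()));
  Sn.diag() += 1e-8;
  double nun = nu0 + n_k;
  Sigma_out = riwish(Sn, nun);
  arma::mat Lsig = arma::chol(arma::symmatu(Sigma_out), "lower");
  arma::mat R = arma::chol(arma::symmatu(Kn), "upper");   // Kn = R'R
  arma::mat Z(d, p);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < p; ++j) Z(i, j) = norm_rand();
  // noise = Lsig * Z * R^{-T}; solve R M' = Z' for M = Z R^{-T}
  arma::mat M = arma::solve(arma::trimatu(R), Z.t()).t();
  A_out = Mn + Lsig * M;
}

// [[Rcpp::export]]
List cpp_arhmm_gibbs(const List& ys, int L, int K, double alpha, double kappa,
                     const arma::mat& M0, const arma::mat& K0,
                     const arma::mat& S0, double nu0, int n_iter) {
  int S = ys.size();
  std::vector<ARData> dat(S);
  int d = 0;
  for (int s = 0; s < S; ++s) {
    arma::mat y = as<arma::mat>(ys[s]);
    d = y.n_cols;
    dat[s] = build_design(y, L);
  }
  int p = d * L + 1;

  // init: uniform random labels on effective frames
  std::vector<arma::ivec> z(S);
  for (int s = 0; s < S; ++s) {
    int n = dat[s].Y.n_rows;
    z[s].set_size(n);
    for (int t = 0; t < n; ++t) z[s][t] = (int)std::floor(unif_rand() * K);
  }

  std::vector<arma::mat> A(K), Sigma(K);
  arma::mat P(K, K, arma::fill::value(1.0 / K));

  for (int it = 0; it < n_iter; ++it) {
    // (ii) parameter updates given labels -----------------------------------
    std::vector<arma::mat> XtX(K, arma::mat(p, p, arma::fill::zeros));
    std::vector<arma::mat> XtY(K, arma::mat(p, d, arma::fill::zeros));
    std::vector<arma::mat> YtY(K, arma::mat(d, d, arma::fill::zeros));
    arma::vec nk(K, arma::fill::zeros);
    arma::mat trans_counts(K, K, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      int n = dat[s].Y.n_rows;
      for (int t = 0; t < n; ++t) {
        int k = z[s][t];
        arma::rowvec xr = dat[s].X.row(t), yr = dat[s].Y.row(t);
        XtX[k] += xr.t() * xr;
        XtY[k] += xr.t() * yr;
        YtY[k] += yr.t() * yr;
        nk[k] += 1.0;
        if (t > 0) trans_counts(z[s][t - 1], k) += 1.0;
      }
    }
    for (int k = 0; k < K; ++k)
      sample_mniw(XtX[k], XtY[k], YtY[k], nk[k], M0, K0, S0, nu0, A[k], Sigma[k]);

    // sticky Dirichlet rows: concentration alpha/K per cell + kappa on diag
    for (int i = 0; i < K; ++i) {
      arma::rowvec w(K);
      for (int j = 0; j < K; ++j) {
        double shape = alpha / K + trans_counts(i, j) + (i == j ? kappa : 0.0);
        w[j] = R::rgamma(shape, 1.0);
      }
      double tot = arma::accu(w);
      if (tot <= 0) { w.fill(1.0 / K); tot = 1.0; }
      P.row(i) = w / tot;
    }

    // (i) label sampling by FFBS --------------------------------------------
    for (int s = 0; s < S; ++s) {
      arma::mat ll = loglik_matrix(dat[s], A, Sigma);
      arma::mat alpha_f = forward_filter(ll, P, nullptr);
      z[s] = backward_sample(alpha_f, P);
    }
  }

  // pack final sample; pad first L frames with the first effective label
  List labels(S);
  arma::vec usage(K, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    int n = z[s].n_elem;
    IntegerVector lab(n + L);
    for (int t = 0; t < L; ++t) lab[t] = (int)z[s][0];
    for (int t = 0; t < n; ++t) {
      lab[L + t] = (int)z[s][t];
      usage[z[s][t]] += 1.0;
    }
    labels[s] = lab;
  }
  List A_out(K), Sig_out(K);
  for (int k = 0; k < K; ++k) { A_out[k] = A[k]; Sig_out[k] = Sigma[k]; }
  return List::create(_["labels"] = labels, _["A"] = A_out,
                      _["Sigma"] = Sig_out, _["trans"] = P,
                      _["usage"] = usage);
}

// [[Rcpp::export]]
IntegerVector cpp_viterbi(const arma::mat& y, int L, const List& A_list,
                          const List& Sigma_list, const arma::mat& P) {
  int K = A_list.size();
  std::vector<arma::mat> A(K), Sigma(K);
  for (int k = 0; k < K; ++k) {
    A[k] = as<arma::mat>(A_list[k]);
    Sigma[k] = as<arma::mat>(Sigma_list[k]);
  }
  ARData dat = build_design(y, L);
  arma::mat ll = loglik_matrix(dat, A, Sigma);
  int n = ll.n_rows;
  arma::mat logP = arma::log(P + 1e-300);
  arma::mat delta(n, K);
  arma::imat psi(n, K);
  delta.row(0) = ll.row(0) - std::log((double)K);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      arma::vec cand = delta.row(t - 1).t() + logP.col(k);
      arma::uword best = cand.index_max();
      psi(t, k) = (int)best;
      delta(t, k) = cand[best] + ll(t, k);
    }
  }
  IntegerVector path(n + L);
  int cur = (int)delta.row(n - 1).index_max();
  path[n + L - 1] = cur;
  for (int t = n - 2; t >= 0; --t) {
    cur = psi(t + 1, cur);
    path[L + t] = cur;
  }
  for (int t = 0; t < L; ++t) path[t] = path[L];
  return path;
}

// [[Rcpp::export]]
double cpp_forward_loglik(const arma::mat& y, int L, const List& A_list,
                          const List& Sigma_list, const arma::mat& P) {
  int K = A_list.size();
  std::vector<arma::mat> A(K), Sigma(K);
  for (int k = 0; k < K; ++k) {
    A[k] = as<arma::mat>(A_list[k]);
    Sigma[k] = as<arma::mat>(Sigma_list[k]);
  }
  ARData dat = build_design(y, L);
  arma::mat ll = loglik_matrix(dat, A, Sigma);
  double out = 0.0;
  forward_filter(ll, P, &out);
  return out;
}
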