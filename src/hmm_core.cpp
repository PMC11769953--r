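// Scaled forward-backward and Viterbi recursions for a single chain.
// Inputs are log-domain: logB (T x K observation log-densities), logpi (K),
// logA (K x K). logA/logpi need not be normalized (variational E-steps pass
// exponentials of expected logs, which are sub-normalized); the returned
// log_evidence is the log normalizing constant of the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".fb_chain")]]
List fb_chain(const arma::mat& logB, const arma::vec& logpi,
              const arma::mat& logA, bool want_xi) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  if (!logB.is_finite() || !logpi.is_finite() || !logA.is_finite())
    stop("non-finite values in forward-backward inputs");

  // per-row max shift keeps exp() in range for long chains
  arma::vec shift(T);
  arma::mat B(T, K);
  for (arma::uword t = 0; t < T; ++t) {
    shift(t) = logB.row(t).max();
    B.row(t) = arma::exp(logB.row(t) - shift(t));
  }
  arma::vec pi = arma::exp(logpi - logpi.max());
  arma::mat A = arma::exp(logA - logA.max());

  arma::mat alpha(T, K), beta(T, K);
  arma::vec c(T);  // scaling constants

  alpha.row(0) = (pi % B.row(0).t()).t();
  c(0) = arma::accu(alpha.row(0));
  if (c(0) <= 0) stop("zero forward mass at t = 1");
  alpha.row(0) /= c(0);
  for (arma::uword t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A) % B.row(t);
    c(t) = arma::accu(alpha.row(t));
    if (c(t) <= 0) stop("zero forward mass");
    alpha.row(t) /= c(t);
  }

  beta.row(T - 1).ones();
  for (arma::uword t = T - 1; t-- > 0;) {
    beta.row(t) = ((beta.row(t + 1) % B.row(t + 1)) * A.t()) / c(t + 1);
  }

  arma::mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);  // guard tiny drift

  arma::mat xi_sum(K, K, arma::fill::zeros);
  arma::cube xi;
  if (want_xi) xi.set_size(K, K, T > 1 ? T - 1 : 0);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    arma::mat x = (alpha.row(t).t() * (beta.row(t + 1) % B.row(t + 1))) % A;
    x /= c(t + 1);
    double s = arma::accu(x);
    x /= s;  // exact renormalization per slice
    xi_sum += x;
    if (want_xi) xi.slice(t) = x;
  }

  double logZ = arma::accu(arma::log(c)) + arma::accu(shift) +
                logpi.max() + (double)(T - 1) * logA.max();

  List out = List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                          _["log_evidence"] = logZ);
  if (want_xi) out["xi"] = xi;
  return out;
}

// [[Rcpp::export(name = ".viterbi_chain")]]
IntegerVector viterbi_chain(const arma::mat& logB, const arma::vec& logpi,
                            const arma::mat& logA) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  if (!logB.is_finite() || !logpi.is_finite() || !logA.is_finite())
    stop("non-finite values in viterbi inputs");
  arma::mat delta(T, K);
  arma::umat psi(T, K, arma::fill::zeros);
  delta.row(0) = (logpi + logB.row(0).t()).t();
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword k = 0; k < K; ++k) {
      arma::vec cand = delta.row(t - 1).t() + logA.col(k);
      arma::uword best = cand.index_max();
      psi(t, k) = best;
      delta(t, k) = cand(best) + logB(t, k);
    }
  }
  IntegerVector path(T);
  arma::uword s = delta.row(T - 1).index_max();
  path[T - 1] = (int)s;
  for (arma::uword t = T - 1; t-- > 0;) {
    s = psi(t + 1, s);
    path[t] = (int)s;
  }
  return path;  // 0-based states
}
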